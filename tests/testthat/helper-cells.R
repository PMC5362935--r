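# Shared synthetic-cell builders for the test suite.

# An ohmic membrane with total conductance g_t_nS of which a fraction `rel`
# is chloride, both reversing as they should (non-Cl at -74 mV, Cl at E_Cl).
std_cell <- function(g_t_nS = 0.48, rel = 0.111, rs_Mohm = 20,
                     noise_sd_pA = 5, cl_i_mM = 9, kcc2_active = FALSE) {
  synthetic_cell(
    leak = list(form = "linear", g_nS = g_t_nS * (1 - rel), e_rev_mV = -74),
    g_cl_rest_nS = g_t_nS * rel, rs_Mohm = rs_Mohm,
    noise_sd_pA = noise_sd_pA, state = cell_state(cl_i_mM = cl_i_mM),
    kcc2_active = kcc2_active)
}

# The single-compartment state at the reference model parameters, starting
# from a 60 mM chloride load.
loaded_state <- function(cl_i_mM = 60, g_cl_nS = 0.054, v_m_mV = -74) {
  cell_state(cl_i_mM = cl_i_mM, cl_o_mM = 146.4, k_i_mM = 145, k_o_mM = 5,
             v_m_mV = v_m_mV, g_cl_nS = g_cl_nS, g_kcc2 = 6.7e-21,
             v_equ_L = 5.0e-13, temp_K = 295)
}

# A protocol-free sweep constructed directly from vectors (for tests of the
# analysis stages on exactly controlled input).
manual_sweep <- function(time_s, v_cmd_mV, i_pA) {
  structure(data.frame(time_s = time_s, v_cmd_mV = v_cmd_mV, i_pA = i_pA),
            class = c("ephys_sweep", "data.frame"))
}
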