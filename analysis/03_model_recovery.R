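#!/usr/bin/env Rscript
# Step 3: single-compartment chloride model - recovery scenarios.
#
# Forward-Euler runs of the KCC2 + conductive-leak model from a 60 mM load
# at the reference parameters (g_KCC2 = 6.7e-21 mol^2 V^-1 C^-1 s^-1,
# v_equ = 5.0e-13 L, [Cl]o = 146.4, [K]i = 145, [K]o = 5 mM, T = 295 K,
# dt = 50 ms): the three mechanism scenarios at -74 mV, the voltage
# dependence of the combined recovery, and the g_Cl dependence of rate and
# steady state.

suppressPackageStartupMessages(library(clhomeo))
dir.create("results", showWarnings = FALSE)

base <- function(...) cell_state(cl_i_mM = 60, g_cl_nS = 0.054,
                                 g_kcc2 = 6.7e-21, ...)
thin <- function(sim) sim[seq(1, nrow(sim), by = 100), c("time_s", "cl_mM", "e_cl_mV")]

# mechanism scenarios at -74 mV
scen <- list(kcc2_only = "kcc2", leak_only = "conductive",
             combined = c("kcc2", "conductive"))
traj <- NULL; fits <- NULL
for (nm in names(scen)) {
  sim <- simulate_cl(base(v_m_mV = -74), 1500, modes = scen[[nm]])
  tr <- thin(sim); tr$scenario <- nm
  traj <- rbind(traj, tr)
  fit <- fit_single_exponential(sim$time_s, sim$cl_mM)
  fits <- rbind(fits, data.frame(
    scenario = nm, tau_s = fit$tau_s, asymptote_mM = fit$asymptote_mM,
    steady_state_mM = steady_state_cl(base(v_m_mV = -74), scen[[nm]]),
    cl_at_1500_mM = tail(sim$cl_mM, 1)))
}
write.table(traj, "results/03_recovery_trajectories.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(fits, "results/03_recovery_fits.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# voltage dependence of the combined recovery
vm_tab <- do.call(rbind, lapply(c(-74, -50, -34, -14), function(vm) {
  st <- base(v_m_mV = vm)
  sim <- simulate_cl(st, 1500)
  data.frame(v_m_mV = vm,
             tau_s = fit_single_exponential(sim$time_s, sim$cl_mM)$tau_s,
             steady_state_mM = steady_state_cl(st))
}))
write.table(vm_tab, "results/03_voltage_dependence.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# g_Cl dependence: speed/steady-state trade-off at -74 and -50 mV
gcl_tab <- do.call(rbind, lapply(c(-74, -50), function(vm) {
  do.call(rbind, lapply(c(0.014, 0.054, 0.15, 0.4), function(g) {
    st <- base(v_m_mV = vm); st$g_cl_nS <- g
    ss <- steady_state_cl(st)
    sim <- simulate_cl(st, 3000)
    half <- sim$time_s[min(which(sim$cl_mM <= 60 - (60 - ss) / 2))]
    data.frame(v_m_mV = vm, g_cl_nS = g, half_time_s = half,
               steady_state_mM = ss)
  }))
}))
write.table(gcl_tab, "results/03_gcl_dependence.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Recovery from a 60 mM load at -74 mV:\n")
print(fits, row.names = FALSE)
cat("\nKCC2-only tau is the quantity the transporter factor is calibrated\n")
cat("against (499 s); the combined scenario recovers faster and settles\n")
cat("slightly above the KCC2-only steady state. Tables in results/03_*.tsv\n")
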