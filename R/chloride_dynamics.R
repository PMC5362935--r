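#' Single-compartment cell state for chloride dynamics
#'
#' State and parameters of the one-compartment chloride model: intracellular
#' chloride (the only dynamic state variable), fixed extracellular chloride
#' and intra-/extracellular potassium, an imposed membrane potential (voltage
#' clamp), a resting chloride conductance, a KCC2 transport proportionality
#' factor ("apparent conductance"), the equivalent cytosolic volume in which
#' transported charge changes concentration, and temperature.
#'
#' @param cl_i_mM Intracellular chloride (mM), > 0.
#' @param cl_o_mM Extracellular chloride (mM).
#' @param k_i_mM,k_o_mM Intra-/extracellular potassium (mM).
#' @param v_m_mV Membrane potential (mV).
#' @param g_cl_nS Chloride leak conductance (nS).
#' @param g_kcc2 KCC2 proportionality factor (mol^2 V^-1 C^-1 s^-1).
#' @param v_equ_L Equivalent cytosolic volume (L).
#' @param temp_K Absolute temperature (K).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(cl_i_mM = 9, cl_o_mM = 146.4, k_i_mM = 145, k_o_mM = 5,
                       v_m_mV = -74, g_cl_nS = 0.054, g_kcc2 = 6.7e-21,
                       v_equ_L = 5.0e-13, temp_K = 295) {
  stopifnot(cl_i_mM > 0, cl_o_mM > 0, k_i_mM > 0, k_o_mM > 0,
            g_cl_nS >= 0, g_kcc2 >= 0, v_equ_L > 0, temp_K > 0)
  structure(list(cl_i_mM = cl_i_mM, cl_o_mM = cl_o_mM, k_i_mM = k_i_mM,
                 k_o_mM = k_o_mM, v_m_mV = v_m_mV, g_cl_nS = g_cl_nS,
                 g_kcc2 = g_kcc2, v_equ_L = v_equ_L, temp_K = temp_K),
            class = "cell_state")
}

.state_nernst_ctx <- function(state) {
  nernst_context(cl_o_mM = state$cl_o_mM, temp_K = state$temp_K)
}

#' Thermodynamic driving force for KCC2
#'
#' The combined K+ and Cl- chemical potential difference that drives
#' electroneutral K-Cl cotransport:
#' RT (ln(\[Cl\]i/\[Cl\]o) + ln(\[K\]i/\[K\]o)), in J/mol. Positive values
#' drive outward transport (chloride extrusion). KCC2 transport is
#' voltage-independent, so the membrane potential does not enter.
#'
#' @param state A [cell_state()].
#' @return Driving force in J mol^-1.
#' @export
kcc2_driving_force <- function(state) {
  stopifnot(state$cl_i_mM > 0, state$k_i_mM > 0)
  .GAS_CONSTANT * state$temp_K *
    (log(state$cl_i_mM / state$cl_o_mM) + log(state$k_i_mM / state$k_o_mM))
}

#' One Euler step of KCC2-mediated chloride change
#'
#' Concentration change over `dt_s` due to KCC2 transport:
#' -dt * driving_force * g_KCC2 / v_equ, returned in mM. Negative whenever
#' the driving force is positive (outward transport lowers \[Cl\]i).
#'
#' @param state A [cell_state()].
#' @param dt_s Time step (s), > 0.
#' @return Change in \[Cl\]i (mM) over one step.
#' @export
kcc2_step <- function(state, dt_s) {
  stopifnot(dt_s > 0)
  -dt_s * kcc2_driving_force(state) * state$g_kcc2 / state$v_equ_L * 1000
}

#' One Euler step of conductive (channel-mediated) chloride change
#'
#' Chloride leak current I = g_Cl (V_m - E_Cl) (outward positive; positive
#' current corresponds to chloride influx) converted into a concentration
#' change: I * dt / (F * v_equ), in mM.
#'
#' @param state A [cell_state()].
#' @param dt_s Time step (s), > 0.
#' @return Change in \[Cl\]i (mM) over one step.
#' @export
conductive_step <- function(state, dt_s) {
  stopifnot(dt_s > 0)
  e_cl <- nernst(state$cl_i_mM, .state_nernst_ctx(state))
  i_pA <- state$g_cl_nS * (state$v_m_mV - e_cl)    # nS * mV = pA
  i_pA * 1e-12 * dt_s / (.FARADAY * state$v_equ_L) * 1000
}

#' Simulate the intracellular chloride time course
#'
#' Forward-Euler integration of d\[Cl\]i/dt as the sum of a KCC2-mediated
#' flux and a conductive flux through the chloride leak, each switchable via
#' `modes`. Membrane potential and chloride conductance may be constants or
#' functions of time (schedules), which supports loading phases at
#' depolarized potentials and time-varying conductances such as trains of
#' miniature synaptic events.
#'
#' @param state A [cell_state()] supplying the initial condition and
#'   parameters.
#' @param duration_s Simulated time (s), > 0.
#' @param dt_s Integration step (s); default 0.05 s.
#' @param modes Character vector, subset of `c("kcc2", "conductive")`.
#' @param v_m Membrane potential: a scalar (mV) or `function(t)`; defaults to
#'   `state$v_m_mV`.
#' @param g_cl Chloride conductance: a scalar (nS) or `function(t)`; defaults
#'   to `state$g_cl_nS`.
#' @return A `cl_simulation`: data frame with columns `time_s`, `cl_mM`,
#'   `e_cl_mV`, `d_kcc2_mM`, `d_cond_mM` (per-step component changes booked
#'   at the step start; the totals reproduce the trajectory exactly), with
#'   the state and settings in attributes.
#' @export
simulate_cl <- function(state, duration_s, dt_s = 0.05,
                        modes = c("kcc2", "conductive"),
                        v_m = NULL, g_cl = NULL) {
  stopifnot(duration_s > 0, dt_s > 0)
  modes <- match.arg(modes, c("kcc2", "conductive"), several.ok = TRUE)
  n <- floor(duration_s / dt_s)
  tgrid <- seq(0, by = dt_s, length.out = n + 1)
  vm <- if (is.function(v_m)) v_m(tgrid) else rep(if (is.null(v_m)) state$v_m_mV else v_m, n + 1)
  gcl <- if (is.function(g_cl)) g_cl(tgrid) else rep(if (is.null(g_cl)) state$g_cl_nS else g_cl, n + 1)
  stopifnot(length(vm) == n + 1, length(gcl) == n + 1)

  nern <- 1000 * .GAS_CONSTANT * state$temp_K / .FARADAY  # mV
  kratio <- log(state$k_i_mM / state$k_o_mM)
  kfac <- .GAS_CONSTANT * state$temp_K * state$g_kcc2 / state$v_equ_L * 1000
  cfac <- 1e-12 * dt_s / (.FARADAY * state$v_equ_L) * 1000
  do_k <- "kcc2" %in% modes
  do_c <- "conductive" %in% modes

  cl <- numeric(n + 1); ecl <- numeric(n + 1)
  dk <- numeric(n + 1); dc <- numeric(n + 1)
  cl[1] <- state$cl_i_mM
  for (i in seq_len(n)) {
    e <- nern * log(cl[i] / state$cl_o_mM)
    ecl[i] <- e
    if (do_k) dk[i] <- -dt_s * kfac * (log(cl[i] / state$cl_o_mM) + kratio)
    if (do_c) dc[i] <- gcl[i] * (vm[i] - e) * cfac
    cl[i + 1] <- cl[i] + dk[i] + dc[i]
    if (cl[i + 1] <= 0)
      stop("[Cl-]i became non-positive at t = ", round(tgrid[i + 1], 3),
           " s; use a smaller dt_s")
  }
  ecl[n + 1] <- nern * log(cl[n + 1] / state$cl_o_mM)
  out <- data.frame(time_s = tgrid, cl_mM = cl, e_cl_mV = ecl,
                    d_kcc2_mM = dk, d_cond_mM = dc)
  structure(out, class = c("cl_simulation", "data.frame"),
            state = state, dt_s = dt_s, modes = modes)
}

#' Steady-state intracellular chloride
#'
#' Closed-form fixed points of the chloride model: KCC2 only gives
#' \[Cl\]o \[K\]o / \[K\]i (voltage-independent); conductive only gives
#' \[Cl\]o exp(V_m F / RT), i.e. E_Cl settles at the membrane potential.
#' With both fluxes the steady state is the root of the summed fluxes,
#' bracketed by the two closed forms and found by `uniroot`; E_Cl then
#' settles between the membrane potential and the potassium equilibrium
#' potential, weighted by the relative strengths of g_Cl and g_KCC2.
#'
#' @param state A [cell_state()].
#' @param modes Subset of `c("kcc2", "conductive")`.
#' @return Steady-state \[Cl\]i (mM).
#' @export
steady_state_cl <- function(state, modes = c("kcc2", "conductive")) {
  modes <- match.arg(modes, c("kcc2", "conductive"), several.ok = TRUE)
  nern <- 1000 * .GAS_CONSTANT * state$temp_K / .FARADAY
  ss_k <- state$cl_o_mM * state$k_o_mM / state$k_i_mM
  ss_c <- state$cl_o_mM * exp(state$v_m_mV / nern)
  if (identical(sort(modes), "kcc2")) return(ss_k)
  if (identical(sort(modes), "conductive")) return(ss_c)
  if (state$g_cl_nS == 0) return(ss_k)
  if (state$g_kcc2 == 0) return(ss_c)
  flux <- function(cl) {
    s <- state; s$cl_i_mM <- cl
    kcc2_step(s, 1) + conductive_step(s, 1)
  }
  lo <- min(ss_k, ss_c); hi <- max(ss_k, ss_c)
  if (abs(hi - lo) < 1e-12) return(lo)
  stats::uniroot(flux, lower = lo, upper = hi, tol = 1e-10,
                 extendInt = "no")$root
}

#' Equivalent cytosolic volume and charge bookkeeping
#'
#' `equivalent_volume()` converts a measured charge transfer Q and the
#' chloride concentration change it produced into the equivalent cytosolic
#' volume v_equ = Q / (F * d\[Cl\]i); `charge_for_load()` is the exact
#' inverse, the charge needed to change \[Cl\]i by `d_cl_mM` in a volume
#' `v_equ_L`. `cytosol_volume_L()` gives the geometric reference: a stated
#' fraction (default one half) of a sphere of given radius.
#'
#' @param q_C Charge transfer (C).
#' @param d_cl_mM Chloride concentration change (mM), non-zero.
#' @param v_equ_L Equivalent volume (L).
#' @param radius_um Cell radius (micrometres).
#' @param fraction Fraction of total cell volume occupied by the
#'   chloride-accessible cytosol.
#' @return Volume in litres, or charge in coulombs.
#' @examples
#' equivalent_volume(2.46e-9, 51)      # about 5e-13 L
#' cytosol_volume_L(6.2)               # about 5e-13 L
#' @export
equivalent_volume <- function(q_C, d_cl_mM) {
  if (d_cl_mM == 0) stop("d_cl_mM must be non-zero")
  q_C / (.FARADAY * d_cl_mM / 1000)
}

#' @rdname equivalent_volume
#' @export
charge_for_load <- function(v_equ_L, d_cl_mM) {
  if (d_cl_mM == 0) stop("d_cl_mM must be non-zero")
  v_equ_L * .FARADAY * d_cl_mM / 1000
}

#' @rdname equivalent_volume
#' @export
cytosol_volume_L <- function(radius_um, fraction = 0.5) {
  stopifnot(radius_um > 0, fraction > 0, fraction <= 1)
  fraction * 4 / 3 * pi * (radius_um * 1e-6)^3 * 1000  # m^3 -> L
}
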