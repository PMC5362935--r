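#' Ramp protocol construction
#'
#' Builds a declarative voltage-clamp protocol: an ordered sequence of
#' segments, each a zigzag ramp train (triangle wave) around a holding
#' potential, plus agonist application windows with first-order
#' solution-exchange kinetics. Three templates are provided:
#'
#' * `"gcl_estimation"` - the resting-chloride-conductance protocol: ramp
#'   trains around -74 mV (baseline conductance/reversal and a brief agonist
#'   probe of E_Cl), a 20 s agonist application at -14 mV that loads the
#'   cell with chloride (E_Cl read at the end of the load), a second train
#'   at -74 mV (repeat conductance/reversal), and a final probe train at
#'   -34 mV.
#' * `"load_and_probe"` - a chloride-loading segment at -14 mV followed by
#'   brief probe ramp trains at scheduled recovery times, holding at a
#'   configurable recovery potential between probes.
#' * `"clc2_steps"` - a family of hyperpolarizing voltage steps reaching
#'   below -65 mV, suitable for detecting inwardly rectifying chloride
#'   channel currents. No agonist windows.
#'
#' Ramps traverse `ramp_rate_V_s / (2 * cycle_hz)` millivolts per half
#' cycle, symmetric about the holding potential.
#'
#' @param template One of `"gcl_estimation"`, `"load_and_probe"`,
#'   `"clc2_steps"`.
#' @param overrides Named list overriding template parameters. Common keys:
#'   `ramp_rate_V_s` (default 1.6), `cycle_hz` (20), `dt_s` (1e-4),
#'   `tau_exchange_s` (0.05), `g_probe_nS` (2), `g_load_nS` (8),
#'   `load_duration_s` (20), `holding_rest_mV` (-74), `holding_load_mV`
#'   (-14), `holding_probe2_mV` (-34). For `"load_and_probe"` additionally
#'   `probe_times_s`, `probe_holdings_mV`, `recovery_holding_mV`,
#'   `total_duration_s`.
#' @return A `ramp_protocol`: list with `segments` (data frame: `label`,
#'   `holding_mV`, `duration_s`, `ramp_amplitude_mV`, `ramp_rate_V_s`,
#'   `cycle_hz`, `start_s`, `end_s`), `agonist_windows` (data frame:
#'   `start_s`, `end_s`, `g_ag_nS`, `tau_exchange_s`), `dt_s`, `name`.
#' @export
make_protocol <- function(template = c("gcl_estimation", "load_and_probe",
                                       "clc2_steps"),
                          overrides = list()) {
  template <- match.arg(template)
  p <- list(ramp_rate_V_s = 1.6, cycle_hz = 20, dt_s = 1e-4,
            tau_exchange_s = 0.05, g_probe_nS = 2, g_load_nS = 8,
            load_duration_s = 20, holding_rest_mV = -74,
            holding_load_mV = -14, holding_probe2_mV = -34,
            probe_times_s = c(60, 120, 300, 600, 900),
            probe_holdings_mV = NULL, recovery_holding_mV = -74,
            probe_duration_s = 2, total_duration_s = NULL)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown) > 0)
    stop("unknown override(s): ", paste(unknown, collapse = ", "))
  p[names(overrides)] <- overrides
  amp <- 1000 * p$ramp_rate_V_s / (2 * p$cycle_hz)  # mV per half cycle

  seg <- function(label, holding, duration, ramped = TRUE) {
    data.frame(label = label, holding_mV = holding, duration_s = duration,
               ramp_amplitude_mV = if (ramped) amp else 0,
               ramp_rate_V_s = if (ramped) p$ramp_rate_V_s else 0,
               cycle_hz = if (ramped) p$cycle_hz else 0)
  }

  if (template == "gcl_estimation") {
    segments <- rbind(
      seg("rest1",  p$holding_rest_mV, 12),
      seg("load",   p$holding_load_mV, p$load_duration_s + 6),
      seg("rest2",  p$holding_rest_mV, 12),
      seg("probe2", p$holding_probe2_mV, 10))
    segments$start_s <- cumsum(c(0, segments$duration_s[-nrow(segments)]))
    segments$end_s <- segments$start_s + segments$duration_s
    t_load <- segments$start_s[2]
    windows <- data.frame(
      start_s = c(5, t_load + 3, segments$start_s[4] + 4),
      end_s = c(7, t_load + 3 + p$load_duration_s, segments$start_s[4] + 6),
      g_ag_nS = c(p$g_probe_nS, p$g_load_nS, p$g_probe_nS),
      tau_exchange_s = p$tau_exchange_s)
  } else if (template == "load_and_probe") {
    probe_t <- sort(p$probe_times_s)
    holdings <- p$probe_holdings_mV
    if (is.null(holdings)) holdings <- rep(p$recovery_holding_mV, length(probe_t))
    stopifnot(length(holdings) == length(probe_t))
    segments <- seg("load", p$holding_load_mV, p$load_duration_s + 6)
    t_end_load <- p$load_duration_s + 6
    if (any(probe_t <= t_end_load))
      stop("probe_times_s must lie after the loading segment (",
           t_end_load, " s)")
    prev_end <- t_end_load
    for (k in seq_along(probe_t)) {
      hold_dur <- probe_t[k] - p$probe_duration_s / 2 - prev_end
      if (hold_dur < 0) stop("probe times too close together")
      if (hold_dur > 0)
        segments <- rbind(segments,
                          seg(paste0("hold", k), p$recovery_holding_mV,
                              hold_dur, ramped = FALSE))
      segments <- rbind(segments,
                        seg(paste0("probe", k), holdings[k], p$probe_duration_s))
      prev_end <- probe_t[k] + p$probe_duration_s / 2
    }
    total <- p$total_duration_s
    if (!is.null(total) && total > prev_end)
      segments <- rbind(segments, seg("tail", p$recovery_holding_mV,
                                      total - prev_end, ramped = FALSE))
    segments$start_s <- cumsum(c(0, segments$duration_s[-nrow(segments)]))
    segments$end_s <- segments$start_s + segments$duration_s
    probe_rows <- grep("^probe", segments$label)
    windows <- data.frame(
      start_s = c(3, segments$start_s[probe_rows] + 0.8),
      end_s = c(3 + p$load_duration_s, segments$end_s[probe_rows] - 0.1),
      g_ag_nS = c(p$g_load_nS, rep(p$g_probe_nS, length(probe_rows))),
      tau_exchange_s = p$tau_exchange_s)
  } else {  # clc2_steps
    step_v <- seq(-134, -44, by = 10)
    segments <- do.call(rbind, lapply(seq_along(step_v), function(k) {
      rbind(seg(paste0("pre", k), -44, 0.5, ramped = FALSE),
            seg(paste0("step", k), step_v[k], 1, ramped = FALSE))
    }))
    segments$start_s <- cumsum(c(0, segments$duration_s[-nrow(segments)]))
    segments$end_s <- segments$start_s + segments$duration_s
    windows <- data.frame(start_s = numeric(0), end_s = numeric(0),
                          g_ag_nS = numeric(0), tau_exchange_s = numeric(0))
  }

  proto <- structure(list(segments = segments, agonist_windows = windows,
                          dt_s = p$dt_s, name = template, params = p),
                     class = "ramp_protocol")
  validate_protocol(proto)
  proto
}

#' @rdname make_protocol
#' @param protocol A `ramp_protocol` to validate.
#' @export
validate_protocol <- function(protocol) {
  s <- protocol$segments
  if (any(s$duration_s <= 0)) stop("segment durations must be positive")
  if (protocol$dt_s <= 0) stop("sampling interval must be positive")
  ramped <- s$cycle_hz > 0
  expected <- 1000 * s$ramp_rate_V_s[ramped] / (2 * s$cycle_hz[ramped])
  if (any(abs(s$ramp_amplitude_mV[ramped] - expected) > 1e-9))
    stop("ramp amplitude inconsistent with rate/(2*frequency)")
  w <- protocol$agonist_windows
  if (nrow(w) > 0 && any(w$end_s <= w$start_s))
    stop("agonist windows must have positive duration")
  if (nrow(w) > 0 && any(w$g_ag_nS < 0)) stop("agonist conductances must be >= 0")
  invisible(protocol)
}

#' Command-voltage waveform of a protocol
#'
#' Expands a [make_protocol()] description into the sampled command voltage:
#' a symmetric triangle wave about each segment's holding potential (starting
#' at the holding potential, ascending), or a constant for unramped segments.
#'
#' @param protocol A `ramp_protocol`.
#' @return Data frame with `time_s`, `v_cmd_mV`, `segment` (label).
#' @export
protocol_voltage <- function(protocol) {
  s <- protocol$segments
  dt <- protocol$dt_s
  total <- s$end_s[nrow(s)]
  n <- round(total / dt)
  time_s <- (seq_len(n) - 1) * dt
  idx <- findInterval(time_s, s$start_s)
  tl <- time_s - s$start_s[idx]
  v <- s$holding_mV[idx]
  r <- s$cycle_hz[idx] > 0
  if (any(r)) {
    x <- (tl[r] * s$cycle_hz[idx][r] + 0.25) %% 1
    tri <- 1 - 4 * abs(x - 0.5)                 # -1 at x=0/1, +1 at x=0.5
    v[r] <- v[r] + (s$ramp_amplitude_mV[idx][r] / 2) * tri
  }
  data.frame(time_s = time_s, v_cmd_mV = v, segment = s$label[idx])
}

#' Ground-truth synthetic cell
#'
#' Parameter set for the sweep generator: a non-chloride leak (linear
#' conductance with its own reversal, or the exponential form
#' I = A + B exp(V/C)), a resting chloride conductance reversing at E_Cl,
#' series resistance, Gaussian recording-noise amplitude, and an embedded
#' [cell_state()] that supplies ionic concentrations and, when chloride
#' dynamics are coupled, the equivalent volume and KCC2 parameters.
#'
#' @param leak Non-chloride leak: `list(form = "linear", g_nS, e_rev_mV)` or
#'   `list(form = "exponential", a_pA, b_pA, c_mV)` (`c_mV` non-zero).
#' @param g_cl_rest_nS Resting chloride conductance (nS).
#' @param rs_Mohm Series resistance (Mohm), >= 0.
#' @param noise_sd_pA Gaussian current-noise SD (pA); default 5.
#' @param state A [cell_state()]; its `cl_i_mM` is the initial intracellular
#'   chloride and its `g_cl_nS` is ignored in favour of `g_cl_rest_nS`.
#' @param kcc2_active Include the KCC2 flux when dynamics are coupled?
#'   Default `FALSE` (KCC2-blocked recording conditions).
#' @return An object of class `synthetic_cell`.
#' @export
synthetic_cell <- function(leak = list(form = "linear", g_nS = 0.43,
                                       e_rev_mV = -74),
                           g_cl_rest_nS = 0.054, rs_Mohm = 20,
                           noise_sd_pA = 5, state = cell_state(),
                           kcc2_active = FALSE) {
  stopifnot(rs_Mohm >= 0, noise_sd_pA >= 0, g_cl_rest_nS >= 0)
  form <- match.arg(leak$form, c("linear", "exponential"))
  if (form == "linear") stopifnot(leak$g_nS >= 0)
  if (form == "exponential") stopifnot(leak$c_mV != 0)
  structure(list(leak = leak, g_cl_rest_nS = g_cl_rest_nS,
                 rs_Mohm = rs_Mohm, noise_sd_pA = noise_sd_pA,
                 state = state, kcc2_active = isTRUE(kcc2_active)),
            class = "synthetic_cell")
}

#' Simulate a voltage-clamp sweep
#'
#' Generates the measured current for a protocol applied to a synthetic
#' cell. At each sample the membrane potential solves
#' V_m = v_cmd - I(V_m) * Rs (direct solve for linear membranes, damped
#' fixed point otherwise); the agonist conductance relaxes toward its
#' window target with first-order solution-exchange kinetics; i.i.d.
#' Gaussian recording noise is added to the measured current only. With
#' `couple_cl_dynamics = TRUE`, intracellular chloride is advanced every
#' sample by the chloride channel flux I_Cl dt / (F v_equ) (plus the KCC2
#' flux if the cell's `kcc2_active` is set), so agonist application at
#' depolarized potentials loads the cell with chloride and E_Cl drifts
#' accordingly.
#'
#' @param cell A [synthetic_cell()].
#' @param protocol A [make_protocol()] result.
#' @param couple_cl_dynamics Advance \[Cl\]i each sample? Default `FALSE`
#'   (E_Cl fixed at its initial value).
#' @param seed Integer seed; generation is reproducible bit-for-bit.
#' @param cl_schedule Optional prescribed \[Cl\]i trajectory: a
#'   `function(t)` returning mM, imposed sample-by-sample instead of the
#'   coupled dynamics. Useful for building sweeps whose E_Cl history is
#'   known exactly. Ignored when `couple_cl_dynamics = TRUE`.
#' @return An `ephys_sweep`: data frame `time_s`, `v_cmd_mV`, `i_pA`, with
#'   attributes `protocol`, `seed`, `cell`, and `truth` (data frame of the
#'   generator's internal `v_m_mV`, `cl_i_mM`, `e_cl_mV`, `g_ag_nS`).
#' @export
simulate_sweep <- function(cell, protocol, couple_cl_dynamics = FALSE,
                           seed = 1, cl_schedule = NULL) {
  validate_protocol(protocol)
  wave <- protocol_voltage(protocol)
  n <- nrow(wave)
  target <- numeric(n)
  w <- protocol$agonist_windows
  tau <- if (nrow(w) > 0) w$tau_exchange_s[1] else 0.05
  for (k in seq_len(nrow(w)))
    target[wave$time_s >= w$start_s[k] & wave$time_s < w$end_s[k]] <- w$g_ag_nS[k]

  set.seed(seed)
  noise <- if (cell$noise_sd_pA > 0) stats::rnorm(n, 0, cell$noise_sd_pA) else numeric(n)

  lk <- cell$leak
  lin <- identical(lk$form, "linear")
  st <- cell$state
  res <- simulate_sweep_core(
    wave$v_cmd_mV, protocol$dt_s,
    leak_form = if (lin) 0L else 1L,
    leak_g = if (lin) lk$g_nS else 0,
    leak_erev = if (lin) lk$e_rev_mV else 0,
    leak_a = if (lin) 0 else lk$a_pA,
    leak_b = if (lin) 0 else lk$b_pA,
    leak_c = if (lin) 1 else lk$c_mV,
    g_cl = cell$g_cl_rest_nS, g_ag_target = target,
    tau_exchange = tau, rs_mohm = cell$rs_Mohm, noise = noise,
    couple = isTRUE(couple_cl_dynamics), kcc2_on = cell$kcc2_active,
    cl_i0 = st$cl_i_mM, cl_o = st$cl_o_mM, k_i = st$k_i_mM,
    k_o = st$k_o_mM, temp = st$temp_K, g_kcc2 = st$g_kcc2,
    v_equ = st$v_equ_L,
    cl_schedule = if (is.null(cl_schedule) || isTRUE(couple_cl_dynamics))
      numeric(0) else cl_schedule(wave$time_s))

  truth <- data.frame(v_m_mV = res$v_m_mV, cl_i_mM = res$cl_i_mM,
                      g_ag_nS = res$g_ag_nS)
  truth$e_cl_mV <- nernst(truth$cl_i_mM,
                          nernst_context(st$cl_o_mM, st$temp_K))
  out <- data.frame(time_s = wave$time_s, v_cmd_mV = wave$v_cmd_mV,
                    i_pA = res$i_pA)
  structure(out, class = c("ephys_sweep", "data.frame"),
            protocol = protocol, seed = seed, cell = cell, truth = truth)
}

#' Simulate a train of miniature synaptic conductance events
#'
#' Poisson-timed events, each a difference-of-exponentials conductance
#' kernel normalized so that its peak equals `g_peak_nS`. Intended to
#' emulate spontaneous miniature inhibitory synaptic conductances whose
#' frequency and decay can be scaled to mimic pharmacological modulation.
#'
#' @param rate_Hz Mean event rate (Hz), >= 0.
#' @param g_peak_nS Peak conductance per event (nS).
#' @param tau_rise_s,tau_decay_s Kernel time constants (s); decay > rise.
#' @param duration_s Trace duration (s), > 0.
#' @param dt_s Sampling interval (s).
#' @param seed Integer seed.
#' @return Data frame `time_s`, `g_nS`; event times in attribute `events_s`.
#' @export
simulate_mini_train <- function(rate_Hz, g_peak_nS = 0.5, tau_rise_s = 0.001,
                                tau_decay_s = 0.02, duration_s = 10,
                                dt_s = 1e-3, seed = 1) {
  stopifnot(rate_Hz >= 0, g_peak_nS >= 0, tau_rise_s >= 0,
            tau_decay_s > tau_rise_s, duration_s > 0, dt_s > 0)
  set.seed(seed)
  n_ev <- stats::rpois(1, rate_Hz * duration_s)
  events <- sort(stats::runif(n_ev, 0, duration_s))
  time_s <- seq(0, duration_s, by = dt_s)
  g <- numeric(length(time_s))
  if (n_ev > 0 && g_peak_nS > 0) {
    # peak of exp(-t/td) - exp(-t/tr) at t* = log(td/tr) * tr*td/(td - tr)
    tstar <- log(tau_decay_s / tau_rise_s) * tau_rise_s * tau_decay_s /
      (tau_decay_s - tau_rise_s)
    norm <- exp(-tstar / tau_decay_s) - exp(-tstar / tau_rise_s)
    for (ev in events) {
      rel <- time_s - ev
      sel <- rel >= 0
      g[sel] <- g[sel] + g_peak_nS *
        (exp(-rel[sel] / tau_decay_s) - exp(-rel[sel] / tau_rise_s)) / norm
    }
  }
  structure(data.frame(time_s = time_s, g_nS = g), events_s = events,
            class = c("mini_train", "data.frame"))
}

#' Write and read sweeps as delimited text
#'
#' Sweeps are stored as tab-separated text with mandatory header columns
#' `time_s`, `v_cmd_mV`, `i_pA`, plus a JSON sidecar (`<path>.json`) holding
#' the protocol, seed and, for synthetic sweeps, the ground-truth cell
#' parameters.
#'
#' @param sweep An `ephys_sweep`.
#' @param path Path of the TSV file to write/read.
#' @return `read_sweep()` returns an `ephys_sweep` (truth traces are not
#'   round-tripped; the cell and protocol metadata are).
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(as.data.frame(sweep)[c("time_s", "v_cmd_mV", "i_pA")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(seed = attr(sweep, "seed"),
               protocol = .protocol_to_list(attr(sweep, "protocol")),
               cell = .cell_to_list(attr(sweep, "cell")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_s", "v_cmd_mV", "i_pA") %in% names(d)))
  if (is.unsorted(d$time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  out <- structure(d, class = c("ephys_sweep", "data.frame"))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "seed") <- meta$seed
    attr(out, "protocol") <- .protocol_from_list(meta$protocol)
    attr(out, "cell") <- .cell_from_list(meta$cell)
  }
  out
}

.protocol_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(name = p$name, dt_s = p$dt_s, segments = p$segments,
       agonist_windows = p$agonist_windows, params = p$params)
}

.protocol_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  structure(list(segments = as.data.frame(l$segments),
                 agonist_windows = as.data.frame(l$agonist_windows),
                 dt_s = l$dt_s, name = l$name, params = l$params),
            class = "ramp_protocol")
}

.cell_to_list <- function(cell) {
  if (is.null(cell)) return(NULL)
  list(leak = cell$leak, g_cl_rest_nS = cell$g_cl_rest_nS,
       rs_Mohm = cell$rs_Mohm, noise_sd_pA = cell$noise_sd_pA,
       kcc2_active = cell$kcc2_active, state = unclass(cell$state))
}

.cell_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  synthetic_cell(leak = l$leak, g_cl_rest_nS = l$g_cl_rest_nS,
                 rs_Mohm = l$rs_Mohm, noise_sd_pA = l$noise_sd_pA,
                 state = do.call(cell_state, l$state),
                 kcc2_active = l$kcc2_active)
}
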