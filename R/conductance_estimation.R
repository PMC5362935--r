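#' Relative resting chloride conductance from reversal-potential shifts
#'
#' The core estimator: if the total membrane conductance g_T and the
#' non-chloride equilibrium potentials are unchanged while E_Cl is shifted
#' (by loading the cell with chloride), the conductance form of the
#' Goldman-Hodgkin-Katz relation reduces to
#' g_Cl / g_T = (E_rev2 - E_rev1) / (E_Cl2 - E_Cl1),
#' i.e. the shift of the total-current reversal potential relative to the
#' shift of the chloride Nernst potential.
#'
#' @param e_rev1_mV,e_rev2_mV Total-current reversal potentials before and
#'   after the chloride load (mV).
#' @param e_cl1_mV,e_cl2_mV Chloride equilibrium potentials at the same two
#'   times (mV); must differ.
#' @return Dimensionless ratio g_Cl / g_T. Values outside \[0, 1\] are
#'   returned as-is (never clipped); flagging is the caller's job.
#' @examples
#' relative_gcl(-60, -57, -80, -30)  # 0.06
#' @export
relative_gcl <- function(e_rev1_mV, e_rev2_mV, e_cl1_mV, e_cl2_mV) {
  if (e_cl2_mV == e_cl1_mV) stop("E_Cl shift is zero; estimator undefined")
  (e_rev2_mV - e_rev1_mV) / (e_cl2_mV - e_cl1_mV)
}

#' Interpolate E_Cl to an intermediate measurement time
#'
#' \[Cl\]i keeps changing between the post-load E_Cl measurements, so E_Cl
#' at the time of the second conductance/reversal measurement is obtained by
#' linear interpolation in time between the two flanking E_Cl estimates.
#'
#' @param e_cl_a_mV,t_a_s First E_Cl estimate (mV) and its time (s).
#' @param e_cl_b_mV,t_b_s Second E_Cl estimate and time.
#' @param t_target_s Time to interpolate to. Extrapolation outside
#'   \[t_a, t_b\] is allowed but flagged with a warning.
#' @return Interpolated E_Cl (mV).
#' @export
interpolate_ecl <- function(e_cl_a_mV, t_a_s, e_cl_b_mV, t_b_s, t_target_s) {
  if (t_a_s == t_b_s) stop("the two E_Cl times must differ")
  if (t_target_s < min(t_a_s, t_b_s) || t_target_s > max(t_a_s, t_b_s))
    warning("t_target_s outside the two E_Cl measurement times; extrapolating")
  e_cl_a_mV + (e_cl_b_mV - e_cl_a_mV) * (t_target_s - t_a_s) / (t_b_s - t_a_s)
}

#' Total-conductance stability check
#'
#' The estimator requires a total conductance that does not change with the
#' chloride load; cells whose paired measurements differ by 30% or more are
#' rejected.
#'
#' @param g_t1_nS,g_t2_nS Total conductance before/after the load (nS), > 0.
#' @return List with `pass` (logical), `ratio` (g_t2/g_t1) and
#'   `rel_change`.
#' @export
qc_total_conductance <- function(g_t1_nS, g_t2_nS) {
  if (g_t1_nS <= 0 || g_t2_nS <= 0) stop("conductances must be positive")
  rel <- abs(g_t2_nS - g_t1_nS) / g_t1_nS
  list(pass = rel < 0.30, ratio = g_t2_nS / g_t1_nS, rel_change = rel)
}

#' Convert an in-blockers estimate to the blocker-free basis
#'
#' Recordings for the estimator are made with background blockers that
#' reduce the total resting conductance to a fraction (`factor`, measured
#' mean 0.54) of its blocker-free value. The chloride conductance itself is
#' unaffected, so the relative g_Cl on the blocker-free basis is the
#' in-blockers ratio multiplied by that factor (the denominator g_T grows
#' by 1/factor).
#'
#' @param rel_gcl_in_blockers Relative g_Cl measured in blockers.
#' @param factor Blocker attenuation factor in (0, 1\]; default 0.54.
#' @return Relative g_Cl on the blocker-free basis.
#' @export
blocker_correction <- function(rel_gcl_in_blockers, factor = 0.54) {
  if (factor <= 0 || factor > 1) stop("factor must be in (0, 1]")
  rel_gcl_in_blockers * factor
}

#' Absolute resting chloride conductance
#'
#' @param rel_gcl Relative g_Cl (dimensionless, > 0 for a meaningful value).
#' @param g_t_nS Total conductance on the same basis (nS).
#' @return Absolute g_Cl in pS.
#' @export
absolute_gcl <- function(rel_gcl, g_t_nS) {
  rel_gcl * g_t_nS * 1000
}

.intervals_minus <- function(lo, hi, windows) {
  # subtract a data frame of (start_s, end_s) windows from [lo, hi]
  segs <- data.frame(lo = lo, hi = hi)
  if (!is.null(windows) && nrow(windows) > 0) {
    for (k in seq_len(nrow(windows))) {
      out <- list()
      for (j in seq_len(nrow(segs))) {
        a <- segs$lo[j]; b <- segs$hi[j]
        ws <- windows$start_s[k]; we <- windows$end_s[k]
        if (we <= a || ws >= b) { out[[length(out) + 1]] <- c(a, b); next }
        if (ws > a) out[[length(out) + 1]] <- c(a, ws)
        if (we < b) out[[length(out) + 1]] <- c(we, b)
      }
      segs <- if (length(out)) as.data.frame(do.call(rbind, out)) else
        data.frame(lo = numeric(0), hi = numeric(0))
      names(segs) <- c("lo", "hi")
    }
  }
  segs[segs$hi - segs$lo > 0.25, , drop = FALSE]
}

#' Run the resting-chloride-conductance protocol analysis
#'
#' Orchestrates the full estimator on a sweep recorded (or synthesized) with
#' the `"gcl_estimation"` protocol: series-resistance correction; leak
#' models fitted to agonist-free ramps pooled across holding levels -
#' separately for ramps before and after the chloride load, because the
#' chloride component of the leak itself reverses at E_Cl and therefore
#' shifts with the load; g_T1/E_rev1 from the first train around -74 mV and
#' g_T2/E_rev2 from the second; E_Cl from leak-subtracted agonist I-V curves
#' at the end of each agonist application (the brief probe before loading,
#' the end of the 20 s load, and the final probe around -34 mV), each
#' subtracted with the leak model of its own epoch; linear interpolation of
#' E_Cl to the time of the second conductance measurement; the <30% g_T
#' stability check; and the relative (in-blockers and blocker-free basis)
#' and absolute chloride conductances.
#'
#' @param sweep An `ephys_sweep` covering the whole protocol.
#' @param protocol The `ramp_protocol` used (defaults to the sweep's
#'   `protocol` attribute).
#' @param rs_Mohm Series resistance used for offline correction (Mohm).
#' @param config Named list of options: `leak_form` ("exponential"),
#'   `blocker_factor` (0.54), `bin_mV` (1), `blank_ms` (2), `probe_eval_s`
#'   (1; length of the window at the end of each agonist application used
#'   for the E_Cl I-V), `settle_factor` (10; agonist decay margin in units
#'   of the exchange time constant), `gT_halfwidth_mV` (10), `ctx`
#'   (a [nernst_context()]).
#' @return A `gcl_estimate`: list with reversal potentials, E_Cl values and
#'   times, total conductances, the interpolated E_Cl2, relative g_Cl on
#'   both bases, absolute g_Cl (pS), derived \[Cl\]i values, the pre- and
#'   post-load leak models, QC results and flags.
#' @export
run_gcl_protocol <- function(sweep, protocol = attr(sweep, "protocol"),
                             rs_Mohm, config = list()) {
  cfg <- list(leak_form = "exponential", blocker_factor = 0.54, bin_mV = 1,
              blank_ms = 2, probe_eval_s = 1, settle_factor = 10,
              gT_halfwidth_mV = 10, ctx = nernst_context())
  cfg[names(config)] <- config
  if (is.null(protocol)) stop("protocol must be supplied")
  seg <- protocol$segments
  need <- c("rest1", "load", "rest2", "probe2")
  if (!all(need %in% seg$label))
    stop("protocol must contain phases: ", paste(need, collapse = ", "))
  win <- protocol$agonist_windows
  if (nrow(win) < 3) stop("protocol must contain three agonist applications")

  v_corr <- correct_series_resistance(sweep, rs_Mohm)
  tau <- win$tau_exchange_s[1]
  settle <- cfg$settle_factor * tau
  inflated <- transform(win, end_s = end_s + settle)

  seg_win <- function(label) {
    r <- seg[seg$label == label, ]
    c(r$start_s, r$end_s)
  }
  free_windows <- function(label) {
    w <- seg_win(label)
    segs <- .intervals_minus(w[1], w[2], inflated)
    lapply(seq_len(nrow(segs)), function(j) c(segs$lo[j], segs$hi[j]))
  }
  iv_free <- function(label) {
    fw <- free_windows(label)
    if (length(fw) == 0) stop("no agonist-free ramps in phase ", label)
    build_iv_from_ramp(sweep, v_corr, fw, bin_mV = cfg$bin_mV,
                       blank_ms = cfg$blank_ms)
  }

  iv1 <- iv_free("rest1")
  iv2 <- iv_free("rest2")

  # identify windows by location: probe1 in rest1, load in load, probe2 in probe2
  w_in <- function(label) {
    sw <- seg_win(label)
    which(win$start_s >= sw[1] & win$end_s <= sw[2])[1]
  }
  k1 <- w_in("rest1"); k2 <- w_in("load"); k3 <- w_in("probe2")
  if (any(is.na(c(k1, k2, k3))))
    stop("could not locate the three agonist windows within their phases")

  # agonist-free intervals across all phases, split into pre-/post-load
  # epochs: the chloride component of the leak reverses at E_Cl, so the leak
  # curve itself shifts with the load and each epoch needs its own fit
  free_all <- do.call(rbind, lapply(seg$label, function(lb) {
    s <- .intervals_minus(seg_win(lb)[1], seg_win(lb)[2], inflated)
  }))
  mid <- (free_all$lo + free_all$hi) / 2
  pooled_iv <- function(rows) {
    ws <- lapply(rows, function(j) c(free_all$lo[j], free_all$hi[j]))
    ivs <- Filter(Negate(is.null), lapply(ws, function(w)
      tryCatch(build_iv_from_ramp(sweep, v_corr, w, bin_mV = cfg$bin_mV,
                                  blank_ms = cfg$blank_ms),
               error = function(e) NULL)))
    if (length(ivs) == 0) stop("no usable agonist-free ramps in epoch")
    pool_iv_curves(ivs, bin_mV = cfg$bin_mV)
  }
  leak_pre <- fit_leak_model(pooled_iv(which(mid < win$start_s[k2])),
                             form = cfg$leak_form)
  leak_post <- fit_leak_model(pooled_iv(which(mid > win$end_s[k2])),
                              form = cfg$leak_form)

  # agonist I-V at the end of each application window
  agonist_iv <- function(k, leak) {
    w <- c(max(win$start_s[k] + 5 * tau, win$end_s[k] - cfg$probe_eval_s),
           win$end_s[k])
    iv <- build_iv_from_ramp(sweep, v_corr, w, bin_mV = cfg$bin_mV,
                             blank_ms = cfg$blank_ms)
    list(iv = subtract_leak(iv, leak), t_mid = mean(w))
  }
  ag1 <- agonist_iv(k1, leak_pre)
  ag2a <- agonist_iv(k2, leak_post)
  ag2b <- agonist_iv(k3, leak_post)
  e_cl1 <- estimate_reversal_potential(ag1$iv)
  e_cl2a <- estimate_reversal_potential(ag2a$iv)
  e_cl2b <- estimate_reversal_potential(ag2b$iv)

  hold1 <- seg$holding_mV[seg$label == "rest1"]
  e_rev1 <- estimate_reversal_potential(iv1)
  e_rev2 <- estimate_reversal_potential(iv2)
  g_t1 <- estimate_slope_conductance(iv1, center_mV = hold1,
                                     halfwidth_mV = cfg$gT_halfwidth_mV)
  g_t2 <- estimate_slope_conductance(iv2, center_mV = hold1,
                                     halfwidth_mV = cfg$gT_halfwidth_mV)
  t_gt2 <- mean(seg_win("rest2"))

  e_cl2 <- interpolate_ecl(e_cl2a, ag2a$t_mid, e_cl2b, ag2b$t_mid, t_gt2)
  qc <- qc_total_conductance(g_t1, g_t2)
  rel_ib <- relative_gcl(e_rev1, e_rev2, e_cl1, e_cl2)
  rel_bf <- blocker_correction(rel_ib, cfg$blocker_factor)
  abs_pS <- absolute_gcl(rel_ib, mean(c(g_t1, g_t2)))

  flags <- character(0)
  if (!qc$pass) flags <- c(flags, "gT_change_exceeds_30pct")
  if (rel_ib < 0 || rel_ib > 1) flags <- c(flags, "relative_gcl_out_of_range")

  structure(list(
    e_rev1_mV = e_rev1, e_rev2_mV = e_rev2,
    e_cl1_mV = e_cl1, e_cl2a_mV = e_cl2a, t_a_s = ag2a$t_mid,
    e_cl2b_mV = e_cl2b, t_b_s = ag2b$t_mid, e_cl2_mV = e_cl2,
    t_gt2_s = t_gt2, g_t1_nS = g_t1, g_t2_nS = g_t2,
    rel_gcl_in_blockers = rel_ib, blocker_factor = cfg$blocker_factor,
    rel_gcl_blocker_free = rel_bf, abs_gcl_pS = abs_pS,
    cl_i1_mM = cl_from_potential(e_cl1, cfg$ctx),
    cl_i2_mM = cl_from_potential(e_cl2, cfg$ctx),
    leak_pre = leak_pre, leak_post = leak_post,
    qc = qc, flags = flags), class = "gcl_estimate")
}

#' @export
print.gcl_estimate <- function(x, ...) {
  cat("Resting chloride conductance estimate\n")
  cat(sprintf("  E_rev: %7.2f -> %7.2f mV (shift %+.2f mV)\n",
              x$e_rev1_mV, x$e_rev2_mV, x$e_rev2_mV - x$e_rev1_mV))
  cat(sprintf("  E_Cl:  %7.2f -> %7.2f mV (shift %+.2f mV)\n",
              x$e_cl1_mV, x$e_cl2_mV, x$e_cl2_mV - x$e_cl1_mV))
  cat(sprintf("  g_T:   %.3f / %.3f nS (QC %s)\n", x$g_t1_nS, x$g_t2_nS,
              if (x$qc$pass) "pass" else "FAIL"))
  cat(sprintf("  relative g_Cl: %.4f (in blockers), %.4f (blocker-free basis)\n",
              x$rel_gcl_in_blockers, x$rel_gcl_blocker_free))
  cat(sprintf("  absolute g_Cl: %.1f pS\n", x$abs_gcl_pS))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the intracellular chloride time course from a probe sweep
#'
#' For a `"load_and_probe"` recording, extracts one E_Cl (and \[Cl\]i)
#' estimate per probe ramp train. Each probe's leak is fitted to that
#' train's own agonist-free ramps (adjacent control ramps, so the slowly
#' drifting chloride component of the leak is captured at its current
#' state), falling back to a leak pooled over all probe trains when a local
#' fit is not possible; the probe's leak-subtracted agonist I-V gives its
#' reversal, and times are the probe window midpoints.
#'
#' @inheritParams run_gcl_protocol
#' @return Data frame `time_s`, `e_cl_mV`, `cl_mM`, one row per probe.
#' @export
estimate_cl_timecourse <- function(sweep, protocol = attr(sweep, "protocol"),
                                   rs_Mohm, config = list()) {
  cfg <- list(leak_form = "exponential", bin_mV = 1, blank_ms = 2,
              probe_eval_s = 1, settle_factor = 10, ctx = nernst_context())
  cfg[names(config)] <- config
  if (is.null(protocol)) stop("protocol must be supplied")
  seg <- protocol$segments
  win <- protocol$agonist_windows
  v_corr <- correct_series_resistance(sweep, rs_Mohm)
  tau <- win$tau_exchange_s[1]
  inflated <- transform(win, end_s = end_s + cfg$settle_factor * tau)

  probe_rows <- grep("^probe", seg$label)
  if (length(probe_rows) == 0) stop("protocol has no probe segments")
  probe_free <- lapply(probe_rows, function(r) {
    segs <- .intervals_minus(seg$start_s[r], seg$end_s[r], inflated)
    lapply(seq_len(nrow(segs)), function(j) c(segs$lo[j], segs$hi[j]))
  })
  local_iv <- function(fw) {
    ivs <- Filter(Negate(is.null), lapply(fw, function(w)
      tryCatch(build_iv_from_ramp(sweep, v_corr, w, bin_mV = cfg$bin_mV,
                                  blank_ms = cfg$blank_ms),
               error = function(e) NULL)))
    if (length(ivs) == 0) return(NULL)
    pool_iv_curves(ivs, cfg$bin_mV)
  }
  pooled_all <- local_iv(unlist(probe_free, recursive = FALSE))
  if (is.null(pooled_all)) stop("no agonist-free probe ramps for the leak fit")
  leak_global <- fit_leak_model(pooled_all, form = cfg$leak_form)

  out <- NULL
  for (idx in seq_along(probe_rows)) {
    r <- probe_rows[idx]
    k <- which(win$start_s >= seg$start_s[r] & win$end_s <= seg$end_s[r])[1]
    if (is.na(k)) next
    iv_loc <- local_iv(probe_free[[idx]])
    leak <- if (!is.null(iv_loc) && nrow(iv_loc) >= 10)
      fit_leak_model(iv_loc, form = cfg$leak_form) else leak_global
    w <- c(max(win$start_s[k] + 5 * tau, win$end_s[k] - cfg$probe_eval_s),
           win$end_s[k])
    iv <- build_iv_from_ramp(sweep, v_corr, w, bin_mV = cfg$bin_mV,
                             blank_ms = cfg$blank_ms)
    iv <- subtract_leak(iv, leak, on_extrapolation = "warn")
    e <- tryCatch(estimate_reversal_potential(iv), error = function(e) NA_real_)
    out <- rbind(out, data.frame(time_s = mean(w), e_cl_mV = e,
                                 cl_mM = if (is.na(e)) NA_real_ else
                                   cl_from_potential(e, cfg$ctx)))
  }
  out
}
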