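#' Offline series-resistance correction
#'
#' The access resistance between pipette and cell drops part of the command
#' voltage across itself, so the membrane sees
#' V_m(t) = v_cmd(t) - i(t) * Rs. This applies that correction elementwise
#' (1 pA across 1 Mohm = 1e-3 mV).
#'
#' @param sweep An `ephys_sweep` (or data frame with `v_cmd_mV`, `i_pA`).
#' @param rs_Mohm Series resistance (Mohm), >= 0.
#' @return Corrected membrane voltage trace (mV).
#' @export
correct_series_resistance <- function(sweep, rs_Mohm) {
  if (rs_Mohm < 0) stop("rs_Mohm must be >= 0")
  sweep$v_cmd_mV - sweep$i_pA * rs_Mohm * 1e-3
}

#' Build an I-V curve from ramp samples
#'
#' Re-grids ramp samples onto a uniform voltage axis: monotone half-ramps
#' are identified from the command waveform, a blanking window around each
#' ramp turning point discards capacitive-transient samples, and the
#' remaining samples are binned by corrected membrane voltage (mean current
#' and mean voltage per bin). When both ramp directions are kept (the
#' default) their samples share bins, so direction-antisymmetric artefacts
#' average out.
#'
#' @param sweep An `ephys_sweep`.
#' @param v_corrected Corrected membrane voltage from
#'   [correct_series_resistance()] (same length as the sweep).
#' @param windows_s Numeric vector `c(t0, t1)` or a list of such windows;
#'   samples with `t0 <= time_s < t1` are pooled.
#' @param bin_mV Voltage bin width (mV); default 1.
#' @param blank_ms Blanking around ramp turning points (ms); default 2.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return An `iv_curve`: data frame `v_mV`, `i_pA`, `n` (samples per bin),
#'   sorted by voltage, with attributes `leak_subtracted` (FALSE) and
#'   `windows_s`.
#' @export
build_iv_from_ramp <- function(sweep, v_corrected, windows_s,
                               bin_mV = 1, blank_ms = 2,
                               direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (!is.list(windows_s)) windows_s <- list(windows_s)
  t <- sweep$time_s
  sel <- rep(FALSE, length(t))
  for (w in windows_s) sel <- sel | (t >= w[1] & t < w[2])
  if (sum(sel) < 10) stop("selected window contains too few samples")

  dv <- diff(sweep$v_cmd_mV)
  dirn <- sign(c(dv[1], dv))                      # per-sample ramp direction
  if (all(dirn[sel] == 0))
    stop("selected window contains no ramp (constant command voltage)")
  # blank around direction changes (ramp turning points, segment edges)
  turn <- which(diff(dirn) != 0)
  dt <- stats::median(diff(t))
  halfwidth <- max(0L, round(blank_ms * 1e-3 / dt))
  if (length(turn) > 0 && halfwidth > 0) {
    bad <- unique(unlist(lapply(turn, function(k)
      seq(max(1, k - halfwidth), min(length(t), k + 1 + halfwidth)))))
    sel[bad] <- FALSE
  }
  if (direction == "up") sel <- sel & dirn > 0
  if (direction == "down") sel <- sel & dirn < 0
  sel <- sel & dirn != 0
  if (sum(sel) < 10) stop("too few ramp samples after blanking")

  v <- v_corrected[sel]; i <- sweep$i_pA[sel]; dr <- factor(dirn[sel])
  bin <- floor(v / bin_mV)
  # per-direction bin means first, then equal-weight average of the two
  # limbs, so direction-antisymmetric artefacts cancel even in bins where
  # the limbs contribute unequal sample counts
  vm <- rowMeans(tapply(v, list(bin, dr), mean), na.rm = TRUE)
  im <- rowMeans(tapply(i, list(bin, dr), mean), na.rm = TRUE)
  nn <- rowSums(tapply(v, list(bin, dr), length), na.rm = TRUE)
  ord <- order(vm)
  structure(data.frame(v_mV = as.numeric(vm)[ord], i_pA = as.numeric(im)[ord],
                       n = as.integer(nn)[ord]),
            class = c("iv_curve", "data.frame"),
            leak_subtracted = FALSE, windows_s = windows_s)
}

#' Pool several I-V curves
#'
#' Sample-weighted merge of I-V curves that share a bin width, used to fit a
#' single leak model over agonist-free ramps taken at several holding
#' potentials (and hence voltage ranges).
#'
#' @param ivs List of `iv_curve` objects.
#' @param bin_mV Bin width used to align curves (mV).
#' @return A pooled `iv_curve`.
#' @export
pool_iv_curves <- function(ivs, bin_mV = 1) {
  stopifnot(length(ivs) >= 1)
  d <- do.call(rbind, lapply(ivs, as.data.frame))
  bin <- floor(d$v_mV / bin_mV + 0.5)  # curves carry mean-v per bin
  vm <- tapply(d$v_mV * d$n, bin, sum) / tapply(d$n, bin, sum)
  im <- tapply(d$i_pA * d$n, bin, sum) / tapply(d$n, bin, sum)
  nn <- tapply(d$n, bin, sum)
  ord <- order(vm)
  structure(data.frame(v_mV = as.numeric(vm)[ord], i_pA = as.numeric(im)[ord],
                       n = as.integer(nn)[ord]),
            class = c("iv_curve", "data.frame"),
            leak_subtracted = FALSE, windows_s = NULL)
}

#' Fit a leak model to an agonist-free I-V curve
#'
#' Leak current (including small voltage-dependent components) is described
#' either by a line or by I = A + B exp(V/C). The exponential fit is
#' initialized from a linear pre-fit and run from starts with C of either
#' sign, constrained to 2 <= |C| <= 200 mV for numerical stability; if it
#' fails to converge the linear fit is returned with a `fallback` flag.
#'
#' @param iv An `iv_curve` with at least 10 grid points.
#' @param form `"exponential"` or `"linear"`.
#' @return A `leak_model`: list with `form`, `coef` (named: `slope_nS` and
#'   `intercept_pA`, or `a_pA`, `b_pA`, `c_mV`), `domain_mV`, `resid_sd_pA`,
#'   `converged`, `fallback`.
#' @export
fit_leak_model <- function(iv, form = c("exponential", "linear")) {
  form <- match.arg(form)
  if (nrow(iv) < 10) stop("need at least 10 I-V grid points to fit a leak")
  v <- iv$v_mV; i <- iv$i_pA
  linfit <- stats::lm(i ~ v)
  slope <- unname(stats::coef(linfit)[2]); icpt <- unname(stats::coef(linfit)[1])
  domain <- range(v)
  if (form == "linear") {
    return(structure(list(form = "linear",
                          coef = c(slope_nS = slope, intercept_pA = icpt),
                          domain_mV = domain,
                          resid_sd_pA = stats::sd(stats::resid(linfit)),
                          converged = TRUE, fallback = FALSE),
                     class = "leak_model"))
  }
  vbar <- mean(v)
  tries <- list()
  for (c0 in c(25, -25)) {
    b0 <- slope * c0 / exp(vbar / c0)
    a0 <- mean(i) - b0 * exp(vbar / c0)
    fit <- tryCatch(
      minpack.lm::nlsLM(i ~ a + b * exp(v / cc),
                        start = list(a = a0, b = b0, cc = c0),
                        lower = c(-Inf, -Inf, if (c0 > 0) 2 else -200),
                        upper = c(Inf, Inf, if (c0 > 0) 200 else -2),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) tries[[length(tries) + 1]] <- fit
  }
  if (length(tries) == 0) {
    out <- fit_leak_model(iv, "linear")
    out$fallback <- TRUE
    out$converged <- FALSE
    return(out)
  }
  sse <- vapply(tries, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- tries[[which.min(sse)]]
  cf <- stats::coef(best)
  structure(list(form = "exponential",
                 coef = c(a_pA = unname(cf["a"]), b_pA = unname(cf["b"]),
                          c_mV = unname(cf["cc"])),
                 domain_mV = domain,
                 resid_sd_pA = stats::sd(stats::resid(best)),
                 converged = TRUE, fallback = FALSE),
            class = "leak_model")
}

#' Evaluate a leak model at given voltages
#'
#' @param object A `leak_model`.
#' @param v_mV Voltages (mV).
#' @param ... Unused.
#' @return Predicted leak current (pA).
#' @export
predict.leak_model <- function(object, v_mV, ...) {
  cf <- object$coef
  if (object$form == "linear")
    cf[["slope_nS"]] * v_mV + cf[["intercept_pA"]]
  else
    cf[["a_pA"]] + cf[["b_pA"]] * exp(v_mV / cf[["c_mV"]])
}

#' Model-based leak subtraction
#'
#' Subtracts the fitted leak model evaluated at the agonist curve's own
#' corrected voltages - not a pointwise subtraction of the leak trace. This
#' matters because series resistance shifts the membrane voltage by
#' different amounts when agonist current flows, so the same sample index
#' corresponds to different true voltages with and without agonist; model
#' evaluation removes that bias.
#'
#' @param iv_agonist An `iv_curve` recorded with agonist present.
#' @param leak A fitted [fit_leak_model()] result.
#' @param extrapolation_margin_mV Allowed excursion beyond the leak-fit
#'   voltage domain (mV) before `on_extrapolation` triggers; default 5.
#' @param on_extrapolation `"warn"` or `"error"`.
#' @return The leak-subtracted `iv_curve` (`leak_subtracted` attribute set).
#' @export
subtract_leak <- function(iv_agonist, leak, extrapolation_margin_mV = 5,
                          on_extrapolation = c("warn", "error")) {
  on_extrapolation <- match.arg(on_extrapolation)
  dom <- leak$domain_mV
  if (!is.null(dom)) {
    beyond <- max(0, dom[1] - min(iv_agonist$v_mV),
                  max(iv_agonist$v_mV) - dom[2])
    if (beyond > extrapolation_margin_mV) {
      msg <- sprintf("I-V voltages extend %.1f mV beyond the leak-fit domain",
                     beyond)
      if (on_extrapolation == "error") stop(msg) else warning(msg)
    }
  }
  out <- iv_agonist
  out$i_pA <- iv_agonist$i_pA - predict(leak, iv_agonist$v_mV)
  attr(out, "leak_subtracted") <- TRUE
  out
}

#' Reversal potential from an I-V curve
#'
#' Locates the zero-current crossing by linear interpolation between the two
#' grid points bracketing the sign change. With multiple crossings (noisy
#' curves near zero), a local linear regression over a +/-5 mV window around
#' the crossing closest to the median crossing is used instead and a
#' warning is emitted.
#'
#' @param iv An `iv_curve` whose current brackets zero.
#' @return Reversal potential (mV).
#' @export
estimate_reversal_potential <- function(iv) {
  v <- iv$v_mV; i <- iv$i_pA
  exact <- which(i == 0)
  cross <- which(i[-length(i)] * i[-1] < 0)
  roots <- c(v[exact],
             v[cross] - i[cross] * (v[cross + 1] - v[cross]) /
               (i[cross + 1] - i[cross]))
  if (length(roots) == 0)
    stop("no zero-current crossing within the I-V voltage range")
  if (length(roots) == 1) return(unname(roots))
  warning("multiple zero crossings; using local regression near the median crossing")
  centre <- roots[which.min(abs(roots - stats::median(roots)))]
  sel <- abs(v - centre) <= 5
  if (sum(sel) < 3) sel <- rank(abs(v - centre)) <= 3
  fit <- stats::lm(i[sel] ~ v[sel])
  unname(-stats::coef(fit)[1] / stats::coef(fit)[2])
}

#' Slope conductance over a voltage window
#'
#' Ordinary least-squares slope of current on voltage over the requested
#' window. For ramp data in pA and mV the slope is in nS.
#'
#' @param iv An `iv_curve`.
#' @param center_mV Window centre (mV); defaults to the curve's reversal
#'   potential if it brackets zero, otherwise the median voltage.
#' @param halfwidth_mV Half-width of the window (mV); default 10.
#' @param window_mV Optional explicit window `c(lo, hi)`, overriding
#'   `center_mV`/`halfwidth_mV`.
#' @return Slope conductance (nS).
#' @export
estimate_slope_conductance <- function(iv, center_mV = NULL,
                                       halfwidth_mV = 10, window_mV = NULL) {
  if (is.null(window_mV)) {
    if (is.null(center_mV)) {
      center_mV <- tryCatch(estimate_reversal_potential(iv),
                            error = function(e) stats::median(iv$v_mV),
                            warning = function(w) stats::median(iv$v_mV))
    }
    window_mV <- center_mV + c(-1, 1) * halfwidth_mV
  }
  sel <- iv$v_mV >= window_mV[1] & iv$v_mV <= window_mV[2]
  if (sum(sel) < 5) stop("fewer than 5 I-V points in the conductance window")
  unname(stats::coef(stats::lm(iv$i_pA[sel] ~ iv$v_mV[sel]))[2])
}
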