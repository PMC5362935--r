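#' Single-exponential fit of a chloride time course
#'
#' Fits y(t) = asymptote + amplitude * exp(-(t - t0)/tau) by nonlinear least
#' squares, initialized from a log-linear pre-fit on asymptote-subtracted
#' data. Used for both loading (rising) and recovery (decaying) phases;
#' recoveries are sometimes bi-exponential or near-linear in real cells, but
#' the single exponential is the common summary for comparing conditions.
#'
#' @param time_s Probe times (s), strictly increasing, length >= 4.
#' @param cl_mM Chloride estimates (mM) at those times.
#' @param t0_s Phase start time; default `min(time_s)`.
#' @return An `exp_fit`: list with `asymptote_mM`, `amplitude_mM`, `tau_s`,
#'   `resid_sd_mM`, `converged`, `flags` (character; `"degenerate"` for
#'   flat series where tau is unidentifiable, `"tau_at_bound"` when the
#'   optimizer ends on its tau bound).
#' @export
fit_single_exponential <- function(time_s, cl_mM, t0_s = min(time_s)) {
  stopifnot(length(time_s) == length(cl_mM), length(time_s) >= 4)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  t <- time_s - t0_s
  y <- cl_mM
  span <- max(t) - min(t)
  rng <- diff(range(y))
  ntail <- max(1L, ceiling(length(y) * 0.2))
  asym0 <- mean(utils::tail(y, ntail))
  amp0 <- y[1] - asym0
  if (rng < 1e-9 || abs(amp0) < rng * 1e-3) {
    return(structure(list(asymptote_mM = mean(y), amplitude_mM = 0,
                          tau_s = NA_real_, resid_sd_mM = stats::sd(y),
                          converged = FALSE, flags = "degenerate"),
                     class = "exp_fit"))
  }
  # log-linear pre-fit for tau, nudging the asymptote guess past the data
  asym_g <- asym0 - sign(amp0) * 0.05 * abs(amp0)
  z <- (y - asym_g) / (y[1] - asym_g)
  ok <- z > 1e-6
  tau0 <- if (sum(ok) >= 3) {
    sl <- stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else span / 3
  } else span / 3
  tau0 <- min(max(tau0, span / 100), span * 10)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * exp(-t / tau),
                      start = list(a = asym_g, b = y[1] - asym_g, tau = tau0),
                      lower = c(-Inf, -Inf, span * 1e-4),
                      upper = c(Inf, Inf, span * 1e3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(asymptote_mM = asym0, amplitude_mM = amp0,
                          tau_s = NA_real_, resid_sd_mM = NA_real_,
                          converged = FALSE, flags = "nonconvergent"),
                     class = "exp_fit"))
  }
  cf <- stats::coef(fit)
  flags <- character(0)
  if (cf[["tau"]] <= span * 1.01e-4 || cf[["tau"]] >= span * 0.99e3)
    flags <- c(flags, "tau_at_bound")
  structure(list(asymptote_mM = unname(cf["a"]),
                 amplitude_mM = unname(cf["b"]), tau_s = unname(cf["tau"]),
                 resid_sd_mM = stats::sd(stats::resid(fit)),
                 converged = TRUE, flags = flags),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exp fit: asymptote %.2f mM, amplitude %.2f mM, tau %.1f s%s\n",
              x$asymptote_mM, x$amplitude_mM, x$tau_s,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Normalized recovery measures
#'
#' Two conventions, both returned: (i) the chloride level normalized to the
#' peak reached during loading, \[Cl\]i(t)/peak; and (ii) the fraction of
#' the load eliminated, (peak - \[Cl\]i(t))/(peak - baseline).
#'
#' @param time_s,cl_mM The recovery time course.
#' @param t_s Time at which to evaluate (interpolated between probes).
#' @param baseline_mM Pre-load baseline chloride (mM).
#' @param peak_mM Peak chloride at the end of loading (mM); must exceed the
#'   baseline.
#' @return List with `normalized_level` and `fraction_recovered`.
#' @export
recovery_fraction <- function(time_s, cl_mM, t_s, baseline_mM, peak_mM) {
  if (peak_mM <= baseline_mM) stop("peak_mM must exceed baseline_mM")
  cl_t <- interpolate_at(time_s, cl_mM, t_s)
  list(normalized_level = cl_t / peak_mM,
       fraction_recovered = (peak_mM - cl_t) / (peak_mM - baseline_mM))
}

#' Linear interpolation within a probe series
#'
#' Probes fall at slightly different times in different cells; comparisons
#' at common times use linear interpolation between the two bracketing
#' probes. Extrapolation beyond the series is an error.
#'
#' @param time_s Probe times, strictly increasing.
#' @param cl_mM Values at the probes.
#' @param t_s Target time(s), inside `range(time_s)`.
#' @return Interpolated value(s) (mM).
#' @export
interpolate_at <- function(time_s, cl_mM, t_s) {
  if (any(t_s < min(time_s) | t_s > max(time_s)))
    stop("t_s outside the probe time range; extrapolation not supported")
  stats::approx(time_s, cl_mM, xout = t_s, rule = 1)$y
}

#' Perturbation bound for a probe application
#'
#' Each probe application of agonist transfers charge; the implied chloride
#' concentration change Q / (F v_equ) must stay small (the protocols aim
#' for < 1 mM) for probes to be non-perturbing. Probes applied near E_Cl
#' transfer almost no charge.
#'
#' @param q_C Integrated agonist charge of one probe (C).
#' @param v_equ_L Equivalent cytosolic volume (L).
#' @return Bound on the \[Cl\]i change (mM).
#' @export
probe_perturbation_bound <- function(q_C, v_equ_L) {
  stopifnot(v_equ_L > 0)
  abs(q_C) / (.FARADAY * v_equ_L) * 1000
}
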