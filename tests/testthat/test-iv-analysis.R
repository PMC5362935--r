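test_that("series-resistance correction applies V = v_cmd - i*Rs", {
  sw <- manual_sweep(0:2 * 1e-4, c(-14, -14, -14), c(1000, 0, -500))
  expect_equal(correct_series_resistance(sw, 20), c(-34, -14, -4))
  expect_equal(correct_series_resistance(sw, 0), sw$v_cmd_mV)
  expect_error(correct_series_resistance(sw, -1))
})

test_that("correction recovers the generator's internal membrane voltage", {
  p <- make_protocol("gcl_estimation")
  cell <- std_cell(noise_sd_pA = 0)
  sw <- simulate_sweep(cell, p, couple_cl_dynamics = TRUE, seed = 4)
  v <- correct_series_resistance(sw, cell$rs_Mohm)
  expect_lt(max(abs(v - attr(sw, "truth")$v_m_mV)), 1e-6)
})

test_that("ramp re-gridding reproduces an ohmic line and cancels antisymmetric offsets", {
  p <- make_protocol("gcl_estimation")
  p$agonist_windows <- p$agonist_windows[0, ]
  cell <- synthetic_cell(leak = list(form = "linear", g_nS = 1, e_rev_mV = 0),
                         g_cl_rest_nS = 0, rs_Mohm = 0, noise_sd_pA = 0)
  sw <- simulate_sweep(cell, p, seed = 1)
  iv <- build_iv_from_ramp(sw, sw$v_cmd_mV, c(0, 12))
  expect_lt(max(abs(iv$i_pA - iv$v_mV)), 1e-9)

  # equal and opposite offsets on up/down limbs average out in shared bins
  dirn <- sign(c(diff(sw$v_cmd_mV)[1], diff(sw$v_cmd_mV)))
  sw2 <- sw; sw2$i_pA <- sw$i_pA + 30 * dirn
  iv2 <- build_iv_from_ramp(sw2, sw2$v_cmd_mV, c(1, 11))
  expect_lt(max(abs(iv2$i_pA - iv2$v_mV)), 0.5)
  up <- build_iv_from_ramp(sw2, sw2$v_cmd_mV, c(1, 11), direction = "up")
  expect_equal(mean(up$i_pA - up$v_mV), 30, tolerance = 0.05)

  # an 80 mV ramp cycle at 1.6 V/s and 10 kHz leaves plenty of samples
  expect_gt(sum(iv$n), 500)
  expect_error(build_iv_from_ramp(sw, sw$v_cmd_mV, c(0, 5e-4)))
})

test_that("leak fitting recovers exponential parameters and degenerates gracefully", {
  v <- seq(-114, -14, by = 1)
  gen <- function(a, b, cc) a + b * exp(v / cc)
  iv <- structure(data.frame(v_mV = v, i_pA = gen(-10, 2, 20), n = 100L),
                  class = c("iv_curve", "data.frame"))
  fit <- fit_leak_model(iv, "exponential")
  expect_equal(unname(fit$coef["a_pA"]), -10, tolerance = 0.01)
  expect_equal(unname(fit$coef["b_pA"]), 2, tolerance = 0.01)
  expect_equal(unname(fit$coef["c_mV"]), 20, tolerance = 0.01)

  # linear data under the exponential form: the bounded |C| <= 200 mV fit is
  # the near-linear limit; predictions match within the 5 pA noise floor
  ivl <- structure(data.frame(v_mV = v, i_pA = v, n = 100L),
                   class = c("iv_curve", "data.frame"))
  fexp <- fit_leak_model(ivl, "exponential")
  expect_lt(max(abs(predict(fexp, v) - v)), 5)

  flin <- fit_leak_model(ivl, "linear")
  expect_equal(unname(flin$coef["slope_nS"]), 1, tolerance = 1e-9)
  expect_equal(unname(flin$coef["intercept_pA"]), 0, tolerance = 1e-9)

  expect_error(fit_leak_model(ivl[1:5, ], "linear"))
})

test_that("model-based leak subtraction is exact on its own leak and identity for zero leak", {
  v <- seq(-94, -54, by = 1)
  leak <- structure(list(form = "exponential",
                         coef = c(a_pA = -10, b_pA = 2, c_mV = 20),
                         domain_mV = range(v), resid_sd_pA = 0,
                         converged = TRUE, fallback = FALSE),
                    class = "leak_model")
  iv <- structure(data.frame(v_mV = v, i_pA = predict(leak, v), n = 10L),
                  class = c("iv_curve", "data.frame"))
  out <- subtract_leak(iv, leak)
  expect_true(all(abs(out$i_pA) < 1e-12))
  expect_true(attr(out, "leak_subtracted"))

  zero <- structure(list(form = "linear",
                         coef = c(slope_nS = 0, intercept_pA = 0),
                         domain_mV = c(-200, 100), resid_sd_pA = 0,
                         converged = TRUE, fallback = FALSE),
                    class = "leak_model")
  expect_equal(subtract_leak(iv, zero)$i_pA, iv$i_pA)

  far <- iv; far$v_mV <- far$v_mV + 60
  expect_warning(subtract_leak(far, leak))
  expect_error(subtract_leak(far, leak, on_extrapolation = "error"))
})

test_that("leak subtraction on generator output recovers the agonist conductance", {
  # with Rs = 0 and no noise the subtracted curve is g_ag*(V - E_Cl)
  p <- make_protocol("gcl_estimation")
  cell <- std_cell(rs_Mohm = 0, noise_sd_pA = 0, cl_i_mM = 9)
  sw <- simulate_sweep(cell, p, seed = 1)
  v <- correct_series_resistance(sw, 0)
  w <- p$agonist_windows[1, ]   # probe in rest1
  leak_iv <- build_iv_from_ramp(sw, v, c(0, w$start_s - 0.1))
  leak <- fit_leak_model(leak_iv, "exponential")
  ag <- build_iv_from_ramp(sw, v, c(w$end_s - 1, w$end_s))
  ag <- subtract_leak(ag, leak)
  e_cl <- nernst(9)
  g_ag <- w$g_ag_nS
  expect_lt(max(abs(ag$i_pA - g_ag * (ag$v_mV - e_cl))), 1)
  # and the extracted reversal sits within a grid step of the set E_Cl
  expect_equal(estimate_reversal_potential(ag), e_cl, tolerance = 1)
})

test_that("reversal extraction interpolates the zero crossing", {
  v <- seq(-50, 10, by = 1)
  iv <- structure(data.frame(v_mV = v, i_pA = v, n = 1L),
                  class = c("iv_curve", "data.frame"))
  expect_equal(estimate_reversal_potential(iv), 0)
  iv$i_pA <- 1 * (v + 22.7)
  expect_equal(estimate_reversal_potential(iv), -22.7)
  iv$i_pA <- v + 100
  expect_error(estimate_reversal_potential(iv))
  # multiple crossings: local regression around the median crossing, warned
  vv <- seq(-30, -10, by = 1)
  ii <- vv + 20
  ii[vv == -24] <- 0.3; ii[vv == -23] <- -0.2   # two spurious crossings
  ivm <- structure(data.frame(v_mV = vv, i_pA = ii, n = 1L),
                   class = c("iv_curve", "data.frame"))
  expect_warning(e <- estimate_reversal_potential(ivm))
  expect_equal(e, -20, tolerance = 2.5)
})

test_that("slope conductance is an OLS slope and matches analytic derivatives", {
  v <- seq(-94, -54, by = 1)
  iv <- structure(data.frame(v_mV = v, i_pA = v, n = 1L),
                  class = c("iv_curve", "data.frame"))
  # ohmic curve: invariant to window choice
  expect_equal(estimate_slope_conductance(iv, center_mV = -74), 1)
  expect_equal(estimate_slope_conductance(iv, center_mV = -74, halfwidth_mV = 5), 1)
  expect_equal(estimate_slope_conductance(iv, window_mV = c(-90, -60)), 1)
  expect_error(estimate_slope_conductance(iv, window_mV = c(-54.5, -54)))

  # exponential leak: local slope approximates (B/C) exp(V/C)
  vv <- seq(-76, -72, by = 0.2)
  ive <- structure(data.frame(v_mV = vv, i_pA = -10 + 2 * exp(vv / 20), n = 1L),
                   class = c("iv_curve", "data.frame"))
  expect_equal(estimate_slope_conductance(ive, center_mV = -74, halfwidth_mV = 2),
               2 / 20 * exp(-74 / 20), tolerance = 0.01)
})

test_that("synthetic resting conductance is recovered within 5%", {
  p <- make_protocol("gcl_estimation")
  p$agonist_windows <- p$agonist_windows[0, ]
  cell <- std_cell(g_t_nS = 0.48, noise_sd_pA = 0)
  sw <- simulate_sweep(cell, p, seed = 1)
  v <- correct_series_resistance(sw, cell$rs_Mohm)
  iv <- build_iv_from_ramp(sw, v, c(0, 12))
  g <- estimate_slope_conductance(iv, center_mV = -74)
  expect_equal(g, 0.48, tolerance = 0.05)
})

test_that("Nernst relations are exact, inverse and monotone", {
  ctx <- nernst_context(cl_o_mM = 146.4, temp_K = 295)
  expect_equal(nernst(146.4, ctx), 0)
  expect_equal(nernst(60, ctx), -22.67, tolerance = 0.005)
  for (x in c(1, 9, 60, 146.4))
    expect_equal(cl_from_potential(nernst(x, ctx), ctx), x, tolerance = 1e-12)
  cl <- seq(1, 150, by = 1)
  expect_true(all(diff(nernst(cl, ctx)) > 0))
  e <- seq(-100, 10, by = 1)
  expect_true(all(diff(cl_from_potential(e, ctx)) > 0))
  # fixed offset shifts potentials additively
  ctx2 <- nernst_context(146.4, 295, offset_mV = -4)
  expect_equal(nernst(60, ctx2), nernst(60, ctx) - 4)
  expect_error(nernst(-1, ctx))
})

test_that("solution chloride is the stoichiometric sum over salts", {
  expect_equal(solution_chloride(c(NaCl = 137, KCl = 5, CaCl2 = 1, MgCl2 = 1.2)),
               146.4)
  expect_equal(solution_chloride(c(NaCl = 150, KCl = 5, CaCl2 = 2, MgCl2 = 1.2)),
               161.4)
  expect_equal(solution_chloride(list()), 0)
  expect_error(solution_chloride(c(NaGluconate = 140)))
})
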