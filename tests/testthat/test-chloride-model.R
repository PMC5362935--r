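test_that("KCC2 driving force follows the summed chemical potentials", {
  # at thermodynamic equilibrium the logs cancel
  eq <- cell_state(cl_i_mM = 146.4 * 5 / 145, k_i_mM = 145, k_o_mM = 5)
  expect_equal(kcc2_driving_force(eq), 0, tolerance = 1e-9)

  st <- loaded_state(cl_i_mM = 60)
  expect_equal(kcc2_driving_force(st), 6.07e3, tolerance = 0.002)

  # doubling both chloride concentrations leaves the ratio unchanged
  st2 <- st; st2$cl_i_mM <- 120; st2$cl_o_mM <- 292.8
  expect_equal(kcc2_driving_force(st2), kcc2_driving_force(st))
})

test_that("single Euler steps match direct evaluation of the flux laws", {
  st <- loaded_state(cl_i_mM = 60)
  expect_equal(kcc2_step(st, 0.05), -4.07e-3, tolerance = 0.002)
  expect_equal(conductive_step(st, 0.05), -2.87e-3, tolerance = 0.002)

  # signs: outward KCC2 transport for positive driving force; conductive
  # loading whenever V_m is above E_Cl
  expect_lt(kcc2_step(st, 0.05), 0)
  st_dep <- loaded_state(cl_i_mM = 60, v_m_mV = -14)   # V_m > E_Cl = -22.7
  expect_gt(conductive_step(st_dep, 0.05), 0)
  eq <- st; eq$cl_i_mM <- cl_from_potential(-74, nernst_context())
  eq$v_m_mV <- -74
  expect_equal(conductive_step(eq, 0.05), 0, tolerance = 1e-12)
})

test_that("long simulations settle at the closed-form steady states", {
  st <- loaded_state(cl_i_mM = 60)
  cond <- simulate_cl(st, duration_s = 4000, modes = "conductive")
  expect_equal(tail(cond$e_cl_mV, 1), -74, tolerance = 0.5)
  kcc2 <- simulate_cl(st, duration_s = 4000, modes = "kcc2")
  expect_equal(tail(kcc2$cl_mM, 1), 146.4 * 5 / 145, tolerance = 0.02)

  ss_c <- steady_state_cl(st, "conductive")
  ss_k <- steady_state_cl(st, "kcc2")
  expect_equal(ss_c, 146.4 * exp(-74 / (1000 * 8.314 * 295 / 96485)),
               tolerance = 1e-9)
  expect_equal(ss_c, 7.96, tolerance = 0.01)
  expect_equal(ss_k, 5.048, tolerance = 0.001)

  # combined: strictly between the single-mode fixed points, monotone in g_Cl
  ss_b <- steady_state_cl(st)
  expect_gt(ss_b, min(ss_c, ss_k)); expect_lt(ss_b, max(ss_c, ss_k))
  ss_by_g <- vapply(c(0.02, 0.054, 0.15, 0.4), function(g) {
    s <- st; s$g_cl_nS <- g; steady_state_cl(s)
  }, numeric(1))
  expect_true(all(diff(ss_by_g) > 0))
})

test_that("combined recovery is faster than either mechanism alone", {
  st <- loaded_state(cl_i_mM = 60)
  both <- simulate_cl(st, 1200, modes = c("kcc2", "conductive"))
  kcc2 <- simulate_cl(st, 1200, modes = "kcc2")
  cond <- simulate_cl(st, 1200, modes = "conductive")
  # flux additivity: the combined trajectory undercuts the conductive-only
  # one everywhere (its steady state is lower), and the KCC2-only one for
  # as long as both still sit above the combined steady state - at late
  # times KCC2 alone keeps extruding below it, so the curves cross
  expect_true(all(both$cl_mM[-1] <= cond$cl_mM[-1] + 1e-12))
  above <- kcc2$cl_mM > steady_state_cl(st) + 0.5
  expect_true(all(both$cl_mM[above][-1] <= kcc2$cl_mM[above][-1] + 1e-12))
  expect_lt(min(both$cl_mM - pmin(kcc2$cl_mM, cond$cl_mM)), 0)
})

test_that("per-step bookkeeping and charge conservation hold", {
  st <- loaded_state(cl_i_mM = 60)
  sim <- simulate_cl(st, 300, modes = c("kcc2", "conductive"))
  n <- nrow(sim)
  # total change per step equals the sum of component changes
  expect_equal(diff(sim$cl_mM), (sim$d_kcc2_mM + sim$d_cond_mM)[-n],
               tolerance = 1e-12)
  # F * v_equ * (conductive concentration change) equals the integral of I
  i_pA <- st$g_cl_nS * (st$v_m_mV - sim$e_cl_mV)
  q_int <- sum(i_pA[-n]) * attr(sim, "dt_s") * 1e-12
  q_conc <- 96485 * st$v_equ_L * sum(sim$d_cond_mM) / 1000
  expect_equal(q_conc, q_int, tolerance = 1e-6)
})

test_that("single-mode trajectories approach their fixed points monotonically", {
  for (start in c(60, 2)) {
    st <- loaded_state(cl_i_mM = start)
    for (m in c("kcc2", "conductive")) {
      sim <- simulate_cl(st, 600, modes = m)
      d <- diff(sim$cl_mM)
      expect_true(all(d >= -1e-12) || all(d <= 1e-12))
    }
  }
})

test_that("the 50 ms Euler step tracks a 1 ms reference within 1%", {
  st <- loaded_state(cl_i_mM = 60)
  coarse <- simulate_cl(st, 600, dt_s = 0.05)
  fine <- simulate_cl(st, 600, dt_s = 0.001)
  common <- seq(0, 600, by = 1)
  a <- approx(coarse$time_s, coarse$cl_mM, xout = common)$y
  b <- approx(fine$time_s, fine$cl_mM, xout = common)$y
  expect_lt(max(abs(a - b)) / diff(range(b)), 0.01)
})

test_that("the Euler model matches an independent adaptive ODE solution", {
  library(deSolve)
  st <- loaded_state(cl_i_mM = 60)
  rhs <- function(t, y, parms) {
    cl <- y[1]
    nern <- 1000 * 8.314 * 295 / 96485
    e_cl <- nern * log(cl / 146.4)
    dk <- -8.314 * 295 * (log(cl / 146.4) + log(145 / 5)) *
      st$g_kcc2 / st$v_equ_L * 1000
    dc <- st$g_cl_nS * (st$v_m_mV - e_cl) * 1e-12 / (96485 * st$v_equ_L) * 1000
    list(dk + dc)
  }
  ref <- ode(c(cl = 60), seq(0, 900, by = 5), rhs, NULL, method = "lsoda",
             rtol = 1e-8, atol = 1e-10)
  sim <- simulate_cl(st, 900, dt_s = 0.05)
  mine <- approx(sim$time_s, sim$cl_mM, xout = ref[, "time"])$y
  expect_lt(max(abs(mine - ref[, "cl"])) / diff(range(ref[, "cl"])), 0.01)
})

test_that("recovery half-time decreases strictly with chloride conductance", {
  half_time <- function(g) {
    st <- loaded_state(cl_i_mM = 60, g_cl_nS = g)
    ss <- steady_state_cl(st)
    sim <- simulate_cl(st, 2500, modes = c("kcc2", "conductive"))
    sim$time_s[min(which(sim$cl_mM <= 60 - (60 - ss) / 2))]
  }
  ht <- vapply(c(0.02, 0.054, 0.15, 0.4), half_time, numeric(1))
  expect_true(all(diff(ht) < 0))
})

test_that("time-varying schedules load and a mini train adds conductance", {
  st <- cell_state(cl_i_mM = 9, g_cl_nS = 0.054, g_kcc2 = 0)
  # depolarized loading phase then recovery at -74 mV
  vm <- function(t) ifelse(t < 300, -14, -74)
  sim <- simulate_cl(st, 1200, modes = "conductive", v_m = vm, g_cl = 2)
  peak <- max(sim$cl_mM)
  expect_gt(peak, 40)
  expect_lt(tail(sim$cl_mM, 1), peak)

  train <- simulate_mini_train(rate_Hz = 10, g_peak_nS = 0.5, duration_s = 300,
                               dt_s = 0.05, seed = 2)
  g_fun <- approxfun(train$time_s, 0.054 + train$g_nS, rule = 2)
  with_minis <- simulate_cl(loaded_state(60), 300, modes = "conductive",
                            g_cl = g_fun)
  without <- simulate_cl(loaded_state(60), 300, modes = "conductive")
  expect_lt(tail(with_minis$cl_mM, 1), tail(without$cl_mM, 1))
})

test_that("positivity violations abort with a diagnostic", {
  st <- loaded_state(cl_i_mM = 0.05, g_cl_nS = 50, v_m_mV = -200)
  expect_error(simulate_cl(st, 100, dt_s = 10, modes = "conductive"),
               "smaller dt_s")
})

test_that("equivalent volume bookkeeping is exact and matches cell geometry", {
  expect_equal(equivalent_volume(2.46e-9, 51), 5.0e-13, tolerance = 0.001)
  expect_equal(charge_for_load(equivalent_volume(2.46e-9, 51), 51), 2.46e-9)
  for (q in c(1e-10, 2.46e-9)) {
    v <- equivalent_volume(q, 51)
    expect_equal(charge_for_load(v, 51), q, tolerance = 1e-12)
  }
  expect_equal(cytosol_volume_L(6.2), 4.99e-13, tolerance = 0.001)
  expect_error(equivalent_volume(1e-9, 0))
})
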