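test_that("scheme derivatives match the mechanism and conserve mass", {
  p <- rate_parameters(k_on = 1.72e6, k_off = 7.50e-4)

  # no inhibitor: binding flux zero, product flux Michaelis-Menten
  st0 <- assay_state(E_free = 0.5e-9, I_free = 0, S = 500e-6)
  d0 <- scheme_rhs("one_step", p, st0)
  expect_identical(unname(d0["EI"]), 0)
  expect_equal(unname(d0["P"]), p$k_cat * 0.5e-9 * 500e-6 / (200e-6 + 500e-6))

  # hand arithmetic at S = 0 (no substrate protection term)
  st <- assay_state(E_free = 0.5e-9, I_free = 10e-9, EI = 2e-10, S = 0)
  d <- scheme_rhs("one_step", p, st)
  expect_equal(unname(d["EI"]),
               1.72e6 * 0.5e-9 * 10e-9 - 7.50e-4 * 2e-10)

  # two-step with zero isomerisation reduces to one-step
  d2 <- scheme_rhs("two_step", p, st)
  expect_identical(d2, d)

  # conservation of the derivative combinations, over random states
  set.seed(1)
  for (i in 1:25) {
    pp <- rate_parameters(k_on = 10^runif(1, 2, 7),
                          k_off = 10^runif(1, -5, -1),
                          k_isom_f = 10^runif(1, -4, -1),
                          k_isom_r = 10^runif(1, -4, -1))
    ss <- assay_state(E_free = runif(1, 0, 1e-9), I_free = runif(1, 0, 5e-8),
                      EI = runif(1, 0, 1e-9), EI_star = runif(1, 0, 1e-9),
                      S = runif(1, 0, 1e-3), P = runif(1, 0, 1e-4))
    dd <- scheme_rhs("two_step", pp, ss)
    tol <- 1e-12 * max(abs(dd))  # cancellation at machine precision
    expect_lt(abs(dd[["E_free"]] + dd[["EI"]] + dd[["EI_star"]]), tol)
    expect_lt(abs(dd[["I_free"]] + dd[["EI"]] + dd[["EI_star"]]), tol)
    expect_identical(unname(dd["S"] + dd["P"]), 0)
    expect_gte(unname(dd["P"]), 0)
  }

  expect_error(assay_state(E_free = -1e-9, I_free = 0, S = 1e-4),
               "negative")
  expect_error(rate_parameters(k_on = 1e6, K_m = 0), "K_m")
  expect_error(scheme_rhs("irreversible", p, st), "k_off")
})

test_that("simulated progress curves are monotone, conservative, and linear without inhibitor", {
  # zero-order regime: S0 >> Km, no inhibitor, short horizon
  p <- rate_parameters(k_on = 1e6, k_off = 1e-3, k_cat = 10, K_m = 1e-7)
  cond <- assay_conditions(E_total = 0.5e-9, I_total = 0, S_0 = 500e-6,
                           times = seq(0, 60, 1))
  cv <- simulate_progress("one_step", p, cond)
  slope <- p$k_cat * 0.5e-9
  expect_lt(max(abs(cv$product_M[-1] - slope * cv$time_s[-1]) /
                  (slope * cv$time_s[-1])), 1e-3)
  expect_identical(cv$product_M[1], 0)
  expect_true(all(diff(cv$product_M) >= 0))
  expect_lt(conservation_error(cv), 1e-9)

  # monotone product for assorted parameter sets
  set.seed(7)
  for (i in 1:5) {
    pp <- rate_parameters(k_on = 10^runif(1, 4, 7), k_off = 10^runif(1, -4, -2))
    cc <- assay_conditions(E_total = 1e-9, I_total = runif(1, 0, 5e-8),
                           times = seq(0, 900, 5))
    sim <- simulate_progress("one_step", pp, cc)
    expect_true(all(diff(sim$product_M) >= -1e-15))
    expect_lt(conservation_error(sim), 1e-9)
  }
})

test_that("ODE agrees with the closed-form slow-binding oracle in the excess-inhibitor limit", {
  p <- rate_parameters(k_on = 1.72e6, k_off = 7.50e-4)
  E <- 0.5e-9
  I <- 100e-9   # 200x enzyme: negligible inhibitor depletion
  S0 <- 500e-6
  cond <- assay_conditions(E_total = E, I_total = I, S_0 = S0,
                           times = seq(0, 1800, 2))
  cv <- simulate_progress("one_step", p, cond)
  expect_lt(max(cv$product_M) / S0, 0.05)  # depletion < 5% precondition
  k_obs <- kobs_one_step(p, I, S0)
  v0 <- p$k_cat * E * S0 / (p$K_m + S0)
  vs <- v0 * p$k_off / k_obs
  mw <- morrison_walsh_curve(v0, vs, k_obs, cond$times)
  expect_lt(max(abs(cv$product_M[-1] - mw[-1]) / mw[-1]), 0.01)
})

test_that("irreversible scheme saturates to bound inhibitor and residual velocity", {
  # inhibitor sub-stoichiometric so free enzyme persists
  p <- rate_parameters(k_on = 1e7, k_off = 0)
  E <- 1e-9
  I <- 0.4e-9
  cond <- assay_conditions(E_total = E, I_total = I,
                           times = seq(0, 3600, 10))
  cv <- simulate_progress("irreversible", p, cond)
  st <- attr(cv, "states")
  n <- nrow(st)
  expect_equal(st$EI[n], min(E, I), tolerance = 1e-3)
  v_resid <- p$k_cat * (E - I) * st$S[n] / (p$K_m + st$S[n])
  slope_end <- (cv$product_M[n] - cv$product_M[n - 1]) / 10
  expect_equal(slope_end, v_resid, tolerance = 1e-3)
})

test_that("two-step trajectories with zero isomerisation equal one-step bit for bit", {
  p <- rate_parameters(k_on = 1e6, k_off = 1e-3, k_isom_f = 0, k_isom_r = 0)
  cond <- assay_conditions(E_total = 0.5e-9, I_total = 2e-8,
                           times = seq(0, 600, 1))
  a <- simulate_progress("one_step", p, cond)
  b <- simulate_progress("two_step", p, cond)
  expect_identical(a$product_M, b$product_M)
})

test_that("kobs closed form: limits and hand arithmetic", {
  p <- rate_parameters(k_on = 1.26e4, k_off = 2.35e-2)
  expect_identical(kobs_one_step(p, 0, 0), p$k_off)
  expect_equal(kobs_one_step(p, 1e-6, 0), 3.61e-2, tolerance = 1e-3)
  # full substrate protection
  expect_equal(kobs_one_step(p, 1e-6, 1e6 * p$K_m), p$k_off,
               tolerance = 1e-5)
  expect_gte(kobs_one_step(p, 1e-8, 1e-4), p$k_off)
})

test_that("closed-form slow-binding curve: line, limit form, hand value, asymptote", {
  times <- seq(0, 1000, 10)
  expect_equal(morrison_walsh_curve(2e-9, 2e-9, 0.02, times), 2e-9 * times)
  expect_equal(morrison_walsh_curve(2e-9, 1e-10, 0, times), 2e-9 * times)
  expect_equal(morrison_walsh_curve(1e-9, 0, 0.01, 100),
               1e-7 * (1 - exp(-1)))
  expect_equal(morrison_walsh_curve(1e-9, 0, 0.01, 100), 6.321e-8,
               tolerance = 1e-4)
  # late-time slope approaches vs
  p <- morrison_walsh_curve(3e-9, 5e-10, 0.02, c(900, 1000))
  expect_equal(diff(p) / 100, 5e-10, tolerance = 1e-6)
})
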