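test_that("decoupled network poles are the leak rates", {
  p <- network_params(0, 1.2, 0.3)
  sys <- build_linear_system(p, "full")
  got <- sort(Re(sys$poles))
  want <- sort(-1 / c(0.02, 0.01, 0.005, 0.1, 0.005, 0.1, 0.01, 0.01))
  expect_equal(got, want, tolerance = 1e-9)
  expect_true(all(abs(Im(sys$poles)) < 1e-6))

  sysr <- build_linear_system(p, "reduced")
  expect_equal(sort(Re(sysr$poles)),
               sort(-1 / c(0.02, 0.005, 0.1, 0.005, 0.1)), tolerance = 1e-9)
})

test_that("stability report handles a constructed pole pair", {
  # rotation-form system with poles exactly -1 +- 2*pi*3 i
  om <- 2 * pi * 3
  sys <- linear_system(matrix(c(-1, -om, om, -1), 2, 2), B = c(1, 0),
                       C = c(1, 0))
  rep <- stability_report(sys)
  expect_true(rep$stable)
  expect_true(rep$oscillatory)
  expect_equal(rep$resonant_freq, 3, tolerance = 1e-9)
  expect_equal(rep$tau_n, 1, tolerance = 1e-9)

  unst <- stability_report(linear_system(diag(c(0.5, -3)), c(1, 1), c(1, 0)))
  expect_false(unst$stable)
  expect_true(is.na(unst$tau_n))
})

test_that("published stability verdicts hold at the canonical parameters", {
  expect_false(stability_report(
    build_linear_system(canonical_params(dq = -0.02), "full"))$stable)
  r5 <- stability_report(
    build_linear_system(canonical_params(dq = 0.05), "full"))
  expect_true(r5$stable)
  expect_false(r5$oscillatory)
  r1 <- stability_report(
    build_linear_system(canonical_params(dq = 0.1), "full"))
  expect_true(r1$stable)
  expect_gt(r1$tau_n, 1)          # seconds-range time constant
})

test_that("imaginary-axis crossings match the published critical values", {
  red <- find_imag_axis_crossing(canonical_params(), "reduced",
                                 "decreasing_dq")
  expect_equal(red$dq, -0.0425, tolerance = 0.01)

  full15 <- find_imag_axis_crossing(network_params(30, 1.5, 0.3), "full",
                                    "decreasing_dq")
  expect_equal(full15$dq, -0.0226, tolerance = 0.01)

  full12 <- find_imag_axis_crossing(canonical_params(), "full",
                                    "decreasing_dq")
  expect_gt(full12$dq, -0.02)          # dq = -0.02 is already unstable
  expect_equal(full12$frequency_hz, 2, tolerance = 0.3)

  gam <- find_imag_axis_crossing(canonical_params(), "full",
                                 "increasing_dq")
  expect_gt(gam$dq, 0.1)
  expect_lt(gam$dq, 0.15)
  expect_equal(gam$frequency_hz, 60, tolerance = 0.2)

  expect_error(find_imag_axis_crossing(canonical_params(), "full",
                                       bracket = c(0.0, 0.05)),
               "bracket")
})

test_that("critical damping sits between the instability and zero", {
  red <- find_critical_damping(canonical_params(), "reduced")
  expect_equal(red, -0.0095, tolerance = 0.02)
  full <- find_critical_damping(canonical_params(), "full")
  unst <- find_imag_axis_crossing(canonical_params(), "full",
                                  "decreasing_dq")$dq
  expect_lt(full, 0)
  expect_gt(full, unst)
})

test_that("rise time obeys the ln(9) law for single-pole dynamics", {
  one_pole <- linear_system(matrix(-1), B = 1, C = 1)
  expect_equal(rise_time(one_pole), log(9), tolerance = 1e-3)

  # dominant-eigenvalue regime of the full network
  sys <- build_linear_system(canonical_params(dq = 0.1), "full")
  rep <- stability_report(sys)
  others <- sys$poles[abs(sys$poles - rep$dominant_pole) > 1e-9]
  expect_gt(min(-Re(others)) / (1 / rep$tau_n), 5)
  expect_equal(rise_time(sys) / rep$tau_n, log(9), tolerance = 0.05)
})

test_that("published rise times are reproduced", {
  # slow NMDA-dominated network: seconds-range rise
  rt_slow <- rise_time(build_linear_system(canonical_params(dq = 0.1),
                                           "full"))
  expect_gt(rt_slow, 3)
  expect_lt(rt_slow, 6)
  # fastest critically damped configuration
  p_fast <- network_params(30, 1.2, 0.004, -0.003,
                           time_constants(tau_nmda = 0.4))
  expect_equal(rise_time(build_linear_system(p_fast, "full")) * 1e3,
               52.5, tolerance = 0.1)
})

test_that("trajectory rise times agree with linear-system rise times", {
  set.seed(3)
  checked <- 0
  for (p in random_params(40, seed = 31)) {
    sys <- build_linear_system(p, "full")
    rep <- stability_report(sys)
    if (!rep$stable || rep$tau_n > 1) next
    rt_lin <- rise_time(sys)
    ss <- as.numeric(sys$C %*% fixed_point(sys, 1))
    traj <- simulate_full(p, make_input("step", 1),
                          duration = max(1, 12 * rep$tau_n), dt = 2e-4,
                          rectify = FALSE)
    rt_sim <- rise_time(traj, steady_state = ss)
    expect_equal(rt_sim, rt_lin, tolerance = 0.01,
                 label = sprintf("w=%.1f k=%.2f q=%.2f dq=%.3f",
                                 p$w, p$k, p$q, p$dq))
    checked <- checked + 1
    if (checked >= 12) break
  }
  expect_gte(checked, 8)
})

test_that("transfer magnitude matches the one-pole low-pass closed form", {
  one_pole <- linear_system(matrix(-1), B = 2, C = 1)  # dc gain 2, tau 1 s
  tm <- transfer_magnitude(one_pole, c(0, 1 / (2 * pi), 10))
  expect_equal(tm$magnitude[1], 2)
  expect_equal(tm$magnitude[2], 2 / sqrt(2), tolerance = 1e-9)
  expect_lt(tm$magnitude[3], 0.05)
  expect_error(transfer_magnitude(
    linear_system(matrix(0.1), 1, 1), 1), "stable")
})

test_that("transfer peaks sit in the delta and gamma bands near the instabilities", {
  freqs <- seq(0.25, 90, by = 0.25)
  # slightly above the delta-side instability
  sys_d <- build_linear_system(canonical_params(dq = -0.016), "full")
  tm_d <- transfer_magnitude(sys_d, freqs)
  pk_d <- freqs[which.max(tm_d$magnitude)]
  expect_gte(pk_d, 1); expect_lte(pk_d, 4)
  # near the NMDA-side instability
  sys_g <- build_linear_system(canonical_params(dq = 0.14), "full")
  tm_g <- transfer_magnitude(sys_g, freqs)
  pk_g <- freqs[which.max(tm_g$magnitude)]
  expect_gt(pk_g, 30); expect_lt(pk_g, 80)
})

test_that("transfer peak agrees with the crossing frequency at the boundary", {
  cr <- find_imag_axis_crossing(canonical_params(), "full", "decreasing_dq")
  sys <- build_linear_system(
    network_params(30, 1.2, 0.3, cr$dq + 2e-4), "full")  # just inside
  freqs <- seq(0.2, 10, by = 0.05)
  tm <- transfer_magnitude(sys, freqs)
  expect_equal(freqs[which.max(tm$magnitude)], cr$frequency_hz,
               tolerance = 0.06)
})

test_that("rise time increases monotonically with dq on the overdamped branch", {
  gam <- find_imag_axis_crossing(canonical_params(), "full",
                                 "increasing_dq")$dq
  dqs <- seq(0, 0.9 * gam, length.out = 50)
  rts <- vapply(dqs, function(d)
    rise_time(build_linear_system(canonical_params(dq = d), "full")),
    numeric(1))
  expect_true(all(diff(rts) > 0))
})

test_that("sweep_map reports sentinels where no delta instability exists", {
  p <- canonical_params()
  m <- sweep_map(p, list(q = c(0.005, 0.3), tau_nmda = 0.1),
                 "critical_dq_unstable", "full")
  expect_true(is.na(m$value[m$q == 0.005]))
  expect_false(is.na(m$value[m$q == 0.3]))

  freqs <- sweep_map(p, list(q = c(0.2, 0.4), tau_nmda = c(0.1, 0.2)),
                     "resonant_freq", "full")
  ok <- !is.na(freqs$value)
  expect_true(all(freqs$value[ok] > 0.5 & freqs$value[ok] < 5))
})

test_that("longer NMDA decay speeds up the critically damped rise time", {
  p <- network_params(30, 1.2, 0.05)
  m <- sweep_map(p, list(q = 0.05, tau_nmda = c(0.1, 0.4)),
                 "critical_rise_time", "full")
  expect_lt(m$value[m$tau_nmda == 0.4], m$value[m$tau_nmda == 0.1])
})
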