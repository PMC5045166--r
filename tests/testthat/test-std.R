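test_that("depression derivative and fixed point are consistent", {
  # u = 0.2, tau_r = 0.5 s, R = 10 Hz -> x* = 0.5 and zero derivative
  expect_equal(std_fixed_point(0.2, 0.5, 10), 0.5)
  expect_equal(std_derivative(0.5, 0.2, 0.5, 10), 0)
  # no drive: pure recovery toward 1 at rate 1/tau_r
  expect_equal(std_derivative(0.4, 0.2, 0.5, 0), (1 - 0.4) / 0.5)
  # fully recovered synapse under drive can only depress
  expect_lt(std_derivative(1, 0.2, 0.5, 5), 0)
})

test_that("std parameter validation enforces the usage-rate bounds", {
  expect_error(std_params(u = 0.2, du = 0.3), "u - |du|", fixed = TRUE)
  expect_error(std_params(u = 0.9, du = 0.2), "u + |du|", fixed = TRUE)
  expect_error(std_params(tau_r = 0), "tau_r")
  expect_silent(std_params(0.2, -0.03, 0.5))
})

test_that("effective weights follow the receptor-specific depression", {
  w_full <- effective_weights(1, 1, 50, 1.2)
  expect_equal(w_full$jee_ampa, 25)
  expect_equal(w_full$jee_nmda, 25)
  expect_equal(w_full$jie_ampa, 25)
  expect_equal(w_full$jie_nmda, 25)

  w_dep <- effective_weights(0.4, 0.6, 50, 1.2)
  expect_equal(w_dep$jee_ampa, 10)
  expect_equal(w_dep$jee_nmda, 15)
  expect_equal(w_dep$jie_ampa, 12.5)
  expect_equal(w_dep$jie_nmda, 12.5)
  expect_equal(w_dep$jei, 60)

  # equal depression leaves the effective NMDA shift at zero
  pos <- effective_position(0.7, 0.7, 50)
  expect_equal(pos$dq_eff, 0)
  expect_equal(pos$we, 35)
  # the published spot check: x_nmda = 0.6, x_ampa = 0.4 -> dq_eff = 0.1
  expect_equal(effective_position(0.4, 0.6, 50)$dq_eff, 0.1)
  expect_error(effective_position(0, 0, 50), "undefined")
})

test_that("effective position is consistent with weight inversion", {
  for (x in list(c(0.9, 0.7), c(0.5, 0.6), c(1, 0.3))) {
    ww <- effective_weights(x[1], x[2], 50, 1.2)
    pos <- effective_position(x[1], x[2], 50)
    expect_equal(ww$jee_ampa + ww$jee_nmda, pos$we)
    expect_equal(ww$jee_nmda / (ww$jee_ampa + ww$jee_nmda) - 0.5,
                 pos$dq_eff)
  }
})

test_that("strength balance is preserved for any depression state", {
  set.seed(9)
  for (i in 1:50) {
    x <- runif(2, 0.05, 1)
    expect_lt(abs(balance_lhs(effective_weights(x[1], x[2], 50, 1.2))),
              1e-12 * 1.2 * 50^2)
  }
})

test_that("depressed simulation requires q = 0.5 and keeps x in bounds", {
  expect_error(simulate_rate_std(canonical_params(), std_params(),
                                 make_input("step", 1), 0.1),
               "q = 0.5")
  p <- network_params(50, 1.2, 0.5)
  tr <- simulate_rate_std(p, std_params(0.2, -0.02, 0.5),
                          make_input("pulse", 10, 0, 1,
                                     smoothing_sigma = 0.1),
                          duration = 1.4, dt = 2e-4)
  expect_true(all(tr$x_ampa >= 0 & tr$x_ampa <= 1))
  expect_true(all(tr$x_nmda >= 0 & tr$x_nmda <= 1))
  expect_true(all(tr$re >= 0))
})

test_that("constant drive brings x to the analytic fixed point", {
  # clamp the excitatory rate via a strong external drive is indirect;
  # instead drive the std subsystem through a network whose rate settles
  p <- network_params(50, 1.2, 0.5)
  s <- std_params(0.2, 0, 0.5)
  tr <- simulate_rate_std(p, s, make_input("step", 10, onset = 0,
                                           smoothing_sigma = 0.1),
                          duration = 8, dt = 2e-4)
  r_end <- tr$re[nrow(tr)]
  expect_equal(tr$x_ampa[nrow(tr)],
               std_fixed_point(0.2, 0.5, r_end), tolerance = 1e-4)
  expect_equal(tr$x_nmda[nrow(tr)],
               std_fixed_point(0.2, 0.5, r_end), tolerance = 1e-4)
})

test_that("du = 0 keeps the effective NMDA shift at zero throughout", {
  p <- network_params(50, 1.2, 0.5)
  tr <- simulate_rate_std(p, std_params(0.2, 0, 0.5),
                          make_input("pulse", 10, 0, 1,
                                     smoothing_sigma = 0.1),
                          duration = 1.2, dt = 2e-4)
  expect_equal(max(abs(tr$dq_eff)), 0, tolerance = 1e-12)
})

test_that("negative du destabilizes and positive du slows the pulse response", {
  p <- network_params(50, 1.2, 0.5)
  pulse <- make_input("pulse", 10, onset = 0, offset = 1,
                      smoothing_sigma = 0.1)
  # total variation over range of the 30 ms-smoothed response: ~1 for a
  # monotone-ish rise, well above 2 when a delta-band oscillation rides
  # on the pulse
  tv_ratio <- function(tr, t0, t1) {
    sel <- tr$time >= t0 & tr$time <= t1
    s <- stats::filter(tr$re[sel], rep(1, 301) / 301, sides = 2)
    s <- s[!is.na(s)]
    sum(abs(diff(s))) / diff(range(s))
  }
  # du < 0: NMDA depresses harder, effective dq goes negative, and a
  # growing delta-band oscillation develops during the pulse
  tr_neg <- simulate_rate_std(p, std_params(0.2, -0.03, 0.5), pulse,
                              duration = 1.05, dt = 1e-4, bound = 1e7)
  expect_lt(min(tr_neg$dq_eff), -0.02)
  expect_gt(tv_ratio(tr_neg, 0.2, 1), 2)

  # du > 0: slow, essentially oscillation-free rise
  tr_pos <- simulate_rate_std(p, std_params(0.2, 0.03, 0.5), pulse,
                              duration = 1.05, dt = 1e-4)
  expect_gt(max(tr_pos$dq_eff), 0.02)
  expect_lt(tv_ratio(tr_pos, 0.2, 1), 1.6)
  i30 <- which.min(abs(tr_pos$time - 0.3))
  i75 <- which.min(abs(tr_pos$time - 0.75))
  expect_gt(tr_pos$re[i75], tr_pos$re[i30])   # still rising late in pulse
})

test_that("instantaneous linearization tracks the nonlinear oscillation onset", {
  p <- network_params(50, 1.2, 0.5)
  pulse <- make_input("pulse", 10, onset = 0, offset = 1,
                      smoothing_sigma = 0.1)
  tr <- simulate_rate_std(p, std_params(0.2, -0.03, 0.5), pulse,
                          duration = 1.0, dt = 1e-4, bound = 1e7)
  lin <- instantaneous_linearization(tr, every = 0.01, rise_times = FALSE)
  # starts at the balanced point: dq_eff = 0, stable
  expect_equal(lin$dq_eff[1], 0)
  expect_true(lin$stable[1])
  # the frozen systems cross into the instability region early in the
  # pulse, and the nonlinear trajectory oscillates after the crossing
  expect_true(any(!lin$stable))
  t_cross <- lin$time[which(!lin$stable)[1]]
  expect_lt(t_cross, 0.3)
  sel <- tr$time >= t_cross & tr$time <= 1
  s <- stats::filter(tr$re[sel], rep(1, 301) / 301, sides = 2)
  s <- s[!is.na(s)]
  expect_gt(sum(abs(diff(s))) / diff(range(s)), 2)
})

test_that("instantaneous linearization at full efficacy matches the static net", {
  p <- network_params(50, 1.2, 0.5)
  tr <- simulate_rate_std(p, std_params(0.2, -0.03, 0.5),
                          make_input("zero"), duration = 0.02, dt = 1e-4)
  lin <- instantaneous_linearization(tr, every = 0.01)
  static <- stability_report(build_linear_system(p, "full"))
  expect_equal(lin$we[1], 50)
  expect_equal(lin$dq_eff[1], 0)
  expect_equal(lin$stable[1], static$stable)
  expect_equal(lin$rise_time[1],
               rise_time(build_linear_system(p, "full")), tolerance = 1e-6)
})

test_that("positive du keeps the frozen networks slow relative to balanced depression", {
  # with du > 0 the effective NMDA surplus slows every frozen network
  # well beyond its balanced (du = 0) counterpart at the same time point
  p <- network_params(50, 1.2, 0.5)
  pulse <- make_input("pulse", 10, onset = 0, offset = 1,
                      smoothing_sigma = 0.1)
  tr0 <- simulate_rate_std(p, std_params(0.2, 0, 0.5), pulse,
                           duration = 1.0, dt = 2e-4)
  trp <- simulate_rate_std(p, std_params(0.2, 0.03, 0.5), pulse,
                           duration = 1.0, dt = 2e-4)
  l0 <- instantaneous_linearization(tr0, every = 0.1)
  lp <- instantaneous_linearization(trp, every = 0.1)
  expect_true(all(lp$stable))
  during <- l0$time >= 0.1 & l0$time <= 1
  expect_true(all(lp$rise_time[during] > 2 * l0$rise_time[during]))
})
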