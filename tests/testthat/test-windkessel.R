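test_that("Windkessel integration matches analytic decay and fixed point", {
  p <- windkessel_params(1e8, 1e-8)      # tau = 1 s
  zero <- flow_rate_waveform(c(0, 0.5), c(0, 0), 1)
  s <- wk2_integrate(zero, p, 80)
  expect_equal(s$pressure_mmHg[nrow(s)], 80 * exp(-1), tolerance = 1e-9)

  q0 <- 6e-5
  const <- flow_rate_waveform(c(0, 0.5), c(q0, q0), 1)
  s2 <- wk2_integrate(const, p, 0, t_span = c(0, 10))
  expect_equal(s2$pressure_mmHg[nrow(s2)], q0 * 1e8 / 133.322,
               tolerance = 1e-4)
  expect_error(wk2_integrate(zero, p, 80, dt = 0.1), "period/1000")
})

test_that("numeric periodic solution matches the closed form to 1e-6", {
  R <- 2.0e8; C <- 9e-9
  fl <- std_flow()
  per <- wk2_periodic(fl, windkessel_params(R, C), dt = 1 / 4000)
  oracle <- wk2_closed_form(3.4e-4, 0.3, 1, R, C)
  pa <- per$pressure_mmHg * 133.322
  ref <- oracle$P(per$time_s)
  expect_lt(max(abs(pa - ref)) / max(abs(ref)), 1e-5)
  expect_equal(attr(per, "P0_mmHg") * 133.322, oracle$P0,
               tolerance = 1e-5)
})

test_that("periodic solution obeys the mean identity and diastolic decay", {
  R <- 2.0e8; C <- 9e-9
  oracle <- wk2_closed_form(3.4e-4, 0.3, 1, R, C)
  meanQ <- 3.4e-4 * 2 * 0.3 / pi   # analytic mean of the sinusoidal systole
  expect_equal(oracle$mean, R * meanQ, tolerance = 1e-10)

  # numeric waveform: diastolic segment is a pure exponential decay
  per <- wk2_periodic(std_flow(), windkessel_params(R, C), dt = 1 / 4000)
  dia <- per[per$time_s >= 0.35 & per$time_s <= 0.95, ]
  pred <- dia$pressure_mmHg[1] *
    exp(-(dia$time_s - dia$time_s[1]) / (R * C))
  expect_lt(max(abs(dia$pressure_mmHg - pred) / pred), 1e-6)
})

test_that("calibration hits the (80, 120) mmHg targets on the standard flow", {
  wk <- wk2_calibrate(std_flow(), 80, 120)
  per <- attr(wk, "waveform")
  expect_equal(min(per$pressure_mmHg), 80, tolerance = 0.1)
  expect_equal(max(per$pressure_mmHg), 120, tolerance = 0.1)
  expect_true(wk$R_out > 0 && wk$C_out > 0)
})

test_that("calibration round trip recovers known (R, C) within 1%", {
  fl <- std_flow()
  set.seed(11)
  for (i in 1:3) {
    Rstar <- 10^runif(1, 8.0, 8.5)
    Cstar <- 10^runif(1, -8.3, -7.9)
    per <- wk2_periodic(fl, windkessel_params(Rstar, Cstar))
    wk <- wk2_calibrate(fl, min(per$pressure_mmHg), max(per$pressure_mmHg))
    expect_equal(wk$R_out, Rstar, tolerance = 0.01)
    expect_equal(wk$C_out, Cstar, tolerance = 0.01)
  }
})

test_that("degenerate constant flow cannot be calibrated", {
  const <- flow_rate_waveform(c(0, 0.5), c(6e-5, 6e-5), 1)
  expect_error(wk2_calibrate(const, 80, 120), "calibration error")
})
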