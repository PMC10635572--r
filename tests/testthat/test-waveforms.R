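test_that("synthetic waveform reproduces the sinusoidal systole", {
  wf <- synth_waveform(2.7, T_sys = 0.3, period = 1.0)
  expect_equal(wf$fun(0.15), 2.7, tolerance = 1e-8)
  expect_lt(abs(wf$fun(0.3)), 1e-6)
  expect_equal(wf$U_peak, 2.7)
  # integral over a period equals U_peak * 2 T_sys / pi (quadrature oracle)
  q <- integrate(wf$fun, 0, 1, subdivisions = 2000, rel.tol = 1e-9)$value
  expect_equal(q, 2.7 * 2 * 0.3 / pi, tolerance = 1e-4)
})

test_that("waveform CSV round trip retains samples exactly and rejects bad input", {
  wf <- synth_waveform(2.7, 0.3, 1.0)
  f <- tempfile(fileext = ".csv")
  write_waveform(wf, f)
  back <- load_waveform(f)
  expect_identical(back$time, wf$time)
  expect_identical(back$velocity, wf$velocity)
  expect_equal(back$U_peak, wf$U_peak)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("time_s", "0", "0.1"), bad)        # single column
  expect_error(load_waveform(bad), "two columns")
  writeLines("time_s,velocity_m_s\n0.2,1\n0.1,2", bad)
  expect_error(load_waveform(bad), "increasing")
  expect_warning(velocity_waveform(c(0, 0.5), c(-0.2, 1)), "clamped")
})

test_that("jet radius follows the plug-jet formula", {
  expect_equal(jet_radius(pi, 1), 1)
  expect_equal(jet_radius(4e-4, 2.7), sqrt(4e-4 / (pi * 2.7)))
  # consistent with the reported 7.0 mm at the diseased operating point
  expect_equal(jet_radius(4e-4, 2.7), 7.0e-3, tolerance = 0.02)
  expect_equal(jet_radius(4e-4, 0.9), 1.19e-2, tolerance = 1e-3)
  expect_error(jet_radius(0, 1), "positive")
  expect_error(jet_radius(4e-4, -1), "positive")
})

test_that("inflow centroid is the first moment of area", {
  n <- 21
  x <- seq(-1, 1, length.out = n); y <- seq(-1, 1, length.out = n)
  disc <- outer(x^2, y^2, "+") <= 0.63^2   # radius off the lattice ties
  expect_equal(inflow_centroid(disc, x, y), c(0, 0), tolerance = 1e-12)

  two <- matrix(FALSE, n, n); two[6, 11] <- TRUE; two[16, 11] <- TRUE
  expect_equal(inflow_centroid(two, x, y)[1], (x[6] + x[16]) / 2)

  set.seed(4)
  blob <- matrix(runif(n * n) < 0.3, n, n)
  idx <- which(blob, arr.ind = TRUE)
  brute <- c(sum(x[idx[, 1]]), sum(y[idx[, 2]])) / nrow(idx)
  expect_equal(inflow_centroid(blob, x, y), brute)
  expect_error(inflow_centroid(blob & FALSE, x, y), "empty")
})

test_that("flow-rate rescale preserves shape and scales the peak", {
  wf <- synth_waveform(2.7, 0.3, 1.0)
  fl <- flowrate_waveform(wf, 0.85, 4e-4)
  expect_equal(fl$Q_peak, 3.4e-4)
  expect_equal(flowrate_waveform(wf, 1, 4e-4)$Q_peak, 4e-4)
  tt <- seq(0, 1, by = 0.01)
  expect_equal(fl$fun(tt), 0.85 * 4e-4 * wf$fun(tt) / 2.7, tolerance = 1e-12)
  z <- velocity_waveform(c(0, 0.5), c(0, 0))
  expect_equal(max(flowrate_waveform(z)$flow), 0)
})

test_that("restored-inflow transform reproduces the valve-replacement arithmetic", {
  r <- restored_inflow(2.7, area_factor = 3, velocity_factor = 1)
  expect_equal(r$U_peak, 0.9)
  expect_equal(r$r_jet, jet_radius(4e-4, 2.7) * sqrt(3))
  rs <- restored_inflow(0.9, r_jet = r$r_jet, area_factor = 1,
                        velocity_factor = 2)
  expect_equal(rs$U_peak, 1.8)
  id <- restored_inflow(2.7, area_factor = 1, velocity_factor = 1)
  expect_equal(id$U_peak, 2.7)
  expect_equal(id$r_jet, jet_radius(4e-4, 2.7))
})
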