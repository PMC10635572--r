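test_that("beat instances follow the named-fraction definitions", {
  fl <- std_flow()
  inst <- beat_instances(fl)
  expect_equal(inst$PF, 0.15, tolerance = 1e-3)
  expect_equal(inst$MA, inst$PF / 2)
  expect_equal(inst$QA3, (inst$MA + inst$PF) / 2)
  expect_equal(inst$MD, (inst$PF + inst$ES) / 2)
  expect_equal(inst$QD, (inst$PF + inst$MD) / 2)
  # ES: first decay below 2% of peak, sin(pi t / 0.3) = 0.02
  expect_equal(inst$ES, 0.3 - 0.3 * asin(0.02) / pi, tolerance = 2e-3)
  with(inst, expect_true(0 < MA && MA < QA3 && QA3 < PF && PF < QD &&
                         QD < MD && MD < ES && ES <= fl$period))
  flat <- flow_rate_waveform(seq(0, 0.9, by = 0.1),
                             c(0, 1, 1, 1, 1, 0, 0, 0, 0, 0), 1)
  expect_warning(beat_instances(flat), "earliest maximum")
  nodecay <- flow_rate_waveform(c(0, 0.5), c(1e-4, 1.2e-4), 1)
  expect_warning(beat_instances(nodecay), "ES set to period")
})

# a quiescent hydrostatic context on a simple cylinder
hydro_ctx <- function(p0 = 2.5) {
  geom <- make_straight_tube(0.01, 0.06, 0.002)
  cfg <- sim_config(Re = 100, U0 = 1, L0 = 0.02)
  ctx <- ns_context(geom, cfg)
  st <- flow_state(geom$grid)
  st$p[] <- p0
  list(ctx = ctx, st = st, p0 = p0)
}

test_that("wall traction reduces to -p n for a hydrostatic field", {
  hc <- hydro_ctx()
  tr <- wall_traction(hc$st, hc$ctx)
  pdim <- hc$p0 * hc$ctx$config$rho * hc$ctx$config$U0^2
  expect_equal(tr$values, -pdim * tr$normals, tolerance = 1e-6)
  wss <- wss_magnitude(tr)
  expect_lt(max(wss$values), 1e-6 * pdim)
})

test_that("planar Couette traction is mu U / h exactly", {
  n <- c(12, 32, 8)
  grid <- cartesian_grid(n, 0.025)
  co <- aortaflow:::grid_coords(grid)
  gap <- 0.5
  geom <- levelset_geometry(grid, 0.15 - co$y)   # wall at y = 0.15
  cfg <- sim_config(Re = 50, periodic = c(TRUE, FALSE, TRUE))
  ctx <- ns_context(geom, cfg)
  st <- flow_state(grid)
  U <- 2
  yc <- aortaflow:::grid_axes(grid)[[2]]
  for (i in seq_len(n[1] + 1)) for (k in seq_len(n[3]))
    st$u[i, , k] <- pmax(U * (yc - 0.15) / gap, 0)
  # iterate the (under-relaxed) reconstruction to its fixed point so the
  # ghost band holds the converged linear extension
  for (i in 1:30) st <- ibm_reconstruct(st, ctx)
  samples <- surface_points(geom)
  keep <- samples$points[, 2] < 0.3   # stay on the flat wall
  samples <- list(points = samples$points[keep, ], normals = samples$normals[keep, ])
  tr <- wall_traction(st, ctx, samples)
  wss <- wss_magnitude(tr)
  exact <- ctx$config$mu * U / gap * ctx$config$U0 / ctx$config$L0 *
    ctx$config$L0    # gap and U are already in solver units here
  expect_equal(mean(wss$values), ctx$config$mu * U / gap, tolerance = 1e-6)
})

test_that("WSS magnitude is invariant under normal flips and normal offsets", {
  set.seed(3)
  m <- 40
  n <- matrix(rnorm(3 * m), m)
  n <- n / sqrt(rowSums(n^2))
  t <- matrix(rnorm(3 * m), m)
  base <- list(values = t, normals = n, points = matrix(0, m, 3), time = 0)
  w1 <- wss_magnitude(base)$values
  w2 <- wss_magnitude(list(values = t, normals = -n, points = base$points,
                           time = 0))$values
  expect_equal(w1, w2, tolerance = 1e-12)
  lam <- rnorm(m)
  w3 <- wss_magnitude(list(values = t + lam * n, normals = n,
                           points = base$points, time = 0))$values
  expect_equal(w1, w3, tolerance = 1e-9)
  # tangentiality of the projected traction
  tt <- t - rowSums(t * n) * n
  expect_lt(max(abs(rowSums(tt * n))), 1e-10 * max(sqrt(rowSums(tt^2))))
  # purely normal traction has zero shear; simple arithmetic case
  expect_lt(wss_magnitude(list(values = 5 * n[1, , drop = FALSE],
                               normals = n[1, , drop = FALSE],
                               points = matrix(0, 1, 3), time = 0))$values,
            1e-12)
  w4 <- wss_magnitude(list(values = matrix(c(1, 1, 0), 1),
                           normals = matrix(c(0, 0, 1), 1),
                           points = matrix(0, 1, 3), time = 0))$values
  expect_equal(as.numeric(w4), sqrt(2))
})

test_that("wall pressure extrapolation is exact for uniform and linear fields", {
  hc <- hydro_ctx(1.2)
  wp <- wall_pressure(hc$st, hc$ctx)
  pdim <- 1.2 * hc$ctx$config$rho * hc$ctx$config$U0^2
  expect_equal(wp$values, rep(pdim, length(wp$values)), tolerance = 1e-9)
  # linear field p = alpha z
  co <- aortaflow:::grid_coords(hc$ctx$grid)
  alpha <- 4
  hc$st$p <- alpha * co$z / hc$ctx$config$L0
  wp2 <- wall_pressure(hc$st, hc$ctx)
  scale <- hc$ctx$config$rho * hc$ctx$config$U0^2
  expected <- alpha * wp2$points[, 3] / hc$ctx$config$L0 * scale
  inner <- wp2$points[, 3] > 0.01 & wp2$points[, 3] < 0.05
  expect_equal(wp2$values[inner], expected[inner], tolerance = 1e-6)
})

test_that("band unwrapping parameterizes a cylinder cut uniformly", {
  geom <- make_straight_tube(0.01, 0.06, 0.0015)
  cfg <- sim_config(Re = 100, U0 = 1, L0 = 0.02)
  ctx <- ns_context(geom, cfg)
  band <- band_spec(point = c(0, 0, 0.03), normal = c(0, 0, 1),
                    halfwidth = 0.0015, radius = 0.02)
  sel <- aortaflow:::select_band(surface_points(geom), band, geom$grid$h)
  expect_gte(length(sel$theta), 24)
  expect_true(all(diff(sel$theta) >= 0))
  gaps <- diff(c(sel$theta, sel$theta[1] + 2 * pi))
  # stair-step sampling of the ring covers the whole circle
  expect_lt(max(gaps), 0.3)
  # marked origin (+x) maps to theta ~ 0
  expect_lt(min(sel$theta), 0.2)

  # hotspot equivariance: rotating a delta-like WSS pattern shifts theta
  st <- flow_state(geom$grid)
  mk_band <- function(phase) {
    vals <- exp(cos(sel$theta - phase) * 6)
    structure(list(theta = sel$theta, points = sel$points, times = 0,
                   values = matrix(vals, 1)), class = "band_series")
  }
  f0 <- focality_score(mk_band(0.5))
  f1 <- focality_score(mk_band(0.5 + pi / 3))
  expect_equal(f0, f1, tolerance = 0.05)   # same concentration, shifted
  peak0 <- sel$theta[which.max(mk_band(0.5)$values)]
  peak1 <- sel$theta[which.max(mk_band(0.5 + pi / 3)$values)]
  expect_equal((peak1 - peak0) %% (2 * pi), pi / 3, tolerance = 0.2)

  # a plane cutting two vessels is rejected
  band2 <- band_spec(point = c(0, 0, 0.03), normal = c(0, 1, 0),
                     halfwidth = 0.0025, radius = 0.05)
  expect_error(aortaflow:::select_band(surface_points(geom), band2,
                                       geom$grid$h),
               "band error|no wall samples")
})

test_that("probe series interpolation is exact for constant and linear fields", {
  geom <- make_straight_tube(0.01, 0.06, 0.002)
  cfg <- sim_config(Re = 100, U0 = 1, L0 = 0.02)
  ctx <- ns_context(geom, cfg)
  st <- flow_state(geom$grid)
  st$p[] <- 3
  pts <- rbind(c(0.002, 0.001, 0.03), c(0, 0, 0.02))
  v <- aortaflow:::sample_pressure(st, ctx, pts)
  scale <- ctx$config$rho * ctx$config$U0^2
  expect_equal(v, rep(3 * scale, 2), tolerance = 1e-12)
  co <- aortaflow:::grid_coords(geom$grid)
  st$p <- co$z * 7
  v2 <- aortaflow:::sample_pressure(st, ctx, pts)
  expect_equal(v2, pts[, 3] * 7 * scale, tolerance = 1e-9)
  # a probe inside the solid is a placement error
  expect_error(run_beat(geom, cfg,
                        build_inflow(geom, synth_waveform(1, 0.3, 1),
                                     Q_peak = 1e-4),
                        function(t) 80, t_end = 0.004,
                        probes = rbind(c(0.02, 0.015, 0.03))),
               "placement error")
})

test_that("oscillation metric isolates high-frequency content", {
  fs <- 1400
  tt <- seq(0, 0.3, by = 1 / fs)
  inst <- std_instances()
  loc <- matrix(c(0, 0, 0), 1)
  mk <- function(x) probe_series(tt, matrix(x, ncol = 1), loc, fs)
  # constant signal
  m0 <- oscillation_metric(mk(rep(1000, length(tt))), inst)
  expect_equal(m0$ratio, 0, tolerance = 1e-9)
  # 50 Hz sinusoid of amplitude 50 on a 1000 Pa baseline: ratio ~ 100/1000
  x <- 1000 + 50 * sin(2 * pi * 50 * tt)
  m1 <- oscillation_metric(mk(x), inst)
  expect_lt(abs(m1$ratio - 0.1), 0.015)
  expect_equal(m1$p_i, 1000 + 50 * sin(2 * pi * 50 * inst$QA3),
               tolerance = 1)
  # slow ramp only: buildup, not oscillation
  m2 <- oscillation_metric(mk(1000 + 3000 * tt), inst)
  expect_lt(m2$ratio, 0.02)
  # negative baseline is an undefined-metric error
  expect_error(oscillation_metric(mk(rep(-5, length(tt))), inst),
               "undefined-metric")
})

test_that("buildup detector separates ramps from oscillations across seeds", {
  inst <- std_instances()
  fx <- make_fixtures("probe_signals", seed = 5, ncases = 50)$data
  loc <- matrix(0, 1, 3)
  good <- vapply(fx, function(cs) {
    ps <- probe_series(cs$t, matrix(cs$x, ncol = 1), loc, 1400)
    pressure_buildup_detect(ps, inst)$buildup == cs$label
  }, logical(1))
  expect_true(all(good))
})

test_that("focality score captures concentration on the circle", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  mk <- function(v) structure(list(theta = th, points = NULL, times = 0,
                                   values = matrix(v, 1)),
                              class = "band_series")
  spike <- rep(0, 72); spike[10] <- 5
  expect_equal(focality_score(mk(spike + 1)), 1, tolerance = 1e-9)
  expect_warning(f_uni <- focality_score(mk(rep(2, 72))), "all-zero")
  expect_equal(f_uni, 0)
  anti <- rep(0, 72); anti[10] <- 5; anti[46] <- 5   # antipodal pair
  expect_lt(focality_score(mk(anti + 1)), 1e-6)
})
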