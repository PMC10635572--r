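test_that("Poiseuille pipe flow reproduces the analytic wall shear stress", {
  r <- poiseuille_run(32)
  wss <- wss_magnitude(wall_traction(r$st, r$ctx))
  expect_equal(mean(wss$values), r$wss_exact, tolerance = 0.05)
  # centreline velocity is twice the bulk mean (parabolic profile)
  wmax <- max(r$st$w)
  expect_equal(wmax, r$fx$config$Re * r$fx$force_amp * r$fx$R^2 / 4,
               tolerance = 0.02)
})

test_that("Poiseuille WSS error drops under grid refinement", {
  e32 <- abs(mean(wss_magnitude(wall_traction(poiseuille_run(32)$st,
                                              poiseuille_run(32)$ctx))$values) -
             poiseuille_run(32)$wss_exact) / poiseuille_run(32)$wss_exact
  r64 <- poiseuille_run(64, t_end = 0.1)
  e64 <- abs(mean(wss_magnitude(wall_traction(r64$st, r64$ctx))$values) -
             r64$wss_exact) / r64$wss_exact
  expect_lt(e64, 0.05)
  # quartered error under halved spacing, or both already at the exactness
  # floor of the quadratic-profile reconstruction (~1e-3)
  expect_true(e64 <= e32 / 4 || (e32 < 1e-3 && e64 < 1e-3))
})

test_that("oscillatory pipe flow matches the Womersley profile", {
  fx <- aortaflow:::pipe_benchmark_setup(32, Re = 50, mode = "womersley",
                                         alpha = 5)
  ctx <- ns_context(fx$geom, fx$config)
  st <- apply_bcs(fx$state, 0, ctx)
  Tper <- 2 * pi / fx$omega
  while (st$t < Tper - 1e-12) {
    dt <- min(compute_dt(st, ctx), Tper - st$t)
    st <- advance_rk3(st, dt, ctx)
  }
  n <- ctx$n
  xw <- fx$geom$grid$origin[1] + (seq_len(n[1]) - 0.5) * ctx$h[1]
  yw <- fx$geom$grid$origin[2] + (seq_len(n[2]) - 0.5) * ctx$h[2]
  r <- sqrt(outer(xw^2, yw^2, "+"))
  wex <- womersley_profile(r, fx$R, fx$alpha, fx$omega, 50, 1, t = Tper)
  sel <- r < fx$R - ctx$h[1]
  l2 <- sqrt(sum((st$w[, , 4][sel] - wex[sel])^2) / sum(wex[sel]^2))
  expect_lt(l2, 0.05)
})

test_that("steady cylinder drag agrees between coarse and refined grids", {
  drag_z <- function(hh, t_end = 3.5) {
    # cylinder (diameter 1, axis y) in a z-directed stream, slip side walls
    nx <- round(5 / hh); nz <- round(9 / hh)
    grid <- cartesian_grid(c(nx, 8, nz), hh,
                           origin = c(-nx * hh / 2, 0, 0))
    co <- aortaflow:::grid_coords(grid)
    phi <- 0.5 - sqrt(co$x^2 + (co$z - 3)^2)   # fluid outside the cylinder
    geom <- levelset_geometry(grid, phi)
    zc <- aortaflow:::grid_axes(grid)[[3]]
    geom <- aortaflow:::add_patch(geom, "inlet", axis = -3L,
                                  k_ct = which(zc >= 4 * hh)[1],
                                  mask2d = geom$phi[, , which(zc >= 4 * hh)[1]] < 0)
    geom <- aortaflow:::add_patch(geom, "outlet_desc", axis = 3L,
                                  k_ct = max(which(zc <= 9 - 4 * hh)),
                                  mask2d = geom$phi[, , max(which(zc <= 9 - 4 * hh))] < 0)
    wf <- velocity_waveform(c(0, 5), c(1, 1), period = 10)
    inflow <- build_inflow(geom, wf, plug = "full")
    cfg <- sim_config(Re = 40, U0 = 1, L0 = 1, T = 10, CFL = 0.4,
                      fd_order = 2, periodic = c(FALSE, TRUE, FALSE))
    ctx <- ns_context(geom, cfg, inflow, pressure_outlet = function(t) 0)
    st <- flow_state(grid)
    st$w[] <- 1
    st <- apply_bcs(st, 0, ctx)
    while (st$t < t_end - 1e-12) {
      dt <- min(compute_dt(st, ctx), t_end - st$t)
      st <- advance_rk3(st, dt, ctx, noise = NULL)
    }
    # traction integral over the triangulated cylinder surface
    tri <- surface_triangulation(geom)
    ctr <- (tri[, 1:3] + tri[, 4:6] + tri[, 7:9]) / 3
    e1 <- tri[, 4:6] - tri[, 1:3]; e2 <- tri[, 7:9] - tri[, 1:3]
    areas <- sqrt((e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])^2 +
                  (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3])^2 +
                  (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2) / 2
    nrm <- surface_normals(geom, ctr)
    samples <- list(points = ctr, normals = nrm)
    tr <- wall_traction(st, ctx, samples)
    pw <- wall_pressure(st, ctx, samples)$values
    # force on the cylinder: pressure pushes along the outward-of-fluid
    # normal, shear drags along the flow; traction is -p n + shear
    shear_z <- tr$values[, 3] + pw * nrm[, 3]
    span <- diff(range(ctr[, 2]))
    sum((pw * nrm[, 3] + shear_z) * areas) / span
  }
  f_coarse <- drag_z(1 / 10)
  f_fine <- drag_z(1 / 14)
  expect_gt(f_fine, 0)                       # drag points downstream
  expect_equal(f_coarse, f_fine, tolerance = 0.10)
})
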