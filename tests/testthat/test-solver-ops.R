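test_that("sixth-order stencils converge at design order on periodic fields", {
  ns <- c(24, 48, 96)
  errs <- sapply(ns, function(n) {
    x <- 2 * pi * (0:(n - 1)) / n
    d <- fd_apply(sin(3 * x), 1, 1, 6, h = 2 * pi / n, periodic = TRUE)
    max(abs(d - 3 * cos(3 * x)))
  })
  expect_gte(-loglog_slope(1 / ns, 1 / errs), 5.8)
  # constant fields are annihilated
  expect_lt(max(abs(fd_apply(rep(3, 32), 1, 1, 6, 0.1, TRUE))), 1e-12)
  # second derivatives too
  errs2 <- sapply(ns, function(n) {
    x <- 2 * pi * (0:(n - 1)) / n
    d <- fd_apply(sin(2 * x), 1, 2, 6, h = 2 * pi / n, periodic = TRUE)
    max(abs(d + 4 * sin(2 * x)))
  })
  expect_gte(-loglog_slope(1 / ns, 1 / errs2), 5.5)
})

test_that("central stencils are exact on polynomials of matching degree", {
  x <- seq(0, 1, length.out = 25)
  h <- x[2] - x[1]
  for (o in c(2, 4, 6)) {
    f <- x^o
    d <- fd_apply(f, 1, 1, o, h)
    inner <- (o / 2 + 1):(25 - o / 2)
    expect_lt(max(abs(d[inner] - o * x[inner]^(o - 1))), 1e-10)
  }
  expect_error(fd_apply(x, 3, 1, 6, h), "axis out of range")
})

test_that("low-storage RK3 shows third-order convergence on a linear ODE", {
  lam <- -2
  dts <- c(0.1, 0.05, 0.025)
  errs <- sapply(dts, function(dt)
    abs(rk3_lowstorage(1, function(t, y) lam * y, dt, round(1 / dt)) -
        exp(lam)))
  expect_gte(loglog_slope(dts, errs), 2.9)
  # one large step has O(dt^4) local error
  e1 <- abs(rk3_lowstorage(1, function(t, y) lam * y, 0.1, 1) - exp(-0.2))
  expect_lt(e1, abs(lam * 0.1)^4)
})

test_that("compute_dt follows the CFL and diffusive limits", {
  grid <- cartesian_grid(c(16, 16, 16), 0.01)
  geom <- levelset_geometry(grid, array(-1, grid$n))
  cfg <- sim_config(Re = 100, CFL = 0.5, periodic = rep(TRUE, 3))
  ctx <- ns_context(geom, cfg)
  st <- flow_state(grid)
  dtd <- 0.25 * 0.01^2 * 100
  expect_equal(compute_dt(st, ctx), dtd)       # rest state: diffusive cap
  st$u[2, 3, 4] <- 1
  expect_equal(compute_dt(st, ctx), min(0.5 * 0.01 / 1, dtd))
  st$u[2, 3, 4] <- 2                           # doubling velocity halves dt
  expect_equal(compute_dt(st, ctx), min(0.5 * 0.01 / 2, dtd))
})

test_that("pressure Poisson solves a manufactured Dirichlet problem", {
  fx <- make_fixtures("manufactured_solution", seed = 1, n = 48L)$data
  p <- pressure_poisson(fx$rhs, fx$grid, dirichlet = fx$dirichlet,
                        celltype = fx$ctype, tol = 1e-10)
  inner <- fx$ctype == 1L
  err <- max(abs(p[inner] - fx$exact[inner]))
  expect_lt(err, 5e-4)                         # O(h^2) discretization level
  # halving h reduces the error ~4x
  fx2 <- make_fixtures("manufactured_solution", seed = 1, n = 96L)$data
  p2 <- pressure_poisson(fx2$rhs, fx2$grid, dirichlet = fx2$dirichlet,
                         celltype = fx2$ctype, tol = 1e-11)
  err2 <- max(abs(p2[fx2$ctype == 1L] - fx2$exact[fx2$ctype == 1L]))
  expect_lt(err2, err / 3)
})

test_that("pressure Poisson handles uniform Dirichlet and pure Neumann", {
  grid <- cartesian_grid(c(16, 16, 8), 0.1)
  ct <- array(1L, grid$n); ct[1, , ] <- 2L
  dv <- array(7.5, grid$n)
  p <- pressure_poisson(array(0, grid$n), grid, dirichlet = dv,
                        celltype = ct, tol = 1e-12)
  expect_equal(as.numeric(p), rep(7.5, prod(grid$n)), tolerance = 1e-9)
  # incompatible all-Neumann rhs: projected, mean-zero solution, warning
  rhs <- array(1, grid$n)
  expect_warning(p2 <- pressure_poisson(rhs, grid, tol = 1e-10),
                 "projected")
  expect_lt(abs(mean(p2)), 1e-10)
})

test_that("immersed-boundary reconstruction preserves wall-compatible fields", {
  # flat wall at y = 0.2, uniform shear u = gamma * (y - 0.2)
  n <- c(16, 24, 8)
  grid <- cartesian_grid(n, 0.05)
  co <- aortaflow:::grid_coords(grid)
  geom <- levelset_geometry(grid, 0.2 - co$y)  # fluid above the wall
  cfg <- sim_config(Re = 100, periodic = c(TRUE, FALSE, TRUE))
  ctx <- ns_context(geom, cfg)
  st <- flow_state(grid)
  gamma <- 3
  yc <- aortaflow:::grid_axes(grid)[[2]]
  for (i in seq_len(n[1] + 1)) for (k in seq_len(n[3]))
    st$u[i, , k] <- pmax(gamma * (yc - 0.2), 0)
  before <- st$u
  st2 <- ibm_reconstruct(st, ctx)
  fluid_face <- !ctx$solidU
  expect_lt(max(abs(st2$u[fluid_face] - before[fluid_face])), 1e-10)

  # wall-aligned uniform flow tangent to the plane is untouched in fluid
  st$u[] <- 1
  stu <- ibm_reconstruct(st, ctx)
  yfluid <- which(yc > 0.2 + 2 * 0.05)
  expect_equal(max(abs(stu$u[, yfluid, ] - 1)), 0, tolerance = 1e-12)
})
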