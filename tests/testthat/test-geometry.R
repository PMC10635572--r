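test_that("signed distance of a straight tube and mirror symmetry are exact", {
  # branch-free tube of radius 15 mm along z: phi on the axis is -15 mm
  spec <- idealized_aorta_spec(lumen_radius = 0.015,
                               branch_radius = numeric(0),
                               branch_theta = numeric(0))
  grid <- default_idealized_grid(spec, 0.002)
  geom <- make_idealized_aorta(spec, grid)
  ax <- aortaflow:::grid_axes(grid)
  i0 <- which.min(abs(ax[[1]] - spec$arch_radius))
  j0 <- which.min(abs(ax[[2]]))
  kmid <- round(grid$n[3] * 0.3)   # mid-ascending section
  expect_equal(geom$phi[i0, j0, kmid],
               -0.015 + sqrt((ax[[1]][i0] - spec$arch_radius)^2 + ax[[2]][j0]^2),
               tolerance = 1e-12)

  # arch-plane (y = 0) mirror symmetry to machine precision
  full <- make_idealized_aorta(idealized_aorta_spec())
  ny <- full$grid$n[2]
  expect_equal(full$phi, full$phi[, ny:1, ], tolerance = 1e-14)

  # x-mirrored spec (branches at pi - theta) mirrors phi exactly
  sp <- idealized_aorta_spec()
  spm <- idealized_aorta_spec(branch_theta = rev(pi - sp$branch_theta),
                              branch_radius = rev(sp$branch_radius))
  g1 <- make_idealized_aorta(sp)
  g2 <- make_idealized_aorta(spm)
  nx <- g1$grid$n[1]
  expect_equal(g2$phi, g1$phi[nx:1, , ], tolerance = 1e-12)
})

test_that("idealized surface area agrees with a refined triangulation", {
  spec <- idealized_aorta_spec()
  a1 <- surface_area(surface_triangulation(
    make_idealized_aorta(spec, default_idealized_grid(spec, 0.0015))))
  a2 <- surface_area(surface_triangulation(
    make_idealized_aorta(spec, default_idealized_grid(spec, 0.00075))))
  expect_lt(abs(a1 - a2) / a2, 0.02)
})

test_that("idealized spec validation rejects impossible geometry", {
  expect_error(idealized_aorta_spec(lumen_radius = 0.04), "arch radius")
  expect_error(idealized_aorta_spec(branch_radius = c(0.02, 0.004, 0.004)),
               "smaller than the lumen")
  expect_error(idealized_aorta_spec(branch_theta = c(1.25, 1.26, 1.95)),
               "intersect")
  spec <- idealized_aorta_spec()
  tiny <- cartesian_grid(c(16, 16, 16), 0.002)
  expect_error(make_idealized_aorta(spec, tiny), "bounds error")
})

test_that("mask-derived signed distance matches the exact EDT on a ball", {
  n <- 48L; sp <- 5e-4
  idx <- seq_len(n)
  ctr <- (n + 1) / 2
  r <- sqrt(outer(outer((idx - ctr)^2, (idx - ctr)^2, "+"),
                  (idx - ctr)^2, "+"))
  mask <- array(0L, c(n, n, n)); mask[r <= 15] <- 1L
  g <- levelset_from_mask(mask, sp)
  centre <- g$phi[ctr - 0.5, ctr - 0.5, ctr - 0.5]
  expect_lt(abs(centre - (-15 * sp)), sp)   # within one voxel
  # anisotropic spacing honoured: z distances scale with the z spacing
  g2 <- levelset_from_mask(mask, c(sp, sp, 2 * sp))
  ksurf <- ctr - 0.5
  expect_gt(abs(g2$phi[ksurf, ksurf, 4] ), abs(g$phi[ksurf, ksurf, 4]))
  expect_error(levelset_from_mask(array(0L, c(8, 8, 8)), sp), "empty")
  expect_error(levelset_from_mask(array(1L, c(8, 8, 8)), sp), "no wall")
})

test_that("rasterized idealized geometry round-trips through the mask reader", {
  spec <- idealized_aorta_spec()
  grid <- default_idealized_grid(spec, 0.002)
  geom <- make_idealized_aorta(spec, grid)
  mask <- array(as.integer(geom$phi < 0), grid$n)
  g2 <- levelset_from_mask(mask, grid$h, grid$origin)
  agree <- mean((g2$cell_tags != 0) == (geom$cell_tags != 0))
  expect_gte(agree, 0.99)
})

test_that("surface normals are unit outward vectors", {
  sg <- cartesian_grid(c(32, 32, 32), 1 / 32)
  co <- aortaflow:::grid_coords(sg)
  ctr <- c(0.5, 0.5, 0.5)
  sphere <- levelset_geometry(sg, sqrt((co$x - 0.5)^2 + (co$y - 0.5)^2 +
                                       (co$z - 0.5)^2) - 0.3)
  n1 <- surface_normals(sphere, matrix(c(0.8, 0.5, 0.5), 1))
  expect_equal(as.numeric(n1), c(1, 0, 0), tolerance = 1e-3)
  expect_equal(sqrt(sum(n1^2)), 1, tolerance = 1e-6)

  cyl <- levelset_geometry(sg, sqrt((co$x - 0.5)^2 + (co$y - 0.5)^2) - 0.3)
  n2 <- surface_normals(cyl, matrix(c(0.8, 0.5, 0.5), 1))
  expect_lt(abs(n2[3]), 1e-3)

  flat <- levelset_geometry(sg, array(1e-6, sg$n))  # |grad phi| ~ 0
  expect_error(surface_normals(flat, matrix(ctr, 1)), "degenerate")

  # idealized wall normals converge under grid refinement (sampled on the
  # smooth limb walls; branch-junction creases have no defined normal)
  spec <- idealized_aorta_spec()
  gc <- make_idealized_aorta(spec, default_idealized_grid(spec, 0.002))
  gf <- make_idealized_aorta(spec, default_idealized_grid(spec, 0.001))
  sp <- surface_points(gc)
  z_arch <- spec$inlet_extension + spec$asc_length
  smooth <- which(sp$points[, 3] < z_arch)
  keep <- smooth[seq(1, length(smooth), by = 5)]
  nf <- surface_normals(gf, sp$points[keep, ])
  ang <- acos(pmin(1, rowSums(sp$normals[keep, ] * nf)))
  expect_lt(max(ang), 2 * pi / 180)
})

test_that("cell classification partitions the grid with a one-cell boundary", {
  sg <- cartesian_grid(c(16, 16, 16), 1 / 16)
  co <- aortaflow:::grid_coords(sg)
  half <- levelset_geometry(sg, co$x - 0.5)     # half-space phi = x - 0.5
  tags <- classify_cells(half)
  expect_equal(sum(tags == 0) + sum(tags == 1) + sum(tags == 2), prod(sg$n))
  per_k <- apply(tags == 2, c(2, 3), sum)
  expect_true(all(per_k == 1))                  # single-cell-thick layer

  co32 <- aortaflow:::grid_coords(cartesian_grid(c(32, 32, 32), 1 / 32))
  ball <- levelset_geometry(cartesian_grid(c(32, 32, 32), 1 / 32),
                            sqrt((co32$x - 0.5)^2 + (co32$y - 0.5)^2 +
                                 (co32$z - 0.5)^2) - 0.3)
  nb <- sum(ball$cell_tags == 2)
  shell <- 4 * pi * 0.3^2 / (1 / 32)^2          # sphere-shell cell estimate
  expect_lt(abs(nb - shell) / shell, 0.35)
  expect_true(all(ball$phi[ball$cell_tags == 2] < 0))

  solid <- levelset_geometry(sg, array(1, sg$n))
  expect_error(ns_context(solid, sim_config(Re = 100)), "refuses to start")
})

test_that("fringe masks extrude the patch cross-section outward", {
  geom <- make_straight_tube(0.01, 0.08, 0.002)
  f4 <- define_fringe(geom, "inlet", 4)
  expect_equal(sum(f4), 4 * sum(geom$patches$inlet$mask2d))
  fo <- define_fringe(geom, "outlet_desc", 4)
  expect_false(any(f4 & fo))                    # disjoint
  expect_error(define_fringe(geom, "inlet", 50), "bounds error")
  expect_error(define_fringe(geom, "nope", 2), "unknown patch")
  # straight tube: fringe axis is the z centreline direction by construction
  zl <- which(apply(f4, 3, any))
  expect_equal(length(zl), 4)
  expect_true(all(diff(zl) == 1))
})

test_that("mask raw export round-trips through the sidecar reader", {
  set.seed(2)
  m <- array(as.integer(runif(8 * 8 * 8) > 0.5), c(8, 8, 8))
  pre <- tempfile()
  write_mask_raw(m, c(1e-3, 1e-3, 2e-3), c(0, 0, 0), pre)
  back <- read_mask_raw(pre)
  expect_identical(back$mask, m)
  expect_equal(back$spacing, c(1e-3, 1e-3, 2e-3))
  writeBin(as.raw(1:10), paste0(pre, "2.raw"))
  jsonlite::write_json(list(dims = c(8L, 8L, 8L), spacing_m = rep(1e-3, 3),
                            origin_m = rep(0, 3)),
                       paste0(pre, "2.json"), auto_unbox = TRUE)
  expect_error(read_mask_raw(paste0(pre, "2")), "format error")
})
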