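test_that("Taylor-Green vortex decays at the analytic viscous rate", {
  tg <- taylor_green_run()
  exact <- exp(-4 * tg$t_end / tg$Re)
  expect_equal(tg$ke / tg$ke0, exact, tolerance = 0.005)
})

test_that("projection enforces discrete incompressibility below 1e-8", {
  tg <- taylor_green_run()
  div <- aortaflow:::divergence_cpp(as.numeric(tg$st$u), as.numeric(tg$st$v),
                                    as.numeric(tg$st$w), tg$ctx$n, tg$ctx$h)
  expect_lt(max(abs(div)), 1e-8)

  run <- tube_run()
  ctx <- run$ctx; st <- run$final
  div2 <- aortaflow:::divergence_masked_cpp(
    as.numeric(st$u), as.numeric(st$v), as.numeric(st$w),
    as.integer(ctx$contU), as.integer(ctx$contV), as.integer(ctx$contW),
    ctx$n, ctx$h)
  expect_lt(max(abs(div2[ctx$ctype == 1L])), 1e-8)
})

test_that("steady plug inflow through a straight tube conserves mass", {
  run <- tube_run()
  fl <- flux_at_interfaces(run)
  expect_lt(abs(fl["Qin"] - fl["Qout"]) / abs(fl["Qin"]), 0.005)
  # per-step correction stays small once the flow is established
  tail_corr <- utils::tail(run$diagnostics$corr, 50)
  expect_lt(max(tail_corr), 0.05)
  # developed centreline velocity exceeds the plug mean (profile fills in)
  expect_gt(max(run$final$w), 0.95)
})

test_that("a zero-velocity state without forcing stays exactly zero", {
  geom <- make_straight_tube(0.01, 0.06, 0.0025)
  wf <- velocity_waveform(c(0, 0.5), c(0, 0), period = 1)
  inflow <- build_inflow(geom, wf, Q_peak = 1e-4)
  cfg <- sim_config(Re = 200, U0 = 1, L0 = 0.02, T = 1)
  run <- run_beat(geom, cfg, inflow, windkessel = NULL, t_end = 0.02)
  expect_lt(max(abs(run$final$u)), 1e-12)
  expect_lt(max(abs(run$final$v)), 1e-12)
  expect_lt(max(abs(run$final$w)), 1e-12)
})

test_that("kinetic energy is non-increasing in a closed box without inflow", {
  n <- c(24, 24, 24)
  grid <- cartesian_grid(n, 1 / 24)
  co <- aortaflow:::grid_coords(grid)
  box <- pmax(abs(co$x - 0.5), abs(co$y - 0.5), abs(co$z - 0.5)) - 0.4
  geom <- levelset_geometry(grid, box)
  cfg <- sim_config(Re = 100, CFL = 0.4, fd_order = 2)
  ctx <- ns_context(geom, cfg)
  st <- flow_state(grid)
  # smooth solenoidal eddy confined to the box interior
  xc <- aortaflow:::grid_axes(grid)[[1]]
  for (k in 1:24) {
    st$u[2:25, , k] <- outer(sin(pi * (0:23) / 23), cos(pi * (0:23) / 23))
    st$v[, 2:25, k] <- -outer(cos(pi * (0:23) / 23), sin(pi * (0:23) / 23))
  }
  st <- apply_bcs(st, 0, ctx)
  st <- aortaflow:::project_stage(st, ctx, 1e-2, 0)
  ke <- kinetic_energy(st, ctx)
  for (s in 1:25) {
    st <- advance_rk3(st, compute_dt(st, ctx), ctx)
    ke2 <- kinetic_energy(st, ctx)
    expect_lte(ke2, ke * (1 + 1e-10))
    ke <- ke2
  }
})

test_that("runs are deterministic and checkpoint-restart is bitwise exact", {
  geom <- make_straight_tube(0.01, 0.06, 0.0025)
  wf <- synth_waveform(1, 0.3, 1)
  inflow <- build_inflow(geom, wf, Q_peak = pi * 0.006^2)
  cfg <- sim_config(Re = 200, U0 = 1, L0 = 0.02, T = 1,
                    noise_amp = 0.01, noise_seed = 42)
  probes <- matrix(c(0, 0, 0.03), 1)
  r1 <- run_beat(geom, cfg, inflow, function(t) 80, t_end = 0.03,
                 probes = probes)
  r2 <- run_beat(geom, cfg, inflow, function(t) 80, t_end = 0.03,
                 probes = probes)
  expect_identical(r1$probe$values, r2$probe$values)
  expect_identical(r1$final$u, r2$final$u)

  # split run at a natural step boundary: first half, checkpoint, resume
  t_split <- r1$times[10]
  rhalf <- run_beat(geom, cfg, inflow, function(t) 80, t_end = t_split)
  ck <- tempfile(fileext = ".rds")
  write_checkpoint(rhalf$final, cfg, ck)
  rrest <- run_beat(geom, cfg, inflow, function(t) 80, t_end = 0.03,
                    resume = ck)
  expect_identical(rrest$final$u, r1$final$u)
  expect_identical(rrest$final$p, r1$final$p)

  # a checkpoint from a different configuration is refused
  cfg2 <- sim_config(Re = 150, U0 = 1, L0 = 0.02, T = 1,
                     noise_amp = 0.01, noise_seed = 42)
  expect_error(run_beat(geom, cfg2, inflow, function(t) 80, t_end = 0.03,
                        resume = ck), "different configuration")
})
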