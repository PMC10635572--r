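#' Simulation configuration
#'
#' Dimensionless operating point and numerical settings of the flow solver.
#' The solver integrates the dimensionless incompressible Navier-Stokes
#' equations; `U0` (reference velocity, normally the diseased peak jet
#' velocity) and `L0` (reference length, normally the inlet lumen diameter)
#' map physical inputs onto solver units, and `Re = U0 * L0 / nu` sets the
#' effective viscosity.
#'
#' @param Re Reynolds number.
#' @param U0 reference velocity (m/s).
#' @param L0 reference length (m).
#' @param CFL Courant number in `(0, 0.9]`, default 0.5.
#' @param fd_order interior finite-difference order: 2, 4 or 6.
#' @param T beat period (s).
#' @param noise_amp inflow white-noise amplitude as a fraction of the peak
#'   jet velocity (applied in the jet region only).
#' @param noise_seed RNG seed for the inflow perturbation.
#' @param filter_amp amplitude of the sixth-difference low-pass filter
#'   applied to the velocity once per step (damping factor `1 - filter_amp`
#'   at the Nyquist mode, zero effect on polynomials up to degree 5);
#'   the usual companion of non-dissipative central schemes on coarse
#'   grids. 0 disables.
#' @param periodic logical triple: periodic axes (benchmark modes).
#' @param force function of time (s) returning the dimensionless body-force
#'   triple, or a constant triple; default none.
#' @param rho,mu fluid constants used only to dimensionalize outputs
#'   (kg/m^3, Pa s). The effective viscosity entering wall-stress
#'   dimensionalization is `rho * U0 * L0 / Re` so that reported stresses
#'   are consistent with the simulated momentum balance.
#' @param cadence_probes probe/band sampling rate (Hz), default 1400.
#' @param cadence_fields field snapshot rate (Hz), default 20.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(Re, U0 = 1, L0 = 1, CFL = 0.5, fd_order = 6, T = 1,
                       noise_amp = 0, noise_seed = 1L, filter_amp = 0.1,
                       periodic = c(FALSE, FALSE, FALSE),
                       force = NULL, rho = 1060, mu = NULL,
                       cadence_probes = 1400, cadence_fields = 20) {
  stopifnot(Re > 0, CFL > 0, CFL <= 0.9, fd_order %in% c(2, 4, 6),
            filter_amp >= 0, filter_amp < 1)
  nu <- U0 * L0 / Re
  if (is.null(mu)) mu <- rho * nu
  if (is.null(force)) force <- function(t) c(0, 0, 0)
  if (is.numeric(force)) {
    fconst <- rep_len(force, 3)
    force <- function(t) fconst
  }
  structure(list(Re = Re, U0 = U0, L0 = L0, nu = nu, CFL = CFL,
                 fd_order = as.integer(fd_order), T = T,
                 noise_amp = noise_amp, noise_seed = as.integer(noise_seed),
                 filter_amp = filter_amp,
                 periodic = periodic, force = force, rho = rho, mu = mu,
                 cadence_probes = cadence_probes,
                 cadence_fields = cadence_fields),
            class = "sim_config")
}

#' Staggered flow state
#'
#' Face-normal velocity components on the MAC lattice plus cell-centred
#' pressure, all dimensionless (`u/U0`, `p/(rho U0^2)`); `t` is physical
#' time in seconds.
#'
#' @param grid a `cartesian_grid`.
#' @param t initial time (s).
#' @return Object of class `flow_state` with zero fields.
#' @export
flow_state <- function(grid, t = 0) {
  n <- grid$n
  structure(list(u = array(0, c(n[1] + 1, n[2], n[3])),
                 v = array(0, c(n[1], n[2] + 1, n[3])),
                 w = array(0, c(n[1], n[2], n[3] + 1)),
                 p = array(0, n), t = t, step = 0L),
            class = "flow_state")
}

#' Apply a central finite-difference derivative
#'
#' First or second derivative along one axis, with centred stencils of the
#' requested order in the interior. Near non-periodic edges the stencil
#' degrades gracefully (widest centred stencil that fits, one-sided second
#' order at the ends). The gradient, divergence, Laplacian and advection
#' operators of the solver are compositions of this primitive.
#'
#' @param field numeric vector/matrix/array (1-D to 3-D).
#' @param axis axis along which to differentiate (1-based).
#' @param deriv derivative order, 1 or 2.
#' @param fd_order stencil order: 2, 4 or 6.
#' @param h grid spacing along `axis`.
#' @param periodic is the axis periodic?
#' @return Array of the same shape.
#' @export
fd_apply <- function(field, axis, deriv = 1, fd_order = 6, h = 1,
                     periodic = FALSE) {
  d <- dim(field)
  if (is.null(d)) d <- length(field)
  d3 <- c(d, 1, 1)[1:3]
  if (axis < 1 || axis > length(d))
    stop("axis out of range", call. = FALSE)
  stopifnot(deriv %in% c(1, 2), fd_order %in% c(2, 4, 6))
  out <- fd_apply_cpp(as.numeric(field), as.integer(d3), as.integer(axis - 1),
                      as.integer(deriv), as.integer(fd_order), h, periodic)
  if (!is.null(dim(field))) dim(out) <- dim(field)
  out
}

# low-storage 3-stage Runge-Kutta (Williamson) coefficients
RK3_A <- c(0, -5 / 9, -153 / 128)
RK3_B <- c(1 / 3, 15 / 16, 8 / 15)
RK3_C <- c(0, 1 / 3, 3 / 4)      # stage start abscissae
RK3_E <- c(1 / 3, 3 / 4, 1)      # stage end abscissae

#' Low-storage third-order Runge-Kutta integration of an ODE
#'
#' The same 3-stage Williamson scheme the flow solver uses for its
#' advective-diffusive terms, exposed for scalar/vector ODEs.
#'
#' @param y0 initial value (numeric vector).
#' @param rhs function `(t, y) -> dy/dt`.
#' @param dt step size.
#' @param nsteps number of steps.
#' @param t0 initial time.
#' @return Final value after `nsteps` steps.
#' @export
rk3_lowstorage <- function(y0, rhs, dt, nsteps, t0 = 0) {
  y <- y0
  t <- t0
  for (s in seq_len(nsteps)) {
    q <- 0 * y
    for (k in 1:3) {
      q <- RK3_A[k] * q + dt * rhs(t + RK3_C[k] * dt, y)
      y <- y + RK3_B[k] * q
    }
    t <- t + dt
  }
  y
}

# ---------------------------------------------------------------------------
# solver context: everything precomputable from geometry + config

# face-centred average of a cell field along one axis (clamped or wrapped)
face_avg <- function(f, axis, periodic) {
  n <- dim(f)[axis]
  lo <- if (periodic) c(n, 1:n) else c(1, 1:n)
  hi <- if (periodic) c(1:n, 1) else c(1:n, n)
  if (axis == 1) (f[lo, , , drop = FALSE] + f[hi, , , drop = FALSE]) / 2
  else if (axis == 2) (f[, lo, , drop = FALSE] + f[, hi, , drop = FALSE]) / 2
  else (f[, , lo, drop = FALSE] + f[, , hi, drop = FALSE]) / 2
}

# shift an array along an axis with clamped edges
shift_clamp <- function(a, axis, by) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1), n)
  if (axis == 1) a[idx, , , drop = FALSE]
  else if (axis == 2) a[, idx, , drop = FALSE]
  else a[, , idx, drop = FALSE]
}

#' Build a solver context
#'
#' Precomputes, in solver (dimensionless) units, everything the time
#' stepper needs: cell classification for the pressure solve, fixed-face
#' masks, the sharp-interface reconstruction plan for near-wall faces, the
#' stencil-order map (interior order reduced to 2 within two cells of the
#' immersed boundary and the fringes), the inflow jet plan and the outlet
#' fringe plans.
#'
#' @param geom a `levelset_geometry`.
#' @param config a `sim_config`.
#' @param inflow optional `inflow_profile` (requires an `"inlet"` patch).
#' @param pressure_outlet optional function of time (s) returning the
#'   descending-outlet Windkessel pressure in mmHg; applied as a Dirichlet
#'   value on the `"outlet_desc"` fringe.
#' @param fringe_depth fringe depth in cells (default: all layers outside
#'   the anatomical cut plane).
#' @return Object of class `ns_context`.
#' @export
ns_context <- function(geom, config, inflow = NULL, pressure_outlet = NULL,
                       fringe_depth = NULL) {
  grid <- geom$grid
  n <- grid$n
  L0 <- config$L0
  h <- grid$h / L0
  per <- config$periodic
  phi <- geom$phi / L0
  tags <- geom$cell_tags
  if (!any(tags != 0))
    stop("no fluid cells: simulation refuses to start", call. = FALSE)

  ctx <- list(geom = geom, config = config, grid = grid, n = n, h = h,
              periodic = per, t0 = L0 / config$U0, inflow = inflow,
              pressure_outlet = pressure_outlet)

  # fringe masks per patch; when the geometry carries explicit branch-cell
  # masks (idealized aorta), the whole neck tubes are prescribed suction
  # regions and need no extruded fringe
  has_branch_cells <- !is.null(geom$branch_cells)
  fringes <- list()
  for (pn in names(geom$patches)) {
    if (has_branch_cells && startsWith(pn, "branch_")) next
    p <- geom$patches[[pn]]
    avail <- if (p$axis < 0) p$k_ct - 1 else n[3] - p$k_ct
    dep <- if (is.null(fringe_depth)) avail else min(fringe_depth, avail)
    if (dep >= 2) fringes[[pn]] <- define_fringe(geom, pn, dep)
  }
  ctx$fringes <- fringes
  anyfringe <- array(FALSE, n)
  for (f in fringes) anyfringe <- anyfringe | f
  if (has_branch_cells)
    for (bm in geom$branch_cells) anyfringe <- anyfringe | bm

  # stencil-order map
  fluid_for_depth <- (tags != 0) & !anyfringe
  depth <- interior_depth_cpp(as.integer(fluid_for_depth), n, per, 4L)
  dim(depth) <- n
  ord <- array(2L, n)
  ord[depth >= 4] <- config$fd_order
  ord[depth == 3] <- min(4L, config$fd_order)
  ctx$orderCell <- as.integer(ord)
  # the low-pass filter acts only on well-resolved interior faces; across
  # the wall kink it would inject spurious momentum
  deep <- depth >= 4
  all_fluid <- all(deep)
  ctx$filtU <- if (all_fluid) NULL else face_avg(deep + 0, 1, per[1]) >= 1
  ctx$filtV <- if (all_fluid) NULL else face_avg(deep + 0, 2, per[2]) >= 1
  ctx$filtW <- if (all_fluid) NULL else face_avg(deep + 0, 3, per[3]) >= 1

  # face-interpolated phi and masks
  phiU <- face_avg(phi, 1, per[1]); phiV <- face_avg(phi, 2, per[2])
  phiW <- face_avg(phi, 3, per[3])
  solidU <- phiU >= 0; solidV <- phiV >= 0; solidW <- phiW >= 0

  inletF <- if (!is.null(inflow)) fringes[["inlet"]] else array(FALSE, n)
  # neck-artery tubes carry a prescribed share of the instantaneous inflow
  # (the "adaptive" 15% split) as a suction patch at their mouths; all
  # their cells sit outside the pressure solve and their faces are fixed
  # like the inlet's
  branchF <- array(FALSE, n)
  if (has_branch_cells) {
    for (bm in geom$branch_cells) branchF <- branchF | bm
  } else {
    for (pn in names(fringes))
      if (!pn %in% c("inlet", "outlet_desc")) branchF <- branchF | fringes[[pn]]
  }
  prescF <- inletF | branchF
  adjx <- function(f) { # cell mask -> x-face adjacency, etc.
    n1 <- dim(f)[1]
    f[c(1, 1:n1), , , drop = FALSE] | f[c(1:n1, n1), , , drop = FALSE]
  }
  adjy <- function(f) {
    n2 <- dim(f)[2]
    f[, c(1, 1:n2), , drop = FALSE] | f[, c(1:n2, n2), , drop = FALSE]
  }
  adjz <- function(f) {
    n3 <- dim(f)[3]
    f[, , c(1, 1:n3), drop = FALSE] | f[, , c(1:n3, n3), drop = FALSE]
  }
  fixU <- solidU | adjx(prescF)
  fixV <- solidV | adjy(prescF)
  fixW <- solidW | adjz(prescF)
  # continuity masks: the discrete mass balance lives on the staircase cell
  # boundary — a face whose centre is fluid but whose neighbour cell is
  # solid carries reconstructed velocity for stencils, never flux
  cellSolid <- tags == 0L
  ctx$contU <- solidU | adjx(cellSolid)
  ctx$contV <- solidV | adjy(cellSolid)
  ctx$contW <- solidW | adjz(cellSolid)
  # non-periodic domain boundary faces are never updated by the projection
  if (!per[1]) { fixU[1, , ] <- TRUE; fixU[n[1] + 1, , ] <- TRUE }
  if (!per[2]) { fixV[, 1, ] <- TRUE; fixV[, n[2] + 1, ] <- TRUE }
  if (!per[3]) { fixW[, , 1] <- TRUE; fixW[, , n[3] + 1] <- TRUE }
  ctx$fixU <- as.integer(fixU); ctx$fixV <- as.integer(fixV)
  ctx$fixW <- as.integer(fixW)
  ctx$solidU <- solidU; ctx$solidV <- solidV; ctx$solidW <- solidW

  # cell types for the pressure Poisson solve: the descending fringe holds
  # the Windkessel Dirichlet pressure; inlet and neck fringes (prescribed
  # velocity) are excluded
  ctype <- array(0L, n)
  ctype[tags != 0] <- 1L
  ctype[prescF] <- 0L
  dirv <- array(0, n)
  if (!is.null(fringes[["outlet_desc"]]))
    ctype[fringes[["outlet_desc"]]] <- 2L
  ctx$ctype <- as.integer(ctype)
  ctx$dirval <- as.numeric(dirv)
  ctx$fluid_cells <- array((ctype != 0L) + 0, n)

  # sharp-interface reconstruction plan per component
  ctx$recon <- list(
    u = recon_plan(phiU, ctx, 0L, geom),
    v = recon_plan(phiV, ctx, 1L, geom),
    w = recon_plan(phiW, ctx, 2L, geom))
  # ghost faces keep their relaxed values between passes; only deep solid
  # faces are hard-zeroed
  zu <- solidU; zu[ctx$recon$u$idx + 1L] <- FALSE
  zv <- solidV; zv[ctx$recon$v$idx + 1L] <- FALSE
  zw <- solidW; zw[ctx$recon$w$idx + 1L] <- FALSE
  ctx$zeroU <- zu; ctx$zeroV <- zv; ctx$zeroW <- zw

  # inflow jet plan: z-faces adjacent to the inlet fringe
  if (!is.null(inflow)) {
    fz <- adjz(inletF)
    idx <- which(fz)
    ai <- arrayInd(idx, dim(fz))
    fx <- grid$origin[1] + (ai[, 1] - 0.5) * grid$h[1]
    fy <- grid$origin[2] + (ai[, 2] - 0.5) * grid$h[2]
    injet <- if (inflow$r_jet <= 0) rep(FALSE, length(fx))
             else (fx - inflow$C[1])^2 + (fy - inflow$C[2])^2 <= inflow$r_jet^2
    ctx$jet_faces <- idx[injet]
    ctx$cusp_faces <- idx[!injet]
    # inlet interface plane for flux accounting (open faces only: rim
    # faces inside the wall carry ghost values, not flux)
    kin <- geom$patches[["inlet"]]$k_ct
    ctx$inlet_kface <- kin
    ctx$inlet_mask2d <- geom$patches[["inlet"]]$mask2d & !array(ctx$contW, c(n[1], n[2], n[3] + 1))[, , kin]
  }

  # outlet plans
  outs <- list()
  for (pn in names(geom$patches)) {
    if (pn == "inlet" || is.null(fringes[[pn]])) next
    p <- geom$patches[[pn]]
    f <- fringes[[pn]]
    kf <- if (p$axis < 0) p$k_ct else p$k_ct + 1L  # interface z-face plane
    klayers <- which(apply(f, 3, any))
    faces <- if (p$axis < 0) c(klayers, kf) else c(kf, klayers + 1L)
    kind <- if (pn == "outlet_desc") "windkessel" else "prescribed"
    open2d <- p$mask2d & !array(ctx$contW, c(n[1], n[2], n[3] + 1))[, , kf]
    outs[[pn]] <- list(name = pn, sgn = sign(p$axis), mask2d = open2d,
                       kface = kf, face_layers = sort(unique(faces)),
                       area = sum(open2d) * h[1] * h[2],
                       cells = which(f), kind = kind)
  }
  if (has_branch_cells) {
    freeF <- (tags != 0) & !branchF & !inletF
    for (b in names(geom$branch_cells)) {
      B <- geom$branch_cells[[b]]
      up <- array(FALSE, c(n[1], n[2], n[3] + 1))
      dn <- up
      up[, , 2:n[3]] <- B[, , 2:n[3]] & freeF[, , 1:(n[3] - 1)]
      dn[, , 2:n[3]] <- freeF[, , 2:n[3]] & B[, , 1:(n[3] - 1)]
      contW3 <- array(ctx$contW, c(n[1], n[2], n[3] + 1))
      up <- up & !contW3    # suction acts through open faces only
      dn <- dn & !contW3
      adj <- array(FALSE, c(n[1], n[2], n[3] + 1))
      adj[, , 1:n[3]] <- B
      adj[, , 2:(n[3] + 1)] <- adj[, , 2:(n[3] + 1)] | B
      # free lumen cells feeding the mouth: pressure sensed here drives the
      # adaptive split of the neck flow
      iu <- which(up, arr.ind = TRUE)
      idn <- which(dn, arr.ind = TRUE)
      pc <- rbind(cbind(iu[, 1], iu[, 2], iu[, 3] - 1L),
                  idn[, , drop = FALSE])
      probe_cells <- unique((pc[, 1]) + n[1] * ((pc[, 2] - 1L) +
                            n[2] * (pc[, 3] - 1L)))
      outs[[b]] <- list(name = b, kind = "suction",
                        wfaces_all = which(adj),
                        mouth_up = which(up), mouth_dn = which(dn),
                        n_mouth = sum(up) + sum(dn),
                        probe_cells = probe_cells)
    }
  }
  ctx$outlets <- outs
  ctx$imbalance_steps <- 0L
  class(ctx) <- "ns_context"
  ctx
}

# reconstruction plan for one component: faces to rebuild, probe points,
# linear factors d/hp. All in solver units, kernel coordinates (origin 0).
recon_plan <- function(phiF, ctx, stag, geom) {
  n <- ctx$n; h <- ctx$h
  nb <- !(phiF < 0)
  # near-wall fluid faces, plus a ghost band of just-solid faces that keeps
  # stencils and interpolants smooth across the wall
  gb <- 1.5 * min(h)
  near <- ((phiF < 0) &
    (shift_clamp(nb, 1, -1) | shift_clamp(nb, 1, 1) |
     shift_clamp(nb, 2, -1) | shift_clamp(nb, 2, 1) |
     shift_clamp(nb, 3, -1) | shift_clamp(nb, 3, 1))) |
    (phiF >= 0 & phiF < gb)
  idx <- which(near)
  if (!length(idx))
    return(list(idx = integer(0), f1 = numeric(0), pts1 = matrix(0, 0, 3),
                f2 = numeric(0), pts2 = matrix(0, 0, 3)))
  ai <- arrayInd(idx, dim(phiF))
  off <- c(0.5, 0.5, 0.5); off[stag + 1] <- 0
  pos <- cbind((ai[, 1] - 1 + off[1]) * h[1],
               (ai[, 2] - 1 + off[2]) * h[2],
               (ai[, 3] - 1 + off[3]) * h[3])
  # outward normal at the face from the cell-centred phi gradient
  pts_m <- sweep(pos * ctx$config$L0, 2, geom$grid$origin, "+")
  nrm <- tryCatch(surface_normals(geom, pts_m), error = function(e) NULL)
  if (is.null(nrm)) {
    # degenerate normals somewhere: fall back per-point
    g <- phi_gradient(geom)
    pl <- pos * ctx$config$L0
    nrm <- sapply(1:3, function(a)
      sample_comp_cpp(as.numeric(g[[a]]), n, 3L, n, geom$grid$h,
                      rep(FALSE, 3), pl))
    nrm <- matrix(nrm, ncol = 3)
    mag <- sqrt(rowSums(nrm^2))
    bad <- mag < 0.1
    if (any(bad)) {
      message("ibm: ", sum(bad),
              " degenerate normals replaced by nearest-axis fallback")
      nrm[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
      mag[bad] <- 1
    }
    nrm <- nrm / mag
  }
  d <- -phiF[idx]                      # distance to the wall
  # probe depths below the wall: deep enough that the probes' interpolation
  # stencils clear the reconstructed near-wall band (otherwise mutually
  # reconstructed faces in concave corners feed back with gain > 1)
  hp1 <- 2.0 * min(h)
  hp2 <- 4.0 * min(h)
  wall <- pos + nrm * d
  # quadratic no-slip profile through (0, 0), (hp1, u1), (hp2, u2)
  f1 <- d * (d - hp2) / (hp1 * (hp1 - hp2))
  f2 <- d * (d - hp1) / (hp2 * (hp2 - hp1))
  list(idx = as.integer(idx - 1L),
       f1 = f1, pts1 = wall - nrm * hp1,
       f2 = f2, pts2 = wall - nrm * hp2)
}

#' Sharp-interface immersed-boundary reconstruction
#'
#' Sets solid-face velocities to zero and rebuilds near-wall face velocities
#' as a linear no-slip profile between the wall (located by the
#' signed-distance field) and an interpolated fluid probe along the local
#' normal.
#'
#' @param state a `flow_state`.
#' @param ctx an `ns_context`.
#' @return The reconstructed `flow_state`.
#' @export
ibm_reconstruct <- function(state, ctx) {
  n <- ctx$n; h <- ctx$h; per <- ctx$periodic
  state$u[ctx$zeroU] <- 0
  state$v[ctx$zeroV] <- 0
  state$w[ctx$zeroW] <- 0
  r <- ctx$recon
  if (length(r$u$idx))
    state$u <- array(ibm_apply_cpp(as.numeric(state$u), dim(state$u), 0L, n,
                                   h, per, r$u$idx, r$u$f1, r$u$pts1,
                                   r$u$f2, r$u$pts2),
                     dim(state$u))
  if (length(r$v$idx))
    state$v <- array(ibm_apply_cpp(as.numeric(state$v), dim(state$v), 1L, n,
                                   h, per, r$v$idx, r$v$f1, r$v$pts1,
                                   r$v$f2, r$v$pts2),
                     dim(state$v))
  if (length(r$w$idx))
    state$w <- array(ibm_apply_cpp(as.numeric(state$w), dim(state$w), 2L, n,
                                   h, per, r$w$idx, r$w$f1, r$w$pts1,
                                   r$w$f2, r$w$pts2),
                     dim(state$w))
  state
}

# periodic image planes kept in sync
sync_periodic <- function(state, ctx) {
  n <- ctx$n
  if (ctx$periodic[1]) state$u[n[1] + 1, , ] <- state$u[1, , ]
  if (ctx$periodic[2]) state$v[, n[2] + 1, ] <- state$v[, 1, ]
  if (ctx$periodic[3]) state$w[, , n[3] + 1] <- state$w[, , 1]
  state
}

#' Apply boundary conditions
#'
#' Solid and near-wall faces are reconstructed (no slip on the immersed
#' wall); the inlet fringe forces the plug-jet profile at time `t` (plus
#' the optional seeded jet perturbation); outlet fringes are set to
#' zero-gradient velocity with a global flux correction so that total
#' outflow matches total inflow.
#'
#' @param state a `flow_state`.
#' @param t time (s) at which waveform values are evaluated.
#' @param ctx an `ns_context`.
#' @param noise optional numeric vector of per-jet-face velocity
#'   perturbations (solver units), usually drawn by [run_beat()].
#' @return The updated `flow_state`; flux diagnostics in attribute `"flux"`.
#' @export
apply_bcs <- function(state, t, ctx, noise = NULL) {
  state <- ibm_reconstruct(state, ctx)
  flux <- c(Q_in = 0, Q_out = 0, corr = 0)
  if (!is.null(ctx$inflow)) {
    uval <- ctx$inflow$waveform$fun(t) / ctx$config$U0
    jet <- rep(uval, length(ctx$jet_faces))
    if (!is.null(noise)) jet <- pmax(jet + noise, 0)
    state$w[ctx$jet_faces] <- jet
    state$w[ctx$cusp_faces] <- 0
    flux["Q_in"] <- sum(state$w[, , ctx$inlet_kface][ctx$inlet_mask2d]) *
      ctx$h[1] * ctx$h[2]
  }
  # in-plane components vanish on all prescribed (inlet/neck fringe) faces
  state$u[ctx$fixU == 1L & !ctx$solidU] <- 0
  state$v[ctx$fixV == 1L & !ctx$solidV] <- 0
  if (length(ctx$outlets)) {
    Qout <- 0
    # neck outlets carry 15% of the instantaneous inflow in total, split
    # adaptively in proportion to each mouth's overpressure relative to the
    # outlet reference: a branch sitting on the impingement stagnation
    # pocket discharges it preferentially
    suction <- Filter(function(o) o$kind == "suction", ctx$outlets)
    if (length(suction)) {
      pref <- if (!is.null(ctx$pressure_outlet))
        ctx$pressure_outlet(t) * 133.322 /
          (ctx$config$rho * ctx$config$U0^2) else 0
      dem <- vapply(suction, function(o)
        max(mean(state$p[o$probe_cells]) - pref, 0), numeric(1))
      target <- if (sum(dem) > 1e-12) dem / sum(dem)
                else rep(1 / length(suction), length(suction))
      # the split relaxes toward the overpressure-proportional target over
      # a few milliseconds; an instantaneous split flickers between
      # branches and rings the pressure field
      prev <- state$neck_share
      if (is.null(prev) || length(prev) != length(target))
        prev <- rep(1 / length(suction), length(suction))
      share <- 0.98 * prev + 0.02 * target
      state$neck_share <- share
      Qneck <- 0.15 * flux[["Q_in"]]
      for (qi in seq_along(suction)) {
        o <- suction[[qi]]
        qb <- share[qi] * Qneck
        state$w[o$wfaces_all] <- 0
        qf <- qb / (o$n_mouth * ctx$h[1] * ctx$h[2])
        state$w[o$mouth_up] <- qf
        state$w[o$mouth_dn] <- -qf
        Qout <- Qout + qb
      }
    }
    npresc <- sum(vapply(ctx$outlets, function(o) o$kind == "prescribed",
                         logical(1)))
    for (o in ctx$outlets) {
      if (o$kind != "prescribed") next
      qb <- if (npresc > 0) 0.15 / npresc * flux[["Q_in"]] else 0
      wb <- o$sgn * qb / o$area
      for (kf in o$face_layers)
        state$w[, , kf][o$mask2d] <- wb
      Qout <- Qout + qb
    }
    # descending outlet: zero-gradient copy plus the closing correction
    for (o in ctx$outlets) {
      if (o$kind != "windkessel") next
      src <- state$w[, , o$kface]
      dv <- (flux[["Q_in"]] - Qout -
             o$sgn * sum(src[o$mask2d]) * ctx$h[1] * ctx$h[2]) / o$area
      for (kf in o$face_layers)
        state$w[, , kf][o$mask2d] <- src[o$mask2d] + o$sgn * dv
      Qout <- Qout + o$sgn * sum(src[o$mask2d]) * ctx$h[1] * ctx$h[2]
      flux["corr"] <- if (abs(flux[["Q_in"]]) > 1e-12)
        abs(dv) * o$area / abs(flux[["Q_in"]]) else 0
    }
    flux["Q_out"] <- Qout
  }
  state <- sync_periodic(state, ctx)
  attr(state, "flux") <- flux
  state
}

#' Solve the pressure Poisson equation on the masked domain
#'
#' Matrix-free preconditioned conjugate gradients on the 7-point Laplacian
#' restricted to fluid cells; homogeneous Neumann closures on immersed
#' walls and fixed faces, Dirichlet values on marked cells. A pure-Neumann
#' system with incompatible right-hand side is projected onto the
#' compatible subspace (mean removed) with a warning and returns the
#' mean-zero solution.
#'
#' @param rhs numeric array over the grid.
#' @param ctx an `ns_context` (provides masks and spacing), or a
#'   `cartesian_grid` for an unmasked box.
#' @param dirichlet optional numeric array of Dirichlet values on cells
#'   marked type 2 (see `celltype`).
#' @param celltype optional integer array: 0 excluded, 1 unknown,
#'   2 Dirichlet; defaults to the context's.
#' @param tol absolute tolerance on the residual max-norm.
#' @param maxit iteration cap.
#' @param warm optional initial guess.
#' @return Numeric array `p`; iteration count and residual in attributes
#'   `"iter"`, `"resid"`.
#' @export
pressure_poisson <- function(rhs, ctx, dirichlet = NULL, celltype = NULL,
                             tol = 1e-9, maxit = 20000L, warm = NULL) {
  if (inherits(ctx, "cartesian_grid")) {
    n <- ctx$n
    ctx <- list(n = n, h = ctx$h,
                periodic = c(FALSE, FALSE, FALSE),
                ctype = rep(1L, prod(n)), dirval = rep(0, prod(n)),
                fixU = integer((n[1] + 1) * n[2] * n[3]),
                fixV = integer(n[1] * (n[2] + 1) * n[3]),
                fixW = integer(n[1] * n[2] * (n[3] + 1)))
  }
  n <- ctx$n
  ct <- if (is.null(celltype)) ctx$ctype else as.integer(celltype)
  dv <- if (is.null(dirichlet)) ctx$dirval else as.numeric(dirichlet)
  p0 <- if (is.null(warm)) rep(0, prod(n)) else as.numeric(warm)
  sol <- poisson_cg_cpp(as.numeric(rhs), ct, dv,
                        ctx$fixU, ctx$fixV, ctx$fixW,
                        n, ctx$h, ctx$periodic, p0, tol, as.integer(maxit))
  if (sol$resid > tol)
    stop(sprintf("pressure solver did not converge: residual %.3e after %d iterations",
                 sol$resid, sol$iter), call. = FALSE)
  if (isTRUE(sol$projected))
    warning("incompatible Neumann right-hand side projected to mean zero")
  p <- sol$p
  dim(p) <- n
  attr(p, "iter") <- sol$iter
  attr(p, "resid") <- sol$resid
  p
}

# projection of one stage: make the velocity divergence-free (walls
# impermeable: solid/ghost faces carry no flux), carrying the Windkessel
# Dirichlet value on the descending fringe
project_stage <- function(state, ctx, dtk, t) {
  dirv <- ctx$dirval
  if (!is.null(ctx$pressure_outlet)) {
    for (o in ctx$outlets) {
      if (o$kind != "windkessel") next
      dirv[o$cells] <- ctx$pressure_outlet(t) * 133.322 /
        (ctx$config$rho * ctx$config$U0^2)
    }
  }
  rhs <- divergence_masked_cpp(as.numeric(state$u), as.numeric(state$v),
                               as.numeric(state$w),
                               as.integer(ctx$contU), as.integer(ctx$contV),
                               as.integer(ctx$contW), ctx$n, ctx$h) / dtk
  rhs[ctx$ctype != 1L] <- 0
  # divergence after correction equals dtk times the Poisson residual, so
  # this tolerance keeps max |D u| below 1e-8
  p <- pressure_poisson(rhs, ctx, dirichlet = dirv,
                        tol = 8e-9 / dtk, warm = state$p)
  grad_correct_cpp(state$u, state$v, state$w, as.numeric(p), ctx$ctype,
                   ctx$fixU, ctx$fixV, ctx$fixW, ctx$n, ctx$h,
                   ctx$periodic, dtk)
  state$p <- mirror_wall_pressure(p, ctx)
  sync_periodic(state, ctx)
}

# Neumann closure: copy the mean of fluid-neighbour pressures into solid
# cells adjacent to the fluid so near-wall interpolation stays clean
mirror_wall_pressure <- function(p, ctx) {
  fl <- ctx$fluid_cells
  num <- array(0, ctx$n); den <- array(0, ctx$n)
  for (axis in 1:3) for (s in c(-1, 1)) {
    num <- num + shift_clamp(p * fl, axis, s)
    den <- den + shift_clamp(fl, axis, s)
  }
  tgt <- (fl == 0) & (den > 0)
  p[tgt] <- num[tgt] / den[tgt]
  p
}

#' Advance one time step (low-storage RK3 with per-stage projection)
#'
#' Three Williamson stages of the advective-diffusive terms; after each
#' stage the boundary conditions are applied and the velocity is projected
#' onto the divergence-free space through a pressure Poisson solve with the
#' outlet Dirichlet value.
#'
#' @param state a `flow_state`.
#' @param dt time step (s).
#' @param ctx an `ns_context`.
#' @param noise optional jet-face noise vector (see [apply_bcs()]).
#' @return The advanced `flow_state` (time `t + dt`).
#' @export
advance_rk3 <- function(state, dt, ctx, noise = NULL) {
  cfg <- ctx$config
  dtn <- dt / ctx$t0                     # dimensionless step
  if (cfg$filter_amp > 0) {
    n <- ctx$n; per <- ctx$periodic
    fu <- array(filter6_cpp(as.numeric(state$u), dim(state$u), per,
                            n, cfg$filter_amp), dim(state$u))
    fv <- array(filter6_cpp(as.numeric(state$v), dim(state$v), per,
                            n, cfg$filter_amp), dim(state$v))
    fw <- array(filter6_cpp(as.numeric(state$w), dim(state$w), per,
                            n, cfg$filter_amp), dim(state$w))
    if (is.null(ctx$filtU)) {
      state$u <- fu; state$v <- fv; state$w <- fw
    } else {
      state$u[ctx$filtU] <- fu[ctx$filtU]
      state$v[ctx$filtV] <- fv[ctx$filtV]
      state$w[ctx$filtW] <- fw[ctx$filtW]
    }
    state <- sync_periodic(state, ctx)
  }
  qu <- 0; qv <- 0; qw <- 0
  for (k in 1:3) {
    tk <- state$t + RK3_C[k] * dt
    f <- cfg$force(tk)
    F <- ns_rhs_cpp(as.numeric(state$u), as.numeric(state$v),
                    as.numeric(state$w), ctx$n, ctx$h, ctx$periodic,
                    1 / cfg$Re, ctx$orderCell, as.numeric(f))
    qu <- RK3_A[k] * qu + dtn * F$Fu
    qv <- RK3_A[k] * qv + dtn * F$Fv
    qw <- RK3_A[k] * qw + dtn * F$Fw
    state$u <- state$u + array(RK3_B[k] * qu, dim(state$u))
    state$v <- state$v + array(RK3_B[k] * qv, dim(state$v))
    state$w <- state$w + array(RK3_B[k] * qw, dim(state$w))
    te <- state$t + RK3_E[k] * dt
    state <- apply_bcs(state, te, ctx, noise = noise)
    state <- project_stage(state, ctx, RK3_B[k] * dtn, te)
  }
  if (any(!is.finite(state$u)) || any(!is.finite(state$v)) ||
      any(!is.finite(state$w)))
    stop(sprintf("blow-up error at step %d (t = %.5f s): non-finite velocity",
                 state$step + 1L, state$t + dt), call. = FALSE)
  state$t <- state$t + dt
  state$step <- state$step + 1L
  state
}

#' Stable time step from the CFL and diffusive limits
#'
#' Advective limit `dt = CFL / max_cells(|u|/dx + |v|/dy + |w|/dz)` (the
#' summed form: the per-axis rule under-constrains corner flows where all
#' three components are comparable), capped by the explicit diffusive
#' limit `0.25 * dx^2 * Re` (dimensionless); returned in seconds.
#'
#' @param state a `flow_state`.
#' @param ctx an `ns_context`.
#' @return Time step (s).
#' @export
compute_dt <- function(state, ctx) {
  cfg <- ctx$config
  h <- ctx$h
  n <- ctx$n
  # ghost-band faces hold extrapolated (non-physical) values; the CFL limit
  # is taken over fluid faces
  au <- abs(state$u); au[ctx$solidU] <- 0
  av <- abs(state$v); av[ctx$solidV] <- 0
  aw <- abs(state$w); aw[ctx$solidW] <- 0
  if (!all(is.finite(c(max(au), max(av), max(aw)))))
    stop("blow-up error: non-finite velocity in compute_dt", call. = FALSE)
  s <- pmax(au[1:n[1], , , drop = FALSE], au[2:(n[1] + 1), , , drop = FALSE]) / h[1] +
       pmax(av[, 1:n[2], , drop = FALSE], av[, 2:(n[2] + 1), , drop = FALSE]) / h[2] +
       pmax(aw[, , 1:n[3], drop = FALSE], aw[, , 2:(n[3] + 1), drop = FALSE]) / h[3]
  dtd <- 0.25 * min(h)^2 * cfg$Re
  smax <- max(s)
  dtn <- if (smax > 0) min(cfg$CFL / smax, dtd) else dtd
  dtn * ctx$t0
}

#' Total kinetic energy of a state
#'
#' Dimensionless `0.5 * sum(u^2) * dV` over fluid faces.
#'
#' @param state a `flow_state`.
#' @param ctx an `ns_context`.
#' @return Scalar kinetic energy (solver units).
#' @export
kinetic_energy <- function(state, ctx) {
  dv <- prod(ctx$h)
  0.5 * dv * (sum(state$u[!ctx$solidU]^2) + sum(state$v[!ctx$solidV]^2) +
              sum(state$w[!ctx$solidW]^2))
}
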