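#' Idealized candy-cane aorta specification
#'
#' A procedural aorta: straight ascending and descending limbs of uniform
#' lumen radius joined by a half-torus arch in the x-z plane, with three
#' neck-artery branch tubes rising from the arch. The brachiocephalic branch
#' position along the arch is offset-able: positive offsets move it distal
#' (away from the jet impingement site on the outer ascending curvature),
#' negative offsets move it proximal, onto the impingement zone.
#'
#' @param lumen_radius aortic lumen radius (m).
#' @param arch_radius arch centreline radius of curvature (m); must exceed
#'   `lumen_radius`.
#' @param asc_length length of the ascending limb between the inlet plane
#'   and the arch (m).
#' @param inlet_extension,outlet_extension lengths (m) of the straight
#'   extensions outside the anatomical region where inflow/outflow fringe
#'   forcing is applied.
#' @param branch_radius radii of the three branch tubes (m), each smaller
#'   than `lumen_radius`.
#' @param branch_theta arc positions (radians along the arch measured from
#'   the ascending junction, in `(0, pi)`) of brachiocephalic, left carotid
#'   and left subclavian branches.
#' @param branch_length branch tube length above the arch centreline (m);
#'   long enough that branches exit the domain top.
#' @param branch_extension length (m) of the branch fringe extensions below
#'   the domain top.
#' @param brachio_offset arc-position offset (radians) added to the
#'   brachiocephalic `branch_theta[1]`; `>= 0` is distal of default.
#' @return Object of class `idealized_aorta_spec`.
#' @export
idealized_aorta_spec <- function(lumen_radius = 0.0145,
                                 arch_radius = 0.035,
                                 asc_length = 0.045,
                                 inlet_extension = 0.012,
                                 outlet_extension = 0.012,
                                 branch_radius = c(0.0055, 0.004, 0.0045),
                                 branch_theta = c(1.15, 1.60, 2.05),
                                 branch_length = 0.065,
                                 branch_extension = 0.008,
                                 brachio_offset = 0) {
  th <- branch_theta
  if (length(th)) th[1] <- th[1] + brachio_offset
  if (lumen_radius >= arch_radius)
    stop("spec error: lumen radius must be smaller than arch radius",
         call. = FALSE)
  if (length(branch_radius) && any(branch_radius >= lumen_radius))
    stop("spec error: branch radii must be smaller than the lumen radius",
         call. = FALSE)
  if (length(th) > 1) {
    sep <- diff(sort(th)) * arch_radius
    rr <- branch_radius[order(th)]
    need <- rr[-length(rr)] + rr[-1]
    if (any(sep < need))
      stop("spec error: branch tubes intersect along the arch", call. = FALSE)
  }
  if (length(th) && any(th <= 0 | th >= pi))
    stop("spec error: branch arc positions must lie in (0, pi)", call. = FALSE)
  structure(list(lumen_radius = lumen_radius, arch_radius = arch_radius,
                 asc_length = asc_length,
                 inlet_extension = inlet_extension,
                 outlet_extension = outlet_extension,
                 branch_radius = branch_radius, branch_theta = th,
                 branch_length = branch_length,
                 branch_extension = branch_extension,
                 brachio_offset = brachio_offset),
            class = "idealized_aorta_spec")
}

#' Default grid enclosing an idealized aorta
#'
#' Builds a `cartesian_grid` with uniform spacing `h` that encloses the
#' geometry with a margin of at least 4 cells laterally, leaves the branch
#' fringe extensions below the domain top, and keeps the inlet/outlet tubes
#' open at the domain bottom.
#'
#' @param spec an `idealized_aorta_spec`.
#' @param h uniform cell size (m).
#' @return A `cartesian_grid` centred on the arch plane.
#' @export
default_idealized_grid <- function(spec, h = 0.002) {
  a <- spec$lumen_radius; R <- spec$arch_radius
  z_arch <- spec$inlet_extension + spec$asc_length
  half_x <- R + a + 4 * h
  half_y <- a + 4 * h
  z_top <- z_arch + R + a + spec$branch_extension + 6 * h
  n <- c(ceiling(2 * half_x / h), ceiling(2 * half_y / h), ceiling(z_top / h))
  n <- pmax(n, 8L)
  cartesian_grid(n, h, origin = c(-n[1] * h / 2, -n[2] * h / 2, 0))
}

# vectorized distance to a capsule (segment p0-p1 swept by radius r)
capsule_dist <- function(x, y, z, p0, p1, r) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]; vz <- p1[3] - p0[3]
  vv <- vx^2 + vy^2 + vz^2
  t <- ((x - p0[1]) * vx + (y - p0[2]) * vy + (z - p0[3]) * vz) / vv
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - p0[1] - t * vx)^2 + (y - p0[2] - t * vy)^2 +
       (z - p0[3] - t * vz)^2) - r
}

# distance to the upper-half torus arch (centre (0,0,z_arch), plane y)
arch_dist <- function(x, y, z, z_arch, R, a) {
  zz <- z - z_arch
  q <- sqrt(x^2 + zz^2)
  dt <- sqrt((q - R)^2 + y^2) - a
  # outside the arc: nearest end cross-section (spherical cap; the straight
  # limbs overlap these caps so the union stays smooth)
  d0 <- sqrt((x - R)^2 + y^2 + zz^2) - a
  d1 <- sqrt((x + R)^2 + y^2 + zz^2) - a
  ifelse(zz >= 0, dt, pmin(d0, d1))
}

#' Build the idealized aorta level-set geometry
#'
#' Evaluates the exact signed distance to each analytic primitive (straight
#' limbs, half-torus arch, branch tubes) at every cell centre and combines
#' them by minimum; negative values are fluid. Inlet, descending-outlet and
#' three branch-outlet patches are attached with their fringe extensions.
#'
#' @param spec an `idealized_aorta_spec`.
#' @param grid a `cartesian_grid` enclosing the geometry with at least 4
#'   cells of margin (see [default_idealized_grid()]).
#' @return A `levelset_geometry`.
#' @export
make_idealized_aorta <- function(spec, grid = default_idealized_grid(spec)) {
  a <- spec$lumen_radius; R <- spec$arch_radius
  z_arch <- spec$inlet_extension + spec$asc_length
  co <- grid_coords(grid)
  x <- co$x; y <- co$y; z <- co$z
  xmax <- grid$origin[1] + grid$n[1] * grid$h[1]
  ymax <- grid$origin[2] + grid$n[2] * grid$h[2]
  zmax <- grid$origin[3] + grid$n[3] * grid$h[3]
  if (R + a > min(xmax, -grid$origin[1]) - 3 * grid$h[1] ||
      a > min(ymax, -grid$origin[2]) - 3 * grid$h[2] ||
      z_arch + R + a > zmax - 3 * grid$h[3])
    stop("bounds error: geometry exceeds grid with the required margin",
         call. = FALSE)

  below <- grid$origin[3] - 0.05   # limb endpoints outside the box: open ends
  phi_aorta <- pmin(
    capsule_dist(x, y, z, c(R, 0, below), c(R, 0, z_arch), a),
    capsule_dist(x, y, z, c(-R, 0, below), c(-R, 0, z_arch), a),
    arch_dist(x, y, z, z_arch, R, a))
  nb <- length(spec$branch_radius)
  bx <- numeric(nb)
  phi <- phi_aorta
  phi_b <- vector("list", nb)
  for (b in seq_len(nb)) {
    th <- spec$branch_theta[b]
    p0 <- c(R * cos(th), 0, z_arch + R * sin(th))
    p1 <- p0 + c(0, 0, spec$branch_length)
    if (p1[3] < zmax + spec$branch_radius[b])
      stop("spec error: branch tube does not exit the domain top",
           call. = FALSE)
    phi_b[[b]] <- capsule_dist(x, y, z, p0, p1, spec$branch_radius[b])
    phi <- pmin(phi, phi_b[[b]])
    bx[b] <- p0[1]
  }
  dim(phi) <- grid$n

  geom <- levelset_geometry(grid, phi, symmetry_plane = "y=0")
  zc <- grid_axes(grid)[[3]]
  xc <- grid_axes(grid)[[1]]

  # bottom patches: first cell layer inside the anatomical region
  k_in <- which(zc >= spec$inlet_extension)[1]
  k_out <- which(zc >= spec$outlet_extension)[1]
  fluid_in <- geom$phi[, , k_in] < 0
  fluid_out <- geom$phi[, , k_out] < 0
  geom <- add_patch(geom, "inlet", axis = -3L, k_ct = k_in,
                    mask2d = fluid_in & (xc > 0))
  geom <- add_patch(geom, "outlet_desc", axis = -3L, k_ct = k_out,
                    mask2d = fluid_out & (xc < 0))
  # branch patches: last layer below the branch fringe region
  if (nb > 0) {
    k_br <- max(which(zc <= zmax - spec$branch_extension))
    top <- geom$phi[, , k_br] < 0
    idx <- which(top, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      assign_b <- apply(abs(outer(xc[idx[, 1]], bx, "-")), 1, which.min)
      for (b in seq_len(nb)) {
        m <- matrix(FALSE, grid$n[1], grid$n[2])
        sel <- idx[assign_b == b, , drop = FALSE]
        m[sel] <- TRUE
        geom <- add_patch(geom, paste0("branch_", b), axis = 3L,
                          k_ct = k_br, mask2d = m)
      }
    }
  }
  # cells that are fluid only because of a branch tube (the protruding
  # neck-artery volumes, outside the aortic lumen proper); the solver
  # prescribes the neck suction over these
  if (nb > 0) {
    geom$branch_cells <- lapply(seq_len(nb), function(b) {
      m <- (phi_aorta >= 0) & (phi_b[[b]] < 0)
      dim(m) <- grid$n
      m
    })
    names(geom$branch_cells) <- paste0("branch_", seq_len(nb))
  }
  geom$spec <- spec
  geom
}

#' Low-level level-set geometry constructor
#'
#' Wraps a signed-distance field (negative in fluid) on a Cartesian grid and
#' classifies its cells. Used directly by benchmark geometries; application
#' geometries come from [make_idealized_aorta()] or [levelset_from_mask()].
#'
#' @param grid a `cartesian_grid`.
#' @param phi numeric array `grid$n` of signed distances (m), negative in
#'   the fluid.
#' @param symmetry_plane optional plane description string.
#' @return Object of class `levelset_geometry` with fields `grid`, `phi`,
#'   `cell_tags` (0 solid, 1 fluid, 2 boundary) and `patches`.
#' @export
levelset_geometry <- function(grid, phi, symmetry_plane = NULL) {
  stopifnot(inherits(grid, "cartesian_grid"), all(dim(phi) == grid$n))
  tags <- classify_cells_cpp(as.numeric(phi), grid$n)
  dim(tags) <- grid$n
  structure(list(grid = grid, phi = phi, cell_tags = tags,
                 patches = list(), symmetry_plane = symmetry_plane),
            class = "levelset_geometry")
}

# attach a named inlet/outlet patch; cross-section = mask2d at layer k_ct,
# fringe = extrusion outward along the (signed) z axis
add_patch <- function(geom, name, axis, k_ct, mask2d) {
  stopifnot(abs(axis) == 3)  # patches are z-normal in this release
  geom$patches[[name]] <- list(name = name, axis = axis, k_ct = k_ct,
                               mask2d = mask2d)
  geom
}

#' Recompute cell tags from the signed-distance field
#'
#' Fluid cells are `phi < 0`; boundary cells are fluid cells with at least
#' one face-neighbour at `phi >= 0`; the rest are solid. The three tags
#' partition the grid.
#'
#' @param geom a `levelset_geometry`.
#' @return Integer array: 0 = solid, 1 = fluid, 2 = boundary.
#' @export
classify_cells <- function(geom) {
  tags <- classify_cells_cpp(as.numeric(geom$phi), geom$grid$n)
  dim(tags) <- geom$grid$n
  tags
}

#' Outward wall normals at sample points
#'
#' Evaluates `n = grad(phi)/|grad(phi)|` by central differences of the
#' signed-distance field and trilinear interpolation; normals point from
#' fluid into solid.
#'
#' @param geom a `levelset_geometry`.
#' @param points numeric matrix (m x 3) of sample locations (m), within one
#'   cell of the zero level set.
#' @return Numeric matrix (m x 3) of unit normals.
#' @export
surface_normals <- function(geom, points) {
  points <- rbind(points)
  g <- phi_gradient(geom)
  pl <- sweep(points, 2, geom$grid$origin)   # kernel coords start at 0
  n <- sapply(1:3, function(a)
    sample_comp_cpp(as.numeric(g[[a]]), geom$grid$n, 3L, geom$grid$n,
                    geom$grid$h, rep(FALSE, 3), pl))
  n <- matrix(n, ncol = 3)
  mag <- sqrt(rowSums(n^2))
  if (any(mag < 0.1))
    stop("degenerate-normal error: |grad phi| < 0.1 at a sample point",
         call. = FALSE)
  n / mag
}

# cached central-difference gradient of phi
phi_gradient <- function(geom) {
  if (!is.null(attr(geom, "grad"))) return(attr(geom, "grad"))
  n <- geom$grid$n; h <- geom$grid$h
  lapply(1:3, function(a) {
    g <- fd_apply_cpp(as.numeric(geom$phi), n, a - 1L, 1L, 2L, h[a], FALSE)
    dim(g) <- n
    g
  })
}

#' Fringe mask for a patch
#'
#' The patch cross-section extruded `depth` cells outward along the patch
#' axis; entirely outside the anatomical region.
#'
#' @param geom a `levelset_geometry` with patches.
#' @param patch patch name.
#' @param depth number of cell layers (>= 2).
#' @return Logical array over the grid.
#' @export
define_fringe <- function(geom, patch, depth) {
  p <- geom$patches[[patch]]
  if (is.null(p)) stop("unknown patch: ", patch, call. = FALSE)
  stopifnot(depth >= 2)
  n <- geom$grid$n
  dir <- sign(p$axis)
  layers <- p$k_ct + dir * seq_len(depth)
  if (any(layers < 1 | layers > n[3]))
    stop("bounds error: fringe of depth ", depth, " leaves the grid",
         call. = FALSE)
  m <- array(FALSE, n)
  for (k in layers) m[, , k] <- p$mask2d & (geom$phi[, , k] < 0)
  m
}

#' Wall sample points for surface fields
#'
#' One sample per boundary cell, at the foot of the normal on the zero
#' level set: `x_w = x_c - phi(x_c) * n(x_c)`.
#'
#' @param geom a `levelset_geometry`.
#' @return List with `points` (m x 3), `normals` (m x 3) and `cells`
#'   (boundary-cell linear indices).
#' @export
surface_points <- function(geom) {
  cells <- which(geom$cell_tags == 2)
  n <- geom$grid$n
  arr <- arrayInd(cells, n)
  ctr <- sweep((arr - 0.5) %*% diag(geom$grid$h), 2, geom$grid$origin, "+")
  nrm <- surface_normals(geom, ctr)
  pts <- ctr - geom$phi[cells] * nrm
  list(points = pts, normals = nrm, cells = cells)
}
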