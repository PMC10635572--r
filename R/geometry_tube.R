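#' Straight-tube benchmark geometry
#'
#' A circular tube of given radius along z with inlet (`zlo`) and outlet
#' (`zhi`) patches, used for mass-balance and inflow benchmarks.
#'
#' @param radius lumen radius (m).
#' @param length tube length (m).
#' @param h uniform grid spacing (m).
#' @param extension patch cut-plane depth from each end (m).
#' @return A `levelset_geometry` with patches `"inlet"` and `"outlet_desc"`.
#' @export
make_straight_tube <- function(radius, length, h, extension = 6 * h) {
  nxy <- ceiling(2 * (radius + 4 * h) / h)
  nz <- ceiling(length / h)
  grid <- cartesian_grid(c(nxy, nxy, nz), h,
                         origin = c(-nxy * h / 2, -nxy * h / 2, 0))
  co <- grid_coords(grid)
  phi <- sqrt(co$x^2 + co$y^2) - radius
  geom <- levelset_geometry(grid, phi)
  zc <- grid_axes(grid)[[3]]
  k_in <- which(zc >= extension)[1]
  k_out <- max(which(zc <= length - extension))
  geom <- add_patch(geom, "inlet", axis = -3L, k_ct = k_in,
                    mask2d = geom$phi[, , k_in] < 0)
  geom <- add_patch(geom, "outlet_desc", axis = 3L, k_ct = k_out,
                    mask2d = geom$phi[, , k_out] < 0)
  geom
}
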