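#' Build the plug-jet inflow profile
#'
#' Splits the inlet cross-section `Omega_in` into a circular jet core
#' `Omega_jet` of radius `r_jet` about the first-moment centroid and a
#' stagnant cusp region `Omega_cusp`; the axial inflow velocity is the echo
#' waveform on the jet and zero on the cusp, with no transverse components
#' (uni-directional plug profile).
#'
#' @param geom a `levelset_geometry` with an inlet patch.
#' @param waveform a `velocity_waveform` (the echo trace).
#' @param Q_peak peak flow rate (m^3/s), default 4e-4.
#' @param patch inlet patch name, default `"inlet"`.
#' @param plug `"jet"` (stenotic core of radius `r_jet`, the default) or
#'   `"full"` (plug over the whole cross-section, for benchmark inflows).
#' @return Object of class `inflow_profile` with masks `omega_in`,
#'   `omega_jet`, `omega_cusp`, centroid `C` (m), `r_jet` (m) and the
#'   waveform.
#' @export
build_inflow <- function(geom, waveform, Q_peak = 4e-4, patch = "inlet",
                         plug = c("jet", "full")) {
  plug <- match.arg(plug)
  p <- geom$patches[[patch]]
  if (is.null(p)) stop("geometry has no patch named ", patch, call. = FALSE)
  stopifnot(inherits(waveform, "velocity_waveform"))
  mask <- p$mask2d
  ax <- grid_axes(geom$grid)
  C <- inflow_centroid(mask, ax[[1]], ax[[2]])
  if (plug == "full") {
    jet <- mask
    r_jet <- Inf
  } else if (waveform$U_peak <= 0) {
    # a silent trace drives no jet at all
    r_jet <- 0
    jet <- mask & FALSE
  } else {
    r_jet <- jet_radius(Q_peak, waveform$U_peak)
    area_in <- sum(mask) * geom$grid$h[1] * geom$grid$h[2]
    if (pi * r_jet^2 > area_in)
      stop("spec error: jet radius ", signif(r_jet, 3),
           " m exceeds the lumen cross-section; lower U_peak or enlarge ",
           "the lumen", call. = FALSE)
    dx2 <- outer((ax[[1]] - C[1])^2, (ax[[2]] - C[2])^2, "+")
    jet <- mask & (dx2 <= r_jet^2)
  }
  structure(list(omega_in = mask, omega_jet = jet,
                 omega_cusp = mask & !jet, C = C, r_jet = r_jet,
                 waveform = waveform, Q_peak = Q_peak, k_ct = p$k_ct),
            class = "inflow_profile")
}

#' Discrete peak flux carried by an inflow profile
#'
#' Jet-cell count times cell area times peak velocity; approaches `Q_peak`
#' as the rasterization refines.
#'
#' @param profile an `inflow_profile`.
#' @param grid the grid it was built on.
#' @return Peak volumetric flux (m^3/s).
#' @export
inflow_peak_flux <- function(profile, grid) {
  sum(profile$omega_jet) * grid$h[1] * grid$h[2] * profile$waveform$U_peak
}
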