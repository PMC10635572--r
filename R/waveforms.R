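#' @useDynLib aortaflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# mmHg <-> Pa conversion used everywhere a clinical pressure meets the solver.
MMHG_PA <- 133.322

#' Create a periodic velocity waveform
#'
#' A sampled inflow velocity trace over one cardiac cycle, as extracted from
#' continuous-wave Doppler echocardiography. Samples live on `[0, period)`;
#' interpolation between samples is periodic cubic.
#'
#' @param time numeric vector of sample times (s), strictly increasing,
#'   `0 <= t < period`.
#' @param velocity numeric vector of velocities (m/s), same length as `time`.
#'   Negative values (backflow is not part of the forward-flow model) are
#'   clamped to zero with a warning.
#' @param period cycle duration T in seconds (default 1 s, i.e. 60 bpm).
#' @return An object of class `velocity_waveform` with fields `time`,
#'   `velocity`, `period`, `U_peak` and an interpolator `fun(t)`.
#' @export
velocity_waveform <- function(time, velocity, period = 1) {
  stopifnot(length(time) == length(velocity), length(time) >= 2, period > 0)
  if (is.unsorted(time, strictly = TRUE))
    stop("waveform time must be strictly increasing", call. = FALSE)
  if (any(time < 0) || any(time >= period))
    stop("waveform samples must satisfy 0 <= t < period", call. = FALSE)
  if (any(velocity < 0)) {
    warning("negative velocities clamped to 0 (forward-flow model)")
    velocity <- pmax(velocity, 0)
  }
  wf <- new_waveform(time, velocity, period, "velocity_waveform")
  wf$U_peak <- max(velocity)
  wf
}

#' Create a periodic flow-rate waveform
#'
#' @param time sample times (s), strictly increasing, within `[0, period)`.
#' @param flow volumetric flow rate samples (m^3/s).
#' @param period cycle duration (s).
#' @return An object of class `flow_rate_waveform` with `Q_peak` and a
#'   periodic interpolator `fun(t)`.
#' @export
flow_rate_waveform <- function(time, flow, period = 1) {
  stopifnot(length(time) == length(flow), length(time) >= 2, period > 0)
  if (is.unsorted(time, strictly = TRUE))
    stop("waveform time must be strictly increasing", call. = FALSE)
  if (any(time < 0) || any(time >= period))
    stop("waveform samples must satisfy 0 <= t < period", call. = FALSE)
  wf <- new_waveform(time, flow, period, "flow_rate_waveform")
  names(wf)[names(wf) == "velocity"] <- "flow"
  wf$Q_peak <- max(flow)
  wf
}

# shared constructor: closes the period for a periodic cubic spline
new_waveform <- function(time, value, period, class) {
  tt <- c(time, time[1] + period)
  vv <- c(value, value[1])
  f0 <- stats::splinefun(tt, vv, method = "periodic")
  # forward-flow model: cubic ringing below zero is clamped
  fun <- function(t) pmax(f0(time[1] + (t - time[1]) %% period), 0)
  structure(list(time = time, velocity = value, period = period, fun = fun),
            class = class)
}

#' Read a velocity or flow-rate waveform from CSV
#'
#' Expects two numeric columns (`time_s` and either `velocity_m_s` or
#' `flow_m3_s`); the stored samples are retained exactly.
#'
#' @param file path or connection to a CSV file.
#' @param period cycle duration (s); defaults to 1 s (60 bpm).
#' @return A `velocity_waveform` or `flow_rate_waveform`, by column name.
#' @export
load_waveform <- function(file, period = 1) {
  df <- utils::read.csv(file)
  if (ncol(df) < 2)
    stop("waveform CSV must have two columns (time + value)", call. = FALSE)
  if (!all(vapply(df[1:2], is.numeric, logical(1))))
    stop("waveform CSV columns must be numeric", call. = FALSE)
  if (is.unsorted(df[[1]], strictly = TRUE))
    stop("waveform CSV time column must be strictly increasing", call. = FALSE)
  if ("flow_m3_s" %in% names(df))
    flow_rate_waveform(df[[1]], df[["flow_m3_s"]], period)
  else
    velocity_waveform(df[[1]], df[[2]], period)
}

#' Write a waveform to CSV
#'
#' @param wf a `velocity_waveform` or `flow_rate_waveform`.
#' @param file output path.
#' @export
write_waveform <- function(wf, file) {
  if (inherits(wf, "flow_rate_waveform")) {
    vals <- wf$flow
    hdr <- "time_s,flow_m3_s"
  } else {
    vals <- wf$velocity
    hdr <- "time_s,velocity_m_s"
  }
  # full 17-digit precision so samples round trip bit-exactly
  writeLines(c(hdr, sprintf("%.17g,%.17g", wf$time, vals)), file)
  invisible(file)
}

#' Synthesize a sinusoidal-systole velocity waveform
#'
#' The standard model trace: `U(t) = U_peak * sin(pi t / T_sys)` during
#' systole (`0 <= t <= T_sys`) and zero during diastole.
#'
#' @param U_peak peak velocity (m/s).
#' @param T_sys systolic duration (s), default 0.3 s.
#' @param period cycle duration (s), default 1 s.
#' @param n number of samples over one period.
#' @return A `velocity_waveform`.
#' @export
synth_waveform <- function(U_peak, T_sys = 0.3, period = 1, n = 200) {
  stopifnot(T_sys > 0, T_sys < period)
  t <- seq(0, period, length.out = n + 1)[-(n + 1)]
  v <- ifelse(t <= T_sys, U_peak * sin(pi * t / T_sys), 0)
  v <- pmax(v, 0)
  velocity_waveform(t, v, period)
}

#' Aortic jet radius from peak flow rate and peak velocity
#'
#' The unique radius for which a plug jet of speed `U_peak` carries the
#' peak flow rate: `r_jet = sqrt(Q_peak / (pi * U_peak))`.
#'
#' @param Q_peak peak flow rate (m^3/s); the standard reference value is
#'   4e-4 m^3/s.
#' @param U_peak peak jet velocity from echocardiography (m/s).
#' @return Jet radius in metres.
#' @export
jet_radius <- function(Q_peak, U_peak) {
  if (!is.numeric(Q_peak) || !is.numeric(U_peak) || Q_peak <= 0 || U_peak <= 0)
    stop("Q_peak and U_peak must be positive", call. = FALSE)
  sqrt(Q_peak / (pi * U_peak))
}

#' First moment of area (centroid) of an inlet cross-section
#'
#' @param mask logical matrix marking the inlet cells Omega_in.
#' @param x,y coordinates (m) of the cell centres along the two in-plane
#'   axes (vectors of length `nrow(mask)` / `ncol(mask)`).
#' @return Numeric pair `c(x, y)`: the area-weighted mean position.
#' @export
inflow_centroid <- function(mask, x, y) {
  stopifnot(is.logical(mask), length(x) == nrow(mask), length(y) == ncol(mask))
  if (!any(mask)) stop("empty inlet mask", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  c(mean(x[idx[, 1]]), mean(y[idx[, 2]]))
}

#' Rescale a velocity waveform into a descending-aorta flow-rate waveform
#'
#' Shape-preserving rescale `Q(t) = fraction * Q_peak * U(t) / U_peak`. The
#' standard fraction 0.85 assumes roughly 5% of aortic flow feeds each of
#' the three neck arteries.
#'
#' @param vel a `velocity_waveform`.
#' @param fraction fraction of peak inflow carried by the descending aorta,
#'   in `(0, 1]`; default 0.85.
#' @param Q_peak peak aortic flow rate (m^3/s), default 4e-4.
#' @return A `flow_rate_waveform` with `Q_peak = fraction * Q_peak`.
#' @export
flowrate_waveform <- function(vel, fraction = 0.85, Q_peak = 4e-4) {
  stopifnot(inherits(vel, "velocity_waveform"), fraction > 0, fraction <= 1)
  if (vel$U_peak <= 0) {
    return(flow_rate_waveform(vel$time, rep(0, length(vel$time)), vel$period))
  }
  flow_rate_waveform(vel$time, fraction * Q_peak * vel$velocity / vel$U_peak,
                     vel$period)
}

#' Virtually restored (post-valve-replacement) jet parameters
#'
#' Models valve replacement by scaling the jet area while maintaining the
#' flow-rate waveform: the peak velocity falls as `1 / area_factor` and the
#' jet radius grows as `sqrt(area_factor)`. A stressed variant additionally
#' multiplies the peak velocity by `velocity_factor`.
#'
#' @param U_peak diseased peak jet velocity (m/s).
#' @param r_jet diseased jet radius (m); if `NULL`, computed from `Q_peak`.
#' @param area_factor jet area multiplier (3 = standard restored model).
#' @param velocity_factor extra velocity multiplier (2 = stressed variant).
#' @param Q_peak peak flow rate (m^3/s) used when `r_jet` is not given.
#' @return List with the restored `U_peak` (m/s) and `r_jet` (m).
#' @export
restored_inflow <- function(U_peak, r_jet = NULL, area_factor = 3,
                            velocity_factor = 1, Q_peak = 4e-4) {
  stopifnot(area_factor > 0, velocity_factor > 0, U_peak > 0)
  if (is.null(r_jet)) r_jet <- jet_radius(Q_peak, U_peak)
  list(U_peak = U_peak / area_factor * velocity_factor,
       r_jet  = r_jet * sqrt(area_factor))
}
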