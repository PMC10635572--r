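#' Named beat instances of a flow waveform
#'
#' Peak flow (PF) is the waveform's (earliest) maximum; end systole (ES) is
#' the first time after PF where the flow falls to 2% of the peak;
#' mid-acceleration (MA) is halfway between the pulse start and PF,
#' three-quarters acceleration (3QA) halfway between MA and PF,
#' mid-deceleration (MD) halfway between PF and ES and quarter-deceleration
#' (QD) halfway between PF and MD.
#'
#' @param wf a `velocity_waveform` or `flow_rate_waveform`.
#' @return Object of class `beat_instances`: list with `MA`, `QA3`, `PF`,
#'   `QD`, `MD`, `ES` (seconds).
#' @export
beat_instances <- function(wf) {
  tt <- seq(0, wf$period, length.out = 20001)
  v <- wf$fun(tt)
  pk <- max(v)
  at_max <- which(v >= pk * (1 - 1e-9))
  if (length(at_max) > 1 && (tt[at_max[length(at_max)]] - tt[at_max[1]]) >
      2 * diff(tt)[1])
    warning("flat-topped waveform: earliest maximum taken as PF")
  PF <- tt[at_max[1]]
  after <- which(tt > PF & v <= 0.02 * pk)
  if (length(after) == 0) {
    warning("flow never decays below 2% of peak after PF; ES set to period")
    ES <- wf$period
  } else {
    ES <- tt[after[1]]
  }
  MA <- PF / 2
  QA3 <- (MA + PF) / 2
  MD <- (PF + ES) / 2
  QD <- (PF + MD) / 2
  structure(list(MA = MA, QA3 = QA3, PF = PF, QD = QD, MD = MD, ES = ES),
            class = "beat_instances")
}

# dimensional velocity (m/s) at physical points; quadratic interpolation
# (the near-wall ghost band keeps the stencils smooth across the wall)
sample_velocity <- function(state, ctx, pts_m, order = 2L) {
  pts <- sweep(rbind(pts_m), 2, ctx$grid$origin) / ctx$config$L0
  n <- ctx$n; h <- ctx$h; per <- ctx$periodic
  cbind(
    sample_comp_cpp(as.numeric(state$u), dim(state$u), 0L, n, h, per, pts,
                    order),
    sample_comp_cpp(as.numeric(state$v), dim(state$v), 1L, n, h, per, pts,
                    order),
    sample_comp_cpp(as.numeric(state$w), dim(state$w), 2L, n, h, per, pts,
                    order)) * ctx$config$U0
}

# dimensional pressure (Pa) at physical points (trilinear: pressure probes
# are the standard cadence stream; the mirrored wall closure keeps it clean)
sample_pressure <- function(state, ctx, pts_m, order = 1L) {
  pts <- sweep(rbind(pts_m), 2, ctx$grid$origin) / ctx$config$L0
  sample_comp_cpp(as.numeric(state$p), ctx$n, 3L, ctx$n, ctx$h,
                  ctx$periodic, pts, order) * ctx$config$rho * ctx$config$U0^2
}

#' Wall traction vector field
#'
#' Evaluates the fluid traction `sigma . n` at wall sample points. At a
#' no-slip wall the tangential traction reduces to `mu * du_t/dn` (one-sided
#' second-order normal derivative through two fluid probes and the zero wall
#' value) and the normal traction to `-p n` (pressure extrapolated along the
#' normal). Output in pascal.
#'
#' @param state a `flow_state`.
#' @param ctx an `ns_context` (supplies geometry and fluid constants).
#' @param samples optional wall samples from [surface_points()]; defaults
#'   to one sample per boundary cell.
#' @return A surface field: list with `points`, `normals`, `values`
#'   (m x 3 traction, Pa) and `time`.
#' @export
wall_traction <- function(state, ctx, samples = NULL) {
  if (is.null(samples)) samples <- surface_points(ctx$geom)
  pts <- samples$points
  nrm <- samples$normals
  delta <- min(ctx$grid$h)
  u1 <- sample_velocity(state, ctx, pts - delta * nrm)
  u2 <- sample_velocity(state, ctx, pts - 2 * delta * nrm)
  dudn <- (4 * u1 - u2) / (2 * delta)          # derivative into the fluid
  proj <- rowSums(dudn * nrm)
  dut <- dudn - proj * nrm                      # tangential part
  p1 <- sample_pressure(state, ctx, pts - delta * nrm)
  p2 <- sample_pressure(state, ctx, pts - 2 * delta * nrm)
  pw <- 2 * p1 - p2
  tr <- ctx$config$mu * dut - pw * nrm
  list(points = pts, normals = nrm, values = tr, time = state$t)
}

#' Wall shear stress magnitude
#'
#' Magnitude of the tangential part of the traction,
#' `sigma_w = |(sigma.n) - ((sigma.n).n) n|`; invariant under flipping the
#' normal and under adding any multiple of `n` to the traction.
#'
#' @param traction a traction surface field from [wall_traction()].
#' @param normals optional normals (m x 3); defaults to the field's.
#' @return Scalar surface field (`values` in Pa).
#' @export
wss_magnitude <- function(traction, normals = NULL) {
  n <- if (is.null(normals)) traction$normals else rbind(normals)
  mag <- sqrt(rowSums(n^2))
  if (any(abs(mag - 1) > 1e-6)) {
    warning("non-unit normals renormalized")
    n <- n / mag
  }
  t <- traction$values
  tt <- t - rowSums(t * n) * n
  list(points = traction$points, normals = n, values = sqrt(rowSums(tt^2)),
       time = traction$time)
}

#' Wall pressure field
#'
#' Pressure extrapolated linearly to the wall along the inward normal
#' (consistent with the homogeneous Neumann closure), in pascal.
#'
#' @inheritParams wall_traction
#' @return Scalar surface field (`values` in Pa).
#' @export
wall_pressure <- function(state, ctx, samples = NULL) {
  if (is.null(samples)) samples <- surface_points(ctx$geom)
  pts <- samples$points
  nrm <- samples$normals
  delta <- min(ctx$grid$h)
  p1 <- sample_pressure(state, ctx, pts - delta * nrm)
  p2 <- sample_pressure(state, ctx, pts - 2 * delta * nrm)
  list(points = pts, normals = nrm, values = 2 * p1 - p2, time = state$t)
}

#' Circumferential band specification
#'
#' A plane cutting the ascending aorta plus a tolerance: wall samples within
#' `halfwidth` of the plane and within `radius` of `point` form the band.
#'
#' @param point a point on the cut plane (m), roughly on the vessel axis.
#' @param normal plane normal (the local vessel axis direction).
#' @param halfwidth half-thickness of the band (m), typically one cell.
#' @param radius lateral capture radius (m) isolating one vessel.
#' @param origin_dir direction (from the band centroid) marking theta = 0.
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(point, normal = c(0, 0, 1), halfwidth, radius,
                      origin_dir = c(1, 0, 0)) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(point = point, normal = normal, halfwidth = halfwidth,
                 radius = radius, origin_dir = origin_dir),
            class = "band_spec")
}

# select band samples and assign angles about the band centroid
select_band <- function(samples, band, h) {
  d <- sweep(samples$points, 2, band$point)
  axial <- as.numeric(d %*% band$normal)
  lat <- d - outer(axial, band$normal)
  keep <- abs(axial) <= band$halfwidth &
    sqrt(rowSums(lat^2)) <= band$radius
  if (!any(keep)) stop("band error: no wall samples on the band", call. = FALSE)
  pts <- samples$points[keep, , drop = FALSE]
  # single-closed-curve check: flood fill with a 3-cell linking distance
  nk <- nrow(pts)
  thr <- 3 * max(h)
  comp <- integer(nk)
  comp[1] <- 1L
  frontier <- 1L
  while (length(frontier)) {
    newf <- integer(0)
    for (q in frontier) {
      dd <- sqrt(rowSums(sweep(pts, 2, pts[q, ])^2))
      nb <- which(dd < thr & comp == 0L)
      comp[nb] <- 1L
      newf <- c(newf, nb)
    }
    frontier <- newf
  }
  if (any(comp == 0L))
    stop("band error: the cut plane intersects the wall in more than one ",
         "closed curve (does it cut a branch?)", call. = FALSE)
  ctr <- colMeans(pts)
  e1 <- band$origin_dir - sum(band$origin_dir * band$normal) * band$normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(band$normal[2] * e1[3] - band$normal[3] * e1[2],
          band$normal[3] * e1[1] - band$normal[1] * e1[3],
          band$normal[1] * e1[2] - band$normal[2] * e1[1])
  dc <- sweep(pts, 2, ctr)
  theta <- atan2(dc %*% e2, dc %*% e1) %% (2 * pi)
  ordn <- order(theta)
  list(points = pts[ordn, , drop = FALSE],
       normals = samples$normals[keep, , drop = FALSE][ordn, , drop = FALSE],
       theta = as.numeric(theta)[ordn])
}

#' Unwrap wall shear stress onto a circumferential band
#'
#' Collects WSS on a closed band around the vessel, parameterized by the
#' angle theta about the band centroid (origin marked by the band spec's
#' `origin_dir`, positive direction fixed by the plane normal), over a set
#' of flow states.
#'
#' @param states list of `flow_state` snapshots.
#' @param ctx an `ns_context`.
#' @param band a `band_spec`.
#' @return Object of class `band_series`: `theta` (radians, increasing),
#'   `points`, `times`, `values` (time x theta matrix, Pa).
#' @export
band_unwrap <- function(states, ctx, band) {
  sel <- select_band(surface_points(ctx$geom), band, ctx$grid$h)
  samples <- list(points = sel$points, normals = sel$normals)
  vals <- t(vapply(states, function(s)
    wss_magnitude(wall_traction(s, ctx, samples))$values,
    numeric(nrow(sel$points))))
  structure(list(theta = sel$theta, points = sel$points,
                 times = vapply(states, function(s) s$t, numeric(1)),
                 values = vals),
            class = "band_series")
}

#' Probe pressure series
#'
#' Regrids sampled probe pressures onto the uniform probe cadence.
#'
#' @param times sample times (s), increasing.
#' @param values numeric matrix (length(times) x n_probes) of pressures (Pa).
#' @param locations probe locations (n_probes x 3, m).
#' @param cadence target sampling rate (Hz).
#' @return Object of class `probe_series` with uniform `times` and `values`.
#' @export
probe_series <- function(times, values, locations, cadence = 1400) {
  values <- rbind(values)
  ut <- seq(times[1], times[length(times)], by = 1 / cadence)
  uv <- apply(values, 2, function(col)
    stats::approx(times, col, xout = ut, rule = 2)$y)
  structure(list(times = ut, values = matrix(uv, nrow = length(ut)),
                 locations = locations, cadence = cadence),
            class = "probe_series")
}

# one probe's uniform signal restricted to a window
probe_window <- function(series, probe, t0, t1) {
  sel <- series$times >= t0 - 1e-12 & series$times <= t1 + 1e-12
  list(t = series$times[sel], x = series$values[sel, probe])
}

# number of window-edge samples excluded from filtered extrema: even with
# reflection padding the zero-phase filter's first ~1/5 response length at
# each end carries boundary bias
filter_guard <- function(len, fs, cutoff_hz) {
  min(round(0.2 * fs / cutoff_hz), floor(len / 4))
}

butter_filter <- function(x, fs, cutoff_hz, type) {
  wn <- cutoff_hz / (fs / 2)
  if (wn >= 1) stop("cutoff above Nyquist", call. = FALSE)
  bf <- signal::butter(2, wn, type = type)
  # odd-reflection padding tames the zero-phase filter's edge transients
  # on the short beat windows
  n <- length(x)
  np <- min(n - 1, 3 * ceiling(fs / cutoff_hz))
  pad <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, pad))
  y[(np + 1):(np + n)]
}

#' Relative pressure-oscillation metric
#'
#' `|delta_p|_max / p_i`: twice the maximum oscillation amplitude (the
#' max-minus-min of the zero-phase high-pass filtered signal on the
#' `[3QA, MD]` window) over the pressure at the 3QA instance. The high-pass
#' cutoff separates beat-scale buildup from turbulent oscillation.
#'
#' @param series a `probe_series`.
#' @param instances a `beat_instances`.
#' @param probe probe column index, default 1.
#' @param cutoff_hz high-pass cutoff (Hz), default 20.
#' @return List with `ratio`, `dp_max` (Pa) and `p_i` (Pa).
#' @export
oscillation_metric <- function(series, instances, probe = 1, cutoff_hz = 20) {
  w <- probe_window(series, probe, instances$QA3, instances$MD)
  if (length(w$x) < 8)
    stop("probe series does not cover [3QA, MD]", call. = FALSE)
  p_i <- stats::approx(series$times, series$values[, probe],
                       xout = instances$QA3, rule = 2)$y
  hp <- butter_filter(w$x - mean(w$x), series$cadence, cutoff_hz, "high")
  g <- filter_guard(length(hp), series$cadence, cutoff_hz)
  core <- hp[(g + 1):(length(hp) - g)]
  dp <- max(core) - min(core)
  if (p_i <= 0)
    stop(sprintf("undefined-metric error: p_i <= 0 at 3QA (|dp|max = %.3g Pa)",
                 dp), call. = FALSE)
  list(ratio = dp / p_i, dp_max = dp, p_i = p_i)
}

#' Detect pressure buildup at a probe
#'
#' The low-pass component of the probe signal on `[3QA, MD]` is classified
#' as buildup when its minimum stays above the 3QA pressure and its mean
#' exceeds it by a margin.
#'
#' @inheritParams oscillation_metric
#' @param margin_pa buildup margin (Pa), default 200.
#' @return List with `buildup` (logical) and `plateau` (mean low-pass
#'   pressure over the window, Pa).
#' @export
pressure_buildup_detect <- function(series, instances, probe = 1,
                                    cutoff_hz = 20, margin_pa = 200) {
  w <- probe_window(series, probe, instances$QA3, instances$MD)
  p_i <- stats::approx(series$times, series$values[, probe],
                       xout = instances$QA3, rule = 2)$y
  lp <- butter_filter(w$x, series$cadence, cutoff_hz, "low")
  g <- filter_guard(length(lp), series$cadence, cutoff_hz)
  core <- lp[(g + 1):(length(lp) - g)]
  # the window opens at 3QA where the signal equals p_i, so the no-dip
  # condition carries a small allowance for the starting value and the
  # zero-phase filter's edge transient
  list(buildup = (min(core) > p_i - 0.25 * margin_pa) &&
         (mean(core) > p_i + margin_pa),
       plateau = mean(core))
}

#' Circular focality score of a band series
#'
#' Quantifies focal versus dispersed wall shear stress: each angle is
#' weighted by its time-integrated WSS excess above the per-time band
#' median, and the score is the circular concentration
#' `|sum(w exp(i theta))| / sum(w)`; 1 for a single hotspot, 0 for a
#' uniform (or antipodally balanced) elevation.
#'
#' @param band a `band_series`.
#' @param window time interval `c(t0, t1)` (s); default the full series.
#' @return Score in `[0, 1]`.
#' @export
focality_score <- function(band, window = range(band$times)) {
  sel <- band$times >= window[1] - 1e-12 & band$times <= window[2] + 1e-12
  if (!any(sel)) stop("window outside the band series", call. = FALSE)
  v <- band$values[sel, , drop = FALSE]
  med <- apply(v, 1, stats::median)
  excess <- pmax(v - med, 0)
  w <- colSums(excess)
  if (sum(w) <= 0) {
    warning("all-zero band weights; focality score 0")
    return(0)
  }
  Mod(sum(w * exp(1i * band$theta))) / sum(w)
}

#' Peak value of a band series over a window
#'
#' @inheritParams focality_score
#' @return Maximum WSS (Pa) on the band over the window.
#' @export
band_peak <- function(band, window = range(band$times)) {
  sel <- band$times >= window[1] - 1e-12 & band$times <= window[2] + 1e-12
  max(band$values[sel, , drop = FALSE])
}
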