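#' Two-element Windkessel parameters
#'
#' Lumped resistance-capacitance model of the distal circulation,
#' `Q(t) = P(t)/R_out + C_out dP(t)/dt`, relating descending-aorta outflow
#' rate to outlet pressure.
#'
#' @param R_out distal resistance (Pa s / m^3).
#' @param C_out compliance (m^3 / Pa).
#' @param p_dia_mmhg,p_sys_mmhg diastolic / systolic pressure targets (mmHg).
#' @param p0_mmhg initial (periodic) pressure at t = 0 (mmHg), optional.
#' @return Object of class `windkessel_params`.
#' @export
windkessel_params <- function(R_out, C_out, p_dia_mmhg = 80,
                              p_sys_mmhg = 120, p0_mmhg = NA_real_) {
  stopifnot(R_out > 0, C_out > 0, p_dia_mmhg < p_sys_mmhg)
  structure(list(R_out = R_out, C_out = C_out,
                 p_dia_mmhg = p_dia_mmhg, p_sys_mmhg = p_sys_mmhg,
                 p0_mmhg = p0_mmhg),
            class = "windkessel_params")
}

#' Integrate the two-element Windkessel ODE
#'
#' Fixed-step classic Runge-Kutta (4 stage) integration of
#' `C dP/dt = Q(t) - P/R`. Pressures are mmHg at the interface and pascal
#' internally (1 mmHg = 133.322 Pa).
#'
#' @param flow a `flow_rate_waveform` (m^3/s).
#' @param params a `windkessel_params`.
#' @param P0 initial pressure (mmHg).
#' @param t_span integration interval (s), default one period.
#' @param dt step (s); must satisfy `dt <= period / 1000`.
#' @return data.frame with columns `time_s`, `pressure_mmHg`.
#' @export
wk2_integrate <- function(flow, params, P0, t_span = c(0, flow$period),
                          dt = flow$period / 2000) {
  stopifnot(inherits(flow, "flow_rate_waveform"),
            inherits(params, "windkessel_params"))
  if (dt > flow$period / 1000)
    stop("dt must be <= period/1000 for the Windkessel integration",
         call. = FALSE)
  R <- params$R_out; C <- params$C_out
  n <- ceiling((t_span[2] - t_span[1]) / dt)
  tt <- t_span[1] + dt * (0:n)
  Q <- flow$fun(tt)
  # Q at half-steps for the RK4 midpoint stages
  Qh <- flow$fun(tt[-(n + 1)] + dt / 2)
  P <- numeric(n + 1)
  P[1] <- P0 * MMHG_PA
  f <- function(q, p) (q - p / R) / C
  for (i in seq_len(n)) {
    p <- P[i]
    k1 <- f(Q[i],  p)
    k2 <- f(Qh[i], p + dt / 2 * k1)
    k3 <- f(Qh[i], p + dt / 2 * k2)
    k4 <- f(Q[i + 1], p + dt * k3)
    P[i + 1] <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  data.frame(time_s = tt, pressure_mmHg = P / MMHG_PA)
}

#' Periodic Windkessel pressure waveform for given (R, C)
#'
#' Finds the initial pressure for which `P(T) = P(0)` and returns the
#' periodic solution over one cycle. Because the ODE is linear in P, the
#' period map is affine and the fixed point is obtained exactly from two
#' integrations.
#'
#' @inheritParams wk2_integrate
#' @return data.frame `time_s`, `pressure_mmHg` over one period, with the
#'   periodic initial pressure in attribute `P0_mmHg`.
#' @export
wk2_periodic <- function(flow, params, dt = flow$period / 2000) {
  s0 <- wk2_integrate(flow, params, 0, dt = dt)
  s1 <- wk2_integrate(flow, params, 1, dt = dt)
  nT <- nrow(s0)
  b <- s0$pressure_mmHg[nT]
  a <- s1$pressure_mmHg[nT] - b      # contraction factor exp(-T/RC)
  P0 <- b / (1 - a)
  out <- s0
  out$pressure_mmHg <- s0$pressure_mmHg + P0 * (s1$pressure_mmHg - s0$pressure_mmHg)
  attr(out, "P0_mmHg") <- P0
  out
}

#' Calibrate the two-element Windkessel to pressure targets
#'
#' Finds `(R_out, C_out, P0)` such that the periodic pressure waveform
#' driven by `flow` has minimum `p_dia_mmhg` and maximum `p_sys_mmhg`, each
#' within `tol` mmHg. The mean-pressure identity
#' `mean(P) = R_out * mean(Q)` initializes the resistance; the periodic
#' initial condition is found by shooting on the affine period map; the
#' two-parameter root problem is then solved in `log(R), log(C)`.
#'
#' @param flow a `flow_rate_waveform` with nonnegative values and positive
#'   mean.
#' @param p_dia_mmhg,p_sys_mmhg diastolic and systolic targets (mmHg).
#' @param tol calibration tolerance on both extrema (mmHg), default 0.1.
#' @param dt integration step (s).
#' @return A `windkessel_params` with `p0_mmhg` set to the periodic initial
#'   pressure, and the calibrated waveform in attribute `waveform`.
#' @export
wk2_calibrate <- function(flow, p_dia_mmhg = 80, p_sys_mmhg = 120,
                          tol = 0.1, dt = flow$period / 2000) {
  stopifnot(inherits(flow, "flow_rate_waveform"), p_dia_mmhg < p_sys_mmhg)
  Tp <- flow$period
  tt <- seq(0, Tp, length.out = 2001)
  Qs <- flow$fun(tt)
  if (any(Qs < -1e-12 * max(abs(Qs)))) stop("flow must be nonnegative", call. = FALSE)
  Qmean <- mean(Qs[-length(Qs)])
  if (Qmean <= 0) stop("flow must have positive mean", call. = FALSE)
  # degenerate pulse: a constant flow gives a constant periodic pressure
  if (max(Qs) - min(Qs) < 1e-12 * max(Qs))
    stop("calibration error: constant flow has zero pulse pressure; ",
         "cannot match p_sys > p_dia", call. = FALSE)

  extrema <- function(R, C) {
    per <- wk2_periodic(flow, windkessel_params(R, C, p_dia_mmhg, p_sys_mmhg),
                        dt = dt)
    c(min = min(per$pressure_mmHg), max = max(per$pressure_mmHg))
  }
  # initial guesses: R from the mean identity; C from stroke volume / pulse
  Pm_target <- (p_dia_mmhg + 2 * p_sys_mmhg) / 3   # rough waveform mean
  R0 <- Pm_target * MMHG_PA / Qmean
  sv <- Qmean * Tp                                  # stroke volume proxy
  C0 <- sv / ((p_sys_mmhg - p_dia_mmhg) * MMHG_PA)
  obj <- function(th) {
    e <- extrema(exp(th[1]), exp(th[2]))
    (e["min"] - p_dia_mmhg)^2 + (e["max"] - p_sys_mmhg)^2
  }
  opt <- stats::optim(c(log(R0), log(C0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  R <- exp(opt$par[1]); C <- exp(opt$par[2])
  e <- extrema(R, C)
  if (abs(e["min"] - p_dia_mmhg) > tol || abs(e["max"] - p_sys_mmhg) > tol)
    stop(sprintf(paste0("calibration error: best achievable extrema are ",
                        "[%.2f, %.2f] mmHg for targets [%.1f, %.1f]"),
                 e["min"], e["max"], p_dia_mmhg, p_sys_mmhg), call. = FALSE)
  per <- wk2_periodic(flow, windkessel_params(R, C, p_dia_mmhg, p_sys_mmhg),
                      dt = dt)
  out <- windkessel_params(R, C, p_dia_mmhg, p_sys_mmhg,
                           p0_mmhg = attr(per, "P0_mmHg"))
  attr(out, "waveform") <- per
  out
}

#' Export a Windkessel pressure waveform to CSV
#'
#' @param waveform data.frame as returned by [wk2_integrate()] /
#'   [wk2_periodic()].
#' @param file output path (columns `time_s`, `pressure_mmHg`).
#' @export
write_pressure_csv <- function(waveform, file) {
  utils::write.csv(waveform[, c("time_s", "pressure_mmHg")], file,
                   row.names = FALSE)
  invisible(file)
}
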