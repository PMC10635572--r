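#' Simulate a heart beat
#'
#' Advances the flow from `state` (rest by default) over `t` in
#' `[t_start, t_end]` with adaptive CFL-limited steps, forcing the plug-jet
#' inflow and the Windkessel outlet pressure, and streams probe pressures
#' and band WSS at high cadence. Deterministic given the configuration
#' seed.
#'
#' @param geom a `levelset_geometry`.
#' @param config a `sim_config`.
#' @param inflow an `inflow_profile`, or `NULL` for no forcing.
#' @param windkessel a calibrated `windkessel_params` (with its periodic
#'   waveform attribute) or a function of time (s) returning mmHg; `NULL`
#'   for no outlet pressure.
#' @param t_end end time (s), default one period.
#' @param probes optional matrix (m x 3) of probe locations (m).
#' @param band optional `band_spec` for WSS unwrapping.
#' @param snapshot_times times (s) at which to keep full field snapshots.
#' @param fringe_depth fringe depth in cells (see [ns_context()]).
#' @param resume optional checkpoint (path or object from
#'   [read_checkpoint()]) to continue from.
#' @param verbose print progress every 50 steps.
#' @return Object of class `aortaflow_run`: final state, snapshots, probe
#'   and band series, per-step diagnostics, and the solver context.
#' @export
run_beat <- function(geom, config, inflow = NULL, windkessel = NULL,
                     t_end = config$T, probes = NULL, band = NULL,
                     snapshot_times = numeric(0), fringe_depth = NULL,
                     resume = NULL, verbose = FALSE) {
  p_out <- windkessel_pressure_fun(windkessel)
  ctx <- ns_context(geom, config, inflow = inflow, pressure_outlet = p_out,
                    fringe_depth = fringe_depth)

  if (!is.null(resume)) {
    ck <- if (is.character(resume)) read_checkpoint(resume) else resume
    if (!identical(ck$config_key, config_key(config)))
      stop("checkpoint was written with a different configuration",
           call. = FALSE)
    state <- ck$state
    assign(".Random.seed", ck$rng, envir = globalenv())
  } else {
    state <- flow_state(geom$grid)
    set.seed(config$noise_seed)
  }

  if (!is.null(probes)) {
    probes <- rbind(probes)
    phi_p <- sample_comp_cpp(as.numeric(geom$phi), ctx$n, 3L, ctx$n,
                             geom$grid$h,
                             ctx$periodic,
                             sweep(probes, 2, geom$grid$origin))
    if (any(phi_p >= 0))
      stop("placement error: probe(s) ", paste(which(phi_p >= 0),
           collapse = ", "), " lie in the solid", call. = FALSE)
  }
  band_sel <- if (!is.null(band))
    select_band(surface_points(geom), band, geom$grid$h) else NULL

  noise_sd <- if (!is.null(inflow) && config$noise_amp > 0)
    config$noise_amp * inflow$waveform$U_peak / config$U0 else 0

  times <- numeric(0); dts <- numeric(0)
  fluxes <- NULL
  probe_vals <- NULL
  band_vals <- NULL
  snaps <- list(); snap_t <- numeric(0)
  pending_snaps <- sort(snapshot_times[snapshot_times > state$t])
  nbad <- 0L

  while (state$t < t_end - 1e-12) {
    dt_base <- min(compute_dt(state, ctx), 1 / config$cadence_probes)
    rem <- t_end - state$t
    # shorten the step only when the remaining time is meaningfully
    # smaller, so a run split at a step boundary reproduces the unsplit
    # step sequence bitwise
    dt <- if (rem < dt_base * (1 - 1e-9)) rem else dt_base
    if (length(pending_snaps) && pending_snaps[1] - state$t < dt + 1e-15)
      dt <- max(pending_snaps[1] - state$t, 1e-9)
    noise <- if (noise_sd > 0)
      stats::rnorm(length(ctx$jet_faces), 0, noise_sd) else NULL
    state <- advance_rk3(state, dt, ctx, noise = noise)
    fl <- attr(state, "flux")
    # count imbalance only once the inflow is established (the first fringe
    # fill steps are a startup transient, not a mass-conservation failure)
    q_floor <- if (!is.null(inflow) && inflow$waveform$U_peak > 0)
      0.05 * inflow$Q_peak / (config$U0 * config$L0^2) else 1e-9
    if (!is.null(fl) && fl[["Q_in"]] > q_floor && fl[["corr"]] > 0.1) {
      nbad <- nbad + 1L
      if (nbad > 100L)
        stop("imbalance error: flux correction exceeded 10% of inflow for ",
             "more than 100 consecutive steps", call. = FALSE)
    } else {
      nbad <- 0L   # persistent, not intermittent, imbalance is the failure
    }
    times <- c(times, state$t); dts <- c(dts, dt)
    fluxes <- rbind(fluxes, fl)
    if (!is.null(probes))
      probe_vals <- rbind(probe_vals, sample_pressure(state, ctx, probes))
    if (!is.null(band_sel))
      band_vals <- rbind(band_vals,
        wss_magnitude(wall_traction(state, ctx, band_sel))$values)
    if (length(pending_snaps) && state$t >= pending_snaps[1] - 1e-12) {
      snaps[[length(snaps) + 1]] <- state
      snap_t <- c(snap_t, state$t)
      pending_snaps <- pending_snaps[-1]
    }
    if (verbose && state$step %% 50 == 0)
      message(sprintf("step %d  t = %.4f s  dt = %.2e s  umax = %.3f",
                      state$step, state$t, dt,
                      max(abs(state$u), abs(state$v), abs(state$w))))
  }

  run <- list(final = state, snapshots = snaps, snapshot_times = snap_t,
              times = times, dts = dts,
              diagnostics = as.data.frame(fluxes), ctx = ctx,
              config = config)
  if (!is.null(probes))
    run$probe <- probe_series(times, probe_vals, probes,
                              cadence = config$cadence_probes)
  if (!is.null(band_sel))
    run$band <- structure(list(theta = band_sel$theta,
                               points = band_sel$points,
                               times = times, values = band_vals),
                          class = "band_series")
  class(run) <- "aortaflow_run"
  run
}

# periodic interpolator for the outlet pressure waveform
windkessel_pressure_fun <- function(windkessel) {
  if (is.null(windkessel)) return(NULL)
  if (is.function(windkessel)) return(windkessel)
  wf <- attr(windkessel, "waveform")
  if (is.null(wf))
    stop("windkessel_params has no calibrated waveform; run wk2_calibrate ",
         "or pass a function of time", call. = FALSE)
  Tp <- wf$time_s[nrow(wf)]
  function(t) stats::approx(wf$time_s, wf$pressure_mmHg,
                            xout = t %% Tp, rule = 2)$y
}

config_key <- function(config) {
  paste(config$Re, config$U0, config$L0, config$CFL, config$fd_order,
        config$T, config$noise_amp, config$noise_seed, config$filter_amp,
        paste(config$periodic, collapse = ","), sep = "|")
}

#' Write a run checkpoint
#'
#' Stores the flow state, the RNG state and a configuration fingerprint;
#' resuming reproduces the continued run bitwise.
#'
#' @param state a `flow_state`.
#' @param config the `sim_config` of the run.
#' @param file output path.
#' @export
write_checkpoint <- function(state, config, file) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(state = state, rng = rng, config_key = config_key(config),
               step = state$step), file)
  invisible(file)
}

#' Read a run checkpoint
#'
#' @param file checkpoint path.
#' @return Checkpoint list (`state`, `rng`, `config_key`, `step`).
#' @export
read_checkpoint <- function(file) {
  ck <- tryCatch(readRDS(file), error = function(e)
    stop("format error: unreadable checkpoint: ", conditionMessage(e),
         call. = FALSE))
  if (!all(c("state", "config_key") %in% names(ck)))
    stop("format error: not an aortaflow checkpoint", call. = FALSE)
  ck
}
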