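# registry of config keys: default (NULL = required/optional string),
# type, and whether the key is a comma list
config_registry <- function() {
  list(
    "seed" = list(default = 1, type = "int"),
    "geometry.kind" = list(default = "idealized", type = "enum",
                           levels = c("idealized", "mask")),
    "geometry.mask_prefix" = list(default = "", type = "string"),
    "geometry.spec.lumen_radius_m" = list(default = 0.0145, type = "num"),
    "geometry.spec.arch_radius_m" = list(default = 0.035, type = "num"),
    "geometry.spec.asc_length_m" = list(default = 0.045, type = "num"),
    "geometry.spec.inlet_extension_m" = list(default = 0.012, type = "num"),
    "geometry.spec.outlet_extension_m" = list(default = 0.012, type = "num"),
    "geometry.spec.branch_radius_m" =
      list(default = c(0.0055, 0.004, 0.0045), type = "numlist"),
    "geometry.spec.branch_theta_rad" =
      list(default = c(1.15, 1.60, 2.05), type = "numlist"),
    "geometry.spec.branch_length_m" = list(default = 0.065, type = "num"),
    "geometry.spec.branch_extension_m" = list(default = 0.008, type = "num"),
    "geometry.spec.brachio_offset_rad" = list(default = 0, type = "num"),
    "grid.h_m" = list(default = 0.002, type = "num"),
    "waveform.csv" = list(default = "", type = "string"),
    "waveform.u_peak_m_s" = list(default = 2.7, type = "num"),
    "waveform.t_sys_s" = list(default = 0.3, type = "num"),
    "waveform.period_s" = list(default = 1.0, type = "num"),  # 60 bpm
    "waveform.q_peak_m3_s" = list(default = 4e-4, type = "num"),
    "waveform.fraction" = list(default = 0.85, type = "num"),
    "windkessel.p_dia_mmhg" = list(default = 80, type = "num"),
    "windkessel.p_sys_mmhg" = list(default = 120, type = "num"),
    "solver.re" = list(default = 1000, type = "num"),
    "solver.cfl" = list(default = 0.5, type = "num"),
    "solver.fd_order" = list(default = 6, type = "int"),
    "solver.noise.amp" = list(default = 0.01, type = "num"),
    "solver.noise.seed" = list(default = 1, type = "int"),
    "solver.filter_amp" = list(default = 0.1, type = "num"),
    "solver.t_end_s" = list(default = NA_real_, type = "num"),
    "output.cadence_fields_hz" = list(default = 20, type = "num"),
    "output.cadence_probes_hz" = list(default = 1400, type = "num"),
    "output.dir" = list(default = "out", type = "string"))
}

#' Validate a run configuration
#'
#' Parses a flat `key = value` text document with dotted sections. Every
#' physical key carries its unit in the key name (`_m`, `_s`, `_mmhg`, ...);
#' unknown keys (including unit-less spellings of dimensional keys) are
#' rejected by name. Missing keys take the standard defaults (CFL 0.5,
#' 6th-order stencils, 60 bpm, descending fraction 0.85, peak flow
#' 4e-4 m^3/s, diastolic target 80 mmHg).
#'
#' @param file path to a config file, or a character vector of lines via
#'   `text`.
#' @param text character vector of config lines (alternative to `file`).
#' @return Named list of validated values, class `run_config`.
#' @export
validate_config <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  reg <- config_registry()
  vals <- lapply(reg, `[[`, "default")
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("validation error: malformed line: ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    ent <- reg[[key]]
    if (is.null(ent))
      stop("validation error: unknown key '", key,
           "' (dimensional keys carry their unit suffix)", call. = FALSE)
    vals[[key]] <- switch(ent$type,
      num = as_num_checked(val, key),
      int = as.integer(as_num_checked(val, key)),
      numlist = vapply(strsplit(val, ",")[[1]],
                       function(v) as_num_checked(v, key), numeric(1),
                       USE.NAMES = FALSE),
      enum = {
        if (!val %in% ent$levels)
          stop("validation error: key '", key, "' must be one of ",
               paste(ent$levels, collapse = "|"), call. = FALSE)
        val
      },
      string = val)
  }
  structure(vals, class = "run_config")
}

as_num_checked <- function(val, key) {
  if (identical(toupper(trimws(val)), "NA")) return(NA_real_)
  x <- suppressWarnings(as.numeric(val))
  if (is.na(x))
    stop("validation error: key '", key, "' is not numeric: ", val,
         call. = FALSE)
  x
}

#' Write a run configuration
#'
#' @param cfg a `run_config`.
#' @param file output path.
#' @export
write_config <- function(cfg, file) {
  reg <- config_registry()
  lines <- vapply(names(reg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 17), collapse = ","))
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Assemble the simulation objects described by a run configuration
#'
#' @param cfg a `run_config` from [validate_config()].
#' @param base_dir directory against which relative file keys are resolved.
#' @return List with `geom`, `config`, `waveform`, `inflow`, `flow`,
#'   `windkessel`.
#' @export
build_from_config <- function(cfg, base_dir = ".") {
  spec <- idealized_aorta_spec(
    lumen_radius = cfg[["geometry.spec.lumen_radius_m"]],
    arch_radius = cfg[["geometry.spec.arch_radius_m"]],
    asc_length = cfg[["geometry.spec.asc_length_m"]],
    inlet_extension = cfg[["geometry.spec.inlet_extension_m"]],
    outlet_extension = cfg[["geometry.spec.outlet_extension_m"]],
    branch_radius = cfg[["geometry.spec.branch_radius_m"]],
    branch_theta = cfg[["geometry.spec.branch_theta_rad"]],
    branch_length = cfg[["geometry.spec.branch_length_m"]],
    branch_extension = cfg[["geometry.spec.branch_extension_m"]],
    brachio_offset = cfg[["geometry.spec.brachio_offset_rad"]])
  geom <- if (cfg[["geometry.kind"]] == "idealized") {
    make_idealized_aorta(spec, default_idealized_grid(spec, cfg[["grid.h_m"]]))
  } else {
    mk <- read_mask_raw(file.path(base_dir, cfg[["geometry.mask_prefix"]]))
    levelset_from_mask(mk$mask, mk$spacing, mk$origin,
                       patch_faces = c("zlo", "zhi"))
  }
  wf <- if (nzchar(cfg[["waveform.csv"]]))
    load_waveform(file.path(base_dir, cfg[["waveform.csv"]]),
                  period = cfg[["waveform.period_s"]])
  else
    synth_waveform(cfg[["waveform.u_peak_m_s"]], cfg[["waveform.t_sys_s"]],
                   cfg[["waveform.period_s"]])
  flow <- flowrate_waveform(wf, cfg[["waveform.fraction"]],
                            cfg[["waveform.q_peak_m3_s"]])
  config <- sim_config(Re = cfg[["solver.re"]],
                       U0 = wf$U_peak,
                       L0 = 2 * cfg[["geometry.spec.lumen_radius_m"]],
                       CFL = cfg[["solver.cfl"]],
                       fd_order = cfg[["solver.fd_order"]],
                       T = cfg[["waveform.period_s"]],
                       noise_amp = cfg[["solver.noise.amp"]],
                       noise_seed = cfg[["solver.noise.seed"]],
                       filter_amp = cfg[["solver.filter_amp"]],
                       cadence_probes = cfg[["output.cadence_probes_hz"]],
                       cadence_fields = cfg[["output.cadence_fields_hz"]])
  inflow <- build_inflow(geom, wf, Q_peak = cfg[["waveform.q_peak_m3_s"]])
  list(geom = geom, config = config, waveform = wf, inflow = inflow,
       flow = flow, cfg = cfg)
}

#' Write field snapshots losslessly
#'
#' Native-serialization snapshot of a `flow_state` with its grid metadata;
#' round trips bitwise. Use [write_vtk_structured()] for visualization
#' export.
#'
#' @param state a `flow_state`.
#' @param grid the `cartesian_grid` it lives on.
#' @param file output path (conventionally `fields_t<time>.rds`).
#' @export
write_fields <- function(state, grid, file) {
  saveRDS(list(state = state, n = grid$n, h = grid$h,
               origin = grid$origin, format = "aortaflow-fields-1"), file)
  invisible(file)
}

#' Read field snapshots
#'
#' @param file path written by [write_fields()].
#' @param grid optional `cartesian_grid`; a mismatch is a format error.
#' @return List with `state` and grid metadata.
#' @export
read_fields <- function(file, grid = NULL) {
  obj <- tryCatch(readRDS(file), error = function(e)
    stop("format error: unreadable fields file: ", conditionMessage(e),
         call. = FALSE))
  if (!identical(obj$format, "aortaflow-fields-1"))
    stop("format error: not an aortaflow fields file", call. = FALSE)
  if (!is.null(grid) &&
      !(identical(obj$n, grid$n) && isTRUE(all.equal(obj$h, grid$h))))
    stop("format error: grid mismatch on read", call. = FALSE)
  obj
}

#' Generate deterministic input fixtures
#'
#' Synthesizes the external inputs the pipeline otherwise reads from
#' clinical exports: echo-like waveform CSVs, rasterized segmentation
#' masks of the idealized aorta, a manufactured Poisson problem, analytic
#' pipe-flow initial states, and labelled buildup-vs-oscillation probe
#' signal families for classifier tests.
#'
#' @param kind one of `"echo_waveform"`, `"idealized_mask"`,
#'   `"manufactured_solution"`, `"poiseuille_init"`, `"womersley_init"`,
#'   `"probe_signals"`.
#' @param seed RNG seed; outputs are deterministic given the seed.
#' @param dir output directory.
#' @param ... kind-specific parameters (`U_peak`, `h`, `n`, `ncases`, ...).
#' @return List with `paths` (files written) and `data` (the objects).
#' @export
make_fixtures <- function(kind, seed = 1, dir = tempdir(), ...) {
  set.seed(seed)
  args <- list(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(kind,
    echo_waveform = {
      U_peak <- args$U_peak %||% 2.7
      wf <- synth_waveform(U_peak, args$T_sys %||% 0.3,
                           args$period %||% 1.0, n = args$n %||% 100)
      path <- file.path(dir, sprintf("echo_waveform_seed%d.csv", seed))
      write_waveform(wf, path)
      list(paths = path, data = wf)
    },
    idealized_mask = {
      spec <- args$spec %||% idealized_aorta_spec()
      h <- args$h %||% 0.002
      grid <- default_idealized_grid(spec, h)
      geom <- make_idealized_aorta(spec, grid)
      mask <- array(as.integer(geom$phi < 0), grid$n)
      prefix <- file.path(dir, sprintf("idealized_mask_seed%d", seed))
      write_mask_raw(mask, grid$h, grid$origin, prefix)
      list(paths = paste0(prefix, c(".raw", ".json")),
           data = list(mask = mask, grid = grid, geom = geom))
    },
    manufactured_solution = {
      n <- args$n %||% 32L
      grid <- cartesian_grid(c(n, n, 8L), c(pi / n, pi / n, pi / 8))
      co <- grid_coords(grid)
      exact <- sin(co$x) * sin(co$y)
      rhs <- -2 * exact
      ctype <- array(1L, grid$n)
      ctype[1, , ] <- 2L; ctype[n, , ] <- 2L
      ctype[, 1, ] <- 2L; ctype[, n, ] <- 2L
      dirv <- exact
      path <- file.path(dir, sprintf("manufactured_seed%d.rds", seed))
      saveRDS(list(grid = grid, rhs = rhs, exact = exact, ctype = ctype,
                   dirichlet = dirv), path)
      list(paths = path,
           data = list(grid = grid, rhs = rhs, exact = exact,
                       ctype = ctype, dirichlet = dirv))
    },
    poiseuille_init = {
      data <- pipe_benchmark_setup(args$ncell %||% 32L, args$Re %||% 100,
                                   mode = "steady")
      path <- file.path(dir, sprintf("poiseuille_init_seed%d.rds", seed))
      write_fields(data$state, data$geom$grid, path)
      list(paths = path, data = data)
    },
    womersley_init = {
      data <- pipe_benchmark_setup(args$ncell %||% 32L, args$Re %||% 50,
                                   mode = "womersley",
                                   alpha = args$alpha %||% 5)
      path <- file.path(dir, sprintf("womersley_init_seed%d.rds", seed))
      write_fields(data$state, data$geom$grid, path)
      list(paths = path, data = data)
    },
    probe_signals = {
      ncases <- args$ncases %||% 50L
      fs <- args$fs %||% 1400
      tt <- seq(0, 0.25, by = 1 / fs)
      out <- lapply(seq_len(ncases), function(i) {
        buildup <- i %% 2 == 0
        base <- 10000
        # both families develop inside the analysis window (from 3QA on):
        # a beat-scale ramp versus a zero-mean oscillation burst
        x <- if (buildup)
          base + 1500 * pmin(pmax((tt - 0.10) / 0.08, 0), 1) +
            stats::rnorm(length(tt), 0, 30)
        else
          base + 600 * sin(2 * pi * 47 * pmax(tt - 0.115, 0)) *
            (tt > 0.115) + stats::rnorm(length(tt), 0, 30)
        list(t = tt, x = x, label = buildup)
      })
      path <- file.path(dir, sprintf("probe_signals_seed%d.csv", seed))
      df <- do.call(rbind, lapply(seq_along(out), function(i)
        data.frame(case = i, time_s = out[[i]]$t, pressure_pa = out[[i]]$x,
                   buildup = out[[i]]$label)))
      utils::write.csv(df, path, row.names = FALSE)
      list(paths = path, data = out)
    },
    stop("unknown fixture kind: ", kind, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# circular-pipe benchmark: cylinder of diameter 1 along z, periodic axially.
# mode "steady": exact Poiseuille profile driven by a constant body force;
# mode "womersley": oscillatory force, state initialized from the analytic
# profile at t = 0.
pipe_benchmark_setup <- function(ncell, Re, mode = "steady", alpha = 5,
                                 force_amp = 1) {
  Rp <- 0.5
  pad <- 3L
  n <- c(ncell + 2L * pad, ncell + 2L * pad, 8L)
  h <- 1 / ncell
  grid <- cartesian_grid(n, h, origin = c(-n[1] * h / 2, -n[2] * h / 2, 0))
  co <- grid_coords(grid)
  phi <- sqrt(co$x^2 + co$y^2) - Rp
  geom <- levelset_geometry(grid, phi)
  omega <- if (mode == "womersley") alpha^2 / (Re * Rp^2) else 0
  force <- if (mode == "steady") c(0, 0, force_amp)
           else function(t) c(0, 0, force_amp * cos(omega * t))
  config <- sim_config(Re = Re, CFL = 0.4, fd_order = 2, T = 1,
                       periodic = c(FALSE, FALSE, TRUE), force = force)
  state <- flow_state(grid)
  # analytic axial profile on w faces
  xw <- grid$origin[1] + (seq_len(n[1]) - 0.5) * h
  yw <- grid$origin[2] + (seq_len(n[2]) - 0.5) * h
  r2 <- outer(xw^2, yw^2, "+")
  wz <- if (mode == "steady") {
    force_amp * Re / 4 * pmax(Rp^2 - r2, 0)
  } else {
    womersley_profile(sqrt(r2), Rp, alpha, omega, Re, force_amp, t = 0)
  }
  for (k in seq_len(n[3] + 1)) state$w[, , k] <- wz
  list(geom = geom, config = config, state = state, R = Rp,
       omega = omega, alpha = alpha, force_amp = force_amp)
}

#' Analytic oscillatory (Womersley) pipe-flow profile
#'
#' Axial velocity of laminar pipe flow driven by the oscillatory pressure
#' gradient `G cos(omega t)`:
#' `w(r,t) = Re{ (G/(i omega)) (1 - J0(i^{3/2} alpha r/R)/J0(i^{3/2} alpha)) e^{i omega t} }`
#' in solver units (`nu = 1/Re`). The complex Bessel function `J0` is
#' evaluated by its power series.
#'
#' @param r radial coordinate (same units as `R`).
#' @param R pipe radius.
#' @param alpha Womersley number `R * sqrt(omega / nu)`.
#' @param omega angular frequency.
#' @param Re Reynolds number (`nu = 1/Re`).
#' @param G pressure-gradient amplitude.
#' @param t time.
#' @return Axial velocity, zero outside `r > R`.
#' @export
womersley_profile <- function(r, R, alpha, omega, Re, G = 1, t = 0) {
  beta <- complex(real = 0, imaginary = 1)^1.5 * alpha
  num <- besselJ0_complex(beta * r / R)
  den <- besselJ0_complex(beta)
  w <- Re(G / (1i * omega) * (1 - num / den) * exp(1i * omega * t))
  w[r > R] <- 0
  w
}

# power-series J0 for complex argument (converges fast for |z| <~ 12)
besselJ0_complex <- function(z) {
  s <- z * 0 + 1
  term <- s
  q <- -(z / 2)^2
  for (k in 1:40) {
    term <- term * q / k^2
    s <- s + term
  }
  s
}
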