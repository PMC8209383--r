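# Monodomain reaction-diffusion solver on regular sheets, with
# conduction-velocity measurement and diffusion-coefficient calibration.
#
# The monodomain conductivity sigma, surface-to-volume ratio beta and
# membrane capacitance are lumped into a single isotropic diffusion
# coefficient D (mm^2/ms); CV calibration pins the physiology. At fibrotic
# nodes the local diffusivity is D * conductivity_factor and inter-node
# edge diffusivities are harmonic means of the node values (serial
# resistances). Boundaries are no-flux.

#' Simulation configuration
#'
#' @param dt_ms reaction/diffusion time step, ms (default 0.02).
#' @param D baseline diffusion coefficient, mm^2/ms.
#' @param duration_ms total simulated time, ms.
#' @param snapshot_interval_ms recording cadence, ms (>= dt).
#' @param record_start_ms first snapshot time, ms.
#' @param remodeling a [fibrosis_remodeling()] object applied at fibrotic
#'   nodes.
#' @param variant cell variant used throughout the tissue.
#' @param obstacle_mode if `TRUE`, fibrotic nodes are non-conducting
#'   obstacles instead of remodeled myocytes.
#' @param record_cai also record the cytosolic calcium field.
#' @param stim_amplitude,stim_duration_ms stimulus convention
#'   (pA/pF, ms); negative amplitudes depolarize.
#' @param use_tables use the table-accelerated ionic kernel (default);
#'   `FALSE` selects the exact scalar evaluation of all rate expressions
#'   (slow; for numerical validation).
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(dt_ms = 0.02, D = 0.154, duration_ms = 100,
                              snapshot_interval_ms = 1,
                              record_start_ms = 0,
                              remodeling = fibrosis_remodeling(),
                              variant = "epicardial",
                              obstacle_mode = FALSE,
                              record_cai = FALSE,
                              stim_amplitude = -52,
                              stim_duration_ms = 1,
                              use_tables = TRUE) {
  if (dt_ms <= 0 || dt_ms > 0.05)
    stop("dt_ms must be in (0, 0.05]", call. = FALSE)
  if (snapshot_interval_ms < dt_ms)
    stop("snapshot_interval_ms must be >= dt_ms", call. = FALSE)
  structure(list(dt_ms = dt_ms, D = D, duration_ms = duration_ms,
                 snapshot_interval_ms = snapshot_interval_ms,
                 record_start_ms = record_start_ms,
                 remodeling = remodeling, variant = variant,
                 obstacle_mode = obstacle_mode, record_cai = record_cai,
                 stim_amplitude = stim_amplitude,
                 stim_duration_ms = stim_duration_ms,
                 use_tables = use_tables),
            class = "sim_config")
}

.check_stability <- function(config, geometry) {
  lim <- geometry$dx^2 / (4 * config$D)
  if (config$dt_ms > lim)
    stop(sprintf(paste0("dt = %g ms violates the explicit-diffusion ",
                        "stability bound %.4g ms (D = %g mm^2/ms, ",
                        "dx = %g mm)"),
                 config$dt_ms, lim, config$D, geometry$dx), call. = FALSE)
  invisible(TRUE)
}

#' Stimulus protocol container
#'
#' Low-level constructor; see [build_s1s2()] and [plane_wave_protocol()]
#' for the standard protocols.
#'
#' @param s1_nodes 1-based node indices receiving the S1 stimuli.
#' @param s1_starts stimulus onset times, ms.
#' @param s2 optional list with `trigger_nodes`, `reset_nodes`,
#'   `threshold` (mV) and `post_trigger_ms` describing the cross-field
#'   reset; `NULL` disables S2.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(s1_nodes, s1_starts, s2 = NULL) {
  if (!length(s1_nodes)) stop("s1_nodes must be non-empty", call. = FALSE)
  structure(list(s1_nodes = as.integer(s1_nodes),
                 s1_starts = as.numeric(s1_starts), s2 = s2),
            class = "stimulus_protocol")
}

#' Single plane-wave stimulus along the left edge
#'
#' @param geometry a 2D `tissue_geometry`.
#' @param n_cols thickness (columns) of the stimulated strip.
#' @param start_ms stimulus onset.
#' @return a `stimulus_protocol`.
#' @export
plane_wave_protocol <- function(geometry, n_cols = 3, start_ms = 0) {
  nx <- geometry$nx; ny <- geometry$ny
  cols <- seq_len(min(n_cols, nx))
  nodes <- as.vector(outer(cols, (seq_len(ny) - 1L) * nx, `+`))
  stimulus_protocol(nodes, start_ms)
}

#' Run a monodomain simulation
#'
#' Operator-split explicit stepping: per node a reaction step of the
#' ionic model (remodeled parameters at fibrotic nodes), then an explicit
#' 5-point finite-difference diffusion step with harmonic-mean edge
#' diffusivities and no-flux boundaries. Deterministic given its inputs.
#'
#' @param geometry a 2D `tissue_geometry` from [make_sheet()].
#' @param map a `fibrosis_map` on the same geometry, or `NULL` for
#'   fibrosis-free tissue.
#' @param config a [simulation_config()].
#' @param protocol a `stimulus_protocol`.
#' @return object of class `voltage_recording`: `vm` (nodes x frames
#'   matrix, mV), `time_ms`, optional `cai`, per-node
#'   `first_activation_ms` (-20 mV upcrossing), `trigger_time_ms` (S2
#'   reset instant or `NA`), and the geometry/config references.
#' @export
run_simulation <- function(geometry, map = NULL, config, protocol) {
  if (geometry$kind != "sheet2d")
    stop("the electrical solver operates on 2D sheets", call. = FALSE)
  .check_stability(config, geometry)
  labels <- if (is.null(map)) integer(geometry$n_nodes) else map$labels
  if (length(labels) != geometry$n_nodes)
    stop("fibrosis map does not match geometry", call. = FALSE)
  if (any(protocol$s1_nodes < 1 | protocol$s1_nodes > geometry$n_nodes))
    stop("protocol stimulus nodes outside geometry", call. = FALSE)

  pn <- cell_params(config$variant)
  pf <- apply_fibrosis_remodeling(pn, config$remodeling)
  st <- init_cell_state(config$variant)
  s2 <- protocol$s2
  trigger_nodes <- if (is.null(s2)) integer(0) else as.integer(s2$trigger_nodes)
  reset_nodes <- if (is.null(s2)) integer(0) else as.integer(s2$reset_nodes)
  post_trigger <- if (is.null(s2)) 0 else s2$post_trigger_ms
  threshold <- if (is.null(s2)) -20 else (s2$threshold %||% -20)

  raw <- .sim_monodomain_cpp(
    geometry$nx, geometry$ny, geometry$dx, as.integer(labels),
    config$D, config$remodeling$conductivity_factor,
    unclass(pn), unclass(pf), as.numeric(st),
    config$dt_ms, config$duration_ms, post_trigger,
    protocol$s1_starts, config$stim_duration_ms, config$stim_amplitude,
    protocol$s1_nodes - 1L, trigger_nodes - 1L, reset_nodes - 1L,
    threshold, config$snapshot_interval_ms, config$record_start_ms,
    isTRUE(config$record_cai), isTRUE(config$obstacle_mode),
    !isFALSE(config$use_tables))

  structure(list(vm = raw$vm, time_ms = raw$time_ms,
                 cai = raw$cai %||% NULL,
                 first_activation_ms = raw$first_activation_ms,
                 trigger_time_ms = raw$trigger_time_ms,
                 t_end_ms = raw$t_end_ms,
                 geometry = geometry, config = config,
                 protocol = protocol,
                 map_meta = if (is.null(map)) NULL else
                   map[c("pattern", "amount", "seed")]),
            class = "voltage_recording")
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("Voltage recording: %d nodes x %d frames (%.0f-%.0f ms)\n",
              nrow(x$vm), ncol(x$vm),
              if (length(x$time_ms)) min(x$time_ms) else NA,
              if (length(x$time_ms)) max(x$time_ms) else NA))
  if (!is.na(x$trigger_time_ms))
    cat(sprintf("  S2 cross-field reset at %.2f ms\n", x$trigger_time_ms))
  invisible(x)
}

#' Measure plane-wave conduction velocity for a given diffusion coefficient
#'
#' Runs a plane wave along a fibrosis-free strip (default 100 x 10 nodes,
#' dx 0.25 mm) and reports CV as the distance between two sensing lines
#' (at 25% and 75% of the strip length) divided by the difference of
#' their first -20 mV upcrossing times.
#'
#' @param D diffusion coefficient, mm^2/ms (> 0).
#' @param config a [simulation_config()]; `D` inside it is overridden.
#' @param nx,ny,dx strip geometry.
#' @return conduction velocity in cm/s, with the strip recording attached
#'   as attribute `recording`.
#' @export
measure_cv <- function(D, config = simulation_config(), nx = 100, ny = 10,
                       dx = 0.25) {
  if (!is.finite(D) || D <= 0) stop("D must be > 0", call. = FALSE)
  geom <- make_sheet(nx, ny, dx)
  cfg <- config
  cfg$D <- D
  cfg$remodeling <- fibrosis_remodeling()  # strip is fibrosis-free
  # enough time for a wave at >= 15 cm/s to cross the whole strip
  cfg$duration_ms <- max(cfg$duration_ms, 5 + (nx * dx) / 0.15)
  cfg$snapshot_interval_ms <- max(cfg$snapshot_interval_ms, 5)
  cfg$record_cai <- FALSE
  .check_stability(cfg, geom)
  # stimulate a fixed 0.75 mm depth so excitation does not depend on dx
  rec <- run_simulation(geom, NULL, cfg,
                        plane_wave_protocol(geom,
                                            n_cols = max(3, round(0.75 / dx))))
  midrow <- (ny %/% 2) * nx
  xa <- round(0.25 * nx); xb <- round(0.75 * nx)
  ta <- rec$first_activation_ms[midrow + xa]
  tb <- rec$first_activation_ms[midrow + xb]
  if (is.na(ta) || is.na(tb) || tb <= ta)
    stop("propagation failure: the plane wave did not reach the far ",
         "sensing line (D = ", D, " mm^2/ms)", call. = FALSE)
  cv <- (xb - xa) * dx / (tb - ta) * 100  # mm/ms -> cm/s
  attr(cv, "recording") <- rec
  cv
}

#' Calibrate the diffusion coefficient to a target conduction velocity
#'
#' Secant iteration seeded with the cable-theory scaling CV proportional
#' to sqrt(D); converges to within `tol` (default 1%) of the target on
#' the standard fibrosis-free strip.
#'
#' @param target_cv target CV, cm/s (physiological window 20-120).
#' @param config a [simulation_config()].
#' @param tol relative tolerance on the achieved CV.
#' @param max_iter iteration cap.
#' @param ... strip geometry arguments passed to [measure_cv()].
#' @return diffusion coefficient D (mm^2/ms) with attributes
#'   `achieved_cv` and `log` (the iteration history).
#' @export
calibrate_diffusion <- function(target_cv, config = simulation_config(),
                                tol = 0.01, max_iter = 20, ...) {
  if (!is.finite(target_cv) || target_cv < 20 || target_cv > 120)
    stop("target_cv must lie in the physiological window [20, 120] cm/s",
         call. = FALSE)
  log <- data.frame(iter = integer(0), D = numeric(0), cv = numeric(0))
  D0 <- config$D
  cv0 <- as.numeric(measure_cv(D0, config, ...))
  log <- rbind(log, data.frame(iter = 0L, D = D0, cv = cv0))
  if (abs(cv0 - target_cv) <= tol * target_cv) {
    out <- D0
  } else {
    D1 <- D0 * (target_cv / cv0)^2
    cv1 <- as.numeric(measure_cv(D1, config, ...))
    log <- rbind(log, data.frame(iter = 1L, D = D1, cv = cv1))
    it <- 1L
    while (abs(cv1 - target_cv) > 0.8 * tol * target_cv) {
      it <- it + 1L
      if (it > max_iter)
        stop("calibration did not converge in ", max_iter,
             " iterations; history:\n",
             paste(utils::capture.output(print(log)), collapse = "\n"),
             call. = FALSE)
      dcv <- cv1 - cv0
      D2 <- if (abs(dcv) < 1e-12) D1 * (target_cv / cv1)^2
            else D1 + (target_cv - cv1) * (D1 - D0) / dcv
      if (D2 <= 0) D2 <- D1 * (target_cv / cv1)^2
      D0 <- D1; cv0 <- cv1
      D1 <- D2
      cv1 <- as.numeric(measure_cv(D1, config, ...))
      log <- rbind(log, data.frame(iter = it, D = D1, cv = cv1))
    }
    out <- D1
  }
  attr(out, "achieved_cv") <- log$cv[nrow(log)]
  attr(out, "log") <- log
  out
}

#' Persist / restore a voltage recording
#'
#' Recordings are array containers (space x time voltage and calcium
#' movies plus metadata); they are stored via R serialization.
#'
#' @param recording a `voltage_recording`.
#' @param path file path.
#' @export
write_recording <- function(recording, path) {
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) readRDS(path)

#' Export the per-node activation-time map as CSV
#'
#' @param recording a `voltage_recording`.
#' @param path output CSV path.
#' @export
export_activation_csv <- function(recording, path) {
  g <- recording$geometry
  n <- g$n_nodes
  df <- data.frame(node = seq_len(n),
                   x = (seq_len(n) - 1L) %% g$nx + 1L,
                   y = (seq_len(n) - 1L) %/% g$nx + 1L,
                   activation_ms = recording$first_activation_ms)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
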