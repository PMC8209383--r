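# S1-S2 cross-field reentry induction, sustainability classification and
# conduction-velocity scanning.
#
# S1: a train of stimuli at a bottom-edge ("apex-analog") strip drives
# planar wavefronts toward the opposite edge. S2: when the final S1
# wavefront first crosses the activation threshold on the mid-height
# sensing line, i.e. has traveled half way across the sheet, every cell
# in the left half-domain is instantaneously reset to the resting state.
# The surviving right-half wavefront curls into the reset region and
# forms a spiral.

#' Build the standard S1-S2 cross-field protocol
#'
#' Defaults: three S1 stimuli at 600-ms cycle length delivered to a
#' 3-node-thick bottom edge strip; the S2 reset region is the left half
#' of the sheet (columns `[1, nx/2]`); the trigger is the first -20 mV
#' upcrossing on the mid-height row after the final S1 stimulus. The
#' reset restores the complete resting cell state (all 19 state
#' variables), not just the membrane potential, to avoid nonphysical
#' internal-state gradients.
#'
#' @param geometry a 2D `tissue_geometry`.
#' @param s1_count number of S1 stimuli (>= 1).
#' @param s1_cycle_length S1 cycle length, ms.
#' @param s1_thickness thickness (rows) of the apex-analog stimulus strip.
#' @param post_trigger_ms observation window after the S2 reset, ms.
#' @param s2_enabled set `FALSE` for an induction-control run without the
#'   cross-field reset.
#' @param threshold trigger threshold, mV.
#' @return a `stimulus_protocol`.
#' @export
build_s1s2 <- function(geometry, s1_count = 3, s1_cycle_length = 600,
                       s1_thickness = 3, post_trigger_ms = 2000,
                       s2_enabled = TRUE, threshold = -20) {
  if (s1_count < 1) stop("s1_count must be >= 1", call. = FALSE)
  if (s1_cycle_length <= 0)
    stop("s1_cycle_length must be > 0", call. = FALSE)
  nx <- geometry$nx; ny <- geometry$ny
  rows <- seq_len(min(s1_thickness, ny))
  s1_nodes <- as.vector(outer(seq_len(nx), (rows - 1L) * nx, `+`))
  s1_starts <- (seq_len(s1_count) - 1) * s1_cycle_length

  s2 <- NULL
  if (s2_enabled) {
    mid_row <- ny %/% 2L
    trigger_nodes <- (mid_row - 1L) * nx + seq_len(nx)
    left_cols <- seq_len(nx %/% 2L)
    reset_nodes <- as.vector(outer(left_cols, (seq_len(ny) - 1L) * nx, `+`))
    s2 <- list(trigger_nodes = trigger_nodes, reset_nodes = reset_nodes,
               threshold = threshold, post_trigger_ms = post_trigger_ms)
  }
  p <- stimulus_protocol(s1_nodes, s1_starts, s2)
  p$s1_cycle_length <- s1_cycle_length
  p$s1_count <- s1_count
  p
}

#' Run the S1-S2 cross-field induction on a (possibly fibrotic) sheet
#'
#' Wraps [run_simulation()] with sensible recording defaults: snapshots
#' start at the final S1 stimulus so the post-reset dynamics are fully
#' covered for phase analysis. If the final S1 wavefront never reaches
#' the mid-height sensing line, the run is returned with
#' `trigger_time_ms = NA` (induction failure is reported, not raised).
#'
#' @param geometry a 2D `tissue_geometry`.
#' @param map a `fibrosis_map` or `NULL`.
#' @param config a [simulation_config()]; its `duration_ms` acts as a cap
#'   when the trigger never fires.
#' @param protocol a [build_s1s2()] protocol.
#' @return a `voltage_recording`.
#' @export
run_s1s2 <- function(geometry, map = NULL, config, protocol) {
  last_s1 <- max(protocol$s1_starts)
  cfg <- config
  # cap: S1 train + generous transit time + the post-reset window
  transit_cap <- geometry$ny * geometry$dx / 0.1  # full height at 10 cm/s
  post <- if (!is.null(protocol$s2)) protocol$s2$post_trigger_ms else 0
  cfg$duration_ms <- max(cfg$duration_ms, last_s1 + transit_cap + post)
  if (cfg$record_start_ms <= 0) cfg$record_start_ms <- last_s1
  run_simulation(geometry, map, cfg, protocol)
}

#' Classify whether induced reentry is sustained
#'
#' Reentry counts as sustained when, in the final `tail_ms` of the
#' `window_ms` observation window after the S2 reset, at least one
#' snapshot still shows ongoing activation (spatial maximum of Vm above
#' `threshold`).
#'
#' @param recording a `voltage_recording` from [run_s1s2()].
#' @param window_ms observation window after the reset trigger, ms.
#' @param tail_ms length of the terminal assessment window, ms.
#' @param threshold activity threshold, mV (default -40).
#' @return `TRUE`/`FALSE`; `FALSE` when induction itself failed (no
#'   trigger).
#' @export
detect_sustained <- function(recording, window_ms = 2000, tail_ms = 200,
                             threshold = -40) {
  if (tail_ms > window_ms)
    stop("tail_ms must not exceed window_ms", call. = FALSE)
  t0 <- recording$trigger_time_ms
  if (is.na(t0)) return(FALSE)
  t_hi <- t0 + window_ms
  if (max(recording$time_ms) < t_hi - recording$config$snapshot_interval_ms)
    stop("recording too short: covers ",
         round(max(recording$time_ms) - t0), " ms after the reset, ",
         "window_ms = ", window_ms, call. = FALSE)
  sel <- recording$time_ms >= t_hi - tail_ms & recording$time_ms <= t_hi
  if (!any(sel)) stop("no snapshots inside the assessment tail",
                      call. = FALSE)
  any(apply(recording$vm[, sel, drop = FALSE], 2, max) > threshold)
}

#' Scan reentry sustainability across conduction velocities
#'
#' For each CV in `cv_values`: calibrate the diffusion coefficient on the
#' standard fibrosis-free strip, run the S1-S2 protocol on the fibrotic
#' sheet, and classify sustainability. The default grid spans 53 to 100
#' cm/s in 3 cm/s steps (16 values).
#'
#' @param geometry a 2D `tissue_geometry`.
#' @param map a `fibrosis_map`.
#' @param config a [simulation_config()] template.
#' @param cv_values increasing CV grid, cm/s.
#' @param window_ms,tail_ms sustainability criterion passed to
#'   [detect_sustained()].
#' @param protocol optional pre-built [build_s1s2()] protocol.
#' @param keep_recordings retain the per-CV recordings (memory-heavy).
#' @return object of class `cv_scan_result`: data.frame `grid` (cv,
#'   sustained, trigger_time_ms, D), `min_sustaining_cv` (smallest grid
#'   CV whose reentry is sustained, or `NA` if none).
#' @export
cv_scan <- function(geometry, map, config = simulation_config(),
                    cv_values = seq(53, 100, by = 3),
                    window_ms = 2000, tail_ms = 200, protocol = NULL,
                    keep_recordings = FALSE) {
  if (!length(cv_values)) stop("cv_values must be non-empty", call. = FALSE)
  if (is.unsorted(cv_values, strictly = TRUE))
    stop("cv_values must be strictly increasing", call. = FALSE)
  if (is.null(protocol))
    protocol <- build_s1s2(geometry, post_trigger_ms = window_ms)
  rows <- vector("list", length(cv_values))
  recs <- if (keep_recordings) vector("list", length(cv_values)) else NULL
  for (i in seq_along(cv_values)) {
    cv <- cv_values[i]
    row <- data.frame(cv = cv, sustained = NA, trigger_time_ms = NA_real_,
                      D = NA_real_, note = "")
    ok <- TRUE
    D <- tryCatch(calibrate_diffusion(cv, config, dx = geometry$dx),
                  error = function(e) {
                    row$note <<- paste("calibration failed:",
                                       conditionMessage(e))
                    ok <<- FALSE
                    NULL
                  })
    if (ok) {
      cfg <- config
      cfg$D <- as.numeric(D)
      rec <- run_s1s2(geometry, map, cfg, protocol)
      row$D <- as.numeric(D)
      row$trigger_time_ms <- rec$trigger_time_ms
      row$sustained <- detect_sustained(rec, window_ms, tail_ms)
      if (keep_recordings) recs[[i]] <- rec
    }
    rows[[i]] <- row
  }
  grid <- do.call(rbind, rows)
  sus <- grid$cv[which(grid$sustained %in% TRUE)]
  structure(list(grid = grid,
                 min_sustaining_cv = if (length(sus)) min(sus) else NA_real_,
                 map_meta = map[c("pattern", "amount", "seed")],
                 recordings = recs),
            class = "cv_scan_result")
}

#' @export
print.cv_scan_result <- function(x, ...) {
  cat("CV scan:", nrow(x$grid), "velocities;",
      sum(x$grid$sustained %in% TRUE), "sustained; boundary =",
      x$min_sustaining_cv, "cm/s\n")
  invisible(x)
}
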