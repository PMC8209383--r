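# Phase reconstruction by time-delay embedding and phase-singularity
# detection via plaquette winding numbers (topological charge).

# wrap to (-pi, pi]; ties at exactly pi resolve to +pi
wrap_phase <- function(d) d - 2 * pi * ceiling((d - pi) / (2 * pi))

#' Time-delay-embedding phase of a voltage recording
#'
#' The phase of node i at time t is
#' `theta_i(t) = atan2(Vm_i(t + tau) - V*, Vm_i(t) - V*)`,
#' wrapped to `(-pi, pi]`. During a periodic action potential the
#' embedded trajectory encircles the origin `(V*, V*)` once per cycle,
#' so theta advances through 2*pi per activation.
#'
#' @param recording a `voltage_recording`.
#' @param tau_ms embedding delay, ms; must be a positive multiple of the
#'   snapshot interval.
#' @param v_star embedding origin, mV (default -40, mid-range of the AP).
#' @return object of class `phase_map`: `theta` (nodes x times matrix),
#'   `time_ms`, grid dims, and the embedding parameters.
#' @export
compute_phase <- function(recording, tau_ms = 5, v_star = -40) {
  times <- recording$time_ms
  if (length(times) < 2) stop("recording has too few frames", call. = FALSE)
  dt <- times[2] - times[1]
  k <- tau_ms / dt
  if (tau_ms <= 0 || abs(k - round(k)) > 1e-9)
    stop("tau_ms must be a positive multiple of the snapshot interval (",
         dt, " ms)", call. = FALSE)
  k <- as.integer(round(k))
  nt <- length(times)
  if (nt <= k) stop("recording shorter than the embedding delay tau",
                    call. = FALSE)
  v <- recording$vm
  theta <- atan2(v[, (k + 1):nt, drop = FALSE] - v_star,
                 v[, 1:(nt - k), drop = FALSE] - v_star)
  structure(list(theta = theta, time_ms = times[1:(nt - k)],
                 nx = recording$geometry$nx, ny = recording$geometry$ny,
                 tau_ms = tau_ms, v_star = v_star,
                 embedding = "time_delay"),
            class = "phase_map")
}

#' Construct a phase map directly from a phase field
#'
#' Utility for analytic phase fields (tests, method validation).
#'
#' @param theta matrix (nx x ny) or nodes-vector of phases, radians.
#' @param nx,ny grid dimensions.
#' @param time_ms frame time stamp(s).
#' @return a `phase_map` with one frame per column of `theta`.
#' @export
phase_map_from_field <- function(theta, nx, ny, time_ms = 0) {
  th <- matrix(as.numeric(theta), nrow = nx * ny)
  structure(list(theta = wrap_phase(th), time_ms = time_ms,
                 nx = nx, ny = ny, tau_ms = NA_real_, v_star = NA_real_,
                 embedding = "analytic"),
            class = "phase_map")
}

#' Detect phase singularities in one frame by plaquette winding numbers
#'
#' For every 2x2 plaquette of nodes, the four phase differences around
#' the loop (each wrapped to `(-pi, pi]`) are summed; a phase singularity
#' is recorded wherever the loop sum equals +/- 2*pi (tolerance 1e-6),
#' with topological charge equal to the sign of the sum.
#'
#' @param phasemap a `phase_map`.
#' @param t snapshot time, ms; must match a frame of the phase map.
#' @return data.frame with one row per singularity: `time_ms`, `x`, `y`
#'   (1-based lower-left node of the plaquette) and `charge` (+1/-1).
#' @export
detect_ps <- function(phasemap, t = phasemap$time_ms[1]) {
  fi <- which(abs(phasemap$time_ms - t) < 1e-9)
  if (!length(fi))
    stop("t = ", t, " ms is not a snapshot time of this phase map",
         call. = FALSE)
  nx <- phasemap$nx; ny <- phasemap$ny
  th <- matrix(phasemap$theta[, fi[1]], nx, ny)
  # loop (x,y) -> (x+1,y) -> (x+1,y+1) -> (x,y+1) -> (x,y)
  a <- th[-nx, -ny]; b <- th[-1, -ny]; c <- th[-1, -1]; d <- th[-nx, -1]
  s <- wrap_phase(b - a) + wrap_phase(c - b) + wrap_phase(d - c) +
       wrap_phase(a - d)
  hit <- which(abs(abs(s) - 2 * pi) < 1e-6)
  if (!length(hit))
    return(data.frame(time_ms = numeric(0), x = integer(0),
                      y = integer(0), charge = integer(0)))
  xi <- (hit - 1L) %% (nx - 1L) + 1L
  yi <- (hit - 1L) %/% (nx - 1L) + 1L
  data.frame(time_ms = t, x = xi, y = yi,
             charge = as.integer(sign(s[hit])))
}

#' Mean phase-singularity count over a time window
#'
#' Arithmetic mean of per-frame singularity counts over frames sampled
#' every `sample_interval` ms in `[t_start, t_end]`.
#'
#' @param phasemap a `phase_map`.
#' @param t_start,t_end window, ms (defaults: full phase-defined range).
#' @param sample_interval sampling cadence, ms (default 10).
#' @return list with `mean_ps`, per-frame `counts`, the sampled
#'   `time_ms`, and the full `ps_table` of detections.
#' @export
mean_ps_count <- function(phasemap, t_start = min(phasemap$time_ms),
                          t_end = max(phasemap$time_ms),
                          sample_interval = 10) {
  times <- phasemap$time_ms
  want <- seq(t_start, t_end, by = sample_interval)
  idx <- unique(vapply(want, function(w) which.min(abs(times - w)),
                       integer(1)))
  sel <- times[idx]
  sel <- sel[sel >= t_start - 1e-9 & sel <= t_end + 1e-9]
  if (!length(sel)) stop("no frames in the sampling window", call. = FALSE)
  tabs <- lapply(sel, function(tt) detect_ps(phasemap, tt))
  counts <- vapply(tabs, nrow, integer(1))
  list(mean_ps = mean(counts), counts = counts, time_ms = sel,
       ps_table = do.call(rbind, tabs))
}

#' Write a phase-singularity table as CSV
#'
#' @param ps_table data.frame from [detect_ps()] / [mean_ps_count()].
#' @param path output CSV path.
#' @export
write_ps_csv <- function(ps_table, path) {
  write.csv(ps_table, path, row.names = FALSE)
  invisible(path)
}
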