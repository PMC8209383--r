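# Study orchestration: map generation -> entropy -> S1-S2 reentry ->
# phase-singularity counting -> sustainability -> MFE-PS correlation.

#' Study configuration for an ensemble run
#'
#' The `desk2d` profile is a scaled-down 2D version of the full study
#' grid (the original study ran 75 ten-second 3D simulations); its grid,
#' observation window and replicate count are configurable.
#'
#' @param nx,ny,dx sheet geometry.
#' @param patterns,amounts,n_replicates study grid.
#' @param base_seed master seed; determines every per-map seed.
#' @param cv_target conduction velocity the tissue is calibrated to,
#'   cm/s.
#' @param window_ms post-reset observation window, ms.
#' @param tail_ms sustainability assessment tail, ms.
#' @param s1_count,s1_cycle_length S1 pacing train.
#' @param dt_ms,snapshot_interval_ms solver resolution.
#' @param ps_sample_interval phase-singularity sampling cadence, ms.
#' @param tau_ms,v_star phase-embedding parameters.
#' @param cache_dir directory for per-run result caching (`NULL`
#'   disables caching).
#' @return a `study_config` list.
#' @export
study_config <- function(nx = 128, ny = 128, dx = 0.25,
                         patterns = c("diffuse", "patchy", "compact"),
                         amounts = c(0.1, 0.3, 0.5), n_replicates = 3,
                         base_seed = 1L, cv_target = 79,
                         window_ms = 2000, tail_ms = 200,
                         s1_count = 3, s1_cycle_length = 600,
                         dt_ms = 0.02, snapshot_interval_ms = 2,
                         ps_sample_interval = 10,
                         tau_ms = 6, v_star = -40,
                         cache_dir = NULL) {
  structure(as.list(environment()), class = "study_config")
}

.run_key <- function(cfg, pattern, amount, replicate, seed) {
  sprintf("%s_a%03d_r%d_s%d_g%dx%d_dx%d_cv%g_w%g_dt%g",
          pattern, round(amount * 1000), replicate, seed,
          cfg$nx, cfg$ny, round(cfg$dx * 1000), cfg$cv_target,
          cfg$window_ms, cfg$dt_ms)
}

# one (pattern, amount, replicate) cell: returns a one-row data.frame
.run_one <- function(cfg, map, replicate, D) {
  geom <- map$geometry
  mfe <- local_fe(map)$mfe
  sim <- simulation_config(dt_ms = cfg$dt_ms, D = D,
                           duration_ms = cfg$window_ms,
                           snapshot_interval_ms = cfg$snapshot_interval_ms)
  prot <- build_s1s2(geom, s1_count = cfg$s1_count,
                     s1_cycle_length = cfg$s1_cycle_length,
                     post_trigger_ms = cfg$window_ms)
  rec <- run_s1s2(geom, map, sim, prot)
  induced <- !is.na(rec$trigger_time_ms)
  sustained <- FALSE
  mean_ps <- NA_real_
  if (induced) {
    sustained <- detect_sustained(rec, cfg$window_ms, cfg$tail_ms)
    ph <- compute_phase(rec, tau_ms = cfg$tau_ms, v_star = cfg$v_star)
    t0 <- rec$trigger_time_ms
    t1 <- min(t0 + cfg$window_ms, max(ph$time_ms))
    mean_ps <- mean_ps_count(ph, t0, t1, cfg$ps_sample_interval)$mean_ps
  }
  data.frame(pattern = map$pattern, amount = map$amount,
             replicate = replicate, seed = map$seed, mfe = mfe,
             mean_ps = mean_ps, induced = induced, sustained = sustained,
             cv = cfg$cv_target, D = D, stringsAsFactors = FALSE)
}

#' Run the study ensemble
#'
#' For every configured (pattern, amount, replicate): generate the
#' fibrosis map, compute its MFE, calibrate the diffusion coefficient to
#' the target CV, run the S1-S2 cross-field induction, classify
#' sustainability and count phase singularities over the post-reset
#' window. Per-run rows are cached on disk (when `cache_dir` is set) so
#' an interrupted or re-run ensemble reuses finished cells without
#' re-simulation. Per-run failures are recorded and the ensemble
#' continues.
#'
#' @param cfg a [study_config()].
#' @return object of class `ensemble_summary`: `rows` (one data.frame
#'   row per model), `groups` (per pattern x amount aggregates),
#'   `correlations` (per-pattern Pearson r between per-model MFE and
#'   mean PS count, pooled across amounts), `failures`, and the config.
#' @export
run_ensemble <- function(cfg = study_config()) {
  geom <- make_sheet(cfg$nx, cfg$ny, cfg$dx)
  ens <- generate_ensemble(geom, cfg$patterns, cfg$amounts,
                           cfg$n_replicates, cfg$base_seed)
  man <- ens$manifest

  if (!is.null(cfg$cache_dir) && !dir.exists(cfg$cache_dir))
    dir.create(cfg$cache_dir, recursive = TRUE)

  # the strip calibration is shared by every run; cache it alongside
  calib_file <- if (!is.null(cfg$cache_dir))
    file.path(cfg$cache_dir,
              sprintf("calib_cv%g_dx%d_dt%g.rds", cfg$cv_target,
                      round(cfg$dx * 1000), cfg$dt_ms)) else NULL
  if (!is.null(calib_file) && file.exists(calib_file)) {
    D <- readRDS(calib_file)
  } else {
    D <- as.numeric(calibrate_diffusion(
      cfg$cv_target, simulation_config(dt_ms = cfg$dt_ms), dx = cfg$dx))
    if (!is.null(calib_file)) saveRDS(D, calib_file)
  }

  rows <- vector("list", nrow(man))
  failures <- list()
  for (i in seq_len(nrow(man))) {
    key <- .run_key(cfg, man$pattern[i], man$amount[i], man$replicate[i],
                    man$seed[i])
    cache_file <- if (!is.null(cfg$cache_dir))
      file.path(cfg$cache_dir, paste0(key, ".rds")) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[i]] <- readRDS(cache_file)
      next
    }
    t0 <- Sys.time()
    res <- tryCatch(
      .run_one(cfg, ens$maps[[i]], man$replicate[i], D),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
      message(sprintf("[%s] FAILED: %s", key, conditionMessage(res)))
      next
    }
    message(sprintf("[%s] mfe=%.3f mean_ps=%.2f sustained=%s (%.1f s)",
                    key, res$mfe, res$mean_ps, res$sustained,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    if (!is.null(cache_file)) saveRDS(res, cache_file)
    rows[[i]] <- res
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  groups <- NULL
  correlations <- NULL
  if (!is.null(rows) && nrow(rows)) {
    groups <- stats::aggregate(
      cbind(mfe, mean_ps) ~ pattern + amount, data = rows,
      FUN = mean, na.action = stats::na.omit)
    correlations <- do.call(rbind, lapply(split(rows, rows$pattern),
      function(d) {
        ok <- stats::complete.cases(d$mfe, d$mean_ps)
        r <- if (sum(ok) >= 3 && stats::sd(d$mfe[ok]) > 0 &&
                 stats::sd(d$mean_ps[ok]) > 0)
          pearson_r(d$mfe[ok], d$mean_ps[ok]) else NA_real_
        data.frame(pattern = d$pattern[1], n = sum(ok), pearson_r = r,
                   stringsAsFactors = FALSE)
      }))
    rownames(correlations) <- NULL
  }
  structure(list(rows = rows, groups = groups,
                 correlations = correlations, failures = failures,
                 config = cfg, D = D),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble summary: %d models (%d failures), CV %g cm/s\n",
              if (is.null(x$rows)) 0L else nrow(x$rows),
              length(x$failures), x$config$cv_target))
  if (!is.null(x$correlations)) {
    cat("MFE-PS Pearson r by pattern:\n")
    print(x$correlations)
  }
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin guard around [stats::cor()]: requires equal lengths of at least
#' 3 and nonzero variance in both variables.
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' pearson_r(1:5, 2 * (1:5) + 1)  # 1
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  as.numeric(stats::cor(x, y, method = "pearson"))
}

#' Write the report tables of an ensemble summary
#'
#' Emits four CSV tables: MFE by pattern/amount, mean PS by
#' pattern/amount, the per-model sustainability grid, and the
#' per-pattern MFE-PS correlations (empty, with the reason noted, when a
#' pattern has fewer than 3 models). Identical summaries produce
#' byte-identical files.
#'
#' @param summary an `ensemble_summary`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(summary, out_dir) {
  if (is.null(summary$rows) || !nrow(summary$rows))
    stop("empty ensemble summary", call. = FALSE)
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory ", out_dir, call. = FALSE)
  paths <- file.path(out_dir, c("mfe_by_group.csv", "ps_by_group.csv",
                                "sustainability.csv", "correlations.csv"))
  rows <- summary$rows
  mfe <- mean_fe_by_group(rows)
  write.csv(mfe, paths[1], row.names = FALSE)

  ps <- stats::aggregate(mean_ps ~ pattern + amount, data = rows,
                         FUN = mean, na.action = stats::na.omit)
  write.csv(ps[order(ps$pattern, ps$amount), ], paths[2],
            row.names = FALSE)

  sus <- rows[, c("pattern", "amount", "replicate", "seed", "cv",
                  "induced", "sustained")]
  write.csv(sus, paths[3], row.names = FALSE)

  cors <- summary$correlations
  if (is.null(cors)) cors <- data.frame(pattern = character(0),
                                        n = integer(0),
                                        pearson_r = numeric(0))
  cors$note <- ifelse(is.na(cors$pearson_r),
                      "undefined: fewer than 3 models or zero variance",
                      "")
  write.csv(cors, paths[4], row.names = FALSE)
  invisible(paths)
}
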