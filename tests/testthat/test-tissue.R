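test_that("configuration and stability preconditions are enforced", {
  expect_error(simulation_config(dt_ms = 0.1), "dt_ms")
  expect_error(simulation_config(snapshot_interval_ms = 0.001), "snapshot")
  g <- make_sheet(20, 20, 0.1)
  cfg <- simulation_config(D = 0.5, duration_ms = 1)  # bound = 0.005 ms
  expect_error(run_simulation(g, NULL, cfg, plane_wave_protocol(g)),
               "stability")
})

test_that("diffusion conserves a uniform field to no-flux precision", {
  g <- make_sheet(30, 30, 0.25)
  cfg <- simulation_config(duration_ms = 50, stim_amplitude = 0)
  rec <- run_simulation(g, NULL, cfg, plane_wave_protocol(g))
  v_final <- rec$vm[, ncol(rec$vm)]
  expect_lt(stats::var(v_final), 1e-9)
})

test_that("a plane wave activates monotonically with distance", {
  g <- make_sheet(60, 12, 0.25)
  cfg <- simulation_config(duration_ms = 60, snapshot_interval_ms = 5)
  rec <- run_simulation(g, NULL, cfg, plane_wave_protocol(g))
  midrow <- (6L - 1L) * 60L
  act <- rec$first_activation_ms[midrow + 5:55]
  expect_true(all(is.finite(act)))
  expect_true(all(diff(act) >= 0))
})

test_that("identical inputs give bit-identical recordings", {
  g <- make_sheet(30, 10, 0.25)
  cfg <- simulation_config(duration_ms = 40)
  r1 <- run_simulation(g, NULL, cfg, plane_wave_protocol(g))
  r2 <- run_simulation(g, NULL, cfg, plane_wave_protocol(g))
  expect_identical(r1$vm, r2$vm)
  expect_identical(r1$first_activation_ms, r2$first_activation_ms)
})

test_that("the table-accelerated kernel matches the exact scalar path", {
  g <- make_sheet(40, 8, 0.25)
  mk <- function(tab) {
    cfg <- simulation_config(duration_ms = 60, snapshot_interval_ms = 2,
                             use_tables = tab)
    run_simulation(g, NULL, cfg, plane_wave_protocol(g))
  }
  rt <- mk(TRUE); rs <- mk(FALSE)
  expect_lt(max(abs(rt$vm - rs$vm)), 0.5)   # mV, across upstrokes
  # resting/plateau regions agree much tighter than the steep upstroke
  expect_lt(stats::median(abs(rt$vm - rs$vm)), 1e-3)
})

test_that("an all-fibrotic obstacle sheet does not propagate", {
  g <- make_sheet(30, 10, 0.25)
  m <- fibroarrhythm:::new_fibrosis_map(rep(1L, g$n_nodes), "compact", 1,
                                        1, list(), g)
  cfg <- simulation_config(duration_ms = 30, obstacle_mode = TRUE)
  rec <- run_simulation(g, m, cfg, plane_wave_protocol(g))
  expect_true(all(rec$vm[, ncol(rec$vm)] < -80))
  expect_true(all(is.na(rec$first_activation_ms)))
})

test_that("measured CV is positive, finite, and fails below threshold", {
  cv <- measure_cv(0.154)
  expect_true(is.finite(cv) && cv > 0)
  expect_error(measure_cv(1e-5), "propagation failure")
  expect_error(measure_cv(-1), "D must")
})

test_that("CV scales as the square root of the diffusion coefficient", {
  cfg <- simulation_config(dt_ms = 0.005)
  cv1 <- measure_cv(0.154, cfg, nx = 200, ny = 10, dx = 0.125)
  cv4 <- measure_cv(0.616, cfg, nx = 200, ny = 10, dx = 0.125)
  expect_lt(abs(cv4 / cv1 - 2), 0.1)
})

test_that("diffusion calibration converges and is monotone", {
  D79 <- calibrate_diffusion(79)
  expect_lt(abs(attr(D79, "achieved_cv") - 79) / 79, 0.01)
  # fixed point: targeting an already-measured CV returns ~ the same D
  cv0 <- as.numeric(measure_cv(0.154))
  D0 <- calibrate_diffusion(cv0)
  expect_lt(abs(as.numeric(D0) - 0.154) / 0.154, 0.02)
  D53 <- calibrate_diffusion(53)
  expect_gt(as.numeric(D79), as.numeric(D53))
  expect_error(calibrate_diffusion(150), "physiological")
})

test_that("a 30% diffuse strip strictly slows wave transit at equal D", {
  g <- make_sheet(100, 10, 0.25)
  cfg <- simulation_config(duration_ms = 120, snapshot_interval_ms = 5)
  prot <- plane_wave_protocol(g)
  far <- (5L - 1L) * 100L + 95L
  rec0 <- run_simulation(g, NULL, cfg, prot)
  t0 <- rec0$first_activation_ms[far]
  m <- generate_diffuse(g, 0.3, 21)
  cfg$duration_ms <- 250
  rec1 <- run_simulation(g, m, cfg, prot)
  t1 <- rec1$first_activation_ms[far]
  expect_true(is.finite(t0) && is.finite(t1))
  expect_gt(t1, t0)
})

test_that("recordings round-trip through persistence and CSV export", {
  g <- make_sheet(20, 8, 0.25)
  cfg <- simulation_config(duration_ms = 20, record_cai = TRUE)
  rec <- run_simulation(g, NULL, cfg, plane_wave_protocol(g))
  f <- tempfile(fileext = ".rds")
  write_recording(rec, f)
  rec2 <- read_recording(f)
  expect_identical(rec2$vm, rec$vm)
  expect_equal(dim(rec2$cai), dim(rec$vm))
  csv <- tempfile(fileext = ".csv")
  export_activation_csv(rec, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), g$n_nodes)
  unlink(c(f, csv))
})
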