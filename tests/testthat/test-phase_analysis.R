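test_that("time-delay embedding has the documented closed forms", {
  # constant recording above V*: theta = atan2(c, c) = pi/4 everywhere
  vm <- matrix(-40 + 12, nrow = 9, ncol = 20)
  rec <- fake_recording(vm, interval_ms = 1, nx = 3, ny = 3)
  ph <- compute_phase(rec, tau_ms = 5, v_star = -40)
  expect_equal(as.numeric(ph$theta), rep(pi / 4, length(ph$theta)))
  expect_equal(nrow(detect_ps(ph)), 0L)

  # a sinusoidal trace embedded at quarter period advances through 2*pi
  dt <- 1; period <- 40
  tvec <- seq(0, 200, by = dt)
  v <- -40 + 25 * sin(2 * pi * tvec / period)
  vm1 <- matrix(rep(v, each = 9), nrow = 9)
  rec1 <- fake_recording(vm1, interval_ms = dt, nx = 3, ny = 3)
  ph1 <- compute_phase(rec1, tau_ms = period / 4, v_star = -40)
  th <- ph1$theta[1, ]
  unw <- fibroarrhythm:::wrap_phase(diff(th))
  expect_true(all(unw > 0) || all(unw < 0))  # monotone advance
  one_period <- sum(unw[seq_len(period)])
  expect_equal(abs(one_period), 2 * pi, tolerance = 1e-9)

  # preconditions
  expect_error(compute_phase(rec, tau_ms = 2.5), "multiple")
  expect_error(compute_phase(fake_recording(vm[, 1:3, drop = FALSE],
                                            interval_ms = 1, nx = 3, ny = 3),
                             tau_ms = 5), "shorter|few")
})

test_that("an analytic vortex yields exactly one singularity of charge +1", {
  nx <- 16; ny <- 16
  th <- vortex_field(nx, ny, 8.5, 8.5, q = 1)
  pm <- phase_map_from_field(th, nx, ny)
  ps <- detect_ps(pm)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$charge, 1L)
  expect_equal(c(ps$x, ps$y), c(8L, 8L))  # plaquette containing the core

  anti <- phase_map_from_field(vortex_field(nx, ny, 8.5, 8.5, q = -1),
                               nx, ny)
  ps2 <- detect_ps(anti)
  expect_equal(ps2$charge, -1L)

  uniform <- phase_map_from_field(rep(1.1, nx * ny), nx, ny)
  expect_equal(nrow(detect_ps(uniform)), 0L)
})

test_that("a well-separated vortex-antivortex pair has two PSs, net charge 0", {
  nx <- 24; ny <- 16
  th <- vortex_field(nx, ny, 6.5, 8.5, q = 1) +
        vortex_field(nx, ny, 18.5, 8.5, q = -1)
  pm <- phase_map_from_field(th, nx, ny)
  ps <- detect_ps(pm)
  expect_equal(nrow(ps), 2L)
  expect_equal(sum(ps$charge), 0L)
  expect_setequal(ps$charge, c(-1L, 1L))
})

test_that("plaquette charges satisfy the discrete Stokes identity on random smooth fields", {
  set.seed(31)
  for (k in 1:40) {
    th <- matrix(random_smooth_phase(16, 16, n_vortices = sample(0:3, 1)),
                 16, 16)
    pm <- phase_map_from_field(th, 16, 16)
    ps <- detect_ps(pm)
    total_charge <- if (nrow(ps)) sum(ps$charge) else 0L
    boundary <- brute_winding(matrix(pm$theta[, 1], 16, 16), 1, 1, 16, 16)
    expect_equal(total_charge * 2 * pi, boundary, tolerance = 1e-9)
    # every reported singularity is confirmed by a brute-force loop
    # integral around its plaquette
    if (nrow(ps)) for (i in seq_len(nrow(ps))) {
      w <- brute_winding(matrix(pm$theta[, 1], 16, 16),
                         ps$x[i], ps$y[i], ps$x[i] + 1L, ps$y[i] + 1L)
      expect_equal(w, 2 * pi * ps$charge[i], tolerance = 1e-9)
    }
  }
})

test_that("mean PS counting averages frames as stated", {
  nx <- 16; ny <- 16
  v1 <- vortex_field(nx, ny, 8.5, 8.5, 1)
  v3 <- vortex_field(nx, ny, 4.5, 4.5, 1) +
        vortex_field(nx, ny, 12.5, 4.5, -1) +
        vortex_field(nx, ny, 8.5, 12.5, 1)
  # stationary vortex at every frame -> mean exactly 1
  pm_st <- phase_map_from_field(matrix(rep(v1, 6), ncol = 6), nx, ny,
                                time_ms = seq(0, 50, by = 10))
  r_st <- mean_ps_count(pm_st, 0, 50, 10)
  expect_equal(r_st$mean_ps, 1)
  # frames alternating 1 and 3 singularities -> mean 2
  pm_alt <- phase_map_from_field(cbind(v1, v3, v1, v3), nx, ny,
                                 time_ms = c(0, 10, 20, 30))
  r_alt <- mean_ps_count(pm_alt, 0, 30, 10)
  expect_equal(r_alt$counts, c(1L, 3L, 1L, 3L))
  expect_equal(r_alt$mean_ps, 2)
  expect_error(mean_ps_count(pm_alt, 100, 200, 10), "window")
})
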