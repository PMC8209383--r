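test_that("resting initial state is valid, deterministic and a fixed point", {
  s <- init_cell_state("epicardial")
  gates <- s[c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f",
               "f2", "fCass", "Rbar")]
  expect_true(all(gates >= 0 & gates <= 1))
  expect_lt(s["Cai"], 0.001)
  expect_true(all(s[c("Cai", "CaSS", "CaSR", "Nai", "Ki")] > 0))
  expect_identical(init_cell_state("epicardial"), s)
  expect_error(init_cell_state("apex"), "unknown cell variant")

  # one unstimulated step barely moves Vm
  s1 <- step_cell(s, cell_params(), dt = 0.02)
  expect_lt(abs(s1["Vm"] - s["Vm"]), 1e-3)
})

test_that("reported I_ion is the sum of the twelve membrane currents", {
  p <- cell_params()
  membrane <- c("I_Na", "I_K1", "I_to", "I_Kr", "I_Ks", "I_CaL", "I_NaCa",
                "I_NaK", "I_pCa", "I_pK", "I_bCa", "I_bNa")
  set.seed(7)
  for (k in 1:25) {
    s <- init_cell_state()
    s["Vm"] <- runif(1, -90, 40)
    gi <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2",
            "fCass", "Rbar")
    s[gi] <- runif(length(gi))
    s["Cai"] <- runif(1, 2e-5, 1e-3)
    s["CaSS"] <- runif(1, 2e-5, 2e-3)
    s["CaSR"] <- runif(1, 0.5, 4)
    cur <- ionic_currents(s, p)
    expect_lt(abs(cur["I_ion"] - sum(cur[membrane])),
              1e-12 * max(1, abs(cur["I_ion"])))
  }
  expect_error(ionic_currents(replace(init_cell_state(), 1, NaN)),
               "non-finite")
})

test_that("fast sodium current vanishes at its reversal potential", {
  p <- cell_params()
  s <- init_cell_state()
  e_na <- 8314.472 * 310 / 96485.3415 * log(140 / s["Nai"])
  s["Vm"] <- e_na
  s[c("m", "h", "j")] <- 0.5
  expect_lt(abs(ionic_currents(s, p)["I_Na"]), 1e-10)
})

test_that("the inward rectifier dominates outward current at rest", {
  cur <- ionic_currents(init_cell_state(), cell_params())
  outw <- cur[c("I_K1", "I_to", "I_Kr", "I_Ks", "I_pK")]
  outw <- outw[outw > 0]
  expect_identical(names(which.max(outw)), "I_K1")
})

test_that("Rush-Larsen stepping keeps gates in [0,1] and dt is validated", {
  p <- cell_params()
  gi <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2",
          "fCass", "Rbar")
  set.seed(11)
  for (k in 1:10) {
    s <- init_cell_state()
    s["Vm"] <- runif(1, -90, 30)
    s[gi] <- runif(length(gi))
    s2 <- step_cell(s, p, dt = 0.05, i_stim = runif(1, -52, 0),
                    n_steps = 20L)
    expect_true(all(s2[gi] >= 0 & s2[gi] <= 1))
  }
  expect_error(step_cell(init_cell_state(), p, dt = 0.1), "dt must")
  expect_error(step_cell(init_cell_state(), p, dt = 0), "dt must")
})

test_that("a threshold stimulus elicits a fast upstroke", {
  p <- cell_params()
  s <- init_cell_state()
  s <- step_cell(s, p, dt = 0.02, i_stim = -52, n_steps = 50L)  # 1 ms
  s <- step_cell(s, p, dt = 0.02, i_stim = 0, n_steps = 200L)   # +4 ms
  expect_gt(s["Vm"], 10)
})

test_that("fibrotic remodeling scales exactly the three stated currents", {
  p <- cell_params()
  q <- apply_fibrosis_remodeling(p)
  expect_equal(q$G_Na / p$G_Na, 0.60)
  expect_equal(q$G_K1 / p$G_K1, 0.50)
  expect_equal(q$G_CaL / p$G_CaL, 0.50)
  untouched <- setdiff(names(unclass(p)), c("G_Na", "G_K1", "G_CaL"))
  expect_identical(unclass(p)[untouched], unclass(q)[untouched])
  expect_identical(
    unclass(apply_fibrosis_remodeling(p, fibrosis_remodeling(1, 1, 1, 1))),
    unclass(p))
  expect_error(fibrosis_remodeling(scale_K1 = 0), "factors")
  expect_error(fibrosis_remodeling(scale_Na = 1.2), "factors")
})

test_that("paced epicardial AP has spike-and-dome morphology and sane APD90", {
  tr <- pace_single_cell(cell_params(), cycle_length = 600, n_beats = 4)
  expect_gt(tr$apd90_ms, 150)
  expect_lt(tr$apd90_ms, 350)
  expect_gt(tr$peak_vm, 20)
  # notch-then-dome: a local minimum early in the plateau followed by a
  # secondary maximum at least 1 mV higher
  lb <- tr$last_beat
  win <- lb$time_ms > 3 & lb$time_ms < 150
  v <- lb$vm[win]
  i_notch <- which.min(v[seq_len(round(length(v) / 3))])
  expect_gt(max(v[-seq_len(i_notch)]) - v[i_notch], 1)
})

test_that("default remodeling strictly lowers dV/dt_max and AP amplitude", {
  pn <- cell_params()
  pf <- apply_fibrosis_remodeling(pn)
  tn <- pace_single_cell(pn, 600, 3)
  tf <- pace_single_cell(pf, 600, 3)
  expect_lt(tf$dvdt_max, tn$dvdt_max)
  expect_lt(tf$peak_vm, tn$peak_vm)
})

test_that("pacing is deterministic: one beat equals the start of a longer run", {
  p <- cell_params()
  t1 <- pace_single_cell(p, 400, 1, sample_interval_ms = 0.5)
  t3 <- pace_single_cell(p, 400, 3, sample_interval_ms = 0.5)
  n <- sum(t1$time_ms < 400)
  expect_identical(t1$vm[seq_len(n)], t3$vm[seq_len(n)])
})
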