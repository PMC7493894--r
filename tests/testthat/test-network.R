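# Core simulator: compiled RHS correctness, conservation, observables,
# event detection.

p_def <- default_parameters()

test_that("compiled right-hand side matches an independent R implementation", {
  sys <- build_network(p_def, model_variant())
  s0 <- apply_momp(initial_state(), 1)
  # derivative agreement at scattered states along a trajectory
  tr <- simulate_network(sys, s0, t_end = 60, n_out = 61)
  for (i in c(1, 10, 30, 61)) {
    y <- tr$conc[i, ]
    d_compiled <- deSolve::DLLfunc(func = "derivs_apoptimer",
                                   dllname = "apoptimer",
                                   initfunc = "initmod_apoptimer",
                                   times = 0, y = y,
                                   parms = sys$parms)$dy
    d_r <- rhs_oracle(y, sys$parms)
    expect_equal(unname(d_compiled), unname(d_r[names(y)]),
                 tolerance = 1e-10)
  }
  # full-trajectory agreement against deSolve driven by the R oracle
  tr_r <- deSolve::ode(y = unclass(s0)[colnames(tr$conc)],
                       times = tr$time,
                       func = function(t, y, parms) list(rhs_oracle(y, parms)),
                       parms = sys$parms, method = "lsoda",
                       atol = 1e-19, rtol = 1e-8)
  expect_lt(max(abs(tr$conc - tr_r[, -1])), 1e-6)
})

test_that("conserved moieties stay constant along random trajectories", {
  for (seed in 1:10) {
    s0 <- random_fixture_state(seed,
                               momp_fraction = if (seed %% 2) 1 else 0.05)
    v <- c("normal", "no_xiap", "no_timer",
           "no_xiap_no_timer")[(seed %% 4) + 1]
    tr <- simulate_network(build_network(p_def, variant_by_name(v)), s0,
                           t_end = 240, n_out = 241)
    mt <- moiety_totals(tr)
    for (m in colnames(mt)) {
      if (mt[1, m] > 0)
        expect_lt(max(abs(mt[, m] - mt[1, m])) / mt[1, m], 1e-6)
      else
        expect_lt(max(abs(mt[, m])), 1e-12)
    }
    expect_gte(min(tr$conc), -1e-12)
  }
})

test_that("cleavage is monotone and observables recompute from raw species", {
  sys <- build_network(p_def, model_variant())
  tr <- simulate_network(sys, apply_momp(initial_state(), 1), t_end = 120)
  cl <- c3_substrate_cleavage(tr, tr$time)
  expect_true(all(diff(cl) >= -1e-9))
  expect_equal(cl[1], 0)
  # direct recomputation from species columns
  t_probe <- c(10, 45, 100)
  i <- match(t_probe, tr$time)
  expect_equal(c3_substrate_cleavage(tr, t_probe),
               unname(tr$conc[i, "cSub"] /
                        (tr$conc[i, "Sub"] + tr$conc[i, "cSub"])))
  expect_equal(cleaved_c3_fraction(tr, t_probe),
               unname((tr$conc[i, "C3"] + tr$conc[i, "XIAP_C3"]) /
                        (tr$conc[i, "PC3"] + tr$conc[i, "C3"] +
                           tr$conc[i, "XIAP_C3"])))
  expect_equal(cleaved_c3_fraction(tr, 0), 0)
  expect_error(c3_substrate_cleavage(tr, 500), "horizon")
})

test_that("PC9 processing fractions partition the caspase-9 pool", {
  sys <- build_network(p_def, model_variant())
  tr <- simulate_network(sys, apply_momp(initial_state(), 1), t_end = 60)
  f0 <- pc9_processing_fraction(tr, 0)
  expect_equal(unname(f0["PC9_cytosol"]), 1)
  expect_equal(sum(f0), 1)
  fm <- pc9_processing_fraction(tr, c(5, 20, 60))
  expect_equal(unname(rowSums(fm)), rep(1, 3), tolerance = 1e-6)
  # late in the trajectory the pool has been processed to C9
  f60 <- pc9_processing_fraction(tr, 60)
  expect_gt(f60[["C9_cytosol"]] + f60[["C9_apoptosome"]], 0.5)
})

test_that("non-cleavable PC9 never produces C9 species", {
  sys <- build_network(p_def, model_variant(pc9_cleavable = FALSE))
  tr <- simulate_network(sys, apply_momp(initial_state(), 1), t_end = 120)
  c9_cols <- c("C9", "Apop_C9", "XIAP_C9", "Apop_C9_XIAP")
  expect_equal(max(abs(tr$conc[, c9_cols])), 0)
})

test_that("zeroed XIAP pool is equivalent to deleting the XIAP reactions", {
  s0 <- random_fixture_state(3)
  tr_a <- simulate_network(build_network(p_def,
                                         model_variant(xiap_present = FALSE)),
                           s0, t_end = 120)
  p_cut <- default_parameters(kon_XIAP_C9 = 0, kon_XIAP_C3 = 0,
                              kon_SMAC_XIAP = 0)
  s0_cut <- s0
  s0_cut["XIAP"] <- 0
  tr_b <- simulate_network(build_network(p_cut, model_variant()), s0_cut,
                           t_end = 120)
  shared <- setdiff(colnames(tr_a$conc),
                    c("XIAP", "XIAP_C9", "Apop_C9_XIAP", "XIAP_C3",
                      "SMAC_XIAP"))
  expect_lt(max(abs(tr_a$conc[, shared] - tr_b$conc[, shared])), 1e-8)
})

test_that("no initiator caspase means no substrate cleavage", {
  sys <- build_network(p_def, model_variant())
  tr <- simulate_network(sys, apply_momp(initial_state(PC9 = 0), 1),
                         t_end = 120)
  expect_equal(max(c3_substrate_cleavage(tr, tr$time)), 0)
})

test_that("solution is converged with respect to the tolerances", {
  sys <- build_network(p_def, model_variant())
  s0 <- random_fixture_state(5)
  tr1 <- simulate_network(sys, s0, t_end = 240)
  tr2 <- simulate_network(sys, s0, t_end = 240, atol = 0.5e-19,
                          rtol = 0.5e-8)
  c1 <- c3_substrate_cleavage(tr1, 240)
  c2 <- c3_substrate_cleavage(tr2, 240)
  expect_lt(abs(c1 - c2) / max(c2, 1e-12), 1e-3)
})

test_that("death event detection root-finds the threshold crossing", {
  # constructed trajectory: cleavage rises linearly from 0 to 0.5 over
  # 0..74 min, so it crosses 25% at exactly t = 37
  tt <- seq(0, 240, by = 0.5)
  cl <- pmin(tt / 148, 0.5)
  ev <- detect_death_event(fake_cleavage_trajectory(tt, cl))
  expect_true(ev$died)
  expect_equal(ev$event_time, 37, tolerance = 1e-5)
  # plateau at exactly the threshold: strictly-exceeds rule censors
  ev2 <- detect_death_event(fake_cleavage_trajectory(tt, pmin(tt / 148,
                                                              0.25)))
  expect_false(ev2$died)
  expect_equal(ev2$event_time, 240)
  # never reaching the threshold censors at the horizon
  ev3 <- detect_death_event(fake_cleavage_trajectory(tt, pmin(tt / 1000,
                                                              0.2)))
  expect_false(ev3$died)
  expect_equal(ev3$event_time, 240)
  expect_error(detect_death_event(fake_cleavage_trajectory(tt, cl),
                                  threshold = 1.2), "\\(0, 1\\)")
})

test_that("IETDase activity is the weighted sum of active apoptosome pools", {
  # constructed state: active PC9 moieties 0.5, active C9 0.25
  tt <- c(0, 1, 2, 3, 4)
  conc <- matrix(0, 5, length(apoptimer:::.species_names),
                 dimnames = list(NULL, apoptimer:::.species_names))
  conc[, "Apop_PC9"] <- 0.1      # + 2 * 0.2 -> 0.5 PC9 moieties
  conc[, "Apop_PC9_2"] <- 0.2
  conc[, "Apop_C9"] <- 0.25
  traj <- structure(list(time = tt, conc = conc), class = "trajectory")
  p <- default_parameters(k_PC9 = 2, k_C9 = 1)
  act <- ietdase_activity(traj, p)
  expect_equal(act$activity, rep(2 * 0.5 + 1 * 0.25, 5))
  # degenerate: k_C9 = 0 reduces to the PC9 term
  p0 <- default_parameters(k_PC9 = 2, k_C9 = 0)
  expect_equal(ietdase_activity(traj, p0)$activity, rep(1.0, 5))
  # both pools zero -> zero activity
  conc[] <- 0
  traj0 <- structure(list(time = tt, conc = conc), class = "trajectory")
  expect_equal(ietdase_activity(traj0, p)$activity, rep(0, 5))
})
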