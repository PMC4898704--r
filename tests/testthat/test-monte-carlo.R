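# Monte Carlo ensemble simulation: determinism, degenerate limits,
# analytic survival and equilibrium oracles, error estimator.

test_that("a rate-free ensemble follows the all-folded curve exactly", {
  mod <- toy_model(omega0 = c(0, 0))
  prot <- make_ramp(1e-6, 1.8e-6, 1e-6)
  ens <- simulate_ensemble(prot, R = 1, mod, dt = 1e-3, seed = 1)
  F0 <- force_at(mod$curves, 0, ens$lengths)
  expect_equal(ens$mean_force, F0)
  expect_equal(sum(ens$state_counts[1, ]), length(ens$times))
  ff <- first_unfolding_forces(ens)
  expect_length(ff, 0)
  expect_equal(attr(ff, "n_excluded"), 1)
})

test_that("same seed gives identical results, different seed differs", {
  mod <- toy_model()
  prot <- make_ramp(1e-6, 1.8e-6, 1e-6)
  e1 <- simulate_ensemble(prot, R = 30, mod, seed = 9, keep_traces = TRUE)
  e2 <- simulate_ensemble(prot, R = 30, mod, seed = 9, keep_traces = TRUE)
  e3 <- simulate_ensemble(prot, R = 30, mod, seed = 10)
  expect_identical(e1$mean_force, e2$mean_force)
  expect_identical(e1$traces, e2$traces)
  expect_identical(e1$events, e2$events)
  expect_false(identical(e1$mean_force, e3$mean_force))
})

test_that("single-cluster survival matches the analytic exponential", {
  # constant zero force (hold below slack): hazard n * omega0 exactly
  mod <- toy_model(omega0 = c(0.5), n = c(4))
  prot <- hold_protocol(0.5e-6, duration = 0.5)
  R <- 2000
  ens <- simulate_ensemble(prot, R, mod, dt = 1e-3, seed = 3)
  surv <- ens$state_counts[1, ncol(ens$state_counts)] / R
  p_true <- exp(-4 * 0.5 * 0.5)
  se <- sqrt(p_true * (1 - p_true) / R)
  expect_lt(abs(surv - p_true), 4 * se)
})

test_that("with balanced rates the long-run occupancy is binomial", {
  n <- 6
  mod <- toy_model(omega0 = 2, n = n,
                   refolding = list(omega1 = 2, x_f = 2.2e-9))
  # at zero force u = r = 2/s; equilibrium is Binomial(n, 1/2)
  prot <- hold_protocol(0.5e-6, duration = 8)
  R <- 800
  ens <- simulate_ensemble(prot, R, mod, dt = 2e-3, seed = 5)
  emp <- ens$state_counts[, ncol(ens$state_counts)] / R
  expect_lt(tv_dist(emp, dbinom(0:n, n, 0.5)), 0.08)
})

test_that("counts are monotone without refolding and forces stay in envelope", {
  mod <- toy_model()
  prot <- make_ramp(1e-6, 2e-6, 1e-6)
  ens <- simulate_ensemble(prot, R = 40, mod, seed = 2, keep_traces = TRUE)
  for (s in seq_len(40)) expect_true(all(diff(ens$traces[s, ]) >= 0))
  N <- sum(mod$clusters$n)
  lo <- force_at(mod$curves, N, ens$lengths)
  hi <- force_at(mod$curves, 0, ens$lengths)
  expect_true(all(ens$mean_force >= lo - 1e-18 & ens$mean_force <= hi + 1e-18))
})

test_that("the event-probability guard reports overruns as configured", {
  mod <- toy_model(omega0 = c(50, 80))   # huge rates at dt = 0.05: p >> 1
  prot <- hold_protocol(0.5e-6, duration = 1)
  expect_warning(simulate_ensemble(prot, 5, mod, dt = 0.05, seed = 1),
                 "event probability")
  expect_error(simulate_ensemble(prot, 5, mod, dt = 0.05, seed = 1,
                                 on_overrun = "error"), "reduce dt")
  expect_silent(e <- simulate_ensemble(prot, 5, mod, dt = 0.05, seed = 1,
                                       on_overrun = "ignore"))
  expect_gt(e$overrun_steps, 0)
  expect_error(mc_step(c(0L, 0L), 0, 0.05, mod$clusters), "reduce dt")
})

test_that("mc_step applies at most one event per draw", {
  cm <- cluster_model(n = c(2, 2), omega0 = c(0.1, 0.2))
  s0 <- c(0L, 0L)
  # z beyond the total probability: no event
  s <- mc_step(s0, 0, 1e-3, cm, z = 0.999)
  expect_equal(attr(s, "event"), 0L)
  expect_equal(as.integer(s), s0)
  # z inside the first cluster interval: unfold there
  s <- mc_step(s0, 0, 1e-3, cm, z = 1e-5)
  expect_equal(attr(s, "event"), 1L)
  expect_equal(as.integer(s), c(1L, 0L))
  # rates 0: state unchanged for any z
  cm0 <- cluster_model(n = 3, omega0 = 0)
  expect_equal(as.integer(mc_step(0L, 1e-11, 1e-3, cm0, z = 1e-12)), 0L)
})

test_that("MCE vanishes for deterministic forces and shrinks like 1/sqrt(R)", {
  mod0 <- toy_model(omega0 = c(0, 0))
  prot <- make_ramp(1e-6, 1.6e-6, 2e-6)
  expect_equal(mce(3, 4, prot, mod0, dt = 2e-3, seed = 1), 0)
  mod <- toy_model()
  m_small <- mce(8, 30, prot, mod, dt = 2e-3, seed = 2)
  m_big <- mce(128, 30, prot, mod, dt = 2e-3, seed = 3)
  # 16x strands ~ 4x error reduction (generous band for H = 30)
  expect_lt(m_big, m_small / 2)
  expect_gt(m_big, m_small / 9)
})
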