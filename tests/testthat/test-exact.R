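# Master-equation solver: generator structure, conservation, closed forms,
# independent oracles (hand matrix, matrix exponential, quadrature, MC),
# refolding dynamics, first-unfolding distribution.

test_that("generator conserves probability and fixes the absorbing state", {
  mod <- toy_model(refolding = NULL)
  A <- generator_matrix(mod, 1.4e-6)
  expect_lt(max(abs(colSums(A))), 1e-12)
  # fully-unfolded state has zero outflow
  S <- ncol(A)
  expect_equal(A[, S], rep(0, S))
  # RHS at the delta distribution reproduces the first column
  prot <- hold_protocol(1.4e-6)
  p <- numeric(S); p[1] <- 1
  expect_equal(master_rhs(p, 0.5, mod, prot), A[, 1])
})

test_that("the m = 1, n = 2 generator equals the hand-written 3-state matrix", {
  mod <- toy_model(omega0 = 0.4, n = 2)
  l <- 1.35e-6
  u <- vapply(0:2, function(i)
    unfold_rate(force_at(mod$curves, i, l), 0.4, 0.25e-9), numeric(1))
  by_hand <- rbind(c(-2 * u[1], 0,     0),
                   c( 2 * u[1], -u[2], 0),
                   c( 0,         u[2], 0))
  expect_equal(generator_matrix(mod, l), by_hand, tolerance = 1e-12)
})

test_that("zero rates keep all probability at the fully-folded state", {
  mod <- toy_model(omega0 = c(0, 0))
  sol <- solve_master(make_ramp(1e-6, 1.8e-6, 1e-6), mod, dt = 1e-3)
  expect_equal(sol$P[1, ], rep(1, length(sol$times)))
  expect_equal(sol$expected_force, force_at(mod$curves, 0, sol$lengths))
})

test_that("probability is conserved and non-negative at every step", {
  sol <- solve_master(make_ramp(1e-6, 2e-6, 1e-6), toy_model(), dt = 1e-3,
                      keep_states = "all")
  expect_lt(max(abs(colSums(sol$P) - 1)), 1e-9)
  expect_equal(sol$n_renorm, 0L)
  expect_true(all(sol$states >= -1e-10))
  # aggregation identities
  cm <- toy_model()$clusters
  expect_equal(aggregate_states(sol$states[, 10], cm), sol$P[, 10])
  expect_equal(sol$P[, 1], c(1, rep(0, 5)))
})

test_that("single-cluster survival converges to the closed form at first order", {
  # constant force hold: P_0(t) = exp(-n u t)
  mod <- toy_model(omega0 = 0.9, n = 5)
  prot <- hold_protocol(0.5e-6, duration = 1)   # F = 0: u = omega0
  p_true <- exp(-5 * 0.9 * 1)
  err <- vapply(c(4e-3, 2e-3, 1e-3), function(dt) {
    sol <- solve_master(prot, mod, dt = dt, keep_states = "none")
    abs(sol$P[1, ncol(sol$P)] - p_true)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  ratio <- err[1] / err[2]
  expect_gt(ratio, 1.7); expect_lt(ratio, 2.3)   # O(dt) convergence
  # Richardson extrapolation removes the first-order error
  sol_x <- solve_master(prot, mod, dt = 2.5e-4, extrapolate = TRUE,
                        keep_states = "none")
  expect_equal(sol_x$P[1, ncol(sol_x$P)], p_true, tolerance = 1e-6)
})

test_that("frozen-force toy model matches the matrix-exponential oracle", {
  mod <- toy_model(omega0 = c(0.3, 0.8))
  l0 <- 1.05e-6                     # ~6.7 pN: rates O(1)
  prot <- hold_protocol(l0, duration = 1)
  # two Richardson levels (dt, dt/2, dt/4) remove the O(dt) and O(dt^2)
  # discretization error, leaving agreement at the oracle level
  s1 <- solve_master(prot, mod, dt = 2e-4, extrapolate = TRUE,
                     keep_states = "none")
  s2 <- solve_master(prot, mod, dt = 1e-4, extrapolate = TRUE,
                     keep_states = "none")
  sol <- s1
  sol$P <- (4 * s2$P[, seq(1, ncol(s2$P), by = 2)] - s1$P) / 3
  # oracle: dense exponential of an independently assembled generator
  cm <- mod$clusters
  S <- prod(cm$n + 1)
  imat <- as.matrix(expand.grid(i1 = 0:cm$n[1], i2 = 0:cm$n[2]))
  A <- matrix(0, S, S)
  for (s in seq_len(S)) {
    i <- imat[s, ]
    F <- force_at(mod$curves, sum(i), l0)
    for (k in 1:2) {
      if (i[k] < cm$n[k]) {
        tgt <- s + c(1, cm$n[1] + 1)[k]
        rate <- (cm$n[k] - i[k]) * unfold_rate(F, cm$omega0[k], cm$x_u[k])
        A[tgt, s] <- A[tgt, s] + rate
        A[s, s] <- A[s, s] - rate
      }
    }
  }
  p0 <- numeric(S); p0[1] <- 1
  pT <- as.numeric(Matrix::expm(Matrix::Matrix(A)) %*% p0)
  PT <- aggregate_states(pT, cm)
  last <- sol$P[, ncol(sol$P)]
  sel <- PT > 5e-3                  # states carrying non-negligible mass
  expect_lt(max(abs(last[sel] - PT[sel]) / PT[sel]), 1e-6)
})

test_that("P_0 and P_1 match direct quadrature of the survival integrals", {
  mod <- toy_model(omega0 = c(0.2, 0.5))
  prot <- make_ramp(1e-6, 1.15e-6, 1e-6)
  dt <- 1e-4
  sol <- solve_master(prot, mod, dt = dt, extrapolate = TRUE,
                      keep_states = "none")
  cm <- mod$clusters
  tt <- sol$times
  Fl <- vapply(0:1, function(i) force_at(mod$curves, i, sol$lengths),
               numeric(length(tt)))
  u <- function(k, F) unfold_rate(F, cm$omega0[k], cm$x_u[k])
  # P_0(t) = exp(-sum_k n_k int u_k(F_0))
  h0 <- cm$n[1] * u(1, Fl[, 1]) + cm$n[2] * u(2, Fl[, 1])
  cum0 <- c(0, cumsum(0.5 * (h0[-1] + h0[-length(h0)]) * diff(tt)))
  P0q <- exp(-cum0)
  sel <- P0q > 1e-3
  expect_lt(max(abs(sol$P[1, sel] - P0q[sel]) / P0q[sel]), 1e-6)
  # P_1(t): one event in cluster l at time tau, survival before and after:
  # P_1 = sum_l int_0^t P_0(tau) n_l u_l(F_0(tau))
  #         exp(-sum_i (n_i - delta_il) int_tau^t u_i(F_1)) dtau
  nt <- length(tt)
  h1 <- cm$n[1] * u(1, Fl[, 2]) + cm$n[2] * u(2, Fl[, 2])
  cum1 <- c(0, cumsum(0.5 * (h1[-1] + h1[-length(h1)]) * diff(tt)))
  cumu <- lapply(1:2, function(l) {
    ul <- u(l, Fl[, 2])
    c(0, cumsum(0.5 * (ul[-1] + ul[-length(ul)]) * diff(tt)))
  })
  selj <- seq(41, nt, by = 40)
  P1q <- vapply(selj, function(j) {
    a <- seq_len(j)
    integrand <- numeric(j)
    for (l in 1:2) {
      surv <- exp(-(cum1[j] - cum1[a]) + (cumu[[l]][j] - cumu[[l]][a]))
      integrand <- integrand + P0q[a] * cm$n[l] * u(l, Fl[a, 1]) * surv
    }
    sum(0.5 * (integrand[-1] + integrand[-j]) * diff(tt[a]))
  }, numeric(1))
  sel1 <- P1q > 1e-3
  expect_lt(max(abs(sol$P[2, selj][sel1] - P1q[sel1]) / P1q[sel1]), 1e-4)
})

test_that("exact aggregated probabilities match MC histograms (TV)", {
  mod <- toy_model(omega0 = 0.8, n = 5)
  prot <- make_ramp(1e-6, 1.35e-6, 1e-6)
  sol <- solve_master(prot, mod, dt = 1e-3, keep_states = "none")
  R <- 2000
  ens <- suppressWarnings(simulate_ensemble(prot, R, mod, dt = 1e-3,
                                            seed = 17, keep_events = FALSE))
  emp <- ens$state_counts[, ncol(ens$state_counts)] / R
  expect_lt(tv_dist(emp, sol$P[, ncol(sol$P)]), 0.1)
})

test_that("refolding master equation: pure decay and binomial equilibrium", {
  n <- 5
  mod <- toy_model(omega0 = 0, n = n,
                   refolding = list(omega1 = 0.6, x_f = 2.2e-9))
  prot <- hold_protocol(0.5e-6, duration = 1)    # F = 0: r = omega1
  init <- numeric(n + 1); init[n + 1] <- 1       # all unfolded
  sol <- solve_master_refolding(prot, mod, dt = 2.5e-4, init = init)
  # staying fully unfolded decays at rate n * r
  expect_equal(sol$P[n + 1, ncol(sol$P)], exp(-n * 0.6 * 1), tolerance = 2e-3)
  # balanced rates: stationary distribution is Binomial(n, u/(u+r))
  mod2 <- toy_model(omega0 = 1.5, n = n,
                    refolding = list(omega1 = 0.5, x_f = 2.2e-9))
  sol2 <- solve_master_refolding(hold_protocol(0.5e-6, duration = 30),
                                 mod2, dt = 2e-3)
  expect_equal(sol2$P[, ncol(sol2$P)], dbinom(0:n, n, 1.5 / 2),
               tolerance = 1e-4)
})

test_that("first-unfolding density integrates to the event mass and matches MC", {
  mod <- toy_model(omega0 = c(0.3, 0.8))
  prot <- make_ramp(1e-6, 1.6e-6, 1e-6)
  d <- first_unfolding_distribution(mod, prot, dt = 1e-4)
  expect_identical(attr(d, "mode"), "force")
  mass <- 1 - attr(d, "no_event_mass")
  # trapezoid integral of the force density
  igr <- sum(0.5 * (d$density_force[-1] + d$density_force[-nrow(d)]) *
               diff(d$force))
  expect_equal(igr, mass, tolerance = 1e-3)
  expect_equal(max(d$cdf), mass, tolerance = 1e-12)
  # Kolmogorov-Smirnov agreement with the Monte Carlo sample
  R <- 1500
  ens <- suppressWarnings(simulate_ensemble(prot, R, mod, dt = 1e-3,
                                            seed = 23))
  ff <- first_unfolding_forces(ens)
  cdf_fun <- stats::approxfun(d$force, d$cdf / mass, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(ff, cdf_fun))
  expect_gt(ks$p.value, 0.01)
  # zero rates: all mass on "no event"
  d0 <- first_unfolding_distribution(toy_model(omega0 = c(0, 0)), prot)
  expect_equal(attr(d0, "no_event_mass"), 1)
})
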