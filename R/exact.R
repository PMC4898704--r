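# Exact unfolding-state probabilities under a length protocol: the linear
# master equation on the cluster-occupancy state space, solved by implicit
# Euler. Without refolding the state graph is acyclic (unfolded counts only
# grow), so each implicit step is a forward substitution level-by-level in
# the total number of unfolded domains -- no matrix factorization needed.
# With refolding the (small) generator is assembled densely per step.

# ---- state space ---------------------------------------------------------

# Lexicographic enumeration of occupancy states (i_1, ..., i_m),
# 0 <= i_k <= n_k, with i_1 varying fastest. State 1 is all-folded.
.state_space <- function(cm) {
  sizes <- cm$n + 1L
  S <- prod(sizes)
  imat <- matrix(0L, nrow = S, ncol = cm$m)
  rep_each <- 1L
  for (k in seq_len(cm$m)) {
    imat[, k] <- rep(rep(0:cm$n[k], each = rep_each), length.out = S)
    rep_each <- rep_each * sizes[k]
  }
  level <- as.integer(rowSums(imat))
  strides <- c(1L, cumprod(sizes))[seq_len(cm$m)]
  list(imat = imat, level = level, strides = strides, S = S,
       by_level = split(seq_len(S), level))
}

# Unfolding transitions grouped by target level and cluster. For level l and
# cluster k: targ (global state index at level l with i_k > 0), its
# predecessor src = targ - stride_k (level l - 1), and the rate coefficient
# (n_k - i_k + 1) of the inflow (equivalently (n_k - i_k') of the source's
# outflow in cluster k).
.unfold_transitions <- function(cm, ss) {
  N <- sum(cm$n)
  out <- vector("list", N)
  tr_k <- vector("list", cm$m)
  for (k in seq_len(cm$m)) {
    sel <- which(ss$imat[, k] > 0L)
    tr_k[[k]] <- list(targ = sel, src = sel - ss$strides[k],
                      coef = as.numeric(cm$n[k] - ss$imat[sel, k] + 1L),
                      lv = ss$level[sel])
  }
  for (l in seq_len(N)) {
    out[[l]] <- lapply(seq_len(cm$m), function(k) {
      keep <- tr_k[[k]]$lv == l
      list(targ = tr_k[[k]]$targ[keep], src = tr_k[[k]]$src[keep],
           coef = tr_k[[k]]$coef[keep])
    })
  }
  out
}

# (N+1) x m matrix of cluster unfolding rates at the per-level forces Fvec
# (Fvec[l+1] = F_l). Row l+1, column k: u_k(F_l).
.rate_matrix <- function(Fvec, cm, temperature) {
  kT <- .kB * temperature
  vapply(seq_len(cm$m),
         function(k) cm$omega0[k] * exp(pmin(Fvec * cm$x_u[k] / kT, 700)),
         numeric(length(Fvec)))
}

# ---- generator (right-hand side) ----------------------------------------

#' Master-equation right-hand side
#'
#' Time derivative of the occupancy-state probabilities: for each state,
#' outflow `-sum_k (n_k - i_k) u_k(F_L(t)) p` (`L` = total unfolded) and
#' inflow `(n_k - i_k + 1) u_k(F_{L-1}(t)) p_pred` from each predecessor
#' state with one fewer domain unfolded in cluster `k`; exhausted clusters
#' and empty clusters contribute nothing (boundary guards). When refolding
#' is enabled the reverse flows `i_k r(F)` are added.
#'
#' @param p probability vector over the occupancy states (lexicographic
#'   enumeration, `i_1` fastest; state 1 = all folded).
#' @param t time \[s\].
#' @param model a [titin_model()].
#' @param protocol a [length_protocol()].
#' @return `dp/dt`, same length as `p`.
#' @export
master_rhs <- function(p, t, model, protocol) {
  cm <- model$clusters
  ss <- .state_space(cm)
  if (length(p) != ss$S) stop("'p' must have one entry per occupancy state",
                              call. = FALSE)
  A <- generator_matrix(model, protocol_length(protocol, t))
  as.numeric(A %*% p)
}

#' Dense generator matrix at a given half-sarcomere length
#'
#' Assembles the master-equation generator `A` (so that `dp/dt = A p`) at a
#' fixed length: unfolding flows `(n_k - i_k) u_k(F_L)` and, when refolding
#' is enabled, refolding flows `i_k r(F_L)`. Column sums are zero
#' (probability conservation). Intended for small state spaces (tests,
#' refolding solver); the ramp solver never forms it.
#'
#' @param model a [titin_model()].
#' @param l half-sarcomere length \[m\].
#' @param max_states guard on the state-space size.
#' @return A dense `S x S` matrix.
#' @export
generator_matrix <- function(model, l, max_states = 20000) {
  cm <- model$clusters
  ss <- .state_space(cm)
  if (ss$S > max_states)
    stop(sprintf("state space too large for a dense generator (%d states)",
                 ss$S), call. = FALSE)
  N <- sum(cm$n)
  Fvec <- vapply(0:N, function(i) force_at(model$curves, i, l), numeric(1))
  U <- .rate_matrix(Fvec, cm, model$params$temperature)
  A <- matrix(0, ss$S, ss$S)
  for (k in seq_len(cm$m)) {
    from <- which(ss$imat[, k] < cm$n[k])
    to <- from + ss$strides[k]
    rate <- (cm$n[k] - ss$imat[from, k]) * U[cbind(ss$level[from] + 1L, k)]
    A[cbind(to, from)] <- A[cbind(to, from)] + rate
    A[cbind(from, from)] <- A[cbind(from, from)] - rate
  }
  if (!is.null(cm$refolding)) {
    rF <- refold_rate(Fvec, cm$refolding$omega1, cm$refolding$x_f,
                      model$params$temperature)
    for (k in seq_len(cm$m)) {
      from <- which(ss$imat[, k] > 0L)
      to <- from - ss$strides[k]
      rate <- ss$imat[from, k] * rF[ss$level[from] + 1L]
      A[cbind(to, from)] <- A[cbind(to, from)] + rate
      A[cbind(from, from)] <- A[cbind(from, from)] - rate
    }
  }
  A
}

# ---- implicit Euler solvers ---------------------------------------------

.solve_master_core <- function(protocol, model, dt, keep_states) {
  cm <- model$clusters
  ss <- .state_space(cm)
  trans <- .unfold_transitions(cm, ss)
  N <- sum(cm$n)
  times <- .time_grid(protocol, dt)
  nt <- length(times)
  Fmat <- .force_time_matrix(model$curves, protocol, times)
  temperature <- model$params$temperature

  outcoef <- matrix(0, nrow = ss$S, ncol = cm$m)
  for (k in seq_len(cm$m)) outcoef[, k] <- cm$n[k] - ss$imat[, k]
  lvl1 <- ss$level + 1L

  P <- matrix(0, nrow = N + 1L, ncol = nt)
  store_all <- switch(keep_states, all = TRUE, none = FALSE,
                      auto = ss$S * nt <= 2e6)
  states <- if (store_all) matrix(0, nrow = ss$S, ncol = nt) else NULL

  p <- numeric(ss$S); p[1L] <- 1
  P[1L, 1L] <- 1
  if (store_all) states[, 1L] <- p
  n_renorm <- 0L

  for (j in 2:nt) {
    dtj <- times[j] - times[j - 1L]
    U <- .rate_matrix(Fmat[, j], cm, temperature)   # fully implicit: t_j
    out <- numeric(ss$S)
    for (k in seq_len(cm$m)) out <- out + outcoef[, k] * U[lvl1, k]
    den <- 1 + dtj * out
    w <- p
    pnew <- numeric(ss$S)
    i0 <- ss$by_level[["0"]]
    pnew[i0] <- w[i0] / den[i0]
    for (l in seq_len(N)) {
      for (k in seq_len(cm$m)) {
        tr <- trans[[l]][[k]]
        if (length(tr$targ))
          w[tr$targ] <- w[tr$targ] + dtj * U[l, k] * tr$coef * pnew[tr$src]
      }
      il <- ss$by_level[[as.character(l)]]
      pnew[il] <- w[il] / den[il]
    }
    if (min(pnew) < -1e-10)
      stop("negative probability beyond tolerance; reduce dt", call. = FALSE)
    s1 <- sum(pnew)
    if (abs(s1 - 1) > 1e-12) { pnew <- pnew / s1; n_renorm <- n_renorm + 1L }
    p <- pnew
    for (l in 0:N) P[l + 1L, j] <- sum(p[ss$by_level[[as.character(l)]]])
    if (store_all) states[, j] <- p
  }

  list(times = times, lengths = protocol_length(protocol, times), P = P,
       Fmat = Fmat, states = states, final_state = p, n_renorm = n_renorm,
       state_space = ss, dt = dt)
}

#' Solve the unfolding master equation under a length protocol
#'
#' Computes the exact (up to time discretization) probabilities of all
#' cluster-occupancy states over time for a strand starting fully folded,
#' by implicit Euler steps `(I - dt A(t_{j+1})) p_{j+1} = p_j` on the
#' linear master equation. Because unfolded counts only grow without
#' refolding, the implicit system is triangular in the total-unfolded
#' ordering and each step is solved exactly by forward substitution --
#' the full `prod(n_k + 1)` state space (161051 states for 5 clusters of
#' 10) is handled without forming a matrix.
#'
#' Probability is conserved exactly by the scheme up to round-off;
#' renormalization is applied (and counted) only if drift exceeds 1e-12.
#' With `extrapolate = TRUE` the first-order time-discretization error is
#' removed by Richardson extrapolation from step sizes `dt` and `dt/2`,
#' giving a second-order continuum-limit estimate of the probabilities.
#'
#' @param protocol a [length_protocol()].
#' @param model a [titin_model()] (refolding must be off; see
#'   [solve_master_refolding()]).
#' @param dt implicit Euler step \[s\].
#' @param keep_states `"auto"` (retain the full state trajectory when it
#'   fits in ~2e6 numbers), `"all"`, or `"none"`. The final state and the
#'   aggregated probabilities are always retained.
#' @param extrapolate logical; Richardson-extrapolate over `dt` halving.
#' @return An object of class `"master_solution"`: `times`, `lengths`,
#'   `P` (`(N+1) x` times matrix of aggregated probabilities `P_0..P_N`),
#'   `expected_force` \[N\], `states` (optional full trajectory),
#'   `final_state`, `n_renorm`, `dt`.
#' @examples
#' \donttest{
#' mod <- titin_model(clusters = cluster_model(n = 50, omega0 = 1e-4),
#'                    length_grid = seq(1e-6, 2e-6, by = 1e-8))
#' sol <- solve_master(make_ramp(1e-6, 2e-6, 1e-6), mod, dt = 5e-3)
#' max(sol$expected_force) * 1e12
#' }
#' @export
solve_master <- function(protocol, model, dt = 1e-3,
                         keep_states = c("auto", "all", "none"),
                         extrapolate = FALSE) {
  stopifnot(inherits(protocol, "length_protocol"), inherits(model, "titin_model"))
  keep_states <- match.arg(keep_states)
  .check_pos(dt, "dt")
  if (!is.null(model$clusters$refolding))
    stop("refolding is enabled in the cluster model; use solve_master_refolding()",
         call. = FALSE)
  res <- .solve_master_core(protocol, model, dt, keep_states)
  if (extrapolate) {
    res_h <- .solve_master_core(protocol, model, dt / 2, "none")
    idx <- seq(1L, length(res_h$times), by = 2L)
    stopifnot(length(idx) == length(res$times))
    res$P <- 2 * res_h$P[, idx, drop = FALSE] - res$P
    res$final_state <- 2 * res_h$final_state - res$final_state
    res$extrapolated <- TRUE
  }
  res$expected_force <- colSums(res$P * res$Fmat)
  res$Fmat <- NULL
  class(res) <- "master_solution"
  res
}

#' @export
print.master_solution <- function(x, ...) {
  cat(sprintf("Master-equation solution: %d aggregated states, %d time points, dt = %.3g s\n",
              nrow(x$P), length(x$times), x$dt))
  cat(sprintf("  E(F) range [%.3g, %.3g] pN; renormalizations: %d\n",
              min(x$expected_force) * 1e12, max(x$expected_force) * 1e12,
              x$n_renorm))
  invisible(x)
}

#' Aggregate occupancy-state probabilities by total unfolded count
#'
#' Sums the probabilities of all occupancy states `(i_1, ..., i_m)` with
#' `i_1 + ... + i_m = l`, giving `P_l` for `l = 0..N`. For one cluster the
#' aggregation is the identity reindexing.
#'
#' @param p probability vector over states (lexicographic enumeration) or a
#'   matrix with one column per time point.
#' @param cm the [cluster_model()] defining the state space.
#' @return A vector (or matrix) of `P_0..P_N`.
#' @export
aggregate_states <- function(p, cm) {
  stopifnot(inherits(cm, "cluster_model"))
  ss <- .state_space(cm)
  N <- sum(cm$n)
  if (is.matrix(p)) {
    stopifnot(nrow(p) == ss$S)
    out <- matrix(0, N + 1L, ncol(p))
    for (l in 0:N)
      out[l + 1L, ] <- colSums(p[ss$by_level[[as.character(l)]], , drop = FALSE])
    out
  } else {
    stopifnot(length(p) == ss$S)
    vapply(0:N, function(l) sum(p[ss$by_level[[as.character(l)]]]), numeric(1))
  }
}

#' Expected strand force from aggregated probabilities
#'
#' `E(F(t)) = sum_l P_l(t) * F_l(l(t))`: the expectation of the strand
#' force over the unfolding states, optionally scaled to a half-sarcomere
#' force by the number of parallel titin strands.
#'
#' @param P `(N+1) x` times matrix of aggregated probabilities (or a
#'   `"master_solution"`, whose grids are used).
#' @param model a [titin_model()] supplying the force curves.
#' @param protocol a [length_protocol()].
#' @param times evaluation times \[s\] (required when `P` is a matrix).
#' @param n_strands optional number of parallel strands to scale by.
#' @return Expected force \[N\] per strand (times `n_strands` if given).
#' @export
expected_force <- function(P, model, protocol, times = NULL, n_strands = NULL) {
  stopifnot(inherits(model, "titin_model"))
  if (inherits(P, "master_solution")) {
    times <- P$times
    P <- P$P
  }
  if (is.null(times)) stop("'times' required", call. = FALSE)
  if (ncol(P) != length(times))
    stop("'P' columns and 'times' lengths differ", call. = FALSE)
  N <- sum(model$clusters$n)
  if (nrow(P) != N + 1L)
    stop("'P' must have N + 1 rows", call. = FALSE)
  Fmat <- .force_time_matrix(model$curves, protocol, times)
  out <- colSums(P * Fmat)
  if (!is.null(n_strands)) out <- out * n_strands
  out
}

#' Solve the master equation with refolding
#'
#' Implicit Euler on the full generator including refolding flows
#' `i_k r(F)`, supporting stretch-shortening-rest protocols. The state
#' graph is no longer acyclic, so each step solves a dense linear system;
#' this is intended for modest state spaces (e.g. the single-cluster model,
#' 51 states). For one cluster the generator is tridiagonal: unfolding
#' moves one step up in the unfolded count, refolding one step down. Large
#' multi-cluster state spaces with refolding are refused: Monte Carlo
#' simulation is the appropriate tool there.
#'
#' @inheritParams solve_master
#' @param model a [titin_model()] whose cluster model has `refolding` set.
#' @param max_states refuse state spaces larger than this.
#' @param init initial occupancy-state probabilities: `NULL` (all folded,
#'   the standard experimental initial condition) or a probability vector
#'   over the lexicographic state enumeration (e.g. to start fully
#'   unfolded when studying pure refolding).
#' @return A `"master_solution"` (see [solve_master()]).
#' @export
solve_master_refolding <- function(protocol, model, dt = 1e-3,
                                   keep_states = c("auto", "all", "none"),
                                   max_states = 4000, init = NULL) {
  stopifnot(inherits(protocol, "length_protocol"), inherits(model, "titin_model"))
  keep_states <- match.arg(keep_states)
  .check_pos(dt, "dt")
  cm <- model$clusters
  if (is.null(cm$refolding))
    stop("cluster model has no refolding parameters", call. = FALSE)
  ss <- .state_space(cm)
  if (ss$S > max_states)
    stop(sprintf("state space with refolding too large (%d states); use Monte Carlo",
                 ss$S), call. = FALSE)
  N <- sum(cm$n)
  times <- .time_grid(protocol, dt)
  nt <- length(times)
  Fmat <- .force_time_matrix(model$curves, protocol, times)
  temperature <- model$params$temperature

  # precomputed transition index sets
  unf <- lapply(seq_len(cm$m), function(k) {
    from <- which(ss$imat[, k] < cm$n[k])
    list(from = from, to = from + ss$strides[k],
         coef = as.numeric(cm$n[k] - ss$imat[from, k]), lv = ss$level[from] + 1L)
  })
  ref <- lapply(seq_len(cm$m), function(k) {
    from <- which(ss$imat[, k] > 0L)
    list(from = from, to = from - ss$strides[k],
         coef = as.numeric(ss$imat[from, k]), lv = ss$level[from] + 1L)
  })

  P <- matrix(0, nrow = N + 1L, ncol = nt)
  store_all <- switch(keep_states, all = TRUE, none = FALSE,
                      auto = ss$S * nt <= 2e6)
  states <- if (store_all) matrix(0, nrow = ss$S, ncol = nt) else NULL
  if (is.null(init)) {
    p <- numeric(ss$S); p[1L] <- 1
  } else {
    if (length(init) != ss$S || any(init < 0) || abs(sum(init) - 1) > 1e-9)
      stop("'init' must be a probability vector over the state space",
           call. = FALSE)
    p <- as.numeric(init)
  }
  for (l in 0:N) P[l + 1L, 1L] <- sum(p[ss$by_level[[as.character(l)]]])
  if (store_all) states[, 1L] <- p
  n_renorm <- 0L
  M <- matrix(0, ss$S, ss$S)
  for (j in 2:nt) {
    dtj <- times[j] - times[j - 1L]
    Fvec <- Fmat[, j]
    U <- .rate_matrix(Fvec, cm, temperature)
    rF <- refold_rate(Fvec, cm$refolding$omega1, cm$refolding$x_f, temperature)
    M[] <- 0
    diagout <- numeric(ss$S)
    for (k in seq_len(cm$m)) {
      tr <- unf[[k]]
      rate <- tr$coef * U[tr$lv, k]
      M[cbind(tr$to, tr$from)] <- M[cbind(tr$to, tr$from)] - dtj * rate
      diagout[tr$from] <- diagout[tr$from] + rate
      tr <- ref[[k]]
      rate <- tr$coef * rF[tr$lv]
      M[cbind(tr$to, tr$from)] <- M[cbind(tr$to, tr$from)] - dtj * rate
      diagout[tr$from] <- diagout[tr$from] + rate
    }
    diag(M) <- 1 + dtj * diagout
    pnew <- solve(M, p)
    if (min(pnew) < -1e-10)
      stop("negative probability beyond tolerance; reduce dt", call. = FALSE)
    s1 <- sum(pnew)
    if (abs(s1 - 1) > 1e-12) { pnew <- pnew / s1; n_renorm <- n_renorm + 1L }
    p <- pnew
    for (l in 0:N) P[l + 1L, j] <- sum(p[ss$by_level[[as.character(l)]]])
    if (store_all) states[, j] <- p
  }

  res <- list(times = times, lengths = protocol_length(protocol, times),
              P = P, states = states, final_state = p, n_renorm = n_renorm,
              state_space = ss, dt = dt,
              expected_force = colSums(P * Fmat))
  class(res) <- "master_solution"
  res
}

#' Exact distribution of the force at the first unfolding event
#'
#' The first unfolding happens at hazard
#' `h(t) = sum_k n_k u_k(F_0(l(t)))` while the survival probability is
#' `P_0(t) = exp(-int_0^t h)` (all domains still folded). The time density
#' of the first event, `h(t) P_0(t)`, is mapped through the monotone
#' all-folded force `F_0(l(t))` to a density over force; the probability
#' that no event occurs within the protocol is reported separately. If
#' `F_0` is not strictly monotone over the protocol the density is
#' returned over time only.
#'
#' @param model a [titin_model()] (refolding ignored: the first event is an
#'   unfolding from the all-folded state either way).
#' @param protocol a [length_protocol()].
#' @param dt quadrature step \[s\].
#' @return A data.frame with columns `time` \[s\], `force` \[N\] (`NA` in
#'   the time-domain fallback), `density_force` \[1/N\], `density_time`
#'   \[1/s\], `cdf` (probability of a first event up to `time`), plus
#'   attributes `"no_event_mass"` (`P_0` at protocol end) and `"mode"`
#'   (`"force"` or `"time"`).
#' @export
first_unfolding_distribution <- function(model, protocol, dt = 1e-4) {
  stopifnot(inherits(protocol, "length_protocol"), inherits(model, "titin_model"))
  cm <- model$clusters
  times <- .time_grid(protocol, dt)
  l_t <- protocol_length(protocol, times)
  F0 <- stats::approx(model$curves$length_grid, model$curves$forces[1L, ],
                      xout = l_t, rule = 2)$y
  U <- .rate_matrix(F0, cm, model$params$temperature)
  h <- as.numeric(U %*% cm$n)
  cumh <- c(0, cumsum(0.5 * (h[-1] + h[-length(h)]) * diff(times)))
  P0 <- exp(-cumh)
  dens_t <- h * P0
  cdf <- 1 - P0
  dF <- diff(F0)
  mode <- if (all(dF > 0)) "force" else "time"
  if (mode == "force") {
    # dF0/dt by central differences
    dFdt <- c(dF[1] / diff(times)[1],
              (F0[-(1:2)] - F0[1:(length(F0) - 2)]) /
                (times[-(1:2)] - times[1:(length(times) - 2)]),
              dF[length(dF)] / diff(times)[length(dF)])
    dens_f <- dens_t / dFdt
  } else {
    dens_f <- rep(NA_real_, length(times))
  }
  out <- data.frame(time = times,
                    force = if (mode == "force") F0 else NA_real_,
                    density_force = dens_f, density_time = dens_t, cdf = cdf)
  attr(out, "no_event_mass") <- P0[length(P0)]
  attr(out, "mode") <- mode
  out
}
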