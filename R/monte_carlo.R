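# Fixed-step Monte Carlo simulation of titin strand ensembles under a
# length protocol: one uniform draw per strand per step, cumulative
# per-cluster event intervals, at most one event per step.

# Internal time grid of a protocol at step dt (always ends exactly at T).
.time_grid <- function(protocol, dt) {
  T <- protocol_duration(protocol)
  n <- ceiling(T / dt - 1e-9)
  t <- seq(0, by = dt, length.out = n + 1L)
  t[n + 1L] <- T
  t
}

#' Advance one Monte Carlo step
#'
#' One step of the fixed-step event scheme for a single strand: a uniform
#' draw `z` is compared against the cumulative intervals of the per-cluster
#' unfolding probabilities `(n_k - i_k) * u_k(F) * dt` (and refolding
#' probabilities `i_k * r(F) * dt` when refolding is enabled); at most one
#' event fires per step. Exposed mainly for inspection and testing;
#' [simulate_ensemble()] runs the vectorized equivalent.
#'
#' @param state integer vector of per-cluster unfolded counts.
#' @param F force acting during the step \[N\].
#' @param dt time step \[s\].
#' @param cm a [cluster_model()].
#' @param z uniform random number in \[0, 1\] (drawn from the session RNG if
#'   missing).
#' @param temperature \[K\].
#' @param max_event_prob guard on the total event probability of the step:
#'   beyond it the single-event scheme is invalid.
#' @param on_overrun `"error"`, `"warn"` or `"ignore"` when the guard is
#'   exceeded.
#' @return The updated state, with attribute `"event"` (`0` = none, `k` =
#'   unfolding in cluster `k`, `-k` = refolding in cluster `k`).
#' @export
mc_step <- function(state, F, dt, cm, z = stats::runif(1), temperature = 300,
                    max_event_prob = 1, on_overrun = "error") {
  haz <- total_hazard(state, F, cm, temperature)
  p <- c(haz$unfold, haz$refold) * dt
  ptot <- sum(p)
  if (ptot > max_event_prob) {
    msg <- sprintf("total event probability %.3g exceeds %.3g; reduce dt",
                   ptot, max_event_prob)
    if (on_overrun == "error") stop(msg, call. = FALSE)
    if (on_overrun == "warn") warning(msg, call. = FALSE)
  }
  cum <- cumsum(p)
  ev <- 0L
  hit <- which(z <= cum)
  if (length(hit)) {
    j <- hit[1L]
    if (j <= cm$m) { state[j] <- state[j] + 1L; ev <- j }
    else { k <- j - cm$m; state[k] <- state[k] - 1L; ev <- -k }
  }
  attr(state, "event") <- ev
  state
}

#' Simulate an ensemble of titin strands
#'
#' Simulates `R` independent titin strands under a length protocol with the
#' fixed-step single-event scheme, all strands starting fully folded. Event
#' probabilities use the force at the start of the step when refolding is
#' off and at the end of the step when refolding is on (following the
#' respective update rules; `rate_timing` overrides this). The ensemble
#' mean force approximates the expected half-sarcomere force per strand;
#' compare [expected_force()] for the exact value.
#'
#' Steps whose total event probability exceeds `max_event_prob` (default 1,
#' the validity bound of the one-draw scheme) are counted and reported via
#' `on_overrun`; near forced unfolding cascades in the steep WLC regime
#' occasional saturated steps are expected and benign for ensemble means
#' (see the methods vignette).
#'
#' @param protocol a [length_protocol()].
#' @param R number of strands (>= 1).
#' @param model a [titin_model()].
#' @param dt time step \[s\].
#' @param seed integer seed; the whole result is reproducible given it.
#' @param rate_timing `"as_printed"` (start-of-step force without
#'   refolding, end-of-step with), `"start"`, or `"end"`.
#' @param max_event_prob guard on the per-step total event probability.
#' @param on_overrun `"warn"` (default), `"error"` or `"ignore"`.
#' @param keep_traces retain the per-strand unfolded-count traces
#'   (`R x` times matrix).
#' @param keep_events retain the event log.
#' @return An object of class `"ensemble_result"`: list with `times`,
#'   `lengths` \[m\], `mean_force` \[N\], `state_counts` (`(N+1) x` times
#'   matrix of strand counts per total-unfolded state), `first_unfold`
#'   (data.frame: strand, time, force \[N\], cluster; `NA` rows for strands
#'   without an unfolding event), `events` (data.frame, if kept), `traces`
#'   (if kept), `overrun_steps`, `R`, `seed`, `dt`.
#' @examples
#' \donttest{
#' mod <- titin_model(length_grid = seq(1e-6, 2e-6, by = 1e-8))
#' ens <- simulate_ensemble(make_ramp(1e-6, 2e-6, 1e-6), R = 20, mod,
#'                          seed = 1)
#' max(ens$mean_force) * 1e12   # peak mean force in pN
#' }
#' @export
simulate_ensemble <- function(protocol, R, model, dt = 1e-3, seed = 1,
                              rate_timing = c("as_printed", "start", "end"),
                              max_event_prob = 1,
                              on_overrun = c("warn", "error", "ignore"),
                              keep_traces = FALSE, keep_events = TRUE) {
  stopifnot(inherits(protocol, "length_protocol"), inherits(model, "titin_model"))
  rate_timing <- match.arg(rate_timing)
  on_overrun <- match.arg(on_overrun)
  R <- .check_count(R, "R")
  .check_pos(dt, "dt")
  cm <- model$clusters
  m <- cm$m
  refold_on <- !is.null(cm$refolding)
  use_end <- switch(rate_timing, as_printed = refold_on,
                    start = FALSE, end = TRUE)
  kT <- .kB * model$params$temperature
  N <- model$iso$n_prox_ig

  times <- .time_grid(protocol, dt)
  nt <- length(times)
  Fmat <- .force_time_matrix(model$curves, protocol, times)

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  K <- matrix(0L, nrow = R, ncol = m)
  nf <- integer(R)
  force_sum <- numeric(nt)
  state_counts <- matrix(0L, nrow = N + 1L, ncol = nt)
  traces <- if (keep_traces) matrix(0L, nrow = R, ncol = nt) else NULL
  first_time <- rep(NA_real_, R); first_force <- rep(NA_real_, R)
  first_cluster <- rep(NA_integer_, R)
  ev_list <- if (keep_events) vector("list", nt) else NULL
  overrun <- 0L

  f0 <- Fmat[1L, 1L]
  force_sum[1L] <- R * f0
  state_counts[1L, 1L] <- R
  if (keep_traces) traces[, 1L] <- 0L

  strands <- seq_len(R)
  for (j in 2:nt) {
    dtj <- times[j] - times[j - 1L]
    jF <- if (use_end) j else j - 1L
    Fs <- Fmat[cbind(nf + 1L, rep.int(jF, R))]
    # cumulative event-probability matrix: m unfolding (+ m refolding) cols
    ncol_ev <- if (refold_on) 2L * m else m
    C <- matrix(0, nrow = R, ncol = ncol_ev)
    acc <- numeric(R)
    for (k in seq_len(m)) {
      u <- cm$omega0[k] * exp(pmin(Fs * cm$x_u[k] / kT, 700))
      acc <- acc + (cm$n[k] - K[, k]) * u * dtj
      C[, k] <- acc
    }
    if (refold_on) {
      r <- cm$refolding$omega1 * exp(-Fs * cm$refolding$x_f / kT)
      for (k in seq_len(m)) {
        acc <- acc + K[, k] * r * dtj
        C[, m + k] <- acc
      }
    }
    if (any(acc > max_event_prob)) {
      overrun <- overrun + 1L
      if (on_overrun == "error")
        stop(sprintf("step %d: total event probability %.3g exceeds %.3g; reduce dt",
                     j - 1L, max(acc), max_event_prob), call. = FALSE)
    }
    z <- stats::runif(R)
    cnt <- integer(R)
    for (cc in seq_len(ncol_ev)) cnt <- cnt + (C[, cc] < z)
    hit <- which(cnt < ncol_ev)
    if (length(hit)) {
      col <- cnt[hit] + 1L
      unf <- col <= m
      if (any(unf)) {
        s <- hit[unf]; k <- col[unf]
        K[cbind(s, k)] <- K[cbind(s, k)] + 1L
        nf[s] <- nf[s] + 1L
        mask <- is.na(first_time[s])
        if (any(mask)) {
          new1 <- s[mask]
          first_time[new1] <- times[j]
          first_force[new1] <- Fs[new1]
          first_cluster[new1] <- k[mask]
        }
      }
      if (any(!unf)) {
        s <- hit[!unf]; k <- col[!unf] - m
        K[cbind(s, k)] <- K[cbind(s, k)] - 1L
        nf[s] <- nf[s] - 1L
      }
      if (keep_events)
        ev_list[[j]] <- data.frame(time = times[j], strand = hit,
                                   cluster = ifelse(col <= m, col, col - m),
                                   type = ifelse(col <= m, "unfold", "refold"),
                                   force = Fs[hit])
    }
    Fnow <- Fmat[cbind(nf + 1L, rep.int(j, R))]
    force_sum[j] <- sum(Fnow)
    tab <- tabulate(nf + 1L, nbins = N + 1L)
    state_counts[, j] <- tab
    if (keep_traces) traces[, j] <- nf
  }

  if (overrun > 0L && on_overrun == "warn")
    warning(sprintf("%d of %d steps exceeded total event probability %.3g; consider a smaller dt",
                    overrun, nt - 1L, max_event_prob), call. = FALSE)

  res <- list(
    times = times,
    lengths = protocol_length(protocol, times),
    mean_force = force_sum / R,
    state_counts = state_counts,
    first_unfold = data.frame(strand = strands, time = first_time,
                              force = first_force, cluster = first_cluster),
    events = if (keep_events) do.call(rbind, ev_list[!vapply(ev_list, is.null, TRUE)]),
    traces = traces,
    overrun_steps = overrun,
    R = R, seed = seed, dt = dt
  )
  class(res) <- "ensemble_result"
  res
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Monte Carlo ensemble: R = %d strands, %d time points, seed %d\n",
              x$R, length(x$times), x$seed))
  cat(sprintf("  mean force range [%.3g, %.3g] pN; %d unfolding events logged\n",
              min(x$mean_force) * 1e12, max(x$mean_force) * 1e12,
              if (is.null(x$events)) NA_integer_
              else sum(x$events$type == "unfold")))
  invisible(x)
}

#' Monte Carlo error of the ensemble-mean force
#'
#' Repeats the `R`-strand ensemble `H` times and returns
#' `MCE(R) = sqrt( max_t ( <F_h(t)^2> - <F_h(t)>^2 ) )`: the sup-norm over
#' the protocol grid of the across-repeat variance of the ensemble-mean
#' force, square-rooted (population variance over the `H` repeats). It
#' scales as `1/sqrt(R)` by the central limit theorem.
#'
#' @param R strands per ensemble.
#' @param H number of independent repeats (>= 2).
#' @inheritParams simulate_ensemble
#' @param ... passed on to [simulate_ensemble()].
#' @return MCE \[N\], with attribute `"mean_forces"` (the `H x` times
#'   matrix) when `keep_matrix = TRUE`.
#' @param keep_matrix retain the matrix of repeat mean forces.
#' @export
mce <- function(R, H, protocol, model, dt = 1e-3, seed = 1,
                keep_matrix = FALSE, ...) {
  H <- .check_count(H, "H")
  if (H < 2L) stop("'H' must be >= 2", call. = FALSE)
  times <- .time_grid(protocol, dt)
  FM <- matrix(NA_real_, nrow = H, ncol = length(times))
  for (h in seq_len(H)) {
    ens <- simulate_ensemble(protocol, R, model, dt = dt,
                             seed = seed + 1009L * h,
                             keep_events = FALSE, ...)
    FM[h, ] <- ens$mean_force
  }
  v <- colMeans(FM^2) - colMeans(FM)^2
  out <- sqrt(max(v))
  if (keep_matrix) attr(out, "mean_forces") <- FM
  out
}

#' Forces at the first unfolding event
#'
#' Extracts, per strand, the force at which its first Ig domain unfolded.
#' Strands without any unfolding event are excluded and their number
#' reported.
#'
#' @param ensemble an [simulate_ensemble()] result.
#' @return Numeric vector of forces \[N\] with attribute `"n_excluded"`.
#' @seealso [freedman_diaconis_bins()] for histogram binning,
#'   [first_unfolding_distribution()] for the exact density.
#' @export
first_unfolding_forces <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  f <- ensemble$first_unfold$force
  out <- f[!is.na(f)]
  attr(out, "n_excluded") <- sum(is.na(f))
  out
}
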