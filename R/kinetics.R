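# Force-dependent unfolding / refolding kinetics (Bell model) and the
# cluster structure of Ig mechanical stability.

#' Bell-model unfolding rate
#'
#' Force-dependent rate of unfolding one Ig domain,
#' `u(F) = omega0 * exp(F * x_u / (kB * T))`: a thermally driven barrier
#' crossing whose barrier is lowered by the applied force. Strictly
#' increasing in `F`. The exponent is capped (default 700) to avoid
#' floating-point overflow; rates at the cap are far beyond any dynamically
#' distinguishable scale.
#'
#' @param F force \[N\] (vectorized), `F >= 0`.
#' @param omega0 spontaneous unfolding rate at zero force \[1/s\].
#' @param x_u width of the unfolding activation barrier \[m\].
#' @param temperature absolute temperature \[K\].
#' @param exp_cap maximum exponent before capping.
#' @return Rate \[1/s\].
#' @examples
#' unfold_rate(0, 1e-4, 0.25e-9)                     # omega0
#' @export
unfold_rate <- function(F, omega0, x_u, temperature = 300, exp_cap = 700) {
  if (any(!is.finite(F)) || any(F < 0)) stop("'F' must be >= 0", call. = FALSE)
  if (any(!is.finite(omega0)) || any(omega0 < 0))
    stop("'omega0' must be >= 0", call. = FALSE)
  omega0 * exp(pmin(F * x_u / (.kB * temperature), exp_cap))
}

#' Bell-model refolding rate
#'
#' Force-dependent rate of refolding one unfolded Ig domain,
#' `r(F) = omega1 * exp(-F * x_f / (kB * T))`: strictly decreasing in `F`,
#' equal to `omega1` at zero force, vanishing at large force.
#'
#' @param F force \[N\] (vectorized), `F >= 0`.
#' @param omega1 spontaneous refolding rate at zero force \[1/s\].
#' @param x_f width of the refolding activation barrier \[m\].
#' @param temperature absolute temperature \[K\].
#' @return Rate \[1/s\].
#' @export
refold_rate <- function(F, omega1, x_f, temperature = 300) {
  if (any(!is.finite(F)) || any(F < 0)) stop("'F' must be >= 0", call. = FALSE)
  if (any(!is.finite(omega1)) || any(omega1 < 0))
    stop("'omega1' must be >= 0", call. = FALSE)
  omega1 * exp(-F * x_f / (.kB * temperature))
}

#' Cluster model of Ig mechanical stability
#'
#' Partitions the `N` proximal Ig domains into `m` clusters, each with its
#' own spontaneous unfolding rate `omega0`, encoding hierarchical
#' mechanical stability (or, equivalently, heterogeneous domain stability).
#' Clusters are ordered by non-decreasing zero-force rate so that
#' `u_1(F) <= u_2(F) <= ... <= u_m(F)` at every force when the activation
#' barrier width is shared; the constructor sorts them if needed.
#'
#' The defaults partition the 50 rabbit-psoas proximal Ig domains into 5
#' clusters of 10 with `omega0` spaced geometrically from 1e-5 to 1e-3 1/s.
#' The zero-force rates are not experimentally pinned down; these values
#' produce unfolding within a 1 to 2 um ramp at 1 um/s and are fully
#' configurable (see the methods vignette).
#'
#' @param n integer vector: domains per cluster; must sum to the isoform's
#'   proximal Ig count when used in a model.
#' @param omega0 numeric vector, one spontaneous unfolding rate per cluster
#'   \[1/s\]. May alternatively vary `x_u` per cluster (vector recycled to
#'   `m`).
#' @param x_u unfolding activation-barrier width(s) \[m\].
#' @param refolding `NULL` (refolding off) or a list with `omega1` \[1/s\]
#'   and `x_f` \[m\].
#' @return An object of class `"cluster_model"`.
#' @examples
#' cluster_model()                                  # 5 x 10 default
#' cluster_model(n = 50, omega0 = 1e-4,
#'               refolding = list(omega1 = 1, x_f = 2.2e-9))
#' @export
cluster_model <- function(n = rep(10L, 5),
                          omega0 = 10^seq(-5, -3, length.out = 5),
                          x_u = 0.25e-9,
                          refolding = NULL) {
  if (length(n) != length(omega0))
    stop("'n' and 'omega0' must have one entry per cluster", call. = FALSE)
  if (any(n != round(n)) || any(n <= 0))
    stop("cluster sizes must be positive integers", call. = FALSE)
  if (any(!is.finite(omega0)) || any(omega0 < 0))
    stop("'omega0' must be non-negative", call. = FALSE)
  m <- length(n)
  x_u <- rep_len(x_u, m)
  if (any(x_u <= 0)) stop("'x_u' must be > 0", call. = FALSE)
  # order so that u_1(F) <= ... <= u_m(F); with shared x_u this is omega0
  # non-decreasing (with distinct x_u, order by rate at zero force).
  ord <- order(omega0, x_u)
  cm <- list(n = as.integer(n[ord]), omega0 = omega0[ord], x_u = x_u[ord],
             m = m, refolding = NULL)
  if (!is.null(refolding)) {
    if (!is.list(refolding) || is.null(refolding$omega1) || is.null(refolding$x_f))
      stop("'refolding' must be a list(omega1 =, x_f =)", call. = FALSE)
    .check_pos(refolding$omega1, "omega1", strict = FALSE)
    .check_pos(refolding$x_f, "x_f")
    cm$refolding <- list(omega1 = refolding$omega1, x_f = refolding$x_f)
  }
  class(cm) <- "cluster_model"
  cm
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Ig cluster model: %d cluster(s), %d domains total\n",
              x$m, sum(x$n)))
  for (k in seq_len(x$m))
    cat(sprintf("  cluster %d: n = %2d, omega0 = %.3g 1/s, x_u = %.3g m\n",
                k, x$n[k], x$omega0[k], x$x_u[k]))
  if (is.null(x$refolding)) cat("  refolding: off\n")
  else cat(sprintf("  refolding: omega1 = %.3g 1/s, x_f = %.3g m\n",
                   x$refolding$omega1, x$refolding$x_f))
  invisible(x)
}

# Per-cluster unfolding rates u_k(F) for scalar F (returns length-m vector)
.cluster_rates <- function(F, cm, temperature) {
  cm$omega0 * exp(pmin(F * cm$x_u / (.kB * temperature), 700))
}

#' Per-cluster event hazards of a strand state
#'
#' Effective event rates of a strand with per-cluster unfolded counts
#' `state`: unfolding hazard `(n_k - i_k) * u_k(F)` for each cluster (zero
#' once a cluster is exhausted) and, when refolding is enabled,
#' refolding hazard `i_k * r(F)`.
#'
#' @param state integer vector of unfolded counts per cluster,
#'   `0 <= state <= n`.
#' @param F force \[N\], scalar.
#' @param cm a [cluster_model()].
#' @param temperature absolute temperature \[K\].
#' @return A list with `unfold` (length `m`) and, when refolding is on,
#'   `refold` (length `m`); rates in \[1/s\].
#' @export
total_hazard <- function(state, F, cm, temperature = 300) {
  stopifnot(inherits(cm, "cluster_model"))
  if (length(state) != cm$m || any(state != round(state)) ||
      any(state < 0) || any(state > cm$n))
    stop("'state' must give unfolded counts within [0, n_k] per cluster",
         call. = FALSE)
  if (length(F) != 1L || !is.finite(F) || F < 0)
    stop("'F' must be a single non-negative force", call. = FALSE)
  u <- .cluster_rates(F, cm, temperature)
  out <- list(unfold = (cm$n - state) * u)
  if (!is.null(cm$refolding))
    out$refold <- state * refold_rate(F, cm$refolding$omega1,
                                      cm$refolding$x_f, temperature)
  out
}

#' Cluster models for the cluster-granularity comparison
#'
#' Builds the pair of cluster models used to ask whether the number of
#' stability clusters matters for ensemble forces: a fine model with one
#' cluster per domain whose spontaneous-rate constants decline linearly
#' across domains and are perturbed by Gaussian noise on the log10 scale
#' (SD configurable, default 0.2), and a coarse model with `m_coarse`
#' equally sized clusters whose rates are spaced equidistantly over the
#' same envelope.
#'
#' @param n_domains total number of unfoldable domains.
#' @param rate_hi,rate_lo envelope of spontaneous unfolding rates \[1/s\]
#'   (first domain gets `rate_hi`, last `rate_lo`).
#' @param m_coarse number of clusters in the coarse model.
#' @param noise_sd standard deviation of the Gaussian perturbation applied
#'   to `log10(omega0)` of the fine model.
#' @param noise_scale `"log10"` (default) applies the perturbation on the
#'   log-ordinate; `"linear"` applies it relative to the rate itself.
#' @param x_u unfolding barrier width \[m\].
#' @param seed integer seed for the perturbation.
#' @return A list with elements `fine` and `coarse`, both [cluster_model()]s.
#' @export
cluster_comparison_models <- function(n_domains = 50, rate_hi = 1e-3,
                                      rate_lo = 1e-5, m_coarse = 5,
                                      noise_sd = 0.2,
                                      noise_scale = c("log10", "linear"),
                                      x_u = 0.25e-9, seed = 1) {
  noise_scale <- match.arg(noise_scale)
  base <- seq(rate_hi, rate_lo, length.out = n_domains)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  eps <- stats::rnorm(n_domains, 0, noise_sd)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  fine_rates <- if (noise_scale == "log10") 10^(log10(base) + eps)
                else pmax(base * (1 + eps), min(base) * 1e-3)
  if (n_domains %% m_coarse != 0)
    stop("'n_domains' must be divisible by 'm_coarse'", call. = FALSE)
  coarse_rates <- seq(rate_hi, rate_lo, length.out = m_coarse)
  list(
    fine = cluster_model(n = rep(1L, n_domains), omega0 = fine_rates, x_u = x_u),
    coarse = cluster_model(n = rep(n_domains %/% m_coarse, m_coarse),
                           omega0 = coarse_rates, x_u = x_u)
  )
}
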