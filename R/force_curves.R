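# The family of strand force-length curves F_i(l), i = 0..N unfolded
# domains: the discrete random variable underlying both the Monte Carlo and
# the master-equation solvers.

#' Tabulate the strand force curves for every unfolding state
#'
#' Solves the strand equilibrium ([solve_strand()]) for every possible
#' number of unfolded Ig domains `i = 0..N` over a grid of half-sarcomere
#' lengths, producing the `N + 1` force curves `F_i(l)`. At a fixed length
#' the force is non-increasing in `i` (each unfolding adds `d_u` of contour
#' length), and each curve is non-decreasing in `l`. The family is the
#' single shared mechanical input of the Monte Carlo and exact solvers, so
#' both methods see identical forces.
#'
#' @param length_grid strictly increasing grid of half-sarcomere lengths
#'   \[m\]; default 1 nm spacing from 1 to 2 um.
#' @param params a [mechanical_params()].
#' @param iso an [isoform()].
#' @return An object of class `"force_curve_family"`: list with
#'   `length_grid` \[m\], `forces` (matrix, `N + 1` rows: row `i + 1` is
#'   `F_i` \[N\]), `params`, `iso`.
#' @examples
#' \donttest{
#' fam <- build_force_curves(seq(1e-6, 2e-6, by = 5e-9))
#' nrow(fam$forces)   # 51 curves for the rabbit psoas isoform
#' }
#' @export
build_force_curves <- function(length_grid = seq(1e-6, 2e-6, by = 1e-9),
                               params = mechanical_params(),
                               iso = isoform()) {
  if (any(diff(length_grid) <= 0))
    stop("'length_grid' must be strictly increasing", call. = FALSE)
  if (length_grid[1] > 1e-6 + 1e-12)
    stop("'length_grid' must start at or below 1 um", call. = FALSE)
  N <- iso$n_prox_ig
  forces <- matrix(NA_real_, nrow = N + 1L, ncol = length(length_grid))
  for (i in 0:N) {
    forces[i + 1L, ] <- tryCatch(
      .strand_force_vec(length_grid, i, params, iso),
      error = function(e) stop(sprintf("force curve i = %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  }
  structure(list(length_grid = as.numeric(length_grid), forces = forces,
                 params = params, iso = iso),
            class = "force_curve_family")
}

#' @export
print.force_curve_family <- function(x, ...) {
  cat(sprintf("Force-curve family: %d curves (0..%d unfolded) on %d lengths [%.3g, %.3g] um\n",
              nrow(x$forces), nrow(x$forces) - 1L, length(x$length_grid),
              min(x$length_grid) * 1e6, max(x$length_grid) * 1e6))
  invisible(x)
}

#' Interpolated strand force at arbitrary lengths
#'
#' Linear interpolation of the tabulated curve `F_i(l)` between grid nodes;
#' exact at the nodes.
#'
#' @param family a [build_force_curves()] result.
#' @param i number of unfolded domains (scalar) or vector recycled against
#'   `l`.
#' @param l half-sarcomere lengths \[m\], within the tabulated range.
#' @return Forces \[N\].
#' @export
force_at <- function(family, i, l) {
  stopifnot(inherits(family, "force_curve_family"))
  N <- nrow(family$forces) - 1L
  if (any(i != round(i)) || any(i < 0) || any(i > N))
    stop("'i' must be integer in [0, N]", call. = FALSE)
  rng <- range(family$length_grid)
  if (any(l < rng[1] - 1e-12) || any(l > rng[2] + 1e-12))
    stop("'l' outside the tabulated length range", call. = FALSE)
  if (length(i) == 1L) {
    stats::approx(family$length_grid, family$forces[i + 1L, ], xout = l,
                  rule = 2)$y
  } else {
    mapply(function(ii, ll) stats::approx(family$length_grid,
                                          family$forces[ii + 1L, ],
                                          xout = ll, rule = 2)$y,
           i, l)
  }
}

# (N+1) x length(t) matrix of forces F_i(l(t)) on a time grid
.force_time_matrix <- function(family, protocol, times) {
  l <- protocol_length(protocol, times)
  rng <- range(family$length_grid)
  if (any(l < rng[1] - 1e-12) || any(l > rng[2] + 1e-12))
    stop("protocol leaves the tabulated length range; rebuild the force ",
         "curves on a wider grid", call. = FALSE)
  t(vapply(seq_len(nrow(family$forces)),
           function(r) stats::approx(family$length_grid, family$forces[r, ],
                                     xout = l, rule = 2)$y,
           numeric(length(times))))
}

#' Export force curves as CSV
#'
#' First column `length_um` (micrometres), then one column per unfolding
#' state `F_0 .. F_N` in piconewtons.
#'
#' @param family a [build_force_curves()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_force_curves_csv <- function(family, path) {
  stopifnot(inherits(family, "force_curve_family"))
  df <- data.frame(length_um = family$length_grid * 1e6,
                   t(family$forces) * 1e12)
  names(df)[-1] <- paste0("F_", 0:(nrow(family$forces) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a titin half-sarcomere model
#'
#' Bundles the mechanical parameters, isoform and Ig cluster model, checks
#' their consistency (cluster sizes must sum to the isoform's proximal Ig
#' count), and precomputes the shared force-curve family.
#'
#' @param params a [mechanical_params()].
#' @param iso an [isoform()].
#' @param clusters a [cluster_model()].
#' @param length_grid grid for [build_force_curves()]; default 1 nm spacing
#'   spanning 1 to 2 um.
#' @param curves optionally, a precomputed [build_force_curves()] family for
#'   the same `params`/`iso` (reused as is).
#' @return An object of class `"titin_model"`.
#' @examples
#' \donttest{
#' mod <- titin_model(length_grid = seq(1e-6, 2e-6, by = 1e-8))
#' }
#' @export
titin_model <- function(params = mechanical_params(), iso = isoform(),
                        clusters = cluster_model(),
                        length_grid = seq(1e-6, 2e-6, by = 1e-9),
                        curves = NULL) {
  stopifnot(inherits(params, "mech_params"), inherits(iso, "isoform"),
            inherits(clusters, "cluster_model"))
  if (sum(clusters$n) != iso$n_prox_ig)
    stop(sprintf("cluster sizes sum to %d but the isoform has %d proximal Ig domains",
                 sum(clusters$n), iso$n_prox_ig), call. = FALSE)
  if (is.null(curves)) curves <- build_force_curves(length_grid, params, iso)
  stopifnot(inherits(curves, "force_curve_family"))
  structure(list(params = params, iso = iso, clusters = clusters,
                 curves = curves),
            class = "titin_model")
}

#' @export
print.titin_model <- function(x, ...) {
  cat("Titin half-sarcomere model\n")
  print(x$iso); print(x$clusters); print(x$curves)
  invisible(x)
}
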