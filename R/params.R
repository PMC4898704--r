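# Boltzmann constant [J/K]
.kB <- 1.380649e-23

.check_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (!strict && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  x
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x <= 0)
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  as.integer(x)
}

#' Mechanical parameters of the titin strand model
#'
#' Collects the spring constants and worm-like-chain (WLC) parameters of the
#' series-element model of a single titin strand in a half sarcomere. All
#' values are SI (metres, newtons, kelvin). The defaults are literature
#' averages for skeletal-muscle titin.
#'
#' The strand is a series chain of: the PEVK segment (modified WLC with
#' stretch modulus `F0`), the folded proximal Ig region (WLC), the unfolded
#' proximal Ig region (WLC gaining `d_u` of contour length per unfolded
#' domain), the distal-Ig end-filament (stiff linear spring `k_end`) and the
#' A-band portion plus slack (stiff linear spring `k_rest` in series with a
#' zero-force slack length `slack_length`).
#'
#' @param pl_pevk persistence length of the PEVK segment \[m\].
#' @param cl_pevk_per_residue contour length contributed by one PEVK residue
#'   \[m\]; the PEVK contour length is `n_pevk_residues * cl_pevk_per_residue`.
#' @param F0 stretch modulus of the PEVK modified WLC \[N\].
#' @param pl_ig persistence length of the Ig-region chains (folded and
#'   unfolded share it) \[m\].
#' @param cl_ig_per_unit contour length contributed by one folded proximal Ig
#'   domain \[m\]. The default (4.5 nm) is the folded-domain size scale; see
#'   the methods vignette for the interpretation choice.
#' @param d_u contour length gained when one Ig domain unfolds \[m\].
#' @param k_end stiffness of the end-filament (distal Ig) spring \[N/m\].
#' @param k_rest stiffness of the A-band + slack spring \[N/m\].
#' @param temperature absolute temperature \[K\].
#' @param slack_length half-sarcomere length taken up at zero force \[m\];
#'   forces are exactly zero below it. The default places force onset near
#'   1 um half-sarcomere length.
#' @return An object of class `"mech_params"` (a named list).
#' @examples
#' p <- mechanical_params()
#' p$F0  # 150 pN stretch modulus
#' @export
mechanical_params <- function(pl_pevk = 6e-10,
                              cl_pevk_per_residue = 3.6e-10,
                              F0 = 150e-12,
                              pl_ig = 8.5e-10,
                              cl_ig_per_unit = 4.5e-9,
                              d_u = 25e-9,
                              k_end = 2,
                              k_rest = 2,
                              temperature = 300,
                              slack_length = 0.9e-6) {
  p <- list(
    pl_pevk = .check_pos(pl_pevk, "pl_pevk"),
    cl_pevk_per_residue = .check_pos(cl_pevk_per_residue, "cl_pevk_per_residue"),
    F0 = .check_pos(F0, "F0"),
    pl_ig = .check_pos(pl_ig, "pl_ig"),
    cl_ig_per_unit = .check_pos(cl_ig_per_unit, "cl_ig_per_unit"),
    d_u = .check_pos(d_u, "d_u"),
    k_end = .check_pos(k_end, "k_end"),
    k_rest = .check_pos(k_rest, "k_rest"),
    temperature = .check_pos(temperature, "temperature"),
    slack_length = .check_pos(slack_length, "slack_length", strict = FALSE)
  )
  class(p) <- "mech_params"
  p
}

#' @export
print.mech_params <- function(x, ...) {
  cat("Titin strand mechanical parameters (SI units)\n")
  cat(sprintf("  PEVK:      pl = %.3g m, cl/residue = %.3g m, F0 = %.3g N\n",
              x$pl_pevk, x$cl_pevk_per_residue, x$F0))
  cat(sprintf("  Ig:        pl = %.3g m, cl/folded domain = %.3g m, d_u = %.3g m\n",
              x$pl_ig, x$cl_ig_per_unit, x$d_u))
  cat(sprintf("  Springs:   k_end = %.3g N/m, k_rest = %.3g N/m\n", x$k_end, x$k_rest))
  cat(sprintf("  T = %g K, slack = %.3g m\n", x$temperature, x$slack_length))
  invisible(x)
}

#' Titin isoform composition
#'
#' Domain counts of the extensible I-band region of a titin isoform. The
#' default is the rabbit psoas 3400-kD isoform: 50 proximal Ig domains,
#' 800 PEVK residues and 26 distal Ig domains. The number of proximal Ig
#' domains is the `N` of the unfolding model: the number of unfolded domains
#' is a discrete random variable on `0..N`.
#'
#' @param n_prox_ig number of proximal (unfoldable) Ig domains.
#' @param n_pevk_residues number of PEVK residues.
#' @param n_dist_ig number of distal Ig domains (end-filament).
#' @return An object of class `"isoform"`.
#' @examples
#' isoform()            # rabbit psoas defaults
#' @export
isoform <- function(n_prox_ig = 50, n_pevk_residues = 800, n_dist_ig = 26) {
  iso <- list(
    n_prox_ig = .check_count(n_prox_ig, "n_prox_ig"),
    n_pevk_residues = .check_count(n_pevk_residues, "n_pevk_residues"),
    n_dist_ig = .check_count(n_dist_ig, "n_dist_ig")
  )
  class(iso) <- "isoform"
  iso
}

#' @export
print.isoform <- function(x, ...) {
  cat(sprintf("Titin isoform: %d proximal Ig, %d PEVK residues, %d distal Ig\n",
              x$n_prox_ig, x$n_pevk_residues, x$n_dist_ig))
  invisible(x)
}
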