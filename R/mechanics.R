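# Force-length mechanics of a single titin strand: WLC / modified-WLC /
# linear-spring elements in series, solved for mechanical equilibrium.

# Dimensionless WLC force: phi(y) = 1/4 (1-y)^-2 - 1/4 + y, y = x/cl in [0,1).
.wlc_phi <- function(y) 0.25 / (1 - y)^2 - 0.25 + y

# d phi / d y
.wlc_dphi <- function(y) 0.5 / (1 - y)^3 + 1

# Inverse of .wlc_phi, vectorized. phi >= 0 -> y in [0,1).
# Bracketed bisection followed by clamped Newton polish (machine precision).
.wlc_phi_inv <- function(phi) {
  stopifnot(all(is.finite(phi)), all(phi >= 0))
  lo <- rep(0, length(phi))
  hi <- rep(1 - 1e-12, length(phi))
  for (i in 1:60) {
    mid <- 0.5 * (lo + hi)
    below <- .wlc_phi(mid) < phi
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  y <- 0.5 * (lo + hi)
  for (i in 1:3) {
    step <- (.wlc_phi(y) - phi) / .wlc_dphi(y)
    y <- pmin(pmax(y - step, 0), 1 - 1e-12)
  }
  y
}

#' Worm-like chain force-extension relation
#'
#' Interpolation formula for the entropic force of a worm-like chain (WLC)
#' held at end-to-end extension `x`:
#' `F = (kB*T/pl) * (1/4 * (1 - x/cl)^-2 - 1/4 + x/cl)`.
#' The force is zero at `x = 0`, strictly increasing, and diverges as `x`
#' approaches the contour length `cl`.
#'
#' @param x end-to-end extension \[m\] (vectorized); requires `0 <= x < cl`.
#' @param pl persistence length \[m\].
#' @param cl contour length \[m\].
#' @param temperature absolute temperature \[K\].
#' @return Force \[N\], same length as `x`.
#' @examples
#' wlc_force(0, 6e-10, 288e-9)                    # 0
#' wlc_force(144e-9, 6e-10, 288e-9)               # 1.25 kB T / pl
#' @export
wlc_force <- function(x, pl, cl, temperature = 300) {
  .check_pos(pl, "pl"); .check_pos(cl, "cl"); .check_pos(temperature, "temperature")
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and >= 0", call. = FALSE)
  if (any(x >= cl))
    stop("'x' must be below the contour length 'cl' (inextensible limit)",
         call. = FALSE)
  (.kB * temperature / pl) * .wlc_phi(x / cl)
}

#' Modified worm-like chain (enthalpic elasticity) force
#'
#' The PEVK segment follows a modified WLC in which a stretch modulus `F0`
#' adds an enthalpic contribution: the force `F` satisfies the implicit
#' relation `F = (kB*T/pl) * phi(x/cl - F/F0)` with
#' `phi(y) = 1/4 (1-y)^-2 - 1/4 + y`. Substituting `y = x/cl - F/F0` makes
#' the relation a monotone scalar root-finding problem; as `F0 -> Inf` the
#' ordinary WLC is recovered. Extensions beyond `cl` are admissible because
#' the chain itself stretches.
#'
#' @param x end-to-end extension \[m\] (vectorized), `x >= 0`.
#' @inheritParams wlc_force
#' @param F0 stretch modulus \[N\].
#' @return Force \[N\].
#' @export
modified_wlc_force <- function(x, pl, cl, F0, temperature = 300) {
  .check_pos(pl, "pl"); .check_pos(cl, "cl"); .check_pos(F0, "F0")
  .check_pos(temperature, "temperature")
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and >= 0", call. = FALSE)
  kT <- .kB * temperature
  # Solve x_elem(F) = x with x_elem(F) = cl * (phi_inv(F pl / kT) + F / F0),
  # strictly increasing in F. Bracket: x_elem(F0 * x / cl) >= x.
  n <- length(x)
  lo <- rep(0, n)
  hi <- F0 * x / cl + 1e-30
  xeval <- function(F) cl * (.wlc_phi_inv(F * pl / kT) + F / F0)
  for (i in 1:110) {
    mid <- 0.5 * (lo + hi)
    below <- xeval(mid) < x
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  F <- 0.5 * (lo + hi)
  resid <- abs(xeval(F) - x)
  if (any(resid > 1e-12 * pmax(x, 1e-12)))
    stop("modified WLC root-find failed to converge: max residual ",
         format(max(resid)), " m", call. = FALSE)
  F
}

#' Series-element descriptors
#'
#' Constructors for the three element kinds making up a titin strand:
#' ordinary WLC (`wlc_element`), modified WLC with stretch modulus
#' (`mwlc_element`) and Hookean spring (`spring_element`). Used with
#' [element_length_at_force()].
#'
#' @param pl persistence length \[m\].
#' @param cl contour length \[m\].
#' @param F0 stretch modulus \[N\].
#' @param k spring stiffness \[N/m\].
#' @param temperature absolute temperature \[K\].
#' @return An object of class `"strand_element"`.
#' @name strand_element
NULL

#' @rdname strand_element
#' @export
wlc_element <- function(pl, cl, temperature = 300) {
  structure(list(type = "wlc", pl = .check_pos(pl, "pl"),
                 cl = .check_pos(cl, "cl", strict = FALSE),
                 temperature = .check_pos(temperature, "temperature")),
            class = "strand_element")
}

#' @rdname strand_element
#' @export
mwlc_element <- function(pl, cl, F0, temperature = 300) {
  structure(list(type = "mwlc", pl = .check_pos(pl, "pl"),
                 cl = .check_pos(cl, "cl", strict = FALSE),
                 F0 = .check_pos(F0, "F0"),
                 temperature = .check_pos(temperature, "temperature")),
            class = "strand_element")
}

#' @rdname strand_element
#' @export
spring_element <- function(k) {
  structure(list(type = "spring", k = .check_pos(k, "k")),
            class = "strand_element")
}

#' Extension of a series element at a given tension
#'
#' Inverts the force-extension relation of an element: the unique extension
#' at which the element carries force `F`. The WLC is inverted numerically
#' (bracketed bisection plus Newton polish); the modified WLC extension is
#' explicit once the dimensionless WLC is inverted; the linear spring is
#' Hooke's law `F / k`. Strictly increasing in `F`. Elements with zero
#' contour length have zero extension at any force.
#'
#' @param element a `"strand_element"` from [wlc_element()],
#'   [mwlc_element()] or [spring_element()].
#' @param F tension \[N\] (vectorized), `F >= 0`.
#' @return Extension \[m\].
#' @export
element_length_at_force <- function(element, F) {
  stopifnot(inherits(element, "strand_element"))
  if (any(!is.finite(F)) || any(F < 0))
    stop("'F' must be finite and >= 0", call. = FALSE)
  switch(element$type,
    spring = F / element$k,
    wlc = {
      if (element$cl == 0) return(rep(0, length(F)))
      kT <- .kB * element$temperature
      element$cl * .wlc_phi_inv(F * element$pl / kT)
    },
    mwlc = {
      if (element$cl == 0) return(rep(0, length(F)))
      kT <- .kB * element$temperature
      element$cl * (.wlc_phi_inv(F * element$pl / kT) + F / element$F0)
    },
    stop("unknown element type")
  )
}

# Strand extension beyond slack at tension F (vectorized over F), for
# n_unfolded unfolded Ig domains. Returns total extension of the extensible
# elements; segment lengths optionally.
.strand_extension <- function(F, n_unfolded, params, iso, segments = FALSE) {
  kT <- .kB * params$temperature
  n_f <- iso$n_prox_ig - n_unfolded
  cl_pevk <- iso$n_pevk_residues * params$cl_pevk_per_residue
  cl_fold <- n_f * params$cl_ig_per_unit
  cl_unf <- n_unfolded * params$d_u
  y_ig <- .wlc_phi_inv(F * params$pl_ig / kT)
  x_pevk <- cl_pevk * (.wlc_phi_inv(F * params$pl_pevk / kT) + F / params$F0)
  x_fold <- cl_fold * y_ig
  x_unf <- cl_unf * y_ig
  x_end <- F / params$k_end
  x_spr <- F / params$k_rest
  tot <- x_pevk + x_fold + x_unf + x_end + x_spr
  if (!segments) return(tot)
  list(total = tot, l_pevk = x_pevk, l_folded_total = x_fold,
       l_unfolded_total = x_unf, l_end = x_end, l_rest_spring = x_spr)
}

# d(extension)/dF, analytic, vectorized (used for Newton).
.strand_extension_deriv <- function(F, n_unfolded, params, iso) {
  kT <- .kB * params$temperature
  n_f <- iso$n_prox_ig - n_unfolded
  cl_pevk <- iso$n_pevk_residues * params$cl_pevk_per_residue
  cl_ig <- n_f * params$cl_ig_per_unit + n_unfolded * params$d_u
  y_ig <- .wlc_phi_inv(F * params$pl_ig / kT)
  y_pevk <- .wlc_phi_inv(F * params$pl_pevk / kT)
  cl_pevk * ((params$pl_pevk / kT) / .wlc_dphi(y_pevk) + 1 / params$F0) +
    cl_ig * (params$pl_ig / kT) / .wlc_dphi(y_ig) +
    1 / params$k_end + 1 / params$k_rest
}

# Solve the force balance: find F >= 0 with slack + extension(F) = l, for a
# vector of lengths l (one n_unfolded). Safeguarded Newton within a bracket.
.strand_force_vec <- function(l, n_unfolded, params, iso) {
  x_t <- l - params$slack_length
  n <- length(l)
  F <- numeric(n)
  act <- which(x_t > 0)
  if (length(act)) {
    xa <- x_t[act]
    keff <- params$k_end * params$k_rest / (params$k_end + params$k_rest)
    lo <- rep(0, length(act))
    hi <- keff * xa * (1 + 1e-9) + 1e-25
    Fa <- pmin(1e-12, hi)          # start at ~1 pN inside the bracket
    for (it in 1:200) {
      r <- .strand_extension(Fa, n_unfolded, params, iso) - xa
      below <- r < 0
      lo[below] <- Fa[below]
      hi[!below] <- Fa[!below]
      if (all(abs(r) <= 1e-14 * xa)) break
      step <- r / .strand_extension_deriv(Fa, n_unfolded, params, iso)
      Fn <- Fa - step
      bad <- !(Fn > lo & Fn < hi)
      Fn[bad] <- 0.5 * (lo[bad] + hi[bad])
      Fa <- Fn
    }
    r <- .strand_extension(Fa, n_unfolded, params, iso) - xa
    if (any(abs(r) > 1e-11 * pmax(xa, 1e-9)))
      stop("strand force balance did not converge (max length residual ",
           format(max(abs(r))), " m)", call. = FALSE)
    F[act] <- Fa
  }
  F
}

#' Mechanical equilibrium of a titin strand
#'
#' Solves the series-chain equilibrium of a single titin strand at imposed
#' half-sarcomere length `l` with `n_unfolded` unfolded Ig domains: the
#' common tension `F` at which the element extensions (PEVK, folded Ig
#' chain, unfolded Ig chain, end-filament spring, A-band/slack spring) sum
#' to `l`. This is the first-order (KKT) condition of the underlying convex
#' energy-minimisation problem; equal tension in all series elements is
#' equivalent to the minimum. Below the slack configuration the force is
#' exactly zero and the remaining length is absorbed by the slack segment.
#'
#' @param l half-sarcomere length \[m\], `l >= 0`.
#' @param n_unfolded number of unfolded proximal Ig domains,
#'   `0 <= n_unfolded <= N`.
#' @param params a [mechanical_params()] object.
#' @param iso an [isoform()] object.
#' @return A list with `force` \[N\] and `segments`, a named list of segment
#'   lengths (`l_pevk`, `l_folded_total`, `l_unfolded_total`, `l_end`,
#'   `l_rest`) that sum to `l`; `l_rest` contains the slack length plus the
#'   A-band spring extension.
#' @examples
#' s <- solve_strand(1.5e-6, 0, mechanical_params(), isoform())
#' s$force * 1e12   # force in pN
#' @export
solve_strand <- function(l, n_unfolded, params = mechanical_params(),
                         iso = isoform()) {
  .check_pos(l, "l", strict = FALSE)
  if (n_unfolded != round(n_unfolded) || n_unfolded < 0 ||
      n_unfolded > iso$n_prox_ig)
    stop("'n_unfolded' must be an integer in [0, N]", call. = FALSE)
  F <- .strand_force_vec(l, n_unfolded, params, iso)
  seg <- .strand_extension(F, n_unfolded, params, iso, segments = TRUE)
  slack_used <- min(l, params$slack_length)
  segments <- list(
    l_pevk = seg$l_pevk,
    l_folded_total = seg$l_folded_total,
    l_unfolded_total = seg$l_unfolded_total,
    l_end = seg$l_end,
    l_rest = seg$l_rest_spring + slack_used
  )
  list(force = F, segments = segments)
}
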