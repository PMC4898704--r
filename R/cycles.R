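# Hysteresis analysis of stretch-shortening cycles: per-cycle loading and
# unloading curves, hysteresis areas, peak forces.

# Identify cycles in a protocol: maximal [start, end] windows from one
# local minimum of the length trace through a local maximum back down.
# Returns a data.frame of cycle boundary times.
.find_cycles <- function(protocol) {
  tt <- protocol$times; ll <- protocol$lengths
  n <- length(tt)
  d <- diff(ll)
  # a cycle starts where a rising segment begins (first segment or preceded
  # by a non-rising one) and ends where the following falling run ends
  starts <- which(d > 0 & c(TRUE, d[-length(d)] <= 0))
  if (!length(starts)) return(NULL)
  cyc <- lapply(starts, function(s) {
    i <- s
    while (i <= length(d) && d[i] > 0) i <- i + 1L   # end of rising run
    if (i > length(d) || d[i] >= 0) return(NULL)      # no descent: not a cycle
    while (i <= length(d) && d[i] < 0) i <- i + 1L   # end of falling run
    c(t_start = tt[s], t_peak = NA_real_, t_end = tt[i])
  })
  cyc <- do.call(rbind, cyc[!vapply(cyc, is.null, TRUE)])
  if (is.null(cyc)) return(NULL)
  as.data.frame(cyc)
}

#' Hysteresis analysis of a cyclic force response
#'
#' Splits a force trace (Monte Carlo ensemble mean or exact expected force)
#' at the cycle boundaries of its protocol and computes, per cycle, the
#' hysteresis area -- the loading-minus-unloading force integrated over
#' length by the trapezoidal rule, i.e. the net mechanical energy dissipated
#' in the cycle \[J\] -- and the peak force over the loading phase. Cycles
#' own the half-open time window from their start up to (not including) the
#' next cycle's start.
#'
#' @param result an `"ensemble_result"`, a `"master_solution"`, or a list
#'   with numeric `times` \[s\] and `force` \[N\].
#' @param protocol the [length_protocol()] the result was computed under;
#'   must contain at least one stretch-shortening cycle.
#' @return An object of class `"cycle_analysis"`: data.frame with one row
#'   per cycle (`cycle`, `t_start`, `t_end`, `peak_force` \[N\],
#'   `hysteresis_area` \[J\]).
#' @export
analyze_cycles <- function(result, protocol) {
  stopifnot(inherits(protocol, "length_protocol"))
  if (inherits(result, "ensemble_result")) {
    times <- result$times; force <- result$mean_force
  } else if (inherits(result, "master_solution")) {
    times <- result$times; force <- result$expected_force
  } else {
    times <- result$times; force <- result$force
    if (is.null(times) || is.null(force))
      stop("'result' must provide times and force", call. = FALSE)
  }
  cyc <- .find_cycles(protocol)
  if (is.null(cyc) || nrow(cyc) == 0L)
    stop("protocol contains no stretch-shortening cycle", call. = FALSE)
  lengths <- protocol_length(protocol, times)
  out <- lapply(seq_len(nrow(cyc)), function(i) {
    sel <- times >= cyc$t_start[i] - 1e-12 & times <= cyc$t_end[i] + 1e-12
    tt <- times[sel]; ff <- force[sel]; ll <- lengths[sel]
    ipk <- which.max(ll)[1]
    peak <- max(ff[seq_len(ipk)])
    # signed line integral of F dl around the loop = loading - unloading area
    area <- sum(0.5 * (ff[-1] + ff[-length(ff)]) * diff(ll))
    data.frame(cycle = i, t_start = cyc$t_start[i], t_end = cyc$t_end[i],
               peak_force = peak, hysteresis_area = area)
  })
  out <- do.call(rbind, out)
  class(out) <- c("cycle_analysis", "data.frame")
  out
}

#' @export
print.cycle_analysis <- function(x, ...) {
  cat("Stretch-shortening cycle analysis\n")
  df <- data.frame(cycle = x$cycle,
                   peak_pN = signif(x$peak_force * 1e12, 4),
                   area_aJ = signif(x$hysteresis_area * 1e18, 4))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
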