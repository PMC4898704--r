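# Piecewise-linear half-sarcomere length protocols: ramps, rests,
# stretch-shortening cycles, CSV round trips and the bundled canonical
# protocols.

#' Piecewise-linear length protocol
#'
#' A length protocol prescribes the half-sarcomere length as a function of
#' time through breakpoints interpolated linearly. Times must be strictly
#' increasing and start at 0; lengths must be positive.
#'
#' @param times numeric vector of breakpoint times \[s\], strictly
#'   increasing, first element 0.
#' @param lengths numeric vector of half-sarcomere lengths \[m\].
#' @return An object of class `"length_protocol"`.
#' @seealso [make_ramp()], [make_cycles()], [make_rest()], [protocol_join()]
#' @export
length_protocol <- function(times, lengths) {
  if (length(times) != length(lengths) || length(times) < 2L)
    stop("'times' and 'lengths' must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(lengths)))
    stop("protocol breakpoints must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (times[1] != 0) stop("protocols must start at t = 0", call. = FALSE)
  if (any(lengths <= 0)) stop("'lengths' must be positive", call. = FALSE)
  structure(list(times = as.numeric(times), lengths = as.numeric(lengths)),
            class = "length_protocol")
}

#' @export
print.length_protocol <- function(x, ...) {
  cat(sprintf("Length protocol: %d breakpoints, duration %.3g s, range [%.3g, %.3g] um\n",
              length(x$times), max(x$times), min(x$lengths) * 1e6,
              max(x$lengths) * 1e6))
  invisible(x)
}

#' Evaluate a protocol at arbitrary times
#'
#' @param protocol a [length_protocol()].
#' @param t times \[s\]; values outside the protocol are held at the ends.
#' @return Half-sarcomere lengths \[m\].
#' @export
protocol_length <- function(protocol, t) {
  stopifnot(inherits(protocol, "length_protocol"))
  stats::approx(protocol$times, protocol$lengths, xout = t, rule = 2)$y
}

#' Protocol duration
#' @param protocol a [length_protocol()].
#' @return Duration \[s\].
#' @export
protocol_duration <- function(protocol) max(protocol$times)

#' Linear length ramp
#'
#' @param l_start,l_end start and end half-sarcomere lengths \[m\],
#'   `l_end != l_start`, both positive.
#' @param speed absolute ramp speed \[m/s\].
#' @return A two-breakpoint [length_protocol()].
#' @examples
#' make_ramp(1e-6, 2e-6, 1e-6)   # 1 -> 2 um at 1 um/s: duration 1 s
#' @export
make_ramp <- function(l_start, l_end, speed = 1e-6) {
  .check_pos(l_start, "l_start"); .check_pos(l_end, "l_end")
  .check_pos(speed, "speed")
  if (l_end == l_start) stop("'l_end' must differ from 'l_start'", call. = FALSE)
  length_protocol(c(0, abs(l_end - l_start) / speed), c(l_start, l_end))
}

#' Constant-length rest period
#'
#' @param length held half-sarcomere length \[m\].
#' @param duration rest duration \[s\].
#' @return A [length_protocol()].
#' @export
make_rest <- function(length, duration) {
  .check_pos(length, "length"); .check_pos(duration, "duration")
  length_protocol(c(0, duration), c(length, length))
}

#' Triangular stretch-shortening cycles
#'
#' `n_cycles` triangle cycles from `base` up to `base + amplitude` and back,
#' at constant absolute speed. With `n_cycles = 0` a constant-length hold of
#' one cycle period is returned. An optional rest (constant length at
#' `base`) can be appended after the cycles.
#'
#' @param base starting (and return) half-sarcomere length \[m\].
#' @param amplitude cycle amplitude \[m\], `0 < amplitude < base`.
#' @param n_cycles number of cycles (>= 0).
#' @param speed lengthening/shortening speed \[m/s\].
#' @param rest_after optional rest duration appended after the last cycle \[s\].
#' @return A [length_protocol()] with `2 * n_cycles + 1` breakpoints
#'   (plus one more if `rest_after` is given).
#' @examples
#' make_cycles(1.85e-6, 0.25e-6, 10)   # 21 breakpoints
#' @export
make_cycles <- function(base, amplitude, n_cycles, speed = 1e-6,
                        rest_after = NULL) {
  .check_pos(base, "base"); .check_pos(amplitude, "amplitude")
  .check_pos(speed, "speed")
  if (amplitude >= base) stop("'amplitude' must be smaller than 'base'", call. = FALSE)
  if (n_cycles != round(n_cycles) || n_cycles < 0)
    stop("'n_cycles' must be a non-negative integer", call. = FALSE)
  half <- amplitude / speed
  if (n_cycles == 0) {
    p <- length_protocol(c(0, 2 * half), c(base, base))
  } else {
    times <- c(0, cumsum(rep(half, 2 * n_cycles)))
    lengths <- c(rbind(rep(base, n_cycles), rep(base + amplitude, n_cycles)))
    lengths <- c(lengths, base)
    p <- length_protocol(times, lengths)
  }
  if (!is.null(rest_after))
    p <- protocol_join(p, make_rest(base, rest_after))
  p
}

#' Concatenate protocols in time
#'
#' Appends protocols, shifting times so each starts where the previous one
#' ended. Adjacent segments must agree in length at the junction (within
#' 1e-12 m); the duplicated junction breakpoint is dropped.
#'
#' @param ... [length_protocol()] objects.
#' @return A [length_protocol()].
#' @export
protocol_join <- function(...) {
  ps <- list(...)
  stopifnot(length(ps) >= 1, all(vapply(ps, inherits, TRUE, "length_protocol")))
  out <- ps[[1]]
  for (p in ps[-1]) {
    if (abs(out$lengths[length(out$lengths)] - p$lengths[1]) > 1e-12)
      stop("protocols do not join continuously in length", call. = FALSE)
    t0 <- max(out$times)
    out <- length_protocol(c(out$times, t0 + p$times[-1]),
                           c(out$lengths, p$lengths[-1]))
  }
  out
}

#' Write / read a protocol as CSV
#'
#' Two-column CSV with header `time_s, length_um` (time in seconds, length
#' in micrometres). The round trip is lossless to full double precision.
#'
#' @param protocol a [length_protocol()].
#' @param path file path.
#' @return `write_protocol_csv` returns `path` invisibly;
#'   `read_protocol_csv` returns a [length_protocol()].
#' @export
write_protocol_csv <- function(protocol, path) {
  stopifnot(inherits(protocol, "length_protocol"))
  df <- data.frame(time_s = protocol$times, length_um = protocol$lengths * 1e6)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol_csv
#' @export
read_protocol_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "length_um") %in% names(df)))
    stop("protocol CSV needs columns 'time_s' and 'length_um'", call. = FALSE)
  length_protocol(df$time_s, df$length_um * 1e-6)
}

#' Canonical study protocols
#'
#' The bundled length protocols used throughout the package:
#' \describe{
#'   \item{`ramp_1to2`}{single 1 to 2 um ramp at 1 um/s: the baseline
#'     length-ramp experiment.}
#'   \item{`hysteresis_rest`}{two 1 to 1.7 to 1 um stretch-shortening
#'     cycles, a 30 s rest at 1 um, then a third cycle: probes hysteresis
#'     recovery through refolding during rest.}
#'   \item{`repeated_cycles`}{lead-in ramp from 1 to 1.85 um (half of a
#'     3.7 um average sarcomere length), then 10 triangle cycles of 0.25 um
#'     amplitude: probes the cycle-to-cycle decline of peak force.}
#' }
#' All at 1 um/s.
#'
#' @param name one of `"ramp_1to2"`, `"hysteresis_rest"`,
#'   `"repeated_cycles"`.
#' @return A [length_protocol()].
#' @export
canonical_protocol <- function(name = c("ramp_1to2", "hysteresis_rest",
                                        "repeated_cycles")) {
  name <- match.arg(name)
  um <- 1e-6
  switch(name,
    ramp_1to2 = make_ramp(1 * um, 2 * um, 1 * um),
    hysteresis_rest = protocol_join(
      make_cycles(1 * um, 0.7 * um, 2, speed = 1 * um, rest_after = 30),
      make_cycles(1 * um, 0.7 * um, 1, speed = 1 * um)
    ),
    repeated_cycles = protocol_join(
      make_ramp(1 * um, 1.85 * um, 1 * um),
      make_cycles(1.85 * um, 0.25 * um, 10, speed = 1 * um)
    )
  )
}
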