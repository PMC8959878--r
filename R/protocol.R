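#' Three-segment clamp protocol
#'
#' A protocol is a pre-clamp, clamp and post-clamp segment. The stimulus
#' (applied current in current mode, holding voltage in voltage mode) is
#' `baseline` outside the clamp segment and `amplitude` inside it. Total
#' duration is capped at 1000 ms.
#'
#' @param mode `"current"` or `"voltage"`.
#' @param pre_ms,clamp_ms,post_ms segment durations (ms), all >= 0;
#'   defaults 10 / 50 / 10.
#' @param amplitude applied value during the clamp segment: nA in current
#'   mode (default 0.1), mV in voltage mode (default -20).
#' @param baseline applied value outside the clamp segment: nA in current
#'   mode (default 0). In voltage mode `NULL` (the default) means the
#'   pre/post segments are held at the model's numerically located resting
#'   potential, resolved when the simulation runs.
#' @return a validated object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(mode = c("current", "voltage"),
                           pre_ms = 10, clamp_ms = 50, post_ms = 10,
                           amplitude = if (mode == "current") 0.1 else -20,
                           baseline = if (mode == "current") 0 else NULL) {
  if (!is.character(mode) || !mode[1] %in% c("current", "voltage"))
    .stop_validation("'mode' must be \"current\" or \"voltage\"")
  mode <- mode[1]
  force(amplitude); force(baseline)
  p <- structure(list(mode = mode, pre_ms = pre_ms, clamp_ms = clamp_ms,
                      post_ms = post_ms, amplitude = amplitude,
                      baseline = baseline),
                 class = "clamp_protocol")
  validate_protocol(p)
}

#' Default clamp protocol (10 / 50 / 10 ms)
#'
#' The default simulation lasts 70 ms: a 10 ms pre-clamp, a 50 ms clamp
#' and a 10 ms post-clamp segment.
#'
#' @param mode `"current"` or `"voltage"`.
#' @return a `clamp_protocol`.
#' @export
default_protocol <- function(mode = c("current", "voltage")) {
  if (!is.character(mode) || !mode[1] %in% c("current", "voltage"))
    .stop_validation("'mode' must be \"current\" or \"voltage\"")
  clamp_protocol(mode = mode[1])
}

#' Total protocol duration (ms)
#' @param protocol a `clamp_protocol`.
#' @return total duration in ms.
#' @export
protocol_duration <- function(protocol) {
  protocol$pre_ms + protocol$clamp_ms + protocol$post_ms
}

#' Validate a clamp protocol
#'
#' Checks that all segment durations are non-negative, the total duration
#' is positive and does not exceed the 1000 ms cap, and the amplitude is
#' finite. Idempotent: returns the protocol unchanged on success.
#'
#' @param protocol a `clamp_protocol`.
#' @return the protocol, invisibly unchanged.
#' @export
validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "clamp_protocol"))
  for (f in c("pre_ms", "clamp_ms", "post_ms")) {
    .check_scalar(protocol[[f]], f)
    if (protocol[[f]] < 0)
      .stop_validation(sprintf("'%s' must be non-negative (got %g)",
                               f, protocol[[f]]))
  }
  total <- protocol_duration(protocol)
  if (total <= 0)
    .stop_validation("total protocol duration must be positive")
  if (total > 1000)
    .stop_validation(sprintf(
      "total protocol duration %g ms exceeds the 1000 ms cap", total))
  .check_scalar(protocol$amplitude, "amplitude")
  if (!is.null(protocol$baseline)) .check_scalar(protocol$baseline, "baseline")
  protocol
}

#' Stimulus value at a given time
#'
#' Segments are half-open, left-inclusive: the clamp amplitude applies on
#' `[pre, pre + clamp)` and the baseline elsewhere in `[0, total]`.
#'
#' @param protocol a `clamp_protocol`.
#' @param t time (ms) in `[0, total]`.
#' @param baseline baseline value to use when the protocol's baseline is
#'   unresolved (`NULL`), e.g. the resting potential in voltage mode.
#' @return the applied value (nA or mV, depending on mode).
#' @export
stimulus_at <- function(protocol, t, baseline = NULL) {
  validate_protocol(protocol)
  total <- protocol_duration(protocol)
  if (!is.numeric(t) || any(!is.finite(t)))
    .stop_validation("'t' must be finite")
  if (any(t < 0 | t > total))
    .stop_validation(sprintf("t outside the protocol window [0, %g] ms", total))
  base <- if (is.null(protocol$baseline)) baseline else protocol$baseline
  if (is.null(base))
    .stop_validation("protocol baseline is unresolved; supply 'baseline'")
  in_clamp <- t >= protocol$pre_ms & t < protocol$pre_ms + protocol$clamp_ms
  ifelse(in_clamp, protocol$amplitude, base)
}

#' @export
print.clamp_protocol <- function(x, ...) {
  unit <- if (x$mode == "current") "nA" else "mV"
  base <- if (is.null(x$baseline)) "rest" else sprintf("%g %s", x$baseline, unit)
  cat(sprintf(
    "%s-clamp protocol: %g / %g / %g ms (total %g ms), amplitude %g %s, baseline %s\n",
    x$mode, x$pre_ms, x$clamp_ms, x$post_ms, protocol_duration(x),
    x$amplitude, unit, base))
  invisible(x)
}
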