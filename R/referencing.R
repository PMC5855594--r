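#' Double-reference a raw sensorgram
#'
#' Background correction used on array-format SPR instruments: the interspot
#' signal (an unmodified surface region exposed only to analyte flow, which
#' carries bulk refractive-index shifts and drift) and a blank
#' (zero-concentration) injection are both subtracted from the raw trace in
#' one pass:
#' corrected(t) = raw(t) - interspot(t) - blank(t).
#'
#' All three traces must share an identical time grid; no resampling is
#' attempted, so kinetic information is never smoothed. Metadata
#' (concentration, schedule, label) is carried over from `raw`.
#'
#' @param raw,interspot,blank [sensorgram()] objects on one time grid.
#' @return The corrected [sensorgram()].
#' @export
double_reference <- function(raw, interspot, blank) {
  for (s in list(raw, interspot, blank))
    if (!inherits(s, "sensorgram")) stop("all inputs must be sensorgram objects")
  if (length(raw$time) != length(interspot$time) ||
      length(raw$time) != length(blank$time) ||
      any(raw$time != interspot$time) || any(raw$time != blank$time))
    stop("time-grid mismatch between raw, interspot and blank traces; ",
         "no resampling is attempted")
  sensorgram(raw$time, raw$response - interspot$response - blank$response,
             raw$conc, raw$schedule, raw$label, conc_b = raw$conc_b)
}

#' Zero a sensorgram on its pre-injection baseline
#'
#' Subtracts the mean response over a window of pre-injection samples
#' (carried with negative times) so the trace starts at approximately zero
#' at injection time.
#'
#' @param s a [sensorgram()] whose grid includes samples at `time < 0`.
#' @param window_s length of the pre-injection averaging window in seconds;
#'   it must cover at least 2 samples.
#' @return The baseline-subtracted [sensorgram()].
#' @export
zero_baseline <- function(s, window_s) {
  stopifnot(inherits(s, "sensorgram"))
  if (!is.numeric(window_s) || !is.finite(window_s) || window_s <= 0)
    stop("'window_s' must be > 0")
  pre <- s$time < 0 & s$time >= -window_s
  if (sum(pre) < 2L)
    stop("baseline window must cover at least 2 pre-injection samples ",
         "(found ", sum(pre), ")")
  sensorgram(s$time, s$response - mean(s$response[pre]), s$conc, s$schedule,
             s$label, conc_b = s$conc_b)
}
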