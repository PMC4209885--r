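#' Specify a digital Butterworth filter
#'
#' The two preprocessing filters of the pipeline are a 1st-order low-pass
#' at 1 Hz (sEMG envelope smoothing) and a 3rd-order high-pass at 0.5 Hz
#' (removal of slow FSR baseline drift), both designed by bilinear
#' transform at the 50 Hz acquisition rate.
#'
#' @param kind "lowpass" or "highpass".
#' @param order filter order (>= 1).
#' @param cutoff_hz cutoff frequency, Hz; must lie below Nyquist.
#' @param sample_rate_hz sampling rate, Hz.
#' @return an object of class `filter_spec`.
#' @export
#' @examples
#' filter_spec("lowpass", 1, 1, 50)    # sEMG envelope filter
#' filter_spec("highpass", 3, 0.5, 50) # FSR drift-removal filter
filter_spec <- function(kind = c("lowpass", "highpass"), order, cutoff_hz,
                        sample_rate_hz = 50) {
  kind <- match.arg(kind)
  if (order < 1 || order != round(order)) {
    stop("`order` must be a positive integer.", call. = FALSE)
  }
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate_hz / 2) {
    stop("`cutoff_hz` must lie in (0, Nyquist).", call. = FALSE)
  }
  structure(list(kind = kind, order = as.integer(order),
                 cutoff_hz = cutoff_hz, sample_rate_hz = sample_rate_hz),
            class = "filter_spec")
}

#' Apply a causal Butterworth filter channel-wise
#'
#' Forward-only IIR filtering with zero initial conditions, applied to each
#' column independently. Causality is deliberate: the decoders target
#' real-time prosthetic control, so zero-phase forward-backward filtering
#' would be unusable online. Transients are not trimmed here; the
#' realistic-scenario sample selector excludes ramp regions instead.
#'
#' @param x numeric vector or `n_samples x n_channels` matrix.
#' @param spec a [filter_spec()].
#' @return filtered signal with the shape of `x`.
#' @export
butterworth_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  if (nrow(xm) < 3 * spec$order) {
    stop(sprintf("Signal too short: %d samples for an order-%d filter (need >= %d).",
                 nrow(xm), spec$order, 3 * spec$order), call. = FALSE)
  }
  ba <- signal::butter(spec$order, spec$cutoff_hz / (spec$sample_rate_hz / 2),
                       type = if (spec$kind == "lowpass") "low" else "high")
  out <- apply(xm, 2, function(col) as.numeric(signal::filter(ba, col)))
  out <- matrix(out, nrow = nrow(xm), dimnames = dimnames(xm))
  if (vec) drop(out) else out
}

#' The default preprocessing applied to each interface stream
#'
#' sEMG: 1st-order low-pass at 1 Hz. FSR (either bracelet): 3rd-order
#' high-pass at 0.5 Hz. Ultrasound features: used as extracted, no
#' filtering.
#'
#' @param stream stream name ("semg", "fsr", "fsr2", "us_features").
#' @param sample_rate_hz sampling rate, Hz.
#' @return a `filter_spec`, or `NULL` when the stream is not filtered.
#' @export
default_filter <- function(stream, sample_rate_hz = 50) {
  switch(stream,
    semg = filter_spec("lowpass", 1, 1, sample_rate_hz),
    fsr = ,
    fsr2 = filter_spec("highpass", 3, 0.5, sample_rate_hz),
    us_features = NULL,
    stop("Unknown stream: ", stream, call. = FALSE))
}

#' Preprocess one stream of a session
#'
#' Applies [default_filter()] (or a caller-supplied `filter_spec`) causally
#' over the full session, as an online system would.
#'
#' @param session a [simulate_session()] recording.
#' @param stream stream name present in `session$streams`.
#' @param spec optional `filter_spec` overriding the default.
#' @return the preprocessed `n x channels` matrix.
#' @export
preprocess_stream <- function(session, stream, spec = NULL) {
  if (!stream %in% names(session$streams)) {
    stop("Session has no stream named '", stream, "'.", call. = FALSE)
  }
  x <- session$streams[[stream]]
  if (is.null(spec)) spec <- default_filter(stream, session$sample_rate)
  if (is.null(spec)) x else butterworth_filter(x, spec)
}
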