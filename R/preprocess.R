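#' Band-pass filter specification
#'
#' Realizes the call-band filter used throughout the pipeline: a Butterworth
#' band-pass of the given order, applied forward-backward (zero phase) so
#' call onsets are not delayed. The default 15-30 Hz band brackets the
#' Antarctic blue whale Z-call fundamental.
#'
#' @param f_low,f_high band edges in Hz; must satisfy
#'   `0 < f_low < f_high < rate/2`.
#' @param order filter order (default 4).
#' @param rate sampling rate of the audio the filter will be applied to.
#' @return object of class `filter_spec` holding the band, order, rate and
#'   realized `signal::butter` coefficients.
#' @export
filter_spec <- function(f_low = 15, f_high = 30, order = 4, rate = 1000) {
  if (!(f_low > 0 && f_low < f_high && f_high < rate / 2))
    stop("band edges must satisfy 0 < f_low < f_high < rate/2")
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  coef <- signal::butter(order, c(f_low, f_high) / (rate / 2), type = "pass")
  structure(list(f_low = f_low, f_high = f_high, order = order,
                 rate = rate, coefficients = coef),
            class = "filter_spec")
}

#' Magnitude response of a realized filter
#'
#' @param spec a [filter_spec].
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param zero_phase if `TRUE` (default) return the forward-backward
#'   (filtfilt) gain, i.e. the squared one-pass magnitude, matching what
#'   [bandpass()] applies; if `FALSE` return the one-pass design magnitude.
#' @return numeric vector of linear magnitude gains.
#' @export
filter_response <- function(spec, freqs, zero_phase = TRUE) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- 2 * pi * freqs / spec$rate
  z <- exp(-1i * w)
  num <- vapply(z, function(zz) sum(spec$coefficients$b * zz^(0:(length(spec$coefficients$b) - 1))), complex(1))
  den <- vapply(z, function(zz) sum(spec$coefficients$a * zz^(0:(length(spec$coefficients$a) - 1))), complex(1))
  h <- Mod(num / den)
  if (zero_phase) h^2 else h
}

#' Band-pass filter a recording
#'
#' Applies the zero-phase Butterworth band-pass described by `spec`,
#' removing energy outside the call band while preserving length and
#' timing.
#'
#' @param rec an [acoustic_recording].
#' @param spec a [filter_spec]; its rate must match the recording's.
#' @return the filtered [acoustic_recording].
#' @export
bandpass <- function(rec, spec = filter_spec(rate = rec$rate)) {
  stopifnot(inherits(rec, "acoustic_recording"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(spec$rate, rec$rate)))
    stop("filter_spec rate (", spec$rate, ") does not match recording rate (",
         rec$rate, ")")
  if (length(rec$samples) < 3 * spec$order)
    stop("recording shorter than the filter warm-up (need >= 3*order samples)")
  y <- signal::filtfilt(spec$coefficients, rec$samples)
  acoustic_recording(y, rec$rate, annotations = rec$annotations,
                     source_id = rec$source_id)
}

#' Normalize a recording to unit peak amplitude
#'
#' Divides the waveform by its maximum absolute value so that
#' `max(abs(samples)) == 1` exactly, removing amplitude differences caused
#' by source distance or gain. Applied once per recording, after filtering.
#'
#' @param rec an [acoustic_recording] (or bare numeric vector).
#' @return the normalized recording (same class as the input).
#' @export
normalize <- function(rec) {
  x <- if (inherits(rec, "acoustic_recording")) rec$samples else rec
  peak <- max(abs(x))
  if (peak == 0) stop("cannot normalize an all-zero signal")
  z <- x / peak
  if (inherits(rec, "acoustic_recording"))
    acoustic_recording(z, rec$rate, annotations = rec$annotations,
                       source_id = rec$source_id)
  else z
}

#' Cut a recording into fixed-length non-overlapping windows
#'
#' Segments the normalized waveform into consecutive half-open windows
#' `[k*W, (k+1)*W)` of `window_s` seconds; the trailing remainder shorter
#' than one window is discarded. If the recording carries annotations, each
#' window is labeled by the annotation with the largest temporal overlap
#' (windows with no overlap, or ties, are labeled `"noise"`).
#'
#' @param rec an [acoustic_recording].
#' @param window_s window length in seconds (default 26, matched to the
#'   longest Z-call duration).
#' @return object of class `segment_set`: list with `segments` (an `s x L`
#'   matrix, one window per row), `window_s`, `rate`, `segment_labels`
#'   (`NULL` when the recording has no annotations).
#' @export
segment_recording <- function(rec, window_s = 26) {
  stopifnot(inherits(rec, "acoustic_recording"), window_s > 0)
  L <- floor(window_s * rec$rate)
  s <- length(rec$samples) %/% L
  if (s < 1)
    stop("recording (", signif(rec$duration_s, 4),
         " s) shorter than one window (", window_s, " s)")
  segs <- matrix(rec$samples[seq_len(s * L)], nrow = s, ncol = L, byrow = TRUE)
  labels <- NULL
  if (!is.null(rec$annotations) && nrow(rec$annotations) > 0) {
    ann <- rec$annotations
    labels <- vapply(seq_len(s), function(k) {
      w0 <- (k - 1) * window_s
      w1 <- k * window_s
      ov <- pmin(ann$end_s, w1) - pmax(ann$begin_s, w0)
      keep <- ov > 0
      if (!any(keep)) return("noise")
      by_label <- tapply(ov[keep], ann$label[keep], sum)
      top <- names(by_label)[by_label == max(by_label)]
      if (length(top) > 1) "noise" else top
    }, character(1))
  }
  structure(list(segments = segs, window_s = window_s, rate = rec$rate,
                 segment_labels = labels),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d windows of %g s (%d samples) at %g Hz\n",
              nrow(x$segments), x$window_s, ncol(x$segments), x$rate))
  if (!is.null(x$segment_labels)) {
    tab <- table(x$segment_labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a segment set as delimited text
#'
#' One window per row, tab-separated, with labels (if any) in a sidecar
#' column file.
#'
#' @param segs a `segment_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segs, path) {
  stopifnot(inherits(segs, "segment_set"))
  utils::write.table(segs$segments, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(segs$segment_labels))
    writeLines(segs$segment_labels, paste0(path, ".labels"))
  invisible(path)
}

#' Frequency grid spacing of a DFT analysis
#'
#' Spacing in Hz between adjacent DFT bins: `rate / nfft`. At a 1 kHz
#' sampling rate with a 2048-point DFT this is 0.488 Hz, the spectrogram
#' grid customary for annotating blue whale recordings.
#'
#' @param rate sampling rate in Hz.
#' @param nfft DFT length in samples.
#' @return bin spacing in Hz.
#' @export
dft_bin_spacing <- function(rate, nfft) {
  stopifnot(rate > 0, nfft >= 1)
  rate / nfft
}
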