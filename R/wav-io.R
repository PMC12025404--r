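#' Construct an acoustic recording
#'
#' Container for a mono sampled waveform with its sampling rate and optional
#' call annotations. Amplitudes are dimensionless floats; PCM integer input
#' is scaled to \[-1, 1\] on read.
#'
#' @param samples numeric vector of finite sample values.
#' @param rate sampling rate in samples/second.
#' @param annotations optional annotation data frame, see
#'   [read_annotations()].
#' @param source_id free-text identifier for provenance.
#' @return object of class `acoustic_recording` with fields `samples`,
#'   `rate`, `duration_s`, `annotations`, `source_id`.
#' @export
acoustic_recording <- function(samples, rate, annotations = NULL,
                               source_id = "") {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a positive number")
  if (!is.null(annotations)) annotations <- validate_annotations(annotations)
  structure(list(samples = samples, rate = rate,
                 duration_s = length(samples) / rate,
                 annotations = annotations, source_id = source_id),
            class = "acoustic_recording")
}

#' @export
print.acoustic_recording <- function(x, ...) {
  cat(sprintf("acoustic_recording: %.2f s at %g Hz (%d samples)%s\n",
              x$duration_s, x$rate, length(x$samples),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  if (!is.null(x$annotations))
    cat(sprintf("  %d annotations: %s\n", nrow(x$annotations),
                paste(unique(x$annotations$label), collapse = ", ")))
  invisible(x)
}

validate_annotations <- function(ann) {
  ann <- as.data.frame(ann)
  need <- c("begin_s", "end_s", "low_hz", "high_hz", "label")
  if (!all(need %in% names(ann)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  if (any(ann$begin_s < 0) || any(ann$begin_s >= ann$end_s))
    stop("annotations must satisfy 0 <= begin_s < end_s")
  ok <- is.na(ann$low_hz) | is.na(ann$high_hz) | ann$low_hz < ann$high_hz
  if (!all(ok)) stop("annotations must satisfy low_hz < high_hz")
  ann$label <- as.character(ann$label)
  ann[need]
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering the encodings used by passive
#' acoustic archives: 16- and 24-bit integer PCM and 32-bit IEEE float.
#' Integer samples are scaled by the full-scale magnitude (e.g. 32768 for
#' 16-bit) so a full-scale file maps to \[-1, 1\]. Multi-channel files are
#' reduced to channel 1 with a warning.
#'
#' @param path path to a `.wav` file.
#' @param source_id optional identifier; defaults to the file name.
#' @return an [acoustic_recording] with empty annotations.
#' @export
read_wav <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, size = 2,
                           endian = "little", signed = FALSE),
        rate = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))  # skip padded chunk
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0)
    stop("corrupt or empty WAV file: ", path)
  samples <- switch(
    as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2, size = 2,
                   endian = "little", signed = TRUE) / 32768,
    "24" = {
      n <- length(data_raw) %/% 3
      b <- matrix(as.integer(data_raw[seq_len(3 * n)]), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    },
    "32" = {
      if (fmt$audio_format == 3)
        readBin(data_raw, "double", length(data_raw) %/% 4, size = 4,
                endian = "little")
      else
        readBin(data_raw, "integer", length(data_raw) %/% 4, size = 4,
                endian = "little") / 2147483648
    },
    stop("unsupported WAV bit depth: ", fmt$bits))
  if (fmt$channels > 1) {
    warning("multi-channel WAV; keeping channel 1 of ", fmt$channels)
    samples <- samples[seq(1, length(samples), by = fmt$channels)]
  }
  acoustic_recording(samples, fmt$rate, source_id = source_id)
}

#' Write a recording as 16-bit PCM WAV
#'
#' Samples are clipped to \[-1, 1\] and scaled by 32767.
#'
#' @param rec an [acoustic_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "acoustic_recording"))
  x <- pmin(pmax(rec$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rec$rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read call annotations from a selection-table-style CSV
#'
#' Expected header: `begin_s,end_s,low_hz,high_hz,label`; times in seconds,
#' frequency bounds in Hz, label a call-type token (e.g. `BmAntZ`, `BmD`,
#' `noise`).
#'
#' @param path CSV path.
#' @return validated annotation data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  validate_annotations(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write call annotations as CSV
#'
#' @param ann annotation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(validate_annotations(ann), path, row.names = FALSE)
  invisible(path)
}
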