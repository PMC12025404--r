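#' Specify a synthetic blue whale call
#'
#' Call templates follow the stereotyped Antarctic repertoire:
#'
#' * `BmAntA` — the first Z-call unit, a near-tonal 25-27 Hz component of
#'   8-12 s;
#' * `BmAntB` — the ~2 s downsweep from about 27 Hz to 20 Hz;
#' * `BmAntZ` — the full three-part Z call (tonal A, downsweep, then a
#'   20-18 Hz tonal tail of 8-12 s; 18-26 s total);
#' * `BmD` — the variable non-song D call, a 22-106 Hz downsweep of 1-4 s.
#'
#' For `BmAntZ` the `part_durations_s` vector gives the three unit lengths
#' and `f_start`/`f_end` are ignored (the parts use their own envelopes).
#'
#' @param call_type one of `"BmAntA"`, `"BmAntB"`, `"BmAntZ"`, `"BmD"`.
#' @param f_start,f_end instantaneous frequency (Hz) at call start/end;
#'   defaults are type-specific.
#' @param duration_s call length in seconds (single-unit types).
#' @param amplitude peak amplitude in relative units.
#' @param part_durations_s for `BmAntZ`: durations of the three parts
#'   (default `c(10, 2, 10)`, total 22 s).
#' @return object of class `call_spec`.
#' @export
call_spec <- function(call_type = c("BmAntZ", "BmAntA", "BmAntB", "BmD"),
                      f_start = NULL, f_end = NULL, duration_s = NULL,
                      amplitude = 1, part_durations_s = c(10, 2, 10)) {
  call_type <- match.arg(call_type)
  defaults <- list(
    BmAntA = list(f_start = 26.5, f_end = 25.5, duration_s = 10),
    BmAntB = list(f_start = 25.5, f_end = 20.0, duration_s = 2),
    BmAntZ = list(f_start = NA, f_end = NA, duration_s = sum(part_durations_s)),
    BmD    = list(f_start = 106, f_end = 22, duration_s = 2))
  d <- defaults[[call_type]]
  spec <- list(call_type = call_type,
               f_start = if (is.null(f_start)) d$f_start else f_start,
               f_end = if (is.null(f_end)) d$f_end else f_end,
               duration_s = if (is.null(duration_s)) d$duration_s else duration_s,
               amplitude = amplitude,
               part_durations_s = part_durations_s)
  if (call_type == "BmAntZ") spec$duration_s <- sum(part_durations_s)
  if (spec$duration_s <= 0) stop("duration_s must be positive")
  structure(spec, class = "call_spec")
}

# linear-FM chirp with cosine-tapered onset/offset
lfm_chirp <- function(f0, f1, duration_s, rate, amplitude = 1,
                      taper_s = 0.5, phase0 = 0) {
  n <- max(1L, round(duration_s * rate))
  t <- (seq_len(n) - 1) / rate
  phase <- phase0 + 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * duration_s))
  x <- amplitude * cos(phase)
  taper_n <- min(round(taper_s * rate), n %/% 2)
  if (taper_n > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(taper_n) / taper_n))
    x[seq_len(taper_n)] <- x[seq_len(taper_n)] * ramp
    x[n - taper_n + seq_len(taper_n)] <- x[n - taper_n + seq_len(taper_n)] * rev(ramp)
  }
  x
}

#' Synthesize a call waveform
#'
#' Linear-FM tonal chirps with 0.5-s cosine-tapered onsets/offsets; the
#' three-part Z call concatenates a 25-27 Hz tonal, a downsweep to 20 Hz,
#' and an 18-20 Hz tonal tail.
#'
#' @param spec a [call_spec].
#' @param rate sampling rate in Hz.
#' @return numeric waveform of length `round(duration_s * rate)`.
#' @export
synth_call <- function(spec, rate) {
  stopifnot(inherits(spec, "call_spec"), rate > 0)
  fmax <- if (spec$call_type == "BmAntZ") 27 else max(spec$f_start, spec$f_end)
  if (fmax >= rate / 2)
    stop("call frequency ", fmax, " Hz is at or above Nyquist (rate ", rate, ")")
  if (spec$call_type == "BmAntZ") {
    p <- spec$part_durations_s
    c(lfm_chirp(26.5, 25.5, p[1], rate, spec$amplitude),
      lfm_chirp(25.5, 20.0, p[2], rate, spec$amplitude),
      lfm_chirp(20.0, 18.2, p[3], rate, spec$amplitude))
  } else {
    lfm_chirp(spec$f_start, spec$f_end, spec$duration_s, rate, spec$amplitude)
  }
}

# frequency bounds of a call template, for annotations
call_band <- function(spec) {
  if (spec$call_type == "BmAntZ") c(18, 27)
  else sort(c(spec$f_start, spec$f_end))
}

# draw a call spec with parameters jittered within the stereotyped envelopes
random_call_spec <- function(call_type) {
  switch(call_type,
    BmAntZ = call_spec("BmAntZ",
                       part_durations_s = c(stats::runif(1, 8, 12), 2,
                                            stats::runif(1, 8, 12)),
                       amplitude = stats::runif(1, 0.7, 1)),
    BmAntA = call_spec("BmAntA", duration_s = stats::runif(1, 8, 12),
                       amplitude = stats::runif(1, 0.7, 1)),
    BmAntB = call_spec("BmAntB", amplitude = stats::runif(1, 0.7, 1)),
    BmD    = call_spec("BmD", duration_s = stats::runif(1, 1, 4),
                       amplitude = stats::runif(1, 0.7, 1)),
    stop("unknown call type: ", call_type))
}

#' Generate seeded background noise
#'
#' White noise is i.i.d. Gaussian; pink noise is white noise shaped to a
#' 1/f amplitude spectrum in the frequency domain. Both are returned with
#' unit standard deviation. Uses the current RNG state.
#'
#' @param n number of samples.
#' @param kind `"white"` or `"pink"`.
#' @return numeric vector of length `n`.
#' @export
synth_noise <- function(n, kind = c("white", "pink")) {
  kind <- match.arg(kind)
  w <- stats::rnorm(n)
  if (kind == "white") return(w)
  spec <- stats::fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # symmetric freq index
  amp <- c(0, 1 / sqrt(f[-1]))
  x <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Specify a synthetic acoustic scene
#'
#' @param duration_s scene length in seconds.
#' @param rate sampling rate (default 1000 Hz, the archival rate for
#'   low-frequency whale recordings).
#' @param calls list of `list(onset_s =, spec =)` entries placing
#'   [call_spec]s in time.
#' @param noise_kind `"white"` or `"pink"`.
#' @param snr_db target in-band (15-30 Hz) signal-to-noise ratio in dB;
#'   `Inf` means no noise, `-Inf`/`NULL` calls are absent.
#' @param seed integer RNG seed controlling the noise realization.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(duration_s, rate = 1000, calls = list(),
                       noise_kind = c("white", "pink"), snr_db = 10,
                       seed = 1) {
  noise_kind <- match.arg(noise_kind)
  stopifnot(duration_s > 0, rate > 0)
  for (cl in calls) {
    if (cl$onset_s < 0 || cl$onset_s + cl$spec$duration_s > duration_s + 1e-9)
      stop("call at onset ", cl$onset_s, " s does not fit in the scene")
  }
  structure(list(duration_s = duration_s, rate = rate, calls = calls,
                 noise_kind = noise_kind, snr_db = snr_db, seed = seed),
            class = "scene_spec")
}

#' Render a synthetic scene to an annotated recording
#'
#' Calls are summed onto seeded background noise; the noise is scaled so
#' that the realized in-band (15-30 Hz) SNR equals `snr_db` (signal and
#' noise powers are measured after passing each through the default
#' call-band filter). Annotations record the exact onsets, offsets,
#' frequency bounds and labels. The same seed yields a bit-identical
#' waveform.
#'
#' @param spec a [scene_spec].
#' @return an [acoustic_recording] with annotations.
#' @export
synth_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- round(spec$duration_s * spec$rate)
  sig <- numeric(n)
  occupied <- numeric(n)
  ann <- list()
  for (cl in spec$calls) {
    w <- synth_call(cl$spec, spec$rate)
    i0 <- round(cl$onset_s * spec$rate)
    idx <- i0 + seq_along(w)
    idx <- idx[idx <= n]
    if (any(occupied[idx] > 0))
      warning("overlapping calls in scene at onset ", cl$onset_s, " s")
    sig[idx] <- sig[idx] + w[seq_along(idx)]
    occupied[idx] <- occupied[idx] + 1
    band <- call_band(cl$spec)
    ann[[length(ann) + 1L]] <- data.frame(
      begin_s = cl$onset_s, end_s = cl$onset_s + cl$spec$duration_s,
      low_hz = band[1], high_hz = band[2], label = cl$spec$call_type)
  }
  noise <- with_seed(spec$seed, synth_noise(n, spec$noise_kind))
  if (length(spec$calls) > 0 && is.infinite(spec$snr_db) && spec$snr_db > 0) {
    noise <- numeric(n)
  } else if (length(spec$calls) > 0 && is.finite(spec$snr_db)) {
    fs <- filter_spec(rate = spec$rate)
    p_sig <- mean(signal::filtfilt(fs$coefficients, sig)^2)
    p_noise <- mean(signal::filtfilt(fs$coefficients, noise)^2)
    noise <- noise * sqrt(p_sig / (p_noise * 10^(spec$snr_db / 10)))
  }
  x <- sig + noise
  annotations <- if (length(ann)) do.call(rbind, ann) else NULL
  acoustic_recording(x, spec$rate, annotations = annotations,
                     source_id = sprintf("synthetic scene seed=%d", spec$seed))
}

#' Generate a labeled synthetic benchmark
#'
#' Renders `n_scenes` single-window scenes (one call type or pure noise
#' each, onsets jittered within the window), preprocesses each through the
#' standard chain (band-pass, peak normalization, segmentation), pools the
#' windows, and returns a stratified seeded 70/30 train/test split. This is
#' the dataset every detector in the package is exercised on.
#'
#' @param n_scenes number of scenes (>= 10).
#' @param class_balance named numeric vector of class proportions over
#'   `{"BmAntA","BmAntB","BmAntZ","BmD","noise"}`; default half Z calls,
#'   half noise.
#' @param snr_db in-band SNR for call scenes (default 10 dB).
#' @param seed integer seed controlling scene draws and the split.
#' @param duration_s scene (and window) duration, default 26 s.
#' @param rate sampling rate, default 1000 Hz.
#' @param noise_kind background noise type.
#' @param train_frac training fraction of the split (default 0.7).
#' @return list with `segments` (a [segment_set] pooling all windows),
#'   `labels` (character, per window), `train_idx`, `test_idx`, and the
#'   generating parameters.
#' @export
make_benchmark <- function(n_scenes = 100,
                           class_balance = c(BmAntZ = 0.5, noise = 0.5),
                           snr_db = 10, seed = 1, duration_s = 26,
                           rate = 1000, noise_kind = "white",
                           train_frac = 0.7) {
  if (n_scenes < 10) stop("need at least 10 scenes")
  stopifnot(abs(sum(class_balance) - 1) < 1e-9)
  counts <- round(class_balance * n_scenes)
  counts[1] <- n_scenes - sum(counts[-1])
  if (any(counts < 2))
    stop("every class needs at least 2 scenes; got: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  classes <- rep(names(counts), counts)
  fs <- filter_spec(rate = rate)
  out <- with_seed(seed, {
    classes <- sample(classes)
    seg_rows <- vector("list", n_scenes)
    labels <- character(n_scenes)
    for (i in seq_len(n_scenes)) {
      cls <- classes[i]
      calls <- list()
      if (cls != "noise") {
        cs <- random_call_spec(cls)
        onset <- stats::runif(1, 0, max(0, duration_s - cs$duration_s))
        calls <- list(list(onset_s = onset, spec = cs))
      }
      sc <- scene_spec(duration_s, rate = rate, calls = calls,
                       noise_kind = noise_kind, snr_db = snr_db,
                       seed = sample.int(2^30, 1))
      rec <- normalize(bandpass(synth_scene(sc), fs))
      ss <- segment_recording(rec, window_s = duration_s)
      seg_rows[[i]] <- ss$segments[1, ]
      labels[i] <- cls
    }
    list(segments = do.call(rbind, seg_rows), labels = labels)
  })
  segs <- structure(list(segments = out$segments, window_s = duration_s,
                         rate = rate, segment_labels = out$labels),
                    class = "segment_set")
  split <- stratified_split(out$labels, train_frac, seed = seed + 1L)
  list(segments = segs, labels = out$labels,
       train_idx = split$train, test_idx = split$test,
       snr_db = snr_db, seed = seed, rate = rate, window_s = duration_s,
       noise_kind = noise_kind, class_balance = class_balance)
}

#' Stratified train/test split
#'
#' Seeded split preserving class proportions within one observation per
#' class.
#'
#' @param labels character vector of class labels.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1)
  with_seed(seed, {
    train <- integer(0)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_tr <- round(train_frac * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}
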