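test_that("Z-call synthesis respects the stereotyped duration envelope", {
  spec <- call_spec("BmAntZ")
  w <- synth_call(spec, 1000)
  expect_equal(length(w) / 1000, 22)             # 10 + 2 + 10, inside 18-26 s
  expect_equal(spec$duration_s, 22)
  long <- call_spec("BmAntZ", part_durations_s = c(12, 2, 12))
  expect_equal(sum(long$part_durations_s), 26)
  expect_error(synth_call(call_spec("BmD", f_start = 600), 1000), "Nyquist")
  expect_equal(synth_call(call_spec("BmAntA", amplitude = 0), 1000),
               rep(0, 10000))
})

test_that("the tonal unit peaks inside its 25-27 Hz band", {
  w <- synth_call(call_spec("BmAntA"), 1000)
  sp <- stats::spec.pgram(w, taper = 0, plot = FALSE, pad = 1)
  peak_hz <- sp$freq[which.max(sp$spec)] * 1000
  expect_gt(peak_hz, 25)
  expect_lt(peak_hz, 27)
})

test_that("scene rendering hits the requested in-band SNR", {
  sc <- scene_spec(30, calls = list(list(onset_s = 3,
                                         spec = call_spec("BmAntZ"))),
                   snr_db = 10, seed = 5)
  rec <- synth_scene(sc)
  # re-measure: signal-only and noise-only renderings of the same scene
  sig <- synth_scene(scene_spec(30, calls = sc$calls, snr_db = Inf, seed = 5))
  noise <- rec$samples - sig$samples
  fs <- filter_spec(rate = 1000)
  p_sig <- mean(signal::filtfilt(fs$coefficients, sig$samples)^2)
  p_noise <- mean(signal::filtfilt(fs$coefficients, noise)^2)
  measured <- 10 * log10(p_sig / p_noise)
  expect_lt(abs(measured - 10), 0.5)
  expect_equal(rec$annotations$label, "BmAntZ")
  expect_equal(rec$annotations$begin_s, 3)
  expect_equal(rec$annotations$end_s, 25)
})

test_that("empty scenes are pure noise and seeds give bit-identical audio", {
  sc0 <- scene_spec(10, calls = list(), seed = 3)
  rec0 <- synth_scene(sc0)
  expect_null(rec0$annotations)
  expect_equal(sd(rec0$samples), 1, tolerance = 0.1)
  expect_identical(synth_scene(sc0)$samples, rec0$samples)
  sc1 <- scene_spec(10, calls = list(), seed = 4)
  expect_false(identical(synth_scene(sc1)$samples, rec0$samples))
  expect_warning(synth_scene(scene_spec(30, calls = list(
    list(onset_s = 0, spec = call_spec("BmAntZ")),
    list(onset_s = 5, spec = call_spec("BmD"))), seed = 1)), "overlap")
})

test_that("band-pass interaction: Z calls pass, D-call energy is trimmed", {
  fs <- filter_spec(rate = 1000)
  z <- synth_call(call_spec("BmAntZ"), 1000)
  loss_db <- 20 * log10(rms(signal::filtfilt(fs$coefficients, z)) / rms(z))
  expect_gt(loss_db, -1)
  d <- synth_call(call_spec("BmD", f_start = 106, f_end = 22,
                            duration_s = 3), 1000)
  d_loss <- 20 * log10(rms(signal::filtfilt(fs$coefficients, d)) / rms(d))
  expect_lt(d_loss, -3)   # most of the sweep lies above the 30 Hz edge
})

test_that("pink noise carries more coarse-scale entropy than white", {
  set.seed(55)
  w <- synth_noise(4096, "white")
  p <- synth_noise(4096, "pink")
  expect_equal(sd(p), 1, tolerance = 1e-9)
  se_w <- sample_entropy(coarse_grain(w, 10), 2, 0.2 * sd(w), "standard")
  se_p <- sample_entropy(coarse_grain(p, 10), 2, 0.2 * sd(p), "standard")
  expect_gt(se_p, se_w)
})

test_that("benchmark generation is stratified, split and reproducible", {
  b <- make_benchmark(n_scenes = 12, seed = 2)
  expect_equal(length(b$labels), 12)
  expect_equal(sort(unique(b$labels)), c("BmAntZ", "noise"))
  expect_equal(as.numeric(table(b$labels)), c(6, 6))
  expect_equal(length(b$train_idx), 8)       # round(0.7 * 6) per class
  expect_equal(length(b$test_idx), 4)
  expect_length(intersect(b$train_idx, b$test_idx), 0)
  # class proportions preserved within one item
  expect_lte(abs(sum(b$labels[b$train_idx] == "BmAntZ") -
                 sum(b$labels[b$train_idx] == "noise")), 1)
  b2 <- make_benchmark(n_scenes = 12, seed = 2)
  expect_identical(b2$segments$segments, b$segments$segments)
  expect_identical(b2$labels, b$labels)
  expect_error(make_benchmark(n_scenes = 5), "at least 10")
  expect_error(make_benchmark(n_scenes = 20,
                              class_balance = c(BmAntZ = 0.97, noise = 0.03)),
               "at least 2")
})

test_that("100-scene split sizes follow the 70/30 allocation", {
  b <- get_benchmark100()
  expect_equal(length(b$train_idx), 70)
  expect_equal(length(b$test_idx), 30)
})

test_that("entropy profiles separate calls from noise with a large effect", {
  b <- get_benchmark100()           # 50 call + 50 noise windows at 10 dB
  fm <- get_mse_features100()
  prof <- rowMeans(fm)              # mean log-entropy across scales 1..12
  call_p <- prof[b$labels != "noise"]
  noise_p <- prof[b$labels == "noise"]
  pooled_sd <- sqrt((var(call_p) + var(noise_p)) / 2)
  cohens_d <- abs(mean(call_p) - mean(noise_p)) / pooled_sd
  expect_gt(cohens_d, 1)
})
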