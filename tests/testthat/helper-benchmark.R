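# Shared synthetic benchmark, built once per test session and cached so
# the detection, separability and ordering checks reuse the same feature
# extraction (the expensive step).
.bench_cache <- new.env(parent = emptyenv())

get_benchmark100 <- function() {
  if (is.null(.bench_cache$bench))
    .bench_cache$bench <- make_benchmark(n_scenes = 100, snr_db = 10,
                                         seed = 42)
  .bench_cache$bench
}

get_mse_features100 <- function() {
  if (is.null(.bench_cache$mse))
    .bench_cache$mse <- extract_features(get_benchmark100()$segments, "mse")
  .bench_cache$mse
}

get_pca_features100 <- function() {
  if (is.null(.bench_cache$pca))
    .bench_cache$pca <- extract_features(get_benchmark100()$segments, "pca")
  .bench_cache$pca
}
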