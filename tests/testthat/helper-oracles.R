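# Literal double-loop sample-entropy oracle, written directly from the
# defining equations and independent of the package's vectorized path:
# explicit embedding, explicit Chebyshev comparisons, explicit pair loops.
sampen_oracle <- function(x, m, r, norm_mode = "paper") {
  n <- length(x)
  M <- n - m + 1L
  emb <- function(mm) {
    MM <- n - mm + 1L
    mat <- matrix(0, MM, mm)
    for (i in seq_len(MM)) mat[i, ] <- x[i:(i + mm - 1L)]
    mat
  }
  count_pairs <- function(vecs) {
    MM <- nrow(vecs)
    cnt <- 0
    for (i in seq_len(MM - 1L)) {
      for (j in (i + 1L):MM) {
        d <- 0
        for (k in seq_len(ncol(vecs)))
          d <- max(d, abs(vecs[i, k] - vecs[j, k]))
        if (d <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  C_m <- count_pairs(emb(m))
  C_m1 <- count_pairs(emb(m + 1L))
  if (norm_mode == "paper") {
    T_m <- m * M / 2
    T_m1 <- (m + 1) * (M - 1) / 2
  } else {
    T_m <- M * (M - 1) / 2
    T_m1 <- (M - 1) * (M - 2) / 2
  }
  se <- if (C_m == 0 || C_m1 == 0) NaN else -log((C_m1 / T_m1) / (C_m / T_m))
  list(C_m = C_m, C_m1 = C_m1, T_m = T_m, T_m1 = T_m1, se = se)
}

# best-permutation agreement between two label vectors (small K)
best_label_agreement <- function(a, b) {
  la <- sort(unique(a))
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- 0
  for (p in perms(la)) {
    remap <- stats::setNames(p, la)
    best <- max(best, mean(remap[as.character(a)] == b))
  }
  best
}

make_tone <- function(freq, duration_s, rate, amplitude = 1) {
  amplitude * sin(2 * pi * freq * (seq_len(duration_s * rate) - 1) / rate)
}

rms <- function(x) sqrt(mean(x^2))
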