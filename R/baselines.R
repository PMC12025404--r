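#' Principal component features
#'
#' Mean-centered SVD projection of a feature (or segment) matrix; scores
#' are ordered by decreasing explained variance.
#'
#' @param X `s x d` matrix, observations in rows.
#' @param n_components number of components, `1 <= n <= min(s, d)`.
#' @return object of class `pca_result`: `components` (`d x n` orthonormal
#'   loadings), `explained_variance` (non-increasing), `projected`
#'   (`s x n` scores), `center`.
#' @export
pca_features <- function(X, n_components) {
  X <- as.matrix(X)
  s <- nrow(X); d <- ncol(X)
  if (s < 2) stop("need at least 2 observations")
  if (n_components < 1 || n_components > min(s, d))
    stop("n_components must be in 1..", min(s, d))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_avail <- ncol(pc$rotation)
  n_take <- min(n_components, n_avail)
  scores <- pc$x[, seq_len(n_take), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_take), drop = FALSE]
  vars <- pc$sdev[seq_len(n_take)]^2
  if (n_take < n_components) {
    # rank-deficient input: pad with zero-variance dimensions
    scores <- cbind(scores, matrix(0, s, n_components - n_take))
    vars <- c(vars, rep(0, n_components - n_take))
  }
  structure(list(components = loadings, explained_variance = vars,
                 projected = scores, center = pc$center),
            class = "pca_result")
}

#' Dynamic mode decomposition of a snapshot matrix
#'
#' Estimates the best-fit linear one-step operator between the time-shifted
#' snapshot matrices `X1` (first `T-1` columns) and `X2` (remaining
#' columns) through an SVD-truncated eigendecomposition. Modes are the
#' projected spatial eigenvectors `X1 V S^{-1} w = U w`; amplitudes solve
#' `b = pinv(Phi) x0` against the first snapshot.
#'
#' @param X `d x T` matrix of snapshots in columns, `T >= 2`.
#' @param rank retained SVD rank; default keeps singular values above
#'   `1e-10 * sigma_1`.
#' @return object of class `dmd_result`: `eigenvalues` (complex, length
#'   `rank`), `modes` (`d x rank` complex matrix), `amplitudes` (complex),
#'   `rank`, `singular_values`.
#' @export
dmd <- function(X, rank = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 snapshots")
  if (all(X == 0)) stop("zero snapshot matrix")
  T_ <- ncol(X)
  X1 <- X[, -T_, drop = FALSE]
  X2 <- X[, -1, drop = FALSE]
  sv <- svd(X1)
  keep <- sv$d > 1e-10 * sv$d[1]
  r_max <- max(1L, sum(keep))
  r <- if (is.null(rank)) r_max else min(as.integer(rank), length(sv$d))
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  Sinv <- diag(1 / sv$d[seq_len(r)], r)
  Atilde <- t(Conj(U)) %*% X2 %*% V %*% Sinv
  eg <- eigen(Atilde)
  modes <- U %*% eg$vectors                      # X1 V S^-1 w = U w
  b <- qr.solve(modes, as.complex(X[, 1]))
  structure(list(eigenvalues = eg$values, modes = modes, amplitudes = b,
                 rank = r, singular_values = sv$d),
            class = "dmd_result")
}

#' Reconstruct snapshots from a DMD fit
#'
#' `Phi diag(b) Vandermonde(lambda)`: for exactly low-rank linear data this
#' reproduces the first `n_steps` snapshots.
#'
#' @param fit a `dmd_result`.
#' @param n_steps number of snapshots to reconstruct.
#' @return complex `d x n_steps` matrix.
#' @export
dmd_reconstruct <- function(fit, n_steps) {
  stopifnot(inherits(fit, "dmd_result"))
  vand <- outer(fit$eigenvalues, 0:(n_steps - 1), `^`)
  fit$modes %*% (vand * fit$amplitudes)
}

#' Per-segment DMD features
#'
#' Each window is reshaped into a `frame_len x T` snapshot matrix (columns
#' are consecutive sub-frames) and decomposed; the features are the
#' magnitudes and normalized angular frequencies of the `n_modes` leading
#' eigenvalues (ordered by amplitude-weighted modulus), giving a
#' `2 * n_modes`-dimensional dynamic signature per window that feeds the
#' same mixture back-end as the entropy features.
#'
#' @param segs a [segment_set] or segment matrix (windows in rows).
#' @param frame_len sub-frame length in samples (default 250, i.e. 0.25 s
#'   at 1 kHz).
#' @param n_modes number of leading modes (default 6).
#' @return `s x (2 n_modes)` numeric matrix.
#' @export
dmd_features <- function(segs, frame_len = 250, n_modes = 6) {
  if (inherits(segs, "segment_set")) segs <- segs$segments
  segs <- as.matrix(segs)
  T_ <- ncol(segs) %/% frame_len
  if (T_ < 3) stop("segments too short for frame_len = ", frame_len)
  out <- matrix(0, nrow(segs), 2 * n_modes,
                dimnames = list(NULL, c(paste0("mod", seq_len(n_modes)),
                                        paste0("freq", seq_len(n_modes)))))
  for (k in seq_len(nrow(segs))) {
    snap <- matrix(segs[k, seq_len(T_ * frame_len)], nrow = frame_len)
    fit <- tryCatch(dmd(snap, rank = min(n_modes * 2, T_ - 1)),
                    error = function(e) NULL)
    if (is.null(fit)) next   # e.g. an all-zero window: features stay 0
    strength <- Mod(fit$amplitudes) * Mod(fit$eigenvalues)
    ord <- order(strength, decreasing = TRUE)
    top <- ord[seq_len(min(n_modes, length(ord)))]
    mods <- Mod(fit$eigenvalues[top])
    freqs <- abs(Arg(fit$eigenvalues[top])) / pi
    out[k, seq_along(mods)] <- mods
    out[k, n_modes + seq_along(freqs)] <- freqs
  }
  out
}

# Morlet CWT (omega0 = 6) via FFT, unit-energy scale normalization.
# Returns list(coef = scales x time complex matrix, freqs = Hz per scale).
morlet_cwt <- function(x, rate, freqs) {
  n <- length(x)
  omega0 <- 6
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))  # wavelength/scale
  scales <- rate / (freqs * fourier_factor)                  # in samples
  xh <- stats::fft(x)
  w <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  coef <- matrix(0i, length(scales), n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    psi_hat <- pi^(-1 / 4) * sqrt(2 * pi * a) * exp(-0.5 * (a * w - omega0)^2) *
      (w > 0)
    coef[i, ] <- stats::fft(xh * psi_hat, inverse = TRUE) / n
  }
  list(coef = coef, freqs = freqs, scales = scales)
}

#' Continuous-wavelet spectral features
#'
#' Morlet CWT over scales mapped to `freq_range`, from which three
#' time-resolved features are assembled per frame: the smoothed, z-scored
#' energy `E(t)` (moving average of `|CWT|^2` over `smoothing_N` samples,
#' averaged across scales), the spectral centroid `F(t)` (energy-weighted
#' mean frequency, Hz), and the base-2 entropy `H(t)` of the per-frame
#' energy distribution across scales (bounded by `log2(n_scales)`).
#' Frames with zero total energy get `NaN` centroid/entropy sentinels.
#'
#' @param x numeric waveform.
#' @param rate sampling rate (Hz).
#' @param freqs analysis frequencies in Hz (default 24 log-spaced values
#'   covering 10-120 Hz, bracketing both Z- and D-call bands).
#' @param smoothing_N moving-average span in samples for the energy
#'   feature (default 0.5 s of samples).
#' @return object of class `wavelet_features`: `wf` (`T x 3` matrix with
#'   columns `E`, `F`, `H`), `p` (scales-by-time energy distribution),
#'   `freqs`, `smoothing_N`.
#' @export
wavelet_features <- function(x, rate, freqs = NULL, smoothing_N = NULL) {
  x <- as.numeric(x)
  if (is.null(freqs)) freqs <- exp(seq(log(10), log(120), length.out = 24))
  if (any(freqs >= rate / 2)) stop("analysis frequencies must be below Nyquist")
  if (is.null(smoothing_N)) smoothing_N <- max(1L, round(0.5 * rate))
  if (length(x) <= smoothing_N) stop("signal shorter than the smoothing span")
  cw <- morlet_cwt(x, rate, freqs)
  energy <- Mod(cw$coef)^2                       # scales x time
  kern <- rep(1 / smoothing_N, smoothing_N)
  E_sm <- t(apply(energy, 1, function(row)
    stats::filter(row, kern, sides = 2, circular = TRUE)))
  E_z <- (E_sm - mean(E_sm)) / stats::sd(E_sm)
  tot <- colSums(energy)
  p <- sweep(energy, 2, tot, "/")
  Ft <- colSums(energy * freqs) / tot
  Ht <- -colSums(ifelse(p > 0, p * log2(p), 0))
  zero <- tot == 0
  Ft[zero] <- NaN
  Ht[zero] <- NaN
  p[, zero] <- NaN
  wf <- cbind(E = colMeans(E_z), F = Ft, H = Ht)
  structure(list(wf = wf, p = p, freqs = freqs, smoothing_N = smoothing_N),
            class = "wavelet_features")
}

#' Per-segment wavelet features
#'
#' Time-averages of the wavelet `E`, `F`, `H` features over each window,
#' giving an `s x 3` matrix shaped like the entropy features. `NaN`
#' sentinel frames (zero energy) are dropped from the averages.
#'
#' @param segs a [segment_set] or segment matrix.
#' @param rate sampling rate; taken from the segment set when available.
#' @param ... passed to [wavelet_features()].
#' @return `s x 3` numeric matrix with columns `E`, `F`, `H`.
#' @export
wf_features <- function(segs, rate = NULL, ...) {
  if (inherits(segs, "segment_set")) {
    if (is.null(rate)) rate <- segs$rate
    segs <- segs$segments
  }
  if (is.null(rate)) stop("rate must be given for a bare segment matrix")
  segs <- as.matrix(segs)
  out <- matrix(0, nrow(segs), 3, dimnames = list(NULL, c("E", "F", "H")))
  for (k in seq_len(nrow(segs))) {
    wf <- wavelet_features(segs[k, ], rate, ...)$wf
    out[k, ] <- colMeans(wf[is.finite(rowSums(wf)), , drop = FALSE])
  }
  out
}
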