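#' Coarse-grain a signal segment
#'
#' Replaces consecutive non-overlapping blocks of `tau` samples by their
#' mean, producing the scale-`tau` coarse-grained series used by multiscale
#' sample entropy. At `tau = 1` the segment is returned unchanged; a partial
#' trailing block is dropped.
#'
#' @param x numeric vector, one signal segment.
#' @param tau positive integer scale factor.
#' @return numeric vector of length `floor(length(x)/tau)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5, 6), 2)  # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, tau) {
  stopifnot(is.numeric(x))
  if (length(tau) != 1L || tau < 1 || tau != round(tau))
    stop("`tau` must be a positive integer")
  if (tau > length(x))
    stop("`tau` exceeds the segment length")
  tau <- as.integer(tau)
  if (tau == 1L) return(as.numeric(x))
  L <- (length(x) %/% tau) * tau
  colMeans(matrix(x[seq_len(L)], nrow = tau))
}

#' Build the delay-embedding matrix of a series
#'
#' Slides a window of length `m` one step at a time along `x`, stacking the
#' windows as rows: row `i` is `x[i..(i+m-1)]`.
#'
#' @param x numeric vector.
#' @param m embedding dimension (template length).
#' @return an `(length(x) - m + 1) x m` numeric matrix.
#' @export
embed_series <- function(x, m) {
  stopifnot(is.numeric(x), m >= 1, m == round(m))
  M <- length(x) - m + 1L
  if (M < 2L) stop("series too short for embedding dimension m")
  out <- matrix(0, nrow = M, ncol = m)
  for (k in seq_len(m)) out[, k] <- x[k:(k + M - 1L)]
  out
}

#' Chebyshev (maximum-coordinate) distance between two vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return `max(abs(u - v))`.
#' @export
chebyshev_dist <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  max(abs(u - v))
}

#' Count template matches for sample entropy
#'
#' Counts the unordered pairs of `m`-dimensional embedding vectors of `x`
#' whose Chebyshev distance is at most `r_abs` (`C_m`), and likewise among
#' the `(m+1)`-dimensional vectors (`C_m1`), then converts the counts into
#' the probabilistic parameters `P_m` and `P_m1` under one of two
#' normalization conventions:
#'
#' * `"paper"`: `T_m = m * M / 2` and `T_m1 = (m + 1) * (M - 1) / 2`, where
#'   `M = length(x) - m + 1` is the number of `m`-templates;
#' * `"standard"`: the unordered pair counts `M (M - 1) / 2` and
#'   `(M - 1)(M - 2) / 2`, the usual sample-entropy normalizer.
#'
#' Both modes use the same match counts; only the denominator differs, so
#' `-log(P_m1 / P_m)` changes by a known constant offset between modes.
#'
#' @param x numeric vector (a coarse-grained segment).
#' @param m embedding dimension.
#' @param r_abs absolute Chebyshev tolerance (> 0).
#' @param norm_mode `"paper"` or `"standard"`.
#' @return list with `C_m`, `C_m1`, `T_m`, `T_m1`, `P_m`, `P_m1`, `M`,
#'   `r_abs`, `norm_mode`.
#' @export
count_matches <- function(x, m = 2, r_abs, norm_mode = c("paper", "standard")) {
  norm_mode <- match.arg(norm_mode)
  stopifnot(is.numeric(x), r_abs > 0)
  M <- length(x) - m + 1L
  if (M < 3L) stop("too few embedding vectors: need length(x) >= m + 2")
  cc <- .sampen_counts_cpp(as.numeric(x), as.integer(m), as.numeric(r_abs))
  if (norm_mode == "paper") {
    T_m  <- m * M / 2
    T_m1 <- (m + 1) * (M - 1) / 2
  } else {
    T_m  <- M * (M - 1) / 2
    T_m1 <- (M - 1) * (M - 2) / 2
  }
  list(C_m = cc$C_m, C_m1 = cc$C_m1, T_m = T_m, T_m1 = T_m1,
       P_m = cc$C_m / T_m, P_m1 = cc$C_m1 / T_m1,
       M = M, r_abs = r_abs, norm_mode = norm_mode)
}

#' Sample entropy of a series
#'
#' `-log(P_m1 / P_m)`: the negative log conditional probability that
#' templates matching for `m` points (within Chebyshev tolerance `r_abs`)
#' still match when extended by one point. Higher values indicate a more
#' irregular series. When either match count is zero the quantity is
#' undefined and `NaN` is returned (flagged with attribute
#' `undefined = TRUE`); [mse_matrix()] imputes such entries.
#'
#' @inheritParams count_matches
#' @return scalar entropy value, or `NaN` if no matches were found.
#' @export
sample_entropy <- function(x, m = 2, r_abs, norm_mode = c("paper", "standard")) {
  cm <- count_matches(x, m = m, r_abs = r_abs, norm_mode = norm_mode)
  if (cm$C_m == 0 || cm$C_m1 == 0) {
    return(structure(NaN, undefined = TRUE))
  }
  -log(cm$P_m1 / cm$P_m)
}

#' Multiscale sample entropy feature matrix
#'
#' Computes sample entropy of every segment at coarse-graining scales
#' `1..tau_max`, giving one `s x tau_max` complexity profile per recording
#' window. The tolerance for segment `k` is `r_coef` times the standard
#' deviation of its original (scale-1) samples and is held fixed across
#' scales, so entropy changes across scales reflect structure, not
#' renormalization. Undefined entries (no template matches) are imputed
#' with the maximum finite value of their scale column, preserving their
#' "maximally irregular" reading.
#'
#' @param segs a [segment_set] or a numeric matrix with one segment per row.
#' @param m embedding dimension (default 2).
#' @param r_coef tolerance as a fraction of the segment standard deviation
#'   (default 0.2; values up to 0.5 are customary).
#' @param tau_max maximum scale factor (default 12).
#' @param norm_mode match-count normalization, see [count_matches()].
#' @return an object of class `mse_matrix`: list with `values` (`s x
#'   tau_max`), `log_values` (`log(1 + values)`, the input to the mixture
#'   model), `m`, `r_coef`, `tau_max`, `norm_mode`, `n_imputed`,
#'   `segment_labels`.
#' @export
mse_matrix <- function(segs, m = 2, r_coef = 0.2, tau_max = 12,
                       norm_mode = c("paper", "standard")) {
  norm_mode <- match.arg(norm_mode)
  labels <- NULL
  if (inherits(segs, "segment_set")) {
    labels <- segs$segment_labels
    segs <- segs$segments
  }
  segs <- as.matrix(segs)
  s <- nrow(segs)
  L <- ncol(segs)
  if (L %/% tau_max < m + 2)
    stop("segments too short for tau_max = ", tau_max,
         ": floor(L/tau_max) must be >= m + 2")
  vals <- matrix(NA_real_, nrow = s, ncol = tau_max,
                 dimnames = list(NULL, paste0("SE", seq_len(tau_max))))
  for (k in seq_len(s)) {
    seg <- segs[k, ]
    r_abs <- r_coef * stats::sd(seg)
    if (!is.finite(r_abs) || r_abs <= 0) {
      # constant segment: zero tolerance is degenerate, flag whole row
      vals[k, ] <- NaN
      next
    }
    for (eta in seq_len(tau_max)) {
      vals[k, eta] <- sample_entropy(coarse_grain(seg, eta), m = m,
                                     r_abs = r_abs, norm_mode = norm_mode)
    }
  }
  n_imputed <- sum(!is.finite(vals))
  if (n_imputed > 0) {
    for (eta in seq_len(tau_max)) {
      bad <- !is.finite(vals[, eta])
      if (any(bad)) {
        fin <- vals[!bad, eta]
        fill <- if (length(fin)) max(fin) else {
          allfin <- vals[is.finite(vals)]
          if (length(allfin)) max(allfin) else 0
        }
        vals[bad, eta] <- fill
      }
    }
  }
  structure(list(values = vals, log_values = log1p(vals),
                 m = m, r_coef = r_coef, tau_max = tau_max,
                 norm_mode = norm_mode, n_imputed = n_imputed,
                 segment_labels = labels),
            class = "mse_matrix")
}

#' @export
print.mse_matrix <- function(x, ...) {
  cat(sprintf("MSE feature matrix: %d segments x %d scales (m = %d, r = %.2f sd, %s normalization)\n",
              nrow(x$values), x$tau_max, x$m, x$r_coef, x$norm_mode))
  if (x$n_imputed > 0)
    cat(sprintf("  %d undefined entries imputed by column maximum\n", x$n_imputed))
  invisible(x)
}
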