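#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Full-covariance GMM fitted by EM with k-means initialization, ridge
#' regularization of the covariances, and multiple seeded restarts; the
#' restart with the highest final log-likelihood is returned. The
#' log-likelihood is non-decreasing across EM iterations.
#'
#' @param X numeric matrix, observations in rows.
#' @param K number of mixture components.
#' @param seed integer seed controlling initialization.
#' @param reg ridge added to each covariance diagonal (default 1e-6).
#' @param tol convergence tolerance on the relative log-likelihood change
#'   (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param n_init number of restarts (default 5).
#' @return object of class `whale_gmm`: `weights`, `means` (`K x d`),
#'   `covariances` (`d x d x K`), `K`, `d`, `loglik`, `loglik_trace`,
#'   `converged`, `seed`, `class_map` (`NULL` until attached by
#'   [map_components_to_classes()]).
#' @export
fit_gmm <- function(X, K, seed = 1, reg = 1e-6, tol = 1e-6,
                    max_iter = 500, n_init = 5) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  n <- nrow(X); d <- ncol(X)
  if (K < 1 || K != round(K)) stop("K must be a positive integer")
  if (K > n) stop("K = ", K, " exceeds the number of observations (", n, ")")
  if (n <= K * d)
    warning("few observations (", n, ") for K*d = ", K * d,
            " mixture parameters; fit may be unstable")
  if (K == 1) {
    mu <- matrix(colMeans(X), nrow = 1)
    Sigma <- array(stats::cov(X) * (n - 1) / n + diag(reg, d), c(d, d, 1))
    ll <- sum(dmvnorm_log(X, mu[1, ], Sigma[, , 1]))
    return(structure(list(weights = 1, means = mu, covariances = Sigma,
                          K = 1L, d = d, loglik = ll, loglik_trace = ll,
                          converged = TRUE, seed = seed, class_map = NULL),
                     class = "whale_gmm"))
  }
  best <- NULL
  for (init in seq_len(n_init)) {
    fit <- with_seed(seed + init - 1L,
                     em_run(X, K, reg = reg, tol = tol, max_iter = max_iter))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts failed")
  best$seed <- seed
  best$class_map <- NULL
  structure(best, class = "whale_gmm")
}

# one EM run from a k-means initialization (uses the current RNG state)
em_run <- function(X, K, reg, tol, max_iter) {
  n <- nrow(X); d <- ncol(X)
  km <- tryCatch(stats::kmeans(X, centers = K, nstart = 1, iter.max = 50),
                 error = function(e) NULL)
  assign0 <- if (is.null(km)) sample(rep_len(seq_len(K), n)) else km$cluster
  weights <- as.numeric(table(factor(assign0, levels = seq_len(K)))) / n
  weights[weights == 0] <- 1 / n
  weights <- weights / sum(weights)
  means <- matrix(0, K, d)
  covariances <- array(0, c(d, d, K))
  gcov <- stats::cov(X) * (n - 1) / n + diag(reg, d)
  for (j in seq_len(K)) {
    idx <- which(assign0 == j)
    means[j, ] <- if (length(idx)) colMeans(X[idx, , drop = FALSE]) else
      X[sample.int(n, 1), ]
    covariances[, , j] <- if (length(idx) > d)
      stats::cov(X[idx, , drop = FALSE]) * (length(idx) - 1) / length(idx) +
        diag(reg, d)
    else gcov
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E step in log space
    logdens <- matrix(0, n, K)
    for (j in seq_len(K))
      logdens[, j] <- log(weights[j]) + dmvnorm_log(X, means[j, ],
                                                    covariances[, , j])
    mx <- apply(logdens, 1, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logdens - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M step
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    weights <- nk / n
    means <- (t(resp) %*% X) / nk
    for (j in seq_len(K)) {
      Xc <- sweep(X, 2, means[j, ])
      covariances[, , j] <- crossprod(Xc * resp[, j], Xc) / nk[j] + diag(reg, d)
    }
  }
  list(weights = weights, means = means, covariances = covariances,
       K = as.integer(K), d = d, loglik = ll, loglik_trace = trace,
       converged = converged)
}

# log density of rows of X under N(mu, Sigma); errors if Sigma is singular
# beyond repair
dmvnorm_log <- function(X, mu, Sigma) {
  d <- length(mu)
  ch <- tryCatch(chol(Sigma), error = function(e)
    tryCatch(chol(Sigma + diag(1e-8, d)), error = function(e2)
      stop("singular covariance matrix despite regularization")))
  Xc <- sweep(as.matrix(X), 2, mu)
  z <- forwardsolve(t(ch), t(Xc))
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
}

#' @export
print.whale_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d components in %d dimensions (loglik %.2f%s)\n",
              x$K, x$d, x$loglik, if (x$converged) "" else ", not converged"))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  if (!is.null(x$class_map))
    cat("  class map:", paste(sprintf("%d->%s", seq_along(x$class_map),
                                      x$class_map), collapse = ", "), "\n")
  invisible(x)
}

#' Bayesian information criterion of a fitted mixture
#'
#' `-2 log L + k log n` with `k = (K - 1) + K d + K d (d + 1) / 2` free
#' parameters (weights, means, full covariances); lower is better.
#'
#' @param model a `whale_gmm`.
#' @param X the data matrix the criterion is evaluated on.
#' @return scalar BIC value.
#' @export
gmm_bic <- function(model, X) {
  stopifnot(inherits(model, "whale_gmm"))
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("dimension mismatch")
  ll <- sum(loglik_rows(model, X))
  k <- (model$K - 1) + model$K * model$d +
    model$K * model$d * (model$d + 1) / 2
  -2 * ll + k * log(nrow(X))
}

loglik_rows <- function(model, X) {
  logdens <- component_logdens(model, X)
  mx <- apply(logdens, 1, max)
  mx + log(rowSums(exp(logdens - mx)))
}

component_logdens <- function(model, X, weighted = TRUE) {
  X <- as.matrix(X)
  out <- matrix(0, nrow(X), model$K)
  for (j in seq_len(model$K)) {
    out[, j] <- dmvnorm_log(X, model$means[j, ], model$covariances[, , j])
    if (weighted) out[, j] <- out[, j] + log(model$weights[j])
  }
  out
}

#' Choose the number of mixture components by BIC
#'
#' Fits a GMM for each candidate `K` and returns the one minimizing the
#' BIC; ties break toward the smallest `K`. Candidates whose fit fails
#' (e.g. degenerate data) are dropped with a message.
#'
#' @param X data matrix.
#' @param k_range candidate component counts (default `1:8`).
#' @param seed seed passed to [fit_gmm()].
#' @param ... further arguments to [fit_gmm()].
#' @return the selected `K` (integer), with attribute `bic` holding the
#'   per-candidate values.
#' @export
select_k <- function(X, k_range = 1:8, seed = 1, ...) {
  stopifnot(length(k_range) >= 1)
  k_range <- sort(unique(as.integer(k_range)))
  bics <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    fit <- tryCatch(suppressWarnings(fit_gmm(X, k_range[i], seed = seed, ...)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      message("fit failed for K = ", k_range[i], "; candidate dropped")
      next
    }
    bics[i] <- gmm_bic(fit, X)
  }
  if (all(is.na(bics))) stop("no candidate K could be fitted")
  best <- k_range[which.min(bics)]  # which.min takes the first (smallest K) tie
  structure(best, bic = stats::setNames(bics, k_range))
}

#' Posterior component membership probabilities
#'
#' Responsibilities `P(j | x_i)` of each mixture component for each row of
#' `X`, computed in log space for numerical stability; rows sum to 1.
#'
#' @param model a `whale_gmm`.
#' @param X data matrix with `model$d` columns.
#' @return `n x K` matrix of posterior probabilities.
#' @export
posteriors <- function(model, X) {
  stopifnot(inherits(model, "whale_gmm"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  if (ncol(X) != model$d) stop("dimension mismatch")
  logdens <- component_logdens(model, X)
  mx <- apply(logdens, 1, max)
  lse <- mx + log(rowSums(exp(logdens - mx)))
  exp(logdens - lse)
}

#' Rank features by mean posterior probability
#'
#' For a mixture fitted to a standardized feature matrix, computes the
#' mean posterior-weighted feature value `MPP(j, f) = mean_i P(j|x_i) *
#' x_{if}` for every component `j` and feature `f`. Because features are
#' centered, `|MPP(j, f)|` is large only when feature `f` separates
#' component `j` from the rest (in either direction), so features are
#' ordered by `max_j |MPP(j, f)|`, descending. Per-component scores
#' (`mean_f MPP(j, f)`) are reported for diagnostics. Zero-variance
#' features are excluded from the ranking with a message.
#'
#' @param model a `whale_gmm` fitted on `X_std`.
#' @param X_std the feature matrix the model was fitted on, standardized
#'   per feature (z-scores); see [scale_features()].
#' @return object of class `feature_ranking`: `mpp` (`K x d`),
#'   `feature_scores`, `feature_order` (a permutation of the feature
#'   indices), `component_scores`, `excluded` (indices of zero-variance
#'   features, ranked last).
#' @export
rank_features <- function(model, X_std) {
  stopifnot(inherits(model, "whale_gmm"))
  X_std <- as.matrix(X_std)
  post <- posteriors(model, X_std)
  s <- nrow(X_std)
  mpp <- t(post) %*% X_std / s                    # K x d
  dimnames(mpp) <- list(paste0("comp", seq_len(model$K)),
                        colnames(X_std))
  sds <- apply(X_std, 2, stats::sd)
  excluded <- which(sds == 0 | !is.finite(sds))
  scores <- apply(abs(mpp), 2, max)
  if (length(excluded)) {
    message("excluding ", length(excluded), " zero-variance feature(s) from ranking")
    scores[excluded] <- -Inf
  }
  ord <- order(scores, decreasing = TRUE)
  if (model$K == 1)
    message("K = 1: all posteriors are 1 and MPP reduces to centered feature means; ranking is uninformative")
  structure(list(mpp = mpp, feature_scores = scores, feature_order = ord,
                 component_scores = rowMeans(mpp), excluded = excluded),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("feature ranking (by max |MPP| across components):\n  ")
  cat(paste(x$feature_order, collapse = " "), "\n")
  invisible(x)
}

#' Reduce a feature matrix to its top-ranked columns
#'
#' Retains the `zeta` best columns of `X` in ranked order; columns are
#' exact copies of the source columns.
#'
#' @param X `s x d` feature matrix.
#' @param ranking a [rank_features()] result for the same feature set.
#' @param zeta number of features to keep, `1 <= zeta <= d`.
#' @return list with `values` (`s x zeta` matrix) and `selected_features`
#'   (source column indices).
#' @export
reduce_features <- function(X, ranking, zeta) {
  stopifnot(inherits(ranking, "feature_ranking"))
  X <- as.matrix(X)
  if (zeta < 1 || zeta > ncol(X)) stop("zeta must be in 1..", ncol(X))
  sel <- ranking$feature_order[seq_len(zeta)]
  list(values = X[, sel, drop = FALSE], selected_features = sel)
}

#' Standardize feature columns to z-scores
#'
#' Centers and scales each column; zero-variance columns are centered but
#' left unscaled. Centering/scaling vectors are attached as attributes so
#' new data can be standardized identically.
#'
#' @param X feature matrix.
#' @param center,scale optional vectors to reuse (e.g. from training data).
#' @return standardized matrix with attributes `center` and `scale`.
#' @export
scale_features <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  out <- sweep(sweep(X, 2, center), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Cluster observations by maximum a posteriori component
#'
#' Assigns each row to the mixture component with the largest posterior
#' probability; exact ties break toward the lowest component index.
#'
#' @param model a `whale_gmm`.
#' @param X data matrix.
#' @return integer component labels in `1..K`.
#' @export
map_cluster <- function(model, X) {
  post <- posteriors(model, X)
  max.col(post, ties.method = "first")
}

#' Map mixture components to class labels by training majority
#'
#' Each component is mapped to the majority true class among the training
#' observations assigned to it; a component with no members maps to
#' `"noise"`. Among per-component majority assignments this maximizes
#' training accuracy.
#'
#' @param clusters integer component labels on the training data (from
#'   [map_cluster()]).
#' @param true_labels aligned character class labels.
#' @param K number of components (default `max(clusters)`).
#' @return character vector: `class_map[j]` is the class of component `j`.
#' @export
map_components_to_classes <- function(clusters, true_labels,
                                      K = max(clusters)) {
  if (length(clusters) != length(true_labels))
    stop("clusters and true_labels must be aligned")
  if (length(true_labels) == 0) stop("no training labels")
  vapply(seq_len(K), function(j) {
    members <- true_labels[clusters == j]
    if (!length(members)) return("noise")
    tab <- table(members)
    names(tab)[which.max(tab)]
  }, character(1))
}

#' Maximum-likelihood classification under a fitted mixture
#'
#' Assigns each row to the component with the highest component density
#' `p(x | theta_j)` (mixing weights ignored), then translates the winning
#' component to its class token via the model's `class_map`. Ties break
#' toward the lowest component index.
#'
#' @param model a `whale_gmm` with a `class_map` attached (see
#'   [map_components_to_classes()]).
#' @param X data matrix (or a single feature vector).
#' @return character class labels.
#' @export
ml_classify <- function(model, X) {
  stopifnot(inherits(model, "whale_gmm"))
  if (is.null(model$class_map))
    stop("model has no component-to-class map; attach one via map_components_to_classes()")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  logdens <- component_logdens(model, X, weighted = FALSE)
  comp <- max.col(logdens, ties.method = "first")
  if (any(comp > length(model$class_map)))
    stop("component without a class mapping")
  model$class_map[comp]
}

#' Serialize a fitted mixture to portable JSON
#'
#' Writes weights, means, covariances, the component-to-class map, the
#' seed and feature metadata as plain text; [read_gmm()] restores an
#' identical model.
#'
#' @param model a `whale_gmm`.
#' @param path output path.
#' @param feature_meta optional list of feature metadata stored verbatim.
#' @return `path`, invisibly.
#' @export
write_gmm <- function(model, path, feature_meta = NULL) {
  stopifnot(inherits(model, "whale_gmm"))
  # matrices are flattened column-major so the JSON layout is unambiguous
  obj <- list(weights = model$weights, means = as.numeric(model$means),
              covariances = lapply(seq_len(model$K),
                                   function(j) as.numeric(model$covariances[, , j])),
              K = model$K, d = model$d, loglik = model$loglik,
              converged = model$converged, seed = model$seed,
              class_map = model$class_map, feature_meta = feature_meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a mixture written by [write_gmm()]
#'
#' @param path JSON path.
#' @return a `whale_gmm` (feature metadata in attribute `feature_meta`).
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- as.integer(obj$K); d <- as.integer(obj$d)
  covs <- array(0, c(d, d, K))
  cov_list <- if (is.matrix(obj$covariances))
    lapply(seq_len(K), function(j) obj$covariances[j, ]) else obj$covariances
  for (j in seq_len(K))
    covs[, , j] <- matrix(as.numeric(unlist(cov_list[[j]])), d, d)
  model <- structure(list(weights = as.numeric(obj$weights),
                          means = matrix(as.numeric(unlist(obj$means)), K, d),
                          covariances = covs, K = K, d = d,
                          loglik = obj$loglik, loglik_trace = NULL,
                          converged = obj$converged, seed = obj$seed,
                          class_map = if (is.null(obj$class_map)) NULL
                                      else as.character(obj$class_map)),
                     class = "whale_gmm")
  attr(model, "feature_meta") <- obj$feature_meta
  model
}
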