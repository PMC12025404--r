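#' Confusion counts
#'
#' With a `positive` class given, returns the binary 2x2 counts (all other
#' labels pooled as negative). Without one, returns one-vs-rest counts per
#' class plus their micro-average.
#'
#' @param truth,predicted aligned character label vectors.
#' @param positive the positive class token, or `NULL` for one-vs-rest.
#' @return for binary: list with `tp`, `tn`, `fp`, `fn`; otherwise a list
#'   of such lists per class plus `micro`.
#' @export
confusion <- function(truth, predicted, positive = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  truth <- as.character(truth); predicted <- as.character(predicted)
  count_one <- function(pos) {
    t_pos <- truth == pos; p_pos <- predicted == pos
    list(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
         fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
  }
  if (!is.null(positive)) return(count_one(positive))
  classes <- sort(unique(c(truth, predicted)))
  per_class <- lapply(classes, count_one)
  names(per_class) <- classes
  micro <- list(tp = sum(vapply(per_class, `[[`, 0, "tp")),
                tn = sum(vapply(per_class, `[[`, 0, "tn")),
                fp = sum(vapply(per_class, `[[`, 0, "fp")),
                fn = sum(vapply(per_class, `[[`, 0, "fn")))
  c(per_class, list(micro = micro))
}

#' Accuracy and error rate from confusion counts
#'
#' Accuracy is `(TP + TN) / (TP + FP + TN + FN)` and the error rate is
#' `(FN + FP)` over the same denominator, so the two always sum to exactly
#' one.
#'
#' @param counts a list with `tp`, `tn`, `fp`, `fn` (from [confusion()]).
#' @return list with `accuracy` and `error_rate`.
#' @export
accuracy_and_error <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("no evaluated observations")
  list(accuracy = (counts$tp + counts$tn) / total,
       error_rate = (counts$fn + counts$fp) / total)
}

#' Feature-feature and feature-target correlation analysis
#'
#' Pearson correlations between every pair of feature columns and between
#' each feature and a binary target class. Constant columns have undefined
#' correlation and are reported as `NA` with a message; an all-constant
#' target is an error.
#'
#' @param features `s x d` numeric matrix.
#' @param target binary class labels (logical, 0/1 numeric, or a character
#'   vector with exactly two levels — the alphabetically later level is
#'   coded 1).
#' @return object of class `correlation_table`: `feature_feature`
#'   (`d x d`, unit diagonal, symmetric), `feature_target` (length `d`).
#' @export
correlation_analysis <- function(features, target) {
  features <- as.matrix(features)
  if (nrow(features) < 3) stop("need at least 3 observations")
  if (is.character(target) || is.factor(target)) {
    lev <- sort(unique(as.character(target)))
    if (length(lev) != 2) stop("character target must have exactly two levels")
    target <- as.numeric(as.character(target) == lev[2])
  }
  target <- as.numeric(target)
  if (stats::sd(target) == 0) stop("target class is constant")
  if (nrow(features) != length(target))
    stop("features and target must be aligned")
  const <- apply(features, 2, stats::sd) == 0
  if (any(const))
    message("constant feature column(s) ", paste(which(const), collapse = ", "),
            ": correlation undefined, reported as NA")
  ff <- suppressWarnings(stats::cor(features))
  ft <- suppressWarnings(as.numeric(stats::cor(features, target)))
  diag(ff) <- ifelse(const, NA_real_, 1)
  structure(list(feature_feature = ff, feature_target = ft),
            class = "correlation_table")
}

#' Run one detection trial with the mixture back-end
#'
#' The shared back-end every feature extractor feeds (Algorithm: log/raw
#' features are standardized; a `K`-component mixture fitted on all
#' windows ranks the features by mean posterior probability; the top
#' `zeta` columns form the reduced matrix; a fresh mixture is fitted on
#' the reduced training rows, its components mapped to classes by training
#' majority, and the held-out rows classified by maximum likelihood).
#'
#' @param features `s x d` feature matrix (e.g. `mse_matrix()$log_values`).
#' @param labels character class labels per window.
#' @param train_idx,test_idx row indices of the split.
#' @param K mixture components (default 2: whale call vs other sound).
#' @param zeta number of features kept after ranking.
#' @param seed EM seed.
#' @param positive positive class for the confusion counts; with the
#'   default `"call"`, all non-`"noise"` labels are pooled into a single
#'   `"call"` class before training (binary detection).
#' @return list with `accuracy`, `error_rate`, `counts`, `predicted`,
#'   `selected_features`, `model`.
#' @export
run_detection_trial <- function(features, labels, train_idx, test_idx,
                                K = 2, zeta = 4, seed = 1,
                                positive = "call") {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (identical(positive, "call"))
    labels <- ifelse(labels == "noise", "noise", "call")
  zeta <- min(zeta, ncol(features))
  X_std <- scale_features(features)
  fit0 <- suppressWarnings(fit_gmm(X_std, K, seed = seed))
  ranking <- suppressMessages(rank_features(fit0, X_std))
  psi <- reduce_features(X_std, ranking, zeta)
  fit <- suppressWarnings(fit_gmm(psi$values[train_idx, , drop = FALSE],
                                  K, seed = seed))
  clusters <- map_cluster(fit, psi$values[train_idx, , drop = FALSE])
  fit$class_map <- map_components_to_classes(clusters, labels[train_idx],
                                             K = fit$K)
  pred <- ml_classify(fit, psi$values[test_idx, , drop = FALSE])
  counts <- confusion(labels[test_idx], pred, positive = positive)
  perf <- accuracy_and_error(counts)
  list(accuracy = perf$accuracy, error_rate = perf$error_rate,
       counts = counts, predicted = pred,
       selected_features = psi$selected_features, model = fit)
}

#' Summarize detection performance over repeated trials
#'
#' Re-runs the detection back-end over several seeds, each seed drawing a
#' fresh stratified train/test split and EM initialization (the features
#' themselves are fixed), and reports the mean, highest and lowest
#' accuracy and error rate.
#'
#' @param features `s x d` feature matrix.
#' @param labels character labels per window.
#' @param seeds integer vector, one per trial.
#' @param train_frac training fraction of each split (default 0.7).
#' @inheritParams run_detection_trial
#' @return object of class `detection_report`: `per_run` data frame and
#'   `mean`/`max`/`min` summaries of accuracy and error rate.
#' @export
multi_run_summary <- function(features, labels, seeds = 1:10, K = 2,
                              zeta = 4, train_frac = 0.7,
                              positive = "call") {
  stopifnot(length(seeds) >= 1)
  runs <- lapply(seeds, function(sd_i) {
    split <- stratified_split(as.character(labels), train_frac, seed = sd_i)
    tr <- run_detection_trial(features, labels, split$train, split$test,
                              K = K, zeta = zeta, seed = sd_i,
                              positive = positive)
    data.frame(seed = sd_i, accuracy = tr$accuracy,
               error_rate = tr$error_rate)
  })
  per_run <- do.call(rbind, runs)
  structure(list(
    per_run = per_run,
    mean = c(accuracy = mean(per_run$accuracy),
             error_rate = mean(per_run$error_rate)),
    max = c(accuracy = max(per_run$accuracy),
            error_rate = max(per_run$error_rate)),
    min = c(accuracy = min(per_run$accuracy),
            error_rate = min(per_run$error_rate)),
    n_runs = length(seeds), K = K, zeta = zeta),
    class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("Detection performance across %d trials (zeta = %d):\n",
              x$n_runs, x$zeta))
  cat(sprintf("  accuracy   mean %.2f%%  highest %.2f%%  lowest %.2f%%\n",
              100 * x$mean["accuracy"], 100 * x$max["accuracy"],
              100 * x$min["accuracy"]))
  cat(sprintf("  error rate mean %.2f%%  highest %.2f%%  lowest %.2f%%\n",
              100 * x$mean["error_rate"], 100 * x$max["error_rate"],
              100 * x$min["error_rate"]))
  invisible(x)
}

#' Extract per-window features by any of the four methods
#'
#' Dispatch over the package's extractors, always returning an `s x d`
#' matrix suitable for the mixture back-end:
#' `"mse"` gives `log(1 + MSE)` entropy profiles, `"pca"` principal
#' component scores of the raw windows, `"dmd"` dynamic-mode eigenvalue
#' signatures, `"wf"` wavelet energy/centroid/entropy averages.
#'
#' @param segs a [segment_set].
#' @param method one of `"mse"`, `"pca"`, `"dmd"`, `"wf"`.
#' @param m,r_coef,tau_max,norm_mode entropy parameters, see
#'   [mse_matrix()].
#' @param n_components PCA score count (default `tau_max`, so all methods
#'   enter the back-end with comparable width).
#' @param ... further arguments to the underlying extractor.
#' @return numeric feature matrix with attribute `method`.
#' @export
extract_features <- function(segs, method = c("mse", "pca", "dmd", "wf"),
                             m = 2, r_coef = 0.2, tau_max = 12,
                             norm_mode = "paper", n_components = tau_max,
                             ...) {
  method <- match.arg(method)
  out <- switch(method,
    mse = mse_matrix(segs, m = m, r_coef = r_coef, tau_max = tau_max,
                     norm_mode = norm_mode)$log_values,
    pca = {
      segmat <- if (inherits(segs, "segment_set")) segs$segments else as.matrix(segs)
      pca_features(segmat, min(n_components, nrow(segmat) - 1, ncol(segmat)))$projected
    },
    dmd = dmd_features(segs, ...),
    wf = wf_features(segs, ...))
  attr(out, "method") <- method
  out
}

#' Write a feature matrix with a metadata sidecar
#'
#' Tab-separated values, one window per row, plus `<path>.meta.json`
#' recording the extraction parameters.
#'
#' @param features feature matrix.
#' @param path output path.
#' @param meta named list of metadata (method, parameters, window, rate).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, meta = list()) {
  utils::write.table(as.matrix(features), path, sep = "\t",
                     row.names = FALSE,
                     col.names = !is.null(colnames(features)))
  if (is.null(meta$method)) meta$method <- attr(features, "method")
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path path to the TSV.
#' @return numeric matrix with attribute `meta` (the sidecar list, if
#'   present).
#' @export
read_features <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- any(grepl("[A-Za-z]", strsplit(first, "\t")[[1]]))
  out <- as.matrix(utils::read.table(path, sep = "\t", header = has_header))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path))
    attr(out, "meta") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  out
}
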