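test_that("single-component fit is the closed-form Gaussian", {
  set.seed(1)
  X <- matrix(rnorm(200 * 3), 200)
  fit <- fit_gmm(X, 1)
  expect_equal(fit$weights, 1)
  expect_equal(fit$means[1, ], colMeans(X))
  n <- nrow(X)
  expect_equal(fit$covariances[, , 1],
               cov(X) * (n - 1) / n + diag(1e-6, 3), tolerance = 1e-12)
})

test_that("EM recovers well-separated clusters with monotone log-likelihood", {
  set.seed(2)
  X <- rbind(matrix(rnorm(1000 * 2, mean = 5), 1000),
             matrix(rnorm(1000 * 2, mean = -5), 1000))
  fit <- fit_gmm(X, 2, seed = 3)
  mus <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(mus[1, ] - c(-5, -5))), 0.1)
  expect_lt(max(abs(mus[2, ] - c(5, 5))), 0.1)
  expect_true(all(diff(fit$loglik_trace) >= -1e-7 * abs(fit$loglik)))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_error(fit_gmm(X, 3000), "exceeds")
})

test_that("log density agrees with an independent multivariate normal", {
  skip_if_not_installed("mclust")
  set.seed(4)
  X <- matrix(rnorm(50 * 3), 50)
  mu <- c(0.5, -1, 2)
  Sigma <- crossprod(matrix(rnorm(9), 3)) + diag(0.5, 3)
  ours <- whalemse:::dmvnorm_log(X, mu, Sigma)
  ref <- mclust::dmvnorm(X, mu, Sigma, log = TRUE)
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("BIC uses the full-covariance free-parameter count", {
  set.seed(5)
  X <- matrix(rnorm(300), ncol = 1)
  fit <- fit_gmm(X, 1)
  ll <- sum(whalemse:::loglik_rows(fit, X))
  expect_equal(gmm_bic(fit, X), -2 * ll + 2 * log(300))  # k = 2 for K=1, d=1

  X2 <- matrix(rnorm(100 * 2), 100)
  fit2 <- suppressWarnings(fit_gmm(X2, 3, seed = 1, n_init = 1))
  k <- (3 - 1) + 3 * 2 + 3 * 2 * 3 / 2
  ll2 <- sum(whalemse:::loglik_rows(fit2, X2))
  expect_equal(gmm_bic(fit2, X2), -2 * ll2 + k * log(100))
})

test_that("BIC model selection returns the requested singleton and ties low", {
  set.seed(6)
  X <- matrix(rnorm(100 * 2), 100)
  expect_equal(as.integer(select_k(X, k_range = 4, seed = 1)), 4L)
  k <- suppressWarnings(select_k(X, k_range = 1:3, seed = 1))
  expect_true(as.integer(k) %in% 1:3)
  expect_length(attr(k, "bic"), 3)
})

test_that("posteriors normalize, respect symmetry and K = 1 degeneracy", {
  set.seed(7)
  X <- matrix(rnorm(40 * 2), 40)
  fit1 <- fit_gmm(X, 1)
  expect_equal(posteriors(fit1, X), matrix(1, 40, 1))

  # hand-built symmetric two-component model: the midpoint splits 50/50
  model <- structure(list(weights = c(0.5, 0.5),
                          means = rbind(c(-2, 0), c(2, 0)),
                          covariances = array(rep(diag(2), 2), c(2, 2, 2)),
                          K = 2L, d = 2L, loglik = NA, converged = TRUE,
                          seed = 1, class_map = NULL), class = "whale_gmm")
  expect_equal(posteriors(model, rbind(c(0, 3)))[1, ], c(0.5, 0.5))
  fit2 <- suppressWarnings(fit_gmm(X, 2, seed = 1, n_init = 1))
  expect_equal(rowSums(posteriors(fit2, X)), rep(1, 40), tolerance = 1e-9)
  expect_error(posteriors(fit2, matrix(c(1, NA), 1)), "finite")
})

test_that("MPP ranking puts the separating feature first", {
  set.seed(8)
  n <- 300
  grp <- rep(0:1, each = n / 2)
  X <- cbind(sep = grp * 6 + rnorm(n),      # 6 sd separation
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  X_std <- scale_features(X)
  fit <- suppressWarnings(fit_gmm(X_std, 2, seed = 2))
  rk <- rank_features(fit, X_std)
  expect_equal(dim(rk$mpp), c(2, 4))
  expect_equal(rk$feature_order[1], 1)
  expect_true(all(sort(rk$feature_order) == 1:4))

  # K = 1 on standardized features: MPP is the centered mean, ~0
  fit1 <- fit_gmm(X_std, 1)
  expect_message(rk1 <- rank_features(fit1, X_std), "uninformative")
  expect_equal(max(abs(rk1$mpp)), 0, tolerance = 1e-10)
})

test_that("feature reduction copies the selected columns in ranked order", {
  set.seed(9)
  X <- matrix(rnorm(50 * 4), 50)
  X_std <- scale_features(X)
  fit <- suppressWarnings(fit_gmm(X_std, 2, seed = 1, n_init = 1))
  rk <- rank_features(fit, X_std)
  red <- reduce_features(X, rk, 4)
  expect_equal(red$values, X[, rk$feature_order], ignore_attr = TRUE)
  red2 <- reduce_features(X, rk, 2)
  expect_equal(red2$values[, 1], X[, rk$feature_order[1]])
  expect_error(reduce_features(X, rk, 0), "zeta")
  expect_error(reduce_features(X, rk, 5), "zeta")
})

test_that("MAP clustering is deterministic and near-perfect at 6 sd", {
  set.seed(10)
  X <- rbind(matrix(rnorm(500), ncol = 1), matrix(rnorm(500, 6), ncol = 1))
  truth <- rep(1:2, each = 500)
  fit <- fit_gmm(X, 2, seed = 4)
  cl <- map_cluster(fit, X)
  expect_gte(best_label_agreement(cl, truth), 0.99)
  expect_identical(cl, map_cluster(fit, X))
  fit1 <- fit_gmm(X, 1)
  expect_true(all(map_cluster(fit1, X) == 1))
})

test_that("component-class mapping follows training majorities", {
  expect_equal(map_components_to_classes(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               c("a", "b"))
  # crossed majorities swap the map
  expect_equal(map_components_to_classes(c(2, 2, 2, 1, 1, 1),
                                         c("a", "a", "b", "b", "b", "a")),
               c("b", "a"))
  # empty component defaults to noise
  expect_equal(map_components_to_classes(c(1, 1), c("call", "call"), K = 2),
               c("call", "noise"))
  expect_error(map_components_to_classes(1:3, c("a", "b")), "aligned")

  # the majority map maximizes training accuracy among per-component
  # assignments: exhaustive check on a small example
  cl <- c(1, 1, 1, 2, 2, 2, 2)
  lab <- c("x", "x", "y", "y", "y", "x", "y")
  got <- map_components_to_classes(cl, lab)
  acc <- function(mp) mean(mp[cl] == lab)
  all_maps <- expand.grid(c("x", "y"), c("x", "y"), stringsAsFactors = FALSE)
  best <- max(apply(all_maps, 1, function(mp) acc(unname(mp))))
  expect_equal(acc(got), best)
})

test_that("ML classification honors the class map and agrees with MAP", {
  set.seed(11)
  X <- rbind(matrix(rnorm(400 * 2, -3), 400), matrix(rnorm(400 * 2, 3), 400))
  labels <- rep(c("noise", "call"), each = 400)
  fit <- fit_gmm(X, 2, seed = 5)
  expect_error(ml_classify(fit, X[1, ]), "class map")
  fit$class_map <- map_components_to_classes(map_cluster(fit, X), labels)
  # a point at a component mean takes that component's class
  expect_equal(ml_classify(fit, fit$means[1, ]), fit$class_map[1])
  # equal priors: ML and MAP agree almost everywhere
  agree <- mean(ml_classify(fit, X) == fit$class_map[map_cluster(fit, X)])
  expect_gte(agree, 0.95)
})

test_that("model serialization round trips through JSON", {
  set.seed(12)
  X <- matrix(rnorm(100 * 2), 100)
  fit <- suppressWarnings(fit_gmm(X, 2, seed = 1, n_init = 1))
  fit$class_map <- c("call", "noise")
  path <- withr::local_tempfile(fileext = ".json")
  write_gmm(fit, path, feature_meta = list(selected_features = c(2, 1)))
  back <- read_gmm(path)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$means, fit$means)
  expect_equal(back$covariances, fit$covariances)
  expect_equal(back$class_map, fit$class_map)
  expect_equal(attr(back, "feature_meta")$selected_features, c(2, 1))
  expect_equal(posteriors(back, X), posteriors(fit, X))
})

test_that("identical configuration and seed reproduce the whole back-end", {
  set.seed(13)
  X <- matrix(rnorm(120 * 5), 120)
  labels <- rep(c("call", "noise"), 60)
  split <- stratified_split(labels, 0.7, seed = 2)
  a <- run_detection_trial(X, labels, split$train, split$test, seed = 9)
  b <- run_detection_trial(X, labels, split$train, split$test, seed = 9)
  expect_identical(a$selected_features, b$selected_features)
  expect_identical(a$predicted, b$predicted)
  expect_identical(a$accuracy, b$accuracy)
})
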