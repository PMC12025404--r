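test_that("coarse-graining averages non-overlapping blocks", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  x <- rnorm(50)
  expect_equal(coarse_grain(x, 1), x)       # scale 1 = unaggregated data
  expect_length(coarse_grain(rnorm(10), 3), 3)  # trailing sample dropped
  expect_error(coarse_grain(rnorm(5), 6), "exceeds")
})

test_that("embedding slides a unit-stride window", {
  expect_equal(embed_series(c(1, 2, 3, 4), 2),
               rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(nrow(embed_series(1:5, 4)), 2)      # m = length - 1
  expect_equal(embed_series(c(3, 1, 4), 1), cbind(c(3, 1, 4)))
  expect_error(embed_series(1:3, 3), "too short")
})

test_that("Chebyshev distance is the max coordinate difference", {
  expect_equal(chebyshev_dist(c(1, 2), c(1, 2)), 0)
  expect_equal(chebyshev_dist(c(0, 3, 1), c(1, 1, 5)), 4)
  set.seed(9)
  for (i in 1:10) {
    u <- rnorm(4); v <- rnorm(4)
    expect_equal(chebyshev_dist(u, v), chebyshev_dist(v, u))
  }
  expect_error(chebyshev_dist(1:2, 1:3), "equal length")
})

test_that("match counting agrees with the double-loop oracle and its algebra", {
  # constant series: every pair matches at both template lengths
  cm <- count_matches(rep(5, 5), m = 2, r_abs = 0.1)
  expect_equal(cm$C_m, 6)    # all pairs of M = 4 vectors
  expect_equal(cm$C_m1, 3)   # all pairs of the 3 (m+1)-vectors

  # normalizer substitution: a length-100 series has M = 99 templates
  cm2 <- count_matches(rnorm(100), m = 2, r_abs = 0.5, norm_mode = "paper")
  expect_equal(cm2$T_m, 2 * (100 - 2 + 1) / 2)
  expect_equal(cm2$T_m1, 3 * (100 - 2) / 2)

  set.seed(11)
  x <- runif(60)
  for (mode in c("paper", "standard")) {
    got <- count_matches(x, m = 2, r_abs = 0.2 * sd(x), norm_mode = mode)
    want <- sampen_oracle(x, 2, 0.2 * sd(x), mode)
    expect_identical(got$C_m, want$C_m)
    expect_identical(got$C_m1, want$C_m1)
    expect_equal(got$T_m, want$T_m)
    expect_equal(got$T_m1, want$T_m1)
  }
})

test_that("sample entropy matches the oracle and flags undefined cases", {
  set.seed(21)
  x <- rnorm(100)
  for (mode in c("paper", "standard")) {
    expect_equal(sample_entropy(x, 2, 0.2 * sd(x), mode),
                 sampen_oracle(x, 2, 0.2 * sd(x), mode)$se,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(as.numeric(sample_entropy(rep(2, 30), 2, 0.5, "standard")), 0)
  # strictly monotone ramp with tiny tolerance: no matches anywhere
  se <- sample_entropy(seq(0, 10, length.out = 40), 2, 1e-6)
  expect_true(is.nan(se))
  expect_true(attr(se, "undefined"))
})

test_that("entropy is non-increasing in the tolerance and counts nest", {
  set.seed(31)
  x <- rnorm(150)
  rs <- seq(0.1, 1.2, by = 0.1) * sd(x)
  ses <- vapply(rs, function(r) sample_entropy(x, 2, r, "standard"), 0)
  expect_true(all(diff(ses) <= 1e-12))
  for (i in 1:10) {
    y <- rnorm(sample(40:120, 1))
    cm <- count_matches(y, m = sample(1:3, 1), r_abs = 0.3 * sd(y))
    expect_lte(cm$C_m1, cm$C_m)
    expect_lte(cm$C_m, cm$M * (cm$M - 1) / 2)
  }
})

test_that("white-noise entropy lands in its Monte-Carlo reference band", {
  # 99% band of standard-mode SampEn(m=2, r=0.2 sd) for Gaussian white
  # noise, n = 5000, estimated beforehand from 100 independent replicates
  # with a brute-force implementation: (2.160, 2.209).
  set.seed(77)
  x <- rnorm(5000)
  se <- sample_entropy(x, 2, 0.2 * sd(x), "standard")
  expect_gt(se, 2.160)
  expect_lt(se, 2.209)
})

test_that("MSE matrix has the contract shape, scale-1 column and imputation", {
  set.seed(41)
  segs <- matrix(rnorm(4 * 600), nrow = 4)
  mm <- mse_matrix(segs, m = 2, r_coef = 0.2, tau_max = 12)
  expect_equal(dim(mm$values), c(4, 12))
  expect_equal(mm$log_values, log(1 + mm$values))
  expect_true(all(is.finite(mm$values)))

  # column 1 equals per-segment plain sample entropy
  plain <- vapply(1:4, function(k)
    sample_entropy(segs[k, ], 2, 0.2 * sd(segs[k, ])), 0)
  expect_equal(mm$values[, 1], plain, ignore_attr = TRUE)

  # a constant segment has zero tolerance (degenerate entropy); the flagged
  # row is imputed with the column max of the finite entries
  segs2 <- rbind(segs, rep(1, 600))
  mm2 <- mse_matrix(segs2, m = 2, r_coef = 0.2, tau_max = 4)
  expect_true(all(is.finite(mm2$values)))
  expect_gt(mm2$n_imputed, 0)
  expect_equal(as.numeric(mm2$values[5, 1]), max(mm2$values[1:4, 1]))

  expect_error(mse_matrix(matrix(rnorm(20), 1), tau_max = 12), "too short")
})

test_that("vectorized entropy equals the literal oracle across seeded cases", {
  set.seed(101)
  cases <- expand.grid(m = 1:3, r_coef = c(0.2, 0.35, 0.5))
  for (i in seq_len(nrow(cases))) {
    for (rep in 1:3) {
      x <- rnorm(sample(50:200, 1))
      r <- cases$r_coef[i] * sd(x)
      for (mode in c("paper", "standard")) {
        expect_equal(sample_entropy(x, cases$m[i], r, mode),
                     sampen_oracle(x, cases$m[i], r, mode)$se,
                     tolerance = 1e-12, ignore_attr = TRUE,
                     label = sprintf("m=%d r=%.2f mode=%s", cases$m[i],
                                     cases$r_coef[i], mode))
      }
    }
  }
})
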