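# Pairwise-additive diploid model: fitting, constrained alternatives,
# cross-validation, logistic boundary, all-pairs scan.

test_that("allele ordering is a symmetric min/max", {
  expect_equal(order_alleles(1.0, 0.0), list(x_j = 0.0, x_k = 1.0))
  expect_equal(order_alleles(0.6, 0.6), list(x_j = 0.6, x_k = 0.6))
  expect_equal(order_alleles(c(0.2, 0.9), c(0.7, 0.1)),
               order_alleles(c(0.7, 0.1), c(0.2, 0.9)))
  expect_error(order_alleles(NA_real_, 1), "non-finite")
})

test_that("OLS recovers noiseless generating coefficients exactly", {
  fit <- published_coef_fit()
  expect_equal(coef(fit), c(a = 0.05, b = 0.28, c = 0.73), tolerance = 1e-10)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
  # dominance limit: data generated as d = x_k gives (0, 0, 1)
  set.seed(2)
  dom <- data.frame(score1 = runif(20), score2 = runif(20))
  dom$d <- pmax(dom$score1, dom$score2)
  expect_equal(coef(fit_diploid_growth(dom)), c(a = 0, b = 0, c = 1),
               tolerance = 1e-10)
  # collinear design (all homozygotes) is flagged
  hom <- data.frame(x_j = c(0.1, 0.4, 0.7, 0.9), x_k = c(0.1, 0.4, 0.7, 0.9),
                    d = c(0.2, 0.5, 0.8, 1.0))
  expect_error(fit_diploid_growth(hom), "collinear")
  expect_error(fit_diploid_growth(hom[1:3, ]), "at least 4")
})

test_that("a 23-pair panel at the assay's conditions reproduces the fit shape", {
  cfg <- sim_config(seed = 101)
  pairs <- simulate_diploid_pairs(config = cfg)
  fit <- fit_diploid_growth(pairs)
  co <- coef(fit)
  expect_lt(abs(co[["a"]] - 0.05), 0.12)
  expect_lt(abs(co[["b"]] - 0.28), 0.15)
  expect_lt(abs(co[["c"]] - 0.73), 0.15)
  expect_gt(fit$r.squared, 0.9)
  cv <- loocv_diploid(pairs)
  expect_gt(cv$rmse, 0.03)
  expect_lt(cv$rmse, 0.12)
  expect_gte(cv$rmse, cv$mae)                         # norm inequality
})

test_that("constrained models nest under the full model", {
  set.seed(3)
  pairs <- data.frame(score1 = runif(23), score2 = runif(23))
  xs <- order_alleles(pairs$score1, pairs$score2)
  pairs$d <- 0.05 + 0.28 * xs$x_j + 0.73 * xs$x_k + rnorm(23, 0, 0.05)
  full <- fit_diploid_growth(pairs)
  fm <- fit_diploid_growth(pairs, "mean")
  fd <- fit_diploid_growth(pairs, "dominant")
  expect_lte(sum(full$residuals^2), sum(fm$residuals^2))
  expect_lte(sum(full$residuals^2), sum(fd$residuals^2))
  cm <- compare_diploid_models(full, fm)
  cd <- compare_diploid_models(full, fd)
  expect_equal(cm$df1, 1)
  expect_equal(cd$df1, 1)
  expect_lt(cm$p.value, 0.05)
  # symmetric data: the mean model attains zero residual
  sym <- data.frame(score1 = runif(10), score2 = runif(10))
  sym$d <- (sym$score1 + sym$score2) / 2
  expect_lt(sum(fit_diploid_growth(sym, "mean")$residuals^2), 1e-20)
  # identical models: F = 0, p = 1
  self <- compare_diploid_models(full, full)
  expect_equal(self$F, 0)
  expect_equal(self$p.value, 1)
})

test_that("the nested F statistic matches hand-computed arithmetic", {
  pairs <- data.frame(x_j = c(0.0, 0.2, 0.4, 0.5, 0.9),
                      x_k = c(0.1, 0.6, 0.5, 0.9, 0.9),
                      d = c(0.10, 0.55, 0.48, 0.80, 0.95))
  full <- fit_diploid_growth(pairs)
  dom <- fit_diploid_growth(pairs, "dominant")
  rss_f <- sum(residuals(full)^2)
  rss_r <- sum(residuals(dom)^2)
  f_hand <- (rss_r - rss_f) / (rss_f / (5 - 3))
  cmp <- compare_diploid_models(full, dom)
  expect_equal(cmp$F, f_hand, tolerance = 1e-12)
  expect_equal(cmp$p.value, stats::pf(f_hand, 1, 2, lower.tail = FALSE))
})

test_that("leave-one-out validation is zero for noiseless data", {
  set.seed(5)
  pairs <- data.frame(score1 = runif(12), score2 = runif(12))
  xs <- order_alleles(pairs$score1, pairs$score2)
  pairs$d <- 0.05 + 0.28 * xs$x_j + 0.73 * xs$x_k
  cv <- loocv_diploid(pairs)
  expect_lt(cv$rmse, 1e-10)
  expect_lt(cv$mae, 1e-10)
  expect_error(loocv_diploid(pairs[1:4, ]), "at least 5")
})

test_that("the logistic boundary is -g/h with separation handled explicitly", {
  set.seed(6)
  y <- c(rnorm(12, 0.45, 0.12), rnorm(12, 0.85, 0.08))
  lab <- rep(c("patient", "carrier"), each = 12)
  lb <- fit_logistic_boundary(y, lab)
  if (!lb$separation) {
    expect_equal(lb$boundary, -lb$g / lb$h, tolerance = 1e-12)
    expect_gt(lb$h, 0)                                 # carrier-positive coding
  }
  expect_gt(lb$boundary, min(y))
  expect_lt(lb$boundary, max(y))
  # complete separation: midpoint with flag
  sep <- fit_logistic_boundary(c(0.1, 0.2, 0.8, 0.9),
                               c("patient", "patient", "carrier", "carrier"))
  expect_true(sep$separation)
  expect_equal(sep$boundary, 0.5)
  expect_length(sep$misclassified, 0)
  expect_error(fit_logistic_boundary(c(0.8, 0.9), c("carrier", "carrier")),
               "both patient and carrier")
})

test_that("all-pairs scan counts, bins and matches a brute-force oracle", {
  fit <- published_coef_fit()
  # published coefficient arithmetic: null/null and WT/WT predictions
  expect_equal(predict(fit, data.frame(score1 = 0, score2 = 0)), 0.05,
               tolerance = 1e-10)
  expect_equal(predict(fit, data.frame(score1 = 1, score2 = 1)), 1.06,
               tolerance = 1e-10)
  # symmetry in input order
  expect_equal(predict(fit, data.frame(score1 = 0.2, score2 = 0.9)),
               predict(fit, data.frame(score1 = 0.9, score2 = 0.2)))
  # monotone in each allele; homozygotes on the line a + (b+c)x
  x <- seq(0, 1, by = 0.1)
  hom <- predict(fit, data.frame(score1 = x, score2 = x))
  expect_equal(hom, 0.05 + 1.01 * x, tolerance = 1e-10)
  expect_true(all(diff(hom) > 0))
  # three-allele toy set against an exhaustive double loop
  sc <- c(0.0, 0.4, 1.0)
  scan <- predict_all_pairs(sc, fit, boundary = 0.73, keep_predictions = TRUE)
  oracle <- c()
  for (i in 1:3) for (j in i:3) {
    oracle <- c(oracle, 0.05 + 0.28 * min(sc[i], sc[j]) + 0.73 * max(sc[i], sc[j]))
  }
  expect_equal(scan$n_pairs, 6)
  expect_equal(sort(scan$predictions$pred), sort(oracle))
  expect_equal(scan$below_boundary, sum(oracle < 0.73))
  expect_equal(sum(scan$histogram$count), scan$n_pairs)   # histogram mass
})

test_that("coefficient recovery is unbiased with calibrated interval coverage", {
  co_true <- c(a = 0.05, b = 0.28, c = 0.73)
  est <- matrix(NA_real_, 200, 3)
  covered <- matrix(NA, 200, 3)
  for (r in 1:200) {
    cfg <- sim_config(seed = 5000 + r, diploid_noise_sd = 0.05)
    pairs <- simulate_diploid_pairs(config = cfg)
    fit <- fit_diploid_growth(pairs)
    est[r, ] <- coef(fit)
    ci <- stats::confint(fit$lm)
    covered[r, ] <- ci[, 1] <= co_true & co_true <= ci[, 2]
  }
  bias <- colMeans(est) - co_true
  expect_true(all(abs(bias) < 0.02))
  expect_true(all(colMeans(covered) >= 0.90))
})
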