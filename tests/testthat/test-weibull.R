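# Weibull distribution utilities, the parameter estimators, and the
# multiplier mapping.

test_that("the distribution object exposes the textbook quantities", {
  d <- weibull_dist(1, 2)          # exponential special case
  expect_equal(d$mean, 2)
  expect_equal(d$entropy, 1 + log(2))
  expect_equal(weibull_dist(2, 1)$pdf(1), 2 * exp(-1))
  for (k in c(0.7, 2, 4.5))
    expect_equal(weibull_dist(k, 1.3)$cdf(1.3), 1 - exp(-1))
  expect_error(weibull_dist(0, 1), "k")
  expect_error(weibull_dist(2, -1), "c")
  s1 <- weibull_dist(2, 1)$sample(5, seed = 8)
  s2 <- weibull_dist(2, 1)$sample(5, seed = 8)
  expect_identical(s1, s2)
})

test_that("the empirical (power-law) estimator matches hand arithmetic", {
  fit <- weibull_fit(c(1, 2, 3), method = "empirical")
  expect_equal(fit$k, 0.5^(-1.086), tolerance = 1e-12)   # sd/mean = 1/2
  expect_equal(fit$k, 2.123, tolerance = 1e-3)
  expect_equal(fit$c, 2 / gamma(1 + 1 / fit$k), tolerance = 1e-12)
  expect_equal(fit$c, 2.258, tolerance = 1e-3)
  # cv = 1 -> exponential: k = 1, c = mean
  x <- c(1, 3)   # mean 2, sd sqrt(2)... construct cv = 1 directly
  x <- c(2 - sqrt(2), 2 + sqrt(2))
  f1 <- weibull_fit(x, method = "empirical")
  expect_equal(f1$k, 1, tolerance = 1e-12)
  expect_equal(f1$c, mean(x), tolerance = 1e-12)
  expect_error(weibull_fit(c(2, 2, 2), method = "empirical"), "variance")
})

test_that("method of moments inverts the analytic moments exactly", {
  d <- weibull_dist(3, 2)
  p <- weibull_from_moments(d$mean, d$sd)
  expect_equal(unname(p), c(3, 2), tolerance = 1e-8)
  # cv = 1 -> k = 1
  expect_equal(weibull_from_moments(5, 5)[["k"]], 1, tolerance = 1e-8)
  expect_error(weibull_from_moments(1, 1e5), "attainable")
  expect_error(weibull_from_moments(100, 1e-4), "attainable")
})

test_that("all data-driven estimators recover generating parameters", {
  set.seed(31)
  x <- rweibull(1e4, 2.6, 1.738)
  for (m in c("mle", "moments")) {
    f <- weibull_fit(x, method = m)
    expect_lt(abs(f$k - 2.6) / 2.6, 0.05)
    expect_lt(abs(f$c - 1.738) / 1.738, 0.05)
  }
  for (m in c("empirical", "nlsm")) {
    f <- weibull_fit(x, method = m)
    expect_lt(abs(f$k - 2.6) / 2.6, 0.10)
    expect_lt(abs(f$c - 1.738) / 1.738, 0.10)
  }
  fb <- weibull_fit_binned(bin_sample(x, 50))
  expect_lt(abs(fb$k - 2.6) / 2.6, 0.10)
  expect_lt(abs(fb$c - 1.738) / 1.738, 0.10)
})

test_that("estimators are scale-equivariant in c and invariant in k", {
  set.seed(5)
  x <- rweibull(3000, 2, 1)
  a <- 7.3
  for (m in c("mle", "moments", "empirical", "nlsm")) {
    f1 <- weibull_fit(x, method = m)
    f2 <- weibull_fit(a * x, method = m)
    expect_equal(f2$k, f1$k, tolerance = 1e-6)
    expect_equal(f2$c, a * f1$c, tolerance = 1e-6)
  }
})

test_that("MLE degenerates and permutations behave as specified", {
  expect_error(weibull_fit(rep(2, 10), method = "mle"), "degenerate")
  set.seed(9)
  x <- rweibull(500, 2.5, 1.2)
  f1 <- weibull_fit(x, method = "nlsm")
  f2 <- weibull_fit(sample(x), method = "nlsm")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("NLSM recovers points generated exactly on a Weibull cdf", {
  # order statistics whose plotting positions sit exactly on the cdf
  n <- 200
  Fi <- (seq_len(n) - 0.3) / (n + 0.4)
  x <- qweibull(Fi, 2.5, 1.2)
  f <- weibull_fit(x, method = "nlsm")
  expect_equal(f$k, 2.5, tolerance = 1e-6)
  expect_equal(f$c, 1.2, tolerance = 1e-6)
})

test_that("binned MMLE is ratio-invariant and close to unbinned MLE", {
  set.seed(13)
  x <- rweibull(1e4, 2, 1)
  b <- bin_sample(x, 50)
  f1 <- weibull_fit_binned(b)
  b2 <- b
  b2$frequencies <- 2 * b$frequencies
  b2$p_nonneg <- 2 * b$p_nonneg
  f2 <- weibull_fit_binned(b2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)

  fm <- weibull_fit(x, method = "mle")
  expect_lt(abs(f1$k - fm$k) / fm$k, 0.05)
  expect_lt(abs(f1$c - fm$c) / fm$c, 0.05)
  expect_error(weibull_fit_binned(list(bin_centers = 1, frequencies = 1,
                                       p_nonneg = 1)), "bins")
})

test_that("the Weibull/multiplier map matches the worked example and inverts", {
  lam <- weibull_to_lambda(3, 1.8498)
  expect_equal(round(lam[["lambda0"]], 4), 0.7466)
  expect_equal(lam[["lambda1"]], -2)
  expect_equal(lam[["lambda2"]], 1.8498^(-3), tolerance = 1e-12)
  expect_equal(round(lam[["lambda2"]], 4), 0.158)

  expect_equal(unname(weibull_to_lambda(1, 1)), c(0, 0, 1))

  set.seed(2)
  for (i in 1:20) {
    k <- runif(1, 0.3, 6); c <- runif(1, 0.2, 5)
    back <- lambda_to_weibull(weibull_to_lambda(k, c))
    expect_equal(unname(back), c(k, c), tolerance = 1e-12)
  }
  expect_error(lambda_to_weibull(c(0, 2, 1)), "lambda1")
  expect_error(lambda_to_weibull(c(0, -1, -2)), "lambda2")
})

test_that("the mapped exponential-family density equals the Weibull pdf", {
  xs <- seq(0.01, 10, length.out = 2000)
  for (p in list(c(2.5, 1.2), c(3, 1.8498), c(1.3, 4))) {
    lam <- weibull_to_lambda(p[1], p[2])
    f <- exp(-lam[1] - lam[2] * log(xs) - lam[3] * xs^p[1])
    expect_lt(max(abs(f - dweibull(xs, p[1], p[2]))), 1e-12)
  }
})

test_that("the estimator comparison table has the expected layout", {
  set.seed(17)
  x <- rweibull(2000, 2.6, 1.738)
  tab <- compare_weibull_estimators(x)
  expect_setequal(tab$method, c("EM", "MOM", "MLE", "MMLE", "NLSM", "MMEM"))
  expect_true(all(is.finite(tab$k)))
  expect_true(all(tab$k > 0 & tab$c > 0))
})
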