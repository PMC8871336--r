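# Bayesian MAP estimation of the kinetic rate constants.

test_that("the negative log-posterior matches hand evaluations", {
  A <- diag(2)
  expect_equal(neg_log_posterior(c(0, 0), A, c(1, 1), sigma2 = 1, alpha = 0),
               2)
  expect_equal(neg_log_posterior(c(1, 1), A, c(1, 1), sigma2 = 1, alpha = 5),
               0)   # zero residual and S(1,1) = 0
  # exact data, alpha = 0 -> 0
  fx <- biexp_fixture(dt = 0.1, t_max = 6)
  ct <- tissue_response(fx$cp, fx$k1, fx$k2)
  D <- murase_design(fx$cp, ct)
  y <- drop(D$A %*% c(0.3, 0.1))
  expect_equal(neg_log_posterior(c(0.3, 0.1), D, y, 1, 0), 0,
               tolerance = 1e-18)
  expect_equal(neg_log_posterior(c(0.3, 0.1), D, y, 1, 2),
               2 * (0.3 * log(0.3) + 0.1 * log(0.1)))
  expect_error(neg_log_posterior(c(1, 1), A, c(1, 1), sigma2 = 0), "sigma2")
  expect_identical(neg_log_posterior(c(-1, 1), A, c(1, 1)), Inf)
})

test_that("MAP at alpha = 0 with interior optimum equals LLSQ", {
  grid <- study_grid()
  cp <- generate_aif_curve(aif_weibull(amplitude = 5), grid)
  ct <- generate_tissue_curve(cp, 0.25, 0.2, noise_sd = 0.02, seed = 3)
  D <- murase_design(cp, ct)
  ls <- suppressWarnings(llsq_fit(D, ct$values))
  mp <- map_fit(D, ct$values, alpha = 0)
  expect_lt(abs(mp$k1 - ls$k1) / abs(ls$k1), 1e-6)
  expect_lt(abs(mp$k2 - ls$k2) / abs(ls$k2), 1e-6)
})

test_that("MAP stays in the non-negative box and beats the clipped LLSQ point", {
  fx <- biexp_fixture(dt = 0.2, t_max = 8)
  ct <- tissue_response(fx$cp, fx$k1, fx$k2)
  D <- murase_design(fx$cp, ct)
  # response built to drive the unconstrained solution negative
  y <- drop(D$A %*% c(0.3, -0.08)) + 0.01 * sin(seq_len(nrow(D$A)))
  ls <- suppressWarnings(llsq_fit(D, y))
  expect_true(ls$k2 < 0)
  mp <- map_fit(D, y, alpha = 0.01)
  expect_gte(mp$k2, 0)
  clipped <- pmax(c(ls$k1, ls$k2), 0)
  expect_lte(mp$diagnostics$posterior,
             neg_log_posterior(clipped, D, y, mp$diagnostics$sigma2, 0.01) +
               1e-10)
})

test_that("regularization path: stronger alpha never increases the penalty", {
  grid <- study_grid()
  cp <- generate_aif_curve(aif_weibull(amplitude = 5), grid)
  ct <- generate_tissue_curve(cp, 0.7, 0.15, noise_sd = 0.05, seed = 11)
  D <- murase_design(cp, ct)
  alphas <- c(0, 0.01, 0.1, 1, 10)
  S <- vapply(alphas, function(a) {
    f <- map_fit(D, ct$values, alpha = a)
    k <- coef(f)
    sum(ifelse(k > 0, k * log(k), 0))
  }, numeric(1))
  expect_true(all(diff(S) <= 1e-8))
})

test_that("K estimates are unbiased as noise vanishes", {
  grid <- study_grid()
  cp <- generate_aif_curve(aif_weibull(amplitude = 5), grid)
  err <- vapply(c(0.05, 0.01, 0.002), function(sd) {
    e <- vapply(1:10, function(s) {
      ct <- generate_tissue_curve(cp, 0.5, 0.2, noise_sd = sd, seed = s)
      f <- kinetic_fit(cp, ct, method = "map")
      abs(f$k1 - 0.5) / 0.5
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("MAP recovery on the simulated study meets the accuracy target", {
  errs <- unlist(lapply(1:10, function(s) {
    st <- simulate_study(study_config(n_patients = 12, seed = s))
    vapply(st$patients, function(p) {
      f <- kinetic_fit(p$cp, p$ctis, method = "map")
      abs(f$k1 - p$k1) / p$k1
    }, numeric(1))
  }))
  expect_lt(median(errs), 0.10)
})

test_that("TLBO optimizer route agrees with quasi-Newton", {
  grid <- study_grid()
  cp <- generate_aif_curve(aif_weibull(amplitude = 5), grid)
  ct <- generate_tissue_curve(cp, 0.4, 0.25, noise_sd = 0.03, seed = 2)
  D <- murase_design(cp, ct)
  qn <- map_fit(D, ct$values, alpha = 0.01)
  tl <- map_fit(D, ct$values, alpha = 0.01, optimizer = "tlbo", seed = 6)
  expect_equal(coef(tl), coef(qn), tolerance = 1e-3)
  tl2 <- map_fit(D, ct$values, alpha = 0.01, optimizer = "tlbo", seed = 6)
  expect_identical(coef(tl), coef(tl2))
})
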