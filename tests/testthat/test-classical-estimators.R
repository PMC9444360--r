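test_that("MLE and UMVUE are the stated functions of (n, T)", {
  s <- lomax_suffstat(qlomax(seq(0.05, 0.95, length.out = 20), 2, 2), 2)
  expect_equal(est_mle(list(n = 20, T = 10)), 2)
  expect_equal(est_mle(list(n = 1, T = 1)), 1)
  expect_equal(est_umvue(list(n = 20, T = 10)), 1.9)
  expect_equal(est_umvue(s) / est_mle(s), 19 / 20)   # ratio identity
  expect_lt(est_umvue(s), est_mle(s))

  expect_error(est_mle(list(n = 3, T = 0)), "degenerate")
  expect_error(est_umvue(list(n = 1, T = 1)), "n >= 2")
})

test_that("UMVUE is unbiased and the MLE has mean theta*n/(n-1)", {
  set.seed(31)
  n <- 20; reps <- 1e4
  for (theta in c(1.5, 2)) {
    U <- matrix(runif(reps * n), reps, n)
    Tv <- rowSums(log1p((1 - U)^(-1 / theta) - 1))
    umv <- (n - 1) / Tv
    mle <- n / Tv
    expect_lt(abs(mean(umv) - theta), 3 * sd(umv) / sqrt(reps))
    expect_lt(abs(mean(mle) - theta * n / (n - 1)), 3 * sd(mle) / sqrt(reps))
  }
})

test_that("plotting positions are valid CDF estimates", {
  for (m in c("median_rank", "mean_rank", "blom")) {
    p <- plotting_positions(25, m)
    expect_true(all(p > 0 & p < 1))
    expect_true(all(diff(p) > 0))
  }
  expect_equal(plotting_positions(10, "median_rank"), ((1:10) - 0.3) / 10.4)
  expect_equal(plotting_positions(10, "mean_rank"), (1:10) / 11)
  expect_equal(plotting_positions(10, "blom"), ((1:10) - 3 / 8) / 10.25)
})

test_that("OLS fit solves the two-point case exactly and matches lm()", {
  # delta = 1, x* = (1, 3), mean-rank y = (log(2/3), log(1/3)):
  # slope = (y2 - y1)/(x2 - x1) = log(1/2)/2
  x <- c(exp(1) - 1, exp(3) - 1)
  f <- ols_fit(x, scale = 1, pp = "mean_rank")
  expect_equal(f$slope, -log(2) / 2, tolerance = 1e-12)
  expect_equal(est_ols(x, 1, "mean_rank"), log(2) / 2, tolerance = 1e-12)

  set.seed(9)
  xr <- rlomax(35, 2, 2)
  fit <- ols_fit(xr, 2, "median_rank")
  xs <- log(2 + sort(xr))
  y <- log(1 - plotting_positions(35, "median_rank"))
  ref <- coef(lm(y ~ xs))
  expect_equal(fit$slope, unname(ref["xs"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(ref["(Intercept)"]), tolerance = 1e-10)

  expect_error(ols_fit(rep(2, 5), 2), "singular")
  expect_error(ols_fit(1.5, 2), "n >= 2")
})

test_that("ridge fit reduces to OLS at lambda = 0 and matches hand sums", {
  set.seed(4)
  x <- rlomax(30, 2.5, 2)
  f0 <- ridge_fit(x, 2, "median_rank", lambda = 0)
  fo <- ols_fit(x, 2, "median_rank")
  expect_identical(f0$slope, fo$slope)

  # hand evaluation of the penalized normal equations on the two-point design:
  # Sx = 4, Sy = log(2/9), Sxy = log(2/3) + 3 log(1/3), Sxx = 10
  x2 <- c(exp(1) - 1, exp(3) - 1)
  Sxy <- log(2 / 3) + 3 * log(1 / 3)
  expected <- (2.75 * Sxy - 4 * log(2 / 9)) / (2.75 * 10 - 16)
  f <- ridge_fit(x2, 1, "mean_rank", lambda = 0.75)
  expect_equal(f$slope, expected, tolerance = 1e-12)
  expect_equal(f$slope, -0.3619365, tolerance = 1e-6)
  expect_equal(est_ridge(x2, 1, "mean_rank", 0.75), -expected)
  expect_equal(f$intercept, (log(2 / 9) - f$slope * 4) / 2.75, tolerance = 1e-12)
})

test_that("ridge estimate is continuous in lambda and data-driven mode is consistent", {
  set.seed(14)
  x <- rlomax(25, 2, 2)
  lams <- seq(0, 1, by = 0.05)
  ests <- vapply(lams, function(l) est_ridge(x, 2, "median_rank", l), 0)
  expect_true(all(abs(diff(ests)) < 0.05))   # no jumps on a 0.05 grid
  expect_true(all(ests > 0))

  lam <- ridge_lambda(x, 2, "median_rank")
  expect_gte(lam, 0); expect_lte(lam, 1)
  expect_identical(ridge_fit(x, 2, "median_rank", "data_driven")$slope,
                   ridge_fit(x, 2, "median_rank", lam)$slope)
})

test_that("regression estimators ignore input ordering", {
  set.seed(21)
  x <- rlomax(40, 2, 2)
  xs <- sample(x)
  expect_identical(est_ols(x, 2), est_ols(xs, 2))
  expect_identical(est_ridge(x, 2, lambda = 0.75), est_ridge(xs, 2, lambda = 0.75))
  expect_identical(est_median(x, 2), est_median(xs, 2))
})

test_that("median estimator inverts the CDF at the sample median", {
  expect_equal(est_median(6, scale = 2), 0.5)           # log2 / log4
  expect_equal(est_median(c(2), scale = 2), 1)          # x_med = delta
  xmed <- 2 * (2^(1 / 2.5) - 1)
  expect_equal(est_median(c(xmed), scale = 2), 2.5)
  # even n: mean of the two central order statistics
  expect_equal(est_median(c(0.1, 1, 3, 100), scale = 2),
               log(2) / log1p(2 / 2))
  expect_error(est_median(c(0, 0, 0), 2), "degenerate")
})

test_that("all five estimators are consistent on a large sample", {
  set.seed(77)
  theta <- 2
  x <- rlomax(1e4, theta, 2)
  s <- lomax_suffstat(x, 2)
  for (est in c(est_mle(s), est_umvue(s), est_ols(x, 2),
                est_ridge(x, 2, lambda = 0.75), est_median(x, 2)))
    expect_lt(abs(est - theta), 0.1)
})
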