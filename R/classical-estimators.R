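#' Likelihood-based shape estimators
#'
#' Point estimators of the Lomax shape \eqn{\vartheta} that depend on the data
#' only through the sufficient statistic \eqn{T = \sum \log(1 + x_i/\delta)}:
#' the maximum-likelihood estimator \eqn{\hat\vartheta_{MLE} = n/T} and the
#' uniformly minimum variance unbiased estimator (Lehmann--Scheffe)
#' \eqn{\hat\vartheta_{UMVUE} = (n-1)/T}. Since \eqn{T} is Gamma with rate
#' \eqn{\vartheta}, the UMVUE is exactly unbiased and its ratio to the MLE is
#' \eqn{(n-1)/n} on every sample.
#'
#' @param stat a `"lomax_suffstat"` object from [lomax_suffstat()].
#' @return The point estimate, a positive scalar.
#' @examples
#' s <- lomax_suffstat(c(1, 2, 5, 9), scale = 2)
#' est_mle(s)
#' est_umvue(s)
#' @export
est_mle <- function(stat) {
  stat <- as_suffstat(stat)
  if (stat$T <= 0)
    stop("degenerate sample: T = 0 (all observations zero); MLE undefined",
         call. = FALSE)
  stat$n / stat$T
}

#' @rdname est_mle
#' @export
est_umvue <- function(stat) {
  stat <- as_suffstat(stat)
  if (stat$n < 2)
    stop("UMVUE requires n >= 2", call. = FALSE)
  if (stat$T <= 0)
    stop("degenerate sample: T = 0 (all observations zero); UMVUE undefined",
         call. = FALSE)
  (stat$n - 1) / stat$T
}

#' Rank-based plotting positions
#'
#' Estimates \eqn{\hat F_i} of the CDF at the i-th order statistic, used to
#' linearize the Lomax CDF for regression fitting. Three standard choices:
#' median rank \eqn{(i-0.3)/(n+0.4)}, mean rank \eqn{i/(n+1)}, and Blom's
#' \eqn{(i-3/8)/(n+1/4)}.
#'
#' @param n sample size.
#' @param method plotting-position rule.
#' @return Numeric vector of length `n`, strictly increasing within (0, 1).
#' @export
plotting_positions <- function(n, method = c("median_rank", "mean_rank", "blom")) {
  method <- match.arg(method)
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  i <- seq_len(n)
  switch(method,
         median_rank = (i - 0.3) / (n + 0.4),
         mean_rank   = i / (n + 1),
         blom        = (i - 3 / 8) / (n + 0.25))
}

# Design sums for the linearized-CDF regression: predictor x* = log(delta +
# x_(i)), response y = log(1 - Fhat_i). Shared by the OLS and ridge fits.
plot_design <- function(x, scale, pp) {
  check_support(x)
  n <- length(x)
  if (n < 2L) stop("regression fit requires n >= 2", call. = FALSE)
  xs <- log(scale + sort(x))
  y <- log(1 - plotting_positions(n, pp))
  list(n = n, Sx = sum(xs), Sy = sum(y), Sxy = sum(xs * y), Sxx = sum(xs^2))
}

new_plotfit <- function(slope, intercept, d, lambda, pp) {
  structure(list(slope = slope, intercept = intercept, lambda = lambda,
                 pp = pp, n = d$n,
                 sums = list(Sx = d$Sx, Sy = d$Sy, Sxy = d$Sxy, Sxx = d$Sxx)),
            class = "lomax_plotfit")
}

#' @export
print.lomax_plotfit <- function(x, ...) {
  cat(sprintf("Linearized-CDF fit (n = %d, pp = %s, lambda = %g):\n",
              x$n, x$pp, x$lambda))
  cat(sprintf("  slope = %.6g, intercept = %.6g, shape estimate = %.6g\n",
              x$slope, x$intercept, -x$slope))
  invisible(x)
}

#' Least-squares and ridge fits of the linearized Lomax CDF
#'
#' The Lomax CDF satisfies
#' \eqn{\log(1 - F(x)) = -\vartheta \log(\delta + x) + \vartheta \log\delta},
#' a line in \eqn{\log(\delta + x)} with slope \eqn{-\vartheta}. Replacing
#' \eqn{F} at the order statistics by plotting positions \eqn{\hat F_i} gives a
#' regression problem whose fitted slope estimates \eqn{-\vartheta}.
#'
#' `ols_fit` is the ordinary least-squares fit. `ridge_fit` shrinks the
#' coefficients with a ridge penalty \eqn{\lambda}:
#' \deqn{\hat\beta_{Rid} = \frac{(n+\lambda)\sum x_i^* y_i - \sum x_i^* \sum y_i}
#'                              {(n+\lambda)\sum x_i^{*2} - (\sum x_i^*)^2},}
#' which reduces exactly to the OLS slope at \eqn{\lambda = 0}. The ridge
#' intercept is \eqn{(\sum y_i - \hat\beta \sum x_i^*)/(n+\lambda)}.
#' `est_ols` and `est_ridge` return \eqn{-}slope as the shape estimate.
#'
#' With `lambda = "data_driven"` the penalty is chosen as
#' \eqn{\lambda = \rho\hat\sigma^2 / \hat\beta'\hat\beta} with \eqn{\rho = 2}
#' (the number of distribution parameters), \eqn{\hat\sigma^2} the OLS residual
#' mean square, and \eqn{\hat\beta = (\hat\alpha_{OLS}, \hat\beta_{OLS})};
#' the result is clamped into \eqn{[0, 1]}.
#'
#' @param x numeric vector of nonnegative observations (any order; order
#'   statistics are formed internally).
#' @param scale known positive scale parameter \eqn{\delta}.
#' @param pp plotting-position rule, see [plotting_positions()].
#' @param lambda ridge penalty: a nonnegative number, or `"data_driven"`.
#' @return `ols_fit`/`ridge_fit` return a `"lomax_plotfit"` with components
#'   `slope`, `intercept`, `lambda`, `pp`, `n` and the design `sums`;
#'   `est_ols`/`est_ridge` return the scalar shape estimate.
#' @examples
#' set.seed(7)
#' x <- rlomax(50, shape = 2, scale = 2)
#' est_ols(x, scale = 2)
#' est_ridge(x, scale = 2, lambda = 0.75)
#' @export
ols_fit <- function(x, scale, pp = c("median_rank", "mean_rank", "blom")) {
  pp <- match.arg(pp)
  check_shape_scale(1, scale)
  d <- plot_design(x, scale, pp)
  den <- d$n * d$Sxx - d$Sx^2
  if (abs(den) < .Machine$double.eps * d$n * d$Sxx)
    stop("singular design: all observations equal", call. = FALSE)
  slope <- (d$n * d$Sxy - d$Sx * d$Sy) / den
  intercept <- d$Sy / d$n - slope * d$Sx / d$n
  new_plotfit(slope, intercept, d, lambda = 0, pp = pp)
}

#' @rdname ols_fit
#' @export
ridge_fit <- function(x, scale, pp = c("median_rank", "mean_rank", "blom"),
                      lambda = 0.75) {
  pp <- match.arg(pp)
  check_shape_scale(1, scale)
  if (identical(lambda, "data_driven"))
    lambda <- ridge_lambda(x, scale, pp)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("'lambda' must be a single nonnegative number or \"data_driven\"",
         call. = FALSE)
  d <- plot_design(x, scale, pp)
  den <- (d$n + lambda) * d$Sxx - d$Sx^2
  if (abs(den) < .Machine$double.eps * (d$n + lambda) * d$Sxx)
    stop("singular design: all observations equal", call. = FALSE)
  slope <- ((d$n + lambda) * d$Sxy - d$Sx * d$Sy) / den
  intercept <- (d$Sy - slope * d$Sx) / (d$n + lambda)
  new_plotfit(slope, intercept, d, lambda = lambda, pp = pp)
}

#' Data-driven ridge penalty
#'
#' \eqn{\lambda = \rho\hat\sigma^2/\hat\beta'\hat\beta} with \eqn{\rho = 2},
#' \eqn{\hat\sigma^2} the OLS residual mean square (denominator \eqn{n - 2}),
#' and \eqn{\hat\beta} the OLS coefficient vector (intercept, slope). Clamped
#' to \eqn{[0, 1]}.
#'
#' @inheritParams ols_fit
#' @return A scalar in \eqn{[0, 1]}.
#' @export
ridge_lambda <- function(x, scale, pp = c("median_rank", "mean_rank", "blom")) {
  pp <- match.arg(pp)
  fit <- ols_fit(x, scale, pp)
  n <- fit$n
  if (n < 3L) stop("data-driven lambda requires n >= 3", call. = FALSE)
  xs <- log(scale + sort(x))
  y <- log(1 - plotting_positions(n, pp))
  rss <- sum((y - fit$intercept - fit$slope * xs)^2)
  sigma2 <- rss / (n - 2)
  lam <- 2 * sigma2 / (fit$intercept^2 + fit$slope^2)
  min(max(lam, 0), 1)
}

#' @rdname ols_fit
#' @export
est_ols <- function(x, scale, pp = c("median_rank", "mean_rank", "blom")) {
  -ols_fit(x, scale, pp)$slope
}

#' @rdname ols_fit
#' @export
est_ridge <- function(x, scale, pp = c("median_rank", "mean_rank", "blom"),
                      lambda = 0.75) {
  -ridge_fit(x, scale, pp, lambda)$slope
}

#' Median-based shape estimator
#'
#' Solves \eqn{F(x_{med}) = 1/2} for \eqn{\vartheta} at the sample median:
#' \eqn{\hat\vartheta_{Med} = \log 2 / \log(1 + x_{med}/\delta)}. For even
#' sample sizes the median is the mean of the two central order statistics.
#'
#' @param x numeric vector of nonnegative observations.
#' @param scale known positive scale parameter \eqn{\delta}.
#' @return The scalar shape estimate.
#' @examples
#' est_median(c(6), scale = 2)  # log(2)/log(4) = 0.5
#' @export
est_median <- function(x, scale) {
  check_shape_scale(1, scale)
  check_support(x)
  if (length(x) < 1L) stop("'x' must be nonempty", call. = FALSE)
  xmed <- stats::median(x)
  if (xmed <= 0)
    stop("degenerate sample: median is 0; median estimator undefined",
         call. = FALSE)
  log(2) / log1p(xmed / scale)
}
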