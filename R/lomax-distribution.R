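#' The Lomax (Pareto type II) distribution
#'
#' Density, distribution function, survival function, quantile function and
#' random generation for the Lomax distribution with shape `shape` (\eqn{\vartheta})
#' and scale `scale` (\eqn{\delta}), supported on \eqn{[0, \infty)}:
#' \deqn{f(x) = \frac{\vartheta}{\delta}\left(1 + \frac{x}{\delta}\right)^{-(\vartheta+1)},
#'       \qquad F(x) = 1 - \left(1 + \frac{x}{\delta}\right)^{-\vartheta}.}
#'
#' The Lomax law is a heavy-tailed lifetime model with decreasing hazard,
#' widely used for failure times, biomedical durations, income and city-size
#' data. The shape parameter controls the tail index; the scale is treated as
#' known throughout this package.
#'
#' Random generation uses the inverse-CDF transform
#' \eqn{x = \delta[(1-U)^{-1/\vartheta} - 1]} with \eqn{U \sim \mathrm{Unif}(0,1)},
#' applied to `runif(n)` draws in order, so a run is bit-reproducible against a
#' recorded uniform stream under the same seed.
#'
#' @param x,q vector of nonnegative quantiles. Negative values are an error:
#'   the support of the model is \eqn{[0,\infty)} and a negative failure time
#'   indicates corrupt input rather than a zero-density point.
#' @param p vector of probabilities in \eqn{[0,1)}.
#' @param n number of observations to draw.
#' @param shape positive shape parameter \eqn{\vartheta}.
#' @param scale positive scale parameter \eqn{\delta}.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are given on
#'   the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise the survival function \eqn{P(X > x)}.
#'
#' @return `dlomax` gives the density, `plomax` the distribution function,
#'   `slomax` the survival (reliability) function, `qlomax` the quantile
#'   function, and `rlomax` a vector of `n` random deviates.
#'
#' @examples
#' dlomax(0, shape = 2, scale = 2)      # density at the origin, theta/delta = 1
#' plomax(2, shape = 1, scale = 2)      # 1 - 2^-1 = 0.5
#' slomax(2, shape = 2, scale = 2)      # (1 + 1)^-2 = 0.25
#' set.seed(1); rlomax(5, shape = 2, scale = 2)
#' @name lomax
NULL

check_shape_scale <- function(shape, scale) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0)
    stop("'shape' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("'scale' must be a single positive finite number", call. = FALSE)
  invisible(TRUE)
}

check_support <- function(x, what = "x") {
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be finite and nonnegative (Lomax support is [0, Inf))", what),
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname lomax
#' @export
dlomax <- function(x, shape, scale, log = FALSE) {
  check_shape_scale(shape, scale)
  check_support(x)
  ld <- log(shape) - log(scale) - (shape + 1) * log1p(x / scale)
  if (log) ld else exp(ld)
}

#' @rdname lomax
#' @export
plomax <- function(q, shape, scale, lower.tail = TRUE, log.p = FALSE) {
  check_shape_scale(shape, scale)
  check_support(q, "q")
  lsurv <- -shape * log1p(q / scale)
  if (!lower.tail) {
    if (log.p) lsurv else exp(lsurv)
  } else {
    p <- -expm1(lsurv)
    if (log.p) log(p) else p
  }
}

#' @rdname lomax
#' @export
slomax <- function(q, shape, scale) {
  plomax(q, shape, scale, lower.tail = FALSE)
}

#' @rdname lomax
#' @export
qlomax <- function(p, shape, scale) {
  check_shape_scale(shape, scale)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("'p' must lie in [0, 1)", call. = FALSE)
  scale * expm1(-log1p(-p) / shape)
}

#' @rdname lomax
#' @export
rlomax <- function(n, shape, scale) {
  check_shape_scale(shape, scale)
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  u <- stats::runif(n)
  # delta * ((1 - U)^(-1/theta) - 1), kept literally in terms of (1 - U)
  scale * ((1 - u)^(-1 / shape) - 1)
}

#' Sufficient statistic for the Lomax shape parameter
#'
#' With the scale \eqn{\delta} known, \eqn{T = \sum_i \log(1 + x_i/\delta)} is a
#' complete sufficient statistic for the shape \eqn{\vartheta}: each summand
#' \eqn{\log(1 + X/\delta)} is exponential with rate \eqn{\vartheta}, so
#' \eqn{T \sim \mathrm{Gamma}(n, \mathrm{rate} = \vartheta)}. Every likelihood-based
#' estimator in this package is a function of `(n, T)` alone.
#'
#' @param x numeric vector of nonnegative observations.
#' @param scale known positive scale parameter \eqn{\delta}.
#' @return An object of class `"lomax_suffstat"`: a list with components `n`
#'   (sample size) and `T` (the statistic).
#' @examples
#' lomax_suffstat(c(0.5, 1.2, 3.0), scale = 2)
#' @export
lomax_suffstat <- function(x, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("'scale' must be a single positive finite number", call. = FALSE)
  if (length(x) < 1L)
    stop("'x' must contain at least one observation", call. = FALSE)
  check_support(x)
  structure(list(n = length(x), T = sum(log1p(x / scale))),
            class = "lomax_suffstat")
}

#' @export
print.lomax_suffstat <- function(x, ...) {
  cat(sprintf("Lomax sufficient statistic: n = %d, T = %.6g\n", x$n, x$T))
  invisible(x)
}

as_suffstat <- function(stat) {
  if (inherits(stat, "lomax_suffstat")) return(stat)
  if (is.list(stat) && all(c("n", "T") %in% names(stat)))
    return(structure(list(n = stat$n, T = stat$T), class = "lomax_suffstat"))
  stop("'stat' must be a 'lomax_suffstat' (see lomax_suffstat())", call. = FALSE)
}
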