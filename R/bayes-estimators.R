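#' Prior specifications for the Lomax shape parameter
#'
#' Four priors for the shape \eqn{\vartheta}, all of which combine with the
#' Lomax likelihood (scale known) into a Gamma posterior on \eqn{\vartheta}:
#'
#' * `extended_jeffreys`: noninformative, \eqn{h(\vartheta) \propto \vartheta^{-2c}},
#'   `c > 0`; posterior \eqn{\mathrm{Gamma}(n - 2c + 1,\ T)}. At `c = 0.5`
#'   (plain Jeffreys) the posterior mean equals the MLE.
#' * `chi_square`: \eqn{\chi^2}-type conjugate prior with hyperparameters
#'   `k, d > 0`; posterior \eqn{\mathrm{Gamma}(n + k/2,\ T + d/2)}.
#' * `inverted_levy`: \eqn{\propto \vartheta^{-1/2} e^{-d\vartheta/2}};
#'   posterior \eqn{\mathrm{Gamma}(n + 1/2,\ T + d/2)}.
#' * `gamma`: natural conjugate \eqn{\mathrm{Gamma}(k, d)} prior; posterior
#'   \eqn{\mathrm{Gamma}(n + k,\ T + d)}.
#'
#' @param family prior family.
#' @param c exponent of the extended Jeffreys prior (default 0.5).
#' @param k,d hyperparameters of the informative priors (defaults 0.6, 0.2).
#' @return An object of class `"lomax_prior"`.
#' @examples
#' lomax_prior("gamma", k = 0.6, d = 0.2)
#' @export
lomax_prior <- function(family = c("extended_jeffreys", "chi_square",
                                   "inverted_levy", "gamma"),
                        c = 0.5, k = 0.6, d = 0.2) {
  family <- match.arg(family)
  chk <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  switch(family,
         extended_jeffreys = chk(c, "c"),
         inverted_levy = chk(d, "d"),
         { chk(k, "k"); chk(d, "d") })
  structure(list(family = family, c = c, k = k, d = d),
            class = "lomax_prior")
}

#' @export
print.lomax_prior <- function(x, ...) {
  hp <- switch(x$family,
               extended_jeffreys = sprintf("c = %g", x$c),
               inverted_levy = sprintf("d = %g", x$d),
               sprintf("k = %g, d = %g", x$k, x$d))
  cat(sprintf("Lomax shape prior: %s (%s)\n", x$family, hp))
  invisible(x)
}

# (shape A, rate B) of the Gamma posterior, vectorized over T. The four
# priors differ only here; every Bayes rule below is a function of (A, B).
posterior_pair <- function(prior, n, T) {
  switch(prior$family,
         extended_jeffreys = list(A = n - 2 * prior$c + 1, B = T),
         chi_square        = list(A = n + prior$k / 2,     B = T + prior$d / 2),
         inverted_levy     = list(A = n + 1 / 2,           B = T + prior$d / 2),
         gamma             = list(A = n + prior$k,         B = T + prior$d))
}

#' Gamma posterior of the Lomax shape parameter
#'
#' Combines a [lomax_prior()] with the sufficient statistic into the posterior
#' \eqn{\pi(\vartheta \mid x) \propto \vartheta^{A-1} e^{-B\vartheta}}, i.e.
#' \eqn{\mathrm{Gamma}(A, \mathrm{rate}\ B)}. See [lomax_prior()] for the
#' (prior, data) to (A, B) mapping.
#'
#' @param prior a `"lomax_prior"`.
#' @param stat a `"lomax_suffstat"` from [lomax_suffstat()].
#' @return An object of class `"gamma_posterior"` with components `shape` (A)
#'   and `rate` (B).
#' @examples
#' s <- lomax_suffstat(c(1, 2, 5, 9), scale = 2)
#' lomax_posterior(lomax_prior("gamma"), s)
#' @export
lomax_posterior <- function(prior, stat) {
  if (!inherits(prior, "lomax_prior"))
    stop("'prior' must be a 'lomax_prior'", call. = FALSE)
  stat <- as_suffstat(stat)
  ab <- posterior_pair(prior, stat$n, stat$T)
  if (ab$A <= 0)
    stop(sprintf("improper posterior: shape A = %g <= 0 (need n > 2c - 1)", ab$A),
         call. = FALSE)
  if (ab$B <= 0)
    stop("improper posterior: rate B <= 0 (degenerate sample with T = 0)",
         call. = FALSE)
  structure(list(shape = ab$A, rate = ab$B), class = "gamma_posterior")
}

#' @export
print.gamma_posterior <- function(x, ...) {
  cat(sprintf("Gamma posterior: shape A = %.6g, rate B = %.6g (mean %.6g)\n",
              x$shape, x$rate, x$shape / x$rate))
  invisible(x)
}

as_posterior <- function(post) {
  if (inherits(post, "gamma_posterior")) return(post)
  if (is.list(post) && all(c("shape", "rate") %in% names(post)))
    return(structure(list(shape = post$shape, rate = post$rate),
                     class = "gamma_posterior"))
  stop("'post' must be a 'gamma_posterior' (see lomax_posterior())",
       call. = FALSE)
}

#' Bayes point estimators under squared-error, LINEX and composite-LINEX loss
#'
#' Given a Gamma posterior \eqn{\mathrm{Gamma}(A, \mathrm{rate}\ B)} for the
#' shape parameter, the Bayes rules have closed forms:
#'
#' * squared-error loss (SELF): the posterior mean \eqn{A/B};
#' * LINEX loss with asymmetry \eqn{a \neq 0}:
#'   \eqn{-\frac{1}{a}\log E[e^{-a\vartheta}] = \frac{A}{a}\log(1 + a/B)},
#'   defined for \eqn{a > -B};
#' * composite LINEX (the symmetrized sum of LINEX at \eqn{\pm a}, \eqn{a > 0}):
#'   \eqn{\frac{1}{2a}\log\frac{E[e^{a\vartheta}]}{E[e^{-a\vartheta}]}
#'        = \frac{A}{2a}\log\frac{B+a}{B-a}}, defined for \eqn{0 < a < B}
#'   (the moment generating function at \eqn{+a} must exist).
#'
#' As \eqn{a \to 0^+} both asymmetric rules tend to the posterior mean, and for
#' every valid \eqn{a}: LINEX < SELF < composite LINEX.
#'
#' @param post a `"gamma_posterior"` from [lomax_posterior()].
#' @param a loss asymmetry constant; see Details for the admissible range.
#' @return The scalar point estimate.
#' @examples
#' post <- lomax_posterior(lomax_prior("gamma"),
#'                         list(n = 20, T = 10))
#' bayes_self(post)
#' bayes_linex(post, a = 1)
#' bayes_clinex(post, a = 1)
#' @export
bayes_self <- function(post) {
  post <- as_posterior(post)
  post$shape / post$rate
}

#' @rdname bayes_self
#' @export
bayes_linex <- function(post, a) {
  post <- as_posterior(post)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("'a' must be a single finite number", call. = FALSE)
  if (a == 0)
    stop("'a' must be nonzero under LINEX loss; use bayes_self() for a -> 0",
         call. = FALSE)
  if (a <= -post$rate)
    stop(sprintf("E[exp(-a*theta)] does not exist for a = %g <= -B = %g",
                 a, -post$rate), call. = FALSE)
  (post$shape / a) * log1p(a / post$rate)
}

#' @rdname bayes_self
#' @export
bayes_clinex <- function(post, a) {
  post <- as_posterior(post)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number under composite LINEX loss",
         call. = FALSE)
  if (a >= post$rate)
    stop(sprintf("E[exp(a*theta)] does not exist for a = %g >= B = %g",
                 a, post$rate), call. = FALSE)
  # (A/2a) log((B+a)/(B-a)) written via atanh, stable as a -> 0+
  (post$shape / a) * atanh(a / post$rate)
}

#' One-call Bayes estimate of the Lomax shape
#'
#' Dispatches a (prior, loss) pair to the closed-form rules in
#' [bayes_self()], [bayes_linex()] and [bayes_clinex()]. The twelve
#' prior-by-loss combinations cover the four priors of [lomax_prior()] under
#' squared-error, LINEX and composite-LINEX loss.
#'
#' @param stat a `"lomax_suffstat"`.
#' @param prior a `"lomax_prior"`.
#' @param loss loss function.
#' @param a asymmetry constant for the LINEX losses (ignored under `"self"`).
#' @return The scalar point estimate.
#' @examples
#' s <- lomax_suffstat(rlomax(30, 2, 2), scale = 2)
#' est_bayes(s, lomax_prior("gamma"), loss = "linex", a = 1.5)
#' @export
est_bayes <- function(stat, prior, loss = c("self", "linex", "clinex"), a = 1) {
  loss <- match.arg(loss)
  post <- lomax_posterior(prior, stat)
  switch(loss,
         self = bayes_self(post),
         linex = bayes_linex(post, a),
         clinex = bayes_clinex(post, a))
}
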