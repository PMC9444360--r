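# Quadrature oracles over a Gamma(A, rate B) posterior, independent of the
# package's closed forms. Integrands are evaluated on the log scale so the
# moment generating function at +a does not overflow.

post_mean_quad <- function(A, B) {
  stats::integrate(function(th) th * stats::dgamma(th, A, rate = B),
                   stats::qgamma(1e-15, A, rate = B),
                   stats::qgamma(1 - 1e-15, A, rate = B),
                   rel.tol = 1e-12)$value
}

post_mgf_quad <- function(A, B, a) {
  # the integrand is a tilted Gamma(A, B - a) kernel; integrate over its
  # effective support so the quadrature never misses the mass spike
  lo <- stats::qgamma(1e-15, A, rate = B - a)
  up <- stats::qgamma(1 - 1e-15, A, rate = B - a)
  stats::integrate(function(th) exp(a * th + stats::dgamma(th, A, rate = B, log = TRUE)),
                   lo, up, rel.tol = 1e-12, subdivisions = 1000L)$value
}

linex_quad <- function(A, B, a) -log(post_mgf_quad(A, B, -a)) / a

clinex_quad <- function(A, B, a) {
  log(post_mgf_quad(A, B, a) / post_mgf_quad(A, B, -a)) / (2 * a)
}

tmin_of <- function(g) {
  t <- attr(g, "t_min")
  if (is.null(t)) 0 else t
}
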