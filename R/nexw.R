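#' The new extended Weibull (NE-W) distribution
#'
#' The NE-X family applied to the Weibull baseline
#' \eqn{F(x) = 1 - e^{-\gamma x^a}}:
#' \deqn{G(x) = 1 - \left[\frac{1 - (1 - e^{-\gamma x^a})^2}
#'   {1 - (1-\theta)(1 - e^{-\gamma x^a})^2}\right]^\theta, \quad x \ge 0.}
#' The three parameters give densities ranging from exponential-like
#' decreasing shapes (\eqn{a, \theta < 1}) to unimodal right-skewed shapes,
#' and hazard rates that can be increasing, decreasing, unimodal or
#' bathtub-shaped, which makes the model useful for remission-time,
#' failure-time and insurance-loss data.
#'
#' @param theta extension parameter, \eqn{\theta > 0}.
#' @param a Weibull shape, \eqn{a > 0}.
#' @param gamma Weibull rate-like scale, \eqn{\gamma > 0}.
#' @return `nexw_model()` returns an [nex_model()] with Weibull baseline.
#' @examples
#' m <- nexw_model(theta = 2, a = 1, gamma = 1)
#' nex_quantile(m, 0.64)   # log(2): baseline cdf 1/2 at the 64th percentile
#' @export
nexw_model <- function(theta, a, gamma) {
  nex_model(theta, weibull_model(a, gamma))
}

#' @rdname nexw_model
#' @param x,q numeric vector of (nonnegative) evaluation points.
#' @param p numeric vector of probabilities in \eqn{[0, 1)}.
#' @param n number of draws.
#' @param seed optional integer seed for [rnexw()].
#' @param log,log.p logical; return log density / log probability?
#' @export
dnexw <- function(x, theta, a, gamma, log = FALSE) {
  nex_pdf(nexw_model(theta, a, gamma), x, log = log)
}

#' @rdname nexw_model
#' @export
pnexw <- function(q, theta, a, gamma, log.p = FALSE) {
  nex_cdf(nexw_model(theta, a, gamma), q, log.p = log.p)
}

#' @rdname nexw_model
#' @export
qnexw <- function(p, theta, a, gamma) {
  nex_quantile(nexw_model(theta, a, gamma), p)
}

#' @rdname nexw_model
#' @export
rnexw <- function(n, theta, a, gamma, seed = NULL) {
  nex_sample(nexw_model(theta, a, gamma), n, seed = seed)
}
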