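#' Baseline distribution objects
#'
#' A baseline model packages the cumulative distribution function, density,
#' quantile function and support of a parent ("baseline") lifetime
#' distribution \eqn{F(x; \xi)}.  The extended-family machinery
#' ([nex_model()], [nex_cdf()], ...) operates on any such object, so new
#' baselines can be extended without touching the family code.
#'
#' @param name character scalar identifying the distribution.
#' @param params named numeric vector of baseline parameters \eqn{\xi}.
#' @param cdf vectorised function of `x` returning \eqn{F(x)}.
#' @param pdf vectorised function of `x` returning \eqn{f(x)}.
#' @param quantile vectorised function of `p` in \eqn{[0, 1)} returning
#'   \eqn{F^{-1}(p)}; may be `NULL`, in which case the extended quantile
#'   falls back to bracketed root finding on the cdf.
#' @param support_low lower endpoint of the support (0 for lifetime models).
#' @param log_sf optional vectorised function returning
#'   \eqn{\log(1 - F(x))} without cancellation; defaults to
#'   `log1p(-cdf(x))`.
#' @param log_pdf optional vectorised function returning \eqn{\log f(x)};
#'   defaults to `log(pdf(x))`.
#' @param quantile_sf optional vectorised function of a survival
#'   probability `s` returning the `x` with \eqn{1 - F(x) = s}; supplying
#'   it keeps extended-family quantiles accurate deep in the upper tail.
#'
#' @return an object of class `nex_baseline`.
#' @seealso [weibull_model()] for the ready-made Weibull baseline.
#' @export
baseline_model <- function(name, params, cdf, pdf, quantile = NULL,
                           support_low = 0,
                           log_sf = NULL, log_pdf = NULL,
                           quantile_sf = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(params), !is.null(names(params)),
            is.function(cdf), is.function(pdf))
  if (is.null(log_sf)) log_sf <- function(x) log1p(-cdf(x))
  if (is.null(log_pdf)) log_pdf <- function(x) log(pdf(x))
  structure(
    list(name = name, params = params, cdf = cdf, pdf = pdf,
         quantile = quantile, support_low = support_low,
         log_sf = log_sf, log_pdf = log_pdf, quantile_sf = quantile_sf),
    class = "nex_baseline")
}

#' @export
print.nex_baseline <- function(x, ...) {
  cat(sprintf("<baseline distribution: %s>\n", x$name))
  cat("  parameters: ",
      paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Two-parameter Weibull baseline
#'
#' The Weibull distribution in its rate-like parameterisation
#' \eqn{F(x) = 1 - e^{-\gamma x^a}} with shape \eqn{a > 0} and scale-rate
#' \eqn{\gamma > 0}.  This is the baseline of the NE-W distribution.
#'
#' @param a shape parameter, \eqn{a > 0}.
#' @param gamma rate-like scale parameter, \eqn{\gamma > 0}.
#' @return a [baseline_model()] object.
#' @examples
#' wb <- weibull_model(a = 1, gamma = 1)
#' wb$cdf(1)       # 1 - exp(-1)
#' wb$quantile(.5) # log(2)
#' @export
weibull_model <- function(a, gamma) {
  check_positive_scalar(a, "a")
  check_positive_scalar(gamma, "gamma")
  force(a); force(gamma)
  baseline_model(
    name = "weibull",
    params = c(a = as.double(a), gamma = as.double(gamma)),
    cdf = function(x) ifelse(x <= 0, 0, -expm1(-gamma * x^a)),
    pdf = function(x) ifelse(x <= 0, 0, a * gamma * x^(a - 1) * exp(-gamma * x^a)),
    quantile = function(p) (-log1p(-p) / gamma)^(1 / a),
    support_low = 0,
    log_sf = function(x) ifelse(x <= 0, 0, -gamma * x^a),
    log_pdf = function(x) ifelse(x <= 0, -Inf,
                                 log(a) + log(gamma) + (a - 1) * log(x) - gamma * x^a),
    quantile_sf = function(s) (-log(s) / gamma)^(1 / a)
  )
}
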