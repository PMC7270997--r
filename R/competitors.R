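## Registry of the fitted lifetime models: the NE-W distribution itself and
## the competitor distributions used in the comparative studies.  Each entry
## bundles parameter names, cdf, log-density, and a moment/least-squares
## initialiser for maximum-likelihood fitting.  All parameters are positive
## reals; positivity is enforced during fitting by optimising on the log
## scale.

## Least-squares Weibull start: regress log(-log S_n(x)) on log x using
## midpoint plotting positions.  Used directly and as a seed for the
## Weibull-based extensions.
weibull_ls_init <- function(x) {
  x <- sort(x)
  n <- length(x)
  p <- (seq_len(n) - 0.5) / n
  lx <- log(x)
  ly <- log(-log1p(-p))
  ok <- is.finite(lx) & is.finite(ly)
  if (sum(ok) < 2L) return(c(a = 1, gamma = 1 / mean(x)))
  fit <- stats::lm.fit(cbind(1, lx[ok]), ly[ok])
  a <- max(fit$coefficients[2L], 1e-3)
  gamma <- exp(fit$coefficients[1L])
  c(a = unname(a), gamma = unname(max(gamma, 1e-12)))
}

## Stable (alpha1^F - 1)/(alpha1 - 1) and its F-derivative factor, written
## through expm1 so the alpha1 -> 1 limit (plain Weibull) is exact.
aptw_ratio <- function(Fx, l) expm1(Fx * l) / expm1(l)

.registry <- list(
  nexw = list(
    label = "NE-W", params = c("theta", "a", "gamma"),
    cdf = function(x, p) pnexw(x, p[["theta"]], p[["a"]], p[["gamma"]]),
    logpdf = function(x, p) dnexw(x, p[["theta"]], p[["a"]], p[["gamma"]], log = TRUE),
    init = function(x) c(theta = 1, weibull_ls_init(x))
  ),
  weibull = list(
    label = "Weibull", params = c("a", "gamma"),
    cdf = function(x, p) ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["a"]])),
    logpdf = function(x, p) ifelse(x <= 0, -Inf,
      log(p[["a"]]) + log(p[["gamma"]]) + (p[["a"]] - 1) * log(x) - p[["gamma"]] * x^p[["a"]]),
    init = function(x) weibull_ls_init(x)
  ),
  exponential = list(
    label = "Exponential", params = c("gamma"),
    cdf = function(x, p) ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x)),
    logpdf = function(x, p) ifelse(x <= 0, -Inf, log(p[["gamma"]]) - p[["gamma"]] * x),
    init = function(x) c(gamma = 1 / mean(x))
  ),
  fwe = list(
    label = "FWE", params = c("alpha", "sigma", "gamma"),
    cdf = function(x, p) {
      h <- p[["sigma"]] * x^2 - p[["gamma"]] * x^(-p[["alpha"]])
      ifelse(x <= 0, 0, -expm1(-exp(h)))
    },
    logpdf = function(x, p) {
      h <- p[["sigma"]] * x^2 - p[["gamma"]] * x^(-p[["alpha"]])
      hp <- 2 * p[["sigma"]] * x + p[["alpha"]] * p[["gamma"]] * x^(-p[["alpha"]] - 1)
      ifelse(x <= 0, -Inf, log(hp) + h - exp(h))
    },
    init = function(x) {
      m <- stats::median(x)
      c(alpha = 1, sigma = log(2)^0.5 / m^2, gamma = log(2)^0.5 * m)
    }
  ),
  aptw = list(
    label = "APTW", params = c("alpha1", "alpha", "gamma"),
    cdf = function(x, p) {
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      l <- log(p[["alpha1"]])
      if (abs(l) < 1e-12) Fx else aptw_ratio(Fx, l)
    },
    logpdf = function(x, p) {
      l <- log(p[["alpha1"]])
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      lf <- ifelse(x <= 0, -Inf,
        log(p[["alpha"]]) + log(p[["gamma"]]) + (p[["alpha"]] - 1) * log(x) -
          p[["gamma"]] * x^p[["alpha"]])
      if (abs(l) < 1e-12) lf else lf + log(l / expm1(l)) + Fx * l
    },
    init = function(x) c(alpha1 = 2, weibull_ls_init(x)[c("a", "gamma")] |>
                           stats::setNames(c("alpha", "gamma")))
  ),
  mow = list(
    label = "MOW", params = c("alpha", "gamma", "sigma"),
    cdf = function(x, p) {
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      Fx / (p[["sigma"]] + (1 - p[["sigma"]]) * Fx)
    },
    logpdf = function(x, p) {
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      lf <- ifelse(x <= 0, -Inf,
        log(p[["alpha"]]) + log(p[["gamma"]]) + (p[["alpha"]] - 1) * log(x) -
          p[["gamma"]] * x^p[["alpha"]])
      lf + log(p[["sigma"]]) - 2 * log(p[["sigma"]] + (1 - p[["sigma"]]) * Fx)
    },
    init = function(x) c(weibull_ls_init(x) |>
                           stats::setNames(c("alpha", "gamma")), sigma = 1)
  ),
  mw = list(
    label = "MW", params = c("alpha", "gamma", "theta"),
    cdf = function(x, p) ifelse(x <= 0, 0,
      -expm1(-p[["theta"]] * x - p[["gamma"]] * x^p[["alpha"]])),
    logpdf = function(x, p) ifelse(x <= 0, -Inf,
      log(p[["theta"]] + p[["alpha"]] * p[["gamma"]] * x^(p[["alpha"]] - 1)) -
        p[["theta"]] * x - p[["gamma"]] * x^p[["alpha"]]),
    init = function(x) {
      w <- weibull_ls_init(x)
      c(alpha = unname(w["a"]), gamma = unname(w["gamma"]),
        theta = 0.5 / mean(x))
    }
  ),
  exaptw = list(
    label = "Ex-APTW", params = c("alpha1", "alpha", "gamma"),
    cdf = function(x, p) {
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      (p[["alpha1"]]^Fx - exp(Fx)) / (p[["alpha1"]] - exp(1))
    },
    logpdf = function(x, p) {
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      lf <- ifelse(x <= 0, -Inf,
        log(p[["alpha"]]) + log(p[["gamma"]]) + (p[["alpha"]] - 1) * log(x) -
          p[["gamma"]] * x^p[["alpha"]])
      dg <- (log(p[["alpha1"]]) * p[["alpha1"]]^Fx - exp(Fx)) / (p[["alpha1"]] - exp(1))
      ifelse(dg > 0, lf + log(dg), -Inf)
    },
    init = function(x) c(alpha1 = 5, weibull_ls_init(x)[c("a", "gamma")] |>
                           stats::setNames(c("alpha", "gamma")))
  ),
  kuw = list(
    label = "Ku-W", params = c("alpha", "gamma", "a", "b"),
    cdf = function(x, p) {
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      -expm1(p[["b"]] * log1p(-Fx^p[["a"]]))
    },
    logpdf = function(x, p) {
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      lf <- ifelse(x <= 0, -Inf,
        log(p[["alpha"]]) + log(p[["gamma"]]) + (p[["alpha"]] - 1) * log(x) -
          p[["gamma"]] * x^p[["alpha"]])
      lf + log(p[["a"]]) + log(p[["b"]]) + (p[["a"]] - 1) * log(Fx) +
        (p[["b"]] - 1) * log1p(-Fx^p[["a"]])
    },
    init = function(x) c(weibull_ls_init(x) |>
                           stats::setNames(c("alpha", "gamma")), a = 1, b = 1)
  ),
  bw = list(
    label = "BW", params = c("alpha", "gamma", "a", "b"),
    cdf = function(x, p) {
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      stats::pbeta(Fx, p[["a"]], p[["b"]])
    },
    logpdf = function(x, p) {
      Fx <- ifelse(x <= 0, 0, -expm1(-p[["gamma"]] * x^p[["alpha"]]))
      lf <- ifelse(x <= 0, -Inf,
        log(p[["alpha"]]) + log(p[["gamma"]]) + (p[["alpha"]] - 1) * log(x) -
          p[["gamma"]] * x^p[["alpha"]])
      lf + stats::dbeta(Fx, p[["a"]], p[["b"]], log = TRUE)
    },
    init = function(x) c(weibull_ls_init(x) |>
                           stats::setNames(c("alpha", "gamma")), a = 1, b = 1)
  ),
  lomax = list(
    label = "Lomax", params = c("alpha", "gamma"),
    cdf = function(x, p) ifelse(x <= 0, 0,
      -expm1(-p[["alpha"]] * log1p(x / p[["gamma"]]))),
    logpdf = function(x, p) ifelse(x <= 0, -Inf,
      log(p[["alpha"]]) - log(p[["gamma"]]) -
        (p[["alpha"]] + 1) * log1p(x / p[["gamma"]])),
    init = function(x) c(alpha = 2, gamma = mean(x))
  ),
  burr = list(
    label = "Burr", params = c("c", "k"),
    cdf = function(x, p) ifelse(x <= 0, 0,
      -expm1(-p[["k"]] * log1p(x^p[["c"]]))),
    logpdf = function(x, p) ifelse(x <= 0, -Inf,
      log(p[["c"]]) + log(p[["k"]]) + (p[["c"]] - 1) * log(x) -
        (p[["k"]] + 1) * log1p(x^p[["c"]])),
    init = function(x) c(c = 1.5, k = 2)
  )
)

get_dist <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(match(name, names(.registry)))) {
    stop(sprintf("unknown model '%s'; available: %s",
                 paste(name, collapse = ","),
                 paste(names(.registry), collapse = ", ")), call. = FALSE)
  }
  .registry[[name]]
}

check_params <- function(dist, params) {
  params <- unlist(params)
  if (is.null(names(params)) || !setequal(names(params), dist$params)) {
    stop(sprintf("parameters for '%s' must be named %s", dist$label,
                 paste(dist$params, collapse = ", ")), call. = FALSE)
  }
  params <- params[dist$params]
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop(sprintf("all parameters of '%s' must be positive and finite",
                 dist$label), call. = FALSE)
  }
  params
}

#' Registered lifetime models
#'
#' `dist_names()` lists the models available to [fit_mle()] and
#' [compare_models()]; `competitor_cdf()` and `competitor_pdf()` evaluate
#' any registered model's distribution and density functions.
#'
#' The registry holds the NE-W model and the comparison set: Weibull,
#' exponential, flexible Weibull extension (FWE), alpha-power transformed
#' Weibull (APTW), Marshall-Olkin Weibull (MOW), modified Weibull (MW),
#' extended alpha-power transformed Weibull (Ex-APTW), Kumaraswamy Weibull
#' (Ku-W), beta Weibull (BW), Lomax, and Burr-XII.
#'
#' @param name model identifier, one of `dist_names()`.
#' @param params named numeric vector of positive parameters; required
#'   names are model-specific (e.g. `c(theta=, a=, gamma=)` for `"nexw"`,
#'   `c(c=, k=)` for `"burr"`).
#' @param x numeric vector of evaluation points.
#' @param log logical; return the log density?
#' @return `competitor_cdf()`/`competitor_pdf()` return a numeric vector;
#'   `dist_names()` a character vector; `n_params()` the number of free
#'   parameters of a model.
#' @examples
#' competitor_cdf("burr", c(c = 1, k = 1), 1)   # 0.5
#' competitor_cdf("mow", c(alpha = 2, gamma = 1, sigma = 1), 1.3)
#' @export
dist_names <- function() names(.registry)

#' @rdname dist_names
#' @export
competitor_cdf <- function(name, params, x) {
  d <- get_dist(name)
  d$cdf(x, check_params(d, params))
}

#' @rdname dist_names
#' @export
competitor_pdf <- function(name, params, x, log = FALSE) {
  d <- get_dist(name)
  lp <- d$logpdf(x, check_params(d, params))
  lp[x <= 0] <- -Inf   # support is (0, Inf) for every registered model
  if (log) lp else exp(lp)
}

#' @rdname dist_names
#' @export
n_params <- function(name) length(get_dist(name)$params)
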