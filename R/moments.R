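## Moments of NE-X models.  Adaptive quadrature is the canonical engine;
## the binomial-series representation is provided as an independent
## cross-check for integer theta.

## Integrate `fun(x)` against the model density over the support, split at
## the median (integrate() applies its own transformation on the infinite
## tail piece).
nex_integrate <- function(model, fun, rel.tol = 1e-10, log_fun = NULL) {
  lo <- model$baseline$support_low
  med <- nex_quantile(model, 0.5)
  f <- if (is.null(log_fun)) {
    function(x) fun(x) * nex_pdf(model, x)
  } else {
    ## integrand assembled in log space to survive exp-growing factors
    function(x) exp(log_fun(x) + nex_pdf(model, x, log = TRUE))
  }
  r1 <- stats::integrate(f, lo, med, rel.tol = rel.tol, abs.tol = 1e-12,
                         subdivisions = 400L, stop.on.error = FALSE)
  r2 <- stats::integrate(f, med, Inf, rel.tol = rel.tol, abs.tol = 1e-12,
                         subdivisions = 400L, stop.on.error = FALSE)
  bad <- !(r1$message %in% c("OK", "roundoff error was detected")) ||
    !(r2$message %in% c("OK", "roundoff error was detected"))
  if (bad) {
    stop(sprintf("quadrature did not converge (lower piece: %s; tail: %s)",
                 r1$message, r2$message), call. = FALSE)
  }
  r1$value + r2$value
}

#' Raw moments of an NE-X model by adaptive quadrature
#'
#' Computes \eqn{\mu'_r = \int x^r g(x)\,dx} over the support, with the
#' domain split at the median and an adaptive transformation on the
#' unbounded tail.
#'
#' @param model an [nex_model()] object.
#' @param r nonnegative integer moment order.
#' @return the raw moment \eqn{\mu'_r} (1 for order zero).
#' @examples
#' raw_moment(nexw_model(1, 1, 1), 1)   # 1.5
#' @export
raw_moment <- function(model, r) {
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r != floor(r)) {
    stop("`r` must be a single nonnegative integer", call. = FALSE)
  }
  if (r == 0) return(1)
  nex_integrate(model, function(x) x^r)
}

## K_{r,m} = int x^r f(x) F(x)^m dx, the baseline-moment kernel of the
## series representation.
moment_kernel <- function(baseline, r, m) {
  f <- function(x) {
    x^r * baseline$pdf(x) * exp(m * log(baseline$cdf(x)))
  }
  med <- if (is.null(baseline$quantile)) invert_cdf(baseline, 0.5) else baseline$quantile(0.5)
  r1 <- stats::integrate(f, baseline$support_low, med, rel.tol = 1e-10,
                         abs.tol = 1e-13, subdivisions = 400L)
  r2 <- stats::integrate(f, med, Inf, rel.tol = 1e-10,
                         abs.tol = 1e-13, subdivisions = 400L)
  r1$value + r2$value
}

#' Raw moments via the binomial series representation
#'
#' Cross-check of [raw_moment()]: expanding the density's denominator
#' \eqn{[1-(1-\theta)F^2]^{-(\theta+1)}} as a binomial series and the
#' factor \eqn{(1-F^2)^{\theta-1}} by the binomial theorem gives
#' \deqn{\mu'_r = 2\theta^2 \sum_{i \ge 0} \sum_{j=0}^{\theta-1}
#'   (-1)^j \binom{i+\theta}{\theta} \binom{\theta-1}{j} (1-\theta)^i
#'   K_{r,\,2(i+j)+1},}
#' with the baseline kernel \eqn{K_{r,m} = \int x^r f F^m dx}.  The finite
#' inner sum has upper limit \eqn{\theta - 1} and is valid only for
#' positive integer \eqn{\theta}; other values are refused rather than
#' silently generalised.
#'
#' For \eqn{\theta \ge 2} the outer terms alternate in sign with
#' non-decaying (for \eqn{\theta > 2}, geometrically growing) magnitude,
#' because the binomial series is used outside its radius of convergence:
#' \eqn{|(1-\theta)F^2| \ge 1} for \eqn{F} near 1.  The termwise-integrated
#' series is therefore resummed with Wynn's epsilon algorithm (a Padé-type
#' accelerant whose even columns converge to the analytic continuation),
#' which recovers the quadrature moment to near machine precision for
#' moderate `i_max`.
#'
#' @param model an [nex_model()] object whose `theta` is a positive integer.
#' @param r positive integer moment order.
#' @param i_max truncation of the outer series (default 30).
#' @return the resummed truncated series value.
#' @seealso [raw_moment()]
#' @export
series_raw_moment <- function(model, r, i_max = 30L) {
  th <- model$theta
  if (abs(th - round(th)) > 1e-9) {
    stop("the series representation requires a positive integer `theta` ",
         "(the inner binomial sum has upper limit theta - 1)", call. = FALSE)
  }
  th <- as.integer(round(th))
  if (i_max < 0) stop("`i_max` must be nonnegative", call. = FALSE)
  b <- model$baseline
  i_top <- if (th == 1L) 0L else as.integer(i_max)   # (1-theta)^i kills i > 0
  K <- new.env(parent = emptyenv())
  getK <- function(m) {
    key <- as.character(m)
    if (is.null(K[[key]])) K[[key]] <- moment_kernel(b, r, m)
    K[[key]]
  }
  terms <- vapply(0:i_top, function(i) {
    inner <- sum(vapply(0:(th - 1L), function(j) {
      (-1)^j * choose(th - 1L, j) * getK(2L * (i + j) + 1L)
    }, numeric(1)))
    2 * th^2 * choose(i + th, th) * (1 - th)^i * inner
  }, numeric(1))
  psums <- cumsum(terms)
  if (th == 1L || length(psums) < 4L) return(psums[length(psums)])
  wynn_epsilon(psums)
}

## Wynn's epsilon table; returns the deepest even-column entry.
wynn_epsilon <- function(S) {
  e_prev <- rep(0, length(S) + 1L)
  e_cur <- S
  best <- S[length(S)]
  k <- 0L
  repeat {
    k <- k + 1L
    if (length(e_cur) < 2L) break
    d <- diff(e_cur)
    if (any(abs(d) < 1e-300)) break
    e_next <- e_prev[2:length(e_cur)] + 1 / d
    e_prev <- e_cur
    e_cur <- e_next
    if (k %% 2L == 0L) best <- e_cur[length(e_cur)]
    if (length(e_cur) < 3L) break
  }
  best
}

#' Descriptive measures of an NE-X model
#'
#' Mean, variance, skewness and kurtosis.  The central moments are obtained
#' by direct central quadrature \eqn{\int (x-\mu)^k g\,dx} rather than by
#' differencing raw moments, which avoids catastrophic cancellation for
#' heavy-tailed parameter settings.  Skewness is
#' \eqn{\mu_3/\mu_2^{3/2}} and kurtosis \eqn{\mu_4/\mu_2^2} (so the normal
#' reference value is 3).
#'
#' @param model an [nex_model()] object with finite first four moments.
#' @return an object of class `nex_moments`: a list with `mean`,
#'   `variance`, `sk`, `kur`, `raw_moments` (orders 1-4) and the model
#'   parameters.
#' @examples
#' describe(nexw_model(1, 1, 1))   # mean 1.5, variance 1.25
#' @export
describe <- function(model) {
  mu <- raw_moment(model, 1)
  mu2 <- nex_integrate(model, function(x) (x - mu)^2)
  mu3 <- nex_integrate(model, function(x) (x - mu)^3)
  mu4 <- nex_integrate(model, function(x) (x - mu)^4)
  raw <- c(mu, vapply(2:4, function(r) raw_moment(model, r), numeric(1)))
  structure(
    list(mean = mu, variance = mu2,
         sk = mu3 / mu2^1.5, kur = mu4 / mu2^2,
         raw_moments = raw,
         theta = model$theta, baseline_params = model$baseline$params),
    class = "nex_moments")
}

#' @export
print.nex_moments <- function(x, ...) {
  cat(sprintf("NE-X descriptive measures (theta = %g; %s)\n", x$theta,
              paste(sprintf("%s = %g", names(x$baseline_params),
                            x$baseline_params), collapse = ", ")))
  cat(sprintf("  mean %.6g  variance %.6g  skewness %.6g  kurtosis %.6g\n",
              x$mean, x$variance, x$sk, x$kur))
  invisible(x)
}

#' @export
as.data.frame.nex_moments <- function(x, ...) {
  cbind(data.frame(theta = x$theta),
        as.data.frame(as.list(x$baseline_params)),
        data.frame(Mean = x$mean, Variance = x$variance,
                   Sk = x$sk, Kur = x$kur))
}

#' Moment generating function of an NE-X model
#'
#' Either the truncated moment series
#' \eqn{M(t) = \sum_{r=0}^{r_{max}} t^r \mu'_r / r!} or direct quadrature
#' of \eqn{\int e^{tx} g(x) dx}; the two serve as mutual cross-checks.
#' The series signals an error when its terms start growing (a sign that
#' `t` is outside the radius of convergence).
#'
#' @param model an [nex_model()] object.
#' @param t evaluation point.
#' @param r_max series truncation order (series method only).
#' @param method `"series"` or `"quadrature"`.
#' @return the value of the mgf at `t`.
#' @examples
#' mgf(nexw_model(1, 1, 1), 0.5)   # 8/3
#' @export
mgf <- function(model, t, r_max = 40L, method = c("series", "quadrature")) {
  method <- match.arg(method)
  if (method == "quadrature") {
    return(nex_integrate(model, log_fun = function(x) t * x))
  }
  if (t == 0) return(1)
  terms <- numeric(r_max + 1L)
  terms[1L] <- 1
  for (r in seq_len(r_max)) {
    terms[r + 1L] <- t^r * raw_moment(model, r) / factorial(r)
    if (r > 4L && abs(terms[r + 1L]) > abs(terms[r]) &&
        abs(terms[r]) > abs(terms[r - 1L])) {
      stop("mgf series diverges at t = ", t,
           " (terms growing); t is outside the radius of convergence",
           call. = FALSE)
    }
    if (abs(terms[r + 1L]) < 1e-14 * abs(sum(terms[1:r]))) {
      return(sum(terms[1:(r + 1L)]))
    }
  }
  sum(terms)
}

#' Descriptive-measure grids for the NE-W distribution
#'
#' Recomputes the mean/variance/skewness/kurtosis of the NE-W distribution
#' over a grid of parameter values, one row per combination, in the column
#' order (theta, a, gamma, Mean, Variance, Sk, Kur).
#'
#' @param theta,a,gamma numeric vectors; the grid is their full crossing.
#' @return a data.frame with one row per parameter combination.
#' @export
descriptive_grid <- function(theta, a, gamma) {
  grid <- expand.grid(theta = theta, a = a, gamma = gamma,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    as.data.frame(describe(nexw_model(grid$theta[i], grid$a[i], grid$gamma[i])))
  })
  do.call(rbind, rows)
}
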