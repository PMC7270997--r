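#' Log-likelihood of a registered model
#'
#' \eqn{\ell(\Theta) = \sum_i \log g(x_i; \Theta)}, accumulated from
#' log-space density terms.  For NE-X models this expands to
#' \eqn{n\log 2 + 2n\log\theta + \sum\log f + (\theta-1)\sum\log(1-F^2)
#' + \sum\log F - (\theta+1)\sum\log(1-(1-\theta)F^2)}.
#'
#' @param model_name a registered model, see [dist_names()].
#' @param params named numeric vector of positive parameters.
#' @param data numeric vector of strictly positive observations.
#' @return the log-likelihood value.
#' @examples
#' log_likelihood("nexw", c(theta = 1, a = 1, gamma = 1), log(2))  # log(1/2)
#' @export
log_likelihood <- function(model_name, params, data) {
  d <- get_dist(model_name)
  params <- check_params(d, params)
  check_data(data)
  sum(d$logpdf(data, params))
}

check_data <- function(data) {
  if (!is.numeric(data) || length(data) == 0L) {
    stop("`data` must be a nonempty numeric vector", call. = FALSE)
  }
  bad <- which(!is.finite(data) | data <= 0)
  if (length(bad)) {
    stop(sprintf("data must be strictly positive and finite; offending index: %d (value %g)",
                 bad[1L], data[bad[1L]]), call. = FALSE)
  }
  invisible(data)
}

#' Maximum-likelihood fit of a registered model
#'
#' Maximises the log-likelihood over the model's positive parameter space
#' by optimising on the log-parameter scale (which enforces positivity
#' without explicit constraints).  A deterministic moment/least-squares
#' start is tried first, followed by `n_restarts` log-uniform random
#' restarts in \eqn{[10^{-2}, 10^2]} per parameter; each start is polished
#' with Nelder-Mead followed by quasi-Newton refinement, and the best local
#' optimum is kept (ties broken by the smaller parameter norm).
#'
#' @param model_name a registered model, see [dist_names()].
#' @param data numeric vector of strictly positive observations.
#' @param init optional named vector of starting values (original scale).
#' @param n_restarts number of additional random restarts (default 3).
#' @param seed optional integer seed governing the random restarts.
#' @param compute_se compute observed-information standard errors?
#' @return an object of class `nex_fit` with elements `model_name`,
#'   `label`, `estimates`, `standard_errors`, `loglik`, `n`, `k`,
#'   `converged`, `n_restarts_used`.
#' @export
fit_mle <- function(model_name, data, init = NULL, n_restarts = 3L,
                    seed = NULL, compute_se = TRUE) {
  d <- get_dist(model_name)
  check_data(data)
  p <- length(d$params)

  negll <- function(logpar) {
    par <- stats::setNames(exp(logpar), d$params)
    v <- suppressWarnings(sum(d$logpdf(data, par)))
    if (!is.finite(v)) return(1e10)
    -v
  }

  start0 <- if (is.null(init)) d$init(data) else check_params(d, init)
  starts <- list(pmin(pmax(start0[d$params], 1e-8), 1e8))
  if (n_restarts > 0L) {
    rand <- with_seed(seed, matrix(stats::runif(n_restarts * p, -2, 2),
                                   n_restarts, p))
    for (i in seq_len(n_restarts)) {
      starts[[i + 1L]] <- stats::setNames(10^rand[i, ], d$params)
    }
  }

  best <- NULL
  used <- 0L
  for (s in starts) {
    used <- used + 1L
    res <- tryCatch({
      r1 <- if (p == 1L) {
        stats::optim(log(s), negll, method = "Brent",
                     lower = -30, upper = 30)
      } else {
        stats::optim(log(s), negll, method = "Nelder-Mead",
                     control = list(maxit = 2000L, reltol = 1e-10))
      }
      r2 <- tryCatch(
        stats::optim(r1$par, negll, method = "BFGS",
                     control = list(maxit = 200L, reltol = 1e-12)),
        error = function(e) r1)
      if (r2$value <= r1$value) r2 else r1
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
    if (is.null(best) ||
        res$value < best$value - 1e-8 ||
        (abs(res$value - best$value) <= 1e-8 &&
         sum(exp(res$par)^2) < sum(exp(best$par)^2))) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop(sprintf("all %d start(s) failed to produce a finite likelihood for '%s'",
                 used, d$label), call. = FALSE)
  }

  est <- stats::setNames(exp(best$par), d$params)
  out <- structure(
    list(model_name = model_name, label = d$label,
         estimates = est, standard_errors = rep(NA_real_, p),
         loglik = -best$value, n = length(data), k = p,
         converged = TRUE, n_restarts_used = used),
    class = "nex_fit")
  if (compute_se) {
    out$standard_errors <- standard_errors(out, data)
  }
  out
}

#' Observed-information standard errors
#'
#' Wald standard errors from the observed information: the square roots of
#' the diagonal of the inverse of the negative Hessian of the
#' log-likelihood at the maximum, with the Hessian computed by central
#' finite differences on the original parameter scale.  If the information
#' matrix is not positive definite a warning is raised and `NA` standard
#' errors are returned.
#'
#' @param fit an `nex_fit` object from [fit_mle()].
#' @param data the data the model was fitted to.
#' @return named numeric vector of standard errors (possibly `NA`).
#' @export
standard_errors <- function(fit, data) {
  d <- get_dist(fit$model_name)
  check_data(data)
  ll <- function(par) {
    v <- suppressWarnings(sum(d$logpdf(data, stats::setNames(par, d$params))))
    if (!is.finite(v)) -1e10 else v
  }
  H <- tryCatch(num_hessian(ll, unname(fit$estimates)),
                error = function(e) NULL)
  p <- length(fit$estimates)
  failed <- stats::setNames(rep(NA_real_, p), names(fit$estimates))
  if (is.null(H) || any(!is.finite(H))) {
    warning("Hessian of the log-likelihood could not be computed; standard errors set to NA")
    return(failed)
  }
  info <- -H
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    warning("observed information is not positive definite; standard errors set to NA")
    return(failed)
  }
  se <- sqrt(diag(solve(info)))
  stats::setNames(se, names(fit$estimates))
}

#' @export
print.nex_fit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit: %s (n = %d)\n", x$label, x$n))
  est <- sprintf("%.4g (%.4g)", x$estimates, x$standard_errors)
  cat("  ", paste(sprintf("%s = %s", names(x$estimates), est),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  log-likelihood %.4f, %d start(s) used\n",
              x$loglik, x$n_restarts_used))
  invisible(x)
}

#' Serialise a fit as an estimate(se) table row
#'
#' One row in the reporting format used for estimate tables: the model
#' label followed by one `"estimate(se)"` string per parameter.
#'
#' @param fit an `nex_fit` object.
#' @return a one-row data.frame.
#' @export
fit_row <- function(fit) {
  vals <- sprintf("%.4g(%.4g)", fit$estimates, fit$standard_errors)
  df <- as.data.frame(as.list(stats::setNames(vals, names(fit$estimates))))
  cbind(data.frame(Dist = fit$label), df)
}
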