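#' Information criteria
#'
#' AIC \eqn{= 2k - 2\ell} and BIC \eqn{= k \log n - 2\ell}; lower values
#' indicate a preferable model.
#'
#' @param loglik maximised log-likelihood \eqn{\ell}.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @return named numeric vector `c(AIC = , BIC = )`.
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(k >= 0, n >= 1)
  c(AIC = 2 * k - 2 * loglik, BIC = k * log(n) - 2 * loglik)
}

#' Anderson-Darling statistic from fitted cdf values
#'
#' \deqn{AD = -n - \frac{1}{n}\sum_{i=1}^n (2i-1)\left[\log G_{(i)} +
#'   \log(1 - G_{(n-i+1)})\right]}
#' evaluated on the fitted cdf values of the sorted sample.  The statistic
#' weights tail discrepancies heavily; values of 0 or 1 in the input hit
#' the log singularities and are rejected.
#'
#' @param g sorted vector of fitted cdf values, all strictly inside (0, 1).
#' @return the AD statistic.
#' @examples
#' ad_stat(c(0.25, 0.75))
#' @export
ad_stat <- function(g) {
  check_sorted_cdf(g)
  if (any(g <= 0 | g >= 1)) {
    stop("fitted cdf values must lie strictly inside (0, 1) for the AD statistic",
         call. = FALSE)
  }
  n <- length(g)
  i <- seq_len(n)
  -n - sum((2 * i - 1) * (log(g) + log1p(-rev(g)))) / n
}

#' Cramer-von Mises statistic from fitted cdf values
#'
#' \deqn{CM = \frac{1}{12n} + \sum_{i=1}^n
#'   \left(\frac{2i-1}{2n} - G_{(i)}\right)^2,}
#' minimised (at \eqn{1/(12n)}) exactly when the fitted values sit on the
#' midpoint plotting positions.
#'
#' @param g sorted vector of fitted cdf values in \eqn{[0, 1]}.
#' @return the CM statistic.
#' @export
cm_stat <- function(g) {
  check_sorted_cdf(g)
  n <- length(g)
  i <- seq_len(n)
  1 / (12 * n) + sum(((2 * i - 1) / (2 * n) - g)^2)
}

#' Kolmogorov-Smirnov statistic and asymptotic p-value
#'
#' \eqn{D = \sup_x |G_n(x) - G(x)|} computed from the fitted cdf values of
#' the sorted sample via the two one-sided step gaps; the p-value uses the
#' asymptotic Kolmogorov distribution
#' \eqn{P(\sqrt{n} D > t) = 2\sum_{j\ge1} (-1)^{j-1} e^{-2 j^2 t^2}}.
#'
#' @param g sorted vector of fitted cdf values in \eqn{[0, 1]}.
#' @return a list with `statistic` and `p_value`.
#' @export
ks_stat <- function(g) {
  check_sorted_cdf(g)
  n <- length(g)
  i <- seq_len(n)
  D <- max(pmax(i / n - g, g - (i - 1) / n))
  list(statistic = D, p_value = kolmogorov_pvalue(sqrt(n) * D))
}

kolmogorov_pvalue <- function(t) {
  if (t <= 0) return(1)
  j <- 1:100
  terms <- (-1)^(j - 1) * exp(-2 * j^2 * t^2)
  min(1, max(0, 2 * sum(terms)))
}

check_sorted_cdf <- function(g) {
  if (!is.numeric(g) || length(g) == 0L || anyNA(g)) {
    stop("fitted cdf values must be a nonempty numeric vector", call. = FALSE)
  }
  if (is.unsorted(g)) {
    stop("fitted cdf values must be sorted ascending", call. = FALSE)
  }
  if (any(g < 0 | g > 1)) {
    stop("fitted cdf values must lie in [0, 1]", call. = FALSE)
  }
  invisible(g)
}

#' Goodness-of-fit report for one fitted model
#'
#' Computes AIC/BIC and the AD, CM and KS statistics (with asymptotic KS
#' p-value) for a fitted model, plus PP-plot coordinates (plotting
#' positions \eqn{i/(n+1)} against the fitted cdf) and the product-limit
#' (Kaplan-Meier) empirical survival coordinates.  All statistics plug in
#' the estimated parameters, so the p-values are conditional on the fit
#' (the usual, mildly anti-conservative convention for comparison tables).
#'
#' @param fit an `nex_fit` object.
#' @param data the data the model was fitted to.
#' @return an object of class `gof_report`: a list with `model_name`,
#'   `label`, `k`, `AIC`, `BIC`, `AD`, `CM`, `KS`, `ks_pvalue`,
#'   `pp_points`, `km_points`, and the `fit` itself.
#' @export
gof_report <- function(fit, data) {
  check_data(data)
  x <- sort(data)
  n <- length(x)
  d <- get_dist(fit$model_name)
  g <- d$cdf(x, fit$estimates)
  ic <- information_criteria(fit$loglik, fit$k, n)
  ks <- ks_stat(g)
  ad <- tryCatch(ad_stat(g), error = function(e) NA_real_)
  km <- survival::survfit(survival::Surv(x, rep(1, n)) ~ 1)
  structure(
    list(model_name = fit$model_name, label = fit$label, k = fit$k,
         AIC = unname(ic["AIC"]), BIC = unname(ic["BIC"]),
         AD = ad, CM = cm_stat(g),
         KS = ks$statistic, ks_pvalue = ks$p_value,
         pp_points = data.frame(empirical = seq_len(n) / (n + 1),
                                theoretical = g),
         km_points = data.frame(x = km$time, survival = km$surv),
         cdf_points = data.frame(x = x, fitted = g,
                                 empirical = seq_len(n) / n),
         fit = fit),
    class = "gof_report")
}

#' Fit and compare several models on one data set
#'
#' Fits each requested model by maximum likelihood and assembles the
#' model-discrimination table (AIC, BIC, CM, AD, KS, p-value), sorted by
#' AIC ascending.  A model whose fit fails contributes a row of `NA`s
#' rather than aborting the comparison; each model's random restarts use a
#' seed derived independently from `seed`, so adding or removing models
#' leaves the other rows unchanged.
#'
#' @param data numeric vector of strictly positive observations.
#' @param model_names character vector of registered models
#'   (see [dist_names()]).
#' @param n_restarts random restarts per model passed to [fit_mle()].
#' @param seed optional integer master seed.
#' @return a data.frame of class `nex_comparison` with columns `Dist`,
#'   `AIC`, `BIC`, `CM`, `AD`, `KS`, `p_value`; the per-model
#'   [gof_report()] objects are attached as attribute `"reports"`.
#' @examples
#' x <- rnexw(200, theta = 2, a = 1.5, gamma = 1, seed = 7)
#' compare_models(x, c("nexw", "weibull", "lomax"), seed = 1)
#' @export
compare_models <- function(data, model_names = c("nexw", "weibull"),
                           n_restarts = 3L, seed = NULL) {
  check_data(data)
  reports <- list()
  rows <- lapply(model_names, function(nm) {
    idx <- match(nm, names(.registry))
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, idx, 0L)
    rep <- tryCatch({
      fit <- fit_mle(nm, data, n_restarts = n_restarts, seed = sub_seed)
      gof_report(fit, data)
    }, error = function(e) e)
    if (inherits(rep, "error")) {
      data.frame(Dist = get_dist(nm)$label, AIC = NA_real_, BIC = NA_real_,
                 CM = NA_real_, AD = NA_real_, KS = NA_real_,
                 p_value = NA_real_, error = conditionMessage(rep))
    } else {
      reports[[nm]] <<- rep
      data.frame(Dist = rep$label, AIC = rep$AIC, BIC = rep$BIC,
                 CM = rep$CM, AD = rep$AD, KS = rep$KS,
                 p_value = rep$ks_pvalue, error = NA_character_)
    }
  })
  tbl <- do.call(rbind, rows)
  tbl <- tbl[order(tbl$AIC), , drop = FALSE]
  rownames(tbl) <- NULL
  if (all(is.na(tbl$error))) tbl$error <- NULL
  structure(tbl, reports = reports, class = c("nex_comparison", "data.frame"))
}

#' Write a comparison table as CSV
#'
#' Serialises a [compare_models()] table with the column headers
#' `Dist., AIC, BIC, CM, AD, KS, p value` and six significant digits.
#'
#' @param tbl an `nex_comparison` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(tbl, path) {
  out <- as.data.frame(tbl)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6L)
  names(out)[names(out) == "Dist"] <- "Dist."
  names(out)[names(out) == "p_value"] <- "p value"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
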