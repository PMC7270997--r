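## Goodness-of-fit statistics and the model-comparison table.
##
## The AD and CM statistics are cross-checked against independent
## evaluations of their defining functionals
##   CM = n * int (Fn(u) - u)^2 du,
##   AD = n * int (Fn(u) - u)^2 / (u (1 - u)) du,
## computed piecewise in closed form over the steps of the empirical cdf
## Fn of the fitted-cdf values.

cm_integral <- function(u) {
  n <- length(u)
  knots <- c(0, sort(u), 1)
  total <- 0
  for (i in seq_len(n + 1)) {
    c0 <- (i - 1) / n
    seg <- function(v) -(c0 - v)^3 / 3
    total <- total + seg(knots[i + 1]) - seg(knots[i])
  }
  n * total
}

ad_integral <- function(u) {
  n <- length(u)
  knots <- c(0, sort(u), 1)
  ## (c-u)^2/(u(1-u)) = (c-u)^2/u + (c-u)^2/(1-u); both antiderivatives
  ## are elementary
  anti <- function(v, c0) {
    ## log coefficients vanish exactly on the first/last interval, where
    ## the corresponding knot touches the singular endpoint
    a1 <- (if (c0 == 0) 0 else c0^2 * log(v)) - 2 * c0 * v + v^2 / 2
    w <- 1 - v
    a2 <- -((if (c0 == 1) 0 else (c0 - 1)^2 * log(w)) +
              2 * (c0 - 1) * w + w^2 / 2)
    a1 + a2
  }
  total <- 0
  for (i in seq_len(n + 1)) {
    c0 <- (i - 1) / n
    total <- total + anti(knots[i + 1], c0) - anti(knots[i], c0)
  }
  n * total
}

test_that("information criteria follow their definitions", {
  ic <- information_criteria(-10, 2, 100)
  expect_identical(unname(ic["AIC"]), 24)
  expect_equal(unname(ic["BIC"]), 2 * log(100) + 20, tolerance = 1e-12)
  expect_identical(unname(information_criteria(-10, 0, 50)["AIC"]), 20)
  ## AIC < BIC whenever n > e^2 and k >= 1
  expect_lt(ic["AIC"], ic["BIC"])
})

test_that("AD statistic matches hand evaluation and rejects boundary values", {
  g <- c(0.25, 0.75)
  hand <- -2 - 0.5 * (1 * (log(0.25) + log(0.25)) + 3 * (log(0.75) + log(0.75)))
  expect_equal(ad_stat(g), hand, tolerance = 1e-12)
  expect_equal(hand, 0.24934, tolerance = 1e-4)
  expect_error(ad_stat(c(0, 0.5)), "strictly inside")
  expect_error(ad_stat(c(0.5, 1)), "strictly inside")
  ## near-perfect fit: plotting positions give a small statistic
  n <- 50
  expect_lt(ad_stat((2 * seq_len(n) - 1) / (2 * n)), 0.4)
})

test_that("CM statistic matches hand evaluation and attains its lower bound", {
  expect_equal(cm_stat(c(0.25, 0.75)), 1 / 24, tolerance = 1e-14)
  expect_equal(cm_stat(0.5), 1 / 12, tolerance = 1e-14)
  set.seed(31)
  for (i in 1:5) {
    u <- sort(stats::runif(20))
    expect_gte(cm_stat(u), 1 / (12 * 20))
  }
})

test_that("KS statistic enumerates both one-sided gaps", {
  ks1 <- ks_stat(0.3)
  expect_equal(ks1$statistic, 0.7, tolerance = 1e-14)
  expect_equal(ks_stat(c(0.25, 0.75))$statistic, 0.25, tolerance = 1e-14)
  set.seed(77)
  for (i in 1:5) {
    n <- 30
    u <- sort(stats::runif(n))
    expect_gte(ks_stat(u)$statistic, 1 / (2 * n))
  }
  expect_error(ks_stat(c(0.5, 0.2)), "sorted")
  expect_error(ks_stat(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("statistics agree with independent reference evaluations", {
  set.seed(2024)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    u <- sort(stats::runif(n))
    ## KS against the base distribution-test implementation
    ref <- unname(stats::ks.test(u, "punif")$statistic)
    expect_equal(ks_stat(u)$statistic, ref, tolerance = 1e-10)
    ## AD / CM against closed-form integration of their functionals
    expect_equal(cm_stat(u), cm_integral(u), tolerance = 1e-8)
    expect_equal(ad_stat(u), ad_integral(u), tolerance = 1e-8)
  }
})

test_that("comparison table rows are independent and complete", {
  x <- rnexw(150, 2, 1.5, 1, seed = 21)
  t1 <- compare_models(x, c("nexw", "weibull", "lomax"), n_restarts = 1,
                       seed = 5)
  t2 <- compare_models(x, c("nexw", "weibull", "lomax", "burr"),
                       n_restarts = 1, seed = 5)
  for (d in c("NE-W", "Weibull", "Lomax")) {
    a <- t1[t1$Dist == d, c("AIC", "BIC", "CM", "AD", "KS")]
    b <- t2[t2$Dist == d, c("AIC", "BIC", "CM", "AD", "KS")]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b, label = d)
  }
  expect_false(is.unsorted(t2$AIC))
  t3 <- compare_models(x, "weibull", n_restarts = 0)
  expect_identical(nrow(t3), 1L)
  expect_true(all(is.finite(unlist(t3[, -1]))))
})

test_that("gof report carries PP and product-limit coordinates", {
  x <- rnexw(80, 1, 1.2, 0.9, seed = 33)
  f <- fit_mle("weibull", x, n_restarts = 0)
  rep <- gof_report(f, x)
  n <- length(x)
  expect_equal(rep$pp_points$empirical, seq_len(n) / (n + 1))
  expect_equal(rep$pp_points$theoretical,
               competitor_cdf("weibull", f$estimates, sort(x)),
               tolerance = 1e-12)
  ## with no censoring the product-limit estimate equals 1 - ecdf
  expect_equal(rep$km_points$survival, 1 - seq_len(n) / n, tolerance = 1e-12)
  expect_identical(rep$k, 2L)
})

test_that("comparison table serialises with the report column set", {
  x <- rnexw(60, 1, 1, 1, seed = 2)
  tbl <- compare_models(x, c("weibull", "lomax"), n_restarts = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison(tbl, path)
  hdr <- readLines(path, n = 1)
  expect_identical(hdr, "Dist.,AIC,BIC,CM,AD,KS,p value")
})
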