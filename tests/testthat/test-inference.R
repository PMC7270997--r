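## Maximum-likelihood machinery: log-likelihood, fitting, standard errors.

test_that("log-likelihood matches the density and is additive", {
  p <- c(theta = 1, a = 1, gamma = 1)
  expect_equal(log_likelihood("nexw", p, log(2)), log(0.5), tolerance = 1e-12)
  x1 <- c(0.4, 1.1, 2.3)
  x2 <- c(0.9, 3.2)
  expect_equal(log_likelihood("nexw", p, c(x1, x2)),
               log_likelihood("nexw", p, x1) + log_likelihood("nexw", p, x2),
               tolerance = 1e-10)
  p2 <- c(theta = 2.3, a = 1.4, gamma = 0.6)
  expect_equal(log_likelihood("nexw", p2, x1),
               sum(dnexw(x1, 2.3, 1.4, 0.6, log = TRUE)), tolerance = 1e-10)
  expect_error(log_likelihood("nexw", p, c(1, -1)), "index: 2")
})

test_that("fit recovers simulated NE-W parameters within sampling error", {
  truth <- c(theta = 1.2, a = 0.9, gamma = 0.7)
  x <- rnexw(5000, 1.2, 0.9, 0.7, seed = 42)
  f <- fit_mle("nexw", x, n_restarts = 2, seed = 1)
  expect_true(f$converged)
  expect_true(all(abs(f$estimates - truth) <= 3 * f$standard_errors))
  ## optimality: the fit cannot be beaten by the generating parameters
  expect_gte(f$loglik, log_likelihood("nexw", truth, x))
  expect_error(fit_mle("nexw", c(1, -1)), "positive")
})

test_that("fit is invariant to data ordering", {
  x <- rnexw(400, 2, 1.5, 1, seed = 8)
  f1 <- fit_mle("nexw", x, n_restarts = 1, seed = 3, compute_se = FALSE)
  f2 <- fit_mle("nexw", sample(x), n_restarts = 1, seed = 3,
                compute_se = FALSE)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  f3 <- fit_mle("nexw", x, n_restarts = 1, seed = 3, compute_se = FALSE)
  expect_identical(f1$estimates, f3$estimates)
})

test_that("standard errors match the analytic exponential information", {
  x <- stats::qexp(seq_len(2000) / 2001, rate = 2)   # noise-free grid sample
  f <- fit_mle("exponential", x)
  ## Fisher information for a rate parameter is n / gamma^2
  expect_equal(unname(f$standard_errors["gamma"]),
               unname(f$estimates["gamma"]) / sqrt(2000), tolerance = 1e-3)
  expect_true(all(f$standard_errors > 0))
})

test_that("standard errors shrink like one over root n", {
  ratios <- vapply(1:5, function(r) {
    x1 <- rnexw(300, 1, 1.2, 0.8, seed = 100 + r)
    x2 <- rnexw(600, 1, 1.2, 0.8, seed = 200 + r)
    f1 <- fit_mle("weibull", x1, n_restarts = 0)
    f2 <- fit_mle("weibull", x2, n_restarts = 0)
    mean(f1$standard_errors / f2$standard_errors)
  }, numeric(1))
  expect_gt(mean(ratios), 1.2)
  expect_lt(mean(ratios), 1.7)
})

test_that("fit results serialise to an estimate(se) row", {
  x <- rnexw(200, 1, 1, 1, seed = 4)
  f <- fit_mle("weibull", x, n_restarts = 0)
  row <- fit_row(f)
  expect_identical(row$Dist, "Weibull")
  expect_match(row$a, "^[0-9.]+\\([0-9.e-]+\\)$")
})
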