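## The NE-X transformation: closed forms, invariants, quantile inversion,
## sampling.  Hand values use the Weibull(a = 1, gamma = 1) baseline at
## x = log 2, where F = 1/2 and f = 1/2.

test_that("cdf matches hand-evaluated closed forms", {
  m1 <- nexw_model(1, 1, 1)
  m2 <- nexw_model(2, 1, 1)
  expect_identical(nex_cdf(m2, 0), 0)
  expect_identical(nex_cdf(m2, -3), 0)
  expect_equal(nex_cdf(m1, log(2)), 0.25, tolerance = 1e-12)   # G = F^2
  expect_equal(nex_cdf(m2, log(2)), 0.64, tolerance = 1e-12)   # 1-(0.75/1.25)^2
  expect_equal(nex_sf(m2, log(2)), 0.36, tolerance = 1e-12)
  expect_identical(nex_sf(m2, 0), 1)
})

test_that("pdf matches hand values, vanishes off-support, equals cdf derivative", {
  m1 <- nexw_model(1, 1, 1)
  m2 <- nexw_model(2, 1, 1)
  expect_identical(nex_pdf(m1, 0), 0)
  expect_equal(nex_pdf(m1, log(2)), 0.5, tolerance = 1e-12)    # 2 f F
  ## 2 theta^2 f F (1-F^2)^(theta-1) / (1-(1-theta)F^2)^(theta+1), f = 1/2
  expect_equal(nex_pdf(m2, log(2)), 2 * 4 * 0.5 * 0.5 * 0.75 / 1.25^3,
               tolerance = 1e-12)
  h <- 1e-5
  for (th in c(0.5, 1, 3)) {
    m <- nexw_model(th, 1.3, 0.8)
    xs <- c(0.2, 0.7, 1.5, 3)
    dd <- (nex_cdf(m, xs + h) - nex_cdf(m, xs - h)) / (2 * h)
    expect_equal(nex_pdf(m, xs), dd, tolerance = 1e-5)
  }
})

test_that("density integrates to one across the parameter grid", {
  for (th in theta_grid) for (a in shape_grid) for (g in rate_grid) {
    m <- nexw_model(th, a, g)
    mass <- stats::integrate(function(x) nex_pdf(m, x), 0, Inf,
                             rel.tol = 1e-10)$value
    expect_lt(abs(mass - 1), 1e-6)
  }
})

test_that("quantile inverts the cdf to high precision", {
  u <- c(1e-6, seq(0.01, 0.99, by = 0.01), 1 - 1e-6)
  for (th in theta_grid) {
    m <- nexw_model(th, 1.3, 0.8)
    expect_lt(max(abs(nex_cdf(m, nex_quantile(m, u)) - u)), 1e-8)
  }
  m2 <- nexw_model(2, 1, 1)
  expect_identical(nex_quantile(m2, 0), 0)
  ## w = 0.6 gives baseline cdf 1/2, so the quantile is the Weibull median
  expect_equal(nex_quantile(m2, 0.64), log(2), tolerance = 1e-12)
  expect_equal(nex_quantile(nexw_model(1, 1, 1), 0.25), log(2),
               tolerance = 1e-12)
  expect_error(nex_quantile(m2, 1), "\\[0, 1\\)")
  expect_error(nex_quantile(m2, -0.1), "\\[0, 1\\)")
})

test_that("quantile falls back to root finding without a closed-form inverse", {
  b <- baseline_model("halfnormal", c(scale = 1),
                      cdf = function(x) pmax(0, 2 * stats::pnorm(x) - 1),
                      pdf = function(x) ifelse(x < 0, 0, 2 * stats::dnorm(x)))
  m <- nex_model(1.5, b)
  u <- c(0.05, 0.5, 0.95)
  expect_lt(max(abs(nex_cdf(m, nex_quantile(m, u)) - u)), 1e-8)
})

test_that("theta = 1 reduces the family to the squared baseline cdf", {
  for (a in shape_grid) {
    m <- nexw_model(1, a, 0.7)
    b <- weibull_model(a, 0.7)
    xs <- seq(0.1, 5, by = 0.3)
    expect_equal(nex_cdf(m, xs), b$cdf(xs)^2, tolerance = 1e-15)
    expect_equal(nex_pdf(m, xs), 2 * b$pdf(xs) * b$cdf(xs), tolerance = 1e-14)
  }
})

test_that("survival is strictly decreasing in theta at fixed x", {
  xs <- c(0.3, 1, 2.5)
  for (x in xs) {
    sf <- vapply(c(0.3, 0.7, 1, 1.5, 2.5, 6, 15),
                 function(th) nex_sf(nexw_model(th, 1.2, 0.9), x), numeric(1))
    expect_true(all(diff(sf) < 0))
  }
})

test_that("hazard matches pdf/sf and rejects the exhausted-support point", {
  m1 <- nexw_model(1, 1, 1)
  expect_equal(nex_hazard(m1, log(2)), 0.5 / 0.75, tolerance = 1e-12)
  m <- nexw_model(2, 1.5, 1)
  xs <- c(0.2, 1, 3)
  expect_equal(nex_hazard(m, xs), nex_pdf(m, xs) / nex_sf(m, xs),
               tolerance = 1e-12)
  expect_error(nex_hazard(m, Inf), "hazard undefined")
})

test_that("sampler is seeded, deterministic, and distributionally correct", {
  m <- nexw_model(2, 1.5, 1)
  expect_identical(nex_sample(m, 0), numeric(0))
  expect_error(nex_sample(m, -1), "nonnegative")
  x1 <- nex_sample(m, 50, seed = 11)
  x2 <- nex_sample(m, 50, seed = 11)
  expect_identical(x1, x2)
  expect_false(identical(x1, nex_sample(m, 50, seed = 12)))
  x <- nex_sample(m, 1e4, seed = 123)
  ks <- stats::ks.test(x, function(q) nex_cdf(m, q))
  expect_gt(ks$p.value, 0.01)
  ## the inverse map itself: u = 0.64 must return the Weibull median
  expect_equal(nex_quantile(nexw_model(2, 1, 1), 0.64), log(2),
               tolerance = 1e-12)
})

test_that("sampling leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(nex_sample(nexw_model(1, 1, 1), 10, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("construction validates parameters", {
  expect_error(nexw_model(-1, 1, 1), "positive")
  expect_error(nexw_model(1, 0, 1), "positive")
  expect_error(nex_model(1, "not a baseline"), "nex_baseline")
})
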