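## Shared fixtures: parameter grids used by several test files.

theta_grid <- c(0.25, 0.5, 1, 2, 5, 20)
shape_grid <- c(0.5, 1, 2)
rate_grid <- c(0.5, 1, 2)

## Valid parameter sets for every registered model, used to exercise the
## whole registry.
registry_params <- list(
  nexw = c(theta = 2, a = 1.5, gamma = 1),
  weibull = c(a = 1.5, gamma = 0.8),
  exponential = c(gamma = 1.2),
  fwe = c(alpha = 1.2, sigma = 0.5, gamma = 0.7),
  aptw = c(alpha1 = 3, alpha = 1.4, gamma = 0.9),
  mow = c(alpha = 1.3, gamma = 0.8, sigma = 2),
  mw = c(alpha = 1.6, gamma = 0.5, theta = 0.4),
  exaptw = c(alpha1 = 5.4, alpha = 1.2, gamma = 0.6),
  kuw = c(alpha = 1.2, gamma = 0.7, a = 1.5, b = 2),
  bw = c(alpha = 1.3, gamma = 0.6, a = 2, b = 1.5),
  lomax = c(alpha = 2.5, gamma = 1.5),
  burr = c(c = 2, k = 1.5)
)

## numeric integral of a model's pdf over (0, Inf)
pdf_mass <- function(name, params) {
  stats::integrate(function(x) competitor_pdf(name, params, x), 0, Inf,
                   rel.tol = 1e-9)$value
}
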