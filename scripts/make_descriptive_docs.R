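#!/usr/bin/env Rscript
## Regenerates the recomputed descriptive-measure grids of the NE-W
## distribution: docs/descriptive-measures.md and the machine-readable
## copy inst/extdata/descriptive_measures.csv.  Run from the repository
## root with the package installed:
##
##   Rscript scripts/make_descriptive_docs.R

library(nexw)

g1 <- descriptive_grid(theta = c(0.9, 1.3, 1.7, 2.1, 2.4, 2.8),
                       a = 0.9, gamma = 1)
g2 <- descriptive_grid(theta = 0.5, a = c(0.7, 1.1, 1.5, 2.5, 4.5),
                       gamma = 1)
for (nm in c("Mean", "Variance", "Sk", "Kur")) {
  g1[[nm]] <- signif(g1[[nm]], 6)
  g2[[nm]] <- signif(g2[[nm]], 6)
}
grid <- rbind(cbind(grid = "theta-varying", g1),
              cbind(grid = "alpha-varying", g2))
num <- vapply(grid, is.numeric, logical(1))
grid[num] <- lapply(grid[num], signif, digits = 6)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(grid, "inst/extdata/descriptive_measures.csv", row.names = FALSE,
          quote = FALSE)

md_table <- function(g) {
  hdr <- paste0("| ", paste(names(g), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(g)), collapse = "|"), "|")
  rows <- apply(g, 1, function(r) paste0("| ", paste(trimws(r), collapse = " | "), " |"))
  c(hdr, sep, rows)
}

lines <- c(
  "# Descriptive measures of the NE-W distribution (recomputed)",
  "",
  "Mean, variance, skewness (Sk = mu3 / mu2^1.5) and kurtosis",
  "(Kur = mu4 / mu2^2) of the NE-W distribution, computed by adaptive",
  "quadrature against the model density (`nexw::describe()`).  Regenerate",
  "with `Rscript scripts/make_descriptive_docs.R`; a machine-readable copy",
  "ships as `inst/extdata/descriptive_measures.csv`.",
  "",
  "## Grid 1: alpha = 0.9, gamma = 1, theta varying",
  "",
  md_table(g1[, c("theta", "Mean", "Variance", "Sk", "Kur")]),
  "",
  "As theta grows the mean and variance decrease: the extension parameter",
  "pushes probability mass toward the origin (the survival function is",
  "strictly decreasing in theta at every x).  The distribution stays",
  "unimodal, right-skewed and leptokurtic throughout the grid.",
  "",
  "## Grid 2: theta = 0.5, gamma = 1, alpha varying",
  "",
  md_table(g2[, c("a", "Mean", "Variance", "Sk", "Kur")]),
  "",
  "## Discrepancy against previously published tabulations",
  "",
  "Published tabulations of these same grids report very different",
  "numbers — for example mean 5.4664 and variance 130.8709 at",
  "theta = 0.9, alpha = 0.9, gamma = 1 (and, in the alpha-varying grid,",
  "two conflicting rows for alpha = 4.5), where quadrature against the",
  "model's own density gives mean 1.8430 and variance 2.3185.  Those",
  "published values are inconsistent with the density they are said to",
  "summarise: direct numerical integration, the closed-form theta = 1",
  "checks, and the series representation all agree with the values above",
  "to at least six significant digits, so the recomputed grids are",
  "reported instead.  Only the qualitative directions (mean and variance",
  "decreasing in theta, right skew throughout) are shared with the",
  "published tables.",
  "")

dir.create("docs", showWarnings = FALSE)
writeLines(unlist(lines), "docs/descriptive-measures.md")
cat("wrote docs/descriptive-measures.md and inst/extdata/descriptive_measures.csv\n")
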