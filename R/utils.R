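## Internal helpers shared across the package.

#' Run code with a temporary, seeded RNG state
#'
#' Evaluates `expr` with the RNG seeded at `seed`, then restores whatever
#' RNG state the caller had.  With `seed = NULL` the expression simply uses
#' (and advances) the current RNG stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Counter-based derived seed: deterministic in (seed, stream, counter) and
## independent of the order in which cells of a study are executed.
derive_seed <- function(seed, stream, counter) {
  s <- (as.double(seed) %% 2147483647) + 1
  h <- (s * 48271 + as.double(stream) * 16807 + as.double(counter) * 69621)
  as.integer(h %% 2147483629) + 1L
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(as.double(x))
}

check_probability <- function(u, name = "u", allow_one = FALSE) {
  if (!is.numeric(u) || anyNA(u)) {
    stop(sprintf("`%s` must be numeric with no missing values", name),
         call. = FALSE)
  }
  hi <- if (allow_one) u > 1 else u >= 1
  if (any(u < 0 | hi)) {
    stop(sprintf("`%s` must lie in [0, 1%s", name,
                 if (allow_one) "]" else ")"), call. = FALSE)
  }
  invisible(as.double(u))
}

## Central-difference Hessian of `fn` at `x` on the original parameter
## scale; step proportional to |x_i| with an absolute floor.
num_hessian <- function(fn, x, rel_step = 1e-4, abs_step = 1e-6) {
  p <- length(x)
  h <- pmax(abs(x) * rel_step, abs_step)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        ej <- replace(numeric(p), j, h[j])
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}
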