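# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring any pre-existing global
# RNG state afterwards. All user-facing stochastic operations route through
# this so no call mutates the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_num <- function(x, field, lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop_cfg(field, "must be a finite numeric value")
  if (any(x < lower) || any(x > upper))
    stop_cfg(field, sprintf("must lie in [%s, %s]", lower, upper))
  invisible(x)
}

# 95% t-based confidence interval on a mean.
mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, n = n)
}
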