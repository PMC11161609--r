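# Method ranking: Friedman test over blocks x methods matrices, Nemenyi
# post-hoc pairwise comparisons against a critical distance, Bonferroni
# correction of the family-wise level.

#' Friedman rank test
#'
#' Within-block ranks (average ranks for ties) over a blocks x methods
#' matrix, with the chi-square statistic
#' `12N/(k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2` and the p-value from the
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param values Numeric matrix, blocks (windows or videos) in rows and
#'   k >= 3 methods in columns.
#' @return List with `statistic`, `p_value`, `mean_ranks`, `n_blocks`,
#'   `k`.
#' @export
friedman_rank_test <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  n <- nrow(values)
  if (k < 3)
    stop("friedman: need at least 3 methods; use a paired test for k = 2")
  if (n < 2) stop("friedman: need at least 2 blocks")
  if (anyNA(values)) stop("friedman: matrix must be complete")
  ranks <- t(apply(values, 1, rank))
  rbar <- colMeans(ranks)
  stat <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  list(statistic = stat,
       p_value = pchisq(stat, df = k - 1, lower.tail = FALSE),
       mean_ranks = rbar, n_blocks = n, k = k)
}

#' Nemenyi post-hoc test
#'
#' Compares mean-rank differences of all method pairs against the
#' critical distance `CD = q_alpha * sqrt(k(k+1)/(6N))`, where `q_alpha`
#' is the studentized-range quantile for k groups divided by sqrt(2).
#' Pairwise p-values come from the studentized range distribution.
#'
#' @param values Blocks x methods matrix (as for
#'   [friedman_rank_test()]).
#' @param alpha Family-wise significance level in (0, 1).
#' @return List with `critical_distance`, `q_alpha`, `mean_ranks` and a
#'   data.frame `pairs` (method_a, method_b, rank_diff, p, significant).
#' @export
nemenyi_test <- function(values, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("nemenyi: alpha must be in (0, 1)")
  values <- as.matrix(values)
  k <- ncol(values)
  n <- nrow(values)
  ranks <- t(apply(values, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  q_alpha <- qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  cd <- q_alpha * se
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("method", seq_len(k))
  cmb <- utils::combn(k, 2)
  pairs <- data.frame(
    method_a = nm[cmb[1, ]],
    method_b = nm[cmb[2, ]],
    rank_diff = abs(rbar[cmb[1, ]] - rbar[cmb[2, ]]),
    stringsAsFactors = FALSE)
  pairs$p <- ptukey(pairs$rank_diff / se * sqrt(2), nmeans = k, df = Inf,
                    lower.tail = FALSE)
  pairs$significant <- pairs$rank_diff >= cd
  list(critical_distance = cd, q_alpha = q_alpha, mean_ranks = rbar,
       pairs = pairs)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("bonferroni: alpha must be in (0, 1)")
  if (n_tests < 1) stop("bonferroni: n_tests must be >= 1")
  alpha / n_tests
}

#' Compare methods on one metric
#'
#' The full ranking protocol for one metric within one dataset or
#' activity group: build the blocks x methods matrix from per-window
#' metric rows (listwise exclusion of incomplete blocks, counts logged),
#' run the Friedman test, and — when it is significant at `alpha` — the
#' Nemenyi pairwise comparisons, reporting decisions both at `alpha` and
#' at the Bonferroni-adjusted per-pair level `alpha / (k(k-1)/2)`.
#'
#' @param rows Data.frame with columns `method`, the metric named by
#'   `metric`, and block identifiers (`video`, `window`), e.g. the
#'   `rows` element of a [evaluate_windows()] report.
#' @param metric Metric column to rank on (`"dtw"`, `"r"`, `"rmse"`,
#'   `"delta_hr_bpm"`).
#' @param alpha Family-wise significance level.
#' @return Object of class `method_comparison`.
#' @export
compare_methods <- function(rows, metric = "dtw", alpha = 0.05) {
  stopifnot(is.data.frame(rows), metric %in% names(rows))
  rows$block <- paste(rows$video, rows$window, sep = "#")
  methods <- sort(unique(rows$method))
  k <- length(methods)
  if (k < 3) stop("compare_methods: need at least 3 methods")
  wide <- matrix(NA_real_, nrow = length(unique(rows$block)), ncol = k,
                 dimnames = list(unique(rows$block), methods))
  for (i in seq_len(nrow(rows)))
    wide[rows$block[i], rows$method[i]] <- rows[[metric]][i]
  complete <- stats::complete.cases(wide)
  excluded <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 2) stop("compare_methods: fewer than 2 complete blocks")
  fr <- friedman_rank_test(wide)
  n_pairs <- k * (k - 1) / 2
  alpha_adj <- bonferroni_alpha(alpha, n_pairs)
  nem <- NULL
  if (fr$p_value < alpha) {
    nem <- nemenyi_test(wide, alpha = alpha)
    nem$pairs$significant_bonferroni <- nem$pairs$p < alpha_adj
  }
  structure(
    list(metric = metric, friedman = fr, nemenyi = nem,
         alpha = alpha, alpha_adjusted = alpha_adj, n_pairs = n_pairs,
         methods = methods, n_blocks = nrow(wide),
         n_excluded_blocks = excluded),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> metric=%s  blocks=%d  methods=%d\n",
              x$metric, x$n_blocks, length(x$methods)))
  cat(sprintf("  Friedman chi2=%.4g (df=%d), p=%.4g\n",
              x$friedman$statistic, x$friedman$k - 1, x$friedman$p_value))
  cat(sprintf("  alpha=%g, Bonferroni-adjusted per-pair alpha=%.4g (%d tests)\n",
              x$alpha, x$alpha_adjusted, x$n_pairs))
  if (!is.null(x$nemenyi)) {
    cat(sprintf("  Nemenyi CD=%.4g\n", x$nemenyi$critical_distance))
    print(x$nemenyi$pairs, digits = 3)
  } else {
    cat("  Friedman not significant; Nemenyi not run\n")
  }
  invisible(x)
}
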