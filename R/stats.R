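# Paired nonparametric inference for plan comparison: Friedman across the
# three constraint levels within a modality, post-hoc Wilcoxon signed-rank
# with Bonferroni correction, and the per-patient reduction summaries.

.as_paired_matrix <- function(x, min_rows = 2) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("paired table must be numeric")
  if (any(!is.finite(x))) stop("paired table has missing or non-finite cells")
  if (nrow(x) < min_rows) stop("paired table needs at least ", min_rows, " rows (patients)")
  x
}

# classical Friedman chi-square with average ranks for within-row ties
.friedman_stat <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  r <- t(apply(x, 1, rank))
  colr <- colSums(r)
  unname((12 / (n * k * (k + 1))) * sum((colr - n * (k + 1) / 2)^2))
}

#' Friedman test for paired multi-level designs
#'
#' Rank-based test that `k >= 3` paired conditions (columns) share a common
#' location, with rows as patients. The default reference distribution is
#' chi-square with `k - 1` degrees of freedom (delegating to
#' [stats::friedman.test()]); `method = "permutation"` instead evaluates the
#' statistic against within-row column permutations — exhaustively when
#' `(k!)^n` is small enough, otherwise by Monte Carlo — which is exact for
#' small samples where the chi-square approximation is coarse.
#'
#' @param x matrix or data.frame, rows = patients, columns = conditions;
#'   complete (no missing cells), at least 3 columns.
#' @param method `"chisq"` or `"permutation"`.
#' @param n_perm Monte Carlo permutation count when exhaustive enumeration
#'   exceeds `exhaustive_limit`.
#' @param exhaustive_limit largest `(k!)^n` that is enumerated exactly.
#' @return a list with `statistic`, `df` (chisq only), `p.value` and
#'   `method`.
#' @export
friedman_test <- function(x, method = c("chisq", "permutation"),
                          n_perm = 20000, exhaustive_limit = 250000) {
  x <- .as_paired_matrix(x)
  if (ncol(x) < 3) stop("Friedman test needs at least 3 conditions")
  method <- match.arg(method)
  if (method == "chisq") {
    # classical average-rank chi-square form; well-defined (statistic 0,
    # p = 1) even when every row is fully tied, where the tie-corrected
    # variant in stats::friedman.test degenerates to 0/0
    stat <- .friedman_stat(x)
    k <- ncol(x)
    return(list(statistic = stat, df = k - 1,
                p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
                method = "chisq"))
  }
  n <- nrow(x)
  k <- ncol(x)
  obs <- .friedman_stat(x)
  perms <- .permutations(k)                      # k! x k
  np_all <- nrow(perms)^n
  rmat <- t(apply(x, 1, rank))
  if (np_all <= exhaustive_limit) {
    P <- np_all
    stat_acc <- matrix(0, P, k)
    idx0 <- 0:(P - 1)
    for (i in seq_len(n)) {
      digit <- (idx0 %/% nrow(perms)^(i - 1)) %% nrow(perms) + 1
      # permuting a row's values permutes its rank vector the same way
      stat_acc <- stat_acc + matrix(rmat[i, ][perms[digit, ]], P, k)
    }
    exact <- TRUE
  } else {
    P <- n_perm
    stat_acc <- matrix(0, P, k)
    for (i in seq_len(n)) {
      digit <- sample.int(nrow(perms), P, replace = TRUE)
      stat_acc <- stat_acc + matrix(rmat[i, ][perms[digit, ]], P, k)
    }
    exact <- FALSE
  }
  stats_perm <- (12 / (n * k * (k + 1))) * rowSums((stat_acc - n * (k + 1) / 2)^2)
  p <- mean(stats_perm >= obs - 1e-9)
  list(statistic = obs, p.value = p,
       method = if (exact) "exact permutation" else "Monte Carlo permutation",
       n_perm = P)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- .permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  unname(out)
}

#' Wilcoxon signed-rank test for paired vectors
#'
#' Two-sided paired test. Zero differences are dropped beforehand (Wilcoxon's
#' convention) and counted in `zeros_dropped`; if every difference is zero
#' the test returns `p = 1` with `all_zero = TRUE` (documented convention).
#' The exact distribution is used for `n <= 25` remaining pairs without
#' midrank ties; otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param a,b equal-length paired numeric vectors (length >= 2).
#' @return a list with `p.value`, `statistic` (V), `n_used`,
#'   `zeros_dropped`, `exact` and `all_zero`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("'a' and 'b' must be equal-length vectors of length >= 2")
  }
  d <- a - b
  if (any(!is.finite(d))) stop("missing or non-finite paired values")
  zeros <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(p.value = 1, statistic = NA_real_, n_used = 0L,
                zeros_dropped = zeros, exact = FALSE, all_zero = TRUE))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 25 && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(p.value = wt$p.value, statistic = unname(wt$statistic),
       n_used = length(d), zeros_dropped = zeros, exact = exact,
       all_zero = FALSE)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p-value; `m` defaults to 3, the number of
#' pairwise post-hoc comparisons in a three-level family (Conv vs BVS-90%,
#' Conv vs BVS-80%, BVS-90% vs BVS-80%).
#'
#' @param p p-values in \[0, 1\].
#' @param m number of comparisons in the family (>= `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = 3) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("'m' must be at least the number of p-values")
  pmin(1, m * p)
}

#' Three-level comparison: Friedman plus conditional post-hoc tests
#'
#' Mirrors the study procedure: a Friedman test across the condition
#' columns; when it is significant at `alpha` (or when
#' `always_posthoc = TRUE`), all pairwise Wilcoxon signed-rank tests with
#' Bonferroni correction over the family.
#'
#' @param x paired table (rows = patients, columns = conditions).
#' @param alpha significance threshold for running the post-hoc family.
#' @param always_posthoc run the pairwise tests unconditionally.
#' @param m Bonferroni family size; defaults to the number of pairs.
#' @return a list with `friedman` and `posthoc` (data.frame of
#'   `comparison`, `p_raw`, `p_adj`, or NULL when not run).
#' @export
compare_levels <- function(x, alpha = 0.05, always_posthoc = FALSE, m = NULL) {
  x <- .as_paired_matrix(x)
  fr <- friedman_test(x)
  posthoc <- NULL
  if (fr$p.value < alpha || always_posthoc) {
    pairs <- utils::combn(colnames(x) %||% paste0("C", seq_len(ncol(x))), 2)
    idx <- utils::combn(ncol(x), 2)
    if (is.null(m)) m <- ncol(idx)
    praw <- vapply(seq_len(ncol(idx)), function(j)
      wilcoxon_signed_rank(x[, idx[1, j]], x[, idx[2, j]])$p.value, 0)
    posthoc <- data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                          p_raw = praw, p_adj = bonferroni_adjust(praw, m))
  }
  list(friedman = fr, posthoc = posthoc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduction summary relative to a baseline condition
#'
#' For each condition column, reports the median and range of the raw
#' metric, and the mean per-patient percent reduction
#' `100 * (baseline - condition) / baseline`. Patients with a zero baseline
#' are excluded from the percent reductions with a warning.
#'
#' @param x paired table (rows = patients, columns = conditions).
#' @param baseline name or index of the baseline column.
#' @return data.frame with one row per condition: `condition`, `median`,
#'   `min`, `max`, `mean_pct_reduction` (0 for the baseline itself), `n`.
#' @export
reduction_summary <- function(x, baseline = 1) {
  x <- .as_paired_matrix(x, min_rows = 1)  # a one-patient summary is degenerate but valid
  if (is.character(baseline)) baseline <- match(baseline, colnames(x))
  if (is.na(baseline) || baseline < 1 || baseline > ncol(x)) {
    stop("baseline column not found")
  }
  base <- x[, baseline]
  ok <- base != 0
  if (!all(ok)) warning(sum(!ok), " patient(s) excluded from percent reductions: zero baseline")
  cn <- colnames(x) %||% paste0("C", seq_len(ncol(x)))
  out <- lapply(seq_len(ncol(x)), function(j) {
    data.frame(condition = cn[j],
               median = stats::median(x[, j]),
               min = min(x[, j]), max = max(x[, j]),
               mean_pct_reduction = if (any(ok))
                 mean(100 * (base[ok] - x[ok, j]) / base[ok]) else NA_real_,
               n = nrow(x))
  })
  do.call(rbind, out)
}
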