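#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square without continuity correction, the test used for
#' categorical group comparisons in demographic tables.
#'
#' @param counts Matrix (at least 2 x 2) of nonnegative integer counts,
#'   categories in rows and groups in columns.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    abort("`counts` must be at least a 2 x 2 table.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be nonnegative integers.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("`counts` has a zero row or column margin.")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value))
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Two-sided t-test computed from the published group means, standard
#' deviations and sizes (no raw data needed), using the pooled variance
#' estimate.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return One-row tibble with `t`, `df`, `p_value`.
#' @export
two_sample_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2.")
  if (sd1 <= 0 || sd2 <= 0) abort("standard deviations must be positive.")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Compare covariates between diagnostic groups
#'
#' Builds a demographic comparison table in the usual "Table 1" layout: for
#' each covariate, counts (categorical, chi-square test) or mean +/- sd
#' (numeric, pooled t-test) by diagnosis group, with the test statistic and
#' p-value on the variable's first row.
#'
#' @param covariates Data frame of per-subject covariates (factors/characters
#'   are treated as categorical, numerics as continuous).
#' @param labels Binary diagnosis vector aligned with `covariates` rows
#'   (1 = unhealthy), or a [response_dataset()] whose labels are used.
#' @return Tibble with columns `variable`, `level`, `total`, `healthy`,
#'   `unhealthy`, `statistic`, `df`, `p_value`.
#' @export
demographic_summary <- function(covariates, labels) {
  if (inherits(labels, "response_dataset")) labels <- labels$labels
  labels <- as.integer(labels)
  if (nrow(covariates) != length(labels)) {
    abort("`covariates` rows must align with `labels`.")
  }
  if (length(unique(labels)) != 2L) {
    abort("two diagnosis groups are required.")
  }
  purrr::imap_dfr(covariates, function(x, nm) {
    if (is.numeric(x)) {
      s <- function(idx) sprintf("%.2f ± %.2f", mean(x[idx]), sd(x[idx]))
      ht <- two_sample_t_test(mean(x[labels == 0]), sd(x[labels == 0]),
                              sum(labels == 0),
                              mean(x[labels == 1]), sd(x[labels == 1]),
                              sum(labels == 1))
      tibble(variable = nm, level = NA_character_,
             total = s(seq_along(x)), healthy = s(which(labels == 0)),
             unhealthy = s(which(labels == 1)),
             statistic = ht$t, df = as.numeric(ht$df), p_value = ht$p_value)
    } else {
      x <- factor(x)
      if (nlevels(x) < 2L) {
        warn(sprintf("covariate '%s' has a single level; skipped.", nm))
        return(NULL)
      }
      counts <- table(x, factor(labels, levels = c(0, 1)))
      ht <- chi_square_test(unclass(counts))
      fmt <- function(n, tot) sprintf("%d (%.1f%%)", n, 100 * n / tot)
      tibble(variable = nm, level = levels(x),
             total = fmt(rowSums(counts), length(x)),
             healthy = fmt(counts[, 1], sum(labels == 0)),
             unhealthy = fmt(counts[, 2], sum(labels == 1)),
             statistic = c(ht$statistic, rep(NA, nlevels(x) - 1L)),
             df = c(ht$df, rep(NA, nlevels(x) - 1L)),
             p_value = c(ht$p_value, rep(NA, nlevels(x) - 1L)))
    }
  })
}
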