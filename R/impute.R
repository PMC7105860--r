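#' Impute missing answers by predictive mean matching
#'
#' Single-pass predictive mean matching (PMM): for each item with missing
#' cells, an ordinary least squares model of that item on all fully observed
#' items yields predicted means; each missing cell is filled with the
#' observed value of one of the `k_donors` subjects whose predictions are
#' nearest to the missing subject's prediction. Donors are observed values
#' of the same column, so binary items stay binary. One completed dataset is
#' returned (no pooling across imputations).
#'
#' @param data A [response_dataset()].
#' @param k_donors Donor pool size (default 5); the donor is drawn uniformly
#'   from the pool.
#' @param seed Integer seed; the completed dataset is bit-identical across
#'   runs with the same seed.
#' @return A completed [response_dataset()] with no missing cells.
#' @export
impute_pmm <- function(data, k_donors = 5, seed = 1L) {
  stopifnot(inherits(data, "response_dataset"))
  k_donors <- assert_scalar_int(k_donors, "k_donors", min = 1)
  x <- data$responses
  miss_cols <- which(colSums(is.na(x)) > 0L)
  if (!length(miss_cols)) return(data)
  full <- colSums(is.na(x)) == 0L
  predictors <- x[, full, drop = FALSE]
  with_seed(seed, {
    for (j in miss_cols) {
      obs <- which(!is.na(x[, j]))
      mis <- which(is.na(x[, j]))
      if (!length(obs)) {
        abort(sprintf("item '%s' is entirely missing; cannot impute.",
                      colnames(x)[j]))
      }
      if (k_donors > length(obs)) {
        abort(sprintf(
          "k_donors = %d exceeds the %d observed donors for item '%s'.",
          k_donors, length(obs), colnames(x)[j]))
      }
      pred <- pmm_predict(predictors, x[, j], obs)
      for (i in mis) {
        d <- abs(pred[obs] - pred[i])
        pool <- obs[order(d, obs)[seq_len(k_donors)]]   # ties: lowest index
        donor <- pool[sample.int(length(pool), 1L)]
        x[i, j] <- x[donor, j]
      }
    }
  })
  out <- data
  out$responses <- x
  out
}

# OLS predicted means of column `y` (observed on rows `obs`) from the fully
# observed predictor block; intercept-only fallback when there are no
# complete predictors or the fit is degenerate.
pmm_predict <- function(predictors, y, obs) {
  n <- length(y)
  if (ncol(predictors) == 0L) return(rep(mean(y[obs]), n))
  xmat <- cbind(1, predictors)
  fit <- lm.fit(xmat[obs, , drop = FALSE], y[obs])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  drop(xmat %*% beta)
}
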