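#' Class-balanced test set and Monte-Carlo cross-validation plan
#'
#' `make_balanced_test_split()` draws the held-out test set: a fraction of
#' the unhealthy subjects (default 20%) plus an equal number of healthy
#' subjects, so the two diagnostic groups are balanced in the test set even
#' when the cohort is not. `make_cv_iterations()` then repeatedly partitions
#' the remaining subjects at random into training and validation sets
#' (Monte-Carlo cross-validation, not k-fold). `make_split_plan()` does both.
#'
#' @param labels Binary diagnosis vector (1 = unhealthy).
#' @param fraction_unhealthy Fraction of unhealthy subjects placed in the
#'   test set (rounded to the nearest integer count).
#' @param seed Integer seed.
#' @return `make_balanced_test_split()`: integer vector of test indices.
#' @export
make_balanced_test_split <- function(labels, fraction_unhealthy = 0.2,
                                     seed = 1L) {
  labels <- as.integer(labels)
  unhealthy <- which(labels == 1L)
  healthy <- which(labels == 0L)
  if (!length(unhealthy) || !length(healthy)) {
    abort("both classes must be present.")
  }
  n_take <- round(fraction_unhealthy * length(unhealthy))
  if (n_take < 1L) abort("`fraction_unhealthy` selects no subjects.")
  if (n_take > length(healthy)) {
    abort(sprintf("need %d healthy subjects to balance the test set, have %d.",
                  n_take, length(healthy)))
  }
  with_seed(seed, {
    sort(c(sample(unhealthy, n_take), sample(healthy, n_take)))
  })
}

#' @rdname make_balanced_test_split
#' @param non_test_idx Indices of subjects outside the test set.
#' @param n_iterations Number of Monte-Carlo train/validation partitions.
#' @param train_fraction Fraction of non-test subjects used for training in
#'   each iteration (default 80%).
#' @return `make_cv_iterations()`: list of `list(train, validation)` index
#'   pairs.
#' @export
make_cv_iterations <- function(non_test_idx, n_iterations = 10,
                               train_fraction = 0.8, seed = 1L) {
  train_fraction <- assert_prob(train_fraction, "train_fraction")
  n_iterations <- assert_scalar_int(n_iterations, "n_iterations", min = 1)
  if (!length(non_test_idx)) abort("empty subject pool.")
  n_train <- round(train_fraction * length(non_test_idx))
  with_seed(seed, {
    purrr::map(seq_len(n_iterations), function(i) {
      tr <- sort(sample(non_test_idx, n_train))
      list(train = tr, validation = sort(setdiff(non_test_idx, tr)))
    })
  })
}

#' @rdname make_balanced_test_split
#' @return `make_split_plan()`: a list of class `split_plan` with `test_idx`,
#'   `cv_iterations` and the seed used.
#' @export
make_split_plan <- function(labels, fraction_unhealthy = 0.2,
                            n_iterations = 10, train_fraction = 0.8,
                            seed = 1L) {
  test_idx <- make_balanced_test_split(labels, fraction_unhealthy,
                                       seed = derive_seed(seed, "test"))
  non_test <- setdiff(seq_along(labels), test_idx)
  cv <- make_cv_iterations(non_test, n_iterations, train_fraction,
                           seed = derive_seed(seed, "cv"))
  structure(list(test_idx = test_idx, cv_iterations = cv,
                 n_subjects = length(labels), seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan> %d test subjects (balanced), %d MC-CV iterations of %d/%d train/validation\n",
    length(x$test_idx), length(x$cv_iterations),
    length(x$cv_iterations[[1]]$train),
    length(x$cv_iterations[[1]]$validation)))
  invisible(x)
}

#' ROC curve of a score vector
#'
#' One operating point per distinct score value (the candidate thresholds)
#' plus the (0,0) and (1,1) endpoints. A subject is predicted unhealthy when
#' its score is greater than or equal to the threshold.
#'
#' @param scores Numeric scores (higher = more likely unhealthy).
#' @param labels Binary labels; both classes required.
#' @return Tibble with `threshold`, `fpr`, `tpr`, ordered from (0,0) to
#'   (1,1).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores/labels length mismatch.")
  if (length(unique(labels)) < 2L) abort("both classes must be present.")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           fpr = sum(pred & labels == 0L) / n_neg,
           tpr = sum(pred & labels == 1L) / n_pos)
  })
  dplyr::distinct(pts, .data$fpr, .data$tpr, .keep_all = TRUE)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC points; numerically identical to the
#' Mann-Whitney probability that a random unhealthy subject outscores a
#' random healthy one (ties counted one half).
#'
#' @param points ROC tibble from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(points) {
  o <- order(points$fpr, points$tpr)
  x <- points$fpr[o]; y <- points$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Optimal threshold by the (0,1) criterion
#'
#' Chooses the candidate threshold whose ROC point is closest (Euclidean
#' distance) to the perfect-classifier corner (0,1), i.e. jointly maximises
#' sensitivity and specificity. Ties are broken toward higher sensitivity,
#' then toward the lower threshold.
#'
#' @param points ROC tibble from [roc_curve()].
#' @return The selected threshold (one of the candidate thresholds).
#' @export
optimal_threshold_01 <- function(points) {
  finite <- points[is.finite(points$threshold), , drop = FALSE]
  if (!nrow(finite)) finite <- points
  d <- sqrt((1 - finite$tpr)^2 + finite$fpr^2)
  best <- finite[d == min(d), , drop = FALSE]
  best <- best[best$tpr == max(best$tpr), , drop = FALSE]
  min(best$threshold)
}

#' Classification metrics at a fixed threshold
#'
#' @param scores,labels Scores and binary labels.
#' @param threshold Score cutoff; `score >= threshold` predicts unhealthy.
#' @return One-row tibble: overall `error`, per-class errors
#'   (`error_unhealthy` = 1 - sensitivity, `error_healthy` = 1 -
#'   specificity), `sensitivity`, `specificity`, `accuracy`.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  sens <- if (n_pos) sum(pred == 1L & labels == 1L) / n_pos else NA_real_
  spec <- if (n_neg) sum(pred == 0L & labels == 0L) / n_neg else NA_real_
  tibble(error = mean(pred != labels),
         error_unhealthy = 1 - sens, error_healthy = 1 - spec,
         sensitivity = sens, specificity = spec,
         accuracy = mean(pred == labels))
}

#' Full ROC analysis with the (0,1)-criterion cutoff
#'
#' @param scores,labels Scores and binary labels.
#' @return Object of class `roc_result`: ROC `points`, `auc`,
#'   `optimal_threshold`, and the [classification_metrics()] at that cutoff.
#' @export
roc_analysis <- function(scores, labels) {
  points <- roc_curve(scores, labels)
  thr <- optimal_threshold_01(points)
  structure(list(points = points, auc = auc(points), optimal_threshold = thr,
                 metrics = classification_metrics(scores, labels, thr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f | threshold = %.3f | sens = %.3f, spec = %.3f, error = %.3f\n",
    x$auc, x$optimal_threshold, x$metrics$sensitivity, x$metrics$specificity,
    x$metrics$error))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  dplyr::bind_cols(tibble(auc = x$auc,
                          optimal_threshold = x$optimal_threshold), x$metrics)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  opt <- object$points[is.finite(object$points$threshold), , drop = FALSE]
  opt <- opt[which.min(abs(opt$threshold - object$optimal_threshold)), ]
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::labs(
      x = "false positive rate (1 - specificity)",
      y = "true positive rate (sensitivity)",
      title = sprintf("ROC (AUC = %.3f, threshold = %.3f)",
                      object$auc, object$optimal_threshold)) +
    ggplot2::coord_equal()
}

#' Search the hidden-layer size by Monte-Carlo cross-validation
#'
#' Trains one network per (architecture, CV iteration) pair on that
#' iteration's training subjects, then scores the held-out balanced test set
#' and evaluates accuracy at the (0,1)-criterion cutoff. The architecture
#' with the highest mean test accuracy wins; ties go to the fewest hidden
#' units (parsimony). The single best-performing fit of the winning
#' architecture is retained together with its cutoff.
#'
#' @param x Full response matrix (subjects x items, imputed).
#' @param y Binary diagnosis labels.
#' @param split A [make_split_plan()].
#' @param hidden_range Integer vector of hidden-unit counts to try
#'   (default 0:50).
#' @param config A [train_config()].
#' @param seed Integer seed; per-fit seeds are derived from it.
#' @return Object of class `arch_search`: `records` (per fit), `summary`
#'   (per architecture), `best_hidden`, `best_fit`, `best_threshold`,
#'   `best_roc`.
#' @export
architecture_search <- function(x, y, split, hidden_range = 0:50,
                                config = train_config(), seed = 1L) {
  stopifnot(inherits(split, "split_plan"))
  x <- as.matrix(x)
  test_x <- x[split$test_idx, , drop = FALSE]
  test_y <- y[split$test_idx]
  fits <- list()
  records <- purrr::map_dfr(hidden_range, function(h) {
    purrr::imap_dfr(split$cv_iterations, function(it, i) {
      fit <- train_rprop(x[it$train, , drop = FALSE], y[it$train], h, config,
                         seed = derive_seed(seed, paste0("fit", h, "_", i)))
      scores <- predict_scores(fit, test_x)
      roc <- roc_analysis(scores, test_y)
      fits[[paste(h, i)]] <<- list(fit = fit, roc = roc)
      tibble(n_hidden = h, iteration = i, epochs = fit$epochs_run,
             converged = fit$converged, auc = roc$auc,
             threshold = roc$optimal_threshold,
             accuracy = roc$metrics$accuracy, error = roc$metrics$error)
    })
  })
  summary <- records |>
    dplyr::group_by(.data$n_hidden) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     mean_auc = mean(.data$auc),
                     mean_epochs = mean(.data$epochs), .groups = "drop")
  best_hidden <- summary |>
    dplyr::filter(.data$mean_accuracy == max(.data$mean_accuracy)) |>
    dplyr::slice_min(.data$n_hidden, n = 1) |>
    dplyr::pull(.data$n_hidden)
  best_rec <- records |>
    dplyr::filter(.data$n_hidden == best_hidden) |>
    dplyr::slice_max(.data$accuracy, n = 1, with_ties = FALSE)
  best <- fits[[paste(best_hidden, best_rec$iteration)]]
  structure(list(records = records, summary = summary,
                 best_hidden = best_hidden, best_fit = best$fit,
                 best_roc = best$roc,
                 best_threshold = best$roc$optimal_threshold, seed = seed),
            class = "arch_search")
}

#' @export
print.arch_search <- function(x, ...) {
  cat(sprintf(
    "<arch_search> %d architectures x %d iterations | best: %d hidden (accuracy %.3f, AUC %.3f, threshold %.3f)\n",
    dplyr::n_distinct(x$records$n_hidden),
    max(x$records$iteration), x$best_hidden,
    max(x$summary$mean_accuracy),
    x$summary$mean_auc[x$summary$n_hidden == x$best_hidden],
    x$best_threshold))
  invisible(x)
}

#' @export
tidy.arch_search <- function(x, ...) x$records

#' @export
glance.arch_search <- function(x, ...) {
  tibble(best_hidden = x$best_hidden,
         best_accuracy = x$best_roc$metrics$accuracy,
         best_auc = x$best_roc$auc, best_threshold = x$best_threshold,
         epochs_run = x$best_fit$epochs_run)
}

#' @export
autoplot.arch_search <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$n_hidden, .data$mean_accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_hidden,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "hidden units", y = "mean test accuracy",
                  title = "architecture search")
}
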