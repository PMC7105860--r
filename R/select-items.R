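#' Configuration for randomized item selection
#'
#' @param n_samples_per_step Random item subsets evaluated at each step.
#'   The desk-scale default is 2,000; the original full-scale procedure used
#'   5,000,000 per step (hours of compute).
#' @param inclusion_probability Probability that each candidate item enters
#'   a sampled subset, strictly in (0, 1).
#' @param max_steps Safety cap on the number of steps.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(n_samples_per_step = 2000,
                             inclusion_probability = 0.5,
                             max_steps = 25) {
  structure(
    list(n_samples_per_step = assert_scalar_int(n_samples_per_step,
                                                "n_samples_per_step", min = 1),
         inclusion_probability = assert_prob(inclusion_probability,
                                             "inclusion_probability"),
         max_steps = assert_scalar_int(max_steps, "max_steps", min = 1)),
    class = "selection_config")
}

#' Mask a response matrix down to an item subset
#'
#' Items outside the subset are set to 0 (a "no" answer); column order and
#' count are unchanged, so a network trained on the full item set scores the
#' masked matrix without retraining.
#'
#' @param x Subjects x items matrix with item-id column names.
#' @param subset Character vector of item ids to keep active.
#' @return The masked matrix.
#' @export
mask_to_subset <- function(x, subset) {
  unknown <- setdiff(subset, colnames(x))
  if (length(unknown)) {
    abort(sprintf("unknown items in subset: %s",
                  paste(utils::head(unknown, 3), collapse = ", ")))
  }
  x[, !(colnames(x) %in% subset)] <- 0L
  x
}

#' Test-set classification error of an item subset
#'
#' Scores the masked test matrix with the already-trained network and
#' applies the fixed cutoff; no retraining takes place.
#'
#' @param net Trained `rprop_net` or `rprop_fit`.
#' @param threshold Score cutoff from the ROC stage.
#' @param x,y Test-set responses and labels.
#' @param subset Item ids to keep active.
#' @return Scalar classification error.
#' @export
evaluate_subset <- function(net, threshold, x, y, subset) {
  scores <- predict_scores(net, mask_to_subset(as.matrix(x), subset))
  mean(as.integer(scores >= threshold) != as.integer(y))
}

#' Sample random item subsets around a fixed core
#'
#' Each subset is the fixed set plus every candidate item included
#' independently with `inclusion_probability`; duplicates may occur.
#'
#' @param candidates Candidate item ids (disjoint from `fixed`).
#' @param fixed Fixed item ids, present in every subset.
#' @param n Number of subsets.
#' @param inclusion_probability Per-candidate inclusion probability.
#' @param seed Integer seed.
#' @return List of character vectors.
#' @export
sample_subsets <- function(candidates, fixed, n,
                           inclusion_probability = 0.5, seed = 1L) {
  if (length(intersect(candidates, fixed))) {
    abort("`candidates` and `fixed` must be disjoint.")
  }
  inc <- sample_inclusion_matrix(length(candidates), n,
                                 inclusion_probability, seed)
  purrr::map(seq_len(n), function(i) c(fixed, candidates[inc[i, ]]))
}

# n_subsets x n_candidates logical inclusion matrix
sample_inclusion_matrix <- function(n_candidates, n, p, seed) {
  with_seed(seed, {
    matrix(runif(n * n_candidates) < p, nrow = n)
  })
}

#' One step of the randomized selection procedure
#'
#' Evaluates `n_samples_per_step` sampled subsets on the test set; the
#' subsets attaining the minimum error are the step's "best solutions", and
#' the items common to all of them (always including the current fixed set)
#' become fixed for the next step.
#'
#' @param fixed,candidates Current fixed and candidate item ids.
#' @param net,threshold,x,y As in [evaluate_subset()].
#' @param config A [selection_config()].
#' @param seed Integer seed for this step's subset draws.
#' @return List: `best_error`, `best_solutions` (list of item sets),
#'   `common_items`, `new_fixed`, `new_candidates`, `n_best`.
#' @export
selection_step <- function(fixed, candidates, net, threshold, x, y,
                           config = selection_config(), seed = 1L) {
  if (inherits(net, "rprop_fit")) net <- net$net
  x <- as.matrix(x)
  n <- config$n_samples_per_step
  if (!length(candidates)) {
    err <- evaluate_subset(net, threshold, x, y, fixed)
    return(list(best_error = err, best_solutions = list(sort(fixed)),
                common_items = sort(fixed), new_fixed = sort(fixed),
                new_candidates = character(), n_best = 1L))
  }
  inc <- sample_inclusion_matrix(length(candidates), n,
                                 config$inclusion_probability, seed)
  p <- unpack_params(net$theta, net$n_inputs, net$n_hidden)
  fixed_cols <- which(colnames(x) %in% fixed)
  cand_cols <- match(candidates, colnames(x))
  y <- as.integer(y)
  errors <- vapply(seq_len(n), function(i) {
    cols <- c(fixed_cols, cand_cols[inc[i, ]])
    xs <- x[, cols, drop = FALSE]
    score <- if (net$n_hidden > 0L) {
      a1 <- plogis(sweep(xs %*% p$W1[cols, , drop = FALSE], 2L, p$b1))
      drop(plogis(a1 %*% p$W2 - p$b2))
    } else {
      drop(plogis(xs %*% p$W[cols] - p$b))
    }
    mean((score >= threshold) != y)
  }, numeric(1))
  best_error <- min(errors)
  best_rows <- which(errors == best_error)
  sols <- unique(purrr::map(best_rows,
                            function(i) sort(c(fixed, candidates[inc[i, ]]))))
  common <- Reduce(intersect, sols)
  list(best_error = best_error, best_solutions = sols,
       common_items = sort(common),
       new_fixed = sort(union(fixed, common)),
       new_candidates = setdiff(candidates, common), n_best = length(sols))
}

#' Knowledge-based randomized item selection
#'
#' Iterates [selection_step()] starting from the theory-anchored items
#' flagged `fixed` in the catalog: at each step random candidate subsets are
#' scored on the test set with the trained network and fixed cutoff, the
#' common items of the best-scoring subsets join the fixed set, and the
#' procedure stops as soon as a step fails to strictly improve the best
#' error (or candidates run out). The final answer is the
#' best-parsimonious solution: the smallest item set among all step-best
#' solutions attaining the overall minimum error (ties broken by
#' lexicographic item ids).
#'
#' @param net Trained `rprop_net` or `rprop_fit` on the full item set.
#' @param threshold Score cutoff from the ROC stage.
#' @param x,y Test-set responses and labels.
#' @param catalog Item catalog with `item_id`, `area`, `fixed` columns.
#' @param config A [selection_config()].
#' @param seed Integer seed; per-step seeds are derived from it.
#' @return Object of class `selection_result`: `selected_items`, `steps`
#'   trace tibble, `final_error`, `final_auc`, per-class errors, per-area
#'   composition.
#' @export
run_selection <- function(net, threshold, x, y, catalog,
                          config = selection_config(), seed = 1L) {
  if (inherits(net, "rprop_fit")) net <- net$net
  x <- as.matrix(x)
  fixed <- catalog$item_id[catalog$fixed]
  candidates <- setdiff(catalog$item_id, fixed)
  steps <- list()
  all_best <- list()   # per step: error + solutions
  prev_best <- Inf
  for (s in seq_len(config$max_steps)) {
    st <- selection_step(fixed, candidates, net, threshold, x, y, config,
                         seed = derive_seed(seed, paste0("step", s)))
    steps[[s]] <- tibble(
      step = s, best_error = st$best_error, n_best_solutions = st$n_best,
      n_common = length(st$common_items),
      solution_size = length(st$best_solutions[[1]]),
      n_fixed_after = length(st$new_fixed),
      improved = st$best_error < prev_best)
    all_best[[s]] <- list(error = st$best_error, solutions = st$best_solutions)
    if (!(st$best_error < prev_best)) break       # equal error also stops
    prev_best <- st$best_error
    fixed <- st$new_fixed
    candidates <- st$new_candidates
    if (!length(candidates)) break
  }
  steps <- dplyr::bind_rows(steps)
  overall_best <- min(steps$best_error)
  pool <- purrr::list_flatten(purrr::map(
    all_best[which(steps$best_error == overall_best)], "solutions"))
  sizes <- lengths(pool)
  pool <- pool[sizes == min(sizes)]
  keys <- vapply(pool, paste, character(1), collapse = "\r")
  selected <- pool[[order(keys)[1]]]

  scores <- predict_scores(net, mask_to_subset(x, selected))
  metrics <- classification_metrics(scores, y, threshold)
  final_auc <- tryCatch(auc(roc_curve(scores, y)), error = function(e) NA_real_)
  area <- catalog |>
    dplyr::filter(.data$item_id %in% selected) |>
    dplyr::count(.data$area, name = "n_selected")
  structure(
    list(selected_items = selected, steps = steps,
         final_error = overall_best, final_metrics = metrics,
         final_auc = final_auc, per_area = area,
         fixed_items = sort(catalog$item_id[catalog$fixed]), seed = seed),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d items selected in %d steps | test error %.3f (AUC %.3f)\n",
    length(x$selected_items), nrow(x$steps), x$final_error, x$final_auc))
  print(x$per_area)
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) x$steps

#' @export
glance.selection_result <- function(x, ...) {
  tibble(n_selected = length(x$selected_items), n_steps = nrow(x$steps),
         final_error = x$final_error, final_auc = x$final_auc,
         accuracy = x$final_metrics$accuracy,
         error_unhealthy = x$final_metrics$error_unhealthy,
         error_healthy = x$final_metrics$error_healthy)
}

#' @export
autoplot.selection_result <- function(object, ...) {
  long <- object$steps |>
    dplyr::select("step", "solution_size", "n_common", "best_error") |>
    tidyr::pivot_longer(-"step")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "selection step", y = NULL,
                  title = "randomized item selection trace")
}
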