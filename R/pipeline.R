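#' Run the full predictive scale-construction pipeline
#'
#' Orchestrates the end-to-end procedure: (optionally) simulate a
#' study-shaped dataset, impute missing answers by predictive mean matching,
#' draw the class-balanced test set and Monte-Carlo CV plan, search the
#' hidden-layer size with RPROP training, fix the ROC (0,1)-criterion
#' cutoff, run the knowledge-based randomized item selection, and produce
#' per-area principal-component reports for both the full and the selected
#' item sets.
#'
#' All stage seeds derive deterministically from `seed`, so a run is fully
#' reproducible; when `out_dir` is given every intermediate artifact is
#' persisted (imputed data, split plan, trained network, ROC points,
#' selection trace, loadings, report JSON).
#'
#' @param data A [response_dataset()]; if `NULL`, one is simulated from
#'   `sim`.
#' @param sim A [sim_config()] used when `data` is `NULL`.
#' @param hidden_range Hidden-unit counts for the architecture search.
#' @param n_cv Monte-Carlo CV iterations per architecture.
#' @param fraction_unhealthy Test-set fraction of unhealthy subjects.
#' @param train_fraction Training share of each CV iteration.
#' @param train A [train_config()].
#' @param selection A [selection_config()], or `NULL` to skip item
#'   selection.
#' @param n_components Named per-area component counts for the PCA reports,
#'   or `NULL` to skip the explanatory stage.
#' @param k_donors PMM donor-pool size.
#' @param seed Global seed.
#' @param out_dir Optional directory for persisted artifacts.
#' @return Object of class `pipeline_report`; see [glance.pipeline_report()]
#'   for the one-row summary.
#' @export
run_pipeline <- function(data = NULL, sim = sim_config(),
                         hidden_range = 0:50, n_cv = 10,
                         fraction_unhealthy = 0.2, train_fraction = 0.8,
                         train = train_config(),
                         selection = selection_config(),
                         n_components = c(emotional = 7, dissociative = 3,
                                          psychopathological = 7),
                         k_donors = 5, seed = 1L, out_dir = NULL) {
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  if (is.null(data)) {
    sim_out <- stage("simulate", simulate_study(sim, seed = derive_seed(seed, "sim")))
    data <- sim_out$data
    truth <- sim_out$truth
  }
  missing_frac <- missingness(data)
  data <- stage("impute", impute_pmm(data, k_donors = k_donors,
                                     seed = derive_seed(seed, "impute")))
  x <- data$responses
  storage.mode(x) <- "double"
  y <- data$labels

  split <- stage("split", make_split_plan(
    y, fraction_unhealthy = fraction_unhealthy, n_iterations = n_cv,
    train_fraction = train_fraction, seed = derive_seed(seed, "split")))

  search <- stage("architecture_search", architecture_search(
    x, y, split, hidden_range = hidden_range, config = train,
    seed = derive_seed(seed, "search")))
  threshold <- search$best_threshold
  all_items_roc <- search$best_roc

  sel <- NULL
  if (!is.null(selection)) {
    sel <- stage("item_selection", run_selection(
      search$best_fit, threshold, x[split$test_idx, , drop = FALSE],
      y[split$test_idx], data$catalog, config = selection,
      seed = derive_seed(seed, "selection")))
  }

  pca_all <- pca_sel <- NULL
  if (!is.null(n_components)) {
    pca_all <- stage("pca_all_items",
                     area_reports(data, n_components, items = NULL))
    if (!is.null(sel)) {
      pca_sel <- stage("pca_selected_items",
                       area_reports(data, n_components,
                                    items = sel$selected_items))
    }
  }

  report <- structure(
    list(data = data, truth = truth, missing_frac = missing_frac,
         split = split, search = search, threshold = threshold,
         all_items_roc = all_items_roc, selection = sel,
         pca_all = pca_all, pca_selected = pca_sel, seed = seed),
    class = "pipeline_report")
  if (persist) persist_report(report, out_dir)
  report
}

# run area_report for every area that has enough items; areas with fewer
# items than components are skipped with a message (can happen for the
# selected subset of a small area)
area_reports <- function(data, n_components, items = NULL) {
  areas <- intersect(names(n_components), unique(data$catalog$area))
  out <- purrr::map(areas, function(a) {
    keep <- data$catalog$item_id[data$catalog$area == a]
    if (!is.null(items)) keep <- intersect(keep, items)
    if (length(keep) < n_components[[a]] || length(keep) < 2L) {
      message(sprintf("area '%s': %d items < %d components; report skipped",
                      a, length(keep), n_components[[a]]))
      return(NULL)
    }
    area_report(data, area = a, n_components = n_components[[a]],
                items = items)
  })
  purrr::compact(setNames(out, areas))
}

persist_report <- function(report, out_dir) {
  p <- function(...) file.path(out_dir, ...)
  write_responses(report$data, p("imputed_responses.csv"), p("catalog.csv"))
  jsonlite::write_json(
    list(test_idx = report$split$test_idx,
         cv_iterations = report$split$cv_iterations,
         seed = report$split$seed),
    p("split_plan.json"), auto_unbox = TRUE, digits = NA)
  write_network(report$search$best_fit, p("network.json"))
  readr::write_csv(report$all_items_roc$points, p("roc_all_items.csv"))
  readr::write_csv(report$search$records, p("architecture_search.csv"))
  if (!is.null(report$selection)) {
    readr::write_csv(report$selection$steps, p("selection_steps.csv"))
    readr::write_csv(
      dplyr::filter(report$data$catalog,
                    .data$item_id %in% report$selection$selected_items),
      p("selected_items.csv"))
  }
  for (nm in names(report$pca_all %||% list())) {
    readr::write_csv(tidy(report$pca_all[[nm]]),
                     p(sprintf("loadings_all_%s.csv", nm)))
  }
  for (nm in names(report$pca_selected %||% list())) {
    readr::write_csv(tidy(report$pca_selected[[nm]]),
                     p(sprintf("loadings_selected_%s.csv", nm)))
  }
  jsonlite::write_json(report_summary(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

report_summary <- function(x) {
  s <- list(
    n_subjects = nrow(x$data$responses), n_items = ncol(x$data$responses),
    prevalence = mean(x$data$labels), missing_frac = x$missing_frac,
    n_test = length(x$split$test_idx), best_hidden = x$search$best_hidden,
    epochs_run = x$search$best_fit$epochs_run,
    optimal_threshold = x$threshold,
    all_items = list(accuracy = x$all_items_roc$metrics$accuracy,
                     error = x$all_items_roc$metrics$error,
                     auc = x$all_items_roc$auc))
  if (!is.null(x$selection)) {
    s$selected_items <- list(
      n_selected = length(x$selection$selected_items),
      n_steps = nrow(x$selection$steps),
      accuracy = x$selection$final_metrics$accuracy,
      error = x$selection$final_error, auc = x$selection$final_auc)
  }
  for (set in c("pca_all", "pca_selected")) {
    if (!is.null(x[[set]])) {
      s[[set]] <- purrr::map(x[[set]], function(r) {
        list(alpha = r$alpha, kmo = r$kmo,
             cum_pct_explained = utils::tail(r$loadings$cum_pct_explained, 1))
      })
    }
  }
  s
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  data: %d x %d, prevalence %.3f, %.3g%% missing\n",
              nrow(x$data$responses), ncol(x$data$responses),
              mean(x$data$labels), 100 * x$missing_frac))
  cat(sprintf("  best architecture: %d hidden | threshold %.3f\n",
              x$search$best_hidden, x$threshold))
  cat(sprintf("  all items:      accuracy %.3f, AUC %.3f\n",
              x$all_items_roc$metrics$accuracy, x$all_items_roc$auc))
  if (!is.null(x$selection)) {
    cat(sprintf("  selected items: accuracy %.3f, AUC %.3f (%d items, %d steps)\n",
                x$selection$final_metrics$accuracy, x$selection$final_auc,
                length(x$selection$selected_items), nrow(x$selection$steps)))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return Tibble with the headline quantities: best architecture, cutoff,
#'   all-items and selected-items accuracy/AUC, selection size.
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(
    n_subjects = nrow(x$data$responses), n_items = ncol(x$data$responses),
    best_hidden = x$search$best_hidden, optimal_threshold = x$threshold,
    all_items_accuracy = x$all_items_roc$metrics$accuracy,
    all_items_auc = x$all_items_roc$auc,
    selected_accuracy = if (!is.null(x$selection))
      x$selection$final_metrics$accuracy else NA_real_,
    selected_auc = if (!is.null(x$selection)) x$selection$final_auc
      else NA_real_,
    n_selected = if (!is.null(x$selection))
      length(x$selection$selected_items) else NA_integer_)
}
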