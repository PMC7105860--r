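#' Construct a validated questionnaire dataset
#'
#' Bundles a subjects x items binary response matrix (missing cells allowed),
#' a binary diagnosis label per subject (1 = unhealthy, the positive class),
#' subject identifiers, and an item catalog describing each item's area,
#' motivational system and theory-anchored (`fixed`) status.
#'
#' @param responses Matrix or data frame of 0/1/`NA` with item ids as column
#'   names.
#' @param labels Binary vector, one per subject; no missing values.
#' @param subject_ids Optional identifiers (default `S0001`, ...).
#' @param catalog Item catalog tibble with columns `item_id`, `area`,
#'   `system`, `fixed` and optionally `text`. Every response column must
#'   appear exactly once.
#' @return An object of class `response_dataset`.
#' @export
response_dataset <- function(responses, labels, subject_ids = NULL,
                             catalog = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (is.null(colnames(responses))) {
    abort("`responses` must have item ids as column names.")
  }
  bad <- which(!(is.na(responses) | responses == 0L | responses == 1L),
               arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-binary response value at row %d, item '%s'.",
      bad[1, 1], colnames(responses)[bad[1, 2]]))
  }
  if (anyNA(labels)) abort("`labels` must not contain missing values.")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("`labels` must be binary 0/1.")
  if (length(labels) != nrow(responses)) {
    abort("length of `labels` must equal the number of subjects.")
  }
  subject_ids <- subject_ids %||% sprintf("S%04d", seq_len(nrow(responses)))
  if (length(subject_ids) != nrow(responses)) {
    abort("`subject_ids` length must equal the number of subjects.")
  }
  if (is.null(catalog)) {
    catalog <- tibble(item_id = colnames(responses), area = "emotional",
                      system = "none", fixed = FALSE, text = NA_character_)
  }
  catalog <- as_tibble(catalog)
  if (!all(c("item_id", "area", "system", "fixed") %in% names(catalog))) {
    abort("catalog needs columns item_id, area, system, fixed.")
  }
  if (anyDuplicated(catalog$item_id)) abort("catalog item_ids must be unique.")
  if (!setequal(catalog$item_id, colnames(responses)) ||
      nrow(catalog) != ncol(responses)) {
    missing_items <- setdiff(colnames(responses), catalog$item_id)
    extra <- setdiff(catalog$item_id, colnames(responses))
    abort(sprintf(
      "catalog/response mismatch (%d response columns not in catalog, %d catalog items unused).",
      length(missing_items), length(extra)))
  }
  catalog <- catalog[match(colnames(responses), catalog$item_id), ]
  catalog$fixed <- as.logical(catalog$fixed)
  structure(
    list(responses = responses, labels = labels,
         subject_ids = as.character(subject_ids), catalog = catalog),
    class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf(
    "<response_dataset> %d subjects x %d items | %d unhealthy (%.1f%%) | %.2f%% missing\n",
    nrow(x$responses), ncol(x$responses), sum(x$labels),
    100 * mean(x$labels), 100 * missingness(x)))
  tab <- table(x$catalog$area)
  cat("  areas:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("| fixed items: %d\n", sum(x$catalog$fixed)))
  invisible(x)
}

#' Fraction of missing response cells
#' @param data A [response_dataset()].
#' @return Proportion of `NA` cells in the response matrix.
#' @export
missingness <- function(data) {
  stopifnot(inherits(data, "response_dataset"))
  mean(is.na(data$responses))
}

#' Read questionnaire responses and an item catalog from CSV
#'
#' The responses file has a header of item ids plus one label column; cells
#' are 0, 1 or empty (missing). The catalog file has columns `item_id`,
#' `area`, `system`, `fixed` (0/1) and optionally `text`.
#'
#' @param path_responses,path_catalog File paths.
#' @param label_col Name of the diagnosis column in the responses file.
#' @param id_col Optional name of a subject-id column.
#' @return A validated [response_dataset()]; the missingness fraction is
#'   reported as a message.
#' @export
read_responses <- function(path_responses, path_catalog = NULL,
                           label_col = "diagnosis", id_col = NULL) {
  if (!file.exists(path_responses)) {
    abort(sprintf("responses file not found: %s", path_responses))
  }
  df <- readr::read_csv(path_responses, show_col_types = FALSE,
                        progress = FALSE)
  if (!label_col %in% names(df)) {
    abort(sprintf("label column '%s' not found in responses file.", label_col))
  }
  subject_ids <- NULL
  if (!is.null(id_col)) {
    subject_ids <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
  }
  labels <- df[[label_col]]
  df[[label_col]] <- NULL
  not_binary <- !vapply(df, function(x) all(is.na(x) | x %in% c(0, 1)),
                        logical(1))
  if (any(not_binary)) {
    col <- names(df)[which(not_binary)[1]]
    row <- which(!(is.na(df[[col]]) | df[[col]] %in% c(0, 1)))[1]
    abort(sprintf("non-binary value at row %d, item '%s'.", row, col))
  }
  catalog <- if (!is.null(path_catalog)) read_item_catalog(path_catalog)
  out <- response_dataset(as.matrix(df), labels, subject_ids, catalog)
  message(sprintf("read %d subjects x %d items; %.3g%% missing",
                  nrow(out$responses), ncol(out$responses),
                  100 * missingness(out)))
  out
}

#' @rdname read_responses
#' @param path Catalog CSV path.
#' @export
read_item_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("catalog file not found: %s", path))
  cat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("item_id", "area", "system", "fixed")
  if (!all(req %in% names(cat))) {
    abort(sprintf("catalog must have columns %s.", paste(req, collapse = ", ")))
  }
  cat$fixed <- as.logical(as.integer(cat$fixed))
  if (!"text" %in% names(cat)) cat$text <- NA_character_
  as_tibble(cat[c(req, "text")])
}

#' Write a dataset to the CSV dialect `read_responses()` accepts
#'
#' @param data A [response_dataset()].
#' @param path_responses,path_catalog Output paths (catalog optional).
#' @param label_col Name for the label column.
#' @return `data`, invisibly.
#' @export
write_responses <- function(data, path_responses, path_catalog = NULL,
                            label_col = "diagnosis") {
  stopifnot(inherits(data, "response_dataset"))
  df <- as.data.frame(data$responses)
  df[[label_col]] <- data$labels
  readr::write_csv(df, path_responses, na = "")
  if (!is.null(path_catalog)) {
    cat <- data$catalog
    cat$fixed <- as.integer(cat$fixed)
    readr::write_csv(cat, path_catalog, na = "")
  }
  invisible(data)
}
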