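#' Correlation matrix of binary items
#'
#' Pearson correlations, which for 0/1 items are the phi coefficients.
#'
#' @param x Subjects x items binary matrix (no missing values).
#' @return Symmetric items x items correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) abort("need at least 2 items.")
  v <- apply(x, 2L, var)
  if (any(v == 0)) {
    abort(sprintf("item '%s' is constant; correlation undefined.",
                  colnames(x)[which(v == 0)[1]]))
  }
  stats::cor(x)
}

#' Principal components of a correlation matrix
#'
#' Eigendecomposition of the correlation matrix; loadings are eigenvectors
#' scaled by the square root of their eigenvalues, and each component's
#' explained variance is its eigenvalue over the number of items. Component
#' signs are flipped so the largest-magnitude loading in each column is
#' positive.
#'
#' @param correlations Items x items correlation matrix.
#' @param n_components Number of components to retain.
#' @return Object of class `loadings_table`: `loadings` (items x
#'   components), `eigenvalues`, `pct_explained`, `cum_pct_explained`.
#' @export
pca_components <- function(correlations, n_components) {
  correlations <- as.matrix(correlations)
  n_items <- ncol(correlations)
  n_components <- assert_scalar_int(n_components, "n_components", min = 1)
  if (n_components > n_items) abort("`n_components` exceeds the item count.")
  eig <- eigen(correlations, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
    abort("correlation matrix is not positive semidefinite.")
  }
  vals <- pmax(eig$values[seq_len(n_components)], 0)
  load <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(vals), n_components)
  rownames(load) <- rownames(correlations)
  load <- flip_signs(load)
  new_loadings_table(load, eigenvalues = vals, n_items = n_items)
}

flip_signs <- function(load) {
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  load
}

new_loadings_table <- function(load, eigenvalues, n_items) {
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  pct <- 100 * eigenvalues / n_items
  structure(list(loadings = load, eigenvalues = eigenvalues,
                 pct_explained = pct, cum_pct_explained = cumsum(pct),
                 n_items = n_items),
            class = "loadings_table")
}

#' @export
print.loadings_table <- function(x, ...) {
  cat(sprintf("<loadings_table> %d items x %d components (%.1f%% cumulative variance)\n",
              nrow(x$loadings), ncol(x$loadings),
              utils::tail(x$cum_pct_explained, 1)))
  invisible(x)
}

#' @export
tidy.loadings_table <- function(x, ...) {
  as_tibble(x$loadings, rownames = "item_id") |>
    tidyr::pivot_longer(-"item_id", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.loadings_table <- function(x, ...) {
  tibble(component = colnames(x$loadings), eigenvalue = x$eigenvalues,
         pct_explained = x$pct_explained,
         cum_pct_explained = x$cum_pct_explained)
}

#' Varimax rotation of a loadings table
#'
#' Orthogonal rotation maximising the varimax simplicity criterion (Kaiser
#' normalization on by default). Row communalities are preserved; rotated
#' components are re-ordered by explained variance and sign-flipped so each
#' component's dominant item loads positively. Eigenvalues/explained
#' variance are recomputed as rotated sums of squared loadings.
#'
#' @param lt A [pca_components()] result (or bare loadings matrix).
#' @param normalize Kaiser-normalize rows before rotating.
#' @return A rotated `loadings_table` (with the rotation matrix attached as
#'   attribute `rotmat`).
#' @export
varimax_rotate <- function(lt, normalize = TRUE) {
  load <- if (inherits(lt, "loadings_table")) lt$loadings else as.matrix(lt)
  n_items <- if (inherits(lt, "loadings_table")) lt$n_items else nrow(load)
  if (ncol(load) < 2L) abort("varimax needs at least 2 components.")
  vm <- stats::varimax(load, normalize = normalize, eps = 1e-10)
  rot <- load %*% vm$rotmat
  ssq <- colSums(rot^2)
  ord <- order(ssq, decreasing = TRUE)
  rot <- flip_signs(rot[, ord, drop = FALSE])
  out <- new_loadings_table(rot, eigenvalues = ssq[ord], n_items = n_items)
  attr(out, "rotmat") <- vm$rotmat[, ord, drop = FALSE]
  out
}

# varimax simplicity criterion (raw, unnormalized): sum over components of
# the variance of squared loadings. Used by tests as the objective the
# rotation maximises.
varimax_criterion <- function(load) {
  sq <- load^2
  sum(colMeans(sq^2) - colMeans(sq)^2)
}

#' Assign items to components and grade their loadings
#'
#' Each item goes to the component where it loads most strongly (ties to
#' the lowest component index). The assigned loading is graded `negative`
#' (< 0), `very_low` (|loading| < 0.4), `low` (< 0.5) or `adequate`;
#' an item is flagged cross-loading when its second-strongest loading
#' reaches `cross_fraction` of the strongest.
#'
#' @param lt A `loadings_table` (typically rotated).
#' @param cross_fraction Cross-loading threshold as a fraction of the
#'   primary loading (default 0.75).
#' @return Tibble: `item_id`, `component`, `loading`, `quality`,
#'   `cross_loading`.
#' @export
assign_items <- function(lt, cross_fraction = 0.75) {
  load <- lt$loadings
  purrr::map_dfr(seq_len(nrow(load)), function(i) {
    a <- abs(load[i, ])
    j <- which.max(a)
    second <- if (ncol(load) > 1L) max(a[-j]) else 0
    val <- load[i, j]
    quality <- if (val < 0) "negative"
      else if (abs(val) < 0.4) "very_low"
      else if (abs(val) < 0.5) "low"
      else "adequate"
    tibble(item_id = rownames(load)[i] %||% as.character(i),
           component = colnames(load)[j], loading = val, quality = quality,
           cross_loading = second >= cross_fraction * a[j])
  })
}

#' Cronbach's alpha of an item set
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param x Subjects x items matrix.
#' @return Scalar alpha (at most 1; can be negative).
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2L) abort("alpha needs at least 2 items.")
  total_var <- var(rowSums(x))
  if (total_var == 0) abort("total-score variance is zero.")
  k / (k - 1) * (1 - sum(apply(x, 2L, var)) / total_var)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares observed correlations to anti-image partial correlations:
#' `KMO = sum(r^2) / (sum(r^2) + sum(partial^2))` over off-diagonal entries,
#' with partials taken from the inverse correlation matrix.
#'
#' @param correlations Invertible correlation matrix.
#' @return KMO in \[0, 1\].
#' @export
kmo <- function(correlations) {
  r <- as.matrix(correlations)
  inv <- tryCatch(solve(r), error = function(e)
    abort("correlation matrix is singular; KMO undefined."))
  part <- -inv / sqrt(outer(diag(inv), diag(inv)))
  diag(part) <- 0
  diag(r) <- 0
  sum(r^2) / (sum(r^2) + sum(part^2))
}

#' Per-area principal-component report
#'
#' End-to-end explanatory analysis of one area's items: phi correlations,
#' PCA with a theory-fixed number of components, Varimax rotation, item
#' assignment with loading-quality grades, Cronbach's alpha and KMO. This is
#' the per-area table a scale developer inspects after item selection.
#'
#' @param data A [response_dataset()] or a complete binary matrix.
#' @param area Area name to analyse (matched against the catalog); ignored
#'   when `data` is a bare matrix.
#' @param n_components Number of components, fixed by theory (e.g. 7 for the
#'   emotional area).
#' @param items Optional item-id subset (e.g. the selected items) to
#'   restrict the analysis to.
#' @return Object of class `area_report`: rotated `loadings` table,
#'   `assignments`, `alpha`, `kmo`, `area`, `n_items`.
#' @export
area_report <- function(data, area = NULL, n_components = 7, items = NULL) {
  if (inherits(data, "response_dataset")) {
    keep <- data$catalog$item_id
    if (!is.null(area)) {
      keep <- keep[data$catalog$area == area]
      if (!length(keep)) abort(sprintf("no items in area '%s'.", area))
    }
    if (!is.null(items)) keep <- intersect(keep, items)
    x <- data$responses[, keep, drop = FALSE]
  } else {
    x <- as.matrix(data)
    if (!is.null(items)) x <- x[, intersect(colnames(x), items), drop = FALSE]
  }
  if (anyNA(x)) abort("responses contain missing values; impute first.")
  if (ncol(x) < n_components) {
    abort(sprintf("area has %d items but %d components were requested.",
                  ncol(x), n_components))
  }
  r <- correlation_matrix(x)
  unrotated <- pca_components(r, n_components)
  rotated <- if (n_components >= 2L) varimax_rotate(unrotated) else unrotated
  structure(
    list(loadings = rotated, unrotated = unrotated,
         assignments = assign_items(rotated), alpha = cronbach_alpha(x),
         kmo = kmo(r), area = area %||% "all", n_items = ncol(x)),
    class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf(
    "<area_report> area '%s': %d items, %d components | cumulative variance %.1f%% | alpha = %.3f, KMO = %.3f\n",
    x$area, x$n_items, ncol(x$loadings$loadings),
    utils::tail(x$loadings$cum_pct_explained, 1), x$alpha, x$kmo))
  qual <- table(x$assignments$quality)
  cat("  loading quality:",
      paste(sprintf("%s=%d", names(qual), qual), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.area_report <- function(x, ...) {
  dplyr::left_join(x$assignments, tidy(x$loadings),
                   by = c("item_id", "component"),
                   suffix = c("", "_dup")) |>
    dplyr::select("item_id", "component", "loading", "quality",
                  "cross_loading") |>
    dplyr::arrange(.data$component, dplyr::desc(abs(.data$loading)))
}

#' @export
glance.area_report <- function(x, ...) {
  tibble(area = x$area, n_items = x$n_items,
         n_components = ncol(x$loadings$loadings),
         cum_pct_explained = utils::tail(x$loadings$cum_pct_explained, 1),
         alpha = x$alpha, kmo = x$kmo)
}

#' @export
autoplot.area_report <- function(object, ...) {
  tidy(object$loadings) |>
    ggplot2::ggplot(ggplot2::aes(.data$component, .data$item_id,
                                 fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(title = sprintf("rotated loadings - area '%s'", object$area),
                  x = NULL, y = NULL) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Tucker congruence between two loading matrices
#'
#' For each target component, the best absolute congruence coefficient
#' `phi = sum(a*b) / sqrt(sum(a^2) sum(b^2))` over the estimated components
#' (components may come out permuted and sign-flipped).
#'
#' @param estimated,target Loading matrices with matching rows.
#' @return Numeric vector, one best-|phi| per target column.
#' @export
tucker_congruence <- function(estimated, target) {
  estimated <- as.matrix(estimated); target <- as.matrix(target)
  apply(target, 2L, function(b) {
    max(abs(apply(estimated, 2L, function(a) {
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    })))
  })
}
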