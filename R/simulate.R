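#' Configuration for the synthetic questionnaire generator
#'
#' Describes a study-shaped dataset: binary items organised in three areas
#' (emotional characteristics, dissociative phenomena, psychopathological
#' traits), each area driven by a small number of orthogonal latent factors,
#' and a binary diagnosis label whose probability depends on a known subset
#' of "informative" items. Defaults reproduce the reference study design:
#' 604 subjects, 157/24/79 items per area, 7/3/7 factors, 32.5% prevalence
#' and 0.1% missingness.
#'
#' @param n_subjects Number of subjects.
#' @param items_per_area Named integer vector: items in the emotional,
#'   dissociative and psychopathological areas.
#' @param factors_per_area Latent factors per area (same order).
#' @param loading Standardised loading of each item on its assigned factor,
#'   in (0, 1). Items load on exactly one factor; factors are orthogonal.
#' @param endorsement Target marginal endorsement probability of each item
#'   (threshold on the latent Gaussian).
#' @param n_informative Number of items that carry signal about the
#'   diagnosis. Drawn from the first ("pathology") factor of each area.
#' @param beta Log-odds effect of each informative item on the diagnosis.
#' @param prevalence Target diagnosis prevalence; the intercept is
#'   calibrated by bisection so the mean predicted probability matches it.
#' @param n_fixed Number of theory-anchored items flagged `fixed` in the
#'   catalog (never dropped during item selection).
#' @param n_fixed_informative How many of the fixed items are drawn from the
#'   informative set; the remainder are non-informative. Keeping this below
#'   `n_informative` leaves signal for the selection algorithm to discover.
#' @param missing_rate Probability that any single cell is missing (MCAR).
#' @param factor_cor Optional common correlation between latent factors
#'   (default 0 = orthogonal), available for robustness experiments.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_study()], [simulate_responses()]
#' @export
sim_config <- function(n_subjects = 604,
                       items_per_area = c(emotional = 157, dissociative = 24,
                                          psychopathological = 79),
                       factors_per_area = c(7, 3, 7),
                       loading = 0.6,
                       endorsement = 0.5,
                       n_informative = 15,
                       beta = 2,
                       prevalence = 0.325,
                       n_fixed = 21,
                       n_fixed_informative = 5,
                       missing_rate = 0.001,
                       factor_cor = 0) {
  n_subjects <- assert_scalar_int(n_subjects, "n_subjects", min = 2)
  items_per_area <- unlist(items_per_area)     # accept YAML-style lists
  factors_per_area <- unlist(factors_per_area)
  if (length(items_per_area) != 3L || any(items_per_area < 1)) {
    abort("`items_per_area` must give a positive item count for each of the three areas.")
  }
  if (is.null(names(items_per_area))) {
    names(items_per_area) <- c("emotional", "dissociative", "psychopathological")
  }
  if (length(factors_per_area) != 3L || any(factors_per_area < 1)) {
    abort("`factors_per_area` must give a positive factor count per area.")
  }
  if (any(items_per_area < factors_per_area)) {
    abort("each area needs at least as many items as factors.")
  }
  loading <- assert_prob(loading, "loading")
  endorsement <- assert_prob(endorsement, "endorsement")
  prevalence <- assert_prob(prevalence, "prevalence")
  missing_rate <- assert_prob(missing_rate, "missing_rate", open = FALSE)
  n_items <- sum(items_per_area)
  n_informative <- assert_scalar_int(n_informative, "n_informative", min = 0)
  n_fixed <- assert_scalar_int(n_fixed, "n_fixed", min = 0)
  n_fixed_informative <- assert_scalar_int(n_fixed_informative,
                                           "n_fixed_informative", min = 0)
  if (n_informative > n_items || n_fixed > n_items) {
    abort("`n_informative` and `n_fixed` cannot exceed the total item count.")
  }
  n_fixed_informative <- min(n_fixed_informative, n_fixed, n_informative)
  structure(
    list(n_subjects = n_subjects,
         items_per_area = as.integer(items_per_area) |>
           setNames(names(items_per_area)),
         factors_per_area = as.integer(factors_per_area),
         loading = loading, endorsement = endorsement,
         n_informative = n_informative, beta = as.double(beta),
         prevalence = prevalence, n_fixed = n_fixed,
         n_fixed_informative = n_fixed_informative,
         missing_rate = missing_rate, factor_cor = as.double(factor_cor)),
    class = "sim_config")
}

# Panksepp-style labels used for emotional-area factors; other areas get
# generic component labels.
.systems <- c("PANIC/GRIEF", "CARE", "FEAR", "SEEK", "PLAY", "RAGE", "LUST")

# Build the item catalog implied by a sim_config (without fixed flags, which
# need the informative set and are filled in by simulate_study).
sim_catalog_skeleton <- function(config) {
  areas <- names(config$items_per_area)
  purrr::map2_dfr(areas, seq_along(areas), function(area, a) {
    n <- config$items_per_area[[a]]
    k <- config$factors_per_area[[a]]
    fac <- rep_len(seq_len(k), n)        # round-robin item -> factor
    fac <- sort(fac)
    sys <- if (area == "emotional") {
      .systems[(fac - 1L) %% length(.systems) + 1L]
    } else rep("none", n)
    tibble(
      item_id = sprintf("%s%03d", toupper(substr(area, 1, 3)), seq_len(n)),
      area = area, system = sys, factor = fac, fixed = FALSE,
      text = NA_character_)
  })
}

#' Simulate binary item responses from a latent-factor model
#'
#' Each subject draws standard-normal scores on the area factors; an item's
#' latent value is `loading * score + sqrt(1 - loading^2) * noise`, and the
#' binary response indicates the latent value exceeding the endorsement
#' threshold. Factors are orthogonal across and within areas unless
#' `factor_cor` is set.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the draw is bit-reproducible given the seed.
#' @return A list with `responses` (subjects x items 0/1 matrix with item-id
#'   column names), `catalog` (tibble; `factor` column records the planted
#'   assignment) and `truth` (planted loadings and factor scores).
#' @export
simulate_responses <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    catalog <- sim_catalog_skeleton(config)
    n <- config$n_subjects
    n_items <- nrow(catalog)
    k_tot <- sum(config$factors_per_area)
    scores <- matrix(rnorm(n * k_tot), n, k_tot)
    if (config$factor_cor != 0) {
      # exchangeable correlation via a shared component
      rho <- config$factor_cor
      g <- rnorm(n)
      scores <- sqrt(rho) * g + sqrt(1 - rho) * scores
    }
    # global factor index per item
    offs <- cumsum(c(0L, config$factors_per_area))[seq_len(3L)]
    area_idx <- match(catalog$area, names(config$items_per_area))
    gfac <- catalog$factor + offs[area_idx]
    lam <- config$loading
    latent <- lam * scores[, gfac, drop = FALSE] +
      sqrt(1 - lam^2) * matrix(rnorm(n * n_items), n, n_items)
    thr <- qnorm(1 - config$endorsement)
    responses <- (latent > thr) + 0L
    colnames(responses) <- catalog$item_id
    loadings <- matrix(0, n_items, k_tot,
                       dimnames = list(catalog$item_id, NULL))
    loadings[cbind(seq_len(n_items), gfac)] <- lam
    list(responses = responses, catalog = catalog,
         truth = list(loadings = loadings, factor_of_item = gfac,
                      scores = scores, threshold = thr))
  })
}

#' Simulate a diagnosis label driven by informative items
#'
#' The label is Bernoulli with log-odds `b0 + beta * sum(informative
#' responses)`; the intercept `b0` is calibrated by bisection so the mean
#' predicted probability equals the target prevalence.
#'
#' @param responses Subjects x items 0/1 matrix.
#' @param informative_items Character vector of informative item ids
#'   (columns of `responses`).
#' @param beta Common log-odds effect per informative item.
#' @param prevalence Target prevalence in (0, 1).
#' @param seed Integer seed for the Bernoulli draw.
#' @return List with `labels` (0/1 vector), `intercept`, and the linear
#'   predictor `eta`.
#' @export
simulate_diagnosis <- function(responses, informative_items, beta,
                               prevalence, seed = NULL) {
  prevalence <- assert_prob(prevalence, "prevalence")
  if (!all(informative_items %in% colnames(responses))) {
    abort("`informative_items` must name columns of `responses`.")
  }
  eta <- if (length(informative_items)) {
    drop(responses[, informative_items, drop = FALSE] %*%
           rep(beta, length(informative_items)))
  } else rep(0, nrow(responses))
  f <- function(b0) mean(plogis(b0 + eta)) - prevalence
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) abort("target prevalence unattainable.")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  b0 <- (lo + hi) / 2
  labels <- with_seed(seed, rbinom(length(eta), 1L, plogis(b0 + eta)))
  list(labels = labels, intercept = b0, eta = eta)
}

#' Make cells of a response matrix missing completely at random
#'
#' @param responses Subjects x items matrix.
#' @param rate Per-cell missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return The matrix with masked cells set to `NA`.
#' @export
inject_missing <- function(responses, rate, seed = NULL) {
  rate <- assert_prob(rate, "rate", open = FALSE)
  if (rate == 0) return(responses)
  with_seed(seed, {
    mask <- runif(length(responses)) < rate
    responses[mask] <- NA
    responses
  })
}

#' Simulate a complete study-shaped dataset
#'
#' End-to-end generator: latent-factor binary responses, a diagnosis label
#' driven by informative items (drawn from the first "pathology" factor of
#' each area), theory-anchored fixed flags, and MCAR missingness. The result
#' round-trips through [write_responses()] / [read_responses()].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed covering all stages (per-stage seeds are derived
#'   deterministically from it).
#' @return A list with `data` (a [response_dataset()]) and `truth` (planted
#'   loadings, informative item ids, diagnosis intercept).
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_responses(config, seed = derive_seed(seed, "responses"))
  catalog <- sim$catalog

  # informative items: sampled from the pathology (first) factor of each
  # area, spread across areas proportionally to that factor's item pool
  pool <- which(catalog$factor == 1L)
  n_inf <- min(config$n_informative, length(pool))
  informative <- with_seed(derive_seed(seed, "informative"),
                           sort(sample(pool, n_inf)))
  inf_ids <- catalog$item_id[informative]

  diag <- simulate_diagnosis(sim$responses, inf_ids, config$beta,
                             config$prevalence,
                             seed = derive_seed(seed, "diagnosis"))

  # theory-anchored items: partial overlap with the informative set
  fixed_ids <- with_seed(derive_seed(seed, "fixed"), {
    from_inf <- sample(inf_ids, config$n_fixed_informative)
    rest_pool <- setdiff(catalog$item_id, inf_ids)
    c(from_inf, sample(rest_pool, config$n_fixed - length(from_inf)))
  })
  catalog$fixed <- catalog$item_id %in% fixed_ids

  responses <- inject_missing(sim$responses, config$missing_rate,
                              seed = derive_seed(seed, "missing"))
  data <- response_dataset(responses, diag$labels,
                           catalog = catalog[c("item_id", "area", "system",
                                               "fixed", "text")])
  list(data = data,
       truth = list(loadings = sim$truth$loadings,
                    factor_of_item = sim$truth$factor_of_item,
                    informative_items = inf_ids,
                    fixed_items = sort(fixed_ids),
                    intercept = diag$intercept,
                    config = config))
}
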