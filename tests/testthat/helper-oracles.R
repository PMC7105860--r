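# Shared fixtures and independent oracles, built in code at test time.

# central finite-difference gradient of the network error (independent of
# the backpropagation path)
fd_gradient <- function(net, x, y, h = 1e-5) {
  vapply(seq_along(net$theta), function(k) {
    up <- net; up$theta[k] <- up$theta[k] + h
    dn <- net; dn$theta[k] <- dn$theta[k] - h
    (nn_error(up, x, y) - nn_error(dn, x, y)) / (2 * h)
  }, numeric(1))
}

# AUC by exhaustive positive/negative pair counting (ties count 1/2)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force (0,1)-criterion threshold: enumerate every candidate
# threshold, minimise distance to (0,1), ties to higher sensitivity then
# lower threshold
brute_threshold_01 <- function(scores, labels) {
  cand <- sort(unique(scores))
  rows <- t(vapply(cand, function(t) {
    pred <- scores >= t
    c(t = t,
      fpr = sum(pred & labels == 0) / sum(labels == 0),
      tpr = sum(pred & labels == 1) / sum(labels == 1))
  }, numeric(3)))
  d <- sqrt((1 - rows[, "tpr"])^2 + rows[, "fpr"]^2)
  best <- rows[d == min(d), , drop = FALSE]
  best <- best[best[, "tpr"] == max(best[, "tpr"]), , drop = FALSE]
  min(best[, "t"])
}

# raw varimax criterion maximum over a fine grid of planar rotation angles
# (2-component case only)
grid_varimax_max <- function(load, step = 0.001) {
  angles <- seq(0, pi / 2, by = step)
  vals <- vapply(angles, function(a) {
    rotm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    scaleforge:::varimax_criterion(load %*% rotm)
  }, numeric(1))
  max(vals)
}

# tiny deterministic dataset wrapper
toy_dataset <- function(responses, labels, fixed = character()) {
  cat <- tibble::tibble(item_id = colnames(responses), area = "emotional",
                        system = "none",
                        fixed = colnames(responses) %in% fixed,
                        text = NA_character_)
  response_dataset(responses, labels, catalog = cat)
}

# small study-shaped simulation config used across tests; any sim_config
# argument can be overridden
small_sim <- function(...) {
  defaults <- list(n_subjects = 240,
                   items_per_area = c(emotional = 24, dissociative = 8,
                                      psychopathological = 16),
                   factors_per_area = c(3, 2, 3),
                   n_informative = 8, beta = 2, n_fixed = 6,
                   n_fixed_informative = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# build an rprop_net with explicitly chosen parameters
manual_net <- function(n_inputs, n_hidden, theta,
                       config = train_config()) {
  net <- init_network(n_inputs, n_hidden, config, seed = 1L)
  stopifnot(length(theta) == length(net$theta))
  net$theta <- as.double(theta)
  net
}
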