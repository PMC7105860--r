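test_that("initialisation is seeded, clipped and centred", {
  a <- init_network(100, 20, seed = 5)
  b <- init_network(100, 20, seed = 5)
  expect_identical(a$theta, b$theta)
  expect_true(all(a$theta >= -4 & a$theta <= 4))
  expect_gt(length(a$theta), 1e4 / 5)
  big <- init_network(500, 20, seed = 1)   # > 10^4 draws
  expect_true(all(abs(big$theta) <= 4))
  # clipped standard normal: mean 0 within a 4-sigma Monte-Carlo band
  expect_lt(abs(mean(big$theta)), 4 / sqrt(length(big$theta)))
  expect_identical(all.equal(sd(big$theta), 1, tolerance = 0.05), TRUE)
})

test_that("forward pass evaluates the logistic of net input minus bias", {
  # zero weights and bias: logistic(0) = 0.5
  net0 <- manual_net(3, 2, rep(0, scaleforge:::n_params(3, 2)))
  expect_equal(nn_forward(net0, c(1, 0, 1)), 0.5)
  # direct single input, w = 1, b = 0: logistic(2)
  net1 <- manual_net(1, 0, c(1, 0))
  expect_equal(nn_forward(net1, 2), 1 / (1 + exp(-2)))
  expect_equal(round(nn_forward(net1, 2), 5), 0.88080)
  # deeply negative net input approaches 0
  expect_lt(nn_forward(net1, -20), 1e-6)
  expect_error(nn_forward(net1, c(1, 2)), "inputs")
})

test_that("backpropagation gradient matches central finite differences", {
  set.seed(99)
  for (case in 1:100) {
    n_in <- sample(1:4, 1)
    n_hid <- sample(0:3, 1)
    np <- scaleforge:::n_params(n_in, n_hid)
    if (np > 20) next
    net <- manual_net(n_in, n_hid, rnorm(np, sd = 1.5))
    n_obs <- sample(2:6, 1)
    x <- matrix(rnorm(n_obs * n_in), n_obs, n_in)
    y <- rbinom(n_obs, 1, 0.5)
    g <- nn_gradient(net, x, y)
    fd <- fd_gradient(net, x, y)
    denom <- pmax(abs(fd), 1e-3)
    expect_lt(max(abs(g - fd) / denom), 1e-6)
  }
})

test_that("gradient is zero at a perfect fit and additive over the batch", {
  net <- manual_net(2, 1, rep(0, scaleforge:::n_params(2, 1)))
  x <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(nn_gradient(net, x, c(0.5, 0.5)),
               rep(0, length(net$theta)))
  set.seed(3)
  net2 <- manual_net(3, 2, rnorm(scaleforge:::n_params(3, 2)))
  xb <- matrix(rnorm(12), 4, 3)
  yb <- c(0, 1, 1, 0)
  g1 <- nn_gradient(net2, xb, yb)
  g2 <- nn_gradient(net2, rbind(xb, xb), c(yb, yb))
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
})

test_that("the step-size update follows the three-branch rule exactly", {
  run_branch <- function(prev, now) {
    net <- manual_net(1, 0, c(0, 0))
    net$state$delta <- rep(0.10, 2)
    net$state$grad_prev <- rep(prev, 2)
    out <- rprop_step(net, rep(now, 2))
    out$state$delta[1]
  }
  expect_equal(run_branch(0.3, 0.2), 0.12)    # same sign: eta_plus = 1.2
  expect_equal(run_branch(0.3, -0.2), 0.05)   # sign flip: eta_minus = 0.5
  expect_equal(run_branch(0, 0.2), 0.10)      # zero product: unchanged
  expect_equal(run_branch(0, -0.4), 0.10)

  # enumerated sign patterns: delta multiplier is exactly {1.2, 0.5, 1}
  for (prev in c(-1, 0, 1)) for (now in c(-1, 0, 1)) {
    mult <- if (prev * now > 0) 1.2 else if (prev * now < 0) 0.5 else 1
    expect_equal(run_branch(prev, now), 0.10 * mult)
  }
})

test_that("weights move opposite the gradient sign by the step size", {
  net <- manual_net(2, 0, c(1, -1, 0))
  net$state$grad_prev <- c(0.1, -0.1, 0)
  grad <- c(0.2, -0.2, 0.3)
  out <- rprop_step(net, grad)
  delta <- out$state$delta
  expect_equal(out$theta, c(1, -1, 0) - sign(grad) * delta)
  # gradient memory zeroed on sign flips
  net$state$grad_prev <- c(-0.1, 0.1, 0)
  out2 <- rprop_step(net, grad)
  expect_equal(out2$state$grad_prev, c(0, 0, 0.3))
})

test_that("step sizes stay inside [delta_min, delta_max] under iteration", {
  set.seed(8)
  cfg <- train_config(delta_min = 1e-6, delta_max = 50)
  net <- init_network(3, 2, cfg, seed = 2)
  x <- matrix(rnorm(15), 5, 3)
  y <- c(1, 0, 1, 0, 1)
  for (i in 1:300) {
    net <- rprop_step(net, nn_gradient(net, x, y))
    expect_true(all(net$state$delta >= 1e-6 - 1e-15))
    expect_true(all(net$state$delta <= 50 + 1e-12))
  }
})

test_that("degenerate factors eta+ = eta- = 1 freeze the step sizes", {
  net <- init_network(2, 1, seed = 4)
  net$config$eta_plus <- 1
  net$config$eta_minus <- 1
  x <- matrix(rnorm(10), 5, 2)
  y <- c(0, 1, 0, 1, 1)
  d0 <- net$state$delta
  for (i in 1:25) net <- rprop_step(net, nn_gradient(net, x, y))
  expect_equal(net$state$delta, d0)
})

test_that("XOR is solved exactly from favourable initialisations", {
  # a 2-2-1 logistic network trained on XOR lands either in the global
  # optimum (all four patterns right) or in one of the well-known XOR local
  # minima; both basins must be reachable and every run must terminate
  # before the epoch cap
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  y <- c(0, 1, 1, 0)
  runs <- purrr::map_dfr(1:10, function(seed) {
    fit <- train_rprop(x, y, n_hidden = 2, seed = seed)
    tibble::tibble(solved = all(round(predict_scores(fit, x)) == y),
                   epochs = fit$epochs_run,
                   final_e = tail(fit$error_trace, 1))
  })
  expect_gte(sum(runs$solved), 3)
  expect_true(all(runs$epochs < 5000))
  # solved runs drive the squared error to (near) zero; trapped runs
  # plateau at the local-minimum error of about one misclassified pattern
  expect_true(all(runs$final_e[runs$solved] < 0.05))
  expect_true(all(runs$final_e[!runs$solved] > 0.2))
})

test_that("a separable problem is solved exactly with no hidden layer", {
  set.seed(21)
  x <- matrix(runif(80, -1, 1), 40, 2)
  y <- as.integer(x[, 1] + x[, 2] > 0.2)
  cfg <- train_config(init_range = c(-0.5, 0.5))
  fit <- train_rprop(x, y, n_hidden = 0, config = cfg, seed = 2)
  expect_equal(mean(round(predict_scores(fit, x)) == y), 1)
})

test_that("training is deterministic and reports a consistent error trace", {
  set.seed(31)
  x <- matrix(rbinom(200, 1, 0.5), 20, 10)
  y <- rep(c(0, 1), 10)
  f1 <- train_rprop(x, y, 3, seed = 6)
  f2 <- train_rprop(x, y, 3, seed = 6)
  expect_identical(f1$net$theta, f2$net$theta)
  expect_identical(f1$error_trace, f2$error_trace)
  expect_equal(length(f1$error_trace), f1$epochs_run)
  # trainer's reported error equals an independent evaluation at the
  # returned weights
  expect_equal(tail(f1$error_trace, 1), nn_error(f1$net, x, y),
               tolerance = 1e-10)
  expect_error(train_rprop(x, rep(1, 20), 2), "single class")
})

test_that("an already-flat network stops after one epoch without moving", {
  # zero weights, targets 0.5: gradient is exactly zero
  x <- matrix(c(0, 1, 1, 0), 2, 2)
  cfg <- train_config(init_range = c(-1e-9, 1e-9))
  fit <- train_rprop(x, c(0.49999, 0.50001), 1, config = cfg, seed = 1)
  expect_equal(fit$epochs_run, 1)
  expect_true(fit$converged)
  expect_equal(max(abs(fit$net$theta)), 1e-9, tolerance = 1e-6)
})

test_that("prediction is stateless, order-preserving and matches closed forms", {
  set.seed(12)
  net <- init_network(4, 2, seed = 3)
  x <- matrix(rbinom(20, 1, 0.5), 5, 4)
  s <- predict_scores(net, x)
  expect_equal(s[2], nn_forward(net, x[2, ]))
  expect_equal(predict_scores(net, rbind(x, x)), c(s, s))
  # zero-weight network scores logistic(-b) everywhere
  theta <- rep(0, scaleforge:::n_params(4, 0))
  theta[5] <- 0.7                     # output bias
  net0 <- manual_net(4, 0, theta)
  expect_equal(predict_scores(net0, x), rep(plogis(-0.7), 5))
  expect_error(predict_scores(net, x[, 1:3]), "columns")
})

test_that("networks serialise to JSON and reload identically", {
  set.seed(13)
  fit <- train_rprop(matrix(rbinom(80, 1, 0.5), 10, 8),
                     rep(c(0, 1), 5), 2, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_network(fit, f)
  net2 <- read_network(f)
  expect_equal(net2$theta, fit$net$theta)
  x <- matrix(rbinom(24, 1, 0.5), 3, 8)
  expect_equal(predict_scores(net2, x), predict_scores(fit, x))
})
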