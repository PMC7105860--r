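#' Training configuration for the RPROP network
#'
#' Hyperparameters of resilient backpropagation. The defaults are the study
#' settings: decrease/increase factors 0.5 and 1.2, normal weight
#' initialisation clipped to \[-4, 4\], stopping when every component of the
#' error gradient falls below 0.0005 in absolute value, and at most 5000
#' epochs of full-batch training. Step-size bounds and the initial step are
#' the canonical RPROP values.
#'
#' @param eta_minus Step-size decrease factor, in (0, 1).
#' @param eta_plus Step-size increase factor, > 1.
#' @param init_range Two-element clipping range for the standard-normal
#'   initial weights.
#' @param stop_threshold Convergence threshold on the maximum absolute
#'   partial derivative of the error.
#' @param max_epochs Maximum number of full-batch epochs.
#' @param delta_zero,delta_min,delta_max Initial, minimum and maximum
#'   per-connection step sizes.
#' @param backtrack Use the RPROP+ variant (undo the previous weight step
#'   when the gradient changes sign); `FALSE` gives plain RPROP.
#' @return A list of class `train_config`.
#' @export
train_config <- function(eta_minus = 0.5, eta_plus = 1.2,
                         init_range = c(-4, 4), stop_threshold = 0.0005,
                         max_epochs = 5000, delta_zero = 0.1,
                         delta_min = 1e-6, delta_max = 50,
                         backtrack = TRUE) {
  if (!(eta_minus > 0 && eta_minus < 1)) abort("`eta_minus` must be in (0, 1).")
  if (!(eta_plus > 1)) abort("`eta_plus` must exceed 1.")
  if (length(init_range) != 2L || init_range[1] >= init_range[2]) {
    abort("`init_range` must be an increasing pair.")
  }
  if (stop_threshold <= 0) abort("`stop_threshold` must be positive.")
  max_epochs <- assert_scalar_int(max_epochs, "max_epochs", min = 1)
  if (!(delta_min > 0 && delta_zero >= delta_min && delta_max >= delta_zero)) {
    abort("need 0 < delta_min <= delta_zero <= delta_max.")
  }
  structure(list(eta_minus = eta_minus, eta_plus = eta_plus,
                 init_range = as.double(init_range),
                 stop_threshold = stop_threshold, max_epochs = max_epochs,
                 delta_zero = delta_zero, delta_min = delta_min,
                 delta_max = delta_max, backtrack = isTRUE(backtrack)),
            class = "train_config")
}

# ---- parameter vector layout -------------------------------------------
# A network is stored as a flat parameter vector plus an architecture
# descriptor; RPROP state (step sizes, previous gradient, previous step) is
# elementwise on the same layout. n_hidden = 0 means direct input -> output.

n_params <- function(n_inputs, n_hidden) {
  if (n_hidden > 0L) n_inputs * n_hidden + n_hidden + n_hidden + 1L
  else n_inputs + 1L
}

unpack_params <- function(theta, n_inputs, n_hidden) {
  if (n_hidden > 0L) {
    i <- 0L
    W1 <- matrix(theta[i + seq_len(n_inputs * n_hidden)], n_inputs, n_hidden)
    i <- i + n_inputs * n_hidden
    b1 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
    W2 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
    b2 <- theta[i + 1L]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  } else {
    list(W = theta[seq_len(n_inputs)], b = theta[n_inputs + 1L])
  }
}

#' Initialise a network and its RPROP trainer state
#'
#' Weights and biases are i.i.d. standard normal draws clipped to the
#' configured range; every per-connection step size starts at `delta_zero`.
#'
#' @param n_inputs,n_hidden Architecture: input count and hidden-unit count
#'   (0 = logistic regression-style direct connections). One output node.
#' @param config A [train_config()].
#' @param seed Integer seed; initialisation is deterministic given the seed.
#' @return A list of class `rprop_net` with the parameter vector, layout and
#'   trainer state.
#' @export
init_network <- function(n_inputs, n_hidden, config = train_config(),
                         seed = 1L) {
  n_inputs <- assert_scalar_int(n_inputs, "n_inputs", min = 1)
  n_hidden <- assert_scalar_int(n_hidden, "n_hidden", min = 0)
  np <- n_params(n_inputs, n_hidden)
  theta <- with_seed(seed, rnorm(np))
  theta <- pmin(pmax(theta, config$init_range[1]), config$init_range[2])
  structure(
    list(n_inputs = n_inputs, n_hidden = n_hidden, theta = theta,
         config = config,
         state = list(delta = rep(config$delta_zero, np),
                      grad_prev = numeric(np), step_prev = numeric(np))),
    class = "rprop_net")
}

#' @export
print.rprop_net <- function(x, ...) {
  cat(sprintf("<rprop_net> %d inputs -> %s -> 1 output (%d parameters)\n",
              x$n_inputs,
              if (x$n_hidden > 0) sprintf("%d hidden", x$n_hidden) else "direct",
              length(x$theta)))
  invisible(x)
}

#' Forward pass of the logistic network
#'
#' Every neuron computes the logistic function of its net input
#' `sum(inputs * weights) - bias`; outputs are therefore strictly in (0, 1).
#'
#' @param net An `rprop_net`.
#' @param inputs Numeric vector of length `n_inputs`.
#' @return Scalar network output in (0, 1).
#' @seealso [predict_scores()] for matrix input.
#' @export
nn_forward <- function(net, inputs) {
  if (length(inputs) != net$n_inputs) {
    abort(sprintf("expected %d inputs, got %d.", net$n_inputs, length(inputs)))
  }
  drop(forward_matrix(net, matrix(as.double(inputs), nrow = 1L)))
}

# matrix forward pass (n subjects x n_inputs) -> vector of outputs
forward_matrix <- function(net, x) {
  p <- unpack_params(net$theta, net$n_inputs, net$n_hidden)
  if (net$n_hidden > 0L) {
    a1 <- plogis(sweep(x %*% p$W1, 2L, p$b1))
    drop(plogis(a1 %*% p$W2 - p$b2))
  } else {
    drop(plogis(x %*% p$W - p$b))
  }
}

#' Score a response matrix with a trained network
#'
#' @param net An `rprop_net` (or [train_rprop()] fit).
#' @param x Subjects x items numeric matrix with `n_inputs` columns.
#' @return Vector of scores in (0, 1), one per row, in row order.
#' @export
predict_scores <- function(net, x) {
  if (inherits(net, "rprop_fit")) net <- net$net
  x <- as.matrix(x)
  if (ncol(x) != net$n_inputs) {
    abort(sprintf("expected %d input columns, got %d.", net$n_inputs, ncol(x)))
  }
  forward_matrix(net, x)
}

#' Error function and exact gradient by backpropagation
#'
#' The training error is the sum of squared errors
#' `E = sum((output - target)^2)` over the batch; `nn_gradient()` returns
#' its exact gradient with respect to the flat parameter vector.
#'
#' @param net An `rprop_net`.
#' @param x Batch input matrix (rows = examples).
#' @param y Binary target vector.
#' @return `nn_error()`: scalar E. `nn_gradient()`: numeric vector aligned
#'   with `net$theta`.
#' @export
nn_gradient <- function(net, x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) abort("batch must be nonempty.")
  if (ncol(x) != net$n_inputs || length(y) != nrow(x)) {
    abort("batch shape does not match the network.")
  }
  p <- unpack_params(net$theta, net$n_inputs, net$n_hidden)
  if (net$n_hidden > 0L) {
    a1 <- plogis(sweep(x %*% p$W1, 2L, p$b1))
    o <- drop(plogis(a1 %*% p$W2 - p$b2))
    r <- 2 * (o - y) * o * (1 - o)
    g_w2 <- drop(crossprod(a1, r))
    g_b2 <- -sum(r)
    dh <- (r %*% t(p$W2)) * a1 * (1 - a1)
    g_w1 <- crossprod(x, dh)
    g_b1 <- -colSums(dh)
    c(as.vector(g_w1), g_b1, g_w2, g_b2)
  } else {
    o <- drop(plogis(x %*% p$W - p$b))
    r <- 2 * (o - y) * o * (1 - o)
    c(drop(crossprod(x, r)), -sum(r))
  }
}

#' @rdname nn_gradient
#' @export
nn_error <- function(net, x, y) {
  sum((forward_matrix(net, as.matrix(x)) - y)^2)
}

#' One resilient-backpropagation update
#'
#' Applies the three-branch step-size rule to every connection: when the
#' current and previous partial derivatives agree in sign the step size
#' grows by `eta_plus` (capped at `delta_max`); when they disagree it
#' shrinks by `eta_minus` (floored at `delta_min`) and the gradient memory
#' is cleared; otherwise it is unchanged. Weights then move opposite to the
#' gradient sign by their step size; under `backtrack` (RPROP+) a
#' sign-change connection instead undoes its previous move.
#'
#' @param net An `rprop_net` (carries its trainer state).
#' @param grad Current gradient vector aligned with `net$theta`.
#' @return The updated `rprop_net`.
#' @export
rprop_step <- function(net, grad) {
  cfg <- net$config
  st <- net$state
  s <- st$grad_prev * grad
  pos <- s > 0; neg <- s < 0
  delta <- st$delta
  delta[pos] <- pmin(delta[pos] * cfg$eta_plus, cfg$delta_max)
  delta[neg] <- pmax(delta[neg] * cfg$eta_minus, cfg$delta_min)
  step <- -sign(grad) * delta
  if (cfg$backtrack) step[neg] <- -st$step_prev[neg]
  theta <- net$theta + step
  grad_mem <- grad
  grad_mem[neg] <- 0
  net$theta <- theta
  net$state <- list(delta = delta, grad_prev = grad_mem, step_prev = step)
  net
}

#' Train a network with resilient backpropagation
#'
#' Full-batch RPROP: each epoch computes the exact sum-of-squared-errors
#' gradient over the whole batch and applies [rprop_step()]. Training stops
#' when the largest absolute gradient component falls below
#' `stop_threshold`, or after `max_epochs` epochs.
#'
#' @param x Training input matrix (subjects x items).
#' @param y Binary targets (both classes must be present).
#' @param n_hidden Hidden-unit count (0 = direct connections).
#' @param config A [train_config()].
#' @param seed Seed for weight initialisation.
#' @return An object of class `rprop_fit`: the trained `net`, `epochs_run`,
#'   `error_trace` (E per epoch), and `converged`.
#' @examples
#' xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
#' xor_y <- c(0, 1, 1, 0)
#' fit <- train_rprop(xor_x, xor_y, n_hidden = 2, seed = 3)
#' round(predict_scores(fit, xor_x))
#' @export
train_rprop <- function(x, y, n_hidden, config = train_config(), seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.double(y)
  if (length(unique(y)) < 2L) {
    abort("targets contain a single class; both classes are required.")
  }
  net <- init_network(ncol(x), n_hidden, config, seed = seed)
  trace <- numeric(config$max_epochs)
  converged <- FALSE
  epochs <- 0L
  for (e in seq_len(config$max_epochs)) {
    epochs <- e
    grad <- nn_gradient(net, x, y)
    if (max(abs(grad)) < config$stop_threshold) {
      # already at a flat point: no step, trace holds the current error
      trace[e] <- nn_error(net, x, y)
      converged <- TRUE
      break
    }
    net <- rprop_step(net, grad)
    trace[e] <- nn_error(net, x, y)
  }
  structure(list(net = net, n_hidden = n_hidden, epochs_run = epochs,
                 error_trace = trace[seq_len(epochs)], converged = converged,
                 config = config, seed = seed),
            class = "rprop_fit")
}

#' @export
print.rprop_fit <- function(x, ...) {
  cat(sprintf(
    "<rprop_fit> %d inputs, %d hidden | %d epochs (%s) | final E = %.4g\n",
    x$net$n_inputs, x$net$n_hidden, x$epochs_run,
    if (x$converged) "converged" else "epoch limit",
    utils::tail(x$error_trace, 1)))
  invisible(x)
}

#' @export
tidy.rprop_fit <- function(x, ...) {
  p <- unpack_params(x$net$theta, x$net$n_inputs, x$net$n_hidden)
  if (x$net$n_hidden > 0L) {
    dplyr::bind_rows(
      tidyr::expand_grid(from = seq_len(x$net$n_inputs),
                         to = seq_len(x$net$n_hidden)) |>
        dplyr::mutate(layer = "input->hidden",
                      weight = as.vector(p$W1)[(to - 1L) * x$net$n_inputs + from]),
      tibble(from = seq_len(x$net$n_hidden), to = 1L,
             layer = "hidden->output", weight = p$W2),
      tibble(from = NA_integer_, to = seq_len(x$net$n_hidden),
             layer = "hidden bias", weight = p$b1),
      tibble(from = NA_integer_, to = 1L, layer = "output bias",
             weight = p$b2))[c("layer", "from", "to", "weight")]
  } else {
    dplyr::bind_rows(
      tibble(layer = "input->output", from = seq_len(x$net$n_inputs),
             to = 1L, weight = p$W),
      tibble(layer = "output bias", from = NA_integer_, to = 1L,
             weight = p$b))
  }
}

#' @export
glance.rprop_fit <- function(x, ...) {
  tibble(n_inputs = x$net$n_inputs, n_hidden = x$net$n_hidden,
         n_parameters = length(x$net$theta), epochs_run = x$epochs_run,
         converged = x$converged,
         final_error = utils::tail(x$error_trace, 1))
}

#' Serialise a trained network to JSON (and back)
#'
#' Stores the architecture, flat parameter vector, trainer configuration and
#' seed so a fit can be reloaded and reused (e.g. by the item-selection
#' stage) without retraining.
#'
#' @param fit An `rprop_fit` or `rprop_net`.
#' @param path Output JSON path.
#' @return `read_network()` returns an `rprop_net` with the stored weights.
#' @export
write_network <- function(fit, path) {
  net <- if (inherits(fit, "rprop_fit")) fit$net else fit
  jsonlite::write_json(
    list(n_inputs = net$n_inputs, n_hidden = net$n_hidden,
         theta = net$theta, config = unclass(net$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(train_config, j$config[setdiff(names(j$config), NULL)])
  net <- init_network(j$n_inputs, j$n_hidden, cfg, seed = 0L)
  net$theta <- as.double(j$theta)
  net
}
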