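# The perceptron network and its four training algorithms, implemented from
# first principles. Layer sizes follow the two session structures: 5-1 for
# the error-correction (classic perceptron) rule, 5-6-6-1 for the gradient
# trainers. The loss everywhere is mean squared error on the sigmoid output.

#' Initialize a layered perceptron network
#'
#' Weights and biases are drawn uniformly from \[-0.5, 0.5\] using a seeded
#' generator, so the same seed always yields a bit-identical network. The
#' global RNG state is left untouched.
#'
#' @param layer_sizes Integer vector of layer widths, starting with 5 (the
#'   band-amplitude inputs) and ending with 1 (the state output). `c(5, 1)`
#'   for the single-layer perceptron, `c(5, 6, 6, 1)` for the multilayer
#'   network.
#' @param seed Integer seed for the weight draw.
#' @param activation `"sigmoid"` (default) or `"identity"` (linear output;
#'   used for diagnostics on linear problems).
#' @return An `eeg_network`: list with `layer_sizes`, `W` (list of
#'   output-by-input weight matrices), `b` (list of bias vectors),
#'   `activation`.
#' @examples
#' net <- init_network(c(5, 6, 6, 1), seed = 1)
#' sapply(net$W, dim)
#' @export
init_network <- function(layer_sizes, seed, activation = c("sigmoid", "identity")) {
  activation <- match.arg(activation)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    eegbci_stop("eegbci_bad_argument", "layer_sizes must be >= 2 positive integers")
  }
  if (layer_sizes[1L] != 5L || layer_sizes[length(layer_sizes)] != 1L) {
    eegbci_stop("eegbci_bad_argument", "layer_sizes must start with 5 and end with 1")
  }
  L <- length(layer_sizes) - 1L
  with_seed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      nin <- layer_sizes[l]; nout <- layer_sizes[l + 1L]
      W[[l]] <- matrix(stats::runif(nout * nin, -0.5, 0.5), nrow = nout, ncol = nin)
      b[[l]] <- stats::runif(nout, -0.5, 0.5)
    }
    structure(list(layer_sizes = layer_sizes, W = W, b = b,
                   activation = activation),
              class = "eeg_network")
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

act_fun <- function(net) {
  if (net$activation == "sigmoid") sigmoid else identity
}
act_deriv <- function(net, a) {
  # derivative expressed through the activation value a
  if (net$activation == "sigmoid") a * (1 - a) else rep(1, length(a))
}

#' Forward pass
#'
#' @param net An `eeg_network`.
#' @param x Feature vector of length 5 (or an n-by-5 matrix of rows).
#' @return Scalar network output in (0, 1) for the sigmoid activation (vector
#'   of length n for matrix input).
#' @export
forward <- function(net, x) {
  stopifnot(inherits(net, "eeg_network"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != net$layer_sizes[1L]) {
    eegbci_stop("eegbci_bad_argument",
                sprintf("input has %d features; network expects %d",
                        ncol(X), net$layer_sizes[1L]))
  }
  as.numeric(forward_pass(net, X)$activations[[length(net$W) + 1L]])
}

# Full forward pass keeping every layer's activations (n x units matrices).
forward_pass <- function(net, X) {
  f <- act_fun(net)
  A <- vector("list", length(net$W) + 1L)
  A[[1L]] <- X
  for (l in seq_along(net$W)) {
    Z <- A[[l]] %*% t(net$W[[l]])
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    A[[l + 1L]] <- f(Z)
  }
  list(activations = A)
}

#' Binary state prediction
#'
#' Thresholds the network output at 0.5; exact ties map to state 0 (the
#' documented convention).
#'
#' @param net An `eeg_network`.
#' @param x Feature vector (or matrix of rows).
#' @return Integer 0/1 (vector for matrix input).
#' @export
predict_state <- function(net, x) {
  as.integer(forward(net, x) > 0.5)
}

# ---------------------------------------------------------------------------
# Flattened parameter vector and derivatives.

net_flatten <- function(net) {
  unlist(lapply(seq_along(net$W), function(l) c(as.vector(net$W[[l]]), net$b[[l]])))
}

net_unflatten <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]])
    net$W[[l]][] <- theta[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(net$b[[l]])
    net$b[[l]] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  net
}

# Jacobian of the scalar network output w.r.t. the flattened parameters:
# n x p matrix, one row per sample. Column order matches net_flatten.
net_jacobian <- function(net, X) {
  fp <- forward_pass(net, X)
  A <- fp$activations
  L <- length(net$W)
  n <- nrow(X)
  # delta[[l]]: d output / d z_l  (n x units_l)
  delta <- vector("list", L)
  delta[[L]] <- matrix(act_deriv(net, A[[L + 1L]]), nrow = n)
  if (L > 1L) {
    for (l in (L - 1L):1L) {
      delta[[l]] <- (delta[[l + 1L]] %*% net$W[[l + 1L]]) *
        matrix(act_deriv(net, A[[l + 1L]]), nrow = n)
    }
  }
  blocks <- lapply(seq_len(L), function(l) {
    nout <- nrow(net$W[[l]]); nin <- ncol(net$W[[l]])
    # column-major over the weight matrix: (j, k) -> column (k-1)*nout + j
    JW <- delta[[l]][, rep(seq_len(nout), times = nin), drop = FALSE] *
      A[[l]][, rep(seq_len(nin), each = nout), drop = FALSE]
    cbind(JW, delta[[l]])
  })
  do.call(cbind, blocks)
}

# Gradient of MSE = mean((o - t)^2) w.r.t. flattened parameters.
net_gradient <- function(net, X, y) {
  o <- forward(net, X)
  J <- net_jacobian(net, X)
  as.numeric(crossprod(J, 2 * (o - y) / length(y)))
}

net_mse <- function(net, X, y) mean((forward(net, X) - y)^2)

# ---------------------------------------------------------------------------
# Trainer configuration.

#' Trainer configuration
#'
#' Collects the hyperparameters of the four training algorithms. Defaults:
#' learning rate 0.5 for batch backpropagation and 0.1 for the per-sample
#' error-correction rule; the canonical Rprop constants
#' (eta+ 1.2, eta- 0.5, Delta0 0.1, Delta in \[1e-6, 50\]); and
#' Levenberg-Marquardt damping lambda0 1e-3 scaled by 10 up / 0.1 down with
#' at most 5 escalations per epoch. All trainers run for at most `epochs`
#' passes and stop early once the training MSE falls below `mse_goal`.
#'
#' @param algorithm One of `"levenberg_marquardt"`, `"backprop"`, `"rprop"`,
#'   `"error_correction"`.
#' @param learning_rate Step size (backprop, error-correction).
#' @param epochs Maximum training passes. Defaults to 50, except for
#'   Levenberg-Marquardt where it defaults to 5: a handful of damped
#'   Gauss-Newton steps already extracts the generalizable structure of a
#'   session's training pairs, and further steps fit session-specific noise
#'   (see the methods vignette).
#' @param mse_goal Early-stopping MSE threshold (default 0.01).
#' @param eta_plus,eta_minus,delta0,delta_min,delta_max Rprop constants.
#' @param lambda0,lambda_up,lambda_down,max_escalations Levenberg-Marquardt
#'   damping schedule.
#' @return A `trainer_config` list.
#' @export
trainer_config <- function(algorithm = c("levenberg_marquardt", "backprop",
                                         "rprop", "error_correction"),
                           learning_rate = NULL,
                           epochs = NULL, mse_goal = 0.01,
                           eta_plus = 1.2, eta_minus = 0.5,
                           delta0 = 0.1, delta_min = 1e-6, delta_max = 50,
                           lambda0 = 1e-3, lambda_up = 10, lambda_down = 0.1,
                           max_escalations = 5L) {
  algorithm <- match.arg(algorithm)
  if (is.null(learning_rate)) {
    learning_rate <- if (algorithm == "error_correction") 0.1 else 0.5
  }
  if (is.null(epochs)) {
    epochs <- if (algorithm == "levenberg_marquardt") 5L else 50L
  }
  if (!(eta_minus < 1 && 1 < eta_plus)) {
    eegbci_stop("eegbci_bad_argument", "need eta_minus < 1 < eta_plus")
  }
  if (lambda0 < 0) eegbci_stop("eegbci_bad_argument", "lambda0 must be >= 0")
  if (epochs < 1L) eegbci_stop("eegbci_bad_argument", "epochs must be >= 1")
  structure(
    list(algorithm = algorithm, learning_rate = learning_rate,
         epochs = as.integer(epochs), mse_goal = mse_goal,
         eta_plus = eta_plus, eta_minus = eta_minus, delta0 = delta0,
         delta_min = delta_min, delta_max = delta_max,
         lambda0 = lambda0, lambda_up = lambda_up, lambda_down = lambda_down,
         max_escalations = as.integer(max_escalations)),
    class = "trainer_config"
  )
}

#' Layer structure for a training algorithm
#'
#' The error-correction rule can only train a single-layer perceptron (5-1);
#' the gradient-based trainers use the 5-6-6-1 multilayer structure.
#'
#' @param algorithm Algorithm name as in [trainer_config()].
#' @return Integer vector of layer sizes.
#' @export
default_structure <- function(algorithm) {
  if (algorithm == "error_correction") c(5L, 1L) else c(5L, 6L, 6L, 1L)
}

#' Train a network
#'
#' Dispatches to the algorithm named in `config`. All trainers are
#' deterministic given the network, data and configuration.
#'
#' @param net An `eeg_network` from [init_network()].
#' @param X n-by-5 matrix of feature vectors.
#' @param y Length-n vector of binary targets (0/1).
#' @param config A [trainer_config()].
#' @return The trained `eeg_network`, with attribute `history` (per-epoch
#'   training MSE).
#' @export
train_network <- function(net, X, y, config) {
  stopifnot(inherits(net, "eeg_network"), inherits(config, "trainer_config"))
  X <- as.matrix(X)
  if (ncol(X) != net$layer_sizes[1L] || nrow(X) != length(y)) {
    eegbci_stop("eegbci_bad_argument", "X must be n-by-5 with length(y) == n")
  }
  if (!all(y %in% c(0, 1))) {
    eegbci_stop("eegbci_bad_argument", "targets must be binary 0/1")
  }
  switch(config$algorithm,
         error_correction = train_error_correction(net, X, y, config),
         backprop = train_backprop(net, X, y, config),
         rprop = train_rprop(net, X, y, config),
         levenberg_marquardt = train_lm(net, X, y, config))
}

#' Perceptron error-correction training (single-layer)
#'
#' The classic per-sample perceptron rule: for each sample, the predicted
#' class is the thresholded output and the weights move by
#' `lr * (target - predicted) * x`. Converges in finitely many updates on
#' linearly separable data. Stops early after an epoch with no errors.
#'
#' @inheritParams train_network
#' @return The trained network, with attributes `history` (per-epoch error
#'   count) and `epochs_run`.
#' @export
train_error_correction <- function(net, X, y, config) {
  if (length(net$layer_sizes) != 2L) {
    eegbci_stop("eegbci_unsupported_structure",
                "the error-correction rule trains only a single-layer (5-1) perceptron")
  }
  X <- as.matrix(X)
  w <- as.numeric(net$W[[1L]])
  b <- net$b[[1L]]
  lr <- config$learning_rate
  history <- integer(0)
  for (epoch in seq_len(config$epochs)) {
    errors <- 0L
    for (i in seq_len(nrow(X))) {
      xi <- X[i, ]
      pred <- as.integer(sum(w * xi) + b > 0)   # sigmoid(z) > 0.5  <=>  z > 0
      if (pred != y[i]) {
        upd <- lr * (y[i] - pred)
        w <- w + upd * xi
        b <- b + upd
        errors <- errors + 1L
      }
    }
    history <- c(history, errors)
    if (errors == 0L) break
  }
  net$W[[1L]][] <- w
  net$b[[1L]] <- b
  attr(net, "history") <- history
  attr(net, "epochs_run") <- length(history)
  net
}

#' Batch gradient-descent backpropagation training
#'
#' Full-batch gradient descent on the mean-squared-error loss; the gradient
#' is computed by backpropagation through the sigmoid layers.
#'
#' @inheritParams train_network
#' @return The trained network with attribute `history` (per-epoch MSE).
#' @export
train_backprop <- function(net, X, y, config) {
  X <- as.matrix(X)
  history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    g <- net_gradient(net, X, y)
    theta <- net_flatten(net) - config$learning_rate * g
    net <- net_unflatten(net, theta)
    mse <- net_mse(net, X, y)
    history <- c(history, mse)
    if (mse < config$mse_goal) break
  }
  attr(net, "history") <- history
  net
}

# One Rprop- update. grad: current gradient; state: list(delta, prev_sign).
# Returns list(step = weight increment to *add*, state = updated state).
# On a sign flip the step size shrinks, the update is skipped, and the
# stored sign is cleared so the next epoch is treated as fresh.
rprop_update <- function(grad, state, config) {
  s <- sign(grad)
  prod <- s * state$prev_sign
  up <- prod > 0
  down <- prod < 0
  state$delta[up] <- pmin(state$delta[up] * config$eta_plus, config$delta_max)
  state$delta[down] <- pmax(state$delta[down] * config$eta_minus, config$delta_min)
  step <- -s * state$delta
  step[down] <- 0
  s[down] <- 0
  state$prev_sign <- s
  list(step = step, state = state)
}

#' Resilient backpropagation (Rprop-) training
#'
#' Batch training in which each parameter keeps its own step size, grown by
#' `eta_plus` while the gradient sign is stable and shrunk by `eta_minus`
#' (skipping that update) when it flips; the update direction uses only the
#' sign of the gradient, so the trajectory is invariant to any positive
#' rescaling of the loss.
#'
#' @inheritParams train_network
#' @return The trained network with attribute `history` (per-epoch MSE).
#' @export
train_rprop <- function(net, X, y, config) {
  X <- as.matrix(X)
  theta <- net_flatten(net)
  state <- list(delta = rep(config$delta0, length(theta)),
                prev_sign = rep(0, length(theta)))
  history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    g <- net_gradient(net, X, y)
    upd <- rprop_update(g, state, config)
    state <- upd$state
    theta <- theta + upd$step
    net <- net_unflatten(net, theta)
    mse <- net_mse(net, X, y)
    history <- c(history, mse)
    if (mse < config$mse_goal) break
  }
  attr(net, "history") <- history
  net
}

# One Levenberg-Marquardt step at damping lambda: solves
# (J'J + lambda I) delta = J' r  with residuals r = y - o.
lm_step <- function(net, X, y, lambda) {
  o <- forward(net, X)
  r <- y - o
  J <- net_jacobian(net, X)
  A <- crossprod(J) + diag(lambda, ncol(J))
  solve(A, crossprod(J, r))
}

#' Levenberg-Marquardt training
#'
#' Damped Gauss-Newton on the per-sample residuals: each accepted step solves
#' `(J'J + lambda I) delta = J' r`. The damping `lambda` shrinks by
#' `lambda_down` after a step that reduces the sum of squared errors and
#' grows by `lambda_up` after a rejected step; after `max_escalations`
#' consecutive rejections the epoch stalls and training stops. The SSE
#' sequence over accepted steps is strictly decreasing. A singular system
#' is treated as a rejected step (lambda escalates), never an error.
#'
#' @inheritParams train_network
#' @return The trained network with attributes `history` (SSE after each
#'   accepted step) and `lambda` (final damping).
#' @export
train_lm <- function(net, X, y, config) {
  X <- as.matrix(X)
  n <- length(y)
  lambda <- config$lambda0
  sse <- sum((y - forward(net, X))^2)
  history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    accepted <- FALSE
    for (try in seq_len(config$max_escalations + 1L)) {
      delta <- tryCatch(lm_step(net, X, y, lambda), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- net_unflatten(net, net_flatten(net) + as.numeric(delta))
        cand_sse <- sum((y - forward(cand, X))^2)
        if (cand_sse < sse) {
          net <- cand
          sse <- cand_sse
          lambda <- lambda * config$lambda_down
          accepted <- TRUE
          break
        }
      }
      if (try > config$max_escalations) break
      lambda <- if (lambda > 0) lambda * config$lambda_up else config$lambda0
    }
    if (accepted) history <- c(history, sse)
    if (!accepted) break                     # stalled: no step improves
    if (sse / n < config$mse_goal) break
  }
  attr(net, "history") <- history
  attr(net, "lambda") <- lambda
  net
}

# ---------------------------------------------------------------------------
# Serialization: plain JSON text, full double precision, for session resume
# and inspection.

#' Write a network to a JSON file
#'
#' @param net An `eeg_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "eeg_network"))
  obj <- list(
    layer_sizes = net$layer_sizes,
    activation = net$activation,
    # column-major flat weights; shapes are implied by layer_sizes
    weights = lapply(net$W, as.vector),
    biases = net$b
  )
  # I(17) significant digits guarantee doubles survive the text round trip
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Read a network from a JSON file
#'
#' @param path Path written by [write_network()].
#' @return An `eeg_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  sizes <- as.integer(unlist(obj$layer_sizes))
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(as.numeric(unlist(obj$weights[[l]])),
                     nrow = sizes[l + 1L], ncol = sizes[l])
    b[[l]] <- as.numeric(unlist(obj$biases[[l]]))
  }
  structure(list(layer_sizes = sizes, W = W, b = b,
                 activation = obj$activation[[1L]]),
            class = "eeg_network")
}

#' @export
print.eeg_network <- function(x, ...) {
  cat(sprintf("<eeg_network> structure %s, %s activation, %d parameters\n",
              paste(x$layer_sizes, collapse = "-"), x$activation,
              length(net_flatten(x))))
  invisible(x)
}
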