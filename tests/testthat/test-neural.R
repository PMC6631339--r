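# Network mechanics and the four trainers, checked against independent
# numerical oracles.

test_that("init_network is seeded, shaped by layer_sizes, and validated", {
  n1 <- init_network(c(5, 6, 6, 1), seed = 1)
  n2 <- init_network(c(5, 6, 6, 1), seed = 1)
  expect_identical(n1, n2)
  expect_identical(lapply(n1$W, dim),
                   list(c(6L, 5L), c(6L, 6L), c(1L, 6L)))

  single <- init_network(c(5, 1), seed = 3)
  expect_identical(dim(single$W[[1]]), c(1L, 5L))

  expect_false(identical(n1, init_network(c(5, 6, 6, 1), seed = 2)))
  expect_error(init_network(c(4, 1), seed = 1), class = "eegbci_bad_argument")
  expect_error(init_network(c(5, 2), seed = 1), class = "eegbci_bad_argument")
})

test_that("forward matches a straight-line oracle and stays in (0,1)", {
  net <- init_network(c(5, 6, 6, 1), seed = 9)
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(5)
    o <- forward(net, x)
    expect_equal(o, oracle_forward(net, x), tolerance = 1e-12)
    expect_gt(o, 0); expect_lt(o, 1)
  }

  zero <- net
  for (l in seq_along(zero$W)) { zero$W[[l]][] <- 0; zero$b[[l]][] <- 0 }
  expect_identical(forward(zero, rep(1, 5)), 0.5)

  # scaling the output layer with fixed pre-activation sign saturates the output
  outs <- sapply(c(0.5, 1, 3, 50), function(s) {
    big <- net; big$W[[3]][] <- s; big$b[[3]] <- s
    forward(big, rep(0.5, 5))
  })
  expect_true(all(diff(outs[1:3]) > 0))
  expect_gt(outs[4], 0.999)

  expect_error(forward(net, rnorm(4)), class = "eegbci_bad_argument")
})

test_that("predict_state thresholds at 0.5 with ties mapping to 0", {
  net <- init_network(c(5, 1), seed = 1)
  net$W[[1]][] <- 0
  net$b[[1]] <- 5            # sigmoid(5) ~ 0.993
  expect_identical(predict_state(net, rep(0, 5)), 1L)
  net$b[[1]] <- -5
  expect_identical(predict_state(net, rep(0, 5)), 0L)
  net$b[[1]] <- 0            # output exactly 0.5 -> 0
  expect_identical(predict_state(net, rep(0, 5)), 0L)
})

test_that("backpropagation gradients match central differences", {
  set.seed(21)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- rep(c(0, 1), 4)
  for (sizes in list(c(5, 6, 6, 1), c(5, 1))) {
    net <- init_network(sizes, seed = 4)
    g <- eegbci:::net_gradient(net, X, y)
    f <- function(theta) eegbci:::net_mse(eegbci:::net_unflatten(net, theta), X, y)
    gn <- num_grad(f, eegbci:::net_flatten(net))
    expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-5)
  }
})

test_that("error-correction rule converges on separable data, not on XOR", {
  d <- and5_data()
  net <- init_network(c(5, 1), seed = 2)
  cfg <- trainer_config("error_correction", epochs = 100)
  trained <- train_network(net, d$X, d$y, cfg)
  expect_identical(predict_state(trained, d$X), d$y)
  expect_lte(attr(trained, "epochs_run"), 100L)

  # an already perfectly classified set changes nothing
  again <- train_network(trained, d$X, d$y, cfg)
  expect_identical(again$W, trained$W)
  expect_identical(again$b, trained$b)

  # XOR has no linear separator: training accuracy never exceeds 3/4
  x5 <- xor5_data()
  for (ep in c(10, 100, 500)) {
    t2 <- train_network(init_network(c(5, 1), seed = 2), x5$X, x5$y,
                        trainer_config("error_correction", epochs = ep))
    expect_lte(mean(predict_state(t2, x5$X) == x5$y), 0.75)
  }

  expect_error(
    train_error_correction(init_network(c(5, 6, 6, 1), seed = 1), d$X, d$y, cfg),
    class = "eegbci_unsupported_structure"
  )
})

test_that("backprop descends the loss and solves XOR-in-5D", {
  x5 <- xor5_data()
  net <- init_network(c(5, 6, 6, 1), seed = 1)

  frozen <- train_backprop(net, x5$X, x5$y,
                           trainer_config("backprop", learning_rate = 0,
                                          epochs = 5))
  expect_identical(frozen$W, net$W)

  small <- train_backprop(net, x5$X, x5$y,
                          trainer_config("backprop", learning_rate = 0.05,
                                         epochs = 200))
  expect_true(all(diff(attr(small, "history")) <= 1e-12))

  finals <- sapply(1:5, function(seed) {
    t <- train_backprop(init_network(c(5, 6, 6, 1), seed = seed), x5$X, x5$y,
                        trainer_config("backprop", learning_rate = 0.5,
                                       epochs = 5000, mse_goal = 0.04))
    tail(attr(t, "history"), 1)
  })
  expect_lt(min(finals), 0.05)
})

test_that("Rprop uses only gradient signs, follows the canonical schedule", {
  cfg <- trainer_config("rprop")

  # hand-simulated three steps on quadratic loss (w - 3)^2 from w = 0
  w <- 0; state <- list(delta = 0.1, prev_sign = 0)
  steps <- c()
  for (i in 1:3) {
    g <- 2 * (w - 3)
    upd <- eegbci:::rprop_update(g, state, cfg)
    state <- upd$state
    w <- w + upd$step
    steps <- c(steps, upd$step)
  }
  expect_equal(steps, c(0.1, 0.12, 0.144))

  # positive loss scaling leaves the trajectory unchanged (sign invariance)
  set.seed(8)
  state1 <- list(delta = rep(0.1, 6), prev_sign = rep(0, 6))
  state2 <- state1
  for (i in 1:20) {
    g <- rnorm(6)
    u1 <- eegbci:::rprop_update(g, state1, cfg)
    u2 <- eegbci:::rprop_update(7.3 * g, state2, cfg)
    expect_identical(u1$step, u2$step)
    state1 <- u1$state; state2 <- u2$state
  }

  # step sizes stay clamped to [delta_min, delta_max]
  expect_true(all(state1$delta >= cfg$delta_min & state1$delta <= cfg$delta_max))

  # solves XOR-in-5D on most seeds
  x5 <- xor5_data()
  finals <- sapply(1:5, function(seed) {
    t <- train_rprop(init_network(c(5, 6, 6, 1), seed = seed), x5$X, x5$y,
                     trainer_config("rprop", epochs = 2000, mse_goal = 0.04))
    tail(attr(t, "history"), 1)
  })
  expect_gte(sum(finals < 0.05), 3)
})

test_that("Levenberg-Marquardt honours its damping contract", {
  set.seed(31)
  X <- matrix(rnorm(20 * 5), 20, 5)

  # zero residuals: no step moves the weights (net already fits its targets)
  lin <- init_network(c(5, 1), seed = 5, activation = "identity")
  y_lin <- forward(lin, X)
  same <- eegbci:::lm_step(lin, X, y_lin, lambda = 0.5)
  expect_lt(max(abs(same)), 1e-10)

  # huge lambda: step direction aligns with the negative MSE gradient
  net <- init_network(c(5, 6, 6, 1), seed = 6)
  y <- rep(c(0, 1), 10)
  step <- as.numeric(eegbci:::lm_step(net, X, y, lambda = 1e8))
  g <- eegbci:::net_gradient(net, X, y)
  cosang <- sum(step * (-g)) / sqrt(sum(step^2) * sum(g^2))
  expect_lt(acos(min(cosang, 1)), 1e-3)

  # lambda = 0 on a linear single-layer net lands on the least-squares fit
  lin <- init_network(c(5, 1), seed = 7, activation = "identity")
  y_ls <- X %*% c(1, -2, 0.5, 0, 3) + 0.25 + rnorm(20, sd = 0.1)
  one <- eegbci:::lm_step(lin, X, as.numeric(y_ls), lambda = 0)
  moved <- eegbci:::net_unflatten(lin, eegbci:::net_flatten(lin) + as.numeric(one))
  ls <- stats::lm.fit(cbind(X, 1), as.numeric(y_ls))$coefficients
  expect_equal(unname(c(as.numeric(moved$W[[1]]), moved$b[[1]])), unname(ls),
               tolerance = 1e-8)

  # accepted-step SSE sequence strictly decreases on a real problem
  net <- init_network(c(5, 6, 6, 1), seed = 8)
  trained <- train_lm(net, X, y, trainer_config(epochs = 15))
  hist <- attr(trained, "history")
  expect_gt(length(hist), 1)
  expect_true(all(diff(hist) < 0))

  # rank-deficient inputs never crash; lambda escalation copes
  Xd <- X; Xd[, 2:5] <- 0
  expect_no_error(train_lm(init_network(c(5, 1), seed = 1), Xd,
                           rep(c(0, 1), 10), trainer_config(epochs = 3)))
})

test_that("trainers are deterministic and chance-level on unseparated data", {
  set.seed(77)
  X <- matrix(rnorm(300 * 5), 300, 5)        # no class structure at all
  y <- rep(c(0, 1), 150)
  Xtest <- matrix(rnorm(200 * 5), 200, 5)
  ytest <- rep(c(0, 1), 100)
  for (algo in c("error_correction", "backprop", "rprop", "levenberg_marquardt")) {
    cfg <- trainer_config(algo)
    net <- init_network(default_structure(algo), seed = 13)
    a <- train_network(net, X, y, cfg)
    b <- train_network(net, X, y, cfg)
    expect_identical(a, b)
    acc <- mean(predict_state(a, Xtest) == ytest)
    expect_gt(acc, 0.5 - 1.96 * sqrt(0.25 / 200) - 0.05)
    expect_lt(acc, 0.5 + 1.96 * sqrt(0.25 / 200) + 0.05)
  }
})

test_that("network serialization round-trips bit-identically", {
  path <- withr::local_tempfile(fileext = ".json")
  for (sizes in list(c(5, 1), c(5, 6, 6, 1))) {
    net <- init_network(sizes, seed = 99)
    write_network(net, path)
    back <- read_network(path)
    expect_identical(back$layer_sizes, net$layer_sizes)
    expect_identical(back$W, net$W)
    expect_identical(back$b, net$b)
    expect_identical(back$activation, net$activation)
  }
})
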