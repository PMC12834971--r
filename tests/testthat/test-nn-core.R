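## LSTM cell, softmax, entropy, and optimizer primitives.

test_that("LSTM cell reduces correctly under zero weights", {
  H <- 3
  W <- matrix(0, 2, 4 * H); U <- matrix(0, H, 4 * H); b <- numeric(4 * H)
  st <- lstm_cell_step(c(1, 1), numeric(H), numeric(H), W, U, b)
  expect_equal(drop(st$i), rep(0.5, H))
  expect_equal(drop(st$f), rep(0.5, H))
  expect_equal(drop(st$o), rep(0.5, H))
  expect_equal(drop(st$c), rep(0, H))
  expect_equal(drop(st$h), rep(0, H))
  ## with a previous cell state v: c = 0.5 v, h = 0.5 tanh(0.5 v)
  v <- c(0.3, -1.2, 2)
  st2 <- lstm_cell_step(c(1, 1), numeric(H), v, W, U, b)
  expect_equal(drop(st2$c), 0.5 * v)
  expect_equal(drop(st2$h), 0.5 * tanh(0.5 * v))
})

test_that("vectorized LSTM cell matches the scalar oracle", {
  set.seed(17)
  worst <- 0
  for (rep in 1:100) {
    D <- sample(1:4, 1); H <- sample(1:4, 1)
    W <- matrix(rnorm(D * 4 * H), D); U <- matrix(rnorm(H * 4 * H), H)
    b <- rnorm(4 * H)
    x <- rnorm(D); h0 <- rnorm(H); c0 <- rnorm(H)
    got <- lstm_cell_step(x, h0, c0, W, U, b)
    want <- scalar_lstm_oracle(x, h0, c0, W, U, b)
    worst <- max(worst, max(abs(drop(got$h) - want$h)),
                 max(abs(drop(got$c) - want$c)))
  }
  expect_lt(worst, 1e-6)
  expect_error(lstm_cell_step(rnorm(3), rnorm(2), rnorm(2),
                              matrix(0, 2, 8), matrix(0, 2, 8), rep(0, 8)))
})

test_that("temperature softmax is a stabilized simplex map", {
  expect_equal(temperature_softmax(c(1, 1, 1), 0.7), rep(1 / 3, 3))
  expect_equal(temperature_softmax(c(0, log(3)), 1), c(0.25, 0.75))
  ## extreme logits stay finite
  p <- temperature_softmax(c(1e4, 0, -1e4), 1)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1)
  for (temp in c(0.25, 1, 4)) {
    p <- temperature_softmax(matrix(rnorm(30), 5), temp)
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 5))
  }
  ## high-temperature limit approaches uniform
  expect_lt(max(abs(temperature_softmax(rnorm(6), 1e6) - 1 / 6)), 1e-5)
  expect_error(temperature_softmax(c(0, 1), 0), "positive")
  expect_error(temperature_softmax(c(0, 1), -1), "positive")
})

test_that("lower temperature strictly sharpens the argmax", {
  set.seed(4)
  for (rep in 1:20) {
    y <- rnorm(8)
    k <- which.max(y)
    p_hi <- temperature_softmax(y, 1.5)
    p_lo <- temperature_softmax(y, 0.5)
    expect_gt(p_lo[k], p_hi[k])
  }
})

test_that("policy entropy follows the Shannon formula", {
  expect_equal(policy_entropy(rep(1 / 7, 7)), log(7))
  expect_equal(policy_entropy(c(1, 0, 0)), 0)
  expect_equal(policy_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_error(policy_entropy(c(-0.1, 1.1)), "negative")
  expect_error(policy_entropy(c(0.2, 0.2)), "sum")
})

test_that("Adam optimizer descends a quadratic", {
  params <- list(w = matrix(c(5, -3), 1))
  st <- molgen:::optim_init(params)
  for (i in 1:300) {
    g <- list(w = 2 * params$w)
    up <- molgen:::optim_step(params, g, st, lr = 0.05)
    params <- up$params; st <- up$state
  }
  expect_lt(max(abs(params$w)), 1e-2)
  ## decoupled weight decay shrinks parameters with zero gradient
  params2 <- list(w = matrix(1, 1))
  st2 <- molgen:::optim_init(params2)
  up2 <- molgen:::optim_step(params2, list(w = matrix(0, 1)), st2, lr = 0.1,
                             weight_decay = 0.5)
  expect_lt(up2$params$w[1], 1)
})
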