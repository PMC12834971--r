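## Neural-network primitives in base R matrix code: LSTM cells, batch
## normalization, linear layers, temperature softmax, and Adam/AdamW.
## Everything is batched with rows = batch members.  Gradients are
## hand-derived; the test suite checks them against finite differences.

sigmoid <- function(x) 1 / (1 + exp(-x))

one_hot <- function(idx, k) {
  ## idx: 1-based integer vector -> matrix length(idx) x k
  x <- matrix(0, length(idx), k)
  x[cbind(seq_along(idx), idx)] <- 1
  x
}

#' One LSTM cell step
#'
#' Computes the gate equations of an LSTM cell: sigmoid input/forget/output
#' gates, tanh candidate cell, `c_t = f * c_{t-1} + i * c_tilde`,
#' `h_t = o * tanh(c_t)`.
#'
#' @param x Input matrix (batch x input_dim).
#' @param h_prev,c_prev Previous hidden/cell state (batch x hidden).
#' @param W Input weights (input_dim x 4*hidden), gate order i, f, o, c.
#' @param U Recurrent weights (hidden x 4*hidden).
#' @param b Bias vector (length 4*hidden).
#' @return List with `h`, `c`, and the gate activations (`i`, `f`, `o`, `g`).
#' @export
lstm_cell_step <- function(x, h_prev, c_prev, W, U, b) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(h_prev)) h_prev <- matrix(h_prev, nrow = 1)
  if (!is.matrix(c_prev)) c_prev <- matrix(c_prev, nrow = 1)
  H <- ncol(h_prev)
  stopifnot(ncol(x) == nrow(W), nrow(U) == H, ncol(W) == 4 * H,
            ncol(U) == 4 * H, length(b) == 4 * H)
  pre <- x %*% W + h_prev %*% U + matrix(b, nrow(x), 4 * H, byrow = TRUE)
  i <- sigmoid(pre[, 1:H, drop = FALSE])
  f <- sigmoid(pre[, H + 1:H, drop = FALSE])
  o <- sigmoid(pre[, 2 * H + 1:H, drop = FALSE])
  g <- tanh(pre[, 3 * H + 1:H, drop = FALSE])
  c_new <- f * c_prev + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new, i = i, f = f, o = o, g = g)
}

## forward over a token sequence; X = list over time of (B x D) inputs
lstm_seq_forward <- function(X, W, U, b, h0 = NULL, c0 = NULL) {
  B <- nrow(X[[1]]); H <- nrow(U)
  h <- if (is.null(h0)) matrix(0, B, H) else h0
  c <- if (is.null(c0)) matrix(0, B, H) else c0
  steps <- vector("list", length(X))
  hs <- vector("list", length(X))
  for (t in seq_along(X)) {
    st <- lstm_cell_step(X[[t]], h, c, W, U, b)
    steps[[t]] <- list(x = X[[t]], h_prev = h, c_prev = c,
                       i = st$i, f = st$f, o = st$o, g = st$g, c = st$c)
    h <- st$h; c <- st$c
    hs[[t]] <- h
  }
  list(h = hs, cache = steps)
}

## backward through time; dH = list over time of (B x H) grads w.r.t. h_t
## (may contain NULL for steps without output gradient)
lstm_seq_backward <- function(dH, cache, W, U, b) {
  T_ <- length(cache)
  B <- nrow(cache[[1]]$x); D <- ncol(cache[[1]]$x); H <- ncol(cache[[1]]$i)
  dW <- matrix(0, D, 4 * H); dU <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  dX <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dh_next
    if (!is.null(dH[[t]])) dh <- dh + dH[[t]]
    tc <- tanh(cc$c)
    dc <- dc_next + dh * cc$o * (1 - tc^2)
    do_ <- dh * tc
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dpre <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  do_ * cc$o * (1 - cc$o),
                  dg * (1 - cc$g^2))
    dX[[t]] <- dpre %*% t(W)
    dh_next <- dpre %*% t(U)
    dW <- dW + crossprod(cc$x, dpre)
    dU <- dU + crossprod(cc$h_prev, dpre)
    db <- db + colSums(dpre)
  }
  list(dX = dX, dW = dW, dU = dU, db = db, dh0 = dh_next, dc0 = dc_next)
}

## single-cell backward step; cache as produced inside lstm_seq_forward /
## the generation recorders: list(x, h_prev, c_prev, i, f, o, g, c)
lstm_cell_backward <- function(dh, dc_next, cache, W, U) {
  tc <- tanh(cache$c)
  dc <- dc_next + dh * cache$o * (1 - tc^2)
  do_ <- dh * tc
  di <- dc * cache$g
  dg <- dc * cache$i
  df <- dc * cache$c_prev
  dc_prev <- dc * cache$f
  dpre <- cbind(di * cache$i * (1 - cache$i),
                df * cache$f * (1 - cache$f),
                do_ * cache$o * (1 - cache$o),
                dg * (1 - cache$g^2))
  list(dx = dpre %*% t(W),
       dh_prev = dpre %*% t(U),
       dc_prev = dc_prev,
       dW = crossprod(cache$x, dpre),
       dU = crossprod(cache$h_prev, dpre),
       db = colSums(dpre))
}

## --- batch normalization ---------------------------------------------------
## x: pooled matrix (rows = batch * time, cols = features).  train mode uses
## batch statistics (biased variance) and returns updated running stats;
## eval mode is an affine map under the stored running statistics.

bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       mode = c("train", "eval"), momentum = 0.1,
                       eps = 1e-5) {
  mode <- match.arg(mode)
  n <- nrow(x)
  if (mode == "train") {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, invstd, `*`)
    y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
    unbiased <- if (n > 1) v * n / (n - 1) else v
    list(y = y,
         cache = list(xhat = xhat, invstd = invstd, gamma = gamma, n = n),
         running_mean = (1 - momentum) * running_mean + momentum * mu,
         running_var = (1 - momentum) * running_var + momentum * unbiased)
  } else {
    invstd <- 1 / sqrt(running_var + eps)
    xhat <- sweep(sweep(x, 2, running_mean), 2, invstd, `*`)
    y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
    list(y = y,
         cache = list(xhat = xhat, invstd = invstd, gamma = gamma, n = n,
                      eval = TRUE),
         running_mean = running_mean, running_var = running_var)
  }
}

bn_backward <- function(dy, cache) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, `*`)
  if (isTRUE(cache$eval)) {
    dx <- sweep(dxhat, 2, cache$invstd, `*`)
  } else {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dx <- sweep(dxhat, 2, m1) - sweep(cache$xhat, 2, m2, `*`)
    dx <- sweep(dx, 2, cache$invstd, `*`)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## --- softmax / sampling ----------------------------------------------------

#' Temperature softmax
#'
#' `p_k = exp(y_k / T) / sum_n exp(y_n / T)`, computed with max-subtraction
#' for numerical stability.  `T < 1` sharpens, `T > 1` flattens.
#'
#' @param y Logit vector, or matrix with one logit vector per row.
#' @param temperature Positive temperature.
#' @return Probability vector/matrix of the same shape.
#' @export
temperature_softmax <- function(y, temperature = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a positive scalar")
  vec <- !is.matrix(y)
  if (vec) y <- matrix(y, nrow = 1)
  z <- y / temperature
  z <- z - apply(z, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  if (vec) p[1, ] else p
}

#' Shannon entropy of a policy distribution
#'
#' Natural-log entropy `-sum_a p_a log p_a`, with `0 log 0 := 0`.
#'
#' @param probs Probability vector, or matrix of row distributions.
#' @return Scalar entropy, or one entropy per row.
#' @export
policy_entropy <- function(probs) {
  vec <- !is.matrix(probs)
  if (vec) probs <- matrix(probs, nrow = 1)
  if (any(probs < -1e-12)) stop("negative probabilities")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("rows must sum to 1")
  lp <- ifelse(probs > 0, log(probs), 0)
  h <- -rowSums(probs * lp)
  if (vec) h[1] else h
}

## sample one token id per row from row-distributions
sample_rows <- function(p) {
  cum <- t(apply(p, 1, cumsum))
  u <- stats::runif(nrow(p))
  out <- integer(nrow(p))
  for (b in seq_len(nrow(p))) out[b] <- findInterval(u[b], cum[b, ]) + 1L
  pmin(out, ncol(p))
}

## --- optimizers ------------------------------------------------------------

optim_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

## Adam with optional decoupled weight decay (AdamW)
optim_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0, no_decay = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && !(nm %in% no_decay))
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
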