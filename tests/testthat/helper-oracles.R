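## independent scalar-by-scalar reference for the LSTM gate equations
scalar_lstm_oracle <- function(x, h_prev, c_prev, W, U, b) {
  ## loop-free-of-vectorization reference: one scalar at a time
  H <- length(h_prev)
  pre <- numeric(4 * H)
  for (j in seq_len(4 * H)) {
    acc <- b[j]
    for (k in seq_along(x)) acc <- acc + W[k, j] * x[k]
    for (k in seq_len(H)) acc <- acc + U[k, j] * h_prev[k]
    pre[j] <- acc
  }
  i <- 1 / (1 + exp(-pre[1:H]))
  f <- 1 / (1 + exp(-pre[H + 1:H]))
  o <- 1 / (1 + exp(-pre[2 * H + 1:H]))
  g <- tanh(pre[3 * H + 1:H])
  c_new <- f * c_prev + i * g
  list(h = o * tanh(c_new), c = c_new)
}

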