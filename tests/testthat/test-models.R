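## Network variants: logit operations, locality, determinism, and full
## finite-difference gradient checks of the teacher-forced loss.

tiny_vocab <- function() build_vocab(list(c("C", "N", "O")), "SMILES")

test_that("logit operations return vocabulary-sized outputs, deterministically", {
  v <- tiny_vocab()
  fm <- molgen_model(v, "forward", hidden = 6, m_total = 8, seed = 2)
  y <- unidirectional_logits(fm, c(molgen:::vocab_start_id(v), 0L))
  expect_length(y, length(v$tokens))
  expect_identical(y, unidirectional_logits(fm, c(molgen:::vocab_start_id(v), 0L)))
  expect_error(unidirectional_logits(fm, c(99L)))

  fb <- molgen_model(v, "fbrnn", hidden = 6, m_total = 8, seed = 2)
  w <- encode_window(c("C", "N"), v, 8)
  halves <- fbrnn_logits(fb, w$token_ids, w$start_offset)
  expect_length(halves$y_plus, length(v$tokens))
  expect_length(halves$y_minus, length(v$tokens))

  bm <- molgen_model(v, "bimodal", hidden = 6, m_total = 8, seed = 2)
  yb <- bimodal_logits(bm, w$token_ids, 1L)
  expect_length(yb, length(v$tokens))
})

test_that("fbrnn output halves are positionally independent", {
  v <- tiny_vocab()
  fb <- molgen_model(v, "fbrnn", hidden = 6, m_total = 8, seed = 3)
  w <- encode_window(c("C", "N"), v, 8)
  base <- fbrnn_logits(fb, w$token_ids, w$start_offset)
  V <- length(v$tokens)
  fb$params$lin.b[seq_len(V)] <- fb$params$lin.b[seq_len(V)] + 1
  pert <- fbrnn_logits(fb, w$token_ids, w$start_offset)
  expect_equal(pert$y_plus, base$y_plus + 1)
  expect_equal(pert$y_minus, base$y_minus)
})

test_that("zeroing the backward half of the BIMODAL output map removes right-context sensitivity", {
  v <- tiny_vocab()
  bm <- molgen_model(v, "bimodal", hidden = 5, m_total = 9, seed = 4)
  H <- bm$hidden
  bm$params$lin.W[H + seq_len(H), ] <- 0
  w1 <- encode_window(c("C", "N", "O"), v, 9)$token_ids
  w2 <- w1
  pos <- 2L                      # insertion left of most of the window
  ## change only tokens right of the insertion position
  w2[7:9] <- rev(w1[7:9])
  w2[6] <- w1[5]
  y1 <- bimodal_logits(bm, w1, pos)
  y2 <- bimodal_logits(bm, w2, pos)
  expect_equal(y1, y2)
  ## with the full map the right context matters
  bm2 <- molgen_model(v, "bimodal", hidden = 5, m_total = 9, seed = 4)
  expect_gt(max(abs(bimodal_logits(bm2, w1, pos) - bimodal_logits(bm2, w2, pos))), 0)
})

test_that("teacher-forced gradients match finite differences (all variants)", {
  v <- tiny_vocab()
  set.seed(21)
  for (variant in c("forward", "backward", "fbrnn", "bimodal")) {
    m <- molgen_model(v, variant, hidden = 4, m_total = 7, seed = 8)
    B <- 3; M <- 7
    ids <- matrix(sample(seq_along(v$tokens), B * M, TRUE), B, M)
    g <- c(2L, 4L, 6L)
    out <- molgen:::model_pass(m, ids, g, mode = "train", want_grads = TRUE)
    f <- function(params) {
      m2 <- m; m2$params <- params
      molgen:::model_pass(m2, ids, g, mode = "train", want_grads = FALSE)$loss
    }
    worst <- 0
    for (nm in names(m$params)) {
      idx <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
      for (k in idx) {
        eps <- 1e-5
        pp <- m$params; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- m$params; pm[[nm]][k] <- pm[[nm]][k] - eps
        fd <- (f(pp) - f(pm)) / (2 * eps)
        worst <- max(worst, abs(fd - out$grads[[nm]][k]) / max(1, abs(fd)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("a zeroed output layer predicts uniformly: loss = log(V)", {
  v <- tiny_vocab()
  for (variant in c("forward", "fbrnn", "bimodal")) {
    m <- molgen_model(v, variant, hidden = 4, m_total = 7, seed = 9)
    m$params$lin.W[] <- 0
    m$params$lin.b[] <- 0
    w <- encode_window(c("C", "N"), v, 7)
    expect_equal(teacher_forced_loss(m, list(w)),
                 log(length(v$tokens)), tolerance = 1e-10)
  }
})

test_that("loss is invariant to batch order; eval mode is deterministic", {
  m <- toy_model("fbrnn")
  toks <- lapply(toy_corpus()$selfies[1:8], tokenize_selfies)
  wins <- lapply(toks, encode_window, vocab = m$vocab, m_total = m$m_total)
  l1 <- teacher_forced_loss(m, wins, mode = "eval")
  l2 <- teacher_forced_loss(m, rev(wins), mode = "eval")
  expect_equal(l1, l2, tolerance = 1e-12)
  expect_identical(teacher_forced_loss(m, wins, mode = "eval"), l1)
})

test_that("forward and backward models are mirror images under shared weights", {
  v <- tiny_vocab()
  fm <- molgen_model(v, "forward", hidden = 6, m_total = 8, seed = 5)
  bm <- fm; bm$variant <- "backward"
  p1 <- predict(fm, "CNO")
  p2 <- predict(bm, "ONC")
  expect_equal(p1, p2, tolerance = 1e-12)
})
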