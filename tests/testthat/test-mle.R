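test_that("cv folds partition the data deterministically", {
  f <- make_cv_folds(10, 5, seed = 3)
  expect_length(f, 5)
  expect_true(all(vapply(f, function(x) length(x$held_out_indices), numeric(1)) == 2))
  expect_identical(sort(unlist(lapply(f, `[[`, "held_out_indices"))), 1:10)
  f2 <- make_cv_folds(10, 5, seed = 3)
  expect_identical(f, f2)
  f11 <- make_cv_folds(11, 5, seed = 1)
  expect_identical(sort(vapply(f11, function(x) length(x$held_out_indices),
                               numeric(1)), decreasing = TRUE),
                   c(3, 2, 2, 2, 2))
  for (x in f11)
    expect_identical(sort(c(x$train_indices, x$held_out_indices)), 1:11)
  expect_error(make_cv_folds(3, 5), "at least")
})

test_that("training reduces the loss and checkpoints per fold and epoch", {
  dir <- tempfile(); dir.create(dir)
  cv <- molgen_cv(toy_corpus()$selfies[1:60], scheme = "SELFIES",
                  variant = "forward", folds = 2, hidden = 16, epochs = 2,
                  seed = 5, checkpoint_dir = dir)
  expect_length(list.files(dir, pattern = "^fold\\d+_epoch\\d+\\.rds$"), 4)
  expect_length(cv$models, 2)
  expect_true(all(is.finite(cv$held_out_loss)))
  ## final epoch loss below first epoch loss in each fold
  for (m in cv$models) {
    byep <- tapply(m$history$loss, m$history$epoch, mean)
    expect_lt(byep[length(byep)], byep[1])
  }
  ## checkpoint round trip reproduces the held-out loss bit for bit
  m1 <- read_checkpoint(file.path(dir, "fold1_epoch02.rds"))
  toks <- lapply(toy_corpus()$selfies[cv$folds[[1]]$held_out_indices],
                 tokenize_selfies)
  wins <- lapply(toks, encode_window, vocab = m1$vocab, m_total = m1$m_total,
                 placement = "left")
  expect_identical(teacher_forced_loss(m1, wins, mode = "eval"),
                   cv$held_out_loss[1])
})

test_that("the model can memorize a single string", {
  s <- "[C][C][=Branch1][C][=O][N]"
  fit <- molgen(rep(s, 8), scheme = "SELFIES", variant = "forward",
                hidden = 32, epochs = 150, learning_rate = 1e-2, seed = 6)
  w <- encode_window(tokenize_selfies(s), fit$vocab, fit$m_total,
                     placement = "left")
  expect_lt(teacher_forced_loss(fit, list(w), mode = "eval"), 0.01)
  ## and reproduces it when sampling greedily (tiny temperature)
  out <- generate(fit, 3, temperature = 1e-4, seed = 1)
  expect_true(all(out$core == s))
})

test_that("training is reproducible under a fixed seed", {
  f1 <- molgen(toy_corpus()$selfies[1:40], scheme = "SELFIES",
               variant = "fbrnn", hidden = 8, epochs = 1, seed = 11)
  f2 <- molgen(toy_corpus()$selfies[1:40], scheme = "SELFIES",
               variant = "fbrnn", hidden = 8, epochs = 1, seed = 11)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params, f2$params)
})

test_that("non-finite loss aborts with a diagnostic", {
  v <- build_vocab(list(c("C", "N")), "SMILES")
  m <- molgen_model(v, "forward", hidden = 4, m_total = 6, seed = 1)
  m$params$lin.W[] <- NaN
  w <- encode_window(c("C"), v, 6, placement = "left")
  expect_error(
    molgen:::train_model(m, list(c("C")), epochs = 1, batch_size = 1,
                         learning_rate = 1e-3, seed = 1),
    "non-finite")
})
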