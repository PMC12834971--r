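test_that("SMILES tokenizer is lossless and atom-aware", {
  expect_identical(tokenize_smiles("CCO"), c("C", "C", "O"))
  expect_identical(tokenize_smiles("CCl"), c("C", "Cl"))
  expect_identical(tokenize_smiles("BrCC(=O)N"),
                   c("Br", "C", "C", "(", "=", "O", ")", "N"))
  toks <- tokenize_smiles("C1=CC=C2C(=C1)C=CN2")  # indole
  expect_length(toks, 19)
  expect_identical(toks[1], "C")
  expect_identical(toks[19], "2")
  ## bracket atoms and %nn closures stay atomic
  expect_identical(tokenize_smiles("[nH]C%12"), c("[nH]", "C", "%12"))
  ## losslessness on a batch of corpus strings
  for (s in head(toy_corpus()$smiles, 50))
    expect_identical(paste0(tokenize_smiles(s), collapse = ""), s)
  expect_error(tokenize_smiles("C[NH"), "unbalanced")
  expect_error(tokenize_smiles("C]N"), "unbalanced")
  expect_error(tokenize_smiles(""), "empty")
})

test_that("SELFIES tokenizer splits bracketed units and rejects junk", {
  expect_identical(tokenize_selfies("[C][C][N]"), c("[C]", "[C]", "[N]"))
  expect_length(tokenize_selfies("[C][=C][C][=N][C][=C][Ring1][=Branch1]"), 8)
  expect_error(tokenize_selfies("[C]x[C]"), "malformed")
  expect_error(tokenize_selfies("[C][C"), "malformed")
  for (s in head(toy_corpus()$selfies, 50))
    expect_identical(paste0(tokenize_selfies(s), collapse = ""), s)
})

test_that("vocabulary is deterministic, reserved-token aware, serializable", {
  v <- build_vocab(list(c("C"), c("O")), "SMILES")
  expect_setequal(v$tokens, c("C", "O", "G", "A"))
  expect_length(v$tokens, 4)
  v2 <- build_vocab(list(c("O"), c("C")), "SMILES")
  expect_identical(v$tokens, v2$tokens)      # order-insensitive determinism
  expect_error(build_vocab(list(), "SMILES"), "empty corpus")
  expect_error(build_vocab(list(c("C", "G")), "SMILES"), "reserved")
  ## ids form a 0-based bijection
  ids <- molgen:::vocab_ids(v, v$tokens)
  expect_identical(sort(ids), 0:3)
  expect_error(molgen:::vocab_ids(v, "Zz"), "unknown")
  ## JSON round trip is byte-stable
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_vocab(v, f1)
  v_back <- read_vocab(f1)
  write_vocab(v_back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(v_back$tokens, v$tokens)
})

test_that("encode_window places the start token and pads as specified", {
  v <- build_vocab(list(c("C", "O")), "SMILES")
  w <- encode_window(c("C", "C"), v, 5)
  expect_identical(molgen:::vocab_tokens(v, w$token_ids),
                   c("A", "C", "G", "C", "A"))
  expect_identical(w$start_offset, 2L)
  w0 <- encode_window(character(0), v, 3)
  expect_identical(molgen:::vocab_tokens(v, w0$token_ids), c("A", "G", "A"))
  expect_error(encode_window(rep("C", 5), v, 5), "exceeds")
  ## edge placements used by the unidirectional variants
  wl <- encode_window(c("C", "O"), v, 5, placement = "left")
  expect_identical(molgen:::vocab_tokens(v, wl$token_ids),
                   c("G", "C", "O", "A", "A"))
  wr <- encode_window(c("C", "O"), v, 5, placement = "right")
  expect_identical(molgen:::vocab_tokens(v, wr$token_ids),
                   c("A", "A", "C", "O", "G"))
})

test_that("strip_special inverts encode_window for all placements", {
  v <- build_vocab(lapply(toy_corpus()$selfies[1:30], tokenize_selfies),
                   "SELFIES")
  expect_identical(strip_special(encode_window(character(0), v, 3), v), "")
  set.seed(11)
  for (rep in 1:40) {
    toks <- tokenize_selfies(sample(toy_corpus()$selfies[1:30], 1))
    m_total <- length(toks) + sample(1:6, 1)
    pl <- sample(c("fixed", "random", "left", "right"), 1)
    w <- encode_window(toks, v, m_total, placement = pl)
    expect_identical(strip_special(w, v), paste0(toks, collapse = ""))
    expect_length(w$token_ids, m_total)
    ## exactly one start token
    expect_identical(sum(w$token_ids == molgen:::vocab_start_id(v)), 1L)
  }
})
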