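test_that("unique/valid/novel percentages chain as defined", {
  ## ten copies of one valid novel string
  uvn <- compute_uvn(rep("CCO", 10), character(0), "SMILES")
  expect_equal(uvn$pct_unique, 10)
  expect_equal(uvn$pct_valid, 100)
  expect_equal(uvn$pct_novel, 100)
  ## all distinct and valid, all known
  gen <- c("CCO", "CCN", "CCC")
  uvn2 <- compute_uvn(gen, training_set = gen, scheme = "SMILES")
  expect_equal(uvn2$pct_unique, 100)
  expect_equal(uvn2$pct_valid, 100)
  expect_equal(uvn2$pct_novel, 0)
  ## invalid strings drop out between the stages
  uvn3 <- compute_uvn(c("CCO", "C1=CC", "CCO"), character(0), "SMILES")
  expect_equal(uvn3$n_unique, 2L)
  expect_equal(uvn3$n_valid, 1L)
  ## counts never increase along the chain
  expect_true(uvn3$n_sampled >= uvn3$n_unique &&
                uvn3$n_unique >= uvn3$n_valid &&
                uvn3$n_valid >= uvn3$n_novel)
  ## string-level novelty vs structure-level novelty: a rewritten duplicate
  ## is caught by canonicalization
  uvn4 <- compute_uvn("OCC", training_set = "CCO", scheme = "SMILES")
  expect_equal(uvn4$pct_novel, 0)
})

test_that("distribution tests behave at the degenerate and separated extremes", {
  expect_identical(mw_test(rep(1, 5), rep(1, 5)), 1)
  expect_identical(ks_test(rep(1, 5), rep(1, 5)), 1)
  a <- rnorm(100, 0, 0.1); b <- rnorm(100, 10, 0.1)
  expect_lt(mw_test(a, b), 1e-10)
  expect_lt(ks_test(a, b), 1e-10)
  ## agreement with the base statistics routines on fixed samples
  set.seed(2)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  expect_identical(mw_test(x, y),
                   suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value))
  expect_identical(ks_test(x, y), suppressWarnings(stats::ks.test(x, y)$p.value))
  row <- distribution_test(y, x)
  expect_identical(row$constrained_higher, median(y) > median(x))
  expect_identical(row$median_constrained, median(y))
  expect_identical(row$median_null, median(x))
})

test_that("Morgan fingerprints are 2048-bit, deterministic, discriminative", {
  fps <- morgan_fingerprints(c("C", "C", "CC(=O)Nc1ccc(O)cc1"))
  expect_identical(dim(fps), c(3L, 2048L))
  expect_identical(fps[1, ], fps[2, ])
  expect_gt(sum(fps[1, ] != fps[3, ]), 0)
  expect_true(all(fps %in% c(0L, 1L)))
  expect_error(morgan_fingerprints("C1=CC"), "invalid")
})

test_that("2-D embedding keeps well-separated fingerprint clusters apart", {
  set.seed(6)
  ## two synthetic bit-pattern clusters
  a <- matrix(0L, 20, 2048); a[, 1:40] <- 1L
  b <- matrix(0L, 20, 2048); b[, 2001:2048] <- 1L
  a <- a + matrix(rbinom(20 * 2048, 1, 0.002), 20)
  b <- b + matrix(rbinom(20 * 2048, 1, 0.002), 20)
  fps <- pmin(rbind(a, b), 1L)
  emb <- embed_2d(fps, perplexity = 5, seed = 0)
  expect_identical(dim(emb), c(40L, 2L))
  emb2 <- embed_2d(fps, perplexity = 5, seed = 0)
  expect_equal(emb, emb2)
  ## silhouette-style check: nearest centroid is one's own
  lab <- rep(1:2, each = 20)
  cent <- rbind(colMeans(emb[lab == 1, ]), colMeans(emb[lab == 2, ]))
  d_own <- sqrt(rowSums((emb - cent[lab, ])^2))
  d_other <- sqrt(rowSums((emb - cent[3 - lab, ])^2))
  expect_gt(mean(d_other - d_own), 0)
  expect_error(embed_2d(fps, perplexity = 30), "perplexity")
})

test_that("QED/SA summaries match hand computation and ignore order", {
  mols <- c("CCO", "CC(=O)N", "c1ccccc1", "CCN", "CC(=O)Nc1ccc(O)cc1")
  s1 <- qed_sa_summary(mols)
  props <- molgen:::mol_properties(mols)
  expect_equal(s1$qed_mean, mean(props$qed))
  expect_equal(s1$qed_std, sd(props$qed))
  expect_equal(s1$sa_median, median(props$sa))
  s2 <- qed_sa_summary(rev(mols))
  expect_equal(s1, s2)
  single <- qed_sa_summary("CCO")
  expect_identical(single$qed_std, 0)
  expect_identical(single$sa_std, 0)
  expect_error(qed_sa_summary("C1=CC"), "invalid")
})

test_that("generation_metrics reports the headline table row", {
  m <- toy_model("fbrnn")
  row <- generation_metrics(m, toy_corpus()$selfies, n = 40, seed = 3)
  expect_identical(row$scheme, "SELFIES")
  expect_true(row$pct_unique >= 0 && row$pct_unique <= 100)
  expect_true(row$pct_valid >= 0 && row$pct_valid <= 100)
  expect_true(row$pct_novel >= 0 && row$pct_novel <= 100)
})
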