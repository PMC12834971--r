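## The SELFIES codec against the printed encodings of the six bundled
## fragments and against RDKit as a structure oracle.

FRAGMENT_SELFIES <- c(
  Pyridine = "[C][=C][C][=N][C][=C][Ring1][=Branch1]",
  Benzimidazole = "[C][=C][C][=C][C][=Branch1][Ring2][=C][Ring1][=Branch1][N][=C][N][Ring1][=Branch1]",
  Piperazine = "[C][C][N][C][C][N][Ring1][=Branch1]",
  Amide = "[C][C][=Branch1][C][=O][N]",
  Quinoline = "[C][=C][C][=C][C][=C][C][=N][C][Ring1][=Branch1][=C][Ring1][#Branch2]")

test_that("encoder reproduces the reference fragment encodings", {
  seeds <- bundled_seeds()
  for (nm in names(FRAGMENT_SELFIES)) {
    smi <- seeds$smiles[seeds$name == nm]
    expect_identical(selfies_encode(smi), unname(FRAGMENT_SELFIES[nm]),
                     label = nm)
  }
})

test_that("decode inverts encode on the fragments, structurally", {
  seeds <- bundled_seeds()
  for (i in seq_len(nrow(seeds))) {
    back <- selfies_decode(seeds$selfies[i])
    expect_identical(canonical_smiles(back, "SMILES"),
                     canonical_smiles(seeds$smiles[i], "SMILES"),
                     label = seeds$name[i])
  }
})

test_that("SMILES <-> SELFIES round trip preserves canonical structure", {
  corpus <- head(toy_corpus()$smiles, 100)
  enc <- vapply(corpus, selfies_encode, character(1), USE.NAMES = FALSE)
  dec <- vapply(enc, selfies_decode, character(1), USE.NAMES = FALSE)
  expect_identical(canonical_smiles(dec, "SMILES"),
                   canonical_smiles(corpus, "SMILES"))
  ## convert_encoding is the same map
  expect_identical(convert_encoding(corpus[1], "SMILES", "SELFIES"), enc[1])
  expect_identical(convert_encoding(enc[1], "SELFIES", "SMILES"), dec[1])
  expect_identical(convert_encoding(corpus[1], "SMILES", "SMILES"), corpus[1])
  expect_error(selfies_encode("c1ccccc1"), "kekulize")
  expect_error(selfies_encode("C1CC"), "unclosed")
})

test_that("every random SELFIES token string decodes to a valid molecule", {
  set.seed(303)
  alphabet <- c("[C]", "[=C]", "[#C]", "[N]", "[=N]", "[O]", "[=O]",
                "[Branch1]", "[=Branch1]", "[Branch2]", "[Ring1]", "[Ring2]")
  atoms <- c("[C]", "[=C]", "[#C]", "[N]", "[=N]", "[O]", "[=O]")
  n <- 10000
  strings <- vapply(seq_len(n), function(i) {
    len <- sample(2:14, 1)
    paste0(c(sample(atoms, 1), sample(alphabet, len - 1, TRUE)), collapse = "")
  }, character(1))
  smiles <- safe_decode(strings)
  expect_true(all(nzchar(smiles)))
  ## validate against RDKit in one batch
  expect_identical(mean(mol_is_valid(smiles, "SMILES")), 1)
})

test_that("decoder follows the derivation rules on hand-worked cases", {
  ## branch bond order capped by the branch symbol
  expect_identical(selfies_decode("[C][C][=Branch1][C][=O][N]"), "CC(=O)N")
  ## ring back-reference counts atoms, not tokens
  expect_identical(selfies_decode("[C][C][N][C][C][N][Ring1][=Branch1]"),
                   "C1CNCCN1")
  ## saturated chain stops deriving
  expect_identical(selfies_decode("[N][#N][C][C]"), "N#N")
  ## infeasible specials are dropped singly
  expect_identical(selfies_decode("[Branch1][C][N]"), "CN")
  expect_identical(selfies_decode("[Ring1][Ring1][C]"), "C")
  expect_error(selfies_decode("[Qq]"), "unknown")
})

test_that("mol_is_valid matches the toolkit on SMILES", {
  expect_false(mol_is_valid("C1=CC", "SMILES"))    # unclosed ring
  expect_true(mol_is_valid("CCO", "SMILES"))
  expect_identical(mol_is_valid(c("CCO", "C(", "N"), "SMILES"),
                   c(TRUE, FALSE, TRUE))
  expect_false(mol_is_valid("", "SELFIES"))
})
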