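## Synthetic corpora and the bundled seed-fragment catalog.  The toy corpus
## generator draws random SELFIES token strings over a small alphabet --
## valid molecules by construction -- decodes and canonicalizes them, and
## de-duplicates on canonical structure.  It stands in for a large curated
## drug-molecule corpus wherever a training set is needed.

## small alphabet: enough to build branched, unsaturated, ring-bearing
## C/N/O molecules that decode and score quickly
TOY_SELFIES_ALPHABET <- c("[C]", "[=C]", "[N]", "[=N]", "[O]", "[=O]",
                          "[Branch1]", "[=Branch1]", "[Ring1]")

#' Generate a synthetic molecule corpus
#'
#' Draws random SELFIES token strings (first token an atom token, so every
#' draw decodes to a non-empty molecule), decodes them to SMILES,
#' canonicalizes through the RDKit backend, and de-duplicates on canonical
#' structure until `n` distinct molecules are collected.
#'
#' @param n Number of distinct molecules.
#' @param min_tokens,max_tokens Token-length range of the raw SELFIES draws.
#' @param alphabet SELFIES token alphabet to draw from.
#' @param seed RNG seed; the corpus is deterministic given the arguments.
#' @param canonicalize Use the RDKit backend to canonicalize/de-duplicate
#'   (set `FALSE` for backend-free string fixtures; de-duplication then uses
#'   the decoded SMILES text).
#' @return data.frame with `selfies`, `smiles` (decoded), `canonical`.
#' @export
make_toy_corpus <- function(n = 500, min_tokens = 4, max_tokens = 12,
                            alphabet = TOY_SELFIES_ALPHABET, seed = 1L,
                            canonicalize = TRUE) {
  stopifnot(n >= 1, min_tokens >= 2, max_tokens >= min_tokens)
  set.seed(seed)
  atoms <- alphabet[!is.na(vapply(alphabet, function(t)
    if (is.null(parse_selfies_atom(t))) NA else 1, numeric(1)))]
  seen <- character(0)
  rows <- list()
  draws <- 0L
  while (length(rows) < n && draws < 200L * n) {
    batch <- max(64L, n)
    draws <- draws + batch
    selfies <- vapply(seq_len(batch), function(i) {
      len <- sample(min_tokens:max_tokens, 1L)
      paste0(c(sample(atoms, 1L),
               sample(alphabet, len - 1L, replace = TRUE)), collapse = "")
    }, character(1))
    smiles <- vapply(selfies, selfies_decode, character(1), USE.NAMES = FALSE)
    ok <- nzchar(smiles)
    selfies <- selfies[ok]; smiles <- smiles[ok]
    canon <- if (canonicalize) canonical_smiles(smiles, "SMILES") else smiles
    for (i in seq_along(selfies)) {
      if (is.na(canon[i]) || canon[i] %in% seen) next
      seen <- c(seen, canon[i])
      rows[[length(rows) + 1L]] <-
        data.frame(selfies = selfies[i], smiles = smiles[i],
                   canonical = canon[i], stringsAsFactors = FALSE)
      if (length(rows) >= n) break
    }
  }
  if (length(rows) < n)
    stop("could not assemble ", n, " distinct molecules")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The six bundled seed fragments
#'
#' Pharmaceutically common substructures used as constrained-generation
#' seeds: indole, pyridine, benzimidazole, piperazine, the amide group, and
#' quinoline.  SMILES are stored verbatim; the SELFIES forms are derived
#' with [selfies_encode()] (and round-trip back to the same structures).
#'
#' @return data.frame with `name`, `smiles`, `selfies`.
#' @export
bundled_seeds <- function() {
  smiles <- c(
    Indole = "C1=CC=C2C(=C1)C=CN2",
    Pyridine = "C1=CC=NC=C1",
    Benzimidazole = "C1=CC=C2C(=C1)N=CN2",
    Piperazine = "C1CNCCN1",
    Amide = "CC(=O)N",
    Quinoline = "C1=CC=C2C=CC=NC2=C1")
  data.frame(name = names(smiles), smiles = unname(smiles),
             selfies = vapply(unname(smiles), selfies_encode, character(1)),
             stringsAsFactors = FALSE)
}

#' Read / write `.smi` files
#'
#' One molecule per line, optional whitespace-separated name, `#` comments.
#'
#' @param path File path.
#' @return `read_smi`: data.frame with `smiles` and `name`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  data.frame(smiles = vapply(parts, `[`, character(1), 1),
             name = vapply(parts, function(p)
               if (length(p) > 1) paste(p[-1], collapse = " ")
               else NA_character_, character(1)),
             stringsAsFactors = FALSE)
}

#' @rdname read_smi
#' @param smiles Character vector of molecular strings.
#' @param names Optional molecule names.
#' @export
write_smi <- function(smiles, path, names = NULL) {
  lines <- if (is.null(names)) smiles else paste(smiles, names)
  writeLines(lines, path)
  invisible(path)
}
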