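#' Tokenize a SMILES string
#'
#' Splits a SMILES string into atomic tokens: bracket atoms (`[nH]`,
#' `[C@@H]`, ...), two-letter organic-subset atoms (`Cl`, `Br`), single-letter
#' atoms, bond/branch/ring punctuation, and `%nn` two-digit ring closures.
#' Concatenating the returned tokens reproduces the input exactly.
#'
#' @param s A single non-empty SMILES string.
#' @return Character vector of tokens.
#' @examples
#' tokenize_smiles("CC(=O)Nc1ccccc1")
#' @export
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  if (!nzchar(s)) stop("empty SMILES string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced '[' in SMILES string: ", s)
      tokens <- c(tokens, paste0(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "]") {
      stop("unbalanced ']' in SMILES string: ", s)
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)])))
        stop("malformed '%nn' ring closure in SMILES string: ", s)
      tokens <- c(tokens, paste0(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

#' Tokenize a SELFIES string
#'
#' A SELFIES string is a concatenation of bracketed units; each token starts
#' with `[` and ends with `]`.
#'
#' @param s A single SELFIES string (concatenation of `[...]` units).
#' @return Character vector of tokens, each of the form `[...]`.
#' @examples
#' tokenize_selfies("[C][=C][C][=N][C][=C][Ring1][=Branch1]")
#' @export
tokenize_selfies <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  if (!nzchar(s)) stop("empty SELFIES string")
  toks <- regmatches(s, gregexpr("\\[[^][]*\\]", s))[[1]]
  if (paste0(toks, collapse = "") != s)
    stop("malformed SELFIES string (stray characters outside brackets): ", s)
  toks
}

#' Tokenize a molecular string under a scheme
#'
#' @param s String to tokenize.
#' @param scheme `"SMILES"` or `"SELFIES"`.
#' @return Character vector of tokens.
#' @export
tokenize_string <- function(s, scheme = c("SMILES", "SELFIES")) {
  scheme <- match.arg(scheme)
  if (scheme == "SMILES") tokenize_smiles(s) else tokenize_selfies(s)
}
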