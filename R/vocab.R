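#' Token vocabulary for molecular strings
#'
#' Builds an ordered token set from a corpus, adding the dummy start token
#' (`"G"` for SMILES, `"[G]"` for SELFIES) and the padding token (`"A"` /
#' `"[A]"`).  Token ids are 0-based and form a bijection onto
#' `0..length(tokens)-1`; ordering is deterministic for a given corpus
#' (start, pad, then sorted distinct corpus tokens).
#'
#' @param corpus A list of character vectors (token lists), or a character
#'   vector of raw strings which are tokenized with [tokenize_string()].
#' @param scheme `"SMILES"` or `"SELFIES"`.
#' @param extra_tokens Tokens to include beyond the corpus tokens (e.g. the
#'   tokens of seed fragments intended for constrained generation).
#' @return An object of class `"molgen_vocab"`: list with `scheme`, `tokens`,
#'   `start_token`, `pad_token`.
#' @examples
#' build_vocab(list(c("C"), c("O")), "SMILES")
#' @export
build_vocab <- function(corpus, scheme = c("SMILES", "SELFIES"),
                        extra_tokens = character(0)) {
  scheme <- match.arg(scheme)
  if (is.character(corpus)) corpus <- lapply(corpus, tokenize_string, scheme = scheme)
  stopifnot(is.list(corpus))
  if (length(corpus) == 0L) stop("empty corpus")
  start_token <- if (scheme == "SMILES") "G" else "[G]"
  pad_token <- if (scheme == "SMILES") "A" else "[A]"
  corpus_tokens <- sort(unique(c(unlist(corpus, use.names = FALSE), extra_tokens)),
                        method = "radix")
  if (length(corpus_tokens) == 0L) stop("corpus contains no tokens")
  if (any(c(start_token, pad_token) %in% corpus_tokens))
    stop("corpus contains the reserved start/pad token")
  vocab <- list(scheme = scheme,
                tokens = c(start_token, pad_token, corpus_tokens),
                start_token = start_token,
                pad_token = pad_token)
  class(vocab) <- "molgen_vocab"
  vocab
}

#' @export
print.molgen_vocab <- function(x, ...) {
  cat(sprintf("<molgen_vocab> %s, %d tokens (start %s, pad %s)\n",
              x$scheme, length(x$tokens), x$start_token, x$pad_token))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$tokens)

## 0-based id of each token; errors on unknown tokens
vocab_ids <- function(vocab, tokens) {
  idx <- match(tokens, vocab$tokens)
  if (anyNA(idx)) stop("unknown token(s): ",
                       paste(unique(tokens[is.na(idx)]), collapse = " "))
  idx - 1L
}

vocab_tokens <- function(vocab, ids) {
  stopifnot(all(ids >= 0L), all(ids < length(vocab$tokens)))
  vocab$tokens[ids + 1L]
}

vocab_start_id <- function(vocab) vocab_ids(vocab, vocab$start_token)
vocab_pad_id <- function(vocab) vocab_ids(vocab, vocab$pad_token)

#' Serialize / read a vocabulary as JSON
#'
#' @param vocab A `molgen_vocab`.
#' @param path File path.
#' @return `read_vocab` returns the vocabulary; `write_vocab` returns `path`
#'   invisibly.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "molgen_vocab"))
  jsonlite::write_json(unclass(vocab), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- list(scheme = x$scheme, tokens = as.character(x$tokens),
                start_token = x$start_token, pad_token = x$pad_token)
  class(vocab) <- "molgen_vocab"
  vocab
}

vocab_hash <- function(vocab) {
  ## cheap stable digest: sum of char codes weighted by position
  s <- paste(vocab$scheme, paste(vocab$tokens, collapse = "\u1f"), sep = "\u1e")
  codes <- utf8ToInt(s)
  sprintf("%08x", sum(codes * (seq_along(codes) %% 97 + 1)) %% 4294967291)
}
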