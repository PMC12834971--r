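#' Encode a token list into a fixed-length training window
#'
#' Inserts the dummy start token into the token list and pads the result to a
#' fixed total length.  Placement controls where the start token goes within
#' the core: `"fixed"` puts it at the middle of the core, `"random"` at a
#' uniformly drawn legal position, `"left"`/`"right"` at the first/last
#' position (used by the unidirectional variants, whose cores sit at the
#' window edge).  For `"fixed"`/`"random"` the pad tokens are split
#' symmetrically around the core; for `"left"`/`"right"` they form a suffix /
#' prefix respectively.
#'
#' @param tokens Character vector of core tokens (may be empty).
#' @param vocab A [build_vocab()] vocabulary.
#' @param m_total Total window length (must exceed `length(tokens)`).
#' @param placement One of `"fixed"`, `"random"`, `"left"`, `"right"`.
#' @return An object of class `"molgen_window"`: list with `token_ids`
#'   (0-based, length `m_total`), `start_offset` (0-based window position of
#'   the start token), `scheme`.
#' @examples
#' v <- build_vocab(list(c("C", "O")), "SMILES")
#' encode_window(c("C", "C"), v, 5)
#' @export
encode_window <- function(tokens, vocab, m_total,
                          placement = c("fixed", "random", "left", "right")) {
  placement <- match.arg(placement)
  stopifnot(inherits(vocab, "molgen_vocab"))
  m_total <- as.integer(m_total)
  n <- length(tokens)
  if (n + 1L > m_total)
    stop("core of ", n, " tokens plus start token exceeds window length ", m_total)
  g_pos <- switch(placement,   # 0-based insertion index within the core
    fixed = n %/% 2L,
    random = sample.int(n + 1L, 1L) - 1L,
    left = 0L,
    right = n)
  core <- append(tokens, vocab$start_token, after = g_pos)
  n_pad <- m_total - length(core)
  left_pad <- switch(placement,
    fixed = n_pad %/% 2L,
    random = n_pad %/% 2L,
    left = 0L,
    right = n_pad)
  window_tokens <- c(rep(vocab$pad_token, left_pad), core,
                     rep(vocab$pad_token, n_pad - left_pad))
  w <- list(token_ids = vocab_ids(vocab, window_tokens),
            start_offset = as.integer(left_pad + g_pos),
            scheme = vocab$scheme)
  class(w) <- "molgen_window"
  w
}

#' @export
print.molgen_window <- function(x, ...) {
  cat(sprintf("<molgen_window> %s, length %d, start at %d\n",
              x$scheme, length(x$token_ids), x$start_offset))
  invisible(x)
}

#' Strip start and pad tokens from a window
#'
#' The inverse of [encode_window()]: removes the dummy start token and all
#' padding tokens and concatenates the remaining tokens into the raw string.
#'
#' @param window A `molgen_window` (or a plain 0-based id vector).
#' @param vocab The vocabulary the window was encoded with.
#' @return Single string (may be empty).
#' @export
strip_special <- function(window, vocab) {
  ids <- if (inherits(window, "molgen_window")) window$token_ids else window
  keep <- !(ids %in% c(vocab_start_id(vocab), vocab_pad_id(vocab)))
  paste0(vocab_tokens(vocab, ids[keep]), collapse = "")
}

## core token ids (pads/start removed), used internally
window_core_ids <- function(ids, vocab) {
  ids[!(ids %in% c(vocab_start_id(vocab), vocab_pad_id(vocab)))]
}
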