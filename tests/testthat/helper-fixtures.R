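## Shared fixtures, built lazily once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

## small synthetic corpus (no chemistry backend needed)
toy_corpus <- function() memo("corpus", {
  make_toy_corpus(n = 150, seed = 7, canonicalize = FALSE)
})

## seed-fragment catalog token pool, so constrained generation is possible
seed_tokens <- function() memo("seed_tokens", {
  unique(unlist(lapply(bundled_seeds()$selfies, tokenize_selfies)))
})

## small trained models per variant (SELFIES)
toy_model <- function(variant, hidden = 24, epochs = 2, m_total = 24) {
  memo(paste0("model_", variant), {
    molgen(toy_corpus()$selfies, scheme = "SELFIES", variant = variant,
           hidden = hidden, epochs = epochs, m_total = m_total, seed = 42,
           extra_tokens = seed_tokens())
  })
}

## a model rigged to emit only pads: zero linear weights, big pad bias
stub_pad_model <- function(variant, vocab = NULL, m_total = 12) {
  if (is.null(vocab))
    vocab <- build_vocab(list(c("[C]", "[N]", "[O]")), "SELFIES",
                         extra_tokens = seed_tokens())
  m <- molgen_model(vocab, variant, hidden = 4, m_total = m_total, seed = 1)
  m$params$lin.W[] <- 0
  m$params$lin.b[] <- 0
  V <- length(vocab$tokens)
  pad_idx <- match(vocab$pad_token, vocab$tokens)
  slots <- if (variant == "fbrnn") c(pad_idx, V + pad_idx) else pad_idx
  m$params$lin.b[slots] <- 100
  m
}

## decode SELFIES defensively
safe_decode <- function(x) vapply(x, function(s)
  tryCatch(selfies_decode(s), error = function(e) ""), character(1),
  USE.NAMES = FALSE)
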