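## Evaluation battery: unique/valid/novel percentages (computed as a chain:
## valid among unique, novel among valid), nonparametric distribution tests,
## Morgan fingerprints, a 2-D embedding export, and QED/SA summaries.

#' Unique / valid / novel percentages of a generated set
#'
#' `% unique` is the share of distinct raw strings among all samples;
#' `% valid` the share of syntactically valid strings among the distinct
#' ones; `% novel` the share of valid strings whose canonical structure is
#' not in the training set.
#'
#' @param generated Character vector of generated strings.
#' @param training_set Character vector of training strings (same scheme).
#' @param scheme `"SMILES"` or `"SELFIES"`.
#' @return List with `pct_unique`, `pct_valid`, `pct_novel`, `n_sampled`,
#'   and the underlying counts `n_unique`, `n_valid`, `n_novel`.
#' @export
compute_uvn <- function(generated, training_set = character(0),
                        scheme = c("SMILES", "SELFIES")) {
  scheme <- match.arg(scheme)
  stopifnot(length(generated) >= 1)
  uniq <- unique(generated)
  valid_mask <- mol_is_valid(uniq, scheme)
  valid <- uniq[valid_mask]
  if (length(valid)) {
    canon <- canonical_smiles(valid, scheme)
    train_canon <- if (length(training_set))
      unique(stats::na.omit(canonical_smiles(training_set, scheme)))
    else character(0)
    novel <- valid[!is.na(canon) & !(canon %in% train_canon)]
  } else novel <- character(0)
  list(pct_unique = 100 * length(uniq) / length(generated),
       pct_valid = if (length(uniq)) 100 * length(valid) / length(uniq) else 0,
       pct_novel = if (length(valid)) 100 * length(novel) / length(valid) else 0,
       n_sampled = length(generated), n_unique = length(uniq),
       n_valid = length(valid), n_novel = length(novel))
}

#' Mann-Whitney and Kolmogorov-Smirnov two-sample tests
#'
#' Two-sided nonparametric p-values comparing a property distribution under
#' a constraint against the unconstrained (null) distribution.  Degenerate
#' identical constant samples give p = 1.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @return `mw_test`/`ks_test`: the p-value.  `distribution_test`: a one-row
#'   data.frame with medians, the direction flag, and both p-values.
#' @export
mw_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
}

#' @rdname mw_test
#' @export
ks_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(stats::ks.test(a, b)$p.value)
}

#' @rdname mw_test
#' @export
distribution_test <- function(a, b) {
  data.frame(median_constrained = stats::median(a),
             median_null = stats::median(b),
             constrained_higher = stats::median(a) > stats::median(b),
             mw_pvalue = mw_test(a, b),
             ks_pvalue = ks_test(a, b))
}

#' Morgan fingerprints
#'
#' 2048-bit circular (Morgan) fingerprints, radius 2, through the RDKit
#' backend.
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius Morgan radius.
#' @param nbits Fingerprint length.
#' @return 0/1 integer matrix, one row per molecule.
#' @export
morgan_fingerprints <- function(smiles, radius = 2, nbits = 2048) {
  stopifnot(length(smiles) >= 1)
  res <- chem_request(list(op = "morgan", smiles = as.list(smiles),
                           radius = radius, nbits = nbits))
  bits <- res$bits
  if (length(bits) != length(smiles))
    stop("invalid molecule(s) in fingerprint input")
  out <- matrix(0L, length(smiles), nbits)
  for (i in seq_along(smiles)) {
    if (is.null(bits[[i]]) || anyNA(bits[[i]]))
      stop("invalid molecule at position ", i, ": ", smiles[i])
    on <- unlist(bits[[i]])
    if (length(on)) out[i, on + 1L] <- 1L
  }
  out
}

#' 2-D embedding of fingerprints (t-SNE)
#'
#' Delegates to scikit-learn's t-SNE through the Python worker; fixed seed
#' gives reproducible coordinates.
#'
#' @param fps Fingerprint bit matrix ([morgan_fingerprints()]).
#' @param perplexity t-SNE perplexity; requires `nrow(fps) > 3 * perplexity`.
#' @param seed Embedding seed.
#' @param labels Optional labels attached to the output.
#' @return data.frame with `x`, `y` (and `label` when given).
#' @export
embed_2d <- function(fps, perplexity = 30, seed = 0L, labels = NULL) {
  stopifnot(is.matrix(fps))
  if (nrow(fps) <= 3 * perplexity)
    stop("need more than 3 * perplexity points for the embedding")
  bits <- lapply(seq_len(nrow(fps)), function(i) which(fps[i, ] != 0) - 1L)
  res <- chem_request(list(op = "tsne", bits = bits, nbits = ncol(fps),
                           perplexity = perplexity, seed = seed))
  xy <- do.call(rbind, lapply(res$xy, unlist))
  out <- data.frame(x = xy[, 1], y = xy[, 2])
  if (!is.null(labels)) out$label <- labels
  out
}

#' QED / SA summary statistics
#'
#' @param smiles Character vector of valid SMILES.
#' @return One-row data.frame with mean, standard deviation, and median of
#'   QED and raw SA.
#' @export
qed_sa_summary <- function(smiles) {
  props <- mol_properties(smiles)
  if (anyNA(props$qed)) stop("invalid molecule passed to qed_sa_summary")
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  data.frame(qed_mean = mean(props$qed), qed_std = sd0(props$qed),
             qed_median = stats::median(props$qed),
             sa_mean = mean(props$sa), sa_std = sd0(props$sa),
             sa_median = stats::median(props$sa))
}

#' Table of generation metrics for a model
#'
#' Samples `n` strings and reports the unique/valid/novel chain, matching
#' the headline metric table layout.
#'
#' @param model A trained [molgen()] model.
#' @param training_set Training strings for the novelty filter.
#' @param n Number of samples.
#' @param temperature Sampling temperature.
#' @param seed RNG seed.
#' @return One-row data.frame.
#' @export
generation_metrics <- function(model, training_set, n = 100, temperature = 1,
                               seed = NULL) {
  df <- generate(model, n, temperature = temperature, seed = seed)
  uvn <- compute_uvn(df$core, training_set, model$vocab$scheme)
  data.frame(scheme = model$vocab$scheme, variant = model$variant,
             placement = model$placement, hidden = model$hidden,
             pct_unique = uvn$pct_unique, pct_valid = uvn$pct_valid,
             pct_novel = uvn$pct_novel, n_sampled = n)
}
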