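## Teacher-forced maximum-likelihood pre-training with k-fold
## cross-validation.  Each variant is trained the way it generates: the
## forward model predicts next tokens left to right, the backward model the
## same on reversed windows, the FB-RNN both outward halves per step, and
## BIMODAL every insertion position alternately, combining both reading
## directions.  Padding positions are part of the emission schedule, which
## is how the models learn to terminate strings.

#' Deterministic k-fold cross-validation splits
#'
#' @param n_items Number of items.
#' @param k Number of folds (`>= 2`).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` lists with `fold_id`, `train_indices`,
#'   `held_out_indices`; the held-out sets partition `1:n_items`.
#' @export
make_cv_folds <- function(n_items, k, seed = 1L) {
  stopifnot(k >= 2)
  if (n_items < k) stop("need at least as many items as folds")
  set.seed(seed)
  perm <- sample.int(n_items)
  sizes <- rep(n_items %/% k, k)
  extra <- n_items %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    held <- sort(perm[starts[i]:ends[i]])
    list(fold_id = i, train_indices = setdiff(seq_len(n_items), held),
         held_out_indices = held)
  })
}

## windows (list of molgen_window) -> ids matrix (1-based) + start columns
window_matrix <- function(windows) {
  ids <- do.call(rbind, lapply(windows, function(w) w$token_ids)) + 1L
  g <- vapply(windows, function(w) w$start_offset, integer(1)) + 1L
  list(ids = ids, g = g)
}

encode_corpus <- function(token_lists, vocab, m_total, placement) {
  lapply(token_lists, encode_window, vocab = vocab, m_total = m_total,
         placement = placement)
}

#' Teacher-forced cross-entropy loss on encoded windows
#'
#' Mean cross-entropy, over the variant's emission schedule unrolled on the
#' given windows, between the predicted next-token distributions and the
#' true tokens (including pad emissions).
#'
#' @param model A [molgen_model()].
#' @param windows List of [encode_window()] windows (or a single window).
#' @param mode `"train"` uses batch statistics in the normalization layers
#'   (the quantity optimized during training); `"eval"` uses running
#'   statistics and is a deterministic function of the weights.
#' @return Scalar mean loss.
#' @export
teacher_forced_loss <- function(model, windows, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  if (inherits(windows, "molgen_window")) windows <- list(windows)
  wm <- window_matrix(windows)
  model_pass(model, wm$ids, wm$g, mode = mode, want_grads = FALSE)$loss
}

uni_placement <- function(variant, placement) {
  ## unidirectional variants put the start token (and core) at the window edge
  switch(variant, forward = "left", backward = "right", placement)
}

#' Fit a molecular-string generator
#'
#' Tokenizes the corpus, builds the vocabulary, encodes fixed-length
#' windows, and trains the chosen network variant by teacher forcing with
#' Adam.  Under `placement = "random"` the start-token position is
#' re-drawn for every string at every epoch.
#'
#' @param corpus Character vector of molecular strings (one molecule each).
#' @param scheme `"SMILES"` or `"SELFIES"`.
#' @param variant Network variant; see [molgen_model()].
#' @param hidden LSTM hidden size.
#' @param m_total Window length; default fits the longest corpus string with
#'   room for the start token and one pad on each side.
#' @param placement Start-token placement (`"fixed"` middle / `"random"`).
#' @param epochs Training epochs (full corpus passes).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed (weights, shuffling, random placement).
#' @param vocab Optional pre-built vocabulary (must cover the corpus).
#' @param extra_tokens Extra vocabulary tokens (see [build_vocab()]).
#' @param checkpoint_dir Optional directory; one checkpoint per epoch.
#' @param verbose Print per-epoch losses.
#' @return Object of class `"molgen_model"` with a `history` data.frame
#'   (`epoch`, `step`, `loss`) recorded during training.
#' @examples
#' \dontrun{
#' corpus <- make_toy_corpus(n = 100, seed = 1)$selfies
#' fit <- molgen(corpus, scheme = "SELFIES", variant = "fbrnn", epochs = 2)
#' }
#' @export
molgen <- function(corpus, scheme = c("SMILES", "SELFIES"),
                   variant = c("fbrnn", "forward", "backward", "bimodal"),
                   hidden = 64, m_total = NULL,
                   placement = c("fixed", "random"),
                   epochs = 10, batch_size = 32, learning_rate = 1e-3,
                   seed = 1L, vocab = NULL, extra_tokens = character(0),
                   checkpoint_dir = NULL, verbose = FALSE) {
  scheme <- match.arg(scheme); variant <- match.arg(variant)
  placement <- match.arg(placement)
  stopifnot(length(corpus) >= 1, epochs >= 1)
  token_lists <- lapply(corpus, tokenize_string, scheme = scheme)
  if (is.null(vocab)) vocab <- build_vocab(token_lists, scheme, extra_tokens)
  if (is.null(m_total)) m_total <- max(lengths(token_lists)) + 3L
  model <- molgen_model(vocab, variant, hidden = hidden, m_total = m_total,
                        placement = placement, seed = seed)
  model$scheme <- scheme
  model <- train_model(model, token_lists, epochs = epochs,
                       batch_size = batch_size, learning_rate = learning_rate,
                       seed = seed, checkpoint_dir = checkpoint_dir,
                       verbose = verbose)
  model$call <- match.call()
  model$corpus_size <- length(corpus)
  model
}

## core training loop on tokenized strings
train_model <- function(model, token_lists, epochs, batch_size, learning_rate,
                        seed, checkpoint_dir = NULL, fold_id = NA_integer_,
                        verbose = FALSE) {
  placement <- uni_placement(model$variant, model$placement)
  set.seed(seed + 1000L)
  opt <- optim_init(model$params)
  no_decay <- grep("\\.(b|beta|gamma)$", names(model$params), value = TRUE)
  history <- list()
  n <- length(token_lists)
  ## fixed placement: encode once; random: re-encode per epoch
  for (epoch in seq_len(epochs)) {
    windows <- encode_corpus(token_lists, model$vocab, model$m_total, placement)
    perm <- sample.int(n)
    step <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(n, start + batch_size - 1L)]
      wm <- window_matrix(windows[idx])
      out <- model_pass(model, wm$ids, wm$g, mode = "train", want_grads = TRUE)
      if (!is.finite(out$loss))
        stop("non-finite training loss at epoch ", epoch, ", step ", step + 1L)
      up <- optim_step(model$params, out$grads, opt, lr = learning_rate,
                       no_decay = no_decay)
      model$params <- up$params; opt <- up$state
      model$buffers <- out$buffers
      step <- step + 1L
      history[[length(history) + 1L]] <-
        data.frame(fold = fold_id, epoch = epoch, step = step, loss = out$loss)
    }
    if (verbose) {
      ep <- do.call(rbind, history)
      cat(sprintf("epoch %d: mean loss %.4f\n", epoch,
                  mean(ep$loss[ep$epoch == epoch])))
    }
    if (!is.null(checkpoint_dir))
      write_checkpoint(model, file.path(checkpoint_dir,
        sprintf("fold%s_epoch%02d.rds",
                ifelse(is.na(fold_id), "0", fold_id), epoch)),
        meta = list(fold = fold_id, epoch = epoch))
  }
  model$history <- do.call(rbind, history)
  model
}

#' Cross-validated training
#'
#' Runs the k-fold scheme: each fold's model is trained on the complement of
#' its held-out set, with one checkpoint per (fold, epoch) when
#' `checkpoint_dir` is given, and held-out loss recorded per fold.
#'
#' @inheritParams molgen
#' @param folds Number of folds (`>= 2`).
#' @return List of class `"molgen_cv"`: `models` (one per fold), `folds`
#'   (the index splits), `log` (data.frame `fold`, `epoch`, `step`, `loss`),
#'   `held_out_loss` (per fold, eval mode).
#' @export
molgen_cv <- function(corpus, scheme = c("SMILES", "SELFIES"),
                      variant = c("fbrnn", "forward", "backward", "bimodal"),
                      folds = 5, hidden = 64, m_total = NULL,
                      placement = c("fixed", "random"),
                      epochs = 10, batch_size = 32, learning_rate = 1e-3,
                      seed = 1L, extra_tokens = character(0),
                      checkpoint_dir = NULL, verbose = FALSE) {
  scheme <- match.arg(scheme); variant <- match.arg(variant)
  placement <- match.arg(placement)
  token_lists <- lapply(corpus, tokenize_string, scheme = scheme)
  vocab <- build_vocab(token_lists, scheme, extra_tokens)
  if (is.null(m_total)) m_total <- max(lengths(token_lists)) + 3L
  splits <- make_cv_folds(length(corpus), folds, seed = seed)
  models <- vector("list", folds)
  logs <- list()
  held <- numeric(folds)
  for (f in seq_len(folds)) {
    m <- molgen_model(vocab, variant, hidden = hidden, m_total = m_total,
                      placement = placement, seed = seed + f)
    m$scheme <- scheme
    m <- train_model(m, token_lists[splits[[f]]$train_indices],
                     epochs = epochs, batch_size = batch_size,
                     learning_rate = learning_rate, seed = seed + f,
                     checkpoint_dir = checkpoint_dir, fold_id = f,
                     verbose = verbose)
    hw <- encode_corpus(token_lists[splits[[f]]$held_out_indices], vocab,
                        m_total, uni_placement(variant, placement))
    held[f] <- teacher_forced_loss(m, hw, mode = "eval")
    models[[f]] <- m
    logs[[f]] <- m$history
  }
  structure(list(models = models, folds = splits,
                 log = do.call(rbind, logs), held_out_loss = held,
                 scheme = scheme, variant = variant),
            class = "molgen_cv")
}

#' @export
print.molgen_cv <- function(x, ...) {
  cat(sprintf("<molgen_cv> %s %s, %d folds; held-out loss %s\n",
              x$scheme, x$variant, length(x$models),
              paste(sprintf("%.3f", x$held_out_loss), collapse = " ")))
  invisible(x)
}

#' Write / read a model checkpoint
#'
#' A checkpoint stores the configuration, vocabulary (and its hash), all
#' parameter tensors and normalization buffers, plus optional training
#' metadata, under a version field.
#'
#' @param model A `molgen_model`.
#' @param path File path.
#' @param meta Optional metadata list (e.g. fold and epoch).
#' @return `read_checkpoint` returns the model; `write_checkpoint` the path,
#'   invisibly.
#' @export
write_checkpoint <- function(model, path, meta = NULL) {
  obj <- list(format = "molgen_checkpoint", version = 1L,
              model = model, meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "molgen_checkpoint"))
    stop("not a molgen checkpoint: ", path)
  if (obj$version > 1L) stop("checkpoint version ", obj$version, " too new")
  model <- obj$model
  stopifnot(inherits(model, "molgen_model"))
  model
}
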