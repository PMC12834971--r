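#' @export
print.molgen_model <- function(x, ...) {
  cat(sprintf("<molgen_model> %s %s\n", x$vocab$scheme, x$variant))
  cat(sprintf("  hidden %d, window %d, placement %s, vocab %d tokens\n",
              x$hidden, x$m_total, x$placement, vocab_size(x$vocab)))
  if (!is.null(x$history))
    cat(sprintf("  trained: %d epochs, final loss %.4f\n",
                max(x$history$epoch), tail(x$history$loss, 1)))
  if (!is.null(x$episodes))
    cat(sprintf("  fine-tuned: %d episodes, final mean reward %.4f\n",
                nrow(x$episodes), tail(x$episodes$mean_reward, 1)))
  invisible(x)
}

#' @export
summary.molgen_model <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, numeric(1)))
  out <- list(variant = object$variant, scheme = object$vocab$scheme,
              hidden = object$hidden, m_total = object$m_total,
              placement = object$placement, n_parameters = n_par,
              vocab = object$vocab$tokens, history = object$history,
              episodes = object$episodes)
  class(out) <- "summary.molgen_model"
  out
}

#' @export
print.summary.molgen_model <- function(x, ...) {
  cat(sprintf("Molecular string generator (%s, %s reading scheme)\n",
              x$scheme, x$variant))
  cat(sprintf("  %d parameters (hidden %d), window %d, placement %s\n",
              x$n_parameters, x$hidden, x$m_total, x$placement))
  cat(sprintf("  vocabulary (%d): %s\n", length(x$vocab),
              paste(utils::head(x$vocab, 12), collapse = " ")))
  if (!is.null(x$history)) {
    byep <- tapply(x$history$loss, x$history$epoch, mean)
    cat("  mean training loss by epoch:\n")
    print(round(byep, 4))
  }
  if (!is.null(x$episodes)) {
    cat(sprintf("  RL episodes: %d, reward %.4f -> %.4f\n", nrow(x$episodes),
                x$episodes$mean_reward[1], tail(x$episodes$mean_reward, 1)))
  }
  invisible(x)
}

#' @export
coef.molgen_model <- function(object, ...) object$params

#' Next-token distribution of a trained generator
#'
#' @param object A `molgen_model`.
#' @param context Current string (its tokens must be in the vocabulary); the
#'   empty string conditions on the start token only.
#' @param side For the bidirectional variants: which end the next token
#'   would be appended to.
#' @param temperature Sampling temperature applied to the softmax.
#' @param ... Unused.
#' @return Named probability vector over the vocabulary.
#' @export
predict.molgen_model <- function(object, context = "", side = c("right", "left"),
                                 temperature = 1, ...) {
  side <- match.arg(side)
  vocab <- object$vocab
  toks <- if (nzchar(context)) tokenize_string(context, vocab$scheme) else character(0)
  ids0 <- vocab_ids(vocab, toks)              # 0-based
  M <- object$m_total
  if (length(ids0) + 1L > M) stop("context longer than the model window")
  if (object$variant %in% c("forward", "backward")) {
    pref <- c(vocab_start_id(vocab), if (object$variant == "backward") rev(ids0) else ids0)
    y <- unidirectional_logits(object, pref)
  } else {
    ## build a centered window around the context (start token if empty)
    pad <- vocab_pad_id(vocab)
    core <- if (length(ids0)) ids0 else vocab_start_id(vocab)
    n <- length(core)
    g0 <- (M - n) %/% 2L + 1L                 # 1-based column of core start
    win <- rep(pad, M)
    win[g0:(g0 + n - 1L)] <- core
    if (object$variant == "fbrnn") {
      mid <- g0 + (n - 1L) %/% 2L
      halves <- fbrnn_logits(object, win, mid - 1L)
      y <- if (side == "right") halves$y_plus else halves$y_minus
    } else {
      pos <- if (side == "right") g0 + n else g0 - 1L
      pos <- min(max(pos, 1L), M)
      y <- bimodal_logits(object, win, pos - 1L)
    }
  }
  p <- temperature_softmax(y, temperature)
  names(p) <- vocab$tokens
  p
}

#' Simulate molecules from a fitted generator
#'
#' Thin wrapper around [generate()] following the `simulate()` convention.
#'
#' @param object A trained `molgen_model`.
#' @param nsim Number of samples.
#' @param seed RNG seed.
#' @param ... Passed to [generate()] (e.g. `seed_fragment`, `temperature`).
#' @return A [generate()] data.frame.
#' @export
simulate.molgen_model <- function(object, nsim = 1, seed = NULL, ...) {
  generate(object, nsim, seed = seed, ...)
}

#' Per-token log-likelihood of strings under the model
#'
#' Mean teacher-forced log-likelihood (eval-mode normalization) of the
#' strings' windows under the model's emission schedule.
#'
#' @param object A trained `molgen_model`.
#' @param strings Character vector of strings in the model's scheme.
#' @param ... Unused.
#' @return `logLik` object (total over emitted tokens).
#' @export
logLik.molgen_model <- function(object, strings, ...) {
  toks <- lapply(strings, tokenize_string, scheme = object$vocab$scheme)
  wins <- encode_corpus(toks, object$vocab, object$m_total,
                        uni_placement(object$variant, object$placement))
  wm <- window_matrix(wins)
  out <- model_pass(object, wm$ids, wm$g, mode = "eval", want_grads = FALSE)
  ll <- -out$loss * out$n_emit
  structure(ll, df = sum(vapply(object$params, length, numeric(1))),
            nobs = out$n_emit, class = "logLik")
}

#' Plot training / fine-tuning traces
#'
#' @param x A `molgen_model`.
#' @param which `"loss"` (teacher-forced training trace) or `"reward"`
#'   (RL episode trace).
#' @param ... Passed to [plot()].
#' @export
plot.molgen_model <- function(x, which = c("loss", "reward"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    if (is.null(x$history)) stop("model has no training history")
    plot(seq_len(nrow(x$history)), x$history$loss, type = "l",
         xlab = "step", ylab = "teacher-forced loss", ...)
  } else {
    if (is.null(x$episodes)) stop("model has no fine-tuning trace")
    plot(x$episodes$episode, x$episodes$mean_reward, type = "l",
         xlab = "episode", ylab = "mean batch reward", ...)
    graphics::lines(x$episodes$episode,
                    x$episodes$mean_reward + x$episodes$reward_std, lty = 3)
    graphics::lines(x$episodes$episode,
                    x$episodes$mean_reward - x$episodes$reward_std, lty = 3)
  }
  invisible(x)
}
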