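## Model container and the per-variant network passes.
##
## Three reading schemes share the LSTM machinery:
##  * forward / backward: 5 layers (BN1, LSTM1, LSTM2, BN2, Linear); the
##    backward variant is the forward machinery on reversed windows.
##  * fbrnn: same 5 layers with doubled BN1 input (concatenated one-hot pair
##    read outward from the start position) and doubled Linear output whose
##    halves are the next-right (y_plus) and next-left (y_minus) logits.
##  * bimodal: 7 layers (BN1, F-LSTM1, B-LSTM1, F-LSTM2, B-LSTM2, BN2,
##    Linear); the window is read in both directions and the logits for an
##    insertion position p combine the forward hidden state at p-1 with the
##    backward hidden state at p+1 through one linear map.

MOLGEN_VARIANTS <- c("forward", "backward", "fbrnn", "bimodal")

#' Construct an untrained generator model
#'
#' @param vocab A [build_vocab()] vocabulary.
#' @param variant One of `"forward"`, `"backward"`, `"fbrnn"`, `"bimodal"`.
#' @param hidden Hidden size of each LSTM layer.
#' @param m_total Window length the model is trained on.
#' @param placement Start-token placement used for training windows
#'   (`"fixed"`/`"random"` for the bidirectional variants; the
#'   unidirectional variants always use their natural edge placement).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `"molgen_model"`.
#' @export
molgen_model <- function(vocab, variant = c("fbrnn", "forward", "backward", "bimodal"),
                         hidden = 64, m_total = 20,
                         placement = c("fixed", "random"), seed = 1L) {
  variant <- match.arg(variant)
  placement <- match.arg(placement)
  stopifnot(inherits(vocab, "molgen_vocab"), hidden >= 1, m_total >= 3)
  V <- vocab_size(vocab)
  H <- as.integer(hidden)
  set.seed(seed)
  uinit <- function(nr, nc) {
    s <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  binit <- function(n, fan) stats::runif(n, -1 / sqrt(fan), 1 / sqrt(fan))
  lstm_par <- function(prefix, din) {
    p <- list(uinit(din, 4 * H), uinit(H, 4 * H), binit(4 * H, H))
    names(p) <- paste0(prefix, c(".W", ".U", ".b"))
    p
  }
  bn_par <- function(prefix, d) {
    p <- list(rep(1, d), rep(0, d))
    names(p) <- paste0(prefix, c(".gamma", ".beta"))
    p
  }
  din1 <- if (variant == "fbrnn") 2L * V else V
  dout <- if (variant == "fbrnn") 2L * V else V
  dbn2 <- if (variant == "bimodal") 2L * H else H
  params <- c(bn_par("bn1", din1))
  if (variant == "bimodal") {
    params <- c(params, lstm_par("f1", V), lstm_par("f2", H),
                lstm_par("b1", V), lstm_par("b2", H))
    dlin <- 2L * H
  } else {
    params <- c(params, lstm_par("l1", din1), lstm_par("l2", H))
    dlin <- H
  }
  params <- c(params, bn_par("bn2", dbn2),
              list("lin.W" = uinit(dlin, dout), "lin.b" = binit(dout, dlin)))
  buffers <- list(bn1.rm = rep(0, din1), bn1.rv = rep(1, din1),
                  bn2.rm = rep(0, dbn2), bn2.rv = rep(1, dbn2))
  m <- list(variant = variant, vocab = vocab, hidden = H, m_total = as.integer(m_total),
            placement = placement, params = params, buffers = buffers,
            vocab_hash = vocab_hash(vocab), seed = as.integer(seed),
            history = NULL, episodes = NULL)
  class(m) <- "molgen_model"
  m
}

model_vsize <- function(model) vocab_size(model$vocab)

## start-token column (1-based) used by generation / schedules
model_pad_col <- function(model) vocab_pad_id(model$vocab) + 1L
model_start_col <- function(model) vocab_start_id(model$vocab) + 1L

## --- emission schedules ----------------------------------------------------
## cg: 1-based column of the generation origin (start token / seed span).

schedule_bimodal <- function(cg_left, cg_right, M) {
  ## alternating insertion positions around an occupied span [cg_left, cg_right]
  right <- if (cg_right < M) seq(cg_right + 1L, M) else integer(0)
  left <- if (cg_left > 1L) seq(cg_left - 1L, 1L) else integer(0)
  out <- integer(0); side <- character(0)
  i <- 1L
  while (i <= max(length(right), length(left))) {
    if (i <= length(right)) { out <- c(out, right[i]); side <- c(side, "fwd") }
    if (i <= length(left)) { out <- c(out, left[i]); side <- c(side, "bwd") }
    i <- i + 1L
  }
  list(pos = out, side = side)
}

schedule_fbrnn <- function(cg_left, cg_right, M) {
  ## step s reads (col cg_left-s+1, col cg_right+s-1) and predicts
  ## (col cg_left-s, col cg_right+s)
  S <- max(cg_left - 1L, M - cg_right)
  if (S < 1L) return(list(S = 0L))
  list(S = S,
       in_left = cg_left - seq_len(S) + 1L,    # may drop below 1 -> pad input
       in_right = cg_right + seq_len(S) - 1L,  # may exceed M -> pad input
       out_left = cg_left - seq_len(S),        # target col, NA-like when < 1
       out_right = cg_right + seq_len(S))      # target col, invalid when > M
}

## --- teacher-forced pass (training mode) -----------------------------------
## ids: B x M matrix of 1-based token columns; g: 1-based start-token column
## (same for all rows; callers group rows by g).
## Returns loss and, if dlogit_fn is NULL, cross-entropy gradients; a custom
## dlogit_fn(list of emissions) may supply per-emission logit gradients (RL).

stack_rows <- function(lst) do.call(rbind, lst)
unstack_rows <- function(m, B, Tn) lapply(seq_len(Tn), function(t)
  m[(t - 1L) * B + seq_len(B), , drop = FALSE])

model_pass <- function(model, ids, g, mode = c("train", "eval"),
                       want_grads = TRUE, dlogits_fn = NULL,
                       loss_weights = NULL) {
  mode <- match.arg(mode)
  variant <- model$variant
  if (variant %in% c("forward", "backward")) {
    pass_uni(model, ids, mode, want_grads, dlogits_fn, loss_weights)
  } else if (variant == "fbrnn") {
    pass_fbrnn(model, ids, g, mode, want_grads, dlogits_fn, loss_weights)
  } else {
    pass_bimodal(model, ids, g, mode, want_grads, dlogits_fn, loss_weights)
  }
}

ce_dlogits <- function(logits_stacked, target_idx, n_emit, weights = NULL) {
  ## mean cross-entropy over emissions; returns loss and d loss / d logits
  p <- temperature_softmax(logits_stacked, 1)
  rows <- seq_along(target_idx)
  eps_p <- pmax(p[cbind(rows, target_idx)], 1e-12)
  w <- if (is.null(weights)) rep(1, length(target_idx)) else weights
  loss <- sum(w * -log(eps_p)) / sum(w)
  dl <- p
  dl[cbind(rows, target_idx)] <- dl[cbind(rows, target_idx)] - 1
  dl <- dl * (w / sum(w))
  list(loss = loss, dlogits = dl)
}

pass_uni <- function(model, ids, mode, want_grads, dlogits_fn, loss_weights) {
  p <- model$params; bf <- model$buffers
  B <- nrow(ids); M <- ncol(ids); V <- model_vsize(model)
  if (model$variant == "backward") ids <- ids[, rev(seq_len(M)), drop = FALSE]
  Tn <- M - 1L
  x_stacked <- one_hot(as.vector(ids[, seq_len(Tn)]), V)  # (B*Tn) x V, col-major t
  bn1 <- bn_forward(x_stacked, p$bn1.gamma, p$bn1.beta, bf$bn1.rm, bf$bn1.rv, mode)
  X <- unstack_rows(bn1$y, B, Tn)
  l1 <- lstm_seq_forward(X, p$l1.W, p$l1.U, p$l1.b)
  l2 <- lstm_seq_forward(l1$h, p$l2.W, p$l2.U, p$l2.b)
  h_stacked <- stack_rows(l2$h)
  bn2 <- bn_forward(h_stacked, p$bn2.gamma, p$bn2.beta, bf$bn2.rm, bf$bn2.rv, mode)
  logits <- bn2$y %*% p$lin.W + matrix(p$lin.b, nrow(bn2$y), ncol(p$lin.W), byrow = TRUE)
  targets <- as.vector(ids[, seq_len(Tn) + 1L])
  out <- list(logits = logits, targets = targets, n_emit = B * Tn,
              emit_meta = data.frame(row = rep(seq_len(B), Tn),
                                     t = rep(seq_len(Tn), each = B)))
  if (is.null(dlogits_fn)) {
    ce <- ce_dlogits(logits, targets, B * Tn, loss_weights)
    out$loss <- ce$loss
    dlogits <- ce$dlogits
  } else {
    dlogits <- dlogits_fn(out)
  }
  if (!want_grads) return(out)
  g <- list()
  g[["lin.W"]] <- crossprod(bn2$y, dlogits)
  g[["lin.b"]] <- colSums(dlogits)
  dbn2 <- bn_backward(dlogits %*% t(p$lin.W), bn2$cache)
  g[["bn2.gamma"]] <- dbn2$dgamma; g[["bn2.beta"]] <- dbn2$dbeta
  dH2 <- unstack_rows(dbn2$dx, B, Tn)
  bk2 <- lstm_seq_backward(dH2, l2$cache, p$l2.W, p$l2.U, p$l2.b)
  g[["l2.W"]] <- bk2$dW; g[["l2.U"]] <- bk2$dU; g[["l2.b"]] <- bk2$db
  bk1 <- lstm_seq_backward(bk2$dX, l1$cache, p$l1.W, p$l1.U, p$l1.b)
  g[["l1.W"]] <- bk1$dW; g[["l1.U"]] <- bk1$dU; g[["l1.b"]] <- bk1$db
  dbn1 <- bn_backward(stack_rows(bk1$dX), bn1$cache)
  g[["bn1.gamma"]] <- dbn1$dgamma; g[["bn1.beta"]] <- dbn1$dbeta
  out$grads <- g
  if (mode == "train")
    out$buffers <- list(bn1.rm = bn1$running_mean, bn1.rv = bn1$running_var,
                        bn2.rm = bn2$running_mean, bn2.rv = bn2$running_var)
  out
}

pass_fbrnn <- function(model, ids, g, mode, want_grads, dlogits_fn, loss_weights) {
  p <- model$params; bf <- model$buffers
  B <- nrow(ids); M <- ncol(ids); V <- model_vsize(model)
  pad <- model_pad_col(model)
  g <- rep_len(as.integer(g), B)          # per-row start-token column
  S <- max(pmax(g - 1L, M - g))
  stopifnot(S >= 1L)
  gather <- function(colm) {              # colm: B x S of 1-based columns
    bad <- colm < 1L | colm > M
    colm[bad] <- 1L
    out <- matrix(ids[cbind(rep(seq_len(B), S), as.vector(colm))], B, S)
    out[bad] <- pad
    out
  }
  svec <- matrix(rep(seq_len(S), each = B), B, S)
  gmat <- matrix(g, B, S)
  in_r <- gather(gmat + svec - 1L)        # token read on the right at step s
  in_l <- gather(gmat - svec + 1L)        # token read on the left
  x_stacked <- cbind(one_hot(as.vector(in_r), V), one_hot(as.vector(in_l), V))
  bn1 <- bn_forward(x_stacked, p$bn1.gamma, p$bn1.beta, bf$bn1.rm, bf$bn1.rv, mode)
  X <- unstack_rows(bn1$y, B, S)
  l1 <- lstm_seq_forward(X, p$l1.W, p$l1.U, p$l1.b)
  l2 <- lstm_seq_forward(l1$h, p$l2.W, p$l2.U, p$l2.b)
  h_stacked <- stack_rows(l2$h)
  bn2 <- bn_forward(h_stacked, p$bn2.gamma, p$bn2.beta, bf$bn2.rm, bf$bn2.rv, mode)
  lin <- bn2$y %*% p$lin.W + matrix(p$lin.b, nrow(bn2$y), 2L * V, byrow = TRUE)
  ## emissions: per (row, step), y_plus targets col g+s, y_minus targets g-s
  out_r <- gmat + svec
  out_l <- gmat - svec
  valid_r <- out_r <= M                   # B x S, col-major == stacked order
  valid_l <- out_l >= 1L
  rows_r <- which(as.vector(valid_r))
  rows_l <- which(as.vector(valid_l))
  logits <- rbind(lin[rows_r, seq_len(V), drop = FALSE],
                  lin[rows_l, V + seq_len(V), drop = FALSE])
  tgt_r <- ids[cbind(rep(seq_len(B), S)[rows_r], as.vector(out_r)[rows_r])]
  tgt_l <- ids[cbind(rep(seq_len(B), S)[rows_l], as.vector(out_l)[rows_l])]
  targets <- c(tgt_r, tgt_l)
  out <- list(logits = logits, targets = targets, n_emit = length(targets),
              emit_meta = data.frame(
                row = c(rep(seq_len(B), S)[rows_r], rep(seq_len(B), S)[rows_l]),
                t = c(rep(seq_len(S), each = B)[rows_r],
                      rep(seq_len(S), each = B)[rows_l]),
                side = rep(c("plus", "minus"), c(length(tgt_r), length(tgt_l)))))
  if (is.null(dlogits_fn)) {
    ce <- ce_dlogits(logits, targets, length(targets), loss_weights)
    out$loss <- ce$loss
    dlogits <- ce$dlogits
  } else {
    dlogits <- dlogits_fn(out)
  }
  if (!want_grads) return(out)
  dlin <- matrix(0, nrow(lin), 2L * V)
  nr <- length(rows_r)
  if (nr) dlin[rows_r, seq_len(V)] <- dlogits[seq_len(nr), , drop = FALSE]
  if (length(rows_l))
    dlin[rows_l, V + seq_len(V)] <- dlogits[nr + seq_along(rows_l), , drop = FALSE]
  gr <- list()
  gr[["lin.W"]] <- crossprod(bn2$y, dlin)
  gr[["lin.b"]] <- colSums(dlin)
  dbn2 <- bn_backward(dlin %*% t(p$lin.W), bn2$cache)
  gr[["bn2.gamma"]] <- dbn2$dgamma; gr[["bn2.beta"]] <- dbn2$dbeta
  dH2 <- unstack_rows(dbn2$dx, B, S)
  bk2 <- lstm_seq_backward(dH2, l2$cache, p$l2.W, p$l2.U, p$l2.b)
  gr[["l2.W"]] <- bk2$dW; gr[["l2.U"]] <- bk2$dU; gr[["l2.b"]] <- bk2$db
  bk1 <- lstm_seq_backward(bk2$dX, l1$cache, p$l1.W, p$l1.U, p$l1.b)
  gr[["l1.W"]] <- bk1$dW; gr[["l1.U"]] <- bk1$dU; gr[["l1.b"]] <- bk1$db
  dbn1 <- bn_backward(stack_rows(bk1$dX), bn1$cache)
  gr[["bn1.gamma"]] <- dbn1$dgamma; gr[["bn1.beta"]] <- dbn1$dbeta
  out$grads <- gr
  if (mode == "train")
    out$buffers <- list(bn1.rm = bn1$running_mean, bn1.rv = bn1$running_var,
                        bn2.rm = bn2$running_mean, bn2.rv = bn2$running_var)
  out
}

pass_bimodal <- function(model, ids, g, mode, want_grads, dlogits_fn, loss_weights) {
  p <- model$params; bf <- model$buffers
  B <- nrow(ids); M <- ncol(ids); V <- model_vsize(model)
  H <- model$hidden
  g <- rep_len(as.integer(g), B)
  ## per-row alternating emission schedule: every non-start column exactly once
  E <- M - 1L
  P <- matrix(0L, B, E)                   # emission position per (row, e)
  SIDE <- matrix("", B, E)
  for (b in seq_len(B)) {
    sch <- schedule_bimodal(g[b], g[b], M)
    P[b, ] <- sch$pos
    SIDE[b, ] <- sch$side
  }
  x_stacked <- one_hot(as.vector(ids), V)         # (B*M) x V
  bn1 <- bn_forward(x_stacked, p$bn1.gamma, p$bn1.beta, bf$bn1.rm, bf$bn1.rv, mode)
  X <- unstack_rows(bn1$y, B, M)
  f1 <- lstm_seq_forward(X, p$f1.W, p$f1.U, p$f1.b)
  f2 <- lstm_seq_forward(f1$h, p$f2.W, p$f2.U, p$f2.b)
  Xr <- rev(X)
  b1 <- lstm_seq_forward(Xr, p$b1.W, p$b1.U, p$b1.b)
  b2 <- lstm_seq_forward(b1$h, p$b2.W, p$b2.U, p$b2.b)
  ## gather per-row hidden states: forward at P-1, backward at P+1
  hf_rows <- function(tcols) {            # tcols: vector over rows, 0 => zeros
    out <- matrix(0, B, H)
    for (b in seq_len(B)) if (tcols[b] >= 1L) out[b, ] <- f2$h[[tcols[b]]][b, ]
    out
  }
  hb_rows <- function(tcols) {            # col M+1 => zeros
    out <- matrix(0, B, H)
    for (b in seq_len(B)) if (tcols[b] <= M) out[b, ] <- b2$h[[M - tcols[b] + 1L]][b, ]
    out
  }
  z <- vector("list", E)
  for (e in seq_len(E))
    z[[e]] <- cbind(hf_rows(P[, e] - 1L), hb_rows(P[, e] + 1L))
  z_stacked <- stack_rows(z)
  bn2 <- bn_forward(z_stacked, p$bn2.gamma, p$bn2.beta, bf$bn2.rm, bf$bn2.rv, mode)
  logits <- bn2$y %*% p$lin.W + matrix(p$lin.b, nrow(bn2$y), V, byrow = TRUE)
  targets <- ids[cbind(rep(seq_len(B), E), as.vector(P))]
  out <- list(logits = logits, targets = targets, n_emit = B * E,
              emit_meta = data.frame(row = rep(seq_len(B), E),
                                     t = rep(seq_len(E), each = B),
                                     pos = as.vector(P),
                                     side = as.vector(SIDE)))
  if (is.null(dlogits_fn)) {
    ce <- ce_dlogits(logits, targets, B * E, loss_weights)
    out$loss <- ce$loss
    dlogits <- ce$dlogits
  } else {
    dlogits <- dlogits_fn(out)
  }
  if (!want_grads) return(out)
  gr <- list()
  gr[["lin.W"]] <- crossprod(bn2$y, dlogits)
  gr[["lin.b"]] <- colSums(dlogits)
  dbn2 <- bn_backward(dlogits %*% t(p$lin.W), bn2$cache)
  gr[["bn2.gamma"]] <- dbn2$dgamma; gr[["bn2.beta"]] <- dbn2$dbeta
  dz <- unstack_rows(dbn2$dx, B, E)
  zero <- matrix(0, B, H)
  dHf <- rep(list(zero), M)
  dHb <- rep(list(zero), M)   # indexed by backward-pass step (1 = col M)
  for (e in seq_len(E)) {
    dzf <- dz[[e]][, seq_len(H), drop = FALSE]
    dzb <- dz[[e]][, H + seq_len(H), drop = FALSE]
    for (b in seq_len(B)) {
      pp <- P[b, e]
      if (pp - 1L >= 1L) dHf[[pp - 1L]][b, ] <- dHf[[pp - 1L]][b, ] + dzf[b, ]
      if (pp + 1L <= M) {
        tb <- M - (pp + 1L) + 1L
        dHb[[tb]][b, ] <- dHb[[tb]][b, ] + dzb[b, ]
      }
    }
  }
  bkf2 <- lstm_seq_backward(dHf, f2$cache, p$f2.W, p$f2.U, p$f2.b)
  gr[["f2.W"]] <- bkf2$dW; gr[["f2.U"]] <- bkf2$dU; gr[["f2.b"]] <- bkf2$db
  bkf1 <- lstm_seq_backward(bkf2$dX, f1$cache, p$f1.W, p$f1.U, p$f1.b)
  gr[["f1.W"]] <- bkf1$dW; gr[["f1.U"]] <- bkf1$dU; gr[["f1.b"]] <- bkf1$db
  bkb2 <- lstm_seq_backward(dHb, b2$cache, p$b2.W, p$b2.U, p$b2.b)
  gr[["b2.W"]] <- bkb2$dW; gr[["b2.U"]] <- bkb2$dU; gr[["b2.b"]] <- bkb2$db
  bkb1 <- lstm_seq_backward(bkb2$dX, b1$cache, p$b1.W, p$b1.U, p$b1.b)
  gr[["b1.W"]] <- bkb1$dW; gr[["b1.U"]] <- bkb1$dU; gr[["b1.b"]] <- bkb1$db
  dX_total <- mapply(function(a, b) a + b, bkf1$dX, rev(bkb1$dX), SIMPLIFY = FALSE)
  dbn1 <- bn_backward(stack_rows(dX_total), bn1$cache)
  gr[["bn1.gamma"]] <- dbn1$dgamma; gr[["bn1.beta"]] <- dbn1$dbeta
  out$grads <- gr
  if (mode == "train")
    out$buffers <- list(bn1.rm = bn1$running_mean, bn1.rv = bn1$running_var,
                        bn2.rm = bn2$running_mean, bn2.rv = bn2$running_var)
  out
}

## --- exposed logit operations ---------------------------------------------

#' Next-token logits of a unidirectional model
#'
#' Runs the 5-layer stack (eval-mode batch normalization) over a window
#' prefix and returns the logits for the next token.  For the `backward`
#' variant the prefix is the reversed string and the logits predict the
#' previous token of the original orientation.
#'
#' @param model A `forward` or `backward` [molgen_model()].
#' @param prefix_ids Integer vector of 0-based token ids (non-empty; begins
#'   with the start token in ordinary use).
#' @return Numeric logit vector of length `vocab_size`.
#' @export
unidirectional_logits <- function(model, prefix_ids) {
  stopifnot(model$variant %in% c("forward", "backward"), length(prefix_ids) >= 1)
  st <- gen_stack_init(model, 1L)
  for (id in prefix_ids) st <- gen_stack_step(model, st, matrix(id + 1L, 1, 1))
  drop(st$logits)
}

#' Paired next/previous-token logits of an FB-RNN model
#'
#' Reads the window outward from the start-token position and returns the
#' halves of the doubled linear output: `y_plus` (next token to the right)
#' and `y_minus` (next token to the left).
#'
#' @param model An `fbrnn` [molgen_model()].
#' @param window_ids 0-based token ids of the full window.
#' @param start_offset 0-based position of the start token in the window.
#' @return List with `y_plus`, `y_minus`.
#' @export
fbrnn_logits <- function(model, window_ids, start_offset) {
  stopifnot(model$variant == "fbrnn")
  ids <- matrix(window_ids + 1L, nrow = 1)
  out <- pass_fbrnn_eval_step_all(model, ids, start_offset + 1L)
  list(y_plus = out$y_plus, y_minus = out$y_minus)
}

## eval-mode full fbrnn unroll returning final-step halves
pass_fbrnn_eval_step_all <- function(model, ids, cg) {
  M <- ncol(ids)
  sch <- schedule_fbrnn(cg, cg, M)
  st <- gen_stack_init(model, nrow(ids))
  pad <- model_pad_col(model)
  take <- function(cols) {
    bad <- cols < 1L | cols > M
    cols[bad] <- 1L
    out <- ids[, cols, drop = FALSE]
    out[, bad] <- pad
    out
  }
  in_r <- take(sch$in_right); in_l <- take(sch$in_left)
  for (s in seq_len(sch$S))
    st <- gen_stack_step(model, st, cbind(in_r[, s], in_l[, s]))
  V <- model_vsize(model)
  list(y_plus = drop(st$logits[, seq_len(V), drop = FALSE]),
       y_minus = drop(st$logits[, V + seq_len(V), drop = FALSE]))
}

#' Insertion-position logits of a BIMODAL model
#'
#' Reads the current window in both directions and combines the forward
#' hidden state left of the insertion position with the backward hidden
#' state right of it (one linear map over the concatenated states).
#'
#' @param model A `bimodal` [molgen_model()].
#' @param window_ids 0-based token ids of the current window.
#' @param position 0-based insertion position (`direction` follows from the
#'   side the caller appends on).
#' @return Numeric logit vector of length `vocab_size`.
#' @export
bimodal_logits <- function(model, window_ids, position) {
  stopifnot(model$variant == "bimodal")
  ids <- matrix(window_ids + 1L, nrow = 1)
  drop(bimodal_eval_logits(model, ids, position + 1L))
}

## eval-mode bimodal logits at 1-based insertion position pp (batched)
bimodal_eval_logits <- function(model, ids, pp) {
  p <- model$params; bf <- model$buffers
  B <- nrow(ids); M <- ncol(ids); V <- model_vsize(model); H <- model$hidden
  bn1_aff <- bn_eval_affine(p$bn1.gamma, p$bn1.beta, bf$bn1.rm, bf$bn1.rv)
  run <- function(cols, w1, u1, bb1, w2, u2, bb2) {
    h1 <- matrix(0, B, H); c1 <- h1; h2 <- h1; c2 <- h1
    for (t in cols) {
      x <- bn_apply_affine(one_hot(ids[, t], V), bn1_aff)
      s1 <- lstm_cell_step(x, h1, c1, w1, u1, bb1)
      h1 <- s1$h; c1 <- s1$c
      s2 <- lstm_cell_step(h1, h2, c2, w2, u2, bb2)
      h2 <- s2$h; c2 <- s2$c
    }
    h2
  }
  hf <- if (pp - 1L >= 1L)
    run(seq_len(pp - 1L), p$f1.W, p$f1.U, p$f1.b, p$f2.W, p$f2.U, p$f2.b)
  else matrix(0, B, H)
  hb <- if (pp + 1L <= M)
    run(seq(M, pp + 1L), p$b1.W, p$b1.U, p$b1.b, p$b2.W, p$b2.U, p$b2.b)
  else matrix(0, B, H)
  z <- bn_apply_affine(cbind(hf, hb),
                       bn_eval_affine(p$bn2.gamma, p$bn2.beta, bf$bn2.rm, bf$bn2.rv))
  z %*% p$lin.W + matrix(p$lin.b, B, V, byrow = TRUE)
}

## --- incremental eval stack (forward/backward/fbrnn generation) ------------

bn_eval_affine <- function(gamma, beta, rm, rv, eps = 1e-5) {
  s <- gamma / sqrt(rv + eps)
  list(scale = s, shift = beta - rm * s)
}
bn_apply_affine <- function(x, aff)
  sweep(sweep(x, 2, aff$scale, `*`), 2, aff$shift, `+`)

gen_stack_init <- function(model, B) {
  H <- model$hidden
  z <- matrix(0, B, H)
  list(h1 = z, c1 = z, h2 = z, c2 = z, B = B, logits = NULL)
}

## cols: B x 1 (uni) or B x 2 (fbrnn: right, left) of 1-based token columns
gen_stack_step <- function(model, st, cols) {
  p <- model$params; bf <- model$buffers
  V <- model_vsize(model)
  x <- if (ncol(cols) == 1L) one_hot(cols[, 1], V)
       else cbind(one_hot(cols[, 1], V), one_hot(cols[, 2], V))
  x <- bn_apply_affine(x, bn_eval_affine(p$bn1.gamma, p$bn1.beta,
                                         bf$bn1.rm, bf$bn1.rv))
  s1 <- lstm_cell_step(x, st$h1, st$c1, p$l1.W, p$l1.U, p$l1.b)
  s2 <- lstm_cell_step(s1$h, st$h2, st$c2, p$l2.W, p$l2.U, p$l2.b)
  h <- bn_apply_affine(s2$h, bn_eval_affine(p$bn2.gamma, p$bn2.beta,
                                            bf$bn2.rm, bf$bn2.rv))
  logits <- h %*% p$lin.W + matrix(p$lin.b, nrow(h), ncol(p$lin.W), byrow = TRUE)
  list(h1 = s1$h, c1 = s1$c, h2 = s2$h, c2 = s2$c, B = st$B, logits = logits)
}
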