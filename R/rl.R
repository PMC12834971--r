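## Variance-reduced REINFORCE fine-tuning.
##
## Each episode draws a batch of K rollouts at temperature T, scores the
## terminal reward of each completed molecule, subtracts the batch-mean
## baseline, and ascends the surrogate objective
##   (1/K) sum_i (sum_t log pi(a_t^i)) (R^i - Rbar)
##     + beta (1/K) sum_i sum_t H(pi(.|s_t^i))
## with a decoupled-weight-decay Adam (AdamW) step.  Normalization layers
## stay in eval mode throughout: rollouts never mutate running statistics,
## and the replayed gradients are exact for the sampled policy, including
## any seed-preservation masking applied during sampling.

#' Batch-mean reward baseline
#'
#' @param rewards Numeric vector of terminal rewards (length >= 1).
#' @return Arithmetic mean.
#' @export
batch_baseline <- function(rewards) {
  if (length(rewards) == 0L) stop("empty reward batch")
  mean(rewards)
}

#' Reinforcement-learning configuration
#'
#' @param batch_size Rollouts per episode (K).
#' @param temperature Sampling temperature.
#' @param learning_rate AdamW learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param entropy_coef Entropy-bonus coefficient (beta).
#' @param episodes Number of episodes.
#' @param patience,tol Optional early stop: halt when the moving average of
#'   the batch reward has not improved by `tol` for `patience` episodes
#'   (`patience = Inf` disables).
#' @return List of class `"molgen_rl_config"`.
#' @export
rl_config <- function(batch_size = 32, temperature = 1.0,
                      learning_rate = 1e-4, weight_decay = 1e-2,
                      entropy_coef = 1e-4, episodes = 120,
                      patience = Inf, tol = 1e-3) {
  stopifnot(batch_size >= 2, temperature > 0, learning_rate > 0,
            entropy_coef >= 0, episodes >= 1)
  structure(list(batch_size = as.integer(batch_size), temperature = temperature,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 entropy_coef = entropy_coef, episodes = as.integer(episodes),
                 patience = patience, tol = tol),
            class = "molgen_rl_config")
}

#' Roll out a batch of trajectories
#'
#' Generates `K` strings with per-emission records and assembles one
#' trajectory per sample: emitted actions, per-action log-probabilities and
#' policy entropies (frozen pad emissions are not actions), and the terminal
#' reward of the stripped core string.
#'
#' @param model A trained [molgen()] model.
#' @param K Batch size.
#' @param reward Reward function `function(core, scheme) -> numeric`, or a
#'   [reward_weights()] vector for the QED/SA composite.
#' @param seed_fragment Optional seed constraint.
#' @param temperature Sampling temperature.
#' @return List with `trajectories` (length K), `records` (internal replay
#'   data), `cores`, `rewards`, and `props` (QED/SA when available).
#' @export
rollout_batch <- function(model, K, reward, seed_fragment = NULL,
                          temperature = 1.0) {
  df <- generate(model, K, seed_fragment = seed_fragment,
                 temperature = temperature, record = TRUE)
  recs <- attr(df, "record")
  scheme <- model$vocab$scheme
  props <- NULL
  if (inherits(reward, "molgen_weights")) {
    sc <- score_molecules(df$core, scheme, reward)
    rewards <- sc$reward
    props <- sc[, c("qed", "sa", "valid")]
  } else {
    rewards <- reward(df$core, scheme)
  }
  ## per-sample log-prob/entropy sums for reporting and tests
  trajectories <- vector("list", K)
  row0 <- 0L
  k <- 0L
  for (rec in recs) {
    for (b in seq_len(rec$B)) {
      k <- k + 1L
      acts <- integer(0); lps <- numeric(0); ents <- numeric(0)
      for (em in rec$emissions) {
        if (em$active[b]) {
          acts <- c(acts, em$actions[b] - 1L)
          lps <- c(lps, em$logp[b])
          ents <- c(ents, em$entropy[b])
        }
      }
      trajectories[[k]] <- list(actions = acts, log_probs = lps,
                                entropies = ents, reward = NA_real_)
    }
  }
  ## generate() restores the original row order in df; records are grouped
  ## by span, so map rewards back through the grouped order
  ord <- unlist(lapply(recs, function(r) r$order))
  if (is.null(ord)) ord <- seq_len(K)
  for (k in seq_len(K)) trajectories[[k]]$reward <- rewards[ord[k]]
  list(trajectories = trajectories, records = recs, cores = df$core,
       rewards = rewards, rewards_grouped = rewards[ord], props = props,
       samples = df)
}

## --- replay backprop -------------------------------------------------------

zero_grads <- function(params) lapply(params, function(p) p * 0)

acc <- function(g, nm, inc) { g[[nm]] <- g[[nm]] + inc; g }

## gradient of the (negative) surrogate w.r.t. the logits of one emission
emission_dlogits <- function(em, coef_rows, beta, temperature, K) {
  p <- em$probs
  B <- nrow(p)
  dl <- matrix(0, B, ncol(p))
  act_rows <- which(em$active)
  if (length(act_rows) == 0L) return(NULL)
  lp <- ifelse(p > 0, log(p), 0)
  H <- em$entropy
  for (b in act_rows) {
    grad_logp <- -p[b, ]
    grad_logp[em$actions[b]] <- grad_logp[em$actions[b]] + 1
    grad_H <- -p[b, ] * (lp[b, ] + H[b])
    dl[b, ] <- -(coef_rows[b] * grad_logp + beta * grad_H) / (K * temperature)
  }
  dl
}

## backward through a recorded forward/backward/fbrnn rollout chain
chain_replay_backward <- function(model, rec, dlogit_steps, grads) {
  p <- model$params; bf <- model$buffers
  aff1 <- bn_eval_affine(p$bn1.gamma, p$bn1.beta, bf$bn1.rm, bf$bn1.rv)
  aff2 <- bn_eval_affine(p$bn2.gamma, p$bn2.beta, bf$bn2.rm, bf$bn2.rv)
  inv1 <- 1 / sqrt(bf$bn1.rv + 1e-5)
  inv2 <- 1 / sqrt(bf$bn2.rv + 1e-5)
  chain <- rec$chain
  B <- rec$B
  H <- model$hidden
  dh1 <- matrix(0, B, H); dc1 <- dh1; dh2 <- dh1; dc2 <- dh1
  for (k in rev(seq_along(chain))) {
    cc <- chain[[k]]
    dl <- dlogit_steps[[k]]
    dh2_out <- matrix(0, B, H)
    if (!is.null(dl)) {
      grads <- acc(grads, "lin.W", crossprod(cc$hbn, dl))
      grads <- acc(grads, "lin.b", colSums(dl))
      dhbn <- dl %*% t(p$lin.W)
      xhat2 <- sweep(sweep(cc$h2, 2, bf$bn2.rm), 2, inv2, `*`)
      grads <- acc(grads, "bn2.gamma", colSums(dhbn * xhat2))
      grads <- acc(grads, "bn2.beta", colSums(dhbn))
      dh2_out <- sweep(dhbn, 2, aff2$scale, `*`)
    }
    bk2 <- lstm_cell_backward(dh2 + dh2_out, dc2, cc$l2, p$l2.W, p$l2.U)
    grads <- acc(grads, "l2.W", bk2$dW)
    grads <- acc(grads, "l2.U", bk2$dU)
    grads <- acc(grads, "l2.b", bk2$db)
    dh2 <- bk2$dh_prev; dc2 <- bk2$dc_prev
    bk1 <- lstm_cell_backward(dh1 + bk2$dx, dc1, cc$l1, p$l1.W, p$l1.U)
    grads <- acc(grads, "l1.W", bk1$dW)
    grads <- acc(grads, "l1.U", bk1$dU)
    grads <- acc(grads, "l1.b", bk1$db)
    dh1 <- bk1$dh_prev; dc1 <- bk1$dc_prev
    xhat1 <- sweep(sweep(cc$x_raw, 2, bf$bn1.rm), 2, inv1, `*`)
    grads <- acc(grads, "bn1.gamma", colSums(bk1$dx * xhat1))
    grads <- acc(grads, "bn1.beta", colSums(bk1$dx))
  }
  grads
}

## backward through one recorded bimodal emission (its own window passes)
bimodal_replay_backward <- function(model, em, dl, grads) {
  p <- model$params; bf <- model$buffers
  H <- model$hidden
  inv1 <- 1 / sqrt(bf$bn1.rv + 1e-5)
  inv2 <- 1 / sqrt(bf$bn2.rv + 1e-5)
  aff1 <- bn_eval_affine(p$bn1.gamma, p$bn1.beta, bf$bn1.rm, bf$bn1.rv)
  aff2 <- bn_eval_affine(p$bn2.gamma, p$bn2.beta, bf$bn2.rm, bf$bn2.rv)
  cache <- em$cache
  grads <- acc(grads, "lin.W", crossprod(cache$zbn, dl))
  grads <- acc(grads, "lin.b", colSums(dl))
  dzbn <- dl %*% t(p$lin.W)
  xhat2 <- sweep(sweep(cache$z, 2, bf$bn2.rm), 2, inv2, `*`)
  grads <- acc(grads, "bn2.gamma", colSums(dzbn * xhat2))
  grads <- acc(grads, "bn2.beta", colSums(dzbn))
  dz <- sweep(dzbn, 2, aff2$scale, `*`)
  back_dir <- function(caches, dh_last, pre, grads) {
    n <- length(caches)
    if (n == 0L) return(grads)
    B <- nrow(dh_last)
    dh2 <- dh_last; dc2 <- matrix(0, B, H)
    dh1 <- matrix(0, B, H); dc1 <- dh1
    w1 <- p[[paste0(pre, "1.W")]]; u1 <- p[[paste0(pre, "1.U")]]
    w2 <- p[[paste0(pre, "2.W")]]; u2 <- p[[paste0(pre, "2.U")]]
    for (k in rev(seq_len(n))) {
      cc <- caches[[k]]
      bk2 <- lstm_cell_backward(dh2, dc2, cc$l2, w2, u2)
      grads <- acc(grads, paste0(pre, "2.W"), bk2$dW)
      grads <- acc(grads, paste0(pre, "2.U"), bk2$dU)
      grads <- acc(grads, paste0(pre, "2.b"), bk2$db)
      dh2 <- bk2$dh_prev; dc2 <- bk2$dc_prev
      bk1 <- lstm_cell_backward(dh1 + bk2$dx, dc1, cc$l1, w1, u1)
      grads <- acc(grads, paste0(pre, "1.W"), bk1$dW)
      grads <- acc(grads, paste0(pre, "1.U"), bk1$dU)
      grads <- acc(grads, paste0(pre, "1.b"), bk1$db)
      dh1 <- bk1$dh_prev; dc1 <- bk1$dc_prev
      xhat1 <- sweep(sweep(cc$x_raw, 2, bf$bn1.rm), 2, inv1, `*`)
      grads <- acc(grads, "bn1.gamma", colSums(bk1$dx * xhat1))
      grads <- acc(grads, "bn1.beta", colSums(bk1$dx))
    }
    grads
  }
  grads <- back_dir(cache$fw, dz[, seq_len(H), drop = FALSE], "f", grads)
  grads <- back_dir(cache$bw, dz[, H + seq_len(H), drop = FALSE], "b", grads)
  grads
}

## surrogate-loss gradients for a full rollout batch
rl_gradients <- function(model, rollout, advantages_grouped, beta, temperature) {
  grads <- zero_grads(model$params)
  K <- length(advantages_grouped)
  V <- model_vsize(model)
  offset <- 0L
  for (rec in rollout$records) {
    adv <- advantages_grouped[offset + seq_len(rec$B)]
    offset <- offset + rec$B
    if (model$variant == "bimodal") {
      for (em in rec$emissions) {
        dl <- emission_dlogits(em, adv, beta, temperature, K)
        if (!is.null(dl)) grads <- bimodal_replay_backward(model, em, dl, grads)
      }
    } else {
      two_headed <- model$variant == "fbrnn"
      dsteps <- rep(list(NULL), length(rec$chain))
      for (em in rec$emissions) {
        dl <- emission_dlogits(em, adv, beta, temperature, K)
        if (is.null(dl)) next
        wide <- if (two_headed) {
          m <- matrix(0, rec$B, 2L * V)
          if (identical(em$side, "plus")) m[, seq_len(V)] <- dl
          else m[, V + seq_len(V)] <- dl
          m
        } else dl
        k <- em$step
        dsteps[[k]] <- if (is.null(dsteps[[k]])) wide else dsteps[[k]] + wide
      }
      grads <- chain_replay_backward(model, rec, dsteps, grads)
    }
  }
  grads
}

#' One REINFORCE update
#'
#' Computes advantages against the batch-mean baseline, replays the rollout
#' to obtain exact surrogate-loss gradients, and applies one AdamW step.
#'
#' @param model A trained model.
#' @param rollout A [rollout_batch()] result.
#' @param config An [rl_config()].
#' @param opt_state Optimizer state (from a previous call, or NULL).
#' @return List with `model`, `opt_state`, `stats` (one-row data.frame).
#' @export
reinforce_update <- function(model, rollout, config = rl_config(),
                             opt_state = NULL) {
  rewards <- rollout$rewards
  stopifnot(length(rewards) >= 2)
  adv <- rollout$rewards_grouped - batch_baseline(rollout$rewards_grouped)
  grads <- rl_gradients(model, rollout, adv, config$entropy_coef,
                        config$temperature)
  bad <- vapply(grads, function(g) any(!is.finite(g)), logical(1))
  if (any(bad))
    stop("non-finite policy gradient in: ", paste(names(grads)[bad], collapse = ", "))
  if (is.null(opt_state)) opt_state <- optim_init(model$params)
  up <- optim_step(model$params, grads, opt_state, lr = config$learning_rate,
                   weight_decay = config$weight_decay)
  model$params <- up$params
  stats <- data.frame(mean_reward = mean(rewards),
                      reward_std = stats::sd(rewards))
  if (!is.null(rollout$props)) {
    stats$qed_mean <- mean(rollout$props$qed, na.rm = TRUE)
    stats$qed_std <- stats::sd(rollout$props$qed, na.rm = TRUE)
    stats$sa_mean <- mean(rollout$props$sa, na.rm = TRUE)
    stats$sa_std <- stats::sd(rollout$props$sa, na.rm = TRUE)
  }
  list(model = model, opt_state = up$state, stats = stats)
}

#' Fine-tune a generator with REINFORCE
#'
#' Loops rollout + update for `config$episodes` episodes, recording
#' per-episode statistics (the mean/standard deviation of reward, QED and
#' SA over the K rollouts of that episode).
#'
#' @inheritParams rollout_batch
#' @param config An [rl_config()].
#' @param seed RNG seed for the whole fine-tuning run.
#' @param checkpoint_dir Optional directory for episodic checkpoints.
#' @param checkpoint_every Episode cadence for checkpoints.
#' @param verbose Print a line every 10 episodes.
#' @return The fine-tuned model; per-episode statistics in `$episodes`.
#' @export
finetune <- function(model, reward = reward_weights(1, 0),
                     seed_fragment = NULL, config = rl_config(),
                     seed = NULL, checkpoint_dir = NULL,
                     checkpoint_every = 20L, verbose = FALSE) {
  stopifnot(inherits(model, "molgen_model"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(seed_fragment) && !inherits(seed_fragment, "molgen_seed"))
    seed_fragment <- seed_constraint(seed_fragment, model$vocab$scheme)
  opt_state <- NULL
  stats <- list()
  best <- -Inf; stall <- 0L
  for (ep in seq_len(config$episodes)) {
    ro <- rollout_batch(model, config$batch_size, reward,
                        seed_fragment = seed_fragment,
                        temperature = config$temperature)
    up <- reinforce_update(model, ro, config, opt_state)
    model <- up$model; opt_state <- up$opt_state
    row <- cbind(data.frame(episode = ep), up$stats)
    stats[[ep]] <- row
    if (verbose && ep %% 10L == 0L)
      cat(sprintf("episode %d: mean reward %.4f (sd %.4f)\n", ep,
                  row$mean_reward, row$reward_std))
    if (!is.null(checkpoint_dir) && ep %% checkpoint_every == 0L)
      write_checkpoint(model, file.path(checkpoint_dir,
                                        sprintf("rl_episode%03d.rds", ep)),
                       meta = list(episode = ep))
    ## early stop on a stalled moving average of the batch reward
    if (is.finite(config$patience)) {
      win <- vapply(stats[max(1, ep - 9):ep], function(s) s$mean_reward,
                    numeric(1))
      avg <- mean(win)
      if (avg > best + config$tol) { best <- avg; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model$episodes <- do.call(rbind, stats)
  model
}
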