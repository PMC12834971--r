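## REINFORCE: baseline, exact replay gradients, bandit convergence, and the
## entropy bonus.

## independent recomputation of the surrogate objective for a recorded
## fbrnn rollout (teacher-forced replay of the generation chain)
fbrnn_surrogate <- function(model, rollout, adv, beta, temp) {
  J <- 0; K <- length(adv); off <- 0L
  for (rec in rollout$records) {
    ids <- rec$ids; M <- ncol(ids); V <- molgen:::model_vsize(model)
    pad <- molgen:::model_pad_col(model)
    st <- molgen:::gen_stack_init(model, rec$B)
    S <- max(rec$sl - 1L, M - rec$sr)
    a_loc <- adv[off + seq_len(rec$B)]
    emi <- 1L
    for (s in seq_len(S)) {
      in_r <- if (rec$sr + s - 1L <= M) ids[, rec$sr + s - 1L] else rep(pad, rec$B)
      in_l <- if (rec$sl - s + 1L >= 1L) ids[, rec$sl - s + 1L] else rep(pad, rec$B)
      st <- molgen:::gen_stack_step(model, st, cbind(in_r, in_l))
      for (side in c("plus", "minus")) {
        if (side == "plus" && rec$sr + s > M) next
        if (side == "minus" && rec$sl - s < 1L) next
        em <- rec$emissions[[emi]]; emi <- emi + 1L
        z <- if (side == "plus") st$logits[, seq_len(V), drop = FALSE]
             else st$logits[, V + seq_len(V), drop = FALSE]
        z[!em$allowed] <- -Inf
        p <- temperature_softmax(z, temp)
        for (b in which(em$active)) {
          J <- J + a_loc[b] * log(p[b, em$actions[b]]) / K +
            beta * policy_entropy(p[b, ]) / K
        }
      }
    }
    off <- off + rec$B
  }
  J
}

test_that("batch baseline centers the rewards", {
  expect_identical(batch_baseline(c(1, 1, 1)), 1)
  expect_identical(batch_baseline(c(0, 1)), 0.5)
  r <- rnorm(8)
  expect_equal(sum(r - batch_baseline(r)), 0)
  expect_error(batch_baseline(numeric(0)), "empty")
})

test_that("recorded log-probabilities match independent recomputation", {
  m <- toy_model("fbrnn")
  set.seed(31)
  ro <- rollout_batch(m, K = 5, reward = function(core, scheme) nchar(core))
  expect_length(ro$trajectories, 5)
  for (tr in ro$trajectories) {
    expect_length(tr$log_probs, length(tr$actions))
    expect_true(all(tr$log_probs <= 0))
    expect_true(all(tr$entropies >= 0))
  }
  ## recompute each emission's distribution from the final window
  rec <- ro$records[[1]]
  ids <- rec$ids
  st <- molgen:::gen_stack_init(m, rec$B)
  M <- ncol(ids); V <- molgen:::model_vsize(m)
  pad <- molgen:::model_pad_col(m)
  emi <- 1L
  for (s in seq_len(max(rec$sl - 1L, M - rec$sr))) {
    in_r <- if (rec$sr + s - 1L <= M) ids[, rec$sr + s - 1L] else rep(pad, rec$B)
    in_l <- if (rec$sl - s + 1L >= 1L) ids[, rec$sl - s + 1L] else rep(pad, rec$B)
    st <- molgen:::gen_stack_step(m, st, cbind(in_r, in_l))
    for (side in c("plus", "minus")) {
      if (side == "plus" && rec$sr + s > M) next
      if (side == "minus" && rec$sl - s < 1L) next
      em <- rec$emissions[[emi]]; emi <- emi + 1L
      z <- if (side == "plus") st$logits[, seq_len(V), drop = FALSE]
           else st$logits[, V + seq_len(V), drop = FALSE]
      z[!em$allowed] <- -Inf
      p <- temperature_softmax(z, 1)
      for (b in which(em$active))
        expect_equal(em$logp[b], log(p[b, em$actions[b]]), tolerance = 1e-12)
    }
  }
})

test_that("equal rewards give an exactly zero policy-gradient term", {
  m <- toy_model("fbrnn")
  set.seed(8)
  ro <- rollout_batch(m, K = 4, reward = function(core, scheme) rep(1, length(core)))
  adv <- ro$rewards_grouped - batch_baseline(ro$rewards_grouped)
  expect_true(all(adv == 0))
  g <- molgen:::rl_gradients(m, ro, adv, beta = 0, temperature = 1)
  expect_true(all(vapply(g, function(x) max(abs(x)), numeric(1)) == 0))
})

test_that("replay gradients match finite differences of the surrogate", {
  corpus <- toy_corpus()$selfies[1:40]
  m <- molgen(corpus, scheme = "SELFIES", variant = "fbrnn", hidden = 6,
              epochs = 1, m_total = 14, seed = 3)
  set.seed(5)
  ro <- rollout_batch(m, K = 5, reward = function(core, scheme) nchar(core) / 20)
  adv <- ro$rewards_grouped - batch_baseline(ro$rewards_grouped)
  beta <- 1e-2
  grads <- molgen:::rl_gradients(m, ro, adv, beta, 1)
  set.seed(6)
  worst <- 0
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))
    for (k in idx) {
      eps <- 1e-5
      pp <- m$params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- m$params; pm[[nm]][k] <- pm[[nm]][k] - eps
      mp <- m; mp$params <- pp
      mm <- m; mm$params <- pm
      fd <- (fbrnn_surrogate(mp, ro, adv, beta, 1) -
               fbrnn_surrogate(mm, ro, adv, beta, 1)) / (2 * eps)
      worst <- max(worst, abs(fd - (-grads[[nm]][k])) / max(1, abs(fd)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("a single positive-advantage trajectory gains probability", {
  corpus <- toy_corpus()$selfies[1:40]
  m <- molgen(corpus, scheme = "SELFIES", variant = "fbrnn", hidden = 6,
              epochs = 1, m_total = 14, seed = 3)
  set.seed(9)
  ro <- rollout_batch(m, K = 2, reward = function(core, scheme) c(1, 0))
  adv <- c(1, 0) - 0.5
  grads <- molgen:::rl_gradients(m, ro, adv, beta = 0, temperature = 1)
  ## plain gradient-ascent step (no Adam, no decay) must raise the winner's
  ## total log-probability
  m2 <- m
  for (nm in names(grads)) m2$params[[nm]] <- m2$params[[nm]] - 1e-2 * grads[[nm]]
  lp <- function(model) {
    total <- c(0, 0)
    ro2 <- ro
    rec <- ro2$records[[1]]
    st <- molgen:::gen_stack_init(model, rec$B)
    ids <- rec$ids; M <- ncol(ids); V <- molgen:::model_vsize(model)
    pad <- molgen:::model_pad_col(model)
    emi <- 1L
    for (s in seq_len(max(rec$sl - 1L, M - rec$sr))) {
      in_r <- if (rec$sr + s - 1L <= M) ids[, rec$sr + s - 1L] else rep(pad, rec$B)
      in_l <- if (rec$sl - s + 1L >= 1L) ids[, rec$sl - s + 1L] else rep(pad, rec$B)
      st <- molgen:::gen_stack_step(model, st, cbind(in_r, in_l))
      for (side in c("plus", "minus")) {
        if (side == "plus" && rec$sr + s > M) next
        if (side == "minus" && rec$sl - s < 1L) next
        em <- rec$emissions[[emi]]; emi <- emi + 1L
        z <- if (side == "plus") st$logits[, seq_len(V), drop = FALSE]
             else st$logits[, V + seq_len(V), drop = FALSE]
        z[!em$allowed] <- -Inf
        p <- temperature_softmax(z, 1)
        for (b in which(em$active)) total[b] <- total[b] + log(p[b, em$actions[b]])
      }
    }
    total
  }
  expect_gt(lp(m2)[1], lp(m)[1])
})

test_that("a two-armed bandit recovers the optimal arm", {
  ## stateless softmax policy optimized with the package's gradient and
  ## optimizer primitives
  set.seed(123)
  theta <- c(0, 0)
  params <- list(theta = matrix(theta, 1))
  st <- molgen:::optim_init(params)
  K <- 16
  trace <- numeric(200)
  for (it in 1:200) {
    p <- temperature_softmax(params$theta[1, ], 1)
    arms <- sample(1:2, K, TRUE, prob = p)
    rewards <- as.numeric(arms == 1)
    adv <- rewards - mean(rewards)
    em <- list(probs = matrix(p, K, 2, byrow = TRUE), active = rep(TRUE, K),
               actions = arms, entropy = rep(policy_entropy(p), K))
    dl <- molgen:::emission_dlogits(em, adv, beta = 0, temperature = 1, K = K)
    g <- list(theta = matrix(colSums(dl), 1))
    up <- molgen:::optim_step(params, g, st, lr = 0.05)
    params <- up$params; st <- up$state
    trace[it] <- temperature_softmax(params$theta[1, ], 1)[1]
  }
  expect_gt(trace[200], 0.95)
  ## expectation rises over the run (smoothed monotonicity)
  expect_gt(mean(trace[151:200]), mean(trace[1:50]))
})

test_that("baseline subtraction is unbiased within noise and reduces variance", {
  ## rewards share a large common offset (the regime a batch-mean baseline
  ## is for); the estimators are compared as paired differences
  set.seed(77)
  p <- c(0.3, 0.7)
  K <- 32
  rew <- c(1.0, 0.9)
  n_batches <- 10000
  g_nb <- matrix(0, n_batches, 2)     # no baseline
  g_wb <- matrix(0, n_batches, 2)     # batch-mean baseline
  for (i in seq_len(n_batches)) {
    arms <- sample(1:2, K, TRUE, prob = p)
    r <- rew[arms]
    e <- diag(2)[arms, , drop = FALSE]
    score <- e - matrix(p, K, 2, byrow = TRUE)   # grad log pi per draw
    g_nb[i, ] <- colMeans(score * r)
    g_wb[i, ] <- colMeans(score * (r - mean(r)))
  }
  se <- sqrt(apply(g_nb - g_wb, 2, var) / n_batches)
  expect_true(all(abs(colMeans(g_nb) - colMeans(g_wb)) < 3 * se))
  expect_true(all(apply(g_wb, 2, var) < apply(g_nb, 2, var)))
})

test_that("the entropy bonus raises policy entropy when rewards are flat", {
  corpus <- toy_corpus()$selfies[1:40]
  m <- molgen(corpus, scheme = "SELFIES", variant = "fbrnn", hidden = 8,
              epochs = 2, m_total = 14, seed = 3)
  cfg <- rl_config(batch_size = 8, entropy_coef = 0.5, learning_rate = 5e-3,
                   episodes = 15)
  zero_r <- function(core, scheme) rep(0, length(core))
  ent_of <- function(model) {
    set.seed(1234)
    ro <- rollout_batch(model, 16, zero_r)
    mean(unlist(lapply(ro$trajectories, `[[`, "entropies")))
  }
  before <- ent_of(m)
  m2 <- finetune(m, reward = zero_r, config = cfg, seed = 2)
  expect_gt(ent_of(m2), before)
  ## with beta = 0 and flat rewards only weight decay moves parameters
  cfg0 <- rl_config(batch_size = 4, entropy_coef = 0, weight_decay = 0,
                    episodes = 2)
  m3 <- finetune(m, reward = zero_r, config = cfg0, seed = 2)
  expect_equal(m3$params, m$params, tolerance = 1e-12)
})

test_that("finetune records one row of statistics per episode", {
  m <- toy_model("fbrnn")
  cfg <- rl_config(batch_size = 4, episodes = 5, learning_rate = 1e-3)
  ft <- finetune(m, reward = function(core, scheme) nchar(core) / 30,
                 config = cfg, seed = 77)
  expect_identical(nrow(ft$episodes), 5L)
  expect_true(all(c("episode", "mean_reward", "reward_std") %in%
                    names(ft$episodes)))
  expect_true(all(ft$episodes$reward_std >= 0))
})

test_that("a toy length reward is learned within a short run", {
  corpus <- toy_corpus()$selfies[1:80]
  m <- molgen(corpus, scheme = "SELFIES", variant = "fbrnn", hidden = 32,
              epochs = 3, m_total = 16, seed = 13)
  cfg <- rl_config(batch_size = 16, learning_rate = 2e-3, weight_decay = 0,
                   entropy_coef = 1e-4, episodes = 40)
  ft <- finetune(m, reward = function(core, scheme)
    lengths(regmatches(core, gregexpr("]", core))) / 16, config = cfg,
    seed = 5)
  ep <- ft$episodes
  early <- mean(ep$mean_reward[1:5])
  late <- mean(ep$mean_reward[36:40])
  expect_gt(late, early)
})
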