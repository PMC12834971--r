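## Generation: turn a trained model into an unconstrained or seed-constrained
## string sampler.  There is no end-of-string token: every rollout runs to
## the window length under the pad-freeze rule (once a direction emits pad,
## that direction only emits pad), and the final window is stripped of start
## and pad tokens.
##
## Constrained generation initializes the window with the seed token run in
## place of the lone start token.  Because SELFIES overloading lets a
## Branch/Ring symbol emitted LEFT of the seed re-interpret seed tokens as
## index symbols (or split the seed across a branch boundary), and a SMILES
## ring digit emitted left of the seed can capture a seed ring closure,
## leftward emissions are sampled from a masked distribution that excludes
## exactly those tokens.  This makes seed preservation structural rather
## than statistical.

#' Construct and validate a seed constraint
#'
#' @param raw Seed fragment as a SMILES or SELFIES string.
#' @param scheme Encoding scheme of `raw`.
#' @param placement Where the seed sits in the window for the bidirectional
#'   variants (`"fixed"` center or `"random"`).
#' @return Object of class `"molgen_seed"` with `raw`, `scheme`, `tokens`,
#'   `aperiodic`, `placement`.
#' @export
seed_constraint <- function(raw, scheme = c("SMILES", "SELFIES"),
                            placement = c("fixed", "random")) {
  scheme <- match.arg(scheme); placement <- match.arg(placement)
  tokens <- tokenize_string(raw, scheme)
  stopifnot(length(tokens) >= 1)
  structure(list(raw = raw, scheme = scheme, tokens = tokens,
                 aperiodic = check_aperiodicity(tokens),
                 placement = placement),
            class = "molgen_seed")
}

#' @export
print.molgen_seed <- function(x, ...) {
  cat(sprintf("<molgen_seed> %s '%s' (%d tokens, %saperiodic)\n", x$scheme,
              x$raw, length(x$tokens), if (x$aperiodic) "" else "NOT "))
  invisible(x)
}

#' Diagnose a seed constraint
#'
#' Checks that the fragment decodes to a molecule, that both terminal
#' attachment atoms have an open valence (otherwise forward/backward
#' extension yields invalid strings or dropped bonds), and that the token
#' list is not entirely a repetition of a shorter substring.
#'
#' @param seed A [seed_constraint()] (or a raw string plus `scheme`).
#' @param scheme Used when `seed` is a raw string.
#' @return List with `ok` and logical fields `decodable`, `open_valence_left`,
#'   `open_valence_right`, `aperiodic`, plus `reasons` (character).
#' @export
validate_seed <- function(seed, scheme = c("SMILES", "SELFIES")) {
  if (!inherits(seed, "molgen_seed"))
    seed <- seed_constraint(seed, match.arg(scheme))
  reasons <- character(0)
  smiles <- tryCatch(
    if (seed$scheme == "SELFIES") selfies_decode(seed$raw) else seed$raw,
    error = function(e) "")
  graph <- tryCatch(parse_smiles(smiles), error = function(e) NULL)
  decodable <- !is.null(graph) && length(graph$atoms) >= 1
  open_l <- open_r <- NA
  if (decodable) {
    used <- atom_bond_orders(graph)
    cap <- MOLGEN_VALENCE[graph$atoms]
    open_l <- used[1] < cap[1]
    open_r <- used[length(used)] < cap[length(cap)]
    if (!open_l) reasons <- c(reasons, "first attachment atom has no open valence")
    if (!open_r) reasons <- c(reasons, "last attachment atom has no open valence")
  } else {
    reasons <- c(reasons, "seed does not decode to a molecule")
  }
  if (!seed$aperiodic)
    reasons <- c(reasons, "seed token list is a whole-number repetition of a shorter substring")
  list(ok = decodable && isTRUE(open_l) && isTRUE(open_r) && seed$aperiodic,
       decodable = decodable, open_valence_left = open_l,
       open_valence_right = open_r, aperiodic = seed$aperiodic,
       reasons = reasons)
}

## --- leftward-emission guard ----------------------------------------------

smiles_ring_digits <- function(tokens)
  unique(grep("^%?[0-9]+$", tokens, value = TRUE))

## parsed vocabulary table for the derivation simulator: one row per token
## type: 0 other (start/pad), 1 atom, 2 branch, 3 ring
selfies_vocab_table <- function(vocab) {
  V <- length(vocab$tokens)
  tab <- data.frame(type = integer(V), order = integer(V), cap = integer(V),
                    l = integer(V), idx = integer(V))
  for (v in seq_len(V)) {
    tok <- vocab$tokens[v]
    tab$idx[v] <- selfies_index_of(tok)
    a <- parse_selfies_atom(tok)
    if (!is.null(a)) {
      tab$type[v] <- 1L; tab$order[v] <- a$order
      tab$cap[v] <- MOLGEN_VALENCE[[a$elem]]
      next
    }
    sp <- parse_selfies_special(tok)
    if (!is.null(sp)) {
      tab$type[v] <- if (sp$kind == "Branch") 2L else 3L
      tab$order[v] <- sp$order; tab$l[v] <- sp$l
    }
  }
  tab
}

## cap-domain mirror of the SELFIES derivation automaton.  cols: 1-based
## vocab columns of the fragment tokens; entry_cap: capacity of a synthetic
## leading atom (NA = none: fragment starts fresh).  Returns atoms
## (source index in `cols`, 0 for the synthetic atom), caps, free, bonds.
sim_selfies_fragment <- function(cols, tab, entry_cap = NA_integer_) {
  st <- new.env()
  st$src <- integer(0); st$cap <- integer(0); st$free <- integer(0)
  st$bonds <- list()
  add_atom <- function(src, cap) {
    st$src <- c(st$src, src); st$cap <- c(st$cap, cap)
    st$free <- c(st$free, cap)
    length(st$src)
  }
  add_bond <- function(a, b, order) {
    st$bonds[[length(st$bonds) + 1L]] <- c(a, b, order)
    st$free[a] <- st$free[a] - order
    st$free[b] <- st$free[b] - order
  }
  derive <- function(pos, current, state) {
    i <- 1L; n <- length(pos)
    while (i <= n) {
      v <- cols[pos[i]]
      ty <- tab$type[v]
      if (ty == 0L) { i <- i + 1L; next }         # start token: stripped later
      if (ty == 1L) {
        if (!is.na(current) && state == 0L) break
        idx <- add_atom(pos[i], tab$cap[v])
        if (!is.na(current))
          add_bond(current, idx, min(tab$order[v], state, tab$cap[v]))
        current <- idx
        state <- st$free[idx]
        i <- i + 1L
        next
      }
      if (ty == 2L) {                             # branch
        if (is.na(current) || state <= 1L || i + tab$l[v] > n) { i <- i + 1L; next }
        q <- 0L
        for (j in seq_len(tab$l[v])) q <- q * 16L + tab$idx[cols[pos[i + j]]]
        content_from <- i + tab$l[v] + 1L
        content_to <- min(n, content_from + q)
        i <- content_to + 1L
        if (content_from > n) break
        binit <- min(state - 1L, tab$order[v])
        derive(pos[content_from:content_to], current, binit)
        state <- max(0L, min(state - binit, st$free[current]))
        next
      }
      ## ring
      if (is.na(current) || state == 0L || i + tab$l[v] > n) { i <- i + 1L; next }
      q <- 0L
      for (j in seq_len(tab$l[v])) q <- q * 16L + tab$idx[cols[pos[i + j]]]
      i <- i + tab$l[v] + 1L
      target <- max(1L, current - (q + 1L))
      if (target == current) next
      order <- min(tab$order[v], state, st$free[target])
      if (order >= 1L) {
        hit <- 0L
        for (k in seq_along(st$bonds)) {
          e <- st$bonds[[k]]
          if ((e[1] == target && e[2] == current) ||
              (e[1] == current && e[2] == target)) { hit <- k; break }
        }
        if (hit) {
          add <- min(order, 3L - st$bonds[[hit]][3])
          if (add > 0L) {
            st$bonds[[hit]][3] <- st$bonds[[hit]][3] + add
            st$free[current] <- st$free[current] - add
            st$free[target] <- st$free[target] - add
            state <- state - add
          }
        } else {
          add_bond(target, current, order)
          state <- state - order
        }
      }
    }
    invisible()
  }
  if (!is.na(entry_cap)) {
    add_atom(0L, entry_cap)
    derive(seq_along(cols), 1L, entry_cap)
  } else {
    derive(seq_along(cols), NA_integer_, 0L)
  }
  list(src = st$src, cap = st$cap, bonds = st$bonds)
}

## reference derivation of the seed alone: atom caps and internal bonds in
## relative indices
seed_reference <- function(seed_cols, tab) {
  ref <- sim_selfies_fragment(seed_cols, tab)
  list(n = length(ref$src), cap = ref$cap,
       bonds = lapply(ref$bonds, function(e) e))
}

## does a fragment derivation keep the seed intact?  frag_src values in
## [seed_from, seed_to] mark seed-derived atoms.  Intact means: the seed
## atoms derive consecutively with exactly their reference internal bonds;
## external bonds touch only the two terminal attachment atoms, one each;
## and the two attachment partners are not connected outside the seed (no
## new ring may pass through seed atoms, which would re-aromatize them).
fragment_keeps_seed <- function(sim, seed_from, seed_to, ref) {
  at <- which(sim$src >= seed_from & sim$src <= seed_to)
  if (length(at) != ref$n) return(FALSE)
  if (any(sim$cap[at] != ref$cap)) return(FALSE)
  if (ref$n > 1L && any(diff(at) != 1L)) return(FALSE)
  off <- at[1] - 1L
  in_seed <- logical(length(sim$src))
  in_seed[at] <- TRUE
  internal <- list(); external <- list()
  for (f in sim$bonds) {
    ns <- in_seed[f[1]] + in_seed[f[2]]
    if (ns == 2L) internal[[length(internal) + 1L]] <- f
    else if (ns == 1L) external[[length(external) + 1L]] <- f
  }
  if (length(internal) != length(ref$bonds)) return(FALSE)
  for (e in ref$bonds) {
    found <- FALSE
    for (f in internal) {
      if (((f[1] == e[1] + off && f[2] == e[2] + off) ||
           (f[1] == e[2] + off && f[2] == e[1] + off)) && f[3] == e[3]) {
        found <- TRUE; break
      }
    }
    if (!found) return(FALSE)
  }
  first <- at[1]; last <- at[length(at)]
  partners <- list(first = integer(0), last = integer(0))
  for (f in external) {
    sa <- if (in_seed[f[1]]) f[1] else f[2]
    oa <- if (in_seed[f[1]]) f[2] else f[1]
    if (sa == first && (length(partners$first) == 0L || first != last))
      partners$first <- c(partners$first, oa)
    else if (sa == last) partners$last <- c(partners$last, oa)
    else return(FALSE)                      # bond to a seed-interior atom
  }
  if (length(partners$first) > 1L || length(partners$last) > 1L) return(FALSE)
  if (length(partners$first) && length(partners$last)) {
    ## BFS over non-seed atoms: the two attachment sides must be disjoint
    n <- length(sim$src)
    adj <- vector("list", n)
    for (f in sim$bonds) {
      if (!in_seed[f[1]] && !in_seed[f[2]]) {
        adj[[f[1]]] <- c(adj[[f[1]]], f[2])
        adj[[f[2]]] <- c(adj[[f[2]]], f[1])
      }
    }
    seen <- logical(n)
    queue <- partners$first
    seen[queue] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
    }
    if (any(seen[partners$last])) return(FALSE)
  }
  TRUE
}

## precomputed context for the SELFIES leftward guard
guard_context <- function(vocab, seed_cols) {
  tab <- selfies_vocab_table(vocab)
  caps <- sort(unique(tab$cap[tab$type == 1L]))
  list(tab = tab,
       ref = seed_reference(seed_cols, tab),
       caps = caps,
       rep_col = vapply(caps, function(k) which(tab$type == 1L & tab$cap == k)[1],
                        integer(1)))
}

## allowed-token matrix (B x V) for emitting window column `t` to the left of
## an occupied region, with the seed at columns [sl, sr].  ids: B x M.
##
## SMILES: ring digits used inside the seed are excluded (a digit emitted
## left of the seed would re-pair the seed's own ring closures); everything
## else either leaves the seed's parse intact or yields an invalid string.
##
## SELFIES: two layers.  (1) A static scope check excludes Branch/Ring
## symbols whose index window would consume seed tokens, and Branch symbols
## whose declared content would cover the seed only partially.  (2) Each
## atom candidate (by valence-cap class) is checked by simulating the
## derivation of [candidate, already-written suffix] up to the seed end;
## candidates whose fragment fails to derive the seed intact (e.g. by
## saturating the chain before it reaches the seed) are excluded.  Since the
## pad token is always allowed and a special symbol at the core's left edge
## is a no-op, every final core has been validated by the guard of its
## leftmost emission.
guard_left <- function(vocab, ids, t, sl, sr, ctx = NULL) {
  V <- length(vocab$tokens)
  B <- nrow(ids)
  allowed <- matrix(TRUE, B, V)
  if (vocab$scheme == "SMILES") {
    seed_digits <- smiles_ring_digits(vocab$tokens[ids[1, sl:sr]])
    bad <- vocab$tokens %in% seed_digits
    allowed[, bad] <- FALSE
    return(allowed)
  }
  stopifnot(!is.null(ctx))
  tab <- ctx$tab
  ## (1) static scope check for special symbols
  for (v in which(tab$type >= 2L)) {
    idx_cols <- t + seq_len(tab$l[v])
    if (any(idx_cols >= sl & idx_cols <= sr)) {
      allowed[, v] <- FALSE
      next
    }
    if (tab$type[v] == 3L) next
    for (b in seq_len(B)) {
      q <- 0L
      for (cc in idx_cols) {
        vv <- if (cc <= ncol(ids)) ids[b, cc] else NA_integer_
        q <- q * 16L + if (is.na(vv)) 0L else tab$idx[vv]
      }
      cs <- t + tab$l[v] + 1L
      ce <- cs + q
      overlaps <- max(cs, sl) <= min(ce, sr)
      full <- cs <= sl && ce >= sr
      if (overlaps && !full) allowed[b, v] <- FALSE
    }
  }
  ## (2) fragment simulation per atom-capacity class
  seed_from <- sl - t + 1L
  seed_to <- sr - t + 1L
  for (b in seq_len(B)) {
    suffix <- ids[b, (t + 1L):sr]
    for (ci in seq_along(ctx$caps)) {
      sim <- sim_selfies_fragment(c(ctx$rep_col[ci], suffix), tab)
      ok <- fragment_keeps_seed(sim, seed_from, seed_to, ctx$ref)
      if (!ok) {
        cls <- which(tab$type == 1L & tab$cap == ctx$caps[ci])
        allowed[b, cls] <- FALSE
      }
    }
  }
  allowed
}

## rightward-emission guard (SELFIES): the only way a token emitted right of
## the seed can corrupt it is as the final index symbol of a pending Ring
## whose back-count lands on a seed-seed bond.  A pending ring symbol can
## only sit 1..2 positions back, so the guard triggers rarely; when it does,
## candidates are collapsed by index value and each class is checked by
## simulating the full written fragment plus the candidate.
guard_right <- function(vocab, ids, t, lo_row, sl, sr, ctx) {
  V <- length(vocab$tokens)
  B <- nrow(ids)
  allowed <- matrix(TRUE, B, V)
  if (is.null(ctx) || vocab$scheme != "SELFIES") return(allowed)
  tab <- ctx$tab
  ring_near <- function(b) {
    cols_chk <- (t - 2L):(t - 1L)
    cols_chk <- cols_chk[cols_chk > sr & cols_chk >= 1L]
    any(tab$type[ids[b, cols_chk]] == 3L &
          cols_chk + tab$l[ids[b, cols_chk]] >= t)
  }
  idx_classes <- sort(unique(tab$idx))
  rep_idx <- vapply(idx_classes, function(q) which(tab$idx == q)[1], integer(1))
  pad_col <- match(vocab$pad_token, vocab$tokens)
  for (b in seq_len(B)) {
    if (!ring_near(b)) next
    lo <- lo_row[b]
    prefix <- ids[b, lo:(t - 1L)]
    sf <- sl - lo + 1L; st_ <- sr - lo + 1L
    for (ci in seq_along(idx_classes)) {
      sim <- sim_selfies_fragment(c(prefix, rep_idx[ci]), tab)
      if (!fragment_keeps_seed(sim, sf, st_, ctx$ref)) {
        cls <- which(tab$idx == idx_classes[ci])
        allowed[b, setdiff(cls, pad_col)] <- FALSE
      }
    }
  }
  allowed
}

## --- sampling core ---------------------------------------------------------

## one masked-temperature-softmax sampling step; returns actions and the
## per-row log-probability and entropy of the masked policy
sample_step <- function(logits, temperature, allowed) {
  B <- nrow(logits)
  z <- logits
  z[!allowed] <- -Inf
  p <- temperature_softmax(z, temperature)
  act <- sample_rows(p)
  lp <- log(pmax(p[cbind(seq_len(B), act)], 1e-300))
  ent <- policy_entropy(p)
  list(actions = act, logp = lp, entropy = ent, probs = p)
}

## recording variants of the eval stacks ------------------------------------

gen_stack_step_rec <- function(model, st, cols) {
  p <- model$params; bf <- model$buffers
  V <- model_vsize(model)
  x_raw <- if (ncol(cols) == 1L) one_hot(cols[, 1], V)
           else cbind(one_hot(cols[, 1], V), one_hot(cols[, 2], V))
  aff1 <- bn_eval_affine(p$bn1.gamma, p$bn1.beta, bf$bn1.rm, bf$bn1.rv)
  x <- bn_apply_affine(x_raw, aff1)
  s1 <- lstm_cell_step(x, st$h1, st$c1, p$l1.W, p$l1.U, p$l1.b)
  s2 <- lstm_cell_step(s1$h, st$h2, st$c2, p$l2.W, p$l2.U, p$l2.b)
  aff2 <- bn_eval_affine(p$bn2.gamma, p$bn2.beta, bf$bn2.rm, bf$bn2.rv)
  hbn <- bn_apply_affine(s2$h, aff2)
  logits <- hbn %*% p$lin.W + matrix(p$lin.b, nrow(hbn), ncol(p$lin.W), byrow = TRUE)
  cache <- list(x_raw = x_raw,
                l1 = list(x = x, h_prev = st$h1, c_prev = st$c1,
                          i = s1$i, f = s1$f, o = s1$o, g = s1$g, c = s1$c),
                l2 = list(x = s1$h, h_prev = st$h2, c_prev = st$c2,
                          i = s2$i, f = s2$f, o = s2$o, g = s2$g, c = s2$c),
                h2 = s2$h, hbn = hbn)
  list(st = list(h1 = s1$h, c1 = s1$c, h2 = s2$h, c2 = s2$c, B = st$B,
                 logits = logits),
       cache = cache, logits = logits)
}

## --- the generator ---------------------------------------------------------

#' Sample molecular strings from a trained model
#'
#' Draws `n` full-window rollouts at the given temperature, under the
#' model's own reading scheme, optionally constrained on a seed fragment
#' which then appears intact in every sample.
#'
#' @param model A trained [molgen()] / [molgen_model()] object.
#' @param n Number of samples.
#' @param seed_fragment Optional [seed_constraint()] (or raw string in the
#'   model's scheme).
#' @param temperature Sampling temperature.
#' @param seed Optional RNG seed for reproducibility.
#' @param record Keep per-emission records (policy log-probabilities,
#'   entropies, caches) for reinforcement learning.
#' @return data.frame of class `"molgen_samples"` with columns `core`,
#'   `seed_offset` (0-based position of the seed in the core token list, NA
#'   when unconstrained), `n_tokens`; when `record = TRUE` the rollout
#'   record is attached as attribute `"record"`.
#' @export
generate <- function(model, n, seed_fragment = NULL, temperature = 1,
                     seed = NULL, record = FALSE) {
  stopifnot(inherits(model, "molgen_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(seed_fragment) && !inherits(seed_fragment, "molgen_seed"))
    seed_fragment <- seed_constraint(seed_fragment, model$vocab$scheme)
  M <- model$m_total
  vocab <- model$vocab
  core0 <- if (is.null(seed_fragment)) vocab$start_token else seed_fragment$tokens
  n0 <- length(core0)
  if (n0 > M) stop("seed constraint longer than the model window")
  placement <- if (!is.null(seed_fragment)) seed_fragment$placement
               else model$placement
  ## span start per row
  gl <- switch(model$variant,
    forward = rep(1L, n),
    backward = rep(M - n0 + 1L, n),
    if (placement == "fixed") rep((M - n0) %/% 2L + 1L, n)
    else sample.int(M - n0 + 1L, n, replace = TRUE))
  out <- vector("list", 0)
  recs <- list()
  for (g0 in sort(unique(gl))) {
    rows <- which(gl == g0)
    r <- generate_uniform(model, length(rows), core0, g0, temperature,
                          constrained = !is.null(seed_fragment), record = record)
    r$df$.order <- rows
    out[[length(out) + 1L]] <- r$df
    if (record) {
      r$record$order <- rows
      recs[[length(recs) + 1L]] <- r$record
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$.order), setdiff(names(df), ".order"), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("molgen_samples", class(df))
  if (record) attr(df, "record") <- recs
  df
}

## uniform-span batch; core0 at columns g0..g0+n0-1
generate_uniform <- function(model, B, core0, g0, temperature, constrained,
                             record = FALSE) {
  vocab <- model$vocab
  M <- model$m_total
  V <- model_vsize(model)
  pad <- model_pad_col(model)
  n0 <- length(core0)
  sl <- g0; sr <- g0 + n0 - 1L
  ids <- matrix(pad, B, M)
  ids[, sl:sr] <- matrix(rep(vocab_ids(vocab, core0) + 1L, each = B), B)
  emissions <- list()
  chain <- list()
  add_emission <- function(...) emissions[[length(emissions) + 1L]] <<- list(...)
  ctx <- if (constrained && vocab$scheme == "SELFIES")
    guard_context(vocab, vocab_ids(vocab, core0) + 1L) else NULL
  guard <- function(t) {
    if (!constrained) matrix(TRUE, B, V)
    else guard_left(vocab, ids, t, sl, sr, ctx)
  }
  no_guard <- matrix(TRUE, B, V)
  row_lo <- function() apply(ids, 1, function(r) match(TRUE, r != pad))

  if (model$variant %in% c("forward", "backward")) {
    ## operate in reading order: forward reads columns 1..M, backward M..1
    cols_of <- function(k) if (model$variant == "forward") k else M - k + 1L
    st <- gen_stack_init(model, B)
    frozen <- rep(FALSE, B)
    for (k in seq_len(M - 1L)) {
      step <- gen_stack_step_rec(model, st, matrix(ids[, cols_of(k)], B, 1))
      st <- step$st
      if (record) chain[[k]] <- step$cache
      tcol <- cols_of(k + 1L)
      if (k + 1L <= n0) next                      # still reading the seed
      allowed <- if (model$variant == "backward") guard(tcol)
                 else guard_right(vocab, ids, tcol, row_lo(), sl, sr, ctx)
      allowed[, model_start_col(model)] <- allowed[, model_start_col(model)] &
        !constrained
      sm <- sample_step(step$logits, temperature, allowed)
      act <- ifelse(frozen, pad, sm$actions)
      ids[, tcol] <- act
      add_emission(kind = "chain", step = k, col = tcol,
                   active = !frozen, actions = act, logp = sm$logp,
                   entropy = sm$entropy, allowed = allowed, probs = sm$probs)
      frozen <- frozen | act == pad
    }
  } else if (model$variant == "fbrnn") {
    st <- gen_stack_init(model, B)
    frozen_r <- rep(FALSE, B); frozen_l <- rep(FALSE, B)
    S <- max(sl - 1L, M - sr)
    for (s in seq_len(S)) {
      in_r <- if (sr + s - 1L <= M) ids[, sr + s - 1L] else rep(pad, B)
      in_l <- if (sl - s + 1L >= 1L) ids[, sl - s + 1L] else rep(pad, B)
      step <- gen_stack_step_rec(model, st, cbind(in_r, in_l))
      st <- step$st
      if (record) chain[[s]] <- step$cache
      y_plus <- step$logits[, seq_len(V), drop = FALSE]
      y_minus <- step$logits[, V + seq_len(V), drop = FALSE]
      if (sr + s <= M) {
        allowed <- guard_right(vocab, ids, sr + s, row_lo(), sl, sr, ctx)
        allowed[, model_start_col(model)] <- allowed[, model_start_col(model)] &
          !constrained
        sm <- sample_step(y_plus, temperature, allowed)
        act <- ifelse(frozen_r, pad, sm$actions)
        ids[, sr + s] <- act
        add_emission(kind = "chain", step = s, col = sr + s, side = "plus",
                     active = !frozen_r, actions = act, logp = sm$logp,
                     entropy = sm$entropy, allowed = allowed, probs = sm$probs)
        frozen_r <- frozen_r | act == pad
      }
      if (sl - s >= 1L) {
        allowed <- guard(sl - s)
        allowed[, model_start_col(model)] <- allowed[, model_start_col(model)] &
          !constrained
        sm <- sample_step(y_minus, temperature, allowed)
        act <- ifelse(frozen_l, pad, sm$actions)
        ids[, sl - s] <- act
        add_emission(kind = "chain", step = s, col = sl - s, side = "minus",
                     active = !frozen_l, actions = act, logp = sm$logp,
                     entropy = sm$entropy, allowed = allowed, probs = sm$probs)
        frozen_l <- frozen_l | act == pad
      }
    }
  } else {                                        # bimodal
    sch <- schedule_bimodal(sl, sr, M)
    frozen_r <- rep(FALSE, B); frozen_l <- rep(FALSE, B)
    for (e in seq_along(sch$pos)) {
      pp <- sch$pos[e]
      fwd <- sch$side[e] == "fwd"
      rec <- bimodal_eval_logits_rec(model, ids, pp, record)
      allowed <- if (fwd) guard_right(vocab, ids, pp, row_lo(), sl, sr, ctx)
                 else guard(pp)
      allowed[, model_start_col(model)] <- allowed[, model_start_col(model)] &
        !constrained
      sm <- sample_step(rec$logits, temperature, allowed)
      frozen <- if (fwd) frozen_r else frozen_l
      act <- ifelse(frozen, pad, sm$actions)
      ids[, pp] <- act
      add_emission(kind = "bimodal", col = pp, side = sch$side[e],
                   active = !frozen, actions = act, logp = sm$logp,
                   entropy = sm$entropy, allowed = allowed, probs = sm$probs,
                   cache = rec$cache)
      if (fwd) frozen_r <- frozen_r | act == pad
      else frozen_l <- frozen_l | act == pad
    }
  }

  cores <- apply(ids, 1, function(row) strip_special(row - 1L, vocab))
  seed_off <- if (constrained) {
    apply(ids, 1, function(row) {
      nonpad <- which(row != pad & row != model_start_col(model))
      sum(nonpad < sl)
    })
  } else rep(NA_integer_, B)
  df <- data.frame(core = cores, seed_offset = seed_off,
                   n_tokens = apply(ids, 1, function(row)
                     sum(row != pad & row != model_start_col(model))),
                   stringsAsFactors = FALSE)
  list(df = df,
       record = if (record) list(ids = ids, g0 = g0, n0 = n0, sl = sl, sr = sr,
                                 emissions = emissions, chain = chain,
                                 temperature = temperature, B = B)
                else NULL)
}

## bimodal eval logits with optional cache for RL replay
bimodal_eval_logits_rec <- function(model, ids, pp, record = FALSE) {
  p <- model$params; bf <- model$buffers
  B <- nrow(ids); M <- ncol(ids); V <- model_vsize(model); H <- model$hidden
  aff1 <- bn_eval_affine(p$bn1.gamma, p$bn1.beta, bf$bn1.rm, bf$bn1.rv)
  run <- function(cols, pre) {
    h1 <- matrix(0, B, H); c1 <- h1; h2 <- h1; c2 <- h1
    caches <- if (record) vector("list", length(cols)) else NULL
    k <- 0L
    for (t in cols) {
      k <- k + 1L
      x_raw <- one_hot(ids[, t], V)
      x <- bn_apply_affine(x_raw, aff1)
      s1 <- lstm_cell_step(x, h1, c1, p[[paste0(pre, "1.W")]],
                           p[[paste0(pre, "1.U")]], p[[paste0(pre, "1.b")]])
      s2 <- lstm_cell_step(s1$h, h2, c2, p[[paste0(pre, "2.W")]],
                           p[[paste0(pre, "2.U")]], p[[paste0(pre, "2.b")]])
      if (record)
        caches[[k]] <- list(x_raw = x_raw,
                            l1 = list(x = x, h_prev = h1, c_prev = c1,
                                      i = s1$i, f = s1$f, o = s1$o, g = s1$g,
                                      c = s1$c),
                            l2 = list(x = s1$h, h_prev = h2, c_prev = c2,
                                      i = s2$i, f = s2$f, o = s2$o, g = s2$g,
                                      c = s2$c))
      h1 <- s1$h; c1 <- s1$c; h2 <- s2$h; c2 <- s2$c
    }
    list(h = h2, caches = caches)
  }
  fcols <- if (pp - 1L >= 1L) seq_len(pp - 1L) else integer(0)
  bcols <- if (pp + 1L <= M) seq(M, pp + 1L) else integer(0)
  fw <- if (length(fcols)) run(fcols, "f") else list(h = matrix(0, B, H), caches = list())
  bw <- if (length(bcols)) run(bcols, "b") else list(h = matrix(0, B, H), caches = list())
  z <- cbind(fw$h, bw$h)
  aff2 <- bn_eval_affine(p$bn2.gamma, p$bn2.beta, bf$bn2.rm, bf$bn2.rv)
  zbn <- bn_apply_affine(z, aff2)
  logits <- zbn %*% p$lin.W + matrix(p$lin.b, B, V, byrow = TRUE)
  list(logits = logits,
       cache = if (record) list(fw = fw$caches, bw = bw$caches, z = z,
                                zbn = zbn, pp = pp, fcols = fcols,
                                bcols = bcols)
              else NULL)
}

#' Sample with unique/valid/novel filtering
#'
#' Draws batches until `n_target` samples pass the chained filters (unique
#' within the batch, syntactically valid, not present in the training set)
#' or the attempt cap (`50 * n_target` draws) is reached.
#'
#' @inheritParams generate
#' @param n_target Number of filtered samples wanted.
#' @param training_set Character vector of training strings (novelty is
#'   checked on canonical structures).
#' @param batch Draw size per round.
#' @return data.frame of surviving samples with attributes `attempts` and
#'   `capped` (TRUE when the attempt cap was hit).
#' @export
sample_filtered <- function(model, n_target, seed_fragment = NULL,
                            training_set = character(0), temperature = 1,
                            seed = NULL, batch = max(64L, n_target)) {
  stopifnot(n_target >= 1)
  if (!is.null(seed)) set.seed(seed)
  train_canon <- if (length(training_set))
    unique(stats::na.omit(canonical_smiles(training_set, model$vocab$scheme)))
  else character(0)
  kept <- NULL
  seen <- character(0)
  attempts <- 0L
  cap <- 50L * n_target
  while ((is.null(kept) || nrow(kept) < n_target) && attempts < cap) {
    nb <- min(batch, cap - attempts)
    df <- generate(model, nb, seed_fragment = seed_fragment,
                   temperature = temperature)
    attempts <- attempts + nb
    df <- df[!duplicated(df$core) & !(df$core %in% seen) & nzchar(df$core), ,
             drop = FALSE]
    if (nrow(df) == 0L) next
    seen <- c(seen, df$core)
    df$valid <- mol_is_valid(df$core, model$vocab$scheme)
    df <- df[df$valid, , drop = FALSE]
    if (nrow(df) == 0L) next
    canon <- canonical_smiles(df$core, model$vocab$scheme)
    df$canonical <- canon
    df$novel <- !(canon %in% train_canon) & !is.na(canon)
    df <- df[df$novel, , drop = FALSE]
    kept <- rbind(kept, df)
  }
  capped <- is.null(kept) || nrow(kept) < n_target
  if (capped)
    warning("attempt cap reached: ", if (is.null(kept)) 0 else nrow(kept),
            " of ", n_target, " filtered samples obtained")
  if (!is.null(kept) && nrow(kept) > n_target)
    kept <- kept[seq_len(n_target), , drop = FALSE]
  attr(kept, "attempts") <- attempts
  attr(kept, "capped") <- capped
  kept
}

#' Write samples to a `.smi` file with a CSV sidecar
#'
#' @param df A [generate()]/[sample_filtered()] data.frame.
#' @param path Output `.smi` path; the sidecar gets the extension `.csv`.
#' @param scheme Recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_samples <- function(df, path, scheme) {
  writeLines(df$core, path)
  side <- df
  side$scheme <- scheme
  utils::write.csv(side, sub("\\.smi$", ".csv", path), row.names = FALSE)
  invisible(path)
}
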