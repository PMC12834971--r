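## Composite terminal reward: weighted sum of rescaled molecular quality
## terms.  QED enters raw in [0,1]; the synthetic-accessibility score (1 =
## easy ... 10 = hard) is rescaled to -(SA-1)/9 in [-1,0] so that "easier to
## synthesise" means "larger reward" on the QED scale.

#' Rescale a raw synthetic-accessibility score
#'
#' Maps the SA scale `[1, 10]` affinely onto `[0, -1]`: `-(sa - 1) / 9`.
#' Out-of-range input errors unless `clamp = TRUE`, in which case it is
#' clamped to the scale first.
#'
#' @param sa_raw Numeric vector of raw SA scores.
#' @param clamp Clamp inputs into `[1, 10]` instead of erroring.
#' @return Numeric vector in `[-1, 0]`.
#' @examples
#' sa_rescale(c(1, 5.5, 10))   # 0 -0.5 -1
#' @export
sa_rescale <- function(sa_raw, clamp = FALSE) {
  stopifnot(is.numeric(sa_raw))
  if (clamp) sa_raw <- pmin(10, pmax(1, sa_raw))
  if (any(sa_raw < 1 | sa_raw > 10, na.rm = TRUE))
    stop("raw SA score outside [1, 10]; use clamp = TRUE to clamp")
  -(sa_raw - 1) / 9 + 0     # + 0 normalizes IEEE negative zero
}

#' Drug-likeness term of the reward
#'
#' Raw QED score in `[0, 1]` through the RDKit backend; errors on invalid
#' molecules (callers decide the fallback).
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector in `[0, 1]`.
#' @export
qed_term <- function(smiles) {
  props <- mol_properties(smiles)
  if (anyNA(props$qed))
    stop("invalid molecule(s): ", paste(smiles[is.na(props$qed)], collapse = " "))
  props$qed
}

#' Reward weights
#'
#' @param w_q Weight of the QED term.
#' @param w_s Weight of the rescaled-SA term.
#' @param ... Further named weights for registered reward terms.
#' @return Named numeric vector of class `"molgen_weights"`.
#' @export
reward_weights <- function(w_q = 1, w_s = 0, ...) {
  w <- c(q = w_q, s = w_s, unlist(list(...)))
  if (all(w == 0)) stop("at least one reward weight must be nonzero")
  class(w) <- "molgen_weights"
  w
}

#' Weighted composite reward
#'
#' Linear combination `sum_l w_l * p_l` of rescaled property terms.
#'
#' @param p Named numeric vector of property terms (e.g. `c(q = .7, s = -.3)`).
#' @param w A [reward_weights()] vector (or named numeric vector).
#' @return Scalar reward.
#' @export
composite_reward <- function(p, w) {
  wn <- names(w)[unclass(w) != 0]
  missing <- setdiff(wn, names(p))
  if (length(missing))
    stop("property term(s) missing for weights: ", paste(missing, collapse = ", "))
  sum(unclass(w)[wn] * p[wn])
}

#' Score molecules with the terminal QED/SA reward
#'
#' Decodes each core string, computes QED and the rescaled SA term through
#' the RDKit backend, and combines them with `w`.  Invalid molecules receive
#' reward 0.  The reward is terminal-only: intermediate steps of a generation
#' trajectory carry reward 0.
#'
#' @param core Character vector of generated core strings.
#' @param scheme `"SMILES"` or `"SELFIES"`.
#' @param w A [reward_weights()] vector.
#' @return data.frame with `core`, `qed`, `sa` (raw), `reward`.
#' @export
score_molecules <- function(core, scheme = c("SMILES", "SELFIES"),
                            w = reward_weights(1, 0)) {
  scheme <- match.arg(scheme)
  smiles <- if (scheme == "SELFIES")
    vapply(core, function(x)
      tryCatch(selfies_decode(x), error = function(e) ""), character(1))
  else core
  props <- mol_properties(ifelse(nzchar(smiles), smiles, NA_character_))
  reward <- numeric(length(core))
  ok <- !is.na(props$qed)
  if (any(ok)) {
    ps <- sa_rescale(props$sa[ok], clamp = TRUE)
    reward[ok] <- vapply(which(ok), function(i)
      composite_reward(c(q = props$qed[i],
                         s = sa_rescale(min(10, max(1, props$sa[i])))), w),
      numeric(1))
  }
  data.frame(core = core, qed = props$qed, sa = props$sa, reward = reward,
             valid = ok, stringsAsFactors = FALSE)
}

#' Terminal-only reward trajectory
#'
#' @param terminal Scalar terminal reward.
#' @param n_steps Number of emission steps in the trajectory.
#' @return Numeric vector of per-step rewards: zeros, then `terminal`.
#' @export
reward_trajectory <- function(terminal, n_steps) {
  stopifnot(n_steps >= 1)
  c(rep(0, n_steps - 1L), terminal)
}

## --- reward registry -------------------------------------------------------
## Additional terminal rewards (e.g. cheap toy rewards for tests) plug in by
## name; a reward function maps (cores, scheme) -> numeric vector.

reward_registry <- new.env(parent = emptyenv())

#' Register / fetch a named terminal reward function
#'
#' A reward function has signature `function(core, scheme)` and returns one
#' terminal reward per core string.
#'
#' @param name Registry key.
#' @param fn Reward function (omit to fetch).
#' @return The reward function, invisibly for registration.
#' @export
reward_fn <- function(name, fn = NULL) {
  if (is.null(fn)) {
    f <- reward_registry[[name]]
    if (is.null(f)) stop("no reward registered under '", name, "'")
    return(f)
  }
  stopifnot(is.function(fn))
  assign(name, fn, envir = reward_registry)
  invisible(fn)
}

## default: composite QED/SA reward
reward_qed_sa <- function(w) {
  force(w)
  function(core, scheme) score_molecules(core, scheme, w)$reward
}
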