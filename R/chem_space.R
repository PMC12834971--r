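## Counting the constrained string space reachable by unidirectional vs
## bidirectional generators.  A unidirectional model extending a length-N
## constraint to length M over an L-token alphabet reaches L^(M-N) strings;
## a bidirectional one reaches about (M-N+1) times more (the constraint can
## sit at any offset).  The exact size of "length-M strings containing the
## pattern" is computed by a KMP-automaton dynamic program, verifiable by
## brute force; the printed closed-form correction series is reported only
## through its dominant term.  Counts use arbitrary-precision integers
## (base-1e7 limbs) since L^(M-N) overflows doubles quickly.

## --- minimal big integers --------------------------------------------------

big <- function(x) {
  stopifnot(is.numeric(x), x >= 0, x == floor(x), x < 1e15)
  limbs <- integer(0)
  repeat { limbs <- c(limbs, x %% 1e7); x <- x %/% 1e7; if (x == 0) break }
  structure(list(limbs = as.numeric(limbs)), class = "molgen_bigint")
}

big_norm <- function(limbs) {
  carry <- 0
  i <- 1L
  while (i <= length(limbs) || carry > 0) {
    if (i > length(limbs)) limbs[i] <- 0
    v <- limbs[i] + carry
    limbs[i] <- v %% 1e7
    carry <- v %/% 1e7
    i <- i + 1L
  }
  while (length(limbs) > 1L && limbs[length(limbs)] == 0)
    limbs <- limbs[-length(limbs)]
  limbs
}

big_add <- function(a, b) {
  n <- max(length(a$limbs), length(b$limbs))
  la <- c(a$limbs, rep(0, n - length(a$limbs)))
  lb <- c(b$limbs, rep(0, n - length(b$limbs)))
  structure(list(limbs = big_norm(la + lb)), class = "molgen_bigint")
}

big_sub <- function(a, b) {   # requires a >= b
  stopifnot(big_cmp(a, b) >= 0)
  n <- length(a$limbs)
  la <- a$limbs
  lb <- c(b$limbs, rep(0, n - length(b$limbs)))
  borrow <- 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- la[i] - lb[i] - borrow
    borrow <- if (v < 0) { v <- v + 1e7; 1 } else 0
    out[i] <- v
  }
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  structure(list(limbs = out), class = "molgen_bigint")
}

big_mul <- function(a, b) {
  la <- a$limbs; lb <- b$limbs
  out <- numeric(length(la) + length(lb))
  for (i in seq_along(la)) {
    if (la[i] == 0) next
    ## split to keep limb products exact in doubles (< 2^53)
    prod <- la[i] * lb
    for (j in seq_along(lb)) {
      k <- i + j - 1L
      out[k] <- out[k] + prod[j]
      if (out[k] >= 9e15) { # re-normalize early to stay exact
        out[k + 1L] <- out[k + 1L] + out[k] %/% 1e7
        out[k] <- out[k] %% 1e7
      }
    }
  }
  structure(list(limbs = big_norm(out)), class = "molgen_bigint")
}

big_pow <- function(base, exp) {
  stopifnot(exp >= 0, exp == floor(exp))
  out <- big(1)
  b <- if (inherits(base, "molgen_bigint")) base else big(base)
  while (exp > 0) {
    if (exp %% 2 == 1) out <- big_mul(out, b)
    b <- big_mul(b, b)
    exp <- exp %/% 2
  }
  out
}

big_cmp <- function(a, b) {
  if (length(a$limbs) != length(b$limbs))
    return(sign(length(a$limbs) - length(b$limbs)))
  for (i in rev(seq_along(a$limbs))) {
    if (a$limbs[i] != b$limbs[i]) return(sign(a$limbs[i] - b$limbs[i]))
  }
  0L
}

#' @export
as.character.molgen_bigint <- function(x, ...) {
  limbs <- rev(x$limbs)
  paste0(c(format(limbs[1], scientific = FALSE),
           sprintf("%07d", limbs[-1])), collapse = "")
}

#' @export
as.double.molgen_bigint <- function(x, ...) sum(x$limbs * 1e7^(seq_along(x$limbs) - 1))

#' @export
print.molgen_bigint <- function(x, ...) { cat(as.character(x), "\n"); invisible(x) }

#' @export
format.molgen_bigint <- function(x, ...) as.character(x)

## --- the counts ------------------------------------------------------------

#' Constrained-space query
#'
#' @param L Alphabet size (number of distinct tokens).
#' @param M Total string length.
#' @param N Constraint length (ignored when `pattern` given).
#' @param pattern Optional explicit token vector of length `N`.
#' @return List of class `"molgen_space_query"`.
#' @export
space_query <- function(L, M, N = length(pattern), pattern = NULL) {
  stopifnot(L >= 1, M >= 1, N >= 1, N <= M)
  if (!is.null(pattern)) {
    stopifnot(length(pattern) == N, length(unique(pattern)) <= L)
  }
  structure(list(L = as.integer(L), M = as.integer(M), N = as.integer(N),
                 pattern = pattern), class = "molgen_space_query")
}

#' Strings reachable by a unidirectional generator: L^(M-N)
#'
#' @param q A [space_query()].
#' @return `molgen_bigint`.
#' @export
uni_count <- function(q) big_pow(q$L, q$M - q$N)

#' Dominant term of the bidirectional count: L^(M-N) (M-N+1)
#'
#' Positions times completions, before correcting for strings in which the
#' constraint occurs more than once.
#'
#' @param q A [space_query()].
#' @return `molgen_bigint`.
#' @export
bi_dominant_count <- function(q)
  big_mul(big_pow(q$L, q$M - q$N), big(q$M - q$N + 1L))

#' Exact number of length-M strings containing a pattern
#'
#' Counts, over an explicit alphabet, the strings of length `M` that contain
#' `pattern` as a contiguous substring at least once: `L^M` minus the
#' avoiding strings, where avoidance is counted by a dynamic program over the
#' states of the KMP failure-function automaton of the pattern.
#'
#' @param pattern Character vector of tokens (non-empty).
#' @param alphabet Character vector of distinct tokens containing the pattern
#'   tokens.
#' @param M Total string length, `M >= length(pattern)`.
#' @return `molgen_bigint`.
#' @examples
#' bi_exact_count(c("a", "b"), c("a", "b"), 4)   # 11
#' @export
bi_exact_count <- function(pattern, alphabet, M) {
  stopifnot(length(pattern) >= 1, M >= length(pattern),
            !anyDuplicated(alphabet), all(pattern %in% alphabet))
  N <- length(pattern)
  L <- length(alphabet)
  ## KMP failure function
  fail <- integer(N)
  k <- 0L
  for (i in seq_len(N)[-1]) {
    while (k > 0L && pattern[k + 1L] != pattern[i]) k <- fail[k]
    if (pattern[k + 1L] == pattern[i]) k <- k + 1L
    fail[i] <- k
  }
  ## automaton over states 0..N-1 (matched prefix length), absorbing at N
  delta <- matrix(0L, nrow = N, ncol = L)   # state x symbol -> next state
  for (s in 0:(N - 1L)) {
    for (a in seq_len(L)) {
      k <- s
      while (k > 0L && pattern[k + 1L] != alphabet[a]) k <- fail[k]
      if (pattern[k + 1L] == alphabet[a]) k <- k + 1L
      delta[s + 1L, a] <- k
    }
  }
  ## DP: number of length-t strings avoiding the pattern, per state
  ways <- c(list(big(1)), rep(list(big(0)), N - 1L))
  for (t in seq_len(M)) {
    nxt <- rep(list(big(0)), N)
    for (s in seq_len(N)) {
      if (big_cmp(ways[[s]], big(0)) == 0) next
      for (a in seq_len(L)) {
        s2 <- delta[s, a]
        if (s2 < N) nxt[[s2 + 1L]] <- big_add(nxt[[s2 + 1L]], ways[[s]])
      }
    }
    ways <- nxt
  }
  avoid <- Reduce(big_add, ways)
  big_sub(big_pow(L, M), avoid)
}

#' Is a token pattern aperiodic?
#'
#' `TRUE` iff no proper divisor-length period tiles the pattern exactly
#' (e.g. `ABCABC` is periodic, `ABCABCA` is not).
#'
#' @param pattern Character vector of tokens.
#' @return Logical.
#' @export
check_aperiodicity <- function(pattern) {
  n <- length(pattern)
  stopifnot(n >= 1)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n %/% 2)) {
    if (n %% d != 0L) next
    if (all(pattern == rep_len(pattern[seq_len(d)], n))) return(FALSE)
  }
  TRUE
}

#' All three constrained-space counts
#'
#' @param q A [space_query()] (with `pattern` for the exact count; without a
#'   pattern the exact count uses a maximally aperiodic default pattern of
#'   distinct leading tokens, matching the regime Eq-counting assumes).
#' @param alphabet Optional explicit alphabet (defaults to `t1..tL`).
#' @return List with `uni`, `bi_dominant`, `bi_exact` (`molgen_bigint`), and
#'   the query.
#' @export
space_counts <- function(q, alphabet = NULL) {
  stopifnot(inherits(q, "molgen_space_query"))
  if (is.null(alphabet)) alphabet <- paste0("t", seq_len(q$L))
  pattern <- q$pattern
  if (is.null(pattern)) pattern <- rep_len(alphabet, q$N)
  out <- list(uni = uni_count(q),
              bi_dominant = bi_dominant_count(q),
              bi_exact = bi_exact_count(pattern, alphabet, q$M),
              query = q)
  class(out) <- "molgen_space_counts"
  out
}

#' @export
print.molgen_space_counts <- function(x, ...) {
  cat(sprintf("constrained space (L=%d, M=%d, N=%d):\n", x$query$L, x$query$M,
              x$query$N))
  cat("  unidirectional     ", as.character(x$uni), "\n")
  cat("  bidirectional (dom)", as.character(x$bi_dominant), "\n")
  cat("  containment (exact)", as.character(x$bi_exact), "\n")
  invisible(x)
}
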