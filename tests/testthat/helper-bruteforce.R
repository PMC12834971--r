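## Exhaustive-enumeration oracle for substring containment counts.

## number of length-m strings over 1..L containing `pattern` (integer vector)
brute_force_contain <- function(pattern, L, m) {
  n <- length(pattern)
  if (n > m) return(0)
  grid <- as.matrix(expand.grid(rep(list(seq_len(L)), m)))
  hit <- rep(FALSE, nrow(grid))
  for (j in seq_len(m - n + 1)) {
    match_j <- rep(TRUE, nrow(grid))
    for (k in seq_len(n)) match_j <- match_j & grid[, j + k - 1] == pattern[k]
    hit <- hit | match_j
  }
  sum(hit)
}

## all patterns of length 1..max_n over alphabet 1..L
all_patterns <- function(L, max_n) {
  out <- list()
  for (n in seq_len(max_n)) {
    g <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
    for (r in seq_len(nrow(g))) out[[length(out) + 1L]] <- g[r, ]
  }
  out
}
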