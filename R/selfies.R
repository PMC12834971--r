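## SELFIES encoder/decoder (v2-style semantics, achiral organic subset).
##
## The decoder is a derivation automaton: every token sequence over the
## alphabet decodes to a molecule that respects the valence table, which is
## what makes randomly sampled SELFIES strings chemically valid.  Overloading
## is implemented exactly as in the reference scheme: the L symbols following
## a [BranchL]/[RingL]-family symbol are re-read as base-16 index symbols, a
## branch of Q+1 symbols is derived from the branching atom with a capped
## derivation state, and rings bond the current atom to the atom Q+1 places
## back in the derivation order, capped by both remaining valences.

SELFIES_INDEX_ALPHABET <- c("[C]", "[Ring1]", "[Ring2]",
                            "[Branch1]", "[=Branch1]", "[#Branch1]",
                            "[Branch2]", "[=Branch2]", "[#Branch2]",
                            "[O]", "[N]", "[=N]", "[=C]", "[#C]", "[S]", "[P]")

selfies_index_of <- function(token) {
  i <- match(token, SELFIES_INDEX_ALPHABET)
  if (is.na(i)) 0L else i - 1L
}

selfies_index_tokens <- function(q, l) {
  ## base-16 digits of q, most significant first, padded to length l
  digits <- integer(l)
  for (j in seq(l, 1L)) { digits[j] <- q %% 16L; q <- q %/% 16L }
  if (q > 0L) stop("index ", q, " does not fit in ", l, " symbols")
  SELFIES_INDEX_ALPHABET[digits + 1L]
}

parse_selfies_atom <- function(token) {
  m <- regmatches(token, regexec("^\\[([=#]?)([A-Z][a-z]?)\\]$", token))[[1]]
  if (length(m) == 0L || !(m[3] %in% names(MOLGEN_VALENCE))) return(NULL)
  list(order = c(1L, 2L, 3L)[match(m[2], c("", "=", "#"))], elem = m[3])
}

parse_selfies_special <- function(token) {
  m <- regmatches(token, regexec("^\\[([=#]?)(Branch|Ring)([1-3])\\]$", token))[[1]]
  if (length(m) == 0L) return(NULL)
  list(order = c(1L, 2L, 3L)[match(m[2], c("", "=", "#"))],
       kind = m[3], l = as.integer(m[4]))
}

#' Decode a SELFIES string to a SMILES string
#'
#' Implements the SELFIES derivation rules for the achiral organic subset
#' (`B C N O P S F Cl Br I` with optional `=`/`#` bond prefixes,
#' `[Branch1..3]`, `[Ring1..2]` families and index-symbol overloading).
#' Any token sequence over this alphabet derives a valence-correct molecule;
#' symbols that cannot be applied in the current derivation state are
#' skipped, as in the reference automaton.
#'
#' @param s SELFIES string, or a character vector of `[...]` tokens.
#' @return Kekulized SMILES string; `""` if no atom could be derived.
#' @examples
#' selfies_decode("[C][C][N][C][C][N][Ring1][=Branch1]")  # piperazine
#' @export
selfies_decode <- function(s) {
  tokens <- if (length(s) == 1L) tokenize_selfies(s) else as.character(s)
  st <- new.env()
  st$atoms <- character(0)
  st$bonds <- list()
  st$free <- numeric(0)     # remaining valence per atom
  add_atom <- function(elem) {
    st$atoms <- c(st$atoms, elem)
    st$free <- c(st$free, MOLGEN_VALENCE[[elem]])
    length(st$atoms)
  }
  add_bond <- function(a, b, order) {
    st$bonds[[length(st$bonds) + 1L]] <- c(a, b, order)
    st$free[a] <- st$free[a] - order
    st$free[b] <- st$free[b] - order
  }
  ## derive tokens[i..] attached to `anchor` with derivation state `state`
  ## (max order of the next bond from anchor); anchor NA = fresh fragment.
  derive <- function(tokens, anchor, state) {
    i <- 1L
    current <- anchor
    n <- length(tokens)
    while (i <= n) {
      tok <- tokens[i]
      atom <- parse_selfies_atom(tok)
      if (!is.null(atom)) {
        if (!is.na(current) && state == 0L) break  # saturated: rest dropped
        idx <- add_atom(atom$elem)
        if (!is.na(current)) {
          order <- min(atom$order, state, MOLGEN_VALENCE[[atom$elem]])
          add_bond(current, idx, order)
        }
        current <- idx
        state <- st$free[idx]
        i <- i + 1L
        next
      }
      sp <- parse_selfies_special(tok)
      if (is.null(sp)) stop("unknown SELFIES token: ", tok)
      if (sp$kind == "Branch") {
        if (is.na(current) || state <= 1L || i + sp$l > n) {
          ## infeasible (or truncated) branch symbol: dropped singly; its
          ## would-be index symbols are re-examined as ordinary symbols, so
          ## any string containing an atom token derives a non-empty
          ## molecule
          i <- i + 1L
          next
        }
        q <- 0L
        for (j in seq_len(sp$l))
          q <- q * 16L + selfies_index_of(tokens[i + j])
        content_from <- i + sp$l + 1L
        content_to <- min(n, content_from + q)       # Q+1 symbols
        i <- content_to + 1L
        if (content_from > n) break                  # truncated branch: stop
        binit <- min(state - 1L, sp$order)
        derive(tokens[content_from:content_to], current, binit)
        ## rings formed inside the branch may have consumed valence of the
        ## branching atom itself; re-sync with its true remaining capacity
        state <- max(0L, min(state - binit, st$free[current]))
        next
      }
      ## Ring
      if (is.na(current) || state == 0L || i + sp$l > n) {
        i <- i + 1L                                  # dropped singly, as above
        next
      }
      q <- 0L
      for (j in seq_len(sp$l)) q <- q * 16L + selfies_index_of(tokens[i + j])
      i <- i + sp$l + 1L
      target <- max(1L, current - (q + 1L))
      if (target == current) next
      order <- min(sp$order, state, st$free[target])
      if (order >= 1L) {
        ## merge with an existing bond if one is already present
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
  derive(tokens, NA_integer_, 0L)
  if (length(st$atoms) == 0L) return("")
  bonds <- if (length(st$bonds)) as.data.frame(do.call(rbind, st$bonds))
           else data.frame(a = integer(0), b = integer(0), order = integer(0))
  names(bonds) <- c("a", "b", "order")
  write_smiles(list(atoms = st$atoms, bonds = bonds))
}

#' Encode a kekulized SMILES string as SELFIES
#'
#' Follows the SMILES traversal order: atoms become `[atom]` tokens with the
#' incoming bond as `=`/`#` prefix, each ring closure becomes a
#' `[RingL]` + index-symbol pair emitted at the closing atom, and each SMILES
#' branch becomes a `[BranchL]` block whose index symbols encode the token
#' length of the branch content.
#'
#' @param s Kekulized SMILES string ([parse_smiles()] subset).
#' @return SELFIES string.
#' @examples
#' selfies_encode("CC(=O)N")   # "[C][C][=Branch1][C][=O][N]"
#' @export
selfies_encode <- function(s) {
  tokens <- tokenize_smiles(s)
  ## build a nested structure in SMILES order
  ## node: list(elem, bond (to parent), rings = list(c(open_atom_seq, order)),
  ##            children = list(node), seq = atom sequence number)
  st <- new.env(); st$seq <- 0L
  ring_open <- new.env(hash = TRUE)
  parse_chain <- function(pos, parent_seq) {
    ## returns list(nodes = list of sibling-chain nodes, next_pos)
    nodes <- list(); pending <- 0L
    current <- NULL
    i <- pos
    while (i <= length(tokens)) {
      tok <- tokens[i]
      if (tok == ")") { i <- i + 1L; break }
      if (tok == "(") {
        if (is.null(current)) stop("branch before any atom: ", s)
        sub <- parse_chain(i + 1L, current$seq)
        current$children <- c(current$children, list(sub$nodes))
        i <- sub$next_pos
      } else if (tok %in% c("-", "=", "#")) {
        pending <- bond_order_of(tok); i <- i + 1L
      } else if (tok %in% names(MOLGEN_VALENCE)) {
        st$seq <- st$seq + 1L
        node <- new.env()
        node$elem <- tok; node$bond <- if (pending) pending else 1L
        node$rings <- list(); node$children <- list(); node$seq <- st$seq
        node$chain <- NULL
        if (!is.null(current)) current$chain <- node else nodes <- c(nodes, list(node))
        current <- node
        pending <- 0L; i <- i + 1L
      } else if (grepl("^%?[0-9]+$", tok)) {
        d <- sub("^%", "", tok)
        if (is.null(current)) stop("ring closure before any atom: ", s)
        if (is.null(ring_open[[d]])) {
          ring_open[[d]] <- list(seq = current$seq, order = pending, node = current)
        } else {
          op <- ring_open[[d]]
          order <- max(op$order, pending, 1L)
          current$rings <- c(current$rings, list(c(op$seq, order)))
          rm(list = d, envir = ring_open)
        }
        pending <- 0L; i <- i + 1L
      } else if (grepl("^[bcnops]$", tok)) {
        stop("aromatic SMILES atom '", tok, "'; kekulize first ",
             "(see kekulize_smiles()): ", s)
      } else {
        stop("unsupported SMILES token '", tok, "' for SELFIES encoding: ", s)
      }
    }
    list(nodes = nodes, next_pos = i)
  }
  parsed <- parse_chain(1L, NA)
  if (length(ls(ring_open))) stop("unclosed ring bond in SMILES: ", s)
  if (length(parsed$nodes) != 1L)
    stop("disconnected or empty SMILES cannot be SELFIES-encoded: ", s)

  branch_symbol <- function(order, q) {
    l <- if (q < 16) 1L else if (q < 256) 2L else 3L
    c(paste0("[", c("", "=", "#")[order], "Branch", l, "]"),
      selfies_index_tokens(q, l))
  }
  ring_symbol <- function(order, q) {
    l <- if (q < 16) 1L else 2L
    c(paste0("[", c("", "=", "#")[order], "Ring", l, "]"),
      selfies_index_tokens(q, l))
  }
  emit_node <- function(node, first) {
    prefix <- if (first) "" else c("", "=", "#")[node$bond]
    out <- paste0("[", prefix, node$elem, "]")
    for (r in node$rings)
      out <- c(out, ring_symbol(r[2], node$seq - r[1] - 1L))
    for (br in node$children) {
      content <- emit_chain(br[[1]], branch_head = TRUE)
      out <- c(out, branch_symbol(br[[1]]$bond, length(content) - 1L), content)
    }
    if (!is.null(node$chain)) out <- c(out, emit_node(node$chain, FALSE))
    out
  }
  emit_chain <- function(node, branch_head = FALSE) emit_node(node, first = FALSE)
  ## top-level first atom has no incoming bond
  root <- parsed$nodes[[1]]
  out <- emit_node(root, first = TRUE)
  paste0(out, collapse = "")
}

#' Convert a molecular string between SMILES and SELFIES
#'
#' @param s Input string, valid under `from`.
#' @param from,to `"SMILES"` or `"SELFIES"`.
#' @return The converted string (unchanged if `from == to`).
#' @export
convert_encoding <- function(s, from = c("SMILES", "SELFIES"),
                             to = c("SMILES", "SELFIES")) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == to) return(s)
  if (from == "SMILES") selfies_encode(s) else selfies_decode(s)
}
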