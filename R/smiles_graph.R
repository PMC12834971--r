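## Minimal kekulized-SMILES molecular graph layer.
##
## Supports the organic subset written in upper case (B, C, N, O, P, S, F,
## Cl, Br, I), explicit bond orders -, =, #, branches, and ring closures
## (digits and %nn).  Aromatic lower-case SMILES are rejected here; callers
## that may see them kekulize first through the RDKit worker.  This is the
## substrate for the SELFIES codec and for seed-fragment diagnostics; full
## chemistry (validity, canonicalisation) is still delegated to RDKit.

MOLGEN_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
                    F = 1, Cl = 1, Br = 1, I = 1)

bond_order_of <- function(sym) switch(sym, "-" = 1L, "=" = 2L, "#" = 3L,
                                      stop("unsupported bond symbol: ", sym))
bond_symbol_of <- function(order) c("", "=", "#")[order]

#' Parse a kekulized SMILES string into a molecular graph
#'
#' @param s SMILES string (upper-case organic subset, no aromatic atoms, no
#'   bracket atoms, no stereo).
#' @return List with `atoms` (character vector of element symbols, in SMILES
#'   order) and `bonds` (data.frame `a`, `b`, `order`; `a < b` not enforced,
#'   `a` is the earlier atom).
#' @export
parse_smiles <- function(s) {
  tokens <- tokenize_smiles(s)
  atoms <- character(0)
  bonds <- list()
  stack <- integer(0)        # open branch anchors
  prev <- NA_integer_        # current attachment atom
  pending <- 0L              # bond order announced by -, =, #
  ring_open <- list()        # digit -> list(atom, order)
  add_bond <- function(a, b, order) bonds[[length(bonds) + 1L]] <<- c(a, b, order)
  for (tok in tokens) {
    if (tok %in% names(MOLGEN_VALENCE)) {
      atoms <- c(atoms, tok)
      idx <- length(atoms)
      if (!is.na(prev)) add_bond(prev, idx, if (pending) pending else 1L)
      prev <- idx
      pending <- 0L
    } else if (tok %in% c("-", "=", "#")) {
      pending <- bond_order_of(tok)
    } else if (tok == "(") {
      if (is.na(prev)) stop("branch before any atom in SMILES: ", s)
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", s)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("^%?[0-9]+$", tok)) {
      digit <- sub("^%", "", tok)
      if (is.na(prev)) stop("ring closure before any atom in SMILES: ", s)
      if (is.null(ring_open[[digit]])) {
        ring_open[[digit]] <- list(atom = prev, order = pending)
      } else {
        op <- ring_open[[digit]]
        order <- max(op$order, pending, 1L)
        if (op$order && pending && op$order != pending)
          stop("conflicting ring bond orders for closure ", digit, " in ", s)
        add_bond(op$atom, prev, order)
        ring_open[[digit]] <- NULL
      }
      pending <- 0L
    } else if (grepl("^\\[", tok) || tok %in% letters || grepl("^[a-z]$", tok)) {
      stop("unsupported SMILES token '", tok,
           "' (aromatic or bracket atoms; kekulize first): ", s)
    } else {
      stop("unsupported SMILES token '", tok, "' in ", s)
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES: ", s)
  if (length(Filter(Negate(is.null), ring_open)))
    stop("unclosed ring bond in SMILES: ", s)
  if (length(atoms) == 0L) stop("no atoms in SMILES: ", s)
  bonds <- if (length(bonds))
    as.data.frame(do.call(rbind, bonds)) else data.frame(a = integer(0), b = integer(0), order = integer(0))
  names(bonds) <- c("a", "b", "order")
  list(atoms = atoms, bonds = bonds)
}

## bonds incident to each atom, as total bond order
atom_bond_orders <- function(graph) {
  used <- numeric(length(graph$atoms))
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      used[graph$bonds$a[k]] <- used[graph$bonds$a[k]] + graph$bonds$order[k]
      used[graph$bonds$b[k]] <- used[graph$bonds$b[k]] + graph$bonds$order[k]
    }
  }
  used
}

#' Write a molecular graph back to a kekulized SMILES string
#'
#' Depth-first traversal from the first atom; non-tree bonds become ring
#' closures with the smallest free digit.
#'
#' @param graph As returned by [parse_smiles()].
#' @return SMILES string.
#' @export
write_smiles <- function(graph) {
  n <- length(graph$atoms)
  adj <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds$a[k]; b <- graph$bonds$b[k]; o <- graph$bonds$order[k]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  env <- new.env()
  env$visited <- logical(n)
  env$tree_children <- vector("list", n)   # per atom: list of c(child, order)
  env$back_edges <- list()                 # c(opening_atom, closing_atom, order)
  env$open_at <- vector("list", n)         # preorder bookkeeping for digits
  dfs <- function(u) {                     # preorder == emit order
    env$visited[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      v <- nb[k, 1]; o <- nb[k, 2]
      if (env$visited[v]) {
        ## record once, at the later (closing) end
        dup <- any(vapply(env$back_edges, function(e)
          (e[1] == v && e[2] == u) || (e[1] == u && e[2] == v), logical(1)))
        already_tree <- any(vapply(env$tree_children[[v]], function(ch)
          ch[1] == u, logical(1)))
        if (!dup && !already_tree)
          env$back_edges[[length(env$back_edges) + 1L]] <- c(v, u, o)
      } else {
        env$tree_children[[u]] <- c(env$tree_children[[u]], list(c(v, o)))
        dfs(v)
      }
    }
  }
  roots <- integer(0)
  for (root in seq_len(n)) if (!env$visited[root]) { roots <- c(roots, root); dfs(root) }
  ring_marks <- vector("list", n)          # per atom: list of c(digit, order)
  for (i in seq_along(env$back_edges)) {
    e <- env$back_edges[[i]]
    d <- i                                  # digits unique per closure; <= 99 supported
    if (d > 99) stop("more than 99 ring closures")
    ring_marks[[e[1]]] <- c(ring_marks[[e[1]]], list(c(d, e[3])))
    ring_marks[[e[2]]] <- c(ring_marks[[e[2]]], list(c(d, e[3])))
  }
  digit_str <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)
  emit <- function(u) {
    out <- graph$atoms[u]
    for (m in ring_marks[[u]]) out <- paste0(out, bond_symbol_of(m[2]), digit_str(m[1]))
    ch <- env$tree_children[[u]]
    if (length(ch)) {
      for (k in seq_along(ch)) {
        v <- ch[[k]][1]; o <- ch[[k]][2]
        part <- paste0(bond_symbol_of(o), emit(v))
        out <- paste0(out, if (k < length(ch)) paste0("(", part, ")") else part)
      }
    }
    out
  }
  paste(vapply(roots, emit, character(1)), collapse = ".")
}
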