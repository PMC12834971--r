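## RDKit/scikit-learn backend: a persistent Python worker spoken to over a
## JSON-lines protocol.  All chemistry primitives that are not string
## mechanics (validity, canonical SMILES, QED, SA, Morgan bits, substructure
## matches, kekulisation, t-SNE) go through here in batches.

the <- new.env(parent = emptyenv())

worker_script <- function() {
  path <- system.file("python", "chem_worker.py", package = "molgen")
  if (!nzchar(path)) path <- file.path("inst", "python", "chem_worker.py")
  normalizePath(path, mustWork = TRUE)
}

chem_worker <- function() {
  p <- the$worker
  if (!is.null(p) && p$is_alive()) return(p)
  p <- processx::process$new("python", c("-u", worker_script()),
                             stdin = "|", stdout = "|", stderr = "|")
  the$worker <- p
  res <- chem_request(list(op = "ping"), timeout = 60)
  if (!isTRUE(res$pong)) stop("chemistry worker failed to start")
  p
}

chem_request <- function(req, timeout = 600) {
  ## names on payload vectors would turn JSON arrays into objects
  req <- lapply(req, function(x) if (is.null(names(x))) x else unname(x))
  p <- if (isTRUE(req$op == "ping")) the$worker else chem_worker()
  p$write_input(paste0(jsonlite::toJSON(req, auto_unbox = TRUE, null = "null",
                                        digits = NA), "\n"))
  line <- character(0)
  deadline <- Sys.time() + timeout
  buf <- ""
  repeat {
    p$poll_io(1000)
    buf <- paste0(buf, p$read_output())
    if (grepl("\n", buf, fixed = TRUE)) break
    if (!p$is_alive()) stop("chemistry worker died: ", p$read_error())
    if (Sys.time() > deadline) stop("chemistry worker timed out on op ", req$op)
  }
  line <- sub("\n.*$", "", buf)
  res <- jsonlite::fromJSON(line, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!is.null(res$error)) stop("chemistry worker error: ", res$error)
  res
}

#' Is the RDKit chemistry backend available?
#'
#' @return `TRUE` if the Python worker (RDKit + scikit-learn) can be started.
#' @export
chem_backend_available <- function() {
  ok <- tryCatch({ chem_worker(); TRUE }, error = function(e) FALSE)
  ok
}

#' Check syntactic validity of molecular strings
#'
#' SMILES strings are valid iff RDKit parses them.  SELFIES strings are first
#' decoded with [selfies_decode()] (which succeeds for any token sequence
#' over the alphabet) and are valid iff the decoded molecule is non-empty and
#' parseable.
#'
#' @param s Character vector of molecular strings.
#' @param scheme `"SMILES"` or `"SELFIES"`.
#' @return Logical vector.
#' @export
mol_is_valid <- function(s, scheme = c("SMILES", "SELFIES")) {
  scheme <- match.arg(scheme)
  if (length(s) == 0L) return(logical(0))
  if (scheme == "SELFIES") {
    dec <- vapply(s, function(x)
      tryCatch(selfies_decode(x), error = function(e) ""), character(1))
    ok <- nzchar(dec)
    out <- logical(length(s))
    if (any(ok)) out[ok] <- mol_is_valid(dec[ok], "SMILES")
    return(out)
  }
  res <- chem_request(list(op = "valid", smiles = as.list(s)))
  vapply(res$valid, isTRUE, logical(1))
}

#' Canonical SMILES for molecular strings
#'
#' @inheritParams mol_is_valid
#' @return Character vector of RDKit canonical SMILES; `NA` where invalid.
#' @export
canonical_smiles <- function(s, scheme = c("SMILES", "SELFIES")) {
  scheme <- match.arg(scheme)
  if (length(s) == 0L) return(character(0))
  if (scheme == "SELFIES")
    s <- vapply(s, function(x)
      tryCatch(selfies_decode(x), error = function(e) ""), character(1))
  res <- chem_request(list(op = "valid", smiles = as.list(s)))
  vapply(res$canonical, function(x) if (is.null(x)) NA_character_ else x,
         character(1))
}

## QED and raw SA score for SMILES; NA where invalid
mol_properties <- function(smiles) {
  if (length(smiles) == 0L)
    return(data.frame(qed = numeric(0), sa = numeric(0)))
  res <- chem_request(list(op = "props", smiles = as.list(smiles)))
  data.frame(
    qed = vapply(res$qed, function(x) if (is.null(x)) NA_real_ else x, numeric(1)),
    sa = vapply(res$sa, function(x) if (is.null(x)) NA_real_ else x, numeric(1)))
}

#' Substructure containment check
#'
#' @param smiles Character vector of molecule SMILES.
#' @param pattern A single SMILES (or SMARTS) pattern.
#' @return Logical vector (`NA` where the molecule is unparseable).
#' @export
has_substructure <- function(smiles, pattern) {
  if (length(smiles) == 0L) return(logical(0))
  res <- chem_request(list(op = "substruct", smiles = as.list(smiles),
                           pattern = pattern))
  vapply(res$match, function(x) if (is.null(x)) NA else x, logical(1))
}

#' Kekulized SMILES via RDKit
#'
#' @param smiles Character vector.
#' @return Character vector of kekulized SMILES (`NA` where invalid).
#' @export
kekulize_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  res <- chem_request(list(op = "kekulize", smiles = as.list(smiles)))
  vapply(res$smiles, function(x) if (is.null(x)) NA_character_ else x,
         character(1))
}

.onUnload <- function(libpath) {
  p <- the$worker
  if (!is.null(p) && p$is_alive()) try(p$kill(), silent = TRUE)
}
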