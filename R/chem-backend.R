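# Bridge to the RDKit worker process. All molecular primitives used by the
# package (canonical SMILES, substructure matching, SMIRKS application,
# Morgan fingerprints) go through here. The worker is a line-oriented JSON
# server started lazily and reused for the whole session.

.chem <- new.env(parent = emptyenv())

chem_worker_script <- function() {
  system.file("python", "chem_worker.py", package = "retroplan", mustWork = TRUE)
}

chem_python <- function() {
  py <- Sys.getenv("RETROPLAN_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no 'python' executable found on the PATH; the chemistry backend ",
         "requires Python with rdkit installed", call. = FALSE)
  }
  py
}

chem_worker <- function() {
  px <- .chem$proc
  if (!is.null(px) && px$is_alive()) {
    return(px)
  }
  px <- processx::process$new(
    chem_python(), c("-u", chem_worker_script()),
    stdin = "|", stdout = "|", stderr = "|"
  )
  .chem$proc <- px
  .chem$buf <- ""
  resp <- tryCatch(
    chem_request(list(op = "ping")),
    error = function(e) {
      err <- tryCatch(px$read_all_error(), error = function(e2) "")
      px$kill()
      .chem$proc <- NULL
      stop("failed to start the chemistry worker (is rdkit importable from ",
           "'python'?): ", conditionMessage(e),
           if (nzchar(err)) paste0("\nworker stderr:\n", err),
           call. = FALSE)
    }
  )
  px
}

chem_shutdown <- function() {
  px <- .chem$proc
  if (!is.null(px) && px$is_alive()) px$kill()
  .chem$proc <- NULL
  invisible(NULL)
}

chem_request <- function(req, timeout = 600) {
  px <- if (identical(req$op, "ping")) .chem$proc else chem_worker()
  payload <- jsonlite::toJSON(req, auto_unbox = TRUE, null = "null", digits = NA)
  px$write_input(paste0(payload, "\n"))
  buf <- .chem$buf
  deadline <- Sys.time() + timeout
  while (!grepl("\n", buf, fixed = TRUE)) {
    px$poll_io(200)
    chunk <- px$read_output()
    if (nzchar(chunk)) {
      buf <- paste0(buf, chunk)
      next
    }
    if (!px$is_alive()) {
      err <- tryCatch(px$read_all_error(), error = function(e) "")
      .chem$proc <- NULL
      stop("chemistry worker exited unexpectedly",
           if (nzchar(err)) paste0(":\n", err), call. = FALSE)
    }
    if (Sys.time() > deadline) stop("chemistry worker timed out", call. = FALSE)
  }
  nl <- regexpr("\n", buf, fixed = TRUE)
  line <- substr(buf, 1L, nl - 1L)
  .chem$buf <- substr(buf, nl + 1L, nchar(buf))
  resp <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) {
    stop("chemistry backend error: ", resp$error, call. = FALSE)
  }
  resp
}

# --- typed wrappers -------------------------------------------------------

chem_canon <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  res <- chem_request(list(op = "canon", smiles = as.list(smiles)))$result
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

chem_heavy <- function(smiles) {
  if (length(smiles) == 0L) return(integer(0))
  res <- chem_request(list(op = "heavy", smiles = as.list(smiles)))$result
  vapply(res, function(x) if (is.null(x)) NA_integer_ else as.integer(x), integer(1))
}

chem_nfrag <- function(smiles) {
  if (length(smiles) == 0L) return(integer(0))
  res <- chem_request(list(op = "nfrag", smiles = as.list(smiles)))$result
  vapply(res, function(x) if (is.null(x)) NA_integer_ else as.integer(x), integer(1))
}

chem_match <- function(smarts, smiles) {
  if (length(smiles) == 0L) return(logical(0))
  res <- chem_request(list(op = "match", smarts = smarts,
                           smiles = as.list(smiles)))$result
  vapply(res, function(x) if (is.null(x)) NA else isTRUE(x), logical(1))
}

# one row of logicals per SMARTS pattern
chem_match_many <- function(smarts, smiles) {
  if (length(smarts) == 0L || length(smiles) == 0L) {
    return(matrix(logical(0), nrow = length(smarts), ncol = length(smiles)))
  }
  res <- chem_request(list(op = "match_many", smarts = as.list(smarts),
                           smiles = as.list(smiles)))$result
  do.call(rbind, lapply(res, function(row) {
    vapply(row, function(x) if (is.null(x)) NA else isTRUE(x), logical(1))
  }))
}

chem_valid_smirks <- function(smirks) {
  if (length(smirks) == 0L) return(list())
  chem_request(list(op = "valid_smirks", smirks = as.list(smirks)))$result
}

# retro: one SMIRKS applied to several products; returns, per product, a list
# of reactant sets (character vectors in template reactant-pattern order)
chem_retro <- function(smirks, products) {
  if (length(products) == 0L) return(list())
  res <- chem_request(list(op = "retro", smirks = smirks,
                           products = as.list(products)))$result
  lapply(res, function(sets) lapply(sets, function(rs) unlist(rs, use.names = FALSE)))
}

# several SMIRKS applied to one product; result parallel to `smirks`
chem_retro_multi <- function(smirks, product) {
  if (length(smirks) == 0L) return(list())
  res <- chem_request(list(op = "retro_multi", smirks = as.list(smirks),
                           product = product))$result
  lapply(res, function(sets) lapply(sets, function(rs) unlist(rs, use.names = FALSE)))
}

chem_forward <- function(smirks, reactant_sets) {
  if (length(reactant_sets) == 0L) return(list())
  res <- chem_request(list(
    op = "forward", smirks = smirks,
    reactant_sets = lapply(reactant_sets, as.list)
  ))$result
  lapply(res, function(ps) as.character(unlist(ps, use.names = FALSE)))
}

# 0-based on-bit indices of folded Morgan fingerprints
chem_morgan <- function(smiles, nbits = 2048L, radius = 2L) {
  if (length(smiles) == 0L) return(list())
  res <- chem_request(list(op = "morgan", smiles = as.list(smiles),
                           nbits = nbits, radius = radius))$result
  lapply(res, function(x) {
    if (is.null(x)) NULL else as.integer(unlist(x, use.names = FALSE))
  })
}
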