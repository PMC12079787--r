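# Bridge to the bundled RDKit helper script. Results are cached per session
# keyed on (smiles, embed, seed) so repeated parses cost one process call.

.bridge_cache <- new.env(parent = emptyenv())

bridge_python <- function() {
  py <- getOption("bondbreakr.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no 'python' interpreter found on the PATH", call. = FALSE)
  py
}

bridge_script <- function() {
  p <- system.file("python", "mol_bridge.py", package = "bondbreakr")
  if (!nzchar(p)) stop("bundled mol_bridge.py not found", call. = FALSE)
  p
}

bridge_key <- function(smiles, embed, seed) {
  paste(smiles, as.integer(embed), as.integer(seed), sep = "\r")
}

#' Query the RDKit bridge for one or more molecules
#'
#' Low-level access to the bundled RDKit helper. Each query is a list with
#' `smiles`, `embed` (logical) and `seed` (integer). Results are cached for
#' the session.
#'
#' @param queries list of lists with fields `smiles`, `embed`, `seed`.
#' @return list of bridge results; a result is either the parsed molecule
#'   payload or a list with an `error` string.
#' @keywords internal
rdkit_query <- function(queries) {
  keys <- vapply(queries, function(q) bridge_key(q$smiles, q$embed, q$seed), "")
  miss <- !vapply(keys, function(k) !is.null(.bridge_cache[[k]]), TRUE)
  if (any(miss)) {
    req <- list(molecules = lapply(queries[miss], function(q) {
      list(smiles = q$smiles, embed = isTRUE(q$embed), seed = as.integer(q$seed))
    }))
    fin <- tempfile(fileext = ".json")
    fout <- tempfile(fileext = ".json")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    jsonlite::write_json(req, fin, auto_unbox = TRUE, digits = NA)
    status <- system2(bridge_python(), c(bridge_script(), fin, fout),
                      stdout = FALSE, stderr = FALSE)
    if (!identical(status, 0L) || !file.exists(fout)) {
      stop("RDKit bridge call failed (exit status ", status, ")", call. = FALSE)
    }
    res <- jsonlite::read_json(fout, simplifyVector = FALSE)$results
    mk <- keys[miss]
    for (i in seq_along(res)) .bridge_cache[[mk[i]]] <- res[[i]]
  }
  lapply(keys, function(k) .bridge_cache[[k]])
}
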