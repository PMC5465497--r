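#' Download a PDB entry (accession-gated)
#'
#' Fetches coordinates from the RCSB file server into a local cache
#' directory.  Network access is only attempted when explicitly enabled by
#' setting the environment variable `IGRAFT_FETCH_STRUCTURES=true`; all
#' core functionality and tests run on packaged or generated fixtures and
#' never download anything.
#'
#' @param accession 4-character PDB identifier, e.g. `"1H3T"`.
#' @param dir cache directory.
#' @param format `"pdb"` or `"cif"`.
#' @return path to the downloaded (or cached) file.
#' @export
fetch_structure <- function(accession, dir = tempdir(),
                            format = c("pdb", "cif")) {
  format <- match.arg(format)
  if (!structure_fetch_enabled()) {
    stop("structure download is disabled; set IGRAFT_FETCH_STRUCTURES=",
         "true to enable")
  }
  accession <- toupper(accession)
  stopifnot(grepl("^[0-9][A-Z0-9]{3}$", accession))
  dest <- file.path(dir, paste0(accession, ".", format))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.%s", accession,
                   format)
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}

#' @rdname fetch_structure
#' @export
structure_fetch_enabled <- function() {
  tolower(Sys.getenv("IGRAFT_FETCH_STRUCTURES")) %in% c("true", "1",
                                                        "yes")
}
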