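# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# md5 of an in-memory character scalar (tools::md5sum is file-based)
md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf, sep = "")
  unname(tools::md5sum(tf))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# conversion cache lives for the session; openbabel conversions are
# deterministic so memoisation is safe
.pm_cache <- new.env(parent = emptyenv())

ob_convert <- function(from, to, text) {
  key <- paste(from, to, text, sep = "\r")
  hit <- .pm_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, text))
  out <- sub("[\t\n ]+$", "", out)
  .pm_cache[[key]] <- out
  out
}

# Stereo-aware conversion through the obabel command-line tool (the
# in-process route discards tetrahedral/cis-trans stereo, which would
# corrupt full InChIKeys). Cached per session.
ob_cli_convert <- function(from, to, text) {
  key <- paste("cli", from, to, text, sep = "\r")
  hit <- .pm_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    suppressWarnings(system2("obabel", c(paste0("-i", from), paste0("-o", to)),
                             input = text, stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  out <- sub("[\t\n ]+$", "", paste(out, collapse = "\n"))
  .pm_cache[[key]] <- out
  out
}

# Convert one structure to (inchikey, canonical smiles); NA on failure.
structure_identifiers <- function(inchi = NA_character_, smiles = NA_character_) {
  src <- if (!is.na(inchi) && nzchar(inchi)) list(fmt = "inchi", txt = inchi)
         else if (!is.na(smiles) && nzchar(smiles)) list(fmt = "smi", txt = smiles)
         else return(list(inchikey = NA_character_, smiles = NA_character_))
  key <- ob_cli_convert(src$fmt, "inchikey", src$txt)
  can <- ob_cli_convert(src$fmt, "can", src$txt)
  can <- sub("\t.*$", "", can)
  if (!grepl("^[A-Z]{14}-", key)) key <- NA_character_
  if (!nzchar(can)) can <- NA_character_
  list(inchikey = key, smiles = can)
}
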