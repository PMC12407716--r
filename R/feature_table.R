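# Shared data model: the mass feature table and its companions.
#
# A feature table couples three pieces: per-feature annotation metadata
# (m/z, retention time, candidate identity, match-quality metrics), per-sample
# design metadata (organ, processing method, replicate, blank flag), and the
# features x samples intensity matrix. Missing intensities are NA until
# imputation; 0 is a legal value after imputation, so the two are kept apart.

FEATURE_COLS <- c("feature_id", "mz", "rt", "name", "inchi", "smiles",
                  "msms_score", "insilico_score", "top_confidence",
                  "msigma", "mass_error_ppm")
SAMPLE_COLS <- c("sample_id", "organ", "processing", "replicate", "is_blank")
ORGAN_LEVELS <- c("root", "seed", "none")
PROCESSING_LEVELS <- c("extract", "juice", "none")

#' Construct a mass feature table
#'
#' Bundles per-feature metadata, per-sample design metadata and the
#' intensity matrix into a validated `feature_table` object, the container
#' every other function in the package operates on.
#'
#' @param features data.frame with columns `feature_id`, `mz` (Da), `rt`
#'   (min), and optionally `name`, `inchi`, `smiles`, `msms_score`,
#'   `insilico_score`, `top_confidence`, `msigma`, `mass_error_ppm`.
#'   Missing optional columns are added as `NA`.
#' @param samples data.frame with columns `sample_id`, `organ`
#'   (`root`/`seed`/`none`), `processing` (`extract`/`juice`/`none`),
#'   `replicate` (positive integer) and `is_blank` (logical). Blanks must
#'   carry `organ = "none"` and `processing = "none"`.
#' @param intensities numeric matrix, features in rows and samples in
#'   columns, nonnegative; `NA` marks a missing (not-yet-imputed) cell.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, samples, intensities) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in setdiff(FEATURE_COLS, names(features))) {
    features[[col]] <- rep(if (col == "top_confidence") FALSE else NA,
                           nrow(features))
  }
  features <- features[FEATURE_COLS]
  features$top_confidence <- !is.na(features$top_confidence) &
    as.logical(features$top_confidence)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- samples$sample_id
  x <- structure(list(features = features, samples = samples,
                      intensities = intensities),
                 class = "feature_table")
  validate_feature_table(x)
  x
}

#' Validate a feature table's invariants
#'
#' Checks dimensional agreement, identifier uniqueness, nonnegativity of
#' intensities, the instrument m/z acquisition range (50--1300 Da), and the
#' blank-sample metadata rules. Called by the constructor; exported so
#' callers can re-check after manual surgery.
#'
#' @param x a `feature_table`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_feature_table <- function(x) {
  f <- x$features; s <- x$samples; m <- x$intensities
  if (anyDuplicated(f$feature_id))
    stopf("duplicated feature_id: %s",
          paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  if (anyDuplicated(s$sample_id))
    stopf("duplicated sample_id: %s",
          paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  if (nrow(m) != nrow(f) || ncol(m) != nrow(s))
    stopf("intensity matrix is %d x %d but there are %d features and %d samples",
          nrow(m), ncol(m), nrow(f), nrow(s))
  if (any(m < 0, na.rm = TRUE))
    stopf("negative intensities are not allowed")
  if (nrow(f) && (any(f$mz < 50 | f$mz > 1300, na.rm = TRUE) || anyNA(f$mz)))
    stopf("feature m/z must lie within the acquisition range [50, 1300] Da")
  if (nrow(f) && any(f$rt < 0, na.rm = TRUE))
    stopf("retention times must be nonnegative")
  bad_org <- !s$organ %in% ORGAN_LEVELS
  bad_pro <- !s$processing %in% PROCESSING_LEVELS
  if (any(bad_org)) stopf("unknown organ level(s): %s",
                          paste(unique(s$organ[bad_org]), collapse = ", "))
  if (any(bad_pro)) stopf("unknown processing level(s): %s",
                          paste(unique(s$processing[bad_pro]), collapse = ", "))
  if (!is.logical(s$is_blank) || anyNA(s$is_blank))
    stopf("is_blank must be TRUE/FALSE for every sample")
  blank_bad <- s$is_blank & (s$organ != "none" | s$processing != "none")
  if (any(blank_bad))
    stopf("blank samples must have organ = 'none' and processing = 'none': %s",
          paste(s$sample_id[blank_bad], collapse = ", "))
  nb_bad <- !s$is_blank & (s$organ == "none" | s$processing == "none")
  if (any(nb_bad))
    stopf("non-blank samples must have organ and processing set: %s",
          paste(s$sample_id[nb_bad], collapse = ", "))
  if (any(s$replicate < 1 | s$replicate != round(s$replicate)))
    stopf("replicate must be a positive integer")
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  nb <- sum(!x$samples$is_blank)
  cat(sprintf("feature_table: %d features x %d samples (%d blank)\n",
              nrow(x$features), nrow(x$samples), nrow(x$samples) - nb))
  miss <- sum(is.na(x$intensities))
  cat(sprintf("  missing intensity cells: %d (%.1f%%)\n", miss,
              100 * miss / max(1, length(x$intensities))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

# Subset a feature table by feature and/or sample index, keeping all three
# components aligned.
subset_feature_table <- function(x, features = NULL, samples = NULL) {
  fi <- features %||% seq_len(nrow(x$features))
  si <- samples %||% seq_len(nrow(x$samples))
  structure(list(features = x$features[fi, , drop = FALSE],
                 samples = x$samples[si, , drop = FALSE],
                 intensities = x$intensities[fi, si, drop = FALSE]),
            class = "feature_table")
}

nonblank_idx <- function(x) which(!x$samples$is_blank)
blank_idx <- function(x) which(x$samples$is_blank)

#' Read a mass feature table from CSV
#'
#' The feature CSV holds one row per mass feature: the metadata columns
#' (`feature_id`, `mz`, `rt`, then optional identity and match-quality
#' columns) followed by one intensity column per sample. The metadata CSV
#' maps `sample_id` to the design (`organ`, `processing`, `replicate`,
#' `is_blank`). Sample column order in the returned table follows the
#' metadata file. Empty cells and `NA` are read as missing intensities.
#'
#' @param path feature table CSV.
#' @param metadata_path sample metadata CSV.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, metadata_path) {
  if (!file.exists(path)) stopf("feature table file not found: %s", path)
  if (!file.exists(metadata_path)) stopf("metadata file not found: %s", metadata_path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in setdiff(SAMPLE_COLS, names(meta)))
    stopf("metadata is missing mandatory column '%s'", col)
  meta$is_blank <- as.logical(meta$is_blank)
  for (col in c("feature_id", "mz", "rt"))
    if (!col %in% names(raw)) stopf("feature table is missing mandatory column '%s'", col)
  missing_samp <- setdiff(meta$sample_id, names(raw))
  if (length(missing_samp))
    stopf("feature table is missing intensity column(s): %s",
          paste(missing_samp, collapse = ", "))
  ints <- as.matrix(raw[, meta$sample_id, drop = FALSE])
  storage.mode(ints) <- "double"
  feats <- raw[, intersect(FEATURE_COLS, names(raw)), drop = FALSE]
  feature_table(feats, meta, ints)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: writes the wide feature CSV and the
#' sample metadata CSV. Missing intensities become empty cells.
#'
#' @param x a `feature_table`.
#' @param path,metadata_path output CSV paths.
#' @return The two paths, invisibly.
#' @export
write_feature_table <- function(x, path, metadata_path) {
  wide <- cbind(x$features, as.data.frame(x$intensities, check.names = FALSE))
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  utils::write.csv(x$samples, metadata_path, row.names = FALSE, na = "")
  invisible(c(path, metadata_path))
}

#' Build a reference compound set
#'
#' A reference set is the offline stand-in for "compounds previously
#' reported in the genus": a set of InChIKey skeletons (first 14
#' characters, connectivity only -- stereochemistry-insensitive on purpose)
#' with optional source tags.
#'
#' @param keys character vector of full 27-character InChIKeys or
#'   14-character skeletons.
#' @param sources optional character vector (recycled) of source names.
#' @return An object of class `reference_set` with elements `entries`
#'   (sorted unique skeletons) and `sources` (named list skeleton -> tags).
#' @export
reference_set <- function(keys, sources = NULL) {
  keys <- toupper(trimws(keys))
  keys <- keys[nzchar(keys)]
  ok_full <- grepl("^[A-Z]{14}-[A-Z]{8,10}-[A-Z]$", keys)
  ok_skel <- grepl("^[A-Z]{14}$", keys)
  bad <- which(!(ok_full | ok_skel))
  if (length(bad))
    stopf("malformed InChIKey at entry %d: '%s'", bad[1], keys[bad[1]])
  skel <- substr(keys, 1, 14)
  if (is.null(sources)) sources <- rep(NA_character_, length(skel))
  sources <- rep_len(as.character(sources), length(skel))
  tags <- split(sources, skel)
  tags <- lapply(tags, function(v) sort(unique(v[!is.na(v) & nzchar(v)])))
  entries <- sort(unique(skel))
  structure(list(entries = entries, sources = tags[entries]),
            class = "reference_set")
}

#' Read a reference compound list
#'
#' One identifier per line (full InChIKey or 14-character skeleton), with
#' an optional tab-separated source tag. Full keys are truncated to their
#' skeleton; duplicates collapse, merging source tags.
#'
#' @param path plain-text file.
#' @return A [reference_set()].
#' @export
read_reference_set <- function(path) {
  if (!file.exists(path)) stopf("reference list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) return(reference_set(character()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, "", 1L)
  srcs <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_, "")
  ok_full <- grepl("^[A-Za-z]{14}-[A-Za-z]{8,10}-[A-Za-z]$", trimws(keys))
  ok_skel <- grepl("^[A-Za-z]{14}$", trimws(keys))
  bad <- which(!(ok_full | ok_skel))
  if (length(bad))
    stopf("malformed InChIKey on line %d: '%s'", keep[bad[1]], keys[bad[1]])
  reference_set(keys, srcs)
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d compound skeleton(s)\n", length(x$entries)))
  invisible(x)
}

#' @export
length.reference_set <- function(x) length(x$entries)

#' Write analysis results to a directory with a checksum manifest
#'
#' Dispatches on object class: data frames and matrices become CSV,
#' dendrograms become Newick, everything else becomes JSON. File names are
#' the (mandatory) names of `objects`, so output naming is deterministic.
#'
#' @param objects named list of results.
#' @param path output directory (created if absent).
#' @return Invisibly, the manifest data.frame (`file`, `md5`) which is
#'   also written as `manifest.csv`.
#' @export
write_outputs <- function(objects, path) {
  if (is.null(names(objects)) || any(!nzchar(names(objects))))
    stopf("'objects' must be a fully named list")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (file.access(path, 2) != 0) stopf("directory not writable: %s", path)
  files <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    fp <- file.path(path, paste0(nm, output_ext(obj)))
    write_one_output(obj, fp)
    files <- c(files, fp)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

output_ext <- function(obj) {
  if (inherits(obj, "chem_dendrogram") || inherits(obj, "phylo")) ".nwk"
  else if (is.data.frame(obj) || is.matrix(obj)) ".csv"
  else ".json"
}

write_one_output <- function(obj, fp) {
  if (inherits(obj, "chem_dendrogram")) {
    writeLines(obj$newick, fp)
  } else if (inherits(obj, "phylo")) {
    ape::write.tree(obj, file = fp)
  } else if (is.data.frame(obj)) {
    utils::write.csv(obj, fp, row.names = FALSE, na = "")
  } else if (is.matrix(obj)) {
    df <- as.data.frame(obj, check.names = FALSE)
    df <- cbind(id = rownames(obj) %||% seq_len(nrow(obj)), df)
    utils::write.csv(df, fp, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(unclass_deep(obj), fp, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(fp)
}

# strip S3 classes so jsonlite serializes plainly
unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) lapply(unclass(x), unclass_deep) else x
}
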