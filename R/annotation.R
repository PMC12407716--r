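# Chemical annotation: identifier harmonization, classification
# bookkeeping (primary label + hybrid flag), genus-level novelty flagging,
# and the diversity/abundance aggregation tables.

#' Harmonize chemical identifiers
#'
#' For each feature with an InChI or SMILES, derives the canonical trio --
#' InChIKey, 14-character skeleton (connectivity block), canonical SMILES
#' -- via the bundled Open Babel backend. Conversion is offline and
#' deterministic. Unparseable structures are recorded (`ok = FALSE`) and
#' retained; their novelty is later unknown rather than guessed.
#'
#' @param features feature metadata data.frame (or a `feature_table`).
#' @return data.frame: `feature_id`, `inchikey`, `skeleton`, `smiles`,
#'   `ok`.
#' @export
harmonize <- function(features) {
  if (inherits(features, "feature_table")) features <- features$features
  n <- nrow(features)
  inchi <- as.character(features$inchi %||% rep(NA, n))
  smiles <- as.character(features$smiles %||% rep(NA, n))
  key <- smi <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ids <- structure_identifiers(inchi[i], smiles[i])
    key[i] <- ids$inchikey
    smi[i] <- ids$smiles
  }
  had_structure <- (!is.na(inchi) & nzchar(inchi)) |
                   (!is.na(smiles) & nzchar(smiles))
  data.frame(feature_id = features$feature_id,
             inchikey = key,
             skeleton = ifelse(is.na(key), NA_character_, substr(key, 1, 14)),
             smiles = smi,
             ok = had_structure & !is.na(key),
             stringsAsFactors = FALSE)
}

#' Resolve a primary classification from multiple labels
#'
#' Metabolites classified into more than one biosynthetic pathway (or
#' superclass) are "hybrids": they are counted once, under a primary
#' label. The primary label is the first according to `priority`
#' (alphabetical by default -- the tie-break is a documented convention,
#' not chemistry), so the result is invariant under permutation of the
#' input.
#'
#' @param raw_classes character vector of labels (possibly empty).
#' @param priority optional character vector giving a preferred order;
#'   labels not listed fall back to alphabetical order after those listed.
#' @return `list(primary, hybrid)`; empty input gives
#'   `("Unclassified", FALSE)`.
#' @export
assign_primary_class <- function(raw_classes, priority = NULL) {
  raw_classes <- unique(raw_classes[!is.na(raw_classes) & nzchar(raw_classes)])
  if (!length(raw_classes)) return(list(primary = "Unclassified", hybrid = FALSE))
  if (length(raw_classes) == 1L) return(list(primary = raw_classes, hybrid = FALSE))
  ord <- if (is.null(priority)) order(raw_classes) else {
    pos <- match(raw_classes, priority)
    pos[is.na(pos)] <- length(priority) + rank(raw_classes[is.na(pos)])
    order(pos)
  }
  list(primary = raw_classes[ord][1], hybrid = TRUE)
}

#' Flag genus-level novelty
#'
#' A compound is novel when its InChIKey skeleton is absent from the
#' reference set of previously reported genus metabolites. Matching is at
#' the skeleton (connectivity) level, so stereochemical variants of a
#' reported compound do not count as novel. A missing skeleton gives `NA`
#' (unknown), which is excluded from unreported counts downstream.
#'
#' @param skeletons character vector of 14-character skeletons (`NA` ok).
#' @param ref a [reference_set()].
#' @return Logical vector (`TRUE` = novel/unreported), `NA` where unknown.
#' @export
flag_novelty <- function(skeletons, ref) {
  stopifnot(inherits(ref, "reference_set"))
  ifelse(is.na(skeletons), NA, !skeletons %in% ref$entries)
}

#' Relative abundance of features
#'
#' Per feature: 100 x (sum of intensities over all non-blank samples) /
#' (grand sum). Percentages sum to 100 and are invariant under uniform
#' rescaling of the intensity matrix.
#'
#' @param x a curated `feature_table` (>= 1 non-blank sample).
#' @return Named numeric vector of percentages.
#' @export
relative_abundance <- function(x) {
  nb <- nonblank_idx(x)
  if (!length(nb)) stopf("no non-blank samples")
  m <- x$intensities[, nb, drop = FALSE]
  if (anyNA(m)) stopf("relative abundance requires an imputed table")
  tot <- rowSums(m)
  gs <- sum(tot)
  if (gs <= 0) stopf("grand intensity sum is zero")
  stats::setNames(100 * tot / gs, x$features$feature_id)
}

#' Annotate a feature table
#'
#' Orchestrates [harmonize()], classification resolution from a sidecar
#' table, novelty flagging against a reference set, and NP-likeness
#' scoring into one record per feature.
#'
#' @param x a `feature_table`.
#' @param classification data.frame `feature_id`, `pathway`, `superclass`
#'   (each possibly ";"-separated for multi-label metabolites), optional
#'   `class`.
#' @param reference a [reference_set()], or `NULL` to skip novelty
#'   flagging (all novelty `NA`).
#' @param priority optional label priority order for hybrids (see
#'   [assign_primary_class()]).
#' @param np_model NP-likeness model, see [np_likeness_model()]; `NULL`
#'   skips scoring.
#' @return data.frame of annotation records: identifiers, primary
#'   pathway/superclass with hybrid flags, `np_class`, `novel`,
#'   `np_likeness`.
#' @export
annotate_features <- function(x, classification, reference = NULL,
                              priority = NULL, np_model = np_likeness_model()) {
  ids <- harmonize(x$features)
  cls <- classification[match(x$features$feature_id, classification$feature_id), ,
                        drop = FALSE]
  split_multi <- function(v) strsplit(ifelse(is.na(v), "", v), ";", fixed = TRUE)
  pw <- lapply(split_multi(cls$pathway), trimws)
  sc <- lapply(split_multi(cls$superclass), trimws)
  pw_res <- lapply(pw, assign_primary_class, priority = priority)
  sc_res <- lapply(sc, assign_primary_class, priority = priority)
  novel <- if (is.null(reference)) rep(NA, nrow(ids))
           else flag_novelty(ids$skeleton, reference)
  npl <- rep(NA_real_, nrow(ids))
  if (!is.null(np_model)) {
    for (i in which(!is.na(ids$smiles))) {
      npl[i] <- tryCatch(np_likeness(ids$smiles[i], np_model),
                         error = function(e) NA_real_)
    }
  }
  data.frame(feature_id = ids$feature_id,
             inchikey = ids$inchikey,
             skeleton = ids$skeleton,
             smiles = ids$smiles,
             pathway = vapply(pw_res, `[[`, "", "primary"),
             pathway_hybrid = vapply(pw_res, `[[`, TRUE, "hybrid"),
             superclass = vapply(sc_res, `[[`, "", "primary"),
             superclass_hybrid = vapply(sc_res, `[[`, TRUE, "hybrid"),
             np_class = if (!is.null(cls$class)) as.character(cls$class)
                        else NA_character_,
             novel = novel,
             np_likeness = npl,
             stringsAsFactors = FALSE)
}

#' Chemodiversity count table
#'
#' Counts annotated metabolites per classification label, with the number
#' of unreported (novel) ones in parentheses-style companion column --
#' the layout of genus-diversity summary tables. Labels whose members
#' include hybrid classifications are suffixed `" + Hybrids"`. Rows are
#' alphabetical with `Unclassified` last. Novelty `NA` is excluded from
#' the unreported count but included in the total.
#'
#' @param records annotation records from [annotate_features()].
#' @param level `"pathway"` or `"superclass"`.
#' @param within optional pathway label: restrict to records whose primary
#'   pathway equals it (for superclass-within-pathway tables).
#' @return data.frame `label`, `total`, `unreported`.
#' @export
diversity_table <- function(records, level = c("pathway", "superclass"),
                            within = NULL) {
  level <- match.arg(level)
  if (!is.null(within)) records <- records[records$pathway %in% within, , drop = FALSE]
  if (!nrow(records))
    return(data.frame(label = character(), total = integer(),
                      unreported = integer(), stringsAsFactors = FALSE))
  lab <- records[[level]]
  hyb <- records[[paste0(level, "_hybrid")]]
  base <- sort(unique(lab))
  total <- vapply(base, function(l) sum(lab == l), 0L)
  unrep <- vapply(base, function(l)
    sum(records$novel[lab == l], na.rm = TRUE), 0L)
  has_hyb <- vapply(base, function(l) any(hyb[lab == l]), TRUE)
  shown <- ifelse(has_hyb & base != "Unclassified",
                  paste(base, "+ Hybrids"), base)
  out <- data.frame(label = shown, total = as.integer(total),
                    unreported = as.integer(unrep), stringsAsFactors = FALSE)
  ord <- order(base == "Unclassified", base)
  out[ord, , drop = FALSE]
}
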