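# Feature-table curation: identification-quality filtering, missing-value
# imputation, noise removal, blank subtraction. The end product is the
# "working" table all downstream statistics run on.

#' Curation configuration
#'
#' Thresholds driving the curation pipeline. Defaults reflect common
#' practice for QTOF feature tables: a spectral-library MS/MS match score
#' above 600 or an in-silico fragmentation score above 800 (or a
#' top-confidence structure prediction) counts as identification evidence;
#' isotope-pattern fit (mSigma) below 30 and mass accuracy within
#' +/- 2.5 ppm gate spectral quality; features never reaching 20,000
#' counts are treated as noise; 10,000 counts is the per-sample detection
#' threshold used for blank logic and presence/absence calls.
#'
#' Score and mSigma thresholds are strict (`>`/`<`); the ppm window is
#' inclusive.
#'
#' @param msms_min library MS/MS score threshold (exclusive).
#' @param insilico_min in-silico fragmentation score threshold (exclusive).
#' @param msigma_max mSigma isotope-fit ceiling (exclusive).
#' @param ppm_window mass accuracy window in ppm (inclusive, +/-).
#' @param noise_floor features whose maximum non-blank intensity is below
#'   this are removed.
#' @param detect_floor per-sample detection threshold; must not exceed
#'   `noise_floor`.
#' @param blank_rule how "higher intensities in blank samples" is judged:
#'   `"max"` compares maxima (default), `"median"` compares medians.
#' @param impute_scope replicate grouping for imputation: `"cell"` uses
#'   organ x processing cells (default), `"all"` pools every non-blank
#'   sample into one group.
#' @return A `curation_config` list.
#' @export
curation_config <- function(msms_min = 600, insilico_min = 800,
                            msigma_max = 30, ppm_window = 2.5,
                            noise_floor = 20000, detect_floor = 10000,
                            blank_rule = c("max", "median"),
                            impute_scope = c("cell", "all")) {
  blank_rule <- match.arg(blank_rule)
  impute_scope <- match.arg(impute_scope)
  vals <- c(msms_min, insilico_min, msigma_max, ppm_window,
            noise_floor, detect_floor)
  if (any(!is.finite(vals)) || any(vals < 0))
    stopf("all curation thresholds must be finite and nonnegative")
  if (detect_floor > noise_floor)
    stopf("detect_floor (%g) must not exceed noise_floor (%g)",
          detect_floor, noise_floor)
  structure(list(msms_min = msms_min, insilico_min = insilico_min,
                 msigma_max = msigma_max, ppm_window = ppm_window,
                 noise_floor = noise_floor, detect_floor = detect_floor,
                 blank_rule = blank_rule, impute_scope = impute_scope),
            class = "curation_config")
}

#' Identification-criteria filter
#'
#' A feature passes when it has at least one piece of identification
#' evidence -- a library MS/MS score above `msms_min`, an in-silico
#' fragmentation score above `insilico_min`, or a top-confidence structure
#' prediction -- AND its spectral quality holds up: mSigma below
#' `msigma_max` and absolute mass error within `ppm_window`. A missing
#' metric fails its own clause (it cannot count as evidence, and absent
#' quality metrics fail the quality gate).
#'
#' @param features data.frame of feature metadata (or a `feature_table`).
#' @param cfg a [curation_config()].
#' @return Logical vector, one element per feature.
#' @export
passes_identification <- function(features, cfg = curation_config()) {
  if (inherits(features, "feature_table")) features <- features$features
  num <- function(v) suppressWarnings(as.numeric(v))
  msms <- num(features$msms_score)
  insi <- num(features$insilico_score)
  top <- !is.na(features$top_confidence) & as.logical(features$top_confidence)
  msig <- num(features$msigma)
  ppm <- num(features$mass_error_ppm)
  evidence <- (!is.na(msms) & msms > cfg$msms_min) |
              (!is.na(insi) & insi > cfg$insilico_min) |
              top
  quality <- (!is.na(msig) & msig < cfg$msigma_max) &
             (!is.na(ppm) & abs(ppm) <= cfg$ppm_window)
  evidence & quality
}

# replicate-group factor over non-blank samples
impute_groups <- function(x, scope) {
  s <- x$samples
  if (scope == "all") factor(rep("all", nrow(s)))
  else factor(paste(s$organ, s$processing, sep = ":"))
}

#' Impute missing intensities
#'
#' Within each replicate group (organ x processing cell by default): a
#' feature missing in *all* replicates of the group gets 0 there; a
#' feature missing in only *some* replicates gets the feature's minimum
#' observed intensity across all non-blank samples, minus 1 (floored at
#' 0). Missing blank cells become 0. No missing markers remain afterwards.
#'
#' @param x a `feature_table`.
#' @param cfg a [curation_config()]; only `impute_scope` is used.
#' @return The imputed `feature_table`.
#' @export
impute_missing <- function(x, cfg = curation_config()) {
  m <- x$intensities
  nb <- nonblank_idx(x)
  if (!length(nb)) stopf("no non-blank samples to impute")
  grp <- impute_groups(subset_feature_table(x, samples = nb), cfg$impute_scope)
  if (any(table(grp) == 0)) stopf("empty replicate group")
  bl <- blank_idx(x)
  if (length(bl)) {
    mb <- m[, bl, drop = FALSE]
    mb[is.na(mb)] <- 0
    m[, bl] <- mb
  }
  sub <- m[, nb, drop = FALSE]
  # per-feature minimum over all observed non-blank cells (the "minimum
  # intensity minus 1" reference scale for partially missing groups)
  featmin <- apply(sub, 1, function(v) {
    v <- v[!is.na(v)]; if (length(v)) min(v) else NA_real_
  })
  fill <- pmax(featmin - 1, 0)
  for (g in levels(grp)) {
    cols <- which(grp == g)
    block <- sub[, cols, drop = FALSE]
    miss <- is.na(block)
    if (!any(miss)) next
    all_missing <- rowSums(!miss) == 0L
    block[miss & all_missing] <- 0
    partial <- which(rowSums(miss) > 0L & !all_missing)
    for (i in partial) block[i, miss[i, ]] <- fill[i]
    # a group fully missing while the feature is observed elsewhere still
    # counts as "absent across all replicates" of that group -> 0 above
    sub[, cols] <- block
  }
  m[, nb] <- sub
  stopifnot(!anyNA(m))
  x$intensities <- m
  x
}

#' Remove noise and blank-contaminant features
#'
#' Drops, in order: (1) features detected (>= `detect_floor`) only in
#' blank samples; (2) features whose blank intensity exceeds or equals
#' their experimental intensity (maxima compared under
#' `blank_rule = "max"`, medians under `"median"`); (3) features whose
#' maximum non-blank intensity falls below `noise_floor` (strict `<`).
#' With no blank samples present the blank rules are skipped with a
#' warning.
#'
#' @param x a `feature_table` (imputed or not; `NA` treated as absent).
#' @param cfg a [curation_config()].
#' @return `list(table, report)` where `report` tallies each removal class
#'   and maps every input feature to its disposition.
#' @export
remove_noise <- function(x, cfg = curation_config()) {
  nb <- nonblank_idx(x); bl <- blank_idx(x)
  n <- nrow(x$features)
  disposition <- rep("retained", n)
  names(disposition) <- x$features$feature_id
  m <- x$intensities
  max_nb <- apply(m[, nb, drop = FALSE], 1, function(v) {
    v <- v[!is.na(v)]; if (length(v)) max(v) else 0
  })
  if (length(bl)) {
    stat <- switch(cfg$blank_rule,
      max = function(v) { v <- v[!is.na(v)]; if (length(v)) max(v) else 0 },
      median = function(v) { v <- v[!is.na(v)]; if (length(v)) stats::median(v) else 0 })
    blank_stat <- apply(m[, bl, drop = FALSE], 1, stat)
    max_bl <- apply(m[, bl, drop = FALSE], 1, function(v) {
      v <- v[!is.na(v)]; if (length(v)) max(v) else 0
    })
    det_nb <- apply(m[, nb, drop = FALSE], 1,
                    function(v) any(!is.na(v) & v >= cfg$detect_floor))
    det_bl <- max_bl >= cfg$detect_floor
    blank_only <- det_bl & !det_nb
    disposition[blank_only] <- "blank_only"
    stat_nb <- switch(cfg$blank_rule,
      max = max_nb,
      median = apply(m[, nb, drop = FALSE], 1, stat))
    blank_dom <- disposition == "retained" & blank_stat >= stat_nb & blank_stat > 0
    disposition[blank_dom] <- "blank_dominated"
  } else {
    warnf("no blank samples: blank-only and blank-dominated rules skipped")
  }
  below <- disposition == "retained" & max_nb < cfg$noise_floor
  disposition[below] <- "below_floor"
  keep <- which(disposition == "retained")
  report <- curation_report(disposition)
  list(table = subset_feature_table(x, features = keep), report = report)
}

curation_report <- function(disposition) {
  structure(list(
    n_input = length(disposition),
    n_failed_id = sum(disposition == "failed_identification"),
    n_blank_only = sum(disposition == "blank_only"),
    n_blank_dominated = sum(disposition == "blank_dominated"),
    n_below_floor = sum(disposition == "below_floor"),
    n_retained = sum(disposition == "retained"),
    disposition = disposition), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation_report\n")
  cat(sprintf("  input features:        %d\n", x$n_input))
  cat(sprintf("  failed identification: %d\n", x$n_failed_id))
  cat(sprintf("  blank-only:            %d\n", x$n_blank_only))
  cat(sprintf("  blank-dominated:       %d\n", x$n_blank_dominated))
  cat(sprintf("  below noise floor:     %d\n", x$n_below_floor))
  cat(sprintf("  retained:              %d\n", x$n_retained))
  invisible(x)
}

#' Subtract blank background
#'
#' Per feature, subtracts the median intensity over blank samples from
#' every experimental sample, clamping negative remainders at 0, and drops
#' the blank columns. With no blanks present the table is returned
#' unchanged with a warning.
#'
#' @param x a `feature_table` (no missing values).
#' @return A `feature_table` of non-blank samples only.
#' @export
subtract_blanks <- function(x) {
  bl <- blank_idx(x)
  if (!length(bl)) {
    warnf("no blank samples: blank subtraction skipped")
    return(x)
  }
  nb <- nonblank_idx(x)
  med <- apply(x$intensities[, bl, drop = FALSE], 1, stats::median)
  out <- subset_feature_table(x, samples = nb)
  out$intensities <- pmax(sweep(out$intensities, 1, med, `-`), 0)
  out
}

#' Run the full curation pipeline
#'
#' Applies, in order: the identification-criteria filter
#' ([passes_identification()]), missing-value imputation
#' ([impute_missing()]), noise and blank-contaminant removal
#' ([remove_noise()]), and blank subtraction ([subtract_blanks()]).
#' Deterministic: identical inputs give identical outputs.
#'
#' @param x a `feature_table`.
#' @param cfg a [curation_config()].
#' @return `list(table, report)`: the working table and a
#'   `curation_report` whose dispositions partition the input features.
#' @export
curate <- function(x, cfg = curation_config()) {
  n <- nrow(x$features)
  disposition <- rep("retained", n)
  names(disposition) <- x$features$feature_id
  if (n == 0) {
    return(list(table = x, report = curation_report(disposition)))
  }
  ok <- passes_identification(x$features, cfg)
  disposition[!ok] <- "failed_identification"
  x2 <- subset_feature_table(x, features = which(ok))
  x2 <- impute_missing(x2, cfg)
  nr <- remove_noise(x2, cfg)
  disposition[names(nr$report$disposition)] <- nr$report$disposition
  out <- subtract_blanks(nr$table)
  list(table = out, report = curation_report(disposition))
}
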