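# Pipeline orchestration: simulate/read -> curate -> annotate ->
# chemospace -> stats, with a YAML-configurable entry point, provenance
# and a checksum manifest.

#' Default pipeline configuration
#'
#' Nested blocks mirroring the analysis stages. `input` either names the
#' CSV/reference files to read, or (default) requests simulation with a
#' [sim_config()] block. Any stochastic stage takes its seed from the
#' config.
#'
#' @param out_dir output directory.
#' @return Nested configuration list.
#' @export
default_config <- function(out_dir = tempfile("phytomet_run_")) {
  list(
    out_dir = out_dir,
    input = list(simulate = unclass(sim_config())),
    curation = unclass(curation_config()),
    stats = list(distance = "bray-curtis", n_perm = 999, seed = 1,
                 lfc_cut = 1, fdr_cut = 0.05, detect_floor = 10000),
    chemospace = list(linkage = "average")
  )
}

read_run_config <- function(config) {
  if (is_string(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge_lists(base, config)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input (simulation or file reading), curation,
#' annotation (skipped with a warning when no reference list is
#' available -- novelty then stays unknown), chemospace clustering of the
#' annotated structures, and comparative statistics (PCA, PERMANOVA for
#' organ, processing and the sequential organ + processing model,
#' moderated differential abundance for both factors, presence/absence
#' partitions). All outputs, a provenance record and a checksum manifest
#' are written to `out_dir`. Rerunning an identical configuration
#' reproduces identical files.
#'
#' @param config configuration list or path to a YAML file; see
#'   [default_config()].
#' @return The manifest data.frame, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_run_config(if (is_string(config)) config else config)
  notes <- character(0)

  # --- input stage
  if (!is.null(cfg$input$simulate)) {
    sc <- do.call(sim_config, cfg$input$simulate)
    sim <- simulate_feature_table(sc)
    ft <- sim$table; reference <- sim$reference; truth <- sim$truth
    classification <- data.frame(feature_id = truth$feature_id,
                                 pathway = truth$pathway,
                                 superclass = truth$superclass,
                                 stringsAsFactors = FALSE)
  } else {
    ft <- read_feature_table(cfg$input$features, cfg$input$metadata)
    truth <- NULL
    classification <- if (!is.null(cfg$input$classification))
      utils::read.csv(cfg$input$classification, stringsAsFactors = FALSE)
    else NULL
    reference <- if (!is.null(cfg$input$reference) &&
                     file.exists(cfg$input$reference))
      read_reference_set(cfg$input$reference) else NULL
  }
  if (is.null(reference)) {
    warnf("no reference compound list: novelty flagging skipped")
    notes <- c(notes, "novelty flagging skipped: no reference list")
  }

  # --- curation
  ccfg <- do.call(curation_config,
                  cfg$curation[intersect(names(cfg$curation),
                                         names(formals(curation_config)))])
  cur <- curate(ft, ccfg)
  wt <- cur$table

  outputs <- list(curation_report = cur$report)

  # --- annotation
  if (!is.null(classification)) {
    ann <- annotate_features(wt, classification, reference)
    outputs$annotation_records <- ann
    outputs$diversity_pathway <- diversity_table(ann, "pathway")
    outputs$relative_abundance <- data.frame(
      feature_id = names(relative_abundance(wt)),
      percent = as.numeric(relative_abundance(wt)),
      stringsAsFactors = FALSE)
  } else {
    ann <- NULL
    notes <- c(notes, "annotation skipped: no classification table")
  }

  # --- chemospace
  if (!is.null(ann)) {
    smis <- ann$smiles[!is.na(ann$smiles)]
    ids <- ann$feature_id[!is.na(ann$smiles)]
    keep <- !duplicated(smis)
    if (sum(keep) >= 2) {
      fps <- fingerprint(stats::setNames(smis[keep], ids[keep]))
      dend <- chem_cluster(tanimoto_dissimilarity(fps),
                           linkage = cfg$chemospace$linkage)
      outputs$chemospace_dendrogram <- dend
    }
  }

  # --- statistics
  st <- cfg$stats
  dm <- sample_distance(wt, st$distance)
  s <- wt$samples
  outputs$permanova <- list(
    organ = unclass_permanova(permanova(dm, s$organ, st$n_perm, st$seed)),
    processing = unclass_permanova(permanova(dm, s$processing, st$n_perm, st$seed)),
    organ_plus_processing = unclass_permanova(
      permanova(dm, data.frame(organ = s$organ, processing = s$processing),
                st$n_perm, st$seed)),
    distance = st$distance)
  outputs$pca_scores <- pca_feature_table(wt)$scores
  for (fac in c("organ", "processing")) {
    md <- moderated_diff(wt, fac, lfc_cut = st$lfc_cut, fdr_cut = st$fdr_cut)
    outputs[[paste0("diff_", fac)]] <- md$table
    pp <- presence_partition(wt, fac, st$detect_floor)
    outputs[[paste0("presence_", fac)]] <- data.frame(
      level = c(names(pp$detected), "shared"),
      detected = c(vapply(pp$detected, length, 0L), NA),
      exclusive = c(vapply(pp$exclusive, length, 0L),
                    length(pp$shared)),
      stringsAsFactors = FALSE)
  }
  if (!is.null(truth)) outputs$ground_truth <- truth

  # --- provenance + manifest
  cfg_hashable <- cfg; cfg_hashable$out_dir <- NULL
  cfg_json <- jsonlite::toJSON(cfg_hashable, auto_unbox = TRUE, digits = NA)
  outputs$provenance <- list(
    package = "phytomet",
    version = as.character(utils::packageVersion("phytomet")),
    config_md5 = md5_string(as.character(cfg_json)),
    seed = st$seed, notes = as.list(notes))
  manifest <- write_outputs(outputs, cfg$out_dir)
  invisible(manifest)
}

unclass_permanova <- function(p) {
  list(table = p$table, n_perm = p$n_perm, seed = p$seed)
}
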