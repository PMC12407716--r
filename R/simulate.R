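# Synthetic feature-table generator.
#
# Emulates the statistical structure the analysis assumes: a 2x2 design
# (organ: root/seed x processing: extract/juice) with replicates and blank
# injections, log-normal baseline intensities with multiplicative noise,
# planted organ- and method-enrichment effects, blank-only contaminants,
# sub-noise-floor features, and random missingness -- together with a
# ground-truth sidecar and a matching reference compound set so recovery
# can be scored exactly.

#' Simulation configuration
#'
#' Defaults describe a realistic study: 540 features over a 2x2 design
#' with 3 replicates per cell and 2 blanks; baseline intensities
#' log-normal around 1e5 counts with log-sd 1; 15% multiplicative
#' coefficient of variation between replicates; 15% of features
#' organ-enriched and 10% method-enriched at log2 fold change 3; 5%
#' blank-only contaminants; 5% sub-floor noise features; 5% of cells
#' missing.
#'
#' @param n_features number of mass features.
#' @param n_reps replicates per organ x processing cell.
#' @param n_blanks number of blank samples.
#' @param baseline_log_mean,baseline_log_sd natural-log mean/sd of
#'   baseline intensity.
#' @param noise_cv replicate-level multiplicative coefficient of
#'   variation.
#' @param frac_organ_enriched,frac_method_enriched fractions of features
#'   with planted organ/method effects.
#' @param effect_log2fc planted log2 fold change.
#' @param frac_contaminant fraction of blank-only contaminant features.
#' @param frac_subfloor fraction of features kept below the noise floor.
#' @param frac_missing fraction of non-blank cells set missing.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_features = 540, n_reps = 3, n_blanks = 2,
                       baseline_log_mean = log(1e5), baseline_log_sd = 1,
                       noise_cv = 0.15,
                       frac_organ_enriched = 0.15,
                       frac_method_enriched = 0.10,
                       effect_log2fc = 3,
                       frac_contaminant = 0.05, frac_subfloor = 0.05,
                       frac_missing = 0.05, seed = 1) {
  fr <- c(frac_organ_enriched, frac_method_enriched, frac_contaminant,
          frac_subfloor)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stopf("planted fractions must lie in [0,1] and sum to at most 1")
  if (frac_missing < 0 || frac_missing > 1) stopf("frac_missing must be in [0,1]")
  if (n_features < 1 || n_reps < 1 || n_blanks < 0)
    stopf("counts must be positive (n_blanks may be 0)")
  structure(list(n_features = n_features, n_reps = n_reps,
                 n_blanks = n_blanks,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, noise_cv = noise_cv,
                 frac_organ_enriched = frac_organ_enriched,
                 frac_method_enriched = frac_method_enriched,
                 effect_log2fc = effect_log2fc,
                 frac_contaminant = frac_contaminant,
                 frac_subfloor = frac_subfloor,
                 frac_missing = frac_missing, seed = seed),
            class = "sim_config")
}

# packaged structure vocabulary: name, smiles, pathway, superclass
structure_vocabulary <- function() {
  utils::read.delim(system.file("extdata", "np_structures.tsv",
                                package = "phytomet", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

# sampling weights shaped like the biosynthetic-pathway spread of a plant
# metabolome: terpenoids dominate, then shikimates/phenylpropanoids,
# alkaloids, amino acids, polyketides, fatty acids, carbohydrates
pathway_weights <- c(
  "Terpenoids" = 213, "Shikimates and Phenylpropanoids" = 121,
  "Alkaloids" = 56, "Amino acids and Peptides" = 51,
  "Polyketides" = 38, "Fatty acids" = 24, "Carbohydrates" = 7)

#' Simulate a feature table with ground truth
#'
#' Generates intensities as `exp(N(baseline_log_mean, baseline_log_sd))`
#' per feature, multiplied by `2^(+/- effect_log2fc / 2)` in the affected
#' design cells and by log-normal replicate noise with the configured CV.
#' Contaminants are intense only in blanks; sub-floor features never reach
#' the noise floor; missingness is applied at random to non-blank cells of
#' ordinary features. Every feature carries annotation metadata (a
#' structure from the packaged vocabulary, passing match-quality metrics)
#' and the reference compound set contains exactly the structures of
#' features with `in_reference = TRUE`.
#'
#' @param cfg a [sim_config()].
#' @return `list(table, truth, reference)`: the `feature_table`, the
#'   ground-truth data.frame (`role`, `true_log2fc`, classification
#'   labels, `smiles`, `in_reference`), and the [reference_set()].
#' @export
simulate_feature_table <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    nf <- cfg$n_features
    organs <- c("root", "seed"); procs <- c("extract", "juice")
    cells <- expand.grid(organ = organs, processing = procs,
                         stringsAsFactors = FALSE)
    samp <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      data.frame(sample_id = sprintf("%s_%s_%d", substr(cells$organ[i], 1, 1),
                                     substr(cells$processing[i], 1, 1),
                                     seq_len(cfg$n_reps)),
                 organ = cells$organ[i], processing = cells$processing[i],
                 replicate = seq_len(cfg$n_reps), is_blank = FALSE,
                 stringsAsFactors = FALSE)
    }))
    if (cfg$n_blanks > 0) {
      samp <- rbind(samp, data.frame(
        sample_id = sprintf("blank_%d", seq_len(cfg$n_blanks)),
        organ = "none", processing = "none",
        replicate = seq_len(cfg$n_blanks), is_blank = TRUE,
        stringsAsFactors = FALSE))
    }
    ns <- nrow(samp)

    # feature roles
    n_org <- round(cfg$frac_organ_enriched * nf)
    n_met <- round(cfg$frac_method_enriched * nf)
    n_con <- round(cfg$frac_contaminant * nf)
    n_sub <- round(cfg$frac_subfloor * nf)
    roles <- rep("null", nf)
    idx <- sample.int(nf)
    take <- function(k) { out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out }
    org_idx <- take(n_org); met_idx <- take(n_met)
    con_idx <- take(n_con); sub_idx <- take(n_sub)
    roles[org_idx] <- sample(c("organ_enriched_root", "organ_enriched_seed"),
                             n_org, replace = TRUE)
    roles[met_idx] <- sample(c("method_enriched_extract", "method_enriched_juice"),
                             n_met, replace = TRUE)
    roles[con_idx] <- "contaminant"
    roles[sub_idx] <- "subfloor"

    # structures and classifications
    vocab <- structure_vocabulary()
    # weight per structure = pathway weight / structures in that pathway
    w_pathway <- pathway_weights[vocab$pathway]
    n_in_pw <- table(vocab$pathway)[vocab$pathway]
    w <- as.numeric(w_pathway) / as.numeric(n_in_pw)
    pick <- sample.int(nrow(vocab), nf, replace = TRUE, prob = w)
    in_ref_structure <- stats::runif(nrow(vocab)) < 0.25
    in_reference <- in_ref_structure[pick]

    feats <- data.frame(
      feature_id = sprintf("F%04d", seq_len(nf)),
      mz = round(stats::runif(nf, 80, 1200), 4),
      rt = round(stats::runif(nf, 0.5, 40), 2),
      name = vocab$name[pick],
      inchi = NA_character_,
      smiles = vocab$smiles[pick],
      msms_score = round(stats::runif(nf, 650, 950), 1),
      insilico_score = round(stats::runif(nf, 820, 990), 1),
      top_confidence = stats::runif(nf) < 0.5,
      msigma = round(stats::runif(nf, 2, 25), 1),
      mass_error_ppm = round(stats::runif(nf, -2.4, 2.4), 2),
      stringsAsFactors = FALSE)

    base <- exp(stats::rnorm(nf, cfg$baseline_log_mean, cfg$baseline_log_sd))
    log_sd <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- function(n) exp(stats::rnorm(n, -log_sd^2 / 2, log_sd))

    m <- matrix(0, nf, ns)
    nb <- which(!samp$is_blank)
    bl <- which(samp$is_blank)
    half <- cfg$effect_log2fc / 2
    for (j in nb) {
      mult <- rep(1, nf)
      up_org <- if (samp$organ[j] == "root") "organ_enriched_root" else "organ_enriched_seed"
      dn_org <- setdiff(c("organ_enriched_root", "organ_enriched_seed"), up_org)
      up_met <- if (samp$processing[j] == "extract") "method_enriched_extract" else "method_enriched_juice"
      dn_met <- setdiff(c("method_enriched_extract", "method_enriched_juice"), up_met)
      mult[roles == up_org] <- 2^half
      mult[roles == dn_org] <- 2^-half
      mult[roles == up_met] <- 2^half
      mult[roles == dn_met] <- 2^-half
      mult[roles == "contaminant"] <- 0.001   # background trace only
      m[, j] <- base * mult * noise(nf)
    }
    # sub-floor features: rescale so the max non-blank intensity sits
    # below the 20,000-count noise floor (but well above the solvent
    # background, so the planted role stays identifiable)
    for (i in sub_idx) {
      target <- stats::runif(1, 5000, 19000)
      mx <- max(m[i, nb])
      if (mx > 0) m[i, nb] <- m[i, nb] * target / mx
    }
    # blanks: faint solvent background; contaminants at full strength
    if (length(bl)) {
      for (j in bl) {
        bg <- exp(stats::rnorm(nf, log(1000), 0.5))
        bg[roles == "contaminant"] <- base[roles == "contaminant"] *
          noise(sum(roles == "contaminant"))
        m[, j] <- bg
      }
    }
    # missingness on ordinary (non-contaminant, non-subfloor) features
    ord_rows <- which(!roles %in% c("contaminant", "subfloor"))
    cells_ord <- expand.grid(i = ord_rows, j = nb)
    n_miss <- round(cfg$frac_missing * nrow(cells_ord))
    if (n_miss > 0) {
      hit <- cells_ord[sample.int(nrow(cells_ord), n_miss), ]
      m[cbind(hit$i, hit$j)] <- NA
    }

    true_lfc <- rep(0, nf)
    true_lfc[roles == "organ_enriched_seed"] <- cfg$effect_log2fc
    true_lfc[roles == "organ_enriched_root"] <- -cfg$effect_log2fc
    true_lfc[roles == "method_enriched_juice"] <- cfg$effect_log2fc
    true_lfc[roles == "method_enriched_extract"] <- -cfg$effect_log2fc

    truth <- data.frame(feature_id = feats$feature_id, role = roles,
                        true_log2fc = true_lfc,
                        pathway = vocab$pathway[pick],
                        superclass = vocab$superclass[pick],
                        smiles = vocab$smiles[pick],
                        in_reference = in_reference,
                        stringsAsFactors = FALSE)

    ref_smiles <- unique(vocab$smiles[pick][in_reference])
    ref_keys <- vapply(ref_smiles, function(s)
      structure_identifiers(smiles = s)$inchikey, "", USE.NAMES = FALSE)
    ref <- reference_set(ref_keys[!is.na(ref_keys)],
                         rep("simulated-genus-records", sum(!is.na(ref_keys))))

    list(table = feature_table(feats, samp, m), truth = truth, reference = ref)
  })
}

#' Write a small simulated fixture to disk
#'
#' Writes the feature CSV, metadata CSV, ground-truth sidecar and
#' reference list produced by [simulate_feature_table()] under `path`.
#' Regeneration with an unchanged configuration is byte-identical, so the
#' files can be checksum-pinned.
#'
#' @param cfg a [sim_config()]; the default is a compact 80-feature
#'   fixture.
#' @param path output directory.
#' @return Named md5 checksums of the four files, invisibly.
#' @export
regenerate_fixture <- function(cfg = sim_config(n_features = 80, seed = 20260101),
                               path) {
  sim <- simulate_feature_table(cfg)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(path, c("features.csv", "metadata.csv",
                          "truth.csv", "reference.txt"))
  write_feature_table(sim$table, fp[1], fp[2])
  utils::write.csv(sim$truth, fp[3], row.names = FALSE, na = "")
  src <- vapply(sim$reference$sources, function(s)
    if (length(s)) s[1] else "", "")
  writeLines(paste0(sim$reference$entries,
                    ifelse(nzchar(src), paste0("\t", src), "")), fp[4])
  invisible(stats::setNames(tools::md5sum(fp), basename(fp)))
}
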