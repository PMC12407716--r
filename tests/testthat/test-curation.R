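feat_row <- function(msms = NA, insilico = NA, top = FALSE, msigma = NA,
                     ppm = NA) {
  data.frame(feature_id = "f", mz = 200, rt = 5, msms_score = msms,
             insilico_score = insilico, top_confidence = top,
             msigma = msigma, mass_error_ppm = ppm)
}

test_that("identification criteria: OR of evidence, AND quality gate, strict boundaries", {
  cfg <- curation_config()
  expect_true(passes_identification(feat_row(msms = 700, msigma = 10, ppm = 1), cfg))
  # boundary: scores are strict >, ppm window inclusive
  expect_false(passes_identification(feat_row(msms = 600, msigma = 10, ppm = 0), cfg))
  expect_false(passes_identification(feat_row(insilico = 800, msigma = 10, ppm = 0), cfg))
  expect_true(passes_identification(feat_row(insilico = 801, msigma = 10, ppm = 2.5), cfg))
  expect_false(passes_identification(feat_row(insilico = 801, msigma = 10, ppm = 2.51), cfg))
  expect_false(passes_identification(feat_row(msms = 700, msigma = 30, ppm = 0), cfg))
  # quality gate fails despite strong in-silico evidence
  expect_false(passes_identification(feat_row(insilico = 900, msigma = 35, ppm = 0), cfg))
  # top-confidence flag is evidence on its own
  expect_true(passes_identification(feat_row(top = TRUE, msigma = 5, ppm = -2.5), cfg))
  # a missing metric fails its clause
  expect_false(passes_identification(feat_row(msms = 700, ppm = 1), cfg))   # msigma absent
  expect_false(passes_identification(feat_row(msigma = 5, ppm = 1), cfg))   # no evidence
})

test_that("imputation: all-missing group -> 0, partial -> feature minimum minus 1", {
  ft <- toy_table(3, n_reps = 3, blanks = 1)
  # feature 1: missing in all replicates of root:extract
  g1 <- which(ft$samples$organ == "root" & ft$samples$processing == "extract")
  ft$intensities[1, g1] <- NA
  # feature 2: missing in one replicate; smallest observed value 40000
  g2 <- which(ft$samples$organ == "seed" & ft$samples$processing == "juice")
  ft$intensities[2, ] <- 60000
  ft$intensities[2, g2] <- c(NA, 40000, 60000)
  out <- impute_missing(ft)
  expect_equal(unname(out$intensities[1, g1]), c(0, 0, 0))
  expect_equal(unname(out$intensities[2, g2]), c(39999, 40000, 60000))
  # fully observed feature untouched
  expect_equal(out$intensities[3, ], ft$intensities[3, ])
  expect_false(anyNA(out$intensities))
})

test_that("noise removal applies blank-only, blank-dominated and floor rules in order", {
  ft <- toy_table(4, n_reps = 2, blanks = 2, fill = 50000)
  bl <- which(ft$samples$is_blank); nb <- which(!ft$samples$is_blank)
  # f1: present only in blanks
  ft$intensities[1, nb] <- 5000; ft$intensities[1, bl] <- c(50000, 60000)
  # f2: higher in blanks than samples
  ft$intensities[2, nb] <- 80000; ft$intensities[2, bl] <- c(90000, 10)
  # f3: below the noise floor everywhere (strict <)
  ft$intensities[3, nb] <- 19999; ft$intensities[3, bl] <- 0
  # f4: clean
  ft$intensities[4, bl] <- 0
  res <- remove_noise(ft)
  expect_equal(unname(res$report$disposition[1:4]),
               c("blank_only", "blank_dominated", "below_floor", "retained"))
  expect_equal(res$report$n_retained, 1)
  expect_equal(res$table$features$feature_id, "F004")
  # exactly at the floor is retained
  ft$intensities[3, nb] <- 20000
  expect_equal(unname(remove_noise(ft)$report$disposition[3]), "retained")
})

test_that("blank subtraction removes the blank median, clamps at zero and drops blanks", {
  ft <- toy_table(2, n_reps = 1, blanks = 2, fill = 50000)
  bl <- which(ft$samples$is_blank)
  ft$intensities[1, bl] <- c(10000, 12000)   # median 11000
  ft$intensities[2, ] <- 5000
  ft$intensities[2, bl] <- c(11000, 11000)
  out <- subtract_blanks(ft)
  expect_false(any(out$samples$is_blank))
  expect_true(all(out$intensities[1, ] == 39000))
  expect_true(all(out$intensities[2, ] == 0))   # clamped, not negative
  # all-zero blanks: identity on samples
  ft$intensities[, bl] <- 0
  expect_equal(subtract_blanks(ft)$intensities,
               ft$intensities[, -bl, drop = FALSE])
  # no blanks: unchanged with a warning
  ft2 <- toy_table(2, blanks = 0)
  expect_warning(out2 <- subtract_blanks(ft2), "blank")
  expect_equal(out2$intensities, ft2$intensities)
})

test_that("curate is deterministic, partitions dispositions and never leaves NA/negative cells", {
  sim <- simulate_feature_table(sim_config(n_features = 100, seed = 11))
  r1 <- curate(sim$table)
  r2 <- curate(sim$table)
  expect_identical(r1, r2)
  rep <- r1$report
  expect_equal(rep$n_input, 100)
  expect_equal(rep$n_input,
               rep$n_failed_id + rep$n_blank_only + rep$n_blank_dominated +
                 rep$n_below_floor + rep$n_retained)
  expect_equal(sort(unique(names(rep$disposition))),
               sort(sim$table$features$feature_id))
  expect_false(anyNA(r1$table$intensities))
  expect_true(all(r1$table$intensities >= 0))
  # no-failure table keeps everything
  clean <- toy_table(4, n_reps = 2, blanks = 1, fill = 50000)
  clean$intensities[, clean$samples$is_blank] <- 0
  expect_equal(curate(clean)$report$n_retained, 4)
  # empty table gives an all-zero report
  empty <- feature_table(toy_features(0), toy_samples(1, 1),
                         matrix(0, 0, nrow(toy_samples(1, 1))))
  expect_equal(curate(empty)$report$n_input, 0)
})

test_that("raising the noise floor never increases the number of retained features", {
  sim <- simulate_feature_table(sim_config(n_features = 150, seed = 3))
  floors <- c(5000, 20000, 50000, 100000)
  kept <- vapply(floors, function(nf) {
    cfg <- curation_config(noise_floor = nf, detect_floor = min(nf, 10000))
    curate(sim$table, cfg)$report$n_retained
  }, 0)
  expect_true(all(diff(kept) <= 0))
})

test_that("planted contaminants and sub-floor features are recovered exactly", {
  sim <- simulate_feature_table(sim_config(n_features = 200, seed = 5))
  res <- curate(sim$table)
  disp <- res$report$disposition[sim$truth$feature_id]
  con <- sim$truth$role == "contaminant"
  sub <- sim$truth$role == "subfloor"
  expect_true(all(disp[con] %in% c("blank_only", "blank_dominated")))
  expect_true(all(disp[sub] %in% c("below_floor")))
  expect_gte(res$report$n_blank_only + res$report$n_blank_dominated, sum(con))
})
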