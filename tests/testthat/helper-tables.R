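# Small hand-built tables used across tests.

toy_samples <- function(n_reps = 2, blanks = 2) {
  cells <- expand.grid(organ = c("root", "seed"),
                       processing = c("extract", "juice"),
                       stringsAsFactors = FALSE)
  s <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(sample_id = sprintf("%s_%s_%d", cells$organ[i],
                                   cells$processing[i], seq_len(n_reps)),
               organ = cells$organ[i], processing = cells$processing[i],
               replicate = seq_len(n_reps), is_blank = FALSE,
               stringsAsFactors = FALSE)))
  if (blanks > 0)
    s <- rbind(s, data.frame(sample_id = paste0("blank_", seq_len(blanks)),
                             organ = "none", processing = "none",
                             replicate = seq_len(blanks), is_blank = TRUE,
                             stringsAsFactors = FALSE))
  s
}

toy_features <- function(n) {
  if (n == 0) return(toy_features(1)[0, , drop = FALSE])
  data.frame(feature_id = sprintf("F%03d", seq_len(n)),
             mz = seq(100, 900, length.out = n),
             rt = seq(1, 30, length.out = n),
             name = paste0("cmpd", seq_len(n)),
             smiles = rep(c("c1ccccc1", "CCO", "CC(=O)O"), length.out = n),
             msms_score = 700, insilico_score = 850,
             top_confidence = TRUE, msigma = 10, mass_error_ppm = 1,
             stringsAsFactors = FALSE)
}

toy_table <- function(n_features = 5, n_reps = 2, blanks = 2,
                      fill = 50000) {
  s <- toy_samples(n_reps, blanks)
  f <- toy_features(n_features)
  m <- matrix(fill, n_features, nrow(s))
  feature_table(f, s, m)
}

# brute-force one-way PERMANOVA statistics from the textbook group-sum
# formula -- the independent oracle the implementation is checked against
oracle_permanova_f <- function(d, groups) {
  n <- nrow(d)
  a <- length(unique(groups))
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    if (length(i) > 1) {
      sub <- d[i, i]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(i)
    }
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  list(f = f, r2 = ss_between / ss_total)
}

# independent recursive permutation enumerator
oracle_all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_all_perms(n - 1)) {
    for (pos in seq_len(n)) out[[length(out) + 1]] <- append(p, n, after = pos - 1)
  }
  out
}
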