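subset_ft_one <- function(ft) {
  ft$samples <- ft$samples[1, , drop = FALSE]
  ft$intensities <- ft$intensities[, 1, drop = FALSE]
  ft
}

test_that("PCA matches the reference implementation up to sign", {
  sim <- simulate_feature_table(sim_config(n_features = 80, seed = 21,
                                           frac_missing = 0))
  cur <- curate(sim$table)
  p <- pca_feature_table(cur$table)
  expect_equal(sum(p$explained_pct), 100, tolerance = 1e-6)
  # components orthogonal
  cp <- crossprod(p$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8 * max(diag(cp)))
  # reference: prcomp on the same transform
  m <- t(log2(cur$table$intensities + 1))
  m <- m[, apply(m, 2, sd) > 0, drop = FALSE]
  ref <- prcomp(m, center = TRUE, scale. = TRUE)
  k <- ncol(p$scores)
  for (j in seq_len(min(3, k))) {
    expect_lt(min(max(abs(p$scores[, j] - ref$x[, j])),
                  max(abs(p$scores[, j] + ref$x[, j]))), 1e-8)
  }
  expect_equal(p$explained_pct,
               (100 * ref$sdev^2 / sum(ref$sdev^2))[seq_len(k)],
               tolerance = 1e-8)
  # duplicated samples land on the same score point
  ft <- cur$table
  ft$intensities[, 2] <- ft$intensities[, 1]
  p2 <- pca_feature_table(ft)
  expect_equal(unname(p2$scores[1, ]), unname(p2$scores[2, ]), tolerance = 1e-8)
  expect_error(pca_feature_table(subset_ft_one(cur$table)), "2 samples")
})

test_that("bray-curtis and euclidean distances match hand values", {
  s <- data.frame(sample_id = c("s1", "s2"), organ = c("root", "seed"),
                  processing = "extract", replicate = 1, is_blank = FALSE)
  f <- toy_features(2)
  ft <- feature_table(f, s, matrix(c(1, 0, 0, 1) * 1e5, 2, 2))
  d <- sample_distance(ft, "bray-curtis")
  expect_equal(d["s1", "s2"], 1)          # disjoint
  ft2 <- feature_table(f, s, matrix(c(2, 2, 1, 1), 2, 2))
  expect_equal(sample_distance(ft2, "bray-curtis")["s1", "s2"], 1 / 3)
  ft3 <- feature_table(f, s, matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(sample_distance(ft3, "bray-curtis")["s1", "s2"], 0)
  # all-zero sample is an error under bray-curtis
  ft4 <- feature_table(f, s, matrix(c(0, 0, 1, 1), 2, 2))
  expect_error(sample_distance(ft4, "bray-curtis"), "all-zero")
  # euclidean on log2 scale
  dE <- sample_distance(ft2, "euclidean")
  expect_equal(dE["s1", "s2"],
               sqrt(sum((log2(c(2, 2) + 1) - log2(c(1, 1) + 1))^2)))
})

test_that("PERMANOVA reproduces the closed-form two-cluster example", {
  x <- c(0, 1, 10, 11)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- permanova(d, c("A", "A", "B", "B"), n_perm = "all")
  expect_equal(res$table$r2[1], 100 / 101, tolerance = 1e-12)
  expect_equal(res$table$ss[3], 101, tolerance = 1e-12)
  expect_equal(res$table$pseudo_f[1], (100 / 1) / (1 / 2), tolerance = 1e-12)
})

test_that("exhaustive PERMANOVA p equals the brute-force rank over all label permutations", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 6
    groups <- rep(c("a", "b"), each = 3)
    pts <- rnorm(n) + ifelse(groups == "a", 0, 1.2)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    res <- permanova(d, groups, n_perm = "all")
    # oracle: group-sum formula at every enumerated permutation
    perms <- oracle_all_perms(n)
    f_obs <- oracle_permanova_f(d, groups)$f
    f_all <- vapply(perms, function(p) oracle_permanova_f(d[p, p], groups)$f, 0)
    p_oracle <- mean(f_all >= f_obs - 1e-12)
    expect_equal(res$table$p_value[1], p_oracle, tolerance = 1e-12)
    expect_equal(res$table$pseudo_f[1], f_obs, tolerance = 1e-10)
    # Monte-Carlo agrees within the binomial 95% CI
    mc <- permanova(d, groups, n_perm = 999, seed = 5)
    ci <- p_oracle + c(-1, 1) * (1.96 * sqrt(p_oracle * (1 - p_oracle) / 999) + 1 / 999)
    expect_gte(mc$table$p_value[1], ci[1])
    expect_lte(mc$table$p_value[1], ci[2])
  }
})

test_that("PERMANOVA r2 is invariant to relabeling and uniform distance scaling", {
  sim <- simulate_feature_table(sim_config(n_features = 60, seed = 13))
  cur <- curate(sim$table)
  dm <- sample_distance(cur$table, "bray-curtis")
  g <- cur$table$samples$organ
  r1 <- permanova(dm, g, 99, seed = 1)$table$r2[1]
  g2 <- ifelse(g == "root", "X", "Y")
  expect_equal(permanova(dm, g2, 99, seed = 1)$table$r2[1], r1, tolerance = 1e-12)
  dm3 <- as_distance_matrix(unclass(dm) * 3.7)
  expect_equal(permanova(dm3, g, 99, seed = 1)$table$r2[1], r1, tolerance = 1e-12)
})

test_that("PERMANOVA agrees with vegan::adonis2 on R2, F and sequential terms", {
  skip_if_not_installed("vegan")
  sim <- simulate_feature_table(sim_config(n_features = 80, seed = 17))
  cur <- curate(sim$table)
  dm <- sample_distance(cur$table, "bray-curtis")
  s <- cur$table$samples
  res <- permanova(dm, data.frame(organ = s$organ, processing = s$processing),
                   n_perm = 199, seed = 1)
  ref <- vegan::adonis2(as.dist(unclass(dm)) ~ organ + processing,
                        data = s, permutations = 199, by = "terms")
  expect_equal(res$table$ss[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(res$table$r2[1:2], ref$R2[1:2], tolerance = 1e-8)
  expect_equal(res$table$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-8)
})

test_that("BH step-up matches the hand example and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  p <- runif(200)^2
  expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-15)
  # monotone non-decreasing in p-rank after step-up
  expect_true(all(diff(bh_fdr(p)[order(p)]) >= 0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("moderated t collapses to the pooled t as d0 -> 0 and to full shrinkage as d0 -> Inf", {
  sim <- simulate_feature_table(sim_config(n_features = 50, seed = 19,
                                           frac_missing = 0))
  cur <- curate(sim$table)
  md0 <- moderated_diff(cur$table, "organ", prior = list(d0 = 0, s0_sq = 1))
  m <- log2(cur$table$intensities + 1)
  lab <- cur$table$samples$organ
  tt <- apply(m, 1, function(v) {
    unname(t.test(v[lab == "seed"], v[lab == "root"], var.equal = TRUE)$statistic)
  })
  expect_equal(md0$table$mod_t, unname(tt), tolerance = 1e-9)
  mdI <- moderated_diff(cur$table, "organ", prior = list(d0 = Inf, s0_sq = 0.17))
  n1 <- sum(lab == "root"); n2 <- sum(lab == "seed")
  se <- sqrt(0.17 * (1 / n1 + 1 / n2))
  expect_equal(mdI$table$mod_t, md0$table$log2fc / se, tolerance = 1e-9)
})

test_that("moderated differential abundance agrees with the limma reference", {
  skip_if_not_installed("limma")
  sim <- simulate_feature_table(sim_config(n_features = 120, seed = 23,
                                           frac_missing = 0))
  cur <- curate(sim$table)
  md <- moderated_diff(cur$table, "organ")
  m <- log2(cur$table$intensities + 1)
  lab <- factor(cur$table$samples$organ, levels = c("root", "seed"))
  design <- model.matrix(~lab)
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(md$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(md$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(md$table$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-9)
  expect_equal(md$table$mod_t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(md$table$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("variance-prior recovery on simulated scaled-inverse-chi-square variances", {
  d0_true <- 4; s0_true <- 0.25; d <- 4
  d0_hat <- s0_hat <- numeric(10)
  for (s in 1:10) {
    set.seed(1000 + s)
    sigma2 <- d0_true * s0_true / rchisq(2000, d0_true)
    s2 <- sigma2 * rchisq(2000, d) / d
    fit <- fit_variance_prior(s2, d)
    d0_hat[s] <- fit$d0; s0_hat[s] <- fit$s0_sq
  }
  expect_lt(abs(median(d0_hat) - d0_true) / d0_true, 0.30)
  expect_lt(abs(median(s0_hat) - s0_true) / s0_true, 0.15)
  # degenerate input: all variances equal -> complete shrinkage without crash
  fit0 <- fit_variance_prior(rep(0.5, 100), d)
  expect_true(is.infinite(fit0$d0))
})

test_that("presence partition respects the inclusive detection boundary and partitions features", {
  ft <- toy_table(3, n_reps = 1, blanks = 0, fill = 0)
  root <- which(ft$samples$organ == "root")
  seed <- which(ft$samples$organ == "seed")
  ft$intensities[1, root[1]] <- 10000      # exactly at the floor: detected
  ft$intensities[2, ] <- 9999              # everywhere just below: nowhere
  ft$intensities[3, c(root[1], seed[1])] <- 50000
  pp <- presence_partition(ft, "organ", 10000)
  expect_equal(pp$exclusive$root, "F001")
  expect_false("F002" %in% unlist(pp$detected))
  expect_equal(pp$shared, "F003")
  # disjointness + union identity
  excl <- unlist(pp$exclusive, use.names = FALSE)
  expect_equal(anyDuplicated(c(excl, pp$shared)), 0)
  expect_setequal(c(excl, pp$shared), unique(unlist(pp$detected)))
})
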