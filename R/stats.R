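# Comparative statistics: log2 PCA, sample distances, PERMANOVA with
# permutation p-values, empirical-Bayes moderated differential abundance
# with BH FDR, and detection-threshold presence/absence partitioning.
# These are from-scratch implementations; the test suite cross-checks them
# against independent reference packages.

log2p1 <- function(m) log2(m + 1)

#' Principal component analysis of a feature table
#'
#' Transforms intensities to `log2(x + 1)`, centers and scales each
#' feature to unit variance (constant features are dropped with a
#' warning), and eigendecomposes via SVD. Component signs follow the
#' convention that each component's largest-magnitude loading is positive,
#' so results are reproducible across platforms.
#'
#' @param x a curated `feature_table` (>= 2 samples, no missing values).
#' @return A `ft_pca`: `scores` (samples x components), `loadings`
#'   (features x components), `explained_pct`, `dropped` (constant
#'   features).
#' @export
pca_feature_table <- function(x) {
  nb <- nonblank_idx(x)
  if (length(nb) < 2) stopf("PCA needs at least 2 samples")
  m <- t(log2p1(x$intensities[, nb, drop = FALSE]))  # samples x features
  if (anyNA(m)) stopf("PCA requires an imputed table")
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped))
    warnf("dropping %d constant-intensity feature(s) before scaling",
          length(dropped))
  m <- m[, sds > 0, drop = FALSE]
  if (!ncol(m)) stopf("no variable features left for PCA")
  z <- scale(m, center = TRUE, scale = TRUE)
  sv <- svd(z)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 1L)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest |loading| positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- sv$d[seq_len(k)]^2
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained_pct = 100 * ev / sum(sv$d^2),
                 dropped = dropped),
            class = "ft_pca")
}

#' @export
print.ft_pca <- function(x, ...) {
  cat(sprintf("ft_pca: %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  explained %:", paste(sprintf("%.1f", x$explained_pct[seq_len(min(5, length(x$explained_pct)))]),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Between-sample distance matrix
#'
#' Bray-Curtis (`sum |x - y| / sum (x + y)`) on raw curated intensities,
#' or Euclidean, optionally on the `log2(x + 1)` scale. Blank samples are
#' excluded.
#'
#' @param x a curated `feature_table`.
#' @param metric `"bray-curtis"` or `"euclidean"`.
#' @param log2_transform apply `log2(x + 1)` first (default for
#'   Euclidean).
#' @return A labeled symmetric `distance_matrix` over samples.
#' @export
sample_distance <- function(x, metric = c("bray-curtis", "euclidean"),
                            log2_transform = (metric[1] == "euclidean")) {
  metric <- match.arg(metric)
  nb <- nonblank_idx(x)
  m <- x$intensities[, nb, drop = FALSE]
  if (anyNA(m)) stopf("distances require an imputed table")
  if (log2_transform) m <- log2p1(m)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  if (metric == "bray-curtis") {
    if (any(colSums(m) == 0)) stopf("all-zero sample under bray-curtis")
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
    }
  } else {
    d <- as.matrix(stats::dist(t(m)))
  }
  as_distance_matrix(d)
}

# Gower-centered inner-product matrix of squared distances
gower_center <- function(dm) {
  d2 <- dm^2
  n <- nrow(d2)
  cm <- diag(n) - matrix(1 / n, n, n)
  -0.5 * cm %*% d2 %*% cm
}

hat_matrix <- function(X) X %*% MASS_ginv(crossprod(X)) %*% t(X)

# Moore-Penrose pseudoinverse (small symmetric matrices only)
MASS_ginv <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, pos, drop = FALSE] %*%
    diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(sub + (sub >= i), i))
  }
  out
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the sum of squares of a distance matrix by one or more
#' grouping factors (sequential sums of squares in the order given, via
#' Gower centering and hat-matrix traces) and assesses significance by
#' permuting sample labels. For a single factor this reduces to the
#' textbook decomposition `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`.
#'
#' The permutation p-value is `(#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`;
#' with `n_perm = "all"` every permutation is enumerated and the p-value
#' is the exact rank of the observed statistic.
#'
#' @param dm symmetric distance matrix over samples.
#' @param groups factor/character vector (one factor), or a data.frame of
#'   factors for a sequential multi-factor model.
#' @param n_perm number of label permutations (default 999), or `"all"`
#'   for exhaustive enumeration (small n only).
#' @param seed integer seed for the permutation generator.
#' @return A `permanova` object: per-term `df`, `ss`, `r2`, `pseudo_f`,
#'   `p_value`, plus residual/total rows and provenance (`n_perm`,
#'   `seed`).
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1) {
  dm <- as_distance_matrix(unclass(dm))
  n <- nrow(dm)
  if (is.data.frame(groups)) {
    fac <- lapply(groups, function(g) factor(g))
  } else {
    fac <- list(factor(groups))
    names(fac) <- "groups"
  }
  if (is.null(names(fac)) || any(!nzchar(names(fac))))
    names(fac) <- paste0("factor", seq_along(fac))
  if (any(vapply(fac, nlevels, 0L) < 2)) stopf("each factor needs >= 2 levels")
  if (length(fac[[1]]) != n) stopf("group labels must match distance matrix size")
  G <- gower_center(dm)
  ss_total <- sum(diag(G))
  # cumulative hat matrices for sequential SS
  Xc <- matrix(1, n, 1)
  hats <- list()
  dfs <- integer(0)
  for (k in seq_along(fac)) {
    mm <- stats::model.matrix(~f, data.frame(f = fac[[k]]))[, -1, drop = FALSE]
    Xc <- cbind(Xc, mm)
    hats[[k]] <- hat_matrix(Xc)
    dfs[k] <- nlevels(fac[[k]]) - 1L
  }
  df_res <- n - 1L - sum(dfs)
  if (df_res < 1) stopf("no residual degrees of freedom")
  term_stats <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), 0)  # trace(H G), H symmetric
    ss_term <- diff(c(0, tr))
    ss_model <- tr[length(tr)]
    ss_res <- sum(diag(Gm)) - ss_model
    f <- (ss_term / dfs) / (ss_res / df_res)
    list(ss = ss_term, f = f, ss_res = ss_res)
  }
  obs <- term_stats(G)
  perm_f <- function(idx) term_stats(G[idx, idx])$f
  nf <- length(fac)
  if (identical(n_perm, "all")) {
    perms <- all_permutations(n)
    n_used <- nrow(perms)
    fs <- matrix(0, n_used, nf)
    for (i in seq_len(n_used)) fs[i, ] <- perm_f(perms[i, ])
    p <- vapply(seq_len(nf), function(k)
      mean(fs[, k] >= obs$f[k] - 1e-12), 0)
  } else {
    if (!is.numeric(n_perm) || n_perm < 1) stopf("n_perm must be >= 1 or 'all'")
    n_used <- as.integer(n_perm)
    fs <- with_seed(seed, {
      out <- matrix(0, n_used, nf)
      for (i in seq_len(n_used)) out[i, ] <- perm_f(sample.int(n))
      out
    })
    p <- vapply(seq_len(nf), function(k)
      (sum(fs[, k] >= obs$f[k] - 1e-12) + 1) / (n_used + 1), 0)
  }
  res <- data.frame(
    term = c(names(fac), "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    ss = c(obs$ss, obs$ss_res, ss_total),
    r2 = c(obs$ss / ss_total, obs$ss_res / ss_total, 1),
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(p, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(table = res, n_perm = n_used, seed = seed,
                 exhaustive = identical(n_perm, "all")),
            class = "permanova")
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations%s)\n",
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_perm, if (x$exhaustive) "" else sprintf(", seed %d", x$seed)))
  print(cbind(x$table[1], round(x$table[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `p_(i) * n / i`, cumulative minimum from the
#' largest p down, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

# Newton inversion of the trigamma function (for the moment estimator of
# the prior degrees of freedom)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes prior for residual variances
#'
#' Fits a scaled inverse-chi-square prior (`d0` prior degrees of freedom,
#' `s0_sq` prior variance) to observed residual variances by the method of
#' moments on `log(s^2)`, using digamma/trigamma identities for the
#' log-chi-square mean and variance. When the observed spread of
#' `log(s^2)` does not exceed its sampling variance the prior degrees of
#' freedom are infinite (complete shrinkage).
#'
#' @param s2 per-feature residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return `list(d0, s0_sq)`.
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) return(list(d0 = Inf, s0_sq = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  if (n < 2) return(list(d0 = Inf, s0_sq = exp(emean)))
  evar <- mean((e - emean)^2) * n / (n - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated differential abundance
#'
#' Two-group comparison on the `log2(x + 1)` scale with empirical-Bayes
#' variance moderation: per-feature pooled residual variance `s^2` (with
#' `d = n1 + n2 - 2` degrees of freedom) is shrunk toward the fitted prior
#' `s0_sq` via the posterior `s~^2 = (d0 s0_sq + d s^2) / (d0 + d)`; the
#' moderated t is the mean log2 difference over `s~ sqrt(1/n1 + 1/n2)`
#' with `d0 + d` degrees of freedom. BH-adjusted FDR and an enrichment
#' call (`|log2fc| > lfc_cut` and `fdr < fdr_cut`) complete the result.
#'
#' The fold change is `mean(group2) - mean(group1)` on the log2 scale, so
#' positive values mean enriched in `group2`.
#'
#' @param x a curated `feature_table`.
#' @param factor design factor: `"organ"` or `"processing"`.
#' @param contrast length-2 character: `(group1, group2)`. Defaults to
#'   `(root, seed)` or `(extract, juice)`.
#' @param lfc_cut,fdr_cut enrichment thresholds (defaults 1 and 0.05).
#' @param prior optional `list(d0, s0_sq)` to override the fitted prior
#'   (e.g. `d0 = 0` for an ordinary pooled t, `d0 = Inf` for complete
#'   shrinkage).
#' @return A `moderated_diff` object: per-feature table (`log2fc`,
#'   `mod_t`, `df_total`, `p`, `fdr`, `enriched_in`) plus `d0`, `s0_sq`,
#'   the contrast and group sizes.
#' @export
moderated_diff <- function(x, factor = c("organ", "processing"),
                           contrast = NULL, lfc_cut = 1, fdr_cut = 0.05,
                           prior = NULL) {
  factor <- match.arg(factor)
  s <- x$samples[!x$samples$is_blank, , drop = FALSE]
  m <- log2p1(x$intensities[, !x$samples$is_blank, drop = FALSE])
  if (anyNA(m)) stopf("differential abundance requires an imputed table")
  lab <- s[[factor]]
  if (is.null(contrast))
    contrast <- if (factor == "organ") c("root", "seed") else c("extract", "juice")
  g1 <- which(lab == contrast[1]); g2 <- which(lab == contrast[2])
  if (length(g1) < 2) stopf("group '%s' has fewer than 2 replicates", contrast[1])
  if (length(g2) < 2) stopf("group '%s' has fewer than 2 replicates", contrast[2])
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(m[, g1, drop = FALSE]); m2 <- rowMeans(m[, g2, drop = FALSE])
  v1 <- apply(m[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, g2, drop = FALSE], 1, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (is.null(prior)) prior <- fit_variance_prior(s2, d)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + d * s2) / (d0 + d)
  log2fc <- m2 - m1
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  df_total <- d0 + d
  pdf <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(tstat))
  } else {
    2 * stats::pt(-abs(tstat), df = df_total)
  }
  fdr <- bh_fdr(pdf)
  enr <- rep("none", length(log2fc))
  enr[log2fc > lfc_cut & fdr < fdr_cut] <- contrast[2]
  enr[log2fc < -lfc_cut & fdr < fdr_cut] <- contrast[1]
  tab <- data.frame(feature_id = x$features$feature_id,
                    log2fc = log2fc, mod_t = tstat,
                    df_total = rep(df_total, length(log2fc)),
                    p = pdf, fdr = fdr, enriched_in = enr,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, d0 = d0, s0_sq = s0_sq,
                 contrast = contrast, factor = factor,
                 n = c(n1, n2), lfc_cut = lfc_cut, fdr_cut = fdr_cut),
            class = "moderated_diff")
}

#' @export
print.moderated_diff <- function(x, ...) {
  cat(sprintf("moderated_diff: %s vs %s (%s), %d features\n",
              x$contrast[1], x$contrast[2], x$factor, nrow(x$table)))
  cat(sprintf("  prior: d0 = %.3g, s0_sq = %.3g\n", x$d0, x$s0_sq))
  n1 <- sum(x$table$enriched_in == x$contrast[1])
  n2 <- sum(x$table$enriched_in == x$contrast[2])
  cat(sprintf("  enriched (|log2FC| > %g, FDR < %g): %d in %s, %d in %s\n",
              x$lfc_cut, x$fdr_cut, n1, x$contrast[1], n2, x$contrast[2]))
  invisible(x)
}

#' @export
summary.moderated_diff <- function(object, ...) {
  print(object)
  invisible(object$table)
}

#' Presence/absence partition by detection threshold
#'
#' A feature counts as detected in a factor level when its intensity
#' reaches `detect_floor` (inclusive) in at least one sample of that
#' level. Features detected in exactly one level are exclusive to it;
#' features detected in two or more levels are shared.
#'
#' @param x a curated `feature_table`.
#' @param factor `"organ"` or `"processing"`.
#' @param detect_floor detection threshold (default 10000).
#' @return A `presence_partition`: `detected`, `exclusive` (named lists of
#'   feature-id sets) and `shared`.
#' @export
presence_partition <- function(x, factor = c("organ", "processing"),
                               detect_floor = 10000) {
  factor <- match.arg(factor)
  s <- x$samples[!x$samples$is_blank, , drop = FALSE]
  m <- x$intensities[, !x$samples$is_blank, drop = FALSE]
  lev <- sort(unique(s[[factor]]))
  if (length(lev) < 2) stopf("factor '%s' has fewer than 2 levels", factor)
  detected <- lapply(lev, function(l) {
    cols <- which(s[[factor]] == l)
    x$features$feature_id[
      apply(m[, cols, drop = FALSE], 1,
            function(v) any(!is.na(v) & v >= detect_floor))]
  })
  names(detected) <- lev
  counts <- table(unlist(detected))
  exclusive <- lapply(lev, function(l)
    detected[[l]][detected[[l]] %in% names(counts)[counts == 1]])
  names(exclusive) <- lev
  shared <- sort(names(counts)[counts >= 2])
  structure(list(detected = detected, exclusive = exclusive,
                 shared = shared, factor = factor,
                 detect_floor = detect_floor),
            class = "presence_partition")
}

#' @export
print.presence_partition <- function(x, ...) {
  cat(sprintf("presence_partition by %s (detection >= %g)\n",
              x$factor, x$detect_floor))
  for (l in names(x$detected))
    cat(sprintf("  %s: %d detected, %d exclusive\n", l,
                length(x$detected[[l]]), length(x$exclusive[[l]])))
  cat(sprintf("  shared: %d\n", length(x$shared)))
  invisible(x)
}
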