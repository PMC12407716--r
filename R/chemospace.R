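# Chemospace: binary structural fingerprints, Tanimoto (dis)similarity,
# and hierarchical clustering with Newick export -- the machinery behind
# dendrogram-heatmap chemodiversity views.

#' Binary structural fingerprints
#'
#' Computes a deterministic 1024-bit path-based binary fingerprint (Open
#' Babel FP2, linear fragments up to 7 atoms hashed onto the bit vector)
#' for each structure. The exact bit dialect is delegated to the bundled
#' cheminformatics backend; a committed (SMILES, bits) fixture pins it in
#' the test suite so backend upgrades are caught.
#'
#' @param smiles character vector of SMILES; names (or the SMILES
#'   themselves) become row labels.
#' @return Integer matrix, structures x 1024 bits, values 0/1.
#' @export
fingerprint <- function(smiles) {
  if (!length(smiles)) stopf("no structures")
  if (any(is.na(smiles) | !nzchar(smiles))) stopf("empty structure in input")
  labels <- names(smiles) %||% smiles
  can <- vapply(smiles, function(s) {
    out <- ob_convert("smi", "can", s)
    if (!nzchar(out)) stopf("unparseable structure: '%s'", s)
    sub("\t.*$", "", out)
  }, "", USE.NAMES = FALSE)
  txt <- paste0(can, "\tm", seq_along(can), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", txt, identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "FP2")
  fp <- matrix(as.integer(fp != 0), nrow = length(can))
  rownames(fp) <- labels
  fp
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` on binary bit vectors. Two all-zero fingerprints
#' are defined as identical (similarity 1) with a message, since neither
#' carries structural information to distinguish them.
#'
#' @param a,b binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stopf("fingerprint length mismatch: %d vs %d",
                                    length(a), length(b))
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) {
    message("both fingerprints empty; Tanimoto defined as 1")
    return(1)
  }
  sum(a & b) / un
}

#' Pairwise Tanimoto dissimilarity matrix
#'
#' Builds the symmetric matrix of `1 - Tanimoto` over all structure pairs.
#' Rows are ordered by sorted label so downstream clustering is
#' reproducible regardless of input order.
#'
#' @param fps fingerprint matrix from [fingerprint()] (rows = structures).
#' @return Labeled symmetric matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
tanimoto_dissimilarity <- function(fps) {
  fps <- fps[order(rownames(fps)), , drop = FALSE]
  m <- fps %*% t(fps)                      # intersections
  n_bits <- rowSums(fps)
  un <- outer(n_bits, n_bits, `+`) - m     # unions
  sim <- ifelse(un == 0, 1, m / un)
  d <- 1 - sim
  diag(d) <- 0
  dimnames(d) <- list(rownames(fps), rownames(fps))
  as_distance_matrix(d)
}

#' Validate a distance matrix
#'
#' Checks symmetry (within 1e-12), zero diagonal, nonnegativity and
#' labeling; returns the matrix with class `distance_matrix`.
#'
#' @param m square numeric matrix with dimnames.
#' @return The validated matrix.
#' @export
as_distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("distance matrix must be square")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) %||% paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (max(abs(m - t(m))) > 1e-12) stopf("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stopf("distance matrix diagonal must be zero")
  if (any(m < 0)) stopf("distances must be nonnegative")
  class(m) <- c("distance_matrix", class(m))
  m
}

#' Hierarchical clustering of a chemospace
#'
#' Agglomerative clustering of a dissimilarity matrix (average/UPGMA
#' linkage by default -- the conventional choice for fingerprint
#' chemospaces), with deterministic leaf handling: items are ordered by
#' label before clustering so ties break identically across runs. The
#' dendrogram is exported as Newick with branch lengths derived from merge
#' heights.
#'
#' @param dm symmetric dissimilarity matrix (see [as_distance_matrix()]).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return A `chem_dendrogram`: the `hclust` object, its merge table,
#'   merge heights, the Newick string and the `phylo` tree.
#' @export
chem_cluster <- function(dm, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  dm <- as_distance_matrix(dm)
  if (nrow(dm) < 2) stopf("need at least 2 items to cluster")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  hc <- stats::hclust(stats::as.dist(dm), method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc,
                 merge = hc$merge,
                 heights = hc$height,
                 linkage = linkage,
                 newick = ape::write.tree(phy),
                 phylo = phy),
            class = "chem_dendrogram")
}

#' @export
print.chem_dendrogram <- function(x, ...) {
  cat(sprintf("chem_dendrogram: %d leaves, %s linkage\n",
              length(x$hclust$labels), x$linkage))
  cat(" ", substr(x$newick, 1, 70),
      if (nchar(x$newick) > 70) "...\n" else "\n")
  invisible(x)
}

#' @export
plot.chem_dendrogram <- function(x, ...) plot(x$hclust, ...)
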