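# Fragment-based natural-product-likeness scoring.
#
# The score follows the classic fragment-contribution idea: atom-centered
# circular substructure environments (radius 0..2) are enumerated for a
# training corpus of natural products and one of synthetic compounds; each
# fragment gets a log-odds contribution log P(f | natural) / P(f | synthetic)
# (Laplace-smoothed); a query molecule is scored by the sum of contributions
# of its distinct fragments, normalized by heavy-atom count and clipped to
# [-5, 5]. Positive means natural-product-like. The training corpora are
# small curated lists packaged with this source; scores are screening
# metadata, not a filter.

# Parse a SMILES into a heavy-atom molecular graph via an SDF molblock.
mol_graph <- function(smiles) {
  if (!is_string(smiles) || !nzchar(smiles)) stopf("empty structure")
  sdf <- ob_convert("smi", "sdf", smiles)
  if (!nzchar(sdf)) stopf("unparseable structure: '%s'", smiles)
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stopf("unparseable structure: '%s'", smiles)
  atom_lines <- lines[5:(4 + na)]
  elem <- vapply(atom_lines, function(l) trimws(substr(l, 32, 34)), "",
                 USE.NAMES = FALSE)
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    data.frame(a1 = as.integer(substr(bl, 1, 3)),
               a2 = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(a1 = integer(), a2 = integer(), order = integer())
  list(elem = elem, bonds = bonds, n = na)
}

# Atom-centered circular environment identifiers for radii 0..radius.
# Invariants are iteratively refined Morgan-style: an atom's radius-r id
# combines its radius-(r-1) id with the sorted (bond order, neighbor id)
# multiset. Returns the set of distinct fragment identifiers.
atom_environments <- function(graph, radius = 2) {
  n <- graph$n
  nb <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a1[k]; b <- graph$bonds$a2[k]; o <- graph$bonds$order[k]
    nb[[a]] <- rbind(nb[[a]], c(b, o))
    nb[[b]] <- rbind(nb[[b]], c(a, o))
  }
  deg <- vapply(nb, function(m) if (is.null(m)) 0L else nrow(m), 0L)
  val <- vapply(nb, function(m) if (is.null(m)) 0L else sum(m[, 2]), 0L)
  id <- paste0(graph$elem, deg, "v", val)
  frags <- unique(id)
  for (r in seq_len(radius)) {
    id_new <- character(n)
    for (a in seq_len(n)) {
      if (is.null(nb[[a]])) { id_new[a] <- paste0(id[a], "()"); next }
      parts <- paste0(nb[[a]][, 2], "~", id[nb[[a]][, 1]])
      id_new[a] <- paste0(id[a], "(", paste(sort(parts), collapse = ","), ")")
    }
    id <- id_new
    frags <- c(frags, unique(id))
  }
  unique(frags)
}

np_training_path <- function(which) {
  system.file("extdata",
              switch(which,
                     natural = "np_structures.tsv",
                     synthetic = "synthetic_compounds.tsv"),
              package = "phytomet", mustWork = TRUE)
}

#' Natural-product-likeness model
#'
#' Builds (and memoizes) the fragment-contribution table from the two
#' packaged training corpora: a curated list of plant natural products and
#' a curated list of synthetic (drug-like/industrial) compounds. Each
#' fragment's contribution is the Laplace-smoothed log-odds of occurring
#' in a natural product versus a synthetic compound.
#'
#' @param natural,synthetic optional data.frames with a `smiles` column to
#'   train on instead of the packaged corpora.
#' @return An `np_likeness_model`: named numeric vector of fragment
#'   contributions plus training sizes.
#' @export
np_likeness_model <- function(natural = NULL, synthetic = NULL) {
  if (is.null(natural) && is.null(synthetic)) {
    hit <- .pm_cache[["np_model_default"]]
    if (!is.null(hit)) return(hit)
  }
  read_corpus <- function(x, which) {
    if (is.null(x))
      x <- utils::read.delim(np_training_path(which), stringsAsFactors = FALSE)
    x$smiles
  }
  nat <- read_corpus(natural, "natural")
  syn <- read_corpus(synthetic, "synthetic")
  frag_sets <- function(smis) lapply(smis, function(s)
    atom_environments(mol_graph(s)))
  fn <- frag_sets(nat); fs <- frag_sets(syn)
  cn <- table(unlist(fn)); cs <- table(unlist(fs))
  all_f <- union(names(cn), names(cs))
  kn <- as.numeric(cn[all_f]); kn[is.na(kn)] <- 0
  ks <- as.numeric(cs[all_f]); ks[is.na(ks)] <- 0
  contrib <- log(((kn + 1) / (length(fn) + 2)) / ((ks + 1) / (length(fs) + 2)))
  names(contrib) <- all_f
  model <- structure(list(contrib = contrib, n_natural = length(fn),
                          n_synthetic = length(fs)),
                     class = "np_likeness_model")
  if (is.null(natural) && is.null(synthetic))
    .pm_cache[["np_model_default"]] <- model
  model
}

#' @export
print.np_likeness_model <- function(x, ...) {
  cat(sprintf("np_likeness_model: %d fragments (%d natural, %d synthetic training structures)\n",
              length(x$contrib), x$n_natural, x$n_synthetic))
  invisible(x)
}

#' Natural-product-likeness score
#'
#' Scores a structure on a [-5, 5] scale; positive values indicate
#' similarity to natural products. Deterministic: the same structure
#' always yields the same score.
#'
#' @param smiles a SMILES string.
#' @param model an [np_likeness_model()].
#' @return Numeric score in `[-5, 5]`.
#' @export
np_likeness <- function(smiles, model = np_likeness_model()) {
  g <- mol_graph(smiles)
  frags <- atom_environments(g)
  hit <- model$contrib[frags]
  raw <- sum(hit, na.rm = TRUE) / g$n
  max(-5, min(5, raw))
}
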