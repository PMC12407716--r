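Package: phytomet
Title: Curation, Annotation and Comparative Statistics for Untargeted
    Plant Metabolomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with LC-MS mass feature tables from untargeted
    plant metabolomics experiments. Implements feature-table curation
    (identification-quality filtering, missing-value imputation, noise and
    blank-contaminant removal, blank subtraction), chemical annotation
    (identifier harmonization to InChIKeys, biosynthetic-pathway
    classification bookkeeping with hybrid handling, genus-level novelty
    flagging against an offline reference list, fragment-based
    natural-product-likeness scoring), chemodiversity analysis (binary
    structural fingerprints, Tanimoto dissimilarity, hierarchical
    clustering with Newick export), and comparative statistics (log2 PCA,
    PERMANOVA with permutation p-values, empirical-Bayes moderated
    differential abundance with Benjamini-Hochberg FDR, detection-threshold
    presence/absence partitioning). A synthetic-data generator emulating a
    two-organ by two-processing-method design with replicates and blanks
    supports end-to-end validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    limma
Config/testthat/edition: 3
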