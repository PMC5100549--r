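Package: pepscan
Title: High-Density Peptide Microarray Epitope Profiling with Alanine Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linear B-cell epitope mapping of protein antigens on
    high-density peptide microarrays. Designs overlapping 12-mer tiling
    libraries with full alanine-substitution scans from protein FASTA input,
    classifies antibody-binding peptides from replicate spot intensities with
    a percentile-based background model, maps peptide signals back onto
    antigen sequences as residue scores and averaged alanine-substitution
    effects, compares binder sets across experiments, projects per-residue
    values onto multiple sequence alignments, and writes residue values into
    the temperature-factor column of PDB structures. Includes a synthetic
    experiment generator with planted epitopes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
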