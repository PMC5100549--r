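# pepscan

Linear B-cell epitope mapping of protein antigens on high-density
peptide microarrays, built for antivenom immuno-profiling of snake
venom toxins.

Antivenoms are polyclonal antibody preparations, and for most of them
it is unknown which parts of each venom toxin their antibodies
recognise. On a high-density peptide microarray every toxin sequence is
displayed as overlapping 12-mer peptides (tiled at every second
residue), together with every single-position alanine substitution of
every peptide, and antibody binding is read out as spot fluorescence.
`pepscan` implements the analysis around such an experiment for
researchers in toxinology and antibody engineering:

* **Library design** — tile mature sequences into 12-mers, pool and
  deduplicate across homologs while keeping an occurrence map, expand
  with the full alanine scan, and place replicated spots at seeded
  random array positions (`design_library()`).
* **Binder classification** — per-peptide replicate medians; background
  estimated from the lower 70-percentile of wild-type medians under the
  assumption that most peptides bind no antibody; a peptide is an
  antibody target when its median exceeds

  $$T = \hat\mu_{70} + 10\,\hat\sigma_{70}$$

  (`estimate_background()`, `classify_binders()`).
* **Residue-level profiling** — the *residue score* of residue $i$ is
  the mean median of all 12-mers spanning $i$; the *average alanine
  substitution effect* is the mean over covering binder tiles of
  $\log_2(\tilde m_\text{variant}/\tilde m_\text{wt})$, `NA` where no
  covering peptide passed the threshold
  (`residue_scores()`, `alanine_effects()`, `residue_profile()`), with
  projection onto gapped multiple sequence alignments
  (`project_onto_alignment()`).
* **Experiment comparison** — exclusive Venn region counts and
  non-shared fractions between binder sets of different experiments,
  and mapping of binders back to recognised antigens
  (`overlap_counts()`, `non_shared_fraction()`, `toxins_with_binders()`).
* **Structure annotation** — write residue values into the PDB
  temperature-factor column for structure colouring (`annotate_pdb()`).
* **Synthetic experiments** — a generator with planted epitopes,
  known key residues and a near-normal background, plus the exact
  expected outcome (`simulate_experiment()`, `derive_truth()`), used
  throughout the test suite.

The bundled `study_toxins()` table carries the 82-entry inventory of
mamba (*Dendroaspis*) and African cobra (*Naja*) venom toxins —
three-finger toxins, Kunitz-type dendrotoxins and relatives — that the
design conventions were fixed against. Sequences are not bundled; pair
the table with a FASTA of mature sequences via `read_toxins()` and
`validate_study_sequences()`.

## Worked example

A small synthetic study, end to end:

```r
library(pepscan)
library(dplyr)

tox <- synthetic_toxins(10, c(40, 70), seed = 42)
lib <- design_library(tox, seed = 42)
glance(lib)
#>   n_toxins n_tiles redundancy_count  n_wt n_variants n_unique_peptides n_spots
#> 1       10     212                0   212       2413              2625    3473

noise <- noise_model(background_mean = 50, background_sd = 8, replicate_sd = 8)
epi <- plant_epitopes(lib, n_epitopes = 3, amplitude = 160,
                      knockdown = 0.25, seed = 42)
sig <- simulate_experiment(lib, epi, noise, seed = 42, experiment_id = "demo")

meds  <- replicate_median(sig)
model <- estimate_background(meds)
model
#> <background_model> lower 70% of 212 wt medians (subset 148)
#>   mean 45.7393, sd 6.80116, threshold mean + 10 sd = 113.751

binders <- classify_binders(meds, model, experiment_id = "demo")
sum(binders$is_binder)
#> [1] 7
setequal(binder_set(binders), derive_truth(lib, epi, noise)$expected_binders)
#> [1] TRUE
```

The 212 wild-type 12-mers and their 2,413 alanine variants give 3,473
spots (five replicates per wild-type peptide, one per variant). The
background model puts the binder threshold at 113.8 AU, about 64 AU
above the baseline mean; exactly the 7 peptides that fully contain a
planted epitope core exceed it. Mapping back to residues recovers the
planted key positions:

```r
prof <- residue_profile(lib, meds, binders, experiment_id = "demo")
keys <- tidyr::unnest_longer(epi, key_positions, values_to = "residue")
inner_join(prof, select(keys, accession, residue),
           by = c("accession", "residue")) |>
  select(accession, residue, residue_letter, residue_score,
         ala_effect, coverage_binder)
#>   accession residue residue_letter residue_score ala_effect coverage_binder
#> 1 SYN001         20 M                       112.      -1.10               2
#> 2 SYN001         26 P                       108.      -1.30               2
#> 3 SYN005         20 L                       130.      -1.24               3
#> 4 SYN005         22 C                       130.      -1.14               3
#> 5 SYN010         37 C                       104.      -1.15               2
#> 6 SYN010         45 W                       114.      -1.11               2
```

Each planted key residue shows an average alanine-substitution effect
near the theoretical $\log_2\frac{0.25 \cdot 160 + 50}{160 + 50} =
-1.22$: substituting it for alanine costs antibodies most of their
binding, averaged over the 2–3 overlapping binder peptides covering the
residue. Non-key residues sit near 0, and residues covered by no binder
peptide are `NA`.

The same stages are available as file-based pipeline steps
(`run_design()`, `run_simulate()`, `run_classify()`, `run_profile()`,
`run_compare()`, `run_annotate()`) over flat TSV/JSON interfaces, each
writing a manifest with the configuration hash that produced it; see
`run_config()`.

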