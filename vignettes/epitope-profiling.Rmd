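---
title: "Epitope profiling on high-density peptide microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope profiling on high-density peptide microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pepscan)
library(dplyr)
```

## The problem

Polyclonal antivenoms are raised by immunising production animals with
whole snake venoms, and little is usually known about *which parts* of
each venom toxin their antibodies actually recognise. High-density
peptide microarrays make this question tractable for linear epitopes:
every toxin sequence is decomposed into overlapping short peptides,
synthesised on a slide, incubated with antivenom, and antibody binding is
read out as spot fluorescence. Because linear epitope elements are
typically 7–9 residues long, a real epitope produces a *run* of elevated
signals across consecutive overlapping peptides — a signature that
distinguishes it from isolated noisy spots. Adding every single-position
alanine substitution of every peptide (an alanine scan) further reveals
which side chains the antibodies depend on.

`pepscan` implements the full analysis pipeline around such an
experiment: in-silico library design, binder classification,
residue-level profiling, cross-experiment comparison, and structure
annotation, together with a synthetic-data generator that makes every
stage testable against a known ground truth. The bundled
`study_toxins()` table carries the inventory it was built around: 82
mamba (*Dendroaspis*) and African cobra (*Naja*) venom toxins — mostly
three-finger toxins and Kunitz-type dendrotoxins — profiled against
three commercial equine F(ab')~2~ antivenoms at two dilutions each.

## Library design

`design_library()` turns mature toxin sequences into an array layout in
four steps.

**Tiling.** Each sequence is cut into 12-mers starting at every second
residue (`k = 12`, `step = 2`). A 60-residue toxin therefore yields 25
tiles at starts 1, 3, …, 49, each sharing 10 residues with its
neighbour. For odd-length sequences the plain grid leaves the final
residue uncovered; `force_terminal = TRUE` appends one extra window
flush with the C-terminus. The plain grid is the default because it is
the convention under which the design arithmetic of the original study
inventory comes out exactly: the 82 annotated sequence lengths imply
2,150 grid tiles, matching the published accounting of 1,588 unique
peptides plus 562 redundant ones, whereas terminal-forcing would give
2,192.

```{r}
tile_sequence("ACDEFGHIKLMNPQ")
```

**Deduplication.** Tiles are pooled across all toxins and duplicate
sequences removed globally — homologous toxins share long identical
stretches, so many 12-mers occur in several entries. The occurrence map
(`peptide`, `accession`, `start`) is kept, so one measured peptide can
later be mapped back to every toxin carrying it.

**Alanine scan.** Every unique wild-type peptide generates one variant
per non-alanine position, with that residue substituted by `A`.
Self-substitutions are skipped at generation time (replacing alanine
with alanine reproduces the parent), and the variant set is
deduplicated on sequence while retaining all (parent, position)
provenance. A variant whose sequence happens to equal a wild-type
peptide is kept in the variant set by default
(`drop_wt_collisions = FALSE`); it is synthesised once and measured as
a variant.

**Layout.** Wild-type peptides are replicated five times, variants once,
and all spots are assigned uniformly random array positions from a
single seeded generator, so local intensity biases on the slide are
decoupled from peptide identity. The seed is recorded in the library,
and identical inputs plus seed reproduce a byte-identical layout.

```{r}
lib <- design_library(synthetic_toxins(5, c(30, 60), seed = 1), seed = 1)
glance(lib)
```

## Classifying antibody-binding peptides

All classification operates on the per-peptide **median** of replicate
intensities (`replicate_median()`), which is robust to single bad spots;
the replicate SD (sample convention, n−1) is carried along for plotting.

The background model rests on one assumption: the large majority of
peptides are not recognised by any antibody, so the bulk of the median
distribution is unspecific binding and auto-fluorescence, approximately
normal. `estimate_background()` takes the `floor(0.70 * N)` smallest
wild-type medians — the nearest-rank reading of "the lower
70-percentile", chosen because no interpolation scheme is implied by a
percentile cut of an empirical set; the convention is exposed via the
`percentile` argument — and computes their mean and sample SD. A
wild-type peptide is called a binder when its median lies strictly more
than `k = 10` of these SDs above this mean:

$$T = \hat\mu_{70} + 10\,\hat\sigma_{70}, \qquad
\text{binder} \iff \tilde{m} > T.$$

Two properties of this rule are worth noting. First, because the mean
and SD are computed over a *truncated* lower subset, they underestimate
the full background spread; the nominal 10-SD cut corresponds to about
6.5 population SDs for a normal background — still far enough out that
the expected false-positive count in a library of tens of thousands of
peptides is essentially zero. Second, the rule is scale-equivariant:
rescaling all intensities rescales the threshold and leaves the binder
set unchanged, so arrays with different global brightness (different
antivenom formulations, scanner gains) are treated consistently.

Variant medians are computed but never classified — classification
concerns only the original (wild-type) peptides. Each experiment
(antivenom × dilution) is classified against its own background, and
`consensus_binders()` intersects the two dilution experiments of one
antivenom before any cross-antivenom comparison.

```{r}
m <- c(8, 9, 10, 10, 10, 10, 11, 12, 500, 600)
estimate_background(m)
```

## Residue-level profiling

Peptide-level calls are mapped back onto sequences in two complementary
ways.

The **residue score** of residue $i$ is the arithmetic mean of the
medians of *all* wild-type tiles whose span contains $i$ — binder and
non-binder alike. It converts the per-tile binding profile into the
antigen's own coordinates and reflects absolute signal strength.

The **average alanine-substitution effect** uses only binder tiles. For
each binder tile $p$ covering residue $i$ at offset $j$, the effect is
$\log_2\!\big(\tilde m_{p[j\to A]} / \tilde m_{p}\big)$, and the
residue's value averages these over all covering binder tiles, so the
position of the residue within each 12-mer (N- versus C-terminal
context) is averaged out. Loss of binding upon substitution is negative
under this orientation (configurable). Conventions for the edge cases:

* residues that are already alanine get 0 (self-substitution is the
  identity), not missing;
* residues covered by no binder tile get `NA` — non-binding peptides
  carry no interpretable substitution signal, and these residues are the
  "grey" positions of an epitope map;
* medians at or below zero are floored to `epsilon = 1` AU (one unit on
  the fluorescence scale) before the ratio, with a warning.

Both quantities are computed per experiment; no cross-dilution averaging
is applied, and `run_profile()`'s `experiment_id` argument selects which
experiment feeds a map. For homolog families,
`project_onto_alignment()` places per-residue values at the columns of a
user-supplied gapped alignment (gap cells carry no value, and the
projection round-trips losslessly), so conserved epitopes line up across
related toxins.

## Comparing experiments and annotating structures

`overlap_counts()` decomposes two or three binder sets into exclusive
Venn regions by direct membership enumeration, and
`non_shared_fraction()` summarises dilution agreement as
$(|A \cup B| - |A \cap B|)/|A \cup B|$ — the union denominator is the
documented default. `toxins_with_binders()` maps a binder set back to
the antigens recognised through at least one peptide.

`annotate_pdb()` writes per-residue values (residue scores or alanine
effects) into the temperature-factor column (columns 61–66) of a PDB
file so any molecular viewer can colour the structure by them. Values
are min–max scaled into [0, 99.99] by default — raw medians can
overflow the fixed-width `%6.2f` field — with the scaling parameters
stored in a JSON sidecar so raw values stay recoverable; unannotated
residues of the targeted chain receive a fill value (0 by default).
Mapping is by author residue numbering, with an `offset` argument to
reconcile sequence and structure numbering. The implementation edits
only the B-factor bytes: atom records, coordinates and numbering are
untouched, which the tests verify byte-by-byte and via an independent
PDB parser.

## The synthetic-data generator

`synthetic_toxins()`, `plant_epitopes()` and `simulate_experiment()`
emulate the signal structure the analysis relies on:

* a near-normal background population: every peptide draws one baseline
  offset per experiment from `Normal(0, background_sd)`, representing
  sequence-dependent unspecific binding and auto-fluorescence
  (defaults: mean 50 AU, SD 8 AU);
* planted epitopes as cores of 7–9 residues placed inside actual tiling
  windows, so every wild-type peptide whose span fully contains a core
  is elevated by the epitope amplitude and elevated signals form runs
  across overlapping tiles (default amplitude 160 AU, i.e. 20
  background SDs);
* five replicate spots per wild-type peptide, each with independent
  `Normal(0, replicate_sd)` spot noise (default 8 AU), clipped at zero;
* key residues within each core whose alanine substitution multiplies
  the amplitude by `knockdown` (default 0.25, an expected effect of
  $\log_2\frac{0.25A + \mu_b}{A + \mu_b}$, about −1.22 at the default
  amplitude and exactly −2 in the idealised zero-background case).

`derive_truth()` computes, without randomness, the exact binder set and
per-residue expected effects implied by a planted design, which is what
the test suite scores the pipeline against.

Deliberate simplifications: substituting a *non-key* epitope residue
leaves the signal unchanged (a sharp oracle, which makes expected
effects exact); partial containment of a core does not attenuate the
signal — a window either contains the core or sits at baseline; there
are no spatial array artifacts, scanner saturation or antibody
competition. Passing the recovery tests therefore demonstrates that the
statistical machinery is correct under its own assumptions, not that
those assumptions hold on any particular real array; on real data the
smooth transition between background and specific binding makes the
percentile and SD-multiplier choices genuinely consequential, which is
why both are configurable.

## Problem sizes and numerical choices

The synthetic validation study uses 30 antigens of 30–80 residues, 10
planted epitopes, and 20 simulation seeds — large enough that the
library holds several hundred wild-type peptides and ~13,000 null
classifications accumulate across seeds, and small enough to keep the
whole suite fast. Under those conditions binder precision and recall
are both exactly 1.0 in every seed, estimated key-residue effects land
within ±0.3 of the truth formula, and no null experiment has produced a
false binder.

Other numerical conventions collected in one place: medians use the
standard even-*n* mean-of-middle-two; SDs are sample SDs (n−1), zero
for a single replicate; background estimation refuses fewer than 10
wild-type medians; the binder rule uses a strict inequality, so a
degenerate all-equal background (SD 0) yields no binders; random layout
and simulation draws run under an isolated RNG state that is restored
afterwards, so package calls never disturb the caller's random stream.

## Limitations

Only linear epitope elements are observable: discontinuous epitopes
whose parts never co-occur within a 12-mer window are invisible, and
the structure-annotation module only visualises — it does not infer —
spatial adjacency of linear elements. Peptides on a slide lack the
native fold's constraints, so binding to a tile is evidence about the
sequence element, not proof the antibody binds the folded toxin. The
library counts of the original inventory can only be reproduced from
the actual mature sequences; the package validates a user-supplied
FASTA against the bundled annotation table (`validate_study_sequences()`)
but does not bundle the sequences themselves.
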