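---
title: "Quantifying polar effects of gene deletions in bacterial operons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polar effects of gene deletions in bacterial operons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operonpolar)
```

## The problem

In bacteria, adjacent genes are commonly co-transcribed as operons.
When a single gene is deleted — typically by replacing its coding
sequence with a selectable resistance cassette, as in genome-wide
deletion libraries — the modification can change the expression of the
*other* genes of the operon. Two distinct phenomena are at play:

1. **A transcriptional polar effect.** The cassette carries its own weak
   promoter and no terminator, so everything transcribed downstream of
   the deletion can be shifted up or down as a block, at both the mRNA
   and the protein level.
2. **A post-transcriptional effect on the gene directly downstream**
   (the *position +1* gene). Even though library designs retain the last
   ~21 nt of the deleted gene to keep the downstream ribosome binding
   site intact, the +1 gene is additionally depleted at the protein
   level only, and more strongly the closer its start codon sits to the
   deleted gene's stop codon — consistent with impaired translation
   initiation / loss of translational coupling.

`operonpolar` turns raw measurements — multiplexed (TMT) protein
signal-sum intensity matrices and strand-separated WIG coverage
tracks — into operon-relative fold-change profiles, classifies
operon-level effects per mutant, and tests the +1 signature and its
distance dependence.

## The analysis model

### Median-reference fold changes

Channel intensities are only comparable within one multiplexed
mass-spectrometry experiment (a *plex*). After within-plex
normalization, the fold change of protein $g$ in mutant $m$ is

$$\mathrm{log_2FC}(g, m) \;=\; \log_2 \frac{x_{gm}}{\operatorname{median}_{m' \in \mathrm{plex}} x_{gm'}},$$

with the focal sample included in the median. With most genes unchanged
in most mutants, the across-mutant median stands in for the wild-type
reference; by construction the median *linear* fold change per
(protein, plex) is exactly 1. Replicate fold changes are averaged on the
log2 scale (symmetric in up/down; a linear-scale option exists).
Transcript abundances are handled analogously: per-position WIG counts
are summed over both strands, summed over the gene body, divided by gene
length, rows with density < 1 count/nt are discarded (before the median
reference is formed, so the median runs over surviving mutants only),
and the same median-reference ratio is taken across mutants.

Two normalization methods are provided. `median_log` equalizes the
per-channel median log-intensity within a plex (a pure scale factor).
`vsn_like` fits a per-channel affine calibration (offset and scale) by
iterated Huber regression of each channel on the plex-wide median
protein profile, monitoring convergence on the spread of
generalized-log–transformed values; it is a deliberate simplification of
variance-stabilizing normalization (no maximum-likelihood arsinh
variance model) and is recorded as such in the output. Both preserve
within-channel rank order. Heavy pipelines in this package's own test
battery use `median_log`, whose single pass keeps the thousand-library
calibration runs fast; `vsn_like` is the default for single analyses.

### Operon-relative positions and the median correction

Each mutant's measured operon mates are indexed relative to the deleted
gene (negative upstream, positive downstream, in transcription order;
the deleted gene itself — position 0 — is kept in fold-change tables but
excluded from every positional analysis). Within each mutant and
datatype, the per-side median correction subtracts the median log2 fold
change of all upstream genes from each upstream gene, and likewise
downstream; it removes the shared transcriptional block shift so that
gene-specific deviations stand out. Corrected values are only emitted
where at least `min_genes = 2` genes are quantified on that side, and
the emitted side medians are 0 by construction.

### Classification and tests

* **Operon classification** takes the median uncorrected log2 fold
  change over downstream positions $\ge +2$ — the +1 gene is excluded
  because it carries the additional post-transcriptional effect — and
  calls the operon `up` / `down` when the median strictly exceeds
  $\pm 1$ (2-fold), `none` otherwise, `not_evaluable` when no such gene
  was measured. Fractions are reported over evaluable mutants.
* **The +1 test** is a two-sample Wilcoxon rank-sum comparing the +1
  values (one per mutant) against the pooled values at positions
  $\ge +2$, on raw or corrected values. The test is exact by full
  enumeration of group assignments when $n_1 + n_2 \le 12$ (valid under
  ties), otherwise it uses the normal approximation with tie and
  continuity corrections. A one-sample signed-rank variant against 0 is
  available behind a flag, because the published analyses name the test
  but not the comparison group; the two-sample reading makes the
  "*additional* downregulation at +1" claim directly testable and is
  the default.
* **Distance correlation**: Spearman rank correlation (average ranks,
  two-sided t-approximation p-value) between the corrected +1 value and
  the intergenic distance, defined as
  (first base of the downstream start codon) − (last base of the deleted
  stop codon) − 1 on wild-type coordinates, so abutting ORFs give 0 and
  overlaps are negative. The published analyses do not state their exact
  offset; any alternative differs by a constant, so rank statistics are
  unaffected.
* **Concordance**: Pearson correlation of log2 fold changes joined on
  (gene, mutant), e.g. protein vs RNA.

All p-values are reported unadjusted, matching how such screens report
these statistics; no multiple-testing correction is applied.

## Design choices where the design was open

* **Downstream correction median includes +1.** The methods convention
  "all genes located downstream" is read literally; since the +1 gene
  may carry a genuine extra effect, an `include_p1 = FALSE` flag
  computes the reference median over positions $\ge +2$ instead (still
  subtracted from all downstream genes).
* **Reference median includes the focal sample.** This makes the
  per-(protein, plex) median fold change exactly 1 and is the literal
  reading of "all the mutants in the same experiment". With $\ge 3$
  mutants per plex the bias is small; fewer mutants trigger a warning.
* **Strict 2-fold threshold.** "At least 2-fold" maps to a strict
  inequality on the log2 median; a median of exactly 1.0 log2 classifies
  as `none`.
* **Transcription order from the operon table.** EcoCyc-style tables
  list genes 5'→3' of the transcript; the table order wins over any
  strand-derived ordering, and operon genes missing from the annotation
  set only forfeit their intergenic distance (with a warning) rather
  than failing the run.
* **Zero intensities are missing.** A zero signal sum is below
  detection, not a measured zero; mapping zeros to `NA` at the container
  boundary keeps every downstream log finite. No imputation anywhere;
  statistics use available cases, so per-position n varies.

## The synthetic library generator

`simulate_library()` builds a toy genome of operons laid head-to-tail on
one chromosome (both strands), deletes one non-terminal gene per
multi-gene operon plus the lone gene of each single-gene operon
(negative controls), and emits exactly the inputs the pipeline consumes,
with ground truth recorded for every drawn effect:

* a **transcriptional operon effect** per mutant — up-shift with
  probability 0.35 (log2 magnitude uniform on (0, 2], i.e. up to
  4-fold) or down-shift with probability 0.30 (uniform on [−3, 0), up
  to 8-fold) — applied to all downstream genes at both the RNA and
  protein level; with these uniform magnitudes roughly 18% / 20% of
  evaluable operons exceed the 2-fold classification threshold,
  matching the reported prevalence in real deletion libraries;
* an **additional protein-only +1 effect**
  $\Delta_{+1} = \mathrm{max}_{+1} \cdot e^{-\max(d,0)/\lambda}$ with
  default maximum −1 log2 at distance 0 and length scale
  $\lambda = 30$ nt; the exponential form is a convenient monotone
  stand-in (any decreasing form would do and the parameters are
  config-exposed), and overlapping ORFs receive the maximal effect;
* default within-operon intergenic distances uniform on [−20, 60] nt —
  short, frequently overlapping spacings typical of operons, which is
  what makes the +1 deficit clearly visible in aggregate;
* protein intensities $2^{(\mathrm{baseline} + \mathrm{effects} +
  \mathcal{N}(0, 0.2) + \mathrm{channel})}$ packed round-robin into TMT
  plexes of 10 channels, two replicates; per-channel log2 scale jitter
  (sd 0.25) gives the normalization step something real to remove;
* RNA coverage as per-position Poisson counts at a mean depth of
  10 counts/nt for a baseline gene, split into forward/reverse tracks by
  gene strand;
* the deleted gene itself drops to a knockout residual of −5 log2
  (position 0 is excluded from the statistics regardless);
* under `condition = "excised"` the upward effect component is zeroed
  (the cassette promoter is gone) while downward effects and the +1
  effect persist.

Identical parameters and seed give byte-identical libraries, including
on disk.

What the generator deliberately does **not** emulate: peptide-level
variation and protein inference, missingness that correlates with
abundance, thermal-stability covariates, sequence-level features (RBS
strength, mRNA folding), internal promoters/terminators, or
non-uniform coverage within genes. Passing recovery tests therefore
demonstrates that the pipeline's inference is correct under the stated
generative model, not that real libraries satisfy that model.

## Numerical and scale choices

* The exact rank-sum branch enumerates all
  $\binom{n_1+n_2}{n_1} \le 924$ assignments; beyond
  $n_1 + n_2 = 12$ the normal approximation with tie and continuity
  corrections takes over (they agree to $|\Delta p| \le 0.02$ at
  $n_1 = n_2 = 6$).
* Correlation p-values use the t-approximation with $n-2$ df;
  $|\rho| = 1$ reports $p = 0$; correlations require $\ge 3$ complete
  pairs ($\ge 4$ for the distance correlation).
* Validation problem sizes were chosen to characterize the statistics
  well at desk scale: 1000 null libraries of 15 operons for the type-I
  error of the +1 test, a 200-operon library for fraction and +1
  recovery, a 40-operon dual-datatype library for the protein-only
  signature, and 250-trial brute-force oracle sweeps on instances of
  size ≤ 8 per operation.
* Genes spanning the origin of a circular chromosome are not supported;
  WIG parsing follows UCSC fixedStep/variableStep/span semantics via
  rtracklayer.

## A worked example

```{r example}
params <- simulation_params(n_operons = 30, seed = 7)
lib <- simulate_library(params)
run <- run_protein_pipeline(lib$intensities, lib$annotations,
                            lib$operons, lib$deletions,
                            normalization = "median_log")
run$fractions
run$p1_test_corrected
run$distance_test
recovery_report(lib, run$effects, run$corrected)
```

The RNA pipeline on the same library shows the transcriptional shifts
but not the +1 deficit:

```{r rna}
rna <- run_rna_pipeline(lib$rna_tracks, lib$annotations, lib$operons,
                        lib$deletions)
rna$p1_test
concordance(run$fold_changes, rna$fold_changes)
```

## Limitations

* The pipeline assumes most genes are unchanged in most mutants; the
  median reference absorbs global scale but not a genuinely shifted
  majority. Sequencing-depth differences beyond that are not separately
  normalized.
* Operon structures are an input; there is no operon prediction and no
  handling of internal promoters or terminators.
* `vsn_like` is not vsn: it calibrates affinely and robustly but fits no
  variance model. For publication-grade normalization of real data,
  run the dedicated normalization first and feed the calibrated matrix
  in.
* When exactly two downstream genes are quantified, the per-side median
  is the mean of the two values, so the correction absorbs half of any
  genuine +1-specific effect; estimates of the +1 deficit are therefore
  conservative for such operons (the recovery validation uses deletions
  with three or more downstream genes, where the median is robust to the
  single +1 outlier).
* Deletions of genes that may regulate their own operon are not detected
  automatically; pass them via `exclude =` to
  `classify_operon_effects()` or the pipeline wrappers.
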