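# operonpolar

Polar effects of single-gene deletions on the other members of
bacterial operons, quantified from multiplexed proteomics and RNA-seq
coverage data.

When a gene inside an operon is replaced by a resistance cassette (as
in genome-wide deletion libraries of *Escherichia coli*), two things
happen to its neighbors:

* **Transcriptional polar effects** — all genes downstream of the
  deletion shift up or down as a block (the cassette carries its own
  weak promoter and no terminator), visible at both the mRNA and the
  protein level.
* **A post-transcriptional effect on the gene directly downstream**
  (position +1): an *additional* protein-only depletion that is
  stronger the closer the downstream start codon sits to the deleted
  gene's stop codon, consistent with impaired translation initiation.

`operonpolar` is for proteomics / functional-genomics groups who work
with deletion or knockdown libraries and need to know how much of a
mutant's phenotype could be carried by its operon mates rather than the
targeted gene.

## What it computes

For protein, per plex (one multiplexed MS experiment), after
within-plex normalization (`vsn_like` affine calibration or
`median_log` scaling):

```
log2FC(g, m) = log2( x[g, m] / median over mutants m' in plex of x[g, m'] )
```

and analogously for RNA with per-gene coverage densities (summed
strand-summed WIG counts / gene length, rows with density < 1 count/nt
removed) against the across-mutant median. Fold changes are averaged
over replicates (log2 scale), positioned relative to the deleted gene
in its operon, and corrected per side by subtracting the upstream /
downstream median of the same mutant. On top of that:

* operon classification per mutant: median log2FC over positions >= +2
  (the +1 gene is excluded), `up`/`down` beyond a strict 2-fold
  threshold; fractions over evaluable mutants;
* the +1 test: Wilcoxon rank-sum of the +1 values against pooled
  positions >= +2 (exact by enumeration when n1+n2 <= 12, valid under
  ties; normal approximation with tie/continuity correction otherwise);
* Spearman correlation of the corrected +1 deficit with the intergenic
  distance (stop codon -> start codon, 0 = abutting, negative =
  overlapping ORFs);
* Pearson concordance between protein and RNA fold changes.

A synthetic-library generator (`simulate_library()`) emits annotations,
operon tables, TMT-style intensity matrices and strand-separated WIG
tracks with known ground truth (operon shifts up to 4-fold up / 8-fold
down; a distance-decaying protein-only +1 effect), so the whole
pipeline is testable without any external download.

## Worked example

```r
library(operonpolar)

lib <- simulate_library(simulation_params(n_operons = 30, seed = 7))
run <- run_protein_pipeline(lib$intensities, lib$annotations,
                            lib$operons, lib$deletions,
                            normalization = "median_log")
run$fractions
#>   condition datatype n_evaluable n_up n_down frac_up frac_down
#> 1  cassette  protein          18    0      4       0 0.2222222
```

Of the 18 mutants with at least one quantified gene at position >= +2,
4 (22%) have their downstream operon block repressed more than 2-fold.
The gene directly downstream of the deletion is additionally depleted
even after the shared operon shift is subtracted:

```r
run$p1_test_corrected
#> Wilcoxon rank sum test (normal approximation)
#>   statistic = 51
#>   p-value   = 1.2912e-06   (unadjusted)
#>   n         = 18 vs 33
run$distance_test
#> Spearman rank correlation (t approximation)
#>   estimate  = 0.7873798
#>   p-value   = 0.00010512   (unadjusted)
#>   n         = 18
```

The positive rho says +1 genes closer to the deleted stop codon are hit
harder. At the RNA level the same library shows no +1 effect — the
signature of a post-transcriptional mechanism — while the operon-block
shifts agree between the two datatypes:

```r
rna <- run_rna_pipeline(lib$rna_tracks, lib$annotations, lib$operons,
                        lib$deletions)
rna$p1_test$p_value
#> [1] 0.8878097
concordance(run$fold_changes, rna$fold_changes)$estimate
#> [1] 0.768808
```

`recovery_report(lib, run$effects, run$corrected)` compares everything
against the simulation's ground truth.

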