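# allomethyl

Methylome trajectories in allopolyploid *Arabidopsis*.

When two species hybridize and double their genomes, the two parental
methylomes are forced into one nucleus. `allomethyl` is a tidyverse-native R
package for asking what happens next: it follows per-cytosine bisulfite
data across a six-line design — the two parents (*A. thaliana* "ath",
*A. arenosa* "aar"), their F1 hybrid, two resynthesized allotetraploids
("a733", "a738", ~10 selfed generations) and the natural allotetraploid
*A. suecica* ("asu", thousands of generations) — and classifies how
methylation differences between the two subgenomes evolve: do they persist,
or do the subgenomes converge?

The package is aimed at plant epigenomics researchers who want a tested,
reusable implementation of this window-based DMR pipeline, plus a fully
controlled synthetic cohort to validate it against.

## The method

1. **Site harmonization.** Per-line replicates are merged by summing counts;
   cytosines need ≥ 3 merged reads; only sites shared by *all* lines and
   lying in conserved homology blocks (≥ 1 kb, alignment score ≥ 1,000) are
   kept. T-subgenome samples are projected into the A-subgenome coordinate
   frame through the homology map so homologous cytosines align.
2. **DMR calling.** Counts are pooled over 100-bp windows per context
   (windows need ≥ 4 CG, ≥ 4 CHG or ≥ 16 CHH cytosines). For each window the
   weighted methylation level is `m = Σ meth / Σ total`, and the 2×2 pooled
   count table is tested with a two-sided Fisher's exact test. Within each
   comparison and context, p-values are Benjamini–Hochberg adjusted; a
   window is a DMR when `q < 0.05` and `|Δm|` reaches the context cutoff
   (0.5 CG, 0.3 CHG, 0.1 CHH). `direction = hyper` means the focal sample
   (allotetraploid, or A subgenome) is more methylated.
3. **Trajectory classification.** *Convergent*: hyper (A > T) in parents,
   F1 and both resynthesized lines, but collapsed (|Δ| < cutoff) in the
   natural line. *Conserved*: hypo-DMR vs the parent in the natural line
   that is already present in the F1 and/or resynthesized lines (reported
   per line and as the all-three intersection). Overlap enrichment between
   window or gene sets uses Fisher's test on the 2×2 membership table.
4. **Gene and expression association.** Genes within 2 kb of a DMR are
   linked to it; per-gene expression ratios are
   `log2((TPM₁ + 1)/(TPM₂ + 1))` on replicate means; groups are compared
   with Mann–Whitney tests; per-gene methylation–expression correlation and
   homolog-pair convergence statistics follow.
5. **LTR dating.** LTR retrotransposon insertion ages from 5′/3′ LTR
   divergence `d` via the Jukes–Cantor correction `K = −¾·ln(1 − 4d/3)` and
   the clock `t = K/2r` with `r = 7 × 10⁻⁹` substitutions/site/generation
   (one generation = one year).

A synthetic cohort generator (`simulate_cohort()`) plants windows with
known trajectories (convergent, conserved, persistent hyper, methylation
gain in the natural line) over beta-distributed baselines, samples reads
binomially under negative-binomial depth, and couples expression negatively
to the planted methylation changes — so recall, precision, and false
discovery control of the whole pipeline can be measured against truth.

## Worked example

```r
library(allomethyl)

run <- run_cohort_analysis(cohort_config(), seed = 1)
glance(run)
#>   n_lines n_shared_sites n_tested_windows n_dmr_total percent_convergent
#> 1       6         239992             7500         865               38.1
#>   association_p seed
#> 1  1.065042e-27    1
```

The cohort plants 210 trajectory windows (60 convergent, 60 conserved,
30 persistent, 60 gain-in-natural) on a 750-kb subgenome pair at depth 20.
`percent_convergent` is the share of parent A-vs-T hyper-DMR windows whose
difference collapses in the natural allotetraploid: 38.1% here, because
the parent-hyper universe also contains the 30 persistent windows and the
60 conserved windows (the A parent is hypermethylated there too, but the
loss already happens in the F1, so they classify as "other" on the
hyper axis). `association_p` is the Mann–Whitney p-value comparing log2
expression ratios of hypo- vs hyper-DMR-linked genes; its tiny value
reflects the planted negative coupling.

Per-comparison DMR counts are in `tidy(run)`; individual stages are plain
functions (`merge_replicates()`, `harmonize()`, `make_windows()`,
`call_dmrs()`, `classify_trajectory()`, `genes_near_dmrs()`, `ltr_age()`,
…) that take and return tibbles, so they compose with the pipe. Each
result type has a plot: `autoplot()` on DMR calls (volcano),
`plot_dmr_counts()`, `plot_trajectory_classes()`,
`plot_expression_by_dmr()`, `plot_ltr_ages()`.

```r
ltr_age(tibble::tibble(element_id = "e1", d = 0.014))
#> # A tibble: 1 × 4
#>   element_id     d      K  t_years
#>   <chr>      <dbl>  <dbl>    <dbl>
#> 1 e1         0.014 0.0141 1009451.
```

## Limitations

The synthetic cohort uses gapless identity homology blocks, identical
cytosine positions on both subgenomes, and site effects shared across
lines; real WGBS data adds alignment ambiguity, coverage biases and
strain-level variation that the generator deliberately omits (see the
methods vignette, `vignettes/methylome-trajectories.Rmd`).
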