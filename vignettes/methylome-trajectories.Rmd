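---
title: "Methylome trajectories in allopolyploids: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome trajectories in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomethyl)
```

## The scientific setting

An allotetraploid carries two complete parental genomes (here called the A
and T subgenomes, after *Arabidopsis arenosa* and *A. thaliana*). The two
parents differ markedly in DNA methylation, especially at CG sites. This
package follows what happens to those differences across a six-line
design: the parents, their F1 hybrid, two resynthesized allotetraploids
(about ten selfed generations old) and the natural allotetraploid
*A. suecica* (many thousands of generations old). The central questions
are statistical: which 100-bp windows are differentially methylated
between which lines, how those differences evolve (convergence of the two
subgenomes versus persistence), and how methylation changes couple to gene
expression.

## The statistical model

### Window testing

Per-cytosine bisulfite counts are pooled within fixed 100-bp genomic
tiles, separately per context (CG, CHG, CHH). The **weighted methylation
level** of a window is the pooled ratio `m = Σ n_meth / Σ n_total`, which
weights each cytosine by its coverage and is therefore robust to uneven
depth. A window is compared between two samples with a **two-sided
Fisher's exact test** on the pooled 2×2 table (methylated/unmethylated ×
sample). The two-sided p-value is the sum of hypergeometric point
probabilities not exceeding that of the observed table (with the customary
`1 + 1e-7` relative tolerance); tables with a zero margin carry no
information and are assigned p = 1. Pooling counts before testing treats
reads, not cytosines, as the sampling unit — consistent with the weighted
methylation level being the tested quantity.

Within one comparison and context, p-values are adjusted by
Benjamini–Hochberg (via `stats::p.adjust`), and a window is called a DMR
when `q < 0.05` **and** the methylation difference reaches the context
cutoff: 0.5 (CG), 0.3 (CHG), 0.1 (CHH). The effect-size cutoff matters:
with hundreds of pooled reads, trivial differences become significant, so
the cutoff fixes the minimum biologically meaningful change. Windows with
fewer than 4 (CG, CHG) or 16 (CHH) cytosines are never tested; CHH sites
are individually weakly methylated, hence the higher site requirement.

"Sliding windows" are implemented as non-overlapping tiles by default
(`step = window_size`). A smaller step is supported, but tiling avoids
double-counting windows in the downstream set arithmetic (overlaps,
inheritance fractions), which is why it is the default; adjacent
significant windows are deliberately *not* merged, so all counts are
window counts.

### Site harmonization

Before any testing, lines are made comparable: replicate counts are summed
per cytosine ("shared methylation sites in replicates are merged"), sites
need ≥ 3 merged reads per line, and the site set is intersected across
**all** lines jointly — one shared-site universe for every comparison
rather than pairwise universes, so every downstream set operation is on
one frame. The ≥ 3-read rule is applied after merging (the merged counts
are what is analysed); applying it per replicate would conflate replicate
depth with biology. Sites must also lie in conserved homology blocks
(length ≥ 1 kb, alignment score ≥ 1,000): outside such blocks, "the same
position" in two genomes is not well defined. T-subgenome samples are
projected through the homology map into A-subgenome coordinates; blocks
are gapless, so the projection is an offset (with strand flip for inverted
blocks). Cytosines are kept per strand throughout — the inputs are
per-strand cytosine reports, and collapsing CG dyads would discard strand
asymmetries.

### Trajectory classification

All classification happens on the shared window universe, with delta
oriented A − T (for subgenome comparisons) or allotetraploid − parent.

* **Convergent**: hyper (A > T) DMR in the parents *and* the F1 *and*
  both resynthesized lines, while in the natural line the window is not a
  DMR and |Δ| is below the context cutoff ("decreased to a similar
  level"). The change threshold plays both roles — a hyper call must
  reach it and the natural line must sit within it — mirroring the single
  0.5 CG change threshold of the study design. Because the two roles pull
  in opposite directions, the convergent count is not globally monotone
  in this threshold; the packaged tests check monotonicity of each role
  separately.
* **Persistent hyper**: the A > T difference survives into the natural
  line. Every parent-hyper window receives exactly one of
  {convergent, persistent_hyper, other}.
* **Conserved**: a hypo-DMR (vs the A parent) in the natural line that is
  already hypo in the F1, in either resynthesized line, or in all three.
  The "and/or" ambiguity of *consistently present in F1, Allo733 or
  Allo738* is resolved by reporting both: per-line flags/fractions *and*
  the all-three intersection.
* **Both**: a window meeting the convergent and conserved definitions
  simultaneously. At the window level this requires a parent A−T
  difference of at least twice the cutoff with intermediate
  allotetraploid levels, so it is essentially empty in practice; the
  overlap of the two classes is biologically a *gene-level* statement,
  computed here with `genes_near_dmrs()` + `overlap_enrichment()`. The
  generator therefore does not plant this class, but the classifier still
  emits the label when the criteria co-occur.

DMRs between A and T are oriented hyper = A > T and hypo = A < T; the
alternative reading of the hypo condition (T < A) is identical to the
hyper one and is taken to be a transcription slip.

### Association with expression

Genes within 2 kb of a DMR (half-open interval arithmetic on the gene
body extended by the flank) are linked to it. Expression ratios are
`log2((mean TPM + 1) / (mean TPM + 1))` over replicates; the pseudocount
of 1 keeps silent genes defined and maps (0, 0) to a ratio of 0. Group
contrasts (e.g. hypo- vs hyper-linked genes) use the Mann–Whitney test
(`stats::wilcox.test`: exact for small tie-free samples, normal
approximation with tie correction otherwise). Per-gene
methylation–expression correlation across the five informative lines is
Pearson by default (five points; rank methods are available via
`method = "spearman"` but discard most of the information at n = 5).
Homolog-pair convergence reuses the CG change cutoff 0.5 as the
methylation-difference threshold, and "upregulated" defaults to a
two-sided two-sample t test across the 3 expression replicates at
p < 0.05 with a positive log ratio — both are arguments, because neither
threshold is canonical.

### LTR insertion dating

For an LTR retrotransposon, the 5′ and 3′ LTRs are identical at insertion
and diverge afterwards; the observed mismatch proportion `d` (gap and N
columns excluded) is corrected for multiple hits with the Jukes–Cantor
model, `K = −¾·ln(1 − 4d/3)` (defined for `d < 0.75`), and converted to
years by `t = K / 2r` with `r = 7 × 10⁻⁹` substitutions per site per
generation and one generation per year. `K = 0.014` therefore dates an
element to 1.0 million years.

## The synthetic cohort generator

`simulate_cohort()` is the test bed: a cohort whose truth is known
exactly.

* **Genome**: one chromosome pair (`sA1`, `sT1`) of equal length
  (default 750 kb), linked by a single gapless identity homology block.
  Cytosine positions are identical on both chromosomes — they are
  "conserved cytosines" by construction — with fixed per-window site
  counts (6 CG, 6 CHG, 20 CHH per 100 bp) so tested windows always meet
  the site minimums.
* **Baselines**: each window draws one baseline methylation level per
  context from a Beta distribution shaped to resemble leaf methylomes
  (means ≈ 0.24 CG, 0.10 CHG, 0.03 CHH), shared by all samples — so
  un-planted windows are exact nulls.
* **Planted classes** (default CG): convergent, conserved,
  persistent_hyper, and asu_hyper (methylation gained in the natural
  line; added so the expression analysis has a hyper-DMR gene group).
  Low/high levels are 0.15/0.75, i.e. a planted effect of |Δμ| = 0.6 —
  comfortably above the 0.5 CG cutoff yet small enough that calling is
  non-trivial at realistic depth. Planted windows sit on spaced tiles
  (default 26 tiles = 2.6 kb apart) so each linked gene (500 bp, placed on
  its window) is within 2 kb of exactly one planted window.
* **Counts**: per cytosine, a site effect `Normal(0, 0.05)` is drawn once
  and shared by all samples and replicates (replicates share biology and
  lines share sequence context; only sampling differs), the probability is
  clipped to [0, 1], read depth is negative binomial (mean 20,
  dispersion 5 — WGBS depth is overdispersed; Poisson is the
  dispersion → ∞ limit), and methylated counts are binomial. Defaults of
  depth 20 and 2 replicates mirror a mid-depth WGBS study.
* **Expression**: each gene has a shared log2 baseline
  (`Normal(5, 1)`); in lines where the gene's subgenome is hypomethylated
  relative to the parent at the planted window, log2 expression rises by
  `effect × (μ_parent − μ_line)/Δμ` (default effect 1), and falls
  symmetrically for methylation gain — planted *negative* coupling.
  Replicate noise is log-normal (sd 0.25 in log2, 3 replicates). Parents
  only express the genes of their own subgenome.
* **Determinism**: one master seed spawns named child streams
  (placement, baseline, counts, expression), so identical
  `(config, seed)` give byte-identical outputs and individual stages can
  be regenerated independently.

What the generator does **not** emulate: alignment ambiguity and mapping
bias, bisulfite conversion failure, coverage waves, non-identity homology
(indels within blocks), strain-level sequence divergence, and chromosomal
methylation gradients. Passing the packaged tests therefore shows that
the *statistics* behave as designed under the stated sampling model — it
does not certify performance on real libraries, where the harmonization
filters carry more of the burden.

## Validation experiments and problem sizes

Three packaged experiments measure the pipeline against the generator's
truth; their sizes were chosen to give stable Monte-Carlo estimates while
staying desk-scale:

* `estimate_null_fdp()`: 200 two-line cohorts with zero planted effects,
  5,000 CG windows at depth 20 each; the mean false-discovery proportion
  `V / max(R, 1)` at q < 0.05 and |Δ| ≥ 0.5 is compared to the nominal
  0.05 plus three standard errors. With the effect cutoff in place,
  discoveries under the null are rare, so the estimate is conservative.
  Only the two compared lines are simulated — the other four would not
  enter the comparison.
* `evaluate_trajectory_recovery()`: 20 full six-line cohorts, 200
  convergent + 200 conserved planted CG windows (|Δμ| = 0.6, depth 20, 2
  replicates); mean recall and precision per class. At these settings a
  single pooled window carries ≈ 240 reads per sample, so per-comparison
  power is ≈ 0.99 and the four-comparison convergent definition retains
  recall above 0.9.
* `evaluate_association_direction()`: one cohort with 200 hypo
  (conserved) and 200 gain windows, one linked gene each; hypo-linked
  genes' log2(natural/parent) ratios must stochastically dominate
  hyper-linked ones (Mann–Whitney).

## Numerical and degenerate-input conventions

* Weighted methylation of an uncovered window is `NA` and the window is
  excluded (flagged by absence from the tested set).
* Fisher tables with a zero margin return p = 1; the vectorized
  implementation chunks its enumeration to bound memory and matches
  `stats::fisher.test` and exhaustive enumeration to ≤ 1e-12.
* Percentages are reported to one decimal with round-half-even, the
  convention used for all `(numerator/denominator)` summaries.
* Empty DMR child sets make inheritance fractions `NA` (with a warning)
  rather than 0 — "none inherited" and "nothing to inherit" are
  different findings.
* Coordinates are 0-based half-open internally everywhere; BED is native,
  GFF3 is converted on read/write, cytosine report positions stay
  1-based as in the input format. Chromosome names match by exact string
  equality.

## Known limitations

* The homolog-frame projection supports gapless blocks only; gapped
  alignments must be pre-split into gapless pieces upstream.
* `classify_trajectory()` assumes the five standard comparisons of the
  six-line design; other pedigrees require calling the flag functions
  directly.
* The window-level "both" class is reported but near-unreachable (see
  above); the convergent/conserved overlap is meaningful at the gene
  level.
* Gene-level and window-level pooling share code paths but differ in
  universe: gene methylation uses all harmonized cytosines in the gene
  interval regardless of window site minimums.
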