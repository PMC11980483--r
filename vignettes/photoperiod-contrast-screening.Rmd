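---
title: "Screening for contrasting photoperiod responses with rank-sum scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for contrasting photoperiod responses with rank-sum scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photorank)
```

## The screening problem

Consider two genotypes of one plant species with opposite photoperiodic
requirements for flowering: genotype A flowers under long days (LD, here 18 h
light) and genotype B under short days (SD, 6 h light). Genes driving floral
induction in both genotypes are expected to respond to photoperiod in
*opposite* directions — activated by LD in A and by SD in B, each according
to its genotype's requirement. Neither a per-genotype DEG list nor a naive
interaction test targets this pattern directly: the object of interest is a
*cross-genotype contrast* in the direction of the photoperiod response,
concentrated in the developmental window when induction actually happens.

photorank implements this screen as a small, fully testable pipeline:

1. **Differential expression** between LD and SD, per genotype, per sampling
   day, per time of day (morning / afternoon series are analyzed
   independently throughout).
2. **Direction-aware ranking** of the DEGs of each comparison by log2 fold
   change: descending (most LD-up first) in genotype A, ascending (most
   SD-up first) in genotype B.
3. **Rank-sum scoring**: for each gene, the four ranks from the inductive
   window (two later sampling days of each genotype) are summed. The genes
   with the smallest sums show the most contrasting photoperiod response.
4. **Filtering and union**: genes with low or fluctuating expression are
   removed; the morning and afternoon candidate lists are united with
   inclusion–exclusion accounting (`n_union = n_m + n_a - n_both`).

A synthetic-data generator with planted gene classes makes every stage's
behaviour measurable against known truth.

## The sampling design

The default design mirrors a diurnal induction time course: genotype A
sampled at 13, 15 and 19 days after sowing (DAS), genotype B at 14, 21 and
24 DAS, each under both photoperiods, at 9:00 (morning) and 15:00
(afternoon), with three biological replicates — 72 libraries in all. The two
*later* sampling days of each genotype form the floral-induction window: by
then plantlets under permissive photoperiod are being induced to flower
while those under non-permissive photoperiod are not. The first day serves
as a pre-induction baseline and does not enter the contrast score.

## The differential expression model

The paper-scale analysis this package abstracts would normally use a
dedicated DE package; photorank instead ships a deliberately small,
closed-form negative binomial test, because the downstream algorithm
consumes only the *ranking* of DEG log fold changes, not shrunken effect
sizes. The divergences from heavier tools are intentional and documented
here.

**Normalization.** Median-of-ratios size factors against the geometric-mean
pseudo-reference, computed over genes with no zero count. Because each ratio
compares a sample to the same gene's geometric mean across samples, the
factors capture relative library depth only; normalized counts stay on the
raw count scale, which keeps all count-denominated thresholds interpretable.
The flip side, worth stating plainly: a *global* rescaling of the matrix is
cancelled rather than propagated, so quantities that involve the pseudocount
or the expression floors can move slightly (order 10^-3 in logFC for
expressed genes) when overall depth changes.

**Dispersion.** Gene-wise negative binomial dispersion `alpha` (in
`var = mu + alpha * mu^2`) by method of moments: within each replicate group
`k` with sample mean `m_k` and variance `s2_k`, the moment term is
`(s2_k - m_k) / m_k^2`; the estimate is the mean of these terms over *all*
replicate groups in the design, floored at 1e-8. Pooling across the whole
design rather than only the two groups being compared is the package's main
stabilizing choice: with three replicates, a two-group estimate has four
degrees of freedom and is so noisy that the Wald test is badly
anticonservative (about 10% of null genes at p ≤ 0.05), while any reference
distribution wide enough to fix that destroys the far-tail power that
multiple-testing correction needs. Pooling 24 conditions gives 48 degrees of
freedom, a nearly unbiased estimate, and calibrated p-values with no
measurable power cost. Dispersion is a gene property; there is no shrinkage
toward a mean–dispersion trend and no sharing across genes.

**The test.** For one (genotype, day, time-of-day) sampling point with group
means `m_LD`, `m_SD` (normalized counts, `n` replicates each):

- `logFC = log2((m_LD + c0) / (m_SD + c0))` with pseudocount `c0 = 0.5`,
  keeping the fold change finite and sign-faithful at zero means;
- delta-method standard error on the log2 scale,
  `SE^2 = (1/ln 2)^2 [ (1/n_LD)(1/(m_LD+c0) + alpha) + (1/n_SD)(1/(m_SD+c0) + alpha) ]`;
- Wald statistic `logFC / SE` referred to a Student t distribution with
  degrees of freedom equal to those behind the dispersion estimate (48 at
  the default design). The t reference, rather than the standard normal,
  accounts for the estimated dispersion; at 48 df it is numerically close to
  normal but measurably better calibrated (null fraction of p ≤ 0.05 ≈
  0.05 instead of ≈ 0.06).
- Genes with base mean below 1 normalized count are assigned p = 1 rather
  than tested; this stabilizes the null and anticipates the low-expression
  filter.
- Benjamini–Hochberg adjustment; `is_deg` at FDR ≤ 0.05 by default.

Swapping the LD and SD labels negates every logFC and leaves every p-value
unchanged; this antisymmetry is property-tested.

## Ranking and the contrast score

Within one diurnal dataset, each of the four inductive comparisons ranks its
DEGs by logFC with rank 1 for the most contrast-consistent gene (LD-first in
genotype A, SD-first in genotype B). Exact ties are broken by lexicographic
gene id so that output is bit-reproducible regardless of input order. The
score `S_g` is the sum of the four ranks; genes are reported in ascending
`S_g` (ties again by id).

Two details are genuinely open design territory:

- **Rank universe.** A gene can be a DEG in some comparisons only. The
  default `intersection` policy scores only genes that are eligible DEGs in
  all four comparisons, ranking within that shared universe, so every
  comparison's ranks are a permutation of `1..N` and
  `4 <= S_g <= 4N`. It is the strictest, most reproducible reading. The
  alternative `penalty` policy ranks each comparison's own DEG list (size
  `N_c`) and charges missing genes `N_c + 1`, trading strictness for
  sensitivity to borderline genes; it is exposed for sensitivity analysis.
- **Joint versus per-genotype sums.** One could first sum the two ranks
  within each genotype and combine afterwards. On a shared universe the
  per-genotype sums add up to exactly the joint four-rank sum, so the
  distinction only matters combined with per-genotype universes; photorank
  implements the joint sum.

**Sign-consistency gate.** A low rank sum can, in pathological cases, arise
without the full contrast pattern (e.g. a gene extreme in three comparisons
and middling in the fourth). Candidate selection therefore requires, by
default, `logFC > 0` in both genotype-A comparisons and `logFC < 0` in both
genotype-B comparisons — the literal encoding of "activated by LD in the
LD-flowering genotype, by SD in the SD-flowering one". The gate is applied
before truncation to `top_k`, so inconsistent genes do not occupy candidate
slots. No principled cutoff for `top_k` exists without an error model of the
rank sums; the package default (25) is of the order of the per-dataset list
sizes such screens report, and recovery experiments simply set
`top_k = n_contrast`.

**Expression filters.** Before ranking, genes must show (i) mean normalized
count ≥ 5 over the analyzed window and (ii) within-condition replicate
coefficient of variation ≤ 1 in every condition of the window. These
thresholds are package defaults — deliberately permissive, aimed at the
clearly untestable genes (near-zero expression; replicate sets like 1, 100,
1) rather than at shaping the candidate list.

## The synthetic-data generator

`simulate_experiment()` draws counts from
`NB(mean = s_j * q_gj, var = mu + alpha * mu^2)` with log-normal per-sample
size factors `s_j` (sigma 0.15, re-centred so their median is exactly 1,
making normalization identifiable) and
`log2 q_gj = baseline_g + drift + class effects`:

- **baseline**: uniform log2 in (5, 12), i.e. ≈ 32–4096 expected counts.
  The main classes model adequately expressed transcripts — the regime in
  which a three-replicate screen can operate — while the dedicated *low*
  class (log2 baseline in (−1, 1.5)) covers the sub-threshold tail that the
  expression filter must remove. The generator makes no attempt to model the
  full empirical abundance distribution of a transcriptome.
- **day drift**: +0.1 log2 per day after the genotype's first sampling day,
  for every gene, so sampling days are genuinely different conditions and
  cross-day ranks cannot degenerate into ties.
- **contrast** genes (default 20): +2 log2 units under LD in genotype A and
  under SD in genotype B, on the two later (inductive) days only.
- **concordant** genes (50): the same effect size with the *same* sign in
  both genotypes (half LD-up, half SD-up), on all days. They are the
  critical decoys: they pass every DE test and rank highly in one genotype's
  direction, and must be rejected by the other genotype's ranking and the
  sign gate.
- **diurnal** genes (50): ±1.5 log2 units tied to time of day, photoperiod-
  blind. Because morning and afternoon are analyzed separately, these genes
  are simply non-DEGs within each dataset; they exercise the pipeline's
  independence of the diurnal axis rather than the replicate-CV filter.
- **null** genes: baseline only.

Dispersion defaults to `alpha = 0.05` (CV ≈ 22% between replicates at high
counts) — a conventional figure for bulk RNA-seq biological replicates, not
fitted to any dataset, since within-genotype replicate variability is rarely
reported.

What passing recovery tests does *and does not* show: with these defaults
the planted contrast genes are recovered essentially perfectly (recall and
precision 1.0 across five seeds), which validates the *logic* of the
ranking, gating and union arithmetic. It does not certify performance on
real data, where dispersion varies with expression, effects are smaller and
heterogeneous, library composition shifts, and annotation errors exist. The
generator is a correctness harness, not a power calculator.

## Numerical choices and degenerate inputs

- Pseudocount 0.5 in logFC; dispersion floor 1e-8; base-mean test floor 1
  normalized count.
- All ranking ties break by lexicographic gene id; all outputs are sorted
  deterministically, so a fixed configuration reproduces byte-identical
  artifacts (this is tested).
- Zero-mean conditions fail the CV filter by convention (CV undefined);
  all-zero genes fail the mean filter first.
- An empty eligible set or empty DEG intersection produces an empty, validly
  shaped candidate table and a warning, not an error.
- With zero candidates, precision is reported as 0 with an explicit
  `precision_undefined` flag rather than NaN.
- `estimate_dispersion()` rejects groups with fewer than two replicates;
  `de_test()` names the exact missing (photoperiod, genotype, day,
  time-of-day) cell.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on simulated data at
the scale the method targets: 2000 genes × 72 libraries for recovery and
null-calibration experiments (five seeds each), 800 genes for the
determinism check, and up to 500-gene random instances (100 of them) for
the brute-force oracle comparison of the rank-sum scorer. Everything
completes in well under a minute on one CPU.

## Known limitations

- The DE stage is a two-group closed-form test: no multi-factor designs, no
  batch terms, no dispersion trend, no logFC moderation. Reproducing the
  exact DEG lists of any particular heavyweight pipeline is a non-goal;
  ranks of clearly contrasting genes, which the screen consumes, are robust
  to this choice.
- Count-scale thresholds mean results are not exactly invariant to global
  sequencing depth (see Normalization above).
- The morning/afternoon union treats the two datasets symmetrically; no
  attempt is made to model diurnal phase beyond analyzing them separately.
- Candidate biological interpretation (homology, annotation, enrichment) is
  out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 1), top_k = 20,
                       out_dir = tempfile("photorank_"))
res <- run_pipeline(cfg)
res$candidates
res$report$summary$metrics
```
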