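---
title: "Methylation or transcription factors? The methyltrx models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation or transcription factors? The methyltrx models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methyltrx` asks one question of a two-group (injured vs sham) design
measured by RNA-seq and capture-based methylation sequencing: are the
persistent expression changes controlled by DNA methylation around genes,
or by a handful of transcription factors? This vignette describes each
model in the pipeline, the assumptions behind it, the parameters that
matter, and the choices made where the design was genuinely open.

## Region geometry

All internal coordinates are 0-based half-open; GTF input (1-based
inclusive) is converted on ingress and egress, BED passes through. The
promoter window spans 5000 bp upstream and 200 bp downstream of the TSS.
Two conventions had to be fixed:

* the TSS base itself belongs to the *downstream* side, so a plus-strand
  promoter is `[tss − 5000, tss + 200)` and the minus strand mirrors the
  same rule around the TSS base, `[tss − 199, tss + 5001)`;
* reads are counted by their start position (a single base), not by
  span overlap, because fragment lengths are not part of the input
  contract.

Windows are clipped to the chromosome; a window entirely outside it is an
error. Promoters overlapping a neighboring gene are *not* clipped
against that neighbor. Exon regions are the per-gene union of exons
(overlaps merged); the body region is the annotated span.

## The differential-count engine

One engine serves both the expression (gene × sample) and methylation
(region × sample) arms. Counts are normalized by median-of-ratios size
factors; the per-feature statistic is a negative-binomial Wald test:

* `log2FC = log2((m_case + 0.5) / (m_control + 0.5))` on normalized
  means — the 0.5 pseudo-count keeps fold-changes finite at zero;
* `SE` by the delta method from the NB variance `v(m) = m + α m²`;
* two-sided p from the normal reference, BH-adjusted.

**Dispersion.** `α` is a method-of-moments estimate from within-group
means and variances. The default pools those moments **across all
features** into one common dispersion:
`α = Σ(v_w − m̄) / Σ m̄²`, floored at 1e-8. With five samples per group a
per-feature moment estimate is so noisy that the Wald reference becomes
markedly anticonservative (about 8–9% rejections at nominal 5% in null
simulations); the pooled estimate restores near-nominal behaviour
(~5.5%) while staying free of any shrinkage machinery. The per-feature
variant remains available via `dispersion = "per_feature"` for data whose
features plausibly differ in overdispersion.

**Normalization anchoring.** The Wald test divides by *un-rescaled*
median-of-ratios factors, so that scaling one sample's column is absorbed
into that sample's factor and the normalized matrix is unchanged up to a
single global constant. The exported `size_factors_median_of_ratios()`
rescales to geometric mean 1, which is the right convention for
*reporting* factors but would spread a column scaling across all samples.
No count-scale statistic with a pseudo-count can be exactly invariant to
the residual global constant; in practice the drift is ~1e-3 in p and the
suite pins the exactly-invariant parts (factor absorption, symmetry in
which sample carries the scaling).

**Filters.** `nb_wald_test(min_mean=)` skips features below a normalized
mean (reported with missing p/q and excluded from the BH family, as in
independent-filtering practice). The regression stage additionally
applies the average-raw-read filter (default 50) with a *strict*
less-than, so a mean of exactly 50 is retained.

## Methylation-expression coupling (preranked GSEA)

The expression ranking scores each gene `sign(log2FC) · (−log₁₀ p)`
(p clamped to the smallest positive double; zero fold-change scores 0;
ties broken lexicographically). The phrasing "rank number" admits a
literal integer-rank reading, which is exposed as
`metric = "signed_rank"`; the continuous metric is the default because it
preserves the same order while keeping the weighted statistic informative.

Gene sets are the genes whose promoter / exon / body region reached
FDR < 0.05 in the methylation arm. The enrichment score is the classic
weighted Kolmogorov–Smirnov running sum with weight exponent 1 (hits add
`|score|¹ / Σ|score|¹`, misses subtract `1/(N − N_hits)`); a sign tie at
the extremum breaks toward positive; all-zero hit weights fall back to
equal weights.

**Permutation null.** Significance uses gene-tag permutation — resampled
gene sets of the same size — rather than phenotype permutation: with five
samples per group there are too few phenotype relabelings to resolve
anything below p ≈ 0.01, whereas gene-tag resampling matches the
preranked construction. The p-value is `(1 + #{|null| ≥ |ES|}) /
(1 + #null)` over same-sign nulls (the +1 smoothing avoids p = 0), NES
divides ES by the mean |same-sign null|, and BH runs across the sets
evaluated in the call. Inside the permutation loop the score is computed
from hit positions alone in O(set size); the suite verifies this fast
path against the full running sum exactly.

## Mediation of injury through methylation

Two per-gene linear models on `log₂(normalized count + 1)` (linear models
on raw counts would be grossly heteroskedastic, and the log keeps planted
multiplicative effects additive):

* (a) expression ~ methylation: the association model, OLS slope with a
  t-test;
* (b) injury → expression via methylation: stage 1 `methylation ~ group`
  gives `a`; stage 2 `expression ~ methylation + group` gives `b` and the
  direct effect; the indirect effect is `a·b` (product of coefficients).
  OLS algebra makes `total = direct + indirect` an exact identity, which
  the suite asserts per gene.

Inference for `a·b` is a percentile bootstrap resampling samples *within*
groups (2000 draws by default, seed-deterministic): the product of two
small-sample coefficients is too non-normal for a Sobel-style normal
approximation. In the planted-chain simulations used by the tests
(a = 1, b = −0.5, Gaussian noise sd 0.2, n = 5+5) this attains ~94%
coverage of the 95% CI and a null false-positive rate well under 5% —
the familiar conservatism of mediation tests near `a = 0`. Degenerate
resamples (zero-variance mediator) are dropped from the bootstrap
distribution; a zero-variance mediator altogether yields a missing row.
The promoter region is the default mediator; `region_kind` selects
others.

## Transcription-factor layer

TFs are network nodes with out-degree ≥ 1. A TF is dysregulated iff
FDR < 0.05 **and** |log2FC| > 1 (both strict, so log2FC = 1.0 is out).
"Nearest downstream neighbors" is read literally as direct out-neighbors
(a multi-hop closure would conflate regulons). A *target* is altered iff
its FDR < 0.05, with no fold-change threshold — the target lists in this
kind of analysis include modest effects, and the |log2FC| > 1 rule is a
TF-selection rule only; this decision is recorded in the output metadata.
TFs are ranked by altered-target count, ties by altered/total ratio then
id; cross-region sharing intersects same-direction lists only.

## Compound-signature query

Replicate score vectors per (compound, cell context) are z-scored and
collapsed by the per-gene median — a consensus that *shrinks*
irreproducible genes toward zero rather than discarding compounds, which
keeps the operation deterministic and testable; a minimum-agreement
filter can be layered on top by the caller. A compound is a hit for a TF
when the TF ranks ≤ k (default 100) by descending (up) or ascending
(down) consensus score; ties break lexicographically by gene id, and
k < n/2 is enforced so the two directions cannot overlap. Membership is
invariant under any strictly monotone transform of the scores, so the
score convention of the provider (moderated z, fold-change, …) does not
matter.

## What the generator emulates — and what it does not

`simulate_dataset()` plants the study conditions: two groups of five,
NB counts (default dispersion 0.1 — typical bulk RNA-seq/MBD-seq
overdispersion), lognormal per-gene baselines (median 200 expression /
100 methylation counts, sdlog 0.5), mild lognormal library factors
(sdlog 0.1), 10% DE genes at |log2FC| 1.5, 5% hypermethylated promoters
at log2FC 1.5 anti-coupled to expression (the coupled genes are *forced*
into the downregulated DE subset — set-level anticorrelation is what the
coupling test consumes, so no mechanistic methylation→expression function
is modelled), four planted TFs (log2FC 2, 50-gene regulons, 30% altered)
over sixteen background TFs (2%), and 200 compounds × {NEU, NEU.KCL,
NPC} × 3 replicates with five planted hits at effect size 10. The DE set
is exactly `round(frac_de · n_genes)` genes; planted TFs, altered targets
and coupled genes are drawn from that budget and the configuration is
rejected if it cannot accommodate them.

Not emulated: batch effects, GC/sequence structure, read-level noise,
per-CpG resolution, correlated genes. Passing tests therefore show that
the *statistics recover what they model* under clean NB noise — not that
the models are robust to the full messiness of real libraries.

## Numerical choices and problem sizes

* Seeds: one global seed fans out to stages through a polynomial hash of
  the stage name (`stage_seed()`), so any stage reruns identically in
  isolation; the pipeline's provenance signatures (md5 of canonical
  parameter JSON) re-execute only stages downstream of a change.
* Degenerate inputs: all-zero features → missing p/q; zero-variance
  mediators → missing rows; empty gene sets → flagged, skipped with a
  warning in batch GSEA; duplicate network edges collapse; self-loops are
  kept but flagged.
* Test problem sizes, chosen to make Monte-Carlo bands tight while a full
  run stays in minutes on one CPU: 2000 genes throughout; 10 null seeds
  for calibration; 20 seeds per coupling arm (1000 permutations); 200
  planted + 2000 null mediation genes (2000 / 1000 bootstrap draws); 20
  TRN seeds; 2 compound-query seeds; the full default pipeline twice for
  byte-identity.

## Known limitations

The Wald reference is asymptotic; at five samples per group it leans on
the pooled dispersion, and data with genuinely feature-specific
overdispersion will be miscalibrated under the default (use
`per_feature` and expect conservative-to-liberal drift). The mediation
model is single-mediator OLS with no confounding adjustment. GSEA
significance is conditional on the observed ranking (gene-tag null), so
it tests set placement, not phenotype association. The compound query
treats contexts independently and models no dose or time structure.
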