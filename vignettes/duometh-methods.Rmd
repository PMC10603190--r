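---
title: "duometh: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duometh: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`duometh` analyses paired whole-genome bisulfite (WGBS/"BS") and oxidative
bisulfite (oxWGBS/"oxBS") sequencing of tumor versus matched normal
tissue, separating 5-methylcytosine (5mC) from 5-hydroxymethylcytosine
(5hmC) at single-CpG resolution and tracing promoter modification
patterns through to gene expression. This vignette documents the
statistical model, every tunable that matters, what the synthetic data
generator does and does not emulate, and the design choices made where
the design was genuinely open.

## 1. Measurement model

Under plain bisulfite treatment both 5mC and 5hmC resist conversion, so
the unconverted-read fraction at a CpG estimates `p_m + p_h`. Under
oxidative bisulfite, 5hmC is first oxidized to 5fC and then converted,
so the unconverted fraction estimates `p_m` alone. With conversion rates
(`conversion_model()`):

* `c_bs` — conversion of unmodified C (default 0.993),
* `c_ox` — oxidative conversion of 5hmC under oxBS (default 0.965),
* `e_m` — false conversion of 5mC (default 0.035), also used for 5hmC
  under plain BS,
* `c_f_bs`/`c_f_ox` — conversion of the 5fC spike-in class (0.595 /
  0.922),

the per-read unconverted probabilities are

```
BS:   q = (p_m + p_h)(1 - e_m) + (1 - p_m - p_h)(1 - c_bs)
oxBS: q = p_m(1 - e_m) + p_h(1 - c_ox) + (1 - p_m - p_h)(1 - c_bs)
```

The defaults are the spike-in regime of a TrueMethyl-style kit; the
spike-in classes are modelled as four pure contexts (C, 5mC, 5hmC, 5fC)
with 500 positions each, collapsing the graded hmC duplexes of real kits
into one 5hmC class, because per-class rates are all a conversion report
resolves.

## 2. Joint (5mC, 5hmC) estimation

`mlml_site()` maximizes `Binom(k_bs; n_bs, p_m + p_h) * Binom(k_ox;
n_ox, p_m)` over the simplex `p_m, p_h >= 0, p_m + p_h <= 1` in closed
form: the interior maximum is the naive subtraction (`p_m = k_ox/n_ox`,
`p_h = k_bs/n_bs - k_ox/n_ox`); when the subtraction is negative the
constrained maximum is on the boundary `p_h = 0`, where both arms
measure the same quantity and the MLE pools the counts
(`(k_bs + k_ox)/(n_bs + n_ox)`). The `conflict` flag records boundary
projection. No iterative solver is used; the closed form is checked
against exhaustive grid search in the test suite. A three-input
(TAB-seq) variant is out of scope.

With a conversion model supplied, arm probabilities are inverted
(moment correction) before the simplex projection; this is OFF by
default for raw comparability with standard MLML-style pipelines and ON
inside `run_pipeline()` for unbiased recovery on simulations.

Two numerical facts shape the tests:

* At 28x the per-site standard deviation of any estimator of `p_h` is
  about 0.08-0.12 (difference of two binomial proportions), so per-site
  accuracy targets below that are unattainable at this depth; recovery
  is therefore assessed on genome means, with counts pooled across a
  group's replicate libraries (`pool_counts()`).
* The boundary projection truncates at zero, so the mean of `p_h`
  estimates is biased upward at low depth; pooling replicates before
  estimation keeps this bias within 0.01 at a genome-wide true mean of
  0.05.

## 3. Region calling

Differential regions are called per modality on site-by-sample
matrices: 5mC regions (DMRs) on the MLML `p_m` track and 5hmC regions
(DhMRs) on the MLML `p_h` track. Using the raw BS beta for DMRs would
conflate the marks: BS beta is `p_m + p_h`, so opposite 5hmC and 5mC
changes at a bidirectional promoter partially cancel (0.3 - 0.15 never
clears the 0.2 filter) and bidirectional patterns would be
unclassifiable by construction.

`dmr_segment()` is a recursive binary segmentation of the per-site
difference of group means: runs are bounded by a maximum intra-region
CpG gap (300 bp default); a segment is emitted once its mean
|difference| clears the modality floor unless the best split exposes a
large-enough child with a clearly higher mean (margin = floor/4);
emitted segments are refined to the longest sub-interval whose mean is
within 0.02 of the best sub-interval of at least the minimum size. Ties
in split position always go to the leftmost candidate, so segmentation
is deterministic. Minimum candidate sizes mirror the filter floors (11
CpGs for 5mC, 5 for 5hmC) and are configurable.

The published filter sets are applied verbatim: DMR = |delta beta| >
0.2, more than 10 CpGs, CpG density > 2%, FDR < 0.001; DhMR = |delta
beta| > 0.1, at least 5 CpGs, FDR < 0.05. The density denominator is
region length in bp, with "possible CpG dyads" (length/2) behind the
`density_denom` flag since the published definition does not say.
FDR is Benjamini-Hochberg per modality across all tested candidates.

**Region statistic.** The reference pipeline fixes thresholds but not
the test. An exact Mann-Whitney on per-sample region means is appealing
(exact at 4 vs 4) but its smallest attainable two-sided p there is 2/70
~ 0.0286, which can never clear FDR < 0.001 -- the DMR filter would be
unsatisfiable at the study's sample size. Segmentation callers in this
field (the Metilene family) instead rank all CpG-by-sample values of a
region between groups, which can reach arbitrarily small p from few
samples. Both are implemented (`region_stat = "pooled"` default,
`"sample_means"` optional); the pooled statistic treats CpGs within a
region as exchangeable replicates and is anticonservative under spatial
correlation, which is the standard trade-off of this caller family.
Promoter assignment is by >= 1 bp overlap (half-open intervals); a
region overlapping several promoters is assigned to all, a promoter hit
by several regions takes the largest |delta beta|, keeping one
direction per gene and modality.

## 4. Integration with expression

Genes detected (nonzero) in at least 25% of samples are kept. Per-gene
log2 fold change is `log2(mean CPM tumor + 1) - log2(mean CPM normal +
1)`; the pseudocount keeps the formula defined at zero, and CPM stands
in for the unspecified normalization of the reference analysis. Genes
bearing both a promoter DMR and DhMR are classified up/up, up/down,
down/up or down/down ("5mC direction / 5hmC direction");
same-direction patterns are "unidirectional", opposite "bidirectional".
Pattern comparisons use the tie-aware exact Mann-Whitney
(`mwu_exact()`: exact null by dynamic programming for combined n <= 25,
normal approximation with continuity and tie correction beyond;
two-sided p = `2 * min(P(W <= w), P(W >= w))` capped at 1).

5hmC strata on |delta beta|: high > 0.14, medium (0.12, 0.14], low
(0.10, 0.12]; at or below 0.10 excluded. Top-gene selection requires
the unidirectional pattern matching the expression direction and at
least a medium 5hmC alteration, ranks by |log2FC| with gene-id
tie-break (significance-based ranking would be an alternative; the
source analysis does not specify). Signature scores are per-sample
means of `log2(TPM + 1)` over a gene set with high/low labels at the
75th/25th linear-interpolation (type-7) percentiles under strict
inequalities; median-split ties in the 5hmC analyses go to the "low"
group. Survival validation against external cohorts is out of scope.

## 5. The synthetic world

`sim_config()` defaults define the reference toy study:

* genome: 2 chromosomes x 500 kb; 120 non-overlapping genes (2-6 kb,
  2-5 exons, 200/300 bp UTRs); promoters `[TSS - 1000, TSS)`
  (configurable; the convention is a common default, and keeping it a
  parameter isolates the guess); CGIs at 60% of promoters plus 15
  intergenic islands; CpG dyads every ~15 bp inside CGIs and ~120 bp
  outside (~13,000 strand-merged sites -- the analysis operates on
  CpG-level beta, so strands are not split).
* true methylome: 5mC Beta-distributed bimodally (CGI mean ~0.07,
  background mean ~0.73), 5hmC mean ~0.05, truncated to the simplex.
* implants: 28 promoter pattern genes (7 per pattern) with paired
  5mC/5hmC implants (delta 5mC +/- 0.3; |delta 5hmC| uniform on
  0.11-0.20), 6 single-mark 5mC and 6 single-mark 5hmC genes, 8
  background implants; inside an implant the regional baseline of both
  marks is redrawn jointly from the feasible box so both groups stay in
  the simplex, and an infeasible request errors with the region named.
  Implant regions must be disjoint or identical.
* sequencing: 4 tumor vs 4 normal samples, Poisson coverage at 28x per
  arm, the conversion chemistry above, and a truncated-Gaussian
  between-sample jitter of sd 0.02 on the true levels (the reference
  study provides no patient-variability model; this is a free
  parameter, chosen small enough not to mask 0.1-scale deltas).
* expression: negative-binomial counts (dispersion 0.1), log-normal
  baselines; pattern-level log2 fold changes -2 (up/up), +0.8
  (down/down), -0.5 (up/down), +0.25 (down/up), scaled for
  unidirectional genes by |delta 5hmC|/0.15 so larger 5hmC alterations
  produce larger expression changes; ~10% of neutral genes are
  near-silent so the detection filter has work to do.

The generator emulates binomial read sampling, conversion chemistry,
spike-ins, implanted differential regions, and pattern-coupled
expression. It does **not** emulate read-level artifacts (sequencing
error, mapping bias, strand asymmetries), genome realism (repeat
content, real CGI structure), spatial autocorrelation of methylation
beyond the implant blocks, or patient-level covariates. A green
recovery test therefore establishes that the estimators and callers
recover the stated statistical structure at the stated depth and sample
size -- not that they are robust to alignment artifacts or biological
heterogeneity the generator does not model.

Sizes were chosen so a complete pipeline run takes seconds, letting the
acceptance suite run 50 replicate seeds of the full chain within a CI
budget; all statistical parameters (depth, group size, conversion
rates, deltas) match the reference regime rather than being scaled
down.

## 6. Seeding and determinism

Every generator takes one top-level seed expanded via `child_seeds()`
into independent per-stage streams (recorded in the outputs); identical
seeds and configs reproduce outputs bit for bit, and the test suite
asserts it. All randomness in tests is seeded; no test depends on run
order.

## 7. Known limitations

* The pooled region statistic ignores within-region spatial correlation
  and is anticonservative; exact per-sample testing is available but
  cannot reach stringent FDR at n = 4 + 4.
* Adaptive segmentation selects noise maxima and then tests the same
  data, so region FDR is approximate -- the false positives observed in
  recovery simulations (precision ~0.9, not 1.0) are this selection
  effect, shared with the reference caller family.
* Boundary truncation biases per-site `p_h` upward at low coverage;
  genome-level summaries should pool replicate libraries.
* Metaprofiles average per region first, then across regions; per-CpG
  averaging would weight CpG-dense regions more heavily and is not
  implemented.
* The enrichment "universe" is all tested candidate regions; a
  genomic-length-based expectation is a documented alternative the
  interface leaves room for but the reference text does not pin down.
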