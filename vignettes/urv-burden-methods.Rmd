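---
title: "Methods: ultra-rare variant collapsing, exact ACAT burden testing, and enrichment"
author: "urvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultra-rare variant collapsing, exact ACAT burden testing, and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`urvburden` implements a gene-based collapsing analysis of ultra-rare coding
variants for case-control cohorts of severe congenital disorders (the design
it emulates is a vertebral-malformation cohort of several hundred undiagnosed
probands against a few thousand screened controls), together with the two
interpretation layers that typically follow such a scan: hypergeometric
gene-set over-representation of the nominally significant genes, and
expression-weighted cell-type enrichment (EWCE-style) of the same genes
against a labeled developmental single-cell atlas. Because real cohorts of
this kind are restricted-access, the package ships first-class synthetic
generators with planted ground truth; every statistical claim made by the
test suite is a claim about recovering that truth.

# The collapsing model

## Ultra-rare variant definition

A variant qualifies as ultra-rare (URV) when

* its gnomAD control population-max allele frequency is at most `popmax_max`
  (default `1e-4`, i.e. 0.01%), with a missing frequency treated as 0
  (absent from the reference panel means novel, the most permissive
  convention for URVs), and
* its cohort allele count is at most `ac_max` (default 3), counted over
  cases and controls jointly, one allele per carrier.

Both thresholds are inclusive and the filter is idempotent. Annotations are
first reduced to one transcript per (variant, gene): the canonical-flagged
transcript when present, ties broken by the lexicographically smallest
transcript id, and — when no canonical flag exists at all — by consequence
severity (pLoF > inframe indel > missense > synonymous > other), then id.

## Weights and burden

Each URV receives a weight in $[0, 1]$ determined only by its consequence
class and, for missense variants, the number of concordant in-silico
damaging predictions. The shipped `functional` table is

| class | weight |
|---|---|
| pLoF | 1.0 |
| inframe indel | 0.8 |
| missense, ≥ 2 damaging predictions | 0.8 |
| missense, 1 damaging prediction | 0.5 |
| missense, 0 damaging predictions | 0.2 |
| synonymous, other | 0 |

These values are a declared default (configurable via YAML), chosen to be
monotone in expected deleteriousness; the package makes no claim that they
match any particular study's supplementary table. A second shipped table,
`synonymous_calibration`, inverts the design (synonymous = 1, everything
else 0) to provide an empirical-null run of the entire pipeline: synonymous
URVs should carry no case-control signal, so their scan doubles as a
calibration readout.

A variant with weight 0 is *not qualified*: it never contributes to a
burden, and a gene enters the test only with at least `min_qualified = 10`
distinct qualified variants in the cohort. The burden of gene $g$ in
individual $i$ is the **maximum** weight among the qualified URVs that $i$
carries in $g$ (0 if none). Carrier status is binary — heterozygous and
homozygous carriers are treated identically — matching a dominant-style
collapsing unit.

# The gene-level test

## Statistic

The burden takes values in a small set determined by the weight table, so
the test dichotomizes it at thresholds $t \in \{>0,\ \ge 0.5,\ =1\}$
(configurable). Each threshold yields a nested 2×2 table (case/control ×
carrier/non-carrier at that threshold), scored with the two-sided Fisher
exact test with mid-p correction, and the per-threshold p-values are pooled
into the equal-weight aggregated Cauchy association (ACAT) statistic

$$T = \frac{1}{J}\sum_{j=1}^{J} \tan\!\big((0.5 - p_j)\,\pi\big).$$

## Exact conditional null

How to convert $T$ into a p-value was a genuinely open design point. The
textbook ACAT route — the standard Cauchy upper tail of $T$ — is exact for
independent or perfectly dependent components, but the nested threshold
tables sit in between: their case counts are strongly positively correlated
under label permutation. Measured on null cohorts of 2500 eligible genes
(750 cases / 3750 controls), the Cauchy-CDF route is visibly conservative at
the center of the distribution (genomic inflation factor
$\lambda_{GC} \approx 0.81$–$0.87$, median p ≈ 0.54) even when each
component is forced to be exactly uniform; replacing the nested tables with
disjoint weight-class tables restores $\lambda_{GC} \approx 1$ but splits a
true signal across classes and costs decisive power.

`urvburden` therefore evaluates the *exact conditional null* of $T$.
Conditional on the burden matrix, the total carrier count of each disjoint
weight class is fixed under case/control label permutation, and the vector
of case shares follows a multivariate hypergeometric distribution. The
per-gene null of $T$ is enumerated over that (small) support, and

$$p_{\text{combined}} = P(T > T_{\text{obs}}) + \tfrac{1}{2} P(T = T_{\text{obs}})$$

with the mid-p half-weight on ties (set `midp = FALSE` for the classical
conservative tail $P(T \ge T_{\text{obs}})$, which is guaranteed
super-uniform). This is exactly the permutation p-value of the ACAT
statistic, computed in closed form instead of by sampling. With
`midp = FALSE`, a gene in which every threshold produces the same table
reports precisely the single two-sided Fisher p of that table.

Three practical consequences:

* **Calibration is by construction.** On null synthetic cohorts the
  empirical type-I error at $\alpha = 0.05$ lands in $[0.040, 0.060]$ and
  $\lambda_{GC}$ in $[0.93, 1.05]$ for both weight tables (the test suite
  asserts the $[0.040, 0.060]$ and $[0.9, 1.1]$ bands).
* **Component pathologies vanish.** Degenerate thresholds (no carriers, or
  everyone a carrier) are dropped; exact Fisher p-values of 1 (a table at
  its mode) cannot annihilate the combination because only the *ordering*
  of $T$ over the enumerated support matters. Mid-p components are still
  used inside $T$ so that near-boundary tangents stay finite and ordering
  stays sensible. A gene with no carriers at all reports $p = 1$.
* **Cost is bounded.** The enumeration grid has
  $\prod_j (K_j + 1)$ cells for class carrier totals $K_j$; for URV-regime
  genes this is a few thousand cells. Genes whose grid would exceed
  3×10^5 cells fall back to the analytic Cauchy CDF — not normally reached
  with ultra-rare variation.

Carrier counts and odds ratios are reported at burden $> 0$, with the
Haldane–Anscombe $+0.5$ correction when any cell is zero.

## Permutation QQ and multiplicity

Expected p-values for QQ plots are computed by re-running the whole scan
under `n_perm = 1000` label permutations (case count preserved) and
averaging order statistics. Because the class carrier totals are fixed
under permutation, the per-gene exact-null lookup built for the observed
test is reused, and each permutation reduces to indexed reads — about
8 ms per permutation on a 2500-gene cohort after a one-time ~7 s build.

The genomic inflation factor is
$\lambda_{GC} = \mathrm{median}\{\chi^2_1(p)\} / 0.4549$, and
multiple-testing control uses Storey–Tibshirani q-values with a single-λ
null-proportion estimate $\hat\pi_0 = \min(1, \overline{\{p > 0.5\}}/0.5)$
(a conservative single-point version of the spline estimator; a
non-positive estimate falls back to $\pi_0 = 1$, which makes the q-values
exactly Benjamini–Hochberg).

# Pathway enrichment

Nominally significant genes ($p < 0.05$ by default) are tested for
over-representation in GMT gene sets with the one-sided upper-tail
hypergeometric test; the fold enrichment is $(k/n) / (K/N)$. The universe
is the set of genes that actually entered the burden test — hits can only
come from tested genes, so a whole-genome universe would overstate
enrichment. Set members outside the universe are dropped before testing.
No multiplicity adjustment is applied by default (an optional BH column is
available), matching common practice for exploratory pathway readouts.

# Cell-type enrichment

Labeled single-cell counts (MatrixMarket + gene/cell TSVs) are
depth-normalized per cell (counts divided by the cell total, rescaled by
the median total), averaged per cell type *within each developmental
stage*, and converted to specificity: a gene's per-type mean divided by the
sum of its means across the stage's cell types, so each expressed gene's
specificity sums to 1 within a stage. Stages are processed independently
because progenitor populations appear and disappear across development;
pooling stages would dilute stage-restricted cell types.

For a target gene list, the observed statistic per (cell type, stage) is
the summed specificity of the target genes; `n_boot = 1000` bootstrap sets
of the same size are drawn uniformly *without replacement* from the
expressed background (no GC/length matching — targets and background come
from the same quantification), and

$$p = \frac{1 + \#\{\text{bootstrap} \ge \text{observed}\}}{1 + n_{\text{boot}}},$$

an add-one-corrected one-sided bootstrap p that is never 0, with
$z = (\text{obs} - \overline{b}) / sd(b)$. Zero bootstrap variance (e.g.
a constant specificity column) reports $z = \mathrm{NA}$ and $p = 1$
rather than an infinity.

# The synthetic generators

`simulate_cohort()` emulates the statistical shape of the target study
design; defaults are fixed once and are not data-fitted:

* 744 cases vs 3740 controls; 2500 genes; per-gene variant counts
  Poisson with mean 120 — in a ~4500-sample cohort a gene plausibly
  accumulates on the order of a hundred distinct ultra-rare variants.
* consequence mix pLoF 0.08, inframe 0.04, missense 0.45, synonymous 0.35,
  other 0.08 — a coding spectrum with enough synonymous mass that the
  calibration table keeps ≥ 2000 genes eligible.
* popmax AF: point mass at 0 (probability 0.3, "novel") plus a log-uniform
  component on $[10^{-7}, 10^{-2}]$, placing mass on both sides of the
  $10^{-4}$ filter threshold so the filter is genuinely exercised.
* per-variant carrier probability $2.5\times 10^{-4}$ (~1.1 carriers per
  variant: mostly singletons/doubletons, the URV regime).
* risk genes: a gene-level carrier indicator with
  $p_1 = R p_0 / (1 - p_0 + R p_0)$ in cases, dealt near-uniformly over the
  gene's *qualifying* variants (functional class, popmax ≤ 10⁻⁴) with
  balanced loads, so planted variants stay singleton/doubleton and the
  planted gene-level carrier probability survives the AC ≤ 3 filter. A
  requested gene-level rate so large that it cannot be carried by
  singleton/doubleton variants (roughly $n \cdot p_0 > 3 \cdot$ pool size)
  would be clipped by the AC filter; choose `variants_per_gene`
  accordingly. Synonymous variants in risk genes remain background, so the
  synonymous calibration run is null even in planted genes.

`simulate_expression()` draws negative-binomial counts (default mean 0.5,
dispersion 0.5) for 12 spine-development cell types across 5 gestational
stages, 200 cells per (type, stage); a planted set multiplies the target
type's mean by a fold factor at every stage.

What the generators deliberately do **not** model: linkage disequilibrium,
relatedness and ancestry stratification, per-gene mutability and length
differences, sequencing/annotation error, covariates, and (for expression)
ambient RNA, doublets, batch and depth gradients. Passing the recovery and
calibration suites therefore demonstrates the statistical machinery is
correct and calibrated under the stated sampling model — not robustness of
real-data analyses to confounding, which requires the upstream QC this
package does not perform.

# Numerical choices

* $\tan((0.5 - p)\pi)$ is evaluated as $1/\tan(p\pi)$ for $p \le 0.25$ and
  $-1/\tan((1-p)\pi)$ for $p \ge 0.75$: the naive subtraction $0.5 - p$
  rounds at $2^{-53}$ and destroys the tangent's relative precision near
  the poles. Inputs are clipped to $[10^{-16}, 1 - 10^{-16}]$.
* Fisher two-sided tails include point probabilities within a relative
  $10^{-7}$ of the observed one (`fisher.test` convention); mid-p halves
  the tied mass.
* Ties of the enumerated statistic are grouped at relative tolerance
  $10^{-9}$ before tail accumulation.
* Percentages in cohort summaries round half-up to one decimal, matching
  printed clinical tables (base `round()` rounds half to even).
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so identical configs give byte-identical output files across runs.

# Problem sizes in the test suite

The suite's heavy checks run at the sizes the design targets: null
calibration on one 750/3750 cohort with 2500 eligible genes (both weight
tables); planted-effect recovery over 100 seeded cohorts of 400 genes with
5 risk genes at OR 4 and gene carrier rate 0.01; EWCE recovery on a
1000-gene, 12 000-cell atlas with a 50-gene fold-8 set plus 100 null
target sets. These sizes were chosen so the whole suite completes in a few
minutes while keeping every binomial acceptance band meaningful.

# Known limitations

* No covariate adjustment (ancestry PCs, sex) — the test conditions only on
  case/control totals.
* The exact null is conditional on the observed burden matrix, as in any
  permutation test; it does not model variant-count differences driven by
  differential coverage between groups.
* The weight tables are declared defaults; sensitivity to them should be
  explored per study (`weight_table()` accepts arbitrary YAML tables).
* $\hat\pi_0$ uses a single λ = 0.5 rather than a spline over a λ grid;
  with thousands of tests this is mildly conservative.
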