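---
title: "Models and methods for allele-specific expression and binding in reporter assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for allele-specific expression and binding in reporter assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assays and the statistical problem

Biallelic reporter assays place a ~200 bp candidate regulatory sequence,
centered on a SNP, into a self-transcribing reporter plasmid, with both
alleles and both insert orientations represented in the library. After
transfection, the ratio of reference to alternate transcripts for each SNP is
compared with the same ratio in the plasmid DNA pool: a shift is
*allele-specific expression* (ASE). A companion binding assay incubates the
same library with a purified transcription factor at several concentrations,
separates protein-bound from unbound DNA, and asks whether the allelic ratio
differs between the two fractions: *allele-specific binding* (ASB).

Three nuisance processes complicate the inference, and each has a dedicated
component in this package:

* **PCR duplication.** Reads are not molecules. Unique molecular identifiers
  (UMIs) attached during cDNA synthesis let duplicates be collapsed
  (`dedup_umi()`); retaining them overstates the effective sample size and
  inflates every downstream test statistic.
* **Plasmid library imbalance.** The two alleles are rarely at 50/50 in the
  input pool, so the null hypothesis for RNA is the *DNA* proportion, not
  one half (`estimate_dna_proportion()`).
* **Overdispersion.** Biological replicates scatter more than binomial
  sampling allows; allele proportions are modelled beta-binomially with a
  single genome-wide correlation parameter $\rho$
  (`estimate_overdispersion()`).

# The allelic-imbalance model

For one SNP in one replicate, let $R$ and $A$ be deduplicated reference and
alternate molecule counts, $N = R + A$, and $p_0$ the pooled plasmid
reference proportion. With $\hat p = (R + \tfrac12)/(N + 1)$,

$$
\hat\beta = \operatorname{logit}\hat p - \operatorname{logit} p_0, \qquad
\operatorname{Var}(\hat\beta) =
  \frac{1 + (N - 1)\rho}{N\,\bar p(1 - \bar p)} +
  \frac{\operatorname{Var}(\hat p_0)}{\big(p_0(1 - p_0)\big)^2},
$$

with $z = \hat\beta/\widehat{\mathrm{se}}$ and a two-sided normal p-value.
The factor $1 + (N-1)\rho$ is the beta-binomial variance inflation; the
second term propagates DNA-proportion uncertainty (delta method) and is
toggleable (`propagate_dna_var`), since whether the original analyses carried
it is not documented.

Two deliberate choices differ from the most literal single-replicate form
and are worth spelling out:

* **Variance stabilization** (`stabilize_variance`, default on). The
  $\bar p(1-\bar p)$ factor is evaluated at the SNP's *replicate-pooled*
  proportion rather than each replicate's own $\hat p$. With a single
  replicate the two coincide. With several, weights built from
  replicate-local $\hat p$ are anticorrelated with that replicate's
  estimate — a replicate that happens to swing away from 0.5 gets a larger
  claimed variance and a smaller weight — which measurably deflates the
  meta-analytic $z$ (median-based $\lambda_{GC} \approx 0.93$ on null
  simulations versus $\approx 1.00$ with pooling).
* **Exact fallback.** Below `exact_min_n = 10` molecules the normal
  approximation is replaced by an exact two-sided beta-binomial tail
  probability (the `binom.test` convention: total probability of outcomes no
  more likely than the observed one).

## Overdispersion estimation

Two estimators are provided. The *moments* form contrasts each SNP against
its DNA proportion,

$$
\hat\rho = \max\!\left(0,\;
\frac{\sum_i (R_i - N_i p_{0i})^2 - N_i p_{0i} q_{0i}}
     {\sum_i N_i (N_i - 1) p_{0i} q_{0i}}\right),
$$

and is exactly right on null data, but any true allelic effect enters the
squared residual, so a realistic mixture of null and functional SNPs biases
it upward (at 20% functional SNPs with effect SD 0.5 and depth 200 the bias
is about +0.012 — larger than the accuracy we require of the estimate).

The pipeline default is therefore a *between-replicate* decomposition: a true
effect shifts every replicate of a SNP identically, so the across-replicate
sample variance $s_i^2$ of $\hat p_{ij} = R_{ij}/N_{ij}$ contains only
overdispersion plus binomial noise,
$E[s_i^2] = \bar p_i \bar q_i\,[\rho(1 - h_i) + h_i]$ with
$h_i = \mathrm{mean}_j(1/N_{ij})$. Solving the pooled moment equation for
$\rho$ (with a small correction for the noise in $\bar p_i \bar q_i$) gives
an estimator immune to true effects and to DNA-proportion error. It needs at
least two replicates; the assay designs modelled here have three to nine.

## Meta-analysis and its shared-error subtlety

Per-replicate results are combined by inverse-variance fixed-effects
weighting, and z-scores by Stouffer's method, with Benjamini–Hochberg
correction and calls at FDR < 10%. One subtlety: every replicate of a SNP
subtracts the *same* $\operatorname{logit} p_0$, so the DNA variance
component is shared rather than independent across replicates. Treating it
as independent would shrink it by $1/k$ in the meta-variance and inflate the
combined statistic ($\lambda_{GC} \approx 1.09$ at nine replicates).
`fixed_effects()` therefore weights by the replicate-specific component and
adds the shared component once; when no shared component is recorded it is
the textbook estimator.

## Genomic inflation

`genomic_inflation()` reports
$\lambda_{GC} = \mathrm{median}\{\chi^2_1(1 - p)\}/0.4549$ (0.4549364 is the
$\chi^2_1$ median). On pure-null simulations the pipeline sits at
$\lambda \approx 1$; datasets with a functional fraction sit well above 1,
which is signal, not miscalibration — the null calibration experiments are
the place to judge the test.

## The duplicate-retention ablation

`run_ase_pipeline(..., dedup = FALSE)` reruns the analysis counting raw
reads instead of UMI-collapsed molecules, holding $\rho$ at the
molecule-level estimate so the two arms differ only in the counts tested.
The held dispersion is a deliberate ablation semantic: under this
simulator's matched beta-binomial model, jointly re-fitting a single
$\rho$ on read counts would absorb most of the *average* duplicate-induced
variance (while leaving depth-dependent miscalibration), because Poisson
duplication noise scales with $1/N$ exactly like binomial noise. Real PCR
noise is heavier-tailed and not absorbable this way. The ablation as
defined isolates the counting error UMIs exist to prevent, and reproduces
the expected picture: inflation roughly 1.5 → 1.9 on the default dataset,
and discoveries from the nine-replicate meta-analysis an order of magnitude
above any single replicate.

# Differential allele-specific binding (ΔAST)

Both binding fractions are tested against the same reference proportion —
the pooled bound + unbound counts — and contrasted per replicate and
concentration:

$$
\Delta\hat\beta = \hat\beta_{\mathrm{bound}} - \hat\beta_{\mathrm{unbound}},
\qquad
\mathrm{se}^2_\Delta = \mathrm{se}^2_b + \mathrm{se}^2_u .
$$

Because $\operatorname{logit} p_0$ cancels exactly in the difference,
library imbalance — and the error in estimating it — cannot masquerade as
binding signal; the inputs are computed without DNA-variance propagation so
the cancelled component is not double-counted. Replicates are combined by
Stouffer within each concentration, the three concentration-level Z's by
Stouffer again for the overall call (concentrations treated as
exchangeable), BH within each level, calls at FDR < 10%. The union of
per-concentration calls is reported alongside the combined-Z set, since
"total" can reasonably mean either.

Per-concentration binding-effect scales default to (0.7, 1.0, 1.1): the low
concentration does not capture all binding, and the monotone ordering
reflects the discovery ordering reported for this assay class. The
region-level nonspecific background (0.10, 0.05, 0.30) is instead *highest*
at the high concentration, so region specificity peaks at the middle
concentration while allelic discovery counts still increase — both
qualitative patterns the binding assay shows. These are documented knobs,
not claims.

# Region-level bound/unbound test

`region_test()` is a deliberately simple negative-binomial Wald test — not a
reimplementation of shrinkage-based differential-count tools: median-of-ratios
size factors; per-region method-of-moments dispersions pooled in ten
mean-rank bins (floored at $10^{-8}$); Wald test on
$\log_2(\mathrm{bound}/\mathrm{unbound})$; BH across regions; and the joint
call gate `log2fc > 1 & q < 0.01` — a region must clear both. One
refinement is on by default: with an asymmetric signal (only bound-enriched
regions), plain median-of-ratios normalization absorbs part of the
enrichment into the bound samples' factors (about 0.25 log2 units when 20%
of regions are enriched fourfold), so size factors are re-estimated on a
null-looking control set after a first pass. No dispersion shrinkage,
outlier filtering, or fold-change moderation is attempted.

# Enrichment machinery

`fisher_enrichment()` builds the 2×2 table of annotation membership against
significance over an explicit universe and reports the conditional-MLE odds
ratio with its exact 95% CI (the exact-test convention; the sample
cross-product ratio is reported alongside). The universe matters: enrichment
over the SNPs testable in both assays is the honest choice for overlap
questions and differs measurably from the full-design universe whenever
testability is annotation-biased.

The motif-direction analysis classifies each SNP-oligo pair as `match`
(motif strand equals the oligo's transcribed strand: forward oligos
transcribe `+`, reverse oligos `-`) or `opposite`, then tests, per factor,
whether per-oligo ASE significance associates with configuration, Bonferroni
corrected over factors. Factors with fewer than two oligos in either
configuration are skipped — the margin is degenerate.

# The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_design()`,
`simulate_dna_counts()`, `simulate_rna_counts()`,
`simulate_rna_molecules()` and `simulate_binding_counts()` realize them.
Defaults mirror the assay structure: nine RNA replicates, seven DNA library
replicates, triplicate bound/unbound fractions at three concentrations, two
oligo orientations per SNP on a 200 bp insert (230 bp with constant
adapters), and design categories (eQTL, CentiSNP, GWAS, negative control)
with negative controls guaranteed effect-free and the CentiSNP label linked
to true functionality at a configurable odds ratio (default 2.5) so
enrichment recovery is testable.

Key generative choices:

* **Overdispersion by beta mixing.** Per SNP × replicate, the allele
  proportion is drawn from a Beta with mean
  $\operatorname{expit}(\operatorname{logit} p_0 + \beta)$ and correlation
  parameter $\rho$ (variance inflation $1 + (N-1)\rho$), matching the test's
  model so calibration experiments are exact. The draw is shared
  (comonotone) across the two orientations of a SNP, so orientation-pooled
  counts remain beta-binomial at the same $\rho$ — replicate-level state
  affects both oligos of a SNP together.
* **Depths** are negative-binomial (`nb_size = 10`, i.e. ~32% CV) around
  100 molecules per SNP per replicate; the plasmid proportion is
  $\mathrm{Beta}(50, 50)$ by default (SD ≈ 0.07 around balance), with a
  concentration of 5 used to stress-test imbalance robustness.
* **UMIs collide realistically.** UMIs are uniform over $4^{10}$; each
  molecule is emitted $1 + \mathrm{Poisson}(\mu_{dup})$ times, duplicates
  sharing the UMI. Exact-match collapse is the dedup contract.
* **Coupled effects.** ASE and ASB effects share a latent Gaussian
  correlation (default 0.5) — binding disruption is one mechanism behind
  expression effects — so the default dataset shows ASE × ASB overlap
  enrichment, as the binding assay is designed to demonstrate.
* **Orientation-specific effects** (off by default) give one factor's SNPs
  an effect only on the oligo transcribed opposite to the motif strand,
  exercising the direction analysis.

What the generator does **not** emulate: sequence content (motif matrices,
GC), read errors, reference-mapping bias (handled upstream by SNP-aware
alignment in real data), UMI errors, and real PCR jackpotting (duplication
is Poisson, not heavy-tailed). Passing calibration and recovery tests on
this generator therefore demonstrates internal consistency of the
statistical machinery under its stated model — not robustness to every
artifact of real sequencing data.

# Numerical choices and degenerate inputs

* Haldane–Anscombe pseudocount 0.5 on all estimated proportions; proportions
  clamped away from 0/1 before logits.
* SNPs with zero DNA or zero RNA molecules are flagged untestable and
  excluded (reported via attributes), never errors; the testability filter
  defaults (RNA ≥ 5, DNA ≥ 10 pooled molecules) stand in for an unpublished
  filter and are config-exposed.
* $\hat\rho$ is clamped to $[0, 0.49]$; a degenerate all-$N{=}1$ dataset
  yields $\rho = 0$ with a warning.
* Exact beta-binomial p-values use a $(1 + 10^{-7})$ tolerance when summing
  "no more likely" outcomes, avoiding floating-point tie misses.
* Fisher p-values are capped at 1 (summation overshoot).
* All simulation stages draw from deterministic per-stage seeds derived from
  the master seed, so replicate-subset generation reproduces slices of the
  full run bit for bit.

# Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` run every experiment at the sizes
the package documents as its operating points: 10,000 SNPs for null
calibration (3 replicates) and for the duplicate ablation (9 replicates,
~36M simulated reads); 5,000 SNPs for effect recovery (depth 200) and for
the ΔAST experiments; 20 × 500 regions for the call gate; all 135,750
2×2 tables with total ≤ 40 for the Fisher oracle; 20,000 SNPs for
enrichment recovery and 4,000 for the direction analysis. Each completes in
well under the few minutes its block allows.

# Known limitations

* The effect-recovery correlation over *all* SNPs (nulls included) is
  bounded by the overdispersion floor $\rho/(pq)/k$ of the per-SNP meta
  variance — about 0.85 at $\rho = 0.05$ with nine replicates regardless of
  depth; recovery is assessed on the functional subset (≈ 0.95), where the
  metric is meaningful.
* The meta-level $\lambda_{GC}$ runs ~2% above 1 on null data (residual
  delta-method approximation of the logit variance); type-I error at 5% is
  unaffected to within simulation error.
* A single genome-wide $\rho$ per fraction is assumed; per-SNP random
  effects are out of scope.
* The region test's Wald p-values rely on binned moment dispersions; with
  very few regions (< ~100) the bins are noisy and the exact FDR of the
  joint gate is approximate (the gate is dominated by the fold-change
  threshold in practice).
* `direction_analysis()` treats oligos as independent; within-SNP
  correlation between the two orientations makes the per-factor Fisher test
  conservative, never anticonservative.
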