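---
title: "Genomic fabrics: model, estimators and design choices"
author: "genofabric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic fabrics: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genofabric)
```

This vignette is the package's own account of the statistical model it
implements: what each estimator assumes, which readings of ambiguous
conventions were adopted and why, what the synthetic-data generator does
and does not emulate, and the numerical choices that matter in corner
cases.

## 1. Data model

The experimental unit is a set of two-color microarray samples — several
phenotypes, `n` biological replicas each (default 4) — in which gene `i`
is probed redundantly by `R_i` spots (1–13). After quality filtering and
normalization the data form, per phenotype, a gene × spot × replica tensor
`a[i, k, ξ]` of strictly positive expression values in units of the
phenotype's median gene. Biological replicas are treated as the same
system under slightly different conditions: the replica-to-replica
variation of a gene is biology, not error, and is itself a quantity of
interest.

### Spot filtering

A spot is retained only if it is flagged `ok` **and** has foreground at
least twice the background in **every** profiled sample; a gene survives
if at least one of its spots does. The any-sample rule makes the retained
spot set identical across samples, which the pooled estimators below
require. Control spots (empty gene symbol) are parsed but excluded from
all statistics.

### Normalization

Background-subtracted intensities (`fg − bg`; the filter guarantees
positivity except for degenerate `fg = bg` spots, which are re-rejected
and reported) are alternately rescaled within and between arrays to the
expression level of the median gene until the *error of estimate* — the
maximum over samples of the relative inter-iteration change of the
cumulative sample scaling factor, in percent — drops below a tolerance
(default 5%). The error statistic is not given a closed definition in the
genomic-fabric literature; this package defines it as above because it is
computable, non-increasing after the first pass, and reproduces the
"alternate until < 5%" behaviour. Dividing each sample by its median-gene
expression makes the subsequent per-sample medians exactly 1, so the loop
converges in at most two passes on clean data; the inter-array step
(alignment to the geometric mean of per-sample medians) is then the
identity, and the final inter-array alignment is performed as a
per-phenotype division by the median-gene AVE. This enforces the unit
contract exactly: `median_genes(AVE) = 1` in every phenotype (tested at
1e-6), and the whole map is invariant under rescaling any input sample by
a positive constant.

Two conventions here are genuinely open and are documented as potential
sources of divergence when re-analysing deposited datasets: whether
background is subtracted before normalization (subtracted here), and
whether the two dye channels of an array are normalized separately (here
each channel is an independent sample, since co-hybridised channels carry
distinct biological replicas).

## 2. The three gene quantifiers

**AVE** is the mean over spots of the replica-mean spot expressions.

**REV** is the chi-square mid-interval estimate of the pooled CV,

$$\mathrm{REV}_i = \frac{1}{2}\left(\frac{r_i}{\chi^2(r_i;0.975)} +
\frac{r_i}{\chi^2(r_i;0.025)}\right)
\sqrt{\frac{1}{R_i}\sum_k \left(\frac{s_{ik}}{\mu_{ik}}\right)^2}
\times 100\%, \qquad r_i = nR_i - 1 .$$

The quantile convention is fixed by the requirement that the correction
exceed 1 for finite `r` (and tend to 1 as `r → ∞`): `χ²(r; q)` is the
quantile with *upper-tail* probability `q`, so the first term is the
larger. At `r = 3` the correction is 7.11; at `r = 399` it is 1.015.

**COR** as commonly typeset (replica mean minus its own mean) is
degenerate; this package adopts the reading that uniquely reproduces the
published critical values 0.95 / 0.707 / 0.273 at `df = 4R − 2`: the
Pearson coefficient of the *spot-centered, replica-resolved* deviations
`d[i,k,ξ] = a[i,k,ξ] − μ[i,k]`. For pairs of equal redundancy the sums run
over all (spot, replica) cells with spots paired by index; for unequal
redundancy the per-replica spot-averaged deviations are correlated and the
conservative effective sample size `n·min(R_a, R_b)` governs the cutoff
(the literature is silent on this case). Cutoffs are the exact two-tailed
critical Pearson values, `t_c/√(t_c² + df)`; whether the published 0.95 is
exact or rounded cannot be settled, so the package computes exactly and
rounds only for display. The ±0.025 independence band matches no standard
α at df = 2; it is implemented as given and left configurable.

A model property worth stating plainly: the `df = 4R − 2` convention
credits each additional spot with independent information about the
replica profile. If the biological replicate effect is shared by all
spots of a gene — as it is in this package's generator, and arguably in
reality — redundant spots add technical, not biological, degrees of
freedom, and the cutoffs for `R > 1` are anti-conservative under the
generator's model. Calibration studies in the test-suite and acceptance
script therefore run at single-spot redundancy, where the threshold is
exact under approximate normality; the `R > 1` cutoffs are verified
analytically against the critical-r table instead. The same property
makes REV estimates of high-`R` genes noisier than their nominal `4R − 1`
degrees of freedom suggest.

## 3. Regulation statistics

The signed expression ratio `x` is the ratio of AVEs, negative reciprocal
when expression falls, so `|x| ≥ 1` always. The gene-specific threshold is
`CUT = 1 + √(2(REV_P² + REV_Q²))/100` with REV in percent — the bracketing
is fixed by dimensional analysis (CUT must be a fold change) and by the
anchor CUT = 2 at REV = 50/50. Significance requires both `|x| > CUT` and
a two-tailed Welch t-test below α = 0.05. The Welch test runs on the `n`
per-replica spot-averaged expressions (4 vs 4), not on all spot × replica
values: spots are technical repeats of the same biological replica and
would spuriously inflate the sample size. No multiple-testing correction
is applied anywhere — fidelity to the per-gene criterion is the point of
the method, and this is stated prominently rather than hidden.

`WIR = AVE_Q · sign(x) · (|x| − 1) · (1 − p)` uses the same Welch p,
uncapped. `WPR` is the mean squared WIR over a gene set's quantified
genes; the uniform ±1 measure is emitted as a derived column.

## 4. Gene commanding height

$$\mathrm{GCH}_i = \frac{\langle \mathrm{REV}\rangle}{\mathrm{REV}_i}
\exp\!\left(\frac{4}{N}\sum_{j\neq i}\mathrm{COR}_{ij}^2 - 1\right)$$

The exponent's typeset form is ambiguous; the reading `(4/N)·Σ` is adopted
because, with 4 replicas, the null expectation of a sample `COR²` is
`1/(n−1) = 1/3`, making the exponent O(1) and `GCH ≈ e^{1/3}` for an
average gene — the only reading that keeps scores on the scale at which
they are reported. `⟨REV⟩` is the arithmetic mean over the quantified
universe (median available as an option); the sum runs over the whole
universe. Genes with `REV = 0` (no observed variability) would have
infinite control; they are flagged and reported separately instead of
dominating the ranking. Ties are broken lexicographically by symbol. The
per-gene `Σ COR²` accumulates in row blocks, so chip-scale universes never
materialise the full correlation matrix.

## 5. The synthetic-data generator

`fabric_design()`/`simulate_experiment()` emulate the study design the
estimators assume: 3 phenotypes × 4 replicas, redundancy 1–13 drawn from a
distribution concentrated on single spots (P(R=1) = 0.70, thinning to
0.002 at R = 13), log-normal base levels (log-mean log 500, log-sd 1),
additive background (level 50 with 5% log-jitter), a corrupted-measurement
rate (default 1%), and multiplicative log-normal noise. The foreground of
gene `i`, spot `k`, replica `ξ` in phenotype `P` is

$$fg = bg + L_i\,F_{iP}\,e^{b_{ik}}\,
e^{\varepsilon_{i\xi P} + \lambda_i z_{\xi P m}}\,e^{\tau_{ik\xi P}}$$

with fixed spot bias `b` (log-sd 0.15), per-replica biological effect `ε`
whose gene-specific CV is uniform on 2–40% (a free choice — the empirical
REV distribution of real cortical data is not published — documented as
such), planted fold multipliers `F`, module latent factors `z` entering
through ±1 loadings times a module `latent_sd` (coordination is planted at
the replica level because COR correlates across replicas), and an
independent per-measurement technical term `τ` (CV 5% by default). The
technical term is this package's addition to the minimal model: without
it, all spots of a gene are deterministic multiples of each other and
redundancy would be statistically vacuous.

What the generator does **not** emulate: dye-swap bias, spatial artifacts,
probe-sequence effects, heavy-tailed outliers, and correlated background.
Passing tests therefore validate the estimators under the model's own
assumptions, not robustness to those artifacts.

### Study conditions used by the validation suite

* *Type-I calibration* — 1,000 genes, no folds, no modules, single-spot
  redundancy (see §2 for why R = 1 is the regime where the cutoff's
  nominal level is exact). Observed significant-coordination fraction
  ≈ 0.05; significant-regulation fraction ≈ 0 (the CUT conjunction is
  deliberately conservative relative to the t-test alone).
* *Fold recovery* — 200 genes planted at 4× (10% biological CV) in a
  4,000-gene universe. The planted fraction is kept at 5% because median
  normalization assumes sparse regulation: planting a third of the
  transcriptome upward drags the median-gene anchor and biases every
  estimated fold downward by tens of percent — a property of
  median normalization worth knowing, not an estimator defect.
* *Module recovery* — five 10-gene synergistic modules, `latent_sd = 1`,
  module-gene CV 2–5%, chosen from a pre-implementation power analysis of
  the bivariate log-normal replicate model (per-pair detection ≈ 0.99 at
  n = 4). Module studies use brighter base levels (log-mean log 5000)
  because a strong latent factor occasionally swings a dim gene below
  twice-background in one replica, and the any-sample filter would then
  delete it — an interaction between planted coordination and quality
  filtering, exercised separately in the filter tests.
* *Master-regulator recovery* — one gene with R = 13, biological CV 1%,
  loaded with 40 partners (20% of a 200-gene universe) on a weak latent
  factor, in an otherwise single-spot universe; the hub attains rank 1 in
  ≥ 95% of 20 seeded runs. Redundant null genes are excluded from this
  study because their REV estimates carry far fewer effective degrees of
  freedom than nominal (§2) and would contaminate a test that is about
  the GCH composition, not REV estimation noise.

Problem sizes throughout (200–4,000 genes) are chosen so the full suite
completes in seconds while every rate is estimated from hundreds of
planted units.

## 6. Degenerate inputs and numerical conventions

* Zero-variance genes: COR undefined → flagged, excluded from networks
  and contributing zero to GCH sums; REV = 0 → infinite-control flag.
* `fg = bg` spots slip through the 2× filter only when both are 0; they
  are re-rejected at background subtraction and reported, never clipped.
* Equal means give `x = 1` exactly (ratio branch `≥`), hence WIR = 0.
* Identical constant replicas in a Welch test give p = 1 (no evidence);
  unequal constants give p = 0.
* Genes, spots and samples are ordered by locale-independent radix sort,
  so results are invariant to input row order.
* Median of an even-sized gene universe follows the usual interpolation;
  the phenotype-level rescale uses that same median, which is what makes
  the unit contract exact rather than approximate.

## 7. Known limitations

Single-channel (within-array) dye effects are not modelled or corrected
beyond median scaling. The pooled COR for equal-redundancy pairs relies
on an arbitrary spot pairing by index; alternatives (all spot pairs,
averaging first) differ when spot biases are large. The significance
framework is per-pair and per-gene with no FDR control, by design —
interpret absolute counts of significant pairs accordingly, especially in
universes of 10⁸ pairs. Re-analysis of deposited studies through
`fabric_from_matrix()` inherits whatever preprocessing the depositors
applied; the unstated conventions listed in §1 can cause bounded
divergence from originally reported per-gene values.
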