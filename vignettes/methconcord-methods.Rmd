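---
title: "Cross-tissue methylation concordance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue methylation concordance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methconcord)
```

## The question

Brain tissue is essentially inaccessible in living cohorts, so epigenetic
studies of neuropsychiatric phenotypes measure DNA methylation (DNAm) in
surrogate tissues — whole blood, saliva, buccal swabs — and hope the surrogate
tracks the brain. "Tracks" hides two very different claims, and this package
keeps them explicit throughout:

1. **Across-subject concordance.** Average each tissue's beta values over
   subjects to get one genome-wide profile per tissue, then correlate profiles
   between tissues (Pearson, over probes). This is dominated by the probe-level
   methylation architecture that all human tissues share — CpG islands
   hypomethylated, intergenic oceans methylated — and is therefore high for
   almost any tissue pair. It answers "do these tissues have similar
   methylomes?", not "is the surrogate informative about this person?".
2. **Within-subject concordance.** For each CpG separately, correlate the
   paired measurements across subjects between two tissues (Spearman, over
   subjects). This is the question a biomarker needs answered: when an
   individual's blood methylation at a CpG is unusually high, is their brain
   methylation at that CpG also unusually high?

The package implements both, plus the supporting stages a real analysis needs:
probe-level QC, a variable-CpG filter, statistical comparison of dependent
correlations, stratification by genomic context, sample-level ordination, and
cell-composition adjustment. A synthetic cohort generator with fully known
latent structure makes every stage testable end to end.

## Within-subject correlation and its small-sample inference

For probe $j$ and tissues $a,b$, the statistic is Spearman's $\rho_j =
\mathrm{cor}(\mathrm{rank}(x_{aj}), \mathrm{rank}(x_{bj}))$ over the subjects
with complete pairs (duplicate samples per subject-tissue are averaged first).
Rank correlation is the right choice at cohort sizes of a couple dozen:
beta values are bounded, often skewed, and a single outlying subject can
manufacture a large Pearson $r$.

Two-sided p-values come from two routes, switched on the number of complete
pairs $n$:

* $n \le 7$ (`exact_cutoff`, tunable): **exhaustive permutation enumeration**.
  All $n!$ assignments of one tissue's ranks are enumerated and
  $p = \#\{|\rho_\pi| \ge |\rho_{obs}|\}/n!$. Ties are handled with average
  ranks, in which case the enumeration runs on the observed tie pattern.
  This is exact by construction; at $n=6$ a perfectly monotone pair gives
  $p = 2/720 \approx 0.0028$, which is also the smallest attainable two-sided
  value — worth knowing before promising genome-wide significance at small $n$.
* $n > 7$: the **t approximation**, $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on
  $n-2$ df. Factorial growth makes enumeration impractical beyond 7, and at
  $n \ge 8$ the approximation's $\alpha=0.05$ decisions agree with the exact
  distribution for all but borderline fixtures (we measure ~97% decision
  agreement even at $n=5..7$, where the package never actually uses it).
  Deep tails of the approximation are not trusted anywhere in the package's
  summaries beyond a Bonferroni count.

Probes with fewer than `min_pairs` (default 5) complete pairs, or with a
constant vector in either tissue, are reported as null records with the pair
count — never silently dropped, never given a fabricated p.

## Variable CpGs

Most CpGs barely vary between people; a cross-tissue correlation there is
uninformative noise around zero. The classifier discards each probe's values
outside the central 10th–90th percentile band (type-7 linear-interpolation
quantiles; `trim = 0.10` per side) and flags the probe as variable when the
remaining values still span at least `min_range = 0.05` on the beta scale —
the boundary is inclusive ("at least 5%"). Summaries can be restricted to
probes variable in the peripheral tissue, in the reference tissue, or both;
the two restrictions give different denominators and both are exposed because
either convention is defensible.

## Comparing dependent correlations

"Is saliva more brain-correlated than blood?" compares $r(\text{brain},
\text{saliva})$ with $r(\text{brain},\text{blood})$ — two correlations sharing
the brain variable, so they are themselves correlated through
$r(\text{saliva},\text{blood})$ and a naive independent-samples z-test is
invalid. `compare_dependent_correlations()` implements the Fisher-z statistic
with the Meng–Rosenthal–Rubin covariance correction for overlapping dependent
correlations:

$$Z = (z_1 - z_2)\sqrt{\frac{n-3}{2(1-r_{xy})h}},\qquad
h = \frac{1 - f\bar r^2}{1-\bar r^2},\quad
f = \min\!\left(1, \frac{1-r_{xy}}{2(1-\bar r^2)}\right),$$

with $z_i = \operatorname{atanh}(r_i)$ and $\bar r^2 = (r_1^2+r_2^2)/2$. At
genome-scale $n$ the normal p-value underflows double precision; the returned
p is floored at the smallest positive double and flagged `p_underflow`, i.e.
reported as a bound rather than a fake zero. A Monte-Carlo calibration under a
trivariate equicorrelated null (n = 50, 10,000 reps) keeps the empirical
type-I rate within a point of 5% in the test suite; the test runs slightly
conservative (~0.045), which is the documented behaviour of the $f$-capped
correction.

## Probe QC

Three annotation-driven exclusion rules (SNP within 5 bp, unreliable
measurement, context-specific/non-CpG probe) remove probes before analysis; a
probe failing several rules is attributed to the first in that canonical
order, so per-rule counts sum to the removed total. Unreliability combines a
strict detection-p rule (entry unreliable iff $p > 0.01$; exactly 0.01 passes)
with an iterative greedy matrix cleaner: repeatedly delete the single probe
*or* sample with the highest fraction of unreliable entries until no row or
column exceeds `stop_fraction` (default 0.05). The greedy procedure's
tie-breaks (row preferred, then lexicographic identifier) are fixed so runs
are reproducible; it is a documented surrogate for the greedy-cut style of
cleaning used by array-QC pipelines, not a clone of any one implementation.

Sample identity is verified on the array's 65 SNP probes, whose beta values
are trimodal (0, 0.5, 1 by genotype) and genotype-determined, hence identical
across a subject's tissues. Pairwise Pearson similarity over SNP probes flags
same-subject pairs below `same_threshold = 0.9` and different-subject pairs
above `diff_threshold = 0.8`; the thresholds are ours (visual clustering has
no number), and zero-variance SNP vectors mark a sample unevaluable instead
of erroring.

## Sample structure

Classical (Torgerson) MDS — double-centering of squared distances,
eigendecomposition, coordinates scaled by root-eigenvalues — embeds all
samples from all tissues; Euclidean distance on beta vectors is the default
metric with `one_minus_r` as an alternative, and the choice is recorded in
the result. Axis signs are fixed by forcing each axis's largest-magnitude
loading positive so plots reproduce. The regression of each subject's
cross-tissue correlation on the distance between that subject's two samples
uses the distances themselves (the full-rank geometry), not the k = 2
projection, to avoid projection artifacts; it reports slope, $r^2$, and the
F-test on (1, n−2) df.

## Cell-composition adjustment

Bulk tissue is a mixture: a sample's beta vector is modelled as
$y \approx R w$ with $R$ the reference cell-type beta profiles and $w$ on the
probability simplex. `estimate_proportions()` solves the constrained least
squares exactly by enumerating candidate active sets (all subsets of cell
types) and solving each subset's KKT system — exact for the small number of
cell types that tissue deconvolution uses, and trivially satisfying
"no vertex of the simplex does better". `adjust_for_composition()` then
residualizes each probe on the estimated proportions (one column dropped to
break the sum-to-one collinearity; pivoted QR tolerates constant
proportions, where adjustment is correctly a no-op), re-centers at the probe
mean, clips to [0,1] with a count of clipped entries, and reports the
per-probe $R^2$ — "how much of this CpG's variation was composition".

Betas, not M-values, are adjusted; the residualization-on-betas choice keeps
the adjusted values interpretable as methylation fractions and matches the
mixture model being linear on the beta scale. A caveat the test suite made
vivid: with $K$ cell types the per-probe regression spends $K-1$ of the
cohort's ~20 df, and at $K=4$ that overfitting alone attenuates mean Spearman
rho by ~0.1 even when composition explains nothing — with 2 effective cell
types the attenuation is within 0.05. Adjusted-vs-raw comparisons should be
read with that df cost in mind.

## The synthetic cohort generator

The generator exists so that every stage above can be tested against known
truth. Its model, chosen once:

* **Latent scale.** Each cell type $k$ has a logit-scale mean $\mu_{kp}$ per
  probe. A subject-level effect $u_{sp} \sim N(0, \sigma_u^2)$ is shared
  across *all* tissues of subject $s$; each sample adds independent noise
  $e \sim N(0, \sigma_e^2)$. Cell-type mixing happens on the **beta** scale
  — bulk methylation is physically a linear mixture of cell methylomes — so a
  sample's value is $\sum_k w_k\,\mathrm{logit}^{-1}(\mu_{kp} + u_{sp} + e)$,
  clipped to $[10^{-6}, 1-10^{-6}]$ to keep logits finite.
* **Cross-tissue correlation** is induced solely by the shared subject
  effect: the latent correlation is $\rho = \sigma_u^2/(\sigma_u^2 +
  \sigma_e^2)$, and `target_rho` is solved for $\sigma_u$ given the
  configured noise. Requesting $\rho = 1$ with noise, or $\rho < 1$ without
  noise, is rejected as unattainable. Observed Spearman correlations sit
  slightly below the latent target (the usual rank-correlation attenuation
  for Gaussian latents, $\approx \frac{6}{\pi}\arcsin(\rho/2)$), which is why
  recovery checks compare against a Monte-Carlo oracle with the same variance
  components rather than against $\rho$ itself.
* **Mixtures.** One Dirichlet draw per sample over cell types, with per-tissue
  concentrations. The defaults encode the emulated study: 21 subjects; brain
  a neuron/glia mixture; blood nearly pure leukocyte; saliva a ~70/30
  leukocyte/epithelial mixture with real sample-to-sample spread
  (concentrations 35/15); buccal ~20/80 (10/40). These defaults are the
  mechanism behind the reproduced tissue ordering: a balanced two-type
  mixture halves the variance of its cell-specific deviation from the shared
  methylation architecture, which pulls saliva's average profile closer to
  brain's than pure blood or epithelial-dominated buccal — without any
  brain-specific signal leaking into saliva.
* **Variable probes.** A configurable fraction (default 0.25) of probes get
  mid-range base methylation (logit base $\sim N(0,1)$), where the inverse
  logit has slope and between-subject spread is visible; the rest sit near
  the 0/1 extremes (|logit| ≥ 3.2, cell-type offsets damped) where the same
  latent noise compresses to a few percent of beta.
* **Determinism.** One root seed; every probe block (1000 probes), stream
  (profiles / subject effects / per-tissue noise), and accessory draw
  (mixtures, detection p, SNP probes) derives its own sub-seed through a
  small-multiplier LCG mix, and every stream draws a full block before
  truncating — so enlarging `n_probes` leaves all earlier probes' values
  bit-identical.
* **Accessories.** Detection p-values are uniform on (0, 0.005) for passing
  entries and (0.02, 1) for failing ones, so the 0.01 rule separates them
  cleanly at any threshold in between. The 65 SNP probes draw
  Hardy–Weinberg genotypes once per subject and reuse them across the
  subject's samples. The annotation table assigns genic class, regulatory
  flags, mQTL and QC flags at plausible marginal rates, and probes to
  synthetic gene symbols (~20 probes/gene).

What the generator deliberately does **not** emulate: Infinium probe-type
chemistry, spatial/batch effects, age or sex trends, genuinely
tissue-specific regulatory signal (differences between tissues arise only
from composition), or correlated probes within CpG islands. Passing tests
therefore demonstrate that the *statistical machinery* is correct and
calibrated — not that any particular real tissue pair attains any particular
concordance.

## Problem sizes and numerical choices

Simulation-backed checks use sizes chosen to keep Monte-Carlo error well
inside the margins being tested: null calibration at 10,000 probes × 21
subjects (binomial SE ≈ 0.002 on a 5% rate); correlation recovery at 5,000
probes × 50 subjects against a matched-components oracle (±0.05 band);
type-I calibration of the dependent-correlation test at 10,000 replicates;
tissue-ordering reproduction at 6,000 probes × 10 seeds, where the
profile-correlation Monte-Carlo error is several-fold smaller than the
saliva-vs-buccal margin (~0.004 in r); and one full pipeline run at 50,000
probes × 4 tissues × 21 subjects. Other fixed numerics: type-7 quantiles
everywhere; inclusive boundary at the variability cutoff; strict inequality
at the detection-p threshold; correlations clipped to [−1,1] against
floating-point overshoot; p-values floored at the smallest positive double
and flagged when underflowed; Bonferroni thresholds computed as
$\alpha/m$ with the family size always reported alongside.

## Limitations

* Exact Spearman inference stops at $n = 7$ pairs; between 8 and ~15 the t
  approximation is adequate for 0.05-level decisions but not for extreme
  tail claims.
* The dependent-correlation test assumes bivariate-normal-ish underlying
  variables; applying it to correlations of averaged methylation profiles
  (hundreds of thousands of non-independent probes as "observations")
  inherits that caveat, and its genome-scale p-values should be read as
  bounds.
* Reference-based composition adjustment is only as good as the reference
  profiles; no real reference panel ships with the package, and for tissues
  without established panels (saliva, buccal) the adjustment can only be
  exercised on synthetic truth.
* The greedy QC cleaner is order-deterministic but greedy; it makes no
  optimality claim beyond its stop criterion.
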