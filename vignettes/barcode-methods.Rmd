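---
title: "Expression barcoding and binarized differential expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression barcoding and binarized differential expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeDE)
```

## The barcode model

A gene's log2 intensity in a sample is modeled as coming from one of two
states.  When the gene is *silenced* (not transcribed), the observed value
is optical and electronic background, well described by a normal
distribution; when it is *expressed*, the value can land anywhere between
the silenced level and the scanner's saturation, modeled as uniform.  For
gene $g$ and sample $i$:

$$ y_{ig} \sim (1 - p_g)\, N(\mu_g, \tau_g^2) \;+\; p_g\, U(\mu_g, S_g), $$

with $p_g$ the expressed fraction of samples and $S_g$ the saturation
value.  The per-gene parameters are tied together hierarchically,

$$ \mu_g \sim N(\xi, \lambda^2), \qquad \tau_g^2 \sim
\mathrm{InvGamma}(\alpha, \beta), $$

so that variance information is borrowed across genes: a gene observed
mostly in the expressed state still gets a usable estimate of its silenced
variance, shrunk toward the across-gene consensus.

A value is called *expressed* (barcode 1) when it is implausibly far into
the upper tail of the silenced normal:

$$ \mathrm{barcode}_{ig} = \mathbf{1}\{\Phi(-(y_{ig} - \mu_g)/\tau_g) < C\},
\qquad C = \Phi(-6.5) \approx 4\times 10^{-11}\ \text{by default}, $$

i.e. a value must sit 6.5 silenced standard deviations above the silenced
mean.  The extreme default reflects the asymmetry of the decision: a
silenced call is the default state, and the expressed call should be
essentially free of false positives so that expressed proportions can be
compared across cohorts and platforms.  `binarize()` exposes $C$ as a
knob; the $z$-threshold form $y > \mu + z_C\,\tau$ is equivalent.

Reference-corpus barcoding pins $(\mu_g, \tau_g)$ from thousands of
archived chips.  This package estimates them from the cohort at hand by
default and accepts externally supplied per-gene values (`frozen`
argument) when reference estimates are available.

## Fitting: EM, shrinkage, and when point estimates are not enough

`barcode_fit()` runs a per-gene EM on the two-component likelihood,
vectorized across genes.  The E-step computes posterior
expressed-membership weights; the M-step re-estimates $(\mu_g, \tau_g^2,
p_g)$ from silenced-weighted moments.  Numerical choices:

* $S_g$ is pinned at the gene's observed maximum + 0.1 rather than
  estimated — the uniform upper endpoint is weakly identified and is, by
  construction, a saturation bound.
* Initialization is robust to the expressed tail: $\mu^0$ = median of the
  lower half of the gene's values, $\tau^{2,0}$ = squared MAD of that
  half, $p^0$ = fraction of values above $\mu^0 + 3\tau^0$.
* Convergence: relative log-likelihood change below `tol` ($10^{-6}$),
  at most `max_iter` (200) iterations; variances floored at $10^{-6}$.
* A constant gene cannot be fit: it is flagged `converged = FALSE` with
  $p = 0$ and the floor variance.

After the per-gene pass, `estimate_hyperparameters()` recovers $(\xi,
\lambda^2)$ as the mean and variance of the fitted $\mu_g$ and
$(\alpha, \beta)$ by matching the inverse-gamma mean
$\beta/(\alpha-1)$ and variance $\beta^2/((\alpha-1)^2(\alpha-2))$ to the
empirical moments of the fitted $\tau^2_g$ ($\alpha$ floored at 2.01 when
the moments are incompatible).  Genes whose first-pass EM collapsed onto
a handful of points (effective silenced count below 5, or non-converged)
are excluded from the moment matching — unpenalized mixture EM can chase
a likelihood spike where a near-zero-variance "silenced" component holds
a single observation, and such fits would corrupt the moment equations.

A second, *hierarchical* EM pass then refines every gene under the
estimated priors, from two starts: the first-pass solution, and a
high-expressed-fraction start anchored at the gene's lower 5% quantile.
The robust initialization can land in an inverted basin for genes
expressed in most samples — the "silenced" normal fits the expressed
cluster and the whole gene is miscalled — and the two refined solutions
are compared by their prior-penalized objective, keeping the better one
per gene.  In the refinement the M-step for $\mu_g$ is
precision-weighted toward $\xi$, and the variance update is the
inverse-gamma posterior mode

$$ \hat\tau_g^2 = \frac{\beta + W_g \hat\tau_{g,w}^2/2}
{\alpha + 1 + W_g/2}, $$

with $W_g$ the effective silenced count and $\hat\tau^2_{g,w}$ the
silenced-weighted variance.  This is where the borrowing of strength
actually happens: the penalized objective is bounded (no variance
spikes), genes observed mostly in the expressed state are pulled toward
the across-gene consensus, and the spread of the variance estimates
contracts (testable as `var(tau2_hat) <= var(tau2_raw)`).

**Weak identifiability and the posterior option.**  When $\tau_g$ is
large relative to the uniform span (roughly $(1-p)\phi(0)/\tau \lesssim
p/(S-\mu)$), the silenced bump is as flat as the uniform floor and
$\mu_g$ is weakly identified at realistic sample sizes.  Point estimates
— EM, multi-start EM, or MAP with the hierarchical prior — can then sit
many conditional standard errors from the truth while looking confident,
because the conditional ("complete-data") information overstates what the
data know; and curvature-based standard errors are unavailable in
principle, since the likelihood is piecewise-discontinuous in $\mu$ (the
uniform support indicator jumps at every data point).  For honest
uncertainty, `barcode_fit(posterior = TRUE)` samples the full posterior
by Gibbs: given the latent labels the model is conditionally conjugate
(inverse-gamma for $\tau^2$, beta for $p$), with a Metropolis step for
$\mu$ whose conditional is non-conjugate through the uniform support and
the $(S-\mu)^{-n_{\mathrm{expr}}}$ factor.  Two chains are seeded at the
two competing EM explanations of each gene (the robust-start solution and
a high-expressed-fraction solution started from the lower 5% quantile)
and pooled; the reported `mu_se` includes the between-chain spread, so a
gene whose explanations disagree carries visibly inflated uncertainty.
On data generated from the model itself, posterior mean ± 3 SD intervals
are calibrated, which is what the parameter-recovery tests check.

## From barcodes to differential expression

Binary calls turn differential expression into a comparison of expressed
proportions.  Genes whose barcode is constant (all 0 or all 1) in any
cohort carry no proportion information and are removed first
(`filter_constant_barcodes()`); the survivors form the *testing
universe*, which is also the universe for every downstream overlap and
enrichment computation — only genes that could have been called can
overlap.  Per gene, the 2×2 table (case/control × expressed/silenced) is
tested with Fisher's exact test (two-sided, point-probability ordering)
and the odds ratio is reported as the raw cross-product $ad/bc$ with 0
and $\infty$ preserved — extreme tables are informative here (a gene
expressed in every case and no control), so no continuity correction is
applied.  Benjamini–Hochberg adjustment runs across all tested genes, and
genes with FDR < 0.05 are called differentially expressed, with direction
classified by expressed proportions.

When several array probes map to one gene, `collapse_probes()` keeps the
probe with the largest absolute log fold change (difference of group
means on the log2 scale), breaking ties by the lexicographically smallest
probe identifier so the choice is reproducible.

## Cross-cohort layers

*Overlap.*  `overlap_test()` partitions the shared universe by membership
in the two DEG sets and applies the same exact test; `venn_summary()`
reports the disjoint partition.  Two sidedness conventions are reported
(`p_value`, `p_one_sided`) since overlap questions are sometimes framed
as pure enrichment.

*Signature.*  `fit_signature()` fits a ridge-penalized logistic model
(Newton iterations with step-halving; penalty default $10^{-3}$,
intercept unpenalized).  The tiny ridge exists because barcode predictors
make complete separation likely — the same phenomenon that produces
infinite odds ratios — and the penalized likelihood remains well-defined
there.  Predictors are barcode values by default (platform-portable) with
log2 expression as a config switch; which scale the original analyses
used is not stated, so both are supported and neither asserted.
`roc_auc()` computes AUC by the rank (Mann–Whitney) formula, ties counted
half, with the curve from a threshold sweep.

*Networks.*  `spearman_matrix()` ranks each gene (average ranks on ties)
and correlates ranks; p-values use the $t$ approximation $t =
\rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df, with exact permutation
p-values available for very small groups (n < 10) where the
approximation degrades.  Correlations are computed on log2 expression,
not barcodes — rank correlation of binary vectors collapses to a 2×2
association and a $|\rho| > 0.4$ rule presumes continuous values.  An
edge requires both $|\rho| > 0.4$ (strict) and BH-FDR < 0.05 (strict),
with the FDR family being the unordered pairs of one (cohort, group)
matrix: each panel/group network is a self-contained multiple-testing
family.  `compare_networks()` reports gained/lost/retained edge sets
between two networks on the same panel.

*Enrichment.*  `hypergeom_enrich()` is deliberately database-free: it
takes user-supplied GMT collections and computes upper-tail
hypergeometric p-values $P(X \ge k)$ (identical to one-sided Fisher on
the membership table — a cross-module consistency test), excluding sets
smaller than 5 within the universe, BH across tested sets.  The universe
is the filtered testing universe, not all annotated genes; enrichment
against a larger universe than could have been tested inflates
significance.

## The synthetic-data generator

`simulate_cohort()` draws cohorts exactly from the hierarchical model:
$\mu_g$, $\tau^2_g$ from the priors, per-gene control expressed
probability uniform on a configurable range, and a planted fraction of
true DEGs whose case probability is shifted additively (the quantity the
downstream exact test detects).  The latent expressed indicators are
returned as the true barcode, so binarization, DEG calling, overlap,
signatures and networks can all be scored against ground truth.

Default hyperparameters mimic a log2 microarray scale — $\xi = 6$
(silenced means near background), $\lambda^2 = 1$, $\alpha = 3$, $\beta =
2$ (silenced variances averaging 1), $S_g = \mu_g + 6$ (expressed values
up to roughly saturation) — and are stand-ins: the real quantities live
in frozen reference-corpus estimates that are out of scope here.  Two
consequences of these defaults are worth knowing:

* Under $\tau^2 \sim \mathrm{IG}(3,2)$ a sizable minority of genes have
  $6.5\,\tau_g$ comparable to the whole uniform span, so the default
  cutoff calls many genuinely expressed values silenced.  Real barcoding
  operates in a lower-noise regime ($\tau \approx 0.1$–0.5); pipeline
  tests therefore also use a concentrated low-noise variance regime
  ($\alpha = 6, \beta = 0.5$), and barcode-fidelity checks use a
  well-separated regime ($S = \mu + 10$, $\tau^2 = 0.25$, expressed draws
  at least $8\tau$ above $\mu$).
* The generator does not model probe-level optics, batch effects,
  normalization artifacts, cross-hybridization or correlated genes.
  Passing tests demonstrate internal statistical correctness of each
  stage against the model's own ground truth — not robustness to the
  failure modes of real microarray data.

## Problem sizes used in the checks

The packaged experiments run at 2,000 genes × 200 samples for parameter
recovery (with posterior sampling), 20 replicates of 2,000 × 200 for null
error control, 2,000 × 300 for the powered DEG cohort, and 600–1,000
genes for pipeline, fidelity and signature checks — large enough for the
asymptotics the tests assert, small enough to run comfortably on one
core.

## Known limitations

* Cohort-estimated barcoding is not reference-corpus barcoding: absolute
  expressed/silenced calls depend on the cohort's composition.  The
  `frozen` mode restores parity when reference $(\mu, \tau)$ tables are
  available.
* The EM point estimate of $\mu_g$ is biased for weakly identified genes
  (see above); use `posterior = TRUE` when per-gene parameter values, not
  just barcode calls, are the object of interest.
* The exact test treats samples as exchangeable within groups; batch or
  pairing structure is not modeled.
* GraphML export and ROC plotting are conveniences; no network layout or
  figure styling is attempted.
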