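---
title: "Dual-factor harmonization of multi-lesion radiomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-factor harmonization of multi-lesion radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiomic features extracted from PET/CT lesions carry two kinds of signal:
the biology of the tumor and the fingerprint of the acquisition environment
— which hospital collected the scan and which scanner model produced it.
In multi-center studies of multi-lesion cancers (Hodgkin lymphoma being the
motivating case) both confounders must be removed at once, and the removal
must not destroy the *relative geometry* of each patient's lesions: the
dispersion of a patient's lesion "point cloud" is itself a prognostic
biomarker of intra-tumor heterogeneity, so a harmonization step that
rescales or reorders lesions patient-by-patient silently corrupts the very
signal the downstream survival model needs.

`cloudharmony` implements the three pieces needed to study this problem in
a self-contained way: a dual adversarial deconfounding autoencoder, the
ComBat family of location/scale harmonizers as benchmarks, and a rank-based
statistic (Point Cloud Semantic Drift) that tests whether a transformation
preserved cloud shape. Because the clinical cohorts this methodology is
aimed at are not public, the package ships a synthetic cohort generator
that reproduces their statistical structure, and all validation runs
against it.

## The dual adversarial deconfounding autoencoder

The backbone is an autoencoder with layer widths 45–32–16–32–45: encoder
$f_\phi$, decoder $g_\psi$, rectifier hidden units, linear output. Two
classification heads $h_{\nu_1}$ (center, 2 classes) and $h_{\nu_2}$
(scanner, 5 classes) branch from the 16-dimensional embedding, each with
two 50-unit hidden layers. Training is an alternating minimax:

* **adversary step** — update $\nu_1, \nu_2$ only, minimizing the
  cross-entropies of the heads' predictions from the (frozen) embedding;
* **autoencoder step** — update $\phi, \psi$ only, minimizing
  $\lVert x - g_\psi(f_\phi(x))\rVert^2
  - \lambda_1 L(h_{\nu_1}(f_\phi(x)), c)
  - \lambda_2 L(h_{\nu_2}(f_\phi(x)), s)$,
  i.e. reconstruct well while making the embedding unclassifiable.

$L$ is categorical cross-entropy: "classification accuracy" is the quantity
of interest but is not differentiable, and cross-entropy is its standard
smooth surrogate. The heads consume the embedding (the network's deepest
layer), not the input. Inputs are z-scored features (`standardize()`);
without a common scale the reconstruction and adversary terms are
incommensurable.

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `lambda_center`, `lambda_scanner` | 1, 1 | adversary weights in the encoder objective |
| `batch_size` | 128 | minibatch size |
| `adversary_steps` | 3 | adversary updates per autoencoder update |
| `lr`, `adversary_lr` | 1e-3 | Adam learning rates |
| `max_epochs`, `patience` | 2000, 20 | early-stopping control |
| `validation_fraction` | 0.1 | lesion-level held-out fraction |
| `monitor` | `"constrained"` | snapshot-selection criterion |

Two of these deserve explanation, because the obvious choices fail in a
measurable way.

**Snapshot selection.** Selecting the epoch that minimizes the raw minimax
objective $rec - \lambda_1 CE_1 - \lambda_2 CE_2$ is tempting but wrong: a
transient spike in the adversary losses (the heads momentarily confused)
makes the objective dip long before the adversarial equilibrium, and that
early snapshot still carries most of the batch signal. The default
`"constrained"` monitor instead tracks validation reconstruction plus a
hinge penalty $\lambda \cdot \max(0, H - CE)$ per head, where $H$ is the
base-rate entropy of the validation labels: an epoch is only rewarded for
reconstructing well if its heads are at chance. At equilibrium the head
cross-entropies sit at the base-rate entropies, the penalty vanishes, and
the criterion reduces to reconstruction.

**Adversary steps.** With a single adversary step per autoencoder step the
heads lag behind the encoder; a lagging adversary that cannot find the
batch signal sends no gradient to remove it, and a post-hoc logistic probe
still recovers the center from the embedding. Three steps keep the heads
sharp; on the default cohort this brings the embedding's center
predictability to within a few points of class prevalence across seeds.

## ComBat, ReComBat, cascades and order selection

The benchmark harmonizers follow the location/scale model: the value of
feature $f$ for sample $j$ in batch $i$ is
$Y_{ijf} = a_f + X\beta_f + \gamma_{if} + \delta_{if}\,\epsilon_{ijf}$,
with additive ($\gamma$) and multiplicative ($\delta$) batch effects.
`combat_fit()` estimates the grand intercept and any covariate
coefficients by least squares, standardizes residuals per feature, and in
`eb-parametric` mode shrinks the per-batch $\hat\gamma, \hat\delta^2$
toward batch-level priors (normal for $\gamma$, inverse-gamma for
$\delta^2$, hyperparameters by method of moments) with the standard
iterative conditional posterior means (tolerance 1e-6, max 500
iterations). `combat_apply()` corrects
$Y^* = (Y - \hat a - X\hat\beta - \hat\gamma^*)/\hat\delta^* + \hat a +
X\hat\beta$. A note on variance conventions: `ls-only` mode uses the
population variance for $\hat\delta^2$, which makes the correction an
exact location/scale identity (a single batch corrects to itself);
`eb-parametric` uses the $n-1$ convention of the reference parametric
implementation, against which the package is cross-checked in the test
suite.

ReComBat is the same estimator with an L2 penalty (default 1e-3) on the
covariate coefficients, which also rescues singular designs. With the
default intercept-only design the two coincide — the package exposes both
because two-factor cascades are run in both orders
(`sequential_harmonize()`), and order instability is one of the phenomena
under study: once interaction terms exist, center-then-scanner and
scanner-then-center produce measurably different tables.

`opnested_select_order()` is a deliberately simplified order selector: it
runs every permutation of the factors, counts residual (feature, factor)
associations with Kruskal–Wallis tests at level $\alpha = 0.05$
(rank-based, since normality of radiomic errors is exactly what is in
doubt), and keeps the order with the fewest significant pairs, ties broken
lexicographically. The published optimal-order procedure additionally
clusters features into confounder-associated subsets; that grouping is out
of scope here and the selector is labelled a variant accordingly.

## Point Cloud Semantic Drift

For each lesion (anchor) in a patient's cloud, rank the remaining lesions
by ascending Euclidean distance, with distance ties broken by lesion id so
the ranking is deterministic, and record scores $M \in (0, 1]$ — distances
divided by their maximum, so the farthest neighbor scores 1 and the
statistic is scale-free. The Spearman footrule between two rankings is the
sum of absolute rank differences, ranks capped at $k+1$ outside the top
$k$. The Point Semantic Drift weights each rank change by the score
change:
$$PSD = \sum_t \lvert M_{transf}(t) - M_{orig}(t)\rvert \cdot
\lvert r_{transf}(t) - r_{orig}(t)\rvert ,$$
so swaps between near and far neighbors cost more than shuffles among
near-equidistant ones. PCSD averages PSD over all anchors of a cloud. By
default $k = K-1$ (no truncation): both rankings always contain the same
lesions, so the cap only matters when a user requests it.

The test: perturb, 100 times, a random half (`subset_fraction = 0.5`,
at least one lesion) of each cloud with i.i.d. Gaussian noise of variance
3 (read as $\sigma^2 = 3$; a flag switches to $\sigma = 3$), compute the
population mean PCSD per perturbation, and report the left-tail empirical
p — the fraction of null draws strictly below the observed drift. A small
p says the transformation drifted the clouds far less than a
structure-blind random map would. The null perturbs the original clouds by
default (`perturb = "transformed"` is available, since either reading is
defensible). Clouds need a standardized scale for the noise variance to
mean anything; the pipeline z-scores features first. Patients with fewer
than 3 lesions are excluded from population statistics: under
max-normalization a 2-lesion cloud has PCSD identically 0, which would
bias the population mean toward zero.

## The synthetic cohort generator

`sim_config()` defaults encode the two-center study the methodology
targets: 128 + 78 patients, Poisson(10.5) lesions per patient truncated at
3 (so the drift statistic is non-degenerate; a flag allows 1–2-lesion
patients), 45 features in 6 collinear blocks loaded from a 5-dimensional
latent signal, 2 scanners in center 1 and 3 in center 2, and ~80%
censoring — the regime of the motivating cohorts (16% and 22% relapse).

Per patient: a latent mean $u_p \sim N(0, I_5)$ and a heterogeneity scale
$h_p \sim \mathrm{LogNormal}(\log 0.5, 0.6)$; per lesion a latent
$z = u_p + h_p \varepsilon$. Features are $zW + \sigma\eta$ with a fixed
loading matrix $W$ whose 6 column blocks share latent factors (the
collinear feature families of real radiomics). Batch effects enter in the
generative location/scale form:
additive per-feature center and scanner shifts (sd 1.0 each), a
center-by-scanner interaction shift (strength 0.3), a center-signed
$\tanh$ warp of the signal (strength 0.3; a nonlinearity that
location/scale correction cannot express), and multiplicative effects that
scale the *full residual* — biological deviation plus noise — because with
an intercept-only design that whole term is the $\epsilon$ of the
location/scale model. The multiplicative effects are per batch *and* per
feature ($\delta_{if}$, log-sd 0.4 around each batch's scalar): a
scanner's scale effect differs across feature families, so it warps clouds
anisotropically rather than uniformly rescaling them, which is what makes
scale confounding consequential for heterogeneity.

Survival: Weibull proportional hazards (shape 1.5, scale 24) with linear
predictor $\eta_p = \beta_h h_p + \beta_m u_{p,1}$ and uniform censoring
calibrated to the target fraction. The defaults $\beta_h = 2,
\beta_m = 0.5$ were set so that an oracle Cox model given the true
$(h_p, u_{p,1})$ reaches test concordance around 0.74 at ~80% censoring —
a moderate, realistic prognostic signal; an early draft used
$\beta_h = 4$, which drives the oracle above 0.9 and makes every
representation look prognostic.

What the generator does **not** emulate: real radiomic marginals (heavy
tails, boundedness of texture indices), feature-family-specific batch
physics, lesion segmentation error, or inter-patient correlation beyond
center membership. Passing tests therefore demonstrate that the algorithms
behave as designed under the assumed generative structure — not that any
particular clinical dataset will show the same effect sizes.

## Numerical choices

* Zero-variance features: sd floored at 1e-8 with a warning rather than
  rejection, so degenerate configurations still run.
* Distance ties in rankings: lesion-id order (radix, locale-independent).
* Paired t-tests with all-zero differences return p = 1 by convention.
* Cloud descriptors use the population sd (divide by $n$).
* Single-lesion patients: zeros in the four cloud indexes plus a
  degeneracy flag.
* Cox fits: ridge penalty 1e-4 (escalated tenfold up to 3 times on
  failure, then the split is recorded as failed); concordance is
  Harrell's C with ties credited 0.5. Single-column representations are
  fit unpenalized.
* Logistic probes: ridge-penalized (multinomial) regression with fixed
  penalty $\lambda = 1/n_{train}$, bootstrap resampling with out-of-bag
  scoring; a bootstrap draw missing a class is redrawn (max 10 times).
* PCA keeps 16 components for non-embedding modalities, matching the
  embedding width.
* All randomness flows through explicit seeds; `full_run()` derives
  per-stage seeds from one global seed by fixed offsets, and two runs with
  one config are byte-identical.

## Problem sizes used for validation

The test suite and the acceptance script exercise the default cohort
(~206 patients, ~2,100 lesions, 45 features), with autoencoder training
capped at 500 epochs (early stopping engages near 100–200), 100 bootstrap
trials for confounder predictability, 100 null draws for the drift test,
and 20 train/test splits for survival evaluation. Structural unit tests
run on miniature cohorts (20–150 patients).

## Known limitations

* The adversarial game removes *lesion-level* predictability of the batch
  labels. Patient-level cloud properties (dispersion) are only normalized
  indirectly, through the pressure to match embedding distributions across
  batches. Consequently the prognostic advantage of embedding-space cloud
  descriptors over confounded raw ones is regime-dependent: it emerges
  when scale effects are per-feature (anisotropic warps) and can vanish
  when batch corruption of dispersion is mild relative to the
  heterogeneity spread, or when the nonlinear embedding chart itself
  distorts dispersion magnitudes patient-by-patient. The acceptance suite
  asserts the ordering in the default regime; users should treat it as a
  property of the regime, not of the architecture.
* Parametric EB shrinkage trades a small residual batch-mean difference
  (measured up to ~0.08 pooled sd on 45 homogeneous features) for
  estimator stability; exact moment removal holds in `ls-only` mode.
* The order selector is a counting variant of the published optimal-order
  procedure; feature-subset grouping is not implemented.
* Frailty (random-effects) Cox modeling, non-parametric EB, and
  longitudinal extensions are out of scope.
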