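# cloudharmony

Dual-factor harmonization of multi-lesion, multi-center radiomics feature
tables, with a shape-invariance test for patient lesion clouds.

## The problem

Quantitative imaging studies of multi-lesion cancers (e.g. Hodgkin
lymphoma) pool lesions from several hospitals and scanner models. The
radiomic feature vector of every lesion then mixes tumor biology with two
nested batch effects — the *center* and the *scanner* — which must be
removed before any cross-center model can be trusted. For multi-lesion
disease there is a second, subtler requirement: each patient is a **point
cloud** of lesions, and the cloud's dispersion encodes intra-tumor
heterogeneity, a prognostic biomarker. Harmonization must therefore strip
the batch signal *without* reordering or rescaling each patient's lesions
relative to one another.

`cloudharmony` provides:

* **Dual adversarial deconfounding autoencoder (Dual AD-AE)** — an
  autoencoder (45–32–16–32–45) whose 16-dim embedding is trained by
  alternating minimax against two adversarial heads that try to predict
  the center and the scanner. The encoder minimizes
  `‖x − g_ψ(f_φ(x))‖² − λ₁·L(h_ν₁(f_φ(x)), c) − λ₂·L(h_ν₂(f_φ(x)), s)`
  (λ₁ = λ₂ = 1, L = cross-entropy), so the embedding reconstructs the
  features while the batch labels become unpredictable.
* **ComBat-family benchmarks** — location/scale correction
  `Y = a_f + Xβ_f + γ_if + δ_if ε_ijf` with parametric empirical-Bayes
  shrinkage of `γ̂, δ̂`, the ridge-regularized ReComBat variant,
  two-factor cascades in both orders, and a residual-association order
  selector (Kruskal–Wallis counting).
* **Point Cloud Semantic Drift (PCSD)** — a rank statistic for cloud
  shape: per anchor lesion, the change in neighbor rankings weighted by
  the change in max-normalized distances
  (`PSD = Σ |ΔM| · |Δrank|`), averaged over anchors; tested against an
  empirical null of 100 Gaussian-noise perturbations (σ² = 3, random half
  of each cloud) with a left-tail empirical p-value.
* **Evaluation procedures** — bootstrap logistic confounder-predictability
  (Experiment-1 style), patient representations (centroid, four
  cloud-topology indexes, combined) fed to repeated-split ridge Cox models
  scored by Harrell's concordance with paired one-sided t-tests
  (Experiment-3 style).
* **A synthetic cohort generator** — lesions nested in patients nested in
  centers, scanners nested in centers, collinear feature blocks, additive +
  per-feature multiplicative + interaction + nonlinear batch effects, and
  heterogeneity-linked censored survival — so the whole pipeline is
  testable without any private clinical data.

## Worked example

```r
library(cloudharmony)

cohort <- generate_cohort(sim_config(n_patients_per_center = c(40, 25), seed = 42))
cohort$confounded
#> <lesion_table> 676 lesions, 65 patients, 2 centers, 5 scanners, d = 45

std   <- standardize(cohort$confounded)
model <- train_adae(init_adae(adae_spec(), seed = 1), std$table,
                    adae_config(max_epochs = 200, seed = 2))
model
#> <dual_adae> 45-32-16, 11,186 parameters, trained 76 epochs (best 56)

emb <- adae_encode(model, std$table)

confounder_accuracy(feature_matrix(std$table), std$table$center,
                    n_trials = 50, seed = 3, name = "raw/center")
#> <accuracy_distribution> raw/center: 0.9995 +/- 0.0016 (50 trials, prevalence 0.641)
confounder_accuracy(emb, std$table$center, n_trials = 50, seed = 3,
                    name = "dual_adae/center")
#> <accuracy_distribution> dual_adae/center: 0.7814 +/- 0.0181 (50 trials, prevalence 0.641)

drift_test(clouds_from_table(std$table),
           clouds_from_table(emb, patient_ids = std$table$patient_id),
           n_iter = 100, noise_variance = 3, seed = 4)
#> <drift_result> 65 patients (0 excluded), mean PCSD 4.1136, empirical p = 0.00
```

Reading the output: the raw features predict the acquiring center almost
perfectly (0.9995), i.e. the batch signal dominates; after adversarial
embedding the accuracy falls toward the majority-class prevalence (0.641 —
on this deliberately small 65-patient demo some patient-level signal
remains at 0.78; on the full-size default cohort it lands within a few
points of prevalence). The drift test compares the observed mean PCSD of
the raw→embedding transformation against 100 random perturbations of the
clouds: an empirical p of 0 means the embedding drifted every patient's
cloud less than any structure-blind random map — the cloud shapes, and
with them the heterogeneity signal, were preserved.

The same pipeline is scriptable from a shell via the bundled CLI
(`system.file("cli/cloudharmony", package = "cloudharmony")`) with
subcommands `simulate`, `harmonize`, `drift-test`, `evaluate` and
`full-run`; `full-run` executes the whole study (simulate → harmonize with
every configured modality → the three experiment reports) and is
byte-reproducible from a single seed.

## Limitations

The generator reproduces the *structure* of multi-center multi-lesion
radiomics (nesting, collinearity, location/scale + nonlinear batch
effects, heterogeneity-linked survival), not the marginal distributions of
real radiomic features; see the methods vignette
(`vignettes/harmonization-methods.Rmd`) for the model details, parameter
rationale, and an honest account of which conclusions are
regime-dependent.
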