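# circlust

Circular functional clustering of high-resolution thickness profiles.

## The problem

Optical coherence tomography can export the neuroretinal rim (NRR)
thickness of an eye at 180 angular positions spaced 2° apart around the
optic nerve head, in TSNIT order (temporal → superior → nasal → inferior →
temporal). Each eye is then not a handful of sector averages but a
*circular curve* `X_i(t)`, `t ∈ [0, 360)`, and questions about structural
phenotypes — how many distinct rim shapes exist in a healthy population,
which eyes share one, and how those groups differ clinically — become
questions about clustering periodic functional data.

`circlust` implements that workflow for biostatisticians and imaging
researchers:

1. **Functional representation.** Each curve is expanded in an orthonormal
   Fourier basis, `X_i(t) ≈ Σ_j γ_ij ψ_j(t)`, the natural periodic basis
   for circular data. The basis order `p` is chosen as the smallest one
   whose fraction of variation explained,
   `FVE(p) = (TV − (1/(n−1)) Σ_i ∮ (X_i^p − X_i)² dt) / TV`, exceeds 0.99,
   where `TV = (1/(n−1)) Σ_i ∮ (X_i − X̄)² dt` is the total variation of
   the curve set.
2. **Quality control.** A curve is an outlier if any point exceeds
   `X_out = max_l X̄(t_l) + 3.5 · max_l sd(X(t_l))`; surviving curves are
   optionally normalized by their circular integral so they compare by
   shape as unit-area circular densities.
3. **Model-based clustering.** The coefficient vectors `γ_i` follow a
   discriminative functional mixture: a K-component Gaussian mixture whose
   cluster means and covariances live in a low-dimensional discriminative
   subspace `U` (`p × d`, orthonormal), with isotropic residual noise
   outside it — component k has density
   `N(γ; U μ_k, U Σ_k Uᵀ + β_k (I − U Uᵀ))`. Twelve covariance-constraint
   variants (full/diagonal/isotropic latent covariance, cluster-specific
   or common, crossed with cluster-specific or common noise) are fit by
   EM, and the number of clusters is selected from AIC/BIC/ICL traces.
4. **Metaclustering.** Clusters are themselves clustered on their mean
   clinical covariates (IOP, CCT, axial length, rim/disc geometry, CDR,
   cup volume) by sparse complete-linkage hierarchical clustering with an
   L1 bound (`wbound`) on nonnegative feature weights, flat-cut at a
   common rescaled height, and matched across age strata.
5. **Baselines and validation.** k-means, k-medoids and Gaussian-mixture
   clustering of the raw grid points, with average silhouette width (ASW)
   for selecting K and the Dunn index for separation — the comparison that
   shows why the functional route is needed.
6. **Synthetic cohorts.** A generator of band-limited circular profiles
   with planted shape clusters, dominant shared anatomical modes, spike
   outliers and cluster-linked covariates, so the full pipeline is
   testable without patient data.

## Worked example

```r
library(circlust)

spec <- synthetic_spec()                         # 3 clusters x 200 eyes
sim  <- simulate_profiles(spec, seed = 1)
out  <- inject_outliers(sim$profiles, count = 3, magnitude = 6, seed = 2)
covs <- simulate_covariates(sim$labels, seed = 3)

run <- run_pipeline(out$profiles, covs, p = 11, K_range = 2:5, d = 2,
                    baseline_K_range = 2:6, seed = 1, n_restarts = 2)
print(run)
#> pipeline_run over 1 age strata
#>   stratum 1 : n = 597 ( 3 outliers removed ), p = 11 , K = 3
```

The manifest records, per age stratum, the counts at every stage. On this
cohort the three injected spikes are flagged by the outlier rule (3
removed from 600), the FVE scan picks `p = 11` (the generating order), the
BIC elbow lands on `K = 3`, and the recovered partition matches the
planted clusters (adjusted Rand index 1.0). The point-clustering baselines
on the same normalized curves choose `K = 2` by ASW — they split along the
dominant shared tilt mode and miss the shape clusters, which is exactly
the gap the functional mixture closes.

```r
base <- cluster_points(normalize_profiles(out$profiles), "kmeans",
                       K_range = 2:6, seed = 1)
print(base)
#> baseline_run: kmeans chose K = 2 by ASW ( 0.27 ), Dunn 0.028
```

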