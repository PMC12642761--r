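# adbcascade

Patient-specific modelling of the Alzheimer's disease biomarker cascade on
brain functional-connectivity graphs.

## What it does, and for whom

Alzheimer's disease unfolds as an ordered cascade — amyloid-beta (Aβ)
deposition, then tau aggregation, then neurodegeneration (N), then
cognitive decline (C). `adbcascade` is for computational neuroscientists
and biostatisticians who want to fit that cascade *regionally*: the three
imaging biomarkers live on the 68 cortical regions of the
Desikan–Killiany atlas and spread along a weighted functional-connectivity
graph, while cognition is a whole-brain scalar driven by network-averaged
neurodegeneration.

The model couples logistic growth with graph-Laplacian diffusion
(elementwise products over regions; `L = D − A` the graph Laplacian):

    dAβ/dt = −D_Aβ L Aβ + λ_Aβ ∘ Aβ ∘ (K_Aβ − Aβ)
    dτ/dt  = −D_τ  L τ  + λ_τAβ ∘ Aβ + λ_τ ∘ τ ∘ (K_τ − τ)
    dN/dt  = −D_N  L N  + λ_Nτ  ∘ τ  + λ_N ∘ N ∘ (K_N − N)
    dC/dt  = λ_CN ∫_G N dv + λ_C C (K_C − C),   ∫_G N dv = Σ d_v N_v / Σ d_v

with 6 global scalars and 8 region-specific parameter vectors. The package
provides:

* **IO & normalization** — longitudinal biomarker tables and FC matrices;
  severity-oriented normalization (`N = 1 − Nct/ref`, `C = 1 − MMSE/30`).
* **Brain graphs** — statistical truncation of FC matrices (r > 0.75,
  p < 1e−5), population averaging, and patient-specific rank-2
  low-rank perturbations `A = Ap + (uvᵀ + vuᵀ)/2 − diag(u∘v)` with a
  closed-form patient Laplacian.
* **Forward simulation** — compiled adaptive Dormand–Prince 5(4)
  integration.
* **Inference** — `adbc_fit()`: a four-stage hierarchical pipeline
  (homogenized scalars → sparse regional deviations → regional initial
  conditions → connectivity perturbation) with homotopy-regularized
  constrained optimization (weights 1000 → 1, decay 10, warm starts).
* **Sensitivity analysis** — Sobol indices (S1/S2/ST) via a
  Saltelli design on scrambled-Halton samples; two-level workflow
  (14-parameter screening over age; regional/lobe interaction analysis).
* **Synthetic cohorts** — observational-study-like longitudinal data with known ground
  truth for parameter-recovery studies.

## Worked example

Generate one synthetic subject with known ground truth, fit the
nonhomogeneous model (stages 1–3), and inspect it:

```r
library(adbcascade)

spec   <- cohort_spec(n_subjects = 1, n_regions = 8, sigma = 0.02, seed = 42)
cohort <- synth_cohort(spec)
s      <- cohort$subjects[[1]]

fit <- adbc_fit(s$records, cohort$population,
                control = adbc_control(seed = 1), stages = 1:3)
summary(fit)
#> Subject: S001
#>
#> Global parameters:
#>   D_Abeta     D_tau       D_N lambda_CN  lambda_C       K_C
#>  0.000000  0.008359  0.000000  0.000000  0.199000  1.253000
#>
#> Regional parameters (mean/min/max):
#>                    mean     min     max
#> lambda_Abeta    0.22960 0.21200 0.24780
#> lambda_tau      0.16640 0.14440 0.19400
#> ...
#> Training accuracy (%):
#>   Abeta     tau       N       C overall
#>   96.49   95.91   97.58   99.88   97.25
#> Held-out accuracy (%):
#>   Abeta     tau       N       C overall
#>   97.21   97.04   97.24   98.78   97.33
```

The accuracies are `100·(1 − Σ‖y − ỹ‖₂ / Σ‖ỹ‖₂)` over training visits and
over the held-out last visit of each modality: this subject's fitted
trajectories reproduce held-out regional observations to within ~3%
relative error. Comparing the fit against the generator's ground truth:

```r
rs <- recovery_score(fit, s$params)
rs[rs$scope == "global", ]
#>   parameter  scope truth estimate rel_error
#> 1   D_Abeta global 0.049   0.0000     1.000
#> 2     D_tau global 0.053   0.0084     0.842
#> 3       D_N global 0.066   0.0000     1.000
#> 4 lambda_CN global 0.034   0.0000     1.000
#> 5  lambda_C global 0.202   0.1990     0.017
#> 6       K_C global 1.079   1.2532     0.161
```

Cognition-rate and capacity parameters recover well; the diffusivities
illustrate a real identifiability limit — at sparse, noisy visits a model
with slightly shrunken regional heterogeneity and zero diffusion fits the
data as well as the truth (a likelihood ridge), so recovered `D` values are
biased toward zero. The methods vignette
(`vignettes/cascade-modelling.Rmd`) discusses this and every other
modelling choice in detail.

`print`, `coef`, `predict`, `plot`, `residuals` and `simulate` methods are
available on the fitted object. A thin command-line wrapper
(`inst/scripts/adbc`) exposes `synth`, `simulate`, `fit` and `sensitivity`
subcommands with YAML configuration and a reproducibility manifest per
output directory.

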