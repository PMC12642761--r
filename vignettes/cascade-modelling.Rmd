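---
title: "Modelling the Alzheimer's biomarker cascade on brain connectivity graphs"
author: "adbcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Alzheimer's biomarker cascade on brain connectivity graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adbcascade)
```

## The model

Alzheimer's disease progresses as a cascade: amyloid-beta deposition
precedes tau aggregation, which precedes neurodegeneration and finally
cognitive decline. Classic biomarker-cascade models describe each marker by
a logistic ordinary differential equation on a single, whole-brain scale.
This package implements a *spatial* generalization: amyloid ($A\beta$), tau
($\tau$) and neurodegeneration ($N$) live on the 68 cortical regions of the
Desikan--Killiany atlas, connected by a weighted undirected graph
$\mathcal{G}$ derived from resting-state functional connectivity, and
pathology diffuses along graph edges while growing logistically within each
region:

$$
\begin{aligned}
\frac{dA\beta}{dt} &= -D_{A\beta}\, L\, A\beta
  + \lambda_{A\beta} \circ A\beta \circ (K_{A\beta} - A\beta)\\
\frac{d\tau}{dt} &= -D_{\tau}\, L\, \tau
  + \lambda_{\tau A\beta} \circ A\beta
  + \lambda_{\tau} \circ \tau \circ (K_{\tau} - \tau)\\
\frac{dN}{dt} &= -D_{N}\, L\, N
  + \lambda_{N\tau} \circ \tau
  + \lambda_{N} \circ N \circ (K_{N} - N)\\
\frac{dC}{dt} &= \lambda_{CN} \int_{\mathcal{G}} N\, dv
  + \lambda_{C}\, C\, (K_C - C)
\end{aligned}
$$

where $\circ$ is the elementwise product over regions, $L = D - A$ is the
graph Laplacian of the adjacency $A$ (degree matrix $D$), and the graph
integral is the degree-weighted mean
$\int_\mathcal{G} N\,dv = \sum_v d_v N_v / \sum_v d_v$. Cognitive
impairment $C$ is a whole-brain scalar: it senses regional
neurodegeneration only through that weighted mean (a property the test
suite checks by redistributing $N$ at constant integral). The Laplacian is
symmetric positive semi-definite, so $-D\,L\,y$ acts diffusively and the
plain regional sum of a purely diffusing field is conserved exactly
($\mathbf{1}^\top L = 0$).

Each upstream biomarker forces its successor *linearly* (the
$\lambda_{\tau A\beta}, \lambda_{N\tau}, \lambda_{CN}$ terms), while each
marker also grows logistically toward its carrying capacity. The linear
placement of the forcing outside the logistic bracket follows the stated
roles of the parameters: the cross-couplings shift the *time of onset* of
the downstream cascade, while the logistic rates set its speed.

The model has exactly **14 named parameters**: 6 global scalars
($D_{A\beta}, D_\tau, D_N$ in 1/yr per unit Laplacian;
$\lambda_{CN}, \lambda_C$ in 1/yr; $K_C$ dimensionless) and 8
region-specific vectors of length 68
($\lambda_{A\beta}, \lambda_\tau, \lambda_N, \lambda_{\tau A\beta},
\lambda_{N\tau}, K_{A\beta}, K_\tau, K_N$). The model clock $t$ is
chronological age in years, started at $t_0 = 50$; the horizon is
$t_{\mathrm{end}} = 100$.

## Data normalization

Raw inputs are regional PET uptake ratios (amyloid, tau), cortical
thickness, and the MMSE cognitive score. All are normalized and oriented so
that every biomarker *increases* with severity on a roughly $[0, 1]$ scale:

* amyloid and tau: $y \mapsto y / y_{\mathrm{ref}}$ with a per-(biomarker,
  region) reference value;
* cortical thickness $N_{ct}$ *decreases* with disease, so
  $N = 1 - N_{ct}/y_{\mathrm{ref}}$;
* MMSE score $S \in [0, 30]$ (30 = intact): $C = 1 - S/30$.

The reference-value rule is configurable (`cohort_max`, `cohort_quantile`,
`fixed_table`). The default is the per-(biomarker, region) cohort maximum,
chosen so that normalized trajectories approach 1 at end stage — the same
convention the fitting objective's end-stage penalty
$\lVert y(100) - \mathbf{1}\rVert^2$ presumes. Whether thickness should be
normalized before or after the $1 - {}\cdot{}$ inversion is a genuine
convention choice; both orders are implemented (`nct_order`), defaulting
to normalize-then-invert.

## Brain graphs

`threshold_fc()` converts a functional-connectivity matrix (regional
Pearson correlations, optionally with p-values) to a graph by *statistical
truncation*: an edge is kept iff $r > 0.75$ and $p < 10^{-5}$, both strict,
weighted by $r$, self-connections removed. Negative correlations never pass
the default threshold; the implementation is positive-weight-only, keeping
edge weights in $[0, 1]$.

A *population* graph averages per-subject adjacencies (each symmetrized as
$(A + A^\top)/2$ to absorb measurement asymmetry). A *patient-specific*
graph is a rank-2 perturbation of the population adjacency,

$$A = A_p + \tfrac12(u v^\top + v u^\top) - \mathrm{diag}(u \circ v),$$

with $u, v \in \mathbb{R}^{68}$ soft-constrained to unit norm. The diagonal
correction exactly cancels the rank-2 term's diagonal, so self-connections
stay absent; entries of $u, v$ may be negative, letting the perturbation
strengthen, weaken, or light up edges, subject to every perturbed weight
staying in $[0, 1]$ (`check_weight_constraints()` audits this box). The
patient Laplacian has the closed form

$$L = L_p + \tfrac12\,\mathrm{diag}\!\big(u (v^\top \mathbf{1}) +
  v (u^\top \mathbf{1})\big) - \tfrac12 (u v^\top + v u^\top),$$

algebraically identical to rebuilding $D - A$ from the perturbed adjacency;
the test suite verifies the identity to $10^{-12}$ on random instances of
several sizes, which is the primary correctness oracle for this algebra.
The graph is treated as fixed over a subject's lifespan.

## Forward integration

The coupled system (205 states at full atlas size) is integrated by an
adaptive embedded Dormand--Prince 5(4) Runge--Kutta scheme implemented in
compiled code, with mixed error control (defaults `rtol = 1e-6`,
`atol = 1e-8`; both configurable). Steps are clipped to land exactly on the
requested output ages, so no interpolation error enters at observation
times. The compiled stepper is cross-checked in the test suite against an
independent general-purpose solver (deSolve) on random instances, and
against the scalar logistic closed form
$y(t) = K y_0 e^{\lambda K t} / (K + y_0(e^{\lambda K t} - 1))$
on a single-node graph. An edgeless graph makes the degree-weighted mean
undefined; inside the dynamics it falls back to the plain mean so
single-node reductions remain well defined, while the user-facing
`graph_integral()` treats the all-isolated graph as an error.

## Hierarchical inference

`adbc_fit()` estimates, for one subject, the 14 parameters, the initial
state at age 50 (a fitted quantity, not read off the noisy first visit),
and optionally the connectivity perturbation $(u, v)$. The objective is the
sum over visits of the squared relative error
$\lVert y(t_i) - \tilde y(t_i)\rVert_2^2 / \lVert \tilde y(t_i)\rVert_2^2$
plus the end-stage penalty $w\lVert y(100) - \mathbf{1}\rVert^2$ per
equation, plus stage-specific regularizers. Inclusion requires at least
three visits in at least one regional modality. Fitting proceeds equation
by equation in cascade order ($A\beta \to \tau \to N \to C$), each equation
conditioning on the previously fitted upstream trajectory, through four
stages:

1. **Homogenized model.** All regional parameters collapse to scalars
   broadcast across regions, with a scalar initial value, inside the boxes
   $D \in [0,2]$, $\lambda \in [0,2]$, $K \in [1,2]$, $y_0 \in [0,1]$
   (cross-couplings reuse the rate box). The scalar diffusivity is pinned
   to 0 here: the homogenized model has a constant regional field, which
   the Laplacian annihilates, so the data contain *no information* about
   $D$ at this stage and any fitted value would be an artifact of the
   starting point.
2. **Regional parameters.** Sparse deviations
   $\epsilon = \theta^{68D} - \theta^s$ from the homogenized solution,
   penalized by $w_{\mathrm{reg}}\lVert\epsilon\rVert_1$, bounded so
   $\theta^s + \epsilon$ stays in its box. The scalar diffusivity is
   re-optimized here — once regions differ, spatial gradients exist and $D$
   becomes identifiable — including a coarse one-dimensional profile over
   $D$ before the final joint polish, because $D$'s basin is shallow.
3. **Regional initial conditions.** Sparse deviations $\epsilon_{y_0}$
   with an $L_1$ penalty $w_0\lVert\epsilon_{y_0}\rVert_1$, model
   parameters frozen; initial values clipped to $[0, \min(1, K_r)]$ per
   region.
4. **Patient-specific connectivity.** $(u, v)$ under the $[0,1]$
   edge-weight box (enforced by a quadratic exterior penalty, weight
   `1e5`, audited at the solution to tolerance $10^{-6}$), with unit-norm
   penalties $w_u(\lVert u\rVert - 1)^2 + w_v(\lVert v\rVert - 1)^2$ and
   sparsity penalties on $\lVert u\rVert_1, \lVert v\rVert_1$. The data
   term pools every biomarker, since the graph affects all of them.

### Homotopy regularization

Each regularization coefficient ($w_{\mathrm{reg}}$, $w_0$, $w_{su}$,
$w_{sv}$) follows a geometric *homotopy schedule* — by default
$1000, 100, 10, 1$ (`homotopy_schedule(1000, 10, 4)`) — and every solve is
warm-started from the previous one. Early, heavily regularized problems
are nearly convex (the penalty dominates and pins the deviations at zero);
the path then deforms continuously toward the weakly regularized target,
avoiding poor local minima. The configured coefficients act as scale
multipliers on this schedule; their defaults
($w_{\mathrm{reg}} = w_0 = w_{su} = w_{sv} = 0.01$) put the *terminal*
penalties about an order of magnitude below a typical data term, which is
of order $M \sigma^2 n / \lVert\tilde y\rVert^2 \approx 10^{-2}$ for
relative-error losses at realistic noise — regularization weights only make
sense relative to the loss scale they compete with.

The end-stage penalty weight $w$ is deliberately *not* scheduled. Holding
it large distorts which basin the optimizer selects — it rewards parameter
sets whose trajectories saturate at exactly 1 regardless of fit — and a
continuation path started in such a basin stays in it. Instead $w$ is held
fixed at a weak default ($0.005$) that shapes extrapolation beyond the last
visit without competing with the data term. This is a deliberate design
departure from scheduling every coefficient uniformly, adopted after the
scheduled variant demonstrably selected saturation-compliant rather than
data-compliant modes.

### Optimizer

Stages use box-constrained quasi-Newton iterations (`optim` L-BFGS-B) with
finite-difference gradients; $L_1$ terms are smoothed as
$\sqrt{x^2 + \varepsilon^2}$ with $\varepsilon = 10^{-4}$ so they remain
differentiable. The homogenized stage is low-dimensional (3--5 scalars per
equation) but multimodal: degenerate fast-saturation modes fit sparse
visits deceptively well. It is therefore started from a coarse factorial
grid — logistic rates sampled *log-uniformly* (they are scale parameters;
physiologic transitions span 2--80 years) crossed with a few capacities and
initial values — plus the configured random multistarts (`multistart`,
default 10). Candidates are ranked by a single evaluation of the *data
term alone* (the shape penalty should not drive basin selection), the top
8 refined briefly, and 3 finalists polished deeply before committing;
ranking basins by early, partially converged iterates is unreliable, which
is why several candidates are carried through.

### Train/test protocol and accuracy

By default the last visit of every modality is held out
(`holdout = "last_visit"`). Accuracy per biomarker is
$100\,(1 - \sum_i\lVert y(t_i)-\tilde y(t_i)\rVert_2 /
\sum_i\lVert\tilde y(t_i)\rVert_2)$, clipped below at 0 — a declared
convention, since accuracy-percentage definitions vary; an alternative can
be computed from `residuals()`. Setting `stages = 1` reproduces the
homogeneous (H) model and `stages = 1:3` the nonhomogeneous (NH) model for
H-vs-NH comparisons; a full fit also records the held-out accuracy of its
stage-1–3 model (`nh_test_accuracy`) so the comparison does not require a
second fit.

### Missing modalities

Subjects may lack modalities. Equations without data are skipped with an
explicit status; if a *downstream* equation has data, the missing upstream
trajectory is substituted by a population-typical one (bounds-midpoint
parameters by default, any `adbc_params` via `upstream_fallback`), and the
substitution is flagged.

## Synthetic cohorts

`synth_cohort()` generates virtual subjects with known ground truth so the
whole pipeline is testable without any clinical download: a connected
population graph with Bernoulli edges weighted $\mathrm{U}(0.75, 1)$
(mimicking correlation-thresholded connectivity), per-subject parameters,
sparse rank-2 connectivity perturbations rescaled until the weight box
holds, noiseless trajectories, irregular visit ages (uniform in
$[55, 95]$, sorted; at least 3 per retained modality), additive Gaussian
observation noise on the normalized scale ($\sigma = 0.02$ by default,
clipped at 0), and optional per-modality missingness (default: complete
multimodal data; dedicated tests exercise nonzero missingness).

True parameters are drawn uniformly from *sub-boxes* of the optimization
bounds: rates $\lambda \in [0.08, 0.25]$/yr, capacities $K \in [1, 1.2]$,
cross-couplings $[0.01, 0.05]$/yr, diffusivities $[0.02, 0.1]$/yr, initial
values $[0.03, 0.12]$. The full boxes are *inference* bounds, not a
generative model: sampling them uniformly yields mostly degenerate subjects
(saturated by age 52, or flat), whereas these sub-boxes produce
sigmoid-like transitions inside the observation window with capacities
near 1, consistent with cohort-max normalization. Regional vectors are
`scalar * (1 + h * U(-1, 1))` with heterogeneity `h = 0.2`, clipped to the
boxes.

What the generator does *not* emulate: real measurement error structure
(spatially correlated, heteroscedastic), diagnosis-dependent visit
schedules, scanner/site effects, longitudinal connectivity change, and
subcortical involvement. Passing recovery tests therefore demonstrate the
*machinery* — not that clinical parameters of real cohorts are identifiable.

## Sensitivity analysis

`sobol_indices()` implements variance-based global sensitivity analysis
with the Saltelli radial design: first-order $S_1$ via the centered
covariance form $\mathrm{cov}(f_B, f_{AB}^{(i)})/V$, total $S_T$ by the
Jansen estimator, and optionally second-order $S_2$ via
$\mathrm{cov}(f(B_A^{(i)}), f(A_B^{(j)}))/V - S_1^{(i)} - S_1^{(j)}$ —
centering cancels mean-level sampling error that the textbook
mean-of-products forms are sensitive to (verified to reduce index error
two- to three-fold across seeds on analytic test functions). Sampling uses a digit-scrambled
Halton sequence (one random digit permutation per prime base, seeded), a
low-discrepancy design that reaches ~0.02 absolute index error at
$N = 2^{10}$ base samples on analytic test functions where plain Monte
Carlo needs far more; no installed package provides a quasi-random
generator, so this one is implemented here and validated against
brute-force conditional-variance quadrature in the tests. Cost is
$N(k+2)$ model evaluations, or $N(2k+2)$ with second-order blocks.
Second-order indices are intrinsically noisy (small differences of large
quantities); interpret individual $S_2$ entries with their ~0.05--0.1
sampling error in mind.

Two analysis levels are provided:

* **Level 1** (`sobol_level1()`): all 14 parameters homogenized and varied
  in boxes, output $C(t)$ on an age grid — the stated quantity of interest
  is late-stage cognition, and evaluating it over age shows *when* each
  parameter matters. The age-aggregated $S_T$ ranking is the screening
  device for influential parameters. Outputs at ages where the trajectory
  is still essentially deterministic (e.g. the initial age) are flagged
  `zero_variance` rather than divided by a near-zero variance.
* **Level 2** (`sobol_level2()`): one region-specific parameter varied
  across its 68 regional ranges (one factor per region), everything else
  fixed (typically at cohort means), output the degree-weighted brain
  total of the parameter's own biomarker at stage ages 60/80/100. Regional
  $S_1$/$S_2$ are aggregated to six anatomical lobes by summation
  (`dk68_lobe_map()` ships a standard Desikan--Killiany assignment,
  user-overridable). `rank_regions()` orders regions by $S_1$ with ties
  broken by $S_T$ then region index, and reports per-lobe counts.

## Numerical choices and degenerate inputs

* Integration failures during fitting (step underflow under pathological
  parameters) are treated as infinite loss rather than errors, so the
  optimizer simply avoids those regions; `adbc_simulate()` itself reports
  such failures as errors carrying the problem context.
* A zero observation norm in a relative-error term floors the denominator
  at $10^{-12}$ with a warning.
* Degenerate (zero-width) sensitivity ranges produce exactly zero indices;
  zero output variance produces all-zero indices with a warning.
* Ties in region ranking resolve by total index, then region index.
* The feasibility audit tolerance for perturbed edge weights is $10^{-6}$;
  `patient_graph()` absorbs only float-level overshoot after a passing
  audit.

## Known limitations

* **Diffusivity--heterogeneity ridge.** With sparse visits and modest
  noise, a model with slightly shrunken regional heterogeneity and zero
  diffusion can fit longitudinal data essentially as well as the true
  combination of larger heterogeneity plus diffusion: the likelihood has a
  ridge, and the $L_1$ regularizer selects its low-heterogeneity end.
  Recovered diffusivities are therefore biased toward zero at realistic
  noise unless visits are dense or heterogeneity is strong. This is a
  property of the inverse problem, not of the optimizer; the package's
  recovery studies make it visible.
* **Cognition-equation identifiability.** $C$ contributes one scalar per
  visit; with ~4-6 visits its four parameters
  ($\lambda_{CN}, \lambda_C, K_C, C_0$) are only weakly separated, and the
  fitted optimum can beat the truth on training loss. $K_C$ recovers well;
  $\lambda_{CN}$ and $\lambda_C$ should be interpreted cautiously at the
  single-subject level.
* The connectome is static; dynamics are deterministic; parameters carry
  no uncertainty quantification.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at sizes a laptop handles
comfortably: graph-algebra identities at $n \in \{4, 10, 68\}$; dynamics
oracles at 1--8 regions; Sobol oracles at $2^9$--$2^{11}$ base samples; and
the cohort-scale recovery study at 10 subjects on 8-region graphs with
$\sigma = 0.02$ — small graphs make the four-stage fit fast while
preserving every structural feature (diffusion, cascade coupling, regional
heterogeneity, connectivity perturbation). The same study, rerun from
scratch, underlies `scripts/acceptance.R`.
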