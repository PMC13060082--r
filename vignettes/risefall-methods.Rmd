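---
title: "Modeling rise-and-fall pathology spread on the connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling rise-and-fall pathology spread on the connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(risefall)
```

# The scientific problem

Misfolded protein pathology (for example alpha-synuclein after focal
preformed-fibril injection) spreads through the brain along axonal
connections, rises locally by templated aggregation, and in many regions
subsequently *falls* — the measured burden declines after a peak, consistent
with degeneration and clearance of the vulnerable tissue. `risefall`
implements a family of nested network dynamical models for this process, a
Bayesian inference layer that estimates regional rise and fall parameters
from longitudinal regional pathology measurements, model-comparison
machinery, and the downstream molecular analyses that relate the inferred
parameters to regional gene expression and cell-type composition.

# Models

Let $W$ be the directed connectivity matrix, with $W_{ij}$ the projection
strength from region $j$ to region $i$, and let the out-degree graph
Laplacian be

$$L_{ij} = -W_{ij} + \delta_{ij} \sum_k W_{ki}.$$

Column sums of $L$ are zero, so pure transport conserves total pathology.
The three nested models for the regional burden $u_i(t)$ are:

* **DIFF** (spreading only): $\dot u_i = -\rho \sum_j L_{ij} u_j$.
* **DIFF-R** (spreading + rise): adds Fisher–KPP logistic growth
  $\alpha u_i(\beta_i - u_i)$ with a region-specific carrying capacity
  $\beta_i$.
* **DIFF-RF** (spreading + rise + fall): makes the carrying capacity a
  state, $\dot\beta_i = -\gamma_i u_i$, so local burden erodes the
  capacity and trajectories rise and then fall. Inference targets the
  initial value $\beta_i(0)$.

Transport direction is a hypothesis: retrograde (transpose of $W$; the
default, and the direction the biology favors), anterograde,
bidirectional (two Laplacians, each with its own rate), or a purely
spatial Euclidean control in which connectivity is replaced by a
symmetric distance kernel. The distance kernel is $1/d_{ij}$ by default;
an exponential kernel $\exp(-d_{ij}/\lambda)$ is available through the
`length_scale` argument, since the exact functional form used by prior
work is not fixed by the model.

The rise term is the standard reduction of heterodimer kinetics
(production, clearance, and templated conversion of healthy protein) in
the regime where healthy protein is abundant and fast-equilibrating;
`simulate_heterodimer()` and `heterodimer_fkpp_params()` document this
reduction, and a test verifies that the two-species system tracks the
logistic trajectory through the rise phase in that regime.

Initial conditions are zero everywhere except a shared inferred value
`u0` at the seed region(s) — one ipsilateral seed region in the default
(striatal-like) design, with a three-seed variant mimicking hippocampal
seeding available by passing several seed labels. Time is measured in
months throughout, matching the sampling grid
`r paste(STUDY_TIMEPOINTS, collapse = ", ")` months.

`beta_i(t)` is allowed to become negative during DIFF-RF integration: the
fall equation imposes no floor, and a negative capacity is exactly what
drives the burden back toward zero. Simulated burden itself is never
clipped; the likelihood is evaluated on the raw ODE solution, matching
the Gaussian observation model.

# Observation model and priors

Replicate-level observations follow
$y_{ijt} \sim \mathcal N(u_i(t;\theta), \sigma^2)$ with one shared noise
scale; missing values are skipped. `default_priors()` encodes the
reference priors of the experimental analysis: $\mathcal N_+(50, 10)$ for
the DIFF transport rate (pure diffusion must carry enough seed mass to
supply the whole network, hence also a wide seed prior), and
half-scale truncated normals ($\mathcal N_+(0, 0.1)$, with
$\mathcal N(0,1)$ for DIFF-R capacities) for the rise-model parameters.
The priors for `u0` and `sigma` are package choices (the reference
analysis does not print them): $\sigma \sim \mathcal N_+(0, 0.1)$,
$u_0 \sim \mathcal N_+(0, 1)$ for the rise models and
$\mathcal N_+(0, 50)$ for DIFF.

`synthetic_priors()` provides unit-scale weakly-informative variants
matched to the synthetic-study generator's parameter scale, and
`empirical_priors()` implements the transfer used when refitting a second
dataset: global priors are moment-matched truncated normals built from a
previous posterior, while regional priors stay at their defaults. Fits of
the synthetic study use the unit-scale priors: the reference priors
concentrate on dynamics far slower than the 9-month design window
(the scale-invariant growth rate $\alpha\beta$ they support is an order
of magnitude below what visible rise-and-fall on this grid requires), so
they would act as a strongly informative mismatch on synthetic data
rather than the weakly-informative role they play on the original scale.

# Posterior sampling

The posterior is explored with an adaptive Metropolis-within-Gibbs
sampler implemented in compiled code alongside the ODE solver.
Positive-support parameters are updated on the log scale (with the
Jacobian included), which both enforces the truncated support exactly and
linearises the strong multiplicative couplings. Per-coordinate proposal
scales adapt in batches of 50 sweeps toward a 0.44 acceptance rate during
warmup only, and are frozen afterwards, so the retained chain is a valid
Markov chain. Gradient-based samplers for this model family are typically
tuned to a 0.65 acceptance target; 0.44 is the standard optimum for
coordinate-wise random-walk updates and is the package default.

Before trajectories saturate, only the product $\alpha\beta_i$ is well
constrained, leaving a long diagonal ridge in
$(\log\alpha, \log\beta_1, \ldots)$. A dedicated *ridge move* — a
correlated proposal that shifts $\log\alpha$ up while shifting every
$\log\beta_i$ down by the same amount (volume-preserving in the sampled
space, hence a plain symmetric proposal) — lets the chain traverse this
ridge in one step; its scale adapts like the coordinate scales. A
sigma-only update reuses the cached trajectory, and integration failures
(blow-ups, step-size collapse) are treated as zero-likelihood proposals
and rejected.

Chains start from a posterior-mode search (`optim` on the transformed
space) with overdispersed jitter, or from prior draws (`init = "prior"`).
One master seed drives everything: chains are run sequentially from a
single seeded RNG stream, so a fit is bit-reproducible. Convergence is
summarised by the classic split Gelman–Rubin statistic per parameter,
with a warning listing parameters above 1.05. Pointwise log-likelihoods
are stored per retained draw for WAIC.

The `posterior_updated()` filter compares pooled posterior draws of each
regional parameter against its analytic prior CDF with a one-sample
Kolmogorov–Smirnov test; parameters with $p \ge 0.001$ are considered not
updated by the data and are excluded from the biological analyses, which
are further restricted to regions with positive posterior-mean rise
parameter (`select_regions()`).

# Model comparison

`waic()` computes $\mathrm{lppd}$ with a log-sum-exp over samples and the
effective parameter count as the sum of per-observation sample variances
of the log-likelihood (ddof = 1, the standard estimator — stated
explicitly because reference descriptions usually leave it implicit);
pointwise contributions feed the paired standard error of WAIC
differences in `delta_table()`, which flags models whose WAIC
distribution overlaps the best model's ($|\Delta| \le 2$ paired SE).
AIC, BIC and MSE are evaluated at the MAP draw — the retained draw with
the highest log-posterior — with free-parameter counts of 3 (DIFF),
$4 + N$ (DIFF-R) and $4 + 2N$ (DIFF-RF) plus one per extra transport
rate. Predictive agreement uses $R^2$ from regression constrained
through the origin on the uncentered total sum of squares; this reduces to the
squared uncentered correlation, so the statistic is scale-invariant and
symmetric, while the fitted slope depends on which series is the
regressor (always the predictions here). Per-timepoint agreement optionally works in
log10 space, dropping (and counting) pairs with a non-positive member,
since zeros are unloggable. Out-of-sample behaviour is probed by
refitting with the final timepoint held out and scoring the held-out
records (`leave_one_timepoint_out()`); null models rewire the connectome
(weight-multiset shuffle by default, degree-preserving swaps behind a
flag, since the reference procedure is described only as random
rewiring) or re-draw the seed location uniformly among non-seed regions.

# The vulnerability axis and enrichment

For every gene, expression across the selected hemisphere-resolved
regions is regressed on standardized $z(\beta)$ and $z(\gamma)$ with an
intercept (expression is not centered, so the intercept is required for
the error term to be mean zero); one QR factorisation solves all genes at
once. PCA on the mean-centered — but *not* variance-scaled — coefficient
cloud $(a_g, b_g)$ gives the first principal component $(c_1, c_2)$,
sign-normalised so the fall loading $c_2 \ge 0$; both coordinates live in
the same regression-coefficient units, and scaling them would distort the
loading ratio. The regional scalar axis is
$\eta = c_1 z(\beta) + c_2 z(\gamma)$, and genes are ranked by the
Pearson correlation of their expression with $\eta$. Expression from a
single-hemisphere atlas is duplicated across hemispheres
(`duplicate_hemispheres()`) so it can meet hemisphere-specific parameter
estimates.

Pre-ranked GSEA follows the weighted Kolmogorov–Smirnov running sum: hits
increment by $|r|^p / N_R$ (default $p = 1$), misses decrement by
$1/(N - N_h)$, the enrichment score is the extremum of larger magnitude
(ties resolved toward the positive extremum), and significance comes from
gene-label permutations — the natural scheme in the pre-ranked setting,
where no phenotype labels exist. NES divides the ES by the mean
$|\mathrm{ES}|$ of matching-sign permutations; p-values use the add-one
estimator over matching-sign permutations and are never exactly zero;
Benjamini–Hochberg FDR is applied across sets. Sets are filtered to
10–500 members after intersection with the ranked list. Permutation
scores are shared across sets of equal size, which keeps 1000
permutations over hundreds of sets cheap. Category over-representation
uses a two-sided Fisher exact test per functional category with BH
correction and a Haldane-corrected log2 odds ratio; the keyword map
binning pathway names into metabolism, protein homeostasis, synaptic
function, neurodegenerative disease and other is shipped as an editable
default (`default_category_keywords()`) because the reference keyword
list is not public.

`compare_axes()` quantifies replication across seeding designs: cosine
and angle between PC1 loading vectors, and gene-level concordance
(Pearson r, with-intercept OLS slope of axis B's gene correlations on
axis A's, sign-agreement fraction over shared genes).

# Cell-type composition

Regional class counts are estimated by distributing each transcriptomic
cluster's cells over structures according to its spatial frequencies,
walking contributions at off-target structures up the ontology's
child-to-parent map until a target region is hit (cells that reach the
root are dropped with a warning), then aggregating by neurotransmitter
class. Fractions are mapped off the simplex with the centered log-ratio
transform; zeros are replaced by half the smallest nonzero fraction
before renormalisation (standard multiplicative replacement — the
reference analysis does not state its rule, so both the pseudocount and
the inclusion of non-neuronal classes in the closure are configurable).
Associations between CLR components (and the monoaminergic score: the
mean CLR fraction of the dopaminergic, noradrenergic, serotonergic and
histaminergic classes) and $\eta$ use Spearman correlation with a
hemisphere-paired permutation test: region identities are shuffled at
the region level so both hemispheres always carry the same predictor
value, with 10,000 permutations, add-one two-sided p-values on $|\rho|$,
and BH correction across cell types.

# The synthetic-study generator

Because the original pathology, transcriptomic and cell-type datasets are
not redistributable, every analysis stage is exercised on synthetic
studies with the same statistical structure (`synth_study()`): a mirrored
two-hemisphere directed connectome with log-normal weights and sparse
commissural links; replicate-level observations at
0.1–9 months generated exactly by the forward model plus i.i.d. Gaussian
noise; regional expression built as
$\mathrm{intercept} + a_g z(\beta) + b_g z(\gamma) + \varepsilon$ with
coefficient pairs drawn along a planted axis direction; Dirichlet
cell-type compositions whose monoaminergic concentrations scale with
$\exp(c \cdot z(\eta))$; and gene-set collections with planted
axis-aligned sets. All couplings are recorded as ground truth and the
whole study is bit-reproducible from one master seed.

Generator defaults are the package's definition of the study conditions
and were fixed once, with this reasoning:

* 20 regions per hemisphere, 3 replicates, 8 timepoints, 2,000 genes,
  100 gene sets: large enough for every statistical structure to be
  expressed, small enough that the full pipeline runs in minutes on one
  CPU (the real design's 412 regions are out of desk scale by intent).
* Edge weights are scaled to unit mean out-strength so transport and
  growth operate on comparable timescales at order-one rates.
* $\rho = 1.2$, $\alpha = 3$, $u_0 = 0.1$, $\beta \sim |N(0.7, 0.25)|$
  and $\gamma \sim |N(0.5, 0.25)|$ in growing regions (75% of regions,
  seed always included; the rest are silent with $\beta = \gamma = 0$):
  these rates place most growing regions' full rise-and-fall arc inside
  the 9-month window, the regime in which rise and fall parameters are
  identifiable at all — mirroring the high-burden regions that drive the
  real analysis.
* $\sigma = 0.02$ (a few percent of peak burden), the precision of a
  regional average over many sampled sections; recovery of the fall
  rates degrades gracefully as this noise grows.
* The default monoaminergic coupling of 3 plants a strong, unambiguous
  composition association for end-to-end recovery; the power analyses of
  the association test instead use coupling 0.4, which realises Spearman
  effects around $\rho \approx 0.6$ at 30 regions — the moderate
  effect-size regime the test is meant to detect.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: spatially correlated or heteroscedastic
measurement noise, registration and segmentation artifacts, region-size
effects, hemispheric asymmetries in expression (expression is duplicated
across hemispheres exactly as the analysis assumes), non-Gaussian burden
distributions, and connectome measurement error.

# Numerical choices

* Integration uses an adaptive embedded Dormand–Prince 4(5) pair written
  alongside the sampler (rtol $10^{-6}$, atol $10^{-9}$ by default:
  below observation noise, above float dust), with `deSolve::lsoda` —
  stiff-capable — available as `method = "lsoda"` and used as the
  cross-check route in tests. The drift operator is applied through the
  sparse pattern of the Laplacian(s) inside inference, where the solver
  dominates runtime.
* Negative burden excursions are not clipped; a warning fires if they
  exceed $-10\,\mathrm{atol}$.
* Degenerate inputs fail loudly: constant vectors cannot be
  standardized, all-zero compositions cannot be CLR-transformed,
  all-zero predictions have no origin slope, gene sets spanning the whole
  ranked list have no enrichment score.
* Proposal adaptation uses the $\min(0.05, b^{-1/2})$ diminishing
  schedule; MAP estimates are taken over retained draws rather than from
  a separate optimiser, trading a little sharpness for exact
  reproducibility of the reported estimate.
* Test and acceptance problem sizes (16–40 regions, hundreds to a few
  thousand retained draws, reduced permutation counts in unit tests) are
  the package's chosen desk-scale operating points; the defaults exposed
  to users remain the full reference settings (4 chains of 1000/1000,
  10,000 composition permutations, 1000 GSEA permutations).

# Known limitations

* $\gamma_i$ is weakly identified in regions that are reached late or
  never accumulate appreciable burden; the KS update filter removes only
  parameters whose posteriors stay at the prior, not parameters whose
  posteriors move for compensatory reasons, so rank-recovery of fall
  rates is intrinsically noisier than for rise parameters.
* Positive-truncated priors on silent regions' $\beta$ leave a small
  positive floor on their estimated growth, which can translate into a
  slight downward pull on the transport rate's marginal posterior; with
  the tight posteriors that low-noise synthetic data produce, nominal
  95% intervals for single global parameters are approximately, not
  exactly, calibrated per dataset.
* The coordinate-wise sampler needs thousands of sweeps where a
  gradient-based sampler would need hundreds; fits beyond ~60 regions
  per model are outside the intended desk scale.
* The models are deterministic ODEs with shared Gaussian noise; no
  stochastic dynamics, no replicate-level random effects, and no
  modelling of the growing between-animal variance at late timepoints.
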