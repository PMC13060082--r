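# risefall

Connectome-based modeling of prion-like protein pathology that *rises and
falls*. After a focal injection of misfolded protein seeds (for example
alpha-synuclein preformed fibrils), pathology spreads along axonal
projections, grows locally, and — in many regions — subsequently declines.
`risefall` is for researchers who want to fit, compare and biologically
interpret network dynamical models of this process on longitudinal
region-by-timepoint-by-animal pathology data.

## The models

With $W_{ij}$ the projection strength from region $j$ to region $i$ and the
out-degree graph Laplacian $L = -W + \mathrm{diag}(\text{out-strengths})$
(zero column sums, so transport conserves mass), the package implements
three nested models of the regional burden $u_i(t)$:

| Model | Dynamics |
|---|---|
| `DIFF` | $\dot u_i = -\rho \sum_j L_{ij} u_j$ |
| `DIFF_R` | adds Fisher–KPP rise $\alpha u_i (\beta_i - u_i)$ |
| `DIFF_RF` | additionally $\dot \beta_i = -\gamma_i u_i$: the carrying capacity falls with accumulated burden |

Transport can be retrograde (transpose of $W$; the default), anterograde,
bidirectional, or a Euclidean distance-kernel control. Parameters —
global transport rate $\rho$, aggregation rate $\alpha$, seed value $u_0$,
noise scale $\sigma$, and regional rise/fall parameters $\beta_i, \gamma_i$
— are estimated by adaptive MCMC under truncated-normal priors from the
replicate-level Gaussian likelihood
$y_{ijt} \sim \mathcal N(u_i(t;\theta), \sigma^2)$. Models are compared by
WAIC (with paired standard errors of differences), AIC/BIC/MSE at the MAP,
origin-constrained $R^2$, leave-one-timepoint-out prediction, and
rewired-connectome / random-seed null models.

Downstream, regional gene expression is regressed per gene on the
standardized rise and fall parameters; PCA of the coefficient pairs yields
a one-dimensional *vulnerability axis* $\eta = c_1 z(\beta) + c_2 z(\gamma)$;
genes ranked by correlation with $\eta$ feed pre-ranked GSEA
(weighted Kolmogorov–Smirnov running sum, gene-label permutation NES) and
Fisher-exact category over-representation; and cell-type composition
(centered log-ratio transformed, including a monoaminergic score) is tested
against $\eta$ with hemisphere-paired permutation tests.

Because the original datasets are not redistributable, the package ships a
first-class synthetic-study generator (`synth_study()`) that reproduces the
statistical structure of the design — mirrored two-hemisphere connectome,
eight timepoints at 0.1–9 months with three replicates, expression and
cell-type data coupled to planted ground truth — so the entire pipeline is
testable end to end.

## Worked example

```r
library(risefall)

study <- synth_study(n_per_hemi = 8, n_genes = 500, n_sets = 40,
                     rng_seed = 42)

post <- fit_model("DIFF_RF", study$transport, study$obs,
                  seeds = study$true_params$seeds,
                  priors = synthetic_priors("DIFF_RF", 16),
                  chains = 2, warmup = 1500, samples = 500, rng_seed = 1)
print(post)
#> DIFF_RF posterior: 36 params, 2 chains x 500 draws, max R-hat 1.150
# (at these scaled-down sampler settings the fit warns that a few
#  parameters sit above the R-hat 1.05 threshold; the package defaults
#  of 4 x 1000/1000 are meant for final fits)

met <- fit_metrics(post, study$transport, study$obs)
print(met$waic)
#> WAIC = -1871.27 (lppd = 962.49, p_waic = 26.85, n = 384)

fb <- regional_update_filter(post, "beta")
fg <- regional_update_filter(post, "gamma")
sel <- select_regions(setNames(fb$posterior_mean, fb$region),
                      setNames(fg$posterior_mean, fg$region),
                      fb$updated, fg$updated)
length(sel)
#> [1] 16

expr <- duplicate_hemispheres(study$expression)[sel, ]
axis <- extract_axis(gene_regressions(
  expr,
  standardize(fb$posterior_mean[match(sel, fb$region)]),
  standardize(fg$posterior_mean[match(sel, fg$region)])))
print(axis)
#> vulnerability axis: eta = -0.413 z(beta) + 0.911 z(gamma); PC1 98.3% of variance

abs(compare_axes(axis$loadings, study$ground_truth$axis_direction)$cosine)
#> [1] 0.999

assoc <- paired_hemisphere_permutation(
  axis$eta, monoaminergic_score(clr_transform(study$celltypes)),
  n_perm = 1000, rng_seed = 2, allow_unpaired = TRUE)
print(assoc)
#>   predictor       rho        pval        qval
#> 1 predictor 0.7810788 0.007992008 0.007992008
```

Reading the output: the fitted rise/fall parameter map recovers the planted
transcriptional axis (cosine 0.999 against the generating direction; PC1
carries most of the coefficient variance), and regions high on the axis
have significantly higher monoaminergic composition (Spearman rho 0.78,
permutation p = 0.008) — the planted coupling.

The user-facing defaults follow the reference experimental analysis
(4 chains of 1000 warmup + 1000 retained draws, KS update filter at
alpha = 0.001, GSEA with 1000 permutations and set sizes 10–500, 10,000
hemisphere-paired permutations); the example above scales the sampler down
to run in seconds. `run_pipeline(run_config(...))` chains every stage and
writes CSV/JSON outputs plus a seed-and-configuration manifest.

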