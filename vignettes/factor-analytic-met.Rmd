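---
title: "Factor analytic mixed models for variety-trial MET data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor analytic mixed models for variety-trial MET data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metfa)
```

## The problem

A national crop variety testing program produces, every season, a set of
designed yield trials at locations spread over the growing regions. Data
accumulate over years; an *environment* is a location–year combination,
and the joint dataset is a multi-environment trial (MET). The purpose of
the analysis is grower-facing: predict how each variety performs in each
environment, with honest uncertainty, and summarise how performance
responds to environmental variation. The obstacle is variety-by-
environment (V×E) interaction. Variance component analyses that report
long-term regional means assume a common genetic variance everywhere and
a very coarse block structure for genetic correlations; most of the
interaction in this kind of data is seasonal rather than regional, so
regional means mask exactly the information growers need.

## Two-stage analysis

`metfa` follows the two-stage tradition of variety testing analysis.

**Stage 1** (`analyze_trial()`) fits, per trial, the additive fixed-effects
model `yield ~ replicate + variety` by least squares and extracts adjusted
variety means, the residual mean square, the variety F ratio, and a weight
per mean equal to the reciprocal of its squared standard error. This is a
deliberately non-spatial first stage: the second stage consumes only means
and diagonal weights, and for a balanced complete block trial the weight
reduces to `r / error_ms`. Spatial field-trend modelling, autoregressive
residuals and design generation are out of scope. The off-diagonal
precision between means within a trial is discarded — consistent with the
diagonal `Σ` of the second-stage model; this is the standard diagonal
approximation and the price of the two-stage shortcut.

**Stage 2** (`met_reml()`) fits, to the stacked means `y` with weights
carried through as supplied (never re-normalised — `Σ` is treated as known
from stage 1),

`y = Xτ + Zu + η`, with `var(u) = G_e ⊗ I_m` and `var(η) = Σ = ⊕ diag(1/w)`.

`τ` is the vector of trial means. Optional iid non-genetic ("peripheral")
random terms for environment attributes (e.g. year) are supported but
default to absent.

### Dataset formation

Environments are keyed by `location_year`; regions and mega-regions are
attributes, never keys. The inclusion rules (`filter_met()`) remove trials
with no genetic variance (variety F ratio below 1 in stage 1, or a
diagonal-model genetic variance estimated at the zero boundary in stage
2), then remove filler varieties and varieties grown in fewer than 4
remaining trials. The variety rule runs once, after trial removal: a
fixed-point iteration could cascade removals unboundedly and the single
pass matches how such datasets are curated in practice. "Filler" has no
operational definition in the data themselves, so an explicit flag column
is required. Connectivity diagnostics (`met_connectivity()`,
`connectivity_components()`) check that the trial graph — an edge when two
trials share at least `min_common` varieties — has a single component;
factor analytic models cannot be fitted across completely disconnected
subsets, while a *moving window* of overlapping variety cohorts keeps
chains of trials estimable. Mega-region assignments are user input, not
discovered automatically: in real programs they are formed with agronomic
advice, which no algorithm here should pretend to replace.

## Variance structures

`G_e` may be diagonal (`vm_diag()`), compound symmetric (`vm_cs()`,
`G_e = σ²_g J + σ²_ge I`), a partitioned variance component model
(`vm_vc()`: main effects plus region / year / region:year interaction
components plus a residual), factor analytic of order k (`vm_fa(k)`,
`G_e = ΛΛ' + Ψ`), or unstructured (`vm_us()`, all `t(t+1)/2` parameters —
feasible only for small, well-connected t). The FA family is the workhorse:
it gives every environment its own genetic variance, every pair its own
correlation, and scales linearly in t.

## REML implementation

The variance parameters maximise the residual log-likelihood

`ℓ = −½ [ log|H| + log|X'H⁻¹X| + y'Py + (n − t) log 2π ]`, `H = Z(G_e ⊗ I_m)Z' + Σ`.

The additive constant is always included, so values are comparable across
structures on the same data.

**Block decomposition.** Records of different varieties are uncorrelated
under `G_e ⊗ I_m`, so `H` is block-diagonal by variety with blocks
`G_e[J_i, J_i] + diag(1/w)` of size at most t. All likelihood pieces,
the analytic gradient, the EBLUPs and the PEV blocks are accumulated from
these small blocks; varieties sharing an incidence pattern and weights
share one Cholesky factorization. With peripheral terms the coupling
across varieties returns and the engine switches to a dense n × n path,
intended for desk-scale n.

**Parametrization and constraints.** All variances are log-transformed
with a floor of 1e-8 standing in for the zero boundary; loadings are
unconstrained except for the `k(k−1)/2` upper-triangle entries fixed at
zero for identifiability (rotation is deferred to post-fit). The
unstructured form is parametrized by its Cholesky factor. Gradients are
analytic throughout: writing `dℓ = −½ tr(D dG_e)` with
`D = Σᵢ lift(P_ii) − lift(r_i r_i')`, each structure's gradient is a cheap
contraction of D (e.g. `−DΛ` for the loadings).

**Optimization.** L-BFGS-B with `factr = 1e7`, `pgtol = 1e-6`,
`maxit = 500`. Starting values are principal-factor moment estimates: the
pairwise-complete covariance of the centred means (measurement variance
subtracted on the diagonal), eigendecomposed and QR-rotated onto the
estimation constraint. An EM warm start was considered and rejected: with
analytic gradients the quasi-Newton iteration reaches the same optima in
fewer likelihood evaluations than EM's per-iteration E-steps would cost.
FA/US fits add deterministic rescaled restarts (default 2 starts) and
keep the best optimum. Because the log-scale gradient of a variance
vanishes at zero, the optimizer can stall just above the floor; a final
polish pins any small variance at the floor whenever doing so does not
lower the likelihood, restoring exact "estimated at zero" semantics (used
by the filtering rule).

**Parameter counting.** `n_params` for FAk is `t(k+1) − k(k−1)/2` plus
any peripheral variances; parameters pinned at the boundary floor are
still counted. Published summaries of this model family occasionally
print counts one lower (plausibly a boundary-fixed specific variance);
this package documents and applies its own rule rather than replicating
unexplained counts.

**Model comparison.** `remlrt()` uses the plain chi-square reference on
the difference in parameter counts. When the null pins parameters on the
boundary of the alternative (extra FA factors), the true null law is a
chi-square mixture and the plain reference is conservative; this is
flagged in the documentation and accepted, since order selection does not
rest on the test. `info_criteria()` computes `AIC = −2ℓ + 2p` and
`BIC = −2ℓ + p log(n − t)`. Order selection (`select_order()`) fits FA1,
FA2, … (warm-starting each from the previous solution plus a small new
column) and stops at the first order whose overall percentage of genetic
variance accounted for,

`v̄ = 100 tr(ΛΛ') / tr(ΛΛ' + Ψ)`,

reaches the threshold (default 80%). REMLRT and AIC are reported but
never decide — they tend to push toward unnecessarily high orders, and
BIC toward underfitting; the goodness-of-fit criterion, together with the
distribution of the per-environment `v_j`, is the pragmatic choice.

## Rotation, predictions, accuracy

The fitted loadings are rotated to the principal-component solution
(`rotate_pc()`): `Λ* = Λ̂V` with V the eigenvectors of `Λ̂'Λ̂`, so factor 1
carries the maximum genetic covariance. Signs are fixed so each rotated
column sums non-negative — a deterministic convention required for
reproducibility, matching the practice of orienting the first factor
positively. The rotated-score PEV is the orthogonal transform
`(V' ⊗ I) V_f (V ⊗ I)`; re-fitting with `Λ*` held fixed gives the
identical matrix because the likelihood is rotation invariant, and the
package keeps that second route only as a cross-check. Standard errors of
rotated scores are square roots of the PEV diagonal; covariance terms are
not folded into any single-score interval.

Predictions decompose exactly as `ũ_ij = β̃_ij + δ̃_ij`
(`fa_predictions()`). The regression component `β̃ = Σ_r λ*_rj f̃*_ri`
is the repeatable, factor-driven part and the quantity reported to
growers: it exists for every variety × environment cell, including
environments where the variety was never grown, whereas `δ̃` is
environment-specific and zero off the observed cells. Its PEV is
`V_β = (Λ* ⊗ I) V_f* (Λ*' ⊗ I)`; like all PEV here it ignores the
uncertainty in the estimated variance parameters — no delta-method
inflation is attempted, and outputs say so. Accuracy is the standard
individual-prediction form `sqrt(1 − PEV(ũ_ij)/G_e[j,j])`, averaged over
the varieties grown in an environment for per-environment values;
negative numerical reliabilities are clipped to zero with a warning.

Caveats carried into the reporting surface: predictions in environments
with low `v_j` rest on a weak regression and deserve caution, and a
variety observed only at a narrow range of loadings has poorly determined
scores — `latent_regression()` flags observed x-ranges covering less than
half the full loading range.

## Reporting

The genetic correlation matrix `C_e = D_e G_e D_e` is displayed after
agglomerative hierarchical clustering on the dissimilarity `1 − C_e`
(`order_correlation()`). Average linkage is the default — the linkage is
genuinely open (only the algorithm family and the dissimilarity are
canonical) and configurable. Latent regression plots show, per variety
and factor, the partial regression component against the rotated
loadings with slope `f̃*`; `regional_predictions()` averages `β̃` over any
grower-defined environment group with weights normalised within group and
standard errors from the full `V_β` block (not independent diagonals);
`environment_panel()` emits the long-format table behind per-region
panels (predictions ± SE by location × year, observed flag, trial mean
yield as a quantitative grading of the environment). Every figure is a
thin `autoplot()` over one of these tables, so the module is fully
testable headless and all figure content is derivable from the CSVs
alone. Long-term regional comparisons for a variance-component fit are
obtained by aggregating `met_blups()` over regions; no dedicated
operation exists because the FA-based `regional_predictions()` is the
recommended surface.

## The synthetic-data generator

`simulate_met()` emulates the structural features of national testing
data that drive the statistics: environments as locations × years with
regions assigned round-robin; yearly variety cohorts with a per-year
retention probability (default 0.75) and a fixed entry rate (default
~15% of m per year), giving the moving-window connectivity of real
programs — a retired variety never returns; genetic effects drawn from an
FA law with positive first-factor loadings (default U(0.2, 0.7) t/ha) and
uniform specific variances (default (0.02, 0.1) (t/ha)²); trial mean
yields U(1, 5) t/ha; and plot error variances log-uniform on (0.01, 2)
(t/ha)², reproducing the orders-of-magnitude heterogeneity of real error
mean squares that makes weighting essential. Weights satisfy
`replicates / error_var` exactly. An option ties first-factor loadings to
trial mean yield (off by default), mirroring the tendency of
high-yielding trials to discriminate varieties most strongly.
`simulate_plots()` lays the same truth out as RCBD plot data (block
effect SD set to a quarter of the plot error SD, so a noise-free trial is
recovered exactly by stage 1), and `recovery_report()` compares a fit
with the truth after orthogonal Procrustes alignment of the loadings —
necessary because FA loadings are identified only up to rotation.

What the generator does **not** emulate: spatial field trend within
trials, frost/disease events as discrete shocks, genetic relatedness
among varieties, non-Gaussian effects, or environmental covariates. Tests
passing on synthetic data therefore certify the estimation and reporting
machinery under the stated generative law — not robustness to field
artefacts outside it.

## Verification set-up and problem sizes

The test suite checks the engine against an independent dense-matrix
brute-force REML oracle on small instances (t ≤ 3, m ≤ 10, all
structures), against closed forms for the single-environment problem
(`σ̂²_g = max(0, s² − 1/w)` and the balanced EBLUP shrinkage factor), and
against invariants (scale equivariance, rotation invariance, the exact
`ũ = β̃ + δ̃` decomposition, PEV route equivalence, PEV monotonicity in
the weights). Replicated-simulation studies use t = 12, m = 200 with 100
replicates for FA2 parameter recovery (truth held fixed across
replicates) and t = 8, m = 40 with 200 replicates for the FA-versus-
diagonal accuracy comparison; these sizes give stable Monte-Carlo
summaries in a few minutes on one CPU and are stated here as the
package's chosen study design. In the accuracy study the specific
variances span (0.01, 0.3) (t/ha)² so that the per-environment `v_j`
varies widely — without that spread the relationship between accuracy
gain and `v_j` is not resolvable.

## Known limitations

* Predictions exist only for environments present in the data: the model
  regresses on estimated loadings of observed environments and has no
  predictive capacity for new locations or seasons; extending prediction
  beyond the dataset needs environmental covariates and different
  machinery.
* Factor interpretation likewise requires external covariate information;
  the package computes the factors and their diagnostics but attaches no
  meaning to them.
* Stage 1 ignores spatial trend; where strong field trend exists, means
  and weights from a spatial first stage can be supplied directly through
  `met_data()` instead.
* PEV-based standard errors and accuracies condition on the estimated
  variance parameters.
* The dense path for peripheral terms scales as n³; it is intended for
  moderate datasets.
* Economic weighting of environments is supported only as the generic
  weighted-average hook in `regional_predictions()`; constructing
  selection indices is the grower's or breeder's decision, not the
  package's.
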