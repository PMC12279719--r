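---
title: "Methods: connectome efficiency and the mediation of age-related EF differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome efficiency and the mediation of age-related EF differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

In older adults, executive functioning (EF) declines with age, and so does
the integrity of the white-matter network connecting brain regions. This
package implements the analysis chain used to ask whether the *efficiency*
of the structural connectome statistically mediates the association between
age and EF: weighted graph-efficiency metrics on 84-node connectivity
matrices, extraction of a latent Common-EF score from a nine-task battery,
covariate-adjusted regional screening under false-discovery-rate control,
and standardized three-path mediation with bias-corrected bootstrap
confidence intervals. Because the raw neuroimaging inputs (diffusion MRI,
tractography, SIFT2 weighting) are far upstream of this package's scope, a
synthetic-cohort generator with *planted* effects makes every stage of the
chain verifiable by parameter recovery.

# Connectomes and the node atlas

A connectome here is one subject's 84 x 84 nonnegative, symmetric,
weighted connectivity matrix with a zero diagonal (intra-regional strength
is not meaningful). Node order is fixed by a bundled atlas: the 34 Desikan
cortical regions per hemisphere, seven subcortical structures per
hemisphere, and the two cerebellar hemispheres. Each node carries one of
seven lobe groups (frontal 22, parietal 10, temporal 18, occipital 8,
insula-cingulate 10, subcortical 14, cerebellum 2) following the
Klein-Tourville grouping of Desikan regions. Published summaries sometimes
file the posterior cingulate under "parietal"; only the
all-cingulate-in-insula-cingulate assignment balances the seven printed
group sizes, so the bundled atlas uses that, and cross-source matching is
done by region name plus hemisphere, never by lobe. Users can override the
atlas with any CSV of `label, hemisphere, group`.

File I/O is deliberately plain: dense square TSV/CSV matrices with an
optional header of node names, printed at 17 significant digits so a
write/read round trip is bit-exact. Matrices asymmetric beyond a relative
1e-8 are rejected; smaller asymmetry is averaged away, since all metrics
assume an undirected network.

# Efficiency metrics

Weights are converted to traversal lengths $d_{ij} = 1/w_{ij}$ (stronger
connections are shorter); absent edges have infinite length and
disconnected pairs contribute $1/\infty = 0$ to efficiency sums. Global
efficiency is the mean inverse shortest-path length over ordered pairs,

$$E_{glob} = \frac{1}{n}\sum_i \frac{\sum_{j \neq i} d_{ij}^{-1}}{n-1},$$

an index of network integration. Regional efficiency asks, for each node
$i$ with neighbours $N_i$ ($k_i = |N_i|$), how efficiently the neighbours
communicate once $i$ is removed. We use the weighted variant that is a
*true generalization* of the binary formula:

$$E_{reg}(i) = \frac{\sum_{j \neq h \in N_i} (w_{ij} w_{ih})^{1/3}
\left[d^{1/3}_{jh}(N_i)\right]^{-1}}{k_i (k_i - 1)},$$

where $d^{1/3}_{jh}(N_i)$ is the shortest path between $j$ and $h$ in the
subgraph induced by $N_i$, computed on cube-root lengths $(1/w)^{1/3}$.
The placement of the cube root matters: applying it to each edge length
*before* the path search (rather than to the finished path length) is what
makes the binary limit exact, and binary-limit equality against an
independently coded binary oracle is the normative test in this package's
suite. A plausible-looking alternative, $(w_{ij} w_{ih} / d_{jh})^{1/3}$
with $d$ on plain $1/w$ lengths, reduces to $d^{-1/3}$ on binary graphs
and fails that test; it is not used. Nodes with fewer than two neighbours
score 0, matching the binary convention. Local efficiency $E_{loc}$ is the
arithmetic mean of $E_{reg}$, an index of segregation; the identity
$E_{loc} = \mathrm{mean}(E_{reg})$ is enforced to 1e-12.

No weight normalization is applied before the metrics: efficiency is
homogeneous of degree 1 in the weights (a property test), so results are
reported on the scale of the input weights, as is conventional for
SIFT2-weighted connectomes whose cohort-mean $E_{glob}$ is of order 0.026.

Supplementary global metrics follow toolbox conventions: density is the
fraction of possible edges present; clustering is the mean weighted
clustering coefficient in the geometric-mean-of-triangles form with
weights normalized by the maximum; strength is the mean row sum;
modularity is the best Newman Q over 20 seeded Louvain restarts (the
restart seed is part of the function signature, so cohort tables are
reproducible).

Shortest paths are delegated to Dijkstra's algorithm in igraph; the test
suite checks it against a hand-coded Floyd-Warshall relaxation, and the
exhaustive two-partition oracle checks the Louvain modularity optimum on
separable fixtures.

# The latent Common-EF factor

Nine task scores (antisaccade, number-Stroop, stop-signal; category
switch, color-shape, number-letter; digit span, keep track, spatial
2-back) enter an orthogonal bifactor confirmatory factor model: a Common
EF factor loads on all nine tasks, shifting-specific and updating-specific
factors load on their three tasks each, and no inhibition-specific factor
is fitted — after removing common variance the inhibition tasks typically
retain no shared residual variance. Factor variances are fixed to 1.

No structural-equation package is assumed: the fit is a direct
maximum-likelihood optimization of
$\Sigma(\theta) = \Lambda \Lambda^\top + \Psi$ against the sample
correlation matrix (tasks are z-scored internally, making the fit
invariant to affine rescaling of any column). Uniquenesses are
parameterized as $0.001 + e^\theta$, a floor that guards against Heywood
cases. The optimizer is BFGS with ten jittered restarts under a fixed
seed; the best converged solution is kept and factor signs are resolved by
making each factor's loading sum positive. Parameter recovery from the
generator's known loadings (0.6 common, 0.5 specifics) is within ±0.02 at
n = 50,000 in the acceptance suite.

Factor scores use the regression (Thomson) method
$\hat f = \Lambda^\top \Sigma^{-1} z$, which is deterministic; a Bartlett
variant is available as a config switch. A caution established while
testing: with these loadings the *factor determinacy* of the common factor
— the theoretical ceiling on the correlation between any score estimate
and the true factor — is
$\sqrt{\lambda^\top \Sigma^{-1} \lambda} \approx 0.884$. Recovery tests
therefore assert agreement with this closed-form ceiling, not an arbitrary
round number.

# Association screens

All bivariate associations are partial Pearson correlations: both
variables are residualized on an intercept plus the nuisance covariates
(sex coded 0/1, education in years, both unstandardized) by least squares,
residuals are correlated, and the two-sided p comes from
$t = r\sqrt{df/(1-r^2)}$ with $df = n - 2 - k$. Regional screens run all
84 node correlations as one family under the Benjamini-Hochberg step-up
rule at $q = 0.05$; the reported critical p is the largest rejected
p-value. One family per screen (rather than separate families for
positive and negative signs) mirrors the one-critical-p-per-table
convention of the regional tables this reproduces; global metrics
($E_{glob}$, $E_{loc}$) are tested as single correlations without FDR.

# Mediation

The simple three-path model regresses (all focal variables z-scored on the
analysis sample): mediator on IV (path $a$), DV on mediator and IV (paths
$b$, $c'$), DV on IV (path $c$). With identical covariate sets OLS gives
$c = c' + ab$ to machine precision, which the suite asserts on every fit.
Inference on the indirect effect $ab$ uses case resampling: subjects are
resampled with replacement 5,000 times (configurable), $ab$ recomputed
each time, and a bias-corrected percentile interval formed with
$z_0 = \Phi^{-1}(\text{proportion of bootstrap } ab \text{ strictly below
the estimate})$, ties excluded and the proportion clamped to
$[1/(B+1), B/(B+1)]$; the bounds are the bootstrap quantiles at
$\Phi(2z_0 \pm z_{\alpha/2})$. No acceleration term is used. Degenerate
resamples (zero variance in a focal variable) are redrawn and counted. A
region "mediates" when its CI excludes zero; following the source
analysis, no multiplicity correction is applied across the per-region
CIs, and this is a documented analytic choice rather than a statistical
recommendation.

Regional mediation restricts candidates to the intersection (hemisphere +
region) of the significant rows of the age screen and the EF screen, then
fits one bootstrap mediation per candidate with that node's $E_{reg}$ as
mediator.

The exhaustive-enumeration oracle for the bootstrap deserves a note: for
n = 7 the $7^7$ ordered resamples collapse to the $\binom{13}{6} = 1716$
multisets with multinomial weights, so the test compares sampled BC bounds
at $B = 10^5$ against exact weighted-quantile bounds.

# The synthetic generator

The generator is first-class, tested code, and its defaults *are* the
study conditions: ages truncated-normal on [60, 85] with mean 68.06 and sd
4.74 (these are the pre-truncation parameters; the realized sample sd is
slightly smaller, ~4.4), 52/84 female, education 18.06 (2.66) years.

A template connectome is built once per cohort: edges are placed with
higher probability within lobe blocks than between (block probabilities
solved so the overall density matches the request), weights are log-normal
with a within-block premium, and the whole matrix is rescaled so the
template's global efficiency equals 0.026 — the magnitude observed for
SIFT2-weighted 84-node connectomes, so that synthetic cohort summaries
live on a realistic scale.

Age acts multiplicatively on the log scale: subject $s$'s weights are the
template times $\exp(\beta_{age}(age_s - 70) + \zeta_s)$, with
$\beta_{age} = -0.01$/year (a 1% decline per year, a realistic
literature-scale effect) and subject-level variability $\zeta_s$ whose sd
is *derived*, not tuned: for a target standardized age-efficiency path
$a$, $\sigma_\zeta = |\beta_{age}| \sigma_{age} \sqrt{1/a^2 - 1}$, which
makes the population correlation between age and log-efficiency exactly
$a$ (default -0.44, the local-efficiency magnitude of interest).
Independent per-edge log-normal noise (sd 0.05) roughens individual
matrices. With a `target_node`, only that node's incident edges are
scaled, planting the effect in one region's $E_{reg}$ (which then scales
as the 2/3 power of the factor, since only the two incident-weight terms
of the formula are touched).

The EF equation uses the efficiency *actually computed from the generated
matrix by the graph code* as its mediator (the strongest possible
integration test): Common EF = $b \cdot z(\log E_{loc}) + c' \cdot z(age)
+ \beta_{sex}\,sex + \beta_{edu}\,z(edu) + \varepsilon$, with defaults
$b = 0.18$, $c' = -0.45$, sex -0.19, education 0.09 — the magnitudes of
the local-efficiency mediation row — and residual sd 0.83 chosen so the EF
variance is approximately 1 under the defaults. Task scores then follow
the bifactor loading convention (common 0.6, specifics 0.5) with
independent unique noise, so CFA recovery and mediation recovery share one
generator. When edge noise is off, per-subject efficiencies follow from
degree-1 homogeneity of the metrics (an exact shortcut, itself property-
tested), which is what makes n = 5,000 behavioural simulations cheap; the
`store = "none"` mode requires that configuration.

What the generator does *not* emulate: tractography artefacts,
distance-dependent connection probability, heavy-tailed SIFT2 weight
distributions, hub structure beyond lobe blocks, or any measurement model
for the task battery beyond linear loadings with Gaussian noise. Passing
recovery tests therefore demonstrates that the *estimators* are correct
and calibrated, not that real connectomes satisfy the generative model.

`recovery_report()` summarizes bias, RMSE, CI coverage and rejection rate
over replicate cohorts. Its default `mode = "paths"` simulates the
mediation triple directly on the standardized scale — that is what makes
1,000-replicate calibration runs feasible — while `mode = "full"` runs the
entire connectome chain per replicate and is intended for small replicate
counts; the end-to-end planted-node test exercises the full chain
separately.

# Numerical and design choices

* Asymmetry tolerance 1e-8 (relative), then symmetrization by averaging.
* $k_i < 2 \Rightarrow E_{reg}(i) = 0$; empty graphs score 0 everywhere;
  $E_{glob}$ of a single node is an error rather than a convention.
* Uniqueness floor 0.001 in the CFA; rank deficiency of the task
  correlation matrix (eigenvalue < 1e-10) is a hard error.
* Bootstrap quantiles use R's default type-7 interpolation; the
  enumeration oracle shows agreement within 0.01 of exact weighted
  quantiles at $B = 10^5$.
* Degrees of freedom for the partial-correlation test are $n - 2 - k$.
* Modularity restarts: 20, seeded; the best Q is reported.
* Covariate scaling in mediation is a config switch
  (`standardize_covariates`), defaulting to raw scales.
* All randomness flows through explicit `seed` arguments; internal RNG
  use saves and restores the caller's `.Random.seed`.

# Problem sizes used in the shipped tests

Oracle suites use 100-1,000 small random instances (graphs up to n = 12).
Calibration uses 1,000 replicate cohorts of n = 84 at 1,000 bootstrap
resamples; CFA recovery uses one n = 50,000 sample; the end-to-end
planted-node pipeline run uses one n = 300 cohort at 1,000 resamples.
These sizes give Monte-Carlo error comfortably inside the asserted bands
while keeping a full suite run in the tens of minutes on one core.

# Known limitations

* The CFA reports log-likelihood/AIC only; fit indices (CFI, RMSEA) are
  out of scope.
* Mediation is the simple three-path model: no multiple mediators, no
  moderated mediation, no SEM-based latent mediation, and the Sobel test
  is deliberately not offered as a headline statistic.
* The bundled published screen tables are transcriptions of summary
  tables, included to define the regional-mediation candidate set and for
  structural checks; the subject-level data behind them are not shipped,
  so subject-level results cannot be recomputed here.
* Efficiency metrics are scale-dependent by design; comparing cohorts
  processed with different tractography scales requires harmonizing
  weights upstream.
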