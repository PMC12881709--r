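---
title: "Methods: integrated distribution modelling of pest and disease burdens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated distribution modelling of pest and disease burdens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestisdm)
```

## The modelling problem

Tree pest and disease records typically arrive through two very different
channels. Plant-health inspectors visit sites repeatedly and record whether
anything was found on each visit, giving *presence–absence* (PA) data:
detections out of surveys per site, with most visits yielding nothing.
Members of the public report sightings opportunistically, giving
*presence-background* (PB) data: locations of confirmed findings with no
record of effort, and strong spatial reporting bias. Neither stream alone
supports a reliable national risk map; together they can, if both are tied
to one underlying ecological process.

`pestisdm` implements that fusion as an integrated species distribution
model (ISDM). The shared process is a log-Gaussian Cox process (LGCP) whose
intensity $\lambda(s)$ (expected findings per km$^2$) is

$$\log \lambda(s) = \alpha + \sum_k \beta_k x_k(s) + \xi(s),$$

with $x_k$ standardised landscape covariates and $\xi$ a Matérn
($\nu = 1$) Gaussian random field with marginal standard deviation
$\sigma$ and range $\rho$. Each data stream gets its own observation model:

* **PA**: at a site with $n$ surveys, detections are
  $\mathrm{Binomial}(n, p)$ with
  $p = 1 - \exp(-e_{\mathrm{vis}}\lambda(s))$ — the complementary log–log
  link, which is exactly the probability that a Poisson process with
  intensity $\lambda$ leaves at least one detectable event in one visit's
  exposure $e_{\mathrm{vis}}$.
* **PB**: a thinned Poisson point process with log intensity
  $\alpha_{PB} + \sum_k \beta_k x_k(s) + \xi(s) + b(s)$, where $b$ is a
  *second* Matérn field absorbing spatially structured reporting effort.
  The point-process likelihood uses Berman–Turner quadrature at covariate
  cell centres.

The two streams share $\beta$ and $\xi$; each has its own intercept
($\alpha_{PA}$, $\alpha_{PB}$) because the effort scales of inspections and
public reports are incommensurable. The bias field $b$ belongs to the
observation process, not the ecology, so predictions exclude it.

All likelihood evaluations snap observation coordinates to the centre of
their containing cell: the model operates at covariate resolution (1 km by
convention) and sub-cell position carries no information at that scale.

## Spatial fields: basis, precision, priors

The fields are represented through the SPDE approach: a Matérn field is the
solution of a stochastic partial differential equation, which on a discrete
basis yields a *sparse* precision matrix. The basis here is a regular
lattice with bilinear elements (`build_mesh`); the `max_edge_km` argument is
the lattice spacing and plays the role of the maximum triangle edge of a
triangular mesh, with a floor of 1 km so the basis is never finer than the
covariates. The lattice extends 20 km (twice the 10 km prior range
threshold) beyond the data bounding box, because SPDE boundary conditions
inflate variance near the mesh edge. `matern_precision` assembles the
standard $\nu = 1$ ($\alpha = 2$) construction
$Q = \tau^2(\kappa^4 C + 2\kappa^2 G + G C^{-1} G)$ with lumped mass matrix
$C$, tensor-product stiffness $G$, $\kappa = \sqrt{8}/\rho$ and $\tau$
scaled so the marginal standard deviation is $\sigma$. On lattices with
spacing below about $\rho/4$ the implied correlation tracks the analytic
Matérn curve to within 0.05 and interior marginal variances are within a
few percent of nominal; both properties are exercised in the test suite
against dense-inverse oracles.

Hyperparameters carry penalised complexity (PC) priors calibrated by tail
statements: $P(\sigma > 1) = 0.05$ (exponential-tail density, rate
$-\log 0.05 \approx 2.996$) and $P(\rho < 10\,\mathrm{km}) = 0.05$
(density $(\lambda/\rho^2)e^{-\lambda/\rho}$, $\lambda = -10\log 0.05
\approx 29.96$). The $\sigma$ prior's mode is at zero: spatial structure is
absent unless the data demand it. Fixed effects and intercepts get
independent normal priors with mean 0 and precision 1 — deliberately
regularising, since intensity is the exponential of the linear predictor.

```{r pc-priors}
stats::integrate(pc_prior_sigma_density, 1, Inf)$value   # = 0.05
stats::integrate(pc_prior_rho_density, 0, 10)$value      # = 0.05
```

## Inference: empirical-Bayes Laplace

Conditional on $(\sigma, \rho)$ of both fields, the latent state
$(\alpha_{PA}, \alpha_{PB}, \beta, \xi, b)$ has a log-concave posterior
(binomial-cloglog and Poisson-process likelihoods are both concave in the
linear predictor). `fit_isdm` finds its mode by a sparse Newton iteration
with backtracking line search — the joint log posterior increases
monotonically, which the tests assert per fit — and approximates the
posterior by a Gaussian at the mode (Laplace approximation). The
hyperparameters are then chosen on a grid by maximising the
Laplace-approximate marginal likelihood plus the PC prior: first the shared
field's grid with the bias field held at its grid medians, then the bias
field's grid at the selected shared values. Reported fixed-effect summaries
are *averaged over all evaluated grid points* with marginal-likelihood
weights, so hyperparameter uncertainty propagates into the posterior means
and standard deviations; 95% intervals are Gaussian
($\mathrm{mean} \pm 1.96\,\mathrm{sd}$) on the linear-predictor scale.

Numerical guards: cloglog probabilities are clamped to
$[10^{-12}, 1 - 10^{-12}]$, the exposure term $e_{\mathrm{vis}} e^\eta$ is
capped at $10^8$, quadrature exponents at $e^{50}$, and all tail
computations use `expm1`/`log1p` forms. Defaults: $\sigma$ grid
$\{0.1, 0.25, 0.5, 1, 2\}$, $\rho$ grid $\{5, 10, 20, 40\}$ km, bias-field
grids $\{0.25, 0.5, 1\} \times \{10, 20\}$; Newton tolerance $10^{-8}$ on
the step max-norm, at most 100 iterations.

Prediction (`predict_intensity`) evaluates the Gaussian posterior of
$\eta$ at output cells and maps to the intensity scale by lognormal
moments, $\mathrm{mean} = e^{\mu + v/2}$,
$\mathrm{sd} = \mathrm{mean}\sqrt{e^v - 1}$; the process intercept is the
PB intercept when the point stream is present, a choice that cancels in
the 0–1 rescaling (`rescale_unit` divides the sd map by the same positive
factor that rescales the mean, with no shift).

## Covariate engineering

* `gaussian_connectivity`: a weighted sum of a habitat layer around each
  cell with Gaussian distance weights (sd 3 km by default), truncated at
  3 sd = 9 km — the radii that carry 68% and 99.7% of the one-dimensional
  weight profile. Weights are normalised to sum to one (so constant layers
  are invariant and units are preserved), and renormalised over the
  in-domain support at edges.
* `standardize`: subtract the mean, divide by the *population* (1/n)
  standard deviation — a raster is the complete population of its cells.
  Constant layers raise an error rather than silently becoming zero.
* `distance_to_nearest`: planar centre-to-centre km distances (coordinates
  are assumed already on a planar national grid in km); no geodesic
  correction.
* `area_edge_per_cell`: habitat area and habitat/non-habitat boundary
  length per coarse cell from a fine binary raster; only boundaries
  strictly inside a coarse cell count toward its edge length.

## Causal covariate selection

Driver effects are total causal effects identified by the back-door
criterion on a user-editable DAG (`inst/extdata/maximal_dag.txt` ships a
defensible default over elevation, climate, human activity, land-use
change, woodland composition and the latent introduction/establishment
probabilities; it is configuration, not code). `minimal_adjustment_sets`
returns *every* inclusion-minimal observed set that blocks all back-door
paths while containing no descendant of the exposure; when one DAG implies
several minimal sets, each is fitted as a separate model
(`estimate_driver_effect`). Latent nodes may lie on paths but never enter
adjustment sets; if no observed set is valid the function raises an
identifiability error rather than returning nothing. d-separation is
decided by the standard reachability algorithm, and the test suite checks
it — and the minimal sets — against brute-force path enumeration and
exhaustive subset scans on hundreds of random DAGs.

`sensitivity_sequence` rebuilds the analysis under nested sub-DAGs,
starting from the focal variable alone (the unadjusted estimate) and adding
covariates one at a time to the maximal DAG; variables are added in
topological order by default, a reproducible choice that respects
ancestry. Each unique adjustment set across the sequence implies one model.

## WAIC covariate search

Because pointwise WAIC is not well defined for the point-process stream,
covariate search runs on the PA stream alone (`fit_pa_gp_glm`: the same
machinery restricted to the binomial likelihood, same field and priors),
with the winning set then carried into the full ISDM. Candidate sets are
drawn uniformly at random: sizes 5–20, 50 sets per size, 800 total, with
uniqueness enforced by bounded resampling. WAIC uses the standard
decomposition $-2(\mathrm{lppd} - p_{\mathrm{waic}})$ from $S = 1000$
posterior draws by default (overflow-safe log-mean-exp; sample variance
with denominator $S - 1$); ranking ties break toward fewer covariates, then
lexicographically, and failed fits are ranked last with their error
recorded, never dropped.

## Host-cover residuals

`host_cover_residuals` robust-regresses the (rescaled) intensity map on a
host-cover map and returns the residual raster: positive cells carry more
predicted burden than their host cover explains. The regression is a
hand-written Huber IRLS (`huber_rlm`, tuning constant $k = 1.345$, scale
$\mathrm{median}|r|/0.6745$ re-estimated per iteration); each IRLS step
provably decreases the Huber loss at the scale it was taken at, which the
implementation records and the tests assert. The suite cross-checks
coefficients against an independent reference implementation on heavy-tailed
data.

## The synthetic test-bed

Real inspection and report data of this kind are restricted, so the package
ships a generator that emulates their structure with known ground truth:

* **Covariates** follow a linear-Gaussian structural causal model: each DAG
  node is a coefficient-weighted sum of its parents plus Matérn noise
  (`simulate_covariate_fields`). Linearity makes every total effect equal
  to the sum over directed paths of edge-coefficient products
  (`scm_total_effect`), so causal recovery can be checked exactly.
* **Intensity** is log-linear in the covariates plus a Matérn field drawn
  on a 1 km-spacing basis.
* **PB points** are cell-wise Poisson draws from
  $\exp(\log\lambda + b)\cdot|\mathrm{cell}|$, placed uniformly within
  their cell; the thinning field $b$ is drawn from the model's own
  `bias_sd`/`bias_range` by default so the fitted bias field is correctly
  specified.
* **PA surveys** use visit counts from a zero-truncated geometric with
  mean 1.5 (median 1 with a long tail, as in national inspection data) and
  per-visit exposure $e_{\mathrm{vis}} = 1$ cell-area unit — a convention,
  since the intensity-to-detection scale is not separately identifiable
  from data of this form.

All generators are bit-reproducible under a fixed seed.

The standard calibration scenario used by the tests is a 50 × 50 km
landscape, $\beta = (1, -0.5)$ on two independent standardised Matérn
covariates, $\sigma = 0.5$, $\rho = 10$ km, roughly 500 PB points and 200
PA sites; over 20 replicates each coefficient's posterior mean falls within
±2 posterior sd of truth in at least 18. The mesh-stability check compares
5 km and 30 km bases on data whose field range is 40 km — near the PC
prior's median range, and chosen so that *both* bases can resolve the
field; with a 10 km-range field a 30 km basis cannot represent the field at
all, and what the comparison would then measure is basis error, not
sensitivity. The comparison is averaged over three replicate datasets so it
measures the systematic mesh effect rather than one realisation's noise.

## Known limitations

* Empirical-Bayes Laplace slightly understates uncertainty relative to full
  Bayes: hyperparameter averaging is over a finite grid, and the recovery
  tests show posterior sds that are mildly anti-conservative for one of the
  two coefficients while conservative for the other. Interval coverage
  close to, but not exactly at, the nominal level should be expected.
* The regular-lattice basis is the only backend; highly irregular domains
  would be served better by a true triangular mesh.
* The generator draws fields at cell resolution; sub-cell point patterns,
  temporal dynamics, and multi-species dependence are out of scope.
* Passing the synthetic suite shows the machinery is correct under its own
  generative assumptions (linear covariate effects, Matérn fields, cloglog
  detection). Real data violate these in unknown ways — notably
  non-stationary reporting effort and covariate measurement error — and the
  suite says nothing about those violations.
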