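# pestisdm

Integrated species distribution modelling of tree pest and disease burdens,
with causal covariate selection.

## The problem

National pictures of tree pest and disease risk have to be assembled from
two imperfect data streams: repeat-visit plant-health inspections
(presence–absence: detections out of surveys per site, mostly zeros) and
opportunistic public reports (presence-background: confirmed find
locations with no record of effort and strong reporting bias). `pestisdm`
is for quantitative ecologists and plant-health analysts who want to fuse
both streams into one spatial intensity surface, map where burdens are
higher or lower than host availability explains, and estimate the total
causal effect of candidate drivers (urbanisation, recreation, land-use
change, connectivity, ...) rather than mere associations.

## The model

Both streams are observations of one log-Gaussian Cox process with

```
log lambda(s) = alpha + sum_k beta_k x_k(s) + xi(s)
```

where `x_k` are standardised covariate rasters and `xi` is a Matérn
(nu = 1) Gaussian field represented by a sparse SPDE precision matrix on a
lattice basis. Presence–absence sites contribute a binomial likelihood
through the complementary log–log link `p = 1 - exp(-e_vis * lambda)`;
presence-background points contribute a thinned-Poisson point-process
likelihood with a second Gaussian field absorbing reporting bias. Field
hyperparameters carry penalised complexity priors calibrated as
`P(sigma > 1) = 0.05` and `P(rho < 10 km) = 0.05`; fixed effects have
N(0, 1) priors. Inference is empirical-Bayes Laplace: sparse Newton
optimisation of the latent state inside a hyperparameter grid search, with
fixed-effect summaries averaged over the grid by marginal likelihood.

Covariates can be chosen two ways: WAIC search over random candidate sets
(5–20 covariates per set, 50 sets per size, 800 total) fitted on the
presence–absence stream, or back-door adjustment sets derived from a causal
DAG (all inclusion-minimal sets; d-separation and adjustment-set machinery
are built in and oracle-tested). A DAG-sequence sensitivity analysis
rebuilds the adjustment sets under nested sub-graphs of the maximal DAG.

Because the motivating inspection/report datasets are restricted, the
package includes a synthetic-landscape generator with known causal
structure (linear-Gaussian structural equations with Matérn noise), so
every stage — covariate engineering, field machinery, the integrated
likelihood, causal adjustment, WAIC selection — is validated end-to-end
against analytic ground truth.

## Worked example

Simulate a 50 × 50 km landscape where conifer cover increases pest
intensity (beta = 1.0) and elevation decreases it (beta = -0.5), with a
spatial field (sigma = 0.5, rho = 10 km), then fit the integrated model:

```r
library(pestisdm)

truth <- true_model(alpha = -2.4, beta = c(conifer = 1.0, elevation = -0.5),
                    sigma = 0.5, rho = 10)
dat <- simulate_isdm_dataset(grid_spec(50, 50, 1), truth,
                             n_sites = 200, seed = 11)
nrow(dat$pb)                                        # 639 reports
c(sum(dat$pa$n_detections), sum(dat$pa$n_surveys))  # 48 detections / 279 surveys

fit <- fit_isdm(dat$covariates, dat$pa, dat$pb,
                isdm_config(covariates = c("conifer", "elevation")))
fit
#> <isdm_fit> PA+PB; 726 latent values; lml -1042.66
#>   field: sigma=0.5 rho=10; bias field: sigma=0.5 rho=15
#>        parameter   mean     sd   lo95   hi95
#> 1       alpha_pa -2.042 0.2768 -2.585 -1.500
#> 2       alpha_pb -2.107 0.2719 -2.640 -1.574
#> 3   beta_conifer  1.020 0.0717  0.879  1.160
#> 4 beta_elevation -0.633 0.0750 -0.780 -0.486
```

Both coefficients are recovered within two posterior sd, and the
hyperparameter search lands on the generating field (sigma 0.5, rho 10 km).
Prediction and 0–1 rescaling give the map products:

```r
pred <- predict_intensity(fit, dat$covariates)   # bias field excluded
maps <- rescale_unit(pred$mean, pred$sd)
maps$mean01
#> <pest_raster> 'intensity_mean_01' 50 x 50 @ 1 km; range [0, 1]
```

Driver effects with confounding: urbanisation drives recreation *and* pest
arrival, so the raw recreation coefficient is badly biased while the
back-door-adjusted model recovers the true total effect (0.7):

```r
scm <- scm_spec(parse_dag("urban -> recreation"), c("urban->recreation" = 1.0),
                noise_sd = c(urban = 1, recreation = 0.6), noise_range = 10)
truth2 <- true_model(alpha = -2.8, beta = c(recreation = 0.7, urban = 0.8),
                     sigma = 0.4, rho = 10)
dat2 <- simulate_isdm_dataset(grid_spec(50, 50, 1), truth2, scm = scm,
                              n_sites = 200, seed = 7)

dag <- parse_dag("urban -> recreation\nrecreation -> y\nurban -> y")
estimate_driver_effect("recreation", dag, dat2$covariates,
                       dat2$pa, dat2$pb, isdm_config())
#>        focal adjustment_set      mean        sd      lo95      hi95
#> 1 recreation          urban 0.5215019 0.1374593 0.2520816 0.7909221

# unadjusted for comparison: absorbs the confounded path (true value 0.7)
#>         parameter    mean         sd     lo95     hi95
#> 3 beta_recreation 1.44088 0.09270111 1.259185 1.622574
```

The adjusted interval covers the truth; the unadjusted estimate (1.44) is
roughly double it.

## Layout

- `R/` — grid/raster containers, covariate engineering, DAG machinery,
  SPDE fields and PC priors, the integrated model, WAIC selection and
  robust residuals, the synthetic generator.
- `inst/extdata/maximal_dag.txt` — the editable maximal DAG (configuration,
  not code).
- `vignettes/methods.Rmd` — full model description, numerical choices and
  limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles.
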