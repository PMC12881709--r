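test_that("the linear predictor is zero at zero state, identity on a unit coefficient, and linear", {
  g <- grid_spec(10, 10, 1)
  mesh <- build_mesh(g, max_edge_km = 5, extend_km = 5)
  set.seed(41)
  z <- standardize(raster_layer(g, matrix(rnorm(100), 10)))
  pts <- cell_centers(g)

  zero <- list(alpha_pa = 0, alpha_pb = 0, beta = c(z = 0),
               xi = rep(0, mesh$n_nodes), b = rep(0, mesh$n_nodes))
  expect_equal(linear_predictor(zero, list(z = z), pts, mesh), rep(0, 100))

  unit <- zero; unit$beta <- c(z = 1)
  expect_equal(linear_predictor(unit, list(z = z), pts, mesh),
               as.vector(z$values), tolerance = 1e-12)

  s1 <- zero; s1$alpha_pb <- 0.3; s1$xi <- rnorm(mesh$n_nodes)
  s2 <- zero; s2$beta <- c(z = -0.5); s2$b <- rnorm(mesh$n_nodes)
  sum_state <- list(alpha_pa = s1$alpha_pa + s2$alpha_pa,
                    alpha_pb = s1$alpha_pb + s2$alpha_pb,
                    beta = s1$beta + s2$beta, xi = s1$xi + s2$xi,
                    b = s1$b + s2$b)
  for (stream in c("process", "pb")) {
    expect_equal(
      linear_predictor(sum_state, list(z = z), pts, mesh, stream),
      linear_predictor(s1, list(z = z), pts, mesh, stream) +
        linear_predictor(s2, list(z = z), pts, mesh, stream),
      tolerance = 1e-12)
  }
})

test_that("the PA log-likelihood matches limits, closed form and naive summation", {
  pa1 <- pa_table(data.frame(site_id = 1, x_km = 1, y_km = 1,
                             n_surveys = 1, n_detections = 1))
  # e_vis * lambda = 1  =>  p = 1 - exp(-1)
  expect_equal(pa_loglik(0, pa1, e_vis = 1), log1p(-exp(-1)),
               tolerance = 1e-12)

  pa0 <- pa_table(data.frame(site_id = 1:3, x_km = 1, y_km = 1,
                             n_surveys = c(5, 1, 10), n_detections = 0))
  expect_gt(pa_loglik(rep(-40, 3), pa0), -1e-10)   # p -> 0, all-zero certain

  set.seed(42)
  n <- sample(1:10, 100, replace = TRUE)
  eta <- rnorm(100)
  p <- -expm1(-exp(eta))
  k <- rbinom(100, n, p)
  pa <- pa_table(data.frame(site_id = 1:100, x_km = 1, y_km = 1,
                            n_surveys = n, n_detections = k))
  expect_equal(pa_loglik(eta, pa),
               sum(dbinom(k, n, p, log = TRUE)), tolerance = 1e-10)
})

test_that("the point-process log-likelihood has the homogeneous closed form and refinement stability", {
  g <- grid_spec(10, 10, 1)
  quad <- quadrature_cells(g)
  eta0 <- 0.4; n <- 37
  ll <- pb_loglik(rep(eta0, n), rep(eta0, 100), quad$weights)
  expect_equal(ll, n * eta0 - 100 * exp(eta0), tolerance = 1e-12)
  # maximised at log(n / |D|)
  lls <- vapply(seq(-1, 1, by = 0.01), function(a)
    pb_loglik(rep(a, n), rep(a, 100), quad$weights), numeric(1))
  expect_equal(seq(-1, 1, by = 0.01)[which.max(lls)], round(log(n / 100), 2),
               tolerance = 0.011)

  # quadrature refinement changes the integral term by < 0.5 % on a smooth surface
  smooth_eta <- function(p) 0.4 * sin(p[, 1] / 3) + 0.3 * cos(p[, 2] / 4)
  q1 <- quadrature_cells(g, refine = 1L)
  q2 <- quadrature_cells(g, refine = 2L)
  i1 <- sum(q1$weights * exp(smooth_eta(q1$points)))
  i2 <- sum(q2$weights * exp(smooth_eta(q2$points)))
  expect_lt(abs(i1 - i2) / i2, 0.005)
})

test_that("a PB-only homogeneous fit recovers the Poisson MLE intercept", {
  g <- grid_spec(30, 30, 1)
  surf <- simulate_intensity(g, list(), true_model(alpha = 0, sigma = 0),
                             seed = 2)
  pb <- simulate_pb_points(surf$lambda, seed = 3)
  cfg <- isdm_config(include_field = FALSE, include_bias_field = FALSE)
  fit <- fit_isdm(list(), pa = NULL, pb = pb, config = cfg, grid = g)
  a <- fit$summary$mean[fit$summary$parameter == "alpha_pb"]
  expect_lt(abs(a - log(nrow(pb) / 900)), 1e-3)
  expect_true(all(diff(fit$trace) >= -1e-9))   # monotone joint log posterior
})

test_that("an all-zero covariate is prior-dominated and leaves other coefficients unchanged", {
  dat <- recovery_dataset(seed = 51)
  cfg <- quick_config(covariates = c("x1", "x2"))
  base <- fit_isdm(dat$covariates, dat$pa, dat$pb, cfg)
  covs2 <- c(dat$covariates,
             list(null_cov = raster_layer(dat$grid, 0, name = "null_cov")))
  cfg2 <- quick_config(covariates = c("x1", "x2", "null_cov"))
  aug <- fit_isdm(covs2, dat$pa, dat$pb, cfg2)
  for (p in c("alpha_pa", "alpha_pb", "beta_x1", "beta_x2")) {
    expect_equal(aug$summary$mean[aug$summary$parameter == p],
                 base$summary$mean[base$summary$parameter == p],
                 tolerance = 1e-6)
  }
  row <- aug$summary[aug$summary$parameter == "beta_null_cov", ]
  expect_equal(row$mean, 0, tolerance = 1e-6)
  expect_equal(row$sd, 1, tolerance = 1e-3)    # prior sd = precision^(-1/2)
})

test_that("the separate stream likelihoods reproduce the joint objective at the mode", {
  dat <- recovery_dataset(seed = 52)
  cfg <- quick_config(covariates = c("x1", "x2"), include_bias_field = FALSE)
  fit <- fit_isdm(dat$covariates, dat$pa, dat$pb, cfg)
  mesh <- fit$mesh
  state <- list(alpha_pa = fit$x[fit$idx$alpha_pa],
                alpha_pb = fit$x[fit$idx$alpha_pb],
                beta = setNames(fit$x[fit$idx$beta], c("x1", "x2")),
                xi = fit$x[fit$idx$xi], b = NULL)
  # the fitted model works at cell resolution: evaluate at cell centres
  snap <- cbind(floor(dat$pa$x_km) + 0.5, floor(dat$pa$y_km) + 0.5)
  eta_pa <- linear_predictor(state, dat$covariates, snap, mesh, "pa")
  ll_pa <- pa_loglik(eta_pa, dat$pa, cfg$e_vis) -
    sum(lchoose(dat$pa$n_surveys, dat$pa$n_detections))
  quad <- quadrature_cells(dat$grid)
  eta_pts <- linear_predictor(state, dat$covariates,
                              cbind(floor(dat$pb$x_km) + 0.5,
                                    floor(dat$pb$y_km) + 0.5), mesh, "pb")
  eta_quad <- linear_predictor(state, dat$covariates, quad$points, mesh, "pb")
  ll_pb <- pb_loglik(eta_pts, eta_quad, quad$weights)
  # reconstruct the fitted joint objective: likelihoods + Gaussian prior
  f_joint <- utils::tail(fit$trace, 1)
  prior_term <- f_joint - (ll_pa + ll_pb)
  # the prior quadratic form is recovered from the fitted state
  xq <- fit$x
  Qxi <- matern_precision(mesh, hyper_params(fit$hyper$sigma, fit$hyper$rho))
  quad_form <- 0.5 * (sum(xq[c(fit$idx$alpha_pa, fit$idx$alpha_pb,
                               fit$idx$beta)]^2) +
                        sum(xq[fit$idx$xi] *
                              as.numeric(Qxi %*% xq[fit$idx$xi])))
  expect_equal(prior_term, -quad_form, tolerance = 1e-6)
})

test_that("posterior intensity maps are positive, ordered by rescaling, and match lognormal draws", {
  dat <- recovery_dataset(seed = 53)
  cfg <- quick_config(covariates = c("x1", "x2"))
  fit <- fit_isdm(dat$covariates, dat$pa, dat$pb, cfg)
  pred <- predict_intensity(fit, dat$covariates)
  expect_true(all(pred$mean$values > 0))
  expect_true(all(pred$sd$values >= 0))

  # Monte-Carlo oracle for the lognormal moments at a handful of cells
  draws <- sample_posterior(fit, 10000, seed = 7)
  pts <- cell_centers(dat$grid)[c(1, 625, 1250, 2400), ]
  D <- pestisdm:::process_design(fit, dat$covariates, pts)
  eta_draws <- as.matrix(D %*% draws)
  mc_mean <- rowMeans(exp(eta_draws))
  idx <- c(1, 625, 1250, 2400)
  expect_equal(as.vector(pred$mean$values)[idx], mc_mean, tolerance = 0.05)

  sc <- rescale_unit(pred$mean, pred$sd)
  expect_equal(min(sc$mean01$values), 0)
  expect_equal(max(sc$mean01$values), 1)
  expect_equal(order(sc$mean01$values), order(pred$mean$values))
  ratio <- sc$sd01$values / pred$sd$values
  expect_lt(diff(range(ratio)), 1e-12)          # one shared positive factor
  expect_error(rescale_unit(raster_layer(dat$grid, 1), pred$sd), "constant")

  out5 <- grid_spec(10, 10, 5)
  pred5 <- predict_intensity(fit, dat$covariates, out5)
  expect_identical(dim(pred5$mean$values), c(10L, 10L))
  expect_error(predict_intensity(fit, dat$covariates,
                                 grid_spec(10, 10, 50)), "outside")
})

test_that("integrating the PA stream reduces coefficient error under strong PB bias", {
  # directional property over replicates: RMSE(integrated) <= RMSE(PB-only)
  g <- grid_spec(40, 40, 1)
  err_int <- c(); err_pb <- c()
  for (s in 1:6) {
    tm <- true_model(alpha = -1.8, beta = c(x1 = 1.0), sigma = 0.4, rho = 10)
    bias_field <- raster_layer(g, matrix(rep(seq(-1.5, 1.5, length.out = 40),
                                             each = 40), 40, 40, byrow = TRUE))
    dat <- simulate_isdm_dataset(g, tm, n_sites = 150, pb_bias = bias_field,
                                 seed = 60 + s)
    cfg <- quick_config(covariates = "x1")
    fit_i <- fit_isdm(dat$covariates, dat$pa, dat$pb, cfg)
    fit_p <- fit_isdm(dat$covariates, NULL, dat$pb, cfg)
    b_i <- fit_i$summary$mean[fit_i$summary$parameter == "beta_x1"]
    b_p <- fit_p$summary$mean[fit_p$summary$parameter == "beta_x1"]
    err_int <- c(err_int, (b_i - 1)^2)
    err_pb <- c(err_pb, (b_p - 1)^2)
  }
  expect_lte(sqrt(mean(err_int)), sqrt(mean(err_pb)))
})
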