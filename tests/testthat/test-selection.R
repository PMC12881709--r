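test_that("candidate generation yields the full design with unique, bounded sets", {
  nm <- paste0("v", 1:25)
  sets <- generate_candidate_sets(nm, seed = 71)
  expect_length(sets, 800)
  sizes <- vapply(sets, length, integer(1))
  expect_true(all(sizes >= 5 & sizes <= 20))
  expect_true(all(vapply(sets, function(s) !anyDuplicated(s), logical(1))))
  keys <- vapply(sets, paste, "", collapse = "\r")
  expect_false(anyDuplicated(keys) > 0)

  # exchangeability: the multiset of sizes is {5..20} x 50 for any seed
  expect_identical(sort(unique(sizes)), 5:20)
  expect_true(all(table(sizes) == 50))
  sets2 <- generate_candidate_sets(nm, seed = 71)
  expect_identical(sets, sets2)
  sets3 <- generate_candidate_sets(nm, seed = 72)
  expect_false(identical(sets, sets3))

  expect_error(generate_candidate_sets(paste0("v", 1:10)), "at least 20")
})

test_that("WAIC satisfies its decomposition identity and matches the naive formula", {
  set.seed(72)
  L <- matrix(rnorm(50 * 30), 50, 30)
  w <- waic(L)
  expect_identical(w$waic, -2 * (w$lppd - w$p_waic))       # exact identity
  lppd_naive <- sum(log(colMeans(exp(L))))
  p_naive <- sum(apply(L, 2, var))
  expect_equal(w$lppd, lppd_naive, tolerance = 1e-10)
  expect_equal(w$p_waic, p_naive, tolerance = 1e-10)
  expect_gte(w$p_waic, 0)

  # single draw: waic = -2 * sum(L) with a warning
  L1 <- matrix(rnorm(10), 1, 10)
  expect_warning(w1 <- waic(L1), "single")
  expect_equal(w1$waic, -2 * sum(L1), tolerance = 1e-12)

  # identical draws repeated: no effective parameters
  Lr <- matrix(rep(rnorm(10), each = 5), 5, 10)
  wr <- waic(Lr)
  expect_equal(wr$p_waic, 0, tolerance = 1e-12)
  expect_equal(wr$lppd, sum(Lr[1, ]), tolerance = 1e-12)

  # overflow-safe at extreme magnitudes
  wx <- waic(matrix(c(-1e4, -1e4 + 1, 800, 801), 2, 2))
  expect_true(is.finite(wx$waic))
})

test_that("the PA-stream spatial model is the ISDM restricted to PA data", {
  dat <- recovery_dataset(seed = 81)
  cfg <- quick_config(covariates = c("x1", "x2"))
  fit_pa <- fit_pa_gp_glm(dat$covariates, dat$pa, cfg)
  empty_pb <- pb_points(matrix(numeric(0), 0, 2))
  fit_ref <- fit_isdm(dat$covariates, dat$pa, empty_pb, cfg)
  expect_equal(fit_pa$summary$mean, fit_ref$summary$mean, tolerance = 1e-8)
  expect_equal(fit_pa$summary$sd, fit_ref$summary$sd, tolerance = 1e-8)

  # WAIC draws reproducible under the config seed
  fit_pa2 <- fit_pa_gp_glm(dat$covariates, dat$pa, cfg)
  expect_identical(fit_pa$loglik_draws, fit_pa2$loglik_draws)
  expect_identical(dim(fit_pa$loglik_draws), c(200L, nrow(dat$pa)))
})

test_that("WAIC ranking is a permutation and stable for duplicate candidates", {
  dat <- recovery_dataset(seed = 82)
  cands <- list(c("x1", "x2"), "x1", c("x1", "x2"))
  cfg <- quick_config()
  tab <- select_best(cands, dat$covariates, dat$pa, cfg)
  expect_identical(nrow(tab), 3L)
  expect_identical(sort(tab$covariates),
                   sort(vapply(cands, paste, "", collapse = "+")))
  expect_identical(tab$rank, 1:3)
  dup <- tab[tab$covariates == "x1+x2", "waic"]
  expect_equal(dup[1], dup[2], tolerance = 1e-8)   # same seed, same draws
})

test_that("failed candidate fits are ranked last, not dropped", {
  dat <- recovery_dataset(seed = 83)
  cands <- list("x1", "not_a_layer")
  tab <- select_best(cands, dat$covariates, dat$pa, quick_config())
  expect_identical(nrow(tab), 2L)
  bad <- tab[tab$covariates == "not_a_layer", ]
  expect_identical(bad$rank, 2L)
  expect_false(is.na(bad$error))
})

test_that("Huber regression matches OLS on clean data and resists a gross outlier", {
  set.seed(73)
  x <- rnorm(100)
  y <- 1 + 2 * x + rnorm(100, sd = 0.3)
  h <- huber_rlm(x, y)
  o <- stats::lm(y ~ x)
  expect_equal(h$slope, unname(coef(o)[2]), tolerance = 2e-2)
  expect_true(h$converged)

  exact <- huber_rlm(x, 2 * x + 1)
  expect_equal(exact$slope, 2, tolerance = 1e-9)
  expect_equal(exact$intercept, 1, tolerance = 1e-9)

  y2 <- y; y2[1] <- 60
  h2 <- huber_rlm(x, y2)
  o2 <- stats::lm(y2 ~ x)
  expect_lt(abs(h2$slope - 2), abs(unname(coef(o2)[2]) - 2))

  # every IRLS step decreases the Huber loss at the scale it was taken at
  expect_true(all(h2$objective_decrease >= -1e-8))
  expect_true(all(h$objective_decrease >= -1e-8))
  expect_error(huber_rlm(rep(1, 10), rnorm(10)), "constant")
  expect_error(huber_rlm(1:2, 1:2), "at least 3")
})

test_that("Huber IRLS agrees with the reference implementation on noisy data", {
  skip_if_not_installed("MASS")
  set.seed(74)
  x <- rnorm(200)
  y <- -0.5 + 1.3 * x + rt(200, df = 3) * 0.5
  h <- huber_rlm(x, y)
  m <- MASS::rlm(y ~ x, k = 1.345, maxit = 100)
  expect_equal(h$slope, unname(coef(m)[2]), tolerance = 1e-3)
  expect_equal(h$intercept, unname(coef(m)[1]), tolerance = 1e-3)
})

test_that("host-cover residuals vanish on exact fits, shift with perturbations, propagate NA", {
  g <- grid_spec(20, 20, 1)
  set.seed(75)
  cover <- raster_layer(g, matrix(runif(400, 0, 100), 20), name = "cover")
  lin <- raster_layer(g, 0.002 * cover$values + 0.1, name = "intensity")
  res0 <- host_cover_residuals(lin, cover)
  expect_lt(max(abs(res0$values)), 1e-8)

  # add +c to one region: its residuals rise by about c (bulk is downweighted,
  # not shifted)
  pert <- lin
  region <- 1:5
  pert$values[region, ] <- pert$values[region, ] + 0.3
  resp <- host_cover_residuals(pert, cover)
  expect_equal(mean(resp$values[region, ]) - mean(res0$values[region, ]),
               0.3, tolerance = 0.03)
  expect_lt(abs(mean(resp$values[-region, ])), 0.02)

  na_int <- lin
  na_int$values[1, 1] <- NA
  na_cov <- cover
  na_cov$values[2, 2] <- NA
  resna <- host_cover_residuals(na_int, na_cov)
  expect_true(is.na(resna$values[1, 1]))
  expect_true(is.na(resna$values[2, 2]))
  expect_identical(sum(is.na(resna$values)), 2L)

  expect_error(host_cover_residuals(lin, raster_layer(grid_spec(5, 5, 1), 1)),
               "same grid")
})
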