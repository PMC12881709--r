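#' Configuration for an integrated species distribution model fit
#'
#' @param covariates Character vector of covariate layer names entering the
#'   shared log-intensity linearly (may be empty).
#' @param max_edge_km Maximum spacing of the spatial basis nodes (default 5;
#'   the alternatives used for mesh-sensitivity checks are 10/20/30/40).
#' @param min_spacing_km Minimum basis node spacing (default 1 km, the
#'   covariate resolution).
#' @param extend_km Basis extension beyond the data bounding box (km).
#' @param e_vis Per-visit exposure linking intensity to the cloglog
#'   detection probability (default 1).
#' @param prior List of prior settings: \code{sigma0}, \code{alpha_sigma},
#'   \code{rho0}, \code{alpha_rho} calibrate the PC priors of both fields
#'   (defaults P(sigma > 1) = 0.05, P(rho < 10 km) = 0.05);
#'   \code{fixed_precision} is the normal prior precision of every fixed
#'   effect and intercept (default 1, mean 0).
#' @param sigma_grid,rho_grid Candidate values for the shared-field
#'   hyperparameters searched by empirical Bayes.
#' @param bias_sigma_grid,bias_rho_grid Candidate values for the
#'   presence-background bias field (profiled after the shared field; same
#'   PC prior calibration).
#' @param include_field Include the shared Matern field (default TRUE;
#'   FALSE fixes sigma = 0, i.e., no spatial structure).
#' @param include_bias_field Include the second field in the
#'   presence-background observation model (default TRUE when PB data are
#'   present).
#' @param max_iter,tol Inner Newton iteration cap and convergence tolerance
#'   on the step max-norm.
#' @param n_waic_draws Posterior draws used for pointwise WAIC
#'   log-likelihoods (default 1000).
#' @param seed Integer seed for posterior sampling.
#' @return A list of class \code{isdm_config}.
#' @export
isdm_config <- function(covariates = character(), max_edge_km = 5,
                        min_spacing_km = 1, extend_km = 20, e_vis = 1,
                        prior = list(), sigma_grid = c(0.1, 0.25, 0.5, 1, 2),
                        rho_grid = c(5, 10, 20, 40),
                        bias_sigma_grid = c(0.25, 0.5, 1),
                        bias_rho_grid = c(10, 20),
                        include_field = TRUE, include_bias_field = TRUE,
                        max_iter = 100L, tol = 1e-8, n_waic_draws = 1000L,
                        seed = 1L) {
  pr <- utils::modifyList(
    list(sigma0 = 1, alpha_sigma = 0.05, rho0 = 10, alpha_rho = 0.05,
         fixed_precision = 1), prior)
  stopifnot(max_edge_km >= min_spacing_km, e_vis > 0,
            pr$fixed_precision > 0, all(sigma_grid > 0), all(rho_grid > 0))
  structure(list(covariates = covariates, max_edge_km = max_edge_km,
                 min_spacing_km = min_spacing_km, extend_km = extend_km,
                 e_vis = e_vis, prior = pr, sigma_grid = sigma_grid,
                 rho_grid = rho_grid, bias_sigma_grid = bias_sigma_grid,
                 bias_rho_grid = bias_rho_grid,
                 include_field = include_field,
                 include_bias_field = include_bias_field,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_waic_draws = as.integer(n_waic_draws),
                 seed = as.integer(seed)),
            class = "isdm_config")
}

#' Berman-Turner quadrature at raster cell centres
#'
#' @param grid A \code{grid_spec}.
#' @param refine Integer subdivision factor (1 = cell centres; 2 splits each
#'   cell into 4 sub-cells, etc.).
#' @return List with \code{points} (matrix) and \code{weights} (km^2).
#' @export
quadrature_cells <- function(grid, refine = 1L) {
  stopifnot(inherits(grid, "grid_spec"), refine >= 1L)
  refine <- as.integer(refine)
  fine <- grid_spec(grid$nrows * refine, grid$ncols * refine,
                    grid$cell_km / refine, grid$origin)
  list(points = cell_centers(fine),
       weights = rep((grid$cell_km / refine)^2, fine$nrows * fine$ncols))
}

#' Presence-absence binomial log-likelihood under the cloglog link
#'
#' \eqn{\sum_i \log \mathrm{Bin}(k_i \mid n_i, p_i)} with
#' \eqn{p_i = 1 - \exp(-e_{vis} e^{\eta_i})}.  Probabilities are clamped to
#' \code{[1e-12, 1 - 1e-12]} and evaluated with \code{expm1}-grade numerics.
#'
#' @param eta Linear predictor at the PA sites.
#' @param pa A \code{pa_table} (row order matching \code{eta}).
#' @param e_vis Per-visit exposure.
#' @return Log-likelihood (scalar).
#' @export
pa_loglik <- function(eta, pa, e_vis = 1) {
  stopifnot(inherits(pa, "pa_table"), length(eta) == nrow(pa))
  mu <- e_vis * exp(eta)
  p <- pmin(pmax(-expm1(-mu), 1e-12), 1 - 1e-12)
  sum(lchoose(pa$n_surveys, pa$n_detections) +
        pa$n_detections * log(p) + (pa$n_surveys - pa$n_detections) * log1p(-p))
}

#' Thinned-Poisson point-process log-likelihood (Berman-Turner form)
#'
#' \eqn{\sum_j \eta(s_j) - \sum_q w_q e^{\eta(q)}}: the log density of the
#' (possibly bias-thinned) Poisson process up to a data-only constant, with
#' the intensity integral evaluated by cell-centre quadrature.  The linear
#' predictors should already include the bias field where one is modelled.
#'
#' @param eta_points Linear predictor at the observed points.
#' @param eta_quad Linear predictor at the quadrature nodes.
#' @param quad_weights Quadrature weights (km^2).
#' @return Log-likelihood (scalar).
#' @export
pb_loglik <- function(eta_points, eta_quad, quad_weights) {
  stopifnot(length(eta_quad) == length(quad_weights))
  sum(eta_points) - sum(quad_weights * exp(eta_quad))
}

# snap point locations to the centre of their containing cell: the model
# operates at covariate resolution and sub-cell position carries no
# information
snap_points <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  j <- pmin(pmax(ceiling((pts[, 1] - grid$origin[1]) / grid$cell_km), 1L),
            grid$ncols)
  i <- pmin(pmax(ceiling((pts[, 2] - grid$origin[2]) / grid$cell_km), 1L),
            grid$nrows)
  cbind(grid$origin[1] + (j - 0.5) * grid$cell_km,
        grid$origin[2] + (i - 0.5) * grid$cell_km)
}

# covariate design matrix at point locations (values of the containing cell)
covariate_design <- function(covariates, names, pts) {
  if (!length(names)) return(matrix(0, nrow(pts), 0))
  miss <- setdiff(names, names(covariates))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  vapply(names, function(nm) lambda_at(covariates[[nm]], pts),
         numeric(nrow(pts)))
}

#' Linear predictor of a latent state at point locations
#'
#' \eqn{\eta(s) = \alpha + \sum_k \beta_k x_k(s) + \xi(s)}, with the
#' presence-background stream using its own intercept and adding the bias
#' field \eqn{b(s)}.
#'
#' @param state List with \code{alpha_pa}, \code{alpha_pb}, \code{beta}
#'   (named), \code{xi} and \code{b} (basis-node values; may be NULL).
#' @param covariates Named list of \code{pest_raster} layers.
#' @param locations Matrix (n x 2) of km coordinates.
#' @param mesh The \code{mesh_basis} carrying \code{xi} and \code{b}.
#' @param stream \code{"pa"}, \code{"pb"} or \code{"process"} (process =
#'   PB intercept, no bias field).
#' @return Numeric vector of linear predictor values.
#' @export
linear_predictor <- function(state, covariates, locations, mesh,
                             stream = c("process", "pa", "pb")) {
  stream <- match.arg(stream)
  locations <- matrix(as.numeric(locations), ncol = 2)
  alpha <- switch(stream, pa = state$alpha_pa, state$alpha_pb)
  if (is.null(alpha)) alpha <- 0
  eta <- rep(alpha, nrow(locations))
  if (length(state$beta)) {
    X <- covariate_design(covariates, names(state$beta), locations)
    eta <- eta + as.numeric(X %*% state$beta)
  }
  A <- NULL
  if (!is.null(state$xi)) {
    A <- mesh_projector(mesh, locations)
    eta <- eta + as.numeric(A %*% state$xi)
  }
  if (stream == "pb" && !is.null(state$b)) {
    if (is.null(A)) A <- mesh_projector(mesh, locations)
    eta <- eta + as.numeric(A %*% state$b)
  }
  eta
}

# gradient and curvature of the PA log-likelihood wrt eta
pa_eta_derivs <- function(eta, n, k, e_vis) {
  mu <- pmin(e_vis * exp(eta), 1e8)
  emu <- exp(-mu)
  p <- pmin(pmax(-expm1(-mu), 1e-12), 1 - 1e-12)
  u <- mu * emu / p
  g <- k * u - (n - k) * mu
  du <- (mu * emu * (1 - mu) * p - (mu * emu)^2) / p^2
  h <- k * du - (n - k) * mu
  list(g = g, w = pmax(-h, 1e-12))   # w = negative curvature (concave ll)
}

# assemble sparse block design [1_pa | 1_pb | X | A_xi | A_b] for a stream
make_design <- function(n, layout, which_int, X, A, with_bias) {
  blocks <- list()
  z <- function(cols) Matrix::Matrix(0, n, cols, sparse = TRUE)
  blocks$a_pa <- if (layout$n_apa) {
    if (which_int == "pa") Matrix::Matrix(1, n, 1, sparse = TRUE) else z(1)
  }
  blocks$a_pb <- if (layout$n_apb) {
    if (which_int == "pb") Matrix::Matrix(1, n, 1, sparse = TRUE) else z(1)
  }
  blocks$beta <- if (layout$p) Matrix::Matrix(X, sparse = TRUE) else NULL
  blocks$xi <- if (layout$m) { if (is.null(A)) z(layout$m) else A } else NULL
  blocks$b <- if (layout$mb) {
    if (with_bias && !is.null(A)) A else z(layout$mb)
  } else NULL
  do.call(cbind, Filter(Negate(is.null), blocks))
}

# one empirical-Bayes Laplace evaluation at fixed hyperparameters.
# Returns mode, posterior precision Cholesky, and the approximate log
# marginal likelihood (up to data-only constants).
laplace_fit <- function(parts, Q_xi, Q_b, config) {
  layout <- parts$layout
  d <- layout$d
  # prior precision
  prec_fix <- rep(config$prior$fixed_precision, layout$n_apa + layout$n_apb + layout$p)
  Q0 <- Matrix::bdiag(
    c(list(Matrix::Diagonal(length(prec_fix), prec_fix)),
      if (layout$m) list(Q_xi), if (layout$mb) list(Q_b)))
  Q0 <- Matrix::forceSymmetric(Q0)
  x <- rep(0, d)
  f_of <- function(x) {
    ll <- 0
    if (!is.null(parts$D_pa)) {
      eta <- as.numeric(parts$D_pa %*% x)
      mu <- pmin(config$e_vis * exp(eta), 1e8)
      p <- pmin(pmax(-expm1(-mu), 1e-12), 1 - 1e-12)
      ll <- ll + sum(parts$k * log(p) + (parts$n_vis - parts$k) * log1p(-p))
    }
    if (!is.null(parts$D_quad)) {
      eta_q <- as.numeric(parts$D_quad %*% x)
      ll <- ll - sum(parts$w_quad * exp(pmin(eta_q, 50)))
      if (!is.null(parts$D_pb) && nrow(parts$D_pb))
        ll <- ll + sum(as.numeric(parts$D_pb %*% x))
    }
    ll - 0.5 * sum(x * as.numeric(Q0 %*% x))
  }
  f_old <- f_of(x)
  trace <- f_old
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    grad <- -as.numeric(Q0 %*% x)
    H <- Q0
    if (!is.null(parts$D_pa)) {
      eta <- as.numeric(parts$D_pa %*% x)
      dv <- pa_eta_derivs(eta, parts$n_vis, parts$k, config$e_vis)
      grad <- grad + as.numeric(Matrix::crossprod(parts$D_pa, dv$g))
      H <- H + Matrix::crossprod(parts$D_pa, dv$w * parts$D_pa)
    }
    if (!is.null(parts$D_quad)) {
      eta_q <- as.numeric(parts$D_quad %*% x)
      lam_w <- parts$w_quad * exp(pmin(eta_q, 50))
      grad <- grad - as.numeric(Matrix::crossprod(parts$D_quad, lam_w))
      if (!is.null(parts$D_pb) && nrow(parts$D_pb))
        grad <- grad + as.numeric(Matrix::crossprod(
          parts$D_pb, rep(1, nrow(parts$D_pb))))
      H <- H + Matrix::crossprod(parts$D_quad, lam_w * parts$D_quad)
    }
    H <- Matrix::forceSymmetric(H)
    step <- as.numeric(Matrix::solve(H, grad))
    # backtracking line search keeps the joint log posterior monotone
    t <- 1
    repeat {
      x_new <- x + t * step
      f_new <- f_of(x_new)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      t <- t / 2
      if (t < 1e-8) { x_new <- x; f_new <- f_old; break }
    }
    delta <- max(abs(x_new - x))
    x <- x_new
    trace <- c(trace, f_new)
    f_old <- f_new
    if (delta < config$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("inner Newton optimisation did not reach tolerance after ",
            config$max_iter, " iterations (last step ",
            formatC(max(abs(step)), format = "e", digits = 2), ")")
  H <- Matrix::forceSymmetric(H)
  chH <- Matrix::Cholesky(H, perm = TRUE, LDL = FALSE)
  ld_H <- 2 * Matrix::determinant(chH, sqrt = TRUE)$modulus
  ld_Q0 <- as.numeric(Matrix::determinant(Q0, logarithm = TRUE)$modulus)
  # log p(y | theta) ~ ll(xhat) - 0.5 xhat' Q0 xhat + 0.5 logdet Q0 - 0.5 logdet H
  lml <- f_old + 0.5 * ld_Q0 - 0.5 * as.numeric(ld_H)
  list(x = x, H = H, chol_H = chH, lml = lml, trace = trace,
       converged = converged, Q0 = Q0)
}

#' Fit the integrated species distribution model
#'
#' Joint model: a log-Gaussian Cox process whose log intensity is linear in
#' the covariates plus a shared Matern field; the presence-absence stream
#' contributes a binomial likelihood through the cloglog link, the
#' presence-background stream a thinned-Poisson point-process likelihood
#' with its own intercept and (optionally) a second bias field.  Inference
#' is empirical-Bayes Laplace: an inner Newton optimisation of the latent
#' Gaussian state at fixed hyperparameters, and an outer profiled grid
#' search over (sigma, rho) of the shared field and then of the bias field,
#' maximising the Laplace-approximate marginal likelihood plus the PC prior.
#'
#' @param covariates Named list of (standardised) \code{pest_raster} layers.
#' @param pa A \code{pa_table} or NULL.
#' @param pb A \code{pb_points} data frame or NULL (at least one stream must
#'   be non-empty).
#' @param config An \code{isdm_config}.
#' @param grid Optional \code{grid_spec} for the quadrature domain; defaults
#'   to the grid of the first covariate layer.
#' @return An object of class \code{isdm_fit}: posterior summary table
#'   (means, sds, 95\% intervals of the fixed effects, averaged over the
#'   hyperparameter grid with marginal-likelihood weights so hyperparameter
#'   uncertainty is propagated), the modal hyperparameters and the grid
#'   weights (\code{hyper_weights}), log marginal likelihood, the latent
#'   mode and posterior precision at the modal hyperparameters, and
#'   bookkeeping needed for prediction.
#' @export
fit_isdm <- function(covariates, pa = NULL, pb = NULL, config = isdm_config(),
                     grid = NULL) {
  has_pa <- !is.null(pa) && nrow(pa) > 0
  has_pb <- !is.null(pb) && nrow(pb) > 0
  if (!has_pa && !has_pb) stop("at least one data stream must be non-empty")
  if (has_pa) stopifnot(inherits(pa, "pa_table"))
  if (is.null(grid)) {
    if (!length(covariates)) stop("supply 'grid' when there are no covariates")
    grid <- covariates[[1]]$grid
  }
  cn <- config$covariates
  mesh <- build_mesh(grid, config$max_edge_km, config$min_spacing_km,
                     config$extend_km)
  m <- if (config$include_field) mesh$n_nodes else 0L
  mb <- if (has_pb && config$include_bias_field) mesh$n_nodes else 0L
  layout <- list(n_apa = as.integer(has_pa), n_apb = as.integer(has_pb),
                 p = length(cn), m = m, mb = mb)
  layout$d <- layout$n_apa + layout$n_apb + layout$p + m + mb
  parts <- list(layout = layout)
  if (has_pa) {
    sites <- snap_points(grid, cbind(pa$x_km, pa$y_km))
    A_pa <- if (m) mesh_projector(mesh, sites) else NULL
    X_pa <- covariate_design(covariates, cn, sites)
    parts$D_pa <- make_design(nrow(pa), layout, "pa", X_pa, A_pa, FALSE)
    parts$n_vis <- pa$n_surveys
    parts$k <- pa$n_detections
  }
  if (has_pb) {
    quad <- quadrature_cells(grid)
    # quadrature nodes and PB points both live on the PB stream
    A_q <- if (m || mb) mesh_projector(mesh, quad$points) else NULL
    X_q <- covariate_design(covariates, cn, quad$points)
    parts$D_quad <- make_design(nrow(quad$points), layout, "pb", X_q, A_q, TRUE)
    parts$w_quad <- quad$weights
    pts <- cbind(pb$x_km, pb$y_km)
    if (nrow(pts)) {
      inside <- pts[, 1] >= grid$origin[1] &
        pts[, 1] <= grid$origin[1] + grid$ncols * grid$cell_km &
        pts[, 2] >= grid$origin[2] &
        pts[, 2] <= grid$origin[2] + grid$nrows * grid$cell_km
      if (!all(inside)) stop("presence-background point outside domain")
      pts_c <- snap_points(grid, pts)
      A_p <- if (m || mb) mesh_projector(mesh, pts_c) else NULL
      X_p <- covariate_design(covariates, cn, pts_c)
      parts$D_pb <- make_design(nrow(pts), layout, "pb", X_p, A_p, TRUE)
    } else {
      parts$D_pb <- make_design(0L, layout, "pb",
                                matrix(0, 0, layout$p), NULL, TRUE)
    }
  }
  pr <- config$prior
  pc_obj <- function(sg, rg) {
    pc_prior_sigma_density(sg, pr$sigma0, pr$alpha_sigma, log = TRUE) +
      pc_prior_rho_density(rg, pr$rho0, pr$alpha_rho, log = TRUE)
  }
  hyper <- list(sigma = NA_real_, rho = NA_real_,
                bias_sigma = NA_real_, bias_rho = NA_real_)
  nfix <- layout$n_apa + layout$n_apb + layout$p
  fix_moments <- function(cand) {
    if (!nfix) return(list(mean = numeric(), sd = numeric()))
    E <- Matrix::sparseMatrix(i = seq_len(nfix), j = seq_len(nfix), x = 1,
                              dims = c(layout$d, nfix))
    V <- Matrix::solve(cand$H, E)
    list(mean = cand$x[seq_len(nfix)],
         sd = sqrt(pmax(Matrix::diag(Matrix::crossprod(E, V)), 0)))
  }
  best <- NULL
  grid_evals <- list()       # every evaluated hyper combo, for model averaging
  note_eval <- function(cand, sg, rg, bsg, brg, score) {
    key <- paste(sg, rg, bsg, brg, sep = "|")
    if (!is.null(grid_evals[[key]])) return()
    mom <- fix_moments(cand)
    grid_evals[[key]] <<- list(score = score, mean = mom$mean, sd = mom$sd,
                               sigma = sg, rho = rg,
                               bias_sigma = bsg, bias_rho = brg)
  }
  if (m) {
    # profile 1: shared field grid, bias field held at its PC prior medians
    bias_hold <- if (mb) hyper_params(
      stats::median(config$bias_sigma_grid),
      stats::median(config$bias_rho_grid))
    Q_b_hold <- if (mb) matern_precision(mesh, bias_hold)
    bh_s <- if (mb) bias_hold$sigma else NA_real_
    bh_r <- if (mb) bias_hold$rho else NA_real_
    for (sg in config$sigma_grid) for (rg in config$rho_grid) {
      Q_xi <- matern_precision(mesh, hyper_params(sg, rg))
      cand <- laplace_fit(parts, Q_xi, Q_b_hold, config)
      score <- cand$lml + pc_obj(sg, rg) +
        if (mb) pc_obj(bh_s, bh_r) else 0
      note_eval(cand, sg, rg, bh_s, bh_r, score)
      if (is.null(best) || score > best$score) {
        best <- c(cand, list(score = score))
        hyper$sigma <- sg; hyper$rho <- rg
        if (mb) { hyper$bias_sigma <- bh_s; hyper$bias_rho <- bh_r }
      }
    }
    if (mb) {
      # profile 2: bias field grid at the selected shared hyperparameters
      Q_xi <- matern_precision(mesh, hyper_params(hyper$sigma, hyper$rho))
      for (sg in config$bias_sigma_grid) for (rg in config$bias_rho_grid) {
        if (sg == hyper$bias_sigma && rg == hyper$bias_rho) next
        Q_b <- matern_precision(mesh, hyper_params(sg, rg))
        cand <- laplace_fit(parts, Q_xi, Q_b, config)
        score <- cand$lml + pc_obj(hyper$sigma, hyper$rho) + pc_obj(sg, rg)
        note_eval(cand, hyper$sigma, hyper$rho, sg, rg, score)
        if (score > best$score) {
          best <- c(cand, list(score = score))
          hyper$bias_sigma <- sg; hyper$bias_rho <- rg
        }
      }
    }
  } else {
    Q_b <- if (mb) matern_precision(
      mesh, hyper_params(stats::median(config$bias_sigma_grid),
                         stats::median(config$bias_rho_grid)))
    if (mb) { hyper$bias_sigma <- stats::median(config$bias_sigma_grid)
              hyper$bias_rho <- stats::median(config$bias_rho_grid) }
    best <- laplace_fit(parts, NULL, Q_b, config)
    best$score <- best$lml
    note_eval(best, NA_real_, NA_real_, hyper$bias_sigma, hyper$bias_rho,
              best$score)
  }
  # fixed-effect posterior summaries: average over the hyperparameter grid
  # with marginal-likelihood * PC-prior weights, so hyperparameter
  # uncertainty propagates into the reported means and sds
  nm <- c(if (has_pa) "alpha_pa", if (has_pb) "alpha_pb",
          if (layout$p) paste0("beta_", cn))
  scores <- vapply(grid_evals, `[[`, numeric(1), "score")
  wts <- exp(scores - max(scores)); wts <- wts / sum(wts)
  means <- sds <- numeric(nfix)
  if (nfix) {
    M <- vapply(grid_evals, `[[`, numeric(nfix), "mean")
    S <- vapply(grid_evals, `[[`, numeric(nfix), "sd")
    M <- matrix(M, nfix); S <- matrix(S, nfix)
    means <- as.numeric(M %*% wts)
    second <- as.numeric((S^2 + M^2) %*% wts)
    sds <- sqrt(pmax(second - means^2, 0))
  }
  hyper_weights <- data.frame(
    sigma = vapply(grid_evals, `[[`, numeric(1), "sigma"),
    rho = vapply(grid_evals, `[[`, numeric(1), "rho"),
    bias_sigma = vapply(grid_evals, `[[`, numeric(1), "bias_sigma"),
    bias_rho = vapply(grid_evals, `[[`, numeric(1), "bias_rho"),
    weight = wts, row.names = NULL)
  summ <- data.frame(parameter = nm, mean = means, sd = sds,
                     lo95 = means - 1.96 * sds,
                     hi95 = means + 1.96 * sds,
                     row.names = NULL)
  idx <- list(
    alpha_pa = if (has_pa) 1L,
    alpha_pb = if (has_pb) layout$n_apa + 1L,
    beta = if (layout$p) layout$n_apa + layout$n_apb + seq_len(layout$p),
    xi = if (m) nfix + seq_len(m),
    b = if (mb) nfix + m + seq_len(mb))
  structure(list(summary = summ, hyper = hyper, hyper_weights = hyper_weights,
                 lml = best$lml,
                 score = best$score, x = best$x, H = best$H,
                 chol_H = best$chol_H, trace = best$trace,
                 converged = best$converged, layout = layout, idx = idx,
                 mesh = mesh, grid = grid, config = config,
                 covariate_names = cn, has_pa = has_pa, has_pb = has_pb),
            class = "isdm_fit")
}

#' @export
print.isdm_fit <- function(x, ...) {
  cat(sprintf("<isdm_fit> %s; %d latent values; lml %.2f\n",
              paste(c(if (x$has_pa) "PA", if (x$has_pb) "PB"), collapse = "+"),
              x$layout$d, x$lml))
  cat(sprintf("  field: sigma=%.3g rho=%.3g; bias field: sigma=%.3g rho=%.3g\n",
              x$hyper$sigma, x$hyper$rho, x$hyper$bias_sigma, x$hyper$bias_rho))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Coefficient table of an ISDM fit
#'
#' @param object An \code{isdm_fit}.
#' @param ... Unused.
#' @return The posterior summary data frame.
#' @export
coef.isdm_fit <- function(object, ...) object$summary

# design matrix for the ecological process at arbitrary points
process_design <- function(fit, covariates, pts) {
  layout <- fit$layout
  X <- covariate_design(covariates, fit$covariate_names, pts)
  A <- if (layout$m) mesh_projector(fit$mesh, pts) else NULL
  # process intercept: the PB intercept anchors the intensity scale when the
  # point stream is present, otherwise the PA intercept
  which_int <- if (fit$has_pb) "pb" else "pa"
  make_design(nrow(pts), layout, which_int, X, A, with_bias = FALSE)
}

#' Posterior mean and sd maps of the process intensity
#'
#' Computes the Gaussian-approximate posterior of the log intensity
#' \eqn{\eta} at the output cells and maps it to the intensity scale with
#' lognormal moments: mean \eqn{e^{\mu + v/2}}, sd \eqn{mean \sqrt{e^v - 1}}.
#' The presence-background bias field models observation, not ecology, and
#' is excluded.
#'
#' @param fit An \code{isdm_fit}.
#' @param covariates Named list of covariate rasters (on any grid covering
#'   the output grid).
#' @param out_grid Output \code{grid_spec}; defaults to the fitted grid.
#' @return List with \code{mean} and \code{sd} rasters.
#' @export
predict_intensity <- function(fit, covariates, out_grid = NULL) {
  stopifnot(inherits(fit, "isdm_fit"))
  if (is.null(out_grid)) out_grid <- fit$grid
  pts <- cell_centers(out_grid)
  if (any(pts[, 1] < fit$grid$origin[1] |
          pts[, 1] > fit$grid$origin[1] + fit$grid$ncols * fit$grid$cell_km |
          pts[, 2] < fit$grid$origin[2] |
          pts[, 2] > fit$grid$origin[2] + fit$grid$nrows * fit$grid$cell_km))
    stop("output grid extends outside the fitted domain")
  D <- process_design(fit, covariates, pts)
  mu <- as.numeric(D %*% fit$x)
  V <- Matrix::solve(fit$H, Matrix::t(D))          # d x n
  v <- pmax(Matrix::rowSums(as.matrix(Matrix::t(V)) * D), 0)
  mean_v <- exp(mu + v / 2)
  sd_v <- mean_v * sqrt(expm1(v))
  list(mean = raster_layer(out_grid, matrix(mean_v, out_grid$nrows),
                           name = "intensity_mean", units = "points/km^2"),
       sd = raster_layer(out_grid, matrix(sd_v, out_grid$nrows),
                         name = "intensity_sd", units = "points/km^2"))
}

#' Rescale intensity mean and sd maps to the unit interval
#'
#' The mean map is min-max rescaled to [0, 1]; the sd map is divided by the
#' same positive factor (no shift), preserving the coefficient of variation
#' pattern.
#'
#' @param mean,sd \code{pest_raster} layers on the same grid.
#' @return List with \code{mean01} and \code{sd01} rasters.
#' @export
rescale_unit <- function(mean, sd) {
  stopifnot(inherits(mean, "pest_raster"), inherits(sd, "pest_raster"),
            same_grid(mean, sd))
  rng <- range(mean$values, finite = TRUE)
  if (diff(rng) <= 0) stop("mean raster is constant; cannot rescale")
  list(mean01 = raster_layer(mean$grid, (mean$values - rng[1]) / diff(rng),
                             name = paste0(mean$name, "_01")),
       sd01 = raster_layer(sd$grid, sd$values / diff(rng),
                           name = paste0(sd$name, "_01")))
}

#' Back-door-adjusted effect of a focal driver on intensity
#'
#' For each inclusion-minimal back-door adjustment set implied by the causal
#' DAG, fits an ISDM whose covariates are the focal variable plus the set,
#' and reports the focal coefficient's posterior mean and 95\% interval.
#'
#' @param focal Focal covariate name (must be in \code{covariates} and the
#'   DAG).
#' @param maximal_dag A \code{pest_dag} with outcome node \code{outcome}.
#' @param covariates Named list of standardised rasters.
#' @param pa,pb Observation data (either may be NULL).
#' @param config An \code{isdm_config}; its \code{covariates} field is
#'   overridden per adjustment set.
#' @param outcome Outcome node label (default \code{"y"}).
#' @return Data frame with one row per adjustment set: \code{focal},
#'   \code{adjustment_set}, \code{mean}, \code{sd}, \code{lo95}, \code{hi95};
#'   fits attached as attribute \code{"fits"}.
#' @export
estimate_driver_effect <- function(focal, maximal_dag, covariates, pa, pb,
                                   config = isdm_config(), outcome = "y") {
  stopifnot(inherits(maximal_dag, "pest_dag"))
  if (!focal %in% names(covariates)) stop("focal not among covariates")
  adj <- minimal_adjustment_sets(maximal_dag, focal, outcome)
  rows <- list(); fits <- list()
  for (Z in adj$sets) {
    miss <- setdiff(Z, names(covariates))
    if (length(miss))
      stop("adjustment set needs unavailable covariate(s): ",
           paste(miss, collapse = ", "))
    cfg <- config
    cfg$covariates <- c(focal, Z)
    fit <- fit_isdm(covariates, pa, pb, cfg)
    row <- fit$summary[fit$summary$parameter == paste0("beta_", focal), ]
    lab <- if (length(Z)) paste(Z, collapse = "+") else "(unadjusted)"
    rows[[lab]] <- data.frame(focal = focal, adjustment_set = lab,
                              mean = row$mean, sd = row$sd,
                              lo95 = row$lo95, hi95 = row$hi95)
    fits[[lab]] <- fit
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "fits") <- fits
  out
}

#' Posterior draws of the latent state from a Laplace fit
#'
#' @param fit An \code{isdm_fit}.
#' @param n_draws Number of draws.
#' @param seed Optional integer seed.
#' @return Matrix (d x n_draws) of draws from N(mode, H^-1).
#' @export
sample_posterior <- function(fit, n_draws = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "isdm_fit"))
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(fit$layout$d * n_draws), fit$layout$d, n_draws)
  y <- Matrix::solve(fit$chol_H, z, system = "Lt")
  as.matrix(Matrix::solve(fit$chol_H, y, system = "Pt")) + fit$x
}
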