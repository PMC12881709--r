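#' Random candidate covariate sets for WAIC search
#'
#' Draws, for every set size from \code{min_size} to \code{max_size},
#' \code{per_size} distinct covariate subsets sampled uniformly without
#' replacement within a set; with the defaults this yields
#' (20 - 5 + 1) x 50 = 800 candidate models.  Duplicate sets are resampled
#' with bounded retries so the candidate list contains no repeats.
#'
#' @param names Character vector of available covariate names (at least
#'   \code{max_size} of them).
#' @param min_size,max_size Size bounds (defaults 5 and 20).
#' @param per_size Sets per size (default 50).
#' @param seed Integer seed.
#' @param max_retries Retry bound per duplicate before giving up.
#' @return List of character vectors (each sorted), length
#'   \code{(max_size - min_size + 1) * per_size}.
#' @export
generate_candidate_sets <- function(names, min_size = 5, max_size = 20,
                                    per_size = 50, seed = 1L,
                                    max_retries = 1000L) {
  if (length(names) < max_size)
    stop("need at least ", max_size, " covariates, got ", length(names))
  if (anyDuplicated(names)) stop("covariate names must be unique")
  stopifnot(min_size >= 1, max_size >= min_size)
  set.seed(seed)
  out <- list(); seen <- new.env(parent = emptyenv())
  for (size in min_size:max_size) {
    for (r in seq_len(per_size)) {
      for (try in seq_len(max_retries)) {
        s <- sort(sample(names, size))
        key <- paste(s, collapse = "\r")
        if (is.null(seen[[key]])) { seen[[key]] <- TRUE; break }
        if (try == max_retries)
          stop("could not draw ", per_size, " distinct sets of size ", size)
      }
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

#' Binomial-cloglog spatial model on the presence-absence stream
#'
#' The ISDM machinery restricted to the presence-absence data: the same
#' shared Matern field and prior distributions, no point-process stream.
#' Used for WAIC-based covariate search, where the point-process likelihood
#' does not admit a well-defined pointwise WAIC.  Attaches \code{S} posterior
#' draws of the per-site log-likelihood for WAIC.
#'
#' @param covariates Named list of standardised rasters.
#' @param pa A \code{pa_table}.
#' @param config An \code{isdm_config}; \code{n_waic_draws} and \code{seed}
#'   govern the attached draws.
#' @return An \code{isdm_fit} with an extra \code{loglik_draws} matrix
#'   (draws x sites).
#' @export
fit_pa_gp_glm <- function(covariates, pa, config = isdm_config()) {
  stopifnot(inherits(pa, "pa_table"), nrow(pa) > 0)
  fit <- fit_isdm(covariates, pa = pa, pb = NULL, config = config)
  S <- config$n_waic_draws
  draws <- sample_posterior(fit, S, seed = config$seed)
  sites <- snap_points(fit$grid, cbind(pa$x_km, pa$y_km))
  A <- if (fit$layout$m) mesh_projector(fit$mesh, sites) else NULL
  X <- covariate_design(covariates, fit$covariate_names, sites)
  D <- make_design(nrow(pa), fit$layout, "pa", X, A, FALSE)
  eta <- as.matrix(D %*% draws)                   # sites x draws
  mu <- config$e_vis * exp(eta)
  p <- pmin(pmax(-expm1(-mu), 1e-12), 1 - 1e-12)
  ll <- lchoose(pa$n_surveys, pa$n_detections) +
    pa$n_detections * log(p) + (pa$n_surveys - pa$n_detections) * log1p(-p)
  fit$loglik_draws <- t(ll)                       # draws x sites
  fit
}

#' Widely applicable information criterion from pointwise log-likelihoods
#'
#' \eqn{lppd = \sum_i \log( S^{-1} \sum_s e^{L_{si}} )} (overflow-safe
#' log-mean-exp), \eqn{p_{waic} = \sum_i Var_s(L_{si})} (sample variance,
#' denominator S - 1) and \eqn{waic = -2 (lppd - p_{waic})}.
#'
#' @param pointwise_loglik Matrix of log-likelihood values, S draws (rows) by
#'   n observations (columns); all entries finite.
#' @return Object of class \code{waic_result} with \code{lppd},
#'   \code{p_waic}, \code{waic} and the pointwise contributions.
#' @export
waic <- function(pointwise_loglik) {
  L <- as.matrix(pointwise_loglik)
  stopifnot(nrow(L) >= 1, ncol(L) >= 1, all(is.finite(L)))
  S <- nrow(L)
  mx <- apply(L, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(L, 2, mx)))) # log-mean-exp per column
  if (S == 1L) {
    warning("single posterior draw: p_waic set to 0 (variance undefined)")
    p_i <- rep(0, ncol(L))
  } else {
    p_i <- apply(L, 2, stats::var)
  }
  lppd <- sum(lppd_i); p_waic <- sum(p_i)
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic),
                 pointwise = data.frame(lppd = lppd_i, p_waic = p_i)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("<waic_result> waic %.2f (lppd %.2f, p_waic %.2f, n %d)\n",
              x$waic, x$lppd, x$p_waic, nrow(x$pointwise)))
  invisible(x)
}

#' Rank candidate covariate sets by WAIC on the presence-absence stream
#'
#' Fits each candidate with \code{\link{fit_pa_gp_glm}}, computes WAIC and
#' returns the candidates ranked by ascending WAIC (ties broken by fewer
#' covariates, then lexicographically).  Individual fit failures are
#' recorded and ranked last, never dropped.
#'
#' @param candidates List of character vectors (covariate names).
#' @param covariates Named list of standardised rasters.
#' @param pa A \code{pa_table}.
#' @param config Base \code{isdm_config}; the covariate field is overridden
#'   per candidate.
#' @return Data frame with columns \code{rank}, \code{waic}, \code{lppd},
#'   \code{p_waic}, \code{n_covariates}, \code{covariates}, \code{error}.
#' @export
select_best <- function(candidates, covariates, pa, config = isdm_config()) {
  stopifnot(length(candidates) >= 1)
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    cfg <- config
    cfg$covariates <- cand
    res <- tryCatch({
      f <- fit_pa_gp_glm(covariates, pa, cfg)
      w <- waic(f$loglik_draws)
      data.frame(waic = w$waic, lppd = w$lppd, p_waic = w$p_waic,
                 n_covariates = length(cand),
                 covariates = paste(cand, collapse = "+"),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(waic = Inf, lppd = NA_real_, p_waic = NA_real_,
                 n_covariates = length(cand),
                 covariates = paste(cand, collapse = "+"),
                 error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$waic, tab$n_covariates, tab$covariates)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Huber robust simple linear regression by IRLS
#'
#' Iteratively reweighted least squares with the Huber psi function: weight
#' 1 for standardised residuals within \code{k}, else \code{k s / |r|}, with
#' scale \eqn{s = \mathrm{median}|r| / 0.6745} re-estimated each iteration.
#' Converges when the maximum parameter change falls below \code{tol}.
#'
#' @param x,y Numeric vectors (>= 3 finite pairs; \code{x} non-constant).
#' @param k Huber tuning constant (default 1.345, 95\% Gaussian efficiency).
#' @param tol Convergence tolerance on parameter change.
#' @param max_iter Iteration cap.
#' @return Object of class \code{robust_fit}: \code{intercept}, \code{slope},
#'   \code{scale}, \code{residuals}, \code{weights}, \code{iterations},
#'   \code{converged}, \code{objective} (per-iteration Huber loss) and
#'   \code{objective_decrease} (the within-iteration loss reduction at the
#'   iteration's own scale; non-negative for every step).
#' @export
huber_rlm <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 50L) {
  ok <- is.finite(x) & is.finite(y)
  xs <- x[ok]; ys <- y[ok]
  if (length(xs) < 3) stop("need at least 3 finite (x, y) pairs")
  if (stats::sd(xs) == 0) stop("x is constant; slope is not identifiable")
  b <- stats::coef(stats::lm(ys ~ xs))            # OLS start
  huber_loss <- function(r, s) {
    a <- abs(r / s)
    sum(ifelse(a <= k, 0.5 * a^2, k * a - 0.5 * k^2)) * s^2
  }
  obj <- numeric(); decrease <- numeric()
  w <- rep(1, length(xs)); s <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- ys - b[1] - b[2] * xs
    s <- stats::median(abs(r)) / 0.6745
    if (s <= 0) { converged <- TRUE; obj <- c(obj, 0); break }
    a <- abs(r / s)
    w <- ifelse(a <= k, 1, k / a)
    fit <- stats::lm.wfit(cbind(1, xs), ys, w)
    b_new <- fit$coefficients
    # each IRLS step decreases the Huber loss at the scale it was taken at
    obj_new <- huber_loss(ys - b_new[1] - b_new[2] * xs, s)
    obj <- c(obj, obj_new)
    decrease <- c(decrease, huber_loss(r, s) - obj_new)
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Huber IRLS did not converge in ", max_iter,
            " iterations (last change ", formatC(delta, format = "e",
                                                 digits = 2), ")")
  r_all <- y - b[1] - b[2] * x
  structure(list(intercept = unname(b[1]), slope = unname(b[2]), scale = s,
                 residuals = r_all, weights = w, iterations = length(obj),
                 converged = converged, objective = obj,
                 objective_decrease = decrease),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> y = %.4g + %.4g x (scale %.4g, %d iterations%s)\n",
              x$intercept, x$slope, x$scale, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Residuals of predicted intensity against host-species cover
#'
#' Robust-regresses the intensity map on the host cover map and returns the
#' residual raster: positive cells carry more predicted pest/disease burden
#' than expected for their level of host cover, negative cells less.
#' Missing cells in either layer propagate as missing.
#'
#' @param intensity \code{pest_raster} (typically the 0-1 rescaled posterior
#'   mean at prediction resolution).
#' @param cover \code{pest_raster} of host cover on the same grid.
#' @param ... Passed to \code{\link{huber_rlm}}.
#' @return A \code{pest_raster} of residuals, with the \code{robust_fit}
#'   attached as attribute \code{"fit"}.
#' @export
host_cover_residuals <- function(intensity, cover, ...) {
  stopifnot(inherits(intensity, "pest_raster"), inherits(cover, "pest_raster"))
  if (!same_grid(intensity, cover)) stop("rasters are not on the same grid")
  fit <- huber_rlm(as.vector(cover$values), as.vector(intensity$values), ...)
  res <- matrix(fit$residuals, intensity$grid$nrows, intensity$grid$ncols)
  out <- raster_layer(intensity$grid, res,
                      name = paste0(intensity$name, "_residual"),
                      units = intensity$units)
  attr(out, "fit") <- fit
  out
}
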