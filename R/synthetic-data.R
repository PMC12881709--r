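#' Linear-Gaussian structural causal model over covariate layers
#'
#' Specifies how synthetic covariate rasters are generated: each node of the
#' DAG is a linear combination of its parents plus a Matern Gaussian noise
#' field.  Because the structural equations are linear, the total causal
#' effect of any node on any other equals the sum over directed paths of the
#' products of edge coefficients, giving analytically known ground truth for
#' the causal-recovery machinery.
#'
#' @param dag A \code{pest_dag} over covariate names (no latent nodes).
#' @param edge_coef Named numeric vector of linear coefficients, names of the
#'   form \code{"A->B"}; every named edge must exist in \code{dag}.  Edges of
#'   the DAG without a named coefficient default to 0.
#' @param noise_sd,noise_range Per-node Matern noise parameters: either
#'   scalars (shared) or named vectors over the DAG nodes.  \code{noise_sd}
#'   must be positive.
#' @return An object of class \code{scm_spec}.
#' @export
scm_spec <- function(dag, edge_coef = numeric(), noise_sd = 1, noise_range = 5) {
  stopifnot(inherits(dag, "pest_dag"))
  if (length(dag$latent)) stop("covariate SCM nodes must all be observed")
  if (length(edge_coef)) {
    have <- paste0(dag$edges[, 1], "->", dag$edges[, 2])
    bad <- setdiff(names(edge_coef), have)
    if (length(bad)) stop("edge_coef names not in dag: ", paste(bad, collapse = ", "))
  }
  expand <- function(x, what) {
    if (is.null(names(x))) {
      stopifnot(length(x) == 1L)
      x <- stats::setNames(rep(x, length(dag$nodes)), dag$nodes)
    }
    if (!all(dag$nodes %in% names(x))) stop("missing ", what, " for some nodes")
    x[dag$nodes]
  }
  sd <- expand(noise_sd, "noise_sd"); rg <- expand(noise_range, "noise_range")
  if (any(sd <= 0)) stop("noise sd must be positive")
  if (any(rg <= 0)) stop("noise range must be positive")
  structure(list(dag = dag, edge_coef = edge_coef,
                 noise_sd = sd, noise_range = rg),
            class = "scm_spec")
}

#' Total causal effects implied by a linear SCM (path-product oracle)
#'
#' @param scm An \code{scm_spec}.
#' @param from,to Node labels.
#' @return The total effect: sum over all directed paths from \code{from} to
#'   \code{to} of the product of edge coefficients along the path.
#' @export
scm_total_effect <- function(scm, from, to) {
  stopifnot(inherits(scm, "scm_spec"))
  coef_of <- function(a, b) {
    key <- paste0(a, "->", b)
    if (key %in% names(scm$edge_coef)) scm$edge_coef[[key]] else 0
  }
  total <- 0
  walk <- function(v, acc) {
    if (v == to) { total <<- total + acc; return() }
    for (ch in dag_children(scm$dag, v)) walk(ch, acc * coef_of(v, ch))
  }
  walk(from, 1)
  total
}

# Matern noise field evaluated at cell centres, via the lattice SPDE basis at
# the raster's own resolution; consumes the current RNG stream.  The sparse
# Cholesky factor depends only on (grid, range), with sigma a pure scale, so
# factors are memoised across draws.
.field_cache <- new.env(parent = emptyenv())

matern_cell_field <- function(grid, sd, range_km) {
  key <- paste(grid$nrows, grid$ncols, grid$cell_km, grid$origin[1],
               grid$origin[2], signif(range_km, 12), sep = "|")
  ent <- .field_cache[[key]]
  if (is.null(ent)) {
    mesh <- build_mesh(grid, max_edge_km = grid$cell_km,
                       min_spacing_km = grid$cell_km,
                       extend_km = max(2 * range_km, 4 * grid$cell_km))
    Q <- matern_precision(mesh, hyper_params(1, range_km))
    ent <- list(
      ch = Matrix::Cholesky(Matrix::forceSymmetric(Q), perm = TRUE, LDL = FALSE),
      A = mesh_projector(mesh, cell_centers(grid)),
      n = nrow(Q)
    )
    .field_cache[[key]] <- ent
  }
  z <- stats::rnorm(ent$n)
  x <- Matrix::solve(ent$ch, Matrix::solve(ent$ch, z, system = "Lt"),
                     system = "Pt")
  matrix(sd * as.numeric(ent$A %*% x), grid$nrows, grid$ncols)
}

#' Simulate covariate rasters from a linear-Gaussian SCM
#'
#' Generates the nodes in topological order: each raster equals the
#' coefficient-weighted sum of its parents' rasters plus an independent
#' Matern noise field.  Bit-reproducible under a fixed seed.
#'
#' @param grid A \code{grid_spec}.
#' @param scm An \code{scm_spec}.
#' @param seed Integer seed.
#' @return Named list of \code{pest_raster} layers, one per DAG node.
#' @export
simulate_covariate_fields <- function(grid, scm, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(scm, "scm_spec"))
  set.seed(seed)
  out <- list()
  for (v in dag_topological_order(scm$dag)) {
    vals <- matern_cell_field(grid, scm$noise_sd[[v]], scm$noise_range[[v]])
    for (p in dag_parents(scm$dag, v)) {
      key <- paste0(p, "->", v)
      coef <- if (key %in% names(scm$edge_coef)) scm$edge_coef[[key]] else 0
      if (!p %in% names(out)) stop("unknown parent raster '", p, "'")
      vals <- vals + coef * out[[p]]$values
    }
    out[[v]] <- raster_layer(grid, vals, name = v)
  }
  out[scm$dag$nodes]
}

#' Ground-truth process model for synthetic intensity surfaces
#'
#' @param alpha Intercept of the log-intensity (log points per km^2).
#' @param beta Named numeric vector of covariate coefficients.
#' @param sigma,rho Marginal sd (>= 0) and range (km) of the shared Matern
#'   field on the log-intensity.
#' @param bias_sd,bias_range Hyperparameters of the presence-background
#'   thinning (reporting-bias) field.
#' @param e_vis Per-visit exposure scalar (> 0) linking intensity to the
#'   per-visit detection probability \code{1 - exp(-e_vis * lambda)};
#'   defaults to 1 cell area.
#' @return An object of class \code{true_model}.
#' @export
true_model <- function(alpha = 0, beta = numeric(), sigma = 0.5, rho = 10,
                       bias_sd = 0.5, bias_range = 15, e_vis = 1) {
  stopifnot(sigma >= 0, rho > 0, e_vis > 0, bias_sd >= 0, bias_range > 0)
  structure(list(alpha = alpha, beta = beta, sigma = sigma, rho = rho,
                 bias_sd = bias_sd, bias_range = bias_range, e_vis = e_vis),
            class = "true_model")
}

#' Simulate the latent intensity surface of the log-Gaussian Cox process
#'
#' \eqn{\log \lambda(s) = \alpha + \sum_k \beta_k x_k(s) + \xi(s)} with
#' \eqn{\xi} a Matern (nu = 1) field with the model's (sigma, rho); with
#' \code{sigma = 0} the field is identically zero.
#'
#' @param grid A \code{grid_spec}.
#' @param covariates Named list of \code{pest_raster} layers containing every
#'   name in \code{model$beta}.
#' @param model A \code{true_model}.
#' @param seed Integer seed.
#' @return List with \code{lambda} (intensity, points/km^2) and \code{xi}
#'   (field) rasters.
#' @export
simulate_intensity <- function(grid, covariates, model, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(model, "true_model"))
  missing_cov <- setdiff(names(model$beta), names(covariates))
  if (length(missing_cov))
    stop("missing covariate(s): ", paste(missing_cov, collapse = ", "))
  set.seed(seed)
  eta <- matrix(model$alpha, grid$nrows, grid$ncols)
  for (k in names(model$beta))
    eta <- eta + model$beta[[k]] * covariates[[k]]$values
  xi <- if (model$sigma > 0)
    matern_cell_field(grid, model$sigma, model$rho)
  else matrix(0, grid$nrows, grid$ncols)
  list(lambda = raster_layer(grid, exp(eta + xi), name = "lambda",
                             units = "points/km^2"),
       xi = raster_layer(grid, xi, name = "xi"))
}

#' Presence-background point locations
#'
#' @param x Matrix or data frame with x/y km coordinates.
#' @return A \code{pb_points} data frame with columns \code{x_km, y_km}.
#' @export
pb_points <- function(x) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) == 2L)
  names(x) <- c("x_km", "y_km")
  structure(x, class = c("pb_points", "data.frame"))
}

#' Simulate presence-background points by cell-wise Poisson thinning
#'
#' Counts per cell are Poisson with mean \eqn{\exp(\log\lambda + b) \cdot
#' |cell|}; the bias raster \code{b}, when given, is a log-thinning surface
#' added to the log intensity.  Points are placed uniformly within their
#' cell (sub-cell position carries no information at the modelled
#' resolution).
#'
#' @param lambda Intensity \code{pest_raster} (points/km^2, non-negative).
#' @param bias Optional \code{pest_raster} of log thinning factors on the
#'   same grid.
#' @param seed Integer seed.
#' @return A \code{pb_points} data frame.
#' @export
simulate_pb_points <- function(lambda, bias = NULL, seed = 1L) {
  stopifnot(inherits(lambda, "pest_raster"))
  if (any(lambda$values < 0)) stop("lambda must be non-negative")
  g <- lambda$grid
  rate <- lambda$values
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "pest_raster"))
    if (!same_grid(lambda, bias)) stop("bias raster grid mismatch")
    rate <- exp(log(pmax(rate, 0)) + bias$values)
    rate[lambda$values == 0] <- 0
  }
  set.seed(seed)
  mu <- as.vector(rate) * g$cell_km^2
  counts <- stats::rpois(length(mu), mu)
  cc <- cell_centers(g)
  idx <- rep.int(seq_along(counts), counts)
  n <- length(idx)
  half <- g$cell_km / 2
  pb_points(cbind(cc[idx, 1] + stats::runif(n, -half, half),
                  cc[idx, 2] + stats::runif(n, -half, half)))
}

#' Presence-absence survey table
#'
#' @param x Data frame with columns \code{site_id, x_km, y_km, n_surveys,
#'   n_detections}.
#' @return A validated \code{pa_table}.
#' @export
pa_table <- function(x) {
  x <- as.data.frame(x)
  need <- c("site_id", "x_km", "y_km", "n_surveys", "n_detections")
  if (!all(need %in% names(x))) stop("pa_table needs columns: ",
                                     paste(need, collapse = ", "))
  if (any(x$n_surveys < 1)) stop("each site needs at least one survey")
  if (any(x$n_detections < 0 | x$n_detections > x$n_surveys))
    stop("detections must lie in [0, n_surveys]")
  structure(x[need], class = c("pa_table", "data.frame"))
}

# intensity at point locations = value of the containing cell
lambda_at <- function(lambda, pts) {
  g <- lambda$grid
  pts <- matrix(as.numeric(pts), ncol = 2)
  j <- ceiling((pts[, 1] - g$origin[1]) / g$cell_km)
  i <- ceiling((pts[, 2] - g$origin[2]) / g$cell_km)
  if (any(i < 1 | i > g$nrows | j < 1 | j > g$ncols))
    stop("site outside the raster domain")
  lambda$values[cbind(i, j)]
}

#' Simulate repeat-visit presence-absence surveys
#'
#' Each visit detects at least one pest with probability
#' \eqn{p(s) = 1 - \exp(-e_{vis} \lambda(s))} (the complementary log-log
#' link between a Poisson intensity and the probability of at least one
#' event); detections per site are Binomial(visits, p).
#'
#' @param lambda Intensity \code{pest_raster}.
#' @param sites Matrix (n x 2) of site coordinates (km), inside the grid.
#' @param visits Integer vector of per-site visit counts (>= 1).
#' @param e_vis Per-visit exposure (> 0).
#' @param seed Integer seed.
#' @return A \code{pa_table}.
#' @export
simulate_pa_surveys <- function(lambda, sites, visits, e_vis = 1, seed = 1L) {
  stopifnot(inherits(lambda, "pest_raster"), e_vis > 0)
  sites <- matrix(as.numeric(sites), ncol = 2)
  visits <- as.integer(visits)
  stopifnot(length(visits) == nrow(sites), all(visits >= 1))
  lam <- lambda_at(lambda, sites)
  p <- -expm1(-e_vis * lam)
  set.seed(seed)
  k <- stats::rbinom(length(p), visits, p)
  pa_table(data.frame(site_id = seq_along(p), x_km = sites[, 1],
                      y_km = sites[, 2], n_surveys = visits,
                      n_detections = k))
}

#' Draw per-site visit counts from a zero-truncated geometric
#'
#' Mimics national inspection data where most sites are visited once but a
#' long tail of sites receives many repeat visits (median 1, occasional
#' counts into the tens).
#'
#' @param n Number of sites.
#' @param mean_visits Target mean (> 1 not required; default 1.5).
#' @param seed Optional integer seed.
#' @return Integer vector of counts >= 1.
#' @export
sample_visit_counts <- function(n, mean_visits = 1.5, seed = NULL) {
  stopifnot(mean_visits >= 1)
  if (!is.null(seed)) set.seed(seed)
  1L + stats::rgeom(n, prob = 1 / mean_visits)
}

#' Simulate a complete integrated dataset with known truth
#'
#' Convenience wrapper tying the generators together: covariates from an
#' SCM (or independent fields), a latent intensity surface, spatially biased
#' presence-background points and repeat-visit presence-absence surveys at
#' uniformly placed sites.
#'
#' @param grid A \code{grid_spec}.
#' @param model A \code{true_model}.
#' @param scm Optional \code{scm_spec}; by default the covariates named in
#'   \code{model$beta} are simulated as independent Matern fields (sd 1,
#'   range 10 km).
#' @param n_sites Number of presence-absence sites.
#' @param mean_visits Mean of the zero-truncated geometric visit counts.
#' @param pb_bias Log-thinning surface for the presence-background stream:
#'   a \code{pest_raster}, or NULL (the default) to draw a Matern field with
#'   the model's \code{bias_sd} and \code{bias_range} (set \code{bias_sd = 0}
#'   in the model for unthinned points), mirroring the second field in the
#'   observation model.
#' @param standardize_covariates Z-standardise the covariates (default TRUE,
#'   matching the modelling convention).
#' @param seed Integer seed governing all draws.
#' @return List with \code{covariates}, \code{lambda}, \code{xi}, \code{pa},
#'   \code{pb}, \code{sites}, \code{model}, \code{grid}.
#' @export
simulate_isdm_dataset <- function(grid, model, scm = NULL, n_sites = 200,
                                  mean_visits = 1.5, pb_bias = NULL,
                                  standardize_covariates = TRUE, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), inherits(model, "true_model"))
  if (is.null(scm)) {
    nm <- names(model$beta)
    if (!length(nm)) nm <- character()
    dag <- if (length(nm)) dag_create(matrix(character(), 0, 2), nodes = nm)
    scm <- if (length(nm)) scm_spec(dag, noise_sd = 1, noise_range = 10)
  }
  covs <- if (!is.null(scm)) simulate_covariate_fields(grid, scm, seed = seed)
  else list()
  if (standardize_covariates && length(covs))
    covs <- lapply(covs, standardize)
  surf <- simulate_intensity(grid, covs, model, seed = seed + 1L)
  if (is.null(pb_bias) && model$bias_sd > 0) {
    set.seed(seed + 5L)
    pb_bias <- raster_layer(
      grid, matern_cell_field(grid, model$bias_sd, model$bias_range),
      name = "pb_bias")
  }
  pb <- simulate_pb_points(surf$lambda, bias = pb_bias, seed = seed + 2L)
  set.seed(seed + 3L)
  W <- grid$ncols * grid$cell_km; H <- grid$nrows * grid$cell_km
  sites <- cbind(grid$origin[1] + stats::runif(n_sites) * W,
                 grid$origin[2] + stats::runif(n_sites) * H)
  visits <- sample_visit_counts(n_sites, mean_visits)
  pa <- simulate_pa_surveys(surf$lambda, sites, visits, e_vis = model$e_vis,
                            seed = seed + 4L)
  list(covariates = covs, lambda = surf$lambda, xi = surf$xi, pa = pa,
       pb = pb, sites = sites, model = model, grid = grid)
}

#' Bundled national record-count bookkeeping
#'
#' Reads the shipped summary of the two observation streams the package's
#' study design emulates (plant-health inspection presence-absence records
#' and public-report presence-background records) and returns per-stream and
#' total record counts.
#'
#' @return A list with \code{counts} (data frame) and \code{total}.
#' @export
record_counts <- function() {
  path <- system.file("extdata", "record_counts.csv", package = "pestisdm",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(counts = df, total = sum(df$n_records))
}
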