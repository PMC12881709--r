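#' Build a spatial basis ("mesh") over a km-grid domain
#'
#' The latent Matern fields are represented on a discrete basis via the SPDE
#' approximation.  The default (and only) backend is a regular lattice of
#' nodes with bilinear elements; the \code{max_edge_km} argument plays the
#' role of the maximum triangle edge in a triangular mesh and equals the
#' lattice spacing.  The lattice extends \code{extend_km} beyond the domain
#' bounding box to keep SPDE boundary variance inflation away from the data.
#'
#' @param domain A \code{grid_spec}, or a 2x2 matrix \code{rbind(c(xmin,xmax),
#'   c(ymin,ymax))} of the domain bounding box in km.
#' @param max_edge_km Maximum distance between neighbouring basis nodes (km).
#' @param min_spacing_km Minimum allowed node spacing (km, default 1), which
#'   keeps the basis no finer than the covariate rasters.
#' @param extend_km Extension of the lattice beyond the bounding box (km);
#'   default 20 km, i.e., twice the 10 km prior range threshold.
#' @return An object of class \code{mesh_basis} with node coordinates, lattice
#'   spacings and counts.
#' @export
build_mesh <- function(domain, max_edge_km, min_spacing_km = 1,
                       extend_km = 20) {
  if (max_edge_km < min_spacing_km)
    stop("max_edge_km must be >= min_spacing_km")
  if (inherits(domain, "grid_spec")) {
    bbox <- rbind(
      c(domain$origin[1], domain$origin[1] + domain$ncols * domain$cell_km),
      c(domain$origin[2], domain$origin[2] + domain$nrows * domain$cell_km)
    )
  } else {
    bbox <- as.matrix(domain)
    stopifnot(all(dim(bbox) == c(2, 2)), all(bbox[, 2] > bbox[, 1]))
  }
  lo <- bbox[, 1] - extend_km
  hi <- bbox[, 2] + extend_km
  axis_nodes <- function(a, b) {
    L <- b - a
    n <- max(1L, ceiling(L / max_edge_km))       # intervals
    while (n > 1L && L / n < min_spacing_km) n <- n - 1L
    seq(a, b, length.out = n + 1L)
  }
  xs <- axis_nodes(lo[1], hi[1])
  ys <- axis_nodes(lo[2], hi[2])
  structure(
    list(x = xs, y = ys, nx = length(xs), ny = length(ys),
         hx = xs[2] - xs[1], hy = ys[2] - ys[1],
         n_nodes = length(xs) * length(ys), bbox = bbox),
    class = "mesh_basis"
  )
}

#' @export
print.mesh_basis <- function(x, ...) {
  cat(sprintf("<mesh_basis> %d x %d lattice (%d nodes), spacing %.3g x %.3g km\n",
              x$nx, x$ny, x$n_nodes, x$hx, x$hy))
  invisible(x)
}

#' Node coordinates of a mesh basis
#'
#' @param mesh A \code{mesh_basis}.
#' @return Matrix (n_nodes x 2) of node (x, y) km coordinates; node index runs
#'   with y fastest, matching the sparse matrices built from the basis.
#' @export
mesh_nodes <- function(mesh) {
  stopifnot(inherits(mesh, "mesh_basis"))
  cbind(x = rep(mesh$x, each = mesh$ny), y = rep(mesh$y, times = mesh$nx))
}

#' Sparse projector from mesh nodes to point locations
#'
#' Bilinear interpolation weights from the four surrounding lattice nodes;
#' every row sums to 1 for points inside the meshed region.
#'
#' @param mesh A \code{mesh_basis}.
#' @param points Matrix (n x 2) of (x, y) km coordinates.
#' @return A sparse \code{dgCMatrix} (n x n_nodes).
#' @export
mesh_projector <- function(mesh, points) {
  stopifnot(inherits(mesh, "mesh_basis"))
  points <- matrix(as.numeric(points), ncol = 2)
  px <- points[, 1]; py <- points[, 2]
  eps <- 1e-9
  if (any(px < mesh$x[1] - eps | px > mesh$x[mesh$nx] + eps |
          py < mesh$y[1] - eps | py > mesh$y[mesh$ny] + eps))
    stop("points outside the meshed region")
  ix <- pmin(pmax(findInterval(px, mesh$x), 1L), mesh$nx - 1L)
  iy <- pmin(pmax(findInterval(py, mesh$y), 1L), mesh$ny - 1L)
  tx <- pmin(pmax((px - mesh$x[ix]) / mesh$hx, 0), 1)
  ty <- pmin(pmax((py - mesh$y[iy]) / mesh$hy, 0), 1)
  node <- function(jx, jy) (jx - 1L) * mesh$ny + jy
  n <- length(px)
  i <- rep(seq_len(n), 4L)
  j <- c(node(ix, iy), node(ix + 1L, iy), node(ix, iy + 1L), node(ix + 1L, iy + 1L))
  w <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, mesh$n_nodes))
}

#' Matern field hyperparameters
#'
#' @param sigma Marginal standard deviation (>= 0).
#' @param rho Spatial range in km (> 0); the distance at which the Matern
#'   (nu = 1) correlation has dropped to about 0.13.
#' @return An object of class \code{hyper_params}.
#' @export
hyper_params <- function(sigma, rho) {
  stopifnot(sigma >= 0, rho > 0)
  structure(list(sigma = as.numeric(sigma), rho = as.numeric(rho)),
            class = "hyper_params")
}

# 1-D linear-element stiffness (1/h * tridiag(-1, 2, -1), halved at ends) and
# lumped mass (h, halved at ends) on n nodes with spacing h.
fem_1d <- function(n, h) {
  d <- rep(2, n); d[c(1, n)] <- 1
  K <- Matrix::bandSparse(n, k = c(-1, 0, 1),
                          diagonals = list(rep(-1, n - 1), d, rep(-1, n - 1))) / h
  m <- rep(h, n); m[c(1, n)] <- h / 2
  list(K = K, M = Matrix::Diagonal(n, m))
}

#' Sparse SPDE precision matrix of a Matern (nu = 1) field
#'
#' Assembles the standard alpha = 2 SPDE precision
#' \eqn{Q = \tau^2 (\kappa^4 C + 2 \kappa^2 G + G C^{-1} G)} on the bilinear
#' lattice basis, with lumped mass matrix C and tensor-product stiffness G,
#' where \eqn{\kappa = \sqrt{8}/\rho} and
#' \eqn{\tau^2 = 1 / (4 \pi \kappa^2 \sigma^2)} so the implied field has
#' marginal standard deviation approximately \code{sigma} and range
#' \code{rho} away from the lattice boundary.
#'
#' @param mesh A \code{mesh_basis}.
#' @param hp A \code{hyper_params} with \code{sigma > 0}.
#' @return A sparse symmetric positive-definite \code{dsCMatrix} with
#'   attribute \code{kappa}.
#' @export
matern_precision <- function(mesh, hp) {
  stopifnot(inherits(mesh, "mesh_basis"), inherits(hp, "hyper_params"))
  if (hp$sigma <= 0) stop("sigma must be positive to form a precision matrix")
  fx <- fem_1d(mesh$nx, mesh$hx)
  fy <- fem_1d(mesh$ny, mesh$hy)
  C <- Matrix::kronecker(fx$M, fy$M)              # diagonal (lumped)
  G <- Matrix::kronecker(fx$K, fy$M) + Matrix::kronecker(fx$M, fy$K)
  kappa <- sqrt(8) / hp$rho
  tau2 <- 1 / (4 * pi * kappa^2 * hp$sigma^2)
  Cinv <- Matrix::Diagonal(x = 1 / Matrix::diag(C))
  Q <- tau2 * (kappa^4 * C + 2 * kappa^2 * G + G %*% Cinv %*% G)
  Q <- Matrix::forceSymmetric(Q)
  # fail fast on a degenerate assembly
  tryCatch(Matrix::Cholesky(Q, perm = TRUE),
           error = function(e) stop("precision matrix is not positive definite: ",
                                    conditionMessage(e)))
  attr(Q, "kappa") <- kappa
  Q
}

#' Penalised-complexity prior density for the field standard deviation
#'
#' Exponential-tail density \eqn{\pi(\sigma) = \lambda e^{-\lambda \sigma}}
#' with rate \eqn{\lambda = -\log(\alpha)/\sigma_0}, calibrated so that
#' \eqn{P(\sigma > \sigma_0) = \alpha}.  The mode sits at zero: absent support
#' from the data the prior favours no spatial structure.
#'
#' @param sigma Evaluation points (>= 0).
#' @param sigma0 Threshold (default 1).
#' @param alpha Tail probability \eqn{P(\sigma > \sigma_0)} (default 0.05).
#' @param log Return log density?
#' @return Density values.
#' @export
pc_prior_sigma_density <- function(sigma, sigma0 = 1, alpha = 0.05, log = FALSE) {
  stopifnot(sigma0 > 0, alpha > 0, alpha < 1)
  lambda <- -log(alpha) / sigma0
  ld <- ifelse(sigma < 0, -Inf, log(lambda) - lambda * sigma)
  if (log) ld else exp(ld)
}

#' Penalised-complexity prior density for the spatial range
#'
#' Density \eqn{\pi(\rho) = (\lambda/\rho^2) e^{-\lambda/\rho}} with
#' \eqn{\lambda = -\rho_0 \log(\alpha)}, calibrated so that
#' \eqn{P(\rho < \rho_0) = \alpha} (short ranges, i.e., complex fields, are
#' penalised).
#'
#' @param rho Evaluation points (> 0).
#' @param rho0 Threshold in km (default 10).
#' @param alpha Tail probability \eqn{P(\rho < \rho_0)} (default 0.05).
#' @param log Return log density?
#' @return Density values.
#' @export
pc_prior_rho_density <- function(rho, rho0 = 10, alpha = 0.05, log = FALSE) {
  stopifnot(rho0 > 0, alpha > 0, alpha < 1)
  lambda <- -rho0 * log(alpha)
  ld <- ifelse(rho <= 0, -Inf, log(lambda) - 2 * log(rho) - lambda / rho)
  if (log) ld else exp(ld)
}

#' Joint log PC prior density for (sigma, rho)
#'
#' @param hp A \code{hyper_params}.
#' @param sigma0,alpha_sigma Calibration of the sd prior:
#'   \eqn{P(\sigma > \sigma_0) = \alpha_\sigma}.
#' @param rho0,alpha_rho Calibration of the range prior:
#'   \eqn{P(\rho < \rho_0) = \alpha_\rho}.
#' @return The log joint prior density (independent components).
#' @export
pc_prior_logdensity <- function(hp, sigma0 = 1, alpha_sigma = 0.05,
                                rho0 = 10, alpha_rho = 0.05) {
  stopifnot(inherits(hp, "hyper_params"))
  pc_prior_sigma_density(hp$sigma, sigma0, alpha_sigma, log = TRUE) +
    pc_prior_rho_density(hp$rho, rho0, alpha_rho, log = TRUE)
}

#' Sample a zero-mean Gaussian field from a sparse precision matrix
#'
#' Draws \eqn{x \sim N(0, Q^{-1})} by sparse Cholesky back-substitution:
#' with \eqn{P Q P' = L L'}, returns \eqn{x = P' L^{-T} z}, \eqn{z} standard
#' normal.
#'
#' @param Q Sparse symmetric positive-definite precision matrix.
#' @param seed Optional integer seed (draw is bit-reproducible given it).
#' @param n_draws Number of independent draws.
#' @return A numeric vector (one draw) or matrix (nodes x draws).
#' @export
sample_field <- function(Q, seed = NULL, n_draws = 1L) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Q)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Q), perm = TRUE, LDL = FALSE)
  z <- matrix(stats::rnorm(n * n_draws), n, n_draws)
  y <- Matrix::solve(ch, z, system = "Lt")
  x <- as.matrix(Matrix::solve(ch, y, system = "Pt"))
  if (n_draws == 1L) drop(x) else x
}
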