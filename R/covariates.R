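#' Gaussian-kernel connectivity of a raster layer
#'
#' Computes, for every cell, a weighted sum of the layer over surrounding
#' cells with weights following a Gaussian function of centre-to-centre
#' distance, \eqn{w(d) \propto \exp(-d^2 / (2\sigma^2))}.  With the default
#' sd of 3 km, 68\% of the (one-dimensional profile) weight lies within 3 km
#' and 99.7\% within 9 km of the focal cell.  The kernel is truncated at
#' \code{truncation_sigmas * sigma_km} and normalised to sum to one; at the
#' domain edge the weights are renormalised over the in-domain support, so a
#' constant layer maps to itself everywhere.
#'
#' @param x A \code{pest_raster}.
#' @param sigma_km Gaussian standard deviation in km (default 3).
#' @param truncation_sigmas Truncation radius in units of sigma (default 3).
#' @return A \code{pest_raster} of connectivity values.
#' @export
gaussian_connectivity <- function(x, sigma_km = 3, truncation_sigmas = 3) {
  stopifnot(inherits(x, "pest_raster"))
  if (sigma_km <= 0) stop("sigma_km must be positive")
  g <- x$grid
  r <- floor(truncation_sigmas * sigma_km / g$cell_km)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  d2 <- (offs$di^2 + offs$dj^2) * g$cell_km^2
  keep <- sqrt(d2) <= truncation_sigmas * sigma_km + 1e-12
  offs <- offs[keep, ]
  w <- exp(-d2[keep] / (2 * sigma_km^2))
  nr <- g$nrows; nc <- g$ncols
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  v <- x$values
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    # destination rows/cols receiving source shifted by (di, dj)
    i_dst <- max(1, 1 - di):min(nr, nr - di)
    j_dst <- max(1, 1 - dj):min(nc, nc - dj)
    num[i_dst, j_dst] <- num[i_dst, j_dst] + w[k] * v[i_dst + di, j_dst + dj]
    den[i_dst, j_dst] <- den[i_dst, j_dst] + w[k]
  }
  raster_layer(g, num / den, name = paste0(x$name, "_connectivity"),
               units = x$units)
}

#' Mass of the one-dimensional Gaussian kernel profile within a radius
#'
#' Integrates the kernel weight function \eqn{w(d) \propto
#' \exp(-d^2/(2\sigma^2))} over \eqn{[-a, a]} relative to the whole line,
#' i.e., the fraction of one-dimensional kernel weight assigned within
#' \code{a} km of the focal cell.
#'
#' @param sigma_km Kernel standard deviation (km).
#' @param within_km Radius \code{a} (km).
#' @return Fraction in (0, 1).
#' @export
kernel_weight_fraction <- function(sigma_km, within_km) {
  stopifnot(sigma_km > 0, within_km > 0)
  w <- function(d) exp(-d^2 / (2 * sigma_km^2))
  num <- stats::integrate(w, -within_km, within_km, rel.tol = 1e-10)$value
  den <- stats::integrate(w, -Inf, Inf, rel.tol = 1e-10)$value
  num / den
}

#' Z-standardise a raster layer
#'
#' Subtracts the mean and divides by the population (1/n) standard deviation
#' over all finite cells; layers are treated as complete populations of
#' cells.  A constant layer cannot be standardised and signals an error: such
#' a layer carries no information and must be dropped, not silently zeroed.
#'
#' @param x A \code{pest_raster}.
#' @return A \code{pest_raster} with mean 0 and sd 1 (tolerance 1e-9).
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "pest_raster"))
  v <- x$values
  ok <- is.finite(v)
  mu <- mean(v[ok])
  sd_pop <- sqrt(mean((v[ok] - mu)^2))
  if (!is.finite(sd_pop) || sd_pop <= 0)
    stop("degenerate layer '", x$name, "': constant values cannot be standardised")
  out <- x
  out$values <- (v - mu) / sd_pop
  out$units <- "sd units"
  out
}

#' Distance from each cell centre to the nearest feature
#'
#' @param grid A \code{grid_spec}.
#' @param features Matrix (k x 2) of feature (x, y) km coordinates (k >= 1).
#' @param name Layer label.
#' @return A \code{pest_raster} of planar Euclidean distances in km.
#' @export
distance_to_nearest <- function(grid, features, name = "dist_nearest") {
  stopifnot(inherits(grid, "grid_spec"))
  features <- matrix(as.numeric(features), ncol = 2)
  if (nrow(features) < 1L) stop("at least one feature location is required")
  cc <- cell_centers(grid)
  # blockwise min over features keeps memory flat for large k
  dmin <- rep(Inf, nrow(cc))
  for (k in seq_len(nrow(features))) {
    dk <- sqrt((cc[, 1] - features[k, 1])^2 + (cc[, 2] - features[k, 2])^2)
    dmin <- pmin(dmin, dk)
  }
  raster_layer(grid, matrix(dmin, grid$nrows, grid$ncols), name = name,
               units = "km")
}

#' Habitat area and edge length per coarse grid cell
#'
#' Aggregates a fine-resolution binary habitat raster to a coarse grid:
#' \code{area} is the habitat fraction times the coarse cell area (km^2);
#' \code{edge} is the total length (km) of boundaries between habitat and
#' non-habitat fine cells whose shared side lies strictly inside the coarse
#' cell.  Sides on coarse-cell borders and on the domain boundary are not
#' counted.
#'
#' @param fine_binary A \code{pest_raster} with values in \{0, 1\}.
#' @param coarse A \code{grid_spec} whose cell size is an integer multiple of
#'   the fine cell size and which covers the same extent.
#' @return A list with \code{area} and \code{edge} rasters on \code{coarse}.
#' @export
area_edge_per_cell <- function(fine_binary, coarse) {
  stopifnot(inherits(fine_binary, "pest_raster"), inherits(coarse, "grid_spec"))
  v <- fine_binary$values
  if (!all(v %in% c(0, 1))) stop("fine raster must be binary (0/1)")
  f <- fine_binary$grid$cell_km
  ratio <- coarse$cell_km / f
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fine resolution must divide the coarse resolution")
  ratio <- as.integer(round(ratio))
  if (fine_binary$grid$nrows != coarse$nrows * ratio ||
      fine_binary$grid$ncols != coarse$ncols * ratio)
    stop("fine raster extent does not match the coarse grid")
  blk_i <- (seq_len(fine_binary$grid$nrows) - 1L) %/% ratio + 1L
  blk_j <- (seq_len(fine_binary$grid$ncols) - 1L) %/% ratio + 1L
  # habitat fraction per coarse cell: sum over fine rows, then fine columns
  area <- t(rowsum(t(rowsum(v, blk_i)), blk_j)) * f^2
  # vertical interior sides: fine pairs (i, j)-(i, j+1) in the same coarse cell
  ev <- abs(v[, -ncol(v), drop = FALSE] - v[, -1, drop = FALSE])
  same_col <- blk_j[-length(blk_j)] == blk_j[-1]
  ev[, !same_col] <- 0
  edge_v <- t(rowsum(t(rowsum(ev, blk_i)), blk_j[-length(blk_j)]))
  if (ncol(edge_v) < coarse$ncols)   # last coarse column has no j, j+1 pair start
    edge_v <- cbind(edge_v, matrix(0, coarse$nrows, coarse$ncols - ncol(edge_v)))
  # horizontal interior sides: fine pairs (i, j)-(i+1, j) in the same coarse cell
  eh <- abs(v[-nrow(v), , drop = FALSE] - v[-1, , drop = FALSE])
  same_row <- blk_i[-length(blk_i)] == blk_i[-1]
  eh[!same_row, ] <- 0
  edge_h <- t(rowsum(t(rowsum(eh, blk_i[-length(blk_i)])), blk_j))
  if (nrow(edge_h) < coarse$nrows)
    edge_h <- rbind(edge_h, matrix(0, coarse$nrows - nrow(edge_h), coarse$ncols))
  edge <- (edge_v + edge_h) * f
  list(
    area = raster_layer(coarse, area, name = paste0(fine_binary$name, "_area"),
                        units = "km^2"),
    edge = raster_layer(coarse, edge, name = paste0(fine_binary$name, "_edge"),
                        units = "km")
  )
}
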