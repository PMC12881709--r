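test_that("gaussian connectivity preserves constants and matches the analytic impulse ratio", {
  g <- grid_spec(30, 30, 1)
  const <- gaussian_connectivity(raster_layer(g, 3.7))
  expect_equal(range(const$values), c(3.7, 3.7))

  v <- matrix(0, 30, 30); v[15, 15] <- 1
  imp <- gaussian_connectivity(raster_layer(g, v), sigma_km = 3)
  expect_equal(imp$values[15, 18] / imp$values[15, 15], exp(-0.5),
               tolerance = 1e-12)
  expect_error(gaussian_connectivity(raster_layer(g, v), sigma_km = 0),
               "positive")
})

test_that("gaussian connectivity equals the brute-force all-pairs kernel sum", {
  g <- grid_spec(30, 30, 1)
  set.seed(1)
  vals <- matrix(rnorm(900), 30, 30)
  out <- gaussian_connectivity(raster_layer(g, vals), sigma_km = 3)
  ctr <- cell_centers(g)
  oracle <- vapply(seq_len(900), function(c1) {
    d <- sqrt((ctr[, 1] - ctr[c1, 1])^2 + (ctr[, 2] - ctr[c1, 2])^2)
    w <- ifelse(d <= 9 + 1e-12, exp(-d^2 / 18), 0)
    sum(w * as.vector(vals)) / sum(w)
  }, numeric(1))
  expect_equal(as.vector(out$values), oracle, tolerance = 1e-12)
})

test_that("gaussian connectivity is linear in its input layer", {
  g <- grid_spec(20, 20, 1)
  set.seed(2)
  a <- raster_layer(g, matrix(rnorm(400), 20))
  b <- raster_layer(g, matrix(rnorm(400), 20))
  comb <- raster_layer(g, 2 * a$values - 3 * b$values)
  lhs <- gaussian_connectivity(comb)$values
  rhs <- 2 * gaussian_connectivity(a)$values - 3 * gaussian_connectivity(b)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("standardisation uses the population sd and is idempotent and affine-invariant", {
  g <- grid_spec(3, 2, 1)
  r <- raster_layer(g, matrix(c(1, 2, 3, 1, 2, 3), 3, 2))
  s <- standardize(r)
  expect_equal(s$values[, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_lt(abs(mean(s$values)), 1e-9)
  expect_lt(abs(sqrt(mean((s$values - mean(s$values))^2)) - 1), 1e-9)
  expect_equal(standardize(s)$values, s$values, tolerance = 1e-12)

  aff <- raster_layer(g, 4.2 * r$values - 17)
  expect_equal(standardize(aff)$values, s$values, tolerance = 1e-12)
  expect_error(standardize(raster_layer(g, 5)), "degenerate")
})

test_that("standardisation commutes with spatial permutation of cells", {
  g <- grid_spec(8, 8, 1)
  set.seed(3)
  v <- matrix(rnorm(64), 8, 8)
  perm <- sample(64)
  vp <- matrix(as.vector(v)[perm], 8, 8)
  sp <- standardize(raster_layer(g, vp))$values
  s <- standardize(raster_layer(g, v))$values
  expect_equal(as.vector(sp), as.vector(s)[perm], tolerance = 1e-12)
})

test_that("distance-to-nearest matches closed form and the exhaustive oracle", {
  g <- grid_spec(5, 5, 1)
  d <- distance_to_nearest(g, cbind(2.5, 2.5))
  expect_equal(d$values[3, 3], 0)
  expect_equal(d$values[1, 1], sqrt(8), tolerance = 1e-12)

  g2 <- grid_spec(50, 50, 1)
  set.seed(4)
  feats <- cbind(runif(20, 0, 50), runif(20, 0, 50))
  out <- distance_to_nearest(g2, feats)
  ctr <- cell_centers(g2)
  oracle <- apply(ctr, 1, function(p)
    min(sqrt((feats[, 1] - p[1])^2 + (feats[, 2] - p[2])^2)))
  expect_equal(as.vector(out$values), oracle, tolerance = 1e-12)
  expect_error(distance_to_nearest(g, matrix(numeric(0), 0, 2)), "at least one")
})

test_that("distance-to-nearest is 1-Lipschitz under feature displacement", {
  g <- grid_spec(20, 20, 1)
  set.seed(5)
  feats <- cbind(runif(5, 0, 20), runif(5, 0, 20))
  base <- distance_to_nearest(g, feats)
  for (rep in 1:5) {
    delta <- runif(1, 0, 2)
    theta <- runif(1, 0, 2 * pi)
    moved <- feats
    moved[1, ] <- moved[1, ] + delta * c(cos(theta), sin(theta))
    shifted <- distance_to_nearest(g, moved)
    expect_lte(max(abs(shifted$values - base$values)), delta + 1e-12)
  }
})

test_that("area and edge aggregation matches closed forms", {
  fine <- grid_spec(8, 8, 0.5)
  coarse <- grid_spec(2, 2, 2)
  v <- matrix(0, 8, 8); v[3, 3] <- 1
  ae <- area_edge_per_cell(raster_layer(fine, v), coarse)
  expect_equal(ae$area$values[1, 1], 0.25)          # one 0.5 km cell
  expect_equal(ae$edge$values[1, 1], 2)             # 4 sides of 0.5 km

  full <- area_edge_per_cell(raster_layer(fine, matrix(1, 8, 8)), coarse)
  expect_equal(as.vector(full$area$values), rep(4, 4))
  expect_equal(as.vector(full$edge$values), rep(0, 4))
  expect_error(area_edge_per_cell(raster_layer(fine, matrix(0.5, 8, 8)), coarse),
               "binary")
})

test_that("edge length equals a brute-force side count on a random binary grid", {
  fine <- grid_spec(40, 40, 0.25)
  coarse <- grid_spec(10, 10, 1)
  set.seed(6)
  v <- matrix(rbinom(1600, 1, 0.45), 40, 40)
  ae <- area_edge_per_cell(raster_layer(fine, v), coarse)
  # oracle: loop over all interior fine-cell sides
  edge_oracle <- matrix(0, 10, 10)
  blk <- function(i) (i - 1) %/% 4 + 1
  for (i in 1:40) for (j in 1:39) {
    if (blk(j) == blk(j + 1) && v[i, j] != v[i, j + 1])
      edge_oracle[blk(i), blk(j)] <- edge_oracle[blk(i), blk(j)] + 0.25
  }
  for (i in 1:39) for (j in 1:40) {
    if (blk(i) == blk(i + 1) && v[i, j] != v[i + 1, j])
      edge_oracle[blk(i), blk(j)] <- edge_oracle[blk(i), blk(j)] + 0.25
  }
  expect_equal(ae$edge$values, edge_oracle, tolerance = 1e-12)
  area_oracle <- matrix(0, 10, 10)
  for (i in 1:40) for (j in 1:40)
    area_oracle[blk(i), blk(j)] <- area_oracle[blk(i), blk(j)] + v[i, j] * 0.0625
  expect_equal(ae$area$values, area_oracle, tolerance = 1e-12)
})

test_that("rasters round-trip through the plain-text format", {
  g <- grid_spec(6, 4, 2.5, origin = c(10, -5))
  set.seed(7)
  r <- raster_layer(g, matrix(rnorm(24), 6, 4), name = "test", units = "km")
  path <- tempfile(fileext = ".csv")
  write_raster_csv(r, path)
  r2 <- read_raster_csv(path)
  expect_equal(r2$values, r$values, tolerance = 1e-12)
  expect_equal(unclass(r2$grid), unclass(g), tolerance = 1e-12)
  expect_identical(r2$name, "test")
  unlink(path)
})
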