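# shared fixtures and oracles used across test files

# a small hyperparameter search keeps unit-test fits fast; scenarios that
# exercise the search itself pass their own grids
quick_config <- function(...) {
  isdm_config(sigma_grid = c(0.25, 0.5), rho_grid = 10,
              bias_sigma_grid = 0.5, bias_rho_grid = 15,
              n_waic_draws = 200L, ...)
}

# independent d-separation oracle: enumerate every simple undirected path and
# test blocking triple by triple (chains/forks blocked iff mid in Z,
# colliders open iff mid or a descendant of mid is in Z)
dsep_oracle <- function(dag, X, Y, Z = character()) {
  edges <- dag$edges
  adj <- unique(rbind(edges, edges[, 2:1, drop = FALSE]))
  has_edge <- function(a, b) any(edges[, 1] == a & edges[, 2] == b)
  desc_in_Z <- function(v) length(intersect(c(v, dag_descendants(dag, v)), Z)) > 0
  path_active <- function(p) {
    if (length(p) >= 3) {
      for (t in 2:(length(p) - 1)) {
        a <- p[t - 1]; m <- p[t]; b <- p[t + 1]
        collider <- has_edge(a, m) && has_edge(b, m)
        if (collider) {
          if (!desc_in_Z(m)) return(FALSE)
        } else {
          if (m %in% Z) return(FALSE)
        }
      }
    }
    TRUE
  }
  found_active <- FALSE
  walk <- function(v, path) {
    if (found_active) return()
    if (v %in% Y) {
      if (path_active(c(path, v))) found_active <<- TRUE
      return()
    }
    nb <- adj[adj[, 1] == v, 2]
    for (w in setdiff(nb, path)) walk(w, c(path, v))
  }
  for (x in X) walk(x, character())
  !found_active
}

# exhaustive minimal back-door adjustment sets by scanning all subsets of
# observed non-(exposure/outcome) nodes; independent of the implementation
minimal_sets_oracle <- function(dag, exposure, outcome) {
  cand <- setdiff(dag$nodes, c(exposure, outcome, dag$latent))
  forb <- dag_descendants(dag, exposure)
  g <- dag
  g$edges <- dag$edges[dag$edges[, 1] != exposure, , drop = FALSE]
  valid <- list()
  subsets <- list(character(0))
  for (v in cand) subsets <- c(subsets, lapply(subsets, function(s) c(s, v)))
  for (Z in subsets) {
    if (length(intersect(Z, forb))) next
    if (dsep_oracle(g, exposure, outcome, Z)) valid <- c(valid, list(sort(Z)))
  }
  keep <- vapply(seq_along(valid), function(i) {
    !any(vapply(seq_along(valid), function(j) {
      j != i && all(valid[[j]] %in% valid[[i]]) &&
        length(valid[[j]]) < length(valid[[i]])
    }, logical(1)))
  }, logical(1))
  valid <- valid[keep]
  valid[order(vapply(valid, paste, "", collapse = "\r"))]
}

# random DAG over n nodes: each upper-triangular edge present with prob p
random_dag <- function(n, p = 0.4, latent_frac = 0) {
  nodes <- LETTERS[seq_len(n)]
  edges <- matrix(character(), 0, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) edges <- rbind(edges, c(nodes[i], nodes[j]))
  latent <- if (latent_frac > 0)
    nodes[stats::runif(n) < latent_frac] else character()
  dag_create(edges, nodes = nodes, latent = latent)
}

# standard two-covariate recovery scenario: ~500 PB points and 200 PA sites
# on a 50 x 50 km landscape (the package's calibration test-bed)
recovery_dataset <- function(seed) {
  tm <- true_model(alpha = -2.36, beta = c(x1 = 1.0, x2 = -0.5),
                   sigma = 0.5, rho = 10, e_vis = 1)
  simulate_isdm_dataset(grid_spec(50, 50, 1), tm, n_sites = 200, seed = seed)
}
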