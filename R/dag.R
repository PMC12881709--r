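#' Construct a directed acyclic graph over named variables
#'
#' @param edges Two-column character matrix (parent, child); may have 0 rows.
#' @param nodes Optional character vector of node labels (defaults to the
#'   labels appearing in \code{edges}); isolated nodes can be declared here.
#' @param latent Character vector of latent (unobserved) node labels; latent
#'   nodes can appear on paths but never in adjustment sets.
#' @return An object of class \code{pest_dag}.
#' @export
dag_create <- function(edges, nodes = NULL, latent = character()) {
  edges <- matrix(as.character(edges), ncol = 2)
  nodes <- unique(c(nodes, as.vector(t(edges))))
  if (!length(nodes)) stop("a DAG needs at least one node")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
  if (!all(latent %in% nodes)) stop("latent labels not among nodes")
  d <- structure(list(nodes = nodes, edges = edges,
                      latent = unique(latent)), class = "pest_dag")
  cyc <- find_cycle(d)
  if (!is.null(cyc))
    stop("graph is cyclic: ", paste(cyc, collapse = " -> "))
  d
}

#' @export
print.pest_dag <- function(x, ...) {
  cat(sprintf("<pest_dag> %d nodes (%d latent), %d edges\n",
              length(x$nodes), length(x$latent), nrow(x$edges)))
  invisible(x)
}

# returns a cycle as a node sequence, or NULL if acyclic (DFS colouring)
find_cycle <- function(dag) {
  state <- stats::setNames(rep(0L, length(dag$nodes)), dag$nodes)
  kids <- split(dag$edges[, 2], factor(dag$edges[, 1], levels = dag$nodes))
  cycle <- NULL
  visit <- function(v, stack) {
    if (!is.null(cycle)) return()
    if (state[[v]] == 1L) {
      cycle <<- c(stack[which(stack == v):length(stack)], v)
      return()
    }
    if (state[[v]] == 2L) return()
    state[[v]] <<- 1L
    for (c in kids[[v]]) visit(c, c(stack, v))
    state[[v]] <<- 2L
  }
  for (v in dag$nodes) visit(v, character())
  cycle
}

dag_parents <- function(dag, v) dag$edges[dag$edges[, 2] == v, 1]
dag_children <- function(dag, v) dag$edges[dag$edges[, 1] == v, 2]

#' Ancestors / descendants of a node set (exclusive of the set itself)
#'
#' @param dag A \code{pest_dag}.
#' @param v Character vector of node labels.
#' @return Character vector of labels.
#' @export
dag_ancestors <- function(dag, v) {
  found <- character(); front <- v
  while (length(front)) {
    pa <- unique(unlist(lapply(front, dag_parents, dag = dag)))
    front <- setdiff(pa, c(found, v))
    found <- union(found, front)
  }
  found
}

#' @rdname dag_ancestors
#' @export
dag_descendants <- function(dag, v) {
  found <- character(); front <- v
  while (length(front)) {
    ch <- unique(unlist(lapply(front, dag_children, dag = dag)))
    front <- setdiff(ch, c(found, v))
    found <- union(found, front)
  }
  found
}

#' Topological order of a DAG
#'
#' @param dag A \code{pest_dag}.
#' @return Character vector of all nodes, parents before children; ties are
#'   broken by the node declaration order, so the result is deterministic.
#' @export
dag_topological_order <- function(dag) {
  indeg <- stats::setNames(rep(0L, length(dag$nodes)), dag$nodes)
  for (v in dag$edges[, 2]) indeg[[v]] <- indeg[[v]] + 1L
  out <- character()
  avail <- dag$nodes[indeg[dag$nodes] == 0L]
  while (length(avail)) {
    v <- avail[1]
    out <- c(out, v)
    avail <- avail[-1]
    for (c in dag_children(dag, v)) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) avail <- c(avail, c)
    }
    avail <- avail[order(match(avail, dag$nodes))]
  }
  out
}

#' Parse a DAG from its plain-text edge-list format
#'
#' The format is one \code{"A -> B"} edge per line, with optional
#' \code{"latent: X, Y"} and \code{"node: X"} directives, blank lines and
#' \code{#} comments.  Whitespace is insignificant.
#'
#' @param text Character scalar (embedded newlines) or vector of lines.
#' @return A \code{pest_dag}.
#' @seealso \code{\link{serialize_dag}} for the inverse.
#' @export
parse_dag <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  latent <- character(); extra <- character()
  edges <- matrix(character(), 0, 2)
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    if (grepl("^latent\\s*:", ln)) {
      latent <- c(latent, trimws(strsplit(sub("^latent\\s*:", "", ln), ",")[[1]]))
    } else if (grepl("^node\\s*:", ln)) {
      extra <- c(extra, trimws(strsplit(sub("^node\\s*:", "", ln), ",")[[1]]))
    } else if (grepl("->", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "->", fixed = TRUE)[[1]])
      if (length(parts) != 2L || !all(nzchar(parts)))
        stop("malformed edge on line ", k, ": '", lines[k], "'")
      edges <- rbind(edges, parts)
    } else {
      stop("cannot parse line ", k, ": '", lines[k], "'")
    }
  }
  dag_create(edges, nodes = extra, latent = latent)
}

#' Serialise a DAG to its plain-text format
#'
#' @param dag A \code{pest_dag}.
#' @return Character vector of lines; \code{parse_dag(serialize_dag(d))}
#'   reconstructs \code{d}.
#' @export
serialize_dag <- function(dag) {
  stopifnot(inherits(dag, "pest_dag"))
  lines <- character()
  iso <- setdiff(dag$nodes, as.vector(dag$edges))
  if (length(iso)) lines <- c(lines, paste0("node: ", paste(iso, collapse = ", ")))
  if (length(dag$latent))
    lines <- c(lines, paste0("latent: ", paste(dag$latent, collapse = ", ")))
  c(lines, paste(dag$edges[, 1], "->", dag$edges[, 2]))
}

#' Read the bundled maximal pest-introduction/establishment DAG
#'
#' Loads the editable text asset shipped with the package encoding assumed
#' causal links among landscape covariates, the latent introduction and
#' establishment probabilities (\code{p_i}, \code{p_e}) and pest occurrence
#' \code{y}.  The edge list is configuration: users should edit the file (or
#' supply their own) to match their causal assumptions.
#'
#' @param path Optional path to an alternative DAG file.
#' @return A \code{pest_dag}.
#' @export
load_maximal_dag <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "maximal_dag.txt", package = "pestisdm",
                        mustWork = TRUE)
  parse_dag(readLines(path))
}

#' Test d-separation of two node sets given a conditioning set
#'
#' Implements the standard reachability ("Bayes-ball") algorithm: X and Y are
#' d-separated given Z iff every path between them is blocked, with chains
#' and forks blocked by conditioning and colliders open iff the collider or
#' one of its descendants is conditioned on.
#'
#' @param dag A \code{pest_dag}.
#' @param X,Y,Z Disjoint character vectors of node labels (Z may be empty).
#' @return Logical scalar.
#' @export
d_separated <- function(dag, X, Y, Z = character()) {
  stopifnot(inherits(dag, "pest_dag"))
  unknown <- setdiff(c(X, Y, Z), dag$nodes)
  if (length(unknown)) stop("unknown node(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(X, Y)) || length(intersect(X, Z)) ||
      length(intersect(Y, Z))) stop("X, Y, Z must be disjoint")
  anZ <- union(Z, dag_ancestors(dag, Z))
  # states: (node, entered-moving-up) where "up" means the walk may proceed
  # to parents and children, "down" only onwards through children unless the
  # node unlocks a collider
  seen <- new.env(parent = emptyenv())
  queue <- lapply(X, function(x) list(v = x, up = TRUE))
  reached <- character()
  while (length(queue)) {
    st <- queue[[1]]; queue <- queue[-1]
    key <- paste0(st$v, if (st$up) "^" else "v")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    if (!(st$v %in% Z)) reached <- union(reached, st$v)
    if (st$up) {
      if (!(st$v %in% Z)) {
        for (p in dag_parents(dag, st$v)) queue <- c(queue, list(list(v = p, up = TRUE)))
        for (ch in dag_children(dag, st$v)) queue <- c(queue, list(list(v = ch, up = FALSE)))
      }
    } else {
      if (!(st$v %in% Z))
        for (ch in dag_children(dag, st$v)) queue <- c(queue, list(list(v = ch, up = FALSE)))
      if (st$v %in% anZ)
        for (p in dag_parents(dag, st$v)) queue <- c(queue, list(list(v = p, up = TRUE)))
    }
  }
  !any(Y %in% reached)
}

# graph with all edges out of x removed (for back-door checks)
remove_outgoing <- function(dag, x) {
  keep <- !(dag$edges[, 1] %in% x)
  d <- dag
  d$edges <- dag$edges[keep, , drop = FALSE]
  d
}

# Z satisfies the back-door criterion for (exposure, outcome)
backdoor_valid <- function(dag, exposure, outcome, Z) {
  if (length(intersect(Z, c(exposure, outcome, dag_descendants(dag, exposure)))))
    return(FALSE)
  g <- remove_outgoing(dag, exposure)
  d_separated(g, exposure, outcome, Z)
}

#' All inclusion-minimal back-door adjustment sets for a total effect
#'
#' Finds every inclusion-minimal set Z of observed nodes containing no
#' descendant of the exposure such that Z blocks all back-door paths from
#' exposure to outcome (equivalently, exposure and outcome are d-separated by
#' Z in the graph with the exposure's outgoing edges removed).  Candidates
#' are restricted to ancestors of the exposure or outcome, which is without
#' loss for minimal separators.  An empty-set result (\code{list(character(0))})
#' means the unadjusted estimate already identifies the total effect.
#'
#' @param dag A \code{pest_dag}.
#' @param exposure,outcome Observed node labels (distinct).
#' @return An object of class \code{adjustment_result} with fields
#'   \code{exposure}, \code{outcome}, \code{sets} (list of character vectors,
#'   each sorted, the list ordered lexicographically) and \code{criterion}.
#'   Signals an identifiability error when no observed set is valid.
#' @export
minimal_adjustment_sets <- function(dag, exposure, outcome) {
  stopifnot(inherits(dag, "pest_dag"))
  if (exposure == outcome) stop("exposure and outcome must differ")
  if (exposure %in% dag$latent || outcome %in% dag$latent)
    stop("exposure and outcome must be observed")
  if (!all(c(exposure, outcome) %in% dag$nodes))
    stop("unknown node(s): ",
         paste(setdiff(c(exposure, outcome), dag$nodes), collapse = ", "))
  forb <- c(exposure, outcome, dag$latent, dag_descendants(dag, exposure))
  cand <- setdiff(
    intersect(dag$nodes, dag_ancestors(dag, c(exposure, outcome))), forb)
  cand <- cand[order(cand)]
  minimal <- list()
  is_superset <- function(Z) any(vapply(minimal, function(m) all(m %in% Z), logical(1)))
  for (size in 0:length(cand)) {
    subs <- if (size == 0L) list(character(0)) else
      utils::combn(cand, size, simplify = FALSE)
    for (Z in subs) {
      if (is_superset(Z)) next
      if (backdoor_valid(dag, exposure, outcome, Z))
        minimal <- c(minimal, list(sort(Z)))
    }
  }
  if (!length(minimal))
    stop("no observed adjustment set satisfies the back-door criterion for '",
         exposure, "' -> '", outcome, "' (latent confounding)")
  key <- vapply(minimal, paste, "", collapse = "\r")
  minimal <- minimal[order(key)]
  structure(list(exposure = exposure, outcome = outcome, sets = minimal,
                 criterion = "back-door, total effect"),
            class = "adjustment_result")
}

#' @export
print.adjustment_result <- function(x, ...) {
  cat(sprintf("<adjustment_result> %s -> %s (%s)\n", x$exposure, x$outcome,
              x$criterion))
  for (s in x$sets)
    cat("  {", paste(s, collapse = ", "), "}\n")
  invisible(x)
}

#' DAG-sequence sensitivity analysis for one focal variable
#'
#' Builds a sequence of nested DAGs starting from the focal variable alone
#' (the unadjusted effect) and adding the remaining observed variables one at
#' a time until the maximal DAG is reached; each DAG is the induced subgraph
#' on the included variables plus the outcome and all latent ancestors of the
#' outcome.  For every DAG in the sequence the minimal back-door adjustment
#' sets are computed; each unique set across the sequence implies one model
#' fit.
#'
#' @param maximal The maximal \code{pest_dag}.
#' @param focal Observed focal variable.
#' @param outcome Outcome label (default \code{"y"}).
#' @param order Order in which to add the remaining observed variables;
#'   default is their topological order in the maximal DAG.
#' @return A list with \code{steps} (per DAG: \code{dag}, \code{added},
#'   \code{sets}) and \code{unique_sets} (deduplicated list of adjustment
#'   sets across the whole sequence).
#' @export
sensitivity_sequence <- function(maximal, focal, outcome = "y", order = NULL) {
  stopifnot(inherits(maximal, "pest_dag"))
  if (!all(c(focal, outcome) %in% maximal$nodes)) stop("unknown focal/outcome")
  rest <- setdiff(maximal$nodes, c(focal, outcome, maximal$latent))
  if (is.null(order)) {
    order <- intersect(dag_topological_order(maximal), rest)
  } else if (!setequal(order, rest) || anyDuplicated(order)) {
    stop("order must be a permutation of the remaining observed variables")
  }
  lat_anc <- intersect(maximal$latent,
                       c(outcome, dag_ancestors(maximal, outcome)))
  induced <- function(keep) {
    e <- maximal$edges
    e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
    dag_create(e, nodes = keep, latent = intersect(maximal$latent, keep))
  }
  steps <- vector("list", length(order) + 1L)
  for (k in 0:length(order)) {
    keep <- c(focal, outcome, lat_anc, order[seq_len(k)])
    d <- induced(keep)
    steps[[k + 1L]] <- list(
      dag = d,
      added = if (k) order[seq_len(k)] else character(),
      sets = minimal_adjustment_sets(d, focal, outcome)$sets
    )
  }
  all_sets <- unlist(lapply(steps, `[[`, "sets"), recursive = FALSE)
  key <- vapply(all_sets, paste, "", collapse = "\r")
  list(steps = steps, unique_sets = all_sets[!duplicated(key)])
}
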