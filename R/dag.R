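#' Construct a directed acyclic graph
#'
#' Lightweight DAG container used for generator ground truth and as the
#' d-separation oracle when validating causal discovery.
#'
#' @param nodes Character vector of node names.
#' @param edges Tibble/data frame with columns `from`, `to`.
#' @return A `causal_dag` object.
#' @export
causal_dag <- function(nodes, edges) {
  edges <- tibble::as_tibble(edges)[, c("from", "to")]
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes))
  p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) amat[cbind(edges$from, edges$to)] <- TRUE
  if (any(diag(amat))) stop("self-loops are not allowed", call. = FALSE)
  # acyclicity via repeated leaf stripping
  remaining <- rep(TRUE, p)
  repeat {
    indeg <- colSums(amat[remaining, remaining, drop = FALSE])
    leaves <- which(remaining)[indeg == 0]
    if (length(leaves) == 0) break
    remaining[leaves] <- FALSE
  }
  if (any(remaining)) stop("edges contain a cycle", call. = FALSE)
  structure(list(nodes = nodes, edges = edges, amat = amat),
              class = "causal_dag")
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("<causal_dag>", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

dag_parents <- function(dag, node) {
  dag$nodes[dag$amat[, node]]
}

dag_ancestors <- function(dag, nodes) {
  # nodes plus all their ancestors
  found <- unique(nodes)
  frontier <- found
  while (length(frontier) > 0) {
    pa <- unique(unlist(lapply(frontier, dag_parents, dag = dag)))
    frontier <- setdiff(pa, found)
    found <- c(found, frontier)
  }
  found
}

#' d-separation in a DAG
#'
#' Classic ancestral moral graph criterion: restrict to the ancestors of
#' `{x, y} union z`, moralize (marry parents of common children, drop
#' directions), delete `z`, and test whether `x` and `y` are still connected.
#'
#' @param dag A [causal_dag()].
#' @param x,y Node names.
#' @param z Character vector of conditioning nodes (may be empty).
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @export
dseparated <- function(dag, x, y, z = character(0)) {
  stopifnot(x %in% dag$nodes, y %in% dag$nodes, all(z %in% dag$nodes))
  if (x == y) return(FALSE)
  if (x %in% z || y %in% z) {
    stop("conditioning set must exclude x and y", call. = FALSE)
  }
  anc <- dag_ancestors(dag, c(x, y, z))
  a <- dag$amat[anc, anc, drop = FALSE]
  # moralize: connect parents sharing a child, then symmetrize
  moral <- a | t(a)
  for (child in seq_along(anc)) {
    pa <- which(a[, child])
    if (length(pa) > 1) moral[pa, pa] <- TRUE
  }
  diag(moral) <- FALSE
  keep <- !(anc %in% z)
  moral <- moral[keep, keep, drop = FALSE]
  nodes <- anc[keep]
  # breadth-first reachability from x
  reach <- nodes == x
  repeat {
    new <- (as.vector(moral %*% reach) > 0) & !reach
    if (!any(new)) break
    reach <- reach | new
  }
  !reach[nodes == y]
}

#' Random DAG for validation experiments
#'
#' Samples a DAG on `p` nodes by drawing each edge `i -> j` (under a random
#' topological order) independently with probability `prob`.
#'
#' @param p Number of nodes.
#' @param prob Edge probability.
#' @param seed Integer seed.
#' @return A [causal_dag()] with nodes `v1..vp`.
#' @export
random_dag <- function(p, prob = 0.3, seed = 1L) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(p))
  order <- sample(nodes)
  from <- character(0)
  to <- character(0)
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      if (stats::runif(1) < prob) {
        from <- c(from, order[i])
        to <- c(to, order[j])
      }
    }
  }
  causal_dag(nodes, tibble::tibble(from = from, to = to))
}

#' Sample linear-Gaussian data from a DAG
#'
#' Each node is a unit-variance-noise linear function of its parents with the
#' given coefficient; used to validate conditional-independence tests against
#' d-separation.
#'
#' @param dag A [causal_dag()].
#' @param n Sample size.
#' @param coef Edge coefficient (scalar, applied to every edge).
#' @param seed Integer seed.
#' @return A tibble with one column per node.
#' @export
simulate_dag_data <- function(dag, n, coef = 0.6, seed = 1L) {
  set.seed(seed)
  # topological order by leaf stripping
  amat <- dag$amat
  order <- character(0)
  left <- dag$nodes
  while (length(left) > 0) {
    indeg <- colSums(amat[left, left, drop = FALSE])
    roots <- sort(left[indeg == 0])
    order <- c(order, roots)
    left <- setdiff(left, roots)
  }
  x <- matrix(0, n, length(dag$nodes), dimnames = list(NULL, dag$nodes))
  for (node in order) {
    pa <- dag_parents(dag, node)
    mu <- if (length(pa) > 0) rowSums(x[, pa, drop = FALSE]) * coef else 0
    x[, node] <- mu + stats::rnorm(n)
  }
  tibble::as_tibble(x)
}
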