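# Endpoint mark codes used in PAG adjacency matrices: amat[i, j] is the mark
# at node j on the edge between i and j.
MARK_NONE <- 0L
MARK_CIRCLE <- 1L
MARK_ARROW <- 2L
MARK_TAIL <- 3L

mark_label <- function(code) {
  c("none", "circle", "arrow", "tail")[code + 1L]
}

#' Fisher-z conditional independence test
#'
#' Tests whether variables `i` and `j` are partially uncorrelated given
#' `cond_set`, via the Fisher z-transform of the sample partial correlation.
#' Binary variables are treated as linear-Gaussian proxies (standard practice
#' for constraint-based discovery on mixed clinical tables; a documented
#' approximation).
#'
#' @param data Numeric data frame or matrix.
#' @param i,j Column names or indices.
#' @param cond_set Conditioning columns (possibly empty).
#' @param alpha Significance level; `independent = (p_value >= alpha)`.
#' @return A list: `p_value`, `independent`, `statistic`, `degenerate` (TRUE
#'   when the conditioning covariance was singular; dependence is returned).
#' @export
ci_test <- function(data, i, j, cond_set = character(0), alpha = 0.05) {
  x <- as.matrix(data)
  cols <- colnames(x)
  idx <- function(v) if (is.character(v)) match(v, cols) else as.integer(v)
  i <- idx(i); j <- idx(j); s <- idx(cond_set)
  if (i %in% s || j %in% s) {
    stop("conditioning set must exclude i and j", call. = FALSE)
  }
  n <- nrow(x)
  if (n <= length(s) + 3) stop("sample too small for the conditioning set",
                               call. = FALSE)
  cmat <- suppressWarnings(stats::cor(x[, c(i, j, s), drop = FALSE]))
  r <- if (anyNA(cmat)) NA_real_ else partial_correlation(cmat)
  if (is.na(r)) {
    return(list(p_value = 0, independent = FALSE, statistic = Inf,
                degenerate = TRUE))
  }
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  stat <- sqrt(n - length(s) - 3) * abs(atanh(r))
  p <- 2 * stats::pnorm(-stat)
  list(p_value = p, independent = p >= alpha, statistic = stat,
       degenerate = FALSE)
}

# Partial correlation of the first two variables given the rest, from their
# joint correlation matrix; NA if the matrix is (numerically) singular.
partial_correlation <- function(cmat) {
  prec <- tryCatch(solve(cmat), error = function(e) NULL)
  if (is.null(prec)) return(NA_real_)
  -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
}

# Independence closures ------------------------------------------------------

# Fisher-z closure over a fixed dataset; the correlation matrix is computed
# once up front.
make_fisherz_oracle <- function(data, alpha) {
  x <- as.matrix(data)
  cmat <- suppressWarnings(stats::cor(x))
  n <- nrow(x)
  function(i, j, s) {
    sub <- cmat[c(i, j, s), c(i, j, s), drop = FALSE]
    r <- if (anyNA(sub)) NA_real_ else partial_correlation(sub)
    if (is.na(r)) return(FALSE) # degenerate: treat as dependent
    r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
    stat <- sqrt(n - length(s) - 3) * abs(atanh(r))
    2 * stats::pnorm(-stat) >= alpha
  }
}

make_dsep_oracle <- function(dag, nodes) {
  function(i, j, s) {
    dseparated(dag, nodes[i], nodes[j], nodes[s])
  }
}

# Background knowledge --------------------------------------------------------

#' Background knowledge for FCI
#'
#' `fci_knowledge()` builds the generic container; [jci_knowledge()] builds the
#' pooled-context (JCI) version. `forbidden_adjacency` pairs never enter the
#' skeleton; edges listed in `oriented_edges` (and every context-system edge,
#' for JCI) are oriented `from -> to` with a tail at `from` after the skeleton
#' phase, and nodes in `no_incoming` never receive arrowheads during collider
#' orientation.
#'
#' @param nodes All variable names.
#' @param forbidden_adjacency Tibble (`a`, `b`) of excluded adjacencies.
#' @param oriented_edges Tibble (`from`, `to`) of fixed orientations.
#' @param no_incoming Nodes that may not receive arrowheads.
#' @return An `fci_knowledge` object.
#' @export
fci_knowledge <- function(nodes, forbidden_adjacency = NULL,
                          oriented_edges = NULL, no_incoming = character(0)) {
  structure(
    list(nodes = nodes,
         forbidden_adjacency = forbidden_adjacency,
         oriented_edges = oriented_edges,
         no_incoming = no_incoming),
    class = "fci_knowledge"
  )
}

#' Fast Causal Inference (FCI)
#'
#' Constraint-based causal discovery sound under latent confounding: adjacency
#' search with conditioning sets of increasing size (stable ordering, frozen
#' adjacencies per level, lexicographic subset enumeration), possible-d-sep
#' pruning, collider orientation from separating sets, and the standard
#' orientation rules (R1-R4 and the tail-completing R8-R10; the selection-bias
#' rules R5-R7 are omitted as selection bias is assumed absent). Output is a
#' partial ancestral graph (PAG) with circle/arrow/tail endpoint marks.
#'
#' @param x A numeric data frame/matrix (Fisher-z test), or a [causal_dag()]
#'   to run with the exact d-separation oracle.
#' @param alpha Significance level of the conditional-independence test.
#' @param max_cond_size Largest conditioning set searched (tractability cap;
#'   applies to both the adjacency and possible-d-sep phases).
#' @param knowledge Optional [fci_knowledge()] / [jci_knowledge()].
#' @param observed When `x` is a [causal_dag()] oracle: the observed nodes
#'   (defaults to all); the remaining nodes act as latent confounders that the
#'   oracle marginalizes over.
#' @return A `pag` object: `nodes`, integer mark matrix `amat`
#'   (`amat[i, j]` = mark at `j`: 1 circle, 2 arrow, 3 tail), and `sepsets`.
#' @export
fci <- function(x, alpha = 0.05, max_cond_size = 3, knowledge = NULL,
                observed = NULL) {
  if (inherits(x, "causal_dag")) {
    nodes <- if (is.null(observed)) x$nodes else observed
    stopifnot(all(nodes %in% x$nodes))
    indep <- make_dsep_oracle(x, nodes)
  } else {
    nodes <- colnames(x)
    if (is.null(nodes)) nodes <- paste0("v", seq_len(ncol(x)))
    indep <- make_fisherz_oracle(x, alpha)
  }
  p <- length(nodes)
  if (p < 2) stop("need at least 2 variables", call. = FALSE)

  forbidden <- matrix(FALSE, p, p)
  no_head <- rep(FALSE, p)
  fixed <- NULL
  if (!is.null(knowledge)) {
    stopifnot(inherits(knowledge, "fci_knowledge"))
    fa <- knowledge$forbidden_adjacency
    if (!is.null(fa) && nrow(fa) > 0) {
      ia <- match(fa$a, nodes); ib <- match(fa$b, nodes)
      forbidden[cbind(ia, ib)] <- TRUE
      forbidden[cbind(ib, ia)] <- TRUE
    }
    no_head[match(knowledge$no_incoming, nodes)] <- TRUE
    fixed <- knowledge$oriented_edges
  }

  sk <- fci_skeleton(indep, p, max_cond_size, forbidden)
  amat <- sk$amat
  sepsets <- sk$sepsets

  amat <- orient_vstructures(amat, sepsets, no_head)

  # possible-d-sep pruning, then full re-orientation from scratch
  pds_removed <- FALSE
  for (i in seq_len(p)) {
    pds_i <- possible_dsep(amat, i)
    adj_i <- which(amat[i, ] != MARK_NONE)
    for (j in adj_i) {
      if (amat[i, j] == MARK_NONE) next
      cand <- setdiff(pds_i, c(i, j))
      found <- search_sepset(indep, i, j, cand, max_cond_size)
      if (!is.null(found)) {
        amat[i, j] <- MARK_NONE
        amat[j, i] <- MARK_NONE
        sepsets[[i]][[j]] <- found
        sepsets[[j]][[i]] <- found
        pds_removed <- TRUE
      }
    }
  }
  # re-orient from scratch with the final sepsets
  amat[amat != MARK_NONE] <- MARK_CIRCLE
  amat <- orient_vstructures(amat, sepsets, no_head)

  amat <- apply_fixed_orientations(amat, fixed, nodes)
  amat <- fci_orientation_rules(amat, sepsets)
  dimnames(amat) <- list(nodes, nodes)
  structure(list(nodes = nodes, amat = amat, sepsets = sepsets,
                 alpha = alpha, max_cond_size = max_cond_size),
              class = "pag")
}

# Stable adjacency search. Returns circles-only amat and sepsets.
fci_skeleton <- function(indep, p, max_cond_size, forbidden) {
  amat <- matrix(MARK_CIRCLE, p, p)
  diag(amat) <- MARK_NONE
  amat[forbidden] <- MARK_NONE
  sepsets <- replicate(p, vector("list", p), simplify = FALSE)
  for (l in 0:max_cond_size) {
    adj_frozen <- lapply(seq_len(p), function(i) which(amat[i, ] != MARK_NONE))
    for (i in seq_len(p)) {
      for (j in adj_frozen[[i]]) {
        if (j < i && i %in% adj_frozen[[j]]) next # each unordered pair once,
        if (amat[i, j] == MARK_NONE) next         # but both neighbourhoods
        found <- NULL
        for (side in unique(list(c(i, j), c(j, i)))) {
          cand <- setdiff(adj_frozen[[side[1]]], side[2])
          if (length(cand) < l) next
          found <- search_sepset_exact(indep, i, j, cand, l)
          if (!is.null(found)) break
        }
        if (!is.null(found)) {
          amat[i, j] <- MARK_NONE
          amat[j, i] <- MARK_NONE
          sepsets[[i]][[j]] <- found
          sepsets[[j]][[i]] <- found
        }
      }
    }
  }
  list(amat = amat, sepsets = sepsets)
}

# All subsets of `cand` of exactly size l, lexicographic; NULL if none works.
search_sepset_exact <- function(indep, i, j, cand, l) {
  cand <- sort(cand)
  if (l == 0) {
    if (indep(i, j, integer(0))) return(integer(0))
    return(NULL)
  }
  if (length(cand) < l) return(NULL)
  # enumerate index subsets: combn() would misread a length-1 candidate set
  subsets <- utils::combn(length(cand), l, simplify = FALSE)
  for (ix in subsets) {
    s <- cand[ix]
    if (indep(i, j, s)) return(s)
  }
  NULL
}

# Subsets of sizes 0..max_size (used in the possible-d-sep phase).
search_sepset <- function(indep, i, j, cand, max_size) {
  for (l in 0:min(max_size, length(cand))) {
    found <- search_sepset_exact(indep, i, j, cand, l)
    if (!is.null(found)) return(found)
  }
  NULL
}

# Orient unshielded colliders: i *-> k <-* j when k is not in sepset(i, j).
orient_vstructures <- function(amat, sepsets, no_head) {
  p <- nrow(amat)
  for (k in seq_len(p)) {
    if (no_head[k]) next
    nb <- which(amat[k, ] != MARK_NONE)
    if (length(nb) < 2) next
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a >= b) next
        i <- nb[a]; j <- nb[b]
        if (amat[i, j] != MARK_NONE) next # shielded
        s <- sepsets[[i]][[j]]
        if (is.null(s)) next
        if (!(k %in% s)) {
          amat[i, k] <- MARK_ARROW
          amat[j, k] <- MARK_ARROW
        }
      }
    }
  }
  amat
}

# Possible-d-sep set of node i: nodes reachable on a path where every
# consecutive triple is a collider or a triangle.
possible_dsep <- function(amat, i) {
  p <- nrow(amat)
  # state: directed "arrival" edges (from, to); expand respecting the triple rule
  reached <- matrix(FALSE, p, p)
  frontier <- list()
  for (v in which(amat[i, ] != MARK_NONE)) {
    reached[i, v] <- TRUE
    frontier <- c(frontier, list(c(i, v)))
  }
  out <- logical(p)
  out[which(amat[i, ] != MARK_NONE)] <- TRUE
  while (length(frontier) > 0) {
    edge <- frontier[[1]]
    frontier <- frontier[-1]
    a <- edge[1]; b <- edge[2]
    for (c0 in which(amat[b, ] != MARK_NONE)) {
      if (c0 == a || c0 == i) next
      collider <- amat[a, b] == MARK_ARROW && amat[c0, b] == MARK_ARROW
      triangle <- amat[a, c0] != MARK_NONE
      if ((collider || triangle) && !reached[b, c0]) {
        reached[b, c0] <- TRUE
        out[c0] <- TRUE
        frontier <- c(frontier, list(c(b, c0)))
      }
    }
  }
  which(out)
}

apply_fixed_orientations <- function(amat, fixed, nodes) {
  if (is.null(fixed) || nrow(fixed) == 0) return(amat)
  for (r in seq_len(nrow(fixed))) {
    from <- match(fixed$from[r], nodes)
    to <- match(fixed$to[r], nodes)
    if (amat[from, to] != MARK_NONE) {
      amat[from, to] <- MARK_ARROW # arrowhead at `to`
      amat[to, from] <- MARK_TAIL  # tail at `from`
    }
  }
  amat
}

# Zhang's orientation rules R1-R4 and R8-R10, iterated to fixpoint.
fci_orientation_rules <- function(amat, sepsets) {
  p <- nrow(amat)
  adjacent <- function(i, j) amat[i, j] != MARK_NONE
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(p)) {
      for (k in seq_len(p)) {
        if (!adjacent(i, k)) next
        # R1: i *-> k o-* j, i and j non-adjacent  =>  k -> j
        if (amat[i, k] == MARK_ARROW) {
          for (j in seq_len(p)) {
            if (j == i || !adjacent(k, j) || adjacent(i, j)) next
            if (amat[j, k] == MARK_CIRCLE) {
              amat[j, k] <- MARK_TAIL
              amat[k, j] <- MARK_ARROW
              changed <- TRUE
            }
          }
        }
        # R2: chain i -> k *-> j or i *-> k -> j, circle at j on i-j => arrow
        for (j in seq_len(p)) {
          if (j == i || j == k || !adjacent(i, j) || !adjacent(k, j)) next
          if (amat[i, j] != MARK_CIRCLE) next
          chain1 <- amat[i, k] == MARK_ARROW && amat[k, i] == MARK_TAIL &&
            amat[k, j] == MARK_ARROW
          chain2 <- amat[i, k] == MARK_ARROW &&
            amat[k, j] == MARK_ARROW && amat[j, k] == MARK_TAIL
          if (chain1 || chain2) {
            amat[i, j] <- MARK_ARROW
            changed <- TRUE
          }
        }
      }
    }
    # R3: i *-> k <-* j, i,j non-adjacent, l with circles to both i and j,
    # and l *-o k  =>  l *-> k
    for (k in seq_len(p)) {
      heads <- which(amat[, k] == MARK_ARROW)
      if (length(heads) < 2) next
      for (ii in seq_along(heads)) {
        for (jj in seq_along(heads)) {
          if (ii >= jj) next
          i <- heads[ii]; j <- heads[jj]
          if (adjacent(i, j)) next
          for (l in seq_len(p)) {
            if (l %in% c(i, j, k)) next
            if (amat[i, l] == MARK_CIRCLE && amat[j, l] == MARK_CIRCLE &&
                adjacent(l, i) && adjacent(l, j) &&
                adjacent(l, k) && amat[l, k] == MARK_CIRCLE) {
              amat[l, k] <- MARK_ARROW
              changed <- TRUE
            }
          }
        }
      }
    }
    # R4: discriminating paths
    upd <- rule4(amat, sepsets)
    if (upd$changed) {
      amat <- upd$amat
      changed <- TRUE
    }
    # R8: a -> b -> c (or a -o b -> c) and a o-> c  =>  a -> c
    for (a in seq_len(p)) {
      for (c0 in seq_len(p)) {
        if (a == c0 || !adjacent(a, c0)) next
        if (!(amat[a, c0] == MARK_ARROW && amat[c0, a] == MARK_CIRCLE)) next
        for (b in seq_len(p)) {
          if (b == a || b == c0 || !adjacent(a, b) || !adjacent(b, c0)) next
          ab_dir <- amat[a, b] == MARK_ARROW && amat[b, a] == MARK_TAIL
          ab_circ <- amat[a, b] == MARK_CIRCLE && amat[b, a] == MARK_TAIL
          bc_dir <- amat[b, c0] == MARK_ARROW && amat[c0, b] == MARK_TAIL
          if ((ab_dir || ab_circ) && bc_dir) {
            amat[c0, a] <- MARK_TAIL
            changed <- TRUE
            break
          }
        }
      }
    }
    # R9: a o-> c and an uncovered potentially-directed path a, b, ..., c
    # with b not adjacent to c  =>  tail at a
    for (a in seq_len(p)) {
      for (c0 in seq_len(p)) {
        if (a == c0 || !adjacent(a, c0)) next
        if (!(amat[a, c0] == MARK_ARROW && amat[c0, a] == MARK_CIRCLE)) next
        if (exists_uncovered_pd_path(amat, a, c0, avoid_first_adjacent = TRUE)) {
          amat[c0, a] <- MARK_TAIL
          changed <- TRUE
        }
      }
    }
    # R10: a o-> c, b -> c <- d, uncovered pd paths a..b and a..d whose first
    # nodes are distinct and non-adjacent  =>  tail at a
    for (a in seq_len(p)) {
      for (c0 in seq_len(p)) {
        if (a == c0 || !adjacent(a, c0)) next
        if (!(amat[a, c0] == MARK_ARROW && amat[c0, a] == MARK_CIRCLE)) next
        parents_c <- which(amat[, c0] == MARK_ARROW &
                             amat[c0, ] == MARK_TAIL)
        parents_c <- setdiff(parents_c, a)
        if (length(parents_c) < 2) next
        done <- FALSE
        for (b in parents_c) {
          for (d in parents_c) {
            if (b >= d || done) next
            fb <- first_nodes_uncovered_pd(amat, a, b, forbid = c0)
            fd <- first_nodes_uncovered_pd(amat, a, d, forbid = c0)
            for (mu in fb) {
              for (om in fd) {
                if (mu != om && amat[mu, om] == MARK_NONE && mu != a &&
                    om != a) {
                  amat[c0, a] <- MARK_TAIL
                  changed <- TRUE
                  done <- TRUE
                }
              }
            }
          }
        }
      }
    }
  }
  amat
}

# R4 helper: for every circle mark at b on a b-c edge, look for a
# discriminating path <d, ..., a, b, c> and orient per the sepset test.
rule4 <- function(amat, sepsets) {
  p <- nrow(amat)
  changed <- FALSE
  for (b in seq_len(p)) {
    for (c0 in seq_len(p)) {
      if (b == c0 || amat[b, c0] == MARK_NONE) next
      if (amat[c0, b] != MARK_CIRCLE) next # mark at b on b-c edge must be circle
      # candidates a: collider with b (arrowheads both sides), parent of c
      cand_a <- which(amat[, b] == MARK_ARROW & amat[b, ] == MARK_ARROW &
                        amat[, c0] == MARK_ARROW & amat[c0, ] == MARK_TAIL)
      cand_a <- setdiff(cand_a, c0)
      for (a in cand_a) {
        d <- find_discriminating_origin(amat, a, b, c0)
        if (is.null(d)) next
        s <- sepsets[[d]][[c0]]
        if (!is.null(s) && b %in% s) {
          # b is an ancestor of c: orient b -> c
          amat[c0, b] <- MARK_TAIL
          amat[b, c0] <- MARK_ARROW
        } else {
          # collider: a <-> b <-> c (upgrade circles only)
          if (amat[b, a] == MARK_CIRCLE) amat[b, a] <- MARK_ARROW
          amat[b, c0] <- MARK_ARROW
          amat[c0, b] <- MARK_ARROW
        }
        changed <- TRUE
        break
      }
    }
  }
  list(amat = amat, changed = changed)
}

# Search backwards from `a` for the origin d of a discriminating path
# <d, ..., a, b, c>: every intermediate vertex is a collider on the path and
# a parent of c; d is not adjacent to c. Breadth-first; returns d or NULL.
find_discriminating_origin <- function(amat, a, b, c0) {
  p <- nrow(amat)
  visited <- rep(FALSE, p)
  visited[c(a, b, c0)] <- TRUE
  frontier <- a
  while (length(frontier) > 0) {
    v <- frontier[1]
    frontier <- frontier[-1]
    # predecessors t with t *-> v (arrow at v)
    for (t in which(amat[, v] == MARK_ARROW)) {
      if (visited[t]) next
      if (amat[t, c0] == MARK_NONE) return(t) # d found: not adjacent to c
      # otherwise t must itself qualify as an intermediate vertex:
      # collider on the path (v *-> t already has arrow at t?) and parent of c
      if (amat[v, t] == MARK_ARROW &&
          amat[t, c0] == MARK_ARROW && amat[c0, t] == MARK_TAIL) {
        visited[t] <- TRUE
        frontier <- c(frontier, t)
      }
    }
  }
  NULL
}

# Potentially-directed edge from u to v: no arrowhead at u, no tail at v.
pd_edge <- function(amat, u, v) {
  amat[u, v] != MARK_NONE && amat[v, u] != MARK_ARROW &&
    amat[u, v] != MARK_TAIL
}

# Existence of an uncovered potentially-directed path from a to c of length
# >= 2; when avoid_first_adjacent, the first intermediate node must not be
# adjacent to c (the R9 condition).
exists_uncovered_pd_path <- function(amat, a, c0, avoid_first_adjacent = FALSE) {
  p <- nrow(amat)
  firsts <- which(vapply(seq_len(p), function(b) {
    b != a && b != c0 && pd_edge(amat, a, b) &&
      (!avoid_first_adjacent || amat[b, c0] == MARK_NONE)
  }, logical(1)))
  for (b in firsts) {
    if (ucp_dfs(amat, a, b, c0, visited = c(a, b))) return(TRUE)
  }
  FALSE
}

# First intermediate nodes b of uncovered pd paths a, b, ..., target.
first_nodes_uncovered_pd <- function(amat, a, target, forbid = integer(0)) {
  p <- nrow(amat)
  out <- integer(0)
  for (b in seq_len(p)) {
    if (b == a || b %in% forbid) next
    if (!pd_edge(amat, a, b)) next
    if (b == target || ucp_dfs(amat, a, b, target, visited = c(a, b, forbid))) {
      out <- c(out, b)
    }
  }
  out
}

# DFS: extend the uncovered pd path prev -> cur to target.
ucp_dfs <- function(amat, prev, cur, target, visited) {
  if (pd_edge(amat, cur, target) && amat[prev, target] == MARK_NONE) {
    return(TRUE)
  }
  for (nxt in seq_len(nrow(amat))) {
    if (nxt %in% visited || nxt == target) next
    if (!pd_edge(amat, cur, nxt)) next
    if (amat[prev, nxt] != MARK_NONE) next # covered triple
    if (ucp_dfs(amat, cur, nxt, target, c(visited, nxt))) return(TRUE)
  }
  FALSE
}

#' @export
print.pag <- function(x, ...) {
  cat("<pag>", length(x$nodes), "nodes,", nrow(pag_edges(x)), "edges\n")
  invisible(x)
}

#' Edge list of a PAG
#'
#' @param pag A `pag` object from [fci()].
#' @return A tibble: `node_a`, `mark_a`, `mark_b`, `node_b`, one row per edge
#'   (marks named `circle`/`arrow`/`tail`; `mark_a` is the mark at `node_a`).
#' @export
pag_edges <- function(pag) {
  p <- length(pag$nodes)
  rows <- list()
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i || pag$amat[i, j] == MARK_NONE) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        node_a = pag$nodes[i],
        mark_a = mark_label(pag$amat[j, i]),
        mark_b = mark_label(pag$amat[i, j]),
        node_b = pag$nodes[j]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(node_a = character(0), mark_a = character(0),
                          mark_b = character(0), node_b = character(0)))
  }
  dplyr::bind_rows(rows)
}

#' @rdname pag_edges
#' @param path File path for the edge-list text serialization.
#' @export
write_pag <- function(pag, path) {
  readr::write_csv(pag_edges(pag), path)
  invisible(path)
}

#' Adjacency set of a node in a PAG
#'
#' @param pag A `pag`.
#' @param node Node name.
#' @return Character vector of adjacent node names.
#' @export
pag_adjacencies <- function(pag, node) {
  i <- match(node, pag$nodes)
  if (is.na(i)) stop("node '", node, "' not in the PAG", call. = FALSE)
  pag$nodes[pag$amat[i, ] != MARK_NONE]
}
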