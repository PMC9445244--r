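# Multiscale binary partitioning of a structure graph.
#
# Every scale pairs each node with a graph-neighbor; under the scale's
# ordering, positions 2i-1 and 2i hold pair i, so a stride-2 1D pooling
# operator is a valid graph pooling. Node counts halve exactly at every
# scale (template counts are powers of two), so no fake-node padding is
# needed. Pairing is a greedy heavy-edge maximal matching seeded by node
# degree, repaired to a perfect matching with augmenting paths;
# deterministic, seed-free, ties broken by node index.

# adjacency list (neighbors + weights) from a dgCMatrix
adjacency_lists <- function(adj) {
  n <- nrow(adj)
  p <- adj@p
  nb <- vector("list", n)
  wt <- vector("list", n)
  for (j in seq_len(n)) {
    idx <- if (p[j + 1] > p[j]) (p[j] + 1):p[j + 1] else integer(0)
    nb[[j]] <- adj@i[idx] + 1L
    wt[[j]] <- adj@x[idx]
  }
  list(nb = nb, wt = wt)
}

graph_components <- function(nb) {
  n <- length(nb)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      new <- nb[[u]][comp[nb[[u]]] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# greedy heavy-edge maximal matching, lowest-degree node first
greedy_matching <- function(nb, wt) {
  n <- length(nb)
  deg <- lengths(nb)
  mate <- integer(n)
  for (u in order(deg, seq_len(n))) {
    if (mate[u] != 0L) next
    cand <- nb[[u]]
    free <- mate[cand] == 0L & cand != u
    if (!any(free)) next
    cand <- cand[free]
    w <- wt[[u]][free]
    best <- cand[w == max(w)]
    if (length(best) > 1L) {
      bd <- deg[best]
      best <- best[bd == min(bd)]
      best <- min(best)
    }
    mate[u] <- best
    mate[best] <- u
  }
  mate
}

# augmenting-path repair toward a perfect matching (no blossom handling;
# sufficient on triangulated sphere-like meshes)
augment_matching <- function(nb, mate) {
  n <- length(nb)
  for (u in seq_len(n)) {
    if (mate[u] != 0L) next
    from_outer <- integer(n)
    via <- integer(n)
    seen <- logical(n)
    seen[u] <- TRUE
    queue <- u
    target <- 0L
    last_outer <- 0L
    while (length(queue) && target == 0L) {
      x <- queue[[1]]
      queue <- queue[-1]
      for (y in nb[[x]]) {
        if (seen[y]) next
        if (mate[y] == 0L && y != u) {
          target <- y
          last_outer <- x
          break
        }
        seen[y] <- TRUE
        m <- mate[y]
        if (m != 0L && !seen[m]) {
          seen[m] <- TRUE
          from_outer[m] <- x
          via[m] <- y
          queue <- c(queue, m)
        }
      }
    }
    if (target == 0L) next
    y <- target
    x <- last_outer
    repeat {
      y_next <- via[x]
      x_next <- from_outer[x]
      mate[x] <- y
      mate[y] <- x
      if (x == u) break
      y <- y_next
      x <- x_next
    }
  }
  mate
}

# BFS graph distance from u restricted to candidate set
bfs_nearest <- function(nb, u, candidates) {
  n <- length(nb)
  dist <- rep(NA_integer_, n)
  dist[u] <- 0L
  queue <- u
  cand <- rep(FALSE, n)
  cand[candidates] <- TRUE
  while (length(queue)) {
    x <- queue[[1]]
    queue <- queue[-1]
    if (cand[x] && x != u) return(x)
    new <- nb[[x]][is.na(dist[nb[[x]]])]
    dist[new] <- dist[x] + 1L
    queue <- c(queue, new)
  }
  min(candidates)
}

# one coarsening level: returns pairs (sorted by min member) and coarse graph
coarsen_once <- function(graph) {
  n <- graph$n_nodes
  al <- adjacency_lists(graph$adjacency)
  mate <- greedy_matching(al$nb, al$wt)
  if (any(mate == 0L)) mate <- augment_matching(al$nb, mate)
  n_nonadj <- 0L
  if (any(mate == 0L)) {
    comp <- graph_components(al$nb)
    for (cid in unique(comp[mate == 0L])) {
      repeat {
        un <- which(mate == 0L & comp == cid)
        if (length(un) < 2L) break
        u <- un[1]
        v <- bfs_nearest(al$nb, u, un[-1])
        mate[u] <- v
        mate[v] <- u
        n_nonadj <- n_nonadj + 1L
      }
    }
    un <- which(mate == 0L)
    while (length(un) >= 2L) {   # stragglers across odd components
      mate[un[1]] <- un[2]
      mate[un[2]] <- un[1]
      n_nonadj <- n_nonadj + 1L
      un <- un[-(1:2)]
    }
    if (any(mate == 0L))
      stop_strucage("no perfect pairing found: odd number of nodes remained",
                    class = "strucage_pairing_error")
    warning(sprintf("binary partition: %d non-adjacent fallback pair(s)",
                    n_nonadj), call. = FALSE)
  }
  a <- pmin(seq_along(mate), mate)
  b <- pmax(seq_along(mate), mate)
  pairs <- unique(cbind(a, b))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  dimnames(pairs) <- NULL
  # coarse adjacency: A2 = P' A P with P the pair-assignment matrix
  pair_id <- integer(n)
  pair_id[pairs[, 1]] <- seq_len(nrow(pairs))
  pair_id[pairs[, 2]] <- seq_len(nrow(pairs))
  P <- Matrix::sparseMatrix(i = seq_len(n), j = pair_id, x = 1,
                            dims = c(n, nrow(pairs)))
  A2 <- Matrix::crossprod(P, graph$adjacency %*% P)
  A2 <- methods::as(A2, "CsparseMatrix")
  Matrix::diag(A2) <- 0
  A2 <- Matrix::drop0(A2)
  off <- graph$offsets
  off$start <- (off$start - 1L) %/% 2L + 1L
  off$end <- off$end %/% 2L
  list(pairs = pairs, pair_id = pair_id,
       graph = structure_graph(A2, offsets = off),
       n_nonadjacent = n_nonadj)
}

#' Multiscale binary partition of a graph
#'
#' Builds `n_levels` successive 2:1 coarsenings of `graph`. At every scale
#' each node is paired with one of its graph neighbors; pair `i` occupies
#' positions `2i-1` and `2i` of that scale's ordering, making stride-2
#' pooling valid, and becomes coarse node `i` of the next scale. Coarse
#' nodes inherit edges from their members (edge weights are summed).
#'
#' @param graph A `structure_graph` (node count divisible by
#'   `2^n_levels`) or a [surface_mesh()].
#' @param n_levels Number of coarsening levels (pooling events supported).
#' @return A `coarsening_hierarchy`: list with `n_levels`, `n_nodes`
#'   (counts per scale, finest first), `graphs` (per-scale
#'   `structure_graph`s in original label order), `pairs` (per-scale
#'   `N_S/2 x 2` matrices of scale-S node labels), `orderings` (per-scale
#'   permutations putting pair `i` at positions `2i-1`, `2i`), and
#'   `n_nonadjacent` (count of fallback pairs that were not graph-adjacent;
#'   0 on well-formed meshes).
#' @export
#' @examples
#' # path graph 1-2-3-4
#' a <- matrix(0, 4, 4); a[cbind(1:3, 2:4)] <- 1; a <- a + t(a)
#' h <- binary_partition(structure_graph(a), 1)
#' h$pairs[[1]]
binary_partition <- function(graph, n_levels) {
  if (inherits(graph, "surface_mesh")) graph <- mesh_to_graph(graph)
  n_levels <- as.integer(n_levels)
  if (n_levels < 0L)
    stop_strucage("n_levels must be >= 0", class = "strucage_config_error")
  if (graph$n_nodes %% (2^n_levels) != 0L)
    stop_strucage("node count ", graph$n_nodes,
                  " is not divisible by 2^", n_levels,
                  class = "strucage_config_error")
  graphs <- list(graph)
  pairs <- list()
  orderings <- list()
  n_nonadj <- 0L
  g <- graph
  for (s in seq_len(n_levels)) {
    step <- coarsen_once(g)
    pairs[[s]] <- step$pairs
    orderings[[s]] <- as.integer(t(step$pairs))
    g <- step$graph
    graphs[[s + 1L]] <- g
    n_nonadj <- n_nonadj + step$n_nonadjacent
  }
  structure(list(n_levels = n_levels,
                 n_nodes = vapply(graphs, `[[`, 0L, "n_nodes"),
                 graphs = graphs, pairs = pairs, orderings = orderings,
                 n_nonadjacent = n_nonadj),
            class = "coarsening_hierarchy")
}

#' @export
print.coarsening_hierarchy <- function(x, ...) {
  cat("coarsening_hierarchy:", paste(x$n_nodes, collapse = " -> "),
      "nodes\n")
  invisible(x)
}

#' Reorder activation rows by a permutation
#'
#' Row `k` of the output is row `permutation[k]` of the input. Used to put
#' each coarsening pair into adjacent rows before pooling.
#'
#' @param features Matrix (`N x F`) or 3-D array (`N x F x batch`).
#' @param permutation Integer bijection on `1..N`.
#' @return Reordered object of the same shape.
#' @export
apply_ordering <- function(features, permutation) {
  n <- if (is.matrix(features) || length(dim(features)) == 3L)
    dim(features)[1] else length(features)
  permutation <- as.integer(permutation)
  if (length(permutation) != n || anyNA(permutation) ||
      !setequal(permutation, seq_len(n)))
    stop_strucage("permutation is not a bijection on 1..", n,
                  class = "strucage_validation_error")
  if (length(dim(features)) == 3L) features[permutation, , , drop = FALSE]
  else if (is.matrix(features)) features[permutation, , drop = FALSE]
  else features[permutation]
}

#' Stride-2 pooling of ordered activations
#'
#' Pools rows `2i-1` and `2i` into output row `i`. The input must already
#' be permuted into the scale's ordering (see [apply_ordering()]).
#'
#' @param features Matrix (`N x F`), 3-D array (`N x F x batch`), or
#'   vector; `N` must be even.
#' @param mode `"max"` or `"mean"`.
#' @return Pooled object with `N/2` rows.
#' @export
#' @examples
#' pool_features(c(1, 3, 2, 4), "max")  # 3 4
pool_features <- function(features, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  vec <- is.null(dim(features))
  if (vec) features <- matrix(features, ncol = 1)
  n <- dim(features)[1]
  if (n %% 2L != 0L)
    stop_strucage("row count ", n, " is not even", class = "strucage_shape_error")
  odd <- seq(1L, n, by = 2L)
  even <- odd + 1L
  if (length(dim(features)) == 3L) {
    a <- features[odd, , , drop = FALSE]
    b <- features[even, , , drop = FALSE]
  } else {
    a <- features[odd, , drop = FALSE]
    b <- features[even, , drop = FALSE]
  }
  out <- if (mode == "max") pmax(a, b) else (a + b) / 2
  if (vec) as.vector(out) else out
}
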