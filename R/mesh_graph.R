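# Conversion of template triangulations to weighted graphs, normalized and
# rescaled Laplacians, per-node input features, and disjoint-union merging
# of several structures into one network input.

#' Convert a triangulated mesh to a structure graph
#'
#' Graph nodes are surface vertices and edges are the unique triangle edges.
#' Edge weights are binary by default (every mesh edge has weight 1), which
#' keeps the Laplacian purely combinatorial; `weighting = "invlength"` uses
#' inverse Euclidean edge length instead.
#'
#' @param mesh A [surface_mesh()].
#' @param weighting `"binary"` (default) or `"invlength"`.
#' @return A `structure_graph`: list with `n_nodes`, `adjacency` (sparse
#'   symmetric `dgCMatrix`, zero diagonal), and `offsets` (data.frame with
#'   one row per structure block: `structure`, `hemisphere`, `start`,
#'   `end`, 1-based inclusive node ranges).
#' @export
#' @examples
#' m <- surface_mesh(diag(3), matrix(1:3, 1))
#' g <- mesh_to_graph(m)
#' g$n_nodes
mesh_to_graph <- function(mesh, weighting = c("binary", "invlength")) {
  weighting <- match.arg(weighting)
  n <- n_vertices(mesh)
  if (nrow(mesh$faces) == 0L) {
    adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n))
  } else {
    e <- unique(face_edges(mesh$faces))
    w <- if (weighting == "binary") rep(1, nrow(e)) else {
      d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
      1 / pmax(d, 1e-12)
    }
    adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                                x = c(w, w), dims = c(n, n))
  }
  structure_graph(adj, offsets = data.frame(
    structure = mesh$structure %||% NA_character_,
    hemisphere = mesh$hemisphere %||% NA_character_,
    start = 1L, end = n, stringsAsFactors = FALSE))
}

#' Construct a structure graph from an adjacency matrix
#'
#' @param adjacency Symmetric nonnegative matrix (dense or sparse); the
#'   diagonal must be zero (no self-loops).
#' @param offsets Optional data.frame of structure blocks (see
#'   [mesh_to_graph()]); defaults to one block covering all nodes.
#' @return A `structure_graph`.
#' @export
structure_graph <- function(adjacency, offsets = NULL) {
  adj <- Matrix::drop0(methods::as(methods::as(
    Matrix::Matrix(adjacency, sparse = TRUE), "generalMatrix"),
    "CsparseMatrix"))
  n <- nrow(adj)
  if (n != ncol(adj))
    stop_strucage("adjacency must be square", class = "strucage_validation_error")
  if (!isTRUE(all.equal(as.numeric(Matrix::diag(adj)), rep(0, n),
                        tolerance = 0)))
    stop_strucage("adjacency has self-loops", class = "strucage_validation_error")
  if (any(adj@x < 0))
    stop_strucage("adjacency weights must be nonnegative",
                  class = "strucage_validation_error")
  if (!Matrix::isSymmetric(adj, tol = 0))
    stop_strucage("adjacency must be symmetric", class = "strucage_validation_error")
  if (is.null(offsets))
    offsets <- data.frame(structure = NA_character_, hemisphere = NA_character_,
                          start = 1L, end = n, stringsAsFactors = FALSE)
  structure(list(n_nodes = n, adjacency = adj, offsets = offsets),
            class = "structure_graph")
}

#' @export
print.structure_graph <- function(x, ...) {
  cat("structure_graph:", x$n_nodes, "nodes,", n_edges(x), "edges,",
      nrow(x$offsets), "block(s)\n")
  invisible(x)
}

#' Number of undirected edges of a structure graph
#' @param graph A `structure_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) as.integer(length(graph$adjacency@x) / 2)

#' Symmetric-normalized, rescaled graph Laplacian
#'
#' Computes `L = I - D^(-1/2) A D^(-1/2)` (isolated nodes get an all-zero
#' row) and rescales it to `Lt = (2 / lambda_max) L - I` so the spectrum
#' lies in `[-1, 1]`, the domain of the Chebyshev polynomials used by the
#' convolution layers. `lambda_max` is estimated by a deterministic
#' Lanczos iteration (cap 100 steps) with the residual bound of the top
#' Ritz pair added, so the value used is an upper bound on the true
#' `lambda_max` (itself capped at the normalized-Laplacian bound 2) and no
#' eigenvalue of `Lt` can exceed 1; if the graph has no edges the fallback
#' `lambda_max = 2` is used.
#'
#' @param graph A `structure_graph` (or a [surface_mesh()], converted with
#'   binary weights).
#' @return A `scaled_laplacian`: list with `matrix` (sparse symmetric) and
#'   `lambda_max`.
#' @export
#' @examples
#' g <- structure_graph(matrix(c(0, 1, 1, 0), 2))
#' round(as.matrix(scaled_laplacian(g)$matrix), 6)
scaled_laplacian <- function(graph) {
  if (inherits(graph, "surface_mesh")) graph <- mesh_to_graph(graph)
  A <- graph$adjacency
  n <- nrow(A)
  d <- Matrix::rowSums(A)
  has <- d > 0
  dinv <- ifelse(has, 1 / sqrt(d), 0)
  Dinv <- Matrix::Diagonal(n, dinv)
  L <- Matrix::Diagonal(n, as.numeric(has)) - Dinv %*% A %*% Dinv
  L <- methods::as(L, "CsparseMatrix")
  lambda <- power_iteration_lambda(L)
  if (is.na(lambda)) lambda <- 2
  Lt <- (2 / lambda) * L - Matrix::Diagonal(n)
  structure(list(matrix = methods::as(Lt, "CsparseMatrix"),
                 lambda_max = lambda),
            class = "scaled_laplacian")
}

# Largest eigenvalue of a sparse symmetric PSD matrix, estimated by a
# Lanczos iteration (deterministic start vector, full reorthogonalization)
# and returned with its residual bound added, so the result is an upper
# bound on lambda_max for any start vector with a component along the top
# eigenspace. Plain power iteration stalls on the near-degenerate top
# spectra of symmetric sphere meshes and can underestimate lambda_max
# enough to push the rescaled spectrum outside [-1, 1].
# Returns NA when the matrix is (numerically) zero.
power_iteration_lambda <- function(L, max_iter = 100L) {
  n <- nrow(L)
  if (length(L@x) == 0L || max(abs(L@x)) < 1e-14) return(NA_real_)
  m <- min(n, max_iter)
  Q <- matrix(0, n, m)
  alpha <- numeric(m)
  beta <- numeric(m)
  q <- det_unit_vector(n)
  Q[, 1] <- q
  q_prev <- rep(0, n)
  b_prev <- 0
  k_used <- m
  for (k in seq_len(m)) {
    w <- as.numeric(L %*% Q[, k]) - b_prev * q_prev
    alpha[k] <- sum(w * Q[, k])
    w <- w - alpha[k] * Q[, k]
    w <- w - Q[, seq_len(k), drop = FALSE] %*%
      crossprod(Q[, seq_len(k), drop = FALSE], w)   # reorthogonalize
    b <- sqrt(sum(w^2))
    if (k == m || b < 1e-12) { k_used <- k; beta[k] <- b; break }
    beta[k] <- b
    q_prev <- Q[, k]
    b_prev <- b
    Q[, k + 1] <- as.numeric(w) / b
  }
  k <- k_used
  T_mat <- diag(alpha[seq_len(k)], k, k)
  if (k > 1) {
    idx <- cbind(seq_len(k - 1), 2:k)
    T_mat[idx] <- beta[seq_len(k - 1)]
    T_mat[idx[, 2:1, drop = FALSE]] <- beta[seq_len(k - 1)]
  }
  ed <- eigen(T_mat, symmetric = TRUE)
  top <- which.max(ed$values)
  theta <- ed$values[top]
  resid <- abs(beta[k] * ed$vectors[k, top])
  min(2, theta + resid + 1e-10 * max(1, theta))
}

#' Build the per-node input feature matrix for one structure
#'
#' Features are vertex coordinates centered and divided by 100. Subcortical
#' structures supply one mesh (3 features per node); the cortex supplies the
#' inner (white/gray) and outer (pial) surfaces with identical vertex
#' counts and template order, concatenated to 6 features per node.
#'
#' @param meshes A single [surface_mesh()] or a list of one (subcortical)
#'   or two (cortex: inner, outer) meshes.
#' @param center Length-3 numeric centering offset in mm (subtracted before
#'   scaling). Typically the per-scan mean over all structures fed to the
#'   network ([scan_center()]); defaults to `c(0, 0, 0)`.
#' @return Numeric `N x 3` or `N x 6` feature matrix.
#' @export
build_features <- function(meshes, center = c(0, 0, 0)) {
  if (inherits(meshes, "surface_mesh")) meshes <- list(meshes)
  if (!length(meshes) %in% 1:2)
    stop_strucage("build_features takes one mesh (subcortical) or two (cortex)",
                  class = "strucage_validation_error")
  ns <- vapply(meshes, n_vertices, 0L)
  if (length(meshes) == 2L && ns[1] != ns[2])
    stop_strucage("inner/outer vertex counts differ (", ns[1], " vs ", ns[2], ")",
                  class = "strucage_validation_error")
  center <- as.numeric(center)
  do.call(cbind, lapply(meshes, function(m)
    sweep(m$vertices, 2, center, "-") / 100))
}

#' Per-scan centering offset
#'
#' Mean coordinate over all vertices of all structures of one scan; used as
#' the `center` argument of [build_features()] so relative structure
#' positions are preserved after centering.
#'
#' @param meshes List of [surface_mesh()] objects belonging to one scan.
#' @return Length-3 numeric vector (mm).
#' @export
scan_center <- function(meshes) {
  if (inherits(meshes, "surface_mesh")) meshes <- list(meshes)
  all_v <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  colMeans(all_v)
}

#' Merge several structure graphs into one disjoint-union graph
#'
#' Builds the block-diagonal adjacency of the given graphs (no edges cross
#' structures) and stacks the matching feature matrices row-wise, padding
#' narrower matrices with zero columns up to the widest (3-feature
#' subcortical rows become `(x, y, z, 0, 0, 0)` next to 6-feature cortical
#' rows) so a single convolution stack can process mixed node types.
#'
#' @param graphs Nonempty list of `structure_graph` objects.
#' @param features Optional list of feature matrices, same length and node
#'   counts as `graphs`.
#' @return If `features` is `NULL`, the merged `structure_graph`; otherwise
#'   `list(graph, features)`.
#' @export
merge_graphs <- function(graphs, features = NULL) {
  if (length(graphs) == 0L)
    stop_strucage("empty graph list", class = "strucage_validation_error")
  if (!is.null(features) && length(features) != length(graphs))
    stop_strucage("features list must match graphs list",
                  class = "strucage_validation_error")
  adj <- Matrix::bdiag(lapply(graphs, `[[`, "adjacency"))
  adj <- methods::as(adj, "CsparseMatrix")
  sizes <- vapply(graphs, `[[`, 0L, "n_nodes")
  shift <- cumsum(c(0L, sizes[-length(sizes)]))
  offsets <- do.call(rbind, Map(function(g, s) {
    o <- g$offsets
    o$start <- o$start + s
    o$end <- o$end + s
    o
  }, graphs, shift))
  rownames(offsets) <- NULL
  g <- structure_graph(adj, offsets = offsets)
  if (is.null(features)) return(g)
  widths <- vapply(features, ncol, 0L)
  wmax <- max(widths)
  feat <- do.call(rbind, lapply(features, function(f) {
    if (ncol(f) < wmax)
      f <- cbind(f, matrix(0, nrow(f), wmax - ncol(f)))
    f
  }))
  list(graph = g, features = feat)
}

#' Export a graph (or scaled Laplacian) as a coordinate-list text file
#'
#' Writes one `node_i node_j weight` line per stored nonzero entry
#' (1-based indices), a plain-text debugging format.
#'
#' @param x A `structure_graph` or `scaled_laplacian`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(x, path) {
  m <- if (inherits(x, "scaled_laplacian")) x$matrix else x$adjacency
  m <- methods::as(m, "TsparseMatrix")
  writeLines(paste(m@i + 1L, m@j + 1L, format(m@x, digits = 17)), path)
  invisible(path)
}
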