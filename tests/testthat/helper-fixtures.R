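# shared fixtures and independent oracles, all built in code

# smallest closed triangulation: a tetrahedron
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  surface_mesh(v, f)
}

path_graph <- function(n) {
  a <- matrix(0, n, n)
  if (n > 1) a[cbind(1:(n - 1), 2:n)] <- 1
  structure_graph(a + t(a))
}

# random symmetric simple graph (may contain isolated nodes)
random_graph <- function(n, p = 0.2) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(runif(length(up)) < p)
  structure_graph(a + t(a))
}

# dense Chebyshev-polynomial oracle: explicit polynomials of the dense
# matrix (independent of the sparse three-term recursion)
cheb_poly_coefs <- list(
  c(1),                       # T0
  c(0, 1),                    # T1
  c(-1, 0, 2),                # T2
  c(0, -3, 0, 4),             # T3
  c(1, 0, -8, 0, 8),          # T4
  c(0, 5, 0, -20, 0, 16))     # T5
cheb_dense_oracle <- function(Lt, X, theta, bias = NULL) {
  Ld <- as.matrix(Lt)
  n <- nrow(Ld)
  pows <- list(diag(n))
  for (k in seq_len(length(theta) - 1)) pows[[k + 1]] <- pows[[k]] %*% Ld
  Y <- matrix(0, n, ncol(theta[[1]]))
  for (k in seq_along(theta)) {
    co <- cheb_poly_coefs[[k]]
    Tk <- matrix(0, n, n)
    for (j in seq_along(co)) if (co[j] != 0) Tk <- Tk + co[j] * pows[[j]]
    Y <- Y + Tk %*% X %*% theta[[k]]
  }
  if (!is.null(bias)) Y <- sweep(Y, 2, bias, "+")
  Y
}

random_theta <- function(K, fin, fout) {
  lapply(seq_len(K), function(k) matrix(rnorm(fin * fout), fin, fout))
}

# a small fully-specified network for forward/backward tests
tiny_network <- function(n_nodes = 16, n_blocks = 2, seed = 7,
                         dropout = 0, filters = 5) {
  g <- mesh_to_graph(make_sphere_mesh(n_nodes))
  cfg <- age_network_config(conv_filters = filters, last_conv_filters = 7,
                            dense_units = 6, n_residual_blocks = n_blocks,
                            K_first = 3, K_block = 2,
                            dropout_softmax_branch = dropout, l2_lambda = 0)
  build_age_network(g, cfg, n_features = 3, seed = seed)
}

zero_params <- function(params) {
  walk <- function(x) if (is.list(x)) lapply(x, walk) else x * 0
  walk(params)
}

# per-scan training data from a radius-encodes-age sphere family
sphere_age_dataset <- function(n_scans, n_nodes = 16, seed = 1) {
  set.seed(seed)
  m <- make_sphere_mesh(n_nodes)
  age <- runif(n_scans, 45, 90)
  x <- array(0, c(n_nodes, 3, n_scans))
  for (i in seq_len(n_scans)) {
    r <- 1 + 0.01 * (age[i] - 65)
    x[, , i] <- build_features(surface_mesh(m$vertices * r, m$faces))
  }
  list(x = x, age = age, subject_id = sprintf("s%03d", seq_len(n_scans)),
       scan_id = sprintf("s%03d_1", seq_len(n_scans)))
}
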