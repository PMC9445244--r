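# graph construction, Laplacians, features, merging

test_that("mesh edges become unique undirected graph edges", {
  tri <- surface_mesh(diag(3), matrix(1:3, 1))
  g <- mesh_to_graph(tri)
  expect_equal(g$n_nodes, 3L)
  expect_equal(n_edges(g), 3L)
  g4 <- mesh_to_graph(tetra_mesh())       # tetrahedron is K4
  expect_equal(g4$n_nodes, 4L)
  expect_equal(n_edges(g4), 6L)
  expect_equal(as.matrix(g4$adjacency), matrix(1, 4, 4) - diag(4),
               ignore_attr = TRUE)
})

test_that("sphere edge count equals 3F/2 and matches brute-force hashing", {
  m <- make_sphere_mesh(128)
  g <- mesh_to_graph(m)
  expect_equal(n_edges(g), as.integer(3 * nrow(m$faces) / 2))
  # independent count: hash sorted vertex pairs of every face edge
  e <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(1, 3)])
  keys <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_equal(n_edges(g), length(keys))
})

test_that("graph adjacency is symmetric with empty diagonal", {
  set.seed(1)
  for (rep in 1:5) {
    g <- random_graph(20, 0.25)
    A <- g$adjacency
    expect_true(Matrix::isSymmetric(A))
    expect_true(all(Matrix::diag(A) == 0))
  }
})

test_that("scaled Laplacian of K2 has the closed form with eigenvalues +/-1", {
  g <- structure_graph(matrix(c(0, 1, 1, 0), 2))
  L <- scaled_laplacian(g)
  expect_equal(L$lambda_max, 2, tolerance = 1e-6)
  expect_equal(as.matrix(L$matrix), rbind(c(0, -1), c(-1, 0)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sort(eigen(as.matrix(L$matrix))$values), c(-1, 1),
               tolerance = 1e-6)
})

test_that("edgeless graph falls back to lambda_max = 2 giving -I", {
  g <- structure_graph(matrix(0, 3, 3))
  L <- scaled_laplacian(g)
  expect_equal(L$lambda_max, 2)
  expect_equal(as.matrix(L$matrix), -diag(3), ignore_attr = TRUE)
})

test_that("rescaled spectra lie in [-1, 1] within 1e-8 (dense check)", {
  set.seed(2)
  graphs <- c(list(mesh_to_graph(make_sphere_mesh(256)),
                   mesh_to_graph(make_sphere_mesh(16), weighting = "invlength"),
                   path_graph(12)),
              lapply(1:5, function(i) random_graph(12, 0.3)))
  for (g in graphs) {
    ev <- eigen(as.matrix(scaled_laplacian(g)$matrix), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lte(max(ev), 1 + 1e-8)
    expect_gte(min(ev), -1 - 1e-8)
  }
})

test_that("features are centered coordinates divided by 100", {
  m <- surface_mesh(rbind(c(10, -20, 30), c(0, 0, 0), c(2, 2, 2)),
                    matrix(1:3, 1))
  f <- build_features(m)
  expect_equal(f[1, ], c(0.1, -0.2, 0.3))
  f2 <- build_features(m, center = c(10, -20, 30))
  expect_equal(f2[1, ], c(0, 0, 0))
  # column means track vertex means when already centered at the origin
  mc <- surface_mesh(m$vertices - rep(colMeans(m$vertices), each = 3),
                     m$faces)
  expect_equal(colMeans(build_features(mc)), colMeans(mc$vertices) / 100)
})

test_that("cortical inner+outer surfaces give 6 features per node", {
  inner <- make_sphere_mesh(64, radius = 50)
  outer <- surface_mesh(inner$vertices * 1.06, inner$faces)
  f <- build_features(list(inner, outer))
  expect_equal(dim(f), c(64L, 6L))
  expect_equal(f[, 4:6], f[, 1:3] * 1.06)
  bad <- make_sphere_mesh(32)
  expect_error(build_features(list(inner, bad)),
               class = "strucage_validation_error")
})

test_that("feature scaling is exactly linear in coordinates", {
  m <- make_sphere_mesh(16, radius = 3)
  m100 <- surface_mesh(m$vertices * 100, m$faces)
  expect_equal(build_features(m100), build_features(m) * 100)
})

test_that("merging graphs is a disjoint union with zero-padded features", {
  g1 <- mesh_to_graph(make_sphere_mesh(64))
  g2 <- mesh_to_graph(make_sphere_mesh(32))
  f1 <- matrix(rnorm(64 * 6), 64, 6)
  f2 <- matrix(rnorm(32 * 3), 32, 3)
  mg <- merge_graphs(list(g1, g2), list(f1, f2))
  expect_equal(mg$graph$n_nodes, 96L)
  expect_equal(n_edges(mg$graph), n_edges(g1) + n_edges(g2))
  # no edge crosses the block boundary
  A <- mg$graph$adjacency
  expect_equal(sum(abs(A[1:64, 65:96])), 0)
  expect_equal(dim(mg$features), c(96L, 6L))
  expect_equal(mg$features[65:96, 4:6], matrix(0, 32, 3), ignore_attr = TRUE)
  # Laplacian of the union equals the block-diagonal of the parts
  Lm <- scaled_laplacian(mg$graph)$matrix
  expect_equal(sum(abs(Lm[1:64, 65:96])), 0)
  # merging a single graph is the identity
  expect_equal(as.matrix(merge_graphs(list(g1))$adjacency),
               as.matrix(g1$adjacency))
})

test_that("edge-list export is a readable node_i node_j weight table", {
  g <- mesh_to_graph(tetra_mesh())
  path <- withr::local_tempfile(fileext = ".txt")
  write_edgelist(g, path)
  tab <- read.table(path)
  expect_equal(nrow(tab), 12L)   # both directions of 6 undirected edges
  expect_true(all(tab$V3 == 1))
})
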