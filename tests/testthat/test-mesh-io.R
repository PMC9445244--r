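# PLY/OFF readers and writers; vertex order must survive round trips
# because template correspondence is positional.

test_that("ASCII PLY of a tetrahedron parses with order preserved", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "comment smallest closed triangulation",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 4",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "3 0 1 2", "3 0 1 3", "3 0 2 3", "3 1 2 3"), path)
  m <- read_mesh(path)
  expect_equal(n_vertices(m), 4L)
  expect_equal(nrow(m$faces), 4L)
  expect_equal(m$vertices[2, ], c(1, 0, 0))
  expect_equal(m$faces[1, ], c(1L, 2L, 3L))
})

test_that("write/read round-trips are bit-exact for PLY and OFF", {
  m <- make_sphere_mesh(64, radius = 7.5)
  for (fmt in c("ply", "off")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path, format = fmt)
    m2 <- read_mesh(path)
    expect_identical(m2$faces, m$faces)
    expect_identical(m2$vertices, m$vertices)
  }
})

test_that("binary little-endian PLY is read correctly", {
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4",
               "property list uchar int vertex_indices",
               "end_header"), con)
  for (i in 1:4)
    writeBin(as.numeric(m$vertices[i, ]), con, size = 4, endian = "little")
  for (i in 1:4) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4, endian = "little")
  }
  close(con)
  m2 <- read_mesh(path)
  expect_identical(m2$faces, m$faces)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-7)
})

test_that("malformed meshes and files are rejected", {
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "4 0 0 0 0"), path)
  expect_error(read_mesh(path), class = "strucage_validation_error")
  writeLines("not a mesh at all", path)
  expect_error(read_mesh(path, format = "ply"),
               class = "strucage_format_error")
  expect_error(read_mesh(tempfile()), class = "strucage_io_error")
  # out-of-range face index
  expect_error(surface_mesh(diag(3), matrix(c(1, 2, 4), 1)),
               class = "strucage_validation_error")
  # repeated vertex in a face
  expect_error(surface_mesh(diag(3), matrix(c(1, 1, 2), 1)),
               class = "strucage_validation_error")
  # edge shared by three faces is non-manifold
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(surface_mesh(v, f), class = "strucage_validation_error")
})

test_that("template vertex counts are enforced when requested", {
  tpl <- make_template("accumbens")
  expect_equal(n_vertices(tpl$mesh), 256L)
  expect_error(surface_mesh(diag(3), matrix(1:3, 1), structure = "accumbens",
                            check_template = TRUE),
               class = "strucage_validation_error")
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(tpl$mesh, path)
  m <- read_mesh(path, structure = "accumbens", hemisphere = "L")
  expect_equal(n_vertices(m), template_node_counts()[["accumbens"]])
})
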