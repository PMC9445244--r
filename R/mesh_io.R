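# Surface mesh container and PLY/OFF readers/writers.
#
# Vertex order is meaningful: template correspondence is positional, so no
# function in this file (or anywhere else in the package) re-indexes
# vertices silently. Faces are stored 1-based internally; PLY/OFF files use
# the usual 0-based convention on disk.

#' Construct a surface mesh
#'
#' A `surface_mesh` is a triangulated surface of one brain structure in
#' template-registered vertex correspondence: all scans of a given structure
#' share one fixed triangulation, and vertex `i` means the same anatomical
#' location on every scan.
#'
#' @param vertices Numeric `N x 3` matrix of vertex coordinates
#'   (millimetres).
#' @param faces Integer `F x 3` matrix of 1-based vertex indices (triangles).
#' @param structure Optional structure label, one of
#'   `names(template_node_counts())`.
#' @param hemisphere Optional hemisphere, `"L"` or `"R"`.
#' @param check_template If `TRUE` and `structure` is given, require the
#'   vertex count to equal the template count for that structure.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `structure`, `hemisphere`.
#' @export
#' @examples
#' m <- surface_mesh(diag(3), matrix(c(1, 2, 3), 1))
#' n_vertices(m)
surface_mesh <- function(vertices, faces, structure = NULL, hemisphere = NULL,
                         check_template = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L)
    stop_strucage("vertices must have 3 columns",
                  class = "strucage_validation_error")
  if (ncol(faces) != 3L)
    stop_strucage("faces must be triangles (3 indices per face)",
                  class = "strucage_validation_error")
  n <- nrow(vertices)
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > n))
    stop_strucage("face indices out of range [1, ", n, "]",
                  class = "strucage_validation_error")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    stop_strucage("degenerate face (repeated vertex index)",
                  class = "strucage_validation_error")
  # each undirected edge may appear in at most 2 faces
  if (nrow(faces) > 0L) {
    e <- face_edges(faces)
    key <- (e[, 1] - 1) * n + e[, 2]
    if (any(table(key) > 2L))
      stop_strucage("non-manifold mesh: an edge belongs to more than 2 faces",
                    class = "strucage_validation_error")
  }
  if (!is.null(structure)) {
    check_structure_label(structure)
    if (check_template && n != template_node_counts()[[structure]])
      stop_strucage("vertex count ", n, " does not match the ", structure,
                    " template count ", template_node_counts()[[structure]],
                    class = "strucage_validation_error")
  }
  if (!is.null(hemisphere) && !hemisphere %in% c("L", "R"))
    stop_strucage("hemisphere must be 'L' or 'R'",
                  class = "strucage_validation_error")
  structure(list(vertices = vertices, faces = faces,
                 structure = structure, hemisphere = hemisphere),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces")
  if (!is.null(x$structure))
    cat(" [", x$structure, if (!is.null(x$hemisphere)) x$hemisphere, "]")
  cat("\n")
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh A [surface_mesh()].
#' @return Integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

# all (sorted) edge instances of a face matrix, one row per face edge
face_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(1, 3), drop = FALSE])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Read a surface mesh from PLY or OFF
#'
#' Supports ASCII and binary-little-endian PLY (float/double vertex
#' properties, uchar/int face lists) and ASCII OFF. Vertex order is
#' preserved exactly as stored in the file.
#'
#' @param path File path.
#' @param format `"auto"` (default, by extension and header), `"ply"` or
#'   `"off"`.
#' @inheritParams surface_mesh
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "off"),
                      structure = NULL, hemisphere = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_strucage("file not found: ", path, class = "strucage_io_error")
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 4L)
    txt <- rawToChar(magic[magic != as.raw(0)])
    format <- if (startsWith(toupper(txt), "PLY")) "ply"
              else if (startsWith(toupper(txt), "OFF")) "off"
              else tolower(tools::file_ext(path))
  }
  mesh <- switch(format,
    ply = read_ply(path),
    off = read_off(path),
    stop_strucage("unknown mesh format '", format, "'",
                  class = "strucage_format_error"))
  surface_mesh(mesh$vertices, mesh$faces, structure = structure,
               hemisphere = hemisphere)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hdr_line <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  if (toupper(read_hdr_line()) != "PLY")
    stop_strucage("not a PLY file: ", path, class = "strucage_format_error")
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  repeat {
    ln <- trimws(read_hdr_line())
    if (ln == "" || startsWith(ln, "comment")) next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop_strucage("PLY file lacks vertex or face element",
                  class = "strucage_format_error")
  if (identical(fmt, "ascii")) {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    nv <- elements$vertex$count
    nf <- elements$face$count
    if (length(body) < nv + nf)
      stop_strucage("PLY body truncated", class = "strucage_format_error")
    vprops <- vapply(elements$vertex$props, function(p) p$name, "")
    vdat <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(nv)]), "\\s+"))),
                   nrow = nv, byrow = TRUE)
    xyz <- match(c("x", "y", "z"), vprops)
    if (anyNA(xyz))
      stop_strucage("PLY vertex element lacks x/y/z",
                    class = "strucage_format_error")
    vertices <- vdat[, xyz, drop = FALSE]
    flines <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    counts <- vapply(flines, function(t) as.integer(t[1]), 0L)
    if (any(counts != 3L))
      stop_strucage("non-triangular face in PLY file",
                    class = "strucage_validation_error")
    faces <- matrix(as.integer(unlist(lapply(flines, `[`, 2:4))),
                    ncol = 3, byrow = TRUE) + 1L
  } else if (identical(fmt, "binary_little_endian")) {
    sz <- function(type) switch(type, char = 1L, uchar = 1L, int8 = 1L,
      uint8 = 1L, short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
      int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L,
      float32 = 4L, double = 8L, float64 = 8L,
      stop_strucage("unsupported PLY type ", type,
                    class = "strucage_format_error"))
    rd <- function(type, n) {
      s <- sz(type)
      what <- if (type %in% c("float", "float32", "double", "float64"))
        "double" else "integer"
      readBin(con, what, n = n, size = s, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    nv <- elements$vertex$count
    vprops <- elements$vertex$props
    vdat <- matrix(0, nv, length(vprops))
    for (i in seq_len(nv))
      for (j in seq_along(vprops))
        vdat[i, j] <- rd(vprops[[j]]$type, 1L)
    xyz <- match(c("x", "y", "z"), vapply(vprops, function(p) p$name, ""))
    vertices <- vdat[, xyz, drop = FALSE]
    nf <- elements$face$count
    fp <- elements$face$props[[1]]
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- rd(fp$count_type, 1L)
      idx <- rd(fp$type, cnt)
      if (cnt != 3L)
        stop_strucage("non-triangular face in PLY file",
                      class = "strucage_validation_error")
      faces[i, ] <- idx + 1L
    }
  } else {
    stop_strucage("unsupported PLY format '", fmt, "'",
                  class = "strucage_format_error")
  }
  list(vertices = vertices, faces = faces)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!startsWith(toupper(trimws(lines[1])), "OFF"))
    stop_strucage("not an OFF file: ", path, class = "strucage_format_error")
  # counts may share the OFF line or follow it
  first <- trimws(sub("^\\s*OFF", "", trimws(lines[1]), ignore.case = TRUE))
  if (nzchar(first)) {
    counts <- as.integer(strsplit(first, "\\s+")[[1]])
    body <- lines[-1]
  } else {
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    body <- lines[-(1:2)]
  }
  nv <- counts[1]; nf <- counts[2]
  if (length(body) < nv + nf)
    stop_strucage("OFF body truncated", class = "strucage_format_error")
  vertices <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(nv)]), "\\s+"))),
                     nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  flines <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  cnts <- vapply(flines, function(t) as.integer(t[1]), 0L)
  if (any(cnts != 3L))
    stop_strucage("non-triangular face in OFF file",
                  class = "strucage_validation_error")
  faces <- matrix(as.integer(unlist(lapply(flines, `[`, 2:4))),
                  ncol = 3, byrow = TRUE) + 1L
  list(vertices = vertices, faces = faces)
}

#' Write a surface mesh to PLY or OFF
#'
#' Writes ASCII PLY (default) or ASCII OFF. A mesh written and re-read
#' round-trips its vertices and faces exactly (coordinates are printed with
#' full `double` precision).
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param format `"ply"` or `"off"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "off")) {
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces - 1L
  vtxt <- apply(v, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  ftxt <- paste(3L, f[, 1], f[, 2], f[, 3])
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices",
             "end_header")
    writeLines(c(hdr, vtxt, ftxt), path)
  } else {
    writeLines(c("OFF", paste(nrow(v), nrow(f), 0L), vtxt, ftxt), path)
  }
  invisible(path)
}
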