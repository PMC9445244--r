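# Synthetic templates and cohorts.
#
# Templates are sphere-like watertight triangulations with exactly the
# per-structure template node counts (powers of two). A subdivided
# octahedron has 2^(2k+2) + 2 vertices, so an exact power-of-two count is
# reached by a few manifold shortest-edge collapses (2 for even powers of
# two, about half the mesh for odd powers). Shape varies through a small
# basis of smooth (spherical-harmonic) radial displacement fields whose
# coefficients are affine in a latent "effective age"; subject identity
# and scan noise perturb the same coefficients, so a subject's deviation
# along the age-linked fields plays the role of a biological brain-age
# gap.

octahedron <- function() {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  list(vertices = v, faces = f)
}

# one 4:1 loop subdivision step with reprojection onto the unit sphere
subdivide_sphere <- function(v, f) {
  n <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  key <- pmin(e[, 1], e[, 2]) * (n + 1) + pmax(e[, 1], e[, 2])
  ukey <- unique(key)
  mid_id <- match(key, ukey) + n
  ue <- e[!duplicated(key), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m13 <- mid_id[2 * nf + seq_len(nf)]
  f2 <- rbind(cbind(f[, 1], m12, m13),
              cbind(m12, f[, 2], m23),
              cbind(m13, m23, f[, 3]),
              cbind(m12, m23, m13))
  list(vertices = rbind(v, mids), faces = f2)
}

# collapse shortest valid edges until exactly `target` vertices remain;
# preserves the closed-manifold property via the link condition
decimate_sphere <- function(v, f, target) {
  n <- nrow(v)
  alive <- rep(TRUE, n)
  adj <- vector("list", n)
  e0 <- unique(rbind(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
                     cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
                     cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))))
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(e0))) {
    a <- e0[r, 1]; b <- e0[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  edges <- e0
  elen <- sqrt(rowSums((v[edges[, 1], , drop = FALSE] -
                        v[edges[, 2], , drop = FALSE])^2))
  fal <- rep(TRUE, nrow(f))
  n_alive <- n
  while (n_alive > target) {
    ord <- order(elen, edges[, 1], edges[, 2])
    done <- FALSE
    for (r in ord) {
      a <- edges[r, 1]; b <- edges[r, 2]
      common <- intersect(adj[[a]], adj[[b]])
      if (length(common) != 2L) next
      # collapse b into a
      v[a, ] <- (v[a, ] + v[b, ]) / 2
      both <- (f[, 1] == a | f[, 2] == a | f[, 3] == a) &
              (f[, 1] == b | f[, 2] == b | f[, 3] == b) & fal
      fal[both] <- FALSE
      hasb <- (f[, 1] == b | f[, 2] == b | f[, 3] == b) & fal
      fb <- f[hasb, , drop = FALSE]
      fb[fb == b] <- a
      f[hasb, ] <- fb
      nb <- setdiff(adj[[b]], a)
      for (x in nb) {
        adj[[x]] <- setdiff(adj[[x]], b)
        if (!(a %in% adj[[x]])) adj[[x]] <- c(adj[[x]], a)
      }
      adj[[a]] <- union(setdiff(adj[[a]], b), nb)
      adj[[b]] <- integer(0)
      alive[b] <- FALSE
      n_alive <- n_alive - 1L
      keep <- edges[, 1] != a & edges[, 2] != a &
              edges[, 1] != b & edges[, 2] != b
      edges <- edges[keep, , drop = FALSE]
      elen <- elen[keep]
      if (length(adj[[a]])) {
        enew <- cbind(pmin(a, adj[[a]]), pmax(a, adj[[a]]))
        edges <- rbind(edges, enew)
        elen <- c(elen, sqrt(rowSums((v[enew[, 1], , drop = FALSE] -
                                      v[enew[, 2], , drop = FALSE])^2)))
      }
      done <- TRUE
      break
    }
    if (!done)
      stop_strucage("decimation stuck: no collapsible edge found",
                    class = "strucage_pairing_error")
  }
  remap <- cumsum(alive)
  f <- f[fal, , drop = FALSE]
  f[] <- remap[f]
  list(vertices = v[alive, , drop = FALSE], faces = f)
}

#' Sphere-like triangulation with an exact power-of-two vertex count
#'
#' Subdivides an octahedron until at least `n_vertices` vertices exist,
#' then applies manifold shortest-edge collapses down to exactly
#' `n_vertices`, and projects all vertices onto a sphere of the requested
#' radius. Deterministic and seed-free.
#'
#' @param n_vertices Target vertex count; a power of two, at least 16.
#' @param radius Sphere radius (mm).
#' @return A [surface_mesh()] (watertight: every edge lies in exactly two
#'   faces).
#' @export
#' @examples
#' m <- make_sphere_mesh(64)
#' n_vertices(m)
make_sphere_mesh <- function(n_vertices, radius = 1) {
  n_vertices <- as.integer(n_vertices)
  if (!is_power_of_two(n_vertices) || n_vertices < 16L)
    stop_strucage("n_vertices must be a power of two >= 16",
                  class = "strucage_config_error")
  m <- octahedron()
  while (nrow(m$vertices) < n_vertices)
    m <- subdivide_sphere(m$vertices, m$faces)
  if (nrow(m$vertices) > n_vertices)
    m <- decimate_sphere(m$vertices, m$faces, n_vertices)
  v <- m$vertices / sqrt(rowSums(m$vertices^2)) * radius
  surface_mesh(v, m$faces)
}

# real spherical harmonics (unnormalized shapes) on unit directions
harmonic_values <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(1, x, y, z, x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1)
}

# template radii in mm, sized so neighbor edge lengths stay realistic
template_radii <- function() {
  c(accumbens = 5, amygdala = 8, caudate = 10, hippocampus = 14,
    pallidum = 8, putamen = 12, thalamus = 15, cortex = 60)
}

#' Build a synthetic structure template
#'
#' A sphere-like mesh with the structure's template node count plus a
#' basis of `n_fields` smooth radial displacement fields (low-order real
#' spherical harmonics, each normalized to unit RMS vertex displacement).
#' Field 1 is uniform radial growth and carries the age signal by default;
#' `seed` rotates the orientation of the higher-order fields.
#'
#' @param structure Structure label (see [template_node_counts()]).
#' @param seed Integer seed (orientation of the deformation basis).
#' @param n_fields Number of displacement fields (at most 9).
#' @param hemisphere `"L"` or `"R"` (the R template is mirrored in x).
#' @return A `synthetic_template`: list with `mesh`, `basis`
#'   (`N x 3 x n_fields` array), `gains` (mm/year per field), `age_ref`
#'   (years), `radius`.
#' @export
make_template <- function(structure, seed = 1L, n_fields = 9L,
                          hemisphere = "L") {
  check_structure_label(structure)
  n <- template_node_counts()[[structure]]
  r <- template_radii()[[structure]]
  mesh <- make_sphere_mesh(n, radius = r)
  if (hemisphere == "R") mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh <- surface_mesh(mesh$vertices, mesh$faces, structure = structure,
                       hemisphere = hemisphere, check_template = TRUE)
  dirs <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  Rb <- euler_rotation_matrix(runif(3, -180, 180))
  H <- harmonic_values(dirs %*% t(Rb))
  H[, 1] <- 1                                  # field 1: uniform radial
  n_fields <- min(as.integer(n_fields), ncol(H))
  basis <- array(0, c(n, 3L, n_fields))
  for (m in seq_len(n_fields)) {
    d <- dirs * H[, m]
    rms <- sqrt(mean(rowSums(d^2)))
    basis[, , m] <- d / rms                    # unit RMS displacement
  }
  # age gains (mm/year of effective age): radial growth plus two
  # low-order asymmetries; remaining fields carry no age signal
  gains <- rep(0, n_fields)
  gains[seq_len(min(3L, n_fields))] <- c(0.05, 0.02, 0.02)[seq_len(min(3L, n_fields))]
  structure(list(structure = structure, hemisphere = hemisphere,
                 mesh = mesh, basis = basis, gains = gains,
                 age_ref = 65, radius = r, seed = as.integer(seed)),
            class = "synthetic_template")
}

#' @export
print.synthetic_template <- function(x, ...) {
  cat("synthetic_template:", x$structure, x$hemisphere, "-",
      n_vertices(x$mesh), "vertices,", dim(x$basis)[3], "fields\n")
  invisible(x)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919 + 12345) %% 2147483647)
}

local_rng <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Synthetic subject descriptor
#'
#' @param subject_id Identifier.
#' @param baseline_age Age at the first scan (years).
#' @param group `"non_converter"`, `"MCI_converter"`, `"ADD_converter"`,
#'   or the baseline-diagnosed `"MCI"` / `"ADD"`.
#' @param offset Structure-age offset in years (0 for non-converters).
#' @param pace Aging-pace multiplier (1 for non-converters; must be > 0).
#' @param shape_sd SD of the subject's random shape coefficients (the
#'   component along the age-linked fields acts as a biological brain-age
#'   gap).
#' @param noise_seed Seed of the subject's shape-noise stream.
#' @return A `synthetic_subject` list.
#' @export
synthetic_subject <- function(subject_id, baseline_age, group = "non_converter",
                              offset = 0, pace = 1, shape_sd = 0.15,
                              noise_seed = 1L) {
  if (pace <= 0)
    stop_strucage("pace must be > 0", class = "strucage_validation_error")
  if (!is.finite(offset))
    stop_strucage("offset must be finite", class = "strucage_validation_error")
  if (group == "non_converter" && (offset != 0 || pace != 1))
    stop_strucage("non-converters must have offset 0 and pace 1",
                  class = "strucage_validation_error")
  structure(list(subject_id = subject_id, baseline_age = baseline_age,
                 group = group, offset = offset, pace = pace,
                 shape_sd = shape_sd, noise_seed = as.integer(noise_seed)),
            class = "synthetic_subject")
}

#' Generate one scan's mesh for a synthetic subject
#'
#' The subject's effective age at the scan is
#' `baseline_age + pace * scan_time + offset`; each basis field's
#' coefficient is its gain times `(effective age - age_ref)`, plus a
#' subject-constant random component (SD `shape_sd`, drawn once per
#' subject) and a per-scan smooth noise component (SD `noise_sd`). All
#' randomness is derived deterministically from the subject's noise seed.
#'
#' @param template A [make_template()] template.
#' @param subject A [synthetic_subject()].
#' @param scan_time Years since baseline (>= 0).
#' @param noise_sd Per-scan coefficient noise SD (mm per unit-RMS field).
#' @param scan_index Integer distinguishing the noise of repeated scans.
#' @return A [surface_mesh()].
#' @export
generate_scan_mesh <- function(template, subject, scan_time = 0,
                               noise_sd = 0.05, scan_index = 1L) {
  if (scan_time < 0)
    stop_strucage("scan_time must be >= 0", class = "strucage_validation_error")
  M <- dim(template$basis)[3]
  eff <- subject$baseline_age + subject$pace * scan_time + subject$offset
  a <- template$gains * (eff - template$age_ref)
  subj_coef <- local_rng(derive_seed(subject$noise_seed, 1L),
                         rnorm(M, 0, subject$shape_sd))
  scan_coef <- if (noise_sd > 0)
    local_rng(derive_seed(subject$noise_seed, 100L + scan_index),
              rnorm(M, 0, noise_sd)) else rep(0, M)
  coef <- a + subj_coef + scan_coef
  disp <- matrix(0, n_vertices(template$mesh), 3L)
  for (m in seq_len(M)) disp <- disp + coef[m] * template$basis[, , m]
  surface_mesh(template$mesh$vertices + disp, template$mesh$faces,
               structure = template$structure,
               hemisphere = template$hemisphere)
}

#' Generate a synthetic cohort of meshes with known ground truth
#'
#' Subjects are drawn per group with baseline ages uniform in
#' `baseline_age_range` and scanned `scans_per_subject` times at evenly
#' spaced intervals over `follow_up_years`. Converter groups
#' (`MCI_converter`, `ADD_converter`) start healthy and switch diagnosis
#' at `switch_time` (default mid-follow-up); their structure age carries a
#' constant offset and an accelerated pace. Baseline-diagnosed groups
#' (`MCI`, `ADD`) carry their diagnosis and offset from the first scan.
#' Default offsets and paces emulate whole-brain-scale pathology: +0.93 /
#' +2.29 years and 1.1228 / 1.3116 times the healthy pace for MCI and ADD
#' converters, and +3.48 / +7.97 years for baseline-diagnosed MCI / ADD.
#'
#' @param n_per_group Named integer vector; names from
#'   `non_converter`, `MCI_converter`, `ADD_converter`, `MCI`, `ADD`.
#' @param structures Structure labels to synthesize.
#' @param scans_per_subject Scans per subject.
#' @param follow_up_years Follow-up span (years).
#' @param baseline_age_range Baseline-age range (years).
#' @param offsets,paces Named vectors of structure-age offsets (years) and
#'   pace multipliers per group.
#' @param shape_sd Subject-level shape-coefficient SD.
#' @param noise_sd Per-scan shape-noise SD.
#' @param switch_time Years after baseline at which converters change
#'   diagnosis; defaults to half the follow-up.
#' @param seed Integer seed; the full cohort is a deterministic function
#'   of the configuration and seed.
#' @param write_dir Optional directory: writes per-scan PLY meshes, the
#'   manifest CSV and the ground-truth CSV.
#' @return A `synthetic_cohort`: list with `manifest` (scan table),
#'   `truth` (per-subject generating parameters), `meshes` (nested list
#'   `meshes[[scan_id]][[structure]]`), `templates`.
#' @export
generate_cohort <- function(n_per_group = c(non_converter = 20L),
                            structures = "accumbens",
                            scans_per_subject = 1L,
                            follow_up_years = 4,
                            baseline_age_range = c(45, 90),
                            offsets = c(non_converter = 0,
                                        MCI_converter = 0.93,
                                        ADD_converter = 2.29,
                                        MCI = 3.48, ADD = 7.97),
                            paces = c(non_converter = 1,
                                      MCI_converter = 1.1228,
                                      ADD_converter = 1.3116,
                                      MCI = 1, ADD = 1),
                            shape_sd = 0.15, noise_sd = 0.05,
                            switch_time = NULL, seed = 1L,
                            write_dir = NULL) {
  stopifnot(all(n_per_group >= 1))
  if (is.null(names(n_per_group)))
    stop_strucage("n_per_group must be named", class = "strucage_config_error")
  switch_time <- switch_time %||% (follow_up_years / 2)
  templates <- lapply(stats::setNames(structures, structures),
                      function(s) make_template(s, seed = derive_seed(seed, match(s, structure_labels()))))
  times <- if (scans_per_subject == 1L) 0 else
    seq(0, follow_up_years, length.out = scans_per_subject)
  manifest <- list(); truth <- list(); meshes <- list()
  sid <- 0L
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      sid <- sid + 1L
      subject_id <- sprintf("sub%04d", sid)
      base_age <- local_rng(derive_seed(seed, 1000L + sid),
                            runif(1, baseline_age_range[1], baseline_age_range[2]))
      subj <- synthetic_subject(subject_id, base_age, group = g,
                                offset = unname(offsets[g]),
                                pace = unname(paces[g]),
                                shape_sd = shape_sd,
                                noise_seed = derive_seed(seed, 2000L + sid))
      truth[[sid]] <- data.frame(subject_id = subject_id, group = g,
                                 baseline_age = base_age,
                                 offset = unname(offsets[g]),
                                 pace = unname(paces[g]),
                                 stringsAsFactors = FALSE)
      for (j in seq_along(times)) {
        scan_id <- sprintf("%s_s%d", subject_id, j)
        diag <- if (g %in% c("MCI", "ADD")) g
                else if (g == "non_converter") "healthy"
                else if (times[j] >= switch_time) sub("_converter", "", g)
                else "healthy"
        manifest[[length(manifest) + 1L]] <- data.frame(
          subject_id = subject_id, scan_id = scan_id,
          age_at_scan = base_age + times[j], delta_scan = times[j],
          diagnosis = diag, stringsAsFactors = FALSE)
        meshes[[scan_id]] <- lapply(templates, function(tpl)
          generate_scan_mesh(tpl, subj, scan_time = times[j],
                             noise_sd = noise_sd, scan_index = j))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  rownames(manifest) <- rownames(truth) <- NULL
  out <- structure(list(manifest = manifest, truth = truth, meshes = meshes,
                        templates = templates, seed = as.integer(seed),
                        noise_sd = noise_sd, shape_sd = shape_sd),
                   class = "synthetic_cohort")
  if (!is.null(write_dir)) write_cohort(out, write_dir)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$truth), "subjects,", nrow(x$manifest),
      "scans,", length(x$templates), "structure(s)\n")
  invisible(x)
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  for (scan_id in names(cohort$meshes))
    for (s in names(cohort$meshes[[scan_id]]))
      write_mesh(cohort$meshes[[scan_id]][[s]],
                 file.path(dir, paste0(scan_id, "_", s, ".ply")))
  invisible(dir)
}

#' Extract a training dataset (feature array) from a synthetic cohort
#'
#' Builds the per-scan feature matrices (coordinates centered per scan and
#' divided by 100) for one or more structures and stacks them into the
#' `nodes x features x scans` array used by the network functions.
#'
#' @param cohort A [generate_cohort()] result.
#' @param structures Structure labels to include (merged in order).
#' @return List with `x` (array), `age`, `subject_id`, `scan_id`,
#'   `graph` (the merged `structure_graph`).
#' @export
cohort_to_dataset <- function(cohort, structures = names(cohort$templates)) {
  graphs <- lapply(structures, function(s)
    mesh_to_graph(cohort$templates[[s]]$mesh))
  graph <- if (length(graphs) == 1L) graphs[[1]] else merge_graphs(graphs)
  manifest <- cohort$manifest
  S <- nrow(manifest)
  x <- NULL
  for (i in seq_len(S)) {
    ms <- cohort$meshes[[manifest$scan_id[i]]][structures]
    ctr <- scan_center(ms)
    feats <- lapply(ms, build_features, center = ctr)
    fm <- do.call(rbind, feats)
    if (is.null(x)) x <- array(0, c(nrow(fm), ncol(fm), S))
    x[, , i] <- fm
  }
  list(x = x, age = manifest$age_at_scan, subject_id = manifest$subject_id,
       scan_id = manifest$scan_id, graph = graph)
}

#' Simulate structure-age tables directly (no meshes)
#'
#' PA-level simulators for validating the statistical models against known
#' generating coefficients.
#'
#' `simulate_structure_ages()` draws a cross-sectional baseline table
#' `PA = intercept + age_coef * age + offset(diagnosis) + N(0, resid_sd)`.
#'
#' @param n Number of subjects.
#' @param intercept,age_coef Generating intercept and age slope.
#' @param offsets Named offsets (years) for `MCI` and `ADD` (healthy = 0).
#' @param resid_sd Residual SD (years); 0 gives a noiseless table.
#' @param age_range Age range (years).
#' @param prob Diagnosis probabilities (healthy, MCI, ADD).
#' @param structure Name of the structure-age column.
#' @param seed Seed.
#' @return Data frame `subject_id`, `age_at_scan`, `diagnosis`, plus the
#'   structure-age column.
#' @export
simulate_structure_ages <- function(n = 300L, intercept = 5, age_coef = 0.9,
                                    offsets = c(MCI = 3.48, ADD = 7.97),
                                    resid_sd = 4, age_range = c(45, 90),
                                    prob = c(0.5, 0.25, 0.25),
                                    structure = "structure_age", seed = 1L) {
  local_rng(seed, {
    age <- runif(n, age_range[1], age_range[2])
    diag <- sample(c("healthy", "MCI", "ADD"), n, replace = TRUE, prob = prob)
    off <- c(healthy = 0, offsets)[diag]
    pa <- intercept + age_coef * age + off + rnorm(n, 0, resid_sd)
    d <- data.frame(subject_id = sprintf("sub%04d", seq_len(n)),
                    age_at_scan = age, diagnosis = diag,
                    stringsAsFactors = FALSE)
    d[[structure]] <- pa
    d
  })
}

#' @rdname simulate_structure_ages
#'
#' `simulate_longitudinal_ages()` draws a longitudinal table
#' `PA = intercept + age_coef * age0 + offset(group) + slope(group) * delta
#' + b0_i + b1_i * delta + N(0, resid_sd)` with per-subject random
#' intercept/slope.
#'
#' @param n_per_group Named counts for the three conversion groups.
#' @param scans_per_subject,follow_up_years Scan schedule.
#' @param slopes Named per-group delta-scan slopes (years/year).
#' @param group_offsets Named converter intercept offsets (years).
#' @param rand_int_sd,rand_slope_sd,long_resid_sd Random-effect and
#'   residual SDs.
#' @export
simulate_longitudinal_ages <- function(n_per_group = c(non_converter = 60L,
                                                       MCI_converter = 45L,
                                                       ADD_converter = 45L),
                                       scans_per_subject = 3L,
                                       follow_up_years = 4,
                                       intercept = 0, age_coef = 1,
                                       slopes = c(non_converter = 1,
                                                  MCI_converter = 1.1228,
                                                  ADD_converter = 1.3116),
                                       group_offsets = c(non_converter = 0,
                                                         MCI_converter = 0.93,
                                                         ADD_converter = 2.29),
                                       rand_int_sd = 3, rand_slope_sd = 0.2,
                                       long_resid_sd = 1.5,
                                       age_range = c(55, 85),
                                       structure = "structure_age",
                                       seed = 1L) {
  local_rng(seed, {
    rows <- list()
    sid <- 0L
    times <- seq(0, follow_up_years, length.out = scans_per_subject)
    for (g in names(n_per_group)) {
      for (i in seq_len(n_per_group[[g]])) {
        sid <- sid + 1L
        age0 <- runif(1, age_range[1], age_range[2])
        b0 <- rnorm(1, 0, rand_int_sd)
        b1 <- rnorm(1, 0, rand_slope_sd)
        pa <- intercept + age_coef * age0 + group_offsets[[g]] +
          slopes[[g]] * times + b0 + b1 * times +
          rnorm(length(times), 0, long_resid_sd)
        rows[[sid]] <- data.frame(
          subject_id = sprintf("sub%04d", sid), group = g,
          age_baseline = age0, delta_scan = times,
          age_at_scan = age0 + times, pa = pa, stringsAsFactors = FALSE)
      }
    }
    d <- do.call(rbind, rows)
    rownames(d) <- NULL
    names(d)[names(d) == "pa"] <- structure
    d$group <- factor(d$group, levels = c("non_converter", "MCI_converter",
                                          "ADD_converter"))
    d
  })
}
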