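# synthetic templates, scan meshes and cohorts

test_that("templates carry the per-structure node counts", {
  expect_equal(n_vertices(make_template("accumbens")$mesh), 256L)
  expect_equal(n_vertices(make_template("hippocampus")$mesh), 2048L)
})

test_that("templates are deterministic in the seed and watertight", {
  t1 <- make_template("accumbens", seed = 4)
  t2 <- make_template("accumbens", seed = 4)
  expect_identical(t1$mesh$vertices, t2$mesh$vertices)
  expect_identical(t1$mesh$faces, t2$mesh$faces)
  expect_identical(t1$basis, t2$basis)
  # watertight: every edge in exactly two faces
  f <- t1$mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
  # displacement fields have unit RMS vertex norm
  for (m in seq_len(dim(t1$basis)[3]))
    expect_equal(sqrt(mean(rowSums(t1$basis[, , m]^2))), 1, tolerance = 1e-10)
})

test_that("average neighbor edge lengths stay realistic", {
  avg_edge <- function(mesh) {
    f <- mesh$faces
    e <- unique(rbind(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
                      cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
                      cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))))
    mean(sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2)))
  }
  for (s in c("accumbens", "hippocampus"))
    expect_lt(avg_edge(make_template(s)$mesh), 2)
  expect_lt(avg_edge(make_template("cortex")$mesh), 3)
})

test_that("scan meshes are deterministic functions of age and seed", {
  tpl <- make_template("accumbens")
  s1 <- synthetic_subject("a", 70, noise_seed = 5)
  m1 <- generate_scan_mesh(tpl, s1, scan_time = 2, noise_sd = 0)
  m2 <- generate_scan_mesh(tpl, s1, scan_time = 2, noise_sd = 0)
  expect_identical(m1$vertices, m2$vertices)
  # an offset of +8 years equals being 8 years older at baseline
  s_off <- synthetic_subject("a", 70, group = "MCI", offset = 8,
                             noise_seed = 5)
  s_old <- synthetic_subject("a", 78, noise_seed = 5)
  expect_equal(generate_scan_mesh(tpl, s_off, 0, noise_sd = 0)$vertices,
               generate_scan_mesh(tpl, s_old, 0, noise_sd = 0)$vertices)
  # with zero gains age leaves no trace in the mesh
  tpl0 <- tpl
  tpl0$gains[] <- 0
  sa <- synthetic_subject("a", 50, shape_sd = 0, noise_seed = 5)
  sb <- synthetic_subject("a", 90, shape_sd = 0, noise_seed = 5)
  expect_equal(generate_scan_mesh(tpl0, sa, 0, noise_sd = 0)$vertices,
               generate_scan_mesh(tpl0, sb, 0, noise_sd = 0)$vertices)
  expect_equal(generate_scan_mesh(tpl0, sa, 0, noise_sd = 0)$vertices,
               tpl$mesh$vertices)
  expect_error(generate_scan_mesh(tpl, s1, scan_time = -1),
               class = "strucage_validation_error")
  expect_error(synthetic_subject("a", 70, pace = 0),
               class = "strucage_validation_error")
  expect_error(synthetic_subject("a", 70, group = "non_converter", offset = 2),
               class = "strucage_validation_error")
})

test_that("cohort manifests carry consistent diagnoses and timings", {
  coh <- generate_cohort(c(non_converter = 10L), scans_per_subject = 3L,
                         follow_up_years = 4, seed = 6)
  expect_equal(nrow(coh$manifest), 30L)
  expect_true(all(coh$manifest$diagnosis == "healthy"))
  expect_true(all(coh$manifest$delta_scan >= 0))
  expect_true(all(coh$manifest$delta_scan[!duplicated(coh$manifest$subject_id)] == 0))
  # converters switch diagnosis at the configured time
  coh2 <- generate_cohort(c(MCI_converter = 2L), scans_per_subject = 3L,
                          follow_up_years = 3, switch_time = 2, seed = 7)
  d <- coh2$manifest$diagnosis[coh2$manifest$subject_id == "sub0001"]
  expect_equal(d, c("healthy", "healthy", "MCI"))
  # baseline-diagnosed groups carry their label from the first scan
  coh3 <- generate_cohort(c(ADD = 2L), scans_per_subject = 2L, seed = 8)
  expect_true(all(coh3$manifest$diagnosis == "ADD"))
})

test_that("identical configuration and seed reproduce the cohort exactly", {
  c1 <- generate_cohort(c(non_converter = 3L), scans_per_subject = 2L, seed = 9)
  c2 <- generate_cohort(c(non_converter = 3L), scans_per_subject = 2L, seed = 9)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$meshes[["sub0002_s2"]][["accumbens"]]$vertices,
                   c2$meshes[["sub0002_s2"]][["accumbens"]]$vertices)
})

test_that("cohorts round-trip to disk as PLY + CSV", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(c(non_converter = 2L), seed = 10, write_dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_true(all(c("group", "baseline_age", "offset", "pace") %in%
                  names(truth)))
  m <- read_mesh(file.path(dir, "sub0001_s1_accumbens.ply"))
  expect_identical(m$vertices, coh$meshes[["sub0001_s1"]][["accumbens"]]$vertices)
})

test_that("the PA-level simulators expose their generating truth", {
  d <- simulate_structure_ages(n = 500, seed = 11)
  expect_setequal(unique(d$diagnosis), c("healthy", "MCI", "ADD"))
  dl <- simulate_longitudinal_ages(seed = 12)
  expect_true(all(table(dl$subject_id) == 3))
  expect_equal(unique(dl$delta_scan), c(0, 2, 4))
})
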