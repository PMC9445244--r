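# cohort selection, cross-sectional OLS, longitudinal mixed model, FDR

test_that("longitudinal inclusion rules match their definitions", {
  rec <- data.frame(
    subject_id = c("one_scan", "late_onset", "late_onset",
                   "young", "young", "mci_base", "mci_base",
                   "conv", "conv", "conv"),
    age_at_scan = c(80, 68, 72, 60, 63, 69, 73, 70, 72, 74),
    diagnosis = c("healthy", "healthy", "healthy", "healthy", "healthy",
                  "MCI", "ADD", "healthy", "MCI", "ADD"),
    stringsAsFactors = FALSE)
  sel <- select_longitudinal_cohort(rec)
  expect_setequal(sel$subject_id, c("late_onset", "conv"))
  expect_equal(as.character(sel$group[sel$subject_id == "late_onset"]),
               "non_converter")     # healthy at 68, last healthy at 72
  expect_equal(as.character(sel$group[sel$subject_id == "conv"]),
               "ADD_converter")     # grouped by the last diagnosis
  # pure filter: row order does not matter
  sel2 <- select_longitudinal_cohort(rec[sample(nrow(rec)), ])
  expect_equal(sel2[order(sel2$subject_id), ], sel[order(sel$subject_id), ],
               ignore_attr = TRUE)
  expect_true(all(sel$subject_id %in% rec$subject_id))
})

test_that("noiseless cross-sectional data is recovered to machine precision", {
  d <- simulate_structure_ages(n = 200, intercept = 5, age_coef = 0.9,
                               offsets = c(MCI = 3, ADD = 7), resid_sd = 0,
                               seed = 2)
  fit <- fit_cross_sectional(d, "structure_age")
  expect_equal(fit$estimate[fit$contrast == "MCI"], 3, tolerance = 1e-6)
  expect_equal(fit$estimate[fit$contrast == "ADD"], 7, tolerance = 1e-6)
  expect_equal(unique(fit$age_coef), 0.9, tolerance = 1e-6)
  expect_equal(unique(fit$intercept), 5, tolerance = 1e-6)
  expect_true(all(fit$p_fdr >= fit$p - 1e-15))
  expect_true(all(fit$ci_lo <= fit$estimate & fit$estimate <= fit$ci_hi))
})

test_that("an absent diagnosis level is a rank error naming the level", {
  d <- simulate_structure_ages(n = 50, prob = c(0.5, 0.5, 0), seed = 3)
  expect_error(fit_cross_sectional(d, "structure_age"), "ADD",
               class = "strucage_rank_error")
})

test_that("cross-sectional recovery stays inside its confidence intervals", {
  # amygdala-like offsets, moderate n kept CPU-friendly
  hits <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    d <- simulate_structure_ages(n = 300, offsets = c(MCI = 3.5, ADD = 8),
                                 resid_sd = 4, seed = 100 + r)
    fit <- fit_cross_sectional(d, "structure_age")
    ok <- fit$ci_lo[1] <= 3.5 && 3.5 <= fit$ci_hi[1] &&
          fit$ci_lo[2] <= 8 && 8 <= fit$ci_hi[2]
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("noiseless longitudinal slopes are exact and ratios follow", {
  d <- simulate_longitudinal_ages(
    n_per_group = c(non_converter = 20, MCI_converter = 15,
                    ADD_converter = 15),
    slopes = c(non_converter = 1, MCI_converter = 1.10,
               ADD_converter = 1.30),
    group_offsets = c(non_converter = 0, MCI_converter = 2,
                      ADD_converter = 2),
    rand_int_sd = 0, rand_slope_sd = 0, long_resid_sd = 0, seed = 4)
  fit <- suppressWarnings(fit_longitudinal(d, "structure_age"))
  est <- function(term) fit$estimate[fit$contrast == term]
  expect_equal(est("slope_HC"), 1.00, tolerance = 1e-6)
  expect_equal(est("slope_MCI"), 1.10, tolerance = 1e-6)
  expect_equal(est("slope_ADD"), 1.30, tolerance = 1e-6)
  # the "+2-year converter effect" intercept offsets are recovered too
  expect_equal(est("MCI_offset"), 2, tolerance = 1e-6)
  expect_equal(est("ADD_offset"), 2, tolerance = 1e-6)
  sl <- aging_slope_percent(fit)
  expect_equal(sl$percent[sl$group == "MCI"], 10, tolerance = 1e-4)
  expect_equal(sl$percent[sl$group == "ADD"], 30, tolerance = 1e-4)
})

test_that("a noisy longitudinal fit recovers slopes within 2 SE", {
  d <- simulate_longitudinal_ages(
    n_per_group = c(non_converter = 60, MCI_converter = 45,
                    ADD_converter = 45),
    rand_int_sd = 3, rand_slope_sd = 0.2, long_resid_sd = 1.5, seed = 5)
  fit <- suppressWarnings(fit_longitudinal(d, "structure_age"))
  truth <- c(slope_HC = 1, slope_MCI = 1.1228, slope_ADD = 1.3116,
             MCI_offset = 0.93, ADD_offset = 2.29)
  for (term in names(truth)) {
    row <- fit[fit$contrast == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 2 * row$se)
  }
})

test_that("aging pace percentages follow the signed ratio convention", {
  d <- data.frame(structure = "s",
                  contrast = c("slope_HC", "slope_MCI", "slope_ADD"),
                  estimate = c(2.0, 2.5, 2.0))
  sl <- aging_slope_percent(d)
  expect_equal(sl$percent, c(25, 0))
  d2 <- data.frame(structure = "s",
                   contrast = c("slope_HC", "slope_ADD"),
                   estimate = c(1.0, 0.968))
  expect_equal(aging_slope_percent(d2)$percent, -3.2, tolerance = 1e-10)
  d3 <- data.frame(structure = "s", contrast = "slope_HC", estimate = 0)
  expect_error(aging_slope_percent(d3), class = "strucage_ratio_error")
})

test_that("FDR adjustment follows the step-up formula and is order-invariant", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(rep(0.2, 5)), rep(0.2, 5))
  # hand-derived: min over j >= i of p_(j) * m / j
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(c(0.001, 0.01, 0.9)),
               c(0.003, 0.015, 0.9))
  set.seed(6)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(fdr_correct(p)[perm], fdr_correct(p[perm]))
  expect_error(fdr_correct(c(0.5, 1.2)), class = "strucage_validation_error")
})
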