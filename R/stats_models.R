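# Cross-sectional and longitudinal analyses of structure age.
#
# Cross-sectional: per structure, OLS of predicted structure age on
# chronological age and diagnosis (healthy reference) at the baseline
# scan; the diagnosis coefficients are the extra predicted years carried
# by MCI and ADD. Longitudinal: per structure, a linear mixed model on
# subjects who were healthy at baseline, had repeated scans and were at
# least 70 at the last scan, grouped by their last diagnosis; fixed
# effects are conversion group, baseline age and one time-since-baseline
# slope per group, with per-subject random intercept and slope. The
# "aging pace" of a converter group is its slope relative to the
# non-converter slope, reported as a signed percent deviation.

#' Select the longitudinal cohort and assign conversion groups
#'
#' Keeps subjects with at least two scans, a healthy diagnosis at the
#' baseline (first) scan and age at the last scan of at least 70 years,
#' and groups them by the diagnosis at the last scan: `non_converter`
#' (healthy), `MCI_converter`, `ADD_converter`.
#'
#' @param records Data frame with one row per scan: columns `subject_id`,
#'   `age_at_scan`, `diagnosis` (`"healthy"`, `"MCI"`, `"ADD"`), and
#'   either `delta_scan` (years since the subject's first scan) or rows
#'   orderable by `age_at_scan`.
#' @param min_last_age Minimum age at last scan (default 70).
#' @return Data frame `subject_id`, `group` (one row per included
#'   subject); empty when no subject qualifies. A pure filter: the result
#'   does not depend on row order.
#' @export
select_longitudinal_cohort <- function(records, min_last_age = 70) {
  stopifnot(all(c("subject_id", "age_at_scan", "diagnosis") %in%
                names(records)))
  records <- records[order(records$subject_id, records$age_at_scan), ]
  out <- do.call(rbind, lapply(split(records, records$subject_id), function(r) {
    if (nrow(r) < 2L) return(NULL)
    if (r$diagnosis[1] != "healthy") return(NULL)
    if (r$age_at_scan[nrow(r)] < min_last_age) return(NULL)
    last <- r$diagnosis[nrow(r)]
    grp <- switch(last, healthy = "non_converter", MCI = "MCI_converter",
                  ADD = "ADD_converter", NA_character_)
    if (is.na(grp)) return(NULL)
    data.frame(subject_id = r$subject_id[1], group = grp,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(subject_id = character(0), group = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$group <- factor(out$group,
                      levels = c("non_converter", "MCI_converter",
                                 "ADD_converter"))
  out
}

#' Cross-sectional model of structure age at baseline
#'
#' Per structure, fits `PA ~ age + diagnosis` by OLS on baseline scans,
#' with diagnosis treatment-coded against the healthy reference. The MCI
#' and ADD coefficients estimate the additional predicted years carried by
#' each diagnosis at a fixed chronological age. P-values of all
#' structure-by-contrast tests are FDR-corrected together.
#'
#' @param records Data frame of baseline scans: columns `subject_id`,
#'   `age_at_scan`, `diagnosis`, plus one numeric column per structure
#'   configuration holding the (corrected) predicted age.
#' @param structures Character vector naming the structure-age columns.
#' @param conf_level Confidence level for the intervals.
#' @return A `model_fit` data frame: one row per structure x contrast with
#'   `estimate`, `se`, `ci_lo`, `ci_hi`, `p`, `p_fdr`.
#' @export
fit_cross_sectional <- function(records, structures, conf_level = 0.95) {
  records$diagnosis <- factor(records$diagnosis,
                              levels = c("healthy", "MCI", "ADD"))
  present <- levels(droplevels(records$diagnosis))
  if (length(present) < 3L)
    stop_strucage("diagnosis level(s) absent: ",
                  paste(setdiff(c("healthy", "MCI", "ADD"), present),
                        collapse = ", "),
                  class = "strucage_rank_error")
  rows <- list()
  for (s in structures) {
    d <- records
    d$PA <- d[[s]]
    fit <- stats::lm(PA ~ age_at_scan + diagnosis, data = d)
    sm <- suppressWarnings(summary(fit))$coefficients
    ci <- suppressWarnings(stats::confint(fit, level = conf_level))
    for (term in c("diagnosisMCI", "diagnosisADD")) {
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s,
        contrast = sub("diagnosis", "", term),
        estimate = sm[term, "Estimate"], se = sm[term, "Std. Error"],
        ci_lo = ci[term, 1], ci_hi = ci[term, 2],
        p = sm[term, "Pr(>|t|)"],
        age_coef = sm["age_at_scan", "Estimate"],
        intercept = sm["(Intercept)", "Estimate"],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_fdr <- fdr_correct(out$p)
  class(out) <- c("model_fit", class(out))
  out
}

#' Longitudinal mixed model of structure aging pace
#'
#' Per structure, fits a linear mixed model on the longitudinal cohort:
#' fixed effects are the conversion group (treatment coding, non-converter
#' reference), age at baseline, and one time-since-baseline slope per
#' group (`delta_scan:group`, no common slope term); random effects are a
#' per-subject intercept and slope on `delta_scan` (correlated bivariate
#' normal, falling back to uncorrelated when the fit is singular). REML
#' estimation; Satterthwaite degrees of freedom for the slope contrasts
#' (converter slope minus non-converter slope), FDR-corrected across all
#' structure x contrast tests.
#'
#' @param records Data frame of scans of the longitudinal cohort: columns
#'   `subject_id`, `age_baseline`, `delta_scan`, `group` (factor as from
#'   [select_longitudinal_cohort()]), plus one column per structure
#'   configuration with the (corrected) predicted age.
#' @param structures Character vector naming the structure-age columns.
#' @param conf_level Confidence level.
#' @return A `model_fit` data frame with one row per structure x term:
#'   group offsets (`MCI_offset`, `ADD_offset`), per-group slopes
#'   (`slope_HC`, `slope_MCI`, `slope_ADD`) and slope contrasts
#'   (`MCI_slope_vs_HC`, `ADD_slope_vs_HC`); slope-contrast and offset
#'   p-values are FDR-corrected together. The lme4 fits are attached as
#'   `attr(, "fits")`.
#' @export
fit_longitudinal <- function(records, structures, conf_level = 0.95) {
  stopifnot(all(c("subject_id", "age_baseline", "delta_scan", "group") %in%
                names(records)))
  records$group <- factor(records$group,
                          levels = c("non_converter", "MCI_converter",
                                     "ADD_converter"))
  if (any(tapply(records$delta_scan, records$subject_id, length) < 2L))
    stop_strucage("every included subject needs at least 2 scans",
                  class = "strucage_validation_error")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  fits <- list()
  for (s in structures) {
    d <- records
    d$PA <- d[[s]]
    fit <- fit_lmm_with_fallback(d)
    fits[[s]] <- fit
    fe <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    nm <- names(fe)
    sl <- function(g) paste0("group", g, ":delta_scan")
    if (!all(c(sl("non_converter"), sl("MCI_converter"),
               sl("ADD_converter")) %in% nm))
      stop_strucage("group slopes missing from fit (level absent?)",
                    class = "strucage_rank_error")
    term_row <- function(term, L) {
      est <- sum(L * fe)
      se <- sqrt(drop(t(L) %*% V %*% L))
      pv <- tryCatch(
        lmerTest::contest1D(fit, L, ddf = "Satterthwaite")[["Pr(>|t|)"]],
        error = function(e) 2 * stats::pnorm(-abs(est / se)))
      data.frame(structure = s, contrast = term, estimate = est, se = se,
                 ci_lo = est - z * se, ci_hi = est + z * se, p = pv,
                 stringsAsFactors = FALSE)
    }
    unit <- function(term) { L <- rep(0, length(fe)); L[match(term, nm)] <- 1; L }
    contrast <- function(a, b) unit(a) - unit(b)
    rows[[length(rows) + 1L]] <- term_row("MCI_offset", unit("groupMCI_converter"))
    rows[[length(rows) + 1L]] <- term_row("ADD_offset", unit("groupADD_converter"))
    rows[[length(rows) + 1L]] <- term_row("slope_HC", unit(sl("non_converter")))
    rows[[length(rows) + 1L]] <- term_row("slope_MCI", unit(sl("MCI_converter")))
    rows[[length(rows) + 1L]] <- term_row("slope_ADD", unit(sl("ADD_converter")))
    rows[[length(rows) + 1L]] <- term_row("MCI_slope_vs_HC",
      contrast(sl("MCI_converter"), sl("non_converter")))
    rows[[length(rows) + 1L]] <- term_row("ADD_slope_vs_HC",
      contrast(sl("ADD_converter"), sl("non_converter")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tested <- out$contrast %in% c("MCI_offset", "ADD_offset",
                                "MCI_slope_vs_HC", "ADD_slope_vs_HC")
  out$p_fdr <- NA_real_
  out$p_fdr[tested] <- fdr_correct(out$p[tested])
  attr(out, "fits") <- fits
  class(out) <- c("model_fit", class(out))
  out
}

fit_lmm_with_fallback <- function(d) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(PA ~ group + age_baseline + group:delta_scan +
                     (1 + delta_scan | subject_id),
                   data = d, REML = TRUE, control = ctrl)))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular random-effect covariance; refitting with uncorrelated random effects",
            call. = FALSE)
    fit2 <- try(suppressMessages(suppressWarnings(
      lmerTest::lmer(PA ~ group + age_baseline + group:delta_scan +
                       (1 + delta_scan || subject_id),
                     data = d, REML = TRUE, control = ctrl))), silent = TRUE)
    if (!inherits(fit2, "try-error")) fit <- fit2
  }
  fit
}

#' Aging pace of converter groups as a percent of the non-converter slope
#'
#' The aging slope of a converter group is the ratio of its
#' `delta_scan:group` fixed effect to the non-converter fixed effect,
#' reported as a signed percent deviation:
#' `(slope_conv / slope_HC - 1) * 100` (so an identical pace is 0% and a
#' slower pace is negative).
#'
#' @param fit A [fit_longitudinal()] result (or a data frame with columns
#'   `structure`, `contrast`, `estimate` holding `slope_HC`, `slope_MCI`,
#'   `slope_ADD` rows).
#' @return Data frame `structure`, `group`, `percent`.
#' @export
#' @examples
#' d <- data.frame(structure = "hippocampus",
#'                 contrast = c("slope_HC", "slope_MCI", "slope_ADD"),
#'                 estimate = c(2, 2.5, 2))
#' aging_slope_percent(d)
aging_slope_percent <- function(fit) {
  out <- list()
  for (s in unique(fit$structure)) {
    d <- fit[fit$structure == s, ]
    hc <- d$estimate[d$contrast == "slope_HC"]
    if (length(hc) != 1L || is.na(hc))
      stop_strucage("non-converter slope missing for ", s,
                    class = "strucage_validation_error")
    if (abs(hc) < 1e-8)
      stop_strucage("non-converter slope is zero for ", s,
                    "; pace ratio undefined", class = "strucage_ratio_error")
    for (g in c("MCI", "ADD")) {
      sl <- d$estimate[d$contrast == paste0("slope_", g)]
      if (length(sl) != 1L) next
      out[[length(out) + 1L]] <- data.frame(
        structure = s, group = g, percent = (sl / hc - 1) * 100,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (monotone in rank order, capped at 1),
#' invariant to the order of the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.03, 0.04))
fdr_correct <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_strucage("p-values must lie in [0, 1]",
                  class = "strucage_validation_error")
  stats::p.adjust(p, method = "BH")
}
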