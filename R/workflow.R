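# Experiment orchestration: subject-level cohort splitting and the
# simulate -> graphs -> train (structure configurations x seeds) ->
# predict (ensemble + TTA) -> bias-correct -> statistics pipeline, with a
# deterministic on-disk layout and a provenance manifest.

#' Split a cohort into train / validation / test at the subject level
#'
#' Subjects with repeated scans are routed to the test set (their
#' longitudinal scans are the material of the longitudinal analysis);
#' training and validation subjects are drawn at random from the
#' single-scan subjects, and every scan of a subject shares its split, so
#' no subject can leak across splits.
#'
#' @param manifest Data frame with columns `subject_id` and `scan_id`.
#' @param fractions Length-3 numeric (train, validation, test) summing
#'   to 1; counts are rounded from the total subject count.
#' @param seed Integer seed for the random draw.
#' @return List with character vectors `train`, `validation`, `test`
#'   (subject ids; disjoint, union = all subjects).
#' @export
split_cohort <- function(manifest, fractions = c(0.661, 0.165, 0.174),
                         seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop_strucage("fractions must be 3 numbers summing to 1",
                  class = "strucage_config_error")
  tab <- table(manifest$subject_id[!duplicated(manifest$scan_id)])
  subjects <- names(tab)
  n_total <- length(subjects)
  multi <- subjects[tab > 1L]
  single <- subjects[tab == 1L]
  n_train <- round(fractions[1] * n_total)
  n_val <- round(fractions[2] * n_total)
  if (length(single) < n_train + n_val)
    stop_strucage("too few single-scan subjects (", length(single),
                  ") for train+validation (", n_train + n_val, ")",
                  class = "strucage_validation_error")
  picked <- local_rng(seed, sample(single, n_train + n_val))
  train <- sort(picked[seq_len(n_train)])
  val <- sort(picked[n_train + seq_len(n_val)])
  test <- sort(setdiff(subjects, c(train, val)))
  list(train = train, validation = val, test = test)
}

#' Experiment configuration
#'
#' Describes a full structure-age experiment: which structure
#' configurations to train (any of the seven subcortical structures,
#' `"cortex"`, `"subcortical"` for all subcortical structures merged, or
#' `"all"` for everything merged), how many seeds per configuration, and
#' the module configurations. The full-scale experiment is 10
#' configurations x 20 seeds = 200 trained networks.
#'
#' @param structure_configs Character vector of configuration names.
#' @param seeds Integer vector of training seeds (one network per
#'   configuration per seed; must be distinct).
#' @param network An [age_network_config()].
#' @param training A [training_config()].
#' @param inference An [inference_config()].
#' @param split_fractions Train/validation/test fractions.
#' @param output_dir Output directory for [run_experiment()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(structure_configs = c("all", "cortex",
                                                    "subcortical",
                                                    setdiff(structure_labels(),
                                                            "cortex")),
                              seeds = 1:20,
                              network = age_network_config(),
                              training = training_config(),
                              inference = inference_config(),
                              split_fractions = c(0.661, 0.165, 0.174),
                              output_dir = "strucage_results") {
  if (length(structure_configs) == 0L)
    stop_strucage("structure_configs must be nonempty",
                  class = "strucage_config_error")
  if (anyDuplicated(seeds))
    stop_strucage("seeds must be distinct", class = "strucage_config_error")
  structure(list(structure_configs = structure_configs,
                 seeds = as.integer(seeds), network = network,
                 training = training, inference = inference,
                 split_fractions = split_fractions,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Number of networks an experiment will train
#'
#' @param config An [experiment_config()].
#' @return `length(structure_configs) * length(seeds)`.
#' @export
#' @examples
#' n_models(experiment_config())  # the full-scale experiment trains 200
n_models <- function(config) {
  length(config$structure_configs) * length(config$seeds)
}

# resolve a configuration name to the structure labels it merges
config_structures <- function(name) {
  if (name == "all") structure_labels()
  else if (name == "subcortical") setdiff(structure_labels(), "cortex")
  else check_structure_label(name)
}

#' Run a full experiment on a synthetic cohort
#'
#' End-to-end pipeline: split the cohort at the subject level, then for
#' every structure configuration train one network per seed, predict the
#' test scans with ensemble + TTA, fit the bias model on validation
#' predictions and correct the test predictions, and run the
#' cross-sectional (when baseline diagnoses vary) and longitudinal (when
#' the longitudinal cohort is nonempty) analyses. Results are written
#' under `config$output_dir` (`models/`, `predictions/`, `bias/`,
#' `stats/`, `manifest.json`); a rerun with the same configuration and
#' cohort reproduces identical outputs.
#'
#' @param config An [experiment_config()].
#' @param cohort A [generate_cohort()] cohort whose templates cover the
#'   requested structure configurations.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `predictions` (data frame),
#'   `bias_models`, `cross_sectional`, `longitudinal`, `aging_slopes`,
#'   `split`, `output_dir`.
#' @export
run_experiment <- function(config, cohort, verbose = FALSE) {
  out_dir <- config$output_dir
  for (d in c("", "models", "predictions", "bias", "stats"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  split <- split_cohort(cohort$manifest, config$split_fractions,
                        seed = config$training$seed)
  manifest <- cohort$manifest
  scan_split <- function(subjects) manifest$subject_id %in% subjects
  pred_rows <- list()
  bias_models <- list()
  for (cfg_name in config$structure_configs) {
    structs <- config_structures(cfg_name)
    if (!all(structs %in% names(cohort$templates)))
      stop_strucage("cohort lacks templates for configuration '", cfg_name,
                    "'", class = "strucage_config_error")
    say("configuration ", cfg_name)
    ds <- cohort_to_dataset(cohort, structs)
    pick <- function(mask) subset_scans(ds, which(mask))
    tr <- pick(scan_split(split$train))
    va <- pick(scan_split(split$validation))
    te <- pick(scan_split(split$test))
    hierarchy <- binary_partition(ds$graph,
                                  config$network$n_residual_blocks + 1L)
    nets <- list()
    for (i in seq_along(config$seeds)) {
      s <- config$seeds[i]
      say("  seed ", s)
      tc <- config$training
      tc$seed <- s
      net <- build_age_network(ds$graph, config$network,
                               n_features = dim(ds$x)[2],
                               hierarchy = hierarchy, seed = s,
                               output_bias_init = mean(tr$age))
      net <- train_age_network(net, tr, va, tc)
      nets[[i]] <- net
      saveRDS(list(config = config$network, seed = s,
                   hierarchy_hash = net$hierarchy_hash,
                   params = net$params, bn_state = net$bn_state,
                   history = attr(net, "history")),
              file.path(out_dir, "models",
                        sprintf("%s_seed%03d.rds", cfg_name, s)))
    }
    icfg <- config$inference
    icfg$ensemble_size <- min(icfg$ensemble_size, length(nets))
    val_pred <- predict_ensemble_tta(nets, va$x, icfg, scan_id = va$scan_id,
                                     seed = derive_seed(config$training$seed,
                                                        3000L))
    bias <- tryCatch(
      fit_bias(va$age, val_pred$aggregated, structure_config = cfg_name),
      strucage_validation_error = function(e) {
        warning("bias model skipped for '", cfg_name, "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    bias_models[[cfg_name]] <- bias
    test_pred <- predict_ensemble_tta(nets, te$x, icfg, scan_id = te$scan_id,
                                      seed = derive_seed(config$training$seed,
                                                         4000L))
    if (!is.null(bias)) {
      test_pred <- apply_bias(bias, test_pred)
    } else {
      test_pred$corrected <- test_pred$aggregated
    }
    pred_rows[[cfg_name]] <- data.frame(
      scan_id = te$scan_id, structure_config = cfg_name,
      n_estimates = ncol(test_pred$raw),
      age_pred_raw_mean = test_pred$aggregated,
      age_pred_corrected = test_pred$corrected,
      stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, pred_rows)
  rownames(predictions) <- NULL
  utils::write.csv(predictions,
                   file.path(out_dir, "predictions", "predictions.csv"),
                   row.names = FALSE)
  saveRDS(bias_models, file.path(out_dir, "bias", "bias_models.rds"))
  # join predictions to the manifest for the analyses
  wide <- stats::reshape(predictions[, c("scan_id", "structure_config",
                                         "age_pred_corrected")],
                         idvar = "scan_id", timevar = "structure_config",
                         direction = "wide")
  names(wide) <- sub("^age_pred_corrected\\.", "", names(wide))
  records <- merge(manifest, wide, by = "scan_id")
  struct_cols <- setdiff(names(wide), "scan_id")
  cross <- NULL
  if (length(unique(records$diagnosis[records$delta_scan == 0])) == 3L) {
    base <- records[records$delta_scan == 0, ]
    cross <- fit_cross_sectional(base, struct_cols)
    utils::write.csv(cross, file.path(out_dir, "stats", "cross_sectional.csv"),
                     row.names = FALSE)
  }
  long <- NULL
  slopes <- NULL
  groups <- select_longitudinal_cohort(records)
  if (nrow(groups) > 0L && length(unique(groups$group)) == 3L) {
    lrec <- merge(records, groups, by = "subject_id")
    base_age <- stats::aggregate(age_at_scan ~ subject_id,
                                 data = lrec[lrec$delta_scan == 0, ], FUN = min)
    names(base_age)[2] <- "age_baseline"
    lrec <- merge(lrec, base_age, by = "subject_id")
    long <- fit_longitudinal(lrec, struct_cols)
    slopes <- aging_slope_percent(long)
    utils::write.csv(long, file.path(out_dir, "stats", "longitudinal.csv"),
                     row.names = FALSE)
    utils::write.csv(slopes, file.path(out_dir, "stats", "aging_slopes.csv"),
                     row.names = FALSE)
  }
  prov <- list(structure_configs = config$structure_configs,
               seeds = config$seeds,
               split_sizes = lengths(split),
               n_models = n_models(config),
               package_version = as.character(utils::packageVersion("strucage")))
  jsonlite::write_json(prov, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(predictions = predictions, bias_models = bias_models,
                 cross_sectional = cross, longitudinal = long,
                 aging_slopes = slopes, split = split,
                 output_dir = out_dir))
}
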