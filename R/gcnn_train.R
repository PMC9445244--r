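# Training (MSE + L2, RMSprop, patience-based LR schedule and early
# stopping), ensemble + test-time-augmentation inference, and accuracy
# metrics.

#' Training configuration
#'
#' Defaults are the full-scale training regime: MSE loss with MAE monitored on the
#' validation set, RMSprop with initial learning rate 0.001, learning rate
#' divided by 10 after 15 epochs without validation-MAE improvement,
#' training stopped after 30, random rotations within 15 degrees during
#' training and 5 degrees during validation, and validation TTA of 3
#' (the mean of three augmented predictions per scan is scored).
#'
#' @param initial_lr Initial learning rate.
#' @param lr_drop_factor Factor by which the learning rate is divided.
#' @param lr_patience_epochs Non-improving epochs before a learning-rate
#'   drop.
#' @param stop_patience_epochs Non-improving epochs before training stops
#'   (must be `>= lr_patience_epochs`).
#' @param train_rotation_deg,val_rotation_deg Augmentation rotation bounds
#'   (degrees).
#' @param val_tta Augmented predictions averaged per validation scan.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param seed Seed controlling shuffling, augmentation and dropout.
#' @param rmsprop_rho,rmsprop_eps RMSprop decay and stabilizer.
#' @return A `training_config` list.
#' @export
training_config <- function(initial_lr = 0.001, lr_drop_factor = 10,
                            lr_patience_epochs = 15L,
                            stop_patience_epochs = 30L,
                            train_rotation_deg = 15, val_rotation_deg = 5,
                            val_tta = 3L, batch_size = 16L,
                            max_epochs = 100L, seed = 1L,
                            rmsprop_rho = 0.9, rmsprop_eps = 1e-7) {
  stopifnot(stop_patience_epochs >= lr_patience_epochs,
            train_rotation_deg >= 0, val_rotation_deg >= 0,
            val_tta >= 1, batch_size >= 1, max_epochs >= 1)
  structure(list(initial_lr = initial_lr, lr_drop_factor = lr_drop_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 stop_patience_epochs = as.integer(stop_patience_epochs),
                 train_rotation_deg = train_rotation_deg,
                 val_rotation_deg = val_rotation_deg,
                 val_tta = as.integer(val_tta),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 rmsprop_rho = rmsprop_rho, rmsprop_eps = rmsprop_eps),
            class = "training_config")
}

#' One step of the patience-based learning-rate schedule
#'
#' Pure helper encapsulating the schedule semantics: after each epoch the
#' state is updated with whether the monitored validation MAE improved.
#' Training stops once `stop_patience` consecutive non-improving epochs
#' have accumulated; otherwise the learning rate is divided by
#' `drop_factor` at every multiple of `lr_patience` non-improving epochs.
#'
#' @param state List with `lr`, `since_best`, `stopped`, `n_drops` (use
#'   `lr_schedule_init()` to create it).
#' @param improved Logical: did this epoch improve the best validation MAE?
#' @param lr_patience,stop_patience,drop_factor Schedule parameters.
#' @return Updated state.
#' @export
lr_schedule_step <- function(state, improved, lr_patience = 15L,
                             stop_patience = 30L, drop_factor = 10) {
  if (improved) {
    state$since_best <- 0L
    return(state)
  }
  state$since_best <- state$since_best + 1L
  if (state$since_best >= stop_patience) {
    state$stopped <- TRUE
  } else if (state$since_best %% lr_patience == 0L) {
    state$lr <- state$lr / drop_factor
    state$n_drops <- state$n_drops + 1L
  }
  state
}

#' @rdname lr_schedule_step
#' @param initial_lr Starting learning rate.
#' @export
lr_schedule_init <- function(initial_lr = 0.001) {
  list(lr = initial_lr, since_best = 0L, stopped = FALSE, n_drops = 0L)
}

# RMSprop over nested parameter/gradient lists
rmsprop_update <- function(params, grads, cache, lr, rho, eps, l2) {
  walk <- function(p, g, c, name) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], c[[nm]], nm)
        p[[nm]] <- r$p
        c[[nm]] <- r$c
      }
      return(list(p = p, c = c))
    }
    g <- as.numeric(g) + 2 * l2 * as.numeric(p) * (name != "bias" &&
                                                   name != "b" &&
                                                   name != "beta" &&
                                                   name != "gamma")
    if (is.null(c)) c <- 0 * as.numeric(p)
    c <- rho * c + (1 - rho) * g^2
    pn <- as.numeric(p) - lr * g / (sqrt(c) + eps)
    attributes(pn) <- attributes(p)
    list(p = pn, c = c)
  }
  # numbered theta lists have no names; give them temporary ones
  walk2 <- function(p, g, c, name) {
    if (is.list(p) && is.null(c)) c <- vector("list", length(p))
    if (is.list(p) && is.null(names(p))) {
      for (i in seq_along(p)) {
        r <- walk2(p[[i]], g[[i]], c[[i]], name)
        p[[i]] <- r$p
        c[[i]] <- r$c
      }
      return(list(p = p, c = c))
    }
    if (is.list(p)) {
      if (is.null(c)) c <- setNames(vector("list", length(p)), names(p))
      for (nm in names(p)) {
        r <- walk2(p[[nm]], g[[nm]], c[[nm]], nm)
        p[[nm]] <- r$p
        c[[nm]] <- r$c
      }
      return(list(p = p, c = c))
    }
    walk(p, g, c, name)
  }
  walk2(params, grads, cache, "root")
}

#' Subset a scan dataset
#'
#' Selects scans (third array dimension and metadata rows) from a dataset
#' as produced by [cohort_to_dataset()]. `idx` may be an integer or
#' logical index, or a character vector of subject ids.
#'
#' @param data List with `x` (`nodes x features x scans`), `age`,
#'   `subject_id`, `scan_id`.
#' @param idx Scans to keep.
#' @return A dataset of the same shape.
#' @export
subset_scans <- function(data, idx) {
  if (is.character(idx)) idx <- data$subject_id %in% idx
  list(x = data$x[, , idx, drop = FALSE], age = data$age[idx],
       subject_id = data$subject_id[idx], scan_id = data$scan_id[idx])
}

n_scans <- function(data) dim(data$x)[3]

#' Train an age network
#'
#' Minimizes MSE plus the L2 penalty of the architecture configuration with
#' RMSprop. Each epoch the validation MAE is computed with
#' rotation-augmented TTA (mean of `val_tta` augmented predictions per
#' scan); the learning-rate schedule and early stopping follow
#' [lr_schedule_step()], and the weights achieving the best validation MAE
#' are restored at the end. Training and validation sets must not share
#' subjects (splits are made at the subject level).
#'
#' @param network An [build_age_network()] object.
#' @param train_data,val_data Lists with `x` (`nodes x features x scans`
#'   array), `age` (years), `subject_id`, `scan_id`.
#' @param config A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained network, with a `history` data.frame (epoch,
#'   train_loss, train_mae, val_mae, lr) and `best_val_mae` attached.
#' @export
train_age_network <- function(network, train_data, val_data,
                              config = training_config(), verbose = FALSE) {
  if (n_scans(train_data) == 0L || n_scans(val_data) == 0L)
    stop_strucage("empty training or validation set",
                  class = "strucage_validation_error")
  overlap <- intersect(unique(train_data$subject_id),
                       unique(val_data$subject_id))
  if (length(overlap) > 0L)
    stop_strucage("subject-level leakage between train and validation: ",
                  paste(utils::head(overlap, 3), collapse = ", "),
                  class = "strucage_leakage_error")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  n_tr <- n_scans(train_data)
  opt_cache <- list()
  sched <- lr_schedule_init(config$initial_lr)
  best <- list(mae = Inf, params = network$params, bn = network$bn_state)
  history <- data.frame()
  l2 <- network$config$l2_lambda
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    ep_loss <- 0; ep_mae <- 0; ep_n <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n_tr)]
      xb <- train_data$x[, , idx, drop = FALSE]
      if (config$train_rotation_deg > 0)
        xb <- random_rotation(xb, config$train_rotation_deg)
      yb <- train_data$age[idx]
      fw <- age_network_forward(network, xb, training = TRUE)
      network$bn_state <- fw$bn_state
      err <- fw$pred - yb
      loss <- mean(err^2)
      dpred <- 2 * err / length(err)
      bw <- age_network_backward(network, fw$cache, dpred)
      upd <- rmsprop_update(network$params, bw$grads, opt_cache,
                            sched$lr, config$rmsprop_rho,
                            config$rmsprop_eps, l2)
      network$params <- upd$p
      opt_cache <- upd$c
      ep_loss <- ep_loss + loss * length(err)
      ep_mae <- ep_mae + sum(abs(err))
      ep_n <- ep_n + length(err)
    }
    # inference-mode statistics: exact training-set moments, not the
    # momentum-lagged running averages
    network <- recalibrate_bn_stats(network, train_data$x,
                                    batch_size = 2L * config$batch_size)
    val_pred <- predict_ages(network, val_data$x, tta = config$val_tta,
                             rotation_deg = config$val_rotation_deg)
    val_mae <- mean(abs(val_pred - val_data$age))
    improved <- val_mae < best$mae
    if (improved)
      best <- list(mae = val_mae, params = network$params,
                   bn = network$bn_state)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n, train_mae = ep_mae / ep_n,
      val_mae = val_mae, lr = sched$lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %8.2f  train MAE %6.2f  val MAE %6.2f  lr %g",
                      epoch, ep_loss / ep_n, ep_mae / ep_n, val_mae, sched$lr))
    sched <- lr_schedule_step(sched, improved,
                              config$lr_patience_epochs,
                              config$stop_patience_epochs,
                              config$lr_drop_factor)
    if (sched$stopped) break
  }
  network$params <- best$params
  network$bn_state <- best$bn
  attr(network, "history") <- history
  attr(network, "best_val_mae") <- best$mae
  network
}

#' Predict ages for a set of scans with one network
#'
#' Inference-mode forward passes (batch-norm running statistics, no
#' dropout), optionally averaged over `tta` randomly rotated copies of each
#' scan.
#'
#' @param network A trained `age_network`.
#' @param x `nodes x features x scans` array (or `nodes x features` matrix
#'   for one scan).
#' @param tta Number of augmented predictions to average per scan (1 = a
#'   single un-averaged pass; rotation is skipped when `rotation_deg = 0`).
#' @param rotation_deg Rotation bound for augmentation (degrees).
#' @param batch_size Scans per forward pass.
#' @return Numeric vector of predicted ages (years), or a matrix
#'   `scans x tta` if `return_all = TRUE`.
#' @param return_all Return every augmented prediction instead of the mean.
#' @param seed Optional integer seed for the augmentation rotations (the
#'   ambient RNG state is restored afterwards); `NULL` uses the current
#'   RNG stream.
#' @export
predict_ages <- function(network, x, tta = 1L, rotation_deg = 5,
                         batch_size = 32L, return_all = FALSE, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
  }
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  S <- dim(x)[3]
  out <- matrix(0, S, tta)
  for (t in seq_len(tta)) {
    # tta = 1 is a single plain pass; augmentation kicks in for tta > 1
    xt <- if (rotation_deg > 0 && tta > 1L)
      random_rotation(x, rotation_deg) else x
    for (s0 in seq(1L, S, by = batch_size)) {
      idx <- s0:min(s0 + batch_size - 1L, S)
      fw <- age_network_forward(network, xt[, , idx, drop = FALSE],
                                training = FALSE)
      out[idx, t] <- fw$pred
    }
  }
  if (return_all) out else rowMeans(out)
}

#' Inference configuration for ensemble + TTA prediction
#'
#' Defaults to the full-scale deployment: an ensemble of 20 seeds, each
#' evaluated on 20 randomly rotated copies of the scan, giving 400 raw
#' estimates per scan, aggregated by the arithmetic mean.
#'
#' @param ensemble_size Number of networks.
#' @param test_tta Augmented predictions per network and scan.
#' @param rotation_deg Rotation bound (degrees; the validation/test value).
#' @return An `inference_config` list.
#' @export
inference_config <- function(ensemble_size = 20L, test_tta = 20L,
                             rotation_deg = 5) {
  stopifnot(ensemble_size >= 1, test_tta >= 1)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 test_tta = as.integer(test_tta),
                 rotation_deg = rotation_deg, aggregation = "mean"),
            class = "inference_config")
}

#' Ensemble + test-time-augmentation age prediction
#'
#' Runs every network of the ensemble on `test_tta` augmented copies of
#' each scan and averages all raw estimates into one aggregated age per
#' scan. All networks must share one structure configuration (same node
#' count, feature width and coarsening hierarchy).
#'
#' @param networks List of trained `age_network`s (uses the first
#'   `ensemble_size` of them; must have at least that many).
#' @param x `nodes x features x scans` array.
#' @param config An [inference_config()].
#' @param scan_id Optional scan identifiers.
#' @param seed Optional integer seed for the augmentation rotations.
#' @return An `age_prediction`: list with `scan_id`, `raw`
#'   (`scans x (ensemble * tta)` matrix), `aggregated` (mean, years) and
#'   `corrected` (`NA` until [apply_bias()] fills it).
#' @export
predict_ensemble_tta <- function(networks, x, config = inference_config(),
                                 scan_id = NULL, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
  }
  if (inherits(networks, "age_network")) networks <- list(networks)
  if (length(networks) < config$ensemble_size)
    stop_strucage("ensemble_size = ", config$ensemble_size, " but only ",
                  length(networks), " networks given",
                  class = "strucage_validation_error")
  networks <- networks[seq_len(config$ensemble_size)]
  fps <- vapply(networks, function(n)
    paste(n$hierarchy_hash, n$n_features), "")
  if (length(unique(fps)) != 1L)
    stop_strucage("networks have mixed structure configurations",
                  class = "strucage_validation_error")
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  S <- dim(x)[3]
  raw <- matrix(NA_real_, S, 0)
  for (net in networks) {
    p <- predict_ages(net, x, tta = config$test_tta,
                      rotation_deg = config$rotation_deg, return_all = TRUE)
    raw <- cbind(raw, p)
  }
  structure(list(scan_id = scan_id %||% seq_len(S), raw = raw,
                 aggregated = rowMeans(raw),
                 corrected = rep(NA_real_, S)),
            class = "age_prediction")
}

#' @export
print.age_prediction <- function(x, ...) {
  cat("age_prediction:", length(x$aggregated), "scan(s),",
      ncol(x$raw), "raw estimates per scan\n")
  invisible(x)
}

#' Accuracy metrics for age predictions
#'
#' @param predictions Numeric vector of predicted ages, or an
#'   `age_prediction` (its corrected ages are used if present, otherwise
#'   the aggregated ones).
#' @param true_ages Numeric vector of chronological ages.
#' @return List with `mae`, `median_ae` (years) and `pearson_r`.
#' @export
#' @examples
#' evaluate_predictions(c(71, 66, 82), c(70, 65, 80))
evaluate_predictions <- function(predictions, true_ages) {
  if (inherits(predictions, "age_prediction"))
    predictions <- if (!anyNA(predictions$corrected)) predictions$corrected
                   else predictions$aggregated
  if (length(predictions) != length(true_ages))
    stop_strucage("length mismatch between predictions and true ages",
                  class = "strucage_validation_error")
  err <- predictions - true_ages
  list(mae = mean(abs(err)), median_ae = stats::median(abs(err)),
       pearson_r = if (length(true_ages) >= 2L)
         stats::cor(predictions, true_ages) else NA_real_)
}
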