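# The residual Chebyshev age-estimation network.
#
# Layout: cheb_conv(K_first, conv_filters) -> pool
#         -> n_residual_blocks x [ BN -> ReLU -> conv(K_block) -> BN -> ReLU
#                                  -> conv(K_block) + identity skip -> pool ]
#         -> BN -> conv(K_block, last_conv_filters) -> global average pool
#         -> branch A: dense(units) + ReLU            (learnable bin ages)
#            branch B: dense(units) + dropout + Softmax (bin probabilities)
#         -> elementwise product -> dense(1) linear = age estimate.
# Pooling events: one after the first convolution and one after each
# residual block, so the coarsening hierarchy needs
# n_residual_blocks + 1 levels.

#' Age-network architecture configuration
#'
#' Defaults are the full-scale training configuration: 64 convolution filters
#' (128 in the last convolutional layer), 75 units in both dense branches,
#' three residual blocks, dropout 0.75 on the Softmax-branch dense layer
#' and L2 penalty `1e-12`. Chebyshev orders default to `K_first = 9` for
#' the large-receptive-field first layer and `K_block = 6` inside residual
#' blocks; both are configurable.
#'
#' @param conv_filters Filters of all convolution layers except the last.
#' @param last_conv_filters Filters of the final convolution layer.
#' @param dense_units Units of both dense branches (number of age bins).
#' @param n_residual_blocks Number of residual blocks (pooling events are
#'   `n_residual_blocks + 1`).
#' @param K_first Chebyshev order of the first convolution.
#' @param K_block Chebyshev order of convolutions inside residual blocks
#'   and of the final convolution.
#' @param dropout_softmax_branch Dropout rate on the Softmax-branch dense
#'   layer (training only).
#' @param l2_lambda L2 regularization weight on convolution and dense
#'   weights.
#' @param pool_mode `"max"` (default) or `"mean"`.
#' @return An `age_network_config` list.
#' @export
age_network_config <- function(conv_filters = 64L, last_conv_filters = 128L,
                               dense_units = 75L, n_residual_blocks = 3L,
                               K_first = 9L, K_block = 6L,
                               dropout_softmax_branch = 0.75,
                               l2_lambda = 1e-12,
                               pool_mode = c("max", "mean")) {
  pool_mode <- match.arg(pool_mode)
  stopifnot(conv_filters >= 1, last_conv_filters >= 1, dense_units >= 1,
            n_residual_blocks >= 1, K_first >= 1, K_block >= 1,
            dropout_softmax_branch >= 0, dropout_softmax_branch < 1,
            l2_lambda >= 0)
  structure(list(conv_filters = as.integer(conv_filters),
                 last_conv_filters = as.integer(last_conv_filters),
                 dense_units = as.integer(dense_units),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 K_first = as.integer(K_first),
                 K_block = as.integer(K_block),
                 dropout_softmax_branch = dropout_softmax_branch,
                 l2_lambda = l2_lambda, pool_mode = pool_mode),
            class = "age_network_config")
}

glorot_uniform <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

init_cheb_theta <- function(K, fin, fout) {
  lapply(seq_len(K), function(k) glorot_uniform(fin, fout,
                                                fan_in = K * fin,
                                                fan_out = fout))
}

hierarchy_fingerprint <- function(h) {
  paste0(paste(h$n_nodes, collapse = "-"), ":",
         paste(vapply(h$graphs, n_edges, 0L), collapse = "-"))
}

#' Build an age-estimation network for a graph
#'
#' Initializes all weights (variance-scaling uniform, controlled by
#' `seed`), precomputes the rescaled Laplacian of every coarsening scale in
#' the scale's pair ordering, and stores the architecture configuration.
#' The output-layer bias may be pre-set to the expected age
#' (`output_bias_init`); starting the regression head at the cohort mean
#' age shortens the early training phase in which the network only learns
#' the overall age scale.
#'
#' @param graph A `structure_graph` (or [surface_mesh()]).
#' @param config An [age_network_config()].
#' @param n_features Input features per node (3 subcortical, 6 cortical).
#' @param hierarchy Optional precomputed [binary_partition()] hierarchy
#'   with at least `n_residual_blocks + 1` levels; computed when missing.
#' @param seed Integer seed for weight initialization.
#' @param output_bias_init Initial value of the final dense layer's bias
#'   (years); typically the training-set mean age. Default 0.
#' @return An `age_network` object.
#' @export
build_age_network <- function(graph, config = age_network_config(),
                              n_features = 3L, hierarchy = NULL, seed = 1L,
                              output_bias_init = 0) {
  if (inherits(graph, "surface_mesh")) graph <- mesh_to_graph(graph)
  n_pool <- config$n_residual_blocks + 1L
  if (is.null(hierarchy)) hierarchy <- binary_partition(graph, n_pool)
  if (hierarchy$n_levels < n_pool)
    stop_strucage("hierarchy has ", hierarchy$n_levels,
                  " levels but the architecture needs ", n_pool,
                  class = "strucage_config_error")
  if (hierarchy$n_nodes[1] != graph$n_nodes)
    stop_strucage("hierarchy does not match graph node count",
                  class = "strucage_config_error")
  # Laplacians per scale, permuted into the scale's pair ordering so that
  # pooling is stride-2 on rows; the coarsest scale keeps natural order.
  laplacians <- vector("list", n_pool + 1L)
  for (s in seq_len(n_pool + 1L)) {
    Lt <- scaled_laplacian(hierarchy$graphs[[s]])$matrix
    if (s <= n_pool) {
      p <- hierarchy$orderings[[s]]
      Lt <- Lt[p, p, drop = FALSE]
    }
    laplacians[[s]] <- Lt
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  Fc <- config$conv_filters
  Fl <- config$last_conv_filters
  U <- config$dense_units
  params <- list(
    conv0 = list(theta = init_cheb_theta(config$K_first, n_features, Fc),
                 bias = rep(0, Fc)))
  bn_state <- list()
  new_bn <- function(f) list(gamma = rep(1, f), beta = rep(0, f))
  new_bn_state <- function(f) list(mean = rep(0, f), var = rep(1, f))
  for (b in seq_len(config$n_residual_blocks)) {
    params[[paste0("block", b)]] <- list(
      bn1 = new_bn(Fc),
      conv1 = list(theta = init_cheb_theta(config$K_block, Fc, Fc),
                   bias = rep(0, Fc)),
      bn2 = new_bn(Fc),
      conv2 = list(theta = init_cheb_theta(config$K_block, Fc, Fc),
                   bias = rep(0, Fc)))
    bn_state[[paste0("block", b, "_bn1")]] <- new_bn_state(Fc)
    bn_state[[paste0("block", b, "_bn2")]] <- new_bn_state(Fc)
  }
  params$bn_top <- new_bn(Fc)
  bn_state$bn_top <- new_bn_state(Fc)
  params$conv_top <- list(theta = init_cheb_theta(config$K_block, Fc, Fl),
                          bias = rep(0, Fl))
  params$bins <- list(W = glorot_uniform(Fl, U), b = rep(0, U))
  params$probs <- list(W = glorot_uniform(Fl, U), b = rep(0, U))
  params$out <- list(W = glorot_uniform(U, 1L), b = output_bias_init)
  structure(list(config = config, n_features = as.integer(n_features),
                 n_nodes = graph$n_nodes,
                 hierarchy = hierarchy,
                 hierarchy_hash = hierarchy_fingerprint(hierarchy),
                 laplacians = laplacians,
                 params = params, bn_state = bn_state,
                 seed = as.integer(seed)),
            class = "age_network")
}

#' @export
print.age_network <- function(x, ...) {
  cat("age_network:", x$n_nodes, "nodes,", x$n_features, "features,",
      x$config$n_residual_blocks, "residual blocks,",
      count_parameters(x), "parameters (seed", x$seed, ")\n")
  invisible(x)
}

#' Number of trainable parameters of an age network
#'
#' Counts convolution coefficients and biases, batch-norm scale/shift, and
#' dense weights/biases. Batch-norm running statistics are not trainable
#' and are excluded.
#'
#' @param network An `age_network`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(network) {
  cnt <- function(x) {
    if (is.list(x)) sum(vapply(x, cnt, 0)) else length(x)
  }
  as.integer(cnt(network$params))
}

# soft-bin head combination: bin ages (ReLU branch) times bin
# probabilities (Softmax branch), linearly combined into one estimate
softbin_combine <- function(bins, probs, W, b) {
  as.numeric(sweep((bins * probs) %*% W, 2, b, "+"))
}

# full forward pass; x is nodes x features x batch in mesh vertex order
age_network_forward <- function(net, x, training = FALSE) {
  cfg <- net$config
  h <- net$hierarchy
  L <- net$laplacians
  n_blocks <- cfg$n_residual_blocks
  cache <- list()
  a <- apply_ordering(x, h$orderings[[1]])
  cv <- cheb_conv_forward(L[[1]], a, net$params$conv0$theta,
                          net$params$conv0$bias)
  cache$conv0 <- cv$cache
  pl <- pool_forward(cv$y, cfg$pool_mode)
  cache$pool0 <- pl$cache
  a <- pl$y
  for (b in seq_len(n_blocks)) {
    pb <- net$params[[paste0("block", b)]]
    a <- apply_ordering(a, h$orderings[[b + 1L]])
    blk <- list(input = a)
    bn1 <- bn_forward(a, pb$bn1$gamma, pb$bn1$beta,
                      net$bn_state[[paste0("block", b, "_bn1")]], training)
    net$bn_state[[paste0("block", b, "_bn1")]] <- bn1$state
    blk$bn1 <- bn1$cache
    r1 <- relu_forward(bn1$y); blk$relu1 <- r1$cache
    c1 <- cheb_conv_forward(L[[b + 1L]], r1$y, pb$conv1$theta, pb$conv1$bias)
    blk$conv1 <- c1$cache
    bn2 <- bn_forward(c1$y, pb$bn2$gamma, pb$bn2$beta,
                      net$bn_state[[paste0("block", b, "_bn2")]], training)
    net$bn_state[[paste0("block", b, "_bn2")]] <- bn2$state
    blk$bn2 <- bn2$cache
    r2 <- relu_forward(bn2$y); blk$relu2 <- r2$cache
    c2 <- cheb_conv_forward(L[[b + 1L]], r2$y, pb$conv2$theta, pb$conv2$bias)
    blk$conv2 <- c2$cache
    out <- a + c2$y                      # identity skip
    pl <- pool_forward(out, cfg$pool_mode)
    blk$pool <- pl$cache
    a <- pl$y
    cache[[paste0("block", b)]] <- blk
  }
  bnt <- bn_forward(a, net$params$bn_top$gamma, net$params$bn_top$beta,
                    net$bn_state$bn_top, training)
  net$bn_state$bn_top <- bnt$state
  cache$bn_top <- bnt$cache
  ct <- cheb_conv_forward(L[[n_blocks + 2L]], bnt$y,
                          net$params$conv_top$theta, net$params$conv_top$bias)
  cache$conv_top <- ct$cache
  # global average pool over nodes -> batch x channels
  dgap <- dim(ct$y)
  g <- t(colMeans(ct$y))                # mean over nodes -> batch x channels
  cache$gap_dims <- dgap
  dA <- dense_forward(g, net$params$bins$W, net$params$bins$b)
  cache$denseA <- dA$cache
  rA <- relu_forward(dA$y); cache$reluA <- rA$cache
  dB <- dense_forward(g, net$params$probs$W, net$params$probs$b)
  cache$denseB <- dB$cache
  dr <- dropout_forward(dB$y, cfg$dropout_softmax_branch, training)
  cache$dropB <- dr$cache
  probs <- softmax_rows(dr$y)
  cache$probs <- probs
  cache$bins <- rA$y
  pred <- softbin_combine(rA$y, probs, net$params$out$W, net$params$out$b)
  list(pred = pred, cache = cache, bn_state = net$bn_state)
}

# backward pass; dpred is a length-B vector of loss gradients
age_network_backward <- function(net, cache, dpred) {
  cfg <- net$config
  h <- net$hierarchy
  n_blocks <- cfg$n_residual_blocks
  p <- net$params
  g <- list()
  B <- length(dpred)
  prod_bp <- cache$bins * cache$probs
  dprod <- matrix(dpred, B, 1) %*% t(p$out$W)
  g$out <- list(W = crossprod(prod_bp, matrix(dpred, B, 1)),
                b = sum(dpred))
  dbins <- dprod * cache$probs
  dprobs <- dprod * cache$bins
  # branch B: softmax <- dropout <- dense
  dlogits <- softmax_backward(dprobs, cache$probs)
  dlogits <- dropout_backward(dlogits, cache$dropB)
  bB <- dense_backward(dlogits, cache$denseB, p$probs$W)
  g$probs <- list(W = bB$dW, b = bB$db)
  # branch A: relu <- dense
  dA <- relu_backward(dbins, cache$reluA)
  bA <- dense_backward(dA, cache$denseA, p$bins$W)
  g$bins <- list(W = bA$dW, b = bA$db)
  dg <- bA$dx + bB$dx                    # B x F_last
  # GAP backward
  dgap <- cache$gap_dims
  Nc <- dgap[1]
  da <- array(rep(t(dg) / Nc, each = Nc), c(Nc, dgap[2], dgap[3]))
  ct <- cheb_conv_backward(da, cache$conv_top, p$conv_top$theta)
  g$conv_top <- list(theta = ct$dtheta, bias = ct$dbias)
  bnt <- bn_backward(ct$dx, cache$bn_top, p$bn_top$gamma)
  g$bn_top <- list(gamma = bnt$dgamma, beta = bnt$dbeta)
  da <- bnt$dx
  for (b in rev(seq_len(n_blocks))) {
    blk <- cache[[paste0("block", b)]]
    pb <- p[[paste0("block", b)]]
    gb <- list()
    da <- pool_backward(da, blk$pool)
    # residual: da flows into both the identity path and the conv path
    c2 <- cheb_conv_backward(da, blk$conv2, pb$conv2$theta)
    gb$conv2 <- list(theta = c2$dtheta, bias = c2$dbias)
    dr2 <- relu_backward(c2$dx, blk$relu2)
    b2 <- bn_backward(dr2, blk$bn2, pb$bn2$gamma)
    gb$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
    c1 <- cheb_conv_backward(b2$dx, blk$conv1, pb$conv1$theta)
    gb$conv1 <- list(theta = c1$dtheta, bias = c1$dbias)
    dr1 <- relu_backward(c1$dx, blk$relu1)
    b1 <- bn_backward(dr1, blk$bn1, pb$bn1$gamma)
    gb$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
    da <- da + b1$dx                     # skip + conv path
    da <- apply_ordering(da, invert_permutation(h$orderings[[b + 1L]]))
    g[[paste0("block", b)]] <- gb
  }
  da <- pool_backward(da, cache$pool0)
  c0 <- cheb_conv_backward(da, cache$conv0, p$conv0$theta)
  g$conv0 <- list(theta = c0$dtheta, bias = c0$dbias)
  dx <- apply_ordering(c0$dx, invert_permutation(h$orderings[[1]]))
  list(grads = g, dx = dx)
}

invert_permutation <- function(p) {
  inv <- integer(length(p))
  inv[p] <- seq_along(p)
  inv
}

# Replace batch-norm running statistics with exact moments over a
# reference set (usually the training data): momentum-smoothed statistics
# lag far behind the batch statistics the weights co-adapt to during
# short training runs, which squashes inference-mode activations.
recalibrate_bn_stats <- function(net, x, batch_size = 32L) {
  S <- dim(x)[3]
  keys <- names(net$bn_state)
  acc <- lapply(net$bn_state, function(s)
    list(mean = 0 * s$mean, var = 0 * s$var))
  nb <- 0L
  cache_of <- function(cache, key) {
    if (key == "bn_top") return(cache$bn_top)
    blk <- sub("_(bn[12])$", "", key)
    cache[[blk]][[sub("^.*_(bn[12])$", "\\1", key)]]
  }
  for (s0 in seq(1L, S, by = batch_size)) {
    idx <- s0:min(s0 + batch_size - 1L, S)
    fw <- age_network_forward(net, x[, , idx, drop = FALSE], training = TRUE)
    for (key in keys) {
      cc <- cache_of(fw$cache, key)
      acc[[key]]$mean <- acc[[key]]$mean + cc$batch_mean
      acc[[key]]$var <- acc[[key]]$var + cc$batch_var
    }
    nb <- nb + 1L
  }
  for (key in keys) {
    net$bn_state[[key]]$mean <- acc[[key]]$mean / nb
    net$bn_state[[key]]$var <- acc[[key]]$var / nb
  }
  net
}
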