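# Differentiable layers for the age network. Activations in the
# convolutional stack are 3-D arrays (nodes x channels x batch); after
# global average pooling they are (batch x channels) matrices. Every
# forward function returns the output plus the cache its backward pass
# needs; backward passes return gradients w.r.t. inputs and parameters.

# ---- Chebyshev graph convolution -------------------------------------------

#' Chebyshev graph convolution
#'
#' Computes `Y = sum_{k=0}^{K-1} T_k(Lt) X theta_k + bias` where `T_k` are
#' Chebyshev polynomials of the rescaled Laplacian `Lt`, evaluated with the
#' three-term recursion `T_0 = I`, `T_1 = Lt`,
#' `T_k = 2 Lt T_{k-1} - T_{k-2}` applied directly to `X` (dense powers of
#' `Lt` are never formed). `K` controls the spatial support of the filter:
#' the output at a node depends on its `K-1`-hop neighborhood.
#'
#' @param laplacian A [scaled_laplacian()] or its sparse `matrix` element.
#' @param x Activation: `N x F_in` matrix or `N x F_in x batch` array.
#' @param theta List of `K` coefficient matrices, each `F_in x F_out`.
#' @param bias Optional length-`F_out` bias (added at every node).
#' @return `N x F_out` matrix or `N x F_out x batch` array matching `x`.
#' @export
#' @examples
#' g <- structure_graph(matrix(c(0, 1, 1, 0), 2))
#' L <- scaled_laplacian(g)
#' cheb_conv(L, diag(2), list(diag(2)))  # K = 1: identity filter
cheb_conv <- function(laplacian, x, theta, bias = NULL) {
  Lt <- if (inherits(laplacian, "scaled_laplacian")) laplacian$matrix else laplacian
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (dim(x)[1] != nrow(Lt))
    stop_strucage("activation rows (", dim(x)[1], ") != Laplacian dimension (",
                  nrow(Lt), ")", class = "strucage_shape_error")
  out <- cheb_conv_forward(Lt, x, theta, bias)$y
  if (was_mat) matrix(out[, , 1], dim(out)[1], dim(out)[2]) else out
}

cheb_conv_forward <- function(Lt, x, theta, bias = NULL) {
  d <- dim(x)
  N <- d[1]; Fin <- d[2]; B <- d[3]
  K <- length(theta)
  Fout <- ncol(theta[[1]])
  Xm <- matrix(x, N, Fin * B)          # columns: channel fastest, then batch
  Tk <- vector("list", K)
  Tk[[1]] <- Xm
  if (K >= 2L) Tk[[2]] <- as.matrix(Lt %*% Xm)
  if (K >= 3L) for (k in 3:K)
    Tk[[k]] <- 2 * as.matrix(Lt %*% Tk[[k - 1]]) - Tk[[k - 2]]
  Yacc <- matrix(0, N * B, Fout)
  for (k in seq_len(K)) {
    Am <- matrix(aperm(array(Tk[[k]], c(N, Fin, B)), c(1, 3, 2)), N * B, Fin)
    Yacc <- Yacc + Am %*% theta[[k]]
  }
  if (!is.null(bias)) Yacc <- sweep(Yacc, 2, bias, "+")
  y <- aperm(array(Yacc, c(N, B, Fout)), c(1, 3, 2))
  list(y = y, cache = list(Lt = Lt, Tk = Tk, dims = c(N, Fin, B, Fout, K)))
}

cheb_conv_backward <- function(dy, cache, theta, has_bias = TRUE) {
  dm <- cache$dims
  N <- dm[1]; Fin <- dm[2]; B <- dm[3]; Fout <- dm[4]; K <- dm[5]
  Lt <- cache$Lt
  dYnb <- matrix(aperm(dy, c(1, 3, 2)), N * B, Fout)
  dtheta <- vector("list", K)
  W <- vector("list", K)               # W_k = dY theta_k', N x (Fin*B) layout
  for (k in seq_len(K)) {
    Am <- matrix(aperm(array(cache$Tk[[k]], c(N, Fin, B)), c(1, 3, 2)),
                 N * B, Fin)
    dtheta[[k]] <- crossprod(Am, dYnb)
    Wnb <- dYnb %*% t(theta[[k]])
    W[[k]] <- matrix(aperm(array(Wnb, c(N, B, Fin)), c(1, 3, 2)), N, Fin * B)
  }
  # dX = sum_k T_k(Lt) W_k by Clenshaw (T_k symmetric since Lt is)
  if (K == 1L) {
    S <- W[[1]]
  } else {
    b1 <- W[[K]]
    b2 <- matrix(0, N, Fin * B)
    if (K >= 3L) for (k in seq(K - 1L, 2L)) {
      b0 <- W[[k]] + 2 * as.matrix(Lt %*% b1) - b2
      b2 <- b1
      b1 <- b0
    }
    S <- W[[1]] + as.matrix(Lt %*% b1) - b2
  }
  dbias <- if (has_bias) colSums(dYnb) else NULL
  list(dx = array(S, c(N, Fin, B)), dtheta = dtheta, dbias = dbias)
}

# ---- batch normalization (per channel over nodes x batch) ------------------

bn_forward <- function(x, gamma, beta, state, training, eps = 1e-3,
                       momentum = 0.99) {
  d <- dim(x)
  N <- d[1]; F <- d[2]; B <- d[3]
  m <- matrix(aperm(x, c(1, 3, 2)), N * B, F)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    v <- pmax(v, 0)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(m, 2, mu, "-"), 2, istd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = aperm(array(y, c(N, B, F)), c(1, 3, 2)),
       cache = list(xhat = xhat, istd = istd, dims = d, training = training,
                    batch_mean = mu, batch_var = v),
       state = state)
}

bn_backward <- function(dy, cache, gamma) {
  d <- cache$dims
  N <- d[1]; F <- d[2]; B <- d[3]
  M <- N * B
  dym <- matrix(aperm(dy, c(1, 3, 2)), M, F)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxm <- sweep(dxhat, 2, s1 / M, "-") -
      sweep(cache$xhat, 2, s2 / M, "*")
    dxm <- sweep(dxm, 2, cache$istd, "*")
  } else {
    dxm <- sweep(dxhat, 2, cache$istd, "*")
  }
  list(dx = aperm(array(dxm, c(N, B, F)), c(1, 3, 2)),
       dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling with cached routing -------------------------------------------

pool_forward <- function(x, mode) {
  n <- dim(x)[1]
  odd <- seq(1L, n, by = 2L)
  a <- x[odd, , , drop = FALSE]
  b <- x[odd + 1L, , , drop = FALSE]
  if (mode == "max") {
    take_a <- a >= b                   # ties route to the first row
    list(y = pmax(a, b), cache = list(take_a = take_a, n = n, mode = mode))
  } else {
    list(y = (a + b) / 2, cache = list(n = n, mode = mode))
  }
}

pool_backward <- function(dy, cache) {
  n <- cache$n
  d <- dim(dy)
  dx <- array(0, c(n, d[2], d[3]))
  odd <- seq(1L, n, by = 2L)
  if (cache$mode == "max") {
    dx[odd, , ] <- dy * cache$take_a
    dx[odd + 1L, , ] <- dy * !cache$take_a
  } else {
    dx[odd, , ] <- dy / 2
    dx[odd + 1L, , ] <- dy / 2
  }
  dx
}

# ---- dense / softmax / dropout ---------------------------------------------

dense_forward <- function(x, W, b) {
  list(y = sweep(x %*% W, 2, b, "+"), cache = x)
}

dense_backward <- function(dy, cache, W) {
  list(dx = dy %*% t(W), dW = crossprod(cache, dy), db = colSums(dy))
}

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

softmax_backward <- function(dy, y) {
  (dy - rowSums(dy * y)) * y
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  keep <- 1 - rate
  mask <- (matrix(runif(length(x)), nrow(x)) < keep) / keep
  list(y = x * mask, cache = mask)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# ---- rotation augmentation -------------------------------------------------

#' Euler Z-Y-X rotation matrix
#'
#' @param angles_deg Length-3 numeric: rotation angles (degrees) about the
#'   z, y and x axes; the matrix is `Rz %*% Ry %*% Rx`.
#' @return A 3 x 3 rotation matrix.
#' @export
euler_rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

#' Randomly rotate coordinate features
#'
#' Samples one Euler Z-Y-X rotation (each angle uniform in
#' `[-max_deg, max_deg]`) and applies it about the origin to every
#' coordinate triple of the feature matrix. Cortical features carry two
#' triples per node (inner and outer surface); both are rotated by the same
#' matrix, so per-node coordinate norms and all inter-node distances are
#' preserved. This is the augmentation used during training (within 15
#' degrees) and validation/test-time augmentation (within 5 degrees).
#'
#' @param features `N x F` matrix with `F` a multiple of 3 (coordinate
#'   triples), or an `N x F x batch` array (an independent rotation is
#'   drawn for each scan in the batch).
#' @param max_deg Maximum absolute rotation angle in degrees.
#' @return Rotated features, same shape.
#' @export
random_rotation <- function(features, max_deg) {
  d <- dim(features)
  ncolf <- if (length(d) == 3L) d[2] else ncol(features)
  if (is.null(ncolf) || ncolf %% 3L != 0L)
    stop_strucage("feature columns must be coordinate triples (multiple of 3)",
                  class = "strucage_validation_error")
  if (length(d) == 3L) {
    for (b in seq_len(d[3]))
      features[, , b] <- rotate_triples(features[, , b, drop = TRUE], max_deg)
    features
  } else {
    rotate_triples(features, max_deg)
  }
}

rotate_triples <- function(m, max_deg) {
  R <- euler_rotation_matrix(runif(3, -max_deg, max_deg))
  for (j in seq(1L, ncol(m), by = 3L)) {
    m[, j:(j + 2L)] <- m[, j:(j + 2L)] %*% t(R)
  }
  m
}
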