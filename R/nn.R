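# Minimal CNN engine: conv (3x3 'same'), ReLU, max-pool, flatten, dropout,
# dense, softmax + cross-entropy, trained by backpropagation with
# mini-batch Adadelta. Convolution uses im2col: every layer precomputes an
# index matrix mapping output cells to their receptive-field pixels in the
# zero-padded input, so a convolution is a single matrix product.

#' Single-neuron response
#'
#' Evaluates `sigma(sum_i w_i x_i - b)` for the two activation functions in
#' use: `relu(t) = max(0, t)` and `sigmoid(t) = 1 / (1 + exp(-t))`.
#'
#' @param x Input vector (may be empty; the empty sum is 0).
#' @param weights Weight vector, same length as `x`.
#' @param bias Scalar bias, subtracted from the weighted sum.
#' @param activation `"relu"` or `"sigmoid"`.
#' @return Scalar response.
#' @export
neuron_response <- function(x, weights, bias = 0,
                            activation = c("relu", "sigmoid")) {
  activation <- match.arg(activation)
  if (length(x) != length(weights)) {
    abort(sprintf("input length %d does not match weight length %d",
                  length(x), length(weights)))
  }
  t <- sum(as.numeric(x) * as.numeric(weights)) - bias
  switch(activation, relu = max(0, t), sigmoid = 1 / (1 + exp(-t)))
}

#' Numerically safe softmax
#'
#' Maps a finite score vector to the probability simplex,
#' `softmax(z)_j = exp(z_j) / sum_k exp(z_k)`, computed after subtracting
#' `max(z)` so extreme scores cannot overflow.
#'
#' @param z Numeric vector of finite scores.
#' @return Probability vector of the same length (non-negative, sums to 1).
#' @export
softmax <- function(z) {
  if (length(z) == 0) abort("softmax of an empty vector is undefined")
  if (any(!is.finite(z))) abort("softmax requires finite inputs")
  e <- exp(z - max(z))
  e / sum(e)
}

# --- index precomputation -------------------------------------------------

# im2col indices for a k x k 'same' convolution over an h x w x c input.
# Returns a (h*w) x (k*k*c) matrix of linear indices into the zero-padded
# array of dim (h+2p, w+2p, c); output cells enumerated column-major.
conv_indices <- function(h, w, c, k) {
  p <- k %/% 2
  hp <- h + 2 * p; wp <- w + 2 * p
  oi <- rep(seq_len(h), times = w)          # output row (1-based)
  oj <- rep(seq_len(w), each = h)           # output col
  cols <- matrix(0L, h * w, k * k * c)
  col <- 0L
  for (ch in seq_len(c)) {
    for (kj in seq_len(k)) {
      for (ki in seq_len(k)) {
        col <- col + 1L
        ri <- oi + ki - 1L                  # row in padded frame
        cj <- oj + kj - 1L
        cols[, col] <- ri + (cj - 1L) * hp + (ch - 1L) * hp * wp
      }
    }
  }
  cols
}

# Pool indices for p x p non-overlapping max pooling over h x w x c
# (h, w divisible by p). Rows enumerate output cells column-major per
# channel; columns are the p*p member pixels (linear indices into input).
pool_indices <- function(h, w, c, p) {
  ho <- h %/% p; wo <- w %/% p
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  base_r <- (oi - 1L) * p
  base_c <- (oj - 1L) * p
  one <- matrix(0L, ho * wo, p * p)
  col <- 0L
  for (pj in seq_len(p)) {
    for (pi in seq_len(p)) {
      col <- col + 1L
      one[, col] <- (base_r + pi) + (base_c + pj - 1L) * h
    }
  }
  out <- matrix(0L, ho * wo * c, p * p)
  for (ch in seq_len(c)) {
    out[((ch - 1) * ho * wo + 1):(ch * ho * wo), ] <- one + (ch - 1L) * h * w
  }
  out
}

pad_array <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

# --- layer construction ---------------------------------------------------

# Builds the layer list (with parameters and cached index matrices) from an
# architecture config. Returns list(layers, n_params).
build_layers <- function(arch) {
  h <- arch$input_size; w <- arch$input_size; c <- 1L
  layers <- list()
  add <- function(l) layers[[length(layers) + 1]] <<- l
  for (bi in seq_along(arch$blocks)) {
    blk <- arch$blocks[[bi]]
    k <- blk$kernel
    for (ci in seq_len(blk$n_conv)) {
      fan_in <- k * k * c
      add(list(
        type = "conv", k = k, filters = blk$filters, h = h, w = w, c_in = c,
        idx = conv_indices(h, w, c, k),
        W = matrix(rnorm(fan_in * blk$filters, 0, sqrt(2 / fan_in)),
                   fan_in, blk$filters),
        b = rep(0, blk$filters)
      ))
      add(list(type = "relu"))
      c <- blk$filters
    }
    p <- arch$pool[[bi]]
    if (h %% p != 0 || w %% p != 0) {
      abort(sprintf(
        "configuration error in block %d: %dx%d feature map not divisible by pool %d",
        bi, h, w, p))
    }
    add(list(type = "maxpool", p = p, h = h, w = w, c = c,
             idx = pool_indices(h, w, c, p)))
    h <- h %/% p; w <- w %/% p
  }
  add(list(type = "flatten", h = h, w = w, c = c))
  n_in <- h * w * c
  if (arch$dropout_rate > 0) add(list(type = "dropout", rate = arch$dropout_rate))
  # small positive bias keeps the hidden ReLU layer initially active,
  # guarding against whole-layer death under sign-normalised updates
  add(list(type = "dense", n_in = n_in, n_out = arch$fc_units,
           W = matrix(rnorm(n_in * arch$fc_units, 0, sqrt(2 / n_in)),
                      n_in, arch$fc_units),
           b = rep(0.1, arch$fc_units)))
  add(list(type = "relu"))
  add(list(type = "dense", n_in = arch$fc_units, n_out = arch$n_classes,
           W = matrix(rnorm(arch$fc_units * arch$n_classes, 0,
                            sqrt(2 / arch$fc_units)),
                      arch$fc_units, arch$n_classes),
           b = rep(0, arch$n_classes)))
  n_params <- sum(purrr::map_dbl(layers, function(l) {
    if (is.null(l$W)) 0 else length(l$W) + length(l$b)
  }))
  list(layers = layers, n_params = n_params)
}

# Row-wise max and argmax over a matrix (ties -> first column).
row_max_arg <- function(m) {
  arg <- max.col(m, ties.method = "first")
  val <- m[cbind(seq_len(nrow(m)), arg)]
  list(val = val, arg = arg)
}

# Forward pass for one sample. x: matrix (input_size x input_size) of
# intensities in [0, 1]; centring them around zero removes the shared
# positive component that makes gradient directions coherent across
# weights (the classic argument for input centring).
# Returns list(scores, cache) when training = TRUE needs dropout masks.
nn_forward <- function(layers, x, training = FALSE) {
  a <- array(x - 0.5, c(nrow(x), ncol(x), 1))
  cache <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      xp <- pad_array(a, l$k %/% 2)
      cols <- matrix(xp[l$idx], nrow = nrow(l$idx))
      out <- cols %*% l$W
      out <- sweep(out, 2, l$b, "+")
      cache[[i]] <- list(cols = cols, dim_in = dim(a))
      a <- array(out, c(l$h, l$w, l$filters))
    } else if (l$type == "relu") {
      cache[[i]] <- list(mask = a > 0)
      a <- a * cache[[i]]$mask
    } else if (l$type == "maxpool") {
      cols <- matrix(a[l$idx], nrow = nrow(l$idx))
      mm <- row_max_arg(cols)
      cache[[i]] <- list(src = l$idx[cbind(seq_len(nrow(l$idx)), mm$arg)],
                         dim_in = dim(a))
      a <- array(mm$val, c(l$h %/% l$p, l$w %/% l$p, l$c))
    } else if (l$type == "flatten") {
      cache[[i]] <- list(dim_in = dim(a))
      a <- as.numeric(a)
    } else if (l$type == "dropout") {
      if (training) {
        mask <- (runif(length(a)) >= l$rate) / (1 - l$rate)
        cache[[i]] <- list(mask = mask)
        a <- a * mask
      } else {
        cache[[i]] <- list(mask = NULL)
      }
    } else if (l$type == "dense") {
      cache[[i]] <- list(x = a)
      a <- drop(crossprod(l$W, a)) + l$b
    }
  }
  list(scores = a, cache = cache)
}

# Backward pass. dscores: gradient of the loss wrt the final scores.
# Returns a list of gradients parallel to `layers` (NULL for param-free).
nn_backward <- function(layers, cache, dscores) {
  grads <- vector("list", length(layers))
  d <- dscores
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = tcrossprod(cache[[i]]$x, d), b = d)
      d <- drop(l$W %*% d)
    } else if (l$type == "dropout") {
      if (!is.null(cache[[i]]$mask)) d <- d * cache[[i]]$mask
    } else if (l$type == "flatten") {
      d <- array(d, cache[[i]]$dim_in)
    } else if (l$type == "maxpool") {
      dx <- array(0, cache[[i]]$dim_in)
      dx[cache[[i]]$src] <- as.numeric(d)
      d <- dx
    } else if (l$type == "relu") {
      d <- d * cache[[i]]$mask
    } else if (l$type == "conv") {
      dout <- matrix(as.numeric(d), ncol = l$filters)
      grads[[i]] <- list(W = crossprod(cache[[i]]$cols, dout),
                         b = colSums(dout))
      dcols <- tcrossprod(dout, l$W)          # (h*w) x (k*k*c_in)
      p <- l$k %/% 2
      dim_in <- cache[[i]]$dim_in
      dxp <- array(0, c(dim_in[1] + 2 * p, dim_in[2] + 2 * p, dim_in[3]))
      for (col in seq_len(ncol(dcols))) {
        dxp[l$idx[, col]] <- dxp[l$idx[, col]] + dcols[, col]
      }
      d <- dxp[(p + 1):(p + dim_in[1]), (p + 1):(p + dim_in[2]), ,
               drop = FALSE]
    }
  }
  grads
}

# Softmax cross-entropy loss and gradient for one sample.
# label: 1-based class index.
softmax_xent <- function(scores, label) {
  pr <- softmax(scores)
  loss <- -log(max(pr[label], 1e-300))
  dscores <- pr
  dscores[label] <- dscores[label] - 1
  list(loss = loss, probs = pr, dscores = dscores)
}

# --- Adadelta -------------------------------------------------------------

adadelta_init <- function(layers) {
  purrr::map(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(Eg_W = l$W * 0, Ed_W = l$W * 0,
         Eg_b = l$b * 0, Ed_b = l$b * 0)
  })
}

# One Adadelta update from accumulated (mean) gradients.
adadelta_step <- function(layers, state, grads, rho, epsilon) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$Eg_W <- rho * s$Eg_W + (1 - rho) * g$W^2
    dW <- -sqrt(s$Ed_W + epsilon) / sqrt(s$Eg_W + epsilon) * g$W
    s$Ed_W <- rho * s$Ed_W + (1 - rho) * dW^2
    layers[[i]]$W <- layers[[i]]$W + dW
    s$Eg_b <- rho * s$Eg_b + (1 - rho) * g$b^2
    db <- -sqrt(s$Ed_b + epsilon) / sqrt(s$Eg_b + epsilon) * g$b
    s$Ed_b <- rho * s$Ed_b + (1 - rho) * db^2
    layers[[i]]$b <- layers[[i]]$b + db
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
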