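# ---- minimal layer engine -------------------------------------------------
# The network is small and fixed, so layers are implemented directly on R
# matrices (BLAS does the heavy lifting via im2col matrix products).

.elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
.elu_grad <- function(x, fx) ifelse(x > 0, 1, fx + 1)

.conv_fwd <- function(x, W, b) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  k <- nrow(W) / C; Lout <- L - k + 1
  Xc <- matrix(0, B * Lout, C * k)
  for (j in seq_len(k)) {
    sl <- x[, , j:(j + Lout - 1), drop = FALSE]
    Xc[, ((j - 1) * C + 1):(j * C)] <- matrix(aperm(sl, c(1, 3, 2)), B * Lout, C)
  }
  Y <- sweep(Xc %*% W, 2, b, "+")
  list(out = aperm(array(Y, c(B, Lout, ncol(W))), c(1, 3, 2)), Xc = Xc,
       dims = c(B = B, C = C, L = L, k = k, Lout = Lout))
}

.conv_bwd <- function(dout, cache, W) {
  dm <- cache$dims
  B <- dm[["B"]]; C <- dm[["C"]]; L <- dm[["L"]]; k <- dm[["k"]]; Lout <- dm[["Lout"]]
  Fn <- ncol(W)
  dY <- matrix(aperm(dout, c(1, 3, 2)), B * Lout, Fn)
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- dY %*% t(W)
  dx <- array(0, c(B, C, L))
  for (j in seq_len(k)) {
    blk <- array(dXc[, ((j - 1) * C + 1):(j * C)], c(B, Lout, C))
    dx[, , j:(j + Lout - 1)] <- dx[, , j:(j + Lout - 1), drop = FALSE] + aperm(blk, c(1, 3, 2))
  }
  list(dx = dx, dW = dW, db = db)
}

.pool_fwd <- function(x) {
  L <- dim(x)[3]
  odd <- x[, , seq(1, L - 1, by = 2), drop = FALSE]
  even <- x[, , seq(2, L, by = 2), drop = FALSE]
  mask <- odd >= even
  list(out = pmax(odd, even), mask = mask)
}

.pool_bwd <- function(dout, cache, Lin) {
  d <- dim(dout)
  dx <- array(0, c(d[1], d[2], Lin))
  dx[, , seq(1, Lin - 1, by = 2)] <- dout * cache$mask
  dx[, , seq(2, Lin, by = 2)] <- dout * !cache$mask
  dx
}

.gap_fwd <- function(x) {
  d <- dim(x)
  matrix(rowMeans(matrix(x, d[1] * d[2], d[3])), d[1], d[2])
}

.gap_bwd <- function(dout, dims) {
  array(rep(dout / dims[3], dims[3]), dims)
}

.dense_fwd <- function(x, W, b) sweep(x %*% W, 2, b, "+")

# ---- architecture ---------------------------------------------------------

#' Network specification
#'
#' The fixed convolutional architecture used for inference on encoded trees:
#' three 1-D convolutions (25, 25 and 40 filters, kernel size 4, no padding)
#' with a max pool (size 2, stride 2) after the second, a global average
#' pool, and a dense stack 48 / 32 / 16 / 8 down to the output head. All
#' layers use the exponential linear unit (ELU) activation; the output layer
#' is linear followed by the clip transform. The three non-sigmoid scalars
#' (carrying capacity, initial population, death rate) are standardized and
#' concatenated onto the input of the first dense layer.
#'
#' Two heads are supported: `"sigmoid"` predicts the four sigmoid
#' parameters (clipped to the clip box), `"per_bin"` predicts the response
#' value in `n_bins` uniform affinity bins over the loss domain.
#'
#' @param width Encoded-matrix width W (input is 4 x W).
#' @param output `"sigmoid"` or `"per_bin"`.
#' @param n_bins Number of affinity bins for the per-bin head.
#' @param n_nonsigmoid Number of conditioning scalars (default 3).
#' @param bounds [param_bounds()] supplying the clip box.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(width = 200L, output = c("sigmoid", "per_bin"),
                         n_bins = 11L, n_nonsigmoid = 3L,
                         bounds = training_bounds()) {
  output <- match.arg(output)
  structure(list(width = as.integer(width), output = output,
                 n_bins = as.integer(n_bins),
                 n_nonsigmoid = as.integer(n_nonsigmoid), bounds = bounds),
            class = "network_spec")
}

# variance-preserving uniform init (var = 1/fan-in): with three stacked
# wide-fan-in convolutions, fan-average scaling amplifies activations ~4x
# per layer and saturates the downstream ELUs
.init_mat <- function(nin, nout) {
  matrix(stats::runif(nin * nout, -1, 1) * sqrt(3 / nin), nin, nout)
}

#' Build the inference network
#'
#' Instantiates the layers of a [network_spec()] with variance-preserving
#' uniform weights (deterministic under `set.seed()`). The output bias is
#' initialized at the
#' center of the sampling box (sigmoid head) or at 1 (per-bin head) so that
#' initial predictions start inside the clip box.
#'
#' @param spec A [network_spec()].
#' @return An object of class `gc_net`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  n_out <- if (spec$output == "sigmoid") 4L else spec$n_bins
  d1_in <- 40L + spec$n_nonsigmoid
  layers <- list(
    conv1 = list(type = "conv", W = .init_mat(4 * 4, 25), b = numeric(25)),
    conv2 = list(type = "conv", W = .init_mat(25 * 4, 25), b = numeric(25)),
    pool = list(type = "pool"),
    conv3 = list(type = "conv", W = .init_mat(25 * 4, 40), b = numeric(40)),
    gap = list(type = "gap"),
    dense1 = list(type = "dense", W = .init_mat(d1_in, 48), b = numeric(48)),
    dense2 = list(type = "dense", W = .init_mat(48, 32), b = numeric(32)),
    dense3 = list(type = "dense", W = .init_mat(32, 16), b = numeric(16)),
    dense4 = list(type = "dense", W = .init_mat(16, 8), b = numeric(8)),
    output = list(type = "dense", W = .init_mat(8, n_out) * 0.1, b = numeric(n_out)))
  if (spec$output == "sigmoid") {
    b <- spec$bounds
    layers$output$b <- c(mean(b$xscale), mean(b$xshift), mean(b$yscale), mean(b$yshift))
  } else {
    layers$output$b <- rep(1, n_out)
  }
  structure(list(spec = spec, layers = layers, trained = FALSE, history = NULL),
            class = "gc_net")
}

#' @export
print.gc_net <- function(x, ...) {
  pc <- network_param_counts(x)
  cat(sprintf("<gc_net> %s head, input 4 x %d, %d trainable parameters%s\n",
              x$spec$output, x$spec$width, sum(pc$n_params),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Trainable parameter counts per layer
#'
#' @param net A [build_network()] model.
#' @return A tibble with columns `layer`, `type` and `n_params`.
#' @export
network_param_counts <- function(net) {
  stopifnot(inherits(net, "gc_net"))
  rows <- lapply(names(net$layers), function(nm) {
    ly <- net$layers[[nm]]
    np <- if (!is.null(ly$W)) length(ly$W) + length(ly$b) else 0L
    tibble::tibble(layer = nm, type = ly$type, n_params = as.integer(np))
  })
  dplyr::bind_rows(rows)
}

# forward pass; returns raw outputs and caches for backprop
.net_forward <- function(net, x, scalars, keep_cache = FALSE) {
  ly <- net$layers
  c1 <- .conv_fwd(x, ly$conv1$W, ly$conv1$b); a1 <- .elu(c1$out)
  c2 <- .conv_fwd(a1, ly$conv2$W, ly$conv2$b); a2 <- .elu(c2$out)
  p <- .pool_fwd(a2)
  c3 <- .conv_fwd(p$out, ly$conv3$W, ly$conv3$b); a3 <- .elu(c3$out)
  g <- .gap_fwd(a3)
  h0 <- cbind(g, scalars)
  z1 <- .dense_fwd(h0, ly$dense1$W, ly$dense1$b); h1 <- .elu(z1)
  z2 <- .dense_fwd(h1, ly$dense2$W, ly$dense2$b); h2 <- .elu(z2)
  z3 <- .dense_fwd(h2, ly$dense3$W, ly$dense3$b); h3 <- .elu(z3)
  z4 <- .dense_fwd(h3, ly$dense4$W, ly$dense4$b); h4 <- .elu(z4)
  out <- .dense_fwd(h4, ly$output$W, ly$output$b)
  res <- list(out = out)
  if (keep_cache) {
    res$cache <- list(x = x, c1 = c1, a1 = a1, c2 = c2, a2 = a2, p = p,
                      c3 = c3, a3 = a3, g = g, h0 = h0,
                      z1 = z1, h1 = h1, z2 = z2, h2 = h2, z3 = z3, h3 = h3,
                      z4 = z4, h4 = h4)
  }
  res
}

# backward pass from d(out); returns gradients named like layers
.net_backward <- function(net, cache, dout) {
  ly <- net$layers
  g <- list()
  dense_bwd <- function(dy, xin, W) {
    list(dW = crossprod(xin, dy), db = colSums(dy), dx = dy %*% t(W))
  }
  o <- dense_bwd(dout, cache$h4, ly$output$W)
  g$output <- o[c("dW", "db")]
  d4 <- o$dx * .elu_grad(cache$z4, cache$h4)
  o <- dense_bwd(d4, cache$h3, ly$dense4$W); g$dense4 <- o[c("dW", "db")]
  d3 <- o$dx * .elu_grad(cache$z3, cache$h3)
  o <- dense_bwd(d3, cache$h2, ly$dense3$W); g$dense3 <- o[c("dW", "db")]
  d2 <- o$dx * .elu_grad(cache$z2, cache$h2)
  o <- dense_bwd(d2, cache$h1, ly$dense2$W); g$dense2 <- o[c("dW", "db")]
  d1 <- o$dx * .elu_grad(cache$z1, cache$h1)
  o <- dense_bwd(d1, cache$h0, ly$dense1$W); g$dense1 <- o[c("dW", "db")]
  dg <- o$dx[, 1:40, drop = FALSE]  # gradient w.r.t. GAP output
  da3 <- .gap_bwd(dg, dim(cache$a3))
  dc3 <- da3 * .elu_grad(cache$c3$out, cache$a3)
  o <- .conv_bwd(dc3, cache$c3, ly$conv3$W); g$conv3 <- o[c("dW", "db")]
  da2 <- .pool_bwd(o$dx, cache$p, dim(cache$a2)[3])
  dc2 <- da2 * .elu_grad(cache$c2$out, cache$a2)
  o <- .conv_bwd(dc2, cache$c2, ly$conv2$W); g$conv2 <- o[c("dW", "db")]
  da1 <- o$dx * .elu_grad(cache$c1$out, cache$a1)
  o <- .conv_bwd(da1, cache$c1, ly$conv1$W); g$conv1 <- o[c("dW", "db")]
  g
}

# ---- response curves and the curve-difference loss ------------------------

#' Affinity grid for the loss domain
#'
#' Uniform grid on \[-2.5, 3\]: below -2.5 response curves are nearly
#' identical, and above 3 they diverge where essentially no affinities are
#' observed.
#'
#' @param step Grid spacing (default 0.1).
#' @return Numeric vector.
#' @export
affinity_grid <- function(step = 0.1) seq(-2.5, 3, by = step)

.trapz_weights <- function(grid) {
  n <- length(grid)
  w <- numeric(n)
  w[-n] <- w[-n] + diff(grid) / 2
  w[-1] <- w[-1] + diff(grid) / 2
  w
}

#' Response curve of a parameter set
#'
#' @param params A [sigmoid_params()].
#' @param grid Affinity grid (default [affinity_grid()]).
#' @return An object of class `response_curve` with fields `grid`, `value`.
#' @export
response_curve <- function(params, grid = affinity_grid()) {
  structure(list(grid = grid, value = sigmoid_response(params, grid)),
            class = "response_curve")
}

.as_curve_values <- function(x, grid) {
  if (inherits(x, "response_curve")) {
    if (!isTRUE(all.equal(x$grid, grid))) stop("curves must share the grid")
    x$value
  } else if (inherits(x, "sigmoid_params")) {
    sigmoid_response(x, grid)
  } else {
    as.numeric(x)
  }
}

#' Curve difference loss
#'
#' The area between the true and inferred response curves divided by the
#' area under the true curve, both computed by the trapezoid rule over the
#' affinity domain \[-2.5, 3\]. A scaled L1 distance: 0 iff the curves are
#' equal on the grid, and insensitive to parameter changes that compensate
#' each other's effect on the curve.
#'
#' @param true True curve: a `response_curve`, [sigmoid_params()], or value
#'   vector on `grid`.
#' @param inferred Inferred curve, same forms accepted.
#' @param grid Shared affinity grid.
#' @return Non-negative scalar loss.
#' @export
curve_difference_loss <- function(true, inferred, grid = affinity_grid()) {
  tv <- .as_curve_values(true, grid)
  iv <- .as_curve_values(inferred, grid)
  if (length(tv) != length(grid) || length(iv) != length(grid)) {
    stop("curves must share the grid")
  }
  w <- .trapz_weights(grid)
  den <- sum(w * tv)
  if (den <= 0) stop("area under the true curve must be positive")
  sum(w * abs(tv - iv)) / den
}

# curves for a matrix of parameter rows (xscale, xshift, yscale, yshift)
.sigmoid_curves <- function(pm, grid) {
  z <- -outer(pm[, 1], rep(1, length(grid))) *
    (matrix(grid, nrow(pm), length(grid), byrow = TRUE) - pm[, 2])
  z <- pmin(pmax(z, -745), 745)
  pm[, 3] / (1 + exp(z)) + pm[, 4]
}

# ---- clip, training, prediction -------------------------------------------

.clip_matrix <- function(raw, spec) {
  if (spec$output == "sigmoid") {
    cl <- spec$bounds$clip
    lo <- c(cl$xscale[1], cl$xshift[1], cl$yscale[1], cl$yshift[1])
    hi <- c(cl$xscale[2], cl$xshift[2], cl$yscale[2], cl$yshift[2])
  } else {
    lo <- rep(0, spec$n_bins)
    hi <- rep(spec$bounds$clip$yscale[2] + spec$bounds$clip$yshift[2], spec$n_bins)
  }
  lo_m <- matrix(lo, nrow(raw), length(lo), byrow = TRUE)
  hi_m <- matrix(hi, nrow(raw), length(hi), byrow = TRUE)
  list(clipped = pmin(pmax(raw, lo_m), hi_m), below = raw < lo_m, above = raw > hi_m)
}

#' Bin centers of the per-bin head
#'
#' `n_bins` uniform bins over the loss domain \[-2.5, 3\].
#'
#' @param n_bins Number of bins.
#' @return Numeric vector of bin centers.
#' @export
bin_centers <- function(n_bins = 11L) {
  edges <- seq(-2.5, 3, length.out = n_bins + 1)
  (edges[-1] + edges[-length(edges)]) / 2
}

# loss and gradient w.r.t. clipped predictions
.loss_and_grad <- function(clipped, truth_pm, spec, grid, w) {
  B <- nrow(clipped)
  if (spec$output == "sigmoid") {
    lt <- .sigmoid_curves(truth_pm, grid)
    lp <- .sigmoid_curves(clipped, grid)
    den <- drop(lt %*% w)
    loss_i <- drop(abs(lp - lt) %*% w) / den
    sgn <- sign(lp - lt)
    common <- sweep(sgn, 2, w, "*") / den  # B x G
    S <- (lp - clipped[, 4]) / clipped[, 3]
    xg <- matrix(grid, B, length(grid), byrow = TRUE)
    dxc <- rowSums(common * clipped[, 3] * S * (1 - S) * (xg - clipped[, 2]))
    dxh <- rowSums(common * clipped[, 3] * S * (1 - S) * (-clipped[, 1]))
    dyc <- rowSums(common * S)
    dyh <- rowSums(common)
    list(loss = loss_i, grad = cbind(dxc, dxh, dyc, dyh) / B)
  } else {
    ctr <- bin_centers(spec$n_bins)
    lt <- .sigmoid_curves(truth_pm, ctr)
    den <- rowSums(lt)
    loss_i <- rowSums(abs(clipped - lt)) / den
    list(loss = loss_i, grad = sign(clipped - lt) / den / B)
  }
}

#' Training configuration
#'
#' Adam optimizer with learning rate 0.01 and exponential-moving-average
#' weight momentum 0.99, batch size 32, 35 epochs; 20% of the sample is held
#' out for testing and 10% of the remainder for validation.
#'
#' @param learning_rate,ema_momentum,batch_size,epochs,test_fraction,validation_fraction
#'   Optimizer and split settings.
#' @param seed Optional seed for the split and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, ema_momentum = 0.99,
                         batch_size = 32L, epochs = 35L,
                         test_fraction = 0.2, validation_fraction = 0.1,
                         seed = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate, ema_momentum = ema_momentum,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 test_fraction = test_fraction,
                 validation_fraction = validation_fraction, seed = seed),
            class = "train_config")
}

#' Train the inference network
#'
#' Minimizes the mean curve-difference loss between each tree's true
#' response curve and the curve implied by the (clipped) predicted
#' parameters, by Adam with backpropagation through the sigmoid curve.
#' The clip is applied during training; its gradient passes through
#' unchanged inside the box and for updates that move an out-of-box output
#' back toward it. An exponential moving average of the weights is
#' maintained and used for prediction.
#'
#' @param net A [build_network()] model.
#' @param encoded A standardized `encoded_set` (see [apply_standardizer()]).
#' @param nonsigmoid Standardized n x 3 matrix of conditioning scalars.
#' @param truth n x 4 matrix (or tibble) of true sigmoid parameters per tree
#'   (columns xscale, xshift, yscale, yshift).
#' @param config A [train_config()].
#' @return The trained `gc_net`, with a `history` tibble (epoch, training
#'   and validation loss) and the held-out test indices.
#' @export
train_network <- function(net, encoded, nonsigmoid, truth,
                          config = train_config()) {
  stopifnot(inherits(net, "gc_net"))
  if (!isTRUE(attr(encoded, "standardized"))) {
    stop("inputs must be standardized with the training scaler (see apply_standardizer)")
  }
  truth <- as.matrix(as.data.frame(truth)[, c("xscale", "xshift", "yscale", "yshift")])
  n <- dim(encoded)[1]
  nonsigmoid <- as.matrix(nonsigmoid)
  stopifnot(nrow(truth) == n, nrow(nonsigmoid) == n)
  if (!is.null(config$seed)) set.seed(config$seed)

  idx <- sample.int(n)
  n_test <- floor(config$test_fraction * n)
  test_idx <- idx[seq_len(n_test)]
  rest <- idx[-seq_len(n_test)]
  n_val <- floor(config$validation_fraction * length(rest))
  val_idx <- rest[seq_len(n_val)]
  train_idx <- rest[-seq_len(n_val)]

  grid <- affinity_grid()
  w <- .trapz_weights(grid)
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-7
  mom <- list(); vel <- list(); ema <- list()
  for (nm in names(net$layers)) {
    ly <- net$layers[[nm]]
    if (is.null(ly$W)) next
    mom[[nm]] <- list(W = ly$W * 0, b = ly$b * 0)
    vel[[nm]] <- list(W = ly$W * 0, b = ly$b * 0)
    ema[[nm]] <- list(W = ly$W, b = ly$b)
  }
  tstep <- 0
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  best_val <- Inf; best <- NULL

  eval_loss <- function(ids) {
    if (length(ids) == 0) return(NA_real_)
    tot <- 0
    for (s in split(ids, ceiling(seq_along(ids) / 256))) {
      f <- .net_forward(net, encoded[s, , , drop = FALSE],
                        nonsigmoid[s, , drop = FALSE])
      cl <- .clip_matrix(f$out, net$spec)
      lg <- .loss_and_grad(cl$clipped, truth[s, , drop = FALSE], net$spec, grid, w)
      tot <- tot + sum(lg$loss)
    }
    tot / length(ids)
  }

  for (epoch in seq_len(config$epochs)) {
    perm <- sample(train_idx)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      f <- .net_forward(net, encoded[bt, , , drop = FALSE],
                        nonsigmoid[bt, , drop = FALSE], keep_cache = TRUE)
      cl <- .clip_matrix(f$out, net$spec)
      lg <- .loss_and_grad(cl$clipped, truth[bt, , drop = FALSE], net$spec, grid, w)
      if (!all(is.finite(lg$loss))) {
        stop("non-finite loss at epoch ", epoch, "; predictions: ",
             paste(utils::head(round(cl$clipped, 3)), collapse = ", "))
      }
      ep_loss <- ep_loss + sum(lg$loss)
      # clip gradient gate: pass inside the box, or when the update moves an
      # out-of-box output back toward it (update direction is -grad)
      gate <- (!cl$below & !cl$above) | (cl$below & lg$grad < 0) | (cl$above & lg$grad > 0)
      dout <- lg$grad * gate
      grads <- .net_backward(net, f$cache, dout)
      # global gradient-norm clip: keeps rare large-loss batches from
      # throwing the dense stack into ELU saturation
      gnorm <- sqrt(sum(vapply(grads, function(g) sum(g$dW^2) + sum(g$db^2),
                               numeric(1))))
      if (is.finite(gnorm) && gnorm > 1) {
        grads <- lapply(grads, function(g) list(dW = g$dW / gnorm,
                                                db = g$db / gnorm))
      }
      tstep <- tstep + 1
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      for (nm in names(grads)) {
        for (pn in c("W", "b")) {
          gmat <- grads[[nm]][[if (pn == "W") "dW" else "db"]]
          mom[[nm]][[pn]] <- b1 * mom[[nm]][[pn]] + (1 - b1) * gmat
          vel[[nm]][[pn]] <- b2 * vel[[nm]][[pn]] + (1 - b2) * gmat^2
          net$layers[[nm]][[pn]] <- net$layers[[nm]][[pn]] -
            lr * corr * mom[[nm]][[pn]] / (sqrt(vel[[nm]][[pn]]) + epsa)
          ema[[nm]][[pn]] <- config$ema_momentum * ema[[nm]][[pn]] +
            (1 - config$ema_momentum) * net$layers[[nm]][[pn]]
        }
      }
    }
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, ep_loss / length(train_idx))
    val_now <- eval_loss(val_idx)
    hist_val <- c(hist_val, val_now)
    # the training length is governed by validation performance: keep the
    # weights (and their EMA) from the best-validation epoch
    if (is.finite(val_now) && val_now < best_val) {
      best_val <- val_now
      best <- list(layers = net$layers, ema = ema, epoch = epoch)
    }
  }

  if (!is.null(best)) {
    net$layers <- best$layers
    ema <- best$ema
    net$best_epoch <- best$epoch
  }
  net$ema <- ema
  net$trained <- TRUE
  net$history <- tibble::tibble(epoch = hist_epoch, train_loss = hist_train,
                                validation_loss = hist_val)
  net$test_idx <- test_idx
  net$val_idx <- val_idx
  net
}

# weights used at prediction time: the EMA copy when available
.predict_net <- function(net) {
  if (!is.null(net$ema)) {
    for (nm in names(net$ema)) {
      net$layers[[nm]]$W <- net$ema[[nm]]$W
      net$layers[[nm]]$b <- net$ema[[nm]]$b
    }
  }
  net
}

#' Predict response parameters for encoded trees
#'
#' Runs the (EMA) network forward and applies the clip transform. Inputs
#' must have been standardized with the training scaler; unscaled inputs are
#' rejected.
#'
#' @param net A trained `gc_net`.
#' @param encoded A standardized `encoded_set`.
#' @param nonsigmoid Standardized matrix (or length-3 vector, recycled) of
#'   conditioning scalars.
#' @return For the sigmoid head, a tibble with columns `xscale`, `xshift`,
#'   `yscale`, `yshift` (one row per tree); for the per-bin head, a matrix
#'   of bin values with bin centers as column names.
#' @export
predict_params <- function(net, encoded, nonsigmoid) {
  stopifnot(inherits(net, "gc_net"))
  if (!isTRUE(attr(encoded, "standardized"))) {
    stop("inputs must be standardized with the training scaler (see apply_standardizer)")
  }
  n <- dim(encoded)[1]
  if (is.null(dim(nonsigmoid))) {
    nonsigmoid <- matrix(nonsigmoid, n, length(nonsigmoid), byrow = TRUE)
  }
  pn <- .predict_net(net)
  out <- NULL
  for (s in split(seq_len(n), ceiling(seq_len(n) / 256))) {
    f <- .net_forward(pn, encoded[s, , , drop = FALSE],
                      nonsigmoid[s, , drop = FALSE])
    out <- rbind(out, .clip_matrix(f$out, net$spec)$clipped)
  }
  if (net$spec$output == "sigmoid") {
    tibble::tibble(xscale = out[, 1], xshift = out[, 2],
                   yscale = out[, 3], yshift = out[, 4])
  } else {
    colnames(out) <- sprintf("x=%.3g", bin_centers(net$spec$n_bins))
    out
  }
}

#' @export
#' @rdname tidy-gcfitness
tidy.gc_net <- function(x, ...) network_param_counts(x)

#' @export
#' @rdname tidy-gcfitness
glance.gc_net <- function(x, ...) {
  tibble::tibble(
    n_params = sum(network_param_counts(x)$n_params),
    output = x$spec$output,
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else max(x$history$epoch),
    final_train_loss = if (is.null(x$history)) NA_real_ else utils::tail(x$history$train_loss, 1),
    final_validation_loss = if (is.null(x$history)) NA_real_ else utils::tail(x$history$validation_loss, 1))
}

#' Plot the training history
#'
#' @param net A trained `gc_net`.
#' @return A ggplot object of train/validation loss per epoch.
#' @export
plot_loss_history <- function(net) {
  stopifnot(inherits(net, "gc_net"), !is.null(net$history))
  df <- tidyr::pivot_longer(net$history, -"epoch",
                            names_to = "subset", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "curve difference loss", color = NULL)
}

#' @export
autoplot.response_curve <- function(object, ...) {
  df <- tibble::tibble(affinity = object$grid, rate = object$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$affinity, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "affinity (log10 relative)", y = "birth rate (1/day)")
}
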