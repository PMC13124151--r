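test_that("layer parameter counts match the architecture table", {
  net <- withr::with_seed(27, build_network(network_spec()))
  pc <- network_param_counts(net)
  counts <- setNames(pc$n_params, pc$layer)
  expect_equal(counts[["conv2"]], 2525L)
  expect_equal(counts[["conv3"]], 4040L)
  expect_equal(counts[["dense2"]], 1568L)
  expect_equal(counts[["dense3"]], 528L)
  expect_equal(counts[["dense4"]], 136L)
})

test_that("the curve difference loss behaves like a scaled L1 area", {
  g <- affinity_grid()
  p <- central_mimic_params()
  expect_equal(curve_difference_loss(p, p), 0)
  # flat curves: |3-2| * 5.5 / (2 * 5.5) = 0.5 exactly
  expect_equal(curve_difference_loss(rep(2, length(g)), rep(3, length(g))), 0.5)
  # the numerator is symmetric
  a <- sigmoid_response(p, g)
  b <- sigmoid_response(sigmoid_params(1, 1, 10, 0.2), g)
  w <- gcfitness:::.trapz_weights(g)
  expect_equal(curve_difference_loss(a, b) * sum(w * a),
               curve_difference_loss(b, a) * sum(w * b), tolerance = 1e-12)
  expect_error(curve_difference_loss(rep(0, length(g)), a), "positive")
  expect_error(curve_difference_loss(a[-1], b[-1]), "grid")
})

test_that("distant parameter sets can produce nearly identical curves", {
  # with the midpoint far right of the domain, shifting it by delta while
  # scaling yscale by exp(xscale * delta) leaves the visible tail unchanged
  a <- sigmoid_params(1.6, 4.0, 20, 0.4)
  b <- sigmoid_params(1.6, 5.0, 20 * exp(1.6), 0.4)
  dpar <- sqrt(sum((unlist(a[1:4]) - unlist(b[1:4]))^2))
  expect_gt(dpar, 10)
  expect_lt(curve_difference_loss(a, b), 0.05)
})

test_that("backpropagation matches numerical gradients", {
  withr::with_seed(28, {
    net <- build_network(network_spec(width = 30L))
    B <- 2
    x <- array(rnorm(B * 4 * 30), c(B, 4, 30))
    sc <- matrix(rnorm(B * 3), B, 3)
    truth <- as.matrix(sample_sigmoid_params(B)[, 1:4])
    grid <- affinity_grid(); w <- gcfitness:::.trapz_weights(grid)
    lossfun <- function(nn) {
      f <- gcfitness:::.net_forward(nn, x, sc)
      cl <- gcfitness:::.clip_matrix(f$out, nn$spec)
      mean(gcfitness:::.loss_and_grad(cl$clipped, truth, nn$spec, grid, w)$loss)
    }
    f <- gcfitness:::.net_forward(net, x, sc, keep_cache = TRUE)
    cl <- gcfitness:::.clip_matrix(f$out, net$spec)
    lg <- gcfitness:::.loss_and_grad(cl$clipped, truth, net$spec, grid, w)
    grads <- gcfitness:::.net_backward(net, f$cache, lg$grad)
    eps <- 1e-6
    for (nm in c("conv1", "conv2", "conv3", "dense1", "dense3", "output")) {
      idx <- sample(length(net$layers[[nm]]$W), 2)
      for (i in idx) {
        up <- net; up$layers[[nm]]$W[i] <- up$layers[[nm]]$W[i] + eps
        dn <- net; dn$layers[[nm]]$W[i] <- dn$layers[[nm]]$W[i] - eps
        num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
        expect_equal(grads[[nm]]$dW[i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("prediction is deterministic, clipped, and uses the conditioning scalars", {
  withr::with_seed(29, {
    net <- build_network(network_spec(width = 30L))
    x <- array(rnorm(2 * 4 * 30), c(2, 4, 30))
    class(x) <- "encoded_set"
    attr(x, "standardized") <- TRUE
    p1 <- predict_params(net, x, c(0, 0, 0))
    p2 <- predict_params(net, x, c(0, 0, 0))
    expect_identical(p1, p2)
    p3 <- predict_params(net, x, c(1, -1, 2))
    expect_false(isTRUE(all.equal(p1, p3)))
    cl <- network_spec()$bounds$clip
    expect_true(all(p1$xscale >= cl$xscale[1] & p1$xscale <= cl$xscale[2]))
    expect_true(all(p1$yscale >= cl$yscale[1] & p1$yscale <= cl$yscale[2]))
    # unscaled input is rejected
    y <- x; attr(y, "standardized") <- NULL
    expect_error(predict_params(net, y, c(0, 0, 0)), "standardized")
  })
})

test_that("the per-bin head returns one value per affinity bin", {
  withr::with_seed(30, {
    net <- build_network(network_spec(width = 30L, output = "per_bin"))
    x <- array(rnorm(3 * 4 * 30), c(3, 4, 30))
    class(x) <- "encoded_set"
    attr(x, "standardized") <- TRUE
    out <- predict_params(net, x, c(0, 0, 0))
    expect_equal(dim(out), c(3L, 11L))
    expect_true(all(out >= 0))
    ctr <- bin_centers(11L)
    expect_true(all(ctr > -2.5 & ctr < 3))
    expect_equal(length(ctr), 11L)
  })
})

test_that("training reduces the loss on a small degenerate sample", {
  fx <- gcf_fixtures()
  withr::with_seed(31, {
    # two distinct truth parameter sets, many trees each
    pa <- sigmoid_params(1.6, 2.0, 18.2, 0.4)
    pb <- sigmoid_params(0.5, 0.0, 2.0, 0.1)
    cfgs <- small_config(mutability_multiplier = 5)
    trees <- list(); truth <- NULL; ns <- NULL
    for (i in 1:80) {
      par <- if (i %% 2 == 0) pa else pb
      tr <- run_gc_simulation(cfgs, par, fx$map, fx$shm)
      trees[[i]] <- true_tree_fallback(tr)
      truth <- rbind(truth, unlist(par[1:4]))
      ns <- rbind(ns, c(50, 8, 0.2))
    }
    colnames(truth) <- c("xscale", "xshift", "yscale", "yshift")
    enc <- encode_trees(trees, width = 40L)
    ns <- ns + matrix(rnorm(length(ns), 0, 1e-6), nrow(ns))  # avoid zero variance
    scaler <- fit_standardizer(enc, ns)
    std <- apply_standardizer(scaler, enc, ns)
    net <- build_network(network_spec(width = 40L))
    net <- train_network(net, std$encoded, std$nonsigmoid, truth,
                         train_config(epochs = 40L, seed = 1))
  })
  h <- net$history
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  # with only two truth curves the network can get close to both
  expect_lt(tail(h$train_loss, 1), 0.45)
  expect_true(all(is.finite(h$validation_loss)))
})
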