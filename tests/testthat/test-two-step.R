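test_that("the default non-sigmoid grid has the 4 x 3 x 4 structure", {
  g <- nonsigmoid_grid()
  expect_equal(nrow(g), 48L)
  expect_setequal(unique(g$capacity), c(500, 750, 1000, 2000))
  expect_setequal(unique(g$init_pop), c(8, 32, 128))
  expect_setequal(unique(g$death_rate), c(0.05, 0.1, 0.2, 0.4))
  expect_equal(g$combo, 1:48)
})

test_that("the medoid is the central curve under the symmetrized curve distance", {
  g <- affinity_grid()
  # identical curves: any is the medoid with score 0, ties -> lowest index
  same <- matrix(rep(2, 3 * length(g)), 3, byrow = TRUE)
  ms <- medoid_curve(same, g)
  expect_equal(ms$index, 1L)
  expect_equal(ms$scores, rep(0, 3))
  # flat curves at 1, 2, 10: brute-force the three candidate scores
  flat <- rbind(rep(1, length(g)), rep(2, length(g)), rep(10, length(g)))
  md <- medoid_curve(flat, g)
  d <- function(a, b) 2 * abs(a - b) / (a + b)  # flat-curve closed form
  scores <- c(d(1, 2) + d(1, 10), d(2, 1) + d(2, 10), d(10, 1) + d(10, 2))
  expect_equal(md$scores, scores, tolerance = 1e-12)
  expect_equal(md$index, which.min(scores))
  expect_equal(md$index, 2L)  # the middle curve
  # the medoid is always one of the inputs
  expect_equal(md$curve$value, flat[2, ], ignore_attr = TRUE)
  # permutation invariance up to relabeling
  md_perm <- medoid_curve(flat[c(3, 2, 1), ], g)
  expect_equal(md_perm$curve$value, md$curve$value, ignore_attr = TRUE)
  # pointwise bands bracket the central value
  expect_true(all(md$bands$q025 < 2 & md$bands$q975 > 2))
})

test_that("data mimics share one truth parameter set and draw sample sizes", {
  fx <- gcf_fixtures()
  p <- central_mimic_params()
  combo <- nonsigmoid_grid()[4, ]
  withr::with_seed(34, {
    mim <- make_data_mimic(p, combo, fx$map, fx$shm, n_gcs = 4,
                           sample_range = c(10, 20),
                           base_config = small_config())
  })
  expect_equal(length(mim$gcs), 4L)
  for (g in mim$gcs) {
    expect_identical(g$truth$params, p)
    expect_equal(g$truth$config$capacity, combo$capacity)
    expect_equal(g$truth$config$death_rate, combo$death_rate)
    expect_gte(length(g$sequences), 10)
    expect_lte(length(g$sequences), 20)
  }
  # default settings request 120 GCs with 60-95 sampled cells
  expect_equal(formals(make_data_mimic)$n_gcs, 120)
  expect_equal(eval(formals(make_data_mimic)$sample_range), c(60, 95))
})

test_that("central-mimic selection is the distance argmin with stable ties", {
  fx <- gcf_fixtures()
  withr::with_seed(35, {
    trs <- lapply(1:3, function(i)
      run_gc_simulation(small_config(), central_mimic_params(), fx$map, fx$shm))
  })
  mk <- function(trs) {
    gcs <- lapply(trs, function(t) list(sequences = unname(node_sequences(t)),
                                        tree = true_tree_fallback(t)))
    gc_sample(gcs, fx$map$naive)
  }
  target <- compute_summary_stats(mk(trs[1:2]), fx$map)
  cand1 <- compute_summary_stats(mk(trs[1:2]), fx$map)  # identical to target
  cand2 <- compute_summary_stats(mk(trs[3]), fx$map)
  sel <- select_central_mimic(list(cand2, cand1), target)
  expect_equal(sel$index, 2L)
  expect_equal(length(sel$distances), 2L)
  expect_equal(sel$distances[2], 0)
  # a single candidate is returned directly
  expect_equal(select_central_mimic(list(cand2), target)$index, 1L)
  # exact ties break toward grid order
  expect_equal(select_central_mimic(list(cand1, cand1), target)$index, 1L)
})

test_that("a one-combo grid reduces the scan to plain conditional inference", {
  fx <- gcf_fixtures()
  withr::with_seed(36, {
    net <- build_network(network_spec(width = 40L))
    cfg <- small_config(mutability_multiplier = 5)
    trees <- lapply(1:3, function(i)
      true_tree_fallback(run_gc_simulation(cfg, central_mimic_params(),
                                           fx$map, fx$shm)))
    enc <- encode_trees(trees, width = 40L)
    ns <- cbind(c(500, 600, 700), c(8, 32, 128), c(0.1, 0.2, 0.3))
    scaler <- fit_standardizer(enc, ns)
    std <- apply_standardizer(scaler, enc)
    g1 <- nonsigmoid_grid(capacity = 500, init_pop = 128, death_rate = 0.2)
    sc <- scan_nonsigmoid(std$encoded, net, scaler, g1)
  })
  expect_equal(nrow(sc), 1L)
  expect_equal(nrow(sc$predictions[[1]]), 3L)  # one parameter set per target GC
  direct <- predict_params(net, std$encoded,
                           (c(500, 128, 0.2) - scaler$nonsigmoid["mean", ]) /
                             scaler$nonsigmoid["sd", ])
  expect_equal(sc$predictions[[1]], direct)
  # the medoid row is one of the per-GC predictions
  expect_true(any(apply(direct, 1, function(r)
    isTRUE(all.equal(as.numeric(r), as.numeric(sc[1, c("xscale", "xshift", "yscale", "yshift")]))))))
})
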