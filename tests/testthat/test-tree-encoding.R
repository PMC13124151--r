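cherry_tree <- function(b_aff = -0.3, a_aff = 0.5) {
  # root at time 0 with leaves B (t=2) and A (t=1)
  annotated_tree(parent = c(0, 1, 1), brlen = c(0, 2, 1),
                 affinity = c(0, b_aff, a_aff), label = c(NA, "B", "A"))
}

test_that("the cherry example encodes to the hand-traced matrix", {
  enc <- encode_tree(cherry_tree(), width = 6L)
  expect_equal(enc[1, ], c(2, 1, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(enc[2, ], rep(0, 6), ignore_attr = TRUE)
  expect_equal(enc[3, ], c(-0.3, 0.5, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(enc[4, ], rep(0, 6), ignore_attr = TRUE)
  expect_equal(attr(enc, "n_leaf"), 2L)
  expect_equal(attr(enc, "n_internal"), 1L)
})

test_that("a single leaf on a root branch encodes its unit depth", {
  tr <- annotated_tree(parent = c(0, 1), brlen = c(0, 7), affinity = c(0, 1.2))
  enc <- encode_tree(scale_to_unit_depth(tr), width = 4L)
  expect_equal(enc[1, ], c(1, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(enc[2, 1], 0)
})

test_that("ladderization is canonical: child input order does not matter", {
  t1 <- annotated_tree(parent = c(0, 1, 1, 2, 2), brlen = c(0, 1, 3, 2, 0.5),
                       affinity = c(0, 0.1, -0.2, 0.6, 0.3))
  # same tree with children listed in the opposite order
  t2 <- annotated_tree(parent = c(0, 1, 1, 3, 3), brlen = c(0, 3, 1, 0.5, 2),
                       affinity = c(0, -0.2, 0.1, 0.3, 0.6))
  expect_equal(unclass(encode_tree(t1, width = 8L)),
               unclass(encode_tree(t2, width = 8L)), ignore_attr = TRUE)
})

test_that("equal-depth siblings fall through the tiebreakers to affinity, then error", {
  # depth tie resolved by affinity
  t_aff <- annotated_tree(parent = c(0, 1, 1), brlen = c(0, 2, 2),
                          affinity = c(0, -0.3, 0.5))
  enc <- encode_tree(t_aff, width = 4L)
  expect_equal(enc[3, 1:2], c(0.5, -0.3), ignore_attr = TRUE)  # larger affinity left
  # exact tie in time, parent time and affinity raises
  t_tie <- annotated_tree(parent = c(0, 1, 1), brlen = c(0, 2, 2),
                          affinity = c(0, 0.5, 0.5))
  expect_error(encode_tree(t_tie, width = 4L), "tie")
})

test_that("unit-depth scaling divides by the mean leaf depth and is idempotent", {
  tr <- annotated_tree(parent = c(0, 1, 1), brlen = c(0, 1, 3),
                       affinity = c(0, 0, 0.2))
  sc <- scale_to_unit_depth(tr)
  expect_equal(sort(sc$depth[sc$is_tip]), c(0.5, 1.5))
  expect_equal(mean(sc$depth[sc$is_tip]), 1)
  expect_equal(scale_to_unit_depth(sc)$depth, sc$depth)
  # ultrametric tree of depth d: every branch divided by d
  ul <- annotated_tree(parent = c(0, 1, 1), brlen = c(0, 4, 4),
                       affinity = c(0, 0.3, -0.3))
  expect_equal(scale_to_unit_depth(ul)$brlen, c(0, 1, 1))
})

test_that("padding is exact and fill counters match the tree", {
  fx <- gcf_fixtures()
  tr <- run_gc_simulation(small_config(), central_mimic_params(), fx$map, fx$shm,
                          seed = 24)
  at <- scale_to_unit_depth(true_tree_fallback(tr))
  enc <- encode_tree(at, width = 50L)
  nl <- attr(enc, "n_leaf"); ni <- attr(enc, "n_internal")
  expect_equal(nl, sum(at$is_tip))
  expect_equal(ni, sum(!at$is_tip))
  expect_true(all(enc[c(1, 3), (nl + 1):50] == 0))
  expect_true(all(enc[c(2, 4), (ni + 1):50] == 0))
  expect_error(encode_tree(at, width = 1L), "width")
})

test_that("negating affinities changes only the affinity rows", {
  # distinct depths everywhere, so no ordering falls through to affinity
  tr <- annotated_tree(parent = c(0, 1, 1, 2, 2), brlen = c(0, 1, 3.5, 2, 0.7),
                       affinity = c(0, 0.1, -0.2, 0.6, 0.3))
  neg <- tr; neg$affinity <- -neg$affinity
  e1 <- encode_tree(tr, width = 8L)
  e2 <- encode_tree(neg, width = 8L)
  expect_equal(e1[1:2, ], e2[1:2, ], ignore_attr = TRUE)
  expect_equal(e1[3:4, ], -e2[3:4, ], ignore_attr = TRUE)
})

test_that("standardization hits mean 0 / variance 1 and padding stays zero", {
  fx <- gcf_fixtures()
  withr::with_seed(26, {
    trees <- lapply(1:12, function(i) {
      true_tree_fallback(run_gc_simulation(small_config(), central_mimic_params(),
                                           fx$map, fx$shm))
    })
  })
  enc <- encode_trees(trees, width = 60L)
  ns <- cbind(capacity = runif(12, 400, 600), init = runif(12, 8, 128),
              death = runif(12, 0.1, 0.3))
  scaler <- fit_standardizer(enc, ns)
  std <- apply_standardizer(scaler, enc, ns)
  fills <- attr(enc, "fills")
  mask <- outer(fills[, 1], 1:60, ">=")
  bl <- c(std$encoded[, 1, ][mask], std$encoded[, 2, ][outer(fills[, 2], 1:60, ">=")])
  expect_lt(abs(mean(bl)), 1e-8)
  expect_lt(abs(stats::var(bl) - 1), 1e-2)
  expect_lt(max(abs(colMeans(std$nonsigmoid))), 1e-8)
  # padding remains exactly zero
  expect_true(all(std$encoded[, 1, ][!mask] == 0))
  # reapplying the persisted scaler reproduces the standardized set
  f <- withr::local_tempfile(fileext = ".yaml")
  write_standardizer(scaler, f)
  sc2 <- read_standardizer(f)
  std2 <- apply_standardizer(sc2, enc, ns)
  expect_equal(std2$encoded, std$encoded, ignore_attr = TRUE, tolerance = 1e-6)
  # a held-out tree standardized with training scalers keeps a nonzero mean
  withr::with_seed(99, {
    held <- true_tree_fallback(run_gc_simulation(
      sim_config(capacity = 30, n_sample = 12, t_final = 6, init_pop = 4,
                 min_survivors = 3), central_mimic_params(), fx$map, fx$shm))
  })
  he <- encode_trees(list(held), width = 60L)
  hs <- apply_standardizer(scaler, he)
  hm <- hs$encoded[, 1, ][outer(attr(he, "fills")[, 1], 1:60, ">=")]
  expect_gt(abs(mean(hm)), 1e-6)
  # zero variance in a group errors
  flat <- enc; flat[, 3:4, ] <- 0
  expect_error(fit_standardizer(flat, ns), "variance")
})
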