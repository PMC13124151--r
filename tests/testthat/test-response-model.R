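test_that("sigmoid response evaluates correctly at landmarks", {
  p <- sigmoid_params(1.6, 2.0, 18.2, 0.4)
  # midpoint: half the scale above the lower asymptote
  expect_equal(sigmoid_response(p, p$xshift), p$yscale / 2 + p$yshift)
  # independent hand arithmetic: 18.2 / (1 + e^3.2) + 0.4
  expect_equal(sigmoid_response(p, 0), 18.2 / (1 + exp(3.2)) + 0.4, tolerance = 1e-12)
  expect_equal(round(sigmoid_response(p, 0), 3), 1.113)
  # asymptotes, overflow-safe
  expect_equal(sigmoid_response(p, -1e6), p$yshift)
  expect_equal(sigmoid_response(p, 1e6), p$yshift + p$yscale)
})

test_that("sigmoid response is monotone non-decreasing for non-negative steepness", {
  withr::with_seed(1, {
    for (i in 1:20) {
      p <- sigmoid_params(runif(1, 0, 3), runif(1, -2, 4), runif(1, 0.5, 40),
                          runif(1, 0, 1))
      v <- sigmoid_response(p, seq(-10, 10, by = 0.05))
      expect_true(all(diff(v) >= 0))
    }
  })
})

test_that("naive birth rate matches its closed form and the algebraic identity", {
  p0 <- sigmoid_params(1.2, 0, 10, 0.3)
  expect_equal(naive_birth_rate(p0), 10 / 2)
  p <- sigmoid_params(1.6, 2.0, 18.2, 0.4)
  expect_equal(naive_birth_rate(p), 18.2 / (1 + exp(3.2)), tolerance = 1e-12)
  expect_equal(round(naive_birth_rate(p), 3), 0.713)
  withr::with_seed(2, {
    for (i in 1:20) {
      q <- sigmoid_params(runif(1, 0.01, 2), runif(1, -0.5, 3),
                          runif(1, 0.5, 35), runif(1, 0, 0.6))
      expect_equal(naive_birth_rate(q) + q$yshift, sigmoid_response(q, 0),
                   tolerance = 1e-12)
      expect_lt(naive_birth_rate(q), q$yscale)
    }
  })
})

test_that("affinity/KD conversions follow the log10-relative definition", {
  expect_equal(affinity_from_kd(4e-8, 4e-8), 0)
  expect_equal(round(affinity_from_kd(1e-10, 4e-8), 1), 2.6)
  expect_equal(round(affinity_from_kd(1e-6, 4e-8), 1), -1.4)
  expect_equal(relative_kd(2), 0.01)
  expect_error(affinity_from_kd(-1e-9), "positive")
  expect_error(affinity_from_kd(0), "positive")
})

test_that("constrained sampling keeps the naive birth rate in bounds", {
  b <- training_bounds()
  withr::with_seed(3, draws <- sample_sigmoid_params(10000, b))
  expect_true(all(draws$xscale >= b$xscale[1] & draws$xscale <= b$xscale[2]))
  expect_true(all(draws$xshift >= b$xshift[1] & draws$xshift <= b$xshift[2]))
  expect_true(all(draws$yscale >= b$yscale[1] & draws$yscale <= b$yscale[2]))
  expect_true(all(draws$yshift >= b$yshift[1] & draws$yshift <= b$yshift[2]))
  # recompute the naive rate independently of the sampler's bookkeeping
  l0 <- draws$yscale / (1 + exp(draws$xscale * draws$xshift))
  expect_true(all(l0 >= b$lambda0[1] & l0 <= b$lambda0[2]))
  expect_equal(l0, draws$lambda0, tolerance = 1e-12)
  # marginal of the first-drawn parameter is uniform on its interval
  ks <- stats::ks.test(draws$xscale, "punif", b$xscale[1], b$xscale[2])
  expect_gt(ks$p.value, 0.001)
})

test_that("the truncated xshift interval matches the constraint arithmetic", {
  # with xscale fixed at 1, the upper bound is log(35/0.1 - 1) = 5.855...,
  # binding below the raw box bound of 10
  b <- param_bounds(xscale = c(1, 1), xshift = c(-0.5, 10))
  withr::with_seed(4, draws <- sample_sigmoid_params(5000, b))
  ub <- log(35 / 0.1 - 1)
  expect_lt(max(draws$xshift), ub + 1e-12)
  expect_gt(max(draws$xshift), ub - 0.05)  # the truncated bound is attained
  # the lower constraint has a negative log argument and is vacuous
  expect_lt(min(draws$xshift), -0.45)
})

test_that("clip_params clamps to the clip box and is idempotent", {
  b <- training_bounds()
  inside <- sigmoid_params(1.6, 2.0, 18.2, 0.4)
  expect_equal(clip_params(inside, b), inside)
  out <- sigmoid_params(1.6, 7, 18.2, 0.4)
  cl <- clip_params(out, b)
  expect_equal(cl$xshift, 5)
  expect_equal(clip_params(cl, b), cl)
})

test_that("parameter bounds round-trip through YAML", {
  b <- param_bounds(xscale = c(0.5, 1.5), lambda0 = c(0.2, 10))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_param_bounds(b, f)
  b2 <- read_param_bounds(f)
  expect_equal(unclass(b2), unclass(b))
})
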