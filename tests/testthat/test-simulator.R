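test_that("the modulation factor follows its closed form", {
  expect_equal(modulation_factor(c(1, 2), c(1.5, 1.5), capacity = 100), 1)
  # ratio 0.5: m = 0.5 at N = N0 and 0.25 at N = 2 N0
  lam <- c(2, 2); mu <- c(1, 1)
  expect_equal(modulation_factor(lam, mu, capacity = 2), 0.5)
  expect_equal(modulation_factor(lam, mu, capacity = 1), 0.25)
  # N -> 0 limit: exponent -> 0 so m -> 1
  expect_equal(modulation_factor(lam, mu, capacity = 1e9), 1, tolerance = 1e-6)
  expect_error(modulation_factor(c(0, 0), mu, 10), "birth")
  expect_error(modulation_factor(lam, c(0, 0), 10), "death")
})

test_that("effective birth rates subtract death after modulation", {
  # m = 0.5, lambda = 2, mu = 0.2 -> 0.8
  expect_equal(0.5 * 2 - 0.2, 0.8)
  withr::with_seed(13, {
    for (i in 1:100) {
      n <- sample(5:50, 1)
      lam <- runif(n, 0.1, 10); mu <- runif(n, 0.05, 2)
      eff <- effective_birth_rate(lam, mu, capacity = n)  # N = N0
      # at capacity the modulated process is exactly critical
      expect_equal(sum(eff), 0, tolerance = 1e-9)
    }
  })
})

test_that("initial expansion produces identical naive cells at time zero", {
  fx <- gcf_fixtures()
  for (n0 in c(1L, 8L, 5L)) {
    cfg <- sim_config(capacity = 50, n_sample = 10, t_final = 1e-9,
                      init_pop = n0, min_survivors = 1)
    tr <- run_gc_simulation(cfg, central_mimic_params(), fx$map, fx$shm, seed = 14)
    expect_equal(length(tr$living), n0)
    expect_true(all(tr$nodes$time == 0))
    expect_true(all(node_sequences(tr) == fx$naive))
    # binary expansion: n0 - 1 zero-length splits
    expect_equal(sum(tr$nodes$fate == "birth"), n0 - 1L)
  }
})

test_that("waiting times are exponential with the modulated total rate", {
  fx <- gcf_fixtures()
  p <- central_mimic_params()
  # mutation off; N = N0 = 128 so m = sum(mu)/sum(lambda) exactly
  cfg <- sim_config(capacity = 128, init_pop = 128, t_final = 5, n_sample = 5,
                    death_rate = 0.2, mutability_multiplier = 0,
                    min_survivors = 1)
  lam <- sigmoid_response(p, 0)
  total <- 2 * 128 * 0.2  # m*sum(lambda) + sum(mu) = 2 sum(mu) at N = N0
  withr::with_seed(15, {
    first <- vapply(1:1000, function(i) {
      tr <- run_gc_simulation(cfg, p, fx$map, fx$shm)
      tr$trajectory$time[1]
    }, numeric(1))
  })
  # empirical mean of Exp(total) within a 3-sigma band
  expect_lt(abs(mean(first) - 1 / total), 3 / total / sqrt(1000))
})

test_that("births add one cell and deaths remove one", {
  fx <- gcf_fixtures()
  cfg <- small_config(mutability_multiplier = 0)
  tr <- run_gc_simulation(cfg, central_mimic_params(), fx$map, fx$shm, seed = 16)
  expect_true(all(abs(diff(c(8, tr$trajectory$n))) == 1))
})

test_that("simulations are deterministic under a seed and self-consistent", {
  fx <- gcf_fixtures()
  cfg <- small_config()
  t1 <- run_gc_simulation(cfg, central_mimic_params(), fx$map, fx$shm, seed = 17)
  t2 <- run_gc_simulation(cfg, central_mimic_params(), fx$map, fx$shm, seed = 17)
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$sampled, t2$sampled)
  # every sampled tip's sequence reproduces its recorded affinity exactly
  sq <- node_sequences(t1)
  rec <- t1$living_state$affinity[match(t1$sampled, t1$living_state$id)]
  expect_identical(unname(affinity_of(fx$map, sq)), rec)
  # death rates follow the functional flag
  ls <- t1$living_state
  expect_identical(ls$mu, ifelse(ls$functional, cfg$death_rate, cfg$stop_death_rate))
  # sampled tips all at the sampling time, count = min(requested, living)
  expect_equal(length(t1$sampled), min(cfg$n_sample, length(t1$living)))
  expect_true(all(t1$nodes$end_time[t1$sampled] == cfg$t_final))
})

test_that("mutation-free simulations keep every sequence naive", {
  fx <- gcf_fixtures()
  cfg <- small_config(mutability_multiplier = 0)
  tr <- run_gc_simulation(cfg, central_mimic_params(), fx$map, fx$shm, seed = 18)
  expect_true(all(node_sequences(tr) == fx$naive))
  expect_true(all(tr$living_state$affinity == 0))
})

test_that("a pure-death response exhausts retries with an informative error", {
  fx <- gcf_fixtures()
  p <- sigmoid_params(1, 0, 1e-6, 0)
  cfg <- small_config(max_retries = 3)
  expect_error(run_gc_simulation(cfg, p, fx$map, fx$shm, seed = 19),
               "discarded 3")
})

test_that("all three capacity methods hold the population near the capacity", {
  fx <- gcf_fixtures()
  p <- central_mimic_params()
  for (method in c("birth", "death", "hard")) {
    cfg <- sim_config(capacity = 100, capacity_method = method, t_final = 15,
                      n_sample = 20, init_pop = 16)
    tr <- run_gc_simulation(cfg, p, fx$map, fx$shm, seed = 20)
    expect_lt(abs(mean_population(tr, 10, 15) - 100) / 100, 0.2)
    if (method == "hard") {
      expect_lte(max(tr$trajectory$n), 100)
    }
  }
})
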