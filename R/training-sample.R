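#' Simulate a network training sample
#'
#' Draws one parameter set per germinal center — sigmoid parameters via
#' [sample_sigmoid_params()] under the naive-birth-rate constraint, and
#' non-sigmoid parameters uniformly from their ranges (carrying capacity
#' \[500, 2000\], initial population \[8, 128\], functional death rate
#' \[0.05, 0.5\], time to sampling \[10, 35\] days, 50-130 sampled cells,
#' mutability multiplier 0.68) — then simulates each GC and converts it with
#' [true_tree_fallback()]. A parameter draw whose simulations are discarded
#' repeatedly (extinction-prone corner of the box) is redrawn.
#'
#' @param n_trees Number of trees.
#' @param map,shm Affinity map and SHM model.
#' @param bounds [param_bounds()] for the sigmoid draw.
#' @param capacity_range,init_range,death_range,t_range,sample_range Ranges
#'   of the non-sigmoid draws.
#' @param multiplier Mutability multiplier for training simulations.
#' @param progress Print a dot every 200 trees.
#' @return A list with `trees` (list of [annotated_tree()]), `truth` (tibble
#'   of sigmoid parameters), and `nonsigmoid` (n x 3 matrix: capacity,
#'   init_pop, death_rate).
#' @export
simulate_training_set <- function(n_trees, map, shm, bounds = training_bounds(),
                                  capacity_range = c(500, 2000),
                                  init_range = c(8, 128),
                                  death_range = c(0.05, 0.5),
                                  t_range = c(10, 35),
                                  sample_range = c(50, 130),
                                  multiplier = 0.68, progress = FALSE) {
  trees <- vector("list", n_trees)
  truth <- matrix(NA_real_, n_trees, 4)
  nonsig <- matrix(NA_real_, n_trees, 3)
  colnames(nonsig) <- c("capacity", "init_pop", "death_rate")
  for (i in seq_len(n_trees)) {
    repeat {
      pr <- sample_sigmoid_params(1, bounds)
      par <- sigmoid_params(pr$xscale, pr$xshift, pr$yscale, pr$yshift)
      cfg <- sim_config(
        capacity = stats::runif(1, capacity_range[1], capacity_range[2]),
        t_final = stats::runif(1, t_range[1], t_range[2]),
        n_sample = sample.int(sample_range[2] - sample_range[1] + 1L, 1L) +
          sample_range[1] - 1L,
        init_pop = sample.int(init_range[2] - init_range[1] + 1L, 1L) +
          init_range[1] - 1L,
        death_rate = stats::runif(1, death_range[1], death_range[2]),
        mutability_multiplier = multiplier)
      tr <- tryCatch(run_gc_simulation(cfg, par, map, shm),
                     error = function(e) NULL)
      if (!is.null(tr)) break
    }
    trees[[i]] <- true_tree_fallback(tr)
    truth[i, ] <- c(pr$xscale, pr$xshift, pr$yscale, pr$yshift)
    nonsig[i, ] <- c(cfg$capacity, cfg$init_pop, cfg$death_rate)
    if (progress && i %% 200 == 0) cat(".")
  }
  if (progress) cat("\n")
  colnames(truth) <- c("xscale", "xshift", "yscale", "yshift")
  list(trees = trees, truth = tibble::as_tibble(truth), nonsigmoid = nonsig)
}
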