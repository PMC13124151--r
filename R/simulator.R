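#' Simulation configuration
#'
#' All non-sigmoid parameters of a germinal-center simulation: the carrying
#' capacity and how it is enforced, the time horizon, sampling size, initial
#' population, death rates, and the mutability multiplier. Defaults are the
#' central data-mimic settings (capacity 500, birth-modulated, 20 days,
#' initial population 128, functional death rate 0.2/day, stop-codon death
#' rate 10/day, multiplier 0.5).
#'
#' @param capacity Carrying capacity N0.
#' @param capacity_method One of `"birth"` (multiply birth rates by the
#'   logistic factor m), `"death"` (divide death rates by m), or `"hard"`
#'   (no rate change; a birth pushing the population above N0 triggers the
#'   immediate removal of one uniformly random living cell).
#' @param t_final Time to sampling (days).
#' @param n_sample Number of cells sampled uniformly without replacement at
#'   `t_final` (capped at the number living).
#' @param init_pop Initial population after the instantaneous naive
#'   expansion.
#' @param death_rate Death rate of functional cells (> 0, per day).
#' @param stop_death_rate Death rate of stop-codon-bearing cells (per day).
#' @param mutability_multiplier Multiplier applied to the SHM model's total
#'   per-sequence mutation rate.
#' @param min_survivors Minimum living cells at `t_final`; below this the
#'   run is discarded and retried.
#' @param max_retries Retries on extinction/too-few-survivors before erroring.
#' @param max_events Event-count guard against runaway simulations.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(capacity = 500, capacity_method = c("birth", "death", "hard"),
                       t_final = 20, n_sample = 75, init_pop = 128,
                       death_rate = 0.2, stop_death_rate = 10,
                       mutability_multiplier = 0.5,
                       min_survivors = 10, max_retries = 10,
                       max_events = 2e6) {
  capacity_method <- match.arg(capacity_method)
  if (death_rate <= 0) stop("functional death rate must be > 0")
  if (t_final <= 0) stop("t_final must be > 0")
  if (init_pop < 1) stop("init_pop must be >= 1")
  structure(list(capacity = capacity, capacity_method = capacity_method,
                 t_final = t_final, n_sample = n_sample, init_pop = init_pop,
                 death_rate = death_rate, stop_death_rate = stop_death_rate,
                 mutability_multiplier = mutability_multiplier,
                 min_survivors = min_survivors, max_retries = max_retries,
                 max_events = max_events),
            class = "sim_config")
}

#' Central data-mimic configuration
#'
#' The evaluation-sample settings: capacity 500, birth-modulated, 20 days to
#' sampling, initial population 128, functional death rate 0.2, stop death
#' rate 10, mutability multiplier 0.5.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()] object.
#' @export
central_mimic_config <- function(...) sim_config(...)

#' Logistic carrying-capacity modulation factor
#'
#' \deqn{m = (\sum_i \mu_i / \sum_i \lambda_i)^{N/N_0}} over the N living
#' cells. For small populations the exponent is near 0 and m is near 1; at
#' the carrying capacity the modulated process is exactly critical:
#' \eqn{\sum_i m\lambda_i = \sum_i \mu_i}.
#'
#' @param lambda Numeric vector of intrinsic birth rates of living cells.
#' @param mu Numeric vector of death rates of living cells.
#' @param capacity Carrying capacity N0.
#' @param n Number of living cells; defaults to `length(lambda)`.
#' @return The dimensionless factor m.
#' @export
modulation_factor <- function(lambda, mu, capacity, n = length(lambda)) {
  sl <- sum(lambda); sm <- sum(mu)
  if (sl <= 0) stop("sum of birth rates must be > 0")
  if (sm <= 0) stop("sum of death rates must be > 0")
  (sm / sl)^(n / capacity)
}

#' Effective birth rates of living cells
#'
#' The net fitness advantage \eqn{m\lambda_i - \mu_i} of each living cell,
#' with m recomputed from the current living set. At the carrying capacity
#' the population mean is exactly 0.
#'
#' @param lambda,mu Rates of living cells.
#' @param capacity Carrying capacity.
#' @return Numeric vector of effective birth rates.
#' @export
effective_birth_rate <- function(lambda, mu, capacity) {
  m <- modulation_factor(lambda, mu, capacity)
  m * lambda - mu
}

#' Run a germinal-center birth-death-mutation simulation
#'
#' Initializes a single naive cell, performs an instantaneous binary
#' expansion to `config$init_pop` cells at time 0, then runs the event loop:
#' at each step an exponential waiting time is drawn for every living cell
#' and event type (birth at the capacity-modulated sigmoid rate, death at
#' the functional/stop rate, mutation at the 5-mer SHM rate) and the minimal
#' pair fires. Birth replaces the parent with two identical children;
#' mutation applies one context-sampled substitution and recomputes the
#' cell's affinity, functionality and rates. At `t_final` a uniform sample
#' of cells is taken. Runs that go extinct or end with fewer than
#' `config$min_survivors` living cells are discarded and retried.
#'
#' @param config A [sim_config()].
#' @param params A [sigmoid_params()] response function.
#' @param map An [affinity_map()] giving each sequence's affinity.
#' @param shm An [shm_model()] giving mutabilities and substitution triples.
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @return An object of class `gc_tree`: the full genealogy (`nodes` tibble
#'   with creation/end times, parent pointers, recorded substitutions and
#'   fates), the living and sampled node ids, per-living-cell state, and the
#'   population trajectory.
#' @export
run_gc_simulation <- function(config, params, map, shm, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(params, "sigmoid_params"),
            inherits(map, "affinity_map"), inherits(shm, "shm_model"))
  if (!is.null(seed)) set.seed(seed)
  method_code <- match(config$capacity_method, c("birth", "death", "hard")) - 1L
  multiplier <- config$mutability_multiplier
  sub <- shm$substitution

  for (attempt in seq_len(config$max_retries)) {
    res <- .simulate_gc_cpp(
      map$naive_int, map$effects, unname(shm$mutability), sub,
      multiplier, map$frame - 1L,
      params$xscale, params$xshift, params$yscale, params$yshift,
      as.integer(config$init_pop), config$capacity, method_code,
      config$t_final, config$death_rate, config$stop_death_rate,
      as.integer(config$max_events))
    if (res$overflow) stop("simulation exceeded max_events; raise max_events or shrink the system")
    n_living <- length(res$living)
    if (n_living >= config$min_survivors) {
      n_s <- min(config$n_sample, n_living)
      sampled_idx <- sample.int(n_living, n_s)
      nodes <- tibble::tibble(
        id = seq_along(res$parent), parent = res$parent,
        time = res$time, end_time = res$end_time,
        mut_site = ifelse(res$mut_site > 0, res$mut_site, NA_integer_),
        mut_from = ifelse(res$mut_from >= 0, res$mut_from, NA_integer_),
        mut_to = ifelse(res$mut_to >= 0, res$mut_to, NA_integer_),
        fate = c("birth", "mutation", "death", "alive")[res$status + 1L])
      out <- structure(list(
        nodes = nodes,
        living = res$living,
        sampled = sort(res$living[sampled_idx]),
        living_state = tibble::tibble(
          id = res$living, affinity = res$living_affinity,
          lambda = res$living_lambda, mu = res$living_mu,
          mutation_rate = res$living_mutrate,
          functional = res$living_functional),
        trajectory = tibble::tibble(time = res$traj_time, n = res$traj_n,
                                    m = res$traj_m),
        config = config, params = params, naive = map$naive,
        map = map, shm = shm, attempts = attempt),
        class = "gc_tree")
      return(out)
    }
  }
  stop(sprintf("simulation discarded %d time(s) (extinction or < %d survivors); retries exhausted",
               config$max_retries, config$min_survivors))
}

#' @export
print.gc_tree <- function(x, ...) {
  cat(sprintf("<gc_tree> %d nodes, %d living at t=%.3g, %d sampled (attempt %d)\n",
              nrow(x$nodes), length(x$living), x$config$t_final,
              length(x$sampled), x$attempts))
  invisible(x)
}

#' Reconstruct node sequences from the recorded mutations
#'
#' Walks each requested node's ancestry, collecting the substitutions on the
#' path from the naive root, and applies them to the naive sequence.
#'
#' @param tree A `gc_tree`.
#' @param ids Node ids (default: the sampled tips).
#' @return Character vector of sequences, named by node id.
#' @export
node_sequences <- function(tree, ids = tree$sampled) {
  stopifnot(inherits(tree, "gc_tree"))
  nd <- tree$nodes
  naive_int <- seq_to_int(tree$naive)
  out <- character(length(ids))
  for (j in seq_along(ids)) {
    path_sites <- integer(0); path_to <- integer(0)
    i <- ids[j]
    while (i > 0) {
      if (!is.na(nd$mut_site[i])) {
        path_sites <- c(path_sites, nd$mut_site[i])
        path_to <- c(path_to, nd$mut_to[i])
      }
      i <- nd$parent[i]
    }
    v <- naive_int
    # apply in chronological (root-to-tip) order so later hits overwrite
    if (length(path_sites)) {
      for (k in rev(seq_along(path_sites))) v[path_sites[k]] <- path_to[k]
    }
    out[j] <- int_to_seq(v)
  }
  stats::setNames(out, ids)
}

#' Mean population size over a late-time window
#'
#' Time-weighted mean of the living-cell count over `[from, to]`, used to
#' check criticality at the carrying capacity.
#'
#' @param tree A `gc_tree`.
#' @param from,to Window bounds (days).
#' @return Mean number of living cells.
#' @export
mean_population <- function(tree, from, to) {
  tr <- tree$trajectory
  times <- c(tr$time, tree$config$t_final)
  # n is piecewise-constant between events: value tr$n[i] holds on
  # [tr$time[i], tr$time[i+1])
  lo <- pmax(times[-length(times)], from)
  hi <- pmin(times[-1], to)
  w <- pmax(hi - lo, 0)
  if (sum(w) == 0) return(NA_real_)
  sum(tr$n * w) / sum(w)
}
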