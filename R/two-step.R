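#' Grid of non-sigmoid parameter combinations
#'
#' The default three-dimensional scan: carrying capacities 500, 750, 1000,
#' 2000; initial populations 8, 32, 128; functional death rates 0.05, 0.1,
#' 0.2, 0.4 — 48 combinations in grid order.
#'
#' @param capacity,init_pop,death_rate Values for each axis.
#' @return A tibble with one row per combination and a `combo` index column.
#' @export
nonsigmoid_grid <- function(capacity = c(500, 750, 1000, 2000),
                            init_pop = c(8, 32, 128),
                            death_rate = c(0.05, 0.1, 0.2, 0.4)) {
  g <- expand.grid(death_rate = death_rate, init_pop = init_pop,
                   capacity = capacity, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(combo = seq_len(nrow(g)), capacity = g$capacity,
                 init_pop = g$init_pop, death_rate = g$death_rate)
}

#' Conditional inference over the non-sigmoid grid
#'
#' For every combination in the grid, predicts the per-GC sigmoid parameters
#' of the target trees conditional on that combination's non-sigmoid values,
#' and computes the medoid parameter set among the per-GC predictions.
#'
#' @param encoded Standardized `encoded_set` of the target trees.
#' @param net A trained `gc_net` (sigmoid head).
#' @param scaler The training `encoding_scaler` (used to standardize each
#'   combination's values).
#' @param grid A [nonsigmoid_grid()] tibble.
#' @return An object of class `gc_scan`: the grid tibble with list-column
#'   `predictions` (per-GC parameter tibbles) and columns
#'   `xscale`, `xshift`, `yscale`, `yshift` holding each combination's
#'   medoid parameters.
#' @export
scan_nonsigmoid <- function(encoded, net, scaler, grid = nonsigmoid_grid()) {
  stopifnot(inherits(net, "gc_net"), inherits(scaler, "encoding_scaler"))
  preds <- vector("list", nrow(grid))
  med <- matrix(NA_real_, nrow(grid), 4)
  for (i in seq_len(nrow(grid))) {
    ns_raw <- c(grid$capacity[i], grid$init_pop[i], grid$death_rate[i])
    ns <- (ns_raw - scaler$nonsigmoid["mean", ]) / scaler$nonsigmoid["sd", ]
    p <- predict_params(net, encoded, ns)
    preds[[i]] <- p
    cur <- .sigmoid_curves(as.matrix(p), affinity_grid())
    md <- medoid_curve(cur)
    med[i, ] <- as.numeric(p[md$index, ])
  }
  out <- grid
  out$predictions <- preds
  out$xscale <- med[, 1]; out$xshift <- med[, 2]
  out$yscale <- med[, 3]; out$yshift <- med[, 4]
  class(out) <- c("gc_scan", class(out))
  out
}

#' Medoid curve of a set of response curves
#'
#' The representative central curve: pairwise distances are the
#' curve-difference loss symmetrized by normalizing the area between two
#' curves by the mean of their areas (so it reduces to the loss when both
#' areas agree), and the medoid minimizes the sum of distances to all other
#' curves — the classic medoid, which unlike a squared-distance variant is
#' robust to outlying predictions. Ties are broken by the lowest input
#' index. Pointwise 68% and 95% quantile bands across the curves are
#' returned alongside.
#'
#' @param curves An n x G matrix of curve values on `grid`, or a list of
#'   `response_curve` objects sharing the grid.
#' @param grid Affinity grid (default [affinity_grid()]).
#' @return An object of class `medoid_curve`: list with `curve` (a
#'   `response_curve`), `index`, `scores` (per-curve distance sums) and
#'   `bands` (tibble of pointwise quantiles).
#' @export
medoid_curve <- function(curves, grid = affinity_grid()) {
  if (is.list(curves) && !is.matrix(curves)) {
    curves <- do.call(rbind, lapply(curves, .as_curve_values, grid = grid))
  }
  n <- nrow(curves)
  w <- .trapz_weights(grid)
  areas <- drop(curves %*% w)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    between <- drop(abs(sweep(curves, 2, curves[i, ])) %*% w)
    dij <- 2 * between / (areas + areas[i])
    scores[i] <- sum(dij)
  }
  idx <- which.min(scores)  # which.min takes the first (lowest-index) tie
  bands <- tibble::tibble(
    affinity = grid,
    q025 = apply(curves, 2, stats::quantile, 0.025, names = FALSE),
    q16 = apply(curves, 2, stats::quantile, 0.16, names = FALSE),
    q84 = apply(curves, 2, stats::quantile, 0.84, names = FALSE),
    q975 = apply(curves, 2, stats::quantile, 0.975, names = FALSE))
  structure(list(curve = structure(list(grid = grid, value = curves[idx, ]),
                                   class = "response_curve"),
                 index = idx, scores = scores, bands = bands),
            class = "medoid_curve")
}

#' @export
print.medoid_curve <- function(x, ...) {
  cat(sprintf("<medoid_curve> index %d among %d curves (score %.4g)\n",
              x$index, length(x$scores), x$scores[x$index]))
  invisible(x)
}

#' @export
#' @rdname tidy-gcfitness
tidy.medoid_curve <- function(x, ...) {
  dplyr::mutate(x$bands, medoid = x$curve$value)
}

#' @export
autoplot.medoid_curve <- function(object, truth = NULL, ...) {
  df <- tidy.medoid_curve(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$affinity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q025, ymax = .data$q975),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q16, ymax = .data$q84),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$medoid), color = "darkorange") +
    ggplot2::labs(x = "affinity (log10 relative)", y = "birth rate (1/day)")
  if (!is.null(truth)) {
    tv <- .as_curve_values(truth, object$curve$grid)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(affinity = object$curve$grid, rate = tv),
      ggplot2::aes(x = .data$affinity, y = .data$rate), color = "darkgreen")
  }
  p
}

#' Generate a data-mimic sample
#'
#' Simulates `n_gcs` germinal centers that all share one sigmoid parameter
#' set and one non-sigmoid combination, with the remaining settings from the
#' central data-mimic configuration (20 days to sampling, 60-95 sampled
#' cells per GC, mutability multiplier 0.5).
#'
#' @param params A [sigmoid_params()] (or one row of a prediction tibble).
#' @param combo A row of a [nonsigmoid_grid()] (fields `capacity`,
#'   `init_pop`, `death_rate`).
#' @param map,shm Affinity map and SHM model.
#' @param n_gcs Number of GCs (default 120).
#' @param sample_range Per-GC sampled-cell range (default c(60, 95)).
#' @param base_config Base [sim_config()] supplying the remaining settings.
#' @return A [gc_sample()].
#' @export
make_data_mimic <- function(params, combo, map, shm, n_gcs = 120,
                            sample_range = c(60, 95),
                            base_config = central_mimic_config()) {
  if (!inherits(params, "sigmoid_params")) {
    params <- sigmoid_params(params$xscale, params$xshift, params$yscale, params$yshift)
  }
  cfg <- base_config
  cfg$capacity <- combo$capacity
  cfg$init_pop <- as.integer(combo$init_pop)
  cfg$death_rate <- combo$death_rate
  simulate_gc_sample(n_gcs, cfg, params, map, shm, sample_range = sample_range)
}

#' Select the central data mimic
#'
#' Among candidate mimic samples, returns the one whose summary statistics
#' most closely match the target's ([stat_distance()]); ties are broken by
#' grid order.
#'
#' @param mimic_stats List of `gc_summary_stats`, one per candidate.
#' @param target_stats `gc_summary_stats` of the target data.
#' @return A list with `index` (argmin) and `distances` (all candidates).
#' @export
select_central_mimic <- function(mimic_stats, target_stats) {
  d <- vapply(mimic_stats, stat_distance, numeric(1), b = target_stats)
  list(index = which.min(d), distances = d)
}

#' Closed-loop end-to-end recovery
#'
#' The full two-step procedure run against a simulated target whose truth is
#' known: simulate a fixed-parameter target sample, predict per-GC sigmoid
#' parameters conditional on every grid combination, generate a data-mimic
#' sample from each combination's medoid parameters, select the combination
#' whose summary statistics best match the target, and report the
#' medoid-vs-truth curve loss together with the per-GC loss distribution.
#'
#' @param target A [gc_sample()] whose GCs carry truth parameters.
#' @param truth_params The shared true [sigmoid_params()].
#' @param truth_combo One-row tibble with the true `capacity`, `init_pop`,
#'   `death_rate`.
#' @param net,scaler Trained network and its standardizer.
#' @param map,shm Affinity map and SHM model.
#' @param grid [nonsigmoid_grid()] to scan.
#' @param n_mimic_gcs GCs per candidate mimic sample.
#' @param crn_seed Optional integer: when supplied, the same seed is set
#'   before generating each candidate's mimic sample (common random
#'   numbers), so that mimic sampling noise largely cancels out of the
#'   between-candidate comparison.
#' @param width Encoding width.
#' @return A list of class `gc_recovery`: selected and truth combos, the
#'   scan table with distances, the medoid curve at the truth combo, the
#'   medoid-vs-truth loss and the per-GC loss distribution.
#' @export
end_to_end_recovery <- function(target, truth_params, truth_combo, net, scaler,
                                map, shm, grid = nonsigmoid_grid(),
                                n_mimic_gcs = 30, crn_seed = NULL,
                                width = 200L) {
  trees <- lapply(target$gcs, function(g) g$tree)
  enc <- encode_trees(trees, width = width)
  std <- apply_standardizer(scaler, enc)
  scan <- scan_nonsigmoid(std$encoded, net, scaler, grid)

  target_stats <- compute_summary_stats(target, map)
  dist <- numeric(nrow(scan))
  for (i in seq_len(nrow(scan))) {
    if (!is.null(crn_seed)) set.seed(crn_seed)
    mim <- make_data_mimic(scan[i, ], scan[i, ], map, shm, n_gcs = n_mimic_gcs)
    dist[i] <- stat_distance(compute_summary_stats(mim, map), target_stats)
  }
  sel <- which.min(dist)

  # losses evaluated at the truth combo's conditional predictions
  truth_row <- which(scan$capacity == truth_combo$capacity &
                       scan$init_pop == truth_combo$init_pop &
                       scan$death_rate == truth_combo$death_rate)
  if (length(truth_row) != 1) stop("truth_combo must match exactly one grid row")
  preds <- scan$predictions[[truth_row]]
  curves <- .sigmoid_curves(as.matrix(preds), affinity_grid())
  md <- medoid_curve(curves)
  tv <- sigmoid_response(truth_params, affinity_grid())
  per_gc_loss <- apply(curves, 1, function(cv) curve_difference_loss(tv, cv))
  medoid_loss <- curve_difference_loss(tv, md$curve$value)

  structure(list(
    scan = dplyr::mutate(dplyr::select(scan, -"predictions"), distance = dist),
    selected_combo = scan[sel, c("capacity", "init_pop", "death_rate")],
    truth_combo = truth_combo[, c("capacity", "init_pop", "death_rate")],
    selected_index = sel,
    medoid = md, medoid_loss = medoid_loss, per_gc_loss = per_gc_loss,
    truth_params = truth_params),
    class = "gc_recovery")
}

#' @export
print.gc_recovery <- function(x, ...) {
  cat(sprintf("<gc_recovery> medoid loss %.3g vs mean per-GC loss %.3g\n",
              x$medoid_loss, mean(x$per_gc_loss)))
  cat(sprintf("  selected combo: capacity %g, init %g, death %g (truth: %g, %g, %g)\n",
              x$selected_combo$capacity, x$selected_combo$init_pop,
              x$selected_combo$death_rate, x$truth_combo$capacity,
              x$truth_combo$init_pop, x$truth_combo$death_rate))
  invisible(x)
}

#' @export
#' @rdname tidy-gcfitness
glance.gc_recovery <- function(x, ...) {
  tibble::tibble(medoid_loss = x$medoid_loss,
                 mean_per_gc_loss = mean(x$per_gc_loss),
                 median_per_gc_loss = stats::median(x$per_gc_loss),
                 combo_recovered = isTRUE(all.equal(
                   as.numeric(x$selected_combo), as.numeric(x$truth_combo))))
}
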