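#' A multi-GC sample
#'
#' A light container for a collection of germinal centers: each element has
#' the sampled sequences (duplicates preserved — abundance matters), the
#' adapter tree and, when simulated, the truth parameters.
#'
#' @param gcs List of per-GC lists with elements `sequences`, `tree` and
#'   optionally `truth`.
#' @param naive Naive sequence shared by all GCs.
#' @return An object of class `gc_sample`.
#' @export
gc_sample <- function(gcs, naive) {
  structure(list(gcs = gcs, naive = naive), class = "gc_sample")
}

#' @export
print.gc_sample <- function(x, ...) {
  cat(sprintf("<gc_sample> %d germinal centers, %s sampled cells\n",
              length(x$gcs), sum(vapply(x$gcs, function(g) length(g$sequences), numeric(1)))))
  invisible(x)
}

#' Simulate a multi-GC sample
#'
#' Runs [run_gc_simulation()] + [true_tree_fallback()] once per GC. Either a
#' single configuration (all GCs identical, the data-mimic situation) or a
#' per-GC list of configurations/parameter sets (the training situation).
#'
#' @param n_gcs Number of germinal centers.
#' @param config A [sim_config()] or list of them (length `n_gcs`).
#' @param params A [sigmoid_params()] or list of them.
#' @param map,shm The affinity map and SHM model.
#' @param sample_range Optional length-2 integer range; when supplied each
#'   GC's sampled-cell count is drawn uniformly from it, overriding
#'   `config$n_sample`.
#' @return A [gc_sample()]; each GC records its truth parameters.
#' @export
simulate_gc_sample <- function(n_gcs, config, params, map, shm,
                               sample_range = NULL) {
  one_cfg <- inherits(config, "sim_config")
  one_par <- inherits(params, "sigmoid_params")
  gcs <- vector("list", n_gcs)
  for (i in seq_len(n_gcs)) {
    cfg <- if (one_cfg) config else config[[i]]
    par <- if (one_par) params else params[[i]]
    if (!is.null(sample_range)) {
      cfg$n_sample <- sample.int(sample_range[2] - sample_range[1] + 1L, 1L) +
        sample_range[1] - 1L
    }
    tr <- run_gc_simulation(cfg, par, map, shm)
    at <- true_tree_fallback(tr)
    gcs[[i]] <- list(sequences = unname(node_sequences(tr, tr$sampled)),
                     tree = at,
                     truth = list(params = par, config = cfg))
  }
  gc_sample(gcs, map$naive)
}

#' Summary statistics of a multi-GC sample
#'
#' The per-sample distributions used for data/simulation matching:
#' \itemize{
#'   \item `leaf_counts` — number of tree leaves (unique sequences) per GC;
#'   \item `shm` — nucleotide mutation count of every sampled sequence;
#'   \item `affinity` — affinity of every sampled cell;
#'   \item `abundance` — multiplicities of identical sampled sequences per GC;
#'   \item `branch_lengths` — all tree branch lengths, pooled;
#'   \item `depths` — mean root-to-tip depth per tree;
#'   \item `basal_lineages` — per GC, the number of lineages branching at
#'     the root (within 1e-6 of the root relative to the mean tip depth),
#'     which measures how many founder lineages the sample represents and
#'     identifies the initial population size.
#' }
#'
#' @param sample A [gc_sample()].
#' @param map An [affinity_map()] used to compute each sampled sequence's
#'   affinity.
#' @return An object of class `gc_summary_stats` (named list of numeric
#'   vectors).
#' @export
compute_summary_stats <- function(sample, map) {
  stopifnot(inherits(sample, "gc_sample"), inherits(map, "affinity_map"))
  naive_int <- seq_to_int(sample$naive)
  leaf_counts <- numeric(0); shm <- numeric(0); affin <- numeric(0)
  abund <- numeric(0); blens <- numeric(0); depths <- numeric(0)
  basal <- numeric(0)
  for (g in sample$gcs) {
    sq <- g$sequences
    leaf_counts <- c(leaf_counts, sum(g$tree$is_tip))
    shm <- c(shm, vapply(sq, function(s) sum(seq_to_int(s) != naive_int),
                         numeric(1), USE.NAMES = FALSE))
    affin <- c(affin, affinity_of(map, sq))
    abund <- c(abund, unname(table(sq)))
    blens <- c(blens, g$tree$brlen[g$tree$parent != 0])
    md <- mean(g$tree$depth[g$tree$is_tip])
    depths <- c(depths, md)
    basal <- c(basal, 1 + sum(!g$tree$is_tip & g$tree$depth <= 1e-6 * md))
  }
  structure(list(leaf_counts = leaf_counts, shm = shm, affinity = affin,
                 abundance = as.numeric(abund), branch_lengths = blens,
                 depths = depths, basal_lineages = basal),
            class = "gc_summary_stats")
}

#' @export
print.gc_summary_stats <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("  %-15s n=%5d  mean=%.4g\n", nm, length(x[[nm]]), mean(x[[nm]])))
  }
  invisible(x)
}

#' @export
#' @rdname tidy-gcfitness
tidy.gc_summary_stats <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x), function(nm) {
    tibble::tibble(component = nm, value = x[[nm]])
  }))
}

# 1-D earth-mover (Wasserstein-1) distance between empirical distributions,
# via their quantile functions on a fixed probability grid
.emd1 <- function(a, b, n_q = 200) {
  p <- (seq_len(n_q) - 0.5) / n_q
  mean(abs(stats::quantile(a, p, names = FALSE, type = 7) -
             stats::quantile(b, p, names = FALSE, type = 7)))
}

#' Distance between two summary-statistic sets
#'
#' Mean over shared components of the 1-D earth-mover distance between the
#' empirical distributions, each component scaled by the pooled standard
#' deviation so components of very different ranges are commensurable.
#' Zero iff all components are distributionally identical; symmetric;
#' invariant to GC ordering.
#'
#' @param a,b `gc_summary_stats` objects.
#' @param components Character vector of components to use (default: all
#'   shared ones).
#' @return Non-negative scalar.
#' @export
stat_distance <- function(a, b, components = NULL) {
  stopifnot(inherits(a, "gc_summary_stats"), inherits(b, "gc_summary_stats"))
  if (is.null(components)) components <- intersect(names(a), names(b))
  d <- 0; used <- 0
  for (nm in components) {
    va <- a[[nm]]; vb <- b[[nm]]
    if (!length(va) || !length(vb)) next
    s <- stats::sd(c(va, vb))
    if (!is.finite(s) || s == 0) {
      # identical constants contribute 0; distinct constants a unit distance
      d <- d + as.numeric(abs(mean(va) - mean(vb)) > 0)
    } else {
      d <- d + .emd1(va, vb) / s
    }
    used <- used + 1
  }
  if (used == 0) stop("no shared components with data")
  d / used
}
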