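ALL_FIVEMERS <- local({
  g <- expand.grid(b1 = DNA_BASES, b2 = DNA_BASES, b3 = DNA_BASES,
                   b4 = DNA_BASES, b5 = DNA_BASES, stringsAsFactors = FALSE)
  # code = sum_i base_i * 4^(i-1), base in 0..3, position 1 leftmost
  apply(g[, 5:1], 1, paste, collapse = "")
})

fivemer_code <- function(fm) {
  v <- vapply(strsplit(fm, ""), function(ch) {
    b <- match(ch, DNA_BASES) - 1L
    as.integer(sum(b * 4L^(0:4)))
  }, integer(1))
  v
}

#' 5-mer context-dependent somatic hypermutation model
#'
#' Each site's mutability is looked up from the 5-mer centered on it; the two
#' terminal positions on each side of the sequence lack a full 5-mer context
#' and are assigned zero mutability. A per-context substitution triple gives
#' the probability of each alternate base when that site mutates. A global
#' `multiplier` modulates the intensity of mutation: it scales the total
#' per-sequence mutation rate but leaves position and base choice unchanged.
#'
#' @param mutability Named numeric vector of length 1024: per-5-mer
#'   mutability (per site per day), names are the 5-mers. Non-negative.
#' @param substitution 1024 x 4 matrix of substitution probabilities (columns
#'   A, C, G, T); each row sums to 1 with 0 probability on the center base.
#' @param multiplier Dimensionless mutability multiplier.
#' @return An object of class `shm_model`.
#' @export
shm_model <- function(mutability, substitution, multiplier = 1) {
  if (length(mutability) != 1024 || any(mutability < 0)) {
    stop("mutability must be a non-negative vector of length 1024")
  }
  if (!is.matrix(substitution) || any(dim(substitution) != c(1024, 4))) {
    stop("substitution must be a 1024 x 4 matrix")
  }
  rs <- rowSums(substitution)
  if (any(abs(rs - 1) > 1e-8)) stop("substitution rows must each sum to 1")
  if (is.null(names(mutability))) names(mutability) <- ALL_FIVEMERS[order(fivemer_code(ALL_FIVEMERS))]
  colnames(substitution) <- DNA_BASES
  structure(list(mutability = mutability, substitution = substitution,
                 multiplier = multiplier),
            class = "shm_model")
}

#' @export
print.shm_model <- function(x, ...) {
  cat(sprintf("<shm_model> 1024 5-mer contexts, multiplier %.3g, mean mutability %.3g\n",
              x$multiplier, mean(x$mutability)))
  invisible(x)
}

# Per-site mutabilities for a sequence (0 at the two terminal sites each side)
site_mutabilities <- function(model, seq) {
  v <- seq_to_int(seq)
  L <- length(v)
  if (L < 5) stop("sequence must have length >= 5")
  out <- numeric(L)
  pow <- 4L^(0:4)
  for (i in 3:(L - 2)) {
    code <- sum(v[(i - 2):(i + 2)] * pow)
    out[i] <- model$mutability[[code + 1L]]
  }
  out
}

#' Total mutation rate of a sequence
#'
#' `multiplier` times the sum over sites of the 5-mer mutability centered at
#' each site. Linear in the multiplier.
#'
#' @param model An [shm_model()].
#' @param seq Nucleotide sequence (length >= 5).
#' @return Mutation rate (mutations per day).
#' @export
sequence_mutation_rate <- function(model, seq) {
  stopifnot(inherits(model, "shm_model"))
  model$multiplier * sum(site_mutabilities(model, seq))
}

#' Sample a single mutation
#'
#' Chooses the site with probability proportional to its 5-mer mutability and
#' the new base from that context's substitution triple. Deterministic under
#' `set.seed()`.
#'
#' @param model An [shm_model()].
#' @param seq Nucleotide sequence.
#' @return A list with `position` (1-based), `new_base` (character) and
#'   `sequence` (the mutated sequence, differing at exactly one position).
#' @export
sample_mutation <- function(model, seq) {
  stopifnot(inherits(model, "shm_model"))
  mut <- site_mutabilities(model, seq)
  tot <- sum(mut)
  if (tot <= 0) stop("all-zero mutability: no site can mutate")
  pos <- sample.int(length(mut), 1, prob = mut)
  v <- seq_to_int(seq)
  code <- sum(v[(pos - 2):(pos + 2)] * 4L^(0:4))
  p <- model$substitution[code + 1L, ]
  newb <- sample.int(4, 1, prob = p)
  v[pos] <- newb - 1L
  list(position = pos, new_base = DNA_BASES[newb], sequence = int_to_seq(v))
}

#' Synthetic 5-mer mutability model
#'
#' A stand-in for a published SHM model: per-5-mer mutabilities are drawn
#' log-normally, a `hotspot_fraction` of contexts is boosted by
#' `hotspot_boost` to give a heavy-tailed hotspot subset, and the table is
#' rescaled so the mean per-site mutability equals `mean_rate`. Substitution
#' triples are drawn from a flat Dirichlet over the three alternate bases.
#' Deterministic under `set.seed()`.
#'
#' The default `mean_rate` of 4e-4 per site per day gives, at the data-mimic
#' multiplier and with selection amplifying mutation accumulation, roughly
#' 1-2% nucleotide divergence over a 20-day reaction.
#'
#' @param hotspot_fraction Fraction of contexts treated as hotspots.
#' @param multiplier Mutability multiplier stored in the model.
#' @param mean_rate Mean per-site mutability after rescaling.
#' @param sdlog Log-scale standard deviation of the base lognormal.
#' @param hotspot_boost Multiplicative boost applied to hotspot contexts.
#' @return An [shm_model()].
#' @export
synthetic_shm_model <- function(hotspot_fraction = 0.05, multiplier = 1,
                                mean_rate = 4e-4, sdlog = 1, hotspot_boost = 8) {
  mut <- stats::rlnorm(1024, meanlog = 0, sdlog = sdlog)
  if (hotspot_fraction > 0) {
    n_hot <- max(1L, round(hotspot_fraction * 1024))
    hot <- sample.int(1024, n_hot)
    mut[hot] <- mut[hot] * hotspot_boost
  }
  mut <- mut * (mean_rate / mean(mut))
  g <- matrix(stats::rgamma(1024 * 4, shape = 1), 1024, 4)
  center <- (fivemer_code(ALL_FIVEMERS) %/% 16L) %% 4L  # position-3 base
  ord <- order(fivemer_code(ALL_FIVEMERS))
  center_sorted <- center[ord]
  sub <- g
  sub[cbind(seq_len(1024), center_sorted + 1L)] <- 0
  sub <- sub / rowSums(sub)
  names(mut) <- ALL_FIVEMERS[ord]
  shm_model(mut, sub, multiplier = multiplier)
}

#' Write/read an SHM model as CSV
#'
#' Columns: `fivemer`, `mutability`, `p_A`, `p_C`, `p_G`, `p_T`. The
#' multiplier is stored in a leading comment-free column `multiplier`
#' repeated on every row.
#'
#' @param model An [shm_model()].
#' @param path CSV path.
#' @return `read_shm_model()` returns an [shm_model()].
#' @export
write_shm_model <- function(model, path) {
  stopifnot(inherits(model, "shm_model"))
  df <- data.frame(fivemer = names(model$mutability),
                   mutability = unname(model$mutability),
                   p_A = model$substitution[, 1], p_C = model$substitution[, 2],
                   p_G = model$substitution[, 3], p_T = model$substitution[, 4],
                   multiplier = model$multiplier)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shm_model
#' @export
read_shm_model <- function(path) {
  df <- utils::read.csv(path)
  ord <- order(fivemer_code(df$fivemer))
  df <- df[ord, ]
  mut <- stats::setNames(df$mutability, df$fivemer)
  sub <- as.matrix(df[, c("p_A", "p_C", "p_G", "p_T")])
  dimnames(sub) <- NULL
  shm_model(mut, sub, multiplier = df$multiplier[1])
}
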