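DNA_BASES <- c("A", "C", "G", "T")

seq_to_int <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  if (anyNA(v)) stop("sequence contains a base other than A/C/G/T")
  v - 1L
}

int_to_seq <- function(v) paste(DNA_BASES[v + 1L], collapse = "")

#' Additive sequence-to-affinity map
#'
#' A deep-mutational-scan style map: every single-nucleotide variant of the
#' naive sequence has a tabulated additive effect (in affinity units), and the
#' affinity of an arbitrary sequence is the sum of the effects of its
#' substitutions relative to the naive sequence (no epistasis). The effect of
#' the naive base at every position is 0 by construction.
#'
#' @param naive Naive nucleotide sequence (character scalar, A/C/G/T).
#' @param effects 4 x L numeric matrix of per-base effects; rows in order
#'   A, C, G, T, columns are positions. Entries for the naive base must be 0.
#' @param frame 1-based reading-frame offset of the first codon (default 1).
#' @return An object of class `affinity_map`.
#' @export
affinity_map <- function(naive, effects, frame = 1L) {
  nv <- seq_to_int(naive)
  L <- length(nv)
  if (!is.matrix(effects) || nrow(effects) != 4 || ncol(effects) != L) {
    stop("effects must be a 4 x nchar(naive) matrix")
  }
  naive_fx <- effects[cbind(nv + 1L, seq_len(L))]
  if (any(naive_fx != 0)) stop("effect of the naive base must be 0 at every position")
  rownames(effects) <- DNA_BASES
  structure(list(naive = toupper(naive), naive_int = nv,
                 effects = effects, frame = as.integer(frame)),
            class = "affinity_map")
}

#' @export
print.affinity_map <- function(x, ...) {
  cat(sprintf("<affinity_map> naive length %d nt, frame %d\n",
              length(x$naive_int), x$frame))
  invisible(x)
}

#' Affinity of sequences under an additive map
#'
#' Sums the tabulated single-variant effects over all positions at which each
#' sequence differs from the naive sequence. Exactly additive and invariant
#' to mutation order; a mutation that is later reverted contributes 0.
#'
#' @param map An [affinity_map()].
#' @param seqs Character vector of sequences, each the same length as the
#'   naive sequence.
#' @return Numeric vector of affinities.
#' @export
affinity_of <- function(map, seqs) {
  stopifnot(inherits(map, "affinity_map"))
  L <- length(map$naive_int)
  vapply(seqs, function(s) {
    v <- seq_to_int(s)
    if (length(v) != L) stop("sequence length does not match the naive sequence")
    sum(map$effects[cbind(v + 1L, seq_len(L))])
  }, numeric(1), USE.NAMES = FALSE)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Is a sequence functional (free of in-frame stop codons)?
#'
#' A sequence is nonfunctional iff its in-frame translation contains a stop
#' codon (TAA/TAG/TGA). A trailing partial codon is ignored. Stop triplets
#' spanning a codon boundary do not count.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param frame 1-based offset of the first codon (default 1).
#' @return Logical vector: `TRUE` for functional sequences.
#' @export
is_functional <- function(seqs, frame = 1L) {
  vapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    starts <- seq.int(frame, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    !any(codons %in% STOP_CODONS)
  }, logical(1), USE.NAMES = FALSE)
}

#' Generate a random functional naive sequence
#'
#' Draws codons uniformly from the 61 non-stop codons, yielding a sequence
#' with no in-frame stop codon. Deterministic under `set.seed()`.
#'
#' @param length Sequence length in nucleotides; must be a multiple of 3.
#' @return Character scalar.
#' @export
random_naive_sequence <- function(length = 60L) {
  if (length %% 3 != 0) stop("length must be a multiple of 3")
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  paste(sample(codons, length / 3, replace = TRUE), collapse = "")
}

#' Synthetic deep-mutational-scan affinity map
#'
#' A stand-in for a real DMS table: each single-nucleotide variant gets an
#' additive effect drawn from a two-component mixture — with probability
#' `deleterious_fraction` a negative exponential effect (scale
#' `effect_scale`), otherwise a positive exponential effect (scale
#' `beneficial_scale`). Most mutations therefore hurt binding while a
#' minority improve it, so random mutants have negative mean affinity with a
#' right tail reaching roughly +1 to +3 at a handful of mutations.
#' Deterministic under `set.seed()`.
#'
#' @param naive Naive sequence; by default a [random_naive_sequence()] of
#'   `length` nt is drawn.
#' @param length Length used when `naive` is not supplied.
#' @param effect_scale Scale of deleterious effects (affinity units).
#' @param beneficial_scale Scale of beneficial effects.
#' @param deleterious_fraction Probability that a variant is deleterious.
#' @return An [affinity_map()].
#' @export
synthetic_dms_map <- function(naive = NULL, length = 60L, effect_scale = 1.8,
                              beneficial_scale = 0.7, deleterious_fraction = 0.75) {
  if (is.null(naive)) naive <- random_naive_sequence(length)
  nv <- seq_to_int(naive)
  L <- length(nv)
  eff <- matrix(0, 4, L)
  n_var <- 3L * L
  sign_del <- stats::runif(n_var) < deleterious_fraction
  mag <- ifelse(sign_del, -stats::rexp(n_var, 1 / effect_scale),
                stats::rexp(n_var, 1 / beneficial_scale))
  k <- 0L
  for (pos in seq_len(L)) {
    for (b in 0:3) {
      if (b == nv[pos]) next
      k <- k + 1L
      eff[b + 1L, pos] <- mag[k]
    }
  }
  affinity_map(naive, eff)
}

#' Write/read an affinity map
#'
#' The effect table is stored as CSV with columns `position` (0-based),
#' `alt_base` and `effect`; the naive sequence is stored as FASTA alongside.
#'
#' @param map An [affinity_map()].
#' @param csv_path Path for the effect-table CSV.
#' @param fasta_path Path for the naive-sequence FASTA.
#' @return `read_affinity_map()` returns an [affinity_map()].
#' @export
write_affinity_map <- function(map, csv_path, fasta_path) {
  stopifnot(inherits(map, "affinity_map"))
  L <- length(map$naive_int)
  rows <- do.call(rbind, lapply(seq_len(L), function(pos) {
    alts <- setdiff(0:3, map$naive_int[pos])
    data.frame(position = pos - 1L, alt_base = DNA_BASES[alts + 1L],
               effect = map$effects[cbind(alts + 1L, pos)])
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  ss <- Biostrings::DNAStringSet(stats::setNames(map$naive, "naive"))
  Biostrings::writeXStringSet(ss, fasta_path)
  invisible(csv_path)
}

#' @rdname write_affinity_map
#' @export
read_affinity_map <- function(csv_path, fasta_path, frame = 1L) {
  naive <- as.character(Biostrings::readDNAStringSet(fasta_path)[[1]])
  tab <- utils::read.csv(csv_path)
  nv <- seq_to_int(naive)
  eff <- matrix(0, 4, length(nv))
  eff[cbind(match(tab$alt_base, DNA_BASES), tab$position + 1L)] <- tab$effect
  affinity_map(naive, eff, frame = frame)
}
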