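#' Annotated tree
#'
#' A rooted tree with branch lengths, per-node sequences and affinities, in
#' parent-pointer form. Node 1 is the root (the naive sequence, affinity 0);
#' `parent` is 0 for the root; `depth` is the root-to-node path length.
#'
#' @param parent Integer vector of parent ids (0 for the root).
#' @param brlen Numeric branch lengths (root entry 0).
#' @param affinity Per-node affinities.
#' @param sequence Per-node nucleotide sequences (may be NA).
#' @param label Node labels (tips must be labelled).
#' @param is_tip Logical: is the node a leaf?
#' @return An object of class `annotated_tree` (a tibble of nodes).
#' @export
annotated_tree <- function(parent, brlen, affinity, sequence = NA_character_,
                           label = NA_character_, is_tip = NULL) {
  n <- length(parent)
  if (is.null(is_tip)) is_tip <- !(seq_len(n) %in% parent)
  depth <- numeric(n)
  ord <- order(seq_len(n))  # parents are created before children by contract
  for (i in seq_len(n)) {
    depth[i] <- if (parent[i] == 0) 0 else depth[parent[i]] + brlen[i]
  }
  out <- tibble::tibble(id = seq_len(n), parent = as.integer(parent),
                        brlen = as.numeric(brlen), depth = depth,
                        affinity = as.numeric(affinity),
                        sequence = rep_len(as.character(sequence), n),
                        label = rep_len(as.character(label), n),
                        is_tip = is_tip)
  class(out) <- c("annotated_tree", class(out))
  out
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf("<annotated_tree> %d tips, %d internal nodes, mean tip depth %.4g\n",
              sum(x$is_tip), sum(!x$is_tip), mean(x$depth[x$is_tip])))
  invisible(x)
}

#' Write sampled sequences plus the naive outgroup as FASTA
#'
#' Duplicate sequences are preserved as distinct records (their abundance
#' matters for summary statistics); the naive outgroup record is appended
#' last under the name `naive`.
#'
#' @param seqs Named (or unnamed) character vector of sampled sequences.
#' @param naive The naive outgroup sequence.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_gc_fasta <- function(seqs, naive, path) {
  if (length(seqs) == 0) stop("empty sample")
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("cell", seq_along(seqs))
  ss <- Biostrings::DNAStringSet(stats::setNames(c(unname(seqs), naive), c(nm, "naive")))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Nearest surviving ancestor helper used during pruning/collapsing
.walk_up <- function(i, parent, surviving) {
  j <- parent[i]
  while (j > 0 && !surviving[j]) j <- parent[j]
  j
}

#' Desk-scale tree adapter: prune, deduplicate, collapse, convert
#'
#' Converts a simulated genealogy into the kind of tree sequence-based
#' inference would produce, without any external program:
#' \enumerate{
#'   \item prunes to the sampled tips and their ancestry;
#'   \item collapses duplicate sampled sequences into a single representative
#'     tip (trees built from observed sequences carry one leaf per unique
#'     sequence; abundance is kept in the sample, not the tree);
#'   \item removes unobservable unifurcations (mutation events, pruned-away
#'     siblings);
#'   \item collapses zero-length internal edges — notably the instantaneous
#'     naive expansion — and deterministically re-binarizes the resulting
#'     polytomies into a caterpillar ordered by child time (descending);
#'   \item converts branch lengths from days to expected substitutions per
#'     site using each branch's parent-sequence SHM rate;
#'   \item annotates every node with its affinity from its sequence.
#' }
#'
#' @param tree A `gc_tree` from [run_gc_simulation()].
#' @param dedup Collapse duplicate sampled sequences (default TRUE).
#' @param units `"subs"` (expected substitutions/site, default) or `"time"`.
#' @return An [annotated_tree()].
#' @export
true_tree_fallback <- function(tree, dedup = TRUE, units = c("subs", "time")) {
  stopifnot(inherits(tree, "gc_tree"))
  units <- match.arg(units)
  nd <- tree$nodes
  n_all <- nrow(nd)
  sampled <- tree$sampled
  if (length(sampled) == 0) stop("tree has no sampled tips")
  seqs_samp <- node_sequences(tree, sampled)
  reps <- if (dedup) sampled[!duplicated(unname(seqs_samp))] else sampled

  keep <- logical(n_all)
  for (id in reps) {
    i <- id
    while (i > 0 && !keep[i]) { keep[i] <- TRUE; i <- nd$parent[i] }
  }

  is_rep <- logical(n_all); is_rep[reps] <- TRUE
  kept_child_count <- tabulate(nd$parent[keep], nbins = n_all)
  # survivors: representative tips, kept nodes with >= 2 kept children, root
  surv <- keep & (is_rep | kept_child_count >= 2 | nd$parent == 0)

  # splice unifurcation chains: each survivor's parent = nearest surviving
  # proper ancestor
  sparent <- integer(n_all)
  for (i in which(surv)) sparent[i] <- .walk_up(i, nd$parent, surv)

  # collapse zero-length internal edges (merge into the oldest equal-time
  # surviving ancestor); tips are never merged away
  # node times are event times: an internal node's time is when it split
  # (its end), a sampled tip sits at the sampling time
  tvec <- nd$end_time
  eps <- 1e-12
  zrep <- seq_len(n_all)  # merged-into representative
  for (i in which(surv)) {
    if (is_rep[i] || sparent[i] == 0) next
    j <- i
    while (sparent[j] > 0 && (tvec[i] - tvec[sparent[j]]) <= eps) j <- sparent[j]
    zrep[i] <- j
  }
  merged_away <- surv & (zrep != seq_len(n_all))
  fin <- surv & !merged_away
  fparent <- integer(n_all)
  for (i in which(fin)) fparent[i] <- if (sparent[i] == 0) 0L else zrep[sparent[i]]

  # assemble children lists on final nodes
  fin_ids <- which(fin)
  root <- fin_ids[fparent[fin_ids] == 0]
  if (length(root) != 1) stop("internal error: tree must have exactly one root")
  children <- split(fin_ids[fparent[fin_ids] != 0], fparent[fin_ids][fparent[fin_ids] != 0])

  # sequences and times on final original nodes
  seq_fin <- node_sequences(tree, fin_ids)
  time_fin <- stats::setNames(tvec[fin_ids], fin_ids)

  # build output arrays, binarizing polytomies into caterpillars
  o_parent <- integer(0); o_time <- numeric(0); o_seq <- character(0)
  o_label <- character(0); o_tip <- logical(0)
  add_node <- function(par, tm, sq, lab, tip) {
    o_parent[length(o_parent) + 1L] <<- par
    o_time[length(o_time) + 1L] <<- tm
    o_seq[length(o_seq) + 1L] <<- sq
    o_label[length(o_label) + 1L] <<- lab
    o_tip[length(o_tip) + 1L] <<- tip
    length(o_parent)
  }
  naive_seq <- tree$naive
  emit <- function(orig_id, new_parent) {
    oid <- as.character(orig_id)
    tip <- is_rep[orig_id]
    lab <- if (tip) paste0("cell", orig_id) else NA_character_
    if (orig_id == root && identical(o_parent, integer(0))) lab <- "naive"
    me <- add_node(new_parent, time_fin[[oid]], seq_fin[[oid]], lab, tip)
    kids <- children[[oid]]
    if (!is.null(kids) && length(kids)) {
      ord <- order(-time_fin[as.character(kids)], kids)
      kids <- kids[ord]
      hang <- me
      while (length(kids) > 2) {
        emit(kids[1], hang)
        hang <- add_node(hang, o_time[hang], o_seq[hang], NA_character_, FALSE)
        kids <- kids[-1]
      }
      for (k in kids) emit(k, hang)
    }
    me
  }
  emit(root, 0L)

  # branch lengths: time difference, optionally converted to expected
  # substitutions/site via the parent sequence's SHM rate
  n_out <- length(o_parent)
  brlen <- numeric(n_out)
  L <- nchar(naive_seq)
  for (i in seq_len(n_out)) {
    if (o_parent[i] == 0) next
    dt <- o_time[i] - o_time[o_parent[i]]
    if (units == "subs") {
      rate <- sequence_mutation_rate(tree$shm, o_seq[o_parent[i]]) *
        tree$config$mutability_multiplier / tree$shm$multiplier
      brlen[i] <- dt * rate / L
    } else {
      brlen[i] <- dt
    }
  }
  aff <- affinity_of(tree$map, o_seq)
  nmut <- vapply(o_seq, function(s) {
    sum(seq_to_int(s) != tree$map$naive_int)
  }, integer(1), USE.NAMES = FALSE)
  at <- annotated_tree(o_parent, brlen, aff, o_seq, o_label, o_tip)
  at$n_mut <- nmut
  attr(at, "naive") <- naive_seq
  at
}

#' Convert an annotated tree to an ape "phylo" object
#'
#' Tip labels are kept; node labels carry the affinity so that newick
#' round-trips preserve the annotation.
#'
#' @param x An [annotated_tree()].
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @export
as.phylo.annotated_tree <- function(x, ...) {
  tips <- which(x$is_tip)
  internals <- which(!x$is_tip)
  n_tip <- length(tips)
  newid <- integer(nrow(x))
  newid[tips] <- seq_len(n_tip)
  # ape convention: root is n_tip + 1
  internals <- c(internals[internals == 1], internals[internals != 1])
  newid[internals] <- n_tip + seq_along(internals)
  edge <- cbind(newid[x$parent[x$parent != 0]], newid[x$id[x$parent != 0]])
  phy <- structure(list(
    edge = edge,
    edge.length = x$brlen[x$parent != 0],
    Nnode = length(internals),
    tip.label = ifelse(is.na(x$label[tips]), paste0("t", tips), x$label[tips]),
    node.label = sprintf("aff=%.17g", x$affinity[internals])),
    class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy)
}

#' Write/read an annotated tree as newick
#'
#' Affinities ride along in the labels (`aff=` prefix on internal nodes,
#' `|aff=` suffix on tips), so topology, branch lengths and the affinity
#' annotation survive a round trip.
#'
#' @param x An [annotated_tree()].
#' @param path Newick file path.
#' @return `read_annotated_newick()` returns an [annotated_tree()] (without
#'   sequences, which newick does not carry).
#' @export
write_annotated_newick <- function(x, path) {
  stopifnot(inherits(x, "annotated_tree"))
  phy <- as.phylo.annotated_tree(x)
  tips <- which(x$is_tip)
  phy$tip.label <- sprintf("%s|aff=%.17g",
                           ifelse(is.na(x$label[tips]), paste0("t", tips), x$label[tips]),
                           x$affinity[tips])
  ape::write.tree(phy, file = path, digits = 17)
  invisible(path)
}

#' @rdname write_annotated_newick
#' @export
read_annotated_newick <- function(path) {
  phy <- ape::read.tree(path)
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  # rebuild parent-pointer form with root first, parents before children
  parent_of <- integer(n_tip + n_node)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  blen_of <- numeric(n_tip + n_node)
  blen_of[phy$edge[, 2]] <- phy$edge.length
  root_ape <- n_tip + 1L
  ordv <- integer(0)
  stack <- root_ape
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    ordv <- c(ordv, v)
    kv <- kids[[as.character(v)]]
    if (!is.null(kv)) stack <- c(stack, kv)
  }
  newid <- integer(n_tip + n_node); newid[ordv] <- seq_along(ordv)
  parse_aff <- function(s) as.numeric(sub("^.*aff=", "", s))
  aff_ape <- c(parse_aff(phy$tip.label),
               ifelse(grepl("aff=", c(phy$node.label)), parse_aff(phy$node.label), 0))
  lab_ape <- c(sub("\\|aff=.*$", "", phy$tip.label), rep(NA_character_, n_node))
  tip_ape <- c(rep(TRUE, n_tip), rep(FALSE, n_node))
  o <- ordv
  annotated_tree(parent = ifelse(parent_of[o] == 0, 0L, newid[parent_of[o]]),
                 brlen = blen_of[o], affinity = aff_ape[o],
                 label = lab_ape[o], is_tip = tip_ape[o])
}

#' Maximum-likelihood tree inference through an external program
#'
#' Thin wrapper around an IQ-TREE-style command line: writes the alignment,
#' infers a tree with ancestral sequence reconstruction, roots on the naive
#' outgroup and annotates all nodes with affinities under `map`. The
#' external binary is optional; when it is not on the PATH an error directs
#' the caller to [true_tree_fallback()], which all desk-scale analyses use.
#'
#' @param fasta_path Alignment FASTA including a `naive` outgroup record.
#' @param map An [affinity_map()] for node annotation.
#' @param tool Name or path of the external binary (default `"iqtree"`).
#' @param args Extra command-line arguments.
#' @param seed Seed forwarded to the external program.
#' @return An [annotated_tree()].
#' @export
infer_tree_external <- function(fasta_path, map, tool = "iqtree",
                                args = character(), seed = 1L) {
  exe <- Sys.which(tool)
  if (!nzchar(exe)) {
    stop("external tool unavailable: '", tool,
         "' not found on PATH; use true_tree_fallback() for simulated trees")
  }
  status <- system2(exe, c("-s", fasta_path, "-o", "naive", "-asr",
                           "-seed", seed, "-redo", args),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("external tree inference failed with status ", status)
  treefile <- paste0(fasta_path, ".treefile")
  if (!file.exists(treefile)) stop("parse failure: expected output ", treefile, " not found")
  phy <- ape::read.tree(treefile)
  phy <- ape::root(phy, outgroup = "naive", resolve.root = TRUE)
  obs <- Biostrings::readDNAStringSet(fasta_path)
  statefile <- paste0(fasta_path, ".state")
  anc <- NULL
  if (file.exists(statefile)) {
    st <- utils::read.table(statefile, header = TRUE, comment.char = "#")
    anc <- vapply(split(st$State, st$Node), paste, character(1), collapse = "")
  }
  n_tip <- length(phy$tip.label)
  seqs <- c(as.character(obs[phy$tip.label]),
            if (!is.null(anc)) unname(anc[phy$node.label]) else rep(NA, phy$Nnode))
  tmp <- tempfile(fileext = ".nwk")
  on.exit(unlink(tmp), add = TRUE)
  ape::write.tree(phy, file = tmp)
  at <- read_annotated_newick(tmp)
  at$affinity <- ifelse(is.na(seqs), 0, affinity_of(map, ifelse(is.na(seqs), map$naive, seqs)))
  at
}
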