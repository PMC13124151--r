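# Children lists keyed by parent id, for an annotated_tree
.child_list <- function(tree) {
  has_par <- tree$parent != 0
  split(tree$id[has_par], tree$parent[has_par])
}

#' Ladderize with deterministic tiebreakers
#'
#' Orders the children of every internal node so that iteration over the tree
#' is repeatable and one-to-one: children are sorted primarily by their node
#' time (root distance), descending, so that longer branches end up toward
#' the left; ties are broken by the time of the immediate ancestral node,
#' then by affinity (both descending). A remaining exact tie raises an error
#' naming the tied nodes — such a tie would make the encoding ambiguous.
#'
#' @param tree An [annotated_tree()].
#' @return The tree with an added `order` column giving each node's rank
#'   among its siblings, and attribute `ladderized = TRUE`.
#' @export
ladderize_with_tiebreakers <- function(tree) {
  stopifnot(inherits(tree, "annotated_tree"))
  kids <- .child_list(tree)
  ordcol <- integer(nrow(tree))
  ordcol[tree$parent == 0] <- 1L
  for (p in names(kids)) {
    ch <- kids[[p]]
    if (length(ch) == 1) { ordcol[ch] <- 1L; next }
    key <- cbind(-tree$depth[ch], -tree$depth[tree$parent[ch]], -tree$affinity[ch])
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (any(dup)) {
      stop("encoding tie: nodes ", paste(ch[dup], collapse = ", "),
           " are identical in time, parent time and affinity")
    }
    o <- order(key[, 1], key[, 2], key[, 3])
    ordcol[ch[o]] <- seq_along(ch)
  }
  tree$order <- ordcol
  attr(tree, "ladderized") <- TRUE
  tree
}

#' Scale a tree to mean unit depth
#'
#' Divides every branch length by the mean root-to-leaf distance, so the
#' scaled tree has mean leaf depth exactly 1. Idempotent after the first
#' application. Facilitates comparison across trees of different depths.
#'
#' @param tree An [annotated_tree()].
#' @return The rescaled tree.
#' @export
scale_to_unit_depth <- function(tree) {
  stopifnot(inherits(tree, "annotated_tree"))
  md <- mean(tree$depth[tree$is_tip])
  if (!is.finite(md) || md <= 0) stop("mean leaf depth must be positive")
  tree$brlen <- tree$brlen / md
  tree$depth <- tree$depth / md
  tree
}

#' Encode a tree as an affinity-augmented CBLV matrix
#'
#' Traverses the ladderized tree inorder (left subtree, node, right subtree).
#' Each visited leaf appends its distance to the most-recently-visited
#' internal node (the root before any internal node has been visited) to row
#' 1; each internal node appends its distance to the root to row 2. Rows 3
#' and 4 carry the corresponding node's affinity at the same column index as
#' its distance. Leaf and internal entries advance independent column
#' counters; the matrix is zero-padded to width `width`.
#'
#' @param tree A ladderized, (typically unit-depth-scaled) [annotated_tree()].
#' @param width Matrix width W (default 200); the tree must have at most W
#'   leaves and at most W internal nodes.
#' @return An object of class `encoded_tree`: a 4 x `width` matrix with
#'   attributes `n_leaf` and `n_internal` (the fill counters).
#' @export
encode_tree <- function(tree, width = 200L) {
  stopifnot(inherits(tree, "annotated_tree"))
  if (!isTRUE(attr(tree, "ladderized"))) tree <- ladderize_with_tiebreakers(tree)
  n_leaf_tot <- sum(tree$is_tip)
  n_int_tot <- sum(!tree$is_tip)
  if (n_leaf_tot > width || n_int_tot > width) {
    stop("tree has more than ", width, " leaves or internal nodes; increase width")
  }
  kids <- .child_list(tree)
  mat <- matrix(0, 4, width)
  i_leaf <- 0L; i_int <- 0L
  last_internal_depth <- 0  # root depth before any internal node is visited
  root <- tree$id[tree$parent == 0]
  visit <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch) || length(ch) == 0) {
      i_leaf <<- i_leaf + 1L
      mat[1, i_leaf] <<- tree$depth[v] - last_internal_depth
      mat[3, i_leaf] <<- tree$affinity[v]
      return(invisible())
    }
    ch <- ch[order(tree$order[ch])]
    visit(ch[1])
    i_int <<- i_int + 1L
    mat[2, i_int] <<- tree$depth[v]
    mat[4, i_int] <<- tree$affinity[v]
    last_internal_depth <<- tree$depth[v]
    for (k in ch[-1]) visit(k)
  }
  visit(root)
  structure(mat, n_leaf = i_leaf, n_internal = i_int, class = "encoded_tree")
}

#' @export
print.encoded_tree <- function(x, ...) {
  cat(sprintf("<encoded_tree> 4 x %d, %d leaves, %d internal nodes\n",
              ncol(x), attr(x, "n_leaf"), attr(x, "n_internal")))
  invisible(x)
}

#' Encode a list of trees
#'
#' Applies unit-depth scaling, ladderization and [encode_tree()] to each
#' tree and stacks the matrices into an array.
#'
#' @param trees List of [annotated_tree()] objects.
#' @param width Matrix width.
#' @param scale Apply [scale_to_unit_depth()] first (default TRUE).
#' @return An object of class `encoded_set`: an `n x 4 x width` array with a
#'   `fills` attribute (n x 2 matrix of leaf/internal counts).
#' @export
encode_trees <- function(trees, width = 200L, scale = TRUE) {
  n <- length(trees)
  arr <- array(0, c(n, 4, width))
  fills <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    tr <- trees[[i]]
    if (scale) tr <- scale_to_unit_depth(tr)
    enc <- encode_tree(tr, width)
    arr[i, , ] <- enc
    fills[i, ] <- c(attr(enc, "n_leaf"), attr(enc, "n_internal"))
  }
  structure(arr, fills = fills, class = "encoded_set")
}

#' Fit the input standardizer
#'
#' Computes, over a training set, the affine transforms taking each variable
#' group to mean 0 and variance 1: one transform for all branch-length
#' entries (rows 1-2), one for all affinity entries (rows 3-4), and one per
#' non-sigmoid parameter. Statistics are computed over real (non-padding)
#' entries only, and padding zeros are re-inserted after standardization so
#' they remain exactly 0.
#'
#' @param encoded An `encoded_set` from [encode_trees()].
#' @param nonsigmoid An n x k matrix of non-sigmoid parameter values (one
#'   row per tree).
#' @return An object of class `encoding_scaler`.
#' @export
fit_standardizer <- function(encoded, nonsigmoid) {
  stopifnot(inherits(encoded, "encoded_set"))
  fills <- attr(encoded, "fills")
  n <- dim(encoded)[1]; W <- dim(encoded)[3]
  mask_leaf <- outer(fills[, 1], seq_len(W), ">=")
  mask_int <- outer(fills[, 2], seq_len(W), ">=")
  bl <- c(encoded[, 1, ][mask_leaf], encoded[, 2, ][mask_int])
  af <- c(encoded[, 3, ][mask_leaf], encoded[, 4, ][mask_int])
  grp <- function(v, nm) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero variance in group ", nm)
    c(mean = mean(v), sd = s)
  }
  ns_stats <- apply(nonsigmoid, 2, grp, nm = "nonsigmoid")
  structure(list(branch = grp(bl, "branch lengths"), affinity = grp(af, "affinities"),
                 nonsigmoid = ns_stats),
            class = "encoding_scaler")
}

#' Apply a fitted standardizer
#'
#' Standardizes real entries with the stored training-set transforms;
#' padding stays exactly 0. The returned set carries the attribute
#' `standardized = TRUE`, which the network's predict step requires.
#'
#' @param scaler An `encoding_scaler` from [fit_standardizer()].
#' @param encoded An `encoded_set`.
#' @param nonsigmoid Matrix of non-sigmoid values to standardize alongside
#'   (optional).
#' @return A list with elements `encoded` (standardized `encoded_set`) and
#'   `nonsigmoid` (standardized matrix or NULL).
#' @export
apply_standardizer <- function(scaler, encoded, nonsigmoid = NULL) {
  stopifnot(inherits(scaler, "encoding_scaler"), inherits(encoded, "encoded_set"))
  fills <- attr(encoded, "fills")
  W <- dim(encoded)[3]
  mask_leaf <- outer(fills[, 1], seq_len(W), ">=")
  mask_int <- outer(fills[, 2], seq_len(W), ">=")
  out <- encoded
  std <- function(x, st) (x - st[["mean"]]) / st[["sd"]]
  for (r in 1:2) {
    msk <- if (r == 1) mask_leaf else mask_int
    v <- out[, r, ]; v[msk] <- std(v[msk], scaler$branch); v[!msk] <- 0
    out[, r, ] <- v
    v <- out[, r + 2, ]; v[msk] <- std(v[msk], scaler$affinity); v[!msk] <- 0
    out[, r + 2, ] <- v
  }
  ns <- NULL
  if (!is.null(nonsigmoid)) {
    nonsigmoid <- as.matrix(nonsigmoid)
    ns <- sweep(sweep(nonsigmoid, 2, scaler$nonsigmoid["mean", ]), 2,
                scaler$nonsigmoid["sd", ], "/")
  }
  attr(out, "standardized") <- TRUE
  list(encoded = out, nonsigmoid = ns)
}

#' Write/read a standardizer as YAML
#'
#' @param scaler An `encoding_scaler`.
#' @param path File path.
#' @return `read_standardizer()` returns an `encoding_scaler`.
#' @export
write_standardizer <- function(scaler, path) {
  yaml::write_yaml(list(branch = as.list(scaler$branch),
                        affinity = as.list(scaler$affinity),
                        nonsigmoid = apply(scaler$nonsigmoid, 2, as.list)),
                   path)
  invisible(path)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  y <- yaml::read_yaml(path)
  ns <- sapply(y$nonsigmoid, function(g) c(mean = g$mean, sd = g$sd))
  structure(list(branch = unlist(y$branch), affinity = unlist(y$affinity),
                 nonsigmoid = ns),
            class = "encoding_scaler")
}
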