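# Neighbor joining, bootstrap supports and cluster monophyly tests.

#' Neighbor-joining tree construction
#'
#' Standard Saitou-Nei agglomeration from a symmetric distance matrix.
#' Ties in the Q criterion are broken by the smallest (row, column) index
#' pair of the current matrix, so the output is fully deterministic.
#' Negative branch lengths are clamped to zero with the deficit moved to the
#' sister branch (the pairwise sum is preserved); at the final trifurcation
#' negative lengths are clamped to zero.
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/column
#'   names, n >= 3. A `dist` object is accepted.
#' @return Unrooted tree of class `phylo` (ape), with branch lengths.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(d)  # branches 1, 1, 3
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa",
                         call. = FALSE)
  if (anyNA(d) || any(!is.finite(d)))
    stop("distance matrix contains NA/NaN/Inf", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  # each active node is a newick fragment
  node <- labels
  D <- d
  fmt <- function(x) sprintf("%.10g", x)
  while (length(node) > 3L) {
    n <- length(node)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    qmin <- min(Q)
    hits <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_node <- paste0("(", node[i], ":", fmt(li), ",",
                       node[j], ":", fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    node <- c(node[keep], new_node)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }
  la <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", node[1L], ":", fmt(la), ",", node[2L], ":", fmt(lb),
                ",", node[3L], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

# All non-trivial bipartitions of an unrooted phylo tree, as canonical keys:
# the sorted tip labels of the side NOT containing the reference tip (the
# lexicographically smallest label), collapsed with "|".
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1L]
  n <- length(tips)
  root <- n + 1L
  internal <- setdiff(unique(tree$edge[, 1L]), root)
  keys <- character(0)
  for (nd in internal) {
    side <- tips[descendant_tips(tree, nd)]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= n_tip) out <- c(out, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1L] == nd, 2L])
  }
  out
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the NJ tree from p-distances over the columns of a multiple
#' alignment, then resamples alignment columns with replacement `n_reps`
#' times; the support of each internal edge is the fraction of replicate NJ
#' trees containing the same bipartition.
#'
#' @param columns Character matrix (rows = taxa with rownames, columns =
#'   alignment columns, gaps as `"-"`); at least 2 columns and 3 taxa.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed for reproducible resampling.
#' @return `phylo` tree; `$node.label` holds the support (fraction in
#'   \[0,1\]) of the edge above each internal node (`NA` for the root).
#' @export
bootstrap_support <- function(columns, n_reps = 100, seed = NULL) {
  stopifnot(is.matrix(columns), !is.null(rownames(columns)))
  if (ncol(columns) < 2L)
    stop("bootstrap needs at least 2 alignment columns", call. = FALSE)
  if (nrow(columns) < 3L)
    stop("bootstrap needs at least 3 taxa", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  main <- neighbor_joining(alignment_pdist(columns))
  counts <- setNames(numeric(length(tree_bipartitions(main))),
                     tree_bipartitions(main))
  for (b in seq_len(n_reps)) {
    idx <- sample.int(ncol(columns), replace = TRUE)
    rep_tree <- neighbor_joining(alignment_pdist(columns[, idx,
                                                         drop = FALSE]))
    rk <- tree_bipartitions(rep_tree)
    hit <- names(counts) %in% rk
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / n_reps
  # attach per-internal-node labels
  tips <- main$tip.label
  ref <- sort(tips)[1L]
  n_tip <- length(tips)
  root <- n_tip + 1L
  labs <- rep(NA_real_, main$Nnode)
  for (nd in setdiff(unique(main$edge[, 1L]), root)) {
    side <- tips[descendant_tips(main, nd)]
    if (length(side) <= 1L || length(side) >= n_tip - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    labs[nd - n_tip] <- support[[key]]
  }
  main$node.label <- labs
  main
}

#' Test whether a gene cluster nests together on a tree
#'
#' A cluster nests (is consistent with origin by tandem duplication) when
#' its members form a monophyletic group on the unrooted tree, i.e. some
#' bipartition separates exactly the members from all other leaves.
#' Single-member sets and sets covering all but at most one leaf are
#' trivially monophyletic.
#'
#' @param tree `phylo` object.
#' @param members Character vector of tip labels; all must be in the tree.
#' @return Logical scalar.
#' @export
cluster_nesting <- function(tree, members) {
  tips <- tree$tip.label
  missing <- setdiff(members, tips)
  if (length(missing))
    stop("cluster member(s) not in tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  members <- unique(members)
  n <- length(tips)
  if (length(members) <= 1L || length(members) >= n - 1L) return(TRUE)
  ref <- sort(tips)[1L]
  side <- if (ref %in% members) setdiff(tips, members) else members
  key <- paste(sort(side), collapse = "|")
  key %in% tree_bipartitions(tree)
}
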