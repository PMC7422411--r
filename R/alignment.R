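# Pairwise and progressive alignment on top of the Gotoh C++ core.

.nlr_env <- new.env(parent = emptyenv())

#' Substitution matrices
#'
#' `blosum62()` returns the BLOSUM62 matrix shipped with Biostrings;
#' `uniform_matrix()` builds a simple match/mismatch matrix over a given
#' alphabet. Both are accepted by [align_pair()].
#'
#' @return Numeric square matrix with identical row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.nlr_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .nlr_env$BLOSUM62 <- e$BLOSUM62
  }
  .nlr_env$BLOSUM62
}

#' @rdname blosum62
#' @param alphabet Character vector of single letters.
#' @param match,mismatch Scores for identical / differing letters.
#' @export
uniform_matrix <- function(alphabet, match = 1, mismatch = 0) {
  n <- length(alphabet)
  m <- matrix(mismatch, n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

# Encode a sequence as 0-based indices into the matrix alphabet; unknown
# residues map to 'X' (with a warning) when the alphabet has one.
encode_seq <- function(seq, alphabet) {
  ch <- strsplit(seq, "")[[1L]]
  idx <- match(ch, alphabet)
  if (anyNA(idx)) {
    if (!"X" %in% alphabet)
      stop("sequence contains symbols outside the scoring alphabet: ",
           paste(unique(ch[is.na(idx)]), collapse = ""), call. = FALSE)
    nlr_warn("%d non-standard residue(s) treated as X", sum(is.na(idx)))
    idx[is.na(idx)] <- match("X", alphabet)
  }
  idx - 1L
}

#' Optimal pairwise alignment with affine gap penalties
#'
#' Computes the optimal global (Needleman-Wunsch style) or local
#' (Smith-Waterman style) alignment under affine gap costs: a gap of length
#' `k` costs `gap_open + k * gap_extend`. Percent identity is computed over
#' aligned columns *including* gap columns by default (set
#' `denominator = "shorter"` to divide by the shorter sequence length
#' instead).
#'
#' @param seq_a,seq_b Non-empty character scalars (protein sequences).
#' @param mode `"global"` (default) or `"local"`.
#' @param matrix Substitution matrix (named square numeric matrix); default
#'   [blosum62()].
#' @param gap_open,gap_extend Positive gap penalties (defaults 10 and 1).
#' @param denominator `"columns"` (default) or `"shorter"`.
#' @param id_a,id_b Optional sequence identifiers carried into the result.
#' @return Object of class `pairwise_alignment`: a list with `id_a`, `id_b`,
#'   `score`, `aligned_a`, `aligned_b` (gap = `-`), `aligned_cols`,
#'   `identities`, `pct_identity`.
#' @examples
#' a <- align_pair("MKV", "MQV", matrix = uniform_matrix(LETTERS),
#'                 gap_open = 10, gap_extend = 1)
#' a$pct_identity  # 66.67
#' @export
align_pair <- function(seq_a, seq_b, mode = c("global", "local"),
                       matrix = blosum62(), gap_open = 10, gap_extend = 1,
                       denominator = c("columns", "shorter"),
                       id_a = "a", id_b = "b") {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("cannot align an empty sequence", call. = FALSE)
  alphabet <- rownames(matrix)
  ea <- encode_seq(toupper(seq_a), alphabet)
  eb <- encode_seq(toupper(seq_b), alphabet)
  r <- .gotoh_align_int(ea, eb, matrix, gap_open, gap_extend,
                        mode == "local")
  ca <- strsplit(toupper(seq_a), "")[[1L]]
  cb <- strsplit(toupper(seq_b), "")[[1L]]
  acols <- ifelse(is.na(r$a_idx), "-", ca[r$a_idx])
  bcols <- ifelse(is.na(r$b_idx), "-", cb[r$b_idx])
  n_cols <- length(acols)
  ident <- sum(!is.na(r$a_idx) & !is.na(r$b_idx) & acols == bcols)
  denom <- if (denominator == "columns") n_cols
           else min(nchar(seq_a), nchar(seq_b))
  structure(list(
    id_a = id_a, id_b = id_b, score = r$score,
    aligned_a = paste(acols, collapse = ""),
    aligned_b = paste(bcols, collapse = ""),
    a_range = if (n_cols) range(r$a_idx, na.rm = TRUE) else c(NA, NA),
    b_range = if (n_cols) range(r$b_idx, na.rm = TRUE) else c(NA, NA),
    aligned_cols = n_cols, identities = ident,
    pct_identity = if (denom > 0) 100 * ident / denom else NA_real_),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Pairwise alignment %s vs %s: score %.1f, %d cols, %.2f%% identity\n",
              x$id_a, x$id_b, x$score, x$aligned_cols, x$pct_identity))
  invisible(x)
}

#' Bin pairwise identities into similarity classes
#'
#' Assigns each pairwise percent identity to exactly one of the bins
#' `"<50%"` = \[0, 50), `"<75%"` = \[50, 75), `"<100%"` = \[75, 100) and
#' `"100%"` = \{100\} (the scheme used to colour within-cluster similarity
#' edges).
#'
#' @param pct_identity Numeric vector in \[0, 100\].
#' @return Factor with levels `<50%`, `<75%`, `<100%`, `100%`.
#' @export
similarity_bins <- function(pct_identity) {
  stopifnot(all(pct_identity >= 0 & pct_identity <= 100))
  cut(pct_identity, breaks = c(-Inf, 50, 75, 100 - 1e-9, Inf),
      labels = c("<50%", "<75%", "<100%", "100%"), right = FALSE)
}

#' p-distances between the rows of a multiple alignment
#'
#' Fraction of differing columns among columns where neither row is a gap;
#' row pairs with no gapless overlap get distance 1. This is the distance
#' fed to [neighbor_joining()] by [bootstrap_support()].
#'
#' @param mat Character matrix (rows = taxa, gaps as `"-"`).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
alignment_pdist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- mat[i, ] != "-" & mat[j, ] != "-"
    d[i, j] <- d[j, i] <-
      if (!any(use)) 1 else mean(mat[i, use] != mat[j, use])
  }
  d
}

# Insert gap columns into a profile (character matrix) according to the
# alignment of its consensus: keep[i] gives, for each output column, the
# source column index or NA for a new all-gap column.
expand_profile <- function(mat, idx) {
  out <- matrix("-", nrow(mat), length(idx), dimnames = list(rownames(mat)))
  out[, !is.na(idx)] <- mat[, idx[!is.na(idx)], drop = FALSE]
  out
}

profile_consensus <- function(mat) {
  apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return("X")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1L]
  })
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by neighbor joining on pairwise alignment distances
#' and merges sequences progressively (profiles are aligned through their
#' majority-rule consensus sequences using the same affine-gap pairwise
#' core). Intended for within-cluster paralog alignment and for bootstrap
#' column resampling; it is not a general-purpose replacement for a full
#' profile-profile aligner.
#'
#' @param seqs Named character vector of >= 2 sequences.
#' @param matrix,gap_open,gap_extend Passed to [align_pair()].
#' @return Character matrix (rows = sequences, columns = alignment columns),
#'   gaps as `"-"`.
#' @export
progressive_msa <- function(seqs, matrix = blosum62(), gap_open = 10,
                            gap_extend = 1) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  nm <- names(seqs)
  merge_two <- function(ma, mb) {
    al <- align_pair(paste(profile_consensus(ma), collapse = ""),
                     paste(profile_consensus(mb), collapse = ""),
                     matrix = matrix, gap_open = gap_open,
                     gap_extend = gap_extend)
    achars <- strsplit(al$aligned_a, "")[[1L]]
    bchars <- strsplit(al$aligned_b, "")[[1L]]
    a_idx <- cumsum(achars != "-"); a_idx[achars == "-"] <- NA
    b_idx <- cumsum(bchars != "-"); b_idx[bchars == "-"] <- NA
    rbind(expand_profile(ma, a_idx), expand_profile(mb, b_idx))
  }
  as_mat <- function(s, id) {
    matrix(strsplit(s, "")[[1L]], nrow = 1L, dimnames = list(id))
  }
  if (length(seqs) == 2L) {
    m <- merge_two(as_mat(seqs[1L], nm[1L]), as_mat(seqs[2L], nm[2L]))
    return(m[nm, , drop = FALSE])
  }
  # guide distances from pairwise global identities
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- align_pair(seqs[i], seqs[j], matrix = matrix,
                     gap_open = gap_open, gap_extend = gap_extend)
    d[i, j] <- d[j, i] <- 1 - al$pct_identity / 100
  }
  guide <- neighbor_joining(d)
  # postorder merge over the guide tree
  build <- function(node) {
    if (node <= length(guide$tip.label))
      return(as_mat(seqs[guide$tip.label[node]], guide$tip.label[node]))
    kids <- guide$edge[guide$edge[, 1L] == node, 2L]
    m <- build(kids[1L])
    for (k in kids[-1L]) m <- merge_two(m, build(k))
    m
  }
  m <- build(length(guide$tip.label) + 1L)
  m[nm, , drop = FALSE]
}
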