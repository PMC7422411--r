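# Physical NLR gene cluster detection and within-cluster similarity.

#' Detect physical NB-ARC gene clusters
#'
#' Implements the tandem-duplication cluster rule: two NB-ARC genes that are
#' consecutive among NB-ARC genes on a chromosome are linked when (a) the
#' gap between them (start of the downstream gene minus end of the upstream
#' gene) is at most `max_gap_bp` and (b) at most `max_intervening` annotated
#' non-NB-ARC genes lie strictly between them ("fewer than eight additional
#' genes" = at most 7). Clusters are the maximal chains of linked
#' consecutive genes; singletons are not reported.
#'
#' @param genes data.frame with `gene_id`, `chromosome`, `start`, `end`
#'   (all annotated genes; non-NB-ARC genes are used only to count
#'   intervening genes).
#' @param nbarc_gene_ids Character vector of NB-ARC gene identifiers.
#' @param max_gap_bp Maximum allowed gap in bases (default 200000).
#' @param max_intervening Maximum intervening non-NB-ARC genes (default 7).
#' @return data.frame with one row per clustered gene: `cluster_id`,
#'   `chromosome`, `gene_id`, `start`, `end`, `member_rank`, `n_members`,
#'   `span` (bp from first member start to last member end).
#' @export
detect_clusters <- function(genes, nbarc_gene_ids, max_gap_bp = 200000,
                            max_intervening = 7) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(genes)))
  g <- genes
  unnamed <- is.na(g$chromosome) | !nzchar(g$chromosome)
  if (any(unnamed)) {
    nlr_warn("%d gene(s) on unnamed chromosome skipped", sum(unnamed))
    g <- g[!unnamed, ]
  }
  if (!identical(order(g$chromosome, g$start), seq_len(nrow(g))))
    nlr_warn("gene table not sorted by chromosome and start; sorting")
  g <- g[order(g$chromosome, g$start, g$end, g$gene_id), ]
  g$is_nbarc <- g$gene_id %in% nbarc_gene_ids

  res <- list()
  cluster_counter <- 0L
  for (chr in unique(g$chromosome)) {
    gc <- g[g$chromosome == chr, , drop = FALSE]
    idx <- which(gc$is_nbarc)
    if (length(idx) < 2L) next
    linked <- logical(length(idx) - 1L)
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      gap <- gc$start[j] - gc$end[i]
      intervening <- (j - i - 1L)  # consecutive NB-ARC genes: all between
                                   # are non-NB-ARC by construction
      linked[k] <- gap <= max_gap_bp && intervening <= max_intervening
    }
    # maximal runs of linked consecutive pairs
    k <- 1L
    while (k <= length(linked)) {
      if (linked[k]) {
        end_k <- k
        while (end_k < length(linked) && linked[end_k + 1L]) end_k <- end_k + 1L
        members <- idx[k:(end_k + 1L)]
        cluster_counter <- cluster_counter + 1L
        res[[length(res) + 1L]] <- data.frame(
          cluster_id = sprintf("cluster_%04d", cluster_counter),
          chromosome = chr,
          gene_id = gc$gene_id[members],
          start = gc$start[members], end = gc$end[members],
          member_rank = seq_along(members),
          n_members = length(members),
          span = max(gc$end[members]) - min(gc$start[members]) + 1L,
          stringsAsFactors = FALSE)
        k <- end_k + 2L
      } else k <- k + 1L
    }
  }
  if (length(res) == 0L)
    return(data.frame(cluster_id = character(), chromosome = character(),
                      gene_id = character(), start = integer(),
                      end = integer(), member_rank = integer(),
                      n_members = integer(), span = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise identity matrix within a gene cluster
#'
#' Runs [align_pair()] (global, affine gaps) over all member pairs and
#' returns the symmetric percent-identity matrix plus the binned edge list
#' used for similarity visualisation.
#'
#' @param sequences Named character vector of member protein sequences.
#' @param ... Passed to [align_pair()].
#' @return List with `pct_identity` (symmetric matrix, diagonal 100),
#'   `edges` (data.frame `id_a`, `id_b`, `score`, `pct_identity`, `bin`).
#' @export
cluster_identity <- function(sequences, ...) {
  n <- length(sequences)
  nm <- names(sequences)
  stopifnot(!is.null(nm), n >= 2L)
  m <- matrix(100, n, n, dimnames = list(nm, nm))
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- align_pair(sequences[[i]], sequences[[j]],
                     id_a = nm[i], id_b = nm[j], ...)
    m[i, j] <- m[j, i] <- al$pct_identity
    edges[[length(edges) + 1L]] <- data.frame(
      id_a = nm[i], id_b = nm[j], score = al$score,
      pct_identity = al$pct_identity, stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  edges$bin <- similarity_bins(edges$pct_identity)
  list(pct_identity = m, edges = edges)
}
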