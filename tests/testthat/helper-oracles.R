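# Independent oracles used by unit and acceptance tests.

# Exhaustive affine-gap alignment score by enumerating every alignment path
# (match / gap-in-b / gap-in-a moves with affine gap state). Deliberately a
# different algorithm from the package's dynamic-programming core: plain
# recursion without memoisation, i.e. a brute-force walk over all paths.
# Scoring model matches align_pair(): a gap of length k costs
# gap_open + k * gap_extend.
brute_force_score <- function(seq_a, seq_b, submat, gap_open, gap_extend) {
  a <- strsplit(seq_a, "")[[1L]]
  b <- strsplit(seq_b, "")[[1L]]
  n <- length(a); m <- length(b)
  rec <- function(i, j, state) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      s <- submat[a[i + 1L], b[j + 1L]] + rec(i + 1L, j + 1L, 0L)
      if (s > best) best <- s
    }
    if (i < n) {
      s <- -(gap_extend + if (state == 1L) 0 else gap_open) +
        rec(i + 1L, j, 1L)
      if (s > best) best <- s
    }
    if (j < m) {
      s <- -(gap_extend + if (state == 2L) 0 else gap_open) +
        rec(i, j + 1L, 2L)
      if (s > best) best <- s
    }
    best
  }
  rec(0L, 0L, 0L)
}

# Connected-components clustering oracle: link consecutive NB-ARC genes on
# a chromosome when the gap and intervening-gene rules hold, then take
# igraph components of size >= 2. Independent of detect_clusters' chain
# scan.
graph_cluster_oracle <- function(genes, nbarc_ids, max_gap_bp = 200000,
                                 max_intervening = 7) {
  out <- list()
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, ]
    g <- g[order(g$start, g$end, g$gene_id), ]
    idx <- which(g$gene_id %in% nbarc_ids)
    if (length(idx) < 2L) next
    edges <- c()
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      gap <- g$start[j] - g$end[i]
      if (gap <= max_gap_bp && (j - i - 1L) <= max_intervening)
        edges <- c(edges, g$gene_id[i], g$gene_id[j])
    }
    gr <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(g$gene_id[idx])
    if (length(edges)) gr <- gr + igraph::edges(edges)
    comp <- igraph::components(gr)
    for (cid in which(comp$csize >= 2L)) {
      members <- names(comp$membership)[comp$membership == cid]
      out[[length(out) + 1L]] <- sort(members)
    }
  }
  out
}

# Canonical, order-free representation of a cluster partition.
partition_key <- function(member_lists) {
  sort(unname(vapply(member_lists, function(x)
    paste(sort(x), collapse = "|"), "")))
}

# Random gene layout on one chromosome for clustering tests; includes the
# exact rule boundaries (gap == max_gap, gap == max_gap + 1) with some
# probability via a discrete gap menu.
random_gene_layout <- function(n = 50, nbarc_frac = 0.4,
                               chromosome = "1A") {
  gap_menu <- c(500L, 5000L, 50000L, 150000L, 200000L, 200001L, 400000L)
  starts <- integer(n); ends <- integer(n)
  cur <- 1000L
  for (i in seq_len(n)) {
    starts[i] <- cur
    ends[i] <- cur + sample(500:5000, 1L)
    cur <- ends[i] + sample(gap_menu, 1L)
  }
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             chromosome = chromosome, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# Random additive distance matrix from a known random topology; returns
# the generating (unrooted) tree and its exact path-length distances.
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.3, 2)
  d <- ape::cophenetic.phylo(tr)
  d <- d[sort(rownames(d)), sort(colnames(d))]
  list(tree = tr, d = d)
}

# Extract the gene-level truth fields of a generator run as a data.frame.
truth_table <- function(gen) {
  tg <- gen$truth$genes
  data.frame(
    gene_id = vapply(tg, `[[`, "", "gene_id"),
    is_nlr = vapply(tg, `[[`, TRUE, "is_nlr"),
    class = vapply(tg, function(t) ifelse(is.na(t$class[1L]),
                                          NA_character_,
                                          as.character(t$class)), ""),
    motif_complete = vapply(tg, function(t)
      as.logical(t$motif_complete[1L]), TRUE),
    cluster_id = vapply(tg, function(t)
      if (is.null(t$cluster_id) || is.na(t$cluster_id[1L]))
        NA_character_ else t$cluster_id, ""),
    id_accession = vapply(tg, function(t)
      ifelse(is.na(t$id_accession[1L]), NA_character_,
             as.character(t$id_accession)), ""),
    variant_event = vapply(tg, `[[`, "", "variant_event"),
    n_transcripts = vapply(tg, function(t) length(t$transcripts), 0L),
    stringsAsFactors = FALSE)
}
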