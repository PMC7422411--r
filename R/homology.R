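# Integrated-domain homology search across comparator proteomes and
# progenitor-subgenome category assignment.

# k-mer index: named list target_id -> character vector of k-mers.
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Search a proteome for homologs of a query (ID) sequence
#'
#' Seed-and-extend: candidate subjects sharing at least one exact `k`-mer
#' with the query are aligned locally (affine-gap Smith-Waterman core,
#' BLOSUM62, gap open 10 / extend 1); hits with percent identity >=
#' `min_identity` and query coverage >= `min_coverage` are returned sorted
#' by identity (descending), ties by subject identifier (ascending).
#' Coverage is the aligned fraction of the query sequence.
#'
#' @param query_seq Query amino-acid sequence (typically the integrated
#'   domain subsequence).
#' @param target_proteome data.frame from [read_fasta()].
#' @param min_identity Minimum percent identity (default 70).
#' @param min_coverage Minimum query coverage fraction (default 0.8).
#' @param k Seed k-mer length (default 5).
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return data.frame `subject_protein_id`, `pct_identity`, `coverage`,
#'   `score` (zero rows when nothing passes).
#' @export
search_homologs <- function(query_seq, target_proteome, min_identity = 70,
                            min_coverage = 0.8, k = 5,
                            matrix = blosum62(), gap_open = 10,
                            gap_extend = 1) {
  empty <- data.frame(subject_protein_id = character(),
                      pct_identity = numeric(), coverage = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nrow(target_proteome) == 0L) {
    nlr_warn("empty target proteome")
    return(empty)
  }
  qk <- kmer_set(query_seq, k)
  if (length(qk) == 0L) return(empty)
  qlen <- nchar(query_seq)
  # shared-seed prefilter, vectorised over subjects
  cand <- rep(FALSE, nrow(target_proteome))
  for (km in qk) {
    cand <- cand | grepl(km, target_proteome$sequence, fixed = TRUE)
    if (all(cand)) break
  }
  rows <- list()
  for (s in which(cand)) {
    subj <- target_proteome$sequence[s]
    al <- align_pair(query_seq, subj, mode = "local", matrix = matrix,
                     gap_open = gap_open, gap_extend = gap_extend)
    if (al$aligned_cols == 0L) next
    cov <- (al$a_range[2L] - al$a_range[1L] + 1L) / qlen
    # identity over the local alignment columns
    if (al$pct_identity >= min_identity && cov >= min_coverage)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_protein_id = target_proteome$protein_id[s],
        pct_identity = al$pct_identity, coverage = cov, score = al$score,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$pct_identity, out$subject_protein_id), ]
  rownames(out) <- NULL
  out
}

#' Homology search for a table of query IDs against several species
#'
#' Convenience wrapper running [search_homologs()] for every query ID
#' against every target species proteome.
#'
#' @param queries data.frame with `query_protein_id`, `query_id_accession`,
#'   `sequence` (the ID subsequence).
#' @param targets Named list (species code -> proteome data.frame).
#' @param ... Passed to [search_homologs()].
#' @return data.frame of hits with `query_protein_id`,
#'   `query_id_accession`, `subject_species`, `subject_protein_id`,
#'   `pct_identity`, `coverage`.
#' @export
search_homologs_multi <- function(queries, targets, ...) {
  rows <- list()
  for (q in seq_len(nrow(queries))) {
    for (sp in names(targets)) {
      h <- search_homologs(queries$sequence[q], targets[[sp]], ...)
      if (nrow(h) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_protein_id = queries$query_protein_id[q],
        query_id_accession = queries$query_id_accession[q],
        subject_species = sp,
        subject_protein_id = h$subject_protein_id,
        pct_identity = h$pct_identity, coverage = h$coverage,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query_protein_id = character(),
                      query_id_accession = character(),
                      subject_species = character(),
                      subject_protein_id = character(),
                      pct_identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag homology hits whose subject is itself an NLR
#'
#' Sets `subject_has_nbarc` TRUE iff the subject protein carries an NB-ARC
#' (PF00931) hit in its species' domain table. Subjects absent from the
#' table are flagged FALSE with a warning.
#'
#' @param hits data.frame with `subject_species` and `subject_protein_id`.
#' @param subject_domain_tables Named list (species code -> domain table).
#' @param nbarc_accessions NB-ARC accession set.
#' @return `hits` with a logical `subject_has_nbarc` column.
#' @export
flag_nlr_homologs <- function(hits, subject_domain_tables,
                              nbarc_accessions = core_accessions()$nbarc) {
  nbarc_by_species <- lapply(subject_domain_tables, function(dt)
    unique(dt$protein_id[dt$accession %in% nbarc_accessions]))
  known_by_species <- lapply(subject_domain_tables, function(dt)
    unique(dt$protein_id))
  flag <- logical(nrow(hits))
  n_missing <- 0L
  for (i in seq_len(nrow(hits))) {
    sp <- hits$subject_species[i]
    id <- hits$subject_protein_id[i]
    if (is.null(known_by_species[[sp]]) ||
        !(id %in% known_by_species[[sp]])) {
      n_missing <- n_missing + 1L
      flag[i] <- FALSE
    } else flag[i] <- id %in% nbarc_by_species[[sp]]
  }
  if (n_missing > 0L)
    nlr_warn("%d subject(s) absent from domain tables; flagged non-NLR",
             n_missing)
  hits$subject_has_nbarc <- flag
  hits
}

#' Assign a progenitor-subgenome category to an ID-bearing wheat gene
#'
#' Compares the gene's best hit identity in the two sequenced progenitor
#' proteomes — *Triticum urartu* (TU, A-subgenome donor) and *Aegilops
#' tauschii* (AT, D-subgenome donor) — against the subgenome the gene
#' resides on. Categories: `"Match"` when the better progenitor is the
#' expected donor (A with TU, D with AT; ties go to the expected donor);
#' `"A"` when an A-subgenome gene is closer to AT; `"D"` when a D-subgenome
#' gene is closer to TU; `"B"` for B-subgenome genes (no sequenced donor);
#' `"U"` when the subgenome is unknown. The identity bin of the better hit
#' is `">90"`, `"70-90"` or `"<70"`.
#'
#' @param gene_id Gene identifier.
#' @param subgenome One of `"A"`, `"B"`, `"D"`, `"unknown"`.
#' @param best_tu,best_at Best percent identity against each progenitor
#'   proteome (0 when there is no hit).
#' @return One-row data.frame `gene_id`, `subgenome`, `best_progenitor`,
#'   `category`, `identity_bin`.
#' @export
assign_progenitor_category <- function(gene_id, subgenome, best_tu = 0,
                                       best_at = 0) {
  stopifnot(subgenome %in% c("A", "B", "D", "unknown"))
  best <- max(best_tu, best_at)
  bin <- if (best > 90) ">90" else if (best >= 70) "70-90" else "<70"
  if (subgenome == "B") {
    cat_ <- "B"; prog <- "none"
  } else if (subgenome == "unknown") {
    cat_ <- "U"; prog <- "none"
  } else {
    expected <- if (subgenome == "A") "TU" else "AT"
    better <- if (best_tu > best_at) "TU"
              else if (best_at > best_tu) "AT"
              else expected                 # ties favour the expected donor
    prog <- better
    cat_ <- if (better == expected) "Match"
            else if (subgenome == "A") "A" else "D"
  }
  data.frame(gene_id = gene_id, subgenome = subgenome,
             best_progenitor = prog, category = cat_, identity_bin = bin,
             stringsAsFactors = FALSE)
}
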