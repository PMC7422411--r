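# Alternative-transcript comparison for NLR-ID genes: integrated-domain
# exclusion / truncation and intron retention.

# CDS segments of a transcript in transcription order (5'->3').
cds_in_tx_order <- function(cds, strand) {
  cds <- cds[order(cds$start), , drop = FALSE]
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  cds
}

# Genomic footprint (list of [start,end] pairs, genomic orientation) of a
# protein residue interval, mapped through CDS segments in tx order.
protein_to_genomic <- function(res_start, res_end, cds, strand) {
  nt_start <- 3L * (res_start - 1L) + 1L
  nt_end <- 3L * res_end
  segs <- cds_in_tx_order(cds, strand)
  out <- list()
  offset <- 0L
  for (k in seq_len(nrow(segs))) {
    w <- segs$end[k] - segs$start[k] + 1L
    seg_lo <- offset + 1L
    seg_hi <- offset + w
    lo <- max(nt_start, seg_lo)
    hi <- min(nt_end, seg_hi)
    if (lo <= hi) {
      if (strand == "+") {
        out[[length(out) + 1L]] <- c(segs$start[k] + (lo - seg_lo),
                                     segs$start[k] + (hi - seg_lo))
      } else {
        out[[length(out) + 1L]] <- c(segs$end[k] - (hi - seg_lo),
                                     segs$end[k] - (lo - seg_lo))
      }
    }
    offset <- seg_hi
  }
  out
}

# Fraction of a genomic footprint covered by a set of intervals.
footprint_coverage <- function(footprint, intervals) {
  total <- sum(vapply(footprint, function(p) p[2L] - p[1L] + 1L, 0L))
  if (total == 0L) return(0)
  covered <- 0L
  for (p in footprint) {
    for (q in seq_len(nrow(intervals))) {
      lo <- max(p[1L], intervals$start[q])
      hi <- min(p[2L], intervals$end[q])
      if (lo <= hi) covered <- covered + (hi - lo + 1L)
    }
  }
  covered / total
}

transcript_class <- function(hits, core) {
  core_acc <- unlist(core, use.names = FALSE)
  has_nbarc <- any(hits$accession %in% core$nbarc)
  has_id <- any(!(hits$accession %in% core_acc) &
                  grepl("^PF\\d{5}$", hits$accession))
  if (has_nbarc && has_id) "NLR-ID"
  else if (has_nbarc) "NLR-only"
  else if (has_id) "ID-only"
  else "neither"
}

#' Compare alternative transcripts of a gene for ID exclusion/truncation
#'
#' The reference transcript is the one with the richest domain content
#' (most distinct accessions; ties broken by longest protein, then by
#' transcript identifier). For every other transcript and every integrated
#' domain (ID) accession on the reference, the variant is called:
#' * `excluded` — the ID is absent,
#' * `truncated` — the ID is present at less than `truncation_fraction` of
#'   the reference instance's length,
#' * `present` — otherwise.
#'
#' Primary evidence is the variant's own protein-level domain annotation.
#' When the variant's annotation lacks the accession and exon/CDS
#' structures are available, the reference instance's coding footprint is
#' projected through the variant's CDS: a fully retained footprint means
#' the annotation row was missing (the ID is called present), a partially
#' retained one truncated, an absent one excluded.
#'
#' @param gene_id Gene identifier.
#' @param transcript_ids Character vector of the gene's transcript ids.
#' @param domain_hits Domain table; protein ids must equal transcript ids
#'   unless `id_map` maps them.
#' @param proteins Optional proteome (for protein lengths / tie-breaks).
#' @param exons,cds Optional exon/CDS tables from [read_gff3()] (enable the
#'   projection fallback and intron-retention calls).
#' @param strand Gene strand (`"+"`/`"-"`), required with `exons`.
#' @param truncation_fraction Length fraction below which a retained ID is
#'   called truncated (default 0.8).
#' @param core Core accession sets.
#' @param id_map Optional data.frame `transcript_id`, `protein_id`.
#' @return Object of class `splice_report`: list with `gene_id`,
#'   `reference_transcript`, `transcripts` (per-transcript data.frame with
#'   `class`, `id_excluded`, `id_truncated`, `retained_introns`) and
#'   `id_calls` (per transcript x ID accession detail).
#' @export
compare_transcript_domains <- function(gene_id, transcript_ids, domain_hits,
                                       proteins = NULL, exons = NULL,
                                       cds = NULL, strand = "+",
                                       truncation_fraction = 0.8,
                                       core = core_accessions(),
                                       id_map = NULL) {
  stopifnot(length(transcript_ids) >= 1L)
  tx2prot <- setNames(transcript_ids, transcript_ids)
  if (!is.null(id_map)) {
    m <- match(transcript_ids, id_map$transcript_id)
    tx2prot[!is.na(m)] <- id_map$protein_id[m[!is.na(m)]]
  }
  hits_of <- function(tx)
    domain_hits[domain_hits$protein_id == tx2prot[[tx]], , drop = FALSE]
  plen_of <- function(tx) {
    if (is.null(proteins)) return(NA_integer_)
    i <- match(tx2prot[[tx]], proteins$protein_id)
    if (is.na(i)) NA_integer_ else proteins$length[i]
  }
  core_acc <- unlist(core, use.names = FALSE)
  is_id_hit <- function(h)
    !(h$accession %in% core_acc) & grepl("^PF\\d{5}$", h$accession)

  # pick the reference transcript
  n_acc <- vapply(transcript_ids, function(tx)
    length(unique(hits_of(tx)$accession)), 0L)
  plens <- vapply(transcript_ids, plen_of, 0L)
  plens[is.na(plens)] <- 0L
  ord <- order(-n_acc, -plens, transcript_ids)
  ref_tx <- transcript_ids[ord[1L]]
  ref_hits <- hits_of(ref_tx)
  ref_ids <- ref_hits[is_id_hit(ref_hits), , drop = FALSE]

  exons_of <- function(tx) {
    if (is.null(exons)) return(NULL)
    e <- exons[exons$transcript_id == tx, c("start", "end"), drop = FALSE]
    if (nrow(e) == 0L) NULL else e[order(e$start), ]
  }
  cds_of <- function(tx) {
    if (is.null(cds)) return(NULL)
    x <- cds[cds$transcript_id == tx, c("start", "end"), drop = FALSE]
    if (nrow(x) == 0L) NULL else x[order(x$start), ]
  }

  id_calls <- list()
  tx_rows <- list()
  for (tx in transcript_ids) {
    h <- hits_of(tx)
    cls <- transcript_class(h, core)
    excl <- FALSE; trunc <- FALSE
    if (!identical(tx, ref_tx) && nrow(ref_ids) > 0L) {
      for (acc in unique(ref_ids$accession)) {
        racc <- ref_ids[ref_ids$accession == acc, , drop = FALSE]
        ref_len <- max(racc$end - racc$start + 1L)
        ref_inst <- racc[which.max(racc$end - racc$start + 1L), ]
        vacc <- h[h$accession == acc, , drop = FALSE]
        status <- NA_character_
        if (nrow(vacc) > 0L) {
          v_len <- max(vacc$end - vacc$start + 1L)
          status <- if (v_len < truncation_fraction * ref_len)
            "truncated" else "present"
        } else {
          ref_cds <- cds_of(ref_tx); v_cds <- cds_of(tx)
          if (!is.null(ref_cds) && !is.null(v_cds)) {
            fp <- protein_to_genomic(ref_inst$start, ref_inst$end,
                                     ref_cds, strand)
            frac <- footprint_coverage(fp, v_cds)
            status <- if (frac == 0) "excluded"
                      else if (frac < truncation_fraction) "truncated"
                      else "present"
          } else status <- "excluded"
        }
        if (status == "excluded") excl <- TRUE
        if (status == "truncated") trunc <- TRUE
        id_calls[[length(id_calls) + 1L]] <- data.frame(
          transcript_id = tx, accession = acc, status = status,
          stringsAsFactors = FALSE)
      }
    }
    ret <- integer(0)
    if (!identical(tx, ref_tx) && !is.null(exons_of(tx)) &&
        !is.null(exons_of(ref_tx)))
      ret <- detect_retained_introns(exons_of(tx), exons_of(ref_tx),
                                     strand, strand)
    tx_rows[[length(tx_rows) + 1L]] <- data.frame(
      transcript_id = tx, is_reference = identical(tx, ref_tx),
      class = cls, id_excluded = excl, id_truncated = trunc,
      retained_introns = paste(ret, collapse = ","),
      stringsAsFactors = FALSE)
  }
  structure(list(
    gene_id = gene_id, reference_transcript = ref_tx,
    transcripts = do.call(rbind, tx_rows),
    id_calls = if (length(id_calls)) do.call(rbind, id_calls) else
      data.frame(transcript_id = character(), accession = character(),
                 status = character(), stringsAsFactors = FALSE)),
    class = "splice_report")
}

#' @export
print.splice_report <- function(x, ...) {
  cat("Splice report for gene", x$gene_id, "- reference:",
      x$reference_transcript, "\n")
  print(x$transcripts[, c("transcript_id", "class", "id_excluded",
                          "id_truncated", "retained_introns")])
  invisible(x)
}

#' Detect introns of a reference transcript retained in a query transcript
#'
#' Reference introns are the gaps between consecutive reference exons,
#' indexed 1..n in transcription order (5'->3'; for minus-strand genes the
#' first intron is the genomically last gap). An intron is retained when it
#' is fully covered by a single exon of the query transcript.
#'
#' @param query_exons,reference_exons data.frames with `start`, `end`
#'   (1-based inclusive genomic coordinates).
#' @param query_strand,reference_strand `"+"` or `"-"`; must agree.
#' @return Sorted integer vector of retained intron indices (possibly
#'   empty).
#' @export
detect_retained_introns <- function(query_exons, reference_exons,
                                    query_strand = "+",
                                    reference_strand = "+") {
  if (!identical(query_strand, reference_strand))
    stop("transcripts are on different strands", call. = FALSE)
  re <- reference_exons[order(reference_exons$start), , drop = FALSE]
  if (nrow(re) < 2L) return(integer(0))
  introns <- data.frame(start = re$end[-nrow(re)] + 1L,
                        end = re$start[-1L] - 1L)
  introns <- introns[introns$start <= introns$end, , drop = FALSE]
  if (nrow(introns) == 0L) return(integer(0))
  # transcription-order index
  idx <- seq_len(nrow(introns))
  if (query_strand == "-") idx <- rev(idx)
  qe <- query_exons
  retained <- vapply(seq_len(nrow(introns)), function(i)
    any(qe$start <= introns$start[i] & qe$end >= introns$end[i]), TRUE)
  sort(idx[retained])
}

#' Attach expression evidence to a splice report
#'
#' Joins a transcript-level expression table onto the per-transcript rows.
#' Transcripts absent from the table get NA values; the number of unmatched
#' transcripts is recorded in the `n_unmatched` attribute.
#'
#' @param report `splice_report` from [compare_transcript_domains()].
#' @param expression_table data.frame keyed by `transcript_id` with numeric
#'   condition columns (see [read_expression_table()]).
#' @return The augmented `splice_report`.
#' @export
join_expression <- function(report, expression_table) {
  stopifnot(inherits(report, "splice_report"),
            "transcript_id" %in% names(expression_table))
  tx <- report$transcripts
  if (!any(tx$transcript_id %in% expression_table$transcript_id)) {
    nlr_warn("no transcript of gene %s found in the expression table",
             report$gene_id)
    return(report)
  }
  cond_cols <- setdiff(names(expression_table), "transcript_id")
  m <- match(tx$transcript_id, expression_table$transcript_id)
  for (cc in cond_cols) tx[[cc]] <- expression_table[[cc]][m]
  attr(tx, "n_unmatched") <- sum(is.na(m))
  report$transcripts <- tx
  report
}
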