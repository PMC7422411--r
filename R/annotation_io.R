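#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()]. Record identifiers are the first
#' whitespace-delimited token of each header; sequences are uppercased.
#' Duplicate identifiers are an error (identifiers must be unique within a
#' proteome).
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data.frame with columns `protein_id`, `sequence`, `length`
#'   (one row per record; zero rows, with a warning, for an empty file).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    nlr_warn("FASTA file '%s' contains no records", path)
    return(data.frame(protein_id = character(), sequence = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate protein identifier(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(aa))
  data.frame(protein_id = ids, sequence = unname(seqs),
             length = unname(nchar(seqs)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteins data.frame with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                         proteins$protein_id))
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Read gene and transcript models from GFF3
#'
#' Parses `gene`, `mRNA`, `exon` and `CDS` features (via
#' [rtracklayer::readGFF()]) into flat gene- and transcript-level tables.
#' Coordinates stay 1-based inclusive. An mRNA whose `Parent` gene is absent
#' is kept by synthesizing a single-transcript gene (with a warning). The
#' subgenome is parsed from the chromosome name: a trailing A/B/D letter
#' after the chromosome-group number (for example `"4A"`) or `"unknown"`.
#'
#' @param path Path to a GFF3 file.
#' @return A list with elements
#'   * `genes`: data.frame `gene_id`, `chromosome`, `start`, `end`, `strand`,
#'     `subgenome`, `n_transcripts`
#'   * `transcripts`: data.frame `transcript_id`, `gene_id`, `chromosome`,
#'     `strand`
#'   * `exons`: data.frame `transcript_id`, `start`, `end`
#'   * `cds`: data.frame `transcript_id`, `start`, `end`, `phase`
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand", "phase"),
    tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]]), "")
  g$seqid <- as.character(g$seqid)
  g$strand <- as.character(g$strand)
  bad <- !(g$strand %in% c("+", "-")) & g$type %in% c("gene", "mRNA")
  if (any(bad))
    stop("unknown strand symbol '", g$strand[bad][1L], "' in '", path, "'",
         call. = FALSE)

  genes <- g[g$type == "gene", ]
  mrna  <- g[g$type == "mRNA", ]
  exon  <- g[g$type == "exon", ]
  cds   <- g[g$type == "CDS", ]

  orphan <- !is.na(mrna$Parent) & !(mrna$Parent %in% genes$ID) |
    is.na(mrna$Parent)
  if (any(orphan)) {
    nlr_warn("%d mRNA feature(s) without a gene parent; synthesizing genes",
             sum(orphan))
    syn <- mrna[orphan, ]
    syn$Parent <- NA_character_
    syn_genes <- data.frame(seqid = syn$seqid, type = "gene",
                            start = syn$start, end = syn$end,
                            strand = syn$strand, phase = NA,
                            ID = paste0(syn$ID, ".gene"),
                            Parent = NA_character_)
    mrna$Parent[orphan] <- paste0(mrna$ID[orphan], ".gene")
    genes <- rbind(genes[, names(syn_genes)], syn_genes)
  }

  # validate CDS containment within exons of the same transcript
  if (nrow(cds) > 0L && nrow(exon) > 0L) {
    exon_by_tx <- split(exon[, c("start", "end")], exon$Parent)
    for (k in seq_len(nrow(cds))) {
      ex <- exon_by_tx[[cds$Parent[k]]]
      if (!is.null(ex) &&
          !any(ex$start <= cds$start[k] & ex$end >= cds$end[k]))
        stop("CDS segment ", cds$start[k], "-", cds$end[k],
             " of transcript '", cds$Parent[k],
             "' is not contained in any exon", call. = FALSE)
    }
  }

  ord <- order(genes$seqid, genes$start)
  genes <- genes[ord, ]
  ntx <- table(mrna$Parent)
  gene_df <- data.frame(
    gene_id = genes$ID, chromosome = genes$seqid,
    start = genes$start, end = genes$end, strand = genes$strand,
    subgenome = parse_subgenome(genes$seqid),
    n_transcripts = as.integer(ntx[genes$ID]),
    stringsAsFactors = FALSE)
  gene_df$n_transcripts[is.na(gene_df$n_transcripts)] <- 0L
  rownames(gene_df) <- NULL

  tx_df <- data.frame(transcript_id = mrna$ID, gene_id = mrna$Parent,
                      chromosome = mrna$seqid, strand = mrna$strand,
                      stringsAsFactors = FALSE)
  exon_df <- data.frame(transcript_id = exon$Parent,
                        start = exon$start, end = exon$end,
                        stringsAsFactors = FALSE)
  exon_df <- exon_df[order(exon_df$transcript_id, exon_df$start), ]
  rownames(exon_df) <- NULL
  cds_df <- data.frame(transcript_id = cds$Parent,
                       start = cds$start, end = cds$end,
                       phase = suppressWarnings(as.integer(cds$phase)),
                       stringsAsFactors = FALSE)
  cds_df <- cds_df[order(cds_df$transcript_id, cds_df$start), ]
  rownames(cds_df) <- NULL
  list(genes = gene_df, transcripts = tx_df, exons = exon_df, cds = cds_df)
}

#' Parse the subgenome letter from a chromosome name
#'
#' Hexaploid wheat chromosome names carry the subgenome as a trailing letter
#' (1A..7D). Anything not matching `<number><A|B|D>` (an optional `chr`
#' prefix is tolerated) is `"unknown"`.
#'
#' @param chromosome Character vector of chromosome names.
#' @return Character vector over `{"A","B","D","unknown"}`.
#' @export
parse_subgenome <- function(chromosome) {
  core <- sub("[LS]$", "", sub("^chr", "", chromosome))  # drop prefix/arm
  out <- rep("unknown", length(chromosome))
  hit <- grepl("^[0-9]+[ABD]$", core)
  out[hit] <- substring(core[hit], nchar(core[hit]))
  out
}

#' Read a protein domain annotation table
#'
#' Accepts the InterProScan 5 TSV dialect (protein accession in column 1,
#' analysis in column 4, signature accession in column 5, description in
#' column 6, start in column 7, stop in column 8) or a reduced 5-column
#' dialect (`protein_id`, `accession`, `name`, `start`, `end`); the dialect is
#' auto-detected from the column count. Rows with `end < start` or
#' unparseable coordinates are rejected with a warning and counted in the
#' `"rejected"` attribute. When `proteins` is supplied, hits extending beyond
#' the protein length are also rejected.
#'
#' @param path Path to the TSV file (no header for the InterProScan dialect;
#'   a header line starting with `protein_id` is tolerated and skipped).
#' @param proteins Optional proteome data.frame from [read_fasta()] used to
#'   validate coordinates.
#' @return data.frame with columns `protein_id`, `accession`, `name`,
#'   `start`, `end`, `source`, `score`; attribute `rejected` holds the count
#'   of discarded rows.
#' @export
read_domain_table <- function(path, proteins = NULL) {
  stopifnot(file.exists(path))
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  raw <- raw[!grepl("^#", raw)]
  if (length(raw) > 0L && grepl("^protein_id\t", raw[1L])) raw <- raw[-1L]
  if (length(raw) == 0L) {
    out <- data.frame(protein_id = character(), accession = character(),
                      name = character(), start = integer(), end = integer(),
                      source = character(), score = numeric())
    attr(out, "rejected") <- 0L
    return(out)
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  rejected <- 0L
  parse_row <- function(f) {
    if (length(f) >= 8L) {          # InterProScan 5 dialect
      c(id = f[1L], source = f[4L], accession = f[5L], name = f[6L],
        start = f[7L], end = f[8L],
        score = if (length(f) >= 9L) f[9L] else NA_character_)
    } else if (length(f) == 5L) {   # reduced dialect
      c(id = f[1L], source = NA_character_, accession = f[2L], name = f[3L],
        start = f[4L], end = f[5L], score = NA_character_)
    } else NULL
  }
  rows <- lapply(fields, parse_row)
  bad_shape <- vapply(rows, is.null, TRUE)
  if (any(bad_shape)) {
    rejected <- rejected + sum(bad_shape)
    nlr_warn("%d unparseable row(s) in '%s' rejected", sum(bad_shape), path)
    rows <- rows[!bad_shape]
  }
  m <- do.call(rbind, rows)
  start <- suppressWarnings(as.integer(m[, "start"]))
  end <- suppressWarnings(as.integer(m[, "end"]))
  src <- m[, "source"]
  src[is.na(src)] <- ifelse(grepl("^PF\\d{5}$", m[is.na(src), "accession"]),
                            "Pfam", "other")
  out <- data.frame(protein_id = m[, "id"], accession = m[, "accession"],
                    name = m[, "name"], start = start, end = end,
                    source = src,
                    score = suppressWarnings(as.numeric(m[, "score"])),
                    stringsAsFactors = FALSE)
  bad <- is.na(out$start) | is.na(out$end) | out$end < out$start |
    out$start < 1L
  if (!is.null(proteins)) {
    plen <- setNames(proteins$length, proteins$protein_id)
    known <- out$protein_id %in% names(plen)
    bad <- bad | (known & out$end > plen[out$protein_id])
  }
  if (any(bad)) {
    rejected <- rejected + sum(bad)
    nlr_warn("%d domain row(s) with invalid coordinates rejected", sum(bad))
    out <- out[!bad, ]
  }
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write pipeline objects to a standard format
#'
#' Dispatches on `format`: `"TSV"` (tab-separated, 1-based inclusive
#' coordinates, header always written), `"JSON"` (via jsonlite), `"BED"`
#' (0-based half-open intervals) or `"Newick"` (for `phylo` trees, via ape).
#'
#' @param x A data.frame (TSV/BED), any list-like object (JSON) or an
#'   [ape::read.tree()]-compatible `phylo` object (Newick).
#' @param path Output path.
#' @param format One of `"TSV"`, `"JSON"`, `"BED"`, `"Newick"`.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, path, format = c("TSV", "JSON", "BED", "Newick")) {
  format <- match.arg(format)
  switch(format,
    TSV = write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE),
    JSON = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null", pretty = TRUE),
    BED = {
      stopifnot(all(c("chromosome", "start", "end", "name") %in% names(x)) ||
                all(c("chromosome", "start", "end") %in% names(x)))
      bed <- data.frame(chrom = x$chromosome,
                        chromStart = to_bed_start(x$start),
                        chromEnd = x$end,
                        name = if ("name" %in% names(x)) x$name else ".")
      write.table(bed, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    },
    Newick = {
      stopifnot(inherits(x, "phylo"))
      ape::write.tree(x, file = path)
    })
  invisible(path)
}

#' Convert between 1-based inclusive and BED (0-based half-open) starts
#'
#' The package keeps 1-based inclusive coordinates everywhere; only the BED
#' writer/reader converts. These two helpers are exact inverses.
#' @param start Integer vector of 1-based inclusive starts.
#' @return Converted start coordinates.
#' @export
to_bed_start <- function(start) as.integer(start) - 1L

#' @rdname to_bed_start
#' @param bed_start Integer vector of 0-based half-open starts.
#' @export
from_bed_start <- function(bed_start) as.integer(bed_start) + 1L

#' Read a BED file written by [write_outputs()]
#'
#' @param path Path to a BED file.
#' @return data.frame with 1-based inclusive `chromosome`, `start`, `end`,
#'   `name`.
#' @export
read_bed <- function(path) {
  b <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chromosome", "start", "end")
  if (ncol(b) >= 4L) names(b)[4L] <- "name"
  b$start <- from_bed_start(b$start)
  b
}

#' Read a transcript-level expression table
#'
#' @param path TSV with a `transcript_id` column and one or more numeric
#'   condition columns.
#' @return data.frame keyed by `transcript_id`.
#' @export
read_expression_table <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  stopifnot("transcript_id" %in% names(x))
  x
}
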