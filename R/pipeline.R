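# End-to-end orchestration: census -> clusters -> integrated domains ->
# homology -> splice variants, on in-memory objects or files.

#' Analyze a proteome/annotation set end to end
#'
#' Runs every analysis stage on in-memory tables (as produced by the
#' readers in this package or by [generate()]): NB-ARC identification and
#' architecture census, physical cluster detection, integrated-domain
#' extraction and profiling, homology against comparator proteomes with
#' progenitor-subgenome categories, and alternative-transcript comparison.
#' Protein identifiers are assumed to equal transcript identifiers unless
#' `id_map` says otherwise.
#'
#' @param proteins Proteome data.frame ([read_fasta()]).
#' @param genes,transcripts,exons,cds Gene model tables ([read_gff3()]).
#' @param domains Domain table ([read_domain_table()]).
#' @param expression Optional expression table.
#' @param comparators Optional named list (species code ->
#'   `list(proteins, domains)`); species `TU` and `AT` drive progenitor
#'   categories, every species contributes homology hits.
#' @param stages Character vector of stages to run (subset of
#'   `c("census", "cluster", "ids", "homology", "splice")`).
#' @param params Named list of overrides: `max_gap_bp`, `max_intervening`,
#'   `min_identity`, `min_coverage`, `kmer`, `truncation_fraction`,
#'   `core`, `motif_patterns`, `category_map`, `id_map`.
#' @return List of stage results (see vignette); class `nlr_analysis`.
#' @export
analyze_nlr <- function(proteins, genes, transcripts, exons = NULL,
                        cds = NULL, domains, expression = NULL,
                        comparators = NULL,
                        stages = c("census", "cluster", "ids", "homology",
                                   "splice"),
                        params = list()) {
  p <- modifyList(list(max_gap_bp = 200000, max_intervening = 7,
                       min_identity = 70, min_coverage = 0.8, kmer = 5,
                       truncation_fraction = 0.8,
                       core = core_accessions(),
                       motif_patterns = default_motif_patterns(),
                       category_map = default_category_map(),
                       id_map = NULL),
                  params)
  out <- list(params = p)
  seq_of <- setNames(proteins$sequence, proteins$protein_id)
  len_of <- setNames(proteins$length, proteins$protein_id)

  tx2gene <- setNames(transcripts$gene_id, transcripts$transcript_id)
  protein_gene <- data.frame(protein_id = transcripts$transcript_id,
                             gene_id = transcripts$gene_id,
                             stringsAsFactors = FALSE)
  if (!is.null(p$id_map)) {
    m <- match(protein_gene$protein_id, p$id_map$transcript_id)
    protein_gene$protein_id[!is.na(m)] <-
      p$id_map$protein_id[m[!is.na(m)]]
  }
  gm <- match(protein_gene$gene_id, genes$gene_id)
  protein_gene$chromosome <- genes$chromosome[gm]
  protein_gene$subgenome <- genes$subgenome[gm] %||%
    parse_subgenome(genes$chromosome[gm])

  nbarc_proteins <- find_nbarc_proteins(domains, p$core$nbarc)
  out$nbarc_proteins <- nbarc_proteins

  # --- census ---------------------------------------------------------------
  if ("census" %in% stages) {
    arch <- vector("list", length(nbarc_proteins))
    motif_hits <- vector("list", length(nbarc_proteins))
    for (i in seq_along(nbarc_proteins)) {
      pid <- nbarc_proteins[i]
      mc <- NA
      if (pid %in% names(seq_of)) {
        h <- domains[domains$protein_id == pid &
                       domains$accession %in% p$core$nbarc, ]
        sc <- scan_motifs(seq_of[[pid]], h$start[1L], h$end[1L],
                          p$motif_patterns)
        mc <- attr(sc, "motif_complete")
        sc$protein_id <- pid
        motif_hits[[i]] <- sc
      }
      arch[[i]] <- classify_architecture(pid, domains, p$core,
                                         motif_complete = mc)
    }
    out$architectures <- do.call(rbind, arch)
    out$motif_hits <- do.call(rbind, motif_hits)
    out$census <- census(out$architectures, protein_gene)
  }

  nbarc_genes <- sort(unique(stats::na.omit(
    protein_gene$gene_id[protein_gene$protein_id %in% nbarc_proteins])))
  out$nbarc_genes <- nbarc_genes

  # --- physical clusters ----------------------------------------------------
  if ("cluster" %in% stages) {
    out$clusters <- detect_clusters(genes, nbarc_genes,
                                    max_gap_bp = p$max_gap_bp,
                                    max_intervening = p$max_intervening)
  }

  # --- integrated domains (gene level: richest protein per gene) -----------
  gene_rep <- NULL
  if (!is.null(out$census) && nrow(out$census$genes) > 0L) {
    gene_rep <- out$census$genes[, c("gene_id", "protein_id")]
  }
  if ("ids" %in% stages && !is.null(gene_rep)) {
    id_rows <- list()
    for (k in seq_len(nrow(gene_rep))) {
      pid <- gene_rep$protein_id[k]
      ids <- extract_ids(pid, domains,
                         protein_length = len_of[pid] %||% NA,
                         core = p$core, category_map = p$category_map)
      if (nrow(ids) > 0L) {
        ids$gene_id <- gene_rep$gene_id[k]
        id_rows[[length(id_rows) + 1L]] <- ids
      }
    }
    out$ids <- if (length(id_rows)) do.call(rbind, id_rows) else
      data.frame()
    out$id_profile <- if (length(id_rows)) positional_profile(out$ids)
      else data.frame()
  }

  # --- homology and progenitor categories ----------------------------------
  if ("homology" %in% stages && !is.null(comparators) &&
      !is.null(out$ids) && nrow(out$ids) > 0L) {
    q <- out$ids
    q <- q[!duplicated(q$gene_id), , drop = FALSE]  # one ID per gene
    queries <- data.frame(
      query_protein_id = q$protein_id,
      query_id_accession = q$accession,
      sequence = substr(seq_of[q$protein_id], q$start, q$end),
      stringsAsFactors = FALSE)
    targets <- lapply(comparators, `[[`, "proteins")
    hits <- search_homologs_multi(queries, targets,
                                  min_identity = p$min_identity,
                                  min_coverage = p$min_coverage,
                                  k = p$kmer)
    dom_tables <- lapply(comparators, `[[`, "domains")
    if (nrow(hits) > 0L)
      hits <- flag_nlr_homologs(hits, dom_tables, p$core$nbarc)
    out$homology_hits <- hits
    # per-species NLR-homolog fraction (best hit per query)
    frac <- list()
    for (sp in names(comparators)) {
      h <- hits[hits$subject_species == sp, , drop = FALSE]
      if (nrow(h) == 0L) next
      best <- h[!duplicated(h$query_protein_id), , drop = FALSE]
      frac[[sp]] <- mean(best$subject_has_nbarc)
    }
    out$nlr_homolog_fraction <- unlist(frac)
    # progenitor categories for ID-bearing genes
    if (all(c("TU", "AT") %in% names(comparators))) {
      rows <- list()
      for (k in seq_len(nrow(q))) {
        pid <- q$protein_id[k]
        gid <- q$gene_id[k]
        sg <- protein_gene$subgenome[match(pid, protein_gene$protein_id)]
        if (is.na(sg)) sg <- "unknown"
        h <- hits[hits$query_protein_id == pid, , drop = FALSE]
        best_tu <- max(c(0, h$pct_identity[h$subject_species == "TU"]))
        best_at <- max(c(0, h$pct_identity[h$subject_species == "AT"]))
        rows[[k]] <- assign_progenitor_category(gid, sg, best_tu, best_at)
      }
      out$progenitor <- do.call(rbind, rows)
      ad <- out$progenitor$subgenome %in% c("A", "D")
      out$progenitor_match_fraction <-
        if (any(ad)) mean(out$progenitor$category[ad] == "Match")
        else NA_real_
    }
  }

  # --- splice variants ------------------------------------------------------
  if ("splice" %in% stages) {
    gene_tx <- split(transcripts$transcript_id, transcripts$gene_id)
    reports <- list()
    for (gid in nbarc_genes) {
      tx_ids <- gene_tx[[gid]]
      if (is.null(tx_ids) || length(tx_ids) < 2L) next
      strand <- genes$strand[match(gid, genes$gene_id)] %||% "+"
      reports[[gid]] <- compare_transcript_domains(
        gid, sort(tx_ids), domains, proteins = proteins,
        exons = exons, cds = cds, strand = strand,
        truncation_fraction = p$truncation_fraction, core = p$core,
        id_map = p$id_map)
      if (!is.null(expression))
        reports[[gid]] <- suppressWarnings(
          join_expression(reports[[gid]], expression))
    }
    out$splice_reports <- reports
    ex_flags <- vapply(reports, function(r)
      any(r$transcripts$id_excluded), TRUE)
    tr_flags <- vapply(reports, function(r)
      any(r$transcripts$id_truncated), TRUE)
    has_ref_id <- vapply(reports, function(r) {
      nrow(r$id_calls) > 0L ||
        any(r$transcripts$class[r$transcripts$is_reference] == "NLR-ID")
    }, TRUE)
    out$splice_summary <- data.frame(
      gene_id = names(reports),
      reference_has_id = has_ref_id,
      any_exclusion = ex_flags, any_truncation = tr_flags,
      stringsAsFactors = FALSE)
  }
  structure(out, class = "nlr_analysis")
}

#' @export
print.nlr_analysis <- function(x, ...) {
  cat("nlrforge analysis\n")
  if (!is.null(x$census))
    cat(sprintf("  NB-ARC genes: %d (%d motif-complete)\n",
                x$census$n_genes, x$census$n_motif_complete_genes))
  if (!is.null(x$clusters))
    cat(sprintf("  clustered genes: %d in %d clusters\n",
                nrow(x$clusters),
                length(unique(x$clusters$cluster_id))))
  if (!is.null(x$ids))
    cat(sprintf("  integrated domains: %d on %d genes\n",
                nrow(x$ids), length(unique(x$ids$gene_id))))
  if (!is.null(x$splice_summary)) {
    s <- x$splice_summary[x$splice_summary$reference_has_id, ]
    cat(sprintf("  ID genes with alternative transcripts: %d (%d excluding, %d truncating)\n",
                nrow(s), sum(s$any_exclusion), sum(s$any_truncation)))
  }
  invisible(x)
}

#' Run the full pipeline from a configuration file
#'
#' File-based front end over [analyze_nlr()]: reads the inputs named in
#' the configuration, runs the requested stages in dependency order,
#' writes one TSV/BED/JSON per report plus a reproducibility manifest
#' (`manifest.json` with the configuration snapshot, input/output MD5
#' checksums, seed and per-stage row counts).
#'
#' Configuration (YAML file or list): `inputs:` with `proteome`, `gff`,
#' `domains`, optional `expression`, optional `comparators` (species ->
#' `{proteome, domains}`); optional `skip:` list of stages; optional
#' `seed`; optional `params:` overrides as in [analyze_nlr()].
#'
#' @param config Path to a YAML file or an equivalent list.
#' @param out_dir Output directory (created if needed).
#' @return The `nlr_analysis` object, invisibly.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs))
  inp <- config$inputs
  for (f in c("proteome", "gff", "domains"))
    if (is.null(inp[[f]]) || !file.exists(inp[[f]]))
      stop("missing required input: ", f, call. = FALSE)
  extra <- c(inp$expression,
             unlist(lapply(inp$comparators, unlist), use.names = FALSE))
  for (f in extra) if (!file.exists(f))
    stop("missing input file: ", f, call. = FALSE)

  if (!is.null(config$seed)) set.seed(config$seed)
  proteins <- read_fasta(inp$proteome)
  gff <- read_gff3(inp$gff)
  domains <- read_domain_table(inp$domains, proteins)
  expression <- if (!is.null(inp$expression))
    read_expression_table(inp$expression) else NULL
  comparators <- NULL
  if (!is.null(inp$comparators)) {
    comparators <- lapply(inp$comparators, function(cc) {
      pr <- read_fasta(cc$proteome)
      list(proteins = pr, domains = read_domain_table(cc$domains, pr))
    })
  }
  stages <- setdiff(c("census", "cluster", "ids", "homology", "splice"),
                    unlist(config$skip))
  res <- analyze_nlr(proteins, gff$genes, gff$transcripts, gff$exons,
                     gff$cds, domains, expression, comparators,
                     stages = stages,
                     params = config$params %||% list())

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(obj, file, format = "TSV") {
    if (is.null(obj)) return()
    path <- file.path(out_dir, file)
    write_outputs(obj, path, format)
    written <<- c(written, path)
  }
  if (!is.null(res$census)) {
    emit(summary(res$census), "census.tsv")
    emit(res$architectures, "architectures.tsv")
  }
  if (!is.null(res$clusters)) {
    emit(res$clusters, "clusters.tsv")
    if (nrow(res$clusters) > 0L) {
      spans <- do.call(rbind, lapply(split(res$clusters,
                                           res$clusters$cluster_id),
        function(cl) data.frame(chromosome = cl$chromosome[1L],
                                start = min(cl$start), end = max(cl$end),
                                name = cl$cluster_id[1L])))
      emit(spans, "clusters.bed", "BED")
    }
  }
  if (!is.null(res$ids) && nrow(res$ids) > 0L) {
    emit(res$ids, "integrated_domains.tsv")
    emit(res$id_profile, "id_profile.tsv")
  }
  if (!is.null(res$homology_hits)) {
    emit(res$homology_hits, "homology_hits.tsv")
    emit(res$progenitor, "progenitor_categories.tsv")
  }
  if (!is.null(res$splice_summary)) {
    emit(res$splice_summary, "splice_summary.tsv")
    emit(lapply(res$splice_reports, function(r)
      list(gene_id = r$gene_id,
           reference_transcript = r$reference_transcript,
           transcripts = r$transcripts)), "splice_reports.json", "JSON")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("nlrforge")),
    seed = config$seed %||% NA,
    stages = stages,
    config = config,
    input_md5 = as.list(tools::md5sum(unlist(c(inp$proteome, inp$gff,
                                               inp$domains, extra)))),
    output_md5 = as.list(tools::md5sum(written)),
    row_counts = list(
      proteins = nrow(proteins), genes = nrow(gff$genes),
      domain_hits = nrow(domains),
      nbarc_genes = length(res$nbarc_genes),
      clustered_genes = if (!is.null(res$clusters)) nrow(res$clusters)
        else NA,
      integrated_domains = if (!is.null(res$ids)) nrow(res$ids) else NA))
  write_outputs(manifest, file.path(out_dir, "manifest.json"), "JSON")
  invisible(res)
}
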