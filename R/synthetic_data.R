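# Synthetic genome/proteome/annotation generator with planted ground truth.
# Every pipeline stage (NB-ARC census, clustering, integrated domains,
# homology, splice variants) can be validated against the emitted TruthSet.

# Background alphabet for generated sequences. G, K, D, P and W are left
# out of the background so that the three NB-ARC motifs (which require
# those residues at anchor positions) cannot arise by chance outside the
# planted motif windows; the generator's divergence substitutions stay
# within this alphabet too, so motif truth labels remain exact under any
# seed. mutate_sequence() itself defaults to the full 20-letter alphabet.
.BG_ALPHABET <- c("A","R","N","C","E","Q","H","I","L","M","F","S","T","Y","V")
.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")

rand_seq <- function(n, alphabet = .BG_ALPHABET)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# Evaluate expr under a throwaway RNG stream, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Point-substitution divergence of a protein sequence
#'
#' Applies i.i.d. per-site substitution: each residue mutates with
#' probability `rate` to a uniformly chosen *different* residue of the
#' 20-letter alphabet. Expected identity to the input is `1 - rate` plus a
#' small back-mutation term (a mutated site matches the original with
#' probability 1/19 when the original is a standard residue).
#'
#' @param seq Protein sequence.
#' @param rate Substitution probability per site, in \[0, 1).
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @param protected Integer positions never mutated (e.g. conserved motif
#'   windows).
#' @param alphabet Residues substitutions are drawn from (default the full
#'   20-letter alphabet; the generator internally restricts this to its
#'   background alphabet so that motif-anchor residues cannot arise by
#'   chance).
#' @return The diverged sequence.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL, protected = integer(0),
                            alphabet = .AA20) {
  stopifnot(rate >= 0, rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  hit <- runif(length(ch)) < rate
  hit[protected] <- FALSE
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(alphabet, a), 1L), "")
  }
  paste(ch, collapse = "")
}

#' Default integrated-domain library for the generator
#'
#' A curated set of the recurrent ID families seen fused into cereal NLRs,
#' each with a deterministic consensus sequence, a functional category and
#' the protein terminus it prefers.
#'
#' @return data.frame `accession`, `name`, `category`, `terminus`,
#'   `length`, `consensus`.
#' @export
default_id_library <- function() {
  if (!is.null(.nlr_env$id_library)) return(.nlr_env$id_library)
  spec <- list(
    c("PF00069", "Protein kinase domain",        "kinase",          "N", 150),
    c("PF07714", "Protein tyrosine kinase",      "kinase",          "N", 140),
    c("PF03106", "WRKY DNA-binding domain",      "DNA-binding",     "C",  60),
    c("PF00847", "AP2 domain",                   "DNA-binding",     "C",  60),
    c("PF02362", "B3 DNA-binding domain",        "DNA-binding",     "C", 100),
    c("PF00249", "Myb-like DNA-binding domain",  "DNA-binding",     "N",  50),
    c("PF02892", "BED zinc finger",              "DNA-binding",     "N",  50),
    c("PF01419", "Jacalin-like lectin domain",   "other-signaling", "C", 120),
    c("PF00085", "Thioredoxin",                  "other-signaling", "C", 100),
    c("PF00179", "Ubiquitin-conjugating enzyme", "other-signaling", "C", 140),
    c("PF01344", "Kelch motif",                  "other-signaling", "C",  50),
    c("PF03081", "Exo70 exocyst subunit",        "other-signaling", "C", 100))
  lib <- data.frame(accession = vapply(spec, `[`, "", 1L),
                    name = vapply(spec, `[`, "", 2L),
                    category = vapply(spec, `[`, "", 3L),
                    terminus = vapply(spec, `[`, "", 4L),
                    length = as.integer(vapply(spec, `[`, "", 5L)),
                    stringsAsFactors = FALSE)
  lib$consensus <- vapply(seq_len(nrow(lib)), function(i)
    with_local_seed(7000L + i, rand_seq(lib$length[i])), "")
  .nlr_env$id_library <- lib
  lib
}

# Core structural block consensus sequences (deterministic). The NB-ARC
# block carries the three planted motifs at fixed offsets.
.NBARC_MOTIFS <- list(
  `P-loop`   = list(offset = 11L, seq = "GAAAAGKT"),
  `Kinase-2` = list(offset = 71L, seq = "LLAADDAW"),
  GLPL       = list(offset = 131L, seq = "GLPL"))

block_library <- function() {
  if (!is.null(.nlr_env$blocks)) return(.nlr_env$blocks)
  blocks <- list(
    CC    = list(accession = "PF18052", name = "RX-CC_like", len = 100L),
    TIR   = list(accession = "PF01582", name = "TIR",        len = 170L),
    RPW8  = list(accession = "PF05659", name = "RPW8",       len = 120L),
    NBARC = list(accession = "PF00931", name = "NB-ARC",     len = 160L),
    LRR   = list(accession = "PF13855", name = "LRR_8",      len = 75L))
  for (i in seq_along(blocks)) {
    blocks[[i]]$consensus <- with_local_seed(8000L + i,
                                             rand_seq(blocks[[i]]$len))
  }
  nb <- blocks$NBARC$consensus
  for (m in .NBARC_MOTIFS) {
    substr(nb, m$offset, m$offset + nchar(m$seq) - 1L) <- m$seq
  }
  blocks$NBARC$consensus <- nb
  blocks$NBARC$protected <- unlist(lapply(.NBARC_MOTIFS, function(m)
    m$offset:(m$offset + nchar(m$seq) - 1L)), use.names = FALSE)
  .nlr_env$blocks <- blocks
  blocks
}

#' Simulation configuration
#'
#' Assembles and validates the generator configuration. The defaults are
#' the package's reference study conditions: a quarter of gene loci encode
#' NLRs, class proportions echo a hexaploid wheat census (CNL and NL
#' dominant, TIR- and RPW8-classes rare), 70% of NB-ARC genes are
#' motif-complete, 40% of NLR loci found tandem-duplicated clusters with 5%
#' within-cluster divergence, a quarter of NLR genes carry an integrated
#' domain, 70% of NLR genes have an alternative transcript, and an ID
#' gene's variant excludes its ID with probability 0.3.
#'
#' @param ... Named overrides of any default field.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_chromosomes = 3L,
    genes_per_chromosome = 100L,
    nlr_fraction = 0.25,
    class_proportions = c(CNL = 0.37, NL = 0.35, CN = 0.12, N = 0.15,
                          TN = 0.005, RNL = 0.005),
    motif_complete_prob = 0.70,
    tandem_dup_prob = 0.4,
    dup_divergence = 0.05,
    base_divergence = 0.08,
    id_insertion_prob = 0.25,
    id_library = default_id_library(),
    alt_transcript_prob = 0.7,
    id_exclusion_prob = 0.3,
    id_truncation_prob = 0.1,
    intron_retention_prob = 0.2,
    progenitor_divergence = 0.05,
    progenitor_cross_divergence = 0.15,
    progenitor_match_prob = 0.41,
    comparator_divergence = 0.08,
    comparator_nlr_homolog_prob = 0.685,
    annotation_fn_rate = 0,
    decoy_domain_prob = 0.3,
    expression_conditions = 4L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  probs <- c("nlr_fraction", "motif_complete_prob", "tandem_dup_prob",
             "dup_divergence", "base_divergence", "id_insertion_prob",
             "alt_transcript_prob", "id_exclusion_prob",
             "id_truncation_prob", "intron_retention_prob",
             "progenitor_divergence", "progenitor_cross_divergence",
             "progenitor_match_prob", "comparator_divergence",
             "comparator_nlr_homolog_prob", "annotation_fn_rate",
             "decoy_domain_prob")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("configuration field '", p, "' must be a probability",
           call. = FALSE)
  if (abs(sum(cfg$class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1", call. = FALSE)
  if (!all(names(cfg$class_proportions) %in%
           c("CNL", "TNL", "RNL", "CN", "TN", "RN", "NL", "N")))
    stop("class_proportions has unknown class labels", call. = FALSE)
  if (cfg$id_exclusion_prob + cfg$id_truncation_prob +
      cfg$intron_retention_prob > 1)
    stop("variant event probabilities exceed 1", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# --- internal gene assembly -------------------------------------------------

# A gene is a list of sequence elements in transcription order, grouped
# into exon chunks. Each element: type (domain/linker), accession, name,
# seq, exon (coding-exon index), protected (positions never mutated).
assemble_elements <- function(class_label, id_row, motif_complete) {
  blocks <- block_library()
  nterm <- switch(substr(class_label, 1L, 1L),
                  C = "CC", T = "TIR", R = "RPW8", NULL)
  has_lrr <- grepl("L$", class_label)
  el <- list()
  add <- function(type, acc, name, seq, exon, protected = integer(0)) {
    el[[length(el) + 1L]] <<- list(type = type, accession = acc,
                                   name = name, seq = seq, exon = exon,
                                   protected = protected)
  }
  exon_i <- 1L
  if (!is.null(id_row) && id_row$terminus == "N") {
    add("domain", id_row$accession, id_row$name, id_row$consensus, exon_i)
    exon_i <- exon_i + 1L
  }
  if (!is.null(nterm)) {
    b <- blocks[[nterm]]
    add("domain", b$accession, b$name, b$consensus, exon_i)
    add("linker", NA, NA, rand_seq(15L), exon_i)
    exon_i <- exon_i + 1L
  }
  nb <- blocks$NBARC
  nb_seq <- nb$consensus
  if (!motif_complete) {
    m <- .NBARC_MOTIFS$`P-loop`
    substr(nb_seq, m$offset, m$offset + nchar(m$seq) - 1L) <-
      strrep("A", nchar(m$seq))
  }
  add("domain", nb$accession, nb$name, nb_seq, exon_i,
      protected = nb$protected)
  exon_i <- exon_i + 1L
  if (has_lrr) {
    b <- blocks$LRR
    add("linker", NA, NA, rand_seq(15L), exon_i)
    add("domain", b$accession, b$name, b$consensus, exon_i)
    exon_i <- exon_i + 1L
  }
  if (!is.null(id_row) && id_row$terminus == "C") {
    add("linker", NA, NA, rand_seq(10L), exon_i)
    add("domain", id_row$accession, id_row$name, id_row$consensus, exon_i)
  }
  el
}

mutate_elements <- function(el, rate) {
  if (rate == 0) return(el)
  for (i in seq_along(el)) {
    el[[i]]$seq <- mutate_sequence(el[[i]]$seq, rate,
                                   protected = el[[i]]$protected,
                                   alphabet = .BG_ALPHABET)
  }
  el
}

# protein sequence + domain rows from an element list
elements_to_protein <- function(el) {
  pos <- 1L
  rows <- list()
  seqs <- character(length(el))
  for (i in seq_along(el)) {
    w <- nchar(el[[i]]$seq)
    if (el[[i]]$type == "domain")
      rows[[length(rows) + 1L]] <- data.frame(
        accession = el[[i]]$accession, name = el[[i]]$name,
        start = pos, end = pos + w - 1L, stringsAsFactors = FALSE)
    seqs[i] <- el[[i]]$seq
    pos <- pos + w
  }
  list(sequence = paste(seqs, collapse = ""),
       domains = if (length(rows)) do.call(rbind, rows) else
         data.frame(accession = character(), name = character(),
                    start = integer(), end = integer(),
                    stringsAsFactors = FALSE))
}

#' Generate a synthetic genome with planted NLR structure
#'
#' Emits a proteome, gene/transcript models, a domain annotation table, an
#' expression table, progenitor and comparator proteomes (with their
#' domain tables) and a machine-readable truth set, all mutually
#' consistent. Identical configurations (including the seed) produce
#' identical output, byte for byte when written with `out_dir`.
#'
#' Planted structure: NLR proteins are assembled from consensus domain
#' blocks (CC/TIR/RPW8 + NB-ARC with P-loop, Kinase-2 and GLPL motifs +
#' LRR) joined by linkers; tandem clusters are created by copying a
#' founder gene next to itself with per-site divergence (motif windows
#' preserved); integrated domains are inserted at the terminus their
#' family prefers; alternative transcripts drop the ID exon, shorten it,
#' or retain the 3'-UTR intron; the domain table is derived from the truth
#' with optional false-negative noise; progenitor proteomes carry diverged
#' ID homologs whose closest donor matches the gene's subgenome with
#' configurable probability. Unrelated neighbouring genes are spaced more
#' than 200 kb apart so that only planted tandem arrays satisfy the
#' clustering rule.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, all standard-format
#'   files plus `truth.json` are written there.
#' @return List with `proteins`, `genes`, `transcripts`, `exons`, `cds`,
#'   `domains`, `expression`, `comparators` (named list of
#'   `list(proteins, domains)` for species HV/TU/AT), and `truth`.
#' @export
generate <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  chrom_names <- as.vector(t(outer(1:7, c("A", "B", "D"), paste0)))
  chroms <- chrom_names[seq_len(config$n_chromosomes)]
  lib <- config$id_library
  classes <- names(config$class_proportions)

  genes <- list(); txs <- list(); exons <- list(); cdss <- list()
  prots <- list(); dom_rows <- list(); truth_genes <- list()
  gene_counter <- 0L

  # genomic exon layout for one gene; returns tx-order starts/ends
  layout_exons <- function(cursor, tx_lens, strand, intron_len = 200L) {
    n_ex <- length(tx_lens)
    if (strand == "+") {
      starts <- cursor + c(0L, cumsum(tx_lens[-n_ex] + intron_len))
    } else {
      lay <- cursor + c(0L, cumsum(rev(tx_lens)[-n_ex] + intron_len))
      starts <- rev(lay)
    }
    list(starts = as.integer(starts),
         ends = as.integer(starts + tx_lens - 1L))
  }

  place_gene <- function(chrom, cursor, class_label, motif_complete,
                         id_row, cluster_id, strand, el) {
    gene_counter <<- gene_counter + 1L
    gid <- sprintf("SYNG%s_%05d", chrom, gene_counter)
    is_nlr <- !is.na(class_label)

    exon_ids <- vapply(el, function(e) e$exon, 0L)
    chunk_ids <- sort(unique(exon_ids))
    coding_lens <- vapply(chunk_ids, function(k)
      3L * sum(vapply(el[exon_ids == k], function(e) nchar(e$seq), 0L)), 0L)
    n_coding <- length(coding_lens)
    tx_lens <- c(coding_lens, 150L, 100L)  # two 3'-UTR exons
    n_ex <- length(tx_lens)
    lay <- layout_exons(cursor, tx_lens, strand)
    starts <- lay$starts; ends <- lay$ends
    gene_start <- min(starts); gene_end <- max(ends)

    ref_prot <- elements_to_protein(el)
    event <- NA_character_  # NA: no alternative transcript at all
    if (is_nlr && runif(1) < config$alt_transcript_prob) {
      if (!is.null(id_row)) {
        event <- sample(c("exclusion", "truncation", "retention", "none"),
                        1L, prob = c(config$id_exclusion_prob,
                                     config$id_truncation_prob,
                                     config$intron_retention_prob,
                                     1 - config$id_exclusion_prob -
                                       config$id_truncation_prob -
                                       config$intron_retention_prob))
      } else {
        event <- sample(c("retention", "none"), 1L,
                        prob = c(config$intron_retention_prob,
                                 1 - config$intron_retention_prob))
      }
    }
    has_variant <- is_nlr && !is.na(event)
    if (!has_variant) event <- "none"

    ref_id <- paste0(gid, ".1")
    tx_list <- list(list(transcript_id = ref_id,
                         exon_idx = seq_len(n_ex), n_coding = n_coding,
                         protein = ref_prot, trunc = NULL,
                         merged_utr = FALSE, utr_short = FALSE))
    excluded_acc <- character(0); truncated_acc <- character(0)
    retained_idx <- integer(0)
    if (has_variant && event == "exclusion") {
      id_exon <- unique(exon_ids[vapply(el, function(e)
        identical(e$accession, id_row$accession), TRUE)])
      el_var <- el[exon_ids != id_exon]
      tx_list[[2L]] <- list(
        transcript_id = paste0(gid, ".2"),
        exon_idx = setdiff(seq_len(n_ex), match(id_exon, chunk_ids)),
        n_coding = n_coding - 1L,
        protein = elements_to_protein(el_var), trunc = NULL,
        merged_utr = FALSE, utr_short = FALSE)
      excluded_acc <- id_row$accession
    } else if (has_variant && event == "truncation") {
      id_el <- which(vapply(el, function(e)
        identical(e$accession, id_row$accession), TRUE))[1L]
      full <- el[[id_el]]$seq
      keep_aa <- as.integer(ceiling(nchar(full) / 2))
      el_var <- el
      el_var[[id_el]]$seq <- if (id_row$terminus == "C")
        substr(full, 1L, keep_aa)
      else substr(full, nchar(full) - keep_aa + 1L, nchar(full))
      tx_list[[2L]] <- list(
        transcript_id = paste0(gid, ".2"), exon_idx = seq_len(n_ex),
        n_coding = n_coding, protein = elements_to_protein(el_var),
        trunc = list(exon = match(el[[id_el]]$exon, chunk_ids),
                     drop_nt = 3L * (nchar(full) - keep_aa),
                     terminus = id_row$terminus),
        merged_utr = FALSE, utr_short = FALSE)
      truncated_acc <- id_row$accession
    } else if (has_variant && event == "retention") {
      tx_list[[2L]] <- list(
        transcript_id = paste0(gid, ".2"), exon_idx = seq_len(n_ex),
        n_coding = n_coding, protein = ref_prot, trunc = NULL,
        merged_utr = TRUE, utr_short = FALSE)
      retained_idx <- n_ex - 1L  # the intron between the two UTR exons,
                                 # counted in transcription order
    } else if (has_variant && event == "none") {
      # alternative transcript with an alternative (shorter) 3' end; the
      # encoded protein and domain content are unchanged
      tx_list[[2L]] <- list(
        transcript_id = paste0(gid, ".2"), exon_idx = seq_len(n_ex),
        n_coding = n_coding, protein = ref_prot, trunc = NULL,
        merged_utr = FALSE, utr_short = TRUE)
    }

    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = gid, chromosome = chrom, start = gene_start,
      end = gene_end, strand = strand, stringsAsFactors = FALSE)
    for (tx in tx_list) {
      s <- starts[tx$exon_idx]; e <- ends[tx$exon_idx]
      if (!is.null(tx$trunc)) {
        k <- which(tx$exon_idx == tx$trunc$exon)
        drop_is_right <- (tx$trunc$terminus == "C") == (strand == "+")
        if (drop_is_right) e[k] <- e[k] - tx$trunc$drop_nt
        else s[k] <- s[k] + tx$trunc$drop_nt
      }
      if (tx$merged_utr) {
        u <- (length(s) - 1L):length(s)
        ms <- min(s[u]); me <- max(e[u])
        s <- c(s[-u], ms); e <- c(e[-u], me)
      }
      if (isTRUE(tx$utr_short)) {
        last <- length(s)  # trim 50 bp off the transcript's 3' end
        if (strand == "+") e[last] <- e[last] - 50L
        else s[last] <- s[last] + 50L
      }
      txs[[length(txs) + 1L]] <<- data.frame(
        transcript_id = tx$transcript_id, gene_id = gid,
        chromosome = chrom, strand = strand,
        start = min(s), end = max(e), stringsAsFactors = FALSE)
      exons[[length(exons) + 1L]] <<- data.frame(
        transcript_id = tx$transcript_id, start = s, end = e,
        stringsAsFactors = FALSE)
      ci <- seq_len(tx$n_coding)
      cdss[[length(cdss) + 1L]] <<- data.frame(
        transcript_id = tx$transcript_id, start = s[ci], end = e[ci],
        phase = 0L, stringsAsFactors = FALSE)
      prots[[length(prots) + 1L]] <<- data.frame(
        protein_id = tx$transcript_id, sequence = tx$protein$sequence,
        length = nchar(tx$protein$sequence), stringsAsFactors = FALSE)
      if (nrow(tx$protein$domains) > 0L) {
        d <- tx$protein$domains
        d$protein_id <- tx$transcript_id
        dom_rows[[length(dom_rows) + 1L]] <<- d
      }
    }

    truth_genes[[length(truth_genes) + 1L]] <<- list(
      gene_id = gid, chromosome = chrom,
      subgenome = parse_subgenome(chrom),
      is_nlr = is_nlr, class = if (is_nlr) class_label else NA,
      motif_complete = if (is_nlr) motif_complete else NA,
      cluster_id = cluster_id,
      id_accession = if (!is.null(id_row)) id_row$accession else NA,
      id_protein = if (!is.null(id_row)) {
        r <- ref_prot$domains[ref_prot$domains$accession ==
                                id_row$accession, ]
        list(start = r$start[1L], end = r$end[1L],
             category = id_row$category, terminus = id_row$terminus)
      } else NULL,
      nbarc_interval = if (is_nlr) {
        r <- ref_prot$domains[ref_prot$domains$accession == "PF00931", ]
        c(r$start[1L], r$end[1L])
      } else NULL,
      transcripts = vapply(tx_list, function(t) t$transcript_id, ""),
      has_alt_transcript = has_variant,
      reference_transcript = ref_id,
      variant_event = event,
      excluded_accessions = excluded_acc,
      truncated_accessions = truncated_acc,
      retained_introns = retained_idx)
    gene_end
  }

  # --- lay out chromosomes --------------------------------------------------
  for (chrom in chroms) {
    cursor <- 10000L
    for (slot in seq_len(config$genes_per_chromosome)) {
      is_nlr <- runif(1) < config$nlr_fraction
      strand <- sample(c("+", "-"), 1L)
      if (!is_nlr) {
        plen <- sample(150:400, 1L)
        decoy <- runif(1) < config$decoy_domain_prob
        el <- if (decoy) {
          acc <- sample(lib$accession, 1L)
          list(list(type = "domain", accession = acc,
                    name = lib$name[match(acc, lib$accession)],
                    seq = rand_seq(plen), exon = 1L,
                    protected = integer(0)))
        } else {
          list(list(type = "linker", accession = NA, name = NA,
                    seq = rand_seq(plen), exon = 1L,
                    protected = integer(0)))
        }
        gene_end <- place_gene(chrom, cursor, NA, NA, NULL,
                               NA_character_, strand, el)
        cursor <- gene_end + sample(201000:260000, 1L)
        next
      }
      class_label <- sample(classes, 1L, prob = config$class_proportions)
      motif_complete <- runif(1) < config$motif_complete_prob
      id_acc <- if (runif(1) < config$id_insertion_prob)
        sample(lib$accession, 1L) else NA_character_
      id_row <- if (!is.na(id_acc)) lib[lib$accession == id_acc, ] else NULL
      founder_el <- assemble_elements(class_label, id_row, motif_complete)
      founder_el <- mutate_elements(founder_el, config$base_divergence)
      n_copies <- if (runif(1) < config$tandem_dup_prob)
        2L + rgeom(1L, 0.75) else 1L
      cluster_id <- if (n_copies >= 2L)
        sprintf("true_cluster_%s_%04d", chrom, slot) else NA_character_
      for (cp in seq_len(n_copies)) {
        el <- if (cp == 1L) founder_el else
          mutate_elements(founder_el, config$dup_divergence)
        gene_end <- place_gene(chrom, cursor, class_label, motif_complete,
                               id_row, cluster_id, strand, el)
        cursor <- gene_end + (if (cp < n_copies) sample(2000:20000, 1L)
                              else sample(201000:260000, 1L))
      }
    }
  }

  genes <- do.call(rbind, genes)
  genes$subgenome <- parse_subgenome(genes$chromosome)
  txs <- do.call(rbind, txs)
  exons <- do.call(rbind, exons)
  cdss <- do.call(rbind, cdss)
  prots <- do.call(rbind, prots)
  domains <- do.call(rbind, dom_rows)
  domains <- domains[, c("protein_id", "accession", "name", "start", "end")]
  domains$source <- "Pfam"
  domains$score <- 0
  rownames(domains) <- NULL

  if (config$annotation_fn_rate > 0) {
    keep <- runif(nrow(domains)) >= config$annotation_fn_rate
    domains <- domains[keep, ]
    rownames(domains) <- NULL
  }

  conds <- paste0("condition_", seq_len(config$expression_conditions))
  expr <- data.frame(transcript_id = txs$transcript_id,
                     stringsAsFactors = FALSE)
  for (cc in conds) expr[[cc]] <- round(exp(rnorm(nrow(txs), 3, 1)), 3)

  # --- progenitor and comparator proteomes ---------------------------------
  truth_named <- setNames(truth_genes,
                          vapply(truth_genes, `[[`, "", "gene_id"))
  id_genes <- Filter(function(t) t$is_nlr && !is.na(t$id_accession),
                     truth_genes)
  comp <- list(HV = list(prot = list(), dom = list()),
               TU = list(prot = list(), dom = list()),
               AT = list(prot = list(), dom = list()))
  prot_seq <- setNames(prots$sequence, prots$protein_id)
  blocks <- block_library()
  for (t in id_genes) {
    ref_prot <- prot_seq[[t$reference_transcript]]
    id_seq <- substr(ref_prot, t$id_protein$start, t$id_protein$end)
    # barley (HV) homolog: in NLR context with configured probability
    hv_id <- paste0("HV_", t$gene_id)
    hv_is_nlr <- runif(1) < config$comparator_nlr_homolog_prob
    hv_idseq <- mutate_sequence(id_seq, config$comparator_divergence,
                                alphabet = .BG_ALPHABET)
    if (hv_is_nlr) {
      hv_seq <- paste0(blocks$NBARC$consensus, rand_seq(10L), hv_idseq)
      comp$HV$dom[[length(comp$HV$dom) + 1L]] <- data.frame(
        protein_id = hv_id, accession = "PF00931", name = "NB-ARC",
        start = 1L, end = blocks$NBARC$len, stringsAsFactors = FALSE)
      id_off <- blocks$NBARC$len + 10L
    } else {
      hv_seq <- paste0(rand_seq(30L), hv_idseq, rand_seq(30L))
      id_off <- 30L
    }
    comp$HV$dom[[length(comp$HV$dom) + 1L]] <- data.frame(
      protein_id = hv_id, accession = t$id_accession,
      name = lib$name[match(t$id_accession, lib$accession)],
      start = id_off + 1L, end = id_off + nchar(hv_idseq),
      stringsAsFactors = FALSE)
    comp$HV$prot[[length(comp$HV$prot) + 1L]] <- data.frame(
      protein_id = hv_id, sequence = hv_seq, stringsAsFactors = FALSE)
    # progenitors: which donor carries the closer homolog
    expected <- switch(t$subgenome, A = "TU", D = "AT", NA_character_)
    match_draw <- runif(1) < config$progenitor_match_prob
    closer <- if (is.na(expected)) NA_character_
              else if (match_draw) expected
              else setdiff(c("TU", "AT"), expected)
    for (sp in c("TU", "AT")) {
      rate <- if (!is.na(closer) && sp == closer)
        config$progenitor_divergence else config$progenitor_cross_divergence
      sp_id <- paste0(sp, "_", t$gene_id)
      sp_seq <- paste0(rand_seq(20L),
                       mutate_sequence(id_seq, rate,
                                       alphabet = .BG_ALPHABET),
                       rand_seq(20L))
      comp[[sp]]$prot[[length(comp[[sp]]$prot) + 1L]] <- data.frame(
        protein_id = sp_id, sequence = sp_seq, stringsAsFactors = FALSE)
      comp[[sp]]$dom[[length(comp[[sp]]$dom) + 1L]] <- data.frame(
        protein_id = sp_id, accession = t$id_accession,
        name = lib$name[match(t$id_accession, lib$accession)],
        start = 21L, end = 20L + nchar(id_seq), stringsAsFactors = FALSE)
    }
    truth_named[[t$gene_id]]$progenitor_category <-
      if (t$subgenome == "B") "B"
      else if (is.na(expected)) "U"
      else if (match_draw) "Match"
      else if (t$subgenome == "A") "A" else "D"
    truth_named[[t$gene_id]]$hv_homolog_is_nlr <- hv_is_nlr
  }
  comparators <- lapply(comp, function(x) {
    p <- if (length(x$prot)) do.call(rbind, x$prot) else
      data.frame(protein_id = character(), sequence = character(),
                 stringsAsFactors = FALSE)
    if (nrow(p)) p$length <- nchar(p$sequence) else p$length <- integer(0)
    d <- if (length(x$dom)) do.call(rbind, x$dom) else
      data.frame(protein_id = character(), accession = character(),
                 name = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    d$source <- rep("Pfam", nrow(d)); d$score <- rep(0, nrow(d))
    list(proteins = p, domains = d)
  })

  truth <- list(config = config[setdiff(names(config), "id_library")],
                genes = unname(truth_named))

  out <- list(proteins = prots, genes = genes, transcripts = txs,
              exons = exons, cds = cdss, domains = domains,
              expression = expr, comparators = comparators, truth = truth)
  if (!is.null(out_dir)) write_generated(out, out_dir)
  out
}

#' Write a generated data set to standard-format files
#'
#' Emits `proteome.fasta`, `genome.gff3`, `domains.tsv`,
#' `expression.tsv`, per-species comparator proteomes/domain tables and
#' `truth.json` into `out_dir`.
#'
#' @param gen Output of [generate()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_generated <- function(gen, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(gen$proteins, file.path(out_dir, "proteome.fasta"))
  write_gff3(gen, file.path(out_dir, "genome.gff3"))
  write_domain_table(gen$domains, file.path(out_dir, "domains.tsv"))
  write_outputs(gen$expression, file.path(out_dir, "expression.tsv"), "TSV")
  for (sp in names(gen$comparators)) {
    write_fasta(gen$comparators[[sp]]$proteins,
                file.path(out_dir, paste0("proteome_", sp, ".fasta")))
    write_domain_table(gen$comparators[[sp]]$domains,
                       file.path(out_dir, paste0("domains_", sp, ".tsv")))
  }
  write_outputs(gen$truth, file.path(out_dir, "truth.json"), "JSON")
  invisible(out_dir)
}

#' Write gene models to GFF3
#'
#' @param gen Generator output (or any list with `genes`, `transcripts`,
#'   `exons`, `cds` tables of the same shape).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gen, path) {
  lines <- c("##gff-version 3")
  fmt <- function(chrom, type, s, e, strand, phase, attrs)
    paste(chrom, "nlrforge", type, s, e, ".", strand, phase, attrs,
          sep = "\t")
  tx_by_gene <- split(gen$transcripts, gen$transcripts$gene_id)
  ex_by_tx <- split(gen$exons, gen$exons$transcript_id)
  cds_by_tx <- split(gen$cds, gen$cds$transcript_id)
  out <- vector("list", nrow(gen$genes))
  for (i in seq_len(nrow(gen$genes))) {
    g <- gen$genes[i, ]
    block <- fmt(g$chromosome, "gene", g$start, g$end, g$strand, ".",
                 paste0("ID=", g$gene_id))
    gtx <- tx_by_gene[[g$gene_id]]
    for (k in seq_len(nrow(gtx))) {
      tx <- gtx[k, ]
      block <- c(block, fmt(g$chromosome, "mRNA", tx$start, tx$end,
                            g$strand, ".",
                            paste0("ID=", tx$transcript_id, ";Parent=",
                                   g$gene_id)))
      ex <- ex_by_tx[[tx$transcript_id]]
      ex <- ex[order(ex$start), ]
      block <- c(block, fmt(g$chromosome, "exon", ex$start, ex$end,
                            g$strand, ".",
                            paste0("Parent=", tx$transcript_id)))
      cd <- cds_by_tx[[tx$transcript_id]]
      if (!is.null(cd)) {
        cd <- cd[order(cd$start), ]
        block <- c(block, fmt(g$chromosome, "CDS", cd$start, cd$end,
                              g$strand, cd$phase,
                              paste0("Parent=", tx$transcript_id)))
      }
    }
    out[[i]] <- block
  }
  writeLines(c(lines, unlist(out)), path)
  invisible(path)
}

#' Write a domain table in the InterProScan 5 TSV dialect
#'
#' @param domains Domain table (`protein_id`, `accession`, `name`, `start`,
#'   `end`, optionally `source`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  src <- if ("source" %in% names(domains)) domains$source else "Pfam"
  score <- if ("score" %in% names(domains)) domains$score else 0
  lines <- paste(domains$protein_id, "-", "-", src, domains$accession,
                 domains$name, domains$start, domains$end, score, "T", "-",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
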