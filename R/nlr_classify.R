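# NB-ARC identification, motif scanning and NLR architecture classification.

#' Default core NLR accession sets
#'
#' Pfam accession sets defining the canonical NLR building blocks. Only the
#' NB-ARC accession (PF00931) is universal; the remaining sets are explicit,
#' curated defaults and every element is overrideable. Coiled-coil evidence
#' additionally accepts any hit named `RX-CC_like` or a `Coils` source row
#' (see [classify_architecture()]).
#'
#' @return Named list of character vectors: `nbarc`, `tir`, `rpw8`, `cc`,
#'   `lrr`.
#' @export
core_accessions <- function() {
  list(nbarc = "PF00931",
       tir   = c("PF01582", "PF13676"),
       rpw8  = "PF05659",
       cc    = "PF18052",
       lrr   = c("PF00560", "PF07725", "PF12799", "PF13306", "PF13855",
                 "PF08263"))
}

#' Default NB-ARC motif patterns
#'
#' Regular expressions for the three conserved NB-ARC motifs whose joint
#' presence marks a motif-complete NB-ARC: the Walker-A P-loop, the Walker-B
#' Kinase-2 motif and the GLPL loop. Literature consensus forms are used;
#' all three are configurable.
#'
#' @return Named character vector (ordered: P-loop, Kinase-2, GLPL).
#' @export
default_motif_patterns <- function() {
  c("P-loop"   = "[GA].{2,4}GK[ST]",
    "Kinase-2" = "[LIVMF]{2}.{2}[DE]D.[WD]",
    "GLPL"     = "G[LIVMF]P[LS]")
}

#' Identify NB-ARC-containing proteins
#'
#' Returns exactly the proteins with at least one domain hit whose accession
#' belongs to the NB-ARC accession set (default PF00931).
#'
#' @param domain_hits data.frame from [read_domain_table()].
#' @param nbarc_accessions Character vector of NB-ARC accessions.
#' @return Character vector of unique protein identifiers.
#' @export
find_nbarc_proteins <- function(domain_hits,
                                nbarc_accessions = core_accessions()$nbarc) {
  if (nrow(domain_hits) == 0L) {
    nlr_warn("empty domain hit table: no NB-ARC proteins found")
    return(character(0))
  }
  sort(unique(domain_hits$protein_id[
    domain_hits$accession %in% nbarc_accessions]))
}

#' Scan a protein's NB-ARC region for conserved motifs
#'
#' Each motif is searched within the NB-ARC interval extended by `flank`
#' residues on both sides. With `ordered = TRUE` (default) the motifs must
#' occur in the canonical order P-loop < Kinase-2 < GLPL: each motif is
#' searched downstream of the previous motif's match. The first match per
#' motif is reported.
#'
#' @param sequence Protein sequence (character scalar).
#' @param nbarc_start,nbarc_end 1-based NB-ARC hit coordinates on the
#'   protein.
#' @param motif_patterns Ordered named character vector of regular
#'   expressions (default [default_motif_patterns()]).
#' @param flank Residues of flank added to each side of the NB-ARC interval
#'   (default 30).
#' @param ordered Enforce the canonical motif order (default TRUE).
#' @return data.frame `motif_name`, `position` (1-based, on the protein),
#'   `matched`; attribute `motif_complete` is TRUE iff all motifs matched.
#' @export
scan_motifs <- function(sequence, nbarc_start, nbarc_end,
                        motif_patterns = default_motif_patterns(),
                        flank = 30L, ordered = TRUE) {
  L <- nchar(sequence)
  stopifnot(nbarc_start >= 1L, nbarc_end <= L, nbarc_start <= nbarc_end)
  for (p in motif_patterns) {
    ok <- tryCatch({ grepl(p, "A"); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("motif pattern does not compile: ", p, call. = FALSE)
  }
  lo <- max(1L, nbarc_start - flank)
  hi <- min(L, nbarc_end + flank)
  region <- substr(sequence, lo, hi)
  hits <- list()
  from <- 1L
  for (nm in names(motif_patterns)) {
    sub <- substr(region, from, nchar(region))
    m <- regexpr(motif_patterns[[nm]], sub, perl = TRUE)
    if (m[1L] == -1L) next
    pos_region <- from + as.integer(m[1L]) - 1L
    matched <- substr(region, pos_region,
                      pos_region + attr(m, "match.length") - 1L)
    hits[[nm]] <- data.frame(motif_name = nm,
                             position = lo + pos_region - 1L,
                             matched = matched, stringsAsFactors = FALSE)
    if (ordered) from <- pos_region + attr(m, "match.length")
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif_name = character(), position = integer(),
               matched = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "motif_complete") <-
    all(names(motif_patterns) %in% out$motif_name)
  out
}

#' Classify the domain architecture of an NB-ARC protein
#'
#' Sets presence flags from accession membership in the configured core
#' sets and composes the class label: the N-terminal letter comes from
#' exactly one of TIR (`T`), CC (`C`) or RPW8 (`R`) — priority TIR > CC >
#' RPW8, with a warning when several co-occur — followed by `N`, and an `L`
#' suffix iff an LRR accession is present. Possible labels: CNL, TNL, RNL,
#' CN, TN, RN, NL, N. Coiled-coil evidence is a `cc` accession, a hit named
#' `RX-CC_like`, or a row whose source is `Coils`.
#'
#' @param protein_id Protein identifier (must be NB-ARC-positive).
#' @param domain_hits Domain table (all proteins or just this one).
#' @param core Accession sets as from [core_accessions()].
#' @param motif_complete Optional logical from [scan_motifs()].
#' @return One-row data.frame: `protein_id`, `has_nbarc`, `has_cc`,
#'   `has_tir`, `has_rpw8`, `has_lrr`, `motif_complete`, `class_label`.
#' @export
classify_architecture <- function(protein_id, domain_hits,
                                  core = core_accessions(),
                                  motif_complete = NA) {
  h <- domain_hits[domain_hits$protein_id == protein_id, , drop = FALSE]
  has_nbarc <- any(h$accession %in% core$nbarc)
  if (!has_nbarc)
    stop("protein '", protein_id, "' has no NB-ARC hit; not classifiable",
         call. = FALSE)
  has_tir <- any(h$accession %in% core$tir)
  has_cc <- any(h$accession %in% core$cc) |
    any(grepl("RX-CC_like", h$name, ignore.case = TRUE)) |
    any(h$source == "Coils", na.rm = TRUE)
  has_rpw8 <- any(h$accession %in% core$rpw8)
  has_lrr <- any(h$accession %in% core$lrr)
  if (sum(c(has_tir, has_cc, has_rpw8)) > 1L)
    nlr_warn("protein '%s' carries multiple N-terminal domain types; using priority TIR > CC > RPW8",
             protein_id)
  data.frame(protein_id = protein_id, has_nbarc = TRUE, has_cc = has_cc,
             has_tir = has_tir, has_rpw8 = has_rpw8, has_lrr = has_lrr,
             motif_complete = motif_complete,
             class_label = compose_class_label(has_tir, has_cc, has_rpw8,
                                               has_lrr),
             stringsAsFactors = FALSE)
}

#' Compose an NLR class label from domain-presence flags
#'
#' @param has_tir,has_cc,has_rpw8,has_lrr Logical flags.
#' @return Class label string (vectorised).
#' @export
compose_class_label <- function(has_tir, has_cc, has_rpw8, has_lrr) {
  nterm <- ifelse(has_tir, "T", ifelse(has_cc, "C", ifelse(has_rpw8, "R", "")))
  paste0(nterm, "N", ifelse(has_lrr, "L", ""))
}

# Rank architectures by richness: number of TRUE flags, ties broken by the
# N-terminal priority TIR > CC > RPW8, then by LRR.
architecture_richness <- function(arch) {
  flags <- arch[, c("has_tir", "has_cc", "has_rpw8", "has_lrr")]
  rowSums(flags) * 10 + 3 * arch$has_tir + 2 * arch$has_cc + arch$has_rpw8
}

#' Census of NLR architectures
#'
#' Summarises per-protein architectures at protein and gene level. A gene is
#' counted once, under its architecture-richest protein (most domain flags;
#' ties by N-terminal priority); a gene is motif-complete if any of its
#' proteins is.
#'
#' @param architectures data.frame of rows from [classify_architecture()].
#' @param protein_gene Optional data.frame `protein_id`, `gene_id` (and
#'   optionally `chromosome`, `subgenome`) mapping proteins to genes. When
#'   absent each protein is treated as its own gene.
#' @return Object of class `nlr_census`: list with `by_class` (gene counts
#'   per class), `by_protein_class`, `by_chromosome`, `by_subgenome`,
#'   `n_genes`, `n_proteins`, `n_motif_complete_genes` and the per-gene
#'   table `genes`.
#' @export
census <- function(architectures, protein_gene = NULL) {
  all_classes <- c("CNL", "TNL", "RNL", "CN", "TN", "RN", "NL", "N")
  if (nrow(architectures) == 0L) {
    z <- setNames(integer(length(all_classes)), all_classes)
    return(structure(list(by_class = z, by_protein_class = z,
                          by_chromosome = table(character(0)),
                          by_subgenome = table(character(0)),
                          n_genes = 0L, n_proteins = 0L,
                          n_motif_complete_genes = 0L,
                          genes = data.frame()), class = "nlr_census"))
  }
  a <- architectures
  if (is.null(protein_gene))
    protein_gene <- data.frame(protein_id = a$protein_id,
                               gene_id = a$protein_id,
                               stringsAsFactors = FALSE)
  a <- merge(a, protein_gene, by = "protein_id", all.x = TRUE)
  a$gene_id[is.na(a$gene_id)] <- a$protein_id[is.na(a$gene_id)]
  a$richness <- architecture_richness(a)
  ord <- order(a$gene_id, -a$richness, a$protein_id)
  a <- a[ord, ]
  genes <- a[!duplicated(a$gene_id), , drop = FALSE]
  mc <- tapply(a$motif_complete, a$gene_id, function(x) any(x %in% TRUE))
  genes$motif_complete <- as.logical(mc[genes$gene_id])
  cls <- factor(genes$class_label, levels = all_classes)
  pcls <- factor(architectures$class_label, levels = all_classes)
  out <- list(
    by_class = table(cls),
    by_protein_class = table(pcls),
    by_chromosome = if ("chromosome" %in% names(genes))
      table(genes$chromosome) else table(character(0)),
    by_subgenome = if ("subgenome" %in% names(genes))
      table(genes$subgenome) else table(character(0)),
    n_genes = nrow(genes),
    n_proteins = nrow(architectures),
    n_motif_complete_genes = sum(genes$motif_complete, na.rm = TRUE),
    genes = genes[, setdiff(names(genes), "richness")])
  structure(out, class = "nlr_census")
}

#' @export
print.nlr_census <- function(x, ...) {
  cat("NLR census:", x$n_genes, "NB-ARC genes /", x$n_proteins,
      "proteins;", x$n_motif_complete_genes, "motif-complete genes\n")
  cat("Gene counts by class:\n")
  print(x$by_class)
  invisible(x)
}

#' @export
summary.nlr_census <- function(object, ...) {
  data.frame(class = names(object$by_class),
             n_genes = as.integer(object$by_class),
             fraction = as.integer(object$by_class) /
               max(1L, object$n_genes))
}
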