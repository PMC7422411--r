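# Integrated-domain (NLR-ID) extraction, relative positioning and
# functional categorisation.

#' Extract integrated domains from an NB-ARC protein
#'
#' Every Pfam hit on the protein whose accession is outside the core NLR
#' sets (NB-ARC, TIR, CC, RPW8, LRR) is an integrated domain (ID). Non-Pfam
#' evidence rows (coils, transmembrane, signal peptide and similar) are not
#' called as IDs. Multiple copies of one accession are all retained;
#' `n_copies_in_protein` records the per-accession copy number.
#'
#' @param protein_id Protein identifier (must be NB-ARC-positive).
#' @param domain_hits Domain table for one or more proteins.
#' @param protein_length Protein length in residues (for relative
#'   positions); may be NA to skip them.
#' @param core Core accession sets, see [core_accessions()].
#' @param category_map Category map, see [default_category_map()].
#' @return data.frame with columns `protein_id`, `accession`, `name`,
#'   `start`, `end`, `rel_start`, `rel_end`, `rel_mid`, `category`,
#'   `n_copies_in_protein` (zero rows if the protein has no ID).
#' @export
extract_ids <- function(protein_id, domain_hits, protein_length = NA,
                        core = core_accessions(),
                        category_map = default_category_map()) {
  h <- domain_hits[domain_hits$protein_id == protein_id, , drop = FALSE]
  if (!any(h$accession %in% core$nbarc))
    stop("protein '", protein_id, "' is not NB-ARC-positive", call. = FALSE)
  core_acc <- unlist(core, use.names = FALSE)
  is_id <- !(h$accession %in% core_acc) &
    (is.na(h$source) | h$source %in% c("Pfam", "other")) &
    grepl("^PF\\d{5}$", h$accession)
  ids <- h[is_id, , drop = FALSE]
  if (nrow(ids) == 0L)
    return(data.frame(protein_id = character(), accession = character(),
                      name = character(), start = integer(),
                      end = integer(), rel_start = numeric(),
                      rel_end = numeric(), rel_mid = numeric(),
                      category = character(),
                      n_copies_in_protein = integer(),
                      stringsAsFactors = FALSE))
  ids <- ids[order(ids$start, ids$accession), ]
  rel <- if (is.na(protein_length)) {
    data.frame(rel_start = NA_real_, rel_end = NA_real_, rel_mid = NA_real_)
  } else relative_position(ids$start, ids$end, protein_length)
  copies <- table(ids$accession)
  out <- data.frame(protein_id = ids$protein_id, accession = ids$accession,
                    name = ids$name, start = ids$start, end = ids$end,
                    rel_start = rel$rel_start, rel_end = rel$rel_end,
                    rel_mid = rel$rel_mid,
                    category = vapply(seq_len(nrow(ids)), function(k)
                      categorize_id(ids$name[k], ids$accession[k],
                                    category_map), ""),
                    n_copies_in_protein =
                      as.integer(copies[ids$accession]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Relative position of a domain on its protein
#'
#' For a hit at 1-based inclusive residues `start..end` on a protein of
#' length `L`: `rel_start = (start - 1) / L`, `rel_end = end / L`,
#' `rel_mid = (rel_start + rel_end) / 2`, all in \[0, 1\]. A hit spanning
#' the whole protein maps to (0, 1, 0.5).
#'
#' @param start,end Integer vectors of hit coordinates.
#' @param protein_length Protein length in residues (> 0).
#' @return data.frame `rel_start`, `rel_end`, `rel_mid`.
#' @export
relative_position <- function(start, end, protein_length) {
  if (any(protein_length <= 0))
    stop("protein length must be positive", call. = FALSE)
  stopifnot(all(start >= 1), all(end >= start), all(end <= protein_length))
  rs <- (start - 1) / protein_length
  re <- end / protein_length
  data.frame(rel_start = rs, rel_end = re, rel_mid = (rs + re) / 2)
}

#' Default integrated-domain category map
#'
#' Curated keyword/accession map grouping ID types into the functional
#' categories kinase, DNA-binding and other-signaling; anything unmatched is
#' `unknown`. Lookup is by accession first, then by case-insensitive name
#' keyword. The shipped map (inst/extdata/id_categories.yaml) covers the
#' recurrent ID families seen in wheat NLR fusions (kinases, WRKY, AP2, B3,
#' Myb, BED zinc finger, jacalin, thioredoxin, ubiquitin-conjugating,
#' kelch, Exo70, ...) and is user-extensible.
#'
#' @return List with elements `accessions` (named character: accession ->
#'   category) and `keywords` (named character: regex -> category, in
#'   priority order).
#' @export
default_category_map <- function() {
  if (is.null(.nlr_env$category_map)) {
    path <- system.file("extdata", "id_categories.yaml",
                        package = "nlrforge")
    .nlr_env$category_map <- yaml::read_yaml(path)
  }
  .nlr_env$category_map
}

#' Assign a functional category to an integrated domain
#'
#' @param name Domain name/description (e.g. `"WRKY DNA-binding domain"`).
#' @param accession Pfam accession (used for the primary lookup).
#' @param category_map Map as from [default_category_map()].
#' @return One of `"kinase"`, `"DNA-binding"`, `"other-signaling"`,
#'   `"unknown"`.
#' @export
categorize_id <- function(name, accession = NA,
                          category_map = default_category_map()) {
  acc_map <- unlist(category_map$accessions)
  if (!is.na(accession) && accession %in% names(acc_map))
    return(unname(acc_map[[accession]]))
  if (!is.na(name)) {
    for (kw in names(category_map$keywords)) {
      if (grepl(kw, name, ignore.case = TRUE))
        return(category_map$keywords[[kw]])
    }
  }
  "unknown"
}

#' Positional profile of integrated-domain types
#'
#' Per ID accession: occurrence count, mean relative start/mid/end (averaged
#' over every occurrence) and functional category — the summary behind
#' "average ID location relative to protein length".
#'
#' @param integrated_domains data.frame of rows from [extract_ids()]
#'   (several proteins concatenated).
#' @return data.frame `accession`, `name`, `category`, `n`, `mean_rel_start`,
#'   `mean_rel_mid`, `mean_rel_end`, sorted by decreasing `n`.
#' @export
positional_profile <- function(integrated_domains) {
  stopifnot(nrow(integrated_domains) >= 1L)
  sp <- split(integrated_domains, integrated_domains$accession)
  rows <- lapply(sp, function(x) data.frame(
    accession = x$accession[1L], name = x$name[1L],
    category = x$category[1L], n = nrow(x),
    mean_rel_start = mean(x$rel_start), mean_rel_mid = mean(x$rel_mid),
    mean_rel_end = mean(x$rel_end), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$n, out$accession), ]
  rownames(out) <- NULL
  out
}
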