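# NB-ARC identification, motif scanning, architecture classes and census.

mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1L]], accession = r[[2L]],
               name = r[[3L]], start = as.integer(r[[4L]]),
               end = as.integer(r[[5L]]), source = "Pfam", score = 0,
               stringsAsFactors = FALSE)))
}

test_that("NB-ARC proteins are exactly those with a PF00931 hit", {
  h <- mk_hits(list("p1", "PF00931", "NB-ARC", 100, 260),
               list("p1", "PF00931", "NB-ARC", 300, 460),
               list("p2", "PF00069", "Protein kinase domain", 1, 150))
  expect_equal(find_nbarc_proteins(h), "p1")  # two hits count once
  expect_warning(out <- find_nbarc_proteins(h[0, ]), "empty")
  expect_length(out, 0L)
})

test_that("motif scan finds canonical motifs in order within the flank", {
  region <- paste0(strrep("A", 20), "GGVGKTT", strrep("A", 30),
                   "LLAADDAW", strrep("A", 30), "GLPL", strrep("A", 10))
  seq <- paste0(strrep("C", 50), region, strrep("C", 50))
  sc <- scan_motifs(seq, 51, 50 + nchar(region))
  expect_setequal(sc$motif_name, c("P-loop", "Kinase-2", "GLPL"))
  expect_true(attr(sc, "motif_complete"))
  # matched substrings equal the sequence at the reported positions
  for (k in seq_len(nrow(sc)))
    expect_equal(substr(seq, sc$position[k],
                        sc$position[k] + nchar(sc$matched[k]) - 1L),
                 sc$matched[k])
  expect_true(all(diff(sc$position[match(c("P-loop", "Kinase-2", "GLPL"),
                                         sc$motif_name)]) > 0))
})

test_that("motif-free regions yield no hits and motif_complete FALSE", {
  seq <- strrep("A", 200)
  sc <- scan_motifs(seq, 30, 170)
  expect_equal(nrow(sc), 0L)
  expect_false(attr(sc, "motif_complete"))
  expect_error(scan_motifs(seq, 30, 170, motif_patterns = c(bad = "[")),
               "compile")
})

test_that("planted generator motifs are recovered at their planted offsets", {
  gen <- generate(simulation_config(seed = 21, n_chromosomes = 1L,
                                    genes_per_chromosome = 40L))
  tg <- gen$truth$genes
  seq_of <- setNames(gen$proteins$sequence, gen$proteins$protein_id)
  offsets <- vapply(nlrforge:::.NBARC_MOTIFS, `[[`, 0L, "offset")
  n_checked <- 0L
  for (t in tg) {
    if (!t$is_nlr || !isTRUE(t$motif_complete)) next
    s <- seq_of[[t$reference_transcript]]
    sc <- scan_motifs(s, t$nbarc_interval[1L], t$nbarc_interval[2L])
    expect_true(attr(sc, "motif_complete"))
    expect_equal(setNames(sc$position, sc$motif_name),
                 t$nbarc_interval[1L] + offsets - 1L)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 3L)
})

test_that("architecture classes compose from domain flags with TIR priority", {
  cnl <- mk_hits(list("p1", "PF00931", "NB-ARC", 200, 360),
                 list("p1", "PF18052", "RX-CC_like", 1, 100),
                 list("p1", "PF13855", "LRR_8", 400, 470))
  expect_equal(classify_architecture("p1", cnl)$class_label, "CNL")

  bare <- mk_hits(list("p2", "PF00931", "NB-ARC", 1, 160))
  expect_equal(classify_architecture("p2", bare)$class_label, "N")

  tn <- mk_hits(list("p3", "PF00931", "NB-ARC", 200, 360),
                list("p3", "PF01582", "TIR", 1, 170))
  expect_equal(classify_architecture("p3", tn)$class_label, "TN")

  both <- mk_hits(list("p4", "PF00931", "NB-ARC", 300, 460),
                  list("p4", "PF01582", "TIR", 1, 170),
                  list("p4", "PF18052", "RX-CC_like", 180, 280))
  expect_warning(a <- classify_architecture("p4", both), "priority")
  expect_equal(a$class_label, "TN")

  expect_error(classify_architecture("p9", bare), "no NB-ARC")

  # coiled-coil evidence via a Coils row counts as CC
  co <- mk_hits(list("p5", "PF00931", "NB-ARC", 200, 360))
  co <- rbind(co, data.frame(protein_id = "p5", accession = "Coil",
                             name = "coiled-coil", start = 1, end = 40,
                             source = "Coils", score = 0))
  expect_equal(classify_architecture("p5", co)$class_label, "CN")
})

test_that("census collapses genes to their richest architecture", {
  h <- rbind(
    mk_hits(list("g1.1", "PF00931", "NB-ARC", 200, 360),
            list("g1.1", "PF18052", "RX-CC_like", 1, 100),
            list("g1.1", "PF13855", "LRR_8", 400, 470)),
    mk_hits(list("g1.2", "PF00931", "NB-ARC", 200, 360),
            list("g1.2", "PF13855", "LRR_8", 400, 470)))
  arch <- rbind(classify_architecture("g1.1", h, motif_complete = TRUE),
                classify_architecture("g1.2", h, motif_complete = FALSE))
  pg <- data.frame(protein_id = c("g1.1", "g1.2"), gene_id = "g1")
  cen <- census(arch, pg)
  expect_equal(cen$n_genes, 1L)
  expect_equal(as.integer(cen$by_class["CNL"]), 1L)
  expect_equal(sum(cen$by_class), 1L)
  expect_equal(cen$n_motif_complete_genes, 1L)  # any protein counts

  empty <- census(arch[0, ])
  expect_equal(empty$n_genes, 0L)
  expect_true(all(empty$by_class == 0L))
})

test_that("census class proportions recover the planted distribution", {
  cfg <- simulation_config(seed = 23, n_chromosomes = 9L,
                           genes_per_chromosome = 90L)
  gen <- generate(cfg)
  res <- analyze_nlr(gen$proteins, gen$genes, gen$transcripts,
                     domains = gen$domains, stages = "census")
  cen <- res$census
  # every NB-ARC gene classified; totals add up
  expect_equal(sum(cen$by_class), cen$n_genes)
  n <- cen$n_genes
  p_obs <- as.numeric(cen$by_class[names(cfg$class_proportions)]) / n
  p_true <- as.numeric(cfg$class_proportions)
  # tandem copies inherit their founder's class, so draws are clustered;
  # use the founder count (about n / mean cluster size) as effective n
  n_eff <- n / 2
  hw <- 2.576 * sqrt(p_true * (1 - p_true) / n_eff)  # 99% binomial CI
  expect_true(all(abs(p_obs - p_true) <= pmax(hw, 3 / n)))
  # motif-complete genes within CI of the planted 0.70
  expect_lt(abs(cen$n_motif_complete_genes / n - cfg$motif_complete_prob),
            2.576 * sqrt(0.7 * 0.3 / n_eff) + 1 / n)
})

test_that("class labels regenerate idempotently from flags", {
  set.seed(24)
  for (k in 1:20) {
    fl <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    lab <- compose_class_label(fl[1], fl[2], fl[3], fl[4])
    expect_match(lab, "^[TCR]?NL?$")
    expect_equal(compose_class_label(fl[1], fl[2], fl[3], fl[4]), lab)
  }
})
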