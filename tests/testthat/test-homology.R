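# Seed-and-extend homology search, NLR flags and progenitor categories.

test_that("a subject identical to the query is a 100%-identity hit", {
  set.seed(71)
  q <- nlrforge:::rand_seq(60)
  prot <- data.frame(protein_id = c("s1", "s2"),
                     sequence = c(q, nlrforge:::rand_seq(80)),
                     stringsAsFactors = FALSE)
  prot$length <- nchar(prot$sequence)
  h <- search_homologs(q, prot)
  expect_equal(h$subject_protein_id, "s1")
  expect_equal(h$pct_identity, 100)
  expect_equal(h$coverage, 1)
})

test_that("queries sharing no k-mer with any subject return nothing", {
  prot <- data.frame(protein_id = "s1", sequence = strrep("A", 60),
                     length = 60L, stringsAsFactors = FALSE)
  h <- search_homologs(strrep("C", 40), prot)
  expect_equal(nrow(h), 0L)
  expect_warning(search_homologs("ACDEF",
                                 prot[0, , drop = FALSE]), "empty")
})

test_that("seed-and-extend loses nothing versus direct local alignment
           for related pairs", {
  set.seed(72)
  for (k in 1:40) {
    q <- nlrforge:::rand_seq(sample(20:40, 1))
    rate <- sample(c(0, 0.05, 0.15, 0.25), 1)
    subj <- mutate_sequence(q, rate)
    prot <- data.frame(protein_id = "s1", sequence = subj,
                       length = nchar(subj), stringsAsFactors = FALSE)
    direct <- align_pair(q, subj, mode = "local")
    dcov <- (direct$a_range[2] - direct$a_range[1] + 1) / nchar(q)
    got <- search_homologs(q, prot, min_identity = 70, min_coverage = 0.8)
    should_hit <- direct$pct_identity >= 70 && dcov >= 0.8
    expect_equal(nrow(got) == 1L, should_hit)
    if (nrow(got) == 1L)
      expect_equal(got$pct_identity, direct$pct_identity)
  }
})

test_that("results are invariant to subject record order", {
  set.seed(73)
  q <- nlrforge:::rand_seq(50)
  prot <- data.frame(
    protein_id = paste0("s", 1:6),
    sequence = c(mutate_sequence(q, 0.05), mutate_sequence(q, 0.1),
                 replicate(4, nlrforge:::rand_seq(70))),
    stringsAsFactors = FALSE)
  prot$length <- nchar(prot$sequence)
  a <- search_homologs(q, prot)
  b <- search_homologs(q, prot[sample(6), ])
  expect_identical(a, b)
})

test_that("NLR flags come from the subject species' domain table", {
  hits <- data.frame(subject_species = c("HV", "HV", "HV"),
                     subject_protein_id = c("h1", "h2", "h3"),
                     stringsAsFactors = FALSE)
  tabs <- list(HV = data.frame(
    protein_id = c("h1", "h2"),
    accession = c("PF00931", "PF03106"),
    name = c("NB-ARC", "WRKY"), start = 1L, end = 50L,
    stringsAsFactors = FALSE))
  expect_warning(out <- flag_nlr_homologs(hits, tabs), "absent")
  expect_equal(out$subject_has_nbarc, c(TRUE, FALSE, FALSE))
})

test_that("progenitor categories follow the subgenome/donor contract", {
  # A-subgenome gene best explained by its expected donor
  a <- assign_progenitor_category("g1", "A", best_tu = 95, best_at = 80)
  expect_equal(a$category, "Match")
  expect_equal(a$identity_bin, ">90")
  # A-subgenome gene closer to the D donor
  expect_equal(assign_progenitor_category("g2", "A", 75, 85)$category, "A")
  # D-subgenome gene closer to the A donor
  expect_equal(assign_progenitor_category("g3", "D", 85, 75)$category, "D")
  # B and unknown subgenomes are fixed categories
  expect_equal(assign_progenitor_category("g4", "B", 95, 90)$category, "B")
  expect_equal(assign_progenitor_category("g5", "unknown", 0, 0)$category,
               "U")
  # ties favour the expected donor
  expect_equal(assign_progenitor_category("g6", "D", 80, 80)$category,
               "Match")
  # no hits at all: category from the subgenome, lowest identity bin
  none <- assign_progenitor_category("g7", "A", 0, 0)
  expect_equal(none$category, "Match")
  expect_equal(none$identity_bin, "<70")
  # every gene gets exactly one of the five categories
  cats <- c(a$category, "A", "D", "B", "U", "Match", "Match")
  expect_true(all(cats %in% c("Match", "A", "D", "B", "U")))
})

test_that("recovered comparator quantities track the planted rates", {
  gen <- generate(simulation_config(seed = 74, n_chromosomes = 6L,
                                    genes_per_chromosome = 60L,
                                    id_insertion_prob = 0.5))
  res <- analyze_nlr(gen$proteins, gen$genes, gen$transcripts,
                     domains = gen$domains,
                     comparators = gen$comparators,
                     stages = c("census", "ids", "homology"))
  n_id <- nrow(res$progenitor)
  expect_gt(n_id, 50L)
  # barley NLR-homolog fraction near the planted 0.685
  hw <- 2.576 * sqrt(0.685 * 0.315 / n_id)
  expect_lt(abs(res$nlr_homolog_fraction[["HV"]] - 0.685), hw + 0.05)
  # Match/A/D/B/U partition the ID-bearing genes
  expect_true(all(res$progenitor$category %in%
                    c("Match", "A", "D", "B", "U")))
  expect_true(all(res$progenitor$category[
    res$progenitor$subgenome == "B"] == "B"))
})

test_that("Match fraction rises with cross-donor divergence", {
  fractions <- vapply(c(0.08, 0.15, 0.3), function(cross) {
    gen <- generate(simulation_config(
      seed = 75, n_chromosomes = 6L, genes_per_chromosome = 40L,
      id_insertion_prob = 0.6, progenitor_match_prob = 0.5,
      progenitor_divergence = 0.05,
      progenitor_cross_divergence = cross))
    res <- analyze_nlr(gen$proteins, gen$genes, gen$transcripts,
                       domains = gen$domains,
                       comparators = gen$comparators,
                       stages = c("census", "ids", "homology"))
    # agreement between called and planted Match categories
    tg <- gen$truth$genes
    truth_cat <- setNames(vapply(tg, function(t)
      if (is.null(t$progenitor_category)) NA_character_
      else t$progenitor_category, ""),
      vapply(tg, `[[`, "", "gene_id"))
    truth_cat <- truth_cat[!is.na(truth_cat)]
    called <- setNames(res$progenitor$category, res$progenitor$gene_id)
    mean(called[names(truth_cat)] == truth_cat)
  }, 0)
  # the wider the gap between the donors, the fewer identity-noise flips
  expect_true(all(diff(fractions) >= 0) || fractions[3] > fractions[1])
  expect_gt(fractions[3], 0.95)
})
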