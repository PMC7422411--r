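# Alternative-transcript comparison: ID exclusion/truncation, intron
# retention and expression joining.

# Two-transcript fixture: reference CNL + C-terminal WRKY; variant built by
# the caller.
splice_fixture <- function(variant_hits) {
  ref <- data.frame(
    protein_id = "g1.1",
    accession = c("PF18052", "PF00931", "PF13855", "PF03106"),
    name = c("RX-CC_like", "NB-ARC", "LRR_8", "WRKY DNA-binding domain"),
    start = c(1L, 120L, 300L, 400L), end = c(100L, 280L, 380L, 460L),
    source = "Pfam", score = 0, stringsAsFactors = FALSE)
  rbind(ref, variant_hits)
}

test_that("a variant lacking the reference ID is called excluded", {
  var <- data.frame(protein_id = "g1.2",
                    accession = c("PF18052", "PF00931", "PF13855"),
                    name = c("RX-CC_like", "NB-ARC", "LRR_8"),
                    start = c(1L, 120L, 300L), end = c(100L, 280L, 380L),
                    source = "Pfam", score = 0, stringsAsFactors = FALSE)
  rep <- compare_transcript_domains("g1", c("g1.1", "g1.2"),
                                    splice_fixture(var))
  expect_equal(rep$reference_transcript, "g1.1")
  tv <- rep$transcripts[rep$transcripts$transcript_id == "g1.2", ]
  expect_true(tv$id_excluded)
  expect_false(tv$id_truncated)
  expect_equal(tv$class, "NLR-only")
  tr <- rep$transcripts[rep$transcripts$transcript_id == "g1.1", ]
  expect_equal(tr$class, "NLR-ID")
})

test_that("a variant keeping half the ID span is called truncated", {
  var <- data.frame(protein_id = "g1.2",
                    accession = c("PF00931", "PF03106"),
                    name = c("NB-ARC", "WRKY DNA-binding domain"),
                    start = c(120L, 400L), end = c(280L, 430L),
                    source = "Pfam", score = 0, stringsAsFactors = FALSE)
  rep <- compare_transcript_domains("g1", c("g1.1", "g1.2"),
                                    splice_fixture(var))
  tv <- rep$transcripts[rep$transcripts$transcript_id == "g1.2", ]
  expect_true(tv$id_truncated)
  expect_false(tv$id_excluded)
  call <- rep$id_calls[rep$id_calls$transcript_id == "g1.2", ]
  expect_equal(call$status, "truncated")
})

test_that("single-transcript genes yield a report without comparisons", {
  rep <- compare_transcript_domains("g1", "g1.1",
                                    splice_fixture(NULL))
  expect_equal(nrow(rep$transcripts), 1L)
  expect_equal(nrow(rep$id_calls), 0L)
})

test_that("retained introns are reported by transcription-order index", {
  ref_ex <- data.frame(start = c(1L, 201L, 401L, 601L, 801L, 1001L),
                       end = c(100L, 300L, 500L, 700L, 900L, 1100L))
  # query merges exons 4 and 5 (spans intron 4)
  q_ex <- data.frame(start = c(1L, 201L, 401L, 601L, 1001L),
                     end = c(100L, 300L, 500L, 900L, 1100L))
  expect_equal(detect_retained_introns(q_ex, ref_ex), 4L)
  expect_equal(detect_retained_introns(ref_ex, ref_ex), integer(0))
  expect_error(detect_retained_introns(q_ex, ref_ex, "+", "-"),
               "different strands")
})

test_that("intron indices are strand-consistent (i maps to n+1-i)", {
  ref_ex <- data.frame(start = c(1L, 201L, 401L, 601L, 801L),
                       end = c(100L, 300L, 500L, 700L, 900L))
  q_ex <- data.frame(start = c(1L, 401L, 601L, 801L),
                     end = c(300L, 500L, 700L, 900L))  # genomic intron 1
  plus <- detect_retained_introns(q_ex, ref_ex, "+", "+")
  minus <- detect_retained_introns(q_ex, ref_ex, "-", "-")
  expect_equal(plus, 1L)
  n_introns <- nrow(ref_ex) - 1L
  expect_equal(minus, n_introns + 1L - plus)
})

test_that("expression joining attaches vectors and is order-invariant", {
  rep <- compare_transcript_domains("g1", c("g1.1", "g1.2"), splice_fixture(
    data.frame(protein_id = "g1.2", accession = "PF00931",
               name = "NB-ARC", start = 120L, end = 280L,
               source = "Pfam", score = 0, stringsAsFactors = FALSE)))
  et <- data.frame(transcript_id = c("g1.2", "g1.1", "zzz"),
                   leaf = c(1.5, 2.5, 9), stress = c(0.1, 0.2, 9))
  j1 <- join_expression(rep, et)
  expect_equal(j1$transcripts$leaf[j1$transcripts$transcript_id == "g1.1"],
               2.5)
  j2 <- join_expression(rep, et[sample(3), ])
  expect_identical(j1$transcripts, j2$transcripts)
  # transcript absent from the table -> NA vector, logged count
  et2 <- et[et$transcript_id == "g1.1", ]
  j3 <- join_expression(rep, et2)
  expect_true(is.na(j3$transcripts$leaf[
    j3$transcripts$transcript_id == "g1.2"]))
  expect_equal(attr(j3$transcripts, "n_unmatched"), 1L)
  # no overlap at all -> warning, unmodified report
  expect_warning(j4 <- join_expression(rep, data.frame(
    transcript_id = "x", leaf = 1)), "no transcript")
  expect_identical(j4$transcripts, rep$transcripts)
})

test_that("planted exclusions, truncations and retained introns are
           recovered exactly from generated genes", {
  gen <- generate(simulation_config(seed = 81, n_chromosomes = 3L,
                                    genes_per_chromosome = 60L,
                                    id_insertion_prob = 0.5))
  tt <- truth_table(gen)
  res <- analyze_nlr(gen$proteins, gen$genes, gen$transcripts, gen$exons,
                     gen$cds, gen$domains,
                     stages = c("census", "splice"))
  for (t in gen$truth$genes) {
    if (!t$is_nlr || length(t$transcripts) < 2L) next
    r <- res$splice_reports[[t$gene_id]]
    expect_equal(any(r$transcripts$id_excluded),
                 length(t$excluded_accessions) > 0L, info = t$gene_id)
    expect_equal(any(r$transcripts$id_truncated),
                 length(t$truncated_accessions) > 0L, info = t$gene_id)
    x <- unlist(strsplit(r$transcripts$retained_introns, ","))
    obs_ri <- sort(unique(as.integer(x[nzchar(x)])))
    expect_equal(obs_ri, sort(as.integer(t$retained_introns)),
                 info = t$gene_id)
  }
})

test_that("exclusion calls via annotation and via exon projection agree
           on noise-free generated data", {
  gen <- generate(simulation_config(seed = 82, n_chromosomes = 2L,
                                    genes_per_chromosome = 50L,
                                    id_insertion_prob = 0.5))
  res_anno <- analyze_nlr(gen$proteins, gen$genes, gen$transcripts,
                          domains = gen$domains,
                          stages = c("census", "splice"))
  res_proj <- analyze_nlr(gen$proteins, gen$genes, gen$transcripts,
                          gen$exons, gen$cds, gen$domains,
                          stages = c("census", "splice"))
  for (gid in names(res_anno$splice_reports)) {
    a <- res_anno$splice_reports[[gid]]$transcripts
    b <- res_proj$splice_reports[[gid]]$transcripts
    expect_equal(a$id_excluded, b$id_excluded, info = gid)
    expect_equal(a$id_truncated, b$id_truncated, info = gid)
  }
})
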