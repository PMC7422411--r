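# Readers, writers and coordinate conventions.

test_that("FASTA reading parses headers, uppercases, and enforces unique ids", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "mkv", ">p2", "ACDE", "FGH"), f)
  pr <- read_fasta(f)
  expect_equal(pr$protein_id, c("p1", "p2"))
  expect_equal(pr$sequence, c("MKV", "ACDEFGH"))
  expect_equal(pr$length, c(3L, 7L))

  writeLines(c(">p1", "MKV", ">p1", "AAA"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(character(0), f)
  expect_warning(out <- read_fasta(f), "no records")
  expect_equal(nrow(out), 0L)
})

test_that("FASTA write-then-read round-trips random proteomes", {
  set.seed(31)
  n <- 100L
  pr <- data.frame(
    protein_id = sprintf("prot%03d", seq_len(n)),
    sequence = vapply(sample(20:200, n, replace = TRUE), function(L)
      paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                     "P","Q","R","S","T","V","W","Y"), L, replace = TRUE),
            collapse = ""), ""),
    stringsAsFactors = FALSE)
  pr$length <- nchar(pr$sequence)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(pr, f)
  back <- read_fasta(f)
  expect_equal(back, pr)
})

test_that("GFF3 reading builds gene/transcript/exon/CDS tables", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1A\tsrc\tgene\t100\t1000\t.\t+\t.\tID=g1",
    "1A\tsrc\tmRNA\t100\t1000\t.\t+\t.\tID=g1.1;Parent=g1",
    "1A\tsrc\texon\t100\t400\t.\t+\t.\tParent=g1.1",
    "1A\tsrc\texon\t600\t1000\t.\t+\t.\tParent=g1.1",
    "1A\tsrc\tCDS\t100\t400\t.\t+\t0\tParent=g1.1",
    "1A\tsrc\tCDS\t600\t800\t.\t+\t0\tParent=g1.1"), f)
  gff <- read_gff3(f)
  expect_equal(gff$genes$gene_id, "g1")
  expect_equal(gff$genes$n_transcripts, 1L)
  expect_equal(gff$genes$subgenome, "A")
  expect_equal(nrow(gff$exons), 2L)
  expect_equal(nrow(gff$cds), 2L)
})

test_that("orphan mRNA is adopted into a synthesized gene with a warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "2B\tsrc\tmRNA\t10\t90\t.\t-\t.\tID=lonely.1",
    "2B\tsrc\texon\t10\t90\t.\t-\t.\tParent=lonely.1"), f)
  expect_warning(gff <- read_gff3(f), "synthesizing")
  expect_equal(nrow(gff$genes), 1L)
  expect_equal(gff$transcripts$gene_id, gff$genes$gene_id)
})

test_that("GFF3 structural violations are errors", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1A\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "1A\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g1.1;Parent=g1",
    "1A\tsrc\texon\t1\t50\t.\t+\t.\tParent=g1.1",
    "1A\tsrc\tCDS\t40\t70\t.\t+\t0\tParent=g1.1"), f)
  expect_error(read_gff3(f), "not contained")

  writeLines(c(
    "##gff-version 3",
    "1A\tsrc\tgene\t1\t100\t.\t?\t.\tID=g1"), f)
  expect_error(suppressWarnings(read_gff3(f)), "strand")
})

test_that("domain tables parse both dialects and reject bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # full InterProScan 5 dialect
  writeLines(c(
    "p1\tmd5\t500\tPfam\tPF00931\tNB-ARC\t180\t450\t1e-50\tT\t-",
    "p1\tmd5\t500\tCoils\tCoil\tCoil\t10\t40\t-\tT\t-",
    "p2\tmd5\t300\tPfam\tPF00069\tProtein kinase domain\t250\t100\t0.1\tT\t-"),
    f)
  expect_warning(d <- read_domain_table(f), "invalid coordinates")
  expect_equal(nrow(d), 2L)
  expect_equal(attr(d, "rejected"), 1L)
  expect_equal(d$accession[1L], "PF00931")
  expect_equal(d$start[1L], 180L)
  expect_equal(d$source[2L], "Coils")

  # reduced 5-column dialect
  writeLines(c("p1\tPF00931\tNB-ARC\t180\t450",
               "p1\tPF03106\tWRKY\t460\t520"), f)
  d2 <- read_domain_table(f)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$source, c("Pfam", "Pfam"))

  # coordinate validation against a proteome
  prot <- data.frame(protein_id = "p1", sequence = strrep("A", 500),
                     length = 500L)
  writeLines("p1\tPF00931\tNB-ARC\t400\t600", f)
  expect_warning(d3 <- read_domain_table(f, prot), "invalid")
  expect_equal(nrow(d3), 0L)
})

test_that("generated annotations round-trip through the standard formats", {
  gen <- generate(simulation_config(seed = 101, n_chromosomes = 1L,
                                    genes_per_chromosome = 15L))
  dir <- withr::local_tempdir()
  write_generated(gen, dir)
  gff <- read_gff3(file.path(dir, "genome.gff3"))
  expect_setequal(gff$genes$gene_id, gen$genes$gene_id)
  expect_equal(nrow(gff$transcripts), nrow(gen$transcripts))
  prot <- read_fasta(file.path(dir, "proteome.fasta"))
  expect_setequal(prot$protein_id, gen$proteins$protein_id)
  expect_identical(
    prot$sequence[match(gen$proteins$protein_id, prot$protein_id)],
    gen$proteins$sequence)
  dom <- read_domain_table(file.path(dir, "domains.tsv"), prot)
  expect_equal(nrow(dom), nrow(gen$domains))
  expect_equal(attr(dom, "rejected"), 0L)
})

test_that("BED conversion is self-inverse and write_outputs honours formats", {
  i <- c(1L, 2L, 10L, 999999L, 1000000L)
  expect_identical(from_bed_start(to_bed_start(i)), i)
  expect_equal(to_bed_start(1L), 0L)

  x <- data.frame(chromosome = "1A", start = 1L, end = 10L, name = "d1")
  f <- withr::local_tempfile(fileext = ".bed")
  write_outputs(x, f, "BED")
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2, 0L)
  expect_equal(bed$V3, 10L)
  expect_equal(read_bed(f)$start, 1L)

  expect_error(write_outputs(x, f, "XLSX"))

  # header-only TSV for an empty table
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_outputs(x[0, ], f2, "TSV")
  expect_equal(readLines(f2), "chromosome\tstart\tend\tname")

  # TSV round-trip is byte-stable
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_outputs(x, f3, "TSV")
  y <- read.table(f3, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_outputs(y, f4, "TSV")
  expect_identical(readLines(f3), readLines(f4))
})

test_that("subgenome parsing handles arm suffixes and unknowns", {
  expect_equal(parse_subgenome(c("4A", "1B", "7D", "3AL", "5BS",
                                 "scaffold_17", "chr2D")),
               c("A", "B", "D", "A", "B", "unknown", "D"))
})
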