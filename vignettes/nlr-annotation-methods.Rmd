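---
title: "Methods: NLR annotation, integrated domains and splice-variant analysis"
author: "nlrforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NLR annotation, integrated domains and splice-variant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

Plant NLR immune receptors share one defining feature: the NB-ARC
nucleotide-binding domain (Pfam PF00931). Everything this package does is
anchored on that observation. The pipeline *consumes* protein domain
annotations (InterProScan-style calls) rather than running any HMM scan
itself, which mirrors how these censuses are actually produced: domain
calls come from the annotation databases, and the analysis layer decides
what they mean. The five analysis stages — census, physical clustering,
integrated domains, homology, splice variants — operate on four plain
tables (proteins, gene models, transcript structures, domain hits) that
the readers in `annotation_io` normalise from FASTA, GFF3 and TSV.

Coordinates are kept **1-based inclusive everywhere inside the package**.
This is a deliberate departure from the common half-open internal
convention: every upstream format here (GFF3, InterProScan TSV) and every
R-side container (IRanges and friends) is 1-based inclusive, so a single
convention end to end removes the conversion layer rather than adding
one. The only place a conversion exists is the BED writer/reader
(0-based half-open), and `to_bed_start()`/`from_bed_start()` are exact
inverses (tested up to 10^6).

# Census: NB-ARC identification, motifs, classes

A protein is NB-ARC-positive iff it has at least one hit from the NB-ARC
accession set (default `{PF00931}`, configurable). Architecture flags
come from accession membership in curated core sets (TIR, RPW8, CC, LRR);
only the NB-ARC accession is canonical, so the other sets are explicit
defaults that users can override — coiled-coil evidence additionally
accepts hits named `RX-CC_like` or `Coils` rows, because coiled-coils are
commonly called by a dedicated predictor rather than Pfam. The class
label is composed deterministically: N-terminal letter from exactly one
of TIR (`T`) > CC (`C`) > RPW8 (`R`) (priority order, conflicts logged),
then `N`, then `L` iff an LRR accession is present.

The three NB-ARC motifs are scanned with configurable regular
expressions inside the NB-ARC hit extended by a 30-residue flank
(default): P-loop `[GA].{2,4}GK[ST]`, Kinase-2
`[LIVMF]{2}.{2}[DE]D.[WD]`, GLPL `G[LIVMF]P[LS]`. These are literature
Walker-A/Walker-B consensus forms, not the output of any de novo motif
discovery, and the package makes no claim that they reproduce a
particular published motif-complete count; they are defaults with an
explicit override path. With `ordered = TRUE` (default) each motif is
searched downstream of the previous one, enforcing the canonical P-loop <
Kinase-2 < GLPL order. The P-loop quantifier is `{2,4}` rather than a
fixed `{4}` so that both the short canonical form (`GGVGKTT`) and the
longer Walker-A spellings match.

Gene-level aggregation: a gene is counted once, under its
architecture-richest protein (most domain flags; ties broken by the same
N-terminal priority, then longest protein). A gene is motif-complete if
*any* of its proteins is. This matches the way gene-level counts are
reported in receptor censuses, where one well-annotated isoform suffices.

# Physical clusters

The clustering rule is the classic tandem-array heuristic: two NB-ARC
genes that are consecutive among NB-ARC genes on a chromosome are linked
iff the gap (start of downstream minus end of upstream, nearest
boundaries — conservative and unambiguous) is at most 200,000 bp *and* at
most 7 annotated non-NB-ARC genes lie strictly between them ("fewer than
eight"). NB-ARC genes never count as intervening. Clusters are maximal
chains; this consecutive-chain reading (rather than all-pairs within a
window) is the implemented semantics, and the unit tests pin the exact
boundaries (gap 200,000 links, 200,001 does not; 7 intervening links, 8
does not). The test suite proves the chain construction equal to
connected components of the pairwise-link graph (igraph as the
independent oracle) on hundreds of random layouts.

Within-cluster similarity uses the package's own affine-gap pairwise
aligner (Rcpp, Gotoh three-state recursion, global by default, local mode
available): BLOSUM62, gap open 10, gap extend 1, a gap of length *k*
costing `open + k·extend`. Percent identity divides identities by
*aligned columns including gap columns* — one declared convention,
switchable to shorter-sequence length. Identities feed the
`<50% / <75% / <100% / 100%` bins used for similarity edge lists. The DP
optimum is verified against exhaustive enumeration of all alignment paths
for every short pair in the acceptance suite.

Trees: Saitou–Nei neighbor joining, with Q-matrix ties broken by the
smallest (row, column) index pair so output is reproducible on degenerate
inputs; negative branch lengths are clamped to zero with the deficit
moved to the sister branch (pair sums preserved). NJ provably recovers
the generating topology on additive matrices (tested for 4–8 leaves
against trees drawn with `ape`). Multiple alignments for bootstrapping
are built progressively over the NJ guide tree, merging profiles through
their majority-rule consensus sequences with the same pairwise core —
adequate for support estimation on within-cluster paralogs, and not
intended as a general MSA replacement. Bootstrap support of an edge is
the fraction of column-resampled replicate NJ trees containing the same
bipartition; `cluster_nesting()` then asks whether a cluster's members
form a bipartition of the unrooted tree (monophyly), the tree-based test
for a tandem-duplication origin.

# Integrated domains

Every Pfam hit on an NB-ARC-positive protein whose accession is outside
the core sets is an integrated domain. Non-Pfam rows (coils,
transmembrane, signal peptides) are never called IDs — they are
structural predictions, not homology domains. Relative position on a
protein of length L is `rel_start = (start−1)/L`, `rel_end = end/L`,
midpoint primary (robust for short domains; all three exported).
Categories (kinase / DNA-binding / other-signaling / unknown) come from a
shipped YAML map (accession first, then case-insensitive name keyword),
covering the recurrent cereal NLR-ID families; it is a curated default,
explicitly user-extensible, and anything unmatched is `unknown` rather
than guessed.

# Homology and progenitor categories

ID homology is computed on the ID subsequence (the fusion is the object
of interest, not the whole receptor), with seed-and-extend search: a
subject must share at least one exact 5-mer with the query, then local
affine-gap alignment decides. Thresholds default to identity ≥ 70% and
query coverage ≥ 0.8; tests confirm the 5-mer prefilter loses nothing
for pairs at or above the identity threshold. "Similarity" is
implemented as alignment percent identity — the reproducible reading of
an ambiguous term.

For allopolyploid progenitor assignment, each ID-bearing gene's best hit
identity in the *T. urartu* (TU) and *Ae. tauschii* (AT) proteomes is
compared with the subgenome the gene sits on: `Match` when the better
donor is the expected one (A↔TU, D↔AT; ties favour the expected donor),
`A`/`D` when the wrong donor is closer, `B` for B-subgenome genes (the
donor lineage is unsequenced), `U` when the subgenome is unknown. The
five categories partition the ID-bearing gene set by construction.

# Splice variants

The reference transcript of a gene is the one with the richest domain
content (most distinct accessions, ties to the longest protein, then
lexicographic). For each other transcript and each reference ID
accession, the call is `present` / `truncated` (present at < 0.8 of the
reference instance length — the threshold is a package choice, exposed as
`truncation_fraction`) / `excluded`. Primary evidence is the variant's
own protein-level annotation; when the variant's annotation lacks the
accession *and* exon/CDS structures are available, the reference
instance's coding footprint is projected through the variant's CDS.
This per-accession fallback is deliberate: domain tables carry false
negatives, but the gene structure is the authoritative record of a
splicing event, so a fully retained footprint is read as an annotation
miss rather than an exclusion. On noise-free synthetic data the two
evidence routes agree exactly (tested).

Retained introns are reference-exon gaps fully covered by a single query
exon, indexed 1..n in transcription order — so "the 4th intron" means the
same thing on either strand, and reversing a gene's orientation maps
index i to n+1−i (tested).

# The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture
dump: it emits mutually consistent FASTA/GFF3/TSV files plus a truth set,
and identical configurations produce byte-identical files.

What it emulates, and the reference study conditions (the
`simulation_config()` defaults, chosen once):

* 25% of gene loci are NLRs (`nlr_fraction = 0.25`), at class
  proportions echoing a hexaploid wheat census — CNL 0.37, NL 0.35,
  CN 0.12, N 0.15, TN and RNL rare — with 70% of NB-ARC genes
  motif-complete.
* NLR proteins are assembled from fixed consensus blocks (CC 100 aa /
  TIR 170 / RPW8 120, NB-ARC 160 with the three motifs planted at fixed
  offsets, LRR 75) joined by short linkers; per-family divergence 0.08.
* 40% of NLR loci found tandem arrays (copies adjacent at 2–20 kb,
  extra copies geometric with mean cluster size ≈ 2.3, per-site
  divergence 0.05); all *unrelated* neighbouring genes are spaced
  > 200 kb apart so the planted arrays are exactly the rule-satisfying
  clusters.
* A quarter of NLR genes carry one ID drawn from a 12-family library
  (kinases at the N-terminus, WRKY/AP2/B3 and the signalling families at
  the C-terminus, each with a deterministic consensus).
* 70% of NLR genes have an alternative transcript; for ID genes its
  event is exclusion 0.3 / truncation 0.1 / intron retention 0.2 /
  otherwise a harmless alternative 3' end, so the exclusion probability
  conditional on having an alternative transcript is the configured 0.3.
  Exclusion drops the ID's exon; truncation keeps the transcription-5'
  half via an alternative splice site; retention merges the two 3'-UTR
  exons (the protein is untouched, as in UTR-retention isoforms).
* Comparator proteomes: a barley-like proteome carries one diverged
  homolog per ID (in an NLR context with probability 0.685), and the two
  progenitor proteomes carry ID homologs whose closer donor matches the
  gene's subgenome with probability 0.41 (close divergence 0.05, cross
  divergence 0.15).
* Optional annotation noise: each domain row is dropped independently
  with `annotation_fn_rate` (0 by default).

Two implementation details matter for exactness. First, divergence is
substitution-only (no indels), keeping identity expectations analytic
(`1 − rate` for background-alphabet substitutions). Second, background
sequence is drawn from a 15-letter alphabet excluding G, K, D, P and W —
the anchor residues of the three NB-ARC motifs — and divergence
substitutions stay within that alphabet outside the planted motif
windows, which are themselves masked from mutation. Biologically this
plays the role of purifying selection on functional motifs; practically
it guarantees that motif truth labels remain exact under any seed, so
planted-truth recovery is a sharp 1.0-accuracy test of the pipeline
machinery rather than a statement about pattern luck.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: indel evolution and alignment-length variation,
fractured or nested real-world domain calls, mis-annotated gene models,
segmental (non-tandem) duplications that the distance rule would
misclassify, expression structure (the expression table is i.i.d.
log-normal), and genuine sequence-level homology between unrelated
families. Conclusions about real proteomes therefore rest on the rule
implementations being correct (the oracle tests), not on the simulator
being realistic.

# Problem sizes and numerical choices

The validation suite runs at the package's reference sizes: ~2,000 gene
loci (21 chromosomes × 96 slots) for exact-recovery checks, 25 replicate
genomes for the noisy-recovery check (cluster fraction and exclusion rate
within 99% binomial intervals of the per-seed planted rates), ≥ 10,000
short pairs for the alignment-enumeration oracle and 100 random additive
matrices for NJ. These sizes were chosen to make the statistical checks
sharp while keeping a full run of the suite comfortable on a laptop.

Tie-breaks and degenerate inputs are all pinned: Q-matrix ties by
smallest index pair; all-equal distance matrices resolve deterministically;
empty sequences are errors while unknown residues degrade to `X` with a
warning; empty domain tables yield empty (not missing) results; an mRNA
without a gene parent is adopted into a synthesized single-transcript
gene; rows with `end < start` are rejected and counted. Thread count is
irrelevant by construction — every stage is single-threaded and
deterministic given the seed.

# Known limitations

* The CC/LRR/TIR accession sets and the ID category map are curated
  defaults; a census on real data should review them against the
  annotation release in use (releases differ in which Pfam models they
  emit).
* The motif regular expressions will not reproduce a count derived from
  unpublished, data-driven motif models; they are transparent consensus
  forms instead.
* The progressive MSA is consensus-based and should not be used as a
  general aligner; for publication-grade alignments feed an external MSA
  into `bootstrap_support()` directly.
* Homology search is desk-scale (k-mer prefilter + exact DP); for
  multi-proteome scans at millions of sequences use a dedicated search
  tool and import the hits.
* The full-scale wheat census depends on the annotation release of the
  input proteome; the package validates methodology on planted truth
  rather than pinning release-specific counts.
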