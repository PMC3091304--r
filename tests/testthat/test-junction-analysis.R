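mk_hits <- function(starts, ov5 = NULL, L = 50L) {
  n <- length(starts)
  ov5 <- if (is.null(ov5)) pmax(1L, -starts) else ov5
  data.frame(read_id = sprintf("r%d", seq_len(n)),
             junction_id = rep("FJ|A|A.e1|B|B.e1|49", n),
             start = starts + 50L, strand = rep("+", n),
             mismatches = rep(0L, n),
             start_offset = starts, overhang_5 = ov5, overhang_3 = L - ov5,
             stringsAsFactors = FALSE)
}

test_that("junction enumeration builds both orientations for all exon pairs", {
  fx <- toy_fixture()
  jdb <- enumerate_fusion_junctions("G1", "G2", fx$model, fx$genome, flank = 49)
  ## 3 exons x 2 exons x 2 orientations = 12 sequences (all distinct here)
  expect_equal(nrow(jdb), 12L)
  expect_setequal(unique(jdb$five_gene), c("G1", "G2"))
  ## minus-strand 5' side: fragment is the reverse complement of the exon's
  ## genomic LEFT edge (G2.e1 lies at [1101,1200] on the minus strand)
  j <- jdb[jdb$five_exon == "G2.e1" & jdb$three_exon == "G1.e1", ]
  manual5 <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(fx$genome[["chr2"]], 1101, 1149)))
  expect_identical(substr(j$seq, 1, 49), manual5)
  ## a 2x2 exon pair gives 8 sequences before dedup
  m <- build_model(list(
    list(gene_id = "A", chrom = "chr1", strand = "+",
         exon_starts = c(101L, 301L), exon_lens = c(100L, 100L), cds = NA),
    list(gene_id = "B", chrom = "chr1", strand = "+",
         exon_starts = c(1001L, 1301L), exon_lens = c(100L, 100L), cds = NA)))
  expect_equal(nrow(enumerate_fusion_junctions("A", "B", m, fx$genome)), 8L)
  ## exons duplicated across transcripts are deduplicated
  m2 <- build_model(list(
    list(gene_id = "A", chrom = "chr1", strand = "+",
         exon_starts = c(101L, 301L), exon_lens = c(100L, 100L), cds = NA,
         transcripts = list(list(exon_idx = 1:2, cds = NA),
                            list(exon_idx = 1:2, cds = NA))),
    list(gene_id = "B", chrom = "chr1", strand = "+",
         exon_starts = c(1001L, 1301L), exon_lens = c(100L, 100L), cds = NA)))
  expect_equal(nrow(enumerate_fusion_junctions("A", "B", m2, fx$genome)), 8L)
  ## gene without exons errors
  expect_error(enumerate_fusion_junctions("A", "ZZ", m, fx$genome), "ZZ")
})

test_that("junction alignment keeps only anchored spanning placements", {
  set.seed(41)
  seq5 <- rand_dna_str(49); seq3 <- rand_dna_str(49)
  jdb <- data.frame(junction_id = "FJ|A|A.e1|B|B.e1|49",
                    five_gene = "A", five_exon = "A.e1",
                    three_gene = "B", three_exon = "B.e1",
                    offset = 49L, seq = paste0(seq5, seq3),
                    alt_labels = "", stringsAsFactors = FALSE)
  full <- paste0(seq5, seq3)
  r_2525 <- substr(full, 25, 74)     # 25|25 split
  r_941  <- substr(full, 41, 90)     # 9|41 split
  r_in5  <- substr(full, 1, 50)      # overhang_3 = 1 < anchor
  reads <- Biostrings::DNAStringSet(c(a = r_2525, b = r_941, c = r_in5))
  hits <- align_unmapped_to_junctions(reads, jdb, detection_params())
  expect_equal(hits$read_id, "a")
  expect_equal(hits$overhang_5, 25L)
  expect_equal(hits$overhang_3, 25L)
  expect_equal(hits$start_offset, -25L)
  ## overhang conservation
  expect_true(all(hits$overhang_5 + hits$overhang_3 == 50L))
  ## reverse-complemented junction read is still found, same offsets
  hits_rc <- align_unmapped_to_junctions(
    Biostrings::DNAStringSet(c(a = revcomp_str(r_2525))), jdb,
    detection_params())
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start_offset, -25L)
})

test_that("a read hitting several junctions keeps only minimum-mismatch hits", {
  set.seed(43)
  seqA <- rand_dna_str(98)
  seqB <- seqA
  ## one substitution inside the read window (25..74)
  substr(seqB, 40, 40) <- chartr("ACGT", "CGTA", substr(seqB, 40, 40))
  jdb <- data.frame(junction_id = c("FJ|A|A.e1|B|B.e1|49", "FJ|A|A.e2|B|B.e1|49"),
                    five_gene = "A", five_exon = c("A.e1", "A.e2"),
                    three_gene = "B", three_exon = "B.e1",
                    offset = 49L, seq = c(seqA, seqB),
                    alt_labels = "", stringsAsFactors = FALSE)
  read <- substr(seqA, 25, 74)
  hits <- align_unmapped_to_junctions(Biostrings::DNAStringSet(c(r = read)),
                                      jdb, detection_params())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$junction_id, "FJ|A|A.e1|B|B.e1|49")
  expect_equal(hits$mismatches, 0L)
})

test_that("tiling classification follows the three-part decision rule", {
  p <- detection_params()
  ## staggered starts, two-sided anchors: genuine
  tc <- tiling_classify(mk_hits(c(-25L, -20L, -15L, -12L, -5L),
                                ov5 = c(25L, 20L, 15L, 12L, 10L)), p)
  expect_equal(tc$tiling_class, "genuine")
  expect_equal(tc$distinct_starts, 5L)
  ## stacked within +-1: artifact by span
  tc2 <- tiling_classify(mk_hits(c(-40L, -40L, -41L, -39L, -40L, -40L),
                                 ov5 = c(40L, 40L, 41L, 39L, 40L, 40L)), p)
  expect_equal(tc2$tiling_class, "artifact")
  expect_true(tc2$span_le_artifact)
  ## two distinct starts with wide span: artifact by count
  tc3 <- tiling_classify(mk_hits(c(-30L, -10L), ov5 = c(30L, 10L)), p)
  expect_equal(tc3$tiling_class, "artifact")
  expect_true(tc3$too_few_starts)
  ## no read anchored on both sides: artifact by anchor rule
  tc4 <- tiling_classify(mk_hits(c(-45L, -44L, -43L, -48L, -42L),
                                 ov5 = c(45L, 44L, 43L, 48L, 42L)), p)
  expect_equal(tc4$tiling_class, "artifact")
  expect_true(tc4$too_few_two_sided)
  expect_error(tiling_classify(mk_hits(integer(0)), p), "empty")
})

test_that("junction calls require the minimum read support and fix orientation", {
  p <- detection_params()
  cand <- data.frame(gene_a = "A", gene_b = "B", pair_count = 4L,
                     pair_ids = "", stringsAsFactors = FALSE)
  ## one spanning read: no call
  h1 <- mk_hits(-25L, ov5 = 25L)
  expect_equal(nrow(call_junctions(cand, h1, p)), 0L)
  ## five spanning reads: one call, A is the 5' partner
  h5 <- mk_hits(c(-25L, -20L, -15L, -12L, -30L),
                ov5 = c(25L, 20L, 15L, 12L, 30L))
  cl <- call_junctions(cand, h5, p)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$five_gene, "A")
  expect_equal(cl$three_gene, "B")
  expect_equal(cl$n_junction_reads, 5L)
  expect_equal(cl$tiling_class, "genuine")
  expect_false(cl$reciprocal)
  ## reciprocal orientations both supported: two calls, flagged
  hba <- mk_hits(c(-25L, -20L, -15L), ov5 = c(25L, 20L, 15L))
  hba$junction_id <- "FJ|B|B.e1|A|A.e1|49"
  cl2 <- call_junctions(cand, rbind(h5, hba), p)
  expect_equal(nrow(cl2), 2L)
  expect_true(all(cl2$reciprocal))
})

test_that("prioritization puts genuine calls first with deterministic tiebreaks", {
  base <- data.frame(five_gene = "A", five_exon = "e", three_gene = "B",
                     three_exon = "e", junction_id = "j", n_pairs = 2L,
                     n_junction_reads = 5L, tiling_class = "genuine",
                     distinct_starts = 3L, reciprocal = FALSE,
                     span_le_artifact = FALSE, too_few_starts = FALSE,
                     too_few_two_sided = FALSE, stringsAsFactors = FALSE)
  a <- base; a$distinct_starts <- 7L; a$five_gene <- "Z"
  b <- base; b$distinct_starts <- 3L
  art <- base; art$tiling_class <- "artifact"
  art$n_junction_reads <- 500L; art$distinct_starts <- 2L
  tie1 <- base; tie1$five_gene <- "A1"
  tie2 <- base; tie2$five_gene <- "A2"
  out <- prioritize_calls(rbind(art, b, a, tie2, tie1))
  expect_equal(out$tiling_class[nrow(out)], "artifact")  # artifact always last
  expect_equal(out$five_gene[1], "Z")                    # most distinct starts
  ## equal stats: lexicographic gene order
  expect_lt(which(out$five_gene == "A1"), which(out$five_gene == "A2"))
})

test_that("junction alignment agrees with the Hamming oracle on junction sequences", {
  set.seed(47)
  jseqs <- Biostrings::DNAStringSet(setNames(
    replicate(20, rand_dna_str(98)), sprintf("J%02d", 1:20)))
  idx <- oracle_index(jseqs, 50L)
  for (k in 1:40) {
    src <- sample(20, 1)
    pos <- sample.int(49, 1)
    read <- as.character(Biostrings::subseq(jseqs[[src]], pos, pos + 49L))
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      at <- sample(1:50, nmut)
      for (i in at) substr(read, i, i) <- chartr("ACGT", "CGTA",
                                                 substr(read, i, i))
    }
    got <- align_read(read, jseqs, 3)
    want <- oracle_align(read, jseqs, 3, index = idx)
    expect_identical(got[c("ref_id", "start", "strand", "mismatches")],
                     want[c("ref_id", "start", "strand", "mismatches")])
  }
})
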