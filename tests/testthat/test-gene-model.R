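test_that("GTF loading applies the 1-based inclusive convention and orders exons by strand", {
  fx <- toy_fixture()
  m <- fx$model
  expect_equal(nrow(m$genes), 2L)
  e1 <- m$exons[m$exons$gene_id == "G1", ]
  expect_equal(e1$start[e1$exon_id == "G1.e1"], 101L)
  expect_equal(e1$end[e1$exon_id == "G1.e1"], 200L)
  ## minus-strand gene: rank 1 is the genomically rightmost exon
  e2 <- transcript_exons(m, "G2.t1")
  expect_identical(e2$exon_id, c("G2.e1", "G2.e2"))
  expect_gt(e2$start[1], e2$start[2])
  ## CDS mapped to transcript coordinates (50 bases into exon 1 + exon 2)
  tx <- m$transcripts[m$transcripts$transcript_id == "G1.t1", ]
  expect_equal(tx$cds_start, 51L)
  expect_equal(tx$cds_end, 200L)
})

test_that("annotation writer round-trips through the loader unchanged", {
  fx <- toy_fixture()
  f2 <- tempfile(fileext = ".gtf")
  write_annotation(fx$model, f2)
  m2 <- load_annotation(f2)
  expect_identical(fx$model$genes, m2$genes)
  expect_identical(fx$model$exons, m2$exons)
  expect_identical(
    fx$model$transcripts[c("transcript_id", "cds_start", "cds_end")],
    m2$transcripts[c("transcript_id", "cds_start", "cds_end")])
})

test_that("malformed GTF and orphan exons raise errors", {
  f <- tempfile(fileext = ".gtf")
  writeLines("chr1\tonly\tthree", f)
  expect_error(load_annotation(f), "parse error")
  writeLines(c(
    'chr1\tx\tgene\t1\t100\t.\t+\t.\tgene_id "G1";',
    'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "G1"; transcript_id "GX.t1"; exon_id "e1";'),
    f)
  expect_error(load_annotation(f), "structural")
})

test_that("generated annotation loads back with every gene retrievable", {
  cfg <- simulation_config(seed = 3, n_genes = 20, n_chromosomes = 4)
  u <- generate_universe(cfg)
  f <- tempfile(fileext = ".gtf")
  write_annotation(u$model, f)
  m <- load_annotation(f)
  expect_equal(nrow(m$genes), 20L)
  for (gid in sprintf("G%02d", 1:20))
    expect_equal(fusionscan:::get_gene(m, gid)$gene_id, gid)
  expect_identical(m$exons, u$model$exons)
})

test_that("gene overlap uses closed-interval intersection on the same chromosome", {
  m <- build_model(list(
    list(gene_id = "A", chrom = "c1", strand = "+",
         exon_starts = c(101L, 250L), exon_lens = c(50L, 50L), cds = NA),
    list(gene_id = "B", chrom = "c1", strand = "+",
         exon_starts = c(201L, 350L), exon_lens = c(50L, 50L), cds = NA),
    list(gene_id = "C", chrom = "c1", strand = "+",
         exon_starts = c(301L, 380L), exon_lens = c(20L, 20L), cds = NA),
    list(gene_id = "D", chrom = "c2", strand = "+",
         exon_starts = 101L, exon_lens = 100L, cds = NA)))
  expect_true(genes_overlap(m, "A", "B"))     # [101,299] vs [201,399]
  expect_false(genes_overlap(m, "A", "C"))    # [101,299] vs [301,399] abut
  expect_false(genes_overlap(m, "A", "D"))    # different chromosomes
  expect_true(genes_overlap(m, "B", "A"))     # symmetric
})

test_that("adjacency requires a fully separating third gene", {
  mk <- function(c_start, c_end) build_model(list(
    list(gene_id = "A", chrom = "c1", strand = "+",
         exon_starts = 100L, exon_lens = 100L, cds = NA),     # [100,199]
    list(gene_id = "B", chrom = "c1", strand = "+",
         exon_starts = 500L, exon_lens = 100L, cds = NA),     # [500,599]
    list(gene_id = "C", chrom = "c1", strand = "-",
         exon_starts = c_start, exon_lens = c_end - c_start + 1L, cds = NA)))
  ## C fully inside the gap: separates -> not adjacent
  expect_false(genes_adjacent(mk(250L, 450L), "A", "B"))
  ## C starts inside A: does not separate -> adjacent
  expect_true(genes_adjacent(mk(150L, 450L), "A", "B"))
  ## no third gene at all
  m2 <- build_model(list(
    list(gene_id = "A", chrom = "c1", strand = "+",
         exon_starts = 100L, exon_lens = 100L, cds = NA),
    list(gene_id = "B", chrom = "c1", strand = "+",
         exon_starts = 500L, exon_lens = 100L, cds = NA)))
  expect_true(genes_adjacent(m2, "A", "B"))
  ## different chromosomes are never adjacent
  fx <- toy_fixture()
  expect_false(genes_adjacent(fx$model, "G1", "G2"))
})

test_that("adjacency is symmetric on a random synthetic model", {
  cfg <- simulation_config(seed = 11, n_genes = 12, n_chromosomes = 2)
  u <- generate_universe(cfg)
  ids <- u$model$genes$gene_id
  set.seed(5)
  for (k in 1:30) {
    pr <- sample(ids, 2)
    expect_identical(genes_adjacent(u$model, pr[1], pr[2]),
                     genes_adjacent(u$model, pr[2], pr[1]))
  }
})

test_that("paralog table is symmetric, rejects self-pairs, reads TSV with comments", {
  tb <- paralog_table(data.frame(a = "G1", b = "G2"))
  expect_true(is_paralog_pair("G2", "G1", tb))
  expect_false(is_paralog_pair("G1", "G3", tb))
  expect_false(is_paralog_pair("G1", "G2", paralog_table()))
  expect_error(paralog_table(data.frame(a = "G1", b = "G1")), "self-pair")
  f <- tempfile()
  writeLines(c("# comment", "GA\tGB"), f)
  expect_true(is_paralog_pair("GB", "GA", load_paralogs(f)))
  ## generator emits its decoys into the table
  cfg <- simulation_config(seed = 2, n_genes = 10, n_paralog_decoys = 2)
  u <- generate_universe(cfg)
  expect_equal(length(u$paralogs$keys), 2L)
  tr <- u$truth[u$truth$event_type == "paralog_decoy", ]
  for (i in seq_len(nrow(tr)))
    expect_true(is_paralog_pair(tr$five_gene[i], tr$three_gene[i], u$paralogs))
})

test_that("splice-junction reference has n-1 junctions per transcript and handles strand", {
  fx <- toy_fixture()
  sj <- build_splice_junction_reference(fx$model, fx$genome, flank = 49)
  expect_equal(nrow(sj), 3L)  # 2 junctions for G1, 1 for G2
  ## completeness: sum over transcripts of max(0, n_exons - 1)
  n_ex <- table(fx$model$exons$transcript_id)
  expect_equal(nrow(sj), sum(pmax(0L, n_ex - 1L)))
  ## minus-strand junction: reverse complement of genomic downstream..upstream
  g <- fx$genome
  manual <- paste0(
    as.character(Biostrings::reverseComplement(Biostrings::subseq(g[["chr2"]], 1101, 1149))),
    as.character(Biostrings::reverseComplement(Biostrings::subseq(g[["chr2"]], 552, 600))))
  expect_identical(sj$seq[sj$gene_id == "G2"], manual)
  expect_equal(sj$offset[sj$gene_id == "G2"], 49L)
  ## exon shorter than flank contributes its full length, no error
  m <- build_model(list(list(gene_id = "S", chrom = "chr1", strand = "+",
                             exon_starts = c(10L, 40L), exon_lens = c(10L, 10L),
                             cds = NA)))
  sj2 <- build_splice_junction_reference(m, fx$genome, flank = 49)
  expect_equal(nchar(sj2$seq), 20L)
  expect_equal(sj2$offset, 10L)
  ## single-exon transcript: no junctions
  m1 <- build_model(list(list(gene_id = "S", chrom = "chr1", strand = "+",
                              exon_starts = 10L, exon_lens = 100L, cds = NA)))
  expect_equal(nrow(build_splice_junction_reference(m1, fx$genome)), 0L)
})

test_that("interval index agrees with a brute-force scan over gene spans", {
  cfg <- simulation_config(seed = 13, n_genes = 20, n_chromosomes = 2)
  u <- generate_universe(cfg)
  m <- u$model
  set.seed(17)
  for (k in 1:50) {
    ch <- sample(names(u$genome), 1)
    pos <- sample.int(Biostrings::width(u$genome)[match(ch, names(u$genome))], 1)
    hit_idx <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(ch, IRanges::IRanges(pos, pos)), m$gene_gr)
    via_index <- sort(S4Vectors::mcols(m$gene_gr)$gene_id[
      S4Vectors::subjectHits(hit_idx)])
    brute <- sort(m$genes$gene_id[m$genes$chrom == ch &
                                  m$genes$start <= pos & m$genes$end >= pos])
    expect_identical(via_index, brute)
  }
})
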