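## two-gene model with controllable CDS and exon lengths on one chromosome;
## exon lengths are multiples chosen so the junction phases are easy to read
frame_model <- function(cds5 = c(1L, 600L), cds3 = c(1L, 600L),
                        lens5 = c(200L, 200L, 200L),
                        lens3 = c(200L, 200L, 200L),
                        tx5_extra = NULL) {
  starts5 <- cumsum(c(101L, head(lens5, -1) + 300L))
  starts3 <- cumsum(c(10001L, head(lens3, -1) + 300L))
  build_model(list(
    list(gene_id = "F5", chrom = "c1", strand = "+", exon_starts = starts5,
         exon_lens = lens5, cds = cds5,
         transcripts = c(list(list(exon_idx = seq_along(lens5), cds = cds5)),
                         tx5_extra)),
    list(gene_id = "F3", chrom = "c1", strand = "+", exon_starts = starts3,
         exon_lens = lens3, cds = cds3)))
}
call_row <- function(e5, e3) data.frame(five_gene = "F5", five_exon = e5,
                                        three_gene = "F3", three_exon = e3,
                                        stringsAsFactors = FALSE)

test_that("frame prediction matches the cumulative-phase rule", {
  ## 5' CDS starts at 101 -> exon2 end contributes 400-101+1 = 300 coding nt;
  ## 3' CDS starts at 198 -> exon2 begins exactly at a codon start (3 coding
  ## nt precede the junction on the 3' side)
  m <- frame_model(cds5 = c(101L, 580L), cds3 = c(198L, 580L))
  expect_true(predict_frame(call_row("F5.e2", "F3.e2"), m))
  ## shift the 5' CDS by one base: 301 coding nt -> out of frame
  m2 <- frame_model(cds5 = c(100L, 580L), cds3 = c(198L, 580L))
  expect_false(predict_frame(call_row("F5.e2", "F3.e2"), m2))
  ## any-combination rule: second 5' transcript restores phase
  m3 <- frame_model(cds5 = c(100L, 580L), cds3 = c(198L, 580L),
                    tx5_extra = list(list(exon_idx = 1:3, cds = c(101L, 580L))))
  expect_true(predict_frame(call_row("F5.e2", "F3.e2"), m3))
  ## junction upstream of the 3' CDS leaves the full ORF intact
  m4 <- frame_model(cds5 = c(550L, 580L), cds3 = c(250L, 580L))
  expect_true(predict_frame(call_row("F5.e1", "F3.e1"), m4))
  ## no CDS on either side
  m5 <- frame_model(cds5 = c(NA, NA), cds3 = c(NA, NA))
  r <- predict_frame(call_row("F5.e2", "F3.e2"), m5)
  expect_false(as.logical(r))
  expect_equal(attr(r, "reason"), "no CDS")
  ## fused exon absent from all transcripts
  expect_error(predict_frame(call_row("F5.e9", "F3.e2"), m), "absent")
})

test_that("frame prediction agrees with the per-base enumeration oracle on random CDS pairs", {
  set.seed(53)
  n_agree <- 0L; n_total <- 0L
  for (k in 1:220) {
    n5 <- sample(2:4, 1); n3 <- sample(2:4, 1)
    lens5 <- sample(60:200, n5, replace = TRUE)
    lens3 <- sample(60:200, n3, replace = TRUE)
    t5 <- sum(lens5); t3 <- sum(lens3)
    cds5 <- sort(sample.int(t5, 2)); cds3 <- sort(sample.int(t3, 2))
    m <- frame_model(cds5 = cds5, cds3 = cds3, lens5 = lens5, lens3 = lens3)
    e5 <- sample(n5 - 1L, 1); e3 <- sample(2:n3, 1)
    got <- as.logical(predict_frame(call_row(sprintf("F5.e%d", e5),
                                             sprintf("F3.e%d", e3)), m))
    want <- oracle_frame(lens5, cds5, e5, lens3, cds3, e3)
    n_total <- n_total + 1L
    if (identical(got, want)) n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, n_total)
})

test_that("splice-variant relaxation can restore frame by skipping one internal exon", {
  ## n5 = 300 (phase 0); fused 3' exon is exon 3 with a skippable 199 nt
  ## internal exon before it: n3 = 200+199-1+1-2 = 397 (phase 1) -> out of
  ## frame strictly, but skipping exon 2 gives n3 = 198 (phase 0) -> in.
  m2 <- frame_model(cds5 = c(101L, 580L), cds3 = c(3L, 599L),
                    lens3 = c(200L, 199L, 200L))
  expect_false(predict_frame(call_row("F5.e2", "F3.e3"), m2))
  expect_true(predict_frame(call_row("F5.e2", "F3.e3"), m2,
                            splice_variants = TRUE))
  ## in-frame without any skip: phase already matches
  m <- frame_model(cds5 = c(101L, 580L), cds3 = c(1L, 599L),
                   lens3 = c(200L, 199L, 200L))
  expect_true(predict_frame(call_row("F5.e2", "F3.e3"), m))  # n3 = 399
})

test_that("RPKM arithmetic, linearity and degenerate inputs", {
  expect_equal(compute_rpkm(100, 2000, 1e6), 50.0)
  expect_equal(compute_rpkm(0, 2000, 1e6), 0.0)
  expect_equal(compute_rpkm(100, 2000, 2e6), 25.0)  # doubling halves
  expect_equal(compute_rpkm(300, 2000, 1e6), 3 * compute_rpkm(100, 2000, 1e6))
  expect_error(compute_rpkm(10, 2000, 0), "total_mapped")
  fx <- toy_fixture()
  expect_equal(gene_exonic_length(fx$model, "G1"), 300L)
  fe <- fusion_expression(447, 98, 1e6)
  expect_equal(fe$raw, 447)
  expect_equal(fusion_expression(0, 98, 1e6)$raw, 0)
  expect_equal(fusion_expression(10, 98, 2e6)$normalized,
               fusion_expression(10, 98, 1e6)$normalized / 2)
})

test_that("chromosomal classification and the published-table split", {
  fx <- toy_fixture()
  expect_equal(classify_chromosomal(
    data.frame(five_gene = "G1", three_gene = "G2"), fx$model), "inter")
  expect_equal(classify_chromosomal(
    data.frame(five_gene = "G1", three_gene = "G1"), fx$model), "intra")
  tab <- system.file("extdata", "table1_fusions.tsv", package = "fusionscan")
  s <- summarize_fusion_table(tab)
  expect_equal(s$intra, 19L)
  expect_equal(s$inter, 8L)
})

test_that("copy-number association flags transitions and amplifications", {
  m <- build_model(list(
    list(gene_id = "A", chrom = "c1", strand = "+",
         exon_starts = 200000L, exon_lens = 5000L, cds = NA),
    list(gene_id = "B", chrom = "c1", strand = "+",
         exon_starts = 500000L, exon_lens = 5000L, cds = NA)))
  cl <- data.frame(five_gene = "A", three_gene = "B")
  p <- detection_params()
  ## gene inside a log2=2.5 segment
  prof <- cn_profile(data.frame(chrom = "c1",
                                start = c(1L, 150000L, 260000L),
                                end = c(149999L, 259999L, 800000L),
                                log2_ratio = c(0, 2.5, 0)))
  cna <- copy_number_association(cl, prof, m, p)
  expect_true(cna$amplified)
  expect_true(cna$at_cn_transition)
  ## flat profile
  flat <- cn_profile(data.frame(chrom = "c1", start = 1L, end = 800000L,
                                log2_ratio = 0))
  cna2 <- copy_number_association(cl, flat, m, p)
  expect_false(cna2$amplified); expect_false(cna2$at_cn_transition)
  ## boundary 50 kb beyond the gene end, window 100 kb -> transition only
  prof3 <- cn_profile(data.frame(chrom = "c1", start = c(1L, 255000L),
                                 end = c(254999L, 800000L),
                                 log2_ratio = c(0, 0.8)))
  cna3 <- copy_number_association(cl, prof3, m, p)
  expect_true(cna3$at_cn_transition)
  expect_false(cna3$amplified)
  ## monotone in the window size
  p_small <- detection_params(transition_window = 10000L)
  expect_false(copy_number_association(cl, prof3, m, p_small)$at_cn_transition)
  p_big <- detection_params(transition_window = 200000L)
  expect_true(copy_number_association(cl, prof3, m, p_big)$at_cn_transition)
  ## absent profile -> unknown; overlapping segments -> structural error
  expect_true(is.na(copy_number_association(cl, NULL, m, p)$amplified))
  expect_error(cn_profile(data.frame(chrom = "c1", start = c(1L, 50L),
                                     end = c(100L, 150L), log2_ratio = 0)),
               "overlap")
  ## TSV round trip preserves the 0-based half-open external convention
  f <- tempfile()
  write_cn_profile(prof, f)
  expect_identical(read_cn_profile(f)$segments, prof$segments)
})

test_that("coverage counts each sequenced base; silent pre-junction exons stay at zero", {
  fx <- toy_fixture()
  ## one 50 bp read fully inside exon 1 of G1
  loci <- data.frame(read_id = "r", locus = "G:chr1:120:+", gene_id = NA,
                     chrom = "chr1", gstart = 120L, gstrand = "+",
                     spanning = FALSE, mismatches = 0L)
  cov <- compute_coverage("G1", loci, fx$model, 50L)
  expect_equal(sum(cov$depth), 50L)
  expect_equal(max(cov$depth), 1L)
  expect_equal(nrow(cov), 300L)  # merged exonic span
  ## no reads -> all zeros
  cov0 <- compute_coverage("G1", loci[0, ], fx$model, 50L)
  expect_true(all(cov0$depth == 0L))
  ## promoter-swap 3' partner in the flagship run: exons upstream of the
  ## fused exon have (near) zero coverage, downstream exons are covered
  fl <- flagship_run()
  u <- fl$universe
  ps_ev <- Filter(function(e) !is.null(e$spec) && isTRUE(e$spec$promoter_swap),
                  u$events)[[1]]
  g3 <- ps_ev$three
  loci_u <- fl$scan$loci[fl$scan$loci$read_id %in%
    fl$scan$assignments$read_id[fl$scan$assignments$category == "unique"], ]
  cov3 <- compute_coverage(g3, loci_u, u$model, 50L)
  ex3 <- transcript_exons(u$model, sprintf("%s.t1", g3))
  fused_rank <- ex3$exon_rank[ex3$exon_id ==
    u$truth$three_exon[u$truth$event_id == ps_ev$id]]
  post <- ex3[ex3$exon_rank >= fused_rank, ]
  post_pos <- unlist(Map(seq, post$start, post$end))
  expect_gt(mean(cov3$depth[cov3$pos %in% post_pos]), 0.3)
  pre <- ex3[ex3$exon_rank < fused_rank, ]
  expect_gt(nrow(pre), 0L)
  pre_pos <- unlist(Map(seq, pre$start, pre$end))
  expect_lt(mean(cov3$depth[cov3$pos %in% pre_pos]), 0.05)
})

test_that("report summarization reproduces the published tallies and handles empties", {
  tab <- system.file("extdata", "table1_fusions.tsv", package = "fusionscan")
  s <- summarize_fusion_table(tab)
  expect_equal(s$total, 27L)
  expect_equal(s$in_frame, 23L)
  expect_equal(s$amplified, 17L)
  expect_equal(unname(s$per_sample[["MCF-7"]]), 3L)
  e <- summarize_report(data.frame())
  expect_equal(e$total, 0L)
  expect_equal(e$in_frame, 0L)
  expect_error(summarize_fusion_table(data.frame(bad = 1)), "missing column")
})
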