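## Shared fixtures and independent oracles. Everything is generated in code;
## heavyweight runs are memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

rand_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")

revcomp_str <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

## Hand-built two-gene toy model (one plus-strand, one minus-strand gene)
## with a deterministic random genome; exercised against hand-computed
## coordinates in several suites.
toy_fixture <- function() {
  if (!is.null(.fixture_env$toy)) return(.fixture_env$toy)
  set.seed(101)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna_str(5000),
                                       chr2 = rand_dna_str(3000)))
  gtf <- c(
    'chr1\tx\tgene\t101\t900\t.\t+\t.\tgene_id "G1"; gene_name "G1"; gene_biotype "protein_coding";',
    'chr1\tx\ttranscript\t101\t900\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";',
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1"; exon_id "G1.e1";',
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1"; exon_id "G1.e2";',
    'chr1\tx\texon\t801\t900\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1"; exon_id "G1.e3";',
    'chr1\tx\tCDS\t151\t200\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";',
    'chr1\tx\tCDS\t301\t400\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";',
    'chr2\tx\tgene\t501\t1200\t.\t-\t.\tgene_id "G2"; gene_name "G2"; gene_biotype "protein_coding";',
    'chr2\tx\ttranscript\t501\t1200\t.\t-\t.\tgene_id "G2"; transcript_id "G2.t1";',
    'chr2\tx\texon\t501\t600\t.\t-\t.\tgene_id "G2"; transcript_id "G2.t1"; exon_id "G2.e2";',
    'chr2\tx\texon\t1101\t1200\t.\t-\t.\tgene_id "G2"; transcript_id "G2.t1"; exon_id "G2.e1";')
  f <- tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  .fixture_env$toy <- list(genome = genome, model = load_annotation(f),
                           gtf_path = f, gtf_lines = gtf)
  .fixture_env$toy
}

## Build a gene_model directly from per-gene descriptions:
## list(gene_id=, chrom=, strand=, exon_starts=, exon_lens=, cds=c(s,e) or NA,
##      biotype=, transcripts = optional list of list(exon_idx=, cds=))
build_model <- function(descs) {
  genes <- list(); txs <- list(); exons <- list()
  for (d in descs) {
    starts <- d$exon_starts; lens <- d$exon_lens
    ends <- starts + lens - 1L
    n <- length(starts)
    rank <- if (d$strand == "+") seq_len(n) else rev(seq_len(n))
    txl <- if (is.null(d$transcripts)) list(list(exon_idx = seq_len(n),
                                                 cds = d$cds))
           else d$transcripts
    genes[[d$gene_id]] <- data.frame(
      gene_id = d$gene_id, gene_name = d$gene_id, chrom = d$chrom,
      start = min(starts), end = max(ends), strand = d$strand,
      biotype = if (is.null(d$biotype)) "protein_coding" else d$biotype,
      stringsAsFactors = FALSE)
    for (ti in seq_along(txl)) {
      tid <- sprintf("%s.t%d", d$gene_id, ti)
      keep <- sort(txl[[ti]]$exon_idx)
      kr <- rank[keep]
      cdsv <- txl[[ti]]$cds
      txs[[tid]] <- data.frame(
        transcript_id = tid, gene_id = d$gene_id, chrom = d$chrom,
        strand = d$strand, start = min(starts[keep]), end = max(ends[keep]),
        cds_start = if (all(is.na(cdsv))) NA_integer_ else cdsv[1],
        cds_end = if (all(is.na(cdsv))) NA_integer_ else cdsv[2],
        stringsAsFactors = FALSE)
      exons[[tid]] <- data.frame(
        exon_id = sprintf("%s.e%d", d$gene_id, rank[keep]),
        transcript_id = tid, gene_id = d$gene_id, chrom = d$chrom,
        start = starts[keep], end = ends[keep], strand = d$strand,
        exon_rank = rank(kr), stringsAsFactors = FALSE)
    }
  }
  fusionscan:::new_gene_model(do.call(rbind, genes), do.call(rbind, txs),
                              do.call(rbind, exons))
}

## ---- independent aligner oracle: naive sliding-window Hamming scan ----

## Precompute window matrices (one row per placement) for each reference.
oracle_index <- function(refs, L) {
  lapply(seq_along(refs), function(ri) {
    R <- utf8ToInt(as.character(refs[[ri]]))
    n <- length(R) - L + 1L
    if (n < 1L) return(NULL)
    idx <- outer(0:(n - 1L), 1:L, "+")
    matrix(R[idx], n, L)
  })
}

oracle_align <- function(read, refs, max_mm, index = NULL) {
  L <- nchar(read)
  if (is.null(index)) index <- oracle_index(refs, L)
  out <- list()
  for (ri in seq_along(refs)) {
    W <- index[[ri]]
    if (is.null(W)) next
    for (st in c("+", "-")) {
      rd <- if (st == "+") read else revcomp_str(read)
      mm <- rowSums(W != matrix(utf8ToInt(rd), nrow(W), L, byrow = TRUE))
      pos <- which(mm <= max_mm)
      if (length(pos) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          read_id = "read", ref_id = names(refs)[ri], start = pos,
          strand = st, mismatches = as.integer(mm[pos]),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(fusionscan:::empty_alignments())
  out <- do.call(rbind, out)
  out <- out[order(out$ref_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- independent frame oracle: per-base phase enumeration ----
## Works from transcript-level quantities only: exon lengths in transcript
## order, CDS interval, fused exon index per side. Enumerates coding state
## base by base rather than using interval arithmetic.
oracle_frame <- function(lens5, cds5, five_idx, lens3, cds3, three_idx) {
  if (any(is.na(cds5)) || any(is.na(cds3))) return(NA)
  base_coding <- function(lens, cds) {
    tl <- sum(lens)
    v <- logical(tl); v[seq(cds[1], cds[2])] <- TRUE
    v
  }
  c5 <- base_coding(lens5, cds5); c3 <- base_coding(lens3, cds3)
  p5 <- sum(lens5[seq_len(five_idx)])
  p3 <- if (three_idx == 1L) 0L else sum(lens3[seq_len(three_idx - 1L)])
  n5 <- sum(c5[seq_len(p5)])
  n3 <- if (p3 == 0L) 0L else sum(c3[seq_len(p3)])
  if (n3 == 0L) return(TRUE)
  if (n5 == 0L) return(FALSE)
  if (n5 >= sum(c5)) return(FALSE)
  if (n3 >= sum(c3)) return(FALSE)
  (n5 %% 3L) == (n3 %% 3L)
}

## ---- memoized flagship run (shared by pipeline + acceptance suites) ----
flagship_run <- function() {
  if (!is.null(.fixture_env$flagship)) return(.fixture_env$flagship)
  cfg <- flagship_config(seed = 42)
  u <- generate_universe(cfg)
  rd <- simulate_reads(u)
  cn <- simulate_cn_profile(u)
  el <- system.time(
    scan <- detect_fusions(rd$pairs, u$model, u$genome,
                           contaminants = u$contaminants,
                           paralogs = u$paralogs, cn = cn))[["elapsed"]]
  .fixture_env$flagship <- list(cfg = cfg, universe = u, reads = rd,
                                cn = cn, scan = scan, elapsed = el)
  .fixture_env$flagship
}

## small single-fusion universe for fast pipeline-level checks
mini_run <- function() {
  if (!is.null(.fixture_env$mini)) return(.fixture_env$mini)
  cfg <- simulation_config(
    seed = 7, n_chromosomes = 3, n_genes = 9,
    fusion_specs = list(fusion_spec(class = "intra", frame = "in")),
    n_readthrough_decoys = 1, n_paralog_decoys = 1, n_artifact_stacks = 1,
    n_overlapping_pairs = 1, background_pairs_per_gene = 15)
  u <- generate_universe(cfg)
  rd <- simulate_reads(u)
  scan <- detect_fusions(rd$pairs, u$model, u$genome,
                         contaminants = u$contaminants, paralogs = u$paralogs)
  .fixture_env$mini <- list(cfg = cfg, universe = u, reads = rd, scan = scan)
  .fixture_env$mini
}
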