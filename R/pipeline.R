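#' Run the full fusion-detection pipeline
#'
#' Orchestrates the published workflow end to end: trim reads, remove
#' contaminant (rRNA/adaptor) pairs, align mates against the genome and the
#' normal splice-junction reference and categorize them (unaligned / unique /
#' multi), collect discordant pairs into candidate gene pairs, filter out
#' overlapping, adjacent (readthrough) and paralogous pairs and pairs below
#' the support threshold, build the artificial exon-exon junction database
#' for each surviving candidate, place the still-unmapped reads on it,
#' require junction-spanning reads with two-sided anchors, classify each
#' junction's start-position pattern as genuine tiling or stacked artifact,
#' and annotate genuine calls with frame, expression, chromosomal class and
#' copy-number association.
#'
#' @param reads A `read_pairs` object, or length-2 character vector of FASTQ
#'   paths (mate1, mate2).
#' @param model A `gene_model` (or a GTF path).
#' @param genome Named `DNAStringSet` (or a FASTA path).
#' @param contaminants Optional `DNAStringSet` / FASTA path of contaminant
#'   sequences.
#' @param paralogs Optional `paralog_table` / TSV path.
#' @param cn Optional `cn_profile` / TSV path.
#' @param params A `detection_params`.
#' @param flank Flank length for junction sequences (default 49).
#' @param biotype_whitelist Optional biotype whitelist for candidates.
#' @param splice_variants Passed to [predict_frame()].
#' @return Object of class `fusion_scan` with components `report` (annotated
#'   genuine calls), `calls` (all junction calls incl. artifacts,
#'   prioritized), `candidates` (filtered candidate pairs), `stage_counts`
#'   (reads in/out per stage), `params`, and supporting tables.
#' @examples
#' \donttest{
#' cfg <- simulation_config(seed = 7, n_genes = 8, fusion_specs = list(
#'   fusion_spec(class = "intra")), background_pairs_per_gene = 10)
#' u <- generate_universe(cfg)
#' rd <- simulate_reads(u)
#' scan <- detect_fusions(rd$pairs, u$model, u$genome,
#'                        contaminants = u$contaminants)
#' summary(scan)
#' }
#' @export
detect_fusions <- function(reads, model, genome, contaminants = NULL,
                           paralogs = NULL, cn = NULL,
                           params = detection_params(), flank = 49L,
                           biotype_whitelist = NULL, splice_variants = FALSE) {
  if (is.character(reads)) reads <- read_pairs_from_fastq(reads[1], reads[2])
  if (is.character(model)) model <- load_annotation(model)
  if (is.character(genome)) genome <- load_genome(genome)
  if (is.character(contaminants)) contaminants <- load_genome(contaminants)
  if (is.character(paralogs)) paralogs <- load_paralogs(paralogs)
  if (is.character(cn)) cn <- read_cn_profile(cn)
  stopifnot(inherits(reads, "read_pairs"), inherits(model, "gene_model"))

  log <- list()
  note <- function(stage, n_in, n_out)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out)

  n0 <- length(reads$pair_ids)
  trimmed <- trim_reads(reads, params$trim_len)
  note("trim", n0, length(trimmed$pair_ids))

  if (!is.null(contaminants)) {
    fc <- filter_contaminants(trimmed, contaminants, params$max_mismatches)
    kept <- fc$kept
    note("decontaminate", length(trimmed$pair_ids), length(kept$pair_ids))
  } else {
    kept <- trimmed
    note("decontaminate", length(trimmed$pair_ids), length(kept$pair_ids))
  }

  sj <- build_splice_junction_reference(model, genome, flank = flank)
  mates <- c(kept$mate1, kept$mate2)
  mp <- map_reads(mates, genome, sj, model, params)
  cat_tab <- table(factor(mp$categories$category,
                          levels = c("unaligned", "unique", "multi")))
  note("align", length(mates), sum(cat_tab[c("unique", "multi")]))

  cands_all <- find_discordant_pairs(mp$assignments)
  note("discordant_pairs", length(kept$pair_ids), sum(cands_all$pair_count))
  cands <- filter_candidates(cands_all, model, paralogs, params,
                             biotype_whitelist)
  note("filter_candidates", nrow(cands_all), nrow(cands))

  ## junction pass on the unaligned reads
  unmapped_ids <- mp$categories$read_id[mp$categories$category == "unaligned"]
  unmapped <- mates[unmapped_ids]
  calls <- list(); junctions <- list(); hits_all <- list()
  for (i in seq_len(nrow(cands))) {
    jdb <- enumerate_fusion_junctions(cands$gene_a[i], cands$gene_b[i],
                                      model, genome, flank = flank)
    hits <- align_unmapped_to_junctions(unmapped, jdb, params)
    cl <- call_junctions(cands[i, ], hits, params)
    junctions[[length(junctions) + 1L]] <- jdb
    if (nrow(hits) > 0L) hits_all[[length(hits_all) + 1L]] <- hits
    if (nrow(cl) > 0L) calls[[length(calls) + 1L]] <- cl
  }
  calls <- if (length(calls) > 0L) prioritize_calls(do.call(rbind, calls))
           else call_junctions(NULL, NULL, params)
  junctions <- if (length(junctions) > 0L) do.call(rbind, junctions) else NULL
  hits_all <- if (length(hits_all) > 0L) do.call(rbind, hits_all) else NULL
  note("junction_calls", nrow(cands), nrow(calls))

  genuine <- calls[calls$tiling_class == "genuine", , drop = FALSE]
  note("tiling_filter", nrow(calls), nrow(genuine))

  ## ---- characterization of genuine calls ----
  total_mapped <- sum(mp$categories$category == "unique")
  assign_counts <- table(mp$assignments$gene_id[!is.na(mp$assignments$gene_id)])
  report <- genuine
  if (nrow(genuine) > 0L) {
    ann <- lapply(seq_len(nrow(genuine)), function(i) {
      call <- genuine[i, ]
      g5 <- get_gene(model, call$five_gene); g3 <- get_gene(model, call$three_gene)
      jlen <- nchar(junctions$seq[match(call$junction_id, junctions$junction_id)])
      fx <- fusion_expression(call$n_junction_reads, jlen, total_mapped)
      cna <- copy_number_association(call, cn, model, params)
      rpk <- function(g) {
        cnt <- if (g$gene_id %in% names(assign_counts))
          as.integer(assign_counts[[g$gene_id]]) else 0L
        compute_rpkm(cnt, gene_exonic_length(model, g$gene_id), total_mapped)
      }
      data.frame(five_chrom = g5$chrom, three_chrom = g3$chrom,
                 chromosomal_class = classify_chromosomal(call, model),
                 in_frame = as.logical(predict_frame(call, model,
                                                     splice_variants)),
                 rpkm_5 = rpk(g5), rpkm_3 = rpk(g3),
                 fusion_expression_raw = fx$raw,
                 fusion_expression_norm = fx$normalized,
                 at_cn_transition = cna$at_cn_transition,
                 amplified = cna$amplified)
    })
    report <- cbind(genuine, do.call(rbind, ann))
    report <- report[, c("five_gene", "five_chrom", "three_gene", "three_chrom",
                         "five_exon", "three_exon", "n_pairs",
                         "n_junction_reads", "in_frame", "amplified",
                         "tiling_class", "distinct_starts", "at_cn_transition",
                         "chromosomal_class", "rpkm_5", "rpkm_3",
                         "fusion_expression_raw", "fusion_expression_norm",
                         "reciprocal", "junction_id")]
    rownames(report) <- NULL
  } else {
    report <- data.frame(five_gene = character(0), five_chrom = character(0),
                         three_gene = character(0), three_chrom = character(0),
                         five_exon = character(0), three_exon = character(0),
                         n_pairs = integer(0), n_junction_reads = integer(0),
                         in_frame = logical(0), amplified = logical(0),
                         tiling_class = character(0), distinct_starts = integer(0),
                         at_cn_transition = logical(0),
                         chromosomal_class = character(0),
                         rpkm_5 = numeric(0), rpkm_3 = numeric(0),
                         fusion_expression_raw = integer(0),
                         fusion_expression_norm = numeric(0),
                         reciprocal = logical(0), junction_id = character(0))
  }

  structure(list(report = report, calls = calls, candidates = cands,
                 raw_candidates = cands_all, stage_counts = do.call(rbind, log),
                 categories = cat_tab, assignments = mp$assignments,
                 loci = mp$loci, junctions = junctions, junction_hits = hits_all,
                 total_mapped = total_mapped, sj = sj, params = params,
                 read_len = params$trim_len),
            class = "fusion_scan")
}

#' @export
print.fusion_scan <- function(x, ...) {
  cat("Fusion scan\n")
  cat(sprintf("  reads: %d unaligned, %d unique, %d multi\n",
              x$categories[["unaligned"]], x$categories[["unique"]],
              x$categories[["multi"]]))
  cat(sprintf("  candidates after filtering: %d\n", nrow(x$candidates)))
  cat(sprintf("  junction calls: %d (%d genuine, %d artifact)\n",
              nrow(x$calls), sum(x$calls$tiling_class == "genuine"),
              sum(x$calls$tiling_class == "artifact")))
  if (nrow(x$report) > 0L) {
    cat("  genuine fusions:\n")
    for (i in seq_len(nrow(x$report))) {
      r <- x$report[i, ]
      cat(sprintf("    %s (%s) -> %s (%s): %d pairs, %d junction reads, %s, %s\n",
                  r$five_gene, r$five_chrom, r$three_gene, r$three_chrom,
                  r$n_pairs, r$n_junction_reads,
                  if (isTRUE(r$in_frame)) "in-frame" else "out-of-frame",
                  r$chromosomal_class))
    }
  } else cat("  no genuine fusions reported\n")
  invisible(x)
}

#' @export
summary.fusion_scan <- function(object, ...) {
  s <- summarize_report(object$report)
  structure(list(counts = s, stage_counts = object$stage_counts),
            class = "summary.fusion_scan")
}

#' @export
print.summary.fusion_scan <- function(x, ...) {
  cat("Fusion scan summary\n")
  cat(sprintf("  total genuine fusions: %d (intra %d, inter %d)\n",
              x$counts$total, x$counts$intra, x$counts$inter))
  cat(sprintf("  in-frame: %d, amplified: %d, at CN transition: %s\n",
              x$counts$in_frame, x$counts$amplified,
              format(x$counts$at_cn_transition)))
  cat("  stage counts:\n")
  print(x$stage_counts, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fusion_scan <- function(x, ...) x$report

#' Write a fusion report TSV
#'
#' Columns mirror the published summary table (5' gene/chromosome, 3'
#' gene/chromosome, paired-end and junction read counts, frame, amplified)
#' plus tiling class, distinct start count and CN-transition flag.
#'
#' @param scan A `fusion_scan` (or its `report` data frame).
#' @param path Output TSV path.
#' @param sample Optional sample label column.
#' @return `path`, invisibly.
#' @export
write_fusion_report <- function(scan, path, sample = NULL) {
  rep <- if (inherits(scan, "fusion_scan")) scan$report else scan
  if (!is.null(sample) && nrow(rep) > 0L) rep <- cbind(sample = sample, rep)
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a published-style fusion table
#'
#' Reads a TSV with columns `sample`, `five_gene`, `five_chrom`,
#' `three_gene`, `three_chrom`, `n_pairs`, `n_junction_reads`, `in_frame`,
#' `amplified` (Yes/No or logical) and tallies total rows, intra-/
#' interchromosomal counts, in-frame and amplified counts and per-sample row
#' counts.
#'
#' @param x Path to the TSV, or an equivalent data frame.
#' @return Named list of counts (see [summarize_report()]).
#' @export
summarize_fusion_table <- function(x) {
  df <- if (is.character(x))
    read.table(x, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               comment.char = "#")
  else x
  need <- c("sample", "five_gene", "five_chrom", "three_gene", "three_chrom",
            "in_frame", "amplified")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("fusion table parse error: missing column(s) ",
         paste(miss, collapse = ", "))
  df$five_chrom <- as.character(df$five_chrom)
  df$three_chrom <- as.character(df$three_chrom)
  summarize_report(df)
}
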