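#' Enumerate all candidate exon-exon fusion junction sequences
#'
#' For one candidate gene pair, builds the artificial junction database: for
#' every exon of gene A and every exon of gene B, the junction sequence A->B
#' (3' end of the A exon followed by 5' start of the B exon) and the junction
#' B->A, each read in the donor transcript's orientation (minus-strand exon
#' fragments reverse-complemented). Exons identical in coordinates across
#' transcripts are used once; junction sequences that come out identical are
#' deduplicated with their labels merged.
#'
#' @param gene_a,gene_b Gene identifiers of the candidate pair.
#' @param model A `gene_model`.
#' @param genome Named `DNAStringSet`.
#' @param flank Maximum bases from each exon (default 49).
#' @return Data frame: `junction_id`, `five_gene`, `five_exon`, `three_gene`,
#'   `three_exon`, `offset` (bases from the 5' exon), `seq`, `alt_labels`
#'   (labels merged by deduplication, comma-separated, may be empty).
#' @export
enumerate_fusion_junctions <- function(gene_a, gene_b, model, genome,
                                       flank = 49L) {
  exs <- function(g) {
    e <- model$exons[model$exons$gene_id == g, , drop = FALSE]
    if (nrow(e) == 0L) stop("gene without exons: ", g)
    e[!duplicated(paste(e$chrom, e$start, e$end, e$strand)), , drop = FALSE]
  }
  ea <- exs(gene_a); eb <- exs(gene_b)
  one <- function(e5, e3) {
    f5 <- exon_flank(genome, e5, side = "3p", flank = flank)
    f3 <- exon_flank(genome, e3, side = "5p", flank = flank)
    data.frame(junction_id = sprintf("FJ|%s|%s|%s|%s|%d", e5$gene_id, e5$exon_id,
                                     e3$gene_id, e3$exon_id, nchar(f5)),
               five_gene = e5$gene_id, five_exon = e5$exon_id,
               three_gene = e3$gene_id, three_exon = e3$exon_id,
               offset = nchar(f5), seq = paste0(f5, f3),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(ea))) for (j in seq_len(nrow(eb))) {
    rows[[length(rows) + 1L]] <- one(ea[i, ], eb[j, ])
    rows[[length(rows) + 1L]] <- one(eb[j, ], ea[i, ])
  }
  df <- do.call(rbind, rows)
  ## deduplicate identical sequences, merging labels
  sp <- split(df, df$seq)
  df <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$junction_id), , drop = FALSE]
    d1 <- d[1, , drop = FALSE]
    d1$alt_labels <- paste(d$junction_id[-1], collapse = ",")
    d1
  }))
  df <- df[order(df$junction_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Align unmapped reads to a fusion-junction database
#'
#' Reads that aligned nowhere on genome or splice-junction references are
#' placed on the candidate junction sequences (ungapped, both strands, at
#' most `max_mismatches` mismatches). Only placements spanning the breakpoint
#' with at least `min_anchor` bases on each side are kept as hits; a read
#' hitting several junction sequences keeps only its minimum-mismatch hits.
#'
#' @param unmapped Named `DNAStringSet` of unaligned reads (trimmed, one
#'   common width).
#' @param junctions Junction table from [enumerate_fusion_junctions()]
#'   (tables for several candidates may be `rbind`ed).
#' @param params A `detection_params`.
#' @return Data frame of hits: `read_id`, `junction_id`, `start` (1-based on
#'   the junction sequence), `strand`, `mismatches`, `start_offset` (signed
#'   read start relative to the breakpoint; negative = starts in the 5'
#'   exon), `overhang_5`, `overhang_3`.
#' @export
align_unmapped_to_junctions <- function(unmapped, junctions,
                                        params = detection_params()) {
  empty <- data.frame(read_id = character(0), junction_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), start_offset = integer(0),
                      overhang_5 = integer(0), overhang_3 = integer(0),
                      stringsAsFactors = FALSE)
  if (length(unmapped) == 0L || nrow(junctions) == 0L) return(empty)
  L <- unique(Biostrings::width(unmapped))
  stopifnot(length(L) == 1L)
  refs <- Biostrings::DNAStringSet(setNames(junctions$seq, junctions$junction_id))
  aln <- align_many(unmapped, refs, params$max_mismatches)
  if (nrow(aln) == 0L) return(empty)
  off <- junctions$offset[match(aln$ref_id, junctions$junction_id)]
  ov5 <- pmax(0L, off - aln$start + 1L)
  ov3 <- L - ov5
  keep <- pmin(ov5, ov3) >= params$min_anchor
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) == 0L) return(empty)
  ov5 <- ov5[keep]; ov3 <- ov3[keep]; off <- off[keep]
  out <- data.frame(read_id = aln$read_id, junction_id = aln$ref_id,
                    start = aln$start, strand = aln$strand,
                    mismatches = aln$mismatches,
                    start_offset = aln$start - 1L - off,
                    overhang_5 = ov5, overhang_3 = ov3,
                    stringsAsFactors = FALSE)
  ## per read, keep only minimum-mismatch hits (ties keep all)
  best <- tapply(out$mismatches, out$read_id, min)
  out <- out[out$mismatches == best[out$read_id], , drop = FALSE]
  out <- out[order(out$junction_id, out$start, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a junction's read pattern as genuine tiling or stacked artifact
#'
#' A genuine fusion junction shows a tiling/ladder pattern of read alignment
#' start positions across the breakpoint; misalignment artifacts pile up at
#' one position (shifted by at most one to two base pairs) and anchor almost
#' exclusively in one of the exons. The junction is called an artifact when
#' the span of start positions is at most `artifact_span` bp, OR fewer than
#' `min_distinct_starts` distinct start positions are seen, OR fewer than
#' `min_two_sided_anchor_reads` hits anchor with at least `min_anchor` bases
#' on both sides; otherwise genuine.
#'
#' @param hits Data frame of hits on ONE junction (see
#'   [align_unmapped_to_junctions()]); each hit must span the breakpoint.
#' @param params A `detection_params`.
#' @return List: `tiling_class` ("genuine" or "artifact"), `distinct_starts`,
#'   and the three logged sub-criteria (`span_le_artifact`,
#'   `too_few_starts`, `too_few_two_sided`).
#' @export
tiling_classify <- function(hits, params = detection_params()) {
  if (is.null(hits) || nrow(hits) == 0L)
    stop("tiling_classify: empty hit list")
  starts <- hits$start_offset
  distinct_starts <- length(unique(starts))
  span_le_artifact <- (max(starts) - min(starts)) <= params$artifact_span
  too_few_starts <- distinct_starts < params$min_distinct_starts
  two_sided <- sum(pmin(hits$overhang_5, hits$overhang_3) >= params$min_anchor)
  too_few_two_sided <- two_sided < params$min_two_sided_anchor_reads
  cls <- if (span_le_artifact || too_few_starts || too_few_two_sided)
    "artifact" else "genuine"
  list(tiling_class = cls, distinct_starts = distinct_starts,
       span_le_artifact = span_le_artifact, too_few_starts = too_few_starts,
       too_few_two_sided = too_few_two_sided)
}

#' Resolve junction calls for one candidate gene pair
#'
#' One call is emitted per junction sequence supported by at least
#' `min_junction_reads` distinct spanning reads; the orientation of the
#' supported junction sequence fixes the 5' and 3' partners. Several
#' surviving junctions for one gene pair are all reported (alternative
#' splicing at the fusion junction); if both the A->B and B->A orientations
#' are supported, the calls are flagged `reciprocal` for review.
#'
#' @param candidate One row of the filtered candidate table.
#' @param hits Junction hits (from [align_unmapped_to_junctions()]) for this
#'   candidate's junction database.
#' @param params A `detection_params`.
#' @return Data frame of calls: `five_gene`, `five_exon`, `three_gene`,
#'   `three_exon`, `junction_id`, `n_pairs`, `n_junction_reads`,
#'   `tiling_class`, `distinct_starts`, `reciprocal`, plus the tiling
#'   sub-criteria; zero rows when nothing passes.
#' @export
call_junctions <- function(candidate, hits, params = detection_params()) {
  empty <- data.frame(five_gene = character(0), five_exon = character(0),
                      three_gene = character(0), three_exon = character(0),
                      junction_id = character(0), n_pairs = integer(0),
                      n_junction_reads = integer(0), tiling_class = character(0),
                      distinct_starts = integer(0), reciprocal = logical(0),
                      span_le_artifact = logical(0), too_few_starts = logical(0),
                      too_few_two_sided = logical(0), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  rows <- list()
  for (jid in unique(hits$junction_id)) {
    h <- hits[hits$junction_id == jid, , drop = FALSE]
    n_reads <- length(unique(h$read_id))
    if (n_reads < params$min_junction_reads) next
    parts <- strsplit(jid, "|", fixed = TRUE)[[1]]
    tc <- tiling_classify(h, params)
    rows[[length(rows) + 1L]] <- data.frame(
      five_gene = parts[2], five_exon = parts[3],
      three_gene = parts[4], three_exon = parts[5],
      junction_id = jid, n_pairs = candidate$pair_count,
      n_junction_reads = n_reads, tiling_class = tc$tiling_class,
      distinct_starts = tc$distinct_starts, reciprocal = FALSE,
      span_le_artifact = tc$span_le_artifact,
      too_few_starts = tc$too_few_starts,
      too_few_two_sided = tc$too_few_two_sided,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  orientations <- unique(paste(out$five_gene, out$three_gene))
  if (length(orientations) > 1L) out$reciprocal <- TRUE
  rownames(out) <- NULL
  out
}

#' Order fusion calls for review
#'
#' Genuine calls come before artifacts; within each class calls are ordered
#' by descending number of distinct junction-read start positions, then
#' descending junction reads, then descending supporting pairs, with gene ids
#' as the final deterministic tiebreak.
#'
#' @param calls Data frame of calls (rbind of [call_junctions()] outputs).
#' @return The same data frame, reordered.
#' @export
prioritize_calls <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  cls <- calls$tiling_class != "genuine"  # FALSE (genuine) sorts first
  o <- order(cls, -calls$distinct_starts, -calls$n_junction_reads,
             -calls$n_pairs, calls$five_gene, calls$three_gene,
             calls$junction_id)
  out <- calls[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
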