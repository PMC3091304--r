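## cumulative transcript position of the END of a given exon (transcript
## orientation); 0 if exon_rank = 0
tpos_exon_end <- function(ex, exon_id) {
  r <- ex$exon_rank[ex$exon_id == exon_id]
  if (length(r) == 0L) return(NA_integer_)
  sum(ex$end[ex$exon_rank <= r] - ex$start[ex$exon_rank <= r] + 1L)
}

## in-frame decision for one 5' transcript / 3' transcript combination
frame_one_combo <- function(tx5, ex5, five_exon, tx3, ex3, three_exon) {
  if (is.na(tx5$cds_start) || is.na(tx3$cds_start)) return(NA)  # no CDS
  p5 <- tpos_exon_end(ex5, five_exon)            # last fused base of 5' tx
  r3 <- ex3$exon_rank[ex3$exon_id == three_exon]
  p3 <- if (r3 == 1L) 0L else
    sum(ex3$end[ex3$exon_rank < r3] - ex3$start[ex3$exon_rank < r3] + 1L)
  cds_len5 <- tx5$cds_end - tx5$cds_start + 1L
  cds_len3 <- tx3$cds_end - tx3$cds_start + 1L
  n5 <- min(max(0L, p5 - tx5$cds_start + 1L), cds_len5)
  n3 <- min(max(0L, p3 - tx3$cds_start + 1L), cds_len3)
  if (n3 == 0L) return(TRUE)                # complete 3' ORF downstream
  if (n5 == 0L) return(FALSE)               # 3' CDS truncated, no 5' coding
  if (n5 >= cds_len5) return(FALSE)         # 5' stop reached before junction
  if (n3 >= cds_len3) return(FALSE)         # junction beyond 3' coding region
  (n5 %% 3L) == (n3 %% 3L)
}

#' Predict whether a fusion junction is in frame
#'
#' A fusion is predicted in-frame if ANY combination of a 5'-partner
#' transcript containing the fused 5' exon with a 3'-partner transcript
#' containing the fused 3' exon retains the coding phase across the junction
#' (cumulative CDS length before the junction, modulo 3, equal on both
#' sides). A junction upstream of the 3' transcript's coding region leaves
#' the complete 3' ORF intact (promoter swap) and counts as in-frame; a
#' junction beyond either coding region, or into a 3' CDS with no 5' coding
#' contribution, does not. With `splice_variants = TRUE` the rule is relaxed:
#' combinations obtained by skipping any single internal exon on either side
#' of the junction are also tried.
#'
#' @param call One fusion call (row with `five_gene`, `five_exon`,
#'   `three_gene`, `three_exon`).
#' @param model A `gene_model`.
#' @param splice_variants Also try single-internal-exon skips (default off).
#' @return Logical; `FALSE` with attribute `reason = "no CDS"` when no
#'   transcript combination has annotated CDS on both sides.
#' @export
predict_frame <- function(call, model, splice_variants = FALSE) {
  tx5s <- model$transcripts[model$transcripts$gene_id == call$five_gene, , drop = FALSE]
  tx3s <- model$transcripts[model$transcripts$gene_id == call$three_gene, , drop = FALSE]
  found_exon <- FALSE; any_cds <- FALSE
  results <- logical(0)
  for (i in seq_len(nrow(tx5s))) {
    ex5 <- transcript_exons(model, tx5s$transcript_id[i])
    if (!call$five_exon %in% ex5$exon_id) next
    for (j in seq_len(nrow(tx3s))) {
      ex3 <- transcript_exons(model, tx3s$transcript_id[j])
      if (!call$three_exon %in% ex3$exon_id) next
      found_exon <- TRUE
      combos5 <- list(ex5); combos3 <- list(ex3)
      if (splice_variants) {
        combos5 <- c(combos5, skip_internal_exon(ex5, keep = call$five_exon))
        combos3 <- c(combos3, skip_internal_exon(ex3, keep = call$three_exon))
      }
      for (e5 in combos5) for (e3 in combos3) {
        r <- frame_one_combo(tx5s[i, ], e5, call$five_exon,
                             tx3s[j, ], e3, call$three_exon)
        if (!is.na(r)) { any_cds <- TRUE; results <- c(results, r) }
      }
    }
  }
  if (!found_exon)
    stop("predict_frame: fused exon absent from all transcripts of its gene")
  if (!any_cds)
    return(structure(FALSE, reason = "no CDS"))
  any(results)
}

## all exon tables obtained by dropping one internal exon (never the fused
## exon, never the first or last); ranks renumbered
skip_internal_exon <- function(ex, keep) {
  n <- nrow(ex)
  if (n <= 2L) return(list())
  out <- list()
  for (k in 2:(n - 1L)) {
    if (ex$exon_id[k] == keep) next
    d <- ex[-k, , drop = FALSE]
    d$exon_rank <- seq_len(nrow(d))
    out[[length(out) + 1L]] <- d
  }
  out
}

#' Gene expression as RPKM
#'
#' Uniquely mapped reads per kilobase of merged exonic gene sequence per
#' million mapped reads.
#'
#' @param unique_read_count Uniquely mapped reads assigned to the gene.
#' @param exonic_length Merged exonic length of the gene in bp.
#' @param total_mapped Total uniquely mapped reads in the sample (> 0).
#' @return RPKM value.
#' @export
compute_rpkm <- function(unique_read_count, exonic_length, total_mapped) {
  if (is.na(total_mapped) || total_mapped <= 0)
    stop("compute_rpkm: total_mapped must be > 0")
  unique_read_count / ((exonic_length / 1000) * (total_mapped / 1e6))
}

#' Merged exonic length of a gene
#' @param model A `gene_model`.
#' @param gene_id Gene identifier.
#' @return Length in bp of the union of the gene's exons.
#' @export
gene_exonic_length <- function(model, gene_id) {
  e <- model$exons[model$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(e) == 0L) stop("gene without exons: ", gene_id)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(e$start, e$end))))
}

#' Fusion gene expression from junction reads
#'
#' The raw number of reads aligning to the fusion junction, plus an
#' RPKM-style normalization using the junction sequence length.
#'
#' @param n_junction_reads Junction-spanning read count of the call.
#' @param junction_length Length of the junction sequence (bp).
#' @param total_mapped Total uniquely mapped reads (> 0).
#' @return List with `raw` and `normalized`.
#' @export
fusion_expression <- function(n_junction_reads, junction_length, total_mapped) {
  list(raw = n_junction_reads,
       normalized = compute_rpkm(n_junction_reads, junction_length, total_mapped))
}

#' Classify a fusion as intra- or interchromosomal
#' @param call Row with `five_gene` and `three_gene`.
#' @param model A `gene_model`.
#' @return `"intra"` if both partners share a chromosome, else `"inter"`.
#' @export
classify_chromosomal <- function(call, model) {
  a <- get_gene(model, call$five_gene); b <- get_gene(model, call$three_gene)
  if (a$chrom == b$chrom) "intra" else "inter"
}

## ---- copy-number profiles ----

#' Read a segmented copy-number profile
#'
#' BED-like TSV with columns chrom, start, end (0-based half-open) and log2
#' ratio; `#` comment lines allowed. Stored 1-based closed internally.
#'
#' @param path TSV path.
#' @return Object of class `cn_profile`: data frame `segments` with `chrom`,
#'   `start`, `end`, `log2_ratio`.
#' @export
read_cn_profile <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "log2_ratio"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  cn_profile(data.frame(chrom = df$chrom, start = df$start + 1L, end = df$end,
                        log2_ratio = df$log2_ratio, stringsAsFactors = FALSE))
}

#' Construct a copy-number profile from 1-based closed segments
#' @param segments Data frame with `chrom`, `start`, `end`, `log2_ratio`.
#' @return Object of class `cn_profile`.
#' @export
cn_profile <- function(segments) {
  s <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  for (ch in unique(s$chrom)) {
    d <- s[s$chrom == ch, , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("cn_profile: overlapping segments on ", ch)
  }
  rownames(s) <- NULL
  structure(list(segments = s), class = "cn_profile")
}

#' Write a copy-number profile as BED-like TSV (0-based half-open)
#' @param profile A `cn_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cn_profile <- function(profile, path) {
  s <- profile$segments
  write.table(data.frame(s$chrom, s$start - 1L, s$end, s$log2_ratio),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Copy-number association of a fusion call
#'
#' `at_cn_transition` is TRUE when any boundary between consecutive segments
#' with |delta log2| >= `cn_delta_log2` falls within either partner gene's
#' span extended by `transition_window` bp; `amplified` is TRUE when either
#' gene overlaps a segment with log2 ratio >= `amplification_log2`.
#'
#' @param call Row with `five_gene` and `three_gene`.
#' @param profile A `cn_profile`, or `NULL` (both flags `NA`).
#' @param model A `gene_model`.
#' @param params A `detection_params`.
#' @return List with logical `at_cn_transition` and `amplified`.
#' @export
copy_number_association <- function(call, profile, model,
                                    params = detection_params()) {
  if (is.null(profile))
    return(list(at_cn_transition = NA, amplified = NA))
  stopifnot(inherits(profile, "cn_profile"))
  genes <- rbind(get_gene(model, call$five_gene), get_gene(model, call$three_gene))
  seg <- profile$segments
  transition <- FALSE; amplified <- FALSE
  for (i in 1:2) {
    g <- genes[i, ]
    d <- seg[seg$chrom == g$chrom, , drop = FALSE]
    if (nrow(d) == 0L) next
    if (any(d$log2_ratio >= params$amplification_log2 &
            d$start <= g$end & d$end >= g$start))
      amplified <- TRUE
    if (nrow(d) > 1L) {
      bnd <- d$end[-nrow(d)]  # boundary between segment k and k+1
      dl <- abs(diff(d$log2_ratio))
      hit <- dl >= params$cn_delta_log2 &
        bnd >= g$start - params$transition_window &
        bnd <= g$end + params$transition_window
      if (any(hit)) transition <- TRUE
    }
  }
  list(at_cn_transition = transition, amplified = amplified)
}

#' Per-base exonic coverage of a gene
#'
#' Depth of uniquely aligned reads over each base of the gene's merged
#' exonic span ("how many times each nucleotide of the gene was sequenced").
#' Supports the exclusive-expression inspection of 3' partners: exons
#' upstream of the fused exon stay near zero when the wild-type gene is
#' silent.
#'
#' @param gene_id Gene identifier.
#' @param loci Data frame of unique read loci (from [map_reads()]; genomic
#'   rows with `chrom`, `gstart`), restricted by the caller to unique reads.
#' @param model A `gene_model`.
#' @param read_len Read length in bp.
#' @return Data frame `pos` (genomic position), `depth`.
#' @export
compute_coverage <- function(gene_id, loci, model, read_len) {
  e <- model$exons[model$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(e) == 0L) stop("gene without exons: ", gene_id)
  exr <- IRanges::reduce(IRanges::IRanges(e$start, e$end))
  pos <- unlist(lapply(seq_along(exr), function(k)
    seq(IRanges::start(exr)[k], IRanges::end(exr)[k])))
  depth <- integer(length(pos))
  l <- loci[!is.na(loci$gstart) & loci$chrom == e$chrom[1], , drop = FALSE]
  if (nrow(l) > 0L) {
    cov_ir <- IRanges::coverage(IRanges::IRanges(l$gstart, l$gstart + read_len - 1L))
    v <- as.integer(cov_ir)
    inb <- pos <= length(v)
    depth[inb] <- v[pos[inb]]
  }
  data.frame(pos = pos, depth = depth)
}

#' Summarize a fusion report
#'
#' Counts of total calls, intra-/interchromosomal calls, in-frame calls,
#' amplified calls, calls at a copy-number transition, and a per-sample
#' breakdown when a `sample` column is present.
#'
#' @param annotations Data frame with columns `chromosomal_class` (or 5'/3'
#'   chromosome columns), `in_frame`, `amplified`, optionally
#'   `at_cn_transition` and `sample`.
#' @return Named list of counts.
#' @export
summarize_report <- function(annotations) {
  a <- annotations
  n <- nrow(a)
  if (n == 0L) {
    return(list(total = 0L, intra = 0L, inter = 0L, in_frame = 0L,
                amplified = 0L, at_cn_transition = 0L,
                per_sample = integer(0)))
  }
  cls <- if ("chromosomal_class" %in% names(a)) a$chromosomal_class
         else ifelse(a$five_chrom == a$three_chrom, "intra", "inter")
  tolog <- function(x) {
    if (is.logical(x)) x
    else toupper(as.character(x)) %in% c("YES", "TRUE", "Y", "1")
  }
  list(total = n,
       intra = sum(cls == "intra"),
       inter = sum(cls == "inter"),
       in_frame = sum(tolog(a$in_frame), na.rm = TRUE),
       amplified = sum(tolog(a$amplified), na.rm = TRUE),
       at_cn_transition = if ("at_cn_transition" %in% names(a))
         sum(tolog(a$at_cn_transition), na.rm = TRUE) else NA_integer_,
       per_sample = if ("sample" %in% names(a)) table(a$sample) else integer(0))
}
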