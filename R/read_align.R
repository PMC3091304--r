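#' Construct a set of read pairs
#'
#' @param mate1,mate2 `DNAStringSet` (or character vectors) of first/second
#'   mates, in order.
#' @param pair_ids Pair identifiers; defaults to names of `mate1` or `pair%d`.
#' @return Object of class `read_pairs` with elements `mate1`, `mate2`
#'   (named `DNAStringSet`s, names `<pair_id>/1` and `<pair_id>/2`) and
#'   `pair_ids`.
#' @export
read_pairs <- function(mate1, mate2, pair_ids = NULL) {
  mate1 <- Biostrings::DNAStringSet(mate1)
  mate2 <- Biostrings::DNAStringSet(mate2)
  if (length(mate1) != length(mate2))
    stop("read_pairs: mate files have different numbers of reads")
  if (is.null(pair_ids)) {
    pair_ids <- if (!is.null(names(mate1))) sub("/[12]$", "", sub("\\s.*$", "", names(mate1)))
                else sprintf("pair%06d", seq_along(mate1))
  }
  if (anyDuplicated(pair_ids)) stop("read_pairs: duplicated pair ids")
  pair_ids <- as.character(pair_ids)
  names(mate1) <- if (length(pair_ids)) paste0(pair_ids, "/1") else character(0)
  names(mate2) <- if (length(pair_ids)) paste0(pair_ids, "/2") else character(0)
  structure(list(mate1 = mate1, mate2 = mate2, pair_ids = pair_ids),
            class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs: %d pairs, mate widths %s\n", length(x$pair_ids),
              paste(unique(c(Biostrings::width(x$mate1),
                             Biostrings::width(x$mate2))), collapse = "/")))
  invisible(x)
}

#' Read paired FASTQ files
#' @param path1,path2 FASTQ paths (gzip allowed), mates in matching order.
#' @return A `read_pairs` object.
#' @export
read_pairs_from_fastq <- function(path1, path2) {
  m1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  m2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  read_pairs(m1, m2)
}

#' Write read pairs as two FASTQ files
#' @param pairs A `read_pairs` object.
#' @param path1,path2 Output FASTQ paths.
#' @return Invisibly, `c(path1, path2)`.
#' @export
write_pairs_fastq <- function(pairs, path1, path2) {
  wr <- function(x, path) {
    q <- Biostrings::BStringSet(vapply(Biostrings::width(x),
                                       function(w) strrep("I", w), ""))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  wr(pairs$mate1, path1); wr(pairs$mate2, path2)
  invisible(c(path1, path2))
}

#' Trim read pairs to a fixed length
#'
#' Each mate is truncated to its first `target_len` bases (the published
#' pipeline trims 56 bp reads to 50 bp). Mates already shorter than
#' `target_len` pass through unchanged; their count is attached as attribute
#' `n_short`.
#'
#' @param pairs A `read_pairs` object.
#' @param target_len Target length in bp (> 0).
#' @return A trimmed `read_pairs` object with attribute `n_short`.
#' @export
trim_reads <- function(pairs, target_len) {
  stopifnot(inherits(pairs, "read_pairs"))
  target_len <- as.integer(target_len)
  if (is.na(target_len) || target_len <= 0L)
    stop("trim_reads: target_len must be > 0")
  n_short <- 0L
  tr <- function(x) {
    w <- Biostrings::width(x)
    n_short <<- n_short + sum(w < target_len)
    Biostrings::subseq(x, 1L, pmin(w, target_len))
  }
  out <- read_pairs(tr(pairs$mate1), tr(pairs$mate2), pairs$pair_ids)
  attr(out, "n_short") <- n_short
  out
}

## ---- ungapped bounded-mismatch alignment ----

empty_alignments <- function() {
  data.frame(read_id = character(0), ref_id = character(0), start = integer(0),
              strand = character(0), mismatches = integer(0),
              stringsAsFactors = FALSE)
}

## Seed-and-verify alignment of equal-width reads against a reference set.
## Reports ALL ungapped end-to-end placements on both strands with Hamming
## distance <= max_mismatches; 'N' in a read counts as a mismatch. Placements
## are reported in forward reference coordinates; strand '-' means the
## reverse complement of the read matches the reference.
align_many <- function(seqs, refs, max_mismatches) {
  if (length(refs) == 0L) stop("align: empty reference set")
  if (length(seqs) == 0L) return(empty_alignments())
  if (is.null(names(seqs))) names(seqs) <- sprintf("read%06d", seq_along(seqs))
  w <- unique(Biostrings::width(seqs))
  if (length(w) != 1L)
    stop("align: reads must have a single common width (trim first)")
  L <- w
  mm <- as.integer(max_mismatches)
  nseed <- mm + 1L
  k <- L %/% nseed
  if (k < 1L) stop("align: reads too short for ", mm, " mismatches")
  seed_off <- (seq_len(nseed) - 1L) * k  # 0-based seed starts within read

  orient <- list(`+` = seqs, `-` = Biostrings::reverseComplement(seqs))
  hits <- vector("list", 64L); nh <- 0L
  for (st in c("+", "-")) {
    oseq <- orient[[st]]
    ## PDict cannot hold ambiguity codes; seed on an N->A substituted copy and
    ## verify against the true read (fixed=TRUE makes N mismatch everything),
    ## which preserves the <=mm guarantee by pigeonhole.
    plain <- Biostrings::DNAStringSet(chartr("NRYSWKMBDHV", "AAAAAAAAAAA",
                                             as.character(oseq)))
    seed_list <- lapply(seed_off, function(o)
      Biostrings::subseq(plain, o + 1L, o + k))
    seeds <- do.call(c, seed_list)
    names(seeds) <- NULL
    pd <- Biostrings::PDict(seeds)
    n <- length(oseq)
    for (r in seq_along(refs)) {
      subject <- refs[[r]]
      rl <- length(subject)
      if (rl < L) next
      m <- Biostrings::matchPDict(pd, subject)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0L) next
      pat <- rep.int(seq_along(cnt), cnt)          # pattern index 1..(nseed*n)
      sstart <- IRanges::start(unlist(m))
      ridx <- ((pat - 1L) %% n) + 1L               # read index
      sidx <- ((pat - 1L) %/% n) + 1L              # seed index
      cand_start <- sstart - seed_off[sidx]
      keep <- cand_start >= 1L & cand_start + L - 1L <= rl
      if (!any(keep)) next
      ridx <- ridx[keep]; cand_start <- cand_start[keep]
      key <- paste(ridx, cand_start)
      dup <- duplicated(key)
      ridx <- ridx[!dup]; cand_start <- cand_start[!dup]
      for (ri in unique(ridx)) {
        at <- cand_start[ridx == ri]
        ed <- Biostrings::neditStartingAt(oseq[[ri]], subject, starting.at = at,
                                          with.indels = FALSE, fixed = TRUE)
        ok <- ed <= mm
        if (!any(ok)) next
        nh <- nh + 1L
        if (nh > length(hits)) hits <- c(hits, vector("list", length(hits)))
        hits[[nh]] <- data.frame(read_id = names(seqs)[ri],
                                 ref_id = names(refs)[r],
                                 start = at[ok], strand = st,
                                 mismatches = as.integer(ed[ok]),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  if (nh == 0L) return(empty_alignments())
  out <- do.call(rbind, hits[seq_len(nh)])
  out <- out[order(out$read_id, out$ref_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align one read against a reference set
#'
#' Ungapped, end-to-end alignment reporting all placements on both strands
#' with at most `max_mismatches` mismatches (`N` in the read counts as a
#' mismatch). This is the internal alignment contract of the pipeline; an
#' external SAM-producing aligner can be substituted upstream if desired.
#'
#' @param seq A DNA string (character or `DNAString`).
#' @param references Named `DNAStringSet` (or character vector) of references.
#' @param max_mismatches Maximum Hamming distance.
#' @return Data frame with columns `read_id`, `ref_id`, `start` (1-based on
#'   the forward reference), `strand`, `mismatches`, ordered by
#'   (ref_id, start, strand).
#' @export
align_read <- function(seq, references, max_mismatches = 3L) {
  refs <- Biostrings::DNAStringSet(references)
  if (length(refs) == 0L) stop("align_read: empty reference set")
  if (is.null(names(refs))) names(refs) <- sprintf("ref%d", seq_along(refs))
  mm <- as.integer(max_mismatches)
  pat <- list(`+` = Biostrings::DNAString(as.character(seq)))
  pat[["-"]] <- Biostrings::reverseComplement(pat[["+"]])
  L <- length(pat[["+"]])
  rows <- list()
  for (r in seq_along(refs)) {
    subject <- refs[[r]]
    if (length(subject) < L) next
    for (st in c("+", "-")) {
      m <- Biostrings::matchPattern(pat[[st]], subject, max.mismatch = mm,
                                    with.indels = FALSE, fixed = TRUE)
      sp <- IRanges::start(m)
      sp <- sp[sp >= 1L & sp + L - 1L <= length(subject)]
      if (length(sp) == 0L) next
      ed <- Biostrings::neditStartingAt(pat[[st]], subject, starting.at = sp,
                                        with.indels = FALSE, fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = "read", ref_id = names(refs)[r], start = sp, strand = st,
        mismatches = as.integer(ed), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_alignments())
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove read pairs matching contaminant sequences
#'
#' A whole pair is removed when either mate aligns (either strand, ungapped,
#' at most `max_mismatches` mismatches) anywhere on any contaminant sequence
#' (ribosomal RNA, adaptors, ...). Set `drop_pairs = FALSE` to drop only the
#' matching mates' pairs... the published pipeline filters whole pairs, which
#' is the default here.
#'
#' @param pairs A `read_pairs` object (trimmed).
#' @param contaminants Named `DNAStringSet` of contaminant sequences.
#' @param max_mismatches Maximum Hamming distance.
#' @return List with `kept` (a `read_pairs`), `removed` (count of removed
#'   pairs) and `removed_ids`.
#' @export
filter_contaminants <- function(pairs, contaminants, max_mismatches = 3L) {
  stopifnot(inherits(pairs, "read_pairs"))
  contaminants <- Biostrings::DNAStringSet(contaminants)
  if (length(contaminants) == 0L)
    return(list(kept = pairs, removed = 0L, removed_ids = character(0)))
  all_mates <- c(pairs$mate1, pairs$mate2)
  aln <- align_many(all_mates, contaminants, max_mismatches)
  bad_pairs <- unique(sub("/[12]$", "", aln$read_id))
  keep <- !(pairs$pair_ids %in% bad_pairs)
  kept <- read_pairs(pairs$mate1[keep], pairs$mate2[keep], pairs$pair_ids[keep])
  list(kept = kept, removed = sum(!keep), removed_ids = bad_pairs)
}

## ---- locus resolution and categorization ----

## Convert splice-junction placements to genomic loci. A placement entirely
## within one exon's portion of the junction sequence is the same locus as the
## corresponding genomic placement; a placement crossing the junction is a
## distinct (junction) locus keyed by the genomic exon boundary.
sj_to_locus <- function(aln, sj, read_len) {
  if (nrow(aln) == 0L) {
    return(data.frame(read_id = character(0), locus = character(0),
                      gene_id = character(0), chrom = character(0),
                      gstart = integer(0), gstrand = character(0),
                      spanning = logical(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  i <- match(aln$ref_id, sj$sj_id)
  off <- sj$offset[i]; chrom <- sj$chrom[i]; gs <- sj$strand[i]
  e5b <- sj$five_end_g[i]; e3b <- sj$three_start_g[i]
  s <- aln$start; L <- read_len
  in5 <- s + L - 1L <= off
  in3 <- s > off
  spanning <- !(in5 | in3)
  gstart <- integer(length(s)); gstrand <- character(length(s))
  plus <- gs == "+"
  ## 5' portion: ends at genomic boundary e5b
  idx <- in5 & plus
  gstart[idx] <- e5b[idx] - off[idx] + s[idx]
  idx <- in5 & !plus
  gstart[idx] <- e5b[idx] + off[idx] - s[idx] - L + 1L
  ## 3' portion: begins at genomic boundary e3b
  idx <- in3 & plus
  gstart[idx] <- e3b[idx] + (s[idx] - off[idx] - 1L)
  idx <- in3 & !plus
  gstart[idx] <- e3b[idx] - (s[idx] - off[idx] - 1L) - L + 1L
  gstrand <- ifelse((aln$strand == "+") == plus, "+", "-")
  locus <- ifelse(spanning,
                  paste0("J:", chrom, ":", gs, ":", e5b, ":", e3b),
                  paste0("G:", chrom, ":", gstart, ":", gstrand))
  data.frame(read_id = aln$read_id, locus = locus,
             gene_id = sj$gene_id[i], chrom = chrom,
             gstart = ifelse(spanning, NA_integer_, gstart),
             gstrand = gstrand, spanning = spanning,
             mismatches = aln$mismatches, stringsAsFactors = FALSE)
}

#' Align reads to genome and splice-junction references and categorize them
#'
#' Each read is placed on the genome and on the normal splice-junction
#' reference; placements are collapsed to distinct loci (a genomic placement
#' and the equivalent non-spanning splice-junction placement of the same
#' transcript region count as one locus) and each read is categorized as
#' `unaligned` (0 loci), `unique` (1) or `multi` (>= 2). Unique reads are
#' assigned to a gene when their placement lies within the exons of exactly
#' one gene (junction placements inherit the junction's gene); reads touching
#' exons of two or more genes, or purely intronic/intergenic reads, stay
#' unassigned.
#'
#' @param seqs Named `DNAStringSet` of (trimmed) reads.
#' @param genome Named `DNAStringSet` of chromosomes.
#' @param sj Splice-junction reference table from
#'   [build_splice_junction_reference()].
#' @param model A `gene_model`.
#' @param params A `detection_params`.
#' @return List with `categories` (read_id, category), `assignments`
#'   (read_id, category, gene_id), `loci` (distinct read loci with genomic
#'   coordinates where defined) and `alignments` (raw genome placements).
#' @export
map_reads <- function(seqs, genome, sj, model, params = detection_params()) {
  L <- unique(Biostrings::width(seqs))
  stopifnot(length(L) == 1L)
  gen_aln <- align_many(seqs, genome, params$max_mismatches)
  gen_loci <- if (nrow(gen_aln) > 0L) {
    data.frame(read_id = gen_aln$read_id,
               locus = paste0("G:", gen_aln$ref_id, ":", gen_aln$start, ":",
                              gen_aln$strand),
               gene_id = NA_character_, chrom = gen_aln$ref_id,
               gstart = gen_aln$start, gstrand = gen_aln$strand,
               spanning = FALSE, mismatches = gen_aln$mismatches,
               stringsAsFactors = FALSE)
  } else sj_to_locus(empty_alignments(), sj, L)
  sj_loci <- if (nrow(sj) > 0L) {
    sj_seqs <- Biostrings::DNAStringSet(setNames(sj$seq, sj$sj_id))
    sj_aln <- align_many(seqs, sj_seqs, params$max_mismatches)
    sj_to_locus(sj_aln, sj, L)
  } else sj_to_locus(empty_alignments(), sj, L)
  loci <- rbind(gen_loci, sj_loci)
  loci <- loci[!duplicated(paste(loci$read_id, loci$locus)), , drop = FALSE]

  all_ids <- names(seqs)
  n_loci <- table(factor(loci$read_id, levels = all_ids))
  category <- ifelse(n_loci == 0L, "unaligned",
                     ifelse(n_loci == 1L, "unique", "multi"))
  categories <- data.frame(read_id = all_ids, category = as.character(category),
                           stringsAsFactors = FALSE)

  ## gene assignment for unique reads
  uniq <- loci[loci$read_id %in% all_ids[category == "unique"], , drop = FALSE]
  gene <- rep(NA_character_, nrow(uniq))
  span <- uniq$spanning
  gene[span] <- uniq$gene_id[span]
  gidx <- which(!span)
  if (length(gidx) > 0L) {
    gr <- GenomicRanges::GRanges(uniq$chrom[gidx],
                                 IRanges::IRanges(uniq$gstart[gidx],
                                                  uniq$gstart[gidx] + L - 1L))
    ov <- GenomicRanges::findOverlaps(gr, model$exon_gr)
    if (length(ov) > 0L) {
      hg <- S4Vectors::mcols(model$exon_gr)$gene_id[S4Vectors::subjectHits(ov)]
      per <- split(hg, S4Vectors::queryHits(ov))
      for (q in names(per)) {
        gs <- unique(per[[q]])
        if (length(gs) == 1L) gene[gidx[as.integer(q)]] <- gs
      }
    }
  }
  assignments <- data.frame(read_id = categories$read_id,
                            category = categories$category,
                            gene_id = NA_character_, stringsAsFactors = FALSE)
  assignments$gene_id[match(uniq$read_id, assignments$read_id)] <- gene
  list(categories = categories, assignments = assignments, loci = loci,
       alignments = gen_aln)
}

#' Assign one uniquely aligned read to a gene
#'
#' Convenience wrapper over the bulk logic in [map_reads()]: the read is
#' assigned to the single gene whose exons contain its unique placement;
#' `NA` when ambiguous (exons of two or more genes) or intronic/intergenic.
#'
#' @param chrom,start,strand Unique genomic placement of the read.
#' @param read_len Read length (bp).
#' @param model A `gene_model`.
#' @return A gene id or `NA`.
#' @export
assign_read_to_gene <- function(chrom, start, strand, read_len, model) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + read_len - 1L))
  ov <- GenomicRanges::findOverlaps(gr, model$exon_gr)
  gs <- unique(S4Vectors::mcols(model$exon_gr)$gene_id[S4Vectors::subjectHits(ov)])
  if (length(gs) == 1L) gs else NA_character_
}

#' Export alignments as SAM
#'
#' Minimal single-end SAM export of ungapped placements for inspection in
#' standard tools. Mismatch counts go to the `NM` tag.
#'
#' @param aln Alignment data frame (`read_id`, `ref_id`, `start`, `strand`,
#'   `mismatches`).
#' @param seqs Named `DNAStringSet` holding the read sequences.
#' @param refs Named `DNAStringSet` of the references aligned against.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, seqs, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), Biostrings::width(refs)))
  body <- character(0)
  if (nrow(aln) > 0L) {
    sq <- as.character(seqs[aln$read_id])
    w <- nchar(sq)
    neg <- aln$strand == "-"
    sq[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(sq[neg])))
    flag <- ifelse(neg, 16L, 0L)
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                    aln$read_id, flag, aln$ref_id, aln$start, w, sq,
                    aln$mismatches)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
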