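#' @importFrom stats setNames rnorm runif
#' @importFrom utils read.table write.table head tail
NULL

## Internal constructor: builds indexes and validates the gene/transcript/exon
## tables. Coordinates are 1-based closed (GRanges convention) throughout.
new_gene_model <- function(genes, transcripts, exons) {
  rownames(genes) <- NULL; rownames(transcripts) <- NULL; rownames(exons) <- NULL
  if (anyDuplicated(genes$gene_id))
    stop("gene model: duplicated gene_id")
  if (!all(exons$start <= exons$end))
    stop("gene model: exon with start > end")
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stop("gene model: transcript without parent gene")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("gene model: exon without parent transcript")
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  transcripts <- transcripts[order(transcripts$transcript_id), , drop = FALSE]
  exons <- exons[order(exons$transcript_id, exons$exon_rank), , drop = FALSE]
  rownames(genes) <- NULL; rownames(transcripts) <- NULL; rownames(exons) <- NULL
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end),
                                    gene_id = genes$gene_id)
  exon_gr <- GenomicRanges::GRanges(exons$chrom,
                                    IRanges::IRanges(exons$start, exons$end),
                                    gene_id = exons$gene_id,
                                    exon_id = exons$exon_id)
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 gene_gr = gene_gr, exon_gr = exon_gr),
            class = "gene_model")
}

#' Load gene annotation from a GTF file
#'
#' Reads gene, transcript, exon and (optional) CDS features from a GTF file
#' (1-based inclusive coordinates) into an indexed `gene_model`. Exons are
#' ordered 5' to 3' in transcript orientation; genomic CDS features are mapped
#' to transcript-level coordinates (`cds_start`/`cds_end`, NA for non-coding
#' transcripts).
#'
#' @param gtf_path Path to a GTF file.
#' @return An object of class `gene_model` with components `genes`,
#'   `transcripts` and `exons` (data frames) plus interval indexes.
#' @seealso [write_annotation()], [build_splice_junction_reference()]
#' @export
load_annotation <- function(gtf_path) {
  gr <- tryCatch(rtracklayer::import(gtf_path, format = "gtf"),
                 error = function(e) stop("GTF parse error in '", gtf_path,
                                          "': ", conditionMessage(e)))
  md <- as.data.frame(gr)
  md$seqnames <- as.character(md$seqnames)
  md$strand <- as.character(md$strand)
  need <- function(df, col) if (!col %in% names(df)) stop(
    "GTF structural error: missing attribute '", col, "'") else df[[col]]

  g <- md[md$type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene_id = need(g, "gene_id"),
    gene_name = if ("gene_name" %in% names(g)) g$gene_name else g$gene_id,
    chrom = g$seqnames, start = g$start, end = g$end, strand = g$strand,
    biotype = if ("gene_biotype" %in% names(g)) g$gene_biotype else "protein_coding",
    stringsAsFactors = FALSE)
  genes$gene_name[is.na(genes$gene_name)] <- genes$gene_id[is.na(genes$gene_name)]
  genes$biotype[is.na(genes$biotype)] <- "protein_coding"

  t <- md[md$type == "transcript", , drop = FALSE]
  if (nrow(t) == 0L)
    stop("GTF structural error: no transcript features")
  transcripts <- data.frame(
    transcript_id = need(t, "transcript_id"),
    gene_id = t$gene_id, chrom = t$seqnames, strand = t$strand,
    start = t$start, end = t$end,
    cds_start = rep(NA_integer_, nrow(t)), cds_end = rep(NA_integer_, nrow(t)),
    stringsAsFactors = FALSE)

  e <- md[md$type == "exon", , drop = FALSE]
  if (nrow(e) == 0L) stop("GTF structural error: no exon features")
  tid <- need(e, "transcript_id")
  if (any(is.na(tid)) || !all(tid %in% transcripts$transcript_id))
    stop("GTF structural error: exon without parent transcript feature")
  eid <- if ("exon_id" %in% names(e)) e$exon_id else NA_character_
  if (all(is.na(eid)))
    eid <- paste0(tid, ":", e$start, "-", e$end)
  exons <- data.frame(
    exon_id = eid, transcript_id = tid, gene_id = e$gene_id,
    chrom = e$seqnames, start = e$start, end = e$end, strand = e$strand,
    stringsAsFactors = FALSE)
  ## exon_rank: 5'->3' in transcript orientation
  exons <- do.call(rbind, lapply(split(exons, exons$transcript_id), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    if (df$strand[1] == "-") df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    df$exon_rank <- seq_len(nrow(df))
    df
  }))

  ## CDS: genomic pieces -> transcript coordinates
  cds <- md[md$type == "CDS", , drop = FALSE]
  if (nrow(cds) > 0L) {
    for (tx in unique(cds$transcript_id)) {
      pieces <- cds[cds$transcript_id == tx, , drop = FALSE]
      ex <- exons[exons$transcript_id == tx, , drop = FALSE]
      ex <- ex[order(ex$exon_rank), , drop = FALSE]
      tpos <- genomic_to_transcript(ex, c(pieces$start, pieces$end))
      if (any(is.na(tpos)))
        stop("GTF structural error: CDS outside exons for transcript ", tx)
      transcripts$cds_start[transcripts$transcript_id == tx] <- min(tpos)
      transcripts$cds_end[transcripts$transcript_id == tx] <- max(tpos)
    }
  }
  new_gene_model(genes, transcripts, exons)
}

#' Write a gene model to GTF
#'
#' Emits gene, transcript, exon and CDS features (1-based inclusive
#' coordinates). `load_annotation(write_annotation(m, f))` reproduces `m`.
#'
#' @param model A `gene_model`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  rows <- list()
  add <- function(chrom, src, type, start, end, strand, attrs) {
    att <- paste(sprintf('%s "%s";', names(attrs), unlist(attrs)), collapse = " ")
    rows[[length(rows) + 1L]] <<- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                          chrom, src, type, start, end, strand, att)
  }
  for (i in seq_len(nrow(model$genes))) {
    g <- model$genes[i, ]
    add(g$chrom, "fusionscan", "gene", g$start, g$end, g$strand,
        list(gene_id = g$gene_id, gene_name = g$gene_name, gene_biotype = g$biotype))
    txs <- model$transcripts[model$transcripts$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      tx <- txs[j, ]
      ex <- transcript_exons(model, tx$transcript_id)
      add(g$chrom, "fusionscan", "transcript", min(ex$start), max(ex$end), g$strand,
          list(gene_id = g$gene_id, transcript_id = tx$transcript_id))
      for (k in seq_len(nrow(ex))) {
        add(g$chrom, "fusionscan", "exon", ex$start[k], ex$end[k], g$strand,
            list(gene_id = g$gene_id, transcript_id = tx$transcript_id,
                 exon_id = ex$exon_id[k]))
      }
      if (!is.na(tx$cds_start)) {
        pieces <- transcript_to_genomic(ex, tx$cds_start, tx$cds_end)
        for (k in seq_len(nrow(pieces))) {
          add(g$chrom, "fusionscan", "CDS", pieces$start[k], pieces$end[k], g$strand,
              list(gene_id = g$gene_id, transcript_id = tx$transcript_id))
        }
      }
    }
  }
  writeLines(unlist(rows), path)
  invisible(path)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d genes, %d transcripts, %d exons on %d sequence(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

## ---- coordinate mapping helpers (exons ordered by exon_rank) ----

## transcript-orientation cumulative offsets; returns integer vector, one per
## queried genomic position (NA if not exonic)
genomic_to_transcript <- function(ex, gpos) {
  lens <- ex$end - ex$start + 1L
  offs <- cumsum(c(0L, lens))[seq_len(nrow(ex))]
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_len(nrow(ex))) {
    inside <- gpos >= ex$start[k] & gpos <= ex$end[k]
    if (!any(inside)) next
    if (ex$strand[k] == "+") {
      out[inside] <- offs[k] + (gpos[inside] - ex$start[k]) + 1L
    } else {
      out[inside] <- offs[k] + (ex$end[k] - gpos[inside]) + 1L
    }
  }
  out
}

## map transcript interval [tstart, tend] to genomic pieces (data.frame start/end)
transcript_to_genomic <- function(ex, tstart, tend) {
  lens <- ex$end - ex$start + 1L
  offs <- cumsum(c(0L, lens))
  out <- NULL
  for (k in seq_len(nrow(ex))) {
    lo <- max(tstart, offs[k] + 1L); hi <- min(tend, offs[k + 1L])
    if (lo > hi) next
    if (ex$strand[k] == "+") {
      gs <- ex$start[k] + (lo - offs[k] - 1L); ge <- ex$start[k] + (hi - offs[k] - 1L)
    } else {
      ge <- ex$end[k] - (lo - offs[k] - 1L); gs <- ex$end[k] - (hi - offs[k] - 1L)
    }
    out <- rbind(out, data.frame(start = gs, end = ge))
  }
  out
}

#' Exons of one transcript, ordered 5' to 3'
#' @param model A `gene_model`.
#' @param transcript_id Transcript identifier.
#' @return Data frame of exons ordered by `exon_rank`.
#' @export
transcript_exons <- function(model, transcript_id) {
  ex <- model$exons[model$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript: ", transcript_id)
  ex[order(ex$exon_rank), , drop = FALSE]
}

transcript_length <- function(model, transcript_id) {
  ex <- transcript_exons(model, transcript_id)
  sum(ex$end - ex$start + 1L)
}

get_gene <- function(model, gene_id) {
  g <- model$genes[model$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("unknown gene: ", gene_id)
  g[1, ]
}

#' Do two genes overlap?
#'
#' TRUE iff both genes lie on the same chromosome and their genomic spans
#' intersect. Strand is ignored: readthrough chimeras and mapping artifacts
#' are strand-agnostic at the filtering stage.
#'
#' @param model A `gene_model`.
#' @param gene_a,gene_b Gene identifiers.
#' @return Logical flag.
#' @export
genes_overlap <- function(model, gene_a, gene_b) {
  a <- get_gene(model, gene_a); b <- get_gene(model, gene_b)
  a$chrom == b$chrom && a$start <= b$end && b$start <= a$end
}

#' Are two genes adjacent?
#'
#' Two non-overlapping genes on the same chromosome are adjacent unless some
#' third gene (of any biotype) lies with both its start and end strictly
#' inside the gap between them; a gene only partially inside the gap does not
#' separate them. Genes on different chromosomes are never adjacent.
#' Candidate fusions between adjacent genes are discarded as likely
#' transcriptional readthrough.
#'
#' @param model A `gene_model`.
#' @param gene_a,gene_b Gene identifiers.
#' @return Logical flag.
#' @export
genes_adjacent <- function(model, gene_a, gene_b) {
  a <- get_gene(model, gene_a); b <- get_gene(model, gene_b)
  if (a$chrom != b$chrom) return(FALSE)
  if (genes_overlap(model, gene_a, gene_b)) return(FALSE)
  gap_lo <- min(a$end, b$end); gap_hi <- max(a$start, b$start)
  others <- model$genes[model$genes$chrom == a$chrom &
                        !(model$genes$gene_id %in% c(gene_a, gene_b)), , drop = FALSE]
  separated <- any(others$start > gap_lo & others$end < gap_hi)
  !separated
}

## ---- paralog table ----

#' Build a paralog table
#'
#' @param pairs Data frame or 2-column matrix of gene-id pairs (unordered).
#' @return Object of class `paralog_table`.
#' @export
paralog_table <- function(pairs = NULL) {
  keys <- character(0)
  if (!is.null(pairs) && NROW(pairs) > 0L) {
    a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
    if (any(a == b)) stop("paralog table: self-pair not allowed")
    keys <- unique(paste(pmin(a, b), pmax(a, b), sep = "\t"))
  }
  structure(list(keys = keys), class = "paralog_table")
}

#' Read a paralog table from a two-column TSV
#'
#' Lines starting with `#` are comments.
#' @param path Path to TSV with two gene-id columns.
#' @return Object of class `paralog_table`.
#' @export
load_paralogs <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (length(ln) == 0L) return(paralog_table())
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("paralog TSV: expected two tab-separated columns")
  paralog_table(data.frame(a = vapply(parts, `[`, "", 1L),
                           b = vapply(parts, `[`, "", 2L)))
}

#' Is a gene pair paralogous?
#' @param gene_a,gene_b Gene identifiers.
#' @param table A `paralog_table`.
#' @return Logical flag (symmetric in its arguments).
#' @export
is_paralog_pair <- function(gene_a, gene_b, table) {
  stopifnot(inherits(table, "paralog_table"))
  paste(min(gene_a, gene_b), max(gene_a, gene_b), sep = "\t") %in% table$keys
}

## ---- genome / sequence helpers ----

#' Load a genome (or any sequence set) from FASTA
#' @param path FASTA path.
#' @return A named `DNAStringSet`.
#' @export
load_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

## genomic slice in a given orientation; returns character scalar
get_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown sequence: ", chrom)
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

## ---- splice-junction reference ----

#' Build the normal splice-junction reference
#'
#' For every transcript and every consecutive exon pair, one sequence of up to
#' `flank` bases of the upstream exon's 3' end joined to up to `flank` bases
#' of the downstream exon's 5' start, in transcript orientation (minus-strand
#' exon fragments are reverse-complemented). Junctions identical at the
#' genomic level across transcripts are emitted once, with all transcript
#' labels retained. Exons shorter than `flank` contribute their full length.
#'
#' @param model A `gene_model`.
#' @param genome Named `DNAStringSet` of chromosome sequences.
#' @param flank Maximum bases taken from each exon; default 49 (= trimmed read
#'   length 50 minus 1) so any junction-spanning placement is representable.
#' @return Data frame with one row per junction: `sj_id`, `gene_id`,
#'   `transcript_ids`, `five_exon`, `three_exon`, `chrom`, `strand`,
#'   `five_end_g`, `three_start_g` (genomic boundary coordinates), `offset`
#'   (bases from the upstream exon) and `seq`.
#' @export
build_splice_junction_reference <- function(model, genome, flank = 49L) {
  out <- list()
  for (tx in model$transcripts$transcript_id) {
    ex <- transcript_exons(model, tx)
    n <- nrow(ex)
    if (n < 2L) next
    for (k in seq_len(n - 1L)) {
      e5 <- ex[k, ]; e3 <- ex[k + 1L, ]
      f5 <- exon_flank(genome, e5, side = "3p", flank = flank)
      f3 <- exon_flank(genome, e3, side = "5p", flank = flank)
      if (e5$strand == "+") {
        key <- paste(e5$chrom, "+", e5$end, e3$start, sep = ":")
        b5 <- e5$end; b3 <- e3$start
      } else {
        key <- paste(e5$chrom, "-", e5$start, e3$end, sep = ":")
        b5 <- e5$start; b3 <- e3$end
      }
      out[[length(out) + 1L]] <- data.frame(
        key = key, gene_id = e5$gene_id, transcript_ids = tx,
        five_exon = e5$exon_id, three_exon = e3$exon_id,
        chrom = e5$chrom, strand = e5$strand,
        five_end_g = b5, three_start_g = b3,
        offset = nchar(f5), seq = paste0(f5, f3),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sj_id = character(0), gene_id = character(0),
                      transcript_ids = character(0), five_exon = character(0),
                      three_exon = character(0), chrom = character(0),
                      strand = character(0), five_end_g = integer(0),
                      three_start_g = integer(0), offset = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  ## deduplicate genomically identical junctions, merging transcript labels
  sp <- split(df, df$key)
  df <- do.call(rbind, lapply(sp, function(d) {
    d1 <- d[1, , drop = FALSE]
    d1$transcript_ids <- paste(sort(unique(d$transcript_ids)), collapse = ",")
    d1
  }))
  df <- df[order(df$gene_id, df$chrom, df$five_end_g, df$three_start_g), , drop = FALSE]
  df$sj_id <- sprintf("SJ|%s|%s|%s", df$gene_id, df$five_exon, df$three_exon)
  rownames(df) <- NULL
  df[, c("sj_id", "gene_id", "transcript_ids", "five_exon", "three_exon",
         "chrom", "strand", "five_end_g", "three_start_g", "offset", "seq")]
}

## flank of an exon in transcript orientation; side "3p" = exon's 3' end,
## side "5p" = exon's 5' start
exon_flank <- function(genome, exon, side, flank) {
  len <- exon$end - exon$start + 1L
  f <- min(flank, len)
  plus <- exon$strand == "+"
  if ((side == "3p") == plus) {
    ## genomic right edge
    get_seq(genome, exon$chrom, exon$end - f + 1L, exon$end, exon$strand)
  } else {
    get_seq(genome, exon$chrom, exon$start, exon$start + f - 1L, exon$strand)
  }
}

## full transcript sequence in transcript orientation
transcript_sequence <- function(model, genome, transcript_id) {
  ex <- transcript_exons(model, transcript_id)
  paste(vapply(seq_len(nrow(ex)), function(k)
    get_seq(genome, ex$chrom[k], ex$start[k], ex$end[k], ex$strand[k]), ""),
    collapse = "")
}
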