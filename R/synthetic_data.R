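#' Specify one planted fusion (or artifact) event
#'
#' @param class `"intra"` or `"inter"`: chromosomal class of the partner pair.
#' @param five_exon_idx,three_exon_idx Exon indices (transcript order, 5'->3')
#'   fused from the 5' and 3' partner.
#' @param frame Target frame status, `"in"` or `"out"` (`"out"` requires
#'   `three_exon_idx >= 2`).
#' @param n_bridging_pairs Discordant pairs straddling the junction.
#' @param n_junction_reads Junction-spanning reads.
#' @param junction_mode `"tiling"` (start offsets uniform over positions with
#'   both overhangs >= the anchor) or `"stacked"` (one offset jittered by at
#'   most 1 bp — the misalignment-artifact signature).
#' @param amplified Cover the 5' partner with a high-level (log2 = 2)
#'   copy-number segment in the simulated profile.
#' @param promoter_swap 5' partner contributes only untranslated sequence
#'   (its CDS is placed downstream of the fused exon); implies the 3'
#'   partner's wild-type locus is silenced (`exclusive_three`).
#' @param exclusive_three Zero background expression for the 3' partner, so
#'   its pre-junction exons show the exclusive-expression coverage pattern.
#' @return List of class `fusion_spec`.
#' @export
fusion_spec <- function(class = c("intra", "inter"),
                        five_exon_idx = 2L, three_exon_idx = 2L,
                        frame = c("in", "out"),
                        n_bridging_pairs = 6L, n_junction_reads = 8L,
                        junction_mode = c("tiling", "stacked"),
                        amplified = FALSE, promoter_swap = FALSE,
                        exclusive_three = promoter_swap) {
  class <- match.arg(class); frame <- match.arg(frame)
  junction_mode <- match.arg(junction_mode)
  if (frame == "out" && three_exon_idx < 2L)
    stop("fusion_spec: frame 'out' requires three_exon_idx >= 2 ",
         "(a junction upstream of the 3' CDS leaves the full ORF in frame)")
  if (promoter_swap && frame == "out")
    stop("fusion_spec: a promoter swap is in-frame by construction")
  structure(list(class = class,
                 five_exon_idx = as.integer(five_exon_idx),
                 three_exon_idx = as.integer(three_exon_idx),
                 frame = frame,
                 n_bridging_pairs = as.integer(n_bridging_pairs),
                 n_junction_reads = as.integer(n_junction_reads),
                 junction_mode = junction_mode,
                 amplified = amplified, promoter_swap = promoter_swap,
                 exclusive_three = exclusive_three),
            class = "fusion_spec")
}

#' Simulation configuration
#'
#' Desk-scale universe emulating the data regime of the published study:
#' multi-chromosome genome with multi-exon genes, 56 bp paired-end reads
#' (trimmed to 50 bp downstream), insert sizes around a median of 100-200 nt,
#' a few percent ribosomal-RNA-like contaminant pairs, low per-base
#' substitution error, planted fusions plus readthrough, paralog and
#' stacked-artifact decoys. The seed fully determines every output.
#'
#' @param seed Integer seed.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_genes Background gene count (decoy copies come on top).
#' @param exons_per_gene,exon_length,intron_length,intergenic_gap Ranges
#'   (length-2 integer vectors) sampled per gene.
#' @param fusion_specs List of [fusion_spec()] (tiling mode = genuine
#'   fusions, stacked mode = artifact stacks).
#' @param n_readthrough_decoys Chimeric transcripts across ADJACENT gene
#'   pairs (exercise the adjacency filter).
#' @param n_paralog_decoys Diverged gene copies placed elsewhere, recorded in
#'   the paralog table, with planted bridging pairs (exercise the paralog
#'   filter).
#' @param n_artifact_stacks Convenience: adds this many stacked-mode
#'   `fusion_spec`s with defaults.
#' @param n_overlapping_pairs Genes sharing an exon with a host gene
#'   (exercise ambiguous assignment).
#' @param background_pairs_per_gene Wild-type expression depth.
#' @param expression_weights Optional named per-gene multipliers.
#' @param read_len,trim_len Read length as sequenced / after trimming.
#' @param insert_median,insert_sd Fragment-length distribution (truncated
#'   normal; the study's libraries had medians of 100 and 200 nt).
#' @param error_rate Per-base substitution probability.
#' @param rrna_fraction Fraction of all pairs copied from contaminants.
#' @param paralog_divergence_period One substitution every this many bases in
#'   paralog copies, so every trimmed-read-length window is uniquely
#'   assignable under the mismatch bound.
#' @param min_anchor Anchor used when drawing valid junction-read offsets.
#' @param duplicated_segment_len Length of an exact intergenic duplication
#'   planted between the first two chromosomes (multi-mapping control).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4L, chrom_length = 30000L,
                              n_genes = 24L,
                              exons_per_gene = c(4L, 6L),
                              exon_length = c(80L, 200L),
                              intron_length = c(100L, 300L),
                              intergenic_gap = c(300L, 800L),
                              fusion_specs = list(),
                              n_readthrough_decoys = 0L,
                              n_paralog_decoys = 0L,
                              n_artifact_stacks = 0L,
                              n_overlapping_pairs = 0L,
                              background_pairs_per_gene = 40L,
                              expression_weights = NULL,
                              read_len = 56L, trim_len = 50L,
                              insert_median = 200L, insert_sd = 10L,
                              error_rate = 0.005, rrna_fraction = 0.05,
                              paralog_divergence_period = 12L,
                              min_anchor = 10L,
                              duplicated_segment_len = 300L,
                              decoy_bridging_pairs = 6L) {
  if (n_artifact_stacks > 0L) {
    fusion_specs <- c(fusion_specs, lapply(seq_len(n_artifact_stacks), function(i)
      fusion_spec(class = "inter", junction_mode = "stacked",
                  n_bridging_pairs = decoy_bridging_pairs,
                  n_junction_reads = decoy_bridging_pairs)))
  }
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_gap = as.integer(intergenic_gap),
              fusion_specs = fusion_specs,
              n_readthrough_decoys = as.integer(n_readthrough_decoys),
              n_paralog_decoys = as.integer(n_paralog_decoys),
              n_overlapping_pairs = as.integer(n_overlapping_pairs),
              background_pairs_per_gene = as.integer(background_pairs_per_gene),
              expression_weights = expression_weights,
              read_len = as.integer(read_len), trim_len = as.integer(trim_len),
              insert_median = as.integer(insert_median),
              insert_sd = as.numeric(insert_sd),
              error_rate = as.numeric(error_rate),
              rrna_fraction = as.numeric(rrna_fraction),
              paralog_divergence_period = as.integer(paralog_divergence_period),
              min_anchor = as.integer(min_anchor),
              duplicated_segment_len = as.integer(duplicated_segment_len),
              decoy_bridging_pairs = as.integer(decoy_bridging_pairs))
  stopifnot(cfg$chrom_length > 0L, cfg$n_genes > 0L, cfg$read_len > 0L,
            cfg$trim_len <= cfg$read_len, cfg$error_rate >= 0,
            cfg$rrna_fraction >= 0, cfg$rrna_fraction < 1)
  for (fs in cfg$fusion_specs) {
    if (max(fs$five_exon_idx, fs$three_exon_idx) + 1L > cfg$exons_per_gene[1])
      stop("simulation_config: fused exon index too large for exons_per_gene")
  }
  structure(cfg, class = "simulation_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rotate_base <- function(x) chartr("ACGT", "CGTA", x)

## deterministic divergence: substitute every `period`-th base
diverge_seq <- function(seq, period) {
  v <- strsplit(seq, "")[[1]]
  idx <- seq(1L, length(v), by = period)
  v[idx] <- rotate_base(v[idx])
  paste(v, collapse = "")
}

rint <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic test universe
#'
#' Builds genome, annotation, paralog table, contaminants and ground truth
#' from a [simulation_config()]. Deterministic under the configured seed.
#' Genes are non-overlapping except planted overlapping decoys; CDSs are
#' placed so each fusion spec's frame target holds exactly; readthrough
#' decoys are chimeric transcripts across ADJACENT gene pairs; paralog
#' decoys are diverged copies recorded in the paralog table.
#'
#' @param config A `simulation_config`.
#' @return Object of class `sim_universe`: `genome` (`DNAStringSet`),
#'   `model` (`gene_model`), `paralogs` (`paralog_table`), `contaminants`
#'   (`DNAStringSet`), `truth` (data frame of planted events), `events`
#'   (internal event descriptions used by [simulate_reads()]), `config`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  genome_chr <- lapply(chroms, function(ch) rand_dna(cfg$chrom_length))
  names(genome_chr) <- chroms

  ## ---- place background genes, block-wise per chromosome ----
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  cursor <- setNames(rep(400L, cfg$n_chromosomes), chroms)
  genes <- list(); exons <- list(); txs <- list()
  gene_chrom <- character(cfg$n_genes); gene_order <- integer(cfg$n_genes)
  gene_exlens <- list(); gene_strand <- character(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    ch <- chroms[min(((i - 1L) %/% per_chrom) + 1L, cfg$n_chromosomes)]
    gid <- sprintf("G%02d", i)
    nex <- rint(cfg$exons_per_gene)
    exlen <- rint(cfg$exon_length, nex)
    inlen <- rint(cfg$intron_length, max(nex - 1L, 0L))
    strand <- sample(c("+", "-"), 1L)
    gstart <- cursor[ch] + rint(cfg$intergenic_gap)
    pos <- gstart
    ex <- data.frame(start = integer(nex), end = integer(nex))
    for (k in seq_len(nex)) {
      ex$start[k] <- pos; ex$end[k] <- pos + exlen[k] - 1L
      pos <- ex$end[k] + if (k < nex) inlen[k] else 0L
    }
    gend <- ex$end[nex]
    if (gend > cfg$chrom_length - 400L)
      stop("generate_universe: genes do not fit chromosome ", ch,
           " (increase chrom_length or reduce n_genes)")
    cursor[ch] <- gend
    rank_order <- if (strand == "+") seq_len(nex) else rev(seq_len(nex))
    exons[[gid]] <- data.frame(
      exon_id = sprintf("%s.e%d", gid, seq_len(nex)[order(rank_order)]),
      transcript_id = sprintf("%s.t1", gid), gene_id = gid,
      chrom = ch, start = ex$start, end = ex$end, strand = strand,
      exon_rank = rank_order, stringsAsFactors = FALSE)
    genes[[gid]] <- data.frame(gene_id = gid, gene_name = gid, chrom = ch,
                               start = gstart, end = gend, strand = strand,
                               biotype = "protein_coding", stringsAsFactors = FALSE)
    gene_chrom[i] <- ch; gene_order[i] <- i
    gene_exlens[[gid]] <- exlen[order(rank_order)]  # lengths in rank order
    gene_strand[i] <- strand
  }
  gene_ids <- names(genes)

  ## ---- partner selection ----
  used <- character(0)
  free <- function() setdiff(gene_ids, used)
  first_free_on <- function(ch, not = character(0))
    head(setdiff(free()[gene_chrom[match(free(), gene_ids)] == ch], not), 1L)
  pick_intra <- function() {
    for (ch in chroms) {
      f <- free()[gene_chrom[match(free(), gene_ids)] == ch]
      if (length(f) == 0L) next
      idx <- match(f, gene_ids)
      for (a in seq_along(f)) for (b in seq_along(f)) {
        if (b <= a) next
        ## some gene (used or free) strictly between them in placement order
        if (idx[b] - idx[a] >= 2L) return(c(f[a], f[b]))
      }
    }
    stop("generate_universe: no non-adjacent same-chromosome gene pair free")
  }
  pick_inter <- function() {
    a <- head(free(), 1L)
    if (length(a) == 0L) stop("generate_universe: no free genes left")
    cha <- gene_chrom[match(a, gene_ids)]
    b <- head(free()[gene_chrom[match(free(), gene_ids)] != cha], 1L)
    if (length(b) == 0L) stop("generate_universe: no inter-chromosomal pair free")
    c(a, b)
  }
  pick_adjacent <- function() {
    f <- free(); idx <- match(f, gene_ids)
    for (a in seq_along(f)) {
      j <- which(idx == idx[a] + 1L)
      if (length(j) == 1L &&
          gene_chrom[idx[a]] == gene_chrom[idx[j]]) return(c(f[a], f[j]))
    }
    stop("generate_universe: no adjacent free gene pair")
  }

  events <- list(); truth <- list()
  ## fusions (incl stacked artifact specs)
  for (si in seq_along(cfg$fusion_specs)) {
    fs <- cfg$fusion_specs[[si]]
    pr <- if (fs$class == "intra") pick_intra() else pick_inter()
    used <- c(used, pr)
    events[[length(events) + 1L]] <-
      list(type = if (fs$junction_mode == "stacked") "artifact_stack" else "fusion",
           id = sprintf("F%d", si), five = pr[1], three = pr[2], spec = fs)
  }
  for (i in seq_len(cfg$n_readthrough_decoys)) {
    pr <- pick_adjacent(); used <- c(used, pr)
    events[[length(events) + 1L]] <-
      list(type = "readthrough", id = sprintf("RT%d", i),
           five = pr[1], three = pr[2],
           n_bridging = cfg$decoy_bridging_pairs)
  }
  paralog_pairs <- NULL
  for (i in seq_len(cfg$n_paralog_decoys)) {
    src <- head(free(), 1L)
    if (length(src) == 0L) stop("generate_universe: no free gene for paralog decoy")
    used <- c(used, src)
    events[[length(events) + 1L]] <-
      list(type = "paralog_decoy", id = sprintf("PAR%d", i), src = src,
           n_bridging = cfg$decoy_bridging_pairs)
  }
  overlap_hosts <- character(0)
  for (i in seq_len(cfg$n_overlapping_pairs)) {
    host <- head(free(), 1L)
    if (length(host) == 0L) stop("generate_universe: no free gene for overlap decoy")
    used <- c(used, host)
    overlap_hosts <- c(overlap_hosts, host)
  }

  ## ---- CDS placement ----
  ## default: coding starts a little inside the first exon, ends near the
  ## transcript end. Promoter-swap events keep BOTH partners' coding regions
  ## downstream of the junction: the 5' partner contributes only
  ## untranslated sequence and the 3' partner's ORF stays intact.
  cds <- list()
  promoter_cs <- list()  # gene -> forced cds_start (transcript coords)
  for (e in events) {
    if (is.null(e$spec) || !isTRUE(e$spec$promoter_swap)) next
    p5 <- sum(gene_exlens[[e$five]][seq_len(e$spec$five_exon_idx)])
    promoter_cs[[e$five]] <- p5 + 10L
    p3 <- if (e$spec$three_exon_idx == 1L) 0L else
      sum(gene_exlens[[e$three]][seq_len(e$spec$three_exon_idx - 1L)])
    promoter_cs[[e$three]] <- p3 + 15L
  }
  for (gid in gene_ids) {
    lens <- gene_exlens[[gid]]
    tlen <- sum(lens)
    cs <- if (!is.null(promoter_cs[[gid]])) promoter_cs[[gid]]
          else 10L + sample(0:5, 1L)
    cds[[gid]] <- c(cs, tlen - 15L)
  }
  ## adjust 3' partner CDS start so frame targets hold exactly
  for (e in events) {
    if (!e$type %in% c("fusion", "artifact_stack")) next
    fs <- e$spec
    if (isTRUE(fs$promoter_swap)) next  # intact 3' ORF: in-frame by design
    lensA <- gene_exlens[[e$five]]; lensB <- gene_exlens[[e$three]]
    p5 <- sum(lensA[seq_len(fs$five_exon_idx)])
    p3 <- if (fs$three_exon_idx == 1L) 0L else
      sum(lensB[seq_len(fs$three_exon_idx - 1L)])
    csA <- cds[[e$five]][1]; ceA <- cds[[e$five]][2]
    n5 <- min(max(0L, p5 - csA + 1L), ceA - csA + 1L)
    csB <- cds[[e$three]][1]
    n3_raw <- p3 - csB + 1L
    if (p3 == 0L) next  # junction upstream of all 3' coding: in-frame target
    delta <- if (fs$frame == "in") (n3_raw - n5) %% 3L else
      (n3_raw - n5 - 1L) %% 3L
    cds[[e$three]][1] <- csB + delta
  }

  ## ---- paralog copies ----
  extra_genes <- list(); extra_exons <- list()
  for (e in events) {
    if (e$type != "paralog_decoy") next
    src <- e$src
    g <- genes[[src]]; ex <- exons[[src]]
    span <- get_seq_chr(genome_chr[[g$chrom]], g$start, g$end)
    copy_seq <- diverge_seq(span, cfg$paralog_divergence_period)
    src_idx <- match(g$chrom, chroms)
    ch2 <- chroms[(src_idx %% cfg$n_chromosomes) + 1L]
    cstart <- cursor[ch2] + rint(cfg$intergenic_gap)
    cend <- cstart + nchar(copy_seq) - 1L
    if (cend > cfg$chrom_length - 400L)
      stop("generate_universe: paralog copy does not fit chromosome ", ch2)
    cursor[ch2] <- cend
    substr(genome_chr[[ch2]], cstart, cend) <- copy_seq
    pid <- paste0(src, "P")
    extra_genes[[pid]] <- data.frame(gene_id = pid, gene_name = pid, chrom = ch2,
                                     start = cstart, end = cend,
                                     strand = g$strand, biotype = g$biotype,
                                     stringsAsFactors = FALSE)
    pex <- ex
    pex$exon_id <- sub(src, pid, pex$exon_id, fixed = TRUE)
    pex$transcript_id <- sprintf("%s.t1", pid)
    pex$gene_id <- pid; pex$chrom <- ch2
    offd <- cstart - g$start
    pex$start <- pex$start + offd; pex$end <- pex$end + offd
    extra_exons[[pid]] <- pex
    cds[[pid]] <- cds[[src]]
    gene_exlens[[pid]] <- gene_exlens[[src]]
    paralog_pairs <- rbind(paralog_pairs, data.frame(a = src, b = pid))
  }
  ## ---- overlapping decoys: share the host's last genomic exon ----
  for (host in overlap_hosts) {
    g <- genes[[host]]; ex <- exons[[host]]
    last_ex <- ex[which.max(ex$end), ]
    oid <- paste0(host, "OV")
    e2_start <- g$end + 60L; e2_end <- e2_start + 99L
    oex <- data.frame(
      exon_id = sprintf("%s.e%d", oid, 1:2),
      transcript_id = sprintf("%s.t1", oid), gene_id = oid,
      chrom = g$chrom, start = c(last_ex$start, e2_start),
      end = c(last_ex$end, e2_end), strand = "+",
      exon_rank = 1:2, stringsAsFactors = FALSE)
    extra_genes[[oid]] <- data.frame(gene_id = oid, gene_name = oid,
                                     chrom = g$chrom, start = last_ex$start,
                                     end = e2_end, strand = "+",
                                     biotype = "protein_coding",
                                     stringsAsFactors = FALSE)
    extra_exons[[oid]] <- oex
    gene_exlens[[oid]] <- oex$end - oex$start + 1L
    cds[[oid]] <- c(10L, sum(oex$end - oex$start + 1L) - 15L)
    cursor[g$chrom] <- max(cursor[g$chrom], e2_end)
  }

  ## ---- exact duplicated segment (multi-mapping control) ----
  duplication <- NULL
  if (cfg$n_chromosomes >= 2L && cfg$duplicated_segment_len > 0L) {
    dl <- cfg$duplicated_segment_len
    s1 <- cfg$chrom_length - dl - 49L
    seg <- get_seq_chr(genome_chr[[chroms[1]]], s1, s1 + dl - 1L)
    substr(genome_chr[[chroms[2]]], s1, s1 + dl - 1L) <- seg
    duplication <- data.frame(chrom_a = chroms[1], chrom_b = chroms[2],
                              start = s1, end = s1 + dl - 1L)
  }

  ## ---- assemble model ----
  all_genes <- do.call(rbind, c(genes, extra_genes))
  all_exons <- do.call(rbind, c(exons, extra_exons))
  all_tx <- do.call(rbind, lapply(names(gene_exlens), function(gid) {
    ex <- all_exons[all_exons$gene_id == gid, , drop = FALSE]
    data.frame(transcript_id = sprintf("%s.t1", gid), gene_id = gid,
               chrom = ex$chrom[1], strand = ex$strand[1],
               start = min(ex$start), end = max(ex$end),
               cds_start = cds[[gid]][1], cds_end = cds[[gid]][2],
               stringsAsFactors = FALSE)
  }))
  model <- new_gene_model(all_genes, all_tx, all_exons)
  genome <- Biostrings::DNAStringSet(unlist(genome_chr))

  ## ---- contaminants ----
  contam <- Biostrings::DNAStringSet(c(
    rRNA_18S = rand_dna(1800L), rRNA_28S = rand_dna(4000L),
    rRNA_5S = rand_dna(120L), rRNA_5.8S = rand_dna(160L),
    adaptor_PE = rand_dna(120L)))

  ## ---- truth table ----
  exon_id_at <- function(gid, rank) {
    ex <- all_exons[all_exons$gene_id == gid, , drop = FALSE]
    ex$exon_id[ex$exon_rank == rank]
  }
  for (e in events) {
    tr <- switch(e$type,
      fusion = , artifact_stack = data.frame(
        event_type = e$type, event_id = e$id,
        five_gene = e$five, three_gene = e$three,
        five_exon = exon_id_at(e$five, e$spec$five_exon_idx),
        three_exon = exon_id_at(e$three, e$spec$three_exon_idx),
        in_frame = e$spec$frame == "in",
        chromosomal_class = e$spec$class,
        n_bridging = e$spec$n_bridging_pairs,
        n_junction_reads = e$spec$n_junction_reads,
        junction_mode = e$spec$junction_mode,
        amplified = e$spec$amplified, stringsAsFactors = FALSE),
      readthrough = data.frame(
        event_type = "readthrough", event_id = e$id,
        five_gene = e$five, three_gene = e$three,
        five_exon = NA_character_, three_exon = NA_character_,
        in_frame = NA, chromosomal_class = "intra",
        n_bridging = e$n_bridging, n_junction_reads = 0L,
        junction_mode = NA_character_, amplified = FALSE,
        stringsAsFactors = FALSE),
      paralog_decoy = data.frame(
        event_type = "paralog_decoy", event_id = e$id,
        five_gene = e$src, three_gene = paste0(e$src, "P"),
        five_exon = NA_character_, three_exon = NA_character_,
        in_frame = NA, chromosomal_class = NA_character_,
        n_bridging = e$n_bridging, n_junction_reads = 0L,
        junction_mode = NA_character_, amplified = FALSE,
        stringsAsFactors = FALSE))
    truth[[length(truth) + 1L]] <- tr
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(event_type = character(0))

  structure(list(genome = genome, model = model,
                 paralogs = paralog_table(paralog_pairs),
                 contaminants = contam, truth = truth, events = events,
                 duplication = duplication, config = cfg),
            class = "sim_universe")
}

## substr on a plain character chromosome
get_seq_chr <- function(chr, start, end) substr(chr, start, end)

#' @export
print.sim_universe <- function(x, ...) {
  cat(sprintf("sim_universe: %d chromosomes, %d genes, %d planted events (seed %d)\n",
              length(x$genome), nrow(x$model$genes),
              nrow(x$truth), x$config$seed))
  invisible(x)
}

## fused transcript sequence and junction position for a fusion event
fused_transcript <- function(universe, ev) {
  m <- universe$model; fs <- ev$spec
  t5 <- sprintf("%s.t1", ev$five); t3 <- sprintf("%s.t1", ev$three)
  s5 <- transcript_sequence(m, universe$genome, t5)
  s3 <- transcript_sequence(m, universe$genome, t3)
  lens5 <- gene_exon_lengths(m, t5); lens3 <- gene_exon_lengths(m, t3)
  j <- sum(lens5[seq_len(fs$five_exon_idx)])
  p3 <- if (fs$three_exon_idx == 1L) 0L else
    sum(lens3[seq_len(fs$three_exon_idx - 1L)])
  list(seq = paste0(substr(s5, 1L, j), substr(s3, p3 + 1L, nchar(s3))),
       junction = j)
}

gene_exon_lengths <- function(model, transcript_id) {
  ex <- transcript_exons(model, transcript_id)
  ex$end - ex$start + 1L
}

## draw junction-read start offsets (overhang on the 5' side of the trimmed
## read), per the configured junction mode
draw_junction_overhangs <- function(n, trim_len, min_anchor, mode) {
  lo <- min_anchor; hi <- trim_len - min_anchor
  if (mode == "tiling") {
    sample(seq(lo, hi), n, replace = TRUE)
  } else {
    base <- sample(seq(lo + 1L, hi - 1L), 1L)
    base + sample(-1:1, n, replace = TRUE)
  }
}

#' Simulate paired-end reads from a universe
#'
#' Background pairs are drawn from wild-type transcripts (uniform fragment
#' start, truncated-normal insert length); fusion bridging pairs straddle the
#' planted junction with one trimmed mate entirely on each side;
#' junction-spanning reads are placed per each spec's `junction_mode`;
#' readthrough and paralog decoys get bridging pairs; an exact planted
#' fraction of pairs is copied from the contaminant sequences; substitution
#' errors are applied per base (contaminant pairs stay exact copies).
#' Deterministic under the configured seed.
#'
#' @param universe A `sim_universe`.
#' @return List with `pairs` (a [read_pairs()] object) and `counts` (named
#'   planted pair counts by class).
#' @export
simulate_reads <- function(universe) {
  cfg <- universe$config
  set.seed(cfg$seed + 1000003L)
  RL <- cfg$read_len; TL <- cfg$trim_len
  m1 <- character(0); m2 <- character(0); ids <- character(0)
  add_pair <- function(a, b, id) {
    m1[[length(m1) + 1L]] <<- a; m2[[length(m2) + 1L]] <<- b
    ids[[length(ids) + 1L]] <<- id
  }
  revcomp <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  frag_pair <- function(tseq, id) {
    tlen <- nchar(tseq)
    fl <- max(RL, min(tlen, round(stats::rnorm(1, cfg$insert_median, cfg$insert_sd))))
    st <- sample.int(tlen - fl + 1L, 1L)
    frag <- substr(tseq, st, st + fl - 1L)
    add_pair(substr(frag, 1L, RL), revcomp(substr(frag, fl - RL + 1L, fl)), id)
  }

  ## background expression
  w <- setNames(rep(1, nrow(universe$model$genes)), universe$model$genes$gene_id)
  if (!is.null(cfg$expression_weights))
    w[names(cfg$expression_weights)] <- cfg$expression_weights
  for (e in universe$events) {
    if (e$type %in% c("fusion", "artifact_stack") && isTRUE(e$spec$exclusive_three))
      w[e$three] <- 0
  }
  tseq_cache <- new.env(parent = emptyenv())
  tseq_of <- function(gid) {
    if (is.null(tseq_cache[[gid]]))
      tseq_cache[[gid]] <- transcript_sequence(universe$model, universe$genome,
                                               sprintf("%s.t1", gid))
    tseq_cache[[gid]]
  }
  for (gid in universe$model$genes$gene_id) {
    nb <- round(w[[gid]] * cfg$background_pairs_per_gene)
    if (nb <= 0L) next
    ts <- tseq_of(gid)
    for (k in seq_len(nb)) frag_pair(ts, sprintf("bg_%s_%04d", gid, k))
  }

  counts <- c(background = length(ids))
  ## planted events
  for (e in universe$events) {
    if (e$type %in% c("fusion", "artifact_stack")) {
      fu <- fused_transcript(universe, e)
      Fq <- fu$seq; j <- fu$junction; lenF <- nchar(Fq)
      for (k in seq_len(e$spec$n_bridging_pairs)) {
        a1 <- sample(seq(max(1L, j - TL - 80L), j - TL + 1L), 1L)
        b <- sample(seq(j + 1L, min(j + 80L, lenF - RL + 1L)), 1L)
        add_pair(substr(Fq, a1, a1 + RL - 1L),
                 revcomp(substr(Fq, b, b + RL - 1L)),
                 sprintf("%s_brg_%03d", e$id, k))
      }
      ov5 <- draw_junction_overhangs(e$spec$n_junction_reads, TL,
                                     cfg$min_anchor, e$spec$junction_mode)
      for (k in seq_along(ov5)) {
        s <- j - ov5[k] + 1L
        b <- sample(seq(j + 1L, lenF - RL + 1L), 1L)
        add_pair(substr(Fq, s, s + RL - 1L),
                 revcomp(substr(Fq, b, b + RL - 1L)),
                 sprintf("%s_jx_%03d", e$id, k))
      }
    } else if (e$type == "readthrough") {
      Cq <- paste0(tseq_of(e$five), tseq_of(e$three))
      j <- nchar(tseq_of(e$five)); lenC <- nchar(Cq)
      for (k in seq_len(e$n_bridging)) {
        a1 <- sample(seq(max(1L, j - TL - 80L), j - TL + 1L), 1L)
        b <- sample(seq(j + 1L, min(j + 80L, lenC - RL + 1L)), 1L)
        add_pair(substr(Cq, a1, a1 + RL - 1L),
                 revcomp(substr(Cq, b, b + RL - 1L)),
                 sprintf("%s_brg_%03d", e$id, k))
      }
    } else if (e$type == "paralog_decoy") {
      sA <- tseq_of(e$src); sB <- tseq_of(paste0(e$src, "P"))
      for (k in seq_len(e$n_bridging)) {
        a1 <- sample.int(nchar(sA) - RL + 1L, 1L)
        b <- sample.int(nchar(sB) - RL + 1L, 1L)
        add_pair(substr(sA, a1, a1 + RL - 1L),
                 revcomp(substr(sB, b, b + RL - 1L)),
                 sprintf("%s_brg_%03d", e$id, k))
      }
    }
  }
  counts <- c(counts, planted = length(ids) - counts[["background"]])

  ## substitution errors on all transcript-derived reads
  if (cfg$error_rate > 0) {
    mutate <- function(s) {
      v <- strsplit(s, "")[[1]]
      hit <- stats::runif(length(v)) < cfg$error_rate
      if (any(hit)) v[hit] <- rotate_base(v[hit])
      paste(v, collapse = "")
    }
    m1 <- vapply(m1, mutate, "", USE.NAMES = FALSE)
    m2 <- vapply(m2, mutate, "", USE.NAMES = FALSE)
  }

  ## contaminant (rRNA-like) pairs: exact copies, deterministic count
  n_other <- length(ids)
  n_rrna <- round(cfg$rrna_fraction * n_other / (1 - cfg$rrna_fraction))
  big <- universe$contaminants[Biostrings::width(universe$contaminants) >=
                                 cfg$insert_median + RL]
  for (k in seq_len(n_rrna)) {
    src <- as.character(big[[sample.int(length(big), 1L)]])
    tlen <- nchar(src)
    fl <- max(RL, min(tlen, round(stats::rnorm(1, cfg$insert_median, cfg$insert_sd))))
    st <- sample.int(tlen - fl + 1L, 1L)
    frag <- substr(src, st, st + fl - 1L)
    add_pair(substr(frag, 1L, RL), revcomp(substr(frag, fl - RL + 1L, fl)),
             sprintf("rrna_%04d", k))
  }
  counts <- c(counts, rrna = n_rrna, total = length(ids))
  list(pairs = read_pairs(m1, m2, ids), counts = counts)
}

#' Simulate a segmented copy-number profile for a universe
#'
#' Fusion specs flagged `amplified` get a high-level segment (log2 = 2)
#' covering the 5' partner gene with boundaries a short distance outside the
#' gene span (hence within any reasonable transition window); everything
#' else is flat at log2 = 0.
#'
#' @param universe A `sim_universe`.
#' @param margin Distance (bp) from gene span to segment boundary; kept below
#'   the minimum intergenic gap so neighbouring genes stay outside the
#'   segment. Overlapping amplified intervals are merged.
#' @return A `cn_profile`.
#' @export
simulate_cn_profile <- function(universe, margin = 100L) {
  cfg <- universe$config
  segs <- list()
  for (ch in names(universe$genome)) {
    clen <- Biostrings::width(universe$genome)[names(universe$genome) == ch]
    amp <- list()
    for (e in universe$events) {
      if (!e$type %in% c("fusion", "artifact_stack")) next
      if (!isTRUE(e$spec$amplified)) next
      g <- get_gene(universe$model, e$five)
      if (g$chrom != ch) next
      amp[[length(amp) + 1L]] <- c(max(1L, g$start - margin),
                                   min(clen, g$end + margin))
    }
    pos <- 1L
    if (length(amp) > 0L) {
      amp <- amp[order(vapply(amp, `[`, 0, 1L))]
      merged <- list(amp[[1]])
      for (a in amp[-1]) {
        last <- merged[[length(merged)]]
        if (a[1] <= last[2] + 1L)
          merged[[length(merged)]] <- c(last[1], max(last[2], a[2]))
        else merged[[length(merged) + 1L]] <- a
      }
      amp <- merged
      for (a in amp) {
        if (a[1] > pos)
          segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = pos,
                                                  end = a[1] - 1L, log2_ratio = 0)
        segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = a[1],
                                                end = a[2], log2_ratio = 2)
        pos <- a[2] + 1L
      }
    }
    if (pos <= clen)
      segs[[length(segs) + 1L]] <- data.frame(chrom = ch, start = pos,
                                              end = clen, log2_ratio = 0)
  }
  cn_profile(do.call(rbind, segs))
}

#' Write a universe (and optionally reads) to plain-text files
#'
#' Emits genome FASTA, annotation GTF, contaminant FASTA, paralog TSV, truth
#' TSV, copy-number TSV and a plain-text `key=value` manifest recording the
#' seed and file names. Byte-identical across runs with the same config.
#'
#' @param universe A `sim_universe`.
#' @param dir Output directory (created if missing).
#' @param reads Optional result of [simulate_reads()] to write as FASTQ.
#' @param cn Optional `cn_profile` to write.
#' @return Named vector of written paths, invisibly.
#' @export
write_universe <- function(universe, dir, reads = NULL, cn = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(universe$genome, p("genome.fa"))
  Biostrings::writeXStringSet(universe$contaminants, p("contaminants.fa"))
  write_annotation(universe$model, p("annotation.gtf"))
  keys <- universe$paralogs$keys
  writeLines(c("# paralog pairs (gene_id <tab> gene_id)", keys), p("paralogs.tsv"))
  write.table(universe$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(genome = "genome.fa", contaminants = "contaminants.fa",
             annotation = "annotation.gtf", paralogs = "paralogs.tsv",
             truth = "truth.tsv")
  if (!is.null(reads)) {
    write_pairs_fastq(reads$pairs, p("reads_1.fastq"), p("reads_2.fastq"))
    files <- c(files, reads_1 = "reads_1.fastq", reads_2 = "reads_2.fastq")
  }
  if (!is.null(cn)) {
    write_cn_profile(cn, p("cn_profile.tsv"))
    files <- c(files, cn_profile = "cn_profile.tsv")
  }
  manifest <- c(sprintf("seed=%d", universe$config$seed),
                sprintf("n_genes=%d", nrow(universe$model$genes)),
                sprintf("n_events=%d", nrow(universe$truth)),
                sprintf("%s=%s", names(files), files))
  writeLines(manifest, p("manifest.txt"))
  invisible(vapply(files, p, ""))
}

#' The flagship test configuration
#'
#' Five genuine fusions (two interchromosomal, one out-of-frame, one
#' promoter swap with exclusive 3'-partner expression, two amplified), two
#' readthrough decoys, two paralog decoys, two stacked artifact stacks and
#' one overlapping gene pair, on a 4 x 30 kb genome with 24 background
#' genes.
#'
#' @param seed Integer seed.
#' @param background_pairs_per_gene Wild-type depth per gene.
#' @return A `simulation_config`.
#' @export
flagship_config <- function(seed = 1L, background_pairs_per_gene = 40L) {
  simulation_config(
    seed = seed,
    fusion_specs = list(
      fusion_spec(class = "intra", five_exon_idx = 2, three_exon_idx = 2,
                  frame = "in", amplified = TRUE),
      fusion_spec(class = "inter", five_exon_idx = 3, three_exon_idx = 2,
                  frame = "in", amplified = TRUE),
      fusion_spec(class = "intra", five_exon_idx = 2, three_exon_idx = 3,
                  frame = "out"),
      fusion_spec(class = "inter", five_exon_idx = 1, three_exon_idx = 2,
                  frame = "in", promoter_swap = TRUE),
      fusion_spec(class = "intra", five_exon_idx = 2, three_exon_idx = 2,
                  frame = "in")),
    n_readthrough_decoys = 2L, n_paralog_decoys = 2L,
    n_artifact_stacks = 2L, n_overlapping_pairs = 1L,
    background_pairs_per_gene = background_pairs_per_gene)
}
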