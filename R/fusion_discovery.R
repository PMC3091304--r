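#' Find discordant read pairs bridging two genes
#'
#' Every pair whose two mates are uniquely aligned and assigned to two
#' different genes contributes one count to the corresponding unordered gene
#' pair. Pairs with an unassigned, unaligned or multi-mapping mate contribute
#' nothing here (unaligned mates are reserved for the junction step).
#'
#' @param assignments Data frame from [map_reads()] (`read_id`, `category`,
#'   `gene_id`) where `read_id` is `<pair_id>/1` or `<pair_id>/2`.
#' @return Data frame of candidates: `gene_a`, `gene_b` (gene_a < gene_b),
#'   `pair_count`, `pair_ids` (semicolon-joined).
#' @export
find_discordant_pairs <- function(assignments) {
  a <- assignments
  a$pair_id <- sub("/[12]$", "", a$read_id)
  a$mate <- sub("^.*/", "", a$read_id)
  ok <- a$category == "unique" & !is.na(a$gene_id)
  a <- a[ok, , drop = FALSE]
  m1 <- a[a$mate == "1", c("pair_id", "gene_id")]
  m2 <- a[a$mate == "2", c("pair_id", "gene_id")]
  mg <- merge(m1, m2, by = "pair_id", suffixes = c("_1", "_2"))
  mg <- mg[mg$gene_id_1 != mg$gene_id_2, , drop = FALSE]
  if (nrow(mg) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      pair_count = integer(0), pair_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  ga <- pmin(mg$gene_id_1, mg$gene_id_2)
  gb <- pmax(mg$gene_id_1, mg$gene_id_2)
  key <- paste(ga, gb, sep = "\t")
  sp <- split(mg$pair_id, key)
  out <- data.frame(
    gene_a = sub("\t.*$", "", names(sp)),
    gene_b = sub("^.*\t", "", names(sp)),
    pair_count = lengths(sp),
    pair_ids = vapply(sp, function(x) paste(sort(x), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  out <- out[order(-out$pair_count, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter fusion candidates
#'
#' Retains gene pairs with at least `min_pair_support` supporting discordant
#' pairs that are neither overlapping nor adjacent (likely transcriptional
#' readthrough) nor paralogous (likely mapping errors). An optional biotype
#' whitelist restricts candidates to genes of the listed biotypes (default:
#' all biotypes eligible).
#'
#' @param candidates Data frame from [find_discordant_pairs()].
#' @param model A `gene_model`.
#' @param paralogs A `paralog_table` (or `NULL` for none).
#' @param params A `detection_params`.
#' @param biotype_whitelist Optional character vector of eligible biotypes.
#' @return Filtered candidate data frame sorted by descending `pair_count`,
#'   then gene ids, with a `filter` attribute counting exclusions per rule.
#' @export
filter_candidates <- function(candidates, model, paralogs = NULL,
                              params = detection_params(),
                              biotype_whitelist = NULL) {
  if (is.null(paralogs)) paralogs <- paralog_table()
  cd <- candidates
  drop_support <- cd$pair_count < params$min_pair_support
  n <- nrow(cd)
  ovl <- adj <- par <- bio <- logical(n)
  for (i in seq_len(n)) {
    if (drop_support[i]) next
    ovl[i] <- genes_overlap(model, cd$gene_a[i], cd$gene_b[i])
    adj[i] <- !ovl[i] && genes_adjacent(model, cd$gene_a[i], cd$gene_b[i])
    par[i] <- is_paralog_pair(cd$gene_a[i], cd$gene_b[i], paralogs)
    if (!is.null(biotype_whitelist)) {
      ba <- get_gene(model, cd$gene_a[i])$biotype
      bb <- get_gene(model, cd$gene_b[i])$biotype
      bio[i] <- !(ba %in% biotype_whitelist && bb %in% biotype_whitelist)
    }
  }
  keep <- !(drop_support | ovl | adj | par | bio)
  out <- cd[keep, , drop = FALSE]
  out <- out[order(-out$pair_count, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter") <- c(below_support = sum(drop_support),
                           overlapping = sum(ovl), adjacent = sum(adj),
                           paralog = sum(par), biotype = sum(bio))
  out
}
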