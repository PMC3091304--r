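#' Detection parameters
#'
#' Bundle of all tunable thresholds driving fusion detection. Defaults follow
#' the published pipeline: candidate gene pairs need at least two supporting
#' discordant read pairs (`min_pair_support`; raise to 3 for deeply sequenced
#' libraries, e.g. above ~8M filtered pairs), junction calls need at least two
#' junction-spanning reads (`min_junction_reads`) each anchored by at least
#' `min_anchor` bases on both sides of the breakpoint, and all alignment is
#' ungapped with at most `max_mismatches` mismatches on reads trimmed to
#' `trim_len` bases.
#'
#' The tiling classifier labels a junction an artifact when the spread of
#' distinct alignment start positions is no wider than `artifact_span` bases,
#' when fewer than `min_distinct_starts` distinct start positions are seen, or
#' when fewer than `min_two_sided_anchor_reads` reads anchor with at least
#' `min_anchor` bases on both sides.
#'
#' Copy-number association flags a call when a segment boundary with
#' |delta log2| >= `cn_delta_log2` lies within `transition_window` bp of either
#' gene, and as amplified when either gene overlaps a segment with log2 ratio
#' >= `amplification_log2`.
#'
#' @param min_pair_support Minimum discordant pairs per candidate gene pair.
#' @param min_junction_reads Minimum junction-spanning reads per reported call.
#' @param min_anchor Minimum read overhang (bp) on each side of a junction.
#' @param max_mismatches Maximum mismatches per ungapped alignment.
#' @param trim_len Read length after trimming (bp).
#' @param min_distinct_starts Tiling rule: minimum distinct start positions.
#' @param artifact_span Tiling rule: maximum start-position span (bp) still
#'   considered a stacked artifact.
#' @param min_two_sided_anchor_reads Tiling rule: minimum reads with both
#'   overhangs >= `min_anchor`.
#' @param amplification_log2 log2 ratio at or above which a segment counts as
#'   high-level amplification.
#' @param transition_window Window (bp) around a gene within which a segment
#'   boundary counts as a copy-number transition.
#' @param cn_delta_log2 Minimum |delta log2| across a boundary to count it.
#' @return A list of class `detection_params`.
#' @examples
#' p <- detection_params(min_pair_support = 3)
#' p$min_anchor
#' @export
detection_params <- function(min_pair_support = 2L,
                             min_junction_reads = 2L,
                             min_anchor = 10L,
                             max_mismatches = 3L,
                             trim_len = 50L,
                             min_distinct_starts = 3L,
                             artifact_span = 2L,
                             min_two_sided_anchor_reads = 1L,
                             amplification_log2 = 1.0,
                             transition_window = 100000L,
                             cn_delta_log2 = 0.3) {
  p <- list(
    min_pair_support = as.integer(min_pair_support),
    min_junction_reads = as.integer(min_junction_reads),
    min_anchor = as.integer(min_anchor),
    max_mismatches = as.integer(max_mismatches),
    trim_len = as.integer(trim_len),
    min_distinct_starts = as.integer(min_distinct_starts),
    artifact_span = as.integer(artifact_span),
    min_two_sided_anchor_reads = as.integer(min_two_sided_anchor_reads),
    amplification_log2 = as.numeric(amplification_log2),
    transition_window = as.integer(transition_window),
    cn_delta_log2 = as.numeric(cn_delta_log2)
  )
  counts <- c("min_pair_support", "min_junction_reads", "min_anchor",
              "min_distinct_starts", "min_two_sided_anchor_reads", "trim_len")
  for (nm in counts) {
    if (is.na(p[[nm]]) || p[[nm]] < 1L)
      stop("detection_params: '", nm, "' must be a count >= 1")
  }
  if (p$max_mismatches < 0L) stop("detection_params: 'max_mismatches' must be >= 0")
  if (p$artifact_span < 0L) stop("detection_params: 'artifact_span' must be >= 0")
  if (p$min_anchor > p$trim_len / 2)
    stop("detection_params: 'min_anchor' must be <= trim_len/2")
  structure(p, class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Fusion detection parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
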