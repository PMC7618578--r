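#' Call deduplicated junctions from a simulated or real read set
#'
#' Convenience chain: merge read pairs, optionally pre-filter for a
#' capture region, split reads into sub-reads against the reference, call
#' junctions and remove PCR duplicates.
#'
#' @param reads A `mccu_reads` object (or list with `r1`, `r2` data
#'   frames).
#' @param reference A [build_fixture()] object or character sequence.
#' @param capture_regions Optional capture intervals for pre-filtering.
#' @param flank Capture flank in bp (default 800).
#' @param min_overlap,max_mismatch_rate Passed to [merge_read_pairs()].
#' @param min_subread,max_mismatches Passed to
#'   [split_and_map_subreads()].
#' @param short_range_threshold Passed to [call_junctions()].
#' @return Deduplicated junction table, with merge statistics in
#'   attribute `merge_stats`.
#' @export
call_junctions_from_reads <- function(reads, reference,
                                      capture_regions = NULL, flank = 800L,
                                      min_overlap = 10L,
                                      max_mismatch_rate = 0.25,
                                      min_subread = 20L, max_mismatches = 2L,
                                      short_range_threshold = 1000L) {
  merged <- merge_read_pairs(reads$r1, reads$r2, min_overlap,
                             max_mismatch_rate)
  rd <- merged$reads
  if (!is.null(capture_regions))
    rd <- prefilter_capture_reads(rd, capture_regions, reference,
                                  flank = flank)
  subreads <- split_and_map_subreads(rd, reference,
                                     min_subread = min_subread,
                                     max_mismatches = max_mismatches)
  jx <- call_junctions(subreads, short_range_threshold)
  out <- deduplicate_junctions(jx)
  attr(out, "merge_stats") <- merged$stats
  out
}
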