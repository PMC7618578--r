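#' Merge paired-end reads by best overlap
#'
#' Aligns the suffix of R1 against the prefix of the reverse complement of
#' R2 (FLASH-style), merging when the best overlap is at least
#' `min_overlap` bp with a mismatch rate at most `max_mismatch_rate`.
#' Disagreeing bases are resolved to the higher-quality call. Unmerged
#' pairs are passed through as two reads flagged unmerged.
#'
#' @param r1,r2 Data frames with columns `id`, `seq`, `qual` (as produced
#'   by [render_sequencing_library()] or [read_fastq()]), or a single
#'   `mccu_reads` object passed as `r1`.
#' @param min_overlap Minimum overlap in bp (default 10).
#' @param max_mismatch_rate Maximum fraction of mismatching bases within
#'   the overlap (default 0.25).
#' @return A list of class `mccu_merged`: `reads` (data frame `id`, `seq`,
#'   `qual`, `merged`, `overlap`) and `stats` (list with `n_pairs`,
#'   `n_merged`, `merged_fraction`).
#' @export
merge_read_pairs <- function(r1, r2 = NULL, min_overlap = 10L,
                             max_mismatch_rate = 0.25) {
  if (inherits(r1, "mccu_reads")) { r2 <- r1$r2; r1 <- r1$r1 }
  if (nrow(r1) != nrow(r2)) stop("R1 and R2 have different read counts")
  bad <- which(r1$id != r2$id)
  if (length(bad))
    stop("read id mismatch between files at pair ", bad[1], ": '",
         r1$id[bad[1]], "' vs '", r2$id[bad[1]], "'")
  res <- cpp_merge_pairs(r1$seq, r2$seq, r1$qual, r2$qual,
                         as.integer(min_overlap), max_mismatch_rate)
  ok <- res$merged
  merged <- data.frame(id = r1$id[ok], seq = res$sequence[ok],
                       qual = res$quality[ok],
                       merged = rep(TRUE, sum(ok)),
                       overlap = res$overlap[ok])
  un <- which(!ok)
  if (length(un)) {
    passthrough <- data.frame(
      id = c(paste0(r1$id[un], "/1"), paste0(r2$id[un], "/2")),
      seq = c(r1$seq[un], r2$seq[un]),
      qual = c(r1$qual[un], r2$qual[un]),
      merged = FALSE, overlap = 0L)
    merged <- rbind(merged, passthrough)
  }
  structure(list(reads = merged,
                 stats = list(n_pairs = nrow(r1), n_merged = sum(ok),
                              merged_fraction = mean(ok))),
            class = "mccu_merged")
}

#' @export
print.mccu_merged <- function(x, ...) {
  cat(sprintf("mccu_merged: %d pairs, %d merged (%.1f%%)\n",
              x$stats$n_pairs, x$stats$n_merged,
              100 * x$stats$merged_fraction))
  invisible(x)
}

#' Pre-filter reads for the captured region
#'
#' Retains a read iff any exact seed of `seed_length` bp from the read
#' occurs, on either strand, within a capture region extended by `flank`
#' bp on both sides. With error-free reads the retained set is a superset
#' of the reads truly overlapping the region.
#'
#' @param reads Data frame with columns `id`, `seq` (e.g.
#'   `merge_read_pairs()$reads`).
#' @param capture_regions Intervals (matrix/data frame, 0-based half-open)
#'   on the reference.
#' @param reference A [build_fixture()] object or a character reference
#'   sequence.
#' @param flank Extension in bp on both sides of each region (default 800).
#' @param seed_length Exact-match seed length in bp (default 20).
#' @return The retained subset of `reads`, with attribute `stats`.
#' @export
prefilter_capture_reads <- function(reads, capture_regions, reference,
                                    flank = 800L, seed_length = 20L) {
  refseq <- if (inherits(reference, "mccu_fixture")) reference$sequence
            else as.character(reference)
  regions <- .as_intervals(capture_regions)
  if (!nrow(regions)) stop("capture_regions must be non-empty")
  L <- nchar(refseq)
  if (any(regions$start < 0 | regions$end > L))
    stop("capture region outside reference bounds [0, ", L, ")")
  if (!nrow(reads))
    return(structure(reads[integer(0), , drop = FALSE],
                     stats = list(n_in = 0L, n_retained = 0L)))
  s <- pmax(regions$start - flank, 0L)
  e <- pmin(regions$end + flank, L)
  target <- paste(substring(refseq, s + 1L, e), collapse = strrep("N", 2L))
  hits <- cpp_map_subreads(reads$seq, target, as.integer(seed_length),
                           as.integer(seed_length), 0L)
  keep <- sort(unique(hits$read))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, stats = list(n_in = nrow(reads), n_retained = length(keep)))
}

#' Split reads into genome-collinear sub-reads
#'
#' Maps each (reconstructed) read to the reference with a k-mer seeded
#' exact-match mapper: maximal exact diagonal runs are chained, runs on
#' the same diagonal are extended across at most `max_mismatches`
#' substitutions, and the read is partitioned at the remaining alignment
#' breakpoints. When the two flanking alignments could both absorb bases
#' at a junction (micro-homology), the ambiguous bases are assigned to the
#' upstream (left-in-read) sub-read and the sub-reads are flagged.
#' Sub-reads shorter than `min_subread` are discarded.
#'
#' @param reads Data frame with columns `id`, `seq`, or a character vector
#'   of sequences.
#' @param reference A [build_fixture()] object or character sequence.
#' @param min_subread Minimum sub-read length in bp (default 20).
#' @param max_mismatches Maximum substitutions tolerated inside one
#'   sub-read (default 2).
#' @param chrom Chromosome name recorded for the genome intervals.
#' @return Data frame of sub-reads: `read_id`, `segment`, `read_start`,
#'   `read_end` (0-based half-open within the read), `chrom`,
#'   `genome_start`, `genome_end`, `strand` (`"+"`/`"-"`), `mismatches`,
#'   `ambiguous`; ordered by read and read interval. Reads with no
#'   sub-read of minimum length are absent (reported in attribute
#'   `unmapped`).
#' @export
split_and_map_subreads <- function(reads, reference, min_subread = 20L,
                                   max_mismatches = 2L, chrom = "fixture") {
  refseq <- if (inherits(reference, "mccu_fixture")) reference$sequence
            else as.character(reference)
  if (is.character(reads)) reads <- data.frame(id = seq_along(reads),
                                               seq = reads)
  k <- as.integer(min(20L, min_subread))
  hits <- cpp_map_subreads(reads$seq, refseq, k, as.integer(min_subread),
                           as.integer(max_mismatches))
  out <- data.frame(read_id = reads$id[hits$read],
                    read_start = hits$read_start, read_end = hits$read_end,
                    chrom = if (nrow(hits)) chrom else character(),
                    genome_start = hits$genome_start,
                    genome_end = hits$genome_end,
                    strand = ifelse(hits$strand > 0, "+", "-"),
                    mismatches = hits$mismatches,
                    ambiguous = hits$ambiguous == 1L)
  out <- out[order(match(out$read_id, reads$id), out$read_start), ,
             drop = FALSE]
  segs <- stats::ave(seq_len(nrow(out)), out$read_id, FUN = seq_along)
  out$segment <- if (nrow(out)) as.integer(segs) else integer()
  out <- out[, c("read_id", "segment", "read_start", "read_end", "chrom",
                 "genome_start", "genome_end", "strand", "mismatches",
                 "ambiguous")]
  rownames(out) <- NULL
  structure(out, unmapped = setdiff(reads$id, out$read_id))
}

#' Write sub-reads as SAM
#'
#' One record per sub-read; the query name is `read_id:segment`, the
#' breakpoint-ambiguity flag is carried in the optional `XB:i` tag and the
#' mismatch count in `NM:i`. Alignments are ungapped (`<len>M`).
#'
#' @param subreads Data frame from [split_and_map_subreads()].
#' @param path Output file path.
#' @param reference_length Reference length (for the `@SQ` header).
#' @param chrom Reference name.
#' @export
write_subreads_sam <- function(subreads, path, reference_length,
                               chrom = "fixture") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", chrom, "\tLN:", reference_length)), con)
  if (nrow(subreads)) {
    len <- subreads$read_end - subreads$read_start
    rec <- paste(paste0(subreads$read_id, ":", subreads$segment),
                 ifelse(subreads$strand == "-", 16L, 0L),
                 chrom, subreads$genome_start + 1L, 60L,
                 paste0(len, "M"), "*", 0L, 0L, "*", "*",
                 paste0("NM:i:", subreads$mismatches),
                 paste0("XB:i:", as.integer(subreads$ambiguous)),
                 paste0("XR:i:", subreads$read_start),
                 sep = "\t")
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read externally aligned sub-reads from SAM
#'
#' Ingestion path for sub-reads aligned outside the package. Query names
#' are expected as `read_id:segment` (as written by
#' [write_subreads_sam()]); plain query names are accepted with segment
#' order taken from file order. Only ungapped records are supported.
#'
#' @param path SAM file path.
#' @return Data frame in the [split_and_map_subreads()] layout.
#' @export
read_subreads_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(), segment = integer(),
                      read_start = integer(), read_end = integer(),
                      chrom = character(), genome_start = integer(),
                      genome_end = integer(), strand = character(),
                      mismatches = integer(), ambiguous = logical()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  qn <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  chrom <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L)) - 1L
  cigar <- vapply(f, `[[`, "", 6L)
  if (any(!grepl("^[0-9]+M$", cigar)))
    stop("only ungapped (<len>M) SAM records are supported")
  len <- as.integer(sub("M$", "", cigar))
  tagval <- function(tag) {
    vapply(f, function(x) {
      hit <- grep(paste0("^", tag, ":i:"), x, value = TRUE)
      if (length(hit)) as.integer(sub(paste0(tag, ":i:"), "", hit[1]))
      else NA_integer_
    }, integer(1))
  }
  nm <- tagval("NM"); xb <- tagval("XB"); xr <- tagval("XR")
  has_seg <- grepl(":[0-9]+$", qn)
  read_id <- ifelse(has_seg, sub(":[0-9]+$", "", qn), qn)
  segment <- ifelse(has_seg, as.integer(sub("^.*:", "", qn)), NA_integer_)
  rs <- ifelse(is.na(xr), 0L, xr)
  out <- data.frame(read_id = read_id, segment = segment,
                    read_start = rs, read_end = rs + len,
                    chrom = chrom, genome_start = pos,
                    genome_end = pos + len,
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    mismatches = ifelse(is.na(nm), 0L, nm),
                    ambiguous = !is.na(xb) & xb == 1L)
  if (anyNA(out$segment))
    out$segment <- as.integer(stats::ave(seq_len(nrow(out)), out$read_id,
                                         FUN = seq_along))
  out <- out[order(match(out$read_id, unique(out$read_id)), out$read_start), ]
  rownames(out) <- NULL
  out
}
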