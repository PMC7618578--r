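#' Call ligation junctions from ordered sub-reads
#'
#' Emits one junction per adjacent sub-read pair in read order. The
#' junction coordinates are the genomic base at the 3' end (in read
#' orientation) of the left sub-read and the 5' start of the right
#' sub-read, 0-based. Direction flags record on which side of the MNase
#' cut the sequenced (protein-protected) fragment lies: a sub-read on the
#' `+` strand ending at the junction protects the sequence upstream of its
#' cut (`toward_upstream`); the strand and junction-abutting end determine
#' the flag for each side. Junctions are canonically sorted so
#' `pos_a <= pos_b`, swapping the direction flags together with the
#' positions. `fragment_ends` are the genomic coordinates of the read's
#' outermost aligned bases.
#'
#' @param subreads Data frame from [split_and_map_subreads()] (one or many
#'   reads; must be ordered by read interval within each read).
#' @param short_range_threshold Distance in bp below which a junction is
#'   classed `short` (default 1000).
#' @return Data frame of junctions: `chrom`, `pos_a`, `pos_b`, `dir_a`,
#'   `dir_b`, `frag_start`, `frag_end`, `read_id`, `range_class`, `cis`.
#'   Reads with a single sub-read contribute no junctions.
#' @export
call_junctions <- function(subreads, short_range_threshold = 1000L) {
  empty <- data.frame(chrom = character(), pos_a = integer(),
                      pos_b = integer(), dir_a = character(),
                      dir_b = character(), frag_start = integer(),
                      frag_end = integer(), read_id = character(),
                      range_class = character(), cis = logical())
  if (!nrow(subreads)) return(empty)
  o <- order(match(subreads$read_id, unique(subreads$read_id)),
             subreads$read_start)
  s <- subreads[o, , drop = FALSE]
  n <- nrow(s)
  adj <- which(s$read_id[-n] == s$read_id[-1])
  if (!length(adj)) return(empty)
  li <- adj; ri <- adj + 1L
  fwd_l <- s$strand[li] == "+"
  fwd_r <- s$strand[ri] == "+"
  pos_l <- ifelse(fwd_l, s$genome_end[li] - 1L, s$genome_start[li])
  dir_l <- ifelse(fwd_l, "toward_upstream", "toward_downstream")
  pos_r <- ifelse(fwd_r, s$genome_start[ri], s$genome_end[ri] - 1L)
  dir_r <- ifelse(fwd_r, "toward_downstream", "toward_upstream")
  fr_start <- stats::ave(s$genome_start, s$read_id, FUN = min)
  fr_end <- stats::ave(s$genome_end, s$read_id, FUN = max)
  swap <- pos_l > pos_r
  out <- data.frame(chrom = s$chrom[li],
                    pos_a = as.integer(ifelse(swap, pos_r, pos_l)),
                    pos_b = as.integer(ifelse(swap, pos_l, pos_r)),
                    dir_a = ifelse(swap, dir_r, dir_l),
                    dir_b = ifelse(swap, dir_l, dir_r),
                    frag_start = as.integer(fr_start[li]),
                    frag_end = as.integer(fr_end[li]),
                    read_id = as.character(s$read_id[li]))
  out$range_class <- ifelse(out$pos_b - out$pos_a < short_range_threshold,
                            "short", "long")
  out$cis <- s$chrom[li] == s$chrom[ri]
  rownames(out) <- NULL
  out
}

#' Remove PCR duplicates from a junction table
#'
#' Junctions collapse on the key `(chrom, pos_a, pos_b, dir_a, dir_b,
#' frag_start, frag_end)`: two molecules produce the same key only when
#' both the ligation coordinates (with orientations) and the sonication
#' fragment ends coincide, the signature of a PCR duplicate. Direction
#' flags are part of the key because two molecules ligated in opposite
#' orientations at the same coordinates are distinct events. One
#' representative per key is retained; the output is stably sorted by
#' `(pos_a, pos_b)`.
#'
#' @param junctions Data frame from [call_junctions()].
#' @return The deduplicated junction table.
#' @export
deduplicate_junctions <- function(junctions) {
  if (!nrow(junctions)) return(junctions)
  key <- paste(junctions$chrom, junctions$pos_a, junctions$pos_b,
               junctions$dir_a, junctions$dir_b, junctions$frag_start,
               junctions$frag_end, sep = "\r")
  out <- junctions[!duplicated(key), , drop = FALSE]
  out <- out[order(out$pos_a, out$pos_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a junction table as tab-separated text or BEDPE
#'
#' @param junctions Junction data frame.
#' @param path Output path.
#' @param format `"tsv"` (native columns, 0-based, stated in the header)
#'   or `"bedpe"`.
#' @export
write_junctions <- function(junctions, path, format = c("tsv", "bedpe")) {
  format <- match.arg(format)
  if (format == "tsv") {
    cols <- c("chrom", "pos_a", "pos_b", "dir_a", "dir_b",
              "frag_start", "frag_end", "read_id")
    con <- file(path, "w")
    writeLines(c("# mccutools junctions; coordinates 0-based",
                 paste(cols, collapse = "\t")), con)
    close(con)
    write.table(junctions[, cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, append = TRUE)
  } else {
    bedpe <- data.frame(chrom1 = junctions$chrom, start1 = junctions$pos_a,
                        end1 = junctions$pos_a + 1L,
                        chrom2 = junctions$chrom, start2 = junctions$pos_b,
                        end2 = junctions$pos_b + 1L,
                        name = junctions$read_id, score = ".",
                        strand1 = ifelse(junctions$dir_a == "toward_upstream",
                                         "+", "-"),
                        strand2 = ifelse(junctions$dir_b == "toward_upstream",
                                         "+", "-"))
    write.table(bedpe, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read a junction table written by [write_junctions()]
#' @param path TSV path.
#' @return Junction data frame.
#' @export
read_junctions <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  out$range_class <- ifelse(out$pos_b - out$pos_a < 1000L, "short", "long")
  out$cis <- TRUE
  out
}
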