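#' Write sequences as FASTA
#' @param x A `mccu_fixture`, or a named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "mccu_fixture")) x <- c(fixture = x$sequence)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Write reads as FASTQ (Phred+33), optionally gzip-compressed
#' @param reads Data frame with `id`, `seq`, `qual`.
#' @param path Output path (compressed when it ends in `.gz`).
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file (plain or gzip)
#' @param path FASTQ path.
#' @return Data frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(s), seq = unname(as.character(s)),
             qual = unname(as.character(S4Vectors::mcols(s)$qualities)),
             row.names = NULL)
}

#' Write intervals as BED (0-based half-open)
#' @param x Data frame with `start`, `end`, optional `name`, `score`,
#'   `strand`.
#' @param path Output path.
#' @param chrom Chromosome used when `x` has no `chrom` column.
#' @export
write_bed <- function(x, path, chrom = "fixture") {
  df <- data.frame(chrom = if (is.null(x$chrom)) chrom else x$chrom,
                   start = x$start, end = x$end)
  for (col in c("name", "score", "strand"))
    if (!is.null(x[[col]])) df[[col]] <- x[[col]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#' @param path BED path.
#' @return Data frame with `chrom`, `start`, `end` (+ name/score/strand
#'   when present).
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' Write a 1D profile as bedGraph
#' @param x Data frame with `start`, `end`, `value` (or `pos`, `value`
#'   for 1-bp bins).
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_bedgraph <- function(x, path, chrom = "fixture") {
  if (!is.null(x$pos)) x <- data.frame(start = x$pos, end = x$pos + 1L,
                                       value = x$value)
  df <- data.frame(chrom = chrom, start = x$start, end = x$end,
                   value = x$value)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph path.
#' @return Data frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "value")
  df
}

#' Design a capture oligonucleotide tiling
#'
#' Tiles a target region with oligos of `oligo_length` bp at the given
#' overlap fraction (step = `round(oligo_length * (1 - overlap))`). A
#' final right-anchored oligo is added when the last step leaves more
#' than half a step of the region uncovered. Every oligo lies fully
#' inside the region.
#'
#' @param region `c(start, end)` interval (0-based half-open).
#' @param oligo_length Oligo length in bp (default 120).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @return Data frame of oligo intervals `start`, `end`, `name`.
#' @examples
#' nrow(design_capture_tiling(c(0, 5040)))  # 83
#' @export
design_capture_tiling <- function(region, oligo_length = 120L,
                                  overlap = 0.5) {
  start <- as.integer(region[1]); end <- as.integer(region[2])
  L <- end - start
  if (L < oligo_length)
    stop("region (", L, " bp) is shorter than the oligo length (",
         oligo_length, " bp)")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- as.integer(round(oligo_length * (1 - overlap)))
  n <- (L - oligo_length) %/% step + 1L
  starts <- start + (seq_len(n) - 1L) * step
  covered_end <- starts[n] + oligo_length
  if (end - covered_end > step / 2)
    starts <- c(starts, end - oligo_length)
  data.frame(start = starts, end = starts + oligo_length,
             name = paste0("oligo", seq_along(starts)))
}

#' Write a machine-readable run manifest
#'
#' Records the parameters, seed, package version and input checksums of a
#' pipeline run as simple `key: value` YAML.
#'
#' @param path Output path.
#' @param params Named list of parameters.
#' @param inputs Optional character vector of input file paths (md5sums
#'   are recorded).
#' @export
write_run_manifest <- function(path, params, inputs = NULL) {
  lines <- c(paste0("package: mccutools"),
             paste0("version: ",
                    as.character(utils::packageVersion("mccutools"))),
             paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  for (nm in names(params))
    lines <- c(lines, paste0(nm, ": ", paste(params[[nm]], collapse = ",")))
  for (f in inputs)
    lines <- c(lines, paste0("md5_", basename(f), ": ",
                             unname(tools::md5sum(f))))
  writeLines(lines, path)
  invisible(path)
}
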