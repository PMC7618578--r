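#' Build a contact matrix from deduplicated junctions
#'
#' Square mode bins both junction ends over `row_region` at `pixel_size`
#' bp per pixel: junction `(a, b)` increments pixel
#' `(floor((a-start)/px), floor((b-start)/px))` and its transpose, so raw
#' square matrices are symmetric and, at 1-bp pixels, the sum over the
#' upper triangle plus diagonal equals the number of in-region junctions.
#' At coarser pixels both orientations of a junction falling into one
#' diagonal pixel are stored, which makes coarse grids exact aggregations
#' of fine grids. Extended mode keeps
#' fine rows over the viewpoint region and bins the partner end
#' genome-wide at a coarser `extended` bp column size (a hybrid between a
#' viewpoint profile and a genome-wide map); junctions with either end in
#' the region contribute one increment per in-region end.
#'
#' @param junctions Deduplicated junction data frame.
#' @param row_region `c(start, end)` interval (0-based half-open).
#' @param pixel_size Row (and square-mode column) pixel size in bp (>= 1).
#' @param extended `NULL` for a square matrix, or the genome-wide column
#'   bin size in bp (default 500 when given as `TRUE`).
#' @param genome_length Genome length for extended columns (defaults to
#'   the largest junction coordinate + 1).
#' @param chrom Chromosome of the region.
#' @return An object of class `mccu_matrix`: list with `counts` (sparse
#'   dgCMatrix), `chrom`, `region`, `pixel`, `col_pixel`, `extended`,
#'   `normalization`, `bias`, `masked`.
#' @export
build_contact_matrix <- function(junctions, row_region, pixel_size = 1L,
                                 extended = NULL, genome_length = NULL,
                                 chrom = NULL) {
  if (pixel_size < 1) stop("pixel_size must be >= 1")
  start <- as.numeric(row_region[1]); end <- as.numeric(row_region[2])
  if (end <= start) stop("empty region")
  n <- as.integer(ceiling((end - start) / pixel_size))
  j <- junctions
  if (!is.null(chrom)) j <- j[j$chrom == chrom, , drop = FALSE]
  if (isTRUE(extended)) extended <- 500L
  if (is.null(extended)) {
    inr <- j$pos_a >= start & j$pos_a < end & j$pos_b >= start & j$pos_b < end
    j <- j[inr, , drop = FALSE]
    ri <- floor((j$pos_a - start) / pixel_size) + 1L
    ci <- floor((j$pos_b - start) / pixel_size) + 1L
    # both orientations are stored; only a junction whose two coordinates
    # coincide adds a single diagonal count, so coarse grids aggregate
    # fine grids exactly
    off <- j$pos_a != j$pos_b
    counts <- Matrix::sparseMatrix(i = c(ri, ci[off]), j = c(ci, ri[off]),
                                   x = 1, dims = c(n, n))
    out <- list(counts = counts, chrom = chrom %||% "fixture",
                region = c(start, end), pixel = pixel_size,
                col_pixel = pixel_size, extended = FALSE,
                normalization = "raw", bias = NULL, masked = NULL)
  } else {
    if (is.null(genome_length))
      genome_length <- max(j$pos_a, j$pos_b, end) + 1
    m <- as.integer(ceiling(genome_length / extended))
    a_in <- j$pos_a >= start & j$pos_a < end
    b_in <- j$pos_b >= start & j$pos_b < end
    ri <- c(floor((j$pos_a[a_in] - start) / pixel_size),
            floor((j$pos_b[b_in] - start) / pixel_size)) + 1L
    ci <- c(floor(j$pos_b[a_in] / extended),
            floor(j$pos_a[b_in] / extended)) + 1L
    counts <- Matrix::sparseMatrix(i = ri, j = ci, x = 1, dims = c(n, m))
    out <- list(counts = counts, chrom = chrom %||% "fixture",
                region = c(start, end), pixel = pixel_size,
                col_pixel = as.integer(extended), extended = TRUE,
                normalization = "raw", bias = NULL, masked = NULL)
  }
  structure(out, class = "mccu_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mccu_matrix <- function(x, ...) {
  cat(sprintf("mccu_matrix: %d x %d pixels (%g bp x %g bp), region [%g, %g), %s%s\n",
              nrow(x$counts), ncol(x$counts), x$pixel, x$col_pixel,
              x$region[1], x$region[2], x$normalization,
              if (x$extended) ", extended" else ""))
  invisible(x)
}

#' @export
as.matrix.mccu_matrix <- function(x, ...) as.matrix(x$counts)

#' ICE matrix balancing
#'
#' Iterative correction: the matrix is repeatedly divided by the outer
#' product of its row-sum factors until the maximum relative deviation of
#' unmasked row sums is below `tol`. Rows whose coverage falls below the
#' `low_coverage_quantile` of nonzero row sums (and all-zero rows) are
#' masked before balancing and returned as `NA`. The bias vector `b`
#' satisfies `raw = b %o% b * balanced` on unmasked entries.
#'
#' @param x A square `mccu_matrix` or plain matrix.
#' @param tol Convergence tolerance on relative row-sum deviation.
#' @param max_iter Maximum iterations (a warning flag is set on
#'   non-convergence).
#' @param low_coverage_quantile Coverage quantile below which rows are
#'   masked (default 0.02).
#' @return For an `mccu_matrix` input, the object with balanced `counts`,
#'   `bias`, `masked` and `normalization = "ice"`; for a matrix input, a
#'   list with `balanced`, `bias`, `masked`, `converged`.
#' @export
ice_normalize <- function(x, tol = 1e-5, max_iter = 200L,
                          low_coverage_quantile = 0.02) {
  obj <- NULL
  if (inherits(x, "mccu_matrix")) { obj <- x; x <- x$counts }
  if (nrow(x) != ncol(x)) stop("ICE balancing requires a square matrix")
  rs <- Matrix::rowSums(x)
  if (all(rs == 0)) stop("cannot balance an all-zero matrix")
  thr <- quantile(rs[rs > 0], low_coverage_quantile)
  masked <- rs == 0 | rs < thr
  keep <- which(!masked)
  M <- x[keep, keep, drop = FALSE]
  bias_k <- rep(1, length(keep))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- Matrix::rowSums(M)
    s <- s / mean(s)
    if (max(abs(s - 1)) < tol) { converged <- TRUE; break }
    s[s == 0] <- 1
    D <- Matrix::Diagonal(x = 1 / sqrt(s))
    M <- D %*% M %*% D
    bias_k <- bias_k * sqrt(s)
  }
  if (!converged)
    warning("ICE balancing did not converge in ", max_iter, " iterations")
  n <- nrow(x)
  bal <- matrix(NA_real_, n, n)
  bal[keep, keep] <- as.matrix(M)
  # invariant of the update: raw = bias %o% bias * balanced on kept rows
  bias <- rep(NA_real_, n)
  bias[keep] <- bias_k
  res <- list(balanced = bal, bias = bias, masked = masked,
              converged = converged)
  if (is.null(obj)) return(res)
  obj$counts <- methods::as(bal, "CsparseMatrix")
  obj$bias <- bias
  obj$masked <- masked
  obj$normalization <- "ice"
  attr(obj, "converged") <- converged
  obj
}

#' Cis normalization of viewpoint rows
#'
#' Single mode scales every viewpoint row to counts per `scale` cis-unique
#' junctions of that viewpoint, correcting oligo capture-efficiency
#' differences between viewpoints. Tiled mode applies the same per-row
#' scaling and then symmetrizes the matrix by averaging with its
#' transpose. Rows with a zero cis total are masked (`NA`), not divided.
#'
#' @param x A `mccu_matrix`, a plain matrix, or a numeric vector
#'   (1D viewpoint profile).
#' @param mode `"single"` or `"tiled"`.
#' @param scale Normalization unit (default 1e5 cis-unique junctions).
#' @param cis_totals Per-row cis-unique junction totals; defaults to the
#'   row sums of the raw counts (or `sum(x)` for a vector profile).
#' @return Object of the same shape with normalized values;
#'   `normalization` set to `"cis_single"` or `"cis_tiled"`.
#' @export
cis_normalize <- function(x, mode = c("single", "tiled"), scale = 1e5,
                          cis_totals = NULL) {
  mode <- match.arg(mode)
  if (is.numeric(x) && is.null(dim(x))) {
    tot <- cis_totals %||% sum(x)
    if (tot == 0) return(rep(NA_real_, length(x)))
    return(x * scale / tot)
  }
  obj <- NULL
  if (inherits(x, "mccu_matrix")) { obj <- x; x <- as.matrix(x$counts) }
  x <- as.matrix(x)
  ct <- cis_totals %||% rowSums(x, na.rm = TRUE)
  if (length(ct) != nrow(x)) stop("cis_totals must have one value per row")
  out <- x * (scale / ct)
  out[ct == 0, ] <- NA_real_
  if (mode == "tiled") {
    if (nrow(out) != ncol(out))
      stop("tiled cis normalization requires a square matrix")
    out <- (out + t(out)) / 2
  }
  if (is.null(obj)) return(out)
  obj$counts <- methods::as(out, "CsparseMatrix")
  obj$normalization <- paste0("cis_", mode)
  obj
}

#' Junction distance spectrum and nucleosomal periodicity
#'
#' Histogram of junction distances `|pos_b - pos_a|` at 1-bp bins over
#' `d_range`, smoothed with a centred moving average, with the dominant
#' period reported as the location of the largest smoothed local maximum
#' beyond 100 bp (internucleosomal linker-linker ligation produces maxima
#' at multiples of the nucleosome repeat length).
#'
#' @param junctions Junction data frame (needs `pos_a`, `pos_b`).
#' @param region Optional `c(start, end)` restriction.
#' @param d_range Distance range in bp (default `c(50, 1000)`).
#' @param smooth_window Moving-average window in bp (odd; default 11).
#' @return List with `histogram` (data frame `distance`, `count`,
#'   `smoothed`), `dominant_period`, `secondary_periods`, `n_junctions`.
#' @export
junction_distance_spectrum <- function(junctions, region = NULL,
                                       d_range = c(50L, 1000L),
                                       smooth_window = 11L) {
  j <- junctions
  if (!is.null(region))
    j <- j[j$pos_a >= region[1] & j$pos_b < region[2], , drop = FALSE]
  if (nrow(j) < 100)
    stop("too few junctions for a distance spectrum: ", nrow(j),
         " (need >= 100)")
  d <- j$pos_b - j$pos_a
  dd <- seq.int(d_range[1], d_range[2])
  counts <- tabulate(d - d_range[1] + 1L, nbins = length(dd))
  half <- smooth_window %/% 2
  sm <- stats::filter(counts, rep(1 / smooth_window, smooth_window),
                      sides = 2)
  sm <- as.numeric(sm)
  interior <- seq.int(half + 2L, length(dd) - half - 1L)
  is_max <- interior[sm[interior] > sm[interior - 1L] &
                     sm[interior] >= sm[interior + 1L]]
  is_max <- is_max[dd[is_max] > 100]
  if (!length(is_max)) {
    dominant <- dd[which.max(sm)]
    secondary <- integer()
  } else {
    ord <- is_max[order(sm[is_max], decreasing = TRUE)]
    dominant <- dd[ord[1]]
    secondary <- dd[ord[-1]]
  }
  list(histogram = data.frame(distance = dd, count = counts, smoothed = sm),
       dominant_period = dominant,
       secondary_periods = head(secondary, 5L),
       n_junctions = nrow(j))
}

#' Write a dense matrix with region metadata, or sparse triplets
#'
#' @param x A `mccu_matrix`.
#' @param path Output path.
#' @param format `"dense"` (TSV with a `#` metadata header) or `"sparse"`
#'   (row, col, value triplets, 1-based).
#' @export
write_matrix <- function(x, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  hdr <- sprintf("# mccu_matrix chrom=%s start=%g end=%g pixel=%g col_pixel=%g norm=%s",
                 x$chrom, x$region[1], x$region[2], x$pixel, x$col_pixel,
                 x$normalization)
  con <- file(path, "w"); writeLines(hdr, con); close(con)
  if (format == "dense") {
    write.table(as.matrix(x$counts), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, append = TRUE)
  } else {
    t3 <- Matrix::summary(methods::as(x$counts, "TsparseMatrix"))
    write.table(data.frame(row = t3$i, col = t3$j, value = t3$x), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#' @param path File path.
#' @param format `"dense"` or `"sparse"`.
#' @return A `mccu_matrix`.
#' @export
read_matrix <- function(path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  body <- read.table(path, sep = "\t", comment.char = "#")
  if (format == "dense") {
    counts <- methods::as(unname(as.matrix(body)), "CsparseMatrix")
  } else {
    n <- ceiling((as.numeric(meta["end"]) - as.numeric(meta["start"])) /
                 as.numeric(meta["pixel"]))
    counts <- Matrix::sparseMatrix(i = body[[1]], j = body[[2]],
                                   x = body[[3]], dims = c(n, n))
  }
  structure(list(counts = counts, chrom = meta[["chrom"]],
                 region = c(as.numeric(meta["start"]),
                            as.numeric(meta["end"])),
                 pixel = as.numeric(meta["pixel"]),
                 col_pixel = as.numeric(meta["col_pixel"]),
                 extended = FALSE, normalization = meta[["norm"]],
                 bias = NULL, masked = NULL),
            class = "mccu_matrix")
}
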