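#' Call and filter viewpoint-profile peaks
#'
#' When given a raw 1D profile, contiguous runs above the local median
#' times `enrichment` become candidate peaks (a deterministic
#' local-enrichment caller); externally supplied peak intervals bypass
#' calling but not filtering. Candidates failing the width window
#' `[min_width, max_width]` or lying closer than `min_distance` bp to the
#' viewpoint are removed.
#'
#' @param profile Either a data frame with columns `pos`, `value`
#'   (a 1-bp-binned viewpoint profile) or a data frame / matrix of peak
#'   intervals (`start`, `end`).
#' @param viewpoint Viewpoint position in bp (or `c(start, end)`, in which
#'   case distance is measured from the interval).
#' @param min_width,max_width Peak width window in bp.
#' @param min_distance Minimum distance from the viewpoint in bp.
#' @param enrichment Local enrichment factor over the running median for
#'   peak calling (default 5).
#' @param median_window Running-median window in bp (odd; default 501).
#' @param chrom Chromosome recorded on the peaks.
#' @return Data frame of peaks: `chrom`, `start`, `end`, `width`,
#'   `distance` (bp from the viewpoint, 0 if overlapping).
#' @export
call_and_filter_peaks <- function(profile, viewpoint, min_width, max_width,
                                  min_distance, enrichment = 5,
                                  median_window = 501L, chrom = "fixture") {
  is_profile <- is.data.frame(profile) && all(c("pos", "value") %in%
                                              names(profile))
  if (is_profile) {
    v <- profile$value
    w <- min(median_window, if (length(v) %% 2 == 0) length(v) - 1
             else length(v))
    if (w %% 2 == 0) w <- w - 1
    loc <- if (w >= 3) stats::runmed(v, w) else rep(median(v), length(v))
    thr <- loc * enrichment
    above <- v > thr & v > 0
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    peaks <- data.frame(start = profile$pos[starts[sel]],
                        end = profile$pos[ends[sel]] + 1L)
  } else {
    peaks <- .as_intervals(profile)
  }
  vp <- range(viewpoint)
  if (!nrow(peaks)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), width = integer(),
                      distance = integer())
    return(out)
  }
  peaks$width <- peaks$end - peaks$start
  peaks$distance <- pmax(0L, pmax(vp[1] - peaks$end + 1L,
                                  peaks$start - vp[2]))
  keep <- peaks$width >= min_width & peaks$width <= max_width &
          peaks$distance >= min_distance
  out <- data.frame(chrom = chrom, peaks[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Compare peak junction counts between conditions
#'
#' Per replicate, each peak's junction count is scaled to counts per
#' `scale` cis-unique junctions of its viewpoint; a Welch two-sample
#' t-test per peak on the normalized replicate counts is
#' Benjamini-Hochberg adjusted, and a peak is flagged as significantly
#' skewed iff `q < alpha` and `|log2fc| > fc_threshold`. The skew is
#' `log2((mean_treated + pc) / (mean_control + pc))` with pseudocount
#' `pc`.
#'
#' @param peaks Peak data frame (needs `start`, `end`).
#' @param junctions_a,junctions_b Lists of junction tables (one per
#'   replicate) for control and treated conditions; a junction is counted
#'   in a peak when either end falls inside it.
#' @param cis_totals_a,cis_totals_b Per-replicate cis-unique junction
#'   totals of the viewpoint (numeric vectors); replicates with a zero
#'   total are masked.
#' @param fc_threshold Absolute log2 fold-change threshold (default 1.5).
#' @param alpha FDR threshold (default 0.05).
#' @param scale Normalization unit (default 1e5).
#' @param pseudocount Pseudocount in normalized units for the skew
#'   (default 0.5).
#' @return The peaks with per-replicate normalized counts, `log2fc`,
#'   `skew`, `p_value`, `q_value`, `significant`.
#' @export
compare_peak_counts <- function(peaks, junctions_a, junctions_b,
                                cis_totals_a, cis_totals_b,
                                fc_threshold = 1.5, alpha = 0.05,
                                scale = 1e5, pseudocount = 0.5) {
  if (length(junctions_a) < 2 || length(junctions_b) < 2)
    stop("at least 2 replicates per condition are required")
  count_peak <- function(j, s, e)
    sum((j$pos_a >= s & j$pos_a < e) | (j$pos_b >= s & j$pos_b < e))
  norm_counts <- function(jl, totals) {
    m <- vapply(seq_along(jl), function(r) {
      raw <- vapply(seq_len(nrow(peaks)), function(k)
        count_peak(jl[[r]], peaks$start[k], peaks$end[k]), numeric(1))
      if (totals[r] == 0) rep(NA_real_, length(raw))
      else raw * scale / totals[r]
    }, numeric(nrow(peaks)))
    matrix(m, nrow = nrow(peaks))
  }
  A <- norm_counts(junctions_a, cis_totals_a)
  B <- norm_counts(junctions_b, cis_totals_b)
  n <- nrow(peaks)
  p <- numeric(n)
  for (k in seq_len(n)) {
    a <- A[k, !is.na(A[k, ])]; b <- B[k, !is.na(B[k, ])]
    p[k] <- if (length(a) < 2 || length(b) < 2 ||
                (stats::var(a) == 0 && stats::var(b) == 0 &&
                 mean(a) == mean(b))) 1
            else tryCatch(t.test(b, a)$p.value, error = function(e) 1)
  }
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  peaks$mean_control <- ma
  peaks$mean_treated <- mb
  peaks$log2fc <- log2((mb + pseudocount) / (ma + pseudocount))
  peaks$skew <- peaks$log2fc
  peaks$p_value <- p
  peaks$q_value <- p.adjust(p, method = "BH")
  peaks$significant <- peaks$q_value < alpha &
                       abs(peaks$log2fc) > fc_threshold
  peaks
}

#' Annotation enrichment of significant vs non-significant peaks
#'
#' Ratio of the fraction of significant peaks intersecting the annotation
#' (>= 1 bp overlap) to the fraction of non-significant peaks doing so,
#' reported as log2. When either fraction is zero a Haldane correction
#' (0.5 added to intersect counts, 1 to totals) keeps the ratio finite
#' and the result is flagged.
#'
#' @param significant,nonsignificant Peak data frames (`start`, `end`).
#' @param annotation Annotation intervals (data frame / matrix, 0-based
#'   half-open).
#' @return List: `log2_ratio`, `frac_significant`, `frac_nonsignificant`,
#'   counts, and `corrected` flag.
#' @export
annotation_enrichment <- function(significant, nonsignificant, annotation) {
  if (!nrow(significant))
    stop("significant peak set is empty; enrichment undefined")
  if (!nrow(nonsignificant))
    stop("non-significant peak set is empty; enrichment undefined")
  ann <- .as_intervals(annotation)
  gr_ann <- GenomicRanges::GRanges("chr", IRanges::IRanges(
    start = ann$start + 1L, end = ann$end))
  hits <- function(p) {
    gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(
      start = p$start + 1L, end = p$end))
    sum(IRanges::overlapsAny(gr, gr_ann))
  }
  ns <- hits(significant); Ns <- nrow(significant)
  nn <- hits(nonsignificant); Nn <- nrow(nonsignificant)
  fs <- ns / Ns; fn <- nn / Nn
  corrected <- fs == 0 || fn == 0
  if (corrected) {
    fs <- (ns + 0.5) / (Ns + 1)
    fn <- (nn + 0.5) / (Nn + 1)
  }
  list(log2_ratio = log2(fs / fn),
       frac_significant = ns / Ns, frac_nonsignificant = nn / Nn,
       n_significant = ns, total_significant = Ns,
       n_nonsignificant = nn, total_nonsignificant = Nn,
       corrected = corrected)
}
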