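#' Build a synthetic chromatin fixture
#'
#' Constructs a reference sequence with an annotated chromatin architecture:
#' nucleosomes tiled at a fixed repeat length over all non-NDR sequence,
#' nucleosome-depleted regions (NDRs), transcription-factor footprints,
#' and CTCF sites. The fixture is the ground truth against which simulated
#' ligation libraries and the downstream pipeline are tested.
#'
#' Coordinates are 0-based half-open throughout. Nucleosome cores occupy
#' 147 bp centred on the dyad; dyads are placed per inter-NDR segment at
#' `segment_start + 73 + phase + i * repeat_length` for all cores that fit.
#' With `phase_mode = "random"` the phase offset is resampled per simulated
#' molecule (individual positions vary, spacing is fixed); the annotation
#' stored in the fixture corresponds to phase 0.
#'
#' @param length Total sequence length in bp (>= 1000).
#' @param repeat_length Nucleosome repeat length (NRL) in bp (>= 157,
#'   i.e. the 147-bp core plus a minimal 10-bp linker).
#' @param ndrs Nucleosome-depleted regions: a two-column matrix or data frame
#'   of 0-based half-open `(start, end)` intervals, sorted, non-overlapping.
#' @param tf_footprints Transcription-factor footprints: data frame with
#'   columns `start`, `end` and optional `label`.
#' @param ctcf_sites Integer vector of CTCF site positions, or a data frame
#'   with columns `pos` and `orientation` (`"+"`/`"-"`).
#' @param phase_mode `"fixed"` (phase 0 for every molecule) or `"random"`
#'   (one uniform phase offset per molecule realization).
#' @param seed Integer seed; the sequence and annotations are reproducible.
#' @return An object of class `mccu_fixture`: a list with elements
#'   `sequence`, `length`, `repeat_length`, `nucleosomes` (data frame of
#'   dyads at phase 0), `ndrs`, `tf_footprints`, `ctcf_sites`,
#'   `phase_mode`, `seed`.
#' @examples
#' fx <- build_fixture(10000, 190, seed = 1)
#' nrow(fx$nucleosomes)  # floor(10000 / 190) = 52
#' @export
build_fixture <- function(length, repeat_length = 190,
                          ndrs = NULL, tf_footprints = NULL,
                          ctcf_sites = NULL,
                          phase_mode = c("fixed", "random"), seed = 1L) {
  phase_mode <- match.arg(phase_mode)
  if (length < 1000) stop("fixture length must be >= 1000 bp")
  if (repeat_length < 157)
    stop("repeat_length must be >= 157 bp (147-bp core + minimal linker)")
  ndrs <- .as_intervals(ndrs)
  if (nrow(ndrs)) {
    if (any(ndrs$start < 0 | ndrs$end > length))
      stop("NDR intervals must lie within [0, length)")
    if (is.unsorted(ndrs$start))
      ndrs <- ndrs[order(ndrs$start), , drop = FALSE]
    if (any(ndrs$end[-nrow(ndrs)] > ndrs$start[-1]))
      stop("NDR intervals overlap; they must be disjoint")
    if (any(ndrs$end <= ndrs$start)) stop("empty NDR interval")
  }
  fp <- .as_intervals(tf_footprints, label = TRUE)
  if (nrow(fp) && any(fp$start < 0 | fp$end > length))
    stop("TF footprint outside sequence bounds")
  ctcf <- .as_ctcf(ctcf_sites)
  if (nrow(ctcf) && any(ctcf$pos < 0 | ctcf$pos >= length))
    stop("CTCF site outside sequence bounds")

  set.seed(seed)
  sequence <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
  dyads <- .tile_dyads(length, repeat_length, ndrs, phase = 0L)
  nucleosomes <- data.frame(dyad = dyads, fixed = phase_mode == "fixed",
                            acetylated = FALSE)
  structure(list(sequence = sequence, length = length,
                 repeat_length = repeat_length, nucleosomes = nucleosomes,
                 ndrs = ndrs, tf_footprints = fp, ctcf_sites = ctcf,
                 phase_mode = phase_mode, seed = seed),
            class = "mccu_fixture")
}

#' @export
print.mccu_fixture <- function(x, ...) {
  cat("mccu_fixture:", x$length, "bp, NRL", x$repeat_length, "bp,",
      nrow(x$nucleosomes), "nucleosomes (phase 0),",
      nrow(x$ndrs), "NDRs,", nrow(x$tf_footprints), "TF footprints,",
      nrow(x$ctcf_sites), "CTCF sites, phase", x$phase_mode, "\n")
  invisible(x)
}

#' Lay out a regular nucleosome array
#'
#' Pure arithmetic helper giving the dyad positions and total span of a
#' regular array of `n_nucleosomes` at the given repeat length, as used to
#' describe chromatin templates for biophysical modelling (e.g. a
#' 16-nucleosome array at a 190-bp NRL spans 3,040 bp).
#'
#' @param n_nucleosomes Number of nucleosomes (>= 1).
#' @param repeat_length Repeat length in bp (>= 157).
#' @return A list with `dyads` (0-based positions) and `span` (bp).
#' @examples
#' layout_nucleosome_array(16, 190)$span  # 3040
#' @export
layout_nucleosome_array <- function(n_nucleosomes, repeat_length = 190) {
  if (n_nucleosomes < 1) stop("n_nucleosomes must be positive")
  if (repeat_length < 157) stop("repeat_length must be >= 157 bp")
  dyads <- floor(repeat_length / 2) + (seq_len(n_nucleosomes) - 1L) * repeat_length
  list(dyads = as.integer(dyads), span = as.integer(n_nucleosomes * repeat_length))
}

# --- internal helpers -------------------------------------------------------

.as_intervals <- function(x, label = FALSE) {
  if (is.null(x)) {
    out <- data.frame(start = integer(), end = integer())
  } else if (is.matrix(x)) {
    out <- data.frame(start = as.integer(x[, 1]), end = as.integer(x[, 2]))
  } else if (is.data.frame(x)) {
    out <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
    if (label && !is.null(x$label)) out$label <- as.character(x$label)
  } else if (is.numeric(x) && length(x) == 2) {
    out <- data.frame(start = as.integer(x[1]), end = as.integer(x[2]))
  } else stop("intervals must be a matrix or data frame with start/end")
  if (label && is.null(out$label))
    out$label <- if (nrow(out)) paste0("fp", seq_len(nrow(out))) else character()
  out
}

.as_ctcf <- function(x) {
  if (is.null(x)) return(data.frame(pos = integer(), orientation = character()))
  if (is.data.frame(x))
    return(data.frame(pos = as.integer(x$pos),
                      orientation = as.character(
                        if (is.null(x$orientation)) "+" else x$orientation)))
  data.frame(pos = as.integer(x), orientation = rep("+", length(x)))
}

# Dyad positions for a given phase offset: tile each inter-NDR segment.
.tile_dyads <- function(length, repeat_length, ndrs, phase = 0L) {
  bounds <- c(0L, as.vector(t(as.matrix(ndrs[, c("start", "end")]))), length)
  segs <- matrix(bounds, ncol = 2, byrow = TRUE)  # non-NDR segments
  dyads <- integer()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1]; e <- segs[i, 2]
    d0 <- s + 73L + phase
    if (d0 + 74L > e) next
    k <- (e - 74L - d0) %/% repeat_length
    dyads <- c(dyads, d0 + (0:k) * repeat_length)
  }
  as.integer(dyads)
}

# CTCF sites are treated as protein footprints of this width for the
# MNase cut model (protected core, enhanced flanks).
.ctcf_footprint_halfwidth <- 9L

# Combined protein footprints (TF + CTCF) as intervals.
.protein_footprints <- function(fixture) {
  fp <- fixture$tf_footprints[, c("start", "end"), drop = FALSE]
  if (nrow(fixture$ctcf_sites)) {
    hw <- .ctcf_footprint_halfwidth
    cf <- data.frame(start = pmax(fixture$ctcf_sites$pos - hw, 0L),
                     end = pmin(fixture$ctcf_sites$pos + hw + 1L,
                                fixture$length))
    fp <- rbind(fp, cf)
  }
  fp
}

#' Per-bp MNase cut weights for every nucleosome phase
#'
#' Cut weight is 0 inside 147-bp nucleosome cores and inside protein
#' footprints (TF footprints and an implicit 19-bp footprint at each CTCF
#' site), `flank_weight` in the `flank_width` bp flanking each footprint
#' edge (MNase cuts are enhanced around bound proteins), and 1 elsewhere
#' (linkers and NDR interiors).
#'
#' @param fixture A [build_fixture()] object.
#' @param flank_width Width in bp of the enhanced-cut flank at footprint
#'   edges (default 5).
#' @param flank_weight Relative cut weight in footprint flanks (default 4).
#' @return A list with `w` (length x n_phase weight matrix), `phases`
#'   (offsets represented by the columns), `ndr_id`, `ctcf_id`, `in_ndr`,
#'   `domain` (per-bp vectors), `is_linker` (length x n_phase logical matrix), and
#'   `flank_dir` (per-bp -1/0/+1: direction of the adjacent footprint).
#' @keywords internal
#' @export
cut_weight_profile <- function(fixture, flank_width = 5L, flank_weight = 4) {
  L <- fixture$length
  nph <- if (fixture$phase_mode == "random") fixture$repeat_length else 1L
  base <- rep(1, L)
  fp <- .protein_footprints(fixture)
  flank_dir <- integer(L)
  for (i in seq_len(nrow(fp))) {
    s <- fp$start[i]; e <- fp$end[i]
    base[(s + 1):e] <- 0                      # footprint core protected
    lf <- max(s - flank_width, 0L); rf <- min(e + flank_width, L)
    if (lf < s) { base[(lf + 1):s] <- flank_weight
                  flank_dir[(lf + 1):s] <- 1L }   # footprint to the right
    if (e < rf) { base[(e + 1):rf] <- flank_weight
                  flank_dir[(e + 1):rf] <- -1L }  # footprint to the left
  }
  ndr_id <- integer(L)
  for (i in seq_len(nrow(fixture$ndrs)))
    ndr_id[(fixture$ndrs$start[i] + 1):fixture$ndrs$end[i]] <- i
  ctcf_id <- integer(L)
  for (i in seq_len(nrow(fixture$ctcf_sites))) {
    p <- fixture$ctcf_sites$pos[i]
    ctcf_id[max(p - 10, 0):min(p + 10, L - 1) + 1] <- i
  }
  in_ndr <- ndr_id > 0
  # nanoscale domains partitioned at NDR midpoints
  mids <- if (nrow(fixture$ndrs))
    as.integer((fixture$ndrs$start + fixture$ndrs$end) / 2) else integer()
  domain <- findInterval(seq_len(L) - 1L, mids)
  w <- matrix(0, nrow = L, ncol = nph)
  is_linker <- matrix(FALSE, nrow = L, ncol = nph)
  flank_mask <- base != 1 | in_ndr
  for (j in seq_len(nph)) {
    ph <- j - 1L
    dy <- .tile_dyads(L, fixture$repeat_length, fixture$ndrs, phase = ph)
    wj <- base
    for (d in dy) wj[max(d - 73, 0):min(d + 73, L - 1) + 1] <- 0
    w[, j] <- wj
    is_linker[, j] <- wj > 0 & !flank_mask
  }
  list(w = w, phases = 0:(nph - 1L), ndr_id = ndr_id, ctcf_id = ctcf_id,
       in_ndr = in_ndr, domain = domain, is_linker = is_linker,
       flank_dir = flank_dir)
}
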