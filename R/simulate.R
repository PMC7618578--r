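#' Define a contact model for the ligation simulator
#'
#' The probability that two MNase cut sites `a`, `b` ligate is proportional
#' to `w(a) * w(b) * d(a,b)^-decay_exponent` times multiplicative factors
#' for pair classes: both sites in the same nanoscale domain (domains are
#' delimited by NDR midpoints), sites in two different NDRs (punctate
#' NDR-NDR contacts), sites at two different CTCF sites (CTCF-CTCF
#' loops), and both sites in internucleosomal linkers (periodic
#' linker-linker ligation).
#'
#' @param background_rate Baseline per-bp-pair weight (> 0).
#' @param within_domain_factor,ndr_pair_factor,ctcf_pair_factor,linker_periodic_factor
#'   Multiplicative enrichment factors, all >= 1.
#' @param decay_exponent Power-law distance-decay exponent (>= 0).
#' @param min_distance Distance floor (bp) below which decay is flat.
#' @return An object of class `mccu_contact_model`.
#' @export
contact_model <- function(background_rate = 1,
                          within_domain_factor = 1,
                          ndr_pair_factor = 1,
                          ctcf_pair_factor = 1,
                          linker_periodic_factor = 1,
                          decay_exponent = 1,
                          min_distance = 20L) {
  f <- c(within_domain_factor, ndr_pair_factor, ctcf_pair_factor,
         linker_periodic_factor)
  if (any(!is.finite(f)) || any(f < 1))
    stop("all contact-model factors must be finite and >= 1")
  if (background_rate < 0 || !is.finite(background_rate))
    stop("background_rate must be finite and nonnegative")
  structure(list(background_rate = background_rate,
                 within_domain_factor = within_domain_factor,
                 ndr_pair_factor = ndr_pair_factor,
                 ctcf_pair_factor = ctcf_pair_factor,
                 linker_periodic_factor = linker_periodic_factor,
                 decay_exponent = decay_exponent,
                 min_distance = as.integer(min_distance)),
            class = "mccu_contact_model")
}

#' @export
print.mccu_contact_model <- function(x, ...) {
  cat("mccu_contact_model: decay", x$decay_exponent,
      "| domain", x$within_domain_factor, "| NDR", x$ndr_pair_factor,
      "| CTCF", x$ctcf_pair_factor, "| linker", x$linker_periodic_factor, "\n")
  invisible(x)
}

#' Simulate proximity-ligation events on a fixture
#'
#' Draws chimeric 3C molecules from a fixture under a contact model. Each
#' molecule is the concatenation of 2 (with probability `p_threeway`, 3)
#' genomic fragments whose ends are MNase cut sites. Cut sites are drawn
#' only from linkers, NDR interiors, and footprint flanks (never inside a
#' 147-bp nucleosome core or a protein footprint); in `phase_mode =
#' "random"` fixtures the nucleosome phase is resampled per molecule. At a
#' footprint flank the protected (footprint-containing) side is retained
#' with probability `p_protected_side`, which generates the corner-pattern
#' geometry around protein-protein contacts.
#'
#' Truth records use the same junction convention as the caller: the
#' coordinate pair is the genomic base at the 3' end (in read orientation)
#' of the upstream fragment and the 5' start of the downstream fragment,
#' 0-based, canonically sorted so `pos_a <= pos_b` with the direction flags
#' swapped together with the positions.
#'
#' @param fixture A [build_fixture()] object.
#' @param model A [contact_model()].
#' @param n_events Number of molecules to simulate (>= 1).
#' @param seed Integer seed.
#' @param p_threeway Probability of a third ligated fragment (default 0.1).
#' @param p_protected_side Probability that a footprint-flank cut retains
#'   the footprint-protected side (default 0.9).
#' @param frag_min,frag_max MNase fragment extent window in bp used to
#'   sample the far (non-ligated) end of each fragment.
#' @return An object of class `mccu_library`: list with `molecules`
#'   (data frame: `molecule`, `sequence`), `truth` (data frame of true
#'   junctions: `molecule`, `junction`, `pos_a`, `pos_b`, `dir_a`,
#'   `dir_b`, `offset` = junction position within the molecule), and
#'   `fixture`.
#' @export
simulate_ligation_events <- function(fixture, model, n_events, seed = 1L,
                                     p_threeway = 0.1,
                                     p_protected_side = 0.9,
                                     frag_min = 100L, frag_max = 250L) {
  stopifnot(inherits(fixture, "mccu_fixture"),
            inherits(model, "mccu_contact_model"))
  if (n_events < 1) stop("n_events must be >= 1")
  prof <- cut_weight_profile(fixture)
  if (all(prof$w == 0)) stop("all cut/model weights are zero")
  set.seed(seed)
  L <- fixture$length
  nph <- ncol(prof$w)
  phase <- if (nph > 1) sample.int(nph, n_events, replace = TRUE) - 1L
           else rep(0L, n_events)
  a <- integer(n_events)
  for (j in unique(phase)) {
    sel <- which(phase == j)
    a[sel] <- sample.int(L, length(sel), replace = TRUE,
                         prob = prof$w[, j + 1L]) - 1L
  }
  b <- cpp_sample_partners(a, phase, prof$w, prof$domain, prof$ndr_id,
                           prof$ctcf_id, prof$is_linker,
                           model$within_domain_factor, model$ndr_pair_factor,
                           model$ctcf_pair_factor,
                           model$linker_periodic_factor,
                           model$decay_exponent, model$min_distance)
  three <- runif(n_events) < p_threeway
  # fragment side at each cut: -1 fragment extends left, +1 right;
  # boundary-clamped so fragments are never empty
  pick_side <- function(pos) {
    fd <- prof$flank_dir[pos + 1L]
    s <- ifelse(runif(length(pos)) < 0.5, -1L, 1L)
    prot <- fd != 0L & runif(length(pos)) < p_protected_side
    s[prot] <- fd[prot]
    s[pos < frag_min] <- 1L
    s[pos > L - 1L - frag_min] <- -1L
    s
  }
  side_a <- pick_side(a)
  side_b <- pick_side(b)
  far_a <- cpp_sample_frag_ends(a, side_a, phase, prof$w, frag_min, frag_max)
  far_b <- cpp_sample_frag_ends(b, side_b, phase, prof$w, frag_min, frag_max)
  idx3 <- which(three)
  c3 <- side_c <- far_c <- integer(0)
  if (length(idx3)) {
    c3 <- cpp_sample_partners(far_b[idx3], phase[idx3], prof$w, prof$domain,
                              prof$ndr_id, prof$ctcf_id, prof$is_linker,
                              model$within_domain_factor,
                              model$ndr_pair_factor, model$ctcf_pair_factor,
                              model$linker_periodic_factor,
                              model$decay_exponent, model$min_distance)
    side_c <- pick_side(c3)
    far_c <- cpp_sample_frag_ends(c3, side_c, phase[idx3], prof$w,
                                  frag_min, frag_max)
  }
  # fragment chains (vectorized): F1 ligated at a, F2 at b (+ F3 at c3)
  s1 <- ifelse(side_a < 0, far_a, a); e1 <- ifelse(side_a < 0, a, far_a)
  fwd1 <- side_a < 0
  s2 <- ifelse(side_b > 0, b, far_b); e2 <- ifelse(side_b > 0, far_b, b)
  fwd2 <- side_b > 0
  p1 <- substring(fixture$sequence, s1 + 1L, e1)
  p2 <- substring(fixture$sequence, s2 + 1L, e2)
  if (any(!fwd1)) p1[!fwd1] <- .revcomp(p1[!fwd1])
  if (any(!fwd2)) p2[!fwd2] <- .revcomp(p2[!fwd2])
  seqs <- paste0(p1, p2)
  truth <- .junction_truth(seq_len(n_events), 1L, s1, e1, fwd1, s2, e2, fwd2,
                           offset = e1 - s1, refseq = fixture$sequence)
  if (length(idx3)) {
    s3 <- ifelse(side_c > 0, c3, far_c); e3 <- ifelse(side_c > 0, far_c, c3)
    fwd3 <- side_c > 0
    p3 <- substring(fixture$sequence, s3 + 1L, e3)
    if (any(!fwd3)) p3[!fwd3] <- .revcomp(p3[!fwd3])
    seqs[idx3] <- paste0(seqs[idx3], p3)
    truth2 <- .junction_truth(idx3, 2L, s2[idx3], e2[idx3], fwd2[idx3],
                              s3, e3, fwd3,
                              offset = (e1 - s1)[idx3] + (e2 - s2)[idx3],
                              refseq = fixture$sequence)
    truth <- rbind(truth, truth2)
  }
  truth <- truth[order(truth$molecule, truth$junction), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(molecules = data.frame(molecule = seq_len(n_events),
                                        sequence = seqs),
                 truth = truth, fixture = fixture),
            class = "mccu_library")
}

# Micro-homology at a junction: length of the common prefix of the
# upstream fragment's genomic continuation (in read orientation) and the
# downstream fragment's read-oriented sequence. The junction caller
# assigns ambiguous bases to the upstream sub-read, so truth coordinates
# are resolved under the same convention.
.microhomology <- function(refseq, sl, el, fwdl, sr, er, fwdr, hmax = 12L) {
  L <- nchar(refseq)
  a <- ifelse(fwdl,
              substring(refseq, el + 1L, pmin(el + hmax, L)),
              .revcomp(substring(refseq, pmax(sl - hmax, 0L) + 1L, sl)))
  b <- ifelse(fwdr,
              substring(refseq, sr + 1L, pmin(sr + hmax, L)),
              .revcomp(substring(refseq, pmax(er - hmax, 0L) + 1L, er)))
  h <- integer(length(a))
  alive <- rep(TRUE, length(a))
  for (p in seq_len(hmax)) {
    ap <- substring(a, p, p); bp <- substring(b, p, p)
    alive <- alive & ap != "" & bp != "" & ap == bp
    h <- h + as.integer(alive)
  }
  h
}

# canonical truth junctions between an upstream and downstream fragment
.junction_truth <- function(mol, jidx, sl, el, fwdl, sr, er, fwdr, offset,
                            refseq) {
  h <- .microhomology(refseq, sl, el, fwdl, sr, er, fwdr)
  pl <- ifelse(fwdl, el - 1L + h, sl - h)
  dl <- ifelse(fwdl, "toward_upstream", "toward_downstream")
  pr <- ifelse(fwdr, sr + h, er - 1L - h)
  dr <- ifelse(fwdr, "toward_downstream", "toward_upstream")
  swap <- pl > pr
  data.frame(molecule = mol, junction = jidx,
             pos_a = ifelse(swap, pr, pl), pos_b = ifelse(swap, pl, pr),
             dir_a = ifelse(swap, dr, dl), dir_b = ifelse(swap, dl, dr),
             offset = offset)
}

#' @export
print.mccu_library <- function(x, ...) {
  cat("mccu_library:", nrow(x$molecules), "molecules,",
      nrow(x$truth), "true junctions\n")
  invisible(x)
}

#' Render a sequencing library from simulated molecules
#'
#' Sonication breaks each molecule into fragments with lengths drawn from
#' Normal(`mean_fragment`, `fragment_sd`) truncated to `[100, 320]` bp
#' (molecules no longer than 320 bp stay intact); each fragment yields one
#' paired-end read (R2 reverse-complemented). The truth table links read
#' ids to the junctions each fragment carries: a junction is `intact` when
#' it retains at least `min_flank` bp on both sides within its fragment
#' and the fragment is short enough for full overlap reconstruction;
#' junctions cut too close to a sonication breakpoint are flagged
#' `truncated`, and junctions falling outside every emitted fragment are
#' flagged `destroyed`.
#'
#' @param library A [simulate_ligation_events()] object, or a data frame
#'   with columns `molecule` and `sequence` (the truth table is then NULL).
#' @param mean_fragment,fragment_sd Sonication fragment length model (bp).
#' @param read_length Read length in bp (>= 50).
#' @param error_rate Uniform substitution error rate in `[0, 0.1]`.
#' @param duplication_rate Probability that a fragment is re-emitted as an
#'   exact PCR duplicate (default 0).
#' @param min_flank Minimum bp on each side of a junction within its
#'   fragment for the junction to count as recoverable (default 20).
#' @param min_overlap Minimum read overlap assumed for full-length
#'   reconstruction, used only to flag over-long fragments (default 10).
#' @param seed Integer seed.
#' @return A list of class `mccu_reads`: `r1`, `r2` (data frames `id`,
#'   `seq`, `qual`), `fragments` (read id, molecule, molecule-interval of
#'   the fragment, duplicate flag), and `truth` (simulated junctions with
#'   `read_id` and `status`).
#' @export
render_sequencing_library <- function(library, mean_fragment = 200,
                                      fragment_sd = 40, read_length = 150L,
                                      error_rate = 0, duplication_rate = 0,
                                      min_flank = 20L, min_overlap = 10L,
                                      seed = 1L) {
  mols <- if (inherits(library, "mccu_library")) library$molecules
          else library
  truth0 <- if (inherits(library, "mccu_library")) library$truth else NULL
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  if (read_length < 50) stop("read_length must be >= 50 bp")
  if (mean_fragment < read_length / 2)
    stop("mean_fragment must be >= read_length / 2")
  set.seed(seed)
  frag <- .sonicate(mols, mean_fragment, fragment_sd)
  if (duplication_rate > 0) {
    dup <- frag[runif(nrow(frag)) < duplication_rate, , drop = FALSE]
    if (nrow(dup)) {
      dup$id <- paste0(dup$id, "d")
      dup$duplicate <- TRUE
      frag <- rbind(frag, dup)
    }
  }
  fseq <- substring(mols$sequence[match(frag$molecule, mols$molecule)],
                    frag$fs + 1L, frag$fe)
  r1 <- substring(fseq, 1L, pmin(read_length, nchar(fseq)))
  r2 <- .revcomp(substring(fseq, pmax(nchar(fseq) - read_length + 1L, 1L),
                           nchar(fseq)))
  if (error_rate > 0) {
    r1 <- .add_errors(r1, error_rate)
    r2 <- .add_errors(r2, error_rate)
  }
  truth <- .link_truth(truth0, frag, read_length, min_flank, min_overlap)
  structure(list(r1 = data.frame(id = frag$id, seq = r1,
                                 qual = strrep("I", nchar(r1))),
                 r2 = data.frame(id = frag$id, seq = r2,
                                 qual = strrep("I", nchar(r2))),
                 fragments = frag, truth = truth),
            class = "mccu_reads")
}

#' @export
print.mccu_reads <- function(x, ...) {
  cat("mccu_reads:", nrow(x$r1), "read pairs from",
      length(unique(x$fragments$molecule)), "molecules\n")
  invisible(x)
}

.sonicate <- function(mols, mean_fragment, fragment_sd) {
  len <- nchar(mols$sequence)
  ml <- vector("list", nrow(mols))
  for (i in seq_len(nrow(mols))) {
    n <- len[i]
    cuts <- integer(0)
    pos <- 0L
    while (n - pos > 320L) {
      l <- as.integer(round(.rtruncnorm1(mean_fragment, fragment_sd,
                                         100, 320)))
      if (n - (pos + l) < 50L) { pos <- pos + l; break }
      pos <- pos + l
      cuts <- c(cuts, pos)
    }
    ml[[i]] <- cuts
  }
  nf <- lengths(ml) + 1L
  molecule <- rep(mols$molecule, nf)
  fs <- unlist(lapply(seq_along(ml), function(i) c(0L, ml[[i]])),
               use.names = FALSE)
  fe <- unlist(lapply(seq_along(ml), function(i) c(ml[[i]], len[i])),
               use.names = FALSE)
  fragidx <- unlist(lapply(nf, seq_len), use.names = FALSE)
  keep <- fe - fs >= 50L
  frag <- data.frame(molecule = molecule[keep], frag = fragidx[keep],
                     fs = fs[keep], fe = fe[keep])
  frag$id <- paste0("m", frag$molecule, "_f", frag$frag)
  frag$duplicate <- FALSE
  frag
}

.rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

.add_errors <- function(seqs, rate) {
  n <- nchar(seqs)
  vapply(seq_along(seqs), function(i) {
    k <- rbinom(1, n[i], rate)
    if (k == 0) return(seqs[i])
    pos <- sample.int(n[i], k)
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    paste(s, collapse = "")
  }, character(1))
}

.link_truth <- function(truth0, frag, read_length, min_flank, min_overlap) {
  if (is.null(truth0) || !nrow(truth0)) return(NULL)
  base <- frag[!frag$duplicate, , drop = FALSE]
  bymol <- split(seq_len(nrow(base)), base$molecule)
  truth <- truth0
  truth$read_id <- NA_character_
  truth$status <- "destroyed"
  key <- as.character(truth$molecule)
  for (i in seq_len(nrow(truth))) {
    rows <- bymol[[key[i]]]
    if (is.null(rows)) next
    o <- truth$offset[i]
    hit <- rows[base$fs[rows] < o & base$fe[rows] > o]
    if (!length(hit)) next
    f <- hit[1]
    truth$read_id[i] <- base$id[f]
    ok <- (o - base$fs[f]) >= min_flank && (base$fe[f] - o) >= min_flank &&
          (base$fe[f] - base$fs[f]) <= 2L * read_length - min_overlap
    truth$status[i] <- if (ok) "intact" else "truncated"
  }
  truth
}
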