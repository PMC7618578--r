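---
title: "Base-pair-resolution Micro-Capture-C analysis with mccutools"
author: "mccutools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-pair-resolution Micro-Capture-C analysis with mccutools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mccutools)
```

## The measurement

Micro-Capture-C ultra (MCCu) is an MNase-based chromosome conformation
capture assay read out at single-base resolution. Chromatin is fixed,
digested with micrococcal nuclease — which cuts accessible DNA but not
DNA protected by nucleosome cores or bound proteins — and proximity
ligated. Sonicating the 3C library to roughly 200 bp and sequencing with
150-bp paired-end reads lets the full fragment sequence be reconstructed
by overlap merging, so the chimeric joint created by ligation (the
*ligation junction*) can be located to the exact base. A 5-kb region at
1-bp pixels is a 5,000 x 5,000 matrix in which every row is the profile
of an individual single-base viewpoint; resolving it requires both deep
capture enrichment and the junction-level bookkeeping this package
implements.

`mccutools` covers the computational side of the assay end to end:

1. a ground-truthed simulator of MCCu sequencing libraries
   (`build_fixture()`, `contact_model()`, `simulate_ligation_events()`,
   `render_sequencing_library()`);
2. read reconstruction: overlap merging, capture pre-filtering, and
   splitting reads into genome-collinear sub-reads
   (`merge_read_pairs()`, `prefilter_capture_reads()`,
   `split_and_map_subreads()`);
3. junction calling with orientation flags and PCR deduplication
   (`call_junctions()`, `deduplicate_junctions()`);
4. contact matrices at arbitrary pixel size with ICE and cis
   normalization, and the junction distance spectrum
   (`build_contact_matrix()`, `ice_normalize()`, `cis_normalize()`,
   `junction_distance_spectrum()`);
5. contact sequence reconstruction from junction directionality
   (`build_directional_matrix()`, `reconstruct_contact_sequences()`);
6. block-level differential testing of base-pair matrices ("basepairC";
   `preprocess_counts()`, `segment_blocks()`, `refine_blocks()`,
   `test_blocks()`);
7. viewpoint peak comparison and annotation enrichment
   (`call_and_filter_peaks()`, `compare_peak_counts()`,
   `annotation_enrichment()`), and capture oligo tiling design
   (`design_capture_tiling()`).

All coordinates are 0-based half-open internally; text reports state
their convention in a header line.

## The simulator and what it emulates

The simulator exists so that every downstream stage can be tested
against exact ground truth. A fixture (`build_fixture()`) is a random
DNA sequence annotated with chromatin architecture: nucleosomes tiled
at a fixed repeat length (NRL; default 190 bp, minimum 157 bp = 147-bp
core + 10-bp linker) over all non-NDR sequence, nucleosome-depleted
regions (NDRs), transcription-factor footprints, and CTCF sites. With
`phase_mode = "random"` the tiling phase is resampled for every
simulated molecule: individual nucleosome positions vary while the
internucleosomal spacing stays fixed, which is the configuration that
produces the characteristic ~NRL periodicity of inactive chromatin.

MNase cutting is modelled as a per-bp weight: 0 inside 147-bp cores and
protein footprints, 1 in linkers and NDR interiors, and 4 in the 5 bp
flanking each footprint edge. The flank enhancement emulates the
observed concentration of MNase cuts around bound transcription
factors; its width and weight are free parameters of
`cut_weight_profile()` because the enhancement is not quantified in the
literature — the defaults are our choice of a visible but not dominant
bias. CTCF sites are treated as 19-bp protein footprints for the cut
model.

Ligation partners are drawn with probability proportional to
`w(a) * w(b) * d^(-gamma)` times class factors from `contact_model()`:
a within-domain factor (nanoscale domains delimited by NDR midpoints),
an NDR-pair factor applied to sites in two *different* NDRs (the
punctate NDR-NDR contacts), a CTCF-pair factor for two different CTCF
sites, and a linker-periodic factor for linker-linker pairs. Applying
the NDR and CTCF factors only across distinct elements, not within one
element, is deliberate: the biology these factors encode is contact
*between* regulatory elements, and a within-element boost would be
indistinguishable from the short-range background. The distance-decay
exponent defaults to 1, the conventional contact-frequency decay in the
sub-megabase regime.

Each molecule is 2 fragments (3 with probability 0.1 — multi-way
ligation rates are not reported, so the rate is an exposed parameter).
Fragment extents are drawn from cut sites 100-250 bp from the ligated
end, giving roughly mononucleosomal MNase fragments. At a footprint
flank, the footprint-protected side is retained with probability 0.9,
which is what creates the corner-pattern quartet around
protein-protein contacts. Sonication breaks molecules into fragments
with Normal(200, 40) lengths truncated to [100, 320] bp, and each
fragment yields a 150-bp read pair; substitution errors (no indels) at
a configurable rate.

One subtlety deserves a note because it dominated junction-calling
accuracy during development: **micro-homology at junctions**. When the
first bases of the downstream fragment happen to equal the genomic
continuation of the upstream fragment, the breakpoint position inside
the read is genuinely ambiguous. The caller resolves it
deterministically by assigning ambiguous bases to the upstream
(left-in-read) sub-read and flagging both sub-reads. The simulator's
truth records apply the same convention, so "base-exact" means exact
under the stated tie-break — the only definition under which base
exactness is measurable at all.

What the simulator does **not** emulate: realistic base composition or
mappability structure (the fixture is uniform random, so the k-mer
mapper operates in a friendlier regime than a repetitive genome);
ligation-bias chemistry; trans-chromosomal contacts; PCR duplicates
beyond exact re-emission; indel sequencing errors. Passing tests on
simulated data therefore demonstrate the correctness of the algorithms
under the stated generative model, not pipeline performance on
repetitive real genomes — for real data the SAM ingestion path
(`read_subreads_sam()`) accepts sub-reads from an external aligner.

## Read reconstruction and junction calling

`merge_read_pairs()` is a FLASH-style best-overlap merger: the suffix
of R1 is aligned against the prefix of the reverse complement of R2 at
every overlap length >= `min_overlap` (default 10 bp); the overlap with
the best score (overlap length minus 5 per mismatch) is accepted when
its mismatch rate is at most `max_mismatch_rate` (default 0.25), and
disagreeing bases take the higher-quality call. With 150-bp reads on
fragments truncated at 320 bp, fragments up to 290 bp can merge; under
the Normal(200, 40) sonication model that is about 99% of fragments,
comfortably reproducing the >90% reconstruction rate the assay relies
on.

`split_and_map_subreads()` replaces the two-stage external alignment
(a permissive aligner to locate capture reads, then a standard aligner
for sub-reads) with a single built-in seeded mapper: maximal exact
20-mer diagonal runs are chained, runs on one diagonal are merged
across at most `max_mismatches = 2` substitutions, and the read is
partitioned at the remaining breakpoints; sub-reads shorter than
`min_subread = 20` bp are dropped. The thresholds are documented
defaults, not values taken from any published pipeline configuration.
This mapper is exact-seed based and ungapped, which is adequate for
desk-scale fixtures and keeps the test suite free of external binary
dependencies.

Junction coordinates are the two cut-adjacent bases themselves: the
genomic base at the 3' end (in read orientation) of the upstream
sub-read and the 5' start of the downstream sub-read. This convention
makes the corner geometry around protected contacts reproducible at
1 bp. Each side carries a direction flag (`toward_upstream` /
`toward_downstream`) recording on which side of the cut the protected,
sequenced fragment lies — the information that contact sequence
reconstruction uses. PCR deduplication collapses on the full key
(positions, both direction flags, and the read's outermost aligned
coordinates): two molecules ligated in opposite orientations at the
same coordinates are distinct events, and two molecules with identical
junctions but different sonication ends are independent captures.

## Matrices and normalization

Square matrices store both orientations of every junction, so raw cis
matrices are symmetric; at 1-bp pixels the upper triangle plus diagonal
sums to the junction count, and a junction whose two ends fall into one
coarse diagonal pixel is counted in both orientations there, which
makes a 10-bp matrix exactly the 10 x 10 aggregation of the 1-bp
matrix. Extended maps keep fine rows over the viewpoint region and
coarse (default 500 bp) genome-wide columns — the hybrid between a
viewpoint profile and a genome-wide map.

`ice_normalize()` performs iterative correction with a coverage mask:
rows below the 0.02 quantile of nonzero coverage are masked (the common
convention for sparse matrices), and the matrix is symmetrically
rescaled by inverse square-root row sums until the maximum relative
row-sum deviation is below `tol = 1e-5` (at most 200 iterations; a
warning flags non-convergence, and the partially balanced result is
still returned). The bias vector satisfies `raw = b %o% b * balanced`
exactly on unmasked entries, and balancing a balanced matrix is a
no-op within tolerance.

`cis_normalize()` scales each viewpoint row to counts per 1e5
cis-unique junctions of that viewpoint, correcting oligo
capture-efficiency differences. Tiled mode applies the same row scaling
and then symmetrizes by averaging with the transpose; the exact tiled
formula is not published, and row-scale-then-symmetrize is our
documented interpretation. Rows with zero cis totals are masked, never
divided.

`junction_distance_spectrum()` histograms junction distances at 1-bp
bins (default range 50-1000 bp), smooths with an 11-bp centred moving
average — wide enough to suppress single-bp cut-bias spikes, narrow
enough not to shift a ~185-bp maximum — and reports the location of the
largest smoothed local maximum beyond 100 bp as the dominant period.
On a random-phase fixture the dominant period recovers the simulated
NRL: linker-to-linker ligation spaces junctions at multiples of the
repeat length even though no individual nucleosome has a fixed
position.

## Contact sequence reconstruction

MNase cuts *outside* protein footprints, so a contact between two bound
proteins shows up as four junction clusters at the corners surrounding
the protected contact point. Because the protected sequence is the
sequenced fragment adjacent to the cut, the direction flags say on
which side of each cut the protein sat. `build_directional_matrix()`
splits junctions into four orientation channels;
`reconstruct_contact_sequences()` smears each channel along each axis
over a `footprint`-length window (default 20 bp, a typical
transcription-factor footprint) extending from the cut in the direction
of the protecting footprint, then sums the channels. The corner quartet
collapses onto the footprint pair. Signal is conserved except at region
edges, where windows are truncated. A uniform window is the default; a
triangular kernel (weight decreasing with distance from the cut) is
available because the underlying protein extent is uncertain —
reconstruction details are not published, and the directional-window
smear is this package's documented interpretation. Junction sets with
random directions reconstruct to a plain symmetric blur, so directional
structure in the output is evidence, not artifact. Reconstructed maps
are displayed with cis normalization.

## basepairC: differential testing of base-pair matrices

Replicated 1-bp count matrices are compared block-wise:

1. **Preprocessing** (`preprocess_counts()`): pixels whose
   all-replicate maximum is below `low_count = 2` are masked; values
   above the 0.999 quantile of the pooled nonzero distribution are
   winsorized; each replicate is scaled to the median replicate total;
   each pixel `(i, j)` is divided by the product of normalized MNase
   cut propensities `c_i * c_j` (a supplied cut profile, or the pooled
   matrix marginals when none is given) and the grand total is
   restored. The marginal estimate deliberately removes *all*
   row/column structure, including genuine viewpoint structure — supply
   a measured cut profile when that matters.
2. **Segmentation** (`segment_blocks()`): binary segmentation with a
   squared-error cost on the row-margin and column-margin profiles of
   the mean-difference grid, penalized by `3 * log(n) * sigma^2` with
   sigma estimated from first differences. The factor 3 was chosen by a
   null/alternative split-rate simulation (0/200 false splits on white
   noise, 93% detection of a 1-sd jump at n = 100); the textbook BIC
   factor 2 splits pure noise a few percent of the time. Blocks are the
   cross product of the two 1D segmentations, tiling the matrix, with a
   minimum side of 10 pixels where feasible and at most 50 changepoints
   per axis. The published description names a joint-segmentation
   package without a formula; crossed-1D binary segmentation is the
   concrete, swappable choice here.
3. **Refinement** (`refine_blocks()`): block mean signals are
   soft-thresholded against `lasso_penalty` times the pooled noise
   scale (the MAD of nonzero pixel values); blocks shrunk to zero are
   dropped as low count. Within retained blocks in the top decile of
   total counts, a tensor-product spline (`mgcv::gam`, `te()` with
   `smooth_df = 5` basis functions per axis) of log counts provides
   per-pixel expected values; at test time, pixel values in those
   blocks are capped at the expectation plus three Poisson standard
   deviations, damping isolated extreme pixels. The LASSO design and
   smooth basis are likewise parameterized interpretations rather than
   published formulas.
4. **Testing** (`test_blocks()` / `fit_zinb_block()`): per block, the
   per-replicate block count sums follow a zero-inflated negative
   binomial with identity-link mean `b0 + b1 * condition`, a common
   dispersion, and a condition-independent structural-zero probability
   (one `pi` keeps the model identifiable at 6 replicates per
   condition). The likelihood clamps negative fitted means at 1e-8 and
   records a boundary flag. Inference on `b1` is a Wald test referred
   to a t distribution with `n - p` degrees of freedom (n replicates,
   p fitted parameters) — with 12 observations the normal reference is
   visibly anticonservative, and the t reference keeps the empirical
   type-I rate near nominal (0.064 at p < 0.05 in the null calibration
   at ZINB(mu 20, size 5, pi 0.2), 6 + 6 replicates). When the
   zero-inflation estimate collapses below 1e-4 the model falls back to
   a plain negative binomial. Benjamini-Hochberg q-values are computed
   across retained blocks only; blocks whose optimizer failed are
   flagged with missing p and excluded from the FDR denominator.

The power simulation in the test suite injects a 2-fold difference at
block-level dispersion (ZINB mu 50 vs 100, size 10, pi 0.05): blocks
aggregate many pixels, so their sums are less dispersed and less
zero-inflated than single pixels — size 10 and pi 0.05 are our
documented choices for that regime, while the null calibration uses the
pixel-scale parameters stated above.

## Peak comparison

`call_and_filter_peaks()` is a deterministic local-enrichment caller
(runs above a running-median threshold times an enrichment factor,
default 5, window 501 bp) plus a BED ingestion path for peaks called
elsewhere; the published analysis used a machine-learned caller, but
the downstream statistics operate on peaks however obtained. Filters —
width window and minimum viewpoint distance — have **no silent
defaults**: the corresponding thresholds in the published analysis are
not stated, so the arguments are required. Counts are normalized per
1e5 cis-unique junctions per viewpoint and replicate; a Welch t-test
per peak (the published description says "Student's t-Test" without
specifying variance pooling; unequal variances is the safer choice),
BH correction, and a significant-skew call at q < 0.05 and
|log2 fold change| > 1.5. The skew is the log2 ratio of normalized
condition means with a 0.5 pseudocount — the published figures plot
skew without defining it, and the log2 mean ratio is our documented
choice, identical to the reported fold change. The peak-detection test
simulates 300-junction peaks with negative-binomial size 200 across
replicates (about 9% replicate CV, a deeply sequenced capture library);
at three replicates per condition, detection of a 4-fold drop depends
strongly on this dispersion. Annotation enrichment is the log2 ratio of
intersection fractions of significant vs non-significant peaks with a
Haldane correction (0.5 / 1 added to counts/totals) when a fraction is
zero.

## Numerical and interface choices

* Problem sizes in the test suite: fixtures of 2-60 kb, libraries of
  2,000-50,000 molecules, matrices up to 5,000 x 5,000 (sparse), 200
  null and 100 alternative blocks in the calibration simulations, and
  20 seeded geometries for reconstruction localization. These sizes
  make every property measurable with stable statistics while the full
  suite stays desk-scale.
* Reconstruction localization is evaluated away from the diagonal
  (|i - j| > 150 px): within-element self-ligation sits on the
  short-range band and is not the long-range footprint-footprint
  contact being localized.
* All simulation entry points take explicit integer seeds, and the same
  seed reproduces byte-identical FASTQ text and result tables; the CLI
  (`inst/cli/mccu`) threads a `--seed` flag through every subcommand
  and writes a YAML run manifest (parameters, package version, input
  checksums) next to each output.
* Matrices are stored sparse (`Matrix::dgCMatrix`); a 5-kb 1-bp matrix
  is allocated densely only when explicitly converted.
* The CLI config file is YAML mirrored by flags, with flags winning.

## Known limitations

The built-in mapper is ungapped and exact-seeded: indels, repeats and
high error rates degrade it, and real-genome data should come in
through the SAM path. The marginal-based MNase correction confounds cut
bias with genuine viewpoint structure (supply a profile). The ZINB
Wald-t inference is approximate at very small replicate counts and the
identity link can sit on the boundary for blocks with near-zero means
(flagged). Segmentation assumes additively separable row/column
structure; strongly non-rectangular differential patterns are tiled by
several blocks rather than delineated. Trans contacts are carried
through labelling only.
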