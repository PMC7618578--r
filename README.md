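# mccutools

Base-pair-resolution Micro-Capture-C (MCCu) contact analysis in R.

MNase-based chromosome conformation capture with oligo capture
enrichment (Micro-Capture-C ultra) reads chromatin contacts out at the
single ligated base: chromatin is fixed, digested with micrococcal
nuclease, proximity ligated, sonicated to ~200 bp and sequenced with
150-bp paired-end reads so that the full fragment — and the exact
position of the chimeric ligation junction inside it — can be
reconstructed. At this resolution every matrix row is an individual
single-base viewpoint (a 5-kb map at 1-bp pixels is 5,000 viewpoint
profiles), contacts between individual transcription-factor motifs
become visible as corner patterns around protein-protected sequence,
and inactive chromatin shows a ~180–190-bp junction periodicity set by
the nucleosome repeat length.

`mccutools` implements the full computational pipeline for such data,
exercised end to end on a bundled, ground-truthed simulator:

* **Simulation** — `build_fixture()` (nucleosomes, NDRs, TF footprints,
  CTCF sites), `contact_model()`, `simulate_ligation_events()`,
  `render_sequencing_library()` (sonication, paired-end reads, truth
  tables).
* **Read reconstruction** — FLASH-style overlap merging
  (`merge_read_pairs()`), capture-region pre-filtering
  (`prefilter_capture_reads()`), splitting reads into genome-collinear
  sub-reads with a built-in seeded mapper (`split_and_map_subreads()`),
  plus SAM ingestion for externally aligned data.
* **Junction calling** — base-exact junction coordinates with
  orientation flags and stringent PCR deduplication
  (`call_junctions()`, `deduplicate_junctions()`; convenience wrapper
  `call_junctions_from_reads()`).
* **Contact matrices** — square and extended maps at any pixel size
  down to 1 bp, ICE balancing, single/tiled cis normalization, and the
  junction distance spectrum (`build_contact_matrix()`,
  `ice_normalize()`, `cis_normalize()`,
  `junction_distance_spectrum()`).
* **Contact sequence reconstruction** — projecting junction counts onto
  the protein-protected sequence using read directionality
  (`build_directional_matrix()`, `reconstruct_contact_sequences()`).
* **basepairC differential testing** — outlier removal, library-size
  and MNase normalization, crossed-1D segmentation, L1 block
  refinement with a tensor-product smooth, and zero-inflated
  negative-binomial block tests with an identity link
  (`preprocess_counts()`, `segment_blocks()`, `refine_blocks()`,
  `test_blocks()`, wrapper `basepairc()`).
* **Peak comparison** — cis-unique-junction normalization, per-peak
  Welch tests with FDR, skew, and annotation enrichment
  (`call_and_filter_peaks()`, `compare_peak_counts()`,
  `annotation_enrichment()`), plus 120-bp / 50%-overlap capture oligo
  tiling (`design_capture_tiling()`).

A thin command-line front end with `simulate`, `reconstruct`,
`junctions`, `matrix`, `reconstruct-seq`, `diff`, `peaks` and
`design-oligos` subcommands is installed at
`system.file("cli", "mccu", package = "mccutools")`.

## Worked example

Simulate a 12-kb random-phase locus with two NDRs that contact each
other, sequence it, call junctions and look at the structure:

```r
library(mccutools)

fx <- build_fixture(12000, 190,
                    ndrs = rbind(c(4000, 4200), c(7000, 7200)),
                    phase_mode = "random", seed = 1)
fx
#> mccu_fixture: 12000 bp, NRL 190 bp, 60 nucleosomes (phase 0), 2 NDRs,
#> 0 TF footprints, 0 CTCF sites, phase random

mod <- contact_model(ndr_pair_factor = 25, decay_exponent = 1)
lib <- simulate_ligation_events(fx, mod, 20000, seed = 2)
reads <- render_sequencing_library(lib, seed = 3)
reads
#> mccu_reads: 39248 read pairs from 20000 molecules

jx <- call_junctions_from_reads(reads, fx)
attr(jx, "merge_stats")$merged_fraction   # fraction of pairs merged
#> [1] 0.9567621
nrow(jx)                                  # unique junctions after dedup
#> [1] 15498

junction_distance_spectrum(jx)$dominant_period
#> [1] 187
```

The dominant junction period (187 bp) recovers the simulated 190-bp
nucleosome repeat from random-phase chromatin: junctions form between
internucleosomal linkers, so their distances concentrate at multiples
of the repeat length even though no individual nucleosome is
positioned. The merged fraction (95.7%) reflects 150-bp read pairs on
~200-bp sonication fragments.

Balance a 10-bp matrix over the two NDRs and compare their contact to
a distance-matched control window:

```r
m10 <- build_contact_matrix(jx, c(3500, 7700), pixel_size = 10)
ice <- ice_normalize(m10)
ice
#> mccu_matrix: 420 x 420 pixels (10 bp x 10 bp), region [3500, 7700), ice

M <- as.matrix(ice$counts)
mean(M[ 51:  70, 351:370], na.rm = TRUE)  # NDR x NDR window
#> [1] 0.1910171
mean(M[101: 120, 251:270], na.rm = TRUE)  # same separation, off-NDR
#> [1] 0.01157513
```

The NDR–NDR window carries ~16-fold more balanced signal than a
distance-matched control, the punctate inter-NDR contact the simulator
was asked to create (`ndr_pair_factor = 25` plus cut-site geometry).

Differential testing between two simulated conditions follows
`?basepairc`; contact sequence reconstruction of footprint-footprint
contacts follows `?reconstruct_contact_sequences`.

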