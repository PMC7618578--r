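revcomp1 <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("read pairs merge at the fragment length", {
  fx <- tiny_fixture()
  frag200 <- substring(fx$sequence, 101, 300)
  frag150 <- substring(fx$sequence, 501, 650)
  r1 <- data.frame(id = c("a", "b"),
                   seq = c(substring(frag200, 1, 150), frag150),
                   qual = strrep("I", c(150, 150)))
  r2 <- data.frame(id = c("a", "b"),
                   seq = c(revcomp1(substring(frag200, 51, 200)),
                           revcomp1(frag150)),
                   qual = strrep("I", c(150, 150)))
  m <- merge_read_pairs(r1, r2)
  expect_true(all(m$reads$merged))
  expect_equal(nchar(m$reads$seq), c(200, 150))   # overlap 100 and 150
  expect_equal(m$reads$seq[1], frag200)
  expect_equal(m$reads$seq[2], frag150)
  expect_equal(m$stats$merged_fraction, 1)
})

test_that("merging is strand-symmetric and reports id mismatches", {
  fx <- tiny_fixture()
  frag <- substring(fx$sequence, 1001, 1220)
  r1 <- data.frame(id = "x", seq = substring(frag, 1, 150),
                   qual = strrep("I", 150))
  r2 <- data.frame(id = "x", seq = revcomp1(substring(frag, 71, 220)),
                   qual = strrep("I", 150))
  m12 <- merge_read_pairs(r1, r2)
  m21 <- merge_read_pairs(r2, r1)  # swap roles
  expect_equal(m21$reads$seq, revcomp1(m12$reads$seq))
  bad <- data.frame(id = "y", seq = r2$seq, qual = r2$qual)
  expect_error(merge_read_pairs(r1, bad), "id mismatch.*'x' vs 'y'")
})

test_that("mismatch-rate and overlap thresholds gate merging", {
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  t <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  r1 <- data.frame(id = "u", seq = s, qual = strrep("I", 150))
  r2 <- data.frame(id = "u", seq = t, qual = strrep("I", 150))
  m <- merge_read_pairs(r1, r2)   # unrelated reads: no credible overlap
  expect_false(any(m$reads$merged))
  expect_equal(nrow(m$reads), 2)  # passed through as two reads
  expect_setequal(m$reads$id, c("u/1", "u/2"))
})

test_that("sonicated library merges above 90 percent", {
  sl <- small_library()
  m <- merge_read_pairs(sl$reads$r1, sl$reads$r2)
  expect_gte(m$stats$merged_fraction, 0.90)
})

test_that("capture pre-filter retains flank reads and drops distal ones", {
  fx <- build_fixture(20000, 190, seed = 21)
  region <- c(10000, 11000)
  near <- data.frame(id = "near",
                     seq = substring(fx$sequence, 10000 - 700 + 1,
                                     10000 - 700 + 150),
                     qual = strrep("I", 150))
  far <- data.frame(id = "far",
                    seq = substring(fx$sequence, 1, 150),
                    qual = strrep("I", 150))
  reads <- rbind(near, far)
  kept <- prefilter_capture_reads(reads, rbind(region), fx)
  expect_equal(kept$id, "near")
  # pre-filter never discards a read truly overlapping region + flank
  sl <- small_library()
  m <- merge_read_pairs(sl$reads$r1, sl$reads$r2)
  kept2 <- prefilter_capture_reads(m$reads, rbind(c(0, 6000)), sl$fixture,
                                   flank = 0)
  expect_equal(nrow(kept2), nrow(m$reads))
  # empty input, invalid region
  empty <- prefilter_capture_reads(reads[0, ], rbind(region), fx)
  expect_equal(nrow(empty), 0)
  expect_error(prefilter_capture_reads(reads, rbind(c(19000, 25000)), fx),
               "bounds")
})

test_that("chimeric reads split into correctly mapped sub-reads", {
  fx <- build_fixture(5000, 190, seed = 23)
  ch <- function(i) substring(fx$sequence, i + 1, i + 1)  # 0-based base
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # choose the downstream block so no micro-homology blurs the breakpoint
  # in either orientation (the caller assigns ambiguous bases upstream)
  b0 <- 3000
  while (ch(b0) == ch(1100) ||                     # A + B junction
         comp[ch(b0 + 99)] == ch(1100) ||          # A + revcomp(B)
         ch(1000) == ch(b0 + 100))                 # B-side continuation
    b0 <- b0 + 7
  a <- substring(fx$sequence, 1001, 1100)   # [1000, 1100)
  b <- substring(fx$sequence, b0 + 1, b0 + 100)   # [b0, b0 + 100)
  sr <- split_and_map_subreads(paste0(a, b), fx)
  expect_equal(nrow(sr), 2)
  expect_equal(sr$read_start, c(0, 100))
  expect_equal(sr$read_end, c(100, 200))
  expect_equal(sr$genome_start, c(1000, b0))
  expect_equal(sr$genome_end, c(1100, b0 + 100))
  expect_equal(sr$strand, c("+", "+"))

  # collinear read -> single sub-read spanning the whole read
  sr1 <- split_and_map_subreads(a, fx)
  expect_equal(nrow(sr1), 1)
  expect_equal(sr1$read_end - sr1$read_start, 100)

  # A + revcomp(B): second sub-read on the minus strand
  sr2 <- split_and_map_subreads(paste0(a, revcomp1(b)), fx)
  expect_equal(sr2$strand, c("+", "-"))
  expect_equal(sr2$genome_start[2], b0)
  expect_equal(sr2$genome_end[2], b0 + 100)
})

test_that("sub-read mapping tolerates substitutions and reports unmapped reads", {
  fx <- build_fixture(5000, 190, seed = 25)
  a <- substring(fx$sequence, 2001, 2150)
  av <- strsplit(a, "")[[1]]
  av[75] <- setdiff(c("A", "C", "G", "T"), av[75])[1]
  sr <- split_and_map_subreads(paste(av, collapse = ""), fx,
                               max_mismatches = 2)
  expect_equal(nrow(sr), 1)
  expect_equal(sr$mismatches, 1)
  expect_equal(sr$genome_start, 2000)
  expect_equal(sr$genome_end, 2150)
  junk <- strrep("ACGTT", 30)
  sr2 <- split_and_map_subreads(c(a, junk), fx)
  expect_equal(attr(sr2, "unmapped"), 2L)
})

test_that("sub-reads round-trip through SAM", {
  sl <- small_library()
  m <- merge_read_pairs(sl$reads$r1, sl$reads$r2)
  sr <- split_and_map_subreads(head(m$reads, 200), sl$fixture)
  tmp <- tempfile(fileext = ".sam")
  write_subreads_sam(sr, tmp, sl$fixture$length)
  back <- read_subreads_sam(tmp)
  rownames(sr) <- rownames(back) <- NULL
  expect_equal(back$genome_start, sr$genome_start)
  expect_equal(back$genome_end, sr$genome_end)
  expect_equal(back$strand, sr$strand)
  expect_equal(back$read_start, sr$read_start)
  expect_equal(back$ambiguous, sr$ambiguous)
  # junctions from ingested SAM match the native path
  expect_equal(deduplicate_junctions(call_junctions(back)),
               deduplicate_junctions(call_junctions(sr)))
})
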