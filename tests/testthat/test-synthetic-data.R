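test_that("fixtures tile nucleosomes at the repeat length and respect NDRs", {
  fx <- build_fixture(10000, 190, seed = 1)
  expect_equal(nrow(fx$nucleosomes), 10000 %/% 190)  # 52

  fx2 <- build_fixture(6000, 190, ndrs = rbind(c(2900, 3100)), seed = 1)
  expect_false(any(fx2$nucleosomes$dyad >= 2900 & fx2$nucleosomes$dyad < 3100))
  # cores never intrude into the NDR
  expect_true(all(fx2$nucleosomes$dyad + 74 <= 2900 |
                  fx2$nucleosomes$dyad - 73 >= 3100))

  # same seed -> identical sequence and annotations
  fx3 <- build_fixture(6000, 190, ndrs = rbind(c(2900, 3100)), seed = 1)
  expect_identical(fx2$sequence, fx3$sequence)
  expect_identical(fx2$nucleosomes, fx3$nucleosomes)
})

test_that("fixture construction rejects invalid inputs", {
  expect_error(build_fixture(500, 190), "length")
  expect_error(build_fixture(5000, 150), "157")
  expect_error(build_fixture(5000, 190, ndrs = rbind(c(100, 400), c(300, 600))),
               "overlap")
  expect_error(build_fixture(5000, 190, ndrs = rbind(c(4800, 5400))),
               "within")
})

test_that("nucleosome array layout arithmetic", {
  expect_equal(layout_nucleosome_array(16, 190)$span, 3040)
  expect_equal(layout_nucleosome_array(1, 190)$span, 190)
  expect_equal(layout_nucleosome_array(10, 185)$span, 1850)
  expect_error(layout_nucleosome_array(0, 190))
})

test_that("cut sites avoid cores and footprints; flanks are enhanced", {
  fx <- build_fixture(3000, 190,
                      ndrs = rbind(c(1400, 1600)),
                      tf_footprints = data.frame(start = 1480, end = 1500),
                      seed = 3)
  prof <- cut_weight_profile(fx)
  w <- prof$w[, 1]
  for (d in fx$nucleosomes$dyad)
    expect_true(all(w[(d - 73):(d + 73) + 1] == 0))
  expect_true(all(w[1481:1500] == 0))          # footprint interior
  expect_true(all(w[1476:1480] == 4))          # left flank
  expect_true(all(w[1501:1505] == 4))          # right flank
})

test_that("single-event simulation yields one molecule with 1-2 junctions", {
  fx <- tiny_fixture()
  lib <- simulate_ligation_events(fx, contact_model(), 1, seed = 5,
                                  p_threeway = 0)
  expect_equal(nrow(lib$molecules), 1)
  expect_equal(nrow(lib$truth), 1)
  lib3 <- simulate_ligation_events(fx, contact_model(), 50, seed = 5,
                                   p_threeway = 1)
  expect_true(all(table(lib3$truth$molecule) == 2))
})

test_that("NDR-NDR contacts are enriched over a distance-matched control", {
  fx <- build_fixture(8000, 190, ndrs = rbind(c(2000, 2200), c(5000, 5200)),
                      seed = 7)
  mod <- contact_model(ndr_pair_factor = 50, decay_exponent = 1)
  lib <- simulate_ligation_events(fx, mod, 50000, seed = 8)
  tr <- lib$truth
  in_iv <- function(p, s, e) p >= s & p < e
  n_ndr <- sum(in_iv(tr$pos_a, 2000, 2200) & in_iv(tr$pos_b, 5000, 5200))
  # control: same widths, same 3-kb separation, offset away from the NDRs
  n_ctl <- sum(in_iv(tr$pos_a, 2600, 2800) & in_iv(tr$pos_b, 5600, 5800))
  expect_gt(n_ndr, n_ctl)
  bt <- binom.test(n_ndr, n_ndr + n_ctl, 0.5, alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})

test_that("background-only junction ends are uniform across linkers", {
  fx <- build_fixture(8000, 190, seed = 9)
  mod <- contact_model(decay_exponent = 0)  # flat model: marginal = cut weight
  lib <- simulate_ligation_events(fx, mod, 10000, seed = 10, p_threeway = 0)
  prof <- cut_weight_profile(fx)
  w <- prof$w[, 1]
  # linker id per bp (runs of nonzero weight)
  r <- rle(w > 0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  li <- which(r$values)
  pos <- c(lib$truth$pos_a, lib$truth$pos_b) + 1L
  probs <- r$lengths[li] / sum(r$lengths[li])
  obs <- vapply(li, function(k) sum(pos >= starts[k] & pos <= ends[k]),
                numeric(1))
  # junction coordinates sit within 1 bp of the sampled cut; count totals
  n <- sum(obs)
  expv <- n * probs
  z <- abs(obs - expv) / sqrt(expv * (1 - probs))
  expect_gte(mean(z <= 3), 0.97)
  expect_true(all(z <= 5))
})

test_that("NDR junction fraction increases monotonically with the pair factor", {
  fx <- build_fixture(6000, 190, ndrs = rbind(c(1500, 1700), c(4000, 4200)),
                      seed = 11)
  frac <- vapply(c(1, 10, 50), function(f) {
    lib <- simulate_ligation_events(fx, contact_model(ndr_pair_factor = f),
                                    50000, seed = 12)
    tr <- lib$truth
    mean(tr$pos_a >= 1500 & tr$pos_a < 1700 &
         tr$pos_b >= 4000 & tr$pos_b < 4200)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("sequencing rendering conserves reads and maps back exactly", {
  sl <- small_library()
  rd <- sl$reads
  # one read pair per fragment; ids unique
  expect_equal(nrow(rd$r1), nrow(rd$fragments))
  expect_equal(nrow(rd$r2), nrow(rd$fragments))
  expect_false(anyDuplicated(rd$r1$id) > 0)
  # with error_rate = 0 every R1 maps exactly at its recorded coordinates
  mol <- sl$lib$molecules
  fseq <- substring(mol$sequence[match(rd$fragments$molecule, mol$molecule)],
                    rd$fragments$fs + 1, rd$fragments$fe)
  expect_true(all(substring(fseq, 1, nchar(rd$r1$seq)) == rd$r1$seq))
  # each truth junction coordinate matches string search of its 20-bp
  # context: the protected-side 20-mer at the coordinate occurs in the
  # molecule (in the read orientation of the carrying fragment, so either
  # forward or reverse-complemented)
  tr <- sl$lib$truth
  set.seed(1)
  tr <- tr[sample.int(nrow(tr), 200), ]
  fix <- sl$fixture$sequence
  molseq <- sl$lib$molecules$sequence[tr$molecule]
  rc1 <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  ctx_a <- ifelse(tr$dir_a == "toward_upstream",
                  substring(fix, tr$pos_a - 18, tr$pos_a + 1),
                  substring(fix, tr$pos_a + 1, tr$pos_a + 20))
  ctx_b <- ifelse(tr$dir_b == "toward_downstream",
                  substring(fix, tr$pos_b + 1, tr$pos_b + 20),
                  substring(fix, tr$pos_b - 18, tr$pos_b + 1))
  hit_a <- mapply(grepl, ctx_a, molseq, MoreArgs = list(fixed = TRUE)) |
           mapply(grepl, rc1(ctx_a), molseq, MoreArgs = list(fixed = TRUE))
  hit_b <- mapply(grepl, ctx_b, molseq, MoreArgs = list(fixed = TRUE)) |
           mapply(grepl, rc1(ctx_b), molseq, MoreArgs = list(fixed = TRUE))
  expect_gte(mean(hit_a), 0.99)
  expect_gte(mean(hit_b), 0.99)
})

test_that("rendering is deterministic and validates error rates", {
  sl <- small_library()
  r1 <- render_sequencing_library(sl$lib, seed = 77)
  r2 <- render_sequencing_library(sl$lib, seed = 77)
  expect_identical(r1$r1, r2$r1)
  expect_identical(r1$truth, r2$truth)
  expect_error(render_sequencing_library(sl$lib, error_rate = 0.5), "error_rate")
  # short fragment: R1 equals the fragment, R2 its reverse complement
  mols <- data.frame(molecule = 1L,
                     sequence = paste(rep("ACGTA", 30), collapse = ""))
  rd <- render_sequencing_library(mols, read_length = 150, seed = 1)
  expect_equal(nchar(rd$r1$seq), 150)
  expect_equal(rd$r1$seq, substring(mols$sequence, 1, 150))
  expect_equal(rd$r2$seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mols$sequence))))
})
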