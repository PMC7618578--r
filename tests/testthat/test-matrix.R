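mk_junctions <- function(pos_a, pos_b, dir_a = "toward_upstream",
                         dir_b = "toward_downstream") {
  n <- length(pos_a)
  data.frame(chrom = "fixture", pos_a = pos_a, pos_b = pos_b,
             dir_a = rep_len(dir_a, n), dir_b = rep_len(dir_b, n),
             frag_start = pos_a - 50L, frag_end = pos_b + 50L,
             read_id = paste0("r", seq_len(n)))
}

test_that("matrix dimensions, binning and symmetry follow the pixel grid", {
  j <- mk_junctions(c(100L, 103L), c(200L, 300L))
  m <- build_contact_matrix(j, c(0, 5000), pixel_size = 1)
  expect_equal(dim(m$counts), c(5000L, 5000L))
  expect_equal(m$counts[101, 201], 1)   # 0-based (100, 200)
  expect_equal(m$counts[201, 101], 1)
  m5 <- build_contact_matrix(j, c(0, 5000), pixel_size = 5)
  expect_equal(dim(m5$counts), c(1000L, 1000L))
  expect_equal(m5$counts[103 %/% 5 + 1, 300 %/% 5 + 1], 1)  # row bin 20
  expect_error(build_contact_matrix(j, c(0, 5000), pixel_size = 0), "pixel")
  expect_error(build_contact_matrix(j, c(100, 100)), "empty")
})

test_that("upper-triangle counts equal in-region junction totals", {
  set.seed(31)
  j <- mk_junctions(sample(0:1999, 500, TRUE), sample(0:1999, 500, TRUE))
  swap <- j$pos_a > j$pos_b
  tmp <- j$pos_a[swap]; j$pos_a[swap] <- j$pos_b[swap]; j$pos_b[swap] <- tmp
  m <- build_contact_matrix(j, c(0, 2000), pixel_size = 1)
  M <- as.matrix(m)
  expect_equal(sum(M[upper.tri(M, diag = TRUE)]), 500)
  expect_true(isSymmetric(M))
})

test_that("coarse pixels aggregate fine pixels exactly", {
  set.seed(32)
  j <- mk_junctions(sample(0:999, 300, TRUE), sample(0:999, 300, TRUE))
  m1 <- as.matrix(build_contact_matrix(j, c(0, 1000), 1))
  m10 <- as.matrix(build_contact_matrix(j, c(0, 1000), 10))
  agg <- matrix(0, 100, 100)
  for (i in 1:100) for (k in 1:100)
    agg[i, k] <- sum(m1[(i - 1) * 10 + 1:10, (k - 1) * 10 + 1:10])
  expect_identical(m10, agg)
})

test_that("extended matrices keep genome-wide partner columns", {
  j <- mk_junctions(c(500L, 8000L), c(8000L, 9000L))
  m <- build_contact_matrix(j, c(0, 1000), pixel_size = 1, extended = 500,
                            genome_length = 10000)
  expect_equal(dim(m$counts), c(1000L, 20L))
  expect_equal(m$counts[501, 8000 %/% 500 + 1], 1)
  # junction with both ends outside the region contributes nothing
  expect_equal(sum(m$counts), 1)
})

test_that("ICE balancing equalizes coverage and factorizes the input", {
  set.seed(33)
  M <- matrix(runif(200 * 200, 0.5, 2), 200); M <- M + t(M)
  r <- ice_normalize(M)
  expect_true(r$converged)
  keep <- !r$masked
  rs <- rowSums(r$balanced[keep, keep])
  expect_lt(sd(rs) / mean(rs), 1e-3)
  expect_true(isSymmetric(r$balanced[keep, keep]))
  recon <- outer(r$bias, r$bias) * r$balanced
  expect_equal(recon[keep, keep], M[keep, keep], tolerance = 1e-10)
  # idempotence: balancing a balanced matrix is a no-op within tolerance
  r2 <- ice_normalize(r$balanced[keep, keep], low_coverage_quantile = 0)
  expect_lt(max(abs(r2$balanced - r$balanced[keep, keep])), 1e-5)
})

test_that("ICE masks empty rows and rejects all-zero matrices", {
  set.seed(34)
  M <- matrix(runif(50 * 50, 0.5, 2), 50); M <- M + t(M)
  M[7, ] <- 0; M[, 7] <- 0
  r <- ice_normalize(M)
  expect_true(r$masked[7])
  expect_true(all(is.na(r$balanced[7, ])))
  keep <- !r$masked
  rs <- rowSums(r$balanced[keep, keep])
  expect_lt(sd(rs) / mean(rs), 1e-3)
  expect_error(ice_normalize(matrix(0, 10, 10)), "all-zero")
  # identical rows: balanced output proportional to input, constant bias
  U <- matrix(1, 20, 20)
  ru <- ice_normalize(U, low_coverage_quantile = 0)
  expect_equal(max(ru$bias) / min(ru$bias), 1, tolerance = 1e-6)
})

test_that("cis normalization scales rows and is library-size invariant", {
  M <- matrix(c(4, 2, 2, 8), 2)
  out <- cis_normalize(M, "single", scale = 1e5, cis_totals = c(2000, 4000))
  expect_equal(out[1, ], M[1, ] * 50)          # 1e5 / 2000
  expect_equal(out[2, ], M[2, ] * 25)
  expect_equal(cis_normalize(2 * M, "single"), cis_normalize(M, "single"))
  # zero cis total masks the row rather than dividing
  out2 <- cis_normalize(M, "single", cis_totals = c(0, 4000))
  expect_true(all(is.na(out2[1, ])))
  # tiled mode symmetrizes to machine precision
  set.seed(35)
  A <- matrix(rpois(900, 5), 30)
  tl <- cis_normalize(A, "tiled")
  expect_lt(max(abs(tl - t(tl))), 1e-12)
  # 1D profile
  expect_equal(cis_normalize(c(1, 2, 3), cis_totals = 2000),
               c(1, 2, 3) * 50)
})

test_that("distance spectrum finds the nucleosome repeat length", {
  set.seed(36)
  # synthetic junction distances peaked at multiples of 188 bp
  d <- sample(c(188, 376, 564), 3000, TRUE, prob = c(0.6, 0.3, 0.1)) +
       sample(-30:30, 3000, TRUE, prob = dnorm(-30:30, 0, 12))
  pos_a <- sample(0:3000, 3000, TRUE)
  sp <- junction_distance_spectrum(mk_junctions(pos_a, pos_a + d))
  expect_true(abs(sp$dominant_period - 188) <= 5)
  expect_true(any(abs(sp$secondary_periods - 376) <= 10))
  expect_error(junction_distance_spectrum(mk_junctions(1:50, 101:150)),
               "too few junctions")
})

test_that("matrices round-trip through dense and sparse text formats", {
  set.seed(37)
  j <- mk_junctions(sample(0:499, 200, TRUE), sample(0:499, 200, TRUE))
  swap <- j$pos_a > j$pos_b
  tmp <- j$pos_a[swap]; j$pos_a[swap] <- j$pos_b[swap]; j$pos_b[swap] <- tmp
  m <- build_contact_matrix(j, c(0, 500), 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_matrix(m, f1, "dense")
  write_matrix(m, f2, "sparse")
  expect_equal(as.matrix(read_matrix(f1, "dense")), as.matrix(m))
  expect_equal(as.matrix(read_matrix(f2, "sparse")), as.matrix(m))
  expect_equal(read_matrix(f1)$region, m$region)
})
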