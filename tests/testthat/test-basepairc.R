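mk_tensor <- function(na = 2, nb = 2, n = 20, mu = 10, seed = 51,
                      cut = NULL) {
  set.seed(seed)
  mk <- function() matrix(rpois(n * n, mu), n)
  count_tensor(replicate(na, mk(), simplify = FALSE),
               replicate(nb, mk(), simplify = FALSE), cut_profile = cut)
}

test_that("preprocessing masks, winsorizes and normalizes library size", {
  tn <- mk_tensor()
  expect_error(preprocess_counts(count_tensor(tn$a[1], tn$b)), "2 replicates")
  # identical replicate sets give a zero condition difference
  set.seed(52)
  m <- matrix(rpois(400, 8), 20)
  tn2 <- count_tensor(list(m, m + 0), list(m, m + 0))
  d <- mean_difference_grid(preprocess_counts(tn2))
  expect_true(all(d[!is.na(d)] == 0))
  # an extreme outlier is winsorized to the pooled 0.999 quantile
  m2 <- m; m2[5, 5] <- 100 * quantile(m[m > 0], 0.999)
  tn3 <- preprocess_counts(count_tensor(list(m2, m), list(m, m)),
                           outlier_quantile = 0.999)
  pooled <- c(m2, m, m, m)
  expect_lte(max(tn3$a[[1]]) * 1,
             quantile(pooled[pooled > 0], 0.999) *
               max(1 / tn3$propensity$row %o% tn3$propensity$col) * 2)
  # low-count pixels are masked
  m3 <- m; m3[1, 1] <- 0
  tn4 <- preprocess_counts(count_tensor(list(m3 * 0, m3 * 0 + 1),
                                        list(m3 * 0, m3 * 0 + 1)),
                           low_count = 2)
  expect_true(all(tn4$mask))
})

test_that("multiplicative cut bias is corrected from a known profile", {
  set.seed(53)
  n <- 40
  ci <- runif(n, 0.5, 2)
  mu <- outer(ci, ci) * 200
  mk <- function() matrix(rpois(n * n, mu), n)
  tn <- count_tensor(replicate(3, mk(), simplify = FALSE),
                     replicate(3, mk(), simplify = FALSE),
                     cut_profile = ci)
  tn <- preprocess_counts(tn, low_count = 0)
  P <- Reduce(`+`, c(tn$a, tn$b)) / 6
  expect_lt(sd(P) / mean(P), 0.05)   # corrected surface is flat
})

test_that("binary segmentation recovers crossed breakpoints", {
  set.seed(54)
  g <- matrix(0, 100, 100)
  g[1:50, 1:50] <- 1
  g <- g + matrix(rnorm(1e4, 0, 0.1), 100)
  b <- segment_blocks(g, min_block = 10)
  # exhaustive single-split oracle on each margin
  oracle_split <- function(y) {
    n <- length(y)
    sse <- vapply(10:(n - 10), function(t)
      sum((y[1:t] - mean(y[1:t]))^2) +
      sum((y[(t + 1):n] - mean(y[(t + 1):n]))^2), numeric(1))
    (10:(n - 10))[which.min(sse)]
  }
  expect_lte(abs(attr(b, "row_cp") - oracle_split(rowMeans(g))), 1)
  expect_lte(abs(attr(b, "col_cp") - oracle_split(colMeans(g))), 1)
  expect_lte(abs(attr(b, "row_cp") - 50), 1)
  expect_equal(nrow(b), 4)
  # constant grid stays one block; small grids return a single block
  expect_equal(nrow(segment_blocks(matrix(2, 50, 50), min_block = 10)), 1)
  expect_equal(nrow(segment_blocks(matrix(rnorm(25), 5), min_block = 10)), 1)
  # changepoint count is capped
  set.seed(55)
  y <- matrix(rep(rep(c(0, 5), 25), each = 4) + rnorm(2000, 0, 0.1), 100, 20)
  bb <- segment_blocks(y, min_block = 2, max_changepoints = 5)
  expect_lte(length(attr(bb, "row_cp")), 5)
})

test_that("L1 refinement drops low-count blocks and smooths spikes", {
  set.seed(56)
  n <- 40
  a <- lapply(1:2, function(i) {
    m <- matrix(rpois(n * n, 1), n)
    m[1:20, 1:20] <- rpois(400, 60)
    m[1:20, 21:40] <- 0; m[21:40, 1:20] <- 0
    m
  })
  tn <- preprocess_counts(count_tensor(a, a, cut_profile = rep(1, n)),
                          low_count = 0)
  blocks <- structure(
    data.frame(row_start = c(1, 1, 21, 21), row_end = c(20, 20, 40, 40),
               col_start = c(1, 21, 1, 21), col_end = c(20, 40, 20, 40),
               status = "retained"),
    class = c("mccu_blocks", "data.frame"))
  r0 <- refine_blocks(blocks, tn, lasso_penalty = 0)
  expect_false(any(r0$status == "dropped_low_count"))
  r1 <- refine_blocks(blocks, tn, lasso_penalty = 1)
  expect_true(all(r1$status[c(2, 3)] == "dropped_low_count"))  # all-zero
  expect_equal(r1$status[1], "smoothed")                       # top decile
  # an isolated spike is damped below half its height by the smooth
  a2 <- lapply(a, function(m) { m[10, 10] <- 600; m })
  tn2 <- preprocess_counts(count_tensor(a2, a2, cut_profile = rep(1, n)),
                           low_count = 0)
  r2 <- refine_blocks(blocks, tn2, lasso_penalty = 1, smooth_df = 5)
  ex <- attr(r2, "expected")[[1]]
  spike <- Reduce(`+`, c(tn2$a, tn2$b))[10, 10] / 4
  expect_lt(ex[10, 10], 0.5 * spike)
  expect_error(refine_blocks(blocks, tn, lasso_penalty = -1), "nonnegative")
})

test_that("ZINB block fit handles degenerate and boundary cases", {
  x <- rep(c(0, 1), each = 4)
  f <- fit_zinb_block(rep(7, 8), x)
  expect_equal(f$effect, 0)
  expect_equal(f$p_value, 1)
  # no zero inflation in the data: falls back to plain NB
  set.seed(57)
  f2 <- fit_zinb_block(rnbinom(8, size = 50, mu = 100) + 1, x)
  expect_true(f2$model %in% c("nb", "zinb"))
  expect_true(is.finite(f2$p_value))
})

test_that("effect estimates recover the injected difference with small bias", {
  set.seed(58)
  x <- rep(c(0, 1), each = 6)
  eff <- replicate(500, {
    y <- c(rzinb(6, 50, 10, 0.1), rzinb(6, 100, 10, 0.1))
    fit_zinb_block(y, x)$effect
  })
  expect_lt(abs(mean(eff, na.rm = TRUE) - 50), 5)  # |bias| < 10% of mu
})

test_that("q-values are BH-monotone and the full pipeline is deterministic", {
  set.seed(59)
  mk <- function(mu) matrix(rpois(900, mu), 30)
  base <- matrix(5, 30, 30); base[10:20, 10:20] <- 15
  trt <- base; trt[10:20, 10:20] <- 30
  ta <- lapply(1:3, function(i) mk(base)); tb <- lapply(1:3, function(i) mk(trt))
  r1 <- basepairc(count_tensor(ta, tb), min_block = 5)
  r2 <- basepairc(count_tensor(ta, tb), min_block = 5)
  expect_identical(r1, r2)
  ok <- !is.na(r1$p_value)
  o <- order(r1$p_value[ok])
  expect_true(all(diff(r1$q_value[ok][o]) >= -1e-12))
  expect_true(all(r1$q_value[ok] >= r1$p_value[ok]))
  # the injected block is recovered as significant
  hit <- r1$row_start <= 10 & r1$row_end >= 20 & r1$col_start <= 10 &
         r1$col_end >= 20 & r1$significant
  expect_true(any(hit))
})
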