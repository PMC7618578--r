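#' Assemble a replicate count tensor for differential testing
#'
#' @param cond_a,cond_b Lists of raw pixel count matrices (one per
#'   replicate; `mccu_matrix` objects are accepted), all sharing a shape.
#' @param cut_profile Optional per-position MNase cut propensity vector
#'   (length = number of row pixels); when absent, propensities are
#'   estimated from the pooled matrix marginals.
#' @param labels Optional condition labels (length 2).
#' @return Object of class `mccu_tensor`.
#' @export
count_tensor <- function(cond_a, cond_b, cut_profile = NULL,
                         labels = c("control", "treated")) {
  as_mat <- function(x) if (inherits(x, "mccu_matrix")) as.matrix(x$counts)
                        else as.matrix(x)
  a <- lapply(cond_a, as_mat)
  b <- lapply(cond_b, as_mat)
  dims <- unique(lapply(c(a, b), dim))
  if (length(dims) != 1) stop("all replicate grids must share a shape")
  if (any(vapply(c(a, b), function(m) any(m < 0), logical(1))))
    stop("counts must be nonnegative")
  structure(list(a = a, b = b, cut_profile = cut_profile, labels = labels,
                 normalized = FALSE),
            class = "mccu_tensor")
}

#' @export
print.mccu_tensor <- function(x, ...) {
  cat(sprintf("mccu_tensor: %d x %d pixels, %d + %d replicates (%s vs %s)%s\n",
              nrow(x$a[[1]]), ncol(x$a[[1]]), length(x$a), length(x$b),
              x$labels[1], x$labels[2],
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Preprocess a count tensor: outliers, library size, MNase bias
#'
#' Four steps: (1) pixels whose maximum over all replicates is below
#' `low_count` are masked; (2) values above the `outlier_quantile` of the
#' pooled nonzero distribution are winsorized to that quantile; (3) each
#' replicate is scaled to the median replicate total (library size);
#' (4) each pixel `(i, j)` is divided by the product of normalized MNase
#' cut propensities `c_i * c_j` (from `cut_profile`, or estimated as the
#' pooled matrix marginals), then the grand total is restored.
#'
#' @param tensor A [count_tensor()].
#' @param low_count Mask threshold on the all-replicate pixel maximum
#'   (default 2).
#' @param outlier_quantile Winsorization quantile of the pooled nonzero
#'   distribution (default 0.999).
#' @return The tensor with normalized replicate grids, a logical `mask`
#'   (TRUE = masked), and the estimated `propensity` vector.
#' @export
preprocess_counts <- function(tensor, low_count = 2L,
                              outlier_quantile = 0.999) {
  stopifnot(inherits(tensor, "mccu_tensor"))
  if (length(tensor$a) < 2 || length(tensor$b) < 2)
    stop("at least 2 replicates per condition are required")
  all_m <- c(tensor$a, tensor$b)
  pixmax <- Reduce(pmax, all_m)
  mask <- pixmax < low_count
  pooled <- unlist(lapply(all_m, as.vector))
  nz <- pooled[pooled > 0]
  qv <- if (length(nz)) quantile(nz, outlier_quantile) else Inf
  all_m <- lapply(all_m, function(m) { m[m > qv] <- qv; m })
  totals <- vapply(all_m, sum, numeric(1))
  target <- median(totals)
  all_m <- lapply(seq_along(all_m),
                  function(i) all_m[[i]] * (target / totals[i]))
  n <- nrow(all_m[[1]]); p <- ncol(all_m[[1]])
  if (!is.null(tensor$cut_profile)) {
    ci <- tensor$cut_profile
    if (length(ci) != n) stop("cut_profile length must match row pixels")
    cj <- if (p == n) ci else rep(mean(ci), p)
  } else {
    P <- Reduce(`+`, all_m) / length(all_m)
    ci <- rowMeans(P); cj <- colMeans(P)
  }
  norm_prop <- function(x) { x <- x / mean(x[x > 0]); x[x <= 0] <- 1; x }
  ci <- norm_prop(ci); cj <- norm_prop(cj)
  denom <- outer(ci, cj)
  gt <- sum(vapply(all_m, sum, numeric(1)))
  all_m <- lapply(all_m, function(m) m / denom)
  gt2 <- sum(vapply(all_m, sum, numeric(1)))
  all_m <- lapply(all_m, function(m) m * (gt / gt2))
  na <- length(tensor$a)
  tensor$a <- all_m[seq_len(na)]
  tensor$b <- all_m[-seq_len(na)]
  tensor$mask <- mask
  tensor$propensity <- list(row = ci, col = cj)
  tensor$normalized <- TRUE
  tensor
}

#' Mean condition-difference grid of a tensor
#' @param tensor A (preprocessed) `mccu_tensor`.
#' @return Matrix of mean(cond_b) - mean(cond_a), masked pixels `NA`.
#' @export
mean_difference_grid <- function(tensor) {
  d <- Reduce(`+`, tensor$b) / length(tensor$b) -
       Reduce(`+`, tensor$a) / length(tensor$a)
  if (!is.null(tensor$mask)) d[tensor$mask] <- NA_real_
  d
}

# 1D binary segmentation, squared-error cost, BIC-style penalty
.binseg1d <- function(y, min_seg, max_cp, sigma2 = NULL) {
  n <- length(y)
  y[!is.finite(y)] <- 0
  if (is.null(sigma2)) {
    dy <- diff(y)
    sigma2 <- (stats::mad(dy) / sqrt(2))^2
    if (!is.finite(sigma2)) sigma2 <- 0
  }
  pen <- 3 * log(n) * max(sigma2, 1e-12)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  segcost <- function(s, e) {   # inclusive indices
    len <- e - s + 1
    sy <- cs[e] - if (s > 1) cs[s - 1] else 0
    sy2 <- cs2[e] - if (s > 1) cs2[s - 1] else 0
    sy2 - sy^2 / len
  }
  best_split <- function(s, e) {
    if (e - min_seg < s + min_seg - 1L) return(NULL)
    ts <- seq.int(s + min_seg - 1L, e - min_seg)
    costs <- vapply(ts, function(t) segcost(s, t) + segcost(t + 1L, e),
                    numeric(1))
    k <- which.min(costs)
    list(t = ts[k], gain = segcost(s, e) - costs[k])
  }
  cps <- integer()
  queue <- list(c(1L, n))
  while (length(queue) && length(cps) < max_cp) {
    # split the segment with the largest gain first
    cands <- lapply(queue, function(se) best_split(se[1], se[2]))
    gains <- vapply(cands, function(z) if (is.null(z)) -Inf else z$gain,
                    numeric(1))
    k <- which.max(gains)
    if (!length(gains) || gains[k] <= pen) break
    se <- queue[[k]]; t <- cands[[k]]$t
    cps <- c(cps, t)
    queue <- c(queue[-k], list(c(se[1], t)), list(c(t + 1L, se[2])))
  }
  sort(cps)
}

#' 2D segmentation of a difference grid via crossed 1D changepoints
#'
#' Binary segmentation (squared-error cost, BIC-style penalty) is run on
#' the row-margin and column-margin profiles of the mean-difference grid;
#' the block grid is their cross product, tiling the matrix.
#'
#' @param x Mean-difference matrix (as from [mean_difference_grid()]), or
#'   a preprocessed `mccu_tensor`.
#' @param min_block Minimum block side length in pixels where feasible
#'   (default 10).
#' @param max_changepoints Maximum changepoints per axis (default 50).
#' @return Object of class `mccu_blocks`: data frame with 1-based
#'   inclusive pixel intervals `row_start`, `row_end`, `col_start`,
#'   `col_end` and `status`; changepoint positions in attributes.
#' @export
segment_blocks <- function(x, min_block = 10L, max_changepoints = 50L) {
  if (inherits(x, "mccu_tensor")) x <- mean_difference_grid(x)
  n <- nrow(x); p <- ncol(x)
  if (n < min_block || p < min_block) {
    blocks <- data.frame(row_start = 1L, row_end = n, col_start = 1L,
                         col_end = p, status = "retained")
    return(structure(blocks, class = c("mccu_blocks", "data.frame"),
                     row_cp = integer(), col_cp = integer()))
  }
  rmar <- rowMeans(x, na.rm = TRUE); rmar[!is.finite(rmar)] <- 0
  cmar <- colMeans(x, na.rm = TRUE); cmar[!is.finite(cmar)] <- 0
  rcp <- .binseg1d(rmar, min_block, max_changepoints)
  ccp <- .binseg1d(cmar, min_block, max_changepoints)
  rb <- cbind(c(1L, rcp + 1L), c(rcp, n))
  cb <- cbind(c(1L, ccp + 1L), c(ccp, p))
  blocks <- expand.grid(r = seq_len(nrow(rb)), c = seq_len(nrow(cb)))
  blocks <- data.frame(row_start = rb[blocks$r, 1], row_end = rb[blocks$r, 2],
                       col_start = cb[blocks$c, 1], col_end = cb[blocks$c, 2],
                       status = "retained")
  structure(blocks, class = c("mccu_blocks", "data.frame"),
            row_cp = rcp, col_cp = ccp)
}

#' Refine segmentation blocks: L1 low-count removal, tensor-product smooth
#'
#' Block mean signals (pooled mean count per pixel) are soft-thresholded
#' against `lasso_penalty` times the pooled noise scale; blocks whose
#' penalized mean shrinks to zero are dropped as low-count. Within
#' retained high-count blocks (top decile of total pooled counts) the
#' per-pixel expected counts are replaced by a tensor-product spline
#' surface of log counts with `smooth_df` basis functions per axis,
#' damping isolated extreme pixels before testing.
#'
#' @param blocks A [segment_blocks()] object.
#' @param tensor The preprocessed `mccu_tensor`.
#' @param lasso_penalty Nonnegative L1 penalty in units of the pooled
#'   noise scale (default 1).
#' @param smooth_df Tensor-product basis dimension per axis (default 5).
#' @return The blocks with `status` updated (`retained`,
#'   `dropped_low_count`, `smoothed`), penalized means in `$penalized`,
#'   and per-block smoothed expected grids in attribute `expected`.
#' @export
refine_blocks <- function(blocks, tensor, lasso_penalty = 1,
                          smooth_df = 5L) {
  if (lasso_penalty < 0) stop("lasso_penalty must be nonnegative")
  stopifnot(inherits(blocks, "mccu_blocks"), inherits(tensor, "mccu_tensor"))
  P <- Reduce(`+`, c(tensor$a, tensor$b)) / (length(tensor$a) +
                                             length(tensor$b))
  if (!is.null(tensor$mask)) P[tensor$mask] <- 0
  nb <- nrow(blocks)
  bmean <- btot <- numeric(nb)
  for (k in seq_len(nb)) {
    sub <- P[blocks$row_start[k]:blocks$row_end[k],
             blocks$col_start[k]:blocks$col_end[k], drop = FALSE]
    bmean[k] <- mean(sub)
    btot[k] <- sum(sub)
  }
  s <- stats::mad(P[P > 0], constant = 1.4826)
  if (!is.finite(s) || s == 0) s <- mean(P[P > 0])
  if (!is.finite(s)) s <- 1
  penalized <- pmax(bmean - lasso_penalty * s, 0)
  blocks$penalized <- penalized
  drop <- lasso_penalty > 0 & penalized <= 0
  blocks$status[drop] <- "dropped_low_count"
  expected <- vector("list", nb)
  kept <- which(!drop)
  if (length(kept)) {
    hi <- btot[kept] >= quantile(btot[kept], 0.9)
    for (k in kept[hi]) {
      ri <- blocks$row_start[k]:blocks$row_end[k]
      ci <- blocks$col_start[k]:blocks$col_end[k]
      if (length(ri) < smooth_df || length(ci) < smooth_df) next
      sub <- P[ri, ci, drop = FALSE]
      df <- data.frame(y = log(as.vector(sub) + 1),
                       r = rep(seq_along(ri), times = length(ci)),
                       c = rep(seq_along(ci), each = length(ri)))
      fit <- try(mgcv::gam(y ~ te(r, c, k = c(smooth_df, smooth_df)),
                           data = df), silent = TRUE)
      if (inherits(fit, "try-error")) next
      expected[[k]] <- matrix(exp(stats::fitted(fit)) - 1,
                              nrow = length(ri))
      blocks$status[k] <- "smoothed"
    }
  }
  attr(blocks, "expected") <- expected
  blocks
}

# ZINB log-likelihood with identity link; structural-zero probability pi
.zinb_nll <- function(par, y, x, zero_inflated = TRUE) {
  mu <- par[1] + par[2] * x
  clamped <- any(mu < 1e-8)
  mu <- pmax(mu, 1e-8)
  size <- exp(par[3])
  ll <- dnbinom(y, size = size, mu = mu, log = TRUE)
  if (zero_inflated) {
    pi <- stats::plogis(par[4])
    ll <- ifelse(y == 0,
                 log(pi + (1 - pi) * exp(ll)),
                 log(1 - pi) + ll)
  }
  nll <- -sum(ll)
  if (!is.finite(nll)) nll <- 1e10
  attr(nll, "clamped") <- clamped
  nll
}

#' Fit a zero-inflated negative binomial contrast on one block
#'
#' Maximum-likelihood fit of `y ~ ZINB(mu = b0 + b1 * condition, size,
#' pi)` with an identity link and a condition-independent structural-zero
#' probability, with a Wald test on `b1` against a t reference with
#' `length(y) - p` degrees of freedom (p = number of fitted parameters).
#' When the zero-inflation estimate hits the boundary (<= 1e-4) the model
#' falls back to a plain negative binomial. Negative fitted means during
#' optimization are clamped at 1e-8 and flagged.
#'
#' @param y Nonnegative integer counts (one per replicate).
#' @param condition 0/1 vector of the same length.
#' @return List: `effect` (b1), `se`, `p_value`, `zero_inflation`,
#'   `size`, `converged`, `boundary`, `model` ("zinb" or "nb").
#' @export
fit_zinb_block <- function(y, condition) {
  x <- as.numeric(condition)
  y <- as.numeric(round(y))
  n <- length(y)
  if (stats::var(y) == 0 && length(unique(y)) == 1)
    return(list(effect = 0, se = NA_real_, p_value = 1,
                zero_inflation = mean(y == 0), size = NA_real_,
                converged = TRUE, boundary = FALSE, model = "degenerate"))
  m0 <- mean(y[x == 0]); m1 <- mean(y[x == 1])
  v <- stats::var(y)
  m <- mean(y)
  size0 <- if (v > m) min(max(m^2 / (v - m), 0.1), 100) else 10
  fit1 <- try(optim(c(max(m0, 0.1), m1 - m0, log(size0),
                      stats::qlogis(0.05)),
                    .zinb_nll, y = y, x = x, zero_inflated = TRUE,
                    method = "BFGS", hessian = TRUE,
                    control = list(maxit = 500)), silent = TRUE)
  use_nb <- inherits(fit1, "try-error") ||
            stats::plogis(fit1$par[4]) <= 1e-4
  if (!use_nb) {
    fit <- fit1; npar <- 4L
    pi_hat <- stats::plogis(fit$par[4]); model <- "zinb"
  } else {
    fit <- try(optim(c(max(m0, 0.1), m1 - m0, log(size0)),
                     .zinb_nll, y = y, x = x, zero_inflated = FALSE,
                     method = "BFGS", hessian = TRUE,
                     control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(list(effect = NA_real_, se = NA_real_, p_value = NA_real_,
                  zero_inflation = NA_real_, size = NA_real_,
                  converged = FALSE, boundary = FALSE, model = "failed"))
    npar <- 3L; pi_hat <- 0; model <- "nb"
  }
  vc <- try(solve(fit$hessian), silent = TRUE)
  se <- if (inherits(vc, "try-error") || !is.finite(vc[2, 2]) ||
            vc[2, 2] <= 0) NA_real_ else sqrt(vc[2, 2])
  b1 <- fit$par[2]
  p <- if (is.na(se)) NA_real_
       else 2 * stats::pt(-abs(b1 / se), df = max(n - npar, 1))
  mu <- pmax(fit$par[1] + fit$par[2] * x, 1e-8)
  list(effect = b1, se = se, p_value = p, zero_inflation = pi_hat,
       size = exp(fit$par[3]),
       converged = fit$convergence == 0 && !is.na(se),
       boundary = any(fit$par[1] + fit$par[2] * x < 1e-8),
       model = model)
}

#' Test segmentation blocks for differential contact counts
#'
#' For each retained block the per-replicate block count sums are modelled
#' with a zero-inflated negative binomial GLM with identity link (see
#' [fit_zinb_block()]); q-values are Benjamini-Hochberg adjusted across
#' retained blocks (blocks whose optimizer failed are flagged and excluded
#' from the FDR denominator). In blocks marked `smoothed` the per-pixel
#' values are damped at the tensor-smooth expectation plus three Poisson
#' standard deviations before summing.
#'
#' @param blocks A [segment_blocks()]/[refine_blocks()] object.
#' @param tensor The preprocessed `mccu_tensor`.
#' @param alpha FDR level recorded with the result (default 0.05).
#' @return Object of class `mccu_block_tests`: data frame with the block
#'   intervals, per-condition mean counts, `effect`, `se`, `p_value`,
#'   `q_value`, `zero_inflation`, `status`.
#' @export
test_blocks <- function(blocks, tensor, alpha = 0.05) {
  stopifnot(inherits(tensor, "mccu_tensor"))
  if (length(tensor$a) < 2 || length(tensor$b) < 2)
    stop("at least 2 replicates per condition are required")
  expected <- attr(blocks, "expected")
  keep <- which(blocks$status != "dropped_low_count")
  reps <- c(tensor$a, tensor$b)
  x <- rep(c(0, 1), c(length(tensor$a), length(tensor$b)))
  res <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    k <- keep[ii]
    ri <- blocks$row_start[k]:blocks$row_end[k]
    ci <- blocks$col_start[k]:blocks$col_end[k]
    exp_k <- if (!is.null(expected) && length(expected) >= k)
      expected[[k]] else NULL
    y <- vapply(reps, function(m) {
      sub <- m[ri, ci, drop = FALSE]
      if (!is.null(exp_k)) sub <- pmin(sub, exp_k + 3 * sqrt(exp_k) + 1)
      sum(sub)
    }, numeric(1))
    f <- fit_zinb_block(y, x)
    res[[ii]] <- data.frame(
      row_start = blocks$row_start[k], row_end = blocks$row_end[k],
      col_start = blocks$col_start[k], col_end = blocks$col_end[k],
      mean_a = mean(y[x == 0]), mean_b = mean(y[x == 1]),
      effect = f$effect, se = f$se, p_value = f$p_value,
      zero_inflation = f$zero_inflation, status = blocks$status[k],
      model = f$model, converged = f$converged)
  }
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("mccu_block_tests", "data.frame")
  out
}

#' Run the full basepairC differential pipeline
#'
#' Convenience wrapper: [preprocess_counts()], [mean_difference_grid()],
#' [segment_blocks()], [refine_blocks()], [test_blocks()].
#'
#' @param tensor A raw [count_tensor()].
#' @param low_count,outlier_quantile Passed to [preprocess_counts()].
#' @param min_block,max_changepoints Passed to [segment_blocks()].
#' @param lasso_penalty,smooth_df Passed to [refine_blocks()].
#' @param alpha Passed to [test_blocks()].
#' @return A `mccu_block_tests` table.
#' @export
basepairc <- function(tensor, low_count = 2L, outlier_quantile = 0.999,
                      min_block = 10L, max_changepoints = 50L,
                      lasso_penalty = 1, smooth_df = 5L, alpha = 0.05) {
  tensor <- preprocess_counts(tensor, low_count, outlier_quantile)
  blocks <- segment_blocks(tensor, min_block, max_changepoints)
  blocks <- refine_blocks(blocks, tensor, lasso_penalty, smooth_df)
  test_blocks(blocks, tensor, alpha)
}

#' Write a block test table as tab-separated text
#' @param x A `mccu_block_tests` table.
#' @param path Output path.
#' @export
write_block_tests <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
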