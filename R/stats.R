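#' Mass-univariate one-sample t-map
#'
#' Per-voxel one-sample t-test of subject-level values against zero,
#' `t = mean / (sd / sqrt(n))`, df = n - 1, two-tailed p. Zero-variance
#' voxels get p = 1 and are flagged.
#'
#' @param maps subject x voxel matrix (e.g. dual-regression betas averaged
#'   across segments and conditions).
#' @return List: `t`, `p`, `mean`, `df`, `flagged` (logical).
#' @export
one_sample_tmap <- function(maps) {
  n <- nrow(maps)
  stopifnot(n >= 2)
  mu <- colMeans(maps)
  s <- sqrt(colSums(sweep(maps, 2, mu)^2) / (n - 1))
  flagged <- s == 0
  s[flagged] <- Inf
  tv <- mu / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tv), df = n - 1)
  p[flagged] <- 1
  list(t = tv, p = p, mean = mu, df = n - 1, flagged = flagged)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Classic step-up procedure: with ordered p-values p(1) <= ... <= p(m),
#' reject all p <= p(i*) where i* = max\{i : p(i) <= i q / m\}.
#'
#' @param pvals p-values in \[0, 1\] (NA allowed; never rejected).
#' @param q FDR level (default 0.05).
#' @return List: `significant` (logical mask), `threshold` (the rejection
#'   p-value threshold, 0 if no rejections), `n_significant`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  ok <- !is.na(pvals)
  m <- sum(ok)
  if (m == 0)
    return(list(significant = logical(length(pvals)), threshold = 0,
                n_significant = 0L))
  stopifnot(all(pvals[ok] >= 0 & pvals[ok] <= 1))
  ps <- sort(pvals[ok])
  below <- which(ps <= seq_len(m) * q / m)
  thr <- if (length(below)) ps[max(below)] else 0
  sig <- !is.na(pvals) & pvals <= thr & thr > 0
  list(significant = sig, threshold = thr, n_significant = sum(sig))
}

#' Estimate spatial smoothness of a map
#'
#' Classic first-difference estimator: per axis, the variance of differences
#' between face-adjacent in-mask voxels relative to the map variance gives
#' the Gaussian-kernel FWHM `voxel * 2 * sqrt(log(2) / ratio)` with
#' `ratio = var(diff) / var(map)`; axes are combined by geometric mean. For
#' pure white noise the estimator converges to ~1.18 voxel.
#'
#' @param map numeric vector over the in-mask voxels.
#' @param mask a [volume_mask()].
#' @return Estimated FWHM in mm.
#' @export
estimate_smoothness <- function(map, mask) {
  stopifnot(length(map) == mask$n_voxels)
  v <- stats::var(map)
  if (v == 0) stop("map is constant; smoothness is undefined")
  g <- mask$grid
  full <- rep(NA_real_, n_grid_voxels(g))
  full[mask$idx] <- map
  arr <- array(full, dim = g$dim)
  ax_fwhm <- numeric(0)
  for (axis in 1:3) {
    x <- if (axis == 1) arr else aperm(arr, switch(axis - 1, c(2, 1, 3),
                                                   c(3, 2, 1)))
    d <- x[-1, , , drop = FALSE] - x[-dim(x)[1], , , drop = FALSE]
    d <- d[!is.na(d)]
    if (length(d) < 2) next
    ratio <- stats::var(d) / v
    ratio <- min(max(ratio, 1e-6), 4)
    ax_fwhm <- c(ax_fwhm, g$voxel_mm * 2 * sqrt(log(2) / ratio))
  }
  if (length(ax_fwhm) == 0)
    stop("mask too thin to estimate smoothness (need >= 2 voxels per axis)")
  exp(mean(log(ax_fwhm)))
}

#' Monte-Carlo cluster-extent threshold
#'
#' Calibrates the minimum cluster size controlling the family-wise
#' cluster-level error at `alpha`: in each iteration, white noise on the
#' grid is smoothed to the target FWHM, standardized over the mask,
#' thresholded two-tailed at `voxel_p`, and the largest face-connected
#' cluster (positive and negative survivors clustered separately) is
#' recorded. The returned extent is the smallest size exceeded or matched by
#' at most an `alpha` fraction of iterations.
#'
#' @param mask a [volume_mask()].
#' @param fwhm assumed smoothness of the statistical map, mm.
#' @param voxel_p two-tailed voxelwise threshold p (e.g. an FDR-derived
#'   threshold).
#' @param alpha cluster-level error rate (default 0.05).
#' @param n_iter Monte-Carlo iterations (>= 100; default 1000).
#' @param seed integer seed.
#' @return An object of class `cluster_threshold`: `min_size_vox`,
#'   `min_size_mm3`, `alpha`, `n_iter`, `fwhm`, `max_sizes` (per-iteration
#'   maxima).
#' @export
montecarlo_cluster_threshold <- function(mask, fwhm, voxel_p, alpha = 0.05,
                                         n_iter = 1000, seed = 1) {
  stopifnot(n_iter >= 100, voxel_p > 0, voxel_p < 1,
            alpha > 0, alpha <= 1)
  g <- mask$grid
  if (mask$n_voxels < 2) stop("mask is degenerate")
  zc <- stats::qnorm(1 - voxel_p / 2)
  sigma_vox <- if (fwhm > 0) fwhm / (2 * sqrt(2 * log(2))) / g$voxel_mm else 0
  set.seed(as.integer(seed))
  nvox_grid <- n_grid_voxels(g)
  max_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    noise <- matrix(stats::rnorm(nvox_grid), ncol = 1)
    if (sigma_vox > 0) noise <- smooth_flat(noise, g$dim, sigma_vox)
    x <- noise[mask$idx, 1]
    x <- (x - mean(x)) / stats::sd(x)
    mx <- 0L
    for (sgn in c(1, -1)) {
      surv <- which(sgn * x > zc)
      if (length(surv) == 0) next
      cl <- label_clusters(mask$idx[surv], g$dim)
      mx <- max(mx, max(tabulate(cl)))
    }
    max_sizes[it] <- mx
  }
  # smallest s with P(max cluster >= s) <= alpha
  s <- 1L
  while (mean(max_sizes >= s) > alpha) s <- s + 1L
  structure(list(min_size_vox = s, min_size_mm3 = s * g$voxel_mm^3,
                 alpha = alpha, n_iter = n_iter, fwhm = fwhm,
                 voxel_p = voxel_p, max_sizes = max_sizes),
            class = "cluster_threshold")
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf("<cluster_threshold> >= %d voxels (%g mm^3) at cluster alpha %g (fwhm %g mm, voxel p %g, %d iterations)\n",
              x$min_size_vox, x$min_size_mm3, x$alpha, x$fwhm, x$voxel_p,
              x$n_iter))
  invisible(x)
}

# within-subject contrast values for a subject x 2 x 2 array
# (dims: subject, drug level, time level)
rm_contrasts <- function(y) {
  list(drug = (y[, 1, 1] + y[, 1, 2] - y[, 2, 1] - y[, 2, 2]) / 2,
       time = (y[, 1, 1] - y[, 1, 2] + y[, 2, 1] - y[, 2, 2]) / 2,
       `drug:time` = (y[, 1, 1] - y[, 1, 2] - y[, 2, 1] + y[, 2, 2]) / 2)
}

#' 2x2 within-subject repeated-measures ANOVA
#'
#' For a complete two-by-two within-subject design, the F statistic of each
#' factor (and the interaction) with df (1, n - 1) equals the squared paired
#' t of the corresponding within-subject contrast; this identity is used
#' directly.
#'
#' @param y numeric subject x 2 x 2 array (dimensions: subject, drug level,
#'   time level), complete (no NA).
#' @return data.frame with rows `drug`, `time`, `drug:time` and columns
#'   `effect`, `F`, `df1`, `df2`, `p`.
#' @export
rmanova_2x2 <- function(y) {
  stopifnot(length(dim(y)) == 3, dim(y)[2] == 2, dim(y)[3] == 2)
  n <- dim(y)[1]
  stopifnot(n >= 2)
  if (any(is.na(y))) {
    bad <- which(apply(is.na(y), 1, any))
    stop(sprintf("missing cell(s) for subject(s): %s",
                 paste(if (!is.null(dimnames(y)[[1]]))
                   dimnames(y)[[1]][bad] else bad, collapse = ", ")))
  }
  cons <- rm_contrasts(y)
  out <- do.call(rbind, lapply(names(cons), function(nm) {
    x <- cons[[nm]]
    vx <- stats::var(x)
    Fv <- if (vx == 0) 0 else n * mean(x)^2 / vx
    data.frame(effect = nm, F = Fv, df1 = 1, df2 = n - 1,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
  }))
  rownames(out) <- out$effect
  out
}

#' Voxelwise 2x2 repeated-measures ANOVA with FDR and cluster thresholding
#'
#' Applies [rmanova_2x2()] at every voxel (vectorized through the
#' within-subject contrasts), then for each factor applies BH-FDR at level
#' `q` across voxels and drops surviving clusters smaller than
#' `min_cluster_mm3`.
#'
#' @param maps 4D numeric array: subject x drug level x time level x voxel.
#' @param mask a [volume_mask()].
#' @param q FDR level (default 0.05).
#' @param min_cluster_mm3 minimum cluster extent (default 270).
#' @return List per effect (`drug`, `time`, `drug:time`): `F`, `p`
#'   (per-voxel), `fdr_threshold`, `significant` (logical after FDR +
#'   cluster rule), `n_significant`.
#' @export
voxelwise_rmanova <- function(maps, mask, q = 0.05, min_cluster_mm3 = 270) {
  stopifnot(length(dim(maps)) == 4, dim(maps)[2] == 2, dim(maps)[3] == 2,
            dim(maps)[4] == mask$n_voxels)
  n <- dim(maps)[1]
  V <- dim(maps)[4]
  cons <- list(
    drug = (maps[, 1, 1, ] + maps[, 1, 2, ] - maps[, 2, 1, ] - maps[, 2, 2, ]) / 2,
    time = (maps[, 1, 1, ] - maps[, 1, 2, ] + maps[, 2, 1, ] - maps[, 2, 2, ]) / 2,
    `drug:time` = (maps[, 1, 1, ] - maps[, 1, 2, ] - maps[, 2, 1, ] + maps[, 2, 2, ]) / 2)
  min_vox <- ceiling(min_cluster_mm3 / mask$grid$voxel_mm^3)
  out <- lapply(cons, function(x) {
    x <- matrix(x, nrow = n)
    mu <- colMeans(x)
    vx <- colSums(sweep(x, 2, mu)^2) / (n - 1)
    Fv <- ifelse(vx == 0, 0, n * mu^2 / vx)
    p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
    fdr <- bh_fdr(p, q)
    sig <- fdr$significant
    if (any(sig)) {
      cl <- label_clusters(mask$idx[sig], mask$grid$dim)
      keep_cl <- which(tabulate(cl) >= min_vox)
      keep <- logical(V)
      keep[which(sig)[cl %in% keep_cl]] <- TRUE
      sig <- keep
    }
    list(F = Fv, p = p, fdr_threshold = fdr$threshold, significant = sig,
         n_significant = sum(sig))
  })
  out
}

#' Post-hoc paired t-test
#'
#' Standard two-tailed paired t (df = n - 1) between two within-subject
#' columns.
#'
#' @param x,y paired numeric vectors (e.g. per-subject Fisher-Z under two
#'   conditions).
#' @return List: `t`, `p`, `df`, `mean_diff`, `flagged` (TRUE when the
#'   difference has zero variance, in which case t is 0 or +-Inf-free and p
#'   is set to NA).
#' @export
posthoc_paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0)
    return(list(t = 0, p = NA_real_, df = length(d) - 1,
                mean_diff = mean(d), flagged = TRUE))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), flagged = FALSE)
}

#' Brain-behavior correlation
#'
#' Averages both variables across conditions within subject, then Pearson
#' correlation with two-tailed p (df = n - 2).
#'
#' @param conn subject x condition matrix of Fisher-Z values for one
#'   connection.
#' @param behavior subject x condition matrix of behavior scores (same
#'   ordering).
#' @return List: `r`, `p`, `df`, `n`.
#' @export
behavior_correlation <- function(conn, behavior) {
  conn <- as.matrix(conn); behavior <- as.matrix(behavior)
  stopifnot(nrow(conn) == nrow(behavior), nrow(conn) >= 3)
  a <- rowMeans(conn)
  b <- rowMeans(behavior)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in averaged connectivity or behavior")
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(a))
}
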