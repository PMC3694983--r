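#' Temporally concatenate subject segments
#'
#' Each subject's segment is z-normalized per voxel and the matrices are
#' stacked along time, giving the aggregate data matrix decomposed by group
#' spatial ICA.
#'
#' @param segments list of [volume_series()] sharing mask and timepoint
#'   count.
#' @return A `(n_subjects * T)` x V numeric matrix, with attribute
#'   `block_rows` recording each subject's row range.
#' @export
concatenate_group <- function(segments) {
  stopifnot(length(segments) >= 1)
  m0 <- segments[[1]]$mask
  T0 <- nrow(segments[[1]]$data)
  for (s in segments) {
    if (!same_mask(s$mask, m0)) stop("segments do not share a mask")
    if (nrow(s$data) != T0) stop("segments do not share a timepoint count")
  }
  norm <- lapply(segments, function(s) znormalize_time(s)$data)
  out <- do.call(rbind, norm)
  attr(out, "block_rows") <- lapply(seq_along(segments), function(i)
    seq.int((i - 1L) * T0 + 1L, i * T0))
  out
}

#' PCA reduction and whitening of an aggregate matrix
#'
#' Retains the top-k principal components of the spatial covariance (via the
#' temporal Gram matrix, which is cheap when time << voxels) and returns the
#' whitened component scores used by FastICA.
#'
#' @param aggregate time x voxel matrix (rows are volumes).
#' @param k number of components to retain (default 40).
#' @return List: `scores` (k x V whitened rows, unit variance, mutually
#'   uncorrelated), `basis` (time x k eigenvectors of the Gram matrix), `d`
#'   (eigenvalues), `explained` (per-component explained-variance fractions),
#'   `n_t`, `n_voxels`.
#' @export
pca_reduce <- function(aggregate, k = 40) {
  n_t <- nrow(aggregate); V <- ncol(aggregate)
  if (k > min(n_t, V))
    stop(sprintf("k = %d exceeds min(timepoints, voxels) = %d",
                 k, min(n_t, V)))
  G <- tcrossprod(aggregate)            # n_t x n_t
  e <- eigen(G, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  keep <- seq_len(k)
  U <- e$vectors[, keep, drop = FALSE]
  d <- ev[keep]
  if (any(d <= 1e-12 * max(ev)))
    stop("aggregate matrix has rank below k; reduce k")
  # whitened spatial scores: rows have unit variance across voxels
  scores <- (t(U) %*% aggregate) / sqrt(d / V)
  list(scores = scores, basis = U, d = d,
       explained = ev[keep] / sum(ev), n_t = n_t, n_voxels = V)
}

# symmetric decorrelation: W <- (W W^T)^(-1/2) W
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
}

#' Symmetric FastICA on whitened spatial scores
#'
#' Fixed-point FastICA with symmetric (parallel) orthogonalization,
#' extracting k maximally non-Gaussian spatial sources. The cubic (kurtosis)
#' contrast is the default; `tanh` is available. Non-convergence within
#' `maxit` iterations triggers a restart from a fresh random rotation (up to
#' `max_restarts`, then an error). Components are sign-fixed to positive
#' skewness and returned Z-scored across voxels.
#'
#' @param reduced output of [pca_reduce()].
#' @param k number of components (defaults to the reduction order).
#' @param seed integer seed controlling the random initial rotation.
#' @param fun contrast: `"cube"` (default) or `"tanh"`.
#' @param tol convergence tolerance on the rotation update (default 1e-4).
#' @param maxit maximum fixed-point iterations per attempt (default 1000).
#' @param max_restarts restarts on non-convergence (default 5).
#' @return An object of class `group_decomposition`: `modes` (k x V,
#'   spatially Z-scored), `mixing` (time x k), `unmixing` (k x k rotation),
#'   `iterations`, `seed`, plus `condition`/`segment` labels (filled by the
#'   pipeline).
#' @export
fastica_spatial <- function(reduced, k = nrow(reduced$scores), seed = 1,
                            fun = c("cube", "tanh"), tol = 1e-4,
                            maxit = 1000, max_restarts = 5) {
  fun <- match.arg(fun)
  Z <- reduced$scores
  stopifnot(k == nrow(Z))
  V <- ncol(Z)
  attempt_seeds <- as.integer(seed) + seq.int(0L, max_restarts)
  W <- NULL; iters <- NA_integer_
  for (att in attempt_seeds) {
    set.seed(att)
    W0 <- sym_decorrelate(matrix(stats::rnorm(k * k), k))
    Wc <- W0
    converged <- FALSE
    for (it in seq_len(maxit)) {
      U <- Wc %*% Z                      # k x V source estimates
      if (fun == "cube") {
        Wn <- (U^3 %*% t(Z)) / V - 3 * Wc
      } else {
        gu <- tanh(U)
        Wn <- (gu %*% t(Z)) / V - diag(rowMeans(1 - gu^2), k) %*% Wc
      }
      Wn <- sym_decorrelate(Wn)
      delta <- max(abs(abs(diag(Wn %*% t(Wc))) - 1))
      Wc <- Wn
      if (delta < tol) { converged <- TRUE; iters <- it; break }
    }
    if (converged) { W <- Wc; break }
  }
  if (is.null(W))
    stop(sprintf(paste0("FastICA did not converge in %d iterations after %d ",
                        "restarts (tol %.1g); last delta above tolerance"),
                 maxit, max_restarts, tol))
  S <- W %*% Z
  # fix intrinsic sign ambiguity: positive skewness per component
  sk <- rowMeans(S^3)
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip
  W <- W * flip
  # mixing in original (time) space: X ~ mixing %*% S_unscaled; report the
  # least-squares temporal profiles of the Z-scored modes
  modes <- t(scale(t(S)))                # spatial Z-scoring per mode
  mixing <- reduced$basis %*% diag(sqrt(reduced$d / reduced$n_voxels), k) %*%
    t(W)
  structure(list(modes = modes, mixing = mixing, unmixing = W,
                 k = k, iterations = iters, seed = as.integer(seed),
                 condition = NA_character_, segment = NA_character_),
            class = "group_decomposition")
}

#' @export
print.group_decomposition <- function(x, ...) {
  cat(sprintf("<group_decomposition> %d spatial modes x %d voxels (%s/%s), converged in %d iterations\n",
              x$k, ncol(x$modes), x$condition, x$segment, x$iterations))
  invisible(x)
}

#' Decompose an aggregate segment into group spatial modes
#'
#' Convenience wrapper: [concatenate_group()] (if given segments),
#' [pca_reduce()] to k dimensions, then [fastica_spatial()].
#'
#' @param segments list of [volume_series()] (one per subject).
#' @param k number of independent components (default 40).
#' @param seed,fun,tol,maxit passed to [fastica_spatial()].
#' @return A `group_decomposition`.
#' @export
group_ica <- function(segments, k = 40, seed = 1, fun = "cube",
                      tol = 1e-4, maxit = 1000) {
  agg <- concatenate_group(segments)
  red <- pca_reduce(agg, k)
  dec <- fastica_spatial(red, k, seed = seed, fun = fun, tol = tol,
                         maxit = maxit)
  dec$condition <- segments[[1]]$condition
  dec$segment <- segments[[1]]$segment
  dec
}

#' Select the default-mode component by template correlation
#'
#' Correlates each Z-scored spatial mode with a spatial template over the
#' in-mask voxels and returns the mode with the highest absolute
#' correlation, sign-flipped (together with its temporal profile) so the
#' template correlation is positive.
#'
#' @param decomp a `group_decomposition`.
#' @param template numeric vector over the same voxels (e.g. a posterior
#'   cingulate map); must have non-zero variance.
#' @return An object of class `template_match`: `index`, `r_abs`, `all_r`,
#'   and `decomp` (the decomposition with the selected mode re-oriented).
#' @export
select_dmn_component <- function(decomp, template) {
  template <- as.numeric(template)
  stopifnot(length(template) == ncol(decomp$modes))
  if (stats::sd(template) == 0) stop("template has zero variance")
  all_r <- as.numeric(stats::cor(t(decomp$modes), template))
  index <- which.max(abs(all_r))
  if (all_r[index] < 0) {
    decomp$modes[index, ] <- -decomp$modes[index, ]
    decomp$mixing[, index] <- -decomp$mixing[, index]
    decomp$unmixing[index, ] <- -decomp$unmixing[index, ]
    all_r[index] <- -all_r[index]
  }
  structure(list(index = index, r_abs = max(abs(all_r)), all_r = all_r,
                 decomp = decomp),
            class = "template_match")
}

#' @export
print.template_match <- function(x, ...) {
  cat(sprintf("<template_match> mode %d selected, max |r| = %.3f\n",
              x$index, x$r_abs))
  invisible(x)
}

#' Posterior cingulate spatial template
#'
#' A Gaussian template centred on the posterior cingulate / precuneus
#' (centre of mass (-1, -47, 24) mm), with FWHM chosen so the blob's volume
#' above half maximum is about 13,300 mm^3 (sphere-equivalent diameter ~29 mm).
#'
#' @param mask a [volume_mask()].
#' @param center mm 3-vector (default `c(-1, -47, 24)`).
#' @param fwhm template FWHM in mm (default 29).
#' @return Numeric vector over in-mask voxels.
#' @export
pcc_template <- function(mask, center = c(-1, -47, 24), fwhm = 29) {
  nd <- node_spec("PCC_template", center, fwhm = fwhm)
  as.numeric(make_spatial_modes(list(nd), mask$grid, mask))
}
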