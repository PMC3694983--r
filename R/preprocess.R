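#' Build a group analysis mask from anatomies
#'
#' Averages the supplied anatomical volumes and keeps every voxel whose mean
#' intensity reaches the given quantile of the intensity distribution --
#' a simple stand-in for tissue tagging that yields a brain-matter mask of
#' controllable coverage.
#'
#' @param anatomies non-empty list of 3D arrays on identical grids (plain
#'   arrays; grid metadata is supplied separately via `grid`).
#' @param intensity_quantile quantile in \[0, 1) of the mean-anatomy intensity
#'   used as threshold (default 0.5). Voxels at or above the threshold are
#'   kept, so quantile 0 keeps the full grid.
#' @param grid optional [vol_grid()]; defaults to an origin-centred grid of
#'   matching dimensions.
#' @return A [volume_mask()]; the selected voxel count and grid fraction are
#'   attached as attribute `coverage` and shown by `print`.
#' @export
build_group_mask <- function(anatomies, intensity_quantile = 0.5,
                             grid = NULL) {
  stopifnot(length(anatomies) >= 1,
            intensity_quantile >= 0, intensity_quantile < 1)
  d <- dim(anatomies[[1]])
  stopifnot(length(d) == 3)
  for (a in anatomies)
    if (!identical(dim(a), d))
      stop("anatomies are not on identical grids")
  if (is.null(grid)) grid <- vol_grid(d)
  stopifnot(identical(grid$dim, as.integer(d)))
  m <- Reduce(`+`, anatomies) / length(anatomies)
  thr <- stats::quantile(m, intensity_quantile, names = FALSE)
  inside <- as.vector(m >= thr)
  if (!any(inside)) stop("mask is empty at this intensity quantile")
  mask <- volume_mask(grid, inside)
  attr(mask, "coverage") <- c(n_voxels = mask$n_voxels,
                              fraction = mask$n_voxels / prod(d))
  mask
}

#' Drop leading volumes of a run
#'
#' @param series a [volume_series()].
#' @param n number of leading volumes to discard (saturation).
#' @return The trimmed series; `t_index` keeps original volume numbers.
#' @export
discard_volumes <- function(series, n) {
  n <- as.integer(n)
  stopifnot(n >= 0, n < nrow(series$data))
  if (n == 0) return(series)
  keep <- seq.int(n + 1L, nrow(series$data))
  with_data(series, series$data[keep, , drop = FALSE], series$t_index[keep])
}

#' Extract one segment by original volume indices
#'
#' @param series a [volume_series()] (possibly already discarded).
#' @param window inclusive `(first, last)` original volume indices.
#' @param trim_head,trim_tail volumes removed from the window edges.
#' @param segment label attached to the output.
#' @return A [volume_series()] covering the requested original indices that
#'   are present in `series`.
#' @export
extract_segment <- function(series, window, trim_head = 0, trim_tail = 0,
                            segment = NA_character_) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  lo <- window[1] + trim_head
  hi <- window[2] - trim_tail
  if (lo > hi) stop("segment window empty after trimming")
  if (window[2] > max(series$t_index))
    stop("segment window extends past the end of the run")
  keep <- which(series$t_index >= lo & series$t_index <= hi)
  if (length(keep) == 0) stop("segment window contains no retained volumes")
  out <- with_data(series, series$data[keep, , drop = FALSE],
                   series$t_index[keep])
  out$segment <- segment
  out
}

#' Discard saturation volumes and split a run into its resting segments
#'
#' Pure index arithmetic: the initial discard and the window trims compose,
#' and each output records the original volume indices it covers.
#'
#' @param series a full-run [volume_series()].
#' @param layout a [run_layout()].
#' @return List with elements `rs1` and `rs2` ([volume_series()] each).
#' @export
discard_and_segment <- function(series, layout) {
  validate_layout(layout)
  if (layout$n_volumes != nrow(series$data))
    stop(sprintf("layout expects %d volumes but the run has %d",
                 layout$n_volumes, nrow(series$data)))
  s <- discard_volumes(series, layout$discard_initial)
  list(
    rs1 = extract_segment(s, layout$rs1_window, trim_head = 0,
                          trim_tail = layout$rs1_trim_tail, segment = "RS1"),
    rs2 = extract_segment(s, layout$rs2_window,
                          trim_head = layout$rs2_trim_head,
                          trim_tail = layout$rs2_trim_tail, segment = "RS2"))
}

#' Remove per-voxel linear trends
#'
#' Least-squares removal of intercept and slope from every voxel time
#' course; residuals are orthogonal to both the constant and the ramp.
#'
#' @param series a [volume_series()] with at least 3 timepoints.
#' @return The detrended series.
#' @export
detrend_linear <- function(series) {
  T_ <- nrow(series$data)
  stopifnot(T_ >= 3)
  X <- cbind(1, seq_len(T_))
  beta <- solve(crossprod(X), crossprod(X, series$data))
  with_data(series, series$data - X %*% beta)
}

#' High-pass filter by whole-run Fourier cycles
#'
#' Projects out the mean and the first `n_cycles` discrete Fourier pairs of
#' every voxel time course -- an exact, parameter-free realization of
#' "n cycles per time course" filtering. The implied cutoff frequency is
#' `n_cycles / (T * tr)` Hz.
#'
#' @param series a [volume_series()].
#' @param n_cycles number of whole-course cycles to remove (>= 1).
#' @return The filtered series, with the cutoff (Hz) in attribute
#'   `cutoff_hz`.
#' @export
highpass_cycles <- function(series, n_cycles = 5) {
  T_ <- nrow(series$data)
  n_cycles <- as.integer(n_cycles)
  stopifnot(n_cycles >= 1, T_ > 2 * n_cycles)
  F <- stats::mvfft(series$data)
  drop_bins <- c(1L, 1L + seq_len(n_cycles), T_ + 1L - seq_len(n_cycles))
  F[drop_bins, ] <- 0
  out <- with_data(series, Re(stats::mvfft(F, inverse = TRUE)) / T_)
  attr(out, "cutoff_hz") <- highpass_cutoff(n_cycles, T_, series$tr)
  out
}

#' Cutoff frequency of cycle-based high-pass filtering
#'
#' @param n_cycles cycles removed per time course.
#' @param n_t timepoints in the course.
#' @param tr repetition time, seconds.
#' @return Cutoff frequency in Hz, `n_cycles / (n_t * tr)`.
#' @export
highpass_cutoff <- function(n_cycles, n_t, tr) n_cycles / (n_t * tr)

# 1D Gaussian kernel matrix (n x n) for separable convolution along one axis,
# zero padding outside; truncated at 3.5 sigma and renormalized so interior
# mass is conserved.
gauss_axis_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3.5 * sigma_vox))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- w[off + r + 1]
  }
  K
}

# Separable 3D Gaussian convolution applied to a (prod(dim) x T) matrix of
# flattened volumes (column-major voxel order).
smooth_flat <- function(flat, dims, sigma_vox) {
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  n_t <- ncol(flat)
  K1 <- gauss_axis_matrix(d1, sigma_vox)
  K2 <- gauss_axis_matrix(d2, sigma_vox)
  K3 <- gauss_axis_matrix(d3, sigma_vox)
  x <- array(flat, dim = c(d1, d2, d3, n_t))
  dim(x) <- c(d1, d2 * d3 * n_t)
  x <- K1 %*% x
  dim(x) <- c(d1, d2, d3, n_t)
  x <- aperm(x, c(2, 1, 3, 4))
  dim(x) <- c(d2, d1 * d3 * n_t)
  x <- K2 %*% x
  dim(x) <- c(d2, d1, d3, n_t)
  x <- aperm(x, c(3, 2, 1, 4))          # (d3, d1, d2, n_t)
  dim(x) <- c(d3, d1 * d2 * n_t)
  x <- K3 %*% x
  dim(x) <- c(d3, d1, d2, n_t)
  x <- aperm(x, c(2, 3, 1, 4))          # back to (d1, d2, d3, n_t)
  dim(x) <- c(d1 * d2 * d3, n_t)
  x
}

#' Spatial Gaussian smoothing
#'
#' Per-timepoint separable 3D Gaussian convolution. Data outside the mask
#' are treated as zero (zero-padding); by default the result is renormalized
#' by the identically smoothed mask indicator, so spatially constant fields
#' remain constant inside the mask and edge voxels are not attenuated
#' (interior voxels are essentially unaffected). `fwhm_mm = 0` is the
#' identity.
#'
#' @param series a [volume_series()].
#' @param fwhm_mm kernel full width at half maximum, mm (default 6).
#' @param mask_correct divide by the smoothed mask indicator (default TRUE).
#' @return The smoothed series (still restricted to the mask).
#' @export
smooth_gaussian <- function(series, fwhm_mm = 6, mask_correct = TRUE) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(series)
  g <- series$mask$grid
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / g$voxel_mm
  flat <- matrix(0, n_grid_voxels(g), nrow(series$data))
  flat[series$mask$idx, ] <- t(series$data)
  sm <- smooth_flat(flat, g$dim, sigma_vox)
  sm <- sm[series$mask$idx, , drop = FALSE]
  if (mask_correct) {
    ind <- matrix(0, n_grid_voxels(g), 1)
    ind[series$mask$idx, 1] <- 1
    w <- smooth_flat(ind, g$dim, sigma_vox)[series$mask$idx, 1]
    sm <- sm / w
  }
  with_data(series, t(sm))
}

#' Z-normalize voxel time courses
#'
#' Each voxel course is centred and scaled to unit standard deviation.
#' Zero-variance voxels are set to all zeros with a warning.
#'
#' @param series a [volume_series()].
#' @return The normalized series.
#' @export
znormalize_time <- function(series) {
  mu <- colMeans(series$data)
  x <- sweep(series$data, 2, mu)
  s <- sqrt(colSums(x^2) / (nrow(x) - 1))
  zero <- s <= 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance voxel(s) set to 0", sum(zero)))
    s[zero] <- 1
    x[, zero] <- 0
  }
  with_data(series, sweep(x, 2, s, `/`))
}

#' Standard temporal/spatial preprocessing of a full run
#'
#' Fixed order: discard leading volumes, linear detrend, cycle-based
#' high-pass, Gaussian smoothing; then segment extraction. Normalization is
#' applied downstream (aggregation and connectivity stages normalize per
#' segment).
#'
#' @param series a full-run [volume_series()].
#' @param layout a [run_layout()].
#' @param n_highpass_cycles cycles removed per full course (default 5).
#' @param smooth_fwhm smoothing FWHM in mm (default 6).
#' @return List with `rs1`, `rs2` (preprocessed segments) and `full` (the
#'   preprocessed run after discard, before segmentation).
#' @export
preprocess_run <- function(series, layout = paper_run_layout(),
                           n_highpass_cycles = 5, smooth_fwhm = 6) {
  validate_layout(layout)
  if (layout$n_volumes != nrow(series$data))
    stop(sprintf("layout expects %d volumes but the run has %d",
                 layout$n_volumes, nrow(series$data)))
  s <- discard_volumes(series, layout$discard_initial)
  s <- detrend_linear(s)
  s <- highpass_cycles(s, n_highpass_cycles)
  s <- smooth_gaussian(s, smooth_fwhm)
  list(
    rs1 = extract_segment(s, layout$rs1_window, 0, layout$rs1_trim_tail, "RS1"),
    rs2 = extract_segment(s, layout$rs2_window, layout$rs2_trim_head,
                          layout$rs2_trim_tail, "RS2"),
    full = s)
}
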