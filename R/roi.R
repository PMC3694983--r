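# 6-neighbour (face-adjacency) connected components among a set of full-grid
# linear voxel indices. Returns an integer cluster label per input voxel.
label_clusters <- function(idx, dims) {
  if (length(idx) == 0) return(integer(0))
  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)             # 0 = not in set
  d1 <- dims[1]; d12 <- dims[1] * dims[2]
  i0 <- (idx - 1L) %% d1
  j0 <- ((idx - 1L) %/% d1) %% dims[2]
  k0 <- (idx - 1L) %/% d12
  labels <- integer(length(idx))
  cur <- 0L
  for (start in seq_along(idx)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      lv <- idx[v]
      nb <- c(if (i0[v] > 0L)           lv - 1L,
              if (i0[v] < d1 - 1L)      lv + 1L,
              if (j0[v] > 0L)           lv - d1,
              if (j0[v] < dims[2] - 1L) lv + d1,
              if (k0[v] > 0L)           lv - d12,
              if (k0[v] < dims[3] - 1L) lv + d12)
      for (n in nb) {
        p <- pos[n]
        if (p != 0L && labels[p] == 0L) {
          labels[p] <- cur
          queue <- c(queue, p)
        }
      }
    }
  }
  labels
}

#' Define regions of interest from a thresholded statistical map
#'
#' Voxels surviving Benjamini-Hochberg FDR at level `q` are grouped into
#' face-connected (6-neighbour) clusters; clusters smaller than the minimum
#' cluster extent are dropped. Each surviving cluster becomes an ROI,
#' labelled by the nearest canonical node centre within `label_radius` mm of
#' its centre of mass, otherwise by its coordinates.
#'
#' @param pvals per-voxel p-values over the mask (in \[0, 1\]).
#' @param mask a [volume_mask()].
#' @param q FDR level (default 0.05).
#' @param min_cluster_mm3 minimum cluster extent in mm^3 (e.g. from
#'   [montecarlo_cluster_threshold()]; default 270).
#' @param statistic optional per-voxel statistic; if supplied, only voxels
#'   with `statistic > 0` are eligible (network ROIs are positively loaded).
#' @param centers optional data.frame with columns `label, x, y, z` of
#'   reference centres for labelling (default the canonical node table).
#' @param label_radius labelling radius in mm (default 20).
#' @return List of `roi` objects (fields `label`, `voxels` = in-mask column
#'   indices, `grid_idx` = full-grid linear indices, `size_mm3`, `center`),
#'   ordered by decreasing size. Empty list (with a warning) if nothing
#'   survives.
#' @export
define_rois <- function(pvals, mask, q = 0.05, min_cluster_mm3 = 270,
                        statistic = NULL,
                        centers = dmn_node_table(), label_radius = 20) {
  stopifnot(length(pvals) == mask$n_voxels,
            all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  surv <- bh_fdr(pvals, q)$significant
  if (!is.null(statistic)) surv <- surv & statistic > 0
  surv[is.na(surv)] <- FALSE
  if (!any(surv)) {
    warning("no voxels survive FDR thresholding; returning no ROIs")
    return(list())
  }
  g <- mask$grid
  vox_mm3 <- g$voxel_mm^3
  min_vox <- ceiling(min_cluster_mm3 / vox_mm3)
  in_cols <- which(surv)
  full_idx <- mask$idx[in_cols]
  cl <- label_clusters(full_idx, g$dim)
  coords <- grid_coords(g)
  rois <- list()
  for (c_id in unique(cl)) {
    members <- which(cl == c_id)
    if (length(members) < min_vox) next
    gi <- full_idx[members]
    com <- colMeans(coords[gi, , drop = FALSE])
    lab <- sprintf("x%+d_y%+d_z%+d", round(com[1]), round(com[2]),
                   round(com[3]))
    if (!is.null(centers) && nrow(centers) > 0) {
      dd <- sqrt((centers$x - com[1])^2 + (centers$y - com[2])^2 +
                   (centers$z - com[3])^2)
      if (min(dd) <= label_radius) lab <- centers$label[which.min(dd)]
    }
    rois[[length(rois) + 1]] <-
      structure(list(label = lab, voxels = in_cols[members], grid_idx = gi,
                     size_mm3 = length(members) * vox_mm3, center = com),
                class = "roi")
  }
  rois <- rois[order(vapply(rois, `[[`, 0, "size_mm3"), decreasing = TRUE)]
  # disambiguate duplicate labels (larger cluster keeps the bare label)
  labs <- vapply(rois, `[[`, "", "label")
  for (l in unique(labs[duplicated(labs)])) {
    at <- which(labs == l)
    for (j in seq_along(at)[-1])
      rois[[at[j]]]$label <- sprintf("%s.%d", l, j)
  }
  rois
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s: %g mm^3 at (%.0f, %.0f, %.0f) mm\n", x$label,
              x$size_mm3, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Mean time course of an ROI
#'
#' Unweighted mean over the ROI's voxels at every timepoint.
#'
#' @param run a [volume_series()].
#' @param roi an `roi` (in-mask voxel column indices).
#' @return Numeric vector of length T.
#' @export
extract_roi_timeseries <- function(run, roi) {
  if (length(roi$voxels) == 0) stop("ROI is empty")
  stopifnot(max(roi$voxels) <= ncol(run$data))
  rowMeans(run$data[, roi$voxels, drop = FALSE])
}

#' Sine/cosine nuisance regressors above a cutoff frequency
#'
#' Pairs of discrete sines and cosines at every frequency `j / (n_t * tr)`
#' strictly above `cutoff_hz`, up to the Nyquist frequency. All-zero columns
#' (the sine at Nyquist for even T) are dropped.
#'
#' @param n_t timepoints.
#' @param tr repetition time, seconds.
#' @param cutoff_hz lower frequency bound (default 0.1 Hz).
#' @return T x m matrix (possibly 0 columns).
#' @export
highfreq_regressors <- function(n_t, tr, cutoff_hz = 0.1) {
  t_sec <- (seq_len(n_t) - 1) * tr
  jmax <- floor(n_t / 2)
  js <- seq_len(jmax)
  js <- js[js / (n_t * tr) > cutoff_hz]
  if (length(js) == 0) return(matrix(0, n_t, 0))
  out <- do.call(cbind, lapply(js, function(j) {
    f <- j / (n_t * tr)
    cbind(sin(2 * pi * f * t_sec), cos(2 * pi * f * t_sec))
  }))
  colnames(out) <- as.vector(t(outer(js, c("sin", "cos"),
                                     function(j, s) sprintf("%s%d", s, j))))
  keep <- apply(out, 2, function(x) max(abs(x)) > 1e-12)
  out[, keep, drop = FALSE]
}

#' Regress nuisance series out of a time course
#'
#' Least-squares residual of the course on an intercept plus the confound
#' columns. Collinear confounds are handled by pseudoinverse with a warning.
#'
#' @param ts numeric time course.
#' @param confounds T x m numeric matrix (m may be 0).
#' @return The residual course.
#' @export
nuisance_regress <- function(ts, confounds) {
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != length(ts) && ncol(confounds) > 0)
    stop("confound matrix length does not match the time course")
  X <- cbind(intercept = 1, confounds)
  beta <- ls_solve(X, matrix(ts, ncol = 1), "confound")
  as.numeric(ts - X %*% beta)
}

#' Fisher's Z transform of a correlation
#'
#' `atanh` after clipping |r| at `1 - 1e-7` so perfect correlations map to a
#' finite value. Errors if |r| > 1.
#'
#' @param r correlation coefficient(s), |r| <= 1.
#' @return Fisher-Z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| > 1 is not a correlation")
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Pairwise Fisher-Z connectivity of ROI courses
#'
#' Z-normalizes each (windowed) course and computes Pearson correlations for
#' every unordered ROI pair, Fisher-Z transformed. Zero-variance courses
#' yield `NA` entries and a warning.
#'
#' @param roi_ts T x n matrix of (residual) ROI courses, columns named by
#'   ROI.
#' @param windows optional named list of index vectors (rows of `roi_ts`)
#'   defining segments; `NULL` treats the whole matrix as one segment.
#' @param subject,condition identifying labels.
#' @return If `windows` is `NULL`, a single `connectivity_record` (fields
#'   `z`, `r`, labels); otherwise a named list of records, one per window.
#' @export
pairwise_connectivity <- function(roi_ts, windows = NULL,
                                  subject = NA_character_,
                                  condition = NA_character_) {
  roi_ts <- as.matrix(roi_ts)
  stopifnot(ncol(roi_ts) >= 2)
  one <- function(rows, segment) {
    x <- roi_ts[rows, , drop = FALSE]
    if (nrow(x) < 3) stop("segment shorter than 3 timepoints")
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      warning(sprintf("zero-variance ROI course(s): %s; pairs flagged NA",
                      paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- scale(x)
    r <- suppressWarnings(stats::cor(x))
    r[sds == 0, ] <- NA; r[, sds == 0] <- NA
    z <- fisher_z(r)
    diag(z) <- NA
    structure(list(z = z, r = r, subject = subject, condition = condition,
                   segment = segment, roi_labels = colnames(roi_ts)),
              class = "connectivity_record")
  }
  if (is.null(windows)) return(one(seq_len(nrow(roi_ts)), NA_character_))
  out <- lapply(names(windows), function(w) one(windows[[w]], w))
  names(out) <- names(windows)
  out
}

#' @export
print.connectivity_record <- function(x, ...) {
  n <- ncol(x$z)
  cat(sprintf("<connectivity_record> %s/%s/%s: %d ROIs, %d unique pairs\n",
              x$subject, x$condition, x$segment, n, n * (n - 1) / 2))
  invisible(x)
}

#' Long-format table of connectivity records
#'
#' @param records list of `connectivity_record` objects.
#' @return data.frame with columns `subject`, `condition`, `segment`,
#'   `connection` (label "A-B"), `z`.
#' @export
connectivity_table <- function(records) {
  do.call(rbind, lapply(records, function(rec) {
    n <- ncol(rec$z)
    pairs <- which(upper.tri(rec$z), arr.ind = TRUE)
    data.frame(subject = rec$subject, condition = rec$condition,
               segment = rec$segment,
               connection = paste(rec$roi_labels[pairs[, 1]],
                                  rec$roi_labels[pairs[, 2]], sep = "-"),
               z = rec$z[pairs])
  }))
}
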