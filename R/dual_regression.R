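# least-squares solve with pseudoinverse fallback for rank deficiency
ls_solve <- function(X, Y, what = "design") {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning(sprintf("rank-deficient %s matrix (rank %d of %d); using pseudoinverse",
                    what, qx$rank, ncol(X)))
    s <- svd(X)
    pos <- s$d > max(s$d) * 1e-10
    return(s$v[, pos, drop = FALSE] %*%
             ((t(s$u[, pos, drop = FALSE]) %*% Y) / s$d[pos]))
  }
  qr.coef(qx, Y)
}

#' Spatial regression: group modes onto individual volumes
#'
#' First dual-regression step. Every timepoint's volume is regressed jointly
#' on all group spatial modes (plus an intercept); the per-timepoint
#' coefficients are the subject-specific temporal profiles of the modes.
#'
#' @param modes k x V matrix of (Z-scored) spatial modes.
#' @param run a [volume_series()] on the same mask.
#' @return T x k matrix of mode time courses (columns named by mode).
#' @export
spatial_regress <- function(modes, run) {
  stopifnot(ncol(modes) == ncol(run$data))
  X <- cbind(1, t(modes))                       # V x (k+1)
  beta <- ls_solve(X, t(run$data), "spatial mode")
  tc <- t(beta[-1, , drop = FALSE])             # T x k
  colnames(tc) <- rownames(modes)
  tc
}

#' Temporal regression: mode time courses onto voxel courses
#'
#' Second dual-regression step. Every voxel time course is regressed jointly
#' on all mode time courses (plus an intercept); the beta maps are the
#' subject-level spatial estimates of each mode.
#'
#' @param timecourses T x k matrix of mode time courses.
#' @param run a [volume_series()] with matching timepoints.
#' @return k x V matrix of subject beta maps.
#' @export
temporal_regress <- function(timecourses, run) {
  stopifnot(nrow(timecourses) == nrow(run$data))
  X <- cbind(1, timecourses)
  beta <- ls_solve(X, run$data, "time-course")
  maps <- beta[-1, , drop = FALSE]
  rownames(maps) <- colnames(timecourses)
  maps
}

#' Dual-regress a group decomposition onto one run
#'
#' Composition of [spatial_regress()] and [temporal_regress()], yielding a
#' subject's mode time courses and beta maps for one run segment.
#'
#' @param decomp a `group_decomposition`.
#' @param run a [volume_series()].
#' @return An object of class `dual_regression`: `timecourses` (T x k),
#'   `maps` (k x V) and identifying labels.
#' @export
dual_regress_run <- function(decomp, run) {
  tc <- spatial_regress(decomp$modes, run)
  maps <- temporal_regress(tc, run)
  structure(list(timecourses = tc, maps = maps,
                 subject = run$subject, condition = run$condition,
                 segment = run$segment),
            class = "dual_regression")
}

#' @export
print.dual_regression <- function(x, ...) {
  cat(sprintf("<dual_regression> %s/%s/%s: %d modes, %d timepoints x %d voxels\n",
              x$subject, x$condition, x$segment, ncol(x$timecourses),
              nrow(x$timecourses), ncol(x$maps)))
  invisible(x)
}
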