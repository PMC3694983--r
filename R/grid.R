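#' Define a 3D sampling grid
#'
#' A grid is the voxel lattice every volume in an analysis lives on: integer
#' dimensions, an isotropic voxel edge length in mm, and the mm coordinate of
#' the centre of the first voxel (0-based indexing, RAS orientation).
#'
#' @param dim integer 3-vector of grid dimensions (voxels per axis).
#' @param voxel_mm voxel edge length in mm (> 0); voxels are isotropic.
#' @param origin mm coordinates of the centre of voxel (0, 0, 0). Default
#'   centres the grid on the coordinate origin.
#' @return An object of class `vol_grid`.
#' @export
vol_grid <- function(dim, voxel_mm = 3, origin = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), voxel_mm > 0)
  if (is.null(origin)) origin <- -(dim - 1) * voxel_mm / 2
  stopifnot(length(origin) == 3)
  structure(list(dim = dim, voxel_mm = voxel_mm, origin = as.numeric(origin)),
            class = "vol_grid")
}

#' Default analysis grid
#'
#' A 30 x 40 x 28 lattice of 3-mm voxels positioned so that all canonical
#' default-mode node coordinates (see [dmn_nodes()]) fall inside it.
#'
#' @return A `vol_grid`.
#' @export
default_grid <- function() vol_grid(c(30L, 40L, 28L), 3, c(-44, -62, -25))

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid> %d x %d x %d voxels, %.3g mm isotropic, origin (%g, %g, %g) mm\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_mm,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

n_grid_voxels <- function(grid) prod(grid$dim)

#' Voxel-centre coordinates of a grid
#'
#' @param grid a `vol_grid`.
#' @return A `prod(dim)` x 3 matrix of mm coordinates in column-major voxel
#'   order (first axis fastest), matching `as.vector()` of a 3D array.
#' @export
grid_coords <- function(grid) {
  d <- grid$dim
  i <- seq_len(d[1]) - 1L
  j <- seq_len(d[2]) - 1L
  k <- seq_len(d[3]) - 1L
  cbind(
    rep(grid$origin[1] + i * grid$voxel_mm, times = d[2] * d[3]),
    rep(rep(grid$origin[2] + j * grid$voxel_mm, each = d[1]), times = d[3]),
    rep(grid$origin[3] + k * grid$voxel_mm, each = d[1] * d[2])
  )
}

# TRUE if an mm point lies within the grid's cell coverage
point_in_grid <- function(grid, mm) {
  lo <- grid$origin - grid$voxel_mm / 2
  hi <- grid$origin + (grid$dim - 1) * grid$voxel_mm + grid$voxel_mm / 2
  all(mm >= lo & mm <= hi)
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(a$dim, b$dim) &&
    abs(a$voxel_mm - b$voxel_mm) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Construct a volume mask
#'
#' @param grid a `vol_grid`.
#' @param inside logical vector (length `prod(grid$dim)`) or 3D logical array
#'   flagging in-mask voxels.
#' @return An object of class `volume_mask` with fields `grid`, `inside`,
#'   `idx` (linear indices of in-mask voxels) and `n_voxels`.
#' @export
volume_mask <- function(grid, inside) {
  inside <- as.logical(as.vector(inside))
  stopifnot(length(inside) == n_grid_voxels(grid))
  if (!any(inside)) stop("mask is empty: no voxels selected")
  structure(list(grid = grid, inside = inside, idx = which(inside),
                 n_voxels = sum(inside)),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask> %d voxels (%.1f%% of %d x %d x %d grid)\n",
              x$n_voxels, 100 * x$n_voxels / n_grid_voxels(x$grid),
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3]))
  invisible(x)
}

same_mask <- function(a, b) {
  same_grid(a$grid, b$grid) && a$n_voxels == b$n_voxels &&
    all(a$idx == b$idx)
}

#' A masked 4D volume series
#'
#' Stores subject functional data as a time x voxel matrix restricted to a
#' mask, with acquisition metadata. The original volume indices (before any
#' discard or segmentation) travel along in `t_index` so segment provenance
#' round-trips.
#'
#' @param data numeric T x V matrix (V = `mask$n_voxels`).
#' @param mask a `volume_mask`.
#' @param tr repetition time, seconds (> 0).
#' @param subject,condition,segment identifying labels.
#' @param t_index integer vector of original 1-based volume indices
#'   (default `1:T`).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, mask, tr, subject = NA_character_,
                          condition = NA_character_, segment = NA_character_,
                          t_index = NULL) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == mask$n_voxels, tr > 0)
  if (is.null(t_index)) t_index <- seq_len(nrow(data))
  stopifnot(length(t_index) == nrow(data))
  structure(list(data = data, mask = mask, tr = tr,
                 subject = subject, condition = condition, segment = segment,
                 t_index = as.integer(t_index)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series> %s/%s/%s: %d timepoints x %d voxels, TR %g s\n",
              x$subject, x$condition, x$segment, nrow(x$data),
              ncol(x$data), x$tr))
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

# Replace the data matrix, keeping metadata
with_data <- function(series, data, t_index = series$t_index) {
  series$data <- data
  series$t_index <- as.integer(t_index)
  series
}

#' Embed a masked voxel vector into its full 3D grid
#'
#' Out-of-mask voxels are zero.
#'
#' @param values numeric vector of length `mask$n_voxels`.
#' @param mask a `volume_mask`.
#' @return A 3D array of dimension `mask$grid$dim`.
#' @export
unmask <- function(values, mask) {
  stopifnot(length(values) == mask$n_voxels)
  arr <- numeric(n_grid_voxels(mask$grid))
  arr[mask$idx] <- values
  array(arr, dim = mask$grid$dim)
}
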