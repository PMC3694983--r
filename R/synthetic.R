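#' Specify a spatial network node
#'
#' A node is a Gaussian blob placed at an mm coordinate; the set of nodes
#' defines the planted spatial modes of the synthetic cohort.
#'
#' @param label short label, e.g. "PCC".
#' @param center mm 3-vector; must lie inside the simulation grid when used.
#' @param fwhm full width at half maximum of the blob, mm (> 0; a value of 0
#'   is interpreted as the delta limit: a single-voxel indicator).
#' @param amplitude peak amplitude, arbitrary units (> 0).
#' @return An object of class `node_spec`.
#' @export
node_spec <- function(label, center, fwhm = 15, amplitude = 1) {
  stopifnot(is.character(label), length(center) == 3, fwhm >= 0, amplitude > 0)
  structure(list(label = label, center = as.numeric(center),
                 fwhm = fwhm, amplitude = amplitude),
            class = "node_spec")
}

#' Canonical default-mode network nodes
#'
#' Seven nodes at the cluster-peak coordinates classically reported for the
#' default-mode network: posterior cingulate/precuneus (PCC), right and left
#' inferior parietal cortex (RIPC, LIPC), right and left parahippocampal
#' complex (RPHC, LPHC), anterior cingulate/ventromedial prefrontal cortex
#' (ACC), and right middle frontal gyrus (RMFG).
#'
#' @param fwhm blob FWHM in mm applied to every node (default 15 mm, roughly
#'   two 3-mm voxels of Gaussian spread, keeping neighbouring blobs separable
#'   by cluster analysis).
#' @return List of `node_spec` objects.
#' @export
dmn_nodes <- function(fwhm = 15) {
  tab <- dmn_node_table()
  lapply(seq_len(nrow(tab)), function(i)
    node_spec(tab$label[i], c(tab$x[i], tab$y[i], tab$z[i]), fwhm = fwhm))
}

dmn_node_table <- function() {
  data.frame(
    label = c("PCC", "RIPC", "LIPC", "RPHC", "ACC", "LPHC", "RMFG"),
    x = c(0, 44, -44, 21, 1, -22, 23),
    y = c(-51, -59, -59, -14, 53, -11, 21),
    z = c(25, 22, 20, -18, 6, -18, 48)
  )
}

#' Render node specifications as spatial mode maps
#'
#' Each node becomes one row: a non-negative 3D Gaussian blob (peak at the
#' voxel nearest the node centre) flattened over the grid or mask.
#'
#' @param nodes non-empty list of [node_spec()] objects.
#' @param grid a [vol_grid()].
#' @param mask optional [volume_mask()]; if given, rows cover in-mask voxels
#'   only (out-of-mask blob mass is dropped).
#' @return A `length(nodes)` x V numeric matrix with `rownames` = node labels.
#' @export
make_spatial_modes <- function(nodes, grid, mask = NULL) {
  stopifnot(length(nodes) >= 1)
  coords <- grid_coords(grid)
  if (!is.null(mask)) {
    stopifnot(same_grid(grid, mask$grid))
    coords <- coords[mask$idx, , drop = FALSE]
  }
  modes <- matrix(0, length(nodes), nrow(coords))
  rownames(modes) <- vapply(nodes, `[[`, "", "label")
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (!point_in_grid(grid, nd$center))
      stop(sprintf("node '%s' center (%g, %g, %g) lies outside the grid",
                   nd$label, nd$center[1], nd$center[2], nd$center[3]))
    d2 <- (coords[, 1] - nd$center[1])^2 + (coords[, 2] - nd$center[2])^2 +
      (coords[, 3] - nd$center[3])^2
    if (nd$fwhm <= 1e-8) {
      # delta limit: indicator of the nearest voxel
      modes[i, which.min(d2)] <- nd$amplitude
    } else {
      modes[i, ] <- nd$amplitude * exp(-4 * log(2) * d2 / nd$fwhm^2)
    }
  }
  modes
}

#' Describe the volume layout of an acquisition run
#'
#' All windows are expressed in original 1-based volume indices of the full
#' run. `discard_initial` drops the leading saturation volumes; each resting
#' segment is a window further trimmed at its task-facing edge(s).
#'
#' @param n_volumes total volumes acquired per run.
#' @param discard_initial leading volumes dropped (saturation).
#' @param rs1_window,rs2_window inclusive `(first, last)` original indices of
#'   the two resting-state windows.
#' @param rs1_trim_tail volumes trimmed from the end of RS1 (task onset).
#' @param rs2_trim_head volumes trimmed from the start of RS2 (task offset).
#' @param rs2_trim_tail volumes trimmed from the end of RS2 (run end).
#' @return An object of class `run_layout`.
#' @export
run_layout <- function(n_volumes, discard_initial = 0,
                       rs1_window, rs2_window,
                       rs1_trim_tail = 0, rs2_trim_head = 0,
                       rs2_trim_tail = 0) {
  l <- list(n_volumes = as.integer(n_volumes),
            discard_initial = as.integer(discard_initial),
            rs1_window = as.integer(rs1_window),
            rs2_window = as.integer(rs2_window),
            rs1_trim_tail = as.integer(rs1_trim_tail),
            rs2_trim_head = as.integer(rs2_trim_head),
            rs2_trim_tail = as.integer(rs2_trim_tail))
  stopifnot(length(l$rs1_window) == 2, length(l$rs2_window) == 2,
            l$discard_initial >= 0, all(c(l$rs1_trim_tail, l$rs2_trim_head,
                                          l$rs2_trim_tail) >= 0))
  class(l) <- "run_layout"
  validate_layout(l)
  l
}

validate_layout <- function(l) {
  w1 <- l$rs1_window; w2 <- l$rs2_window
  if (w1[1] > w1[2] || w2[1] > w2[2]) stop("segment window bounds reversed")
  if (w1[2] < 1 || w2[2] > l$n_volumes) stop("segment window outside the run")
  if (w1[2] >= w2[1]) stop("segment windows overlap or are out of order")
  r <- segment_ranges(l)
  if (length(r$rs1) < 1 || length(r$rs2) < 1)
    stop("segment empty after discard and trimming")
  invisible(l)
}

# Analyzed original-index ranges of the two segments, after discard + trims
segment_ranges <- function(layout) {
  a1 <- max(layout$rs1_window[1], layout$discard_initial + 1L)
  b1 <- layout$rs1_window[2] - layout$rs1_trim_tail
  a2 <- max(layout$rs2_window[1] + layout$rs2_trim_head,
            layout$discard_initial + 1L)
  b2 <- layout$rs2_window[2] - layout$rs2_trim_tail
  list(rs1 = if (a1 <= b1) seq.int(a1, b1) else integer(0),
       rs2 = if (a2 <= b2) seq.int(a2, b2) else integer(0))
}

#' Standard full-run layout
#'
#' A 1,316-volume run at TR 2 s: two leading volumes discarded for
#' saturation; RS1 = volumes 1-210 with the last 4 trimmed (204 timepoints);
#' a task block (211-1106, not analyzed); RS2 = volumes 1107-1316 with the
#' first 4 and last 2 trimmed (204 timepoints, the tail trim mirroring the
#' initial discard so both segments carry equal length).
#'
#' @return A `run_layout`.
#' @export
paper_run_layout <- function() {
  run_layout(1316L, discard_initial = 2L,
             rs1_window = c(1L, 210L), rs2_window = c(1107L, 1316L),
             rs1_trim_tail = 4L, rs2_trim_head = 4L, rs2_trim_tail = 2L)
}

#' Compact two-segment layout
#'
#' Same discard/trim structure as [paper_run_layout()] but with the task
#' block removed: a 420-volume run whose two resting segments have
#' `t_segment` timepoints each. Useful for simulation studies where only the
#' resting segments matter.
#'
#' @param t_segment analyzed timepoints per segment (default 204).
#' @return A `run_layout`.
#' @export
compact_run_layout <- function(t_segment = 204) {
  t_segment <- as.integer(t_segment)
  e1 <- 2L + t_segment + 4L            # rs1 window end
  run_layout(e1 + 4L + t_segment + 2L, discard_initial = 2L,
             rs1_window = c(1L, e1),
             rs2_window = c(e1 + 1L, e1 + 4L + t_segment + 2L),
             rs1_trim_tail = 4L, rs2_trim_head = 4L, rs2_trim_tail = 2L)
}

#' @export
print.run_layout <- function(x, ...) {
  r <- segment_ranges(x)
  cat(sprintf(paste0("<run_layout> %d volumes, discard %d; RS1 %d-%d (%d analyzed), ",
                     "RS2 %d-%d (%d analyzed)\n"),
              x$n_volumes, x$discard_initial,
              x$rs1_window[1], x$rs1_window[2], length(r$rs1),
              x$rs2_window[1], x$rs2_window[2], length(r$rs2)))
  invisible(x)
}

# ---- planted correlation structure ----------------------------------------

check_corr_matrix <- function(m, labels = NULL, what = "correlation matrix") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  bad <- which(abs(m - t(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("%s not symmetric at pair (%s, %s)", what,
                 labels[bad[1, 1]], labels[bad[1, 2]]))
  if (any(abs(diag(m) - 1) > 1e-8))
    stop(sprintf("%s diagonal not 1 at '%s'", what,
                 labels[which(abs(diag(m) - 1) > 1e-8)[1]]))
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    v <- abs(e$vectors[, which.min(e$values)])
    top <- order(v, decreasing = TRUE)[1:2]
    stop(sprintf("%s not positive semi-definite (min eigenvalue %.3g); largest contribution from pair (%s, %s)",
                 what, min(e$values), labels[top[1]], labels[top[2]]))
  }
  invisible(m)
}

# Accept either a single matrix (both segments) or list(rs1 =, rs2 =)
as_segment_corr <- function(x, labels, what) {
  if (is.matrix(x)) x <- list(rs1 = x, rs2 = x)
  stopifnot(all(c("rs1", "rs2") %in% names(x)))
  for (s in c("rs1", "rs2")) check_corr_matrix(x[[s]], labels,
                                               paste(what, s))
  x
}

#' Planted per-condition connectivity of the default cohort
#'
#' Condition- and segment-specific 7 x 7 node correlation matrices. Six
#' drug-sensitive connections (PCC-RIPC, PCC-RPHC, RIPC-RPHC, LIPC-RPHC,
#' RPHC-ACC, RPHC-RMFG) take condition/segment-specific values (expressed
#' here as correlations, r = tanh(Z) of the planted Fisher-Z levels); all
#' remaining pairs share a common baseline correlation identical across
#' conditions.
#'
#' @param base baseline correlation for non-planted pairs (default 0.5;
#'   positive semi-definiteness of all four matrices holds for the default).
#' @return Named list (`escitalopram`, `placebo`) of `list(rs1 =, rs2 =)`
#'   correlation matrices with node-label dimnames.
#' @export
default_connectivity <- function(base = 0.5) {
  rois <- dmn_node_table()$label
  mk <- function(z) {
    m <- matrix(base, 7, 7, dimnames = list(rois, rois))
    diag(m) <- 1
    for (p in names(z)) {
      ab <- strsplit(p, "-", fixed = TRUE)[[1]]
      m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- tanh(z[[p]])
    }
    m
  }
  list(
    escitalopram = list(
      rs1 = mk(c("PCC-RIPC" = 0.98, "PCC-RPHC" = 0.27, "RIPC-RPHC" = 0.21,
                 "LIPC-RPHC" = 0.17, "RPHC-ACC" = 0.14, "RPHC-RMFG" = 0.12)),
      rs2 = mk(c("PCC-RIPC" = 1.06, "PCC-RPHC" = 0.32, "RIPC-RPHC" = 0.20,
                 "LIPC-RPHC" = 0.24, "RPHC-ACC" = 0.18, "RPHC-RMFG" = 0.25))),
    placebo = list(
      rs1 = mk(c("PCC-RIPC" = 1.30, "PCC-RPHC" = 0.73, "RIPC-RPHC" = 0.60,
                 "LIPC-RPHC" = 0.60, "RPHC-ACC" = 0.40, "RPHC-RMFG" = 0.43)),
      rs2 = mk(c("PCC-RIPC" = 1.32, "PCC-RPHC" = 0.82, "RIPC-RPHC" = 0.68,
                 "LIPC-RPHC" = 0.63, "RPHC-ACC" = 0.48, "RPHC-RMFG" = 0.43))))
}

#' Draw time courses with a target correlation matrix
#'
#' Gaussian innovations pushed through the (eigen-)Cholesky factor of the
#' target matrix, so the population correlation equals the target exactly.
#'
#' @param corr valid correlation matrix (symmetric, unit diagonal, PSD).
#' @param n_t number of timepoints.
#' @return An `n_t` x `ncol(corr)` matrix of unit-variance courses.
#' @export
sample_correlated_courses <- function(corr, n_t) {
  check_corr_matrix(corr)
  e <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(corr))
  matrix(stats::rnorm(n_t * nrow(corr)), n_t) %*% t(L)
}

#' Synthetic anatomy field for a node set
#'
#' A smooth pseudo-anatomy: the pointwise maximum of broadened node blobs
#' (FWHM inflated by `scale`), so that thresholding its mean at a quantile
#' yields a mask that covers the nodes plus surrounding "tissue".
#'
#' @param nodes list of [node_spec()].
#' @param grid a [vol_grid()].
#' @param scale FWHM inflation factor (default 3).
#' @return 3D array over the grid.
#' @export
synthetic_anatomy <- function(nodes, grid, scale = 3) {
  wide <- lapply(nodes, function(nd)
    node_spec(nd$label, nd$center, fwhm = max(nd$fwhm, 1) * scale,
              amplitude = 1))
  m <- make_spatial_modes(wide, grid)
  array(apply(m, 2, max), dim = grid$dim)
}

# ---- cohort simulation -----------------------------------------------------

# zero DFT bins above the cutoff, rescale columns to unit SD (the shared
# linear filter preserves the cross-correlation structure)
lowpass_courses <- function(x, tr, cutoff_hz) {
  if (is.null(cutoff_hz) || !is.finite(cutoff_hz)) return(x)
  T_ <- nrow(x)
  jmax <- floor(cutoff_hz * T_ * tr)
  if (jmax >= floor(T_ / 2)) return(x)
  F <- stats::mvfft(x)
  keep <- c(seq_len(jmax + 1L), T_ + 1L - seq_len(jmax))
  F[-keep, ] <- 0
  y <- Re(stats::mvfft(F, inverse = TRUE)) / T_
  sds <- apply(y, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(y, 2, sds, `/`)
}

#' Simulate a multi-subject two-condition resting-state cohort
#'
#' Generates, for every subject x condition, a full masked BOLD run: node
#' time courses with the planted per-condition/segment correlation structure
#' (Cholesky transform of i.i.d. Gaussian innovations), projected through the
#' node spatial modes, plus a random linear + one-cycle cosine drift, a
#' high-frequency "physiological" sinusoid (> 0.1 Hz, random phase),
#' motion-like smooth confound series coupled through a random spatial
#' pattern, and white noise. The planted correlations are imposed exactly on
#' the analyzed sub-windows of each segment; all remaining volumes carry
#' uncorrelated courses.
#'
#' @param nodes list of [node_spec()] (default [dmn_nodes()]).
#' @param corr named list per condition of correlation matrices (or
#'   `list(rs1 =, rs2 =)` pairs); default [default_connectivity()].
#' @param n_subjects number of subjects (>= 2; default 10).
#' @param grid a [vol_grid()] (default [default_grid()]).
#' @param layout a [run_layout()] (default [paper_run_layout()]).
#' @param tr repetition time, seconds (default 2).
#' @param noise named list of amplitudes: `white` (voxel noise SD), `drift`
#'   (slow drift SD), `highfreq` (physiological sinusoid amplitude), `motion`
#'   (motion coupling SD). Node courses have unit SD, so these are relative
#'   to peak signal.
#' @param signal_cutoff_hz node courses are low-pass filtered below this
#'   frequency within each analyzed segment (default 0.1 Hz, the canonical
#'   band of resting-state fluctuations; correlations are preserved by the
#'   common filter). `NULL` keeps the white spectrum.
#' @param center_jitter_mm SD of a per-subject Gaussian displacement of
#'   every node centre (default 2 mm), emulating residual anatomical
#'   variability after spatial normalization; the same displacement applies
#'   to both conditions of a subject. 0 disables it.
#' @param mask optional [volume_mask()]; by default derived from
#'   [synthetic_anatomy()] at the 0.5 intensity quantile.
#' @param behavior_rho,behavior_means,behavior_link passed to
#'   [make_behavior()]; set `behavior_rho = NULL` to skip behavior.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `dmn_cohort`: `runs` (named list of
#'   [volume_series()], one per subject x condition), `mask`, `anatomy`,
#'   `behavior` and `truth` (a `cohort_truth` carrying the planted modes,
#'   correlation structure, realized segment correlations, confound series
#'   and seed).
#' @export
simulate_cohort <- function(nodes = dmn_nodes(),
                            corr = default_connectivity(),
                            n_subjects = 10,
                            grid = default_grid(),
                            layout = paper_run_layout(),
                            tr = 2,
                            noise = list(white = 1.5, drift = 1,
                                         highfreq = 0.5, motion = 0.3),
                            signal_cutoff_hz = 0.1,
                            center_jitter_mm = 2,
                            mask = NULL,
                            behavior_rho = 0.78,
                            behavior_means = c(escitalopram = 67.0,
                                               placebo = 81.4),
                            behavior_link = c("PCC", "RIPC"),
                            seed = 1) {
  stopifnot(n_subjects >= 2, tr > 0)
  noise <- utils::modifyList(list(white = 1.5, drift = 1, highfreq = 0.5,
                                  motion = 0.3), as.list(noise))
  conditions <- names(corr)
  stopifnot(!is.null(conditions), length(conditions) >= 1)
  labels <- vapply(nodes, `[[`, "", "label")
  corr <- lapply(seq_along(corr), function(i)
    as_segment_corr(corr[[i]], labels, paste0("corr[", conditions[i], "]")))
  names(corr) <- conditions

  anatomy <- synthetic_anatomy(nodes, grid)
  if (is.null(mask)) mask <- build_group_mask(list(anatomy), 0.5, grid = grid)
  stopifnot(same_grid(grid, mask$grid))
  modes <- make_spatial_modes(nodes, grid, mask)
  n_nodes <- length(nodes)
  ranges <- segment_ranges(layout)
  T_run <- layout$n_volumes
  t_sec <- (seq_len(T_run) - 1) * tr

  set.seed(as.integer(seed))
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  runs <- list()
  confounds <- list()
  realized <- array(NA_real_,
                    dim = c(n_subjects, length(conditions), 2, n_nodes, n_nodes),
                    dimnames = list(subjects, conditions, c("rs1", "rs2"),
                                    labels, labels))
  for (s in seq_len(n_subjects)) {
    # subject-level anatomy: jittered node centres shared by both conditions
    modes_s <- modes
    if (center_jitter_mm > 0) {
      nodes_s <- lapply(nodes, function(nd) {
        ctr <- nd$center + stats::rnorm(3, sd = center_jitter_mm)
        # keep jittered centres inside the grid
        lo <- grid$origin - grid$voxel_mm / 2
        hi <- grid$origin + (grid$dim - 1) * grid$voxel_mm + grid$voxel_mm / 2
        node_spec(nd$label, pmin(pmax(ctr, lo), hi), nd$fwhm, nd$amplitude)
      })
      modes_s <- make_spatial_modes(nodes_s, grid, mask)
    }
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      courses <- matrix(stats::rnorm(T_run * n_nodes), T_run)
      for (seg in c("rs1", "rs2")) {
        idx <- ranges[[seg]]
        cs <- sample_correlated_courses(corr[[cond]][[seg]], length(idx))
        cs <- lowpass_courses(cs, tr, signal_cutoff_hz)
        courses[idx, ] <- cs
        realized[s, ci, seg, , ] <- stats::cor(cs)
      }
      X <- courses %*% modes_s
      # slow drift: random-coefficient ramp + one-cycle cosine
      ramp <- seq(-1, 1, length.out = T_run)
      cos1 <- cos(2 * pi * (seq_len(T_run) - 1) / T_run)
      drift <- noise$drift * (stats::rnorm(1) * ramp + stats::rnorm(1) * cos1)
      # high-frequency physiological sinusoid, > 0.1 Hz
      f_hf <- stats::runif(1, 0.11, min(0.2, 1 / (2 * tr) - 1e-3))
      hf <- noise$highfreq * sin(2 * pi * f_hf * t_sec + stats::runif(1, 0, 2 * pi))
      # motion-like smooth series, coupled through a random spatial pattern
      mo <- apply(matrix(stats::rnorm(T_run * 6), T_run), 2, cumsum)
      mo <- scale(mo)[, , drop = FALSE]
      mw <- matrix(stats::rnorm(mask$n_voxels * 6, sd = noise$motion / sqrt(6)),
                   ncol = 6)
      X <- X + (drift + hf) + mo %*% t(mw) +
        matrix(stats::rnorm(T_run * mask$n_voxels, sd = noise$white), T_run)
      run_id <- paste(subjects[s], cond, sep = "_")
      runs[[run_id]] <- volume_series(X, mask, tr, subject = subjects[s],
                                      condition = cond)
      confounds[[run_id]] <- cbind(ramp = ramp, cos1 = cos1, highfreq = hf, mo)
      colnames(confounds[[run_id]]) <-
        c("ramp", "cos1", "highfreq", paste0("motion", 1:6))
    }
  }

  truth <- structure(list(modes_true = modes, corr_true = corr,
                          realized = realized, confounds = confounds,
                          nodes = nodes, labels = labels, grid = grid,
                          layout = layout, tr = tr, noise = noise,
                          seed = as.integer(seed)),
                     class = "cohort_truth")
  cohort <- structure(list(runs = runs, mask = mask, anatomy = anatomy,
                           truth = truth, conditions = conditions,
                           subjects = subjects, behavior = NULL),
                      class = "dmn_cohort")
  if (!is.null(behavior_rho)) {
    cohort$behavior <- make_behavior(truth, link_connection = behavior_link,
                                     rho = behavior_rho,
                                     means = behavior_means)
    truth$behavior_true <- cohort$behavior
    cohort$truth <- truth
  }
  cohort
}

#' @export
print.dmn_cohort <- function(x, ...) {
  cat(sprintf("<dmn_cohort> %d subjects x %d conditions, %d voxels in mask, %d volumes/run\n",
              length(x$subjects), length(x$conditions), x$mask$n_voxels,
              x$truth$layout$n_volumes))
  invisible(x)
}

#' Generate alertness ratings linked to planted connectivity
#'
#' Per-subject, per-condition visual-analogue alertness scores (0-100) whose
#' subject-level condition averages correlate (in expectation) `rho` with the
#' subject's condition-averaged realized connectivity on a designated node
#' pair. Construction: alertness = condition mean + sd_alert * (rho * z-hat +
#' sqrt(1 - rho^2) * noise), with z-hat the standardized subject-level
#' Fisher-Z of the link connection; `rho = 1` therefore yields an exact
#' affine function of connectivity.
#'
#' @param truth a `cohort_truth` from [simulate_cohort()].
#' @param link_connection character 2-vector of node labels.
#' @param rho target correlation, |rho| <= 1.
#' @param means named per-condition mean alertness (names must match the
#'   cohort's conditions).
#' @param sd_alert between-subject alertness SD (default 7.5 VAS points).
#' @return data.frame with columns `subject`, `condition`, `alertness`.
#' @export
make_behavior <- function(truth, link_connection = c("PCC", "RIPC"),
                          rho = 0.78,
                          means = c(escitalopram = 67.0, placebo = 81.4),
                          sd_alert = 7.5) {
  stopifnot(abs(rho) <= 1, length(link_connection) == 2)
  labels <- truth$labels
  if (!all(link_connection %in% labels))
    stop(sprintf("unknown connection label(s): %s",
                 paste(setdiff(link_connection, labels), collapse = ", ")))
  conditions <- dimnames(truth$realized)[[2]]
  if (is.null(names(means)) || !all(conditions %in% names(means)))
    stop("'means' must be named by condition: ",
         paste(conditions, collapse = ", "))
  i <- match(link_connection[1], labels)
  j <- match(link_connection[2], labels)
  subjects <- dimnames(truth$realized)[[1]]
  n <- length(subjects)
  # subject-level connectivity: Fisher-Z averaged over conditions and segments
  zbar <- vapply(seq_len(n), function(s)
    mean(atanh(pmin(pmax(truth$realized[s, , , i, j], -1 + 1e-7), 1 - 1e-7))),
    0)
  zhat <- if (stats::sd(zbar) > 0) as.numeric(scale(zbar)) else rep(0, n)
  eps <- stats::rnorm(n)
  dev <- sd_alert * (rho * zhat + sqrt(max(0, 1 - rho^2)) * eps)
  out <- expand.grid(subject = subjects, condition = conditions,
                     stringsAsFactors = FALSE)
  out$alertness <- pmin(100, pmax(0, means[out$condition] +
                                    dev[match(out$subject, subjects)]))
  rownames(out) <- NULL
  out
}

# ---- on-disk form ----------------------------------------------------------

#' Write a cohort to disk
#'
#' One 4D NIfTI per subject/condition run (out-of-mask voxels zero), a mask
#' NIfTI, a ground-truth JSON (seed, planted correlations, node specs,
#' layout), a behavior TSV and a manifest JSON indexing it all.
#'
#' @param cohort a `dmn_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- cohort$mask$grid
  pix <- rep(g$voxel_mm, 3)
  mask_file <- file.path(dir, "mask.nii.gz")
  marr <- array(as.numeric(cohort$mask$inside), dim = g$dim)
  mimg <- RNifti::asNifti(marr)
  RNifti::pixdim(mimg) <- pix
  RNifti::writeNifti(mimg, mask_file)
  runs <- list()
  for (id in names(cohort$runs)) {
    run <- cohort$runs[[id]]
    arr <- array(0, dim = c(g$dim, nrow(run$data)))
    flat <- matrix(0, n_grid_voxels(g), nrow(run$data))
    flat[cohort$mask$idx, ] <- t(run$data)
    arr[] <- flat
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(pix, run$tr)
    f <- file.path(dir, paste0(id, ".nii.gz"))
    RNifti::writeNifti(img, f)
    runs[[id]] <- list(file = basename(f), subject = run$subject,
                       condition = run$condition)
  }
  if (!is.null(cohort$behavior))
    utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  truth_json <- list(
    seed = tr$seed,
    corr_true = lapply(tr$corr_true, function(cc) lapply(cc, unclass)),
    nodes = lapply(tr$nodes, unclass),
    layout = unclass(tr$layout), tr = tr$tr, noise = tr$noise)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(grid = unclass(g), tr = tr$tr, mask = basename(mask_file),
                   behavior = if (!is.null(cohort$behavior)) "behavior.tsv",
                   truth = "truth.json", runs = runs)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return A `dmn_cohort` (with `truth` restricted to what the JSON stores).
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  g <- vol_grid(mf$grid$dim, mf$grid$voxel_mm, mf$grid$origin)
  marr <- as.array(RNifti::readNifti(file.path(dir, mf$mask)))
  mask <- volume_mask(g, marr > 0.5)
  runs <- list()
  rn <- mf$runs
  for (id in names(rn)) {
    arr <- as.array(RNifti::readNifti(file.path(dir, rn[[id]]$file)))
    flat <- matrix(arr, prod(g$dim))
    runs[[id]] <- volume_series(t(flat[mask$idx, , drop = FALSE]), mask,
                                mf$tr, subject = rn[[id]]$subject,
                                condition = rn[[id]]$condition)
  }
  behavior <- NULL
  if (!is.null(mf$behavior) && file.exists(file.path(dir, mf$behavior)))
    behavior <- utils::read.delim(file.path(dir, mf$behavior))
  tj <- jsonlite::read_json(file.path(dir, mf$truth), simplifyVector = TRUE)
  conditions <- unique(vapply(rn, `[[`, "", "condition"))
  subjects <- unique(vapply(rn, `[[`, "", "subject"))
  structure(list(runs = runs, mask = mask, anatomy = NULL,
                 truth = tj, conditions = conditions, subjects = subjects,
                 behavior = behavior),
            class = "dmn_cohort")
}
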