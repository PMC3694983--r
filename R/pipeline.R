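# tiny FNV-1a hash over a canonical JSON rendering; enough to detect config
# drift between pipeline stages (not cryptographic)
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (keeps h a double within 2^32)
    lowbyte <- h %% 256
    h <- h - lowbyte + bitwXor(lowbyte, b)
    # 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end analysis. Serializable
#' (JSON) and hashable, so outputs can carry a provenance fingerprint.
#'
#' @param k_components independent components for group ICA (default 40).
#' @param q_fdr FDR level for all multiple-comparison corrections (0.05).
#' @param cluster_alpha cluster-level error rate (0.05).
#' @param n_mc_iter Monte-Carlo iterations for cluster calibration (1000).
#' @param nuisance_cutoff_hz lower bound of the sine/cosine nuisance band
#'   (0.1 Hz).
#' @param smooth_fwhm spatial smoothing FWHM, mm (6).
#' @param highpass_cycles whole-run cycles removed by the high-pass (5).
#' @param mask_quantile intensity quantile for the group mask (0.5).
#' @param ica_fun,ica_tol,ica_maxit FastICA contrast and stopping rule.
#' @param layout a [run_layout()] (default [paper_run_layout()]).
#' @param template_center,template_fwhm posterior-cingulate template
#'   geometry (mm).
#' @param label_radius ROI labelling radius, mm (20).
#' @param dmn_overlap_r spatial-correlation level above which a component is
#'   treated as network-related and excluded from the nuisance set (0.2).
#' @param seed integer master seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(k_components = 40, q_fdr = 0.05,
                            cluster_alpha = 0.05, n_mc_iter = 1000,
                            nuisance_cutoff_hz = 0.1, smooth_fwhm = 6,
                            highpass_cycles = 5, mask_quantile = 0.5,
                            ica_fun = "cube", ica_tol = 1e-4,
                            ica_maxit = 1000,
                            layout = paper_run_layout(),
                            template_center = c(-1, -47, 24),
                            template_fwhm = 29,
                            label_radius = 20, dmn_overlap_r = 0.2,
                            seed = 1) {
  stopifnot(k_components >= 2, q_fdr > 0, q_fdr < 1,
            cluster_alpha > 0, cluster_alpha <= 1, n_mc_iter >= 100,
            nuisance_cutoff_hz >= 0, smooth_fwhm >= 0, highpass_cycles >= 1,
            mask_quantile >= 0, mask_quantile < 1, label_radius > 0,
            dmn_overlap_r >= 0, dmn_overlap_r <= 1)
  structure(list(k_components = as.integer(k_components), q_fdr = q_fdr,
                 cluster_alpha = cluster_alpha,
                 n_mc_iter = as.integer(n_mc_iter),
                 nuisance_cutoff_hz = nuisance_cutoff_hz,
                 smooth_fwhm = smooth_fwhm,
                 highpass_cycles = as.integer(highpass_cycles),
                 mask_quantile = mask_quantile,
                 ica_fun = ica_fun, ica_tol = ica_tol,
                 ica_maxit = as.integer(ica_maxit),
                 layout = layout,
                 template_center = as.numeric(template_center),
                 template_fwhm = template_fwhm,
                 label_radius = label_radius,
                 dmn_overlap_r = dmn_overlap_r,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> k=%d, q(FDR)=%g, cluster alpha=%g (%d MC iter), seed=%d, hash=%s\n",
              x$k_components, x$q_fdr, x$cluster_alpha, x$n_mc_iter, x$seed,
              config_hash(x)))
  invisible(x)
}

#' Fingerprint of a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return 8-hex-digit hash string.
#' @export
config_hash <- function(config) {
  fnv1a(jsonlite::toJSON(unclass(lapply(unclass(config), unclass)),
                         auto_unbox = TRUE, digits = 12))
}

# subject x condition x segment x voxel array of DMN beta maps
collect_dmn_maps <- function(dr, subjects, conditions, dmn_index, V) {
  arr <- array(NA_real_, c(length(subjects), length(conditions), 2, V),
               dimnames = list(subjects, conditions, c("RS1", "RS2"), NULL))
  for (s in seq_along(subjects))
    for (ci in seq_along(conditions))
      for (gi in 1:2) {
        seg <- c("RS1", "RS2")[gi]
        arr[s, ci, gi, ] <-
          dr[[conditions[ci]]][[subjects[s]]][[seg]]$maps[dmn_index[ci], ]
      }
  arr
}

#' Run the full connectivity analysis
#'
#' End-to-end orchestration: preprocessing and segmentation of every run;
#' per-condition group spatial ICA on the first resting segment with
#' template-based default-mode component selection; dual regression of the
#' group modes onto both segments; ROI definition from the one-sample t-map
#' of the averaged subject maps (FDR + Monte-Carlo-calibrated cluster
#' extent); nuisance-corrected pairwise ROI connectivity; connection-level
#' and voxelwise 2x2 repeated-measures ANOVA with FDR; post-hoc paired
#' tests; and behavior correlation when ratings are available.
#'
#' @param dataset a `dmn_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, numeric tables, maps
#'   and a provenance log are written there. An existing directory written
#'   under a different configuration hash is refused.
#' @param verbose print stage progress (default TRUE).
#' @return An object of class `dmn_pipeline` (see `print`/`summary`/`plot`
#'   methods).
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         output_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(dataset, "dmn_cohort"),
            inherits(config, "pipeline_config"))
  if (length(dataset$runs) == 0) stop("dataset contains no runs")
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(config)
  if (!is.null(output_dir)) check_output_dir(output_dir, hash)
  mask <- dataset$mask
  conditions <- dataset$conditions
  subjects <- dataset$subjects
  stopifnot(length(conditions) == 2)

  say("preprocessing %d runs ...", length(dataset$runs))
  segs <- list()   # segs[[cond]][[subject]] = list(RS1 =, RS2 =)
  for (id in names(dataset$runs)) {
    run <- dataset$runs[[id]]
    pp <- preprocess_run(run, config$layout,
                         n_highpass_cycles = config$highpass_cycles,
                         smooth_fwhm = config$smooth_fwhm)
    segs[[run$condition]][[run$subject]] <- list(RS1 = pp$rs1, RS2 = pp$rs2)
  }

  template <- pcc_template(mask, config$template_center,
                           config$template_fwhm)
  say("group ICA (k = %d) per condition ...", config$k_components)
  matches <- list(); decomp <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    rs1_list <- lapply(subjects, function(s) segs[[cond]][[s]]$RS1)
    dec <- group_ica(rs1_list, k = config$k_components,
                     seed = config$seed + ci, fun = config$ica_fun,
                     tol = config$ica_tol, maxit = config$ica_maxit)
    dec$condition <- cond; dec$segment <- "RS1"
    matches[[cond]] <- select_dmn_component(dec, template)
    decomp[[cond]] <- matches[[cond]]$decomp
  }
  dmn_index <- vapply(matches, `[[`, 0L, "index")

  say("dual regression onto both segments ...")
  dr <- list()
  for (cond in conditions)
    for (s in subjects)
      dr[[cond]][[s]] <- lapply(segs[[cond]][[s]],
                                function(sg) dual_regress_run(decomp[[cond]], sg))

  maps <- collect_dmn_maps(dr, subjects, conditions, dmn_index,
                           mask$n_voxels)
  avg_maps <- apply(maps, c(1, 4), mean)     # subject x voxel
  tmap <- one_sample_tmap(avg_maps)

  say("smoothness estimation and Monte-Carlo cluster calibration ...")
  resid <- sweep(avg_maps, 2, colMeans(avg_maps))
  fwhm_est <- exp(mean(log(vapply(seq_along(subjects), function(s)
    estimate_smoothness(resid[s, ], mask), 0))))
  voxel_p <- bh_fdr(tmap$p, config$q_fdr)$threshold
  rois <- list(); mc <- NULL
  if (voxel_p > 0) {
    mc <- montecarlo_cluster_threshold(mask, fwhm_est, voxel_p,
                                       alpha = config$cluster_alpha,
                                       n_iter = config$n_mc_iter,
                                       seed = config$seed + 101L)
    rois <- define_rois(tmap$p, mask, q = config$q_fdr,
                        min_cluster_mm3 = mc$min_size_mm3,
                        statistic = tmap$t,
                        label_radius = config$label_radius)
  } else {
    warning("no voxels survive FDR in the one-sample t-map; no ROIs defined")
  }

  out <- structure(list(config = config, config_hash = hash, mask = mask,
                        template_match = matches, dmn_index = dmn_index,
                        decompositions = decomp, tmap = tmap,
                        fwhm_est = fwhm_est, cluster_threshold = mc,
                        rois = rois, subject_maps = maps,
                        conditions = conditions, subjects = subjects,
                        records = list(), connectivity = NULL,
                        rmanova = NULL, significant = NULL, posthoc = NULL,
                        behavior_correlations = NULL, voxelwise = NULL),
                   class = "dmn_pipeline")
  if (length(rois) >= 2) {
    say("ROI connectivity (%d ROIs) and inference ...", length(rois))
    out <- pipeline_connectivity_stage(out, dataset, segs, dr)
  } else {
    warning("fewer than 2 ROIs; connectivity stage skipped")
  }

  say("voxelwise repeated-measures ANOVA ...")
  min_mm3 <- if (!is.null(mc)) mc$min_size_mm3 else 270
  vox <- voxelwise_rmanova(maps, mask, q = config$q_fdr,
                           min_cluster_mm3 = min_mm3)
  out$voxelwise <- lapply(vox, function(v)
    v[c("fdr_threshold", "n_significant")])
  out$voxelwise_full <- vox

  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

# connectivity + inference stages, given preprocessed segments and dual
# regression results
pipeline_connectivity_stage <- function(out, dataset, segs, dr) {
  config <- out$config
  conditions <- out$conditions; subjects <- out$subjects
  rois <- out$rois
  roi_labels <- vapply(rois, `[[`, "", "label")
  records <- list()
  for (cond in conditions) {
    for (s in subjects) {
      run_id <- paste(s, cond, sep = "_")
      truth_conf <- dataset$truth$confounds[[run_id]]
      for (seg in c("RS1", "RS2")) {
        sgs <- segs[[cond]][[s]][[seg]]
        drr <- dr[[cond]][[s]][[seg]]
        # nuisance set: components not overlapping the network ROIs
        dmn_map <- out$decompositions[[cond]]$modes[out$dmn_index[cond], ]
        keep_nuis <- nuisance_component_set(out$decompositions[[cond]],
                                            rois, dmn_map,
                                            config$dmn_overlap_r)
        nuis_tc <- drr$timecourses[, keep_nuis, drop = FALSE]
        conf <- nuis_tc
        if (!is.null(truth_conf)) {
          rows <- match(sgs$t_index, seq_len(nrow(truth_conf)))
          conf <- cbind(conf, truth_conf[rows, , drop = FALSE])
        }
        conf <- cbind(conf, highfreq_regressors(nrow(sgs$data), sgs$tr,
                                                config$nuisance_cutoff_hz))
        roi_ts <- vapply(rois, function(r) {
          nuisance_regress(extract_roi_timeseries(sgs, r), conf)
        }, numeric(nrow(sgs$data)))
        colnames(roi_ts) <- roi_labels
        rec <- pairwise_connectivity(roi_ts, subject = s, condition = cond)
        rec$segment <- seg
        records[[paste(run_id, seg, sep = "_")]] <- rec
      }
    }
  }
  out$records <- records
  conn <- connectivity_table(records)
  out$connectivity <- conn

  connections <- sort(unique(conn$connection))
  anova_rows <- list()
  for (cx in connections) {
    y <- array(NA_real_, c(length(subjects), 2, 2),
               dimnames = list(subjects, conditions, c("RS1", "RS2")))
    sub <- conn[conn$connection == cx, ]
    y[cbind(match(sub$subject, subjects), match(sub$condition, conditions),
            match(sub$segment, c("RS1", "RS2")))] <- sub$z
    if (any(is.na(y))) next
    a <- rmanova_2x2(y)
    a$connection <- cx
    anova_rows[[cx]] <- a
  }
  rman <- do.call(rbind, anova_rows)
  rownames(rman) <- NULL
  out$rmanova <- rman

  sig <- lapply(c("drug", "time", "drug:time"), function(ef) {
    sub <- rman[rman$effect == ef, ]
    fdr <- bh_fdr(sub$p, config$q_fdr)
    sub$connection[fdr$significant]
  })
  names(sig) <- c("drug", "time", "drug:time")
  out$significant <- sig

  # post-hoc paired t per segment for drug-significant connections
  ph <- list()
  for (cx in sig$drug) {
    sub <- conn[conn$connection == cx, ]
    row <- list(connection = cx)
    for (seg in c("RS1", "RS2")) {
      zz <- sub[sub$segment == seg, ]
      m <- tapply(zz$z, zz$condition, mean)[conditions]
      v1 <- zz$z[zz$condition == conditions[1]][match(subjects,
              zz$subject[zz$condition == conditions[1]])]
      v2 <- zz$z[zz$condition == conditions[2]][match(subjects,
              zz$subject[zz$condition == conditions[2]])]
      tt <- posthoc_paired_t(v1, v2)
      row[[paste0(seg, "_", conditions[1])]] <- unname(m[1])
      row[[paste0(seg, "_", conditions[2])]] <- unname(m[2])
      row[[paste0(seg, "_t")]] <- tt$t
      row[[paste0(seg, "_p")]] <- tt$p
    }
    ph[[cx]] <- as.data.frame(row, check.names = FALSE)
  }
  out$posthoc <- if (length(ph)) do.call(rbind, ph) else NULL

  if (!is.null(dataset$behavior)) {
    bh <- dataset$behavior
    bmat <- matrix(NA_real_, length(subjects), 2,
                   dimnames = list(subjects, conditions))
    bmat[cbind(match(bh$subject, subjects),
               match(bh$condition, conditions))] <- bh$alertness
    bc <- lapply(connections, function(cx) {
      sub <- conn[conn$connection == cx, ]
      cm <- tapply(sub$z, list(sub$subject, sub$condition), mean)
      cm <- cm[subjects, conditions, drop = FALSE]
      res <- behavior_correlation(cm, bmat)
      data.frame(connection = cx, r = res$r, p = res$p, df = res$df)
    })
    out$behavior_correlations <- do.call(rbind, bc)
  }
  out
}

# indices of components usable as nuisance regressors: spatially unrelated
# to the selected network (low |r| with the network map and peak outside
# every ROI)
nuisance_component_set <- function(decomp, rois, dmn_map, overlap_r) {
  roi_cols <- unlist(lapply(rois, `[[`, "voxels"))
  ok <- logical(decomp$k)
  for (i in seq_len(decomp$k)) {
    m <- decomp$modes[i, ]
    r <- abs(stats::cor(m, dmn_map))
    peak_in_roi <- which.max(abs(m)) %in% roi_cols
    ok[i] <- (r < overlap_r) && !peak_in_roi
  }
  which(ok)
}

check_output_dir <- function(dir, hash) {
  pf <- file.path(dir, "provenance.json")
  if (file.exists(pf)) {
    prev <- jsonlite::read_json(pf)
    if (!identical(prev$config_hash, hash))
      stop(sprintf("output directory %s was written under config hash %s (current %s); refusing to mix results",
                   dir, prev$config_hash, hash))
  }
  invisible(TRUE)
}

#' Write pipeline outputs to disk
#'
#' TSV tables (ROI table, connectivity, ANOVA, post-hoc, behavior
#' correlations), NIfTI maps (group t-map and per-condition network mode)
#' and a provenance JSON carrying the configuration and its hash. Every TSV
#' starts with a `# config_hash:` comment line.
#'
#' @param report a `dmn_pipeline`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_pipeline_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  check_output_dir(dir, report$config_hash)
  wtab <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    f <- file.path(dir, name)
    con <- file(f, "w")
    writeLines(sprintf("# config_hash: %s", report$config_hash), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (length(report$rois) > 0)
    wtab(roi_table(report), "roi_table.tsv")
  wtab(report$connectivity, "connectivity.tsv")
  wtab(report$rmanova, "rmanova.tsv")
  wtab(report$posthoc, "posthoc.tsv")
  wtab(report$behavior_correlations, "behavior_correlations.tsv")
  g <- report$mask$grid
  wnii <- function(values, name) {
    img <- RNifti::asNifti(unmask(values, report$mask))
    RNifti::pixdim(img) <- rep(g$voxel_mm, 3)
    RNifti::writeNifti(img, file.path(dir, name))
  }
  wnii(report$tmap$t, "group_tmap.nii.gz")
  for (cond in report$conditions)
    wnii(report$decompositions[[cond]]$modes[report$dmn_index[cond], ],
         sprintf("dmn_mode_%s.nii.gz", cond))
  prov <- list(config_hash = report$config_hash,
               config = unclass(lapply(unclass(report$config), unclass)),
               package_version = as.character(utils::packageVersion("dmnconn")),
               written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' ROI summary table
#'
#' @param report a `dmn_pipeline`.
#' @return data.frame with columns `label`, `k_mm3`, `x`, `y`, `z`.
#' @export
roi_table <- function(report) {
  do.call(rbind, lapply(report$rois, function(r)
    data.frame(label = r$label, k_mm3 = r$size_mm3,
               x = round(r$center[1], 1), y = round(r$center[2], 1),
               z = round(r$center[3], 1))))
}

#' @export
print.dmn_pipeline <- function(x, ...) {
  cat("Default-mode network connectivity pipeline\n")
  cat(sprintf("  config hash: %s (seed %d)\n", x$config_hash, x$config$seed))
  for (cond in x$conditions)
    cat(sprintf("  %s: DMN mode %d, template |r| = %.3f\n", cond,
                x$dmn_index[cond], x$template_match[[cond]]$r_abs))
  cat(sprintf("  estimated smoothness: %.1f mm FWHM\n", x$fwhm_est))
  if (!is.null(x$cluster_threshold))
    cat(sprintf("  cluster threshold: %g mm^3 (alpha %g)\n",
                x$cluster_threshold$min_size_mm3,
                x$cluster_threshold$alpha))
  cat(sprintf("  ROIs: %d; connections: %d\n", length(x$rois),
              if (is.null(x$rmanova)) 0 else
                length(unique(x$rmanova$connection))))
  if (!is.null(x$significant))
    cat(sprintf("  significant (q = %g): drug %d, time %d, interaction %d\n",
                x$config$q_fdr, length(x$significant$drug),
                length(x$significant$time),
                length(x$significant$`drug:time`)))
  invisible(x)
}

#' @export
summary.dmn_pipeline <- function(object, ...) {
  print(object)
  if (length(object$rois) > 0) {
    cat("\nROI table:\n")
    print(roi_table(object), row.names = FALSE)
  }
  if (!is.null(object$posthoc)) {
    cat("\nPost-hoc paired tests (drug-significant connections):\n")
    print(object$posthoc, row.names = FALSE, digits = 3)
  }
  if (!is.null(object$behavior_correlations)) {
    cat("\nBehavior correlations (condition-averaged):\n")
    print(object$behavior_correlations, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Plot connection-level F values
#'
#' One heat-map panel per within-subject effect, mirroring the classic
#' connection-matrix display; asterisks mark FDR-significant connections.
#'
#' @param x a `dmn_pipeline`.
#' @param ... unused.
#' @export
plot.dmn_pipeline <- function(x, ...) {
  if (is.null(x$rmanova)) {
    warning("no connection-level results to plot")
    return(invisible(NULL))
  }
  labs <- vapply(x$rois, `[[`, "", "label")
  n <- length(labs)
  effects <- c("drug", "time", "drug:time")
  old <- graphics::par(mfrow = c(1, 3), mar = c(6, 6, 3, 1))
  on.exit(graphics::par(old))
  pair_name <- function(i, j) paste(labs[i], labs[j], sep = "-")
  for (ef in effects) {
    M <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
    sub <- x$rmanova[x$rmanova$effect == ef, ]
    sig <- x$significant[[ef]]
    stars <- NULL
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      at <- match(pair_name(i, j), sub$connection)
      if (is.na(at)) at <- match(pair_name(j, i), sub$connection)
      if (!is.na(at)) {
        M[i, j] <- M[j, i] <- sub$F[at]
        if (sub$connection[at] %in% sig)
          stars <- rbind(stars, c(i, j), c(j, i))
      }
    }
    graphics::image(seq_len(n), seq_len(n), M, axes = FALSE,
                    xlab = "", ylab = "", main = paste("F:", ef),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
    graphics::axis(1, seq_len(n), labs, las = 2)
    graphics::axis(2, seq_len(n), labs, las = 2)
    if (!is.null(stars))
      graphics::text(stars[, 1], stars[, 2], "*", cex = 1.5)
  }
  invisible(x)
}
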