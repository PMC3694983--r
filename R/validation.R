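#' Compact seven-node geometry for connection-level simulation studies
#'
#' Seven Gaussian nodes (labels n1..n7) inside a 14 x 14 x 10 grid of 3-mm
#' voxels -- a small world whose 21 node pairs mirror the seven-region
#' connectivity analysis at a fraction of the cost.
#'
#' @param fwhm node FWHM in mm (default 6).
#' @return List with `nodes`, `grid`.
#' @export
compact_network <- function(fwhm = 6) {
  ctr <- list(c(-15, -15, -6), c(15, -15, -6), c(-15, 15, -6), c(15, 15, -6),
              c(0, 0, 6), c(-15, 0, 9), c(15, 0, 9))
  list(nodes = lapply(seq_along(ctr), function(i)
    node_spec(paste0("n", i), ctr[[i]], fwhm)),
    grid = vol_grid(c(14, 14, 10), 3))
}

# correlation pair for a drug-only effect on three planted connections
recovery_corr <- function(delta_r, base_r) {
  lab <- paste0("n", 1:7)
  m0 <- matrix(base_r, 7, 7, dimnames = list(lab, lab)); diag(m0) <- 1
  m1 <- m0
  for (p in list(c(1, 2), c(3, 4), c(5, 6)))
    m1[p[1], p[2]] <- m1[p[2], p[1]] <- base_r + delta_r
  list(drug = m0, placebo = m1)
}

#' Connection-level parameter-recovery study
#'
#' Repeatedly simulates a two-condition cohort in which the drug condition
#' lowers the correlation of three of 21 node pairs by `delta_r` (equally in
#' both resting segments), runs the connection-level analysis chain
#' (temporal preprocessing, ROI extraction at the true nodes, nuisance
#' regression with the high-frequency bank and the generator's motion
#' series, pairwise Fisher-Z connectivity, per-connection 2x2
#' repeated-measures ANOVA, BH-FDR across connections), and scores detection
#' against the planted truth.
#'
#' @param n_seeds number of independent replicate cohorts (default 50).
#' @param delta_r planted drug-only correlation difference (default 0.4;
#'   0 gives a global-null study).
#' @param base_r baseline correlation of all other pairs (default 0.2).
#' @param n_subjects subjects per cohort (default 10).
#' @param t_segment timepoints per resting segment (default 204).
#' @param q FDR level across the 21 connections (default 0.05).
#' @param noise generator noise amplitudes (moderate defaults).
#' @param seed master seed; cohort s uses `seed + s`.
#' @return data.frame, one row per seed x connection, with columns `seed`,
#'   `connection`, `planted`, `effect` flags (`sig_drug`, `sig_time`,
#'   `sig_int`), and `drug_delta_z` (estimated drug-minus-placebo Fisher-Z).
#' @export
recovery_study <- function(n_seeds = 50, delta_r = 0.4, base_r = 0.2,
                           n_subjects = 10, t_segment = 204, q = 0.05,
                           noise = list(white = 0.5, drift = 1,
                                        highfreq = 0.5, motion = 0.3),
                           seed = 1) {
  net <- compact_network()
  corr <- recovery_corr(delta_r, base_r)
  layout <- compact_run_layout(t_segment)
  planted_pairs <- c("n1-n2", "n3-n4", "n5-n6")
  rows <- list()
  for (s in seq_len(n_seeds)) {
    co <- simulate_cohort(net$nodes, corr, n_subjects = n_subjects,
                          grid = net$grid, layout = layout, tr = 2,
                          noise = noise, behavior_rho = NULL,
                          seed = seed + s)
    rois <- lapply(seq_len(7), function(i) {
      mt <- co$truth$modes_true[i, ]
      structure(list(label = paste0("n", i),
                     voxels = which(mt > 0.5 * max(mt))), class = "roi")
    })
    recs <- list()
    for (id in names(co$runs)) {
      run <- co$runs[[id]]
      pp <- discard_volumes(run, layout$discard_initial)
      pp <- detrend_linear(pp)
      pp <- highpass_cycles(pp, 5)
      for (seg_name in c("rs1", "rs2")) {
        w <- if (seg_name == "rs1") layout$rs1_window else layout$rs2_window
        sg <- extract_segment(pp, w,
                              trim_head = if (seg_name == "rs2")
                                layout$rs2_trim_head else 0,
                              trim_tail = if (seg_name == "rs1")
                                layout$rs1_trim_tail else layout$rs2_trim_tail,
                              segment = toupper(seg_name))
        conf <- cbind(co$truth$confounds[[id]][sg$t_index,
                                               paste0("motion", 1:6)],
                      highfreq_regressors(nrow(sg$data), sg$tr, 0.1))
        roi_ts <- vapply(rois, function(r)
          extract_roi_timeseries(sg, r), numeric(nrow(sg$data)))
        colnames(roi_ts) <- paste0("n", 1:7)
        X <- cbind(1, conf)
        roi_ts <- roi_ts - X %*% ls_solve(X, roi_ts, "confound")
        rec <- pairwise_connectivity(roi_ts, subject = run$subject,
                                     condition = run$condition)
        rec$segment <- toupper(seg_name)
        recs[[paste(id, seg_name, sep = "_")]] <- rec
      }
    }
    conn <- connectivity_table(recs)
    subjects <- sort(unique(conn$subject))
    conditions <- c("drug", "placebo")
    res <- list()
    for (cx in unique(conn$connection)) {
      sub <- conn[conn$connection == cx, ]
      y <- array(NA_real_, c(length(subjects), 2, 2))
      y[cbind(match(sub$subject, subjects),
              match(sub$condition, conditions),
              match(sub$segment, c("RS1", "RS2")))] <- sub$z
      a <- rmanova_2x2(y)
      res[[cx]] <- data.frame(
        seed = seed + s, connection = cx,
        planted = cx %in% planted_pairs,
        p_drug = a["drug", "p"], p_time = a["time", "p"],
        p_int = a["drug:time", "p"],
        drug_delta_z = mean(y[, 1, ]) - mean(y[, 2, ]))
    }
    res <- do.call(rbind, res)
    res$sig_drug <- bh_fdr(res$p_drug, q)$significant
    res$sig_time <- bh_fdr(res$p_time, q)$significant
    res$sig_int <- bh_fdr(res$p_int, q)$significant
    rows[[s]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a recovery study
#'
#' @param study output of [recovery_study()].
#' @return List: `sensitivity` (fraction of planted connections flagged by
#'   the drug factor), `fp_rate` (drug flags on null connections),
#'   `time_rate`, `interaction_rate` (flag rates for the null-distributed
#'   factors), `sign_match` (fraction of flagged planted connections whose
#'   estimated drug effect has the planted negative sign), `n_seeds`.
#' @export
summarize_recovery <- function(study) {
  pl <- study[study$planted, ]
  nu <- study[!study$planted, ]
  flagged <- pl[pl$sig_drug, ]
  list(sensitivity = mean(pl$sig_drug),
       fp_rate = mean(nu$sig_drug),
       time_rate = mean(study$sig_time),
       interaction_rate = mean(study$sig_int),
       sign_match = if (nrow(flagged)) mean(flagged$drug_delta_z < 0) else NA,
       n_seeds = length(unique(study$seed)))
}
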