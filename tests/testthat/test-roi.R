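test_that("cluster-size rule keeps only sufficiently large blobs", {
  g <- vol_grid(c(12, 12, 6), 3)
  m <- full_mask(g)
  p <- rep(1, m$n_voxels)
  arr <- array(seq_len(prod(g$dim)), g$dim)
  big <- as.vector(arr[2:4, 2:6, 2])          # 15 contiguous voxels
  small <- as.vector(arr[8:12, 9, 5])         # 5 contiguous voxels
  p[c(big, small)] <- 1e-6
  rois <- define_rois(p, m, q = 0.05, min_cluster_mm3 = 270,
                      centers = NULL)
  expect_length(rois, 1)
  expect_equal(rois[[1]]$size_mm3, 15 * 27)
  expect_setequal(rois[[1]]$grid_idx, big)
})

test_that("all-null p-maps produce no ROIs, with a warning", {
  m <- full_mask(tiny_grid(c(4, 4, 2)))
  expect_warning(rois <- define_rois(rep(1, m$n_voxels), m), "no voxels")
  expect_length(rois, 0)
})

test_that("ROIs are labelled by the nearest canonical centre within 20 mm", {
  g <- default_grid()
  m <- full_mask(g)
  modes <- make_spatial_modes(dmn_nodes(fwhm = 9), g, m)
  p <- rep(1, m$n_voxels)
  p[modes["PCC", ] > 0.3] <- 1e-8
  p[modes["RMFG", ] > 0.3] <- 1e-8
  rois <- define_rois(p, m, min_cluster_mm3 = 54)
  expect_setequal(vapply(rois, `[[`, "", "label"), c("PCC", "RMFG"))
})

test_that("ROI time series is the unweighted voxel mean", {
  s <- noise_series(20, tiny_grid(c(4, 4, 2)), seed = 3)
  roi <- structure(list(label = "r", voxels = c(2, 9, 17, 20, 25, 31, 1, 6,
                                                12, 28)), class = "roi")
  expect_equal(extract_roi_timeseries(s, roi),
               rowMeans(s$data[, roi$voxels]), tolerance = 1e-12)
  same <- with_data(s, matrix(s$data[, 1], 20, ncol(s$data)))
  expect_equal(extract_roi_timeseries(same, roi), s$data[, 1])
  anti <- with_data(s, cbind(s$data[, 1], -s$data[, 1]))
  anti$mask <- volume_mask(tiny_grid(c(2, 1, 1)), c(TRUE, TRUE))
  roi2 <- structure(list(label = "r2", voxels = 1:2), class = "roi")
  expect_equal(extract_roi_timeseries(anti, roi2), rep(0, 20))
  expect_error(extract_roi_timeseries(s, structure(list(voxels = integer(0)),
                                                   class = "roi")), "empty")
})

test_that("nuisance regression removes planted contamination and nothing else", {
  set.seed(14)
  T_ <- 204; tr <- 2
  t_sec <- (seq_len(T_) - 1) * tr
  # clean signal in the resting-state band (< 0.1 Hz)
  freqs <- c(0.013, 0.027, 0.044, 0.061, 0.08)
  clean <- rowSums(vapply(freqs, function(f)
    rnorm(1) * sin(2 * pi * f * t_sec + runif(1, 0, 2 * pi)),
    numeric(T_)))
  contam <- clean + 1.5 * sin(2 * pi * 0.2 * t_sec + 1)
  hf <- highfreq_regressors(T_, tr, 0.1)
  resid <- nuisance_regress(contam, hf)
  expect_gt(cor(resid, clean), 0.99)
  # orthogonal confound: residual is just the centred course
  conf <- sin(2 * pi * 17 * (seq_len(T_) - 0.5) / T_)
  x <- rep(c(1, -1), T_ / 2)
  r2 <- nuisance_regress(x, matrix(conf))
  expect_equal(r2, x - mean(x) - conf * sum(conf * (x - mean(x))) /
                 sum(conf^2), tolerance = 1e-8)
  # course equal to a confound column vanishes
  r3 <- nuisance_regress(conf, cbind(conf, rnorm(T_)))
  expect_lt(sqrt(sum(r3^2)), 1e-8 * sqrt(sum(conf^2)))
})

test_that("high-frequency regressor bank covers exactly the band above cutoff", {
  hf <- highfreq_regressors(204, 2, 0.1)
  js <- 1:102
  expected <- sum(js / 408 > 0.1) * 2 - 1   # sine at Nyquist is identically 0
  expect_equal(ncol(hf), expected)
  expect_true(all(apply(hf, 2, function(x) max(abs(x)) > 1e-12)))
  expect_equal(ncol(highfreq_regressors(50, 2, 0.3)), 0)
})

test_that("fisher transform is exact, odd, clipped and guarded", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(0.1, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.2), "not a correlation")
})

test_that("pairwise connectivity yields all unique pairs with correct sampling spread", {
  set.seed(15)
  x <- matrix(rnorm(204 * 7), 204)
  colnames(x) <- paste0("r", 1:7)
  rec <- pairwise_connectivity(x, subject = "s01", condition = "c")
  expect_equal(sum(upper.tri(rec$z)), 21)
  expect_true(isSymmetric(rec$z))
  expect_true(all(is.na(diag(rec$z))))

  # planted r = 0.6 at T = 204: Fisher sampling theory check
  corr <- matrix(c(1, 0.6, 0.6, 1), 2)
  zs <- replicate(200, {
    y <- sample_correlated_courses(corr, 204)
    pairwise_connectivity(cbind(a = y[, 1], b = y[, 2]))$z[1, 2]
  })
  se <- 1 / sqrt(201)
  expect_gt(mean(abs(zs - atanh(0.6)) <= 3 * se), 0.97)
  expect_lt(abs(mean(zs) - atanh(0.6)), 4 * se / sqrt(200) + 0.01)
  expect_equal(sd(zs), se, tolerance = 0.2)

  # identical courses: clipped, finite
  same <- cbind(a = x[, 1], b = x[, 1])
  expect_equal(pairwise_connectivity(same)$z[1, 2], atanh(1 - 1e-7))

  # zero-variance course flags its pairs missing
  const <- cbind(a = x[, 1], b = rep(2, 204))
  expect_warning(rec0 <- pairwise_connectivity(const), "zero-variance")
  expect_true(is.na(rec0$z[1, 2]))
})

test_that("connectivity is equivariant under ROI relabelling", {
  set.seed(16)
  x <- matrix(rnorm(100 * 4), 100)
  colnames(x) <- c("A", "B", "C", "D")
  perm <- c(3, 1, 4, 2)
  z1 <- pairwise_connectivity(x)$z
  z2 <- pairwise_connectivity(x[, perm])$z
  expect_equal(unname(z2), unname(z1[perm, perm]), tolerance = 1e-12)
})

test_that("windowed connectivity matches per-segment computation", {
  set.seed(17)
  x <- matrix(rnorm(80 * 3), 80)
  colnames(x) <- c("A", "B", "C")
  recs <- pairwise_connectivity(x, windows = list(RS1 = 1:40, RS2 = 41:80))
  expect_named(recs, c("RS1", "RS2"))
  direct <- pairwise_connectivity(x[41:80, ])
  expect_equal(recs$RS2$z, direct$z)
})

test_that("nuisance regression does not destroy planted connectivity", {
  # generator with all structured-nuisance amplitudes zero
  co <- quad_cohort(n_subjects = 2, t_segment = 150, seed = 23,
                    noise = list(white = 0.05, drift = 0, highfreq = 0,
                                 motion = 0), behavior_rho = NULL)
  lay <- co$truth$layout
  run <- co$runs$s01_placebo
  seg <- discard_and_segment(run, lay)$rs1
  pk <- apply(co$truth$modes_true, 1, which.max)
  roiA <- structure(list(label = "A", voxels = pk[1]), class = "roi")
  roiB <- structure(list(label = "B", voxels = pk[2]), class = "roi")
  tsA <- extract_roi_timeseries(seg, roiA)
  tsB <- extract_roi_timeseries(seg, roiB)
  z_raw <- fisher_z(cor(tsA, tsB))
  conf <- highfreq_regressors(nrow(seg$data), seg$tr, 0.1)
  z_res <- fisher_z(cor(nuisance_regress(tsA, conf),
                        nuisance_regress(tsB, conf)))
  expect_lt(abs(z_res - z_raw), 0.05)
})
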