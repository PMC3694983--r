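test_that("one-sample t-map matches the arithmetic oracle", {
  maps <- cbind(1:10, c(-5:-1, 1:5), rep(2, 10))
  res <- one_sample_tmap(maps)
  expect_equal(res$df, 9)
  expect_equal(res$t[1], 5.5 / (sd(1:10) / sqrt(10)))
  expect_equal(sd(1:10), 3.02765, tolerance = 1e-5)
  expect_equal(res$t[2], 0)
  expect_equal(res$p[2], 1)
  expect_true(res$flagged[3])
  expect_equal(res$p[3], 1)
})

test_that("BH step-up matches the hand-worked rule and p.adjust", {
  p <- c(0.01, 0.02, 0.04, 0.6)
  res <- bh_fdr(p, 0.05)
  expect_equal(res$n_significant, 2L)
  expect_equal(res$threshold, 0.02)
  expect_true(all(bh_fdr(rep(0.001, 21), 0.05)$significant))
  # independent oracle: stats::p.adjust on random p-values
  set.seed(40)
  for (i in 1:20) {
    pv <- runif(50)^sample(1:3, 1)
    expect_identical(bh_fdr(pv, 0.05)$significant,
                     p.adjust(pv, "BH") <= 0.05)
  }
  expect_equal(bh_fdr(numeric(0), 0.05)$n_significant, 0L)
})

test_that("BH controls the empirical false-discovery rate under uniform nulls", {
  set.seed(41)
  m <- 100
  fdp <- replicate(2000, {
    res <- bh_fdr(runif(m), 0.05)
    if (res$n_significant == 0) 0 else 1   # all discoveries false under null
  })
  expect_lte(mean(fdp), 0.05 + 0.01)
})

test_that("smoothness estimator recovers white-noise and 6-mm fields", {
  g <- vol_grid(c(20, 20, 20), 3)
  m <- full_mask(g)
  set.seed(42)
  # analytic plim for white noise: var(diff) = 2 var => fwhm = 1.177 voxel
  est_white <- replicate(20, estimate_smoothness(rnorm(m$n_voxels), m))
  expect_equal(mean(est_white), 2 * sqrt(log(2) / 2) * 3, tolerance = 0.03)
  # known 6-mm smoothing recovered within 15%
  sigma_vox <- 6 / (2 * sqrt(2 * log(2))) / 3
  est6 <- replicate(30, {
    flat <- matrix(rnorm(prod(g$dim)), ncol = 1)
    sm <- dmnconn:::smooth_flat(flat, g$dim, sigma_vox)
    estimate_smoothness(sm[m$idx, 1], m)
  })
  expect_equal(mean(est6), 6, tolerance = 0.15)
  # monotone in applied smoothing
  one <- function(f) {
    set.seed(99)
    flat <- matrix(rnorm(prod(g$dim)), ncol = 1)
    sm <- dmnconn:::smooth_flat(flat, g$dim, f / (2 * sqrt(2 * log(2))) / 3)
    estimate_smoothness(sm[m$idx, 1], m)
  }
  expect_lt(one(3), one(9))
  expect_error(estimate_smoothness(rep(1, m$n_voxels), m), "constant")
})

test_that("monte-carlo cluster threshold matches an analytic null approximation", {
  g <- vol_grid(c(10, 10, 10), 3)
  m <- full_mask(g)
  thr <- montecarlo_cluster_threshold(m, fwhm = 0, voxel_p = 0.001,
                                      alpha = 0.05, n_iter = 1000, seed = 3)
  # independent voxels: P(cluster of >= 2) ~ E[# adjacent suprathreshold
  # pairs] = n_pairs * p^2 (per sign) -- far below alpha, while
  # P(any voxel) = 1 - (1 - p)^V well above alpha => threshold = 2
  V <- 1000
  p <- 0.001
  n_pairs <- 3 * 9 * 10 * 10          # face-adjacent pairs in a 10^3 grid
  expect_gt(1 - (1 - p)^V, 0.05)
  expect_lt(2 * n_pairs * (p / 2)^2, 0.05)
  expect_equal(thr$min_size_vox, 2L)
  expect_equal(thr$min_size_mm3, 54)

  # alpha = 1 admits single voxels
  thr1 <- montecarlo_cluster_threshold(m, 0, 0.001, alpha = 1,
                                       n_iter = 100, seed = 4)
  expect_equal(thr1$min_size_vox, 1L)
})

test_that("cluster threshold grows with smoothness", {
  g <- vol_grid(c(14, 14, 14), 3)
  m <- full_mask(g)
  t3 <- montecarlo_cluster_threshold(m, 3, 0.01, n_iter = 200, seed = 5)
  t9 <- montecarlo_cluster_threshold(m, 9, 0.01, n_iter = 200, seed = 5)
  expect_gte(t9$min_size_vox, t3$min_size_vox)
})

test_that("2x2 repeated-measures F equals the squared contrast paired t", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    y <- array(rnorm(n * 4), c(n, 2, 2))
    res <- rmanova_2x2(y)
    d_drug <- (y[, 1, 1] + y[, 1, 2] - y[, 2, 1] - y[, 2, 2]) / 2
    tt <- t.test(d_drug)
    expect_equal(res["drug", "F"], unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(res["drug", "p"], tt$p.value, tolerance = 1e-8)
  }
})

test_that("2x2 repeated-measures table matches the aov sum-of-squares oracle", {
  set.seed(45)
  for (rep in 1:5) {
    n <- 3 + rep
    y <- array(rnorm(n * 4), c(n, 2, 2))
    df <- expand.grid(subject = factor(1:n), drug = factor(1:2),
                      time = factor(1:2))
    df$y <- as.vector(y)
    fit <- summary(aov(y ~ drug * time + Error(subject / (drug * time)),
                       data = df))
    res <- rmanova_2x2(y)
    get_f <- function(stratum, term) {
      tab <- fit[[stratum]][[1]]
      tab[trimws(rownames(tab)) == term, "F value"]
    }
    expect_equal(res["drug", "F"], get_f("Error: subject:drug", "drug"),
                 tolerance = 1e-8)
    expect_equal(res["time", "F"], get_f("Error: subject:time", "time"),
                 tolerance = 1e-8)
    expect_equal(res["drug:time", "F"],
                 get_f("Error: subject:drug:time", "drug:time"),
                 tolerance = 1e-8)
  }
})

test_that("time-symmetric data yield a null time effect and missing cells error", {
  set.seed(46)
  y <- array(rnorm(8 * 4), c(8, 2, 2))
  y[, , 2] <- y[, , 1]
  res <- rmanova_2x2(y)
  expect_equal(res["time", "F"], 0)
  expect_equal(res["drug:time", "F"], 0)
  y[3, 1, 1] <- NA
  expect_error(rmanova_2x2(y), "3")
})

test_that("voxelwise repeated-measures reduces to the scalar test and respects the null", {
  set.seed(47)
  n <- 10
  m1 <- volume_mask(vol_grid(c(1, 1, 1)), TRUE)
  maps <- array(rnorm(n * 4), c(n, 2, 2, 1))
  vox <- voxelwise_rmanova(maps, m1, q = 0.05, min_cluster_mm3 = 27)
  scal <- rmanova_2x2(maps[, , , 1])
  for (ef in c("drug", "time", "drug:time")) {
    expect_equal(vox[[ef]]$F, scal[ef, "F"], tolerance = 1e-10)
    expect_equal(vox[[ef]]$p, scal[ef, "p"], tolerance = 1e-10)
  }
  # global null on a modest grid: almost never any survivors
  g <- tiny_grid(c(6, 6, 4))
  mk <- full_mask(g)
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    maps <- array(rnorm(8 * 4 * mk$n_voxels), c(8, 2, 2, mk$n_voxels))
    sum(vapply(voxelwise_rmanova(maps, mk, 0.05, 27),
               `[[`, 0, "n_significant"))
  }, 0)
  expect_gte(sum(hits <= 1), 9)
})

test_that("a planted map-level drug effect is detected in the right region", {
  set.seed(48)
  g <- tiny_grid(c(8, 8, 4))
  mk <- full_mask(g)
  n <- 10
  base <- matrix(rnorm(n * mk$n_voxels, mean = 2, sd = 0.3), n)
  region <- 1:40
  maps <- array(0, c(n, 2, 2, mk$n_voxels))
  for (d in 1:2) for (tm in 1:2) {
    eff <- base
    if (d == 1) eff[, region] <- eff[, region] / 2   # amplitude halved
    maps[, d, tm, ] <- eff + rnorm(n * mk$n_voxels, sd = 0.2)
  }
  vox <- voxelwise_rmanova(maps, mk, q = 0.05, min_cluster_mm3 = 108)
  expect_gt(sum(vox$drug$significant[region]), 20)
  expect_lt(sum(vox$drug$significant[-region]), 10)
})

test_that("post-hoc paired t matches its construction", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(posthoc_paired_t(x, x)$t, 0)
  set.seed(49)
  sims <- replicate(500, {
    n <- 10; d <- 0.5; s <- 1
    a <- rnorm(n); b <- a - d + rnorm(n, sd = s)
    posthoc_paired_t(a, b)$t
  })
  # E[t] ~ d / (s / sqrt(n))
  expect_equal(mean(sims), 0.5 / (1 / sqrt(10)), tolerance = 0.15)
  res <- posthoc_paired_t(x, x - 2)
  expect_true(res$flagged)
})

test_that("behavior correlation averages conditions before correlating", {
  conn <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  behav <- 10 + 3 * conn
  res <- behavior_correlation(conn, behav)
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_error(behavior_correlation(conn, matrix(1, 4, 2)), "zero variance")
})

test_that("planted behavior link is recovered across replicate cohorts", {
  co <- quad_cohort(n_subjects = 10, t_segment = 60, seed = 51,
                    behavior_rho = NULL)
  zbar <- vapply(1:10, function(s)
    mean(atanh(co$truth$realized[s, , , 1, 2])), 0)
  set.seed(52)
  rs <- replicate(500, {
    b <- make_behavior(co$truth, c("A", "B"), rho = 0.8,
                       means = c(drug = 67, placebo = 81.4))
    bm <- matrix(b$alertness, nrow = 10)
    cm <- cbind(zbar, zbar)
    behavior_correlation(cm, bm)$r
  })
  expect_equal(mean(rs), 0.8, tolerance = 0.1)
})
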