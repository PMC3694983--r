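test_that("spatial modes peak at the voxel nearest each node center", {
  g <- default_grid()
  nodes <- dmn_nodes()
  modes <- make_spatial_modes(nodes, g)
  coords <- grid_coords(g)
  tab <- data.frame(label = vapply(nodes, `[[`, "", "label"),
                    t(vapply(nodes, `[[`, numeric(3), "center")))
  expect_equal(nrow(modes), 7)
  for (i in seq_along(nodes)) {
    ctr <- nodes[[i]]$center
    d2 <- colSums((t(coords) - ctr)^2)
    expect_identical(which.max(modes[i, ]), which.min(d2),
                     label = sprintf("peak voxel of %s", tab$label[i]))
  }
  # PCC row peaks at the voxel nearest (0, -51, 25)
  pcc <- which(rownames(modes) == "PCC")
  expect_equal(coords[which.max(modes[pcc, ]), ], c(0, -51, 25),
               tolerance = 1.5001, ignore_attr = TRUE)
})

test_that("fwhm -> 0 yields a single-voxel indicator row", {
  g <- tiny_grid()
  m <- make_spatial_modes(list(node_spec("pt", c(0, 0, 0), fwhm = 0)), g)
  expect_equal(sum(m > 0), 1)
  expect_equal(max(m), 1)
})

test_that("well-separated blobs have near-zero spatial correlation", {
  g <- vol_grid(c(24, 12, 12), 3)
  nodes <- list(node_spec("L", c(-20, 0, 0), fwhm = 8),
                node_spec("R", c(20, 0, 0), fwhm = 8))
  m <- make_spatial_modes(nodes, g)
  r <- cor(m[1, ], m[2, ])
  expect_lt(abs(r), 0.05)
  # numeric overlap-integral oracle on the same lattice
  coords <- grid_coords(g)
  f <- function(ctr) exp(-4 * log(2) *
                           colSums((t(coords) - ctr)^2) / 64)
  a <- f(c(-20, 0, 0)); b <- f(c(20, 0, 0))
  r_oracle <- cov(a, b) / (sd(a) * sd(b))
  expect_equal(r, r_oracle, tolerance = 1e-10)
})

test_that("a node outside the grid is reported by name", {
  g <- tiny_grid()
  expect_error(make_spatial_modes(list(node_spec("far", c(500, 0, 0))), g),
               "far")
})

test_that("correlated course sampler hits its target and converges", {
  corr <- quad_corr(0.9, base = 0.3)
  set.seed(42)
  avg <- Reduce(`+`, replicate(5, cor(sample_correlated_courses(corr, 20000)),
                               simplify = FALSE)) / 5
  expect_lt(max(abs(avg - corr)), 0.01)
  bad <- corr; bad["A", "B"] <- bad["B", "A"] <- 1.8
  expect_error(sample_correlated_courses(bad, 10), "positive semi-definite")
  asym <- corr; asym[1, 2] <- 0.1
  expect_error(sample_correlated_courses(asym, 10), "symmetric")
})

test_that("planted node-course correlations are realized in the volumes", {
  # near-zero noise: the voxel at each node peak carries the node course
  co <- simulate_cohort(
    nodes = quad_nodes(), grid = quad_grid(),
    corr = list(A = quad_corr(0.9), B = quad_corr(0.3)),
    n_subjects = 8, layout = compact_run_layout(204), tr = 2,
    noise = list(white = 1e-6, drift = 0, highfreq = 0, motion = 0),
    behavior_rho = NULL, seed = 3)
  pk <- apply(co$truth$modes_true, 1, which.max)
  lay <- co$truth$layout
  for (cond in c("A", "B")) {
    rs <- unlist(lapply(co$subjects, function(s) {
      run <- co$runs[[paste0(s, "_", cond)]]
      segs <- discard_and_segment(run, lay)
      vapply(segs, function(sg) cor(sg$data[, pk[1]], sg$data[, pk[2]]), 0)
    }))
    target <- if (cond == "A") 0.9 else 0.3
    expect_lt(abs(mean(rs) - target), 0.05)
  }
  # the recorded realized correlation equals the empirical peak-voxel one
  seg <- discard_and_segment(co$runs$s01_A, lay)$rs1
  expect_equal(unname(co$truth$realized["s01", "A", "rs1", 1, 2]),
               cor(seg$data[, pk[1]], seg$data[, pk[2]]), tolerance = 1e-6)
})

test_that("identity-correlation courses show only null-level sample correlation", {
  # Monte-Carlo null at T = 204: E|r| ~ sqrt(2/pi)/sqrt(T-1)
  set.seed(99)
  T_ <- 204
  vals <- replicate(200, {
    x <- sample_correlated_courses(diag(3), T_)
    r <- cor(x)
    mean(abs(r[upper.tri(r)]))
  })
  expected <- sqrt(2 / pi) / sqrt(T_ - 1)
  expect_lt(abs(mean(vals) - expected), 0.1 * expected)
})

test_that("anatomical jitter varies subjects but not reproducibility", {
  a <- quad_cohort(n_subjects = 2, t_segment = 20, seed = 7, jitter = 3)
  b <- quad_cohort(n_subjects = 2, t_segment = 20, seed = 7, jitter = 3)
  expect_identical(a$runs$s01_drug$data, b$runs$s01_drug$data)
  # with jitter, the two subjects carry different spatial patterns of the
  # same planted courses; without it, spatial profiles coincide
  c0 <- quad_cohort(n_subjects = 2, t_segment = 20, seed = 7, jitter = 0)
  pk <- apply(c0$truth$modes_true, 1, which.max)
  prof <- function(co, s) {
    run <- co$runs[[paste0(s, "_drug")]]
    colMeans(run$data[, pk]^2)
  }
  expect_false(isTRUE(all.equal(prof(a, "s01"), prof(a, "s02"),
                                tolerance = 1e-3)))
})

test_that("identical seeds reproduce the cohort bit for bit", {
  a <- quad_cohort(n_subjects = 2, t_segment = 20, seed = 7)
  b <- quad_cohort(n_subjects = 2, t_segment = 20, seed = 7)
  c <- quad_cohort(n_subjects = 2, t_segment = 20, seed = 8)
  expect_identical(a$runs$s01_drug$data, b$runs$s01_drug$data)
  expect_identical(a$behavior, b$behavior)
  expect_false(identical(a$runs$s01_drug$data, c$runs$s01_drug$data))
})

test_that("volumes are finite and masked-out voxels are written as zero", {
  co <- quad_cohort(n_subjects = 2, t_segment = 10, seed = 2)
  for (r in co$runs) expect_true(all(is.finite(r$data)))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  arr <- as.array(RNifti::readNifti(file.path(d, "s01_drug.nii.gz")))
  out_idx <- which(!co$mask$inside)
  flat <- matrix(arr, prod(dim(arr)[1:3]))
  expect_true(all(flat[out_idx, ] == 0))
  # round trip
  back <- read_cohort(d)
  expect_equal(back$runs$s01_drug$data, co$runs$s01_drug$data,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$mask$idx, co$mask$idx)
})

test_that("behavior generator matches requested means and planted link", {
  co <- quad_cohort(n_subjects = 8, t_segment = 60, seed = 21,
                    behavior_rho = NULL)
  tr <- co$truth

  set.seed(1)
  b1 <- make_behavior(tr, c("A", "B"), rho = 1,
                      means = c(drug = 50, placebo = 70))
  m <- tapply(b1$alertness, b1$condition, mean)
  # rho = 1: deviations identical across conditions, so means shift exactly
  expect_equal(unname(m["placebo"] - m["drug"]), 20, tolerance = 1e-8)
  # exact affine function of the subject-level link connectivity
  zbar <- vapply(seq_len(8), function(s)
    mean(atanh(tr$realized[s, , , 1, 2])), 0)
  a_drug <- b1$alertness[b1$condition == "drug"]
  expect_equal(abs(cor(a_drug, zbar)), 1, tolerance = 1e-8)

  # rho = 0: behavior independent of connectivity across replicates
  rs <- replicate(500, {
    b <- make_behavior(tr, c("A", "B"), rho = 0,
                       means = c(drug = 50, placebo = 70))
    cor(b$alertness[b$condition == "drug"], zbar)
  })
  expect_lt(abs(mean(rs)), 3 / sqrt(500 * 7))

  expect_error(make_behavior(tr, c("A", "nope"), 0.5,
                             c(drug = 1, placebo = 2)), "nope")
})
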