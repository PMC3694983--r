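# Small in-code fixtures shared across the suite.

tiny_grid <- function(dims = c(10, 11, 9), voxel = 3) vol_grid(dims, voxel)

full_mask <- function(grid) volume_mask(grid, rep(TRUE, prod(grid$dim)))

# a series of pure noise on a full-grid mask
noise_series <- function(n_t, grid = tiny_grid(), tr = 2, seed = 1) {
  set.seed(seed)
  m <- full_mask(grid)
  volume_series(matrix(rnorm(n_t * m$n_voxels), n_t), m, tr,
                subject = "s01", condition = "test")
}

# four well-separated nodes inside a 16 x 16 x 12 grid of 3-mm voxels
quad_nodes <- function(fwhm = 6) {
  list(node_spec("A", c(-12, -12, -3), fwhm),
       node_spec("B", c(12, -12, -3), fwhm),
       node_spec("C", c(-12, 12, 3), fwhm),
       node_spec("D", c(12, 12, 3), fwhm))
}

quad_grid <- function() vol_grid(c(16, 16, 12), 3)

# correlation matrix helper for the quad nodes: baseline plus one planted pair
quad_corr <- function(ab = 0.5, base = 0.2) {
  m <- matrix(base, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- ab
  diag(m) <- 1
  m
}

# a compact two-condition cohort for integration-style tests
# jitter disabled by default: unit tests rely on controlled geometry
quad_cohort <- function(n_subjects = 4, t_segment = 80, seed = 5,
                        ab = c(drug = 0.2, placebo = 0.7),
                        noise = list(white = 0.4, drift = 1, highfreq = 0.4,
                                     motion = 0.2),
                        behavior_rho = 0.8, jitter = 0) {
  simulate_cohort(
    nodes = quad_nodes(), grid = quad_grid(),
    corr = list(drug = quad_corr(ab[["drug"]]),
                placebo = quad_corr(ab[["placebo"]])),
    n_subjects = n_subjects, layout = compact_run_layout(t_segment), tr = 2,
    noise = noise, behavior_rho = behavior_rho,
    behavior_means = c(drug = 67.0, placebo = 81.4),
    behavior_link = c("A", "B"), center_jitter_mm = jitter, seed = seed)
}

# seven compact nodes for connection-level recovery studies (labels n1..n7)
seven_nodes <- function(fwhm = 6) {
  ctr <- list(c(-15, -15, -6), c(15, -15, -6), c(-15, 15, -6), c(15, 15, -6),
              c(0, 0, 6), c(-15, 0, 9), c(15, 0, 9))
  lapply(seq_along(ctr), function(i)
    node_spec(paste0("n", i), ctr[[i]], fwhm))
}

seven_grid <- function() vol_grid(c(14, 14, 10), 3)

# planted drug-only effect: pairs (1,2), (3,4), (5,6) get delta_r added in
# the placebo condition; all other pairs share the baseline in both
seven_corr <- function(delta_r = 0.4, base = 0.2) {
  lab <- paste0("n", 1:7)
  m0 <- matrix(base, 7, 7, dimnames = list(lab, lab)); diag(m0) <- 1
  m1 <- m0
  for (p in list(c(1, 2), c(3, 4), c(5, 6))) {
    m1[p[1], p[2]] <- m1[p[2], p[1]] <- base + delta_r
  }
  list(drug = m0, placebo = m1)
}
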