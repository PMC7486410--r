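# assembly_set with prescribed unit-norm patterns, for algebraic tests
make_aset <- function(patterns, zcounts) {
  structure(list(n_significant = ncol(patterns), patterns = patterns,
                 activities = NULL, eigenvalues = NULL,
                 eigen_threshold = NA_real_, zcounts = zcounts,
                 counts = NULL, bin_map = NULL, bin_s = 0.2,
                 frame_rate_hz = 9.85, kept_cells = seq_len(nrow(patterns)),
                 dropped_cells = integer(), underdetermined = FALSE,
                 n_shuffles = 0),
            class = "assembly_set")
}

test_that("assembly activity satisfies its algebraic identities", {
  set.seed(2)
  n <- 12
  w <- rnorm(n); w <- w / sqrt(sum(w^2))
  aset <- make_aset(cbind(w), matrix(0, n, 3))
  # z = 0 -> activity 0
  expect_equal(as.numeric(compute_assembly_activity(aset)), c(0, 0, 0))
  # z = w (the unit pattern itself) -> 1 - sum(w^4)
  expect_equal(
    as.numeric(compute_assembly_activity(aset, cbind(w))),
    1 - sum(w^4))
  # random z against the brute-force quadratic form with zeroed diagonal
  z <- matrix(rnorm(n * 5), n)
  p_mat <- w %*% t(w); diag(p_mat) <- 0
  oracle <- apply(z, 2L, function(v) as.numeric(t(v) %*% p_mat %*% v))
  expect_equal(as.numeric(compute_assembly_activity(aset, z)), oracle,
               tolerance = 1e-10)
  # sign flip of the pattern leaves the quadratic form unchanged
  aset_neg <- make_aset(cbind(-w), NULL)
  expect_equal(compute_assembly_activity(aset_neg, z),
               compute_assembly_activity(aset, z), ignore_attr = TRUE)
  expect_error(compute_assembly_activity(aset, matrix(0, n + 1, 2)),
               "dimension mismatch")
})

test_that("planted assemblies are recovered with matching patterns", {
  sp <- invivo_sim_spec(
    n_cells = 60, duration_s = 150, seed = 17,
    locomotion_bout_s = 5, rest_bout_s = 45,
    loco_modulated_fraction = 0, sce_rate_hz = 0,
    assemblies = list(
      list(members = 1:12, rate_hz = 0.4, member_prob = 0.8),
      list(members = 13:24, rate_hz = 0.4, member_prob = 0.8)))
  ss <- gen_invivo_session(sp)
  aset <- detect_assemblies(ss$raster, ss$epochs$rest, n_shuffles = 200,
                            seed = 1)
  expect_equal(aset$n_significant, 2L)
  expect_equal(sqrt(colSums(aset$patterns^2)), c(1, 1))   # unit norm
  # largest-magnitude weight is positive in every pattern
  for (k in 1:2) {
    pk <- aset$patterns[, k]
    expect_gt(pk[which.max(abs(pk))], 0)
  }
  gt <- lapply(ss$ground_truth$assemblies, function(a) {
    v <- rep(0, 60); v[a$members] <- 1; v / sqrt(sum(v))
  })
  sims <- vapply(gt, function(g) max(abs(t(aset$patterns) %*% g)), numeric(1))
  expect_true(all(sims > 0.8))
  # member of both assemblies is modulated; independent cells mostly are not
  am <- test_assembly_modulation(ss$raster, aset, seed = 2)
  expect_true(mean(am$significant[1:24]) > 0.9)
  expect_lt(mean(am$significant[30:60]), 0.3)
})

test_that("independent activity yields no significant assembly", {
  for (sd in 1:2) {
    r <- poisson_raster(50, 1500, 0.012, frame_rate_hz = 9.85, seed = sd)
    rest <- epoch_set("rest", c(0L, 1500L), 1500L)
    aset <- detect_assemblies(r, rest, n_shuffles = 200, seed = sd + 5)
    expect_equal(aset$n_significant, 0L)
    # no assemblies -> modulation not assessable
    am <- test_assembly_modulation(r, aset)
    expect_true(all(is.na(am$significant)))
  }
})

test_that("pattern count never exceeds min(cells, bins) and cell order is immaterial", {
  r <- poisson_raster(30, 400, 0.05, frame_rate_hz = 10, seed = 3)
  rest <- epoch_set("rest", c(0L, 400L), 400L)
  aset <- detect_assemblies(r, rest, n_shuffles = 100, seed = 2)
  expect_lte(aset$n_significant, min(30, ncol(aset$zcounts)))

  sp <- invivo_sim_spec(
    n_cells = 40, duration_s = 120, seed = 23,
    locomotion_bout_s = 5, rest_bout_s = 45,
    loco_modulated_fraction = 0, sce_rate_hz = 0,
    assemblies = list(list(members = 1:10, rate_hz = 0.5, member_prob = 0.9)))
  ss <- gen_invivo_session(sp)
  perm <- rev(seq_len(40))
  r_perm <- activity_raster(ss$raster$onsets[perm, ], ss$raster$frame_rate_hz)
  a1 <- detect_assemblies(ss$raster, ss$epochs$rest, n_shuffles = 100,
                          seed = 4)
  a2 <- detect_assemblies(r_perm, ss$epochs$rest, n_shuffles = 100, seed = 4)
  expect_equal(a1$n_significant, a2$n_significant)
  # permuting the cells permutes the weights (up to component order/sign)
  expect_gt(abs(sum(a1$patterns[, 1] * a2$patterns[perm, 1])), 0.95)
})

test_that("zero-variance cells are dropped with a message and carry zero weight", {
  sp <- invivo_sim_spec(
    n_cells = 30, duration_s = 120, seed = 31,
    locomotion_bout_s = 5, rest_bout_s = 45,
    loco_modulated_fraction = 0, sce_rate_hz = 0,
    assemblies = list(list(members = 1:8, rate_hz = 0.5, member_prob = 0.9)))
  ss <- gen_invivo_session(sp)
  m <- ss$raster$onsets; m[30, ] <- 0L
  r <- activity_raster(m, ss$raster$frame_rate_hz)
  expect_message(
    aset <- detect_assemblies(r, ss$epochs$rest, n_shuffles = 100, seed = 1),
    "zero-variance")
  expect_true(30L %in% aset$dropped_cells)
  if (aset$n_significant > 0) {
    expect_true(all(aset$patterns[30, ] == 0))
  }
})

test_that("assembly detection is reproducible under a fixed seed", {
  r <- poisson_raster(25, 600, 0.03, frame_rate_hz = 10, seed = 9)
  rest <- epoch_set("rest", c(0L, 600L), 600L)
  a1 <- detect_assemblies(r, rest, n_shuffles = 100, seed = 11)
  a2 <- detect_assemblies(r, rest, n_shuffles = 100, seed = 11)
  expect_identical(a1$eigen_threshold, a2$eigen_threshold)
  expect_identical(a1$patterns, a2$patterns)
})
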