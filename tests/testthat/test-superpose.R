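test_that("kabsch recovers exact rigid transforms", {
  set.seed(101)
  a <- matrix(runif(60, -10, 10), ncol = 3)
  fit_id <- kabsch(a, a)
  expect_lt(fit_id$rmsd_all, 1e-9)
  expect_equal(fit_id$rotation, diag(3), tolerance = 1e-9)

  R <- rand_rotation(); t_vec <- c(4, -2, 7)
  b <- sweep(a %*% R, 2, t_vec, `+`)
  fit <- kabsch(a, b)
  expect_lt(fit$rmsd_all, 1e-9)
  # recovered rotation undoes R
  expect_equal(fit$rotation, t(R), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # predict() maps b back onto a
  expect_equal(predict(fit, b), a, tolerance = 1e-9)
})

test_that("kabsch rejects degenerate input and corrects reflections", {
  a <- matrix(runif(30), ncol = 3)
  expect_error(kabsch(a[1:2, ], a[1:2, ]), "underdetermined")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_warning(kabsch(line, line), "collinear")
  # mirrored coordinates must still yield a proper rotation
  set.seed(7)
  b <- matrix(rnorm(24), ncol = 3)
  m <- b %*% diag(c(-1, 1, 1))
  fit <- expect_silent(kabsch(b, m))
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd_all, 0)
})

test_that("kabsch equals the brute-force rotation-grid minimum", {
  set.seed(11)
  for (rep in 1:2) {
    n <- sample(4:8, 1)
    a <- matrix(runif(3 * n, -2, 2), ncol = 3)
    b <- matrix(runif(3 * n, -2, 2), ncol = 3)
    fit <- kabsch(a, b)
    oracle <- grid_rmsd_oracle(a, b)
    # optimality: the SVD solution can never beat-proof worse than the grid
    expect_lte(fit$rmsd_all, oracle + 1e-9)
    expect_equal(fit$rmsd_all, oracle, tolerance = 0.02)
  }
})

test_that("RMSD is invariant under rigid motion and symmetric in inputs", {
  set.seed(23)
  a <- matrix(rnorm(120, sd = 5), ncol = 3)
  b <- a + matrix(rnorm(120, sd = 0.7), ncol = 3)
  base <- kabsch(a, b)$rmsd_all
  for (i in 1:100) {
    R <- rand_rotation(); t_vec <- rnorm(3, sd = 20)
    b2 <- sweep(b %*% R, 2, t_vec, `+`)
    expect_equal(kabsch(a, b2)$rmsd_all, base, tolerance = 1e-9)
  }
  expect_equal(kabsch(b, a)$rmsd_all, base, tolerance = 1e-9)
})

test_that("iterative refinement rejects constructed outliers exactly", {
  h <- generate_helix_coords(100)
  mob <- h$xyz
  bad <- c(5L, 27L, 51L, 76L, 99L)
  mob[bad, ] <- mob[bad, ] + 10
  b <- structure_model("outliers", resno = 1:100,
                       restype = rep("A", 100), xyz = mob)
  fit <- superpose_models(h, b, cycles = 5, reject_cutoff = 2)
  expect_equal(fit$n_pairs_retained, 95L)
  expect_identical(which(!fit$retained), bad)
  expect_lt(fit$rmsd_refined, fit$rmsd_all + 1e-9)
  # refined RMSD non-increasing across cycle counts
  rmsds <- vapply(0:3, function(cy) {
    superpose_models(h, b, cycles = cy, reject_cutoff = 2)$rmsd_refined
  }, numeric(1))
  expect_true(all(diff(rmsds) <= 1e-9))
  # an impossible cutoff collapses refinement
  expect_error(superpose_models(h, b, reject_cutoff = 1e-12),
               "collapse")
})

test_that("trimming drops termini and respects TM spans", {
  rec <- generate_membrane_protein(
    synthetic_protein_spec(n_tm_segments = 3, tm_length = 15,
                           loop_length = 10, seed = 31))
  n <- nchar(rec$sequence)
  a <- generate_helix_coords(n, sequence = rec$sequence, id = "a")
  b <- perturb_structure(a, 0.2, seed = 32)
  plain <- superpose_models(a, b)
  expect_equal(plain$n_pairs_initial, n)

  trimmed <- superpose_models(a, b, trim = trim_policy(10, 10))
  expect_equal(trimmed$n_pairs_initial, n - 20L)

  # TM-span trimming drops everything outside first TM start..last TM end
  span <- superpose_models(a, b, tm_record = rec)
  tm <- rec$tm_segments
  expect_equal(span$n_pairs_initial,
               as.integer(tm[nrow(tm), "end"] - tm[1, "start"] + 1L))

  loops_dropped <- superpose_models(
    a, b, tm_record = rec, trim = trim_policy(drop_unpaired_loops = TRUE))
  expect_equal(loops_dropped$n_pairs_initial, sum(tm_mask(rec)))
})

test_that("superposition methods expose the fit like a model object", {
  h <- generate_helix_coords(50)
  d <- perturb_structure(h, 0.3, seed = 41)
  fit <- superpose_models(h, d)
  cf <- coef(fit)
  expect_equal(dim(cf$rotation), c(3L, 3L))
  expect_length(cf$translation, 3L)
  expect_length(residuals(fit), fit$n_pairs_initial)
  expect_equal(sqrt(mean(residuals(fit)[fit$retained]^2)),
               fit$rmsd_refined, tolerance = 1e-9)
  expect_output(print(fit), "RMSD")
})
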