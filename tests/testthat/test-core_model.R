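test_that("unfold_mode1 lays out time-major column blocks and refolds", {
  B1 <- matrix(c(1, 2), 1, 2)
  B <- coefficient_tensor(array(c(B1, c(3, 4)), c(1, 2, 2)))
  expect_equal(unfold_mode1(B), matrix(c(1, 2, 3, 4), 1, 4))

  expect_equal(unfold_mode1(array(0, c(3, 2, 4))), matrix(0, 3, 8))

  set.seed(11)
  d <- 4L; c <- 3L; Tn <- 2L
  Bv <- array(rnorm(d * c * Tn), c(d, c, Tn))
  U <- unfold_mode1(Bv)
  for (k in seq_len(d)) for (j in seq_len(c)) for (t in seq_len(Tn))
    expect_identical(U[k, (t - 1L) * c + j], Bv[k, j, t])

  # bijection: refolding recovers B exactly
  expect_equal(unclass(fold_mode1(U, c, Tn)), Bv, ignore_attr = TRUE)
})

test_that("tensor_l21_norm matches the brute-force row-norm oracle", {
  expect_identical(tensor_l21_norm(array(0, c(3, 2, 2))), 0)
  B <- array(0, c(2, 1, 2)); B[1, 1, ] <- c(3, 4)
  expect_equal(tensor_l21_norm(B), 5)
  for (seed in 1:5) {
    set.seed(seed)
    Bv <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
    expect_equal(tensor_l21_norm(Bv), oracle_l21(Bv), tolerance = 1e-12)
    # permutation of (j, t) entries within each feature row is irrelevant
    perm <- sample(12L)
    U <- unfold_mode1(Bv)
    expect_equal(tensor_l21_norm(fold_mode1(U[, perm], 3L, 4L)),
                 tensor_l21_norm(Bv))
  }
})

test_that("trace_norm matches the spectral oracle and basic identities", {
  expect_equal(trace_norm(diag(3)), 3)
  expect_equal(trace_norm(diag(c(3, 4))), 7)
  for (seed in 1:5) {
    set.seed(seed)
    M <- matrix(rnorm(40), 5, 8)
    expect_equal(trace_norm(M), oracle_trace_norm(M), tolerance = 1e-10)
    expect_equal(trace_norm(M), trace_norm(t(M)), tolerance = 1e-10)
  }
})

test_that("longitudinal_loss matches the brute-force residual oracle", {
  inst <- random_instance(3, 4, 2, 2, seed = 3)
  # B = 0 gives T * ||Y||_F^2
  expect_equal(longitudinal_loss(inst$X, array(0, c(3, 2, 2)), inst$Y),
               2 * sum(inst$Y^2))
  # exact interpolation at T = 1 with square invertible X
  set.seed(4)
  X1 <- matrix(rnorm(16), 4, 4)
  Y <- matrix(rnorm(8), 4, 2)
  B1 <- solve(t(X1), Y)
  expect_equal(longitudinal_loss(array(X1, c(4, 4, 1)),
                                 array(B1, c(4, 2, 1)), Y), 0,
               tolerance = 1e-12)
  # random instance vs loops
  set.seed(5)
  Bv <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  expect_equal(longitudinal_loss(inst$X, Bv, inst$Y),
               oracle_loss(inst$X, Bv, inst$Y), tolerance = 1e-10)
})

test_that("longitudinal_loss names the offending axis on mismatch", {
  inst <- random_instance(3, 4, 2, 2, seed = 6)
  expect_error(longitudinal_loss(inst$X, array(0, c(5, 2, 2)), inst$Y),
               "feature axis")
  expect_error(longitudinal_loss(inst$X, array(0, c(3, 7, 2)), inst$Y),
               "SNP axis")
  expect_error(longitudinal_loss(inst$X, array(0, c(3, 2, 3)), inst$Y),
               "time axis")
  expect_error(longitudinal_loss(inst$X, array(0, c(3, 2, 2)),
                                 rbind(inst$Y, 0)), "subject axis")
})

test_that("objective_j2 composes the three terms and honors reductions", {
  inst <- random_instance(4, 6, 3, 2, seed = 7)
  set.seed(8)
  Bv <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  hp <- model_hyperparameters(gamma1 = 0.5, gamma2 = 2)
  expect_equal(objective_j2(inst$X, Bv, inst$Y, hp),
               oracle_objective(inst$X, Bv, inst$Y, 0.5, 2),
               tolerance = 1e-10)
  hp0 <- model_hyperparameters(gamma1 = 0, gamma2 = 0)
  expect_equal(objective_j2(inst$X, Bv, inst$Y, hp0),
               longitudinal_loss(inst$X, Bv, inst$Y))
  # at B = 0 both penalties vanish
  expect_equal(objective_j2(inst$X, array(0, c(4, 3, 2)), inst$Y, hp),
               2 * sum(inst$Y^2))
})

test_that("norm properties: homogeneity, triangle inequality, Frobenius bound", {
  set.seed(9)
  for (r in 1:10) {
    Bv <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
    Bw <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
    a <- rnorm(1)
    expect_equal(tensor_l21_norm(a * Bv), abs(a) * tensor_l21_norm(Bv))
    expect_equal(trace_norm(a * unfold_mode1(Bv)),
                 abs(a) * trace_norm(unfold_mode1(Bv)))
    expect_lte(tensor_l21_norm(Bv + Bw),
               tensor_l21_norm(Bv) + tensor_l21_norm(Bw) + 1e-10)
    expect_lte(trace_norm(unfold_mode1(Bv) + unfold_mode1(Bw)),
               trace_norm(unfold_mode1(Bv)) + trace_norm(unfold_mode1(Bw)) +
                 1e-10)
    # trace norm dominates the Frobenius norm ...
    U <- unfold_mode1(Bv)
    expect_gte(trace_norm(U) + 1e-10, sqrt(sum(U^2)))
    # ... with equality exactly on rank-1 matrices
    u <- rnorm(4); v <- rnorm(6)
    R1 <- outer(u, v)
    expect_equal(trace_norm(R1), sqrt(sum(R1^2)), tolerance = 1e-10)
  }
})

test_that("objective_j2 is convex along random segments", {
  inst <- random_instance(4, 6, 3, 2, seed = 10)
  hp <- model_hyperparameters(gamma1 = 0.7, gamma2 = 1.3)
  set.seed(11)
  for (r in 1:20) {
    B1 <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
    B2 <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
    lam <- runif(1)
    expect_lte(
      objective_j2(inst$X, lam * B1 + (1 - lam) * B2, inst$Y, hp),
      lam * objective_j2(inst$X, B1, inst$Y, hp) +
        (1 - lam) * objective_j2(inst$X, B2, inst$Y, hp) + 1e-10)
  }
})

test_that("type constructors validate their invariants", {
  expect_error(phenotype_tensor(array(c(1, NA), c(1, 2, 1))), "finite")
  expect_error(phenotype_tensor(array(1, c(2, 1, 1))), "two subjects")
  expect_error(phenotype_tensor(array(1, c(2, 3, 1)),
                                feature_ids = c("a", "a")), "duplicates")
  expect_error(genotype_matrix(matrix(c(1, Inf), 2, 1)), "finite")
  expect_error(model_hyperparameters(gamma1 = -1), "gamma1")
  expect_error(model_hyperparameters(epsilon = 0), "epsilon")
  expect_error(model_hyperparameters(max_iter = 0), "max_iter")
  hp <- model_hyperparameters()
  expect_s3_class(hp, "model_hyperparameters")
  expect_identical(hp$max_iter, 200L)
})
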