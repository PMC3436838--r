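test_that("compute_row_weights follows the adopted reweighting formula", {
  U <- matrix(c(3, 4, 0, 0), 2, 2, byrow = TRUE)   # row norms 5 and 0
  w <- compute_row_weights(U, 1e-12)
  expect_equal(w[1], 0.1, tolerance = 1e-8)
  w0 <- compute_row_weights(matrix(0, 1, 3), 1e-8)
  expect_equal(w0, 1 / (2 * 1e-4))
  set.seed(1)
  M <- matrix(rnorm(24), 4, 6)
  expected <- vapply(1:4, function(k) {
    ss <- 0
    for (j in 1:6) ss <- ss + M[k, j]^2
    1 / (2 * sqrt(ss + 1e-8))
  }, numeric(1))
  expect_equal(compute_row_weights(M, 1e-8), expected, tolerance = 1e-12)
})

test_that("compute_lowrank_weights is the inverse square root up to the guard", {
  # orthogonal rows of norm 2: B %*% t(B) = 4 I, so Dtilde -> I/4
  B <- rbind(c(2, 0, 0, 0), c(0, 2, 0, 0))
  Dt <- compute_lowrank_weights(B, 1e-14)
  expect_equal(Dt, diag(2) / 4, tolerance = 1e-6)
  # zero matrix: Dtilde = eps^(-1/2) / 2 * I
  Dt0 <- compute_lowrank_weights(matrix(0, 3, 5), 1e-8)
  expect_equal(Dt0, 5000 * diag(3))
  # random case: spectral oracle plus the defining identity
  set.seed(2)
  U <- matrix(rnorm(6 * 10), 6, 10)
  eps <- 1e-8
  Dt <- compute_lowrank_weights(U, eps)
  e <- eigen(U %*% t(U), symmetric = TRUE)
  oracle <- 0.5 * e$vectors %*% diag(1 / sqrt(e$values + eps)) %*%
    t(e$vectors)
  expect_equal(Dt, oracle, tolerance = 1e-8)
  expect_equal(Dt %*% Dt %*% (U %*% t(U) + eps * diag(6)), diag(6) / 4,
               tolerance = 1e-8)
  # commutes with the Gram matrix
  G <- U %*% t(U)
  expect_equal(Dt %*% G, G %*% Dt, tolerance = 1e-8)
})

test_that("update_coefficients solves the reweighted normal equations", {
  inst <- random_instance(5, 12, 3, 2, seed = 3)
  hp <- model_hyperparameters(gamma1 = 0.8, gamma2 = 1.7)
  set.seed(4)
  state <- list(D = runif(5, 0.5, 2), Dtilde = crossprod(matrix(rnorm(25), 5)))
  state$Dtilde <- state$Dtilde + diag(5)   # make SPD
  B <- update_coefficients(inst$X, inst$Y, state, hp)
  for (t in 1:2) {
    A <- inst$X[, , t] %*% t(inst$X[, , t]) + hp$gamma1 * diag(state$D) +
      hp$gamma2 * state$Dtilde
    rhs <- inst$X[, , t] %*% inst$Y
    res <- A %*% B[, , t] - rhs
    expect_lt(sqrt(sum(res^2)) / sqrt(sum(rhs^2)), 1e-8)
  }
})

test_that("update_coefficients reduces to OLS and ridge", {
  inst <- random_instance(4, 10, 3, 2, seed = 5)
  # gamma = 0, full row rank: per-time OLS
  hp0 <- model_hyperparameters(gamma1 = 0, gamma2 = 0)
  B <- update_coefficients(inst$X, inst$Y, list(D = rep(1, 4),
                                                Dtilde = diag(4)), hp0)
  for (t in 1:2) {
    ols <- solve(inst$X[, , t] %*% t(inst$X[, , t]),
                 inst$X[, , t] %*% inst$Y)
    expect_equal(unclass(B)[, , t], ols, tolerance = 1e-10)
  }
  # D = Dtilde = I with gamma1 + gamma2 = lambda: ridge
  hp <- model_hyperparameters(gamma1 = 0.6, gamma2 = 0.9)
  B <- update_coefficients(inst$X, inst$Y, list(D = rep(1, 4),
                                                Dtilde = diag(4)), hp)
  for (t in 1:2)
    expect_equal(unclass(B)[, , t],
                 fit_ridge(inst$X[, , t], inst$Y, 1.5), tolerance = 1e-10)
})

test_that("objective history is monotone non-increasing over random instances", {
  set.seed(6)
  for (r in 1:15) {
    inst <- random_instance(8, 10, 3, 2, seed = 100 + r)
    g1 <- 10^runif(1, -3, 3); g2 <- 10^runif(1, -3, 3)
    f <- fit_longsparse(inst$X, inst$Y,
                        model_hyperparameters(g1, g2, max_iter = 100L))
    expect_true(all(diff(f$objective_history) <= 1e-10),
                info = sprintf("replicate %d (g1=%g, g2=%g)", r, g1, g2))
    expect_lte(f$n_iter, 100L)
  }
})

test_that("converged fits satisfy the FitResult contract", {
  inst <- random_instance(6, 20, 3, 2, seed = 7)
  hp <- model_hyperparameters(1, 1, tol = 1e-12, max_iter = 20000L)
  f <- fit_longsparse(inst$X, inst$Y, hp)
  expect_true(f$converged)
  h <- f$objective_history
  expect_lt(abs(h[f$n_iter - 1L] - h[f$n_iter]) / max(h[f$n_iter - 1L], 1e-12),
            hp$tol)
  expect_lt(f$kkt_residual, 1e-4)
  # stationarity residual is strictly positive away from the optimum
  expect_gt(kkt_residual(array(0, c(6, 3, 2)), inst$X, inst$Y, hp), 0)
  # and ~0 at the OLS solution when gamma = 0
  hp0 <- model_hyperparameters(0, 0)
  f0 <- fit_longsparse(inst$X, inst$Y, hp0)
  expect_lt(kkt_residual(f0$coefficients, inst$X, inst$Y, hp0,
                         relative = TRUE), 1e-10)
})

test_that("optimal value is initialization-independent (convexity)", {
  inst <- random_instance(6, 12, 3, 2, seed = 8)
  hp <- model_hyperparameters(0.5, 0.5, tol = 1e-10, max_iter = 5000L)
  f1 <- fit_longsparse(inst$X, inst$Y, hp)
  # warm-start from a random point by running one manual sweep first
  set.seed(9)
  U0 <- matrix(rnorm(6 * 6), 6, 6)
  state <- list(D = compute_row_weights(U0, hp$epsilon),
                Dtilde = compute_lowrank_weights(U0, hp$epsilon))
  B0 <- update_coefficients(inst$X, inst$Y, state, hp)
  # continue iterating from B0 with the package's update rule
  obj <- objective_j2(inst$X, B0, inst$Y, hp)
  B <- unclass(B0)
  for (s in 1:5000) {
    U <- unfold_mode1(B)
    state <- list(D = compute_row_weights(U, hp$epsilon),
                  Dtilde = compute_lowrank_weights(U, hp$epsilon))
    B <- unclass(update_coefficients(inst$X, inst$Y, state, hp))
    new_obj <- objective_j2(inst$X, B, inst$Y, hp)
    if (abs(obj - new_obj) / max(obj, 1e-12) < 1e-10) break
    obj <- new_obj
  }
  expect_equal(obj, utils::tail(f1$objective_history, 1L),
               tolerance = 1e-5)
})

test_that("T = 1, gamma2 = 0 matches the reference multi-task l2,1 solver", {
  set.seed(10)
  for (r in 1:3) {
    inst <- random_instance(8, 15, 4, 1, seed = 200 + r)
    g1 <- 10^runif(1, -1, 1)
    hp <- model_hyperparameters(g1, 0, tol = 1e-12, max_iter = 5000L)
    f <- fit_longsparse(inst$X, inst$Y, hp)
    ref <- l21_reference_solver(inst$X[, , 1], inst$Y, g1)
    expect_equal(utils::tail(f$objective_history, 1L), ref$objective,
                 tolerance = 1e-4)
  }
})

test_that("gamma1 = 0, T = 1 matches a proximal trace-norm regression oracle", {
  set.seed(20)
  for (r in 1:3) {
    inst <- random_instance(7, 14, 4, 1, seed = 300 + r)
    g2 <- 10^runif(1, -1, 1)
    f <- fit_longsparse(inst$X, inst$Y,
                        model_hyperparameters(0, g2, tol = 1e-11,
                                              max_iter = 50000L))
    # the ADMM oracle with g1 = 0 reduces to proximal trace-norm regression
    # (the row soft-threshold becomes the identity)
    j_oracle <- admm_oracle(inst$X, inst$Y, 0, g2, iters = 4000L)
    expect_equal(utils::tail(f$objective_history, 1L), j_oracle,
                 tolerance = 1e-4)
  }
})

test_that("large gamma1 shrinks the l2,1 norm of the fit monotonically", {
  inst <- random_instance(8, 12, 3, 2, seed = 11)
  norms <- vapply(10^seq(-1, 3, by = 1), function(g1) {
    f <- fit_longsparse(inst$X, inst$Y,
                        model_hyperparameters(g1, 0.1, max_iter = 500L))
    tensor_l21_norm(f$coefficients)
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
  expect_lt(norms[length(norms)], 0.05 * norms[1])
})

test_that("permuting SNP columns permutes the fitted coefficients", {
  inst <- random_instance(6, 10, 4, 2, seed = 12)
  hp <- model_hyperparameters(0.5, 0.5, tol = 1e-10, max_iter = 2000L)
  f1 <- fit_longsparse(inst$X, inst$Y, hp)
  perm <- c(3, 1, 4, 2)
  f2 <- fit_longsparse(inst$X, inst$Y[, perm], hp)
  expect_equal(unclass(f2$coefficients), unclass(f1$coefficients)[, perm, ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate unregularized problems raise an actionable error", {
  # rank-deficient X (d > n) with gamma1 = gamma2 = 0
  set.seed(13)
  X <- array(rnorm(10 * 4 * 1), c(10, 4, 1))
  Y <- matrix(rnorm(8), 4, 2)
  expect_error(
    fit_longsparse(X, Y, model_hyperparameters(0, 0)),
    "gamma1 > 0 or gamma2 > 0")
})

test_that("misaligned subject ids are rejected", {
  prob <- generate_problem(sim_config(d = 6, n = 10, T = 2, c = 3, k_active = 2,
                                      rank_r = 1, seed = 14))
  Ybad <- genotype_matrix(prob$Y$values, snp_ids = prob$Y$snp_ids,
                          subject_ids = rev(prob$Y$subject_ids))
  expect_error(fit_longsparse(prob$X, Ybad, model_hyperparameters()),
               "subject")
})
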