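#' Row weights for the iteratively reweighted l2,1 penalty
#'
#' Diagonal matrix `D` with `d_kk = 1 / (2 * sqrt(||b^k||^2 + epsilon))`,
#' where `b^k` is row `k` of the mode-1 unfolding. At the reweighted
#' fixed point `D %*% B` is half the (smoothed) gradient of the tensor
#' l2,1-norm.
#'
#' @param B_unfolded `d x (c*T)` matrix, the current mode-1 unfolding.
#' @param epsilon positive smoothing constant removing the zero-row
#'   singularity.
#' @return Numeric vector of length `d`: the diagonal of `D` (all entries
#'   strictly positive, decreasing in the row norm).
#' @export
compute_row_weights <- function(B_unfolded, epsilon) {
  stopifnot(is.matrix(B_unfolded), epsilon > 0)
  1 / (2 * sqrt(rowSums(B_unfolded^2) + epsilon))
}

#' Low-rank weights for the iteratively reweighted trace-norm penalty
#'
#' The symmetric positive-definite matrix
#' `Dtilde = 0.5 * (B %*% t(B) + epsilon * I)^(-1/2)`, computed by symmetric
#' eigendecomposition. At the fixed point `Dtilde %*% B` is half the
#' (smoothed) gradient of the trace norm of `B`.
#'
#' @inheritParams compute_row_weights
#' @return A symmetric positive-definite `d x d` matrix that commutes with
#'   `B_unfolded %*% t(B_unfolded)`.
#' @export
compute_lowrank_weights <- function(B_unfolded, epsilon) {
  stopifnot(is.matrix(B_unfolded), epsilon > 0)
  G <- tcrossprod(B_unfolded)
  e <- eigen(G, symmetric = TRUE)
  # eigenvalues of G are >= 0 up to roundoff; the epsilon shift keeps the
  # inverse square root well defined
  lam <- pmax(e$values, 0) + epsilon
  Dt <- 0.5 * e$vectors %*% (t(e$vectors) / sqrt(lam))
  (Dt + t(Dt)) / 2
}

#' One sweep of per-time-point coefficient updates
#'
#' Given fixed reweighting matrices, each `B_t` solves the symmetric linear
#' system `(X_t %*% t(X_t) + gamma1 * D + gamma2 * Dtilde) B_t = X_t %*% Y`.
#' The system matrix is positive definite whenever `gamma1 > 0` or
#' `gamma2 > 0`.
#'
#' @inheritParams longitudinal_loss
#' @param state list with `D` (length-`d` vector, diagonal row weights) and
#'   `Dtilde` (`d x d` symmetric matrix), as produced by
#'   [compute_row_weights()] / [compute_lowrank_weights()].
#' @param hp a [model_hyperparameters()] object.
#' @return A [coefficient_tensor()] solving the `T` linear systems.
#' @export
update_coefficients <- function(X, Y, state, hp) {
  Xv <- pheno_array(X); Yv <- geno_values(Y)
  d <- dim(Xv)[1L]; Tn <- dim(Xv)[3L]; c <- ncol(Yv)
  stopifnot(length(state$D) == d, all(dim(state$Dtilde) == d))
  B <- array(0, c(d, c, Tn))
  for (t in seq_len(Tn)) {
    A <- tcrossprod(Xv[, , t])
    if (hp$gamma2 > 0) A <- A + hp$gamma2 * state$Dtilde
    if (hp$gamma1 > 0) diag(A) <- diag(A) + hp$gamma1 * state$D
    rhs <- Xv[, , t] %*% Yv
    B[, , t] <- solve_spd(A, rhs, t)
  }
  coefficient_tensor(B)
}

# Cholesky solve with a clear diagnostic for the unregularized rank-deficient
# case.
solve_spd <- function(A, rhs, t) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R))
    stop(sprintf(paste0(
      "linear system at time point %d is singular (rank-deficient X_t with ",
      "gamma1 = gamma2 = 0); set gamma1 > 0 or gamma2 > 0, or use ",
      "fit_linear_regression() for a minimum-norm solution"), t))
  backsolve(R, forwardsolve(t(R), rhs))
}

#' Fit the task-correlated longitudinal sparse regression model
#'
#' Minimizes [objective_j2()] by iteratively reweighted least squares: the
#' reweighting matrices `D` and `Dtilde` are recomputed from the current
#' unfolding once per outer iteration (initialized to the identity, so the
#' first sweep is a ridge solve), followed by `T` positive-definite linear
#' solves. The objective decreases monotonically in every iteration and,
#' since the objective is convex, the iterates approach the global optimum.
#'
#' @inheritParams longitudinal_loss
#' @param hp a [model_hyperparameters()] object; iteration stops when the
#'   relative objective change drops below `hp$tol` or after `hp$max_iter`
#'   iterations.
#' @return An object of class `longsparse_fit`: list with
#'   `coefficients` ([coefficient_tensor()]), `objective_history` (objective
#'   value after each sweep), `n_iter`, `converged`, and `kkt_residual`
#'   (stationarity residual relative to `||X %*% Y||_F`).
#' @examples
#' prob <- generate_problem(sim_config(d = 12, n = 20, c = 4, T = 2, seed = 1))
#' fit <- fit_longsparse(prob$X, prob$Y, model_hyperparameters(1, 1))
#' fit$converged
#' @export
fit_longsparse <- function(X, Y, hp = model_hyperparameters()) {
  Xv <- pheno_array(X); Yv <- geno_values(Y)
  stopifnot(inherits(hp, "model_hyperparameters"))
  if (inherits(X, "phenotype_tensor") && inherits(Y, "genotype_matrix") &&
      !identical(X$subject_ids, Y$subject_ids))
    stop("subject axis mismatch: phenotype and genotype subject ids differ")
  d <- dim(Xv)[1L]; Tn <- dim(Xv)[3L]; c <- ncol(Yv)
  if (dim(Xv)[2L] != nrow(Yv))
    stop(sprintf("subject axis mismatch: X has n = %d, Y has n = %d",
                 dim(Xv)[2L], nrow(Yv)))

  XXt <- vector("list", Tn); XY <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    XXt[[t]] <- tcrossprod(Xv[, , t])
    XY[[t]] <- Xv[, , t] %*% Yv
  }
  state <- list(D = rep(1, d), Dtilde = diag(d))
  B <- array(0, c(d, c, Tn))
  history <- numeric(hp$max_iter)
  converged <- FALSE
  n_iter <- 0L
  for (s in seq_len(hp$max_iter)) {
    for (t in seq_len(Tn)) {
      A <- XXt[[t]]
      if (hp$gamma2 > 0) A <- A + hp$gamma2 * state$Dtilde
      if (hp$gamma1 > 0) diag(A) <- diag(A) + hp$gamma1 * state$D
      B[, , t] <- solve_spd(A, XY[[t]], t)
    }
    obj <- objective_j2(Xv, B, Yv, hp)
    if (!is.finite(obj))
      stop(sprintf("non-finite objective at iteration %d", s))
    history[s] <- obj
    n_iter <- s
    if (s > 1L &&
        abs(history[s - 1L] - history[s]) / max(history[s - 1L], 1e-12) <
          hp$tol) {
      converged <- TRUE
      break
    }
    if (hp$gamma1 == 0 && hp$gamma2 == 0) { converged <- TRUE; break }
    U <- array(B, c(d, c * Tn))
    if (hp$gamma1 > 0) state$D <- compute_row_weights(U, hp$epsilon)
    if (hp$gamma2 > 0) state$Dtilde <- compute_lowrank_weights(U, hp$epsilon)
  }
  Bt <- coefficient_tensor(B)
  structure(list(coefficients = Bt,
                 objective_history = history[seq_len(n_iter)],
                 n_iter = n_iter,
                 converged = converged,
                 kkt_residual = kkt_residual(Bt, Xv, Yv, hp, relative = TRUE),
                 hyperparameters = hp),
            class = "longsparse_fit")
}

#' @export
print.longsparse_fit <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("longsparse fit: %d features x %d SNPs x %d time points\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  gamma1 = %g, gamma2 = %g\n",
              x$hyperparameters$gamma1, x$hyperparameters$gamma2))
  cat(sprintf("  %d iterations, converged = %s, final objective = %.6g\n",
              x$n_iter, x$converged, utils::tail(x$objective_history, 1L)))
  cat(sprintf("  relative KKT residual = %.3g\n", x$kkt_residual))
  invisible(x)
}

#' Smoothed stationarity (KKT) residual
#'
#' Frobenius norm of the stacked residuals
#' `X_t %*% t(X_t) %*% B_t - X_t %*% Y + gamma1 * D %*% B_t +
#'  gamma2 * Dtilde %*% B_t`, with the reweighting matrices evaluated at `B`
#' itself. Near zero at a stationary point of the epsilon-smoothed objective;
#' since the objective is convex, a small residual certifies (near-)global
#' optimality.
#'
#' @inheritParams longitudinal_loss
#' @param hp a [model_hyperparameters()] object.
#' @param relative if `TRUE`, divide by the Frobenius norm of the stacked
#'   `X_t %*% Y` (guarded away from zero).
#' @return Non-negative scalar.
#' @export
kkt_residual <- function(B, X, Y, hp, relative = FALSE) {
  Xv <- pheno_array(X); Bv <- coef_array(B); Yv <- geno_values(Y)
  check_shapes(Xv, Bv, Yv)
  d <- dim(Bv)[1L]; Tn <- dim(Bv)[3L]
  U <- array(Bv, c(d, dim(Bv)[2L] * Tn))
  D <- compute_row_weights(U, hp$epsilon)
  Dt <- compute_lowrank_weights(U, hp$epsilon)
  ss <- 0; scale2 <- 0
  for (t in seq_len(Tn)) {
    XY <- Xv[, , t] %*% Yv
    G <- tcrossprod(Xv[, , t]) %*% Bv[, , t] - XY
    if (hp$gamma1 > 0) G <- G + hp$gamma1 * (D * Bv[, , t])
    if (hp$gamma2 > 0) G <- G + hp$gamma2 * (Dt %*% Bv[, , t])
    ss <- ss + sum(G^2)
    scale2 <- scale2 + sum(XY^2)
  }
  res <- sqrt(ss)
  if (relative) res <- res / max(sqrt(scale2), 1e-12)
  res
}
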