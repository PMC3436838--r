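#' Per-time-point multivariate linear regression
#'
#' Minimum-Frobenius-norm least-squares solution of
#' `t(X_t) %*% B_t ~ Y`, computed from the thin SVD of `t(X_t)` (so
#' rank-deficient designs are handled without error).
#'
#' @param X_t `d x n` phenotype matrix for one time point (features in rows).
#' @param Y `n x c` response matrix (or [genotype_matrix()]).
#' @return A `d x c` coefficient matrix.
#' @export
fit_linear_regression <- function(X_t, Y) {
  Yv <- geno_values(Y)
  A <- t(as.matrix(X_t))                 # n x d design
  if (nrow(A) != nrow(Yv))
    stop(sprintf("subject axis mismatch: X_t has n = %d, Y has n = %d",
                 nrow(A), nrow(Yv)))
  sv <- svd(A)
  pos <- sv$d > max(dim(A)) * .Machine$double.eps * max(sv$d, 1)
  if (!any(pos)) return(matrix(0, ncol(A), ncol(Yv)))
  sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], Yv) / sv$d[pos])
}

#' Per-time-point ridge regression
#'
#' Closed form `B_t = (X_t %*% t(X_t) + penalty * I)^(-1) %*% X_t %*% Y`.
#'
#' @inheritParams fit_linear_regression
#' @param penalty strictly positive ridge penalty.
#' @return A `d x c` coefficient matrix.
#' @export
fit_ridge <- function(X_t, Y, penalty) {
  if (!is.numeric(penalty) || length(penalty) != 1L || penalty <= 0)
    stop("ridge penalty must be > 0")
  Yv <- geno_values(Y)
  X_t <- as.matrix(X_t)
  if (ncol(X_t) != nrow(Yv))
    stop(sprintf("subject axis mismatch: X_t has n = %d, Y has n = %d",
                 ncol(X_t), nrow(Yv)))
  A <- tcrossprod(X_t)
  diag(A) <- diag(A) + penalty
  solve_spd(A, X_t %*% Yv, 1L)
}

#' Per-time-point lasso (elementwise l1) regression
#'
#' Minimizes `||t(X_t) %*% B_t - Y||_F^2 + penalty * sum(abs(B_t))` by
#' monotone accelerated proximal gradient (FISTA with an objective-decrease
#' safeguard). The elementwise l1 penalty makes the problem separable per SNP
#' column; all columns are updated jointly for efficiency.
#'
#' @inheritParams fit_ridge
#' @param penalty non-negative l1 penalty.
#' @param solver_tol relative objective-change stopping tolerance.
#' @param solver_max_iter iteration cap; if reached without convergence the
#'   best iterate is returned with a warning.
#' @return A `d x c` coefficient matrix with attributes `converged` (logical)
#'   and `objective_history`.
#' @export
fit_lasso <- function(X_t, Y, penalty, solver_tol = 1e-8,
                      solver_max_iter = 2000L) {
  if (!is.numeric(penalty) || length(penalty) != 1L || penalty < 0)
    stop("lasso penalty must be >= 0")
  Yv <- geno_values(Y)
  X_t <- as.matrix(X_t)
  if (ncol(X_t) != nrow(Yv))
    stop(sprintf("subject axis mismatch: X_t has n = %d, Y has n = %d",
                 ncol(X_t), nrow(Yv)))
  d <- nrow(X_t); c <- ncol(Yv)
  L <- 2 * svd(X_t, nu = 0, nv = 0)$d[1L]^2   # Lipschitz constant of the loss
  if (L == 0) return(matrix(0, d, c))
  XY <- X_t %*% Yv
  XXt <- tcrossprod(X_t)
  obj <- function(B) {
    sum((crossprod(X_t, B) - Yv)^2) + penalty * sum(abs(B))
  }
  soft <- function(Z, thr) sign(Z) * pmax(abs(Z) - thr, 0)
  B <- matrix(0, d, c)
  Z <- B; tk <- 1
  f_prev <- obj(B)
  history <- f_prev
  converged <- FALSE
  for (s in seq_len(solver_max_iter)) {
    G <- 2 * (XXt %*% Z - XY)
    Bc <- soft(Z - G / L, penalty / L)
    f_c <- obj(Bc)
    if (f_c > f_prev) {
      # momentum overshoot: fall back to a plain proximal step from the best
      # iterate, which the majorization guarantees to be non-increasing
      G <- 2 * (XXt %*% B - XY)
      Bc <- soft(B - G / L, penalty / L)
      f_c <- obj(Bc)
      tk <- 1
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- Bc + ((tk - 1) / tk_new) * (Bc - B)
    rel <- abs(f_prev - f_c) / max(f_prev, 1e-12)
    B <- Bc; f_prev <- f_c; tk <- tk_new
    history <- c(history, f_c)
    if (rel < solver_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("lasso solver reached max_iter without convergence; ",
            "returning best iterate")
  attr(B, "converged") <- converged
  attr(B, "objective_history") <- history
  B
}

#' Trace-norm-only ablation
#'
#' The full longitudinal model with the l2,1 term switched off
#' (`gamma1 = 0`): only the low-rank coupling of SNP columns is kept, no
#' joint feature selection.
#'
#' @inheritParams fit_longsparse
#' @return A `longsparse_fit`, identical to
#'   `fit_longsparse(X, Y, hp with gamma1 = 0)`.
#' @export
fit_trace_only <- function(X, Y, hp) {
  stopifnot(inherits(hp, "model_hyperparameters"))
  if (hp$gamma2 <= 0) stop("fit_trace_only requires gamma2 > 0")
  hp0 <- model_hyperparameters(gamma1 = 0, gamma2 = hp$gamma2,
                               epsilon = hp$epsilon, tol = hp$tol,
                               max_iter = hp$max_iter)
  fit_longsparse(X, Y, hp0)
}

# Fit one of the per-time-point baselines on every slice and stack the
# results into a coefficient tensor. method in c("lr", "rr", "lasso").
fit_baseline_tensor <- function(X, Y, method, penalty = 1,
                                solver_tol = 1e-8, solver_max_iter = 2000L) {
  Xv <- pheno_array(X); Yv <- geno_values(Y)
  Tn <- dim(Xv)[3L]
  B <- array(0, c(dim(Xv)[1L], ncol(Yv), Tn))
  for (t in seq_len(Tn)) {
    B[, , t] <- switch(method,
      lr = fit_linear_regression(Xv[, , t], Yv),
      rr = fit_ridge(Xv[, , t], Yv, penalty),
      lasso = suppressWarnings(
        fit_lasso(Xv[, , t], Yv, penalty, solver_tol, solver_max_iter)),
      stop("unknown baseline method: ", method))
  }
  coefficient_tensor(B)
}
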