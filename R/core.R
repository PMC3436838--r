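#' Mode-1 unfolding of a coefficient tensor
#'
#' Flattens a `d x c x T` tensor into the `d x (c*T)` matrix
#' `[B_1 | B_2 | ... | B_T]` of time-major column blocks: column
#' `(t - 1) * c + j` holds the coefficients of SNP `j` at time `t`.
#'
#' @param B a [coefficient_tensor()] or `d x c x T` array.
#' @return A `d x (c*T)` numeric matrix.
#' @seealso [fold_mode1()] for the inverse.
#' @export
unfold_mode1 <- function(B) {
  Bv <- coef_array(B)
  d <- dim(Bv)[1L]
  dim(Bv) <- c(d, dim(Bv)[2L] * dim(Bv)[3L])
  Bv
}

#' Refold a mode-1 unfolded matrix into a coefficient tensor
#'
#' Inverse of [unfold_mode1()]: `fold_mode1(unfold_mode1(B), c, T)`
#' recovers `B` exactly.
#'
#' @param U a `d x (c*T)` matrix of time-major column blocks.
#' @param n_snps number of SNP columns `c`.
#' @param n_times number of time points `T`.
#' @return A [coefficient_tensor()] of dimension `d x c x T`.
#' @export
fold_mode1 <- function(U, n_snps, n_times) {
  if (!is.matrix(U)) stop("'U' must be a matrix")
  if (ncol(U) != n_snps * n_times)
    stop(sprintf("U has %d columns, expected c * T = %d",
                 ncol(U), n_snps * n_times))
  coefficient_tensor(array(U, c(nrow(U), n_snps, n_times)))
}

#' Tensor l2,1-norm
#'
#' Sum over features of the l2 norm of each feature's entire slab across SNPs
#' and time points; equivalently the matrix l2,1-norm of the mode-1 unfolding.
#' Penalizing it drives whole feature rows to zero simultaneously in every
#' regression task and at every visit.
#'
#' @param B a [coefficient_tensor()] or `d x c x T` array.
#' @return Non-negative scalar; zero iff `B` is the zero tensor.
#' @export
tensor_l21_norm <- function(B) {
  U <- unfold_mode1(B)
  sum(sqrt(rowSums(U^2)))
}

#' Trace norm (nuclear norm)
#'
#' Sum of the singular values of a matrix; the tightest convex surrogate for
#' matrix rank.
#'
#' @param M a numeric matrix with finite entries.
#' @return Non-negative scalar.
#' @export
trace_norm <- function(M) {
  if (!is.matrix(M)) M <- as.matrix(M)
  if (!all(is.finite(M))) stop("'M' must have finite entries")
  sum(svd(M, nu = 0, nv = 0)$d)
}

#' Longitudinal squared-error loss
#'
#' The data-fit term `sum_t || t(X_t) %*% B_t - Y ||_F^2`: the genotype matrix
#' is regressed on the phenotypes of every visit, with one coefficient matrix
#' per visit. The loss is the plain (unhalved, unaveraged) sum of squares; any
#' constant rescaling is absorbed by the penalty weights.
#'
#' @param X a [phenotype_tensor()] (or `d x n x T` array).
#' @param B a [coefficient_tensor()] (or `d x c x T` array).
#' @param Y a [genotype_matrix()] (or `n x c` matrix).
#' @return Non-negative scalar; zero iff the model interpolates every visit.
#' @export
longitudinal_loss <- function(X, B, Y) {
  Xv <- pheno_array(X); Bv <- coef_array(B); Yv <- geno_values(Y)
  check_shapes(Xv, Bv, Yv)
  s <- 0
  for (t in seq_len(dim(Xv)[3L]))
    s <- s + sum((crossprod(Xv[, , t], Bv[, , t]) - Yv)^2)
  s
}

#' Penalized longitudinal regression objective
#'
#' The full model objective
#' `J2(B) = sum_t ||t(X_t) B_t - Y||_F^2 + gamma1 * ||B||_{2,1} +
#'  gamma2 * ||B_(1)||_*`,
#' where `||B||_{2,1}` is the [tensor_l21_norm()] and `||B_(1)||_*` the
#' [trace_norm()] of the mode-1 unfolding. With `gamma1 = gamma2 = 0` it
#' reduces to decoupled per-visit least squares; with `gamma2 = 0` to the
#' joint-selection model; with `gamma1 = 0` to the trace-norm-only ablation.
#' The objective is jointly convex in `B`.
#'
#' @inheritParams longitudinal_loss
#' @param hp a [model_hyperparameters()] object.
#' @return Non-negative scalar.
#' @export
objective_j2 <- function(X, B, Y, hp) {
  stopifnot(inherits(hp, "model_hyperparameters"))
  U <- unfold_mode1(B)
  val <- longitudinal_loss(X, B, Y)
  if (hp$gamma1 > 0) val <- val + hp$gamma1 * sum(sqrt(rowSums(U^2)))
  if (hp$gamma2 > 0) val <- val + hp$gamma2 * trace_norm(U)
  val
}
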