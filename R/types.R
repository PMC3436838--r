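#' Longitudinal phenotype tensor
#'
#' Container for a stack of per-visit imaging-phenotype matrices. Internally
#' features are stored in rows and subjects in columns, so that
#' `t(X_t) %*% B_t` has shape subjects x SNPs; file readers transpose from the
#' subjects-in-rows on-disk layout.
#'
#' @param values numeric array of dimension `d x n x T` (feature, subject,
#'   time) or, for `T = 1`, a `d x n` matrix.
#' @param feature_ids character vector of length `d`.
#' @param subject_ids character vector of length `n`.
#' @param time_labels character vector of length `T`.
#' @return An object of class `phenotype_tensor`: a list with elements
#'   `values`, `feature_ids`, `subject_ids`, `time_labels`.
#' @examples
#' X <- phenotype_tensor(array(rnorm(3 * 4 * 2), c(3, 4, 2)))
#' dim(X$values)
#' @export
phenotype_tensor <- function(values, feature_ids = NULL, subject_ids = NULL,
                             time_labels = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L || !is.numeric(values))
    stop("'values' must be a numeric d x n x T array")
  d <- dim(values)[1L]; n <- dim(values)[2L]; Tn <- dim(values)[3L]
  if (d < 1L) stop("need at least one feature (axis 1)")
  if (n < 2L) stop("need at least two subjects (axis 2)")
  if (Tn < 1L) stop("need at least one time point (axis 3)")
  if (anyNA(values) || !all(is.finite(values)))
    stop("phenotype values must be finite and non-missing; exclude subjects ",
         "with incomplete longitudinal data upstream")
  if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(d))
  if (is.null(subject_ids)) subject_ids <- paste0("subj", seq_len(n))
  if (is.null(time_labels)) time_labels <- paste0("t", seq_len(Tn))
  check_ids(feature_ids, d, "feature_ids")
  check_ids(subject_ids, n, "subject_ids")
  check_ids(time_labels, Tn, "time_labels")
  structure(list(values = unname(values),
                 feature_ids = as.character(feature_ids),
                 subject_ids = as.character(subject_ids),
                 time_labels = as.character(time_labels)),
            class = "phenotype_tensor")
}

#' Genotype (SNP dosage) matrix
#'
#' Subjects in rows, SNPs in columns. Dosages are treated as continuous
#' responses (imputed values); no rounding to \{0, 1, 2\}.
#'
#' @param values numeric `n x c` matrix.
#' @param snp_ids character vector of length `c`.
#' @param subject_ids character vector of length `n`; must match the paired
#'   [phenotype_tensor()] subject order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snp_ids = NULL, subject_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric n x c matrix")
  if (anyNA(values) || !all(is.finite(values)))
    stop("genotype dosages must be finite (imputation is out of scope)")
  n <- nrow(values); c <- ncol(values)
  if (c < 1L) stop("need at least one SNP column")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(c))
  if (is.null(subject_ids)) subject_ids <- paste0("subj", seq_len(n))
  check_ids(snp_ids, c, "snp_ids")
  check_ids(subject_ids, n, "subject_ids")
  structure(list(values = unname(values),
                 snp_ids = as.character(snp_ids),
                 subject_ids = as.character(subject_ids)),
            class = "genotype_matrix")
}

#' Coefficient tensor
#'
#' The learned association weights `B`, a `d x c x T` array (feature, SNP,
#' time). A plain numeric array is accepted anywhere a coefficient tensor is
#' expected; this constructor validates and tags it.
#'
#' @param values numeric `d x c x T` array (a `d x c` matrix is promoted to
#'   `T = 1`).
#' @return An object of class `coefficient_tensor` (a classed array).
#' @export
coefficient_tensor <- function(values) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L || !is.numeric(values))
    stop("'values' must be a numeric d x c x T array")
  if (anyNA(values) || !all(is.finite(values)))
    stop("coefficient tensor entries must be finite")
  structure(unname(values), class = "coefficient_tensor")
}

#' Model hyperparameters
#'
#' @param gamma1 non-negative weight of the tensor l2,1-norm penalty
#'   (joint feature selection across SNPs and time points).
#' @param gamma2 non-negative weight of the trace-norm penalty on the mode-1
#'   unfolding (low-rank coupling of SNP columns).
#' @param epsilon small positive smoothing constant guarding the reweighting
#'   against zero rows / rank deficiency.
#' @param tol positive stopping tolerance on the relative objective change.
#' @param max_iter maximum number of outer iterations.
#' @return An object of class `model_hyperparameters`.
#' @export
model_hyperparameters <- function(gamma1 = 1, gamma2 = 1, epsilon = 1e-8,
                                  tol = 1e-6, max_iter = 200L) {
  stopifnot(is.numeric(gamma1), length(gamma1) == 1L, is.finite(gamma1),
            is.numeric(gamma2), length(gamma2) == 1L, is.finite(gamma2))
  if (gamma1 < 0 || gamma2 < 0) stop("gamma1 and gamma2 must be >= 0")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(gamma1 = gamma1, gamma2 = gamma2, epsilon = epsilon,
                 tol = tol, max_iter = max_iter),
            class = "model_hyperparameters")
}

## ---- internal helpers -----------------------------------------------------

check_ids <- function(ids, len, what) {
  if (length(ids) != len)
    stop(sprintf("%s has length %d, expected %d", what, length(ids), len))
  if (anyDuplicated(ids))
    stop(sprintf("%s contains duplicates", what))
  invisible(TRUE)
}

# Coerce to the bare d x n x T array, accepting the classed container,
# a 3D array, or (T = 1) a matrix.
pheno_array <- function(X) {
  if (inherits(X, "phenotype_tensor")) return(X$values)
  if (is.matrix(X)) return(array(X, c(dim(X), 1L)))
  if (is.array(X) && length(dim(X)) == 3L) return(unclass(X))
  stop("expected a phenotype_tensor, matrix, or d x n x T array")
}

geno_values <- function(Y) {
  if (inherits(Y, "genotype_matrix")) return(Y$values)
  if (is.matrix(Y)) return(Y)
  stop("expected a genotype_matrix or numeric matrix")
}

coef_array <- function(B) {
  if (inherits(B, "coefficient_tensor")) return(unclass(B))
  if (is.matrix(B)) return(array(B, c(dim(B), 1L)))
  if (is.array(B) && length(dim(B)) == 3L) return(unclass(B))
  stop("expected a coefficient_tensor, matrix, or d x c x T array")
}

# Check that (X, B, Y) agree on every shared axis; errors name the axis.
check_shapes <- function(Xv, Bv, Yv) {
  if (dim(Xv)[1L] != dim(Bv)[1L])
    stop(sprintf("feature axis mismatch: X has d = %d, B has d = %d",
                 dim(Xv)[1L], dim(Bv)[1L]))
  if (dim(Xv)[2L] != nrow(Yv))
    stop(sprintf("subject axis mismatch: X has n = %d, Y has n = %d",
                 dim(Xv)[2L], nrow(Yv)))
  if (dim(Bv)[2L] != ncol(Yv))
    stop(sprintf("SNP axis mismatch: B has c = %d, Y has c = %d",
                 dim(Bv)[2L], ncol(Yv)))
  if (dim(Xv)[3L] != dim(Bv)[3L])
    stop(sprintf("time axis mismatch: X has T = %d, B has T = %d",
                 dim(Xv)[3L], dim(Bv)[3L]))
  invisible(TRUE)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed derived from (seed, k); kept well below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 10000L + as.integer(k) %% 10000L
}
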