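## Independent oracles. These deliberately avoid the package's own code paths:
## norms by explicit loops, spectra by eigen on Gram matrices, and two
## reference optimizers (consensus ADMM for the full objective, a classic
## reweighted multi-task l2,1 solver) coded from first principles.

# random test instance: list(X = d x n x T array, Y = n x c matrix)
random_instance <- function(d, n, c, Tn, seed) {
  set.seed(seed)
  list(X = array(rnorm(d * n * Tn), c(d, n, Tn)),
       Y = matrix(rnorm(n * c), n, c))
}

oracle_l21 <- function(B) {
  d <- dim(B)[1L]
  tot <- 0
  for (k in seq_len(d)) {
    ss <- 0
    for (j in seq_len(dim(B)[2L])) for (t in seq_len(dim(B)[3L]))
      ss <- ss + B[k, j, t]^2
    tot <- tot + sqrt(ss)
  }
  tot
}

# trace norm via eigenvalues of the smaller Gram matrix (the larger one pads
# structural zero eigenvalues whose sqrt amplifies roundoff)
oracle_trace_norm <- function(M) {
  G <- if (nrow(M) <= ncol(M)) M %*% t(M) else t(M) %*% M
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  sum(sqrt(pmax(ev, 0)))
}

oracle_loss <- function(X, B, Y) {
  tot <- 0
  for (t in seq_len(dim(X)[3L]))
    for (i in seq_len(dim(X)[2L]))
      for (j in seq_len(ncol(Y))) {
        pred <- sum(X[, i, t] * B[, j, t])
        tot <- tot + (pred - Y[i, j])^2
      }
  tot
}

oracle_objective <- function(X, B, Y, g1, g2) {
  d <- dim(B)[1L]
  U <- matrix(0, d, dim(B)[2L] * dim(B)[3L])
  for (t in seq_len(dim(B)[3L]))
    U[, (t - 1L) * dim(B)[2L] + seq_len(dim(B)[2L])] <- B[, , t]
  oracle_loss(X, B, Y) + g1 * oracle_l21(B) + g2 * oracle_trace_norm(U)
}

# Consensus ADMM on the unfolded coefficient matrix: an independent convex
# optimizer for loss + g1 * l21 + g2 * trace norm. Both proximal operators
# are closed form (row-wise group soft threshold; singular-value soft
# threshold).
admm_oracle <- function(X, Y, g1, g2, rho = 1, iters = 4000L) {
  d <- dim(X)[1L]; Tn <- dim(X)[3L]; c <- ncol(Y)
  W <- matrix(0, d, c * Tn); Z1 <- W; Z2 <- W; U1 <- W; U2 <- W
  ch <- lapply(seq_len(Tn), function(t)
    chol(2 * X[, , t] %*% t(X[, , t]) + 2 * rho * diag(d)))
  XY <- lapply(seq_len(Tn), function(t) 2 * (X[, , t] %*% Y))
  for (s in seq_len(iters)) {
    for (t in seq_len(Tn)) {
      idx <- (t - 1L) * c + seq_len(c)
      rhs <- XY[[t]] + rho * (Z1[, idx] - U1[, idx] + Z2[, idx] - U2[, idx])
      W[, idx] <- backsolve(ch[[t]], forwardsolve(t(ch[[t]]), rhs))
    }
    A1 <- W + U1
    rn <- sqrt(rowSums(A1^2))
    Z1 <- A1 * pmax(0, 1 - (g1 / rho) / pmax(rn, 1e-300))
    A2 <- W + U2
    sv <- svd(A2)
    Z2 <- sv$u %*% (pmax(sv$d - g2 / rho, 0) * t(sv$v))
    U1 <- U1 + W - Z1
    U2 <- U2 + W - Z2
  }
  B <- array((Z1 + Z2) / 2, c(d, c, Tn))
  oracle_objective(X, B, Y, g1, g2)
}

# Classic reweighted multi-task l2,1 solver for a single time point:
# min ||t(X) B - Y||_F^2 + g1 * sum_k ||b^k||_2. Independent of the package
# solver (no trace-norm path, no shared code).
l21_reference_solver <- function(Xmat, Y, g1, eps = 1e-8, iters = 2000L,
                                 tol = 1e-12) {
  d <- nrow(Xmat)
  Dg <- rep(1, d)
  XXt <- Xmat %*% t(Xmat)
  XY <- Xmat %*% Y
  prev <- Inf
  for (s in seq_len(iters)) {
    B <- solve(XXt + g1 * diag(Dg, d), XY)
    obj <- sum((t(Xmat) %*% B - Y)^2) + g1 * sum(sqrt(rowSums(B^2)))
    if (is.finite(prev) && abs(prev - obj) / max(prev, 1e-12) < tol) break
    prev <- obj
    Dg <- 1 / (2 * sqrt(rowSums(B^2) + eps))
  }
  list(B = B, objective = obj)
}

# Moore-Penrose pseudoinverse from the SVD (oracle for minimum-norm least
# squares).
MASS_ginv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# Scalar lasso closed form: min (a b - y)^2 summed + p |b| for one feature /
# one response column. a, y vectors over subjects.
scalar_lasso_oracle <- function(a, y, p) {
  num <- sum(a * y)
  den <- sum(a * a)
  soft <- sign(num) * max(abs(num) - p / 2, 0)
  soft / den
}
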