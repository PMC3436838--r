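#' Global ranking of longitudinally stable imaging markers
#'
#' Scores each imaging feature by the l2 norm of its row in the mode-1
#' unfolding of the fitted coefficient tensor -- exactly the quantity the
#' tensor l2,1 penalty drives to zero -- and sorts descending. Features that
#' carry weight across many SNPs and visits rank highest.
#'
#' @param B a fitted [coefficient_tensor()] (or a `longsparse_fit`).
#' @param feature_ids optional character vector of feature names (defaults to
#'   `feat1..featd`).
#' @return An object of class `marker_ranking`: data frame with columns
#'   `rank`, `feature_id`, `score`, sorted by score descending with stable
#'   ties (input order), plus attribute `scope = "GLOBAL"`.
#' @export
rank_markers_global <- function(B, feature_ids = NULL) {
  if (inherits(B, "longsparse_fit")) B <- B$coefficients
  U <- unfold_mode1(B)
  d <- nrow(U)
  if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(d))
  check_ids(feature_ids, d, "feature_ids")
  score <- sqrt(rowSums(U^2))
  ord <- order(-score)            # radix order is stable: ties keep input order
  out <- data.frame(rank = seq_len(d),
                    feature_id = as.character(feature_ids)[ord],
                    score = score[ord])
  attr(out, "scope") <- "GLOBAL"
  class(out) <- c("marker_ranking", "data.frame")
  out
}

#' Top imaging markers for one SNP
#'
#' For SNP column `j`, each feature is scored by the absolute value of its
#' temporal mean coefficient `|mean_t B[f, j, t]|`, so features whose signs
#' flip across visits (temporally inconsistent) are demoted. The signed mean
#' and the per-visit coefficients are retained for reporting coefficient
#' direction.
#'
#' @inheritParams rank_markers_global
#' @param snp_id the SNP to report on (name, or column index if no ids are
#'   available).
#' @param k number of top markers to return (`1 <= k <= d`).
#' @param snp_ids optional character vector naming the SNP columns.
#' @return A `marker_ranking` data frame with columns `rank`, `feature_id`,
#'   `score`, `signed_mean`, and one `coef_t<t>` column per visit; attribute
#'   `scope` is the SNP id.
#' @export
top_markers_for_snp <- function(B, snp_id, k, feature_ids = NULL,
                                snp_ids = NULL) {
  if (inherits(B, "longsparse_fit")) B <- B$coefficients
  Bv <- coef_array(B)
  d <- dim(Bv)[1L]; c <- dim(Bv)[2L]; Tn <- dim(Bv)[3L]
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(c))
  check_ids(snp_ids, c, "snp_ids")
  if (is.numeric(snp_id)) snp_id <- snp_ids[as.integer(snp_id)]
  j <- match(snp_id, snp_ids)
  if (is.na(j))
    stop("unknown snp_id '", snp_id, "'; available: ",
         paste(snp_ids, collapse = ", "))
  k <- as.integer(k)
  if (k < 1L || k > d) stop(sprintf("k must be in 1..%d", d))
  if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(d))
  check_ids(feature_ids, d, "feature_ids")
  coefs <- matrix(Bv[, j, ], d, Tn)
  signed_mean <- rowMeans(coefs)
  score <- abs(signed_mean)
  ord <- order(-score)[seq_len(k)]
  out <- data.frame(rank = seq_len(k),
                    feature_id = as.character(feature_ids)[ord],
                    score = score[ord],
                    signed_mean = signed_mean[ord])
  per_t <- as.data.frame(coefs[ord, , drop = FALSE])
  names(per_t) <- paste0("coef_t", seq_len(Tn))
  out <- cbind(out, per_t)
  attr(out, "scope") <- snp_id
  class(out) <- c("marker_ranking", "data.frame")
  out
}

#' Support recovery score
#'
#' Fraction of truly active features among the top-`k` globally ranked
#' features of a fitted coefficient tensor.
#'
#' @inheritParams rank_markers_global
#' @param true_support integer vector of active feature indices (or their
#'   ids), with `length(true_support) == k`.
#' @param k size of the top set.
#' @return Scalar in `[0, 1]`.
#' @export
support_recovery_score <- function(B, true_support, k,
                                   feature_ids = NULL) {
  if (inherits(B, "longsparse_fit")) B <- B$coefficients
  d <- dim(coef_array(B))[1L]
  k <- as.integer(k)
  if (k < 1L || k > d) stop(sprintf("k must be in 1..%d", d))
  if (length(true_support) != k)
    stop("true_support must have exactly k elements")
  rk <- rank_markers_global(B, feature_ids)
  top <- rk$feature_id[seq_len(k)]
  if (is.numeric(true_support)) {
    ids <- if (is.null(feature_ids)) paste0("feat", seq_len(d)) else
      as.character(feature_ids)
    true_support <- ids[as.integer(true_support)]
  }
  length(intersect(top, true_support)) / k
}
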