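## Delimited-text interchange: tab-separated, header row, subject id in the
## first column. Phenotype files are subjects x features per visit; genotype
## files are subjects x SNPs (optionally with FID/IID-style leading id
## columns as written by dosage exporters).

read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
}

check_numeric_cells <- function(df, path, first_col = 2L) {
  for (j in seq(first_col, ncol(df))) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                     path, bad[1L], names(df)[j]))
      df[[j]] <- vn
    }
    if (anyNA(df[[j]]) || !all(is.finite(df[[j]])))
      stop(sprintf("missing or non-finite value in %s, column '%s'",
                   path, names(df)[j]))
  }
  df
}

#' Read a longitudinal phenotype tensor from per-visit files
#'
#' Each file is a tab-separated table with subjects in rows (first column =
#' subject id) and features in columns (header = feature ids). All files must
#' list the same subjects and features in the same order; any discrepancy is
#' an error, never a silent reordering.
#'
#' @param paths character vector of `T` file paths, in visit order.
#' @param time_labels optional labels for the visits (default the file base
#'   names).
#' @return A [phenotype_tensor()].
#' @export
load_phenotype_tensor <- function(paths, time_labels = NULL) {
  if (length(paths) < 1L) stop("need at least one phenotype file")
  if (anyDuplicated(paths)) stop("phenotype paths must be distinct")
  tabs <- lapply(paths, function(p) check_numeric_cells(read_tsv_table(p), p))
  subj <- as.character(tabs[[1L]][[1L]])
  feats <- names(tabs[[1L]])[-1L]
  for (i in seq_along(tabs)) {
    s_i <- as.character(tabs[[i]][[1L]])
    f_i <- names(tabs[[i]])[-1L]
    if (!identical(s_i, subj)) {
      bad <- which(s_i != c(subj, rep(NA, max(0, length(s_i) - length(subj)))))
      stop(sprintf(
        "subject mismatch between %s and %s (first discrepancy at row %d)",
        paths[1L], paths[i], if (length(bad)) bad[1L] else
          min(length(s_i), length(subj)) + 1L))
    }
    if (!identical(f_i, feats)) {
      bad <- which(f_i != c(feats, rep(NA, max(0, length(f_i) - length(feats)))))
      stop(sprintf(
        "feature mismatch between %s and %s (first discrepancy at column %d)",
        paths[1L], paths[i], if (length(bad)) bad[1L] else
          min(length(f_i), length(feats)) + 1L))
    }
  }
  d <- length(feats); n <- length(subj); Tn <- length(paths)
  Xv <- array(0, c(d, n, Tn))
  for (t in seq_len(Tn))
    Xv[, , t] <- t(as.matrix(tabs[[t]][, -1L, drop = FALSE]))
  if (is.null(time_labels))
    time_labels <- make.unique(basename(paths), sep = "_")
  phenotype_tensor(Xv, feature_ids = feats, subject_ids = subj,
                   time_labels = time_labels)
}

#' Write a phenotype tensor to per-visit files
#'
#' Inverse of [load_phenotype_tensor()]; round-trips exactly.
#'
#' @param X a [phenotype_tensor()].
#' @param paths character vector of `T` output paths.
#' @return `paths`, invisibly.
#' @export
write_phenotype_tensor <- function(X, paths) {
  stopifnot(inherits(X, "phenotype_tensor"))
  Tn <- dim(X$values)[3L]
  if (length(paths) != Tn)
    stop(sprintf("need %d paths, got %d", Tn, length(paths)))
  for (t in seq_len(Tn)) {
    df <- data.frame(subject_id = X$subject_ids,
                     t(X$values[, , t]), check.names = FALSE)
    names(df) <- c("subject_id", X$feature_ids)
    utils::write.table(df, paths[t], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read a genotype dosage matrix
#'
#' Tab-separated table, subjects in rows, SNP ids in the header, first column
#' = subject id. The additive-dosage export dialect with `FID`/`IID` leading
#' columns is detected (case-insensitively) and the family id dropped.
#' Missing cells are an error: imputation is upstream of this tool.
#'
#' @param path file path.
#' @param subject_ids optional subject order (typically from the paired
#'   [phenotype_tensor()]); rows are aligned to it by id, and any unmatched
#'   subject is an error.
#' @return A [genotype_matrix()].
#' @export
load_genotype_matrix <- function(path, subject_ids = NULL) {
  df <- read_tsv_table(path)
  lead <- tolower(names(df)[seq_len(min(2L, ncol(df)))])
  if (length(lead) == 2L && lead[1L] %in% c("fid", "famid") &&
      lead[2L] %in% c("iid", "id"))
    df <- df[, -1L, drop = FALSE]    # drop family id; individual id remains
  if (ncol(df) < 2L) stop("genotype table in ", path, " has no SNP columns")
  df <- check_numeric_cells(df, path)
  subj <- as.character(df[[1L]])
  Yv <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(Yv) <- NULL
  snps <- names(df)[-1L]
  if (!is.null(subject_ids)) {
    idx <- match(subject_ids, subj)
    if (anyNA(idx))
      stop("subjects missing from genotype file ", path, ": ",
           paste(utils::head(subject_ids[is.na(idx)], 5L), collapse = ", "))
    Yv <- Yv[idx, , drop = FALSE]
    subj <- subject_ids
  }
  genotype_matrix(Yv, snp_ids = snps, subject_ids = subj)
}

#' Write a genotype matrix
#'
#' @param Y a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(Y, path) {
  stopifnot(inherits(Y, "genotype_matrix"))
  df <- data.frame(subject_id = Y$subject_ids, Y$values, check.names = FALSE)
  names(df) <- c("subject_id", Y$snp_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coefficient tensor as per-visit tables
#'
#' One tab-separated features x SNPs table per visit, feature ids in the
#' first column.
#'
#' @param B a [coefficient_tensor()].
#' @param paths `T` output paths.
#' @param feature_ids,snp_ids row and column names.
#' @return `paths`, invisibly.
#' @export
write_coefficient_tensor <- function(B, paths, feature_ids = NULL,
                                     snp_ids = NULL) {
  Bv <- coef_array(B)
  d <- dim(Bv)[1L]; c <- dim(Bv)[2L]; Tn <- dim(Bv)[3L]
  if (length(paths) != Tn)
    stop(sprintf("need %d paths, got %d", Tn, length(paths)))
  if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(d))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(c))
  for (t in seq_len(Tn)) {
    df <- data.frame(feature_id = feature_ids, Bv[, , t],
                     check.names = FALSE)
    names(df) <- c("feature_id", snp_ids)
    utils::write.table(df, paths[t], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read a coefficient tensor from per-visit tables
#'
#' @param paths `T` paths written by [write_coefficient_tensor()].
#' @return A [coefficient_tensor()] with `feature_ids` / `snp_ids`
#'   attributes.
#' @export
load_coefficient_tensor <- function(paths) {
  tabs <- lapply(paths, function(p) check_numeric_cells(read_tsv_table(p), p))
  feats <- as.character(tabs[[1L]][[1L]])
  snps <- names(tabs[[1L]])[-1L]
  for (i in seq_along(tabs)) {
    if (!identical(as.character(tabs[[i]][[1L]]), feats) ||
        !identical(names(tabs[[i]])[-1L], snps))
      stop("coefficient tables disagree on features/SNPs: ", paths[i])
  }
  Bv <- array(0, c(length(feats), length(snps), length(paths)))
  for (t in seq_along(paths))
    Bv[, , t] <- as.matrix(tabs[[t]][, -1L, drop = FALSE])
  B <- coefficient_tensor(Bv)
  attr(B, "feature_ids") <- feats
  attr(B, "snp_ids") <- snps
  B
}
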