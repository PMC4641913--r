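#' Histogram normalization of profile columns
#'
#' Rank-transforms each column (time point) to equally spaced quantiles of
#' a uniform distribution on [-1, 1]: the smallest value maps to -1, the
#' largest to 1, and ties receive the mean of the positions they span. The
#' transform is invariant under any strictly monotone per-column
#' transformation of the input and equalizes the per-time-point value
#' histograms before SOM training, so no single time point dominates the
#' Euclidean metric. A constant column maps to all zeros.
#'
#' @param x numeric matrix, genes x time points (at least 2 rows).
#' @return Matrix of the same shape with values in [-1, 1].
#' @export
histogram_normalize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("histogram normalization needs at least 2 rows")
  apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (r - 1) / (length(col) - 1) * 2 - 1
  })
}

#' Build reaction-norm profiles for the DE gene set
#'
#' Extracts, for each gene called differentially expressed at any time
#' point, its temporal vector of raw log2(pond/upland) ratios across the
#' post-baseline time points, and attaches the histogram-normalized
#' version used for SOM training. Genes with an untestable (both-zero)
#' ratio at some time point have that entry imputed as 0 (no evidence of
#' change).
#'
#' @param dge a `dge_result` from [dge_timecourse()].
#' @param genes optional character vector selecting the genes; defaults to
#'   all genes with `de_any`.
#' @return An object of class `profile_matrix`: list with `raw` and
#'   `normalized` (genes x time points matrices) and `time_points_h`.
#' @export
build_profiles <- function(dge, genes = NULL) {
  stopifnot(inherits(dge, "dge_result"))
  if (is.null(genes)) genes <- dge$genes$gene_id[dge$genes$de_any]
  tab <- dge$table[dge$table$gene_id %in% genes, ]
  raw <- matrix(0, length(genes), length(dge$time_points_h),
                dimnames = list(genes, as.character(dge$time_points_h)))
  idx <- cbind(match(tab$gene_id, genes),
               match(tab$time_h, dge$time_points_h))
  lr <- tab$log2_ratio
  lr[is.na(lr)] <- 0
  raw[idx] <- lr
  structure(list(raw = raw,
                 normalized = histogram_normalize(raw),
                 time_points_h = dge$time_points_h),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$raw), "genes x", ncol(x$raw),
      "time points (raw + histogram-normalized)\n")
  invisible(x)
}
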