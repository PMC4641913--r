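#' Exact test for a gene's counts in two unreplicated count libraries
#'
#' Exact significance test for comparing a gene's digital expression counts
#' between two libraries under Poisson sampling, conditioning on the total
#' count: given `x + y = n`, the count in library 2 follows
#' `Binomial(n, N2/(N1+N2))` under the null of equal relative expression.
#' The two-sided p-value is twice the smaller tail (each tail including the
#' observed count), capped at 1. This construction is exactly symmetric
#' under swapping `(x, N1)` with `(y, N2)` and is numerically stable for
#' counts up to at least 1e6.
#'
#' All arguments are vectorized and recycled.
#'
#' @param x,y non-negative integer counts in libraries 1 and 2.
#' @param N1,N2 positive totals of uniquely mapped reads in the two
#'   libraries.
#' @return Two-sided p-values in (0, 1].
#' @export
ac_test_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  if (any(x != floor(x)) || any(y != floor(y)))
    stop("counts must be integers")
  k <- length(p <- numeric(max(length(x), length(y),
                               length(N1), length(N2))))
  x <- rep_len(x, k); y <- rep_len(y, k)
  N1 <- rep_len(N1, k); N2 <- rep_len(N2, k)
  n <- x + y
  pr <- N2 / (N1 + N2)
  lower <- stats::pbinom(y, n, pr)                      # P(Y <= y)
  upper <- stats::pbinom(y - 1, n, pr, lower.tail = FALSE)  # P(Y >= y)
  # extreme splits underflow to 0; keep p strictly positive
  pmax(pmin(1, 2 * pmin(lower, upper)), .Machine$double.xmin)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values: with p sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1 and mapped back to the
#' input order; tied p-values share a q.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Log2 expression ratio with a one-read floor for zeros
#'
#' Computes `log2(pond / upland)` from RPKM values. A zero RPKM is replaced
#' by the RPKM a single read would have in that library
#' (`1e9 / (N * L)`), so that ratios against silence stay finite and
#' data-driven. Gene pairs with zero RPKM in both libraries are untestable
#' and return `NA`.
#'
#' @param rpkm_pond,rpkm_upland non-negative RPKM values (vectorized).
#' @param floor_pond,floor_upland the one-read RPKM floor of each library
#'   (scalar or per-gene).
#' @return log2 ratios; `NA` where both inputs are zero.
#' @export
log2_ratio <- function(rpkm_pond, rpkm_upland, floor_pond, floor_upland) {
  if (any(rpkm_pond < 0) || any(rpkm_upland < 0))
    stop("RPKM values must be non-negative")
  p <- ifelse(rpkm_pond == 0, floor_pond, rpkm_pond)
  u <- ifelse(rpkm_upland == 0, floor_upland, rpkm_upland)
  out <- log2(p / u)
  out[rpkm_pond == 0 & rpkm_upland == 0] <- NA_real_
  out
}

#' Per-time-point exact-test differential expression
#'
#' For every post-baseline time point, tests each gene's pond count against
#' its upland count with [ac_test_pvalue()], adjusts p-values within the
#' time point by Benjamini-Hochberg ([bh_fdr()]; each of the pairwise
#' comparisons is its own FDR family), and computes the log2 RPKM ratio
#' with the one-read zero floor. A gene enters a time point's family when
#' it passes the detection filter (`min_reads` uniquely mapped reads) in at
#' least one of the two libraries. A gene is called differentially
#' expressed at a time point when `q <= q_max` and `|log2 ratio| >=
#' min_abs_log2`; `de_any` is the union over time points and `fold10_any`
#' flags genes whose expression differs more than 10-fold at some DE time
#' point.
#'
#' @param cm a [count_matrix()] with paired pond/upland libraries at each
#'   post-baseline time point (the 0 h baseline is excluded from testing).
#' @param q_max FDR threshold for the DE call (default 0.001).
#' @param min_abs_log2 minimum |log2 ratio| for the DE call (default 1).
#' @param min_reads detection filter passed to [detect_expressed()].
#' @return An object of class `dge_result`: list with `table` (long
#'   data.frame: gene_id, time_h, count_pond, count_upland, rpkm_pond,
#'   rpkm_upland, log2_ratio, p, q, is_de), `genes` (gene_id, de_any,
#'   fold10_any), and the thresholds used.
#' @export
dge_timecourse <- function(cm, q_max = 0.001, min_abs_log2 = 1,
                           min_reads = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  if (q_max <= 0 || min_abs_log2 <= 0)
    stop("thresholds must be positive")
  meta <- cm$library_meta
  tps <- sort(unique(meta$time_h[meta$condition %in% c("pond", "upland")]))
  rk <- rpkm(cm)
  res <- vector("list", length(tps))
  for (i in seq_along(tps)) {
    tt <- tps[i]
    lp <- meta$library_id[meta$condition == "pond" & meta$time_h == tt]
    lu <- meta$library_id[meta$condition == "upland" & meta$time_h == tt]
    if (length(lp) != 1 || length(lu) != 1)
      stop(sprintf("time point %s h needs exactly one pond and one upland library", tt))
    xp <- cm$counts[, lp]; xu <- cm$counts[, lu]
    keep <- xp >= min_reads | xu >= min_reads
    if (!any(keep)) next
    Np <- cm$library_total[lp]; Nu <- cm$library_total[lu]
    p <- ac_test_pvalue(xu[keep], xp[keep], Nu, Np)
    q <- bh_fdr(p)
    lr <- log2_ratio(rk[keep, lp], rk[keep, lu],
                     1e9 / (Np * cm$gene_length_bp[keep]),
                     1e9 / (Nu * cm$gene_length_bp[keep]))
    res[[i]] <- data.frame(
      gene_id = rownames(cm$counts)[keep],
      time_h = tt,
      count_pond = xp[keep], count_upland = xu[keep],
      rpkm_pond = rk[keep, lp], rpkm_upland = rk[keep, lu],
      log2_ratio = lr, p = p, q = q,
      is_de = !is.na(lr) & q <= q_max & abs(lr) >= min_abs_log2,
      row.names = NULL)
  }
  tab <- do.call(rbind, res)
  de_any <- tapply(tab$is_de, tab$gene_id, any)
  f10 <- tapply(tab$is_de & !is.na(tab$log2_ratio) &
                  abs(tab$log2_ratio) >= log2(10), tab$gene_id, any)
  genes <- data.frame(gene_id = names(de_any),
                      de_any = as.vector(de_any),
                      fold10_any = as.vector(f10[names(de_any)]),
                      row.names = NULL)
  structure(list(table = tab, genes = genes, time_points_h = tps,
                 q_max = q_max, min_abs_log2 = min_abs_log2,
                 min_reads = min_reads),
            class = "dge_result")
}

#' @export
print.dge_result <- function(x, ...) {
  cat("dge_result:", length(unique(x$table$gene_id)), "genes tested over",
      length(x$time_points_h), "time points\n")
  cat(sprintf("  DE (q <= %g, |log2R| >= %g): %d genes; >10-fold: %d\n",
              x$q_max, x$min_abs_log2, sum(x$genes$de_any),
              sum(x$genes$fold10_any)))
  invisible(x)
}

#' Fold-change bin summary of DE calls per time point
#'
#' Tabulates, per time point and direction, how many DE genes fall in the
#' 2-5x, 5-10x and >10x fold-change bins.
#'
#' @param dge a `dge_result`.
#' @return data.frame: time_h, direction, bin, n_genes.
#' @export
fold_change_bins <- function(dge) {
  tab <- dge$table[dge$table$is_de & !is.na(dge$table$log2_ratio), ]
  bin <- cut(abs(tab$log2_ratio), c(1, log2(5), log2(10), Inf),
             labels = c("2-5x", "5-10x", ">10x"), right = FALSE)
  out <- as.data.frame(table(
    time_h = tab$time_h,
    direction = ifelse(tab$log2_ratio > 0, "up", "down"),
    bin = bin))
  names(out)[4] <- "n_genes"
  out$time_h <- as.numeric(as.character(out$time_h))
  out[order(out$time_h, out$direction, out$bin), , drop = FALSE]
}
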