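#' Livak 2^-ddCt relative quantification
#'
#' Computes relative expression from a Ct table: within each (condition,
#' time) stratum, replicate Ct values are averaged on the Ct scale, the
#' reference gene's mean Ct is subtracted (dCt), the calibrator
#' condition's dCt at the same time point is subtracted (ddCt), and the
#' relative quantity is `RQ = 2^-ddCt`. The calibrator condition has
#' `RQ = 1` for every gene by construction.
#'
#' @param ct data.frame with columns `gene_id`, `condition`, `time_h`,
#'   `replicate`, `ct` (a `ct_table` from [simulate_qpcr()] or any table
#'   of the same shape).
#' @param reference_gene id of the internal reference gene; defaults to
#'   the table's `reference_gene` attribute.
#' @param calibrator calibrator condition (default `"upland"`: fold
#'   changes are pond relative to same-time upland).
#' @return data.frame: gene_id, condition, time_h, dct, ddct, rq,
#'   log2_rq, for all non-reference genes.
#' @export
delta_delta_ct <- function(ct, reference_gene = attr(ct, "reference_gene"),
                           calibrator = "upland") {
  ct <- as.data.frame(ct)
  req <- c("gene_id", "condition", "time_h", "ct")
  if (!all(req %in% names(ct)))
    stop("Ct table needs columns gene_id, condition, time_h, ct")
  if (is.null(reference_gene) || !reference_gene %in% ct$gene_id)
    stop("reference gene missing from the Ct table")
  if (!calibrator %in% ct$condition)
    stop("calibrator condition absent from the Ct table")
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and positive")
  m <- stats::aggregate(ct ~ gene_id + condition + time_h, ct, mean)
  ref <- m[m$gene_id == reference_gene, ]
  strata <- unique(m[c("condition", "time_h")])
  if (nrow(merge(strata, ref[c("condition", "time_h")])) < nrow(strata))
    stop("reference gene not measured in every (condition, time) stratum")
  m <- m[m$gene_id != reference_gene, ]
  m$dct <- m$ct - ref$ct[match(paste(m$condition, m$time_h),
                               paste(ref$condition, ref$time_h))]
  cal <- m[m$condition == calibrator, ]
  m$ddct <- m$dct - cal$dct[match(paste(m$gene_id, m$time_h),
                                  paste(cal$gene_id, cal$time_h))]
  m$rq <- 2^(-m$ddct)
  m$log2_rq <- -m$ddct
  m <- m[order(m$gene_id, m$time_h, m$condition),
         c("gene_id", "condition", "time_h", "dct", "ddct", "rq", "log2_rq")]
  rownames(m) <- NULL
  m
}

#' Concordance between RNA-seq and qPCR log fold changes
#'
#' Pearson correlation (with its two-sided test) between the RNA-seq log2
#' ratios and the qPCR log2 relative quantities over the intersection of
#' (gene, time) pairs; pairs with a missing value on either platform are
#' dropped and counted.
#'
#' @param rnaseq_log2 data.frame with `gene_id`, `time_h`, `log2_ratio`.
#' @param qpcr_log2rq data.frame with `gene_id`, `time_h`, `log2_rq`
#'   (e.g. the pond rows of [delta_delta_ct()] output).
#' @return List with `r`, `p`, `n_pairs`, `n_dropped`.
#' @export
platform_concordance <- function(rnaseq_log2, qpcr_log2rq) {
  m <- merge(rnaseq_log2[c("gene_id", "time_h", "log2_ratio")],
             qpcr_log2rq[c("gene_id", "time_h", "log2_rq")],
             by = c("gene_id", "time_h"))
  ok <- is.finite(m$log2_ratio) & is.finite(m$log2_rq)
  if (sum(ok) < 3) stop("need at least 3 complete (gene, time) pairs")
  ct <- stats::cor.test(m$log2_ratio[ok], m$log2_rq[ok],
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       n_pairs = sum(ok), n_dropped = sum(!ok))
}
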