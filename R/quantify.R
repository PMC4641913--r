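#' RPKM normalization of a count matrix
#'
#' Converts uniquely mapped read counts to Reads Per Kilobase of transcript
#' per Million mapped reads: `rpkm = 1e9 * C / (N * L)` where `C` is the
#' count, `N` the library's uniquely mapped read total and `L` the gene
#' length in bp. No between-library normalization beyond the per-million
#' scaling is applied.
#'
#' @param cm a [count_matrix()].
#' @return Numeric matrix of RPKM values, same dimnames as the counts.
#' @export
rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$library_total <= 0))
    stop("all library totals must be positive")
  sweep(sweep(cm$counts, 2, cm$library_total, `/`), 1,
        cm$gene_length_bp, `/`) * 1e9
}

#' Detection filter for expressed genes
#'
#' A gene is called expressed in a library when it has at least `min_reads`
#' uniquely mapped reads there; the default of 2 reads guards against
#' spurious single-read detections. The any-sample flag is the union over
#' libraries.
#'
#' @param cm a [count_matrix()].
#' @param min_reads minimum uniquely mapped reads for detection (default 2).
#' @return A list with `expressed` (logical genes x libraries matrix),
#'   `any_sample` (logical per gene), and `per_library` (data.frame
#'   `library_id`, `n_expressed`).
#' @export
detect_expressed <- function(cm, min_reads = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  if (min_reads < 1) stop("'min_reads' must be >= 1")
  ex <- cm$counts >= min_reads
  list(expressed = ex,
       any_sample = apply(ex, 1, any),
       per_library = data.frame(library_id = colnames(ex),
                                n_expressed = colSums(ex)))
}
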