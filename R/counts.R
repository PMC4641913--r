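#' Gene-level count matrix with library metadata
#'
#' Container for uniquely mapped read counts (genes x libraries) together
#' with per-gene transcript lengths and per-library metadata (condition and
#' sampling time). This is the input object of the quantification and
#' differential-expression stages.
#'
#' @param counts integer matrix of non-negative counts, genes in rows,
#'   libraries in columns. Row and column names are required and are used as
#'   gene and library identifiers.
#' @param gene_length_bp positive integer vector of transcript lengths in
#'   base pairs, one per gene (named or in row order).
#' @param library_meta data.frame with columns `library_id`, `condition`
#'   (one of `"pond"`, `"upland"`, `"baseline"`) and `time_h` (hours), one
#'   row per library.
#' @param library_total optional numeric vector of uniquely mapped reads per
#'   library. Defaults to the column sums of `counts`; an override is
#'   accepted for counts produced by an external mapper whose mapped-read
#'   totals differ from the matrix column sums.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `gene_length_bp`, `library_meta`, `library_total`.
#' @export
count_matrix <- function(counts, gene_length_bp, library_meta,
                         library_total = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have row (gene) and column (library) names")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (!is.null(names(gene_length_bp)))
    gene_length_bp <- gene_length_bp[rownames(counts)]
  gene_length_bp <- as.numeric(gene_length_bp)
  if (length(gene_length_bp) != nrow(counts))
    stop("'gene_length_bp' must supply one length per gene")
  if (any(!is.finite(gene_length_bp)) || any(gene_length_bp < 1))
    stop("gene lengths must be >= 1 bp")
  library_meta <- as.data.frame(library_meta)
  req <- c("library_id", "condition", "time_h")
  if (!all(req %in% names(library_meta)))
    stop("'library_meta' needs columns library_id, condition, time_h")
  if (!setequal(library_meta$library_id, colnames(counts)))
    stop("library metadata does not match count matrix columns")
  library_meta <- library_meta[match(colnames(counts), library_meta$library_id), ,
                               drop = FALSE]
  rownames(library_meta) <- NULL
  if (!all(library_meta$condition %in% c("pond", "upland", "baseline")))
    stop("condition must be one of 'pond', 'upland', 'baseline'")
  if (is.null(library_total)) {
    library_total <- colSums(counts)
  } else {
    if (!is.null(names(library_total)))
      library_total <- library_total[colnames(counts)]
    library_total <- as.numeric(library_total)
    if (length(library_total) != ncol(counts))
      stop("'library_total' must supply one total per library")
  }
  names(library_total) <- colnames(counts)
  structure(
    list(counts = counts,
         gene_length_bp = stats::setNames(gene_length_bp, rownames(counts)),
         library_meta = library_meta,
         library_total = library_total),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "libraries\n")
  cat("  conditions:",
      paste(sprintf("%s=%d", names(table(x$library_meta$condition)),
                    table(x$library_meta$condition)), collapse = ", "), "\n")
  cat("  time points (h):",
      paste(sort(unique(x$library_meta$time_h)), collapse = ", "), "\n")
  cat("  library totals:",
      format(round(mean(x$library_total))), "reads on average\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write a count matrix and its side tables as plain TSV files
#'
#' Writes `counts.tsv` (gene_id plus one column per library),
#' `gene_lengths.tsv` (gene_id, length_bp) and `samples.tsv`
#' (library_id, condition, time_h, library_total) into `dir`.
#'
#' @param cm a [count_matrix()].
#' @param dir output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_counts <- file.path(dir, "counts.tsv")
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv(df, p_counts)
  p_len <- file.path(dir, "gene_lengths.tsv")
  write_tsv(data.frame(gene_id = names(cm$gene_length_bp),
                       length_bp = as.integer(cm$gene_length_bp)), p_len)
  p_sam <- file.path(dir, "samples.tsv")
  sm <- cm$library_meta
  sm$library_total <- cm$library_total[sm$library_id]
  write_tsv(sm, p_sam)
  invisible(c(counts = p_counts, lengths = p_len, samples = p_sam))
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir directory holding `counts.tsv`, `gene_lengths.tsv` and
#'   `samples.tsv`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(dir) {
  cdf <- utils::read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf[[1]]
  len <- utils::read.delim(file.path(dir, "gene_lengths.tsv"))
  sam <- utils::read.delim(file.path(dir, "samples.tsv"))
  count_matrix(counts,
               stats::setNames(len$length_bp, len$gene_id),
               sam[c("library_id", "condition", "time_h")],
               library_total = stats::setNames(sam$library_total,
                                               sam$library_id))
}

# single canonical TSV writer so that repeated runs are byte-identical
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}
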