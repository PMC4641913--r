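#' Pipeline configuration
#'
#' Bundles every stage parameter of the analysis with defaults matching
#' the canonical settings of the method: detection at 2 uniquely mapped
#' reads, DE at FDR <= 0.001 and |log2 ratio| >= 1, a 26 x 17 (442-unit)
#' hexagonal SOM, k-means with k = 11 on the codebooks, a coherence
#' threshold of 0.3, best-matched 50% extraction, and Fisher enrichment at
#' raw p < 0.01 against the annotated-gene universe.
#'
#' @param min_reads detection filter (reads).
#' @param q_max DE FDR threshold.
#' @param min_abs_log2 DE |log2 ratio| threshold.
#' @param som_grid hexagonal SOM grid `c(rows, cols)`.
#' @param som_epochs batch training epochs.
#' @param k number of codebook clusters.
#' @param kmeans_restarts k-means++ restarts.
#' @param coherence_threshold unit-centroid Euclidean distance cutoff.
#' @param enrich_p raw Fisher p threshold for the enriched flag.
#' @param min_term_size minimum universe genes per tested term.
#' @param calibrator qPCR calibrator condition.
#' @param seed integer seed driving the stochastic stages (k-means
#'   seeding).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_reads = 2, q_max = 0.001, min_abs_log2 = 1,
                            som_grid = c(26, 17), som_epochs = 40, k = 11,
                            kmeans_restarts = 25,
                            coherence_threshold = 0.3, enrich_p = 0.01,
                            min_term_size = 1, calibrator = "upland",
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full reaction-norm analysis pipeline
#'
#' Executes quantification (RPKM + detection filter), per-time-point
#' exact-test differential expression, reaction-norm profile
#' construction, SOM co-expression clustering (histogram normalization,
#' batch SOM, k-means on codebooks, coherence filter, best-50%
#' extraction), per-cluster Fisher GO over-representation when an
#' annotation map is supplied, and qPCR concordance when a Ct table is
#' supplied. All stage outputs are written as TSV files under `out_dir`
#' together with a JSON manifest recording parameters, input hashes and
#' per-stage record counts.
#'
#' @param cm a [count_matrix()].
#' @param config a [pipeline_config()].
#' @param annotation optional [gene_term_map()].
#' @param ct optional Ct table for [delta_delta_ct()].
#' @param out_dir optional output directory; when `NULL` nothing is
#'   written.
#' @return An object of class `reactnorm_run`: list with `expressed`,
#'   `dge`, `profiles`, `som`, `unit_labels`, `clusters`, `enrichment`
#'   (or `NULL`), `qpcr` and `concordance` (or `NULL`), `config`, and
#'   `manifest`.
#' @export
run_pipeline <- function(cm, config = pipeline_config(), annotation = NULL,
                         ct = NULL, out_dir = NULL) {
  stopifnot(inherits(cm, "count_matrix"),
            inherits(config, "pipeline_config"))

  expressed <- detect_expressed(cm, config$min_reads)
  dge <- dge_timecourse(cm, q_max = config$q_max,
                        min_abs_log2 = config$min_abs_log2,
                        min_reads = config$min_reads)
  if (sum(dge$genes$de_any) < 2)
    stop("fewer than 2 DE genes; nothing to cluster")
  profiles <- build_profiles(dge)
  som <- som_map(profiles$normalized, grid = config$som_grid,
                 epochs = config$som_epochs)
  labels0 <- cluster_codebooks(som, k = config$k,
                               n_restarts = config$kmeans_restarts,
                               seed = config$seed)
  unit_labels <- coherence_filter(som, labels0,
                                  threshold = config$coherence_threshold)
  clusters <- summarize_clusters(profiles, som, unit_labels)

  enrichment <- NULL
  if (!is.null(annotation)) {
    gl <- clusters$genes
    cl_list <- split(gl$gene_id[!is.na(gl$cluster)],
                     gl$cluster[!is.na(gl$cluster)])
    names(cl_list) <- paste0("CS", names(cl_list))
    keep <- vapply(cl_list, function(g)
      any(g %in% annotation$gene_id), logical(1))
    enrichment <- fisher_enrichment(cl_list[keep], annotation,
                                    min_term_size = config$min_term_size,
                                    p_cut = config$enrich_p)
  }

  qpcr <- concordance <- NULL
  if (!is.null(ct)) {
    qpcr <- delta_delta_ct(ct, calibrator = config$calibrator)
    pond <- qpcr[qpcr$condition == "pond", ]
    concordance <- platform_concordance(dge$table, pond)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("reactnorm")),
    parameters = unclass(config),
    n_genes = nrow(cm$counts),
    n_libraries = ncol(cm$counts),
    stages = list(
      quantification = list(n_expressed_any = sum(expressed$any_sample)),
      differential_expression = list(
        n_tested = length(unique(dge$table$gene_id)),
        n_de_any = sum(dge$genes$de_any),
        n_fold10_any = sum(dge$genes$fold10_any)),
      som_clustering = list(
        n_profiles = nrow(profiles$raw),
        n_clusters = nrow(clusters$median_profiles),
        n_assigned = sum(!is.na(clusters$genes$cluster)),
        n_best50 = sum(clusters$genes$best50)),
      enrichment = if (is.null(enrichment)) "skipped" else
        list(n_tests = nrow(enrichment),
             n_enriched = sum(enrichment$enriched)),
      qpcr = if (is.null(concordance)) "skipped" else
        list(r = concordance$r, p = concordance$p,
             n_pairs = concordance$n_pairs)))

  run <- structure(list(expressed = expressed, dge = dge,
                        profiles = profiles, som = som,
                        unit_labels = unit_labels, clusters = clusters,
                        enrichment = enrichment, qpcr = qpcr,
                        concordance = concordance, config = config,
                        manifest = manifest),
                   class = "reactnorm_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.reactnorm_run <- function(x, ...) {
  s <- x$manifest$stages
  cat("reactnorm_run\n")
  cat("  expressed (any sample):", s$quantification$n_expressed_any, "genes\n")
  cat("  DE genes:", s$differential_expression$n_de_any,
      sprintf("(>10-fold: %d)\n", s$differential_expression$n_fold10_any))
  cat("  clusters:", s$som_clustering$n_clusters,
      sprintf("(%d genes assigned, %d best-50%%)\n",
              s$som_clustering$n_assigned, s$som_clustering$n_best50))
  if (!is.null(x$concordance))
    cat(sprintf("  qPCR concordance: r = %.3f (n = %d)\n",
                x$concordance$r, x$concordance$n_pairs))
  invisible(x)
}

# write every stage output as TSV plus a JSON manifest
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    paths[[name]] <<- p
  }
  w(run$expressed$per_library, "expressed_summary.tsv")
  w(run$dge$table, "dge_tests.tsv")
  w(run$dge$genes, "dge_genes.tsv")
  w(fold_change_bins(run$dge), "fold_change_bins.tsv")
  raw <- run$profiles$raw
  w(data.frame(gene_id = rownames(raw), raw, check.names = FALSE),
    "profiles_raw.tsv")
  gc_ <- run$som$grid_coords
  w(data.frame(unit = seq_len(nrow(run$som$codebook)),
               row = round(gc_[, "y"] / (sqrt(3) / 2)) + 1,
               col = floor(gc_[, "x"]) + 1,
               cluster = as.integer(run$unit_labels),
               run$som$codebook, check.names = FALSE),
    "som_units.tsv")
  w(run$clusters$genes, "gene_clusters.tsv")
  mp <- run$clusters$median_profiles
  w(data.frame(cluster = rownames(mp), mp, check.names = FALSE),
    "median_profiles.tsv")
  if (!is.null(run$enrichment)) w(run$enrichment, "enrichment.tsv")
  if (!is.null(run$qpcr)) {
    w(run$qpcr, "qpcr_rq.tsv")
    w(data.frame(r = run$concordance$r, p = run$concordance$p,
                 n_pairs = run$concordance$n_pairs,
                 n_dropped = run$concordance$n_dropped),
      "qpcr_concordance.tsv")
  }
  manifest <- run$manifest
  manifest$outputs <- lapply(paths, function(p)
    unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
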