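#' Temporal response archetype templates
#'
#' Eleven parametric temporal response shapes on the post-baseline time
#' grid, each scaled to a peak absolute value of 1. The shapes cover the
#' response classes seen in submergence-type time courses: early or delayed
#' sustained induction, early-transient induction with slow or fast decay,
#' an "up-down" impulse peaking a few hours in, sustained repression,
#' transient induction followed by sustained repression, a repression
#' impulse, and late monotone responses in either direction. Values between
#' the anchor hours are piecewise-linear in log-time.
#'
#' @param time_points_h post-baseline sampling times in hours (default the
#'   8-point grid 1, 3, 6, 12, 24, 48, 120, 288).
#' @return Numeric matrix, archetypes x time points, rownames are archetype
#'   names, peak |value| = 1 per row.
#' @export
archetype_templates <- function(time_points_h = c(1, 3, 6, 12, 24, 48, 120, 288)) {
  anchors <- c(1, 3, 6, 12, 24, 48, 120, 288)
  shapes <- rbind(
    sustained_up_early     = c( 0.60,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00,  1.00),
    sustained_up_delayed   = c( 0.00,  0.15,  0.50,  0.85,  1.00,  1.00,  1.00,  1.00),
    impulse_up_slow_decay  = c( 1.00,  0.90,  0.70,  0.50,  0.30,  0.15,  0.05,  0.00),
    impulse_up_fast_decay  = c( 1.00,  0.60,  0.25,  0.10,  0.00,  0.00,  0.00,  0.00),
    up_down_peak_3h        = c( 0.30,  1.00,  0.50,  0.10,  0.00,  0.00,  0.00,  0.00),
    sustained_down         = c( 0.00, -0.15, -0.50, -0.85, -1.00, -1.00, -1.00, -1.00),
    transient_up_then_down = c( 0.60,  0.10, -0.40, -0.80, -1.00, -1.00, -1.00, -1.00),
    impulse_down           = c(-1.00, -0.70, -0.40, -0.20,  0.00,  0.00,  0.00,  0.00),
    late_up                = c( 0.00,  0.00,  0.00,  0.10,  0.30,  0.60,  0.90,  1.00),
    late_down              = c( 0.00,  0.00,  0.00, -0.10, -0.30, -0.60, -0.90, -1.00),
    transient_down_mid     = c( 0.00, -0.20, -0.60, -1.00, -0.60, -0.20,  0.00,  0.00))
  if (identical(as.numeric(time_points_h), anchors)) {
    colnames(shapes) <- as.character(anchors)
    return(shapes)
  }
  # interpolate in log-time onto a non-default grid
  out <- t(apply(shapes, 1, function(v)
    stats::approx(log(anchors), v, xout = log(pmax(time_points_h, min(anchors))),
                  rule = 2)$y))
  colnames(out) <- as.character(time_points_h)
  out
}

#' Simulation configuration for the synthetic time course
#'
#' Defaults emulate the study conditions of a pond-vs-upland submergence
#' time course: a shared 0 h baseline library plus 8 paired post-baseline
#' time points (17 libraries), about 3.95 million uniquely mapped reads per
#' library, roughly 78% of genes expressed somewhere, and 11 planted
#' temporal response archetypes among the responsive genes.
#'
#' @param n_genes number of genes to simulate.
#' @param time_points_h strictly increasing sampling times in hours, must
#'   start at 0 (the shared baseline).
#' @param library_size expected uniquely mapped reads per library.
#' @param gene_length_range bp interval from which gene lengths are drawn
#'   uniformly.
#' @param n_clusters number of planted response archetypes (at most 11, the
#'   number of available templates).
#' @param frac_responsive fraction of genes assigned a non-null archetype
#'   (exact count, not Bernoulli).
#' @param effect_scale peak |log2 fold change| of each archetype.
#' @param profile_noise_sd per-gene, per-time-point Gaussian jitter (log2
#'   units) around the archetype template.
#' @param dispersion negative-binomial overdispersion; 0 means Poisson
#'   counts (the sampling model assumed by the exact test).
#' @param frac_expressed fraction of genes given non-negligible baseline
#'   expression (the remainder stay below the detection filter).
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       time_points_h = c(0, 1, 3, 6, 12, 24, 48, 120, 288),
                       library_size = 3.95e6,
                       gene_length_range = c(300, 3000),
                       n_clusters = 11,
                       frac_responsive = 0.2,
                       effect_scale = 2,
                       profile_noise_sd = 0.2,
                       dispersion = 0,
                       frac_expressed = 0.7796,
                       seed = 1) {
  if (is.unsorted(time_points_h, strictly = TRUE))
    stop("'time_points_h' must be strictly increasing")
  if (time_points_h[1] != 0) stop("'time_points_h' must include 0")
  if (frac_responsive < 0 || frac_responsive >= 1)
    stop("'frac_responsive' must lie in [0, 1)")
  if (effect_scale <= 0) stop("'effect_scale' must be positive")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (n_clusters > nrow(archetype_templates()))
    stop("'n_clusters' exceeds the number of archetype templates")
  structure(list(n_genes = as.integer(n_genes),
                 time_points_h = as.numeric(time_points_h),
                 library_size = library_size,
                 gene_length_range = gene_length_range,
                 n_clusters = as.integer(n_clusters),
                 frac_responsive = frac_responsive,
                 effect_scale = effect_scale,
                 profile_noise_sd = profile_noise_sd,
                 dispersion = dispersion,
                 frac_expressed = frac_expressed,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-condition RNA-seq time course with planted truth
#'
#' Generates a gene x library count matrix with one shared 0 h baseline
#' library and paired pond/upland libraries at every later time point
#' (2*(T-1)+1 libraries). Baseline expected counts come from a long-tailed
#' (log-normal) abundance distribution over the expressed genes; a
#' configured fraction of genes is silent (near-zero expectation). Each
#' responsive gene follows one of the planted archetypes: its pond mean at
#' time t is the upland mean times `2^profile(t)`, where the profile is the
#' archetype template scaled by `effect_scale` plus per-point Gaussian
#' jitter. Counts are Poisson (`dispersion = 0`) or negative binomial.
#'
#' @param config a [sim_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth` (class
#'   `synthetic_truth`: gene table with `archetype` id, 0 for null genes;
#'   `true_log2_profile` matrix over post-baseline time points; the scaled
#'   `templates`; `time_points_h`).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  tp <- config$time_points_h[-1]          # post-baseline grid
  nt <- length(tp)
  gene_id <- sprintf("G%05d", seq_len(n))

  len <- round(stats::runif(n, config$gene_length_range[1],
                            config$gene_length_range[2]))

  # baseline expected counts: expressed genes long-tailed, silent near zero
  n_expr <- round(config$frac_expressed * n)
  expressed <- sort(sample.int(n, n_expr))
  mu0 <- rep(0, n)
  mu0[-expressed] <- stats::runif(n - n_expr, 0.001, 0.05)
  ab <- stats::rlnorm(n_expr, meanlog = 0, sdlog = 1.8)
  mu0[expressed] <- ab / sum(ab) *
    (config$library_size - sum(mu0[-expressed]))

  # archetype assignment: exact responsive count, balanced across
  # archetypes. Responsive genes are drawn from below the top abundance
  # decile: the most abundant constitutive transcripts are not the
  # environmentally plastic ones, and keeping them stable also keeps the
  # two conditions' sequencing depths comparable.
  n_resp <- round(config$frac_responsive * n)
  archetype <- integer(n)
  if (n_resp > 0) {
    pool <- expressed[mu0[expressed] <= stats::quantile(mu0[expressed], 0.9)]
    resp <- sample(pool, n_resp)
    archetype[resp] <- rep_len(seq_len(config$n_clusters), n_resp)
  }

  templates <- archetype_templates(tp) * config$effect_scale
  templates <- templates[seq_len(config$n_clusters), , drop = FALSE]
  profile <- matrix(0, n, nt, dimnames = list(gene_id, as.character(tp)))
  is_resp <- archetype > 0
  if (any(is_resp)) {
    profile[is_resp, ] <- templates[archetype[is_resp], , drop = FALSE] +
      stats::rnorm(sum(is_resp) * nt, 0, config$profile_noise_sd)
  }

  draw <- function(mu) {
    if (config$dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
  }
  libs <- c("baseline_0h",
            as.vector(rbind(paste0("pond_", tp, "h"),
                            paste0("upland_", tp, "h"))))
  counts <- matrix(0L, n, length(libs), dimnames = list(gene_id, libs))
  counts[, 1] <- draw(mu0)
  for (j in seq_len(nt)) {
    counts[, paste0("upland_", tp[j], "h")] <- draw(mu0)
    counts[, paste0("pond_", tp[j], "h")] <- draw(mu0 * 2^profile[, j])
  }
  meta <- data.frame(
    library_id = libs,
    condition = c("baseline", rep(c("pond", "upland"), nt)),
    time_h = c(0, rep(tp, each = 2)))

  cm <- count_matrix(counts, stats::setNames(len, gene_id), meta)
  truth <- structure(
    list(genes = data.frame(gene_id = gene_id, archetype = archetype),
         true_log2_profile = profile,
         templates = templates,
         time_points_h = tp),
    class = "synthetic_truth")
  list(counts = cm, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$genes), "genes,",
      sum(x$genes$archetype > 0), "responsive across",
      nrow(x$templates), "archetypes\n")
  invisible(x)
}

#' Simulate gene-to-term annotations with planted enrichment
#'
#' Every gene is annotated to each of `n_terms` terms independently with
#' probability `background_rate`; for the term planted on a gene's
#' archetype the odds of annotation are multiplied by `enrichment_boost`.
#' The first `n_clusters` terms are the planted ones (term `TERM:0001` for
#' archetype 1, and so on). `enrichment_boost = 1` yields a null map with
#' no archetype-term association; `enrichment_boost = Inf` annotates every
#' archetype member to its planted term.
#'
#' @param truth a `synthetic_truth` from [simulate_timecourse()].
#' @param n_terms total number of terms (must be at least the number of
#'   planted archetypes).
#' @param background_rate per-gene, per-term background annotation
#'   probability.
#' @param enrichment_boost odds multiplier (>= 1) for planted terms within
#'   their archetype.
#' @param seed integer RNG seed.
#' @return A `gene_term_map` (see [gene_term_map()]) whose universe is every
#'   simulated gene, with attribute `planted_terms`: character vector, the
#'   planted term of each archetype.
#' @export
simulate_annotation <- function(truth, n_terms = 200, background_rate = 0.05,
                                enrichment_boost = 10, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_arch <- nrow(truth$templates)
  if (n_terms < n_arch)
    stop("'n_terms' must be at least the number of planted archetypes")
  if (enrichment_boost < 1) stop("'enrichment_boost' must be >= 1")
  set.seed(seed)
  genes <- truth$genes$gene_id
  arch <- truth$genes$archetype
  terms <- sprintf("TERM:%04d", seq_len(n_terms))
  planted <- terms[seq_len(n_arch)]

  bg_odds <- background_rate / (1 - background_rate)
  boosted_p <- if (is.infinite(enrichment_boost)) 1 else {
    o <- bg_odds * enrichment_boost
    o / (1 + o)
  }
  pairs <- vector("list", n_terms)
  for (j in seq_len(n_terms)) {
    p <- rep(background_rate, length(genes))
    if (j <= n_arch) p[arch == j] <- boosted_p
    hit <- stats::runif(length(genes)) < p
    if (any(hit))
      pairs[[j]] <- data.frame(gene_id = genes[hit], term_id = terms[j])
  }
  map <- gene_term_map(do.call(rbind, pairs), universe = genes)
  attr(map, "planted_terms") <- stats::setNames(planted, rownames(truth$templates))
  map
}

#' Simulate a qRT-PCR Ct table consistent with the planted profiles
#'
#' Emits threshold-cycle (Ct) measurements for a subset of genes plus a
#' stably expressed reference gene, for pond and upland conditions at the
#' requested time points, with `n_reps` technical replicates and Gaussian
#' Ct noise. The table is constructed so that the Livak 2^-ddCt inversion
#' against the same-time upland calibrator recovers the gene's planted
#' log2(pond/upland) profile exactly when `noise_sd = 0`.
#'
#' @param truth a `synthetic_truth`.
#' @param genes character vector of target gene ids (subset of the truth).
#' @param time_points_h time points to assay (default: the truth's grid).
#' @param noise_sd Gaussian noise on each Ct measurement, in cycles.
#' @param n_reps replicates per (gene, condition, time).
#' @param seed integer RNG seed.
#' @return A data.frame of class `ct_table` with columns `gene_id`,
#'   `condition`, `time_h`, `replicate`, `ct`, and attribute
#'   `reference_gene` (id `"REF"`).
#' @export
simulate_qpcr <- function(truth, genes, time_points_h = NULL, noise_sd = 0.3,
                          n_reps = 3, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!all(genes %in% truth$genes$gene_id))
    stop("'genes' must be a subset of the simulated genes")
  if (is.null(time_points_h)) time_points_h <- truth$time_points_h
  if (!all(time_points_h %in% truth$time_points_h))
    stop("'time_points_h' must be a subset of the truth's time grid")
  set.seed(seed)
  ref <- "REF"
  base_ct <- stats::setNames(stats::runif(length(genes), 22, 30), genes)
  rows <- list()
  for (tt in time_points_h) {
    prof <- truth$true_log2_profile[genes, as.character(tt)]
    for (cond in c("pond", "upland")) {
      shift <- if (cond == "pond") -prof else rep(0, length(genes))
      for (r in seq_len(n_reps)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = c(genes, ref),
          condition = cond,
          time_h = tt,
          replicate = r,
          ct = c(base_ct + shift, 20) +
            stats::rnorm(length(genes) + 1, 0, noise_sd))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_gene") <- ref
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Write all synthetic inputs of a simulation as TSV files
#'
#' Writes the count matrix side tables (via [write_count_matrix()]), the
#' gene-to-term map (`gene_terms.tsv`), the truth table
#' (`truth.tsv`: gene_id, archetype, one column per time point of the true
#' log2 profile) and, when given, the Ct table (`ct_table.tsv`).
#'
#' @param sim list with `counts` and `truth` from [simulate_timecourse()].
#' @param dir output directory.
#' @param annotation optional `gene_term_map`.
#' @param ct optional `ct_table`.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, annotation = NULL, ct = NULL) {
  paths <- write_count_matrix(sim$counts, dir)
  tr <- cbind(sim$truth$genes,
              as.data.frame(sim$truth$true_log2_profile,
                            check.names = FALSE))
  names(tr)[-(1:2)] <- paste0("log2fc_", names(tr)[-(1:2)], "h")
  p <- file.path(dir, "truth.tsv"); write_tsv(tr, p)
  paths <- c(paths, truth = p)
  if (!is.null(annotation)) {
    p <- file.path(dir, "gene_terms.tsv")
    write_tsv(as.data.frame(annotation), p)
    paths <- c(paths, gene_terms = p)
  }
  if (!is.null(ct)) {
    p <- file.path(dir, "ct_table.tsv")
    write_tsv(as.data.frame(ct), p)
    paths <- c(paths, ct_table = p)
  }
  invisible(paths)
}
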