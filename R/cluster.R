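#' Group SOM codebook vectors by k-means
#'
#' Runs k-means on the codebook vectors of a fitted SOM (not on the genes
#' themselves) to delineate map regions of coherent expression shape.
#' Each restart seeds centers with the k-means++ rule and refines them
#' with Lloyd iterations; the solution with the smallest within-cluster
#' sum of squares is returned. Deterministic under a fixed seed.
#'
#' @param som a fitted [som_map()].
#' @param k number of clusters (default 11).
#' @param n_restarts independent k-means++ restarts (default 25).
#' @param seed integer RNG seed.
#' @return Integer vector of unit cluster labels in `1..k`, with
#'   attributes `wcss` (the winning within-cluster sum of squares) and
#'   `restart_wcss` (all restart values).
#' @export
cluster_codebooks <- function(som, k = 11, n_restarts = 25, seed = 1) {
  stopifnot(inherits(som, "som_map"))
  if (k < 2) stop("'k' must be at least 2")
  cb <- som$codebook
  if (k > nrow(cb)) stop("'k' exceeds the number of units")
  set.seed(seed)
  best <- NULL
  wcss_all <- numeric(0)
  attempts <- 0
  while (length(wcss_all) < n_restarts && attempts < 4 * n_restarts) {
    attempts <- attempts + 1
    centers <- cb[kmeanspp_seed(cb, k), , drop = FALSE]
    fit <- tryCatch(
      stats::kmeans(cb, centers = centers, iter.max = 100,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    wcss_all <- c(wcss_all, fit$tot.withinss)
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on the codebook vectors")
  structure(best$cluster, wcss = best$tot.withinss,
            restart_wcss = wcss_all)
}

# k-means++ seeding: D^2-weighted sequential center choice
kmeanspp_seed <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - rep(x[idx[1], ], each = n))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - rep(x[idx[j], ], each = n))^2))
  }
  idx
}

#' Coherence filter on clustered SOM units
#'
#' Retains a unit's cluster label only when the distance between its
#' codebook vector and its cluster's centroid (the mean codebook of the
#' initial k-means partition, computed once, no iteration) is at most
#' `threshold`; other units become unassigned (`NA`). Genes mapped to a
#' dropped unit fall out of the cluster set.
#'
#' The distance coefficient is, by default, the dimension-normalized
#' Euclidean distance (Euclidean divided by the square root of the number
#' of time points, i.e. the per-time-point RMS difference), so the 0.3
#' cutoff means the same degree of profile disagreement regardless of how
#' many time points were sampled. Set `metric = "euclidean"` for the plain
#' unnormalized distance.
#'
#' @param som a fitted [som_map()].
#' @param unit_labels integer cluster label per unit, as returned by
#'   [cluster_codebooks()].
#' @param threshold maximum unit-to-centroid distance coefficient
#'   (default 0.3, in the normalized-profile codebook space).
#' @param metric `"rms"` (default, dimension-normalized Euclidean) or
#'   `"euclidean"`.
#' @return Integer vector like `unit_labels` with incoherent units set to
#'   `NA`.
#' @export
coherence_filter <- function(som, unit_labels, threshold = 0.3,
                             metric = c("rms", "euclidean")) {
  stopifnot(inherits(som, "som_map"))
  metric <- match.arg(metric)
  if (threshold <= 0) stop("'threshold' must be positive")
  if (length(unit_labels) != nrow(som$codebook))
    stop("'unit_labels' must cover every unit")
  cent <- rowsum(som$codebook, unit_labels) /
    as.vector(table(unit_labels))
  d <- sqrt(rowSums((som$codebook -
                       cent[as.character(unit_labels), , drop = FALSE])^2))
  if (metric == "rms") d <- d / sqrt(ncol(som$codebook))
  out <- unit_labels
  out[d > threshold] <- NA_integer_
  attr(out, "unit_centroid_distance") <- d
  out
}

#' Cluster medians and best-matched 50% membership
#'
#' Builds the final cluster set from the raw (un-normalized) log2-ratio
#' profiles: per cluster, the median profile is the per-time-point median
#' of the raw log2 ratios over all member genes; each member's match is
#' its Euclidean distance to that median profile; the best-matched 50%
#' are the `ceiling(n/2)` members with the smallest distances, ties broken
#' by gene identifier. Cluster labels are renumbered by descending
#' member count for stable reporting.
#'
#' @param profiles a `profile_matrix` (its `raw` slot is used).
#' @param som a fitted [som_map()] whose `bmu` covers the profile genes.
#' @param unit_labels (possibly filtered) unit cluster labels; genes in
#'   `NA` units are left unassigned.
#' @return An object of class `cluster_set`: list with `genes`
#'   (data.frame: gene_id, unit, cluster, distance_to_median, best50;
#'   unassigned genes have `NA` cluster), `median_profiles` (clusters x
#'   time points, raw log2 units), `sizes`, and `time_points_h`.
#' @export
summarize_clusters <- function(profiles, som, unit_labels) {
  stopifnot(inherits(profiles, "profile_matrix"), inherits(som, "som_map"))
  raw <- profiles$raw
  genes <- rownames(raw)
  unit <- som$bmu[genes]
  cl <- unit_labels[unit]
  present <- sort(unique(cl[!is.na(cl)]))
  if (length(present) == 0) stop("no gene falls in a retained cluster")
  # renumber by descending cluster size (gene counts)
  sizes <- table(factor(cl, levels = present))
  new_id <- stats::setNames(rank(-as.vector(sizes), ties.method = "first"),
                            names(sizes))
  cl_new <- ifelse(is.na(cl), NA_integer_,
                   as.integer(new_id[as.character(cl)]))
  k <- length(present)
  med <- matrix(NA_real_, k, ncol(raw),
                dimnames = list(seq_len(k), colnames(raw)))
  dist_to_med <- rep(NA_real_, length(genes))
  best50 <- rep(FALSE, length(genes))
  for (c_id in seq_len(k)) {
    memb <- which(!is.na(cl_new) & cl_new == c_id)
    med[c_id, ] <- apply(raw[memb, , drop = FALSE], 2, stats::median)
    dd <- sqrt(colSums((t(raw[memb, , drop = FALSE]) - med[c_id, ])^2))
    dist_to_med[memb] <- dd
    ord <- memb[order(dd, genes[memb])]
    best50[ord[seq_len(ceiling(length(memb) / 2))]] <- TRUE
  }
  structure(
    list(genes = data.frame(gene_id = genes, unit = unname(unit),
                            cluster = cl_new,
                            distance_to_median = dist_to_med,
                            best50 = best50, row.names = NULL),
         median_profiles = med,
         sizes = as.vector(sort(sizes, decreasing = TRUE)),
         time_points_h = profiles$time_points_h),
    class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", sum(!is.na(x$genes$cluster)), "genes in",
      nrow(x$median_profiles), "clusters;",
      sum(is.na(x$genes$cluster)), "unassigned\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Plot cluster median profiles
#'
#' One line per cluster: the median log2(pond/upland) reaction norm over
#' the time course, on a log-scaled time axis.
#'
#' @param x a `cluster_set`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cluster_set <- function(x, ...) {
  graphics::matplot(x$time_points_h, t(x$median_profiles), type = "b",
                    pch = 16, lty = 1, log = "x",
                    xlab = "time (h)", ylab = "median log2(pond/upland)",
                    ...)
  graphics::abline(h = 0, col = "grey", lty = 2)
  graphics::legend("topright", legend = rownames(x$median_profiles),
                   col = seq_len(nrow(x$median_profiles)), lty = 1,
                   cex = 0.7, ncol = 2)
  invisible(x)
}

#' Score cluster recovery against planted truth
#'
#' Compares a recovered gene-to-cluster assignment with the planted
#' archetype labels of a synthetic run: the adjusted Rand index over the
#' genes present in both (chance-corrected; 1 = identical partitions), and
#' the per-archetype purity (largest fraction of an archetype's genes
#' landing in a single recovered cluster).
#'
#' @param assignments data.frame with `gene_id` and `cluster` (e.g. the
#'   `genes` slot of a `cluster_set`, optionally subset to `best50`).
#' @param truth a `synthetic_truth`.
#' @return List with `ari`, `purity` (named per archetype), and `n_scored`.
#' @export
recovery_score <- function(assignments, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  resp <- truth$genes[truth$genes$archetype > 0, ]
  a <- assignments[!is.na(assignments$cluster) &
                     assignments$gene_id %in% resp$gene_id, ]
  if (nrow(a) == 0) stop("no overlap between assignments and planted genes")
  planted <- resp$archetype[match(a$gene_id, resp$gene_id)]
  ari <- mclust::adjustedRandIndex(a$cluster, planted)
  purity <- sapply(split(a$cluster, planted),
                   function(cl) max(table(cl)) / length(cl))
  list(ari = ari, purity = purity, n_scored = nrow(a))
}
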