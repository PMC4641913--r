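#' Gene-to-term annotation map
#'
#' A long table of (gene, term) annotation pairs together with the gene
#' universe eligible for enrichment testing. Every universe gene appears
#' in the universe even when it carries no term.
#'
#' @param pairs data.frame with columns `gene_id` and `term_id` (duplicate
#'   pairs are collapsed), or `NULL` for an empty map.
#' @param universe character vector of all eligible genes; must contain
#'   every annotated gene.
#' @return An object of class `gene_term_map`: the de-duplicated pairs
#'   data.frame with attribute `universe`.
#' @export
gene_term_map <- function(pairs, universe) {
  if (is.null(pairs))
    pairs <- data.frame(gene_id = character(0), term_id = character(0))
  pairs <- unique(as.data.frame(pairs)[c("gene_id", "term_id")])
  rownames(pairs) <- NULL
  if (!all(pairs$gene_id %in% universe))
    stop("every annotated gene must be in the universe")
  structure(pairs, universe = unique(as.character(universe)),
            class = c("gene_term_map", "data.frame"))
}

#' @export
print.gene_term_map <- function(x, ...) {
  cat("gene_term_map:", nrow(x), "annotations,",
      length(unique(x$term_id)), "terms,",
      length(attr(x, "universe")), "genes in universe\n")
  invisible(x)
}

#' Propagate annotations to ontology ancestors (true-path rule)
#'
#' Closes each gene's term set under `is_a` ancestors: a gene annotated to
#' a term is implicitly annotated to every ancestor of that term. With no
#' ontology supplied the map is returned unchanged. The operation is
#' idempotent.
#'
#' @param map a [gene_term_map()].
#' @param ontology data.frame of directed `is_a` edges with columns
#'   `child` and `parent` (term identifiers); must be acyclic.
#' @return A [gene_term_map()] with ancestor-closed annotations.
#' @export
propagate_annotations <- function(map, ontology = NULL) {
  stopifnot(inherits(map, "gene_term_map"))
  if (is.null(ontology) || nrow(ontology) == 0) return(map)
  g <- igraph::graph_from_data_frame(ontology[c("child", "parent")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) stop("ontology contains a cycle")
  anc <- lapply(igraph::V(g)$name, function(v)
    setdiff(names(igraph::subcomponent(g, v, mode = "out")), v))
  names(anc) <- igraph::V(g)$name
  extra <- anc[map$term_id]
  n_extra <- lengths(extra)
  closed <- rbind(
    as.data.frame(map),
    data.frame(gene_id = rep(map$gene_id, n_extra),
               term_id = unlist(extra, use.names = FALSE)))
  out <- gene_term_map(closed, attr(map, "universe"))
  attr(out, "planted_terms") <- attr(map, "planted_terms")
  out
}

#' Fisher's exact over-representation test per cluster
#'
#' For each (cluster, term) pair builds the 2x2 table (`k` cluster genes
#' with the term, `n - k` without, `K - k` non-cluster genes with it,
#' `N - n - K + k` with neither) and computes the one-sided
#' over-representation p-value, the hypergeometric upper tail
#' `P(X >= k)`. Terms annotating fewer than `min_term_size` universe genes
#' are skipped as vacuous. No multiple-testing correction is applied; the
#' `enriched` flag uses the raw p threshold.
#'
#' @param clusters named list of character vectors of gene ids (or a
#'   single vector for one cluster). Genes outside the universe are an
#'   error.
#' @param map a [gene_term_map()].
#' @param universe optional character vector overriding the test universe;
#'   by default all map-universe genes carrying at least one annotation.
#' @param min_term_size minimum universe genes per term (default 1).
#' @param p_cut raw-p enrichment threshold (default 0.01).
#' @return data.frame: cluster, term_id, k, K, n, N, p, enriched.
#' @export
fisher_enrichment <- function(clusters, map, universe = NULL,
                              min_term_size = 1, p_cut = 0.01) {
  stopifnot(inherits(map, "gene_term_map"))
  if (!is.list(clusters)) clusters <- list(cluster1 = clusters)
  if (is.null(names(clusters)))
    names(clusters) <- paste0("cluster", seq_along(clusters))
  if (is.null(universe)) universe <- unique(map$gene_id)
  if (length(universe) == 0) stop("empty universe")
  ann <- map[map$gene_id %in% universe, , drop = FALSE]
  term_genes <- split(ann$gene_id, ann$term_id)
  term_genes <- term_genes[lengths(term_genes) >= min_term_size]
  N <- length(universe)
  out <- lapply(names(clusters), function(cl_name) {
    cl <- intersect(unique(clusters[[cl_name]]), universe)
    if (length(cl) == 0) stop("cluster '", cl_name,
                              "' has no genes in the universe")
    n <- length(cl)
    k <- vapply(term_genes, function(g) sum(cl %in% g), integer(1))
    K <- lengths(term_genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(cluster = cl_name, term_id = names(term_genes),
               k = unname(k), K = unname(K), n = n, N = N,
               p = unname(p), enriched = unname(p) < p_cut,
               row.names = NULL)
  })
  do.call(rbind, out)
}
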