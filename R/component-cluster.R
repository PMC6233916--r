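#' Average-linkage hierarchical clustering of components
#'
#' UPGMA agglomeration on a precomputed distance-correlation
#' dissimilarity; the inter-cluster distance is the average pairwise
#' dissimilarity between members. Flat clusters are obtained by cutting
#' the tree at `cut_height` (study convention: 0.40 on the 1 - dCor
#' scale); clusters of size one are flagged as singletons. Exact-tie
#' merges follow `stats::hclust` order (lowest index first), so
#' dendrograms are reproducible.
#'
#' @param d a `dissimilarity_matrix`.
#' @param cut_height flat-cut height, default 0.40.
#' @param method linkage passed to [stats::hclust()], default "average".
#' @return list of class `component_clustering`: `tree` (hclust),
#'   `labels` (named integer vector), `k`, `cut_height`, `singleton`
#'   (named logical).
#' @export
agglomerative_cluster <- function(d, cut_height = 0.40, method = "average") {
  hc <- stats::hclust(stats::as.dist(d), method = method)
  if (is.unsorted(hc$height)) {
    stop("linkage produced non-monotone merge heights")   # cannot happen for UPGMA
  }
  labels <- stats::cutree(hc, h = cut_height)
  sizes <- table(labels)
  structure(list(
    tree = hc,
    labels = labels,
    k = max(labels),
    cut_height = cut_height,
    singleton = stats::setNames(as.vector(sizes[as.character(labels)] == 1L),
                                names(labels))
  ), class = "component_clustering")
}

#' @export
print.component_clustering <- function(x, ...) {
  cat(sprintf("component clustering: %d components, %d clusters at cut %.2f (%d singletons)\n",
              length(x$labels), x$k, x$cut_height, sum(x$singleton)))
  invisible(x)
}

#' Divisive (DIANA) clustering on a precomputed dissimilarity
#'
#' Kaufman-Rousseeuw divisive analysis via [cluster::diana()]; the
#' divisive tree is cut to `k` flat clusters.
#'
#' @param d a `dissimilarity_matrix`.
#' @param k number of clusters, 2 <= k <= p.
#' @return named integer labels.
#' @export
divisive_cluster <- function(d, k) {
  p <- nrow(d)
  if (k < 2 || k > p) stop("k must lie in [2, ", p, "]")
  di <- cluster::diana(stats::as.dist(d), diss = TRUE)
  stats::cutree(stats::as.hclust(di), k = k)
}

#' Partitioning around medoids on a precomputed dissimilarity
#'
#' Kaufman-Rousseeuw k-medoids (BUILD + SWAP) via [cluster::pam()]. The
#' SWAP phase can only improve the BUILD objective (sum of dissimilarity
#' to the nearest medoid); this is asserted on every fit.
#'
#' @param d a `dissimilarity_matrix`.
#' @param k number of clusters, 2 <= k <= p.
#' @return named integer labels with medoid ids in attribute `medoids`.
#' @export
pam_cluster <- function(d, k) {
  p <- nrow(d)
  if (k < 2 || k > p) stop("k must lie in [2, ", p, "]")
  dd <- stats::as.dist(d)
  build <- cluster::pam(dd, k = k, diss = TRUE, do.swap = FALSE)
  full <- cluster::pam(dd, k = k, diss = TRUE)
  if (full$objective[["swap"]] > build$objective[["build"]] + 1e-12) {
    stop("PAM SWAP worsened the BUILD objective")   # contract violation
  }
  out <- full$clustering
  attr(out, "medoids") <- full$medoids
  out
}

#' Rand index between two flat partitions
#'
#' Fraction of the `choose(n, 2)` object pairs on which two labelings
#' agree (placed together in both, or apart in both). Plain Rand, not
#' adjusted; invariant to label permutation.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return value in `[0, 1]`.
#' @export
rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2) stop("need at least two objects")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  # agreements = together-together + apart-apart
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

#' Component connectivity graph
#'
#' Node connectivity is the sum of a component's distance correlations to
#' all other components, scaled by the maximum (so the hub has scaled
#' connectivity 1). Edges with dCor below `edge_min_dcor` are dropped
#' from the export (presentation threshold only — connectivity always
#' uses all pairs).
#'
#' @param d a `dissimilarity_matrix`.
#' @param clustering optional `component_clustering` supplying a cluster
#'   attribute per node.
#' @param edge_min_dcor minimum dCor for a retained edge, default 0.3.
#' @return an [igraph::graph][igraph] with vertex attributes
#'   `scaled_connectivity` and `cluster`, edge attribute `dcor`.
#' @export
build_connectivity_graph <- function(d, clustering = NULL, edge_min_dcor = 0.3) {
  dcor <- 1 - unclass(d)
  diag(dcor) <- 0
  k <- rowSums(dcor)
  scaled <- if (max(k) > 0) k / max(k) else rep(1, length(k))
  adj <- dcor
  adj[adj < edge_min_dcor] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$dcor <- igraph::E(g)$weight
  igraph::V(g)$scaled_connectivity <- scaled[igraph::V(g)$name]
  if (!is.null(clustering)) {
    igraph::V(g)$cluster <- unname(clustering$labels[igraph::V(g)$name])
  }
  g
}

#' Write cluster labels and graph exports
#'
#' @param clustering a `component_clustering`.
#' @param graph an igraph object from [build_connectivity_graph()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_component_outputs <- function(clustering, graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels_path <- file.path(dir, "component_clusters.csv")
  utils::write.csv(data.frame(
    component_id = names(clustering$labels),
    cluster_id = unname(clustering$labels),
    is_singleton = unname(clustering$singleton)
  ), labels_path, row.names = FALSE)
  graphml_path <- file.path(dir, "component_network.graphml")
  igraph::write_graph(graph, graphml_path, format = "graphml")
  el <- igraph::as_data_frame(graph, what = "edges")
  edges_path <- file.path(dir, "component_edges.tsv")
  utils::write.table(el[, c("from", "to", "dcor")], edges_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(labels_path, graphml_path, edges_path))
}
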