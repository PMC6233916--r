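#' Bipartite group-component graph
#'
#' Aggregates participants into groups defined by (sensitisation cluster,
#' asthma status); the weighted edge from a group to a component counts
#' the group's members positive to that component. Zero-weight edges are
#' omitted. Total edge weight equals the total number of positive entries
#' in the profile (conservation).
#'
#' @param b filtered `binary_profile`.
#' @param subject_clusters named labels (participant id -> cluster).
#' @param component_clusters named labels (component id -> cluster),
#'   e.g. `$labels` of [agglomerative_cluster()].
#' @param outcomes data.frame with `participant_id` and `asthma`.
#' @return list of class `bipartite_graph`: `graph` (igraph, vertex
#'   attributes `type` ("group"/"component"), `size`, `asthma_status`,
#'   `cluster`), `edges` (data.frame group/component/weight).
#' @export
build_bipartite <- function(b, subject_clusters, component_clusters, outcomes) {
  ids <- rownames(b)
  if (!all(ids %in% names(subject_clusters))) stop("unlabelled subject(s) in profile")
  m <- match(ids, outcomes$participant_id)
  if (anyNA(m)) stop("subjects missing from outcome table")
  asthma <- outcomes$asthma[m]
  grp <- paste0("SC", subject_clusters[ids], "_",
                ifelse(asthma == 1, "asthma", "noasthma"))
  bm <- unclass(b)
  agg <- rowsum(bm, grp)                      # groups x components, positive counts
  ew <- as.data.frame(as.table(as.matrix(agg)), stringsAsFactors = FALSE)
  names(ew) <- c("group", "component", "weight")
  ew <- ew[ew$weight > 0, , drop = FALSE]
  rownames(ew) <- NULL

  gsize <- table(grp)
  verts <- rbind(
    data.frame(name = rownames(agg), type = "group",
               size = as.integer(gsize[rownames(agg)]),
               asthma_status = ifelse(grepl("_asthma$", rownames(agg)), 1L, 0L),
               cluster = sub("^SC([0-9]+)_.*$", "\\1", rownames(agg)),
               stringsAsFactors = FALSE),
    data.frame(name = colnames(bm), type = "component",
               size = as.integer(colSums(bm)),
               asthma_status = NA_integer_,
               cluster = as.character(component_clusters[colnames(bm)]),
               stringsAsFactors = FALSE)
  )
  g <- igraph::graph_from_data_frame(ew, directed = FALSE, vertices = verts)
  structure(list(graph = g, edges = ew), class = "bipartite_graph")
}

#' Asthma odds by number of positive components in a subset
#'
#' Stratifies participants by how many components of `component_subset`
#' they are positive to, and reports each stratum's asthma odds ratio
#' against the lowest (zero/one-positive) stratum with a Wald 95% CI.
#' Strata with an empty comparison are flagged and get no OR.
#'
#' @param b `binary_profile`; @param outcomes data.frame with
#'   `participant_id`, `asthma`.
#' @param component_subset component ids, non-empty.
#' @param breaks count strata as a list of integer vectors, default
#'   `list(0:1, 2:Inf)` style: 0-1 positives (reference) vs 2+.
#' @return data.frame: stratum, n, cases, or, ci_low, ci_high, flagged.
#' @export
multi_positivity_risk <- function(b, outcomes, component_subset,
                                  breaks = c(0, 2)) {
  stopifnot(length(component_subset) > 0)
  if (!all(component_subset %in% colnames(b))) stop("unknown components in subset")
  counts <- rowSums(unclass(b)[, component_subset, drop = FALSE])
  m <- match(rownames(b), outcomes$participant_id)
  if (anyNA(m)) stop("subjects missing from outcome table")
  y <- outcomes$asthma[m]
  stratum <- cut(counts, breaks = c(breaks, Inf), right = FALSE,
                 include.lowest = TRUE)
  levs <- levels(stratum)[table(stratum) > 0]
  ref <- levs[1]
  out <- do.call(rbind, lapply(levs, function(s) {
    in_s <- stratum == s
    n <- sum(in_s); cases <- sum(y[in_s] == 1)
    if (s == ref || length(levs) == 1L) {
      data.frame(stratum = s, n = n, cases = cases, or = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, flagged = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      in_r <- stratum == ref
      est <- odds_ratio_wald(a = cases, b = n - cases,
                             c = sum(y[in_r] == 1), d = sum(y[in_r] == 0))
      data.frame(stratum = s, n = n, cases = cases, or = est$or,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 flagged = est$corrected, stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Write bipartite graph exports
#'
#' @param bg a `bipartite_graph`; @param dir output directory.
#' @export
write_bipartite_outputs <- function(bg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  igraph::write_graph(bg$graph, file.path(dir, "bipartite.graphml"),
                      format = "graphml")
  utils::write.table(bg$edges, file.path(dir, "bipartite_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
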