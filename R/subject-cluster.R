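#' Jaccard distance between two binary vectors
#'
#' `1 - |a AND b| / |a OR b|`. Undefined (and an error here) when both
#' vectors are all-zero — the filtering step guarantees every retained
#' participant has at least one positive.
#'
#' @param a,b equal-length binary vectors.
#' @return value in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  union <- sum(a | b)
  if (union == 0) stop("Jaccard distance undefined for two all-zero profiles")
  1 - sum(a & b) / union
}

#' Pairwise Jaccard distances between participant profiles
#'
#' @param b a `binary_profile` (participants x components); no all-zero
#'   rows allowed.
#' @return a `dist` object over participants.
#' @export
jaccard_matrix <- function(b) {
  if (any(rowSums(unclass(b)) == 0)) {
    stop("all-zero profiles present; filter participants first")
  }
  stats::dist(unclass(b), method = "binary")
}

#' Ward clustering of participants on Jaccard distances
#'
#' Lance-Williams Ward.D2 agglomeration (squared-distance update) on the
#' precomputed Jaccard matrix. Ward on a non-Euclidean distance is a
#' heuristic, adopted deliberately to match common practice for binary
#' sensitisation profiles. Flat labels are produced for every k in
#' `k_range`.
#'
#' @param distances a `dist` of Jaccard distances (from [jaccard_matrix()]).
#' @param k_range candidate cluster counts, each in `[2, n - 1]`.
#' @return list of class `subject_clustering`: `tree`, `labels_by_k`
#'   (matrix, one column per k), `k_range`.
#' @export
ward_cluster <- function(distances, k_range = 2:8) {
  n <- attr(distances, "Size")
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie in [2, ", n - 1, "]")
  }
  hc <- stats::hclust(distances, method = "ward.D2")
  labels <- sapply(k_range, function(k) stats::cutree(hc, k = k))
  colnames(labels) <- as.character(k_range)
  structure(list(tree = hc, labels_by_k = labels, k_range = k_range),
            class = "subject_clustering")
}

#' Calinski-Harabasz selection of the number of subject clusters
#'
#' The CH index is computed on the binary profiles embedded as 0/1
#' coordinates (CH needs centroids; the embedding is the simplest
#' faithful choice): between-cluster dispersion over within-cluster
#' dispersion, each normalised by its degrees of freedom. `k*` is the
#' argmax over the clustering's `k_range`; k = 1 is undefined and never
#' in the trace.
#'
#' @param profiles binary matrix whose rows were clustered.
#' @param clustering a `subject_clustering` from [ward_cluster()].
#' @return list: `k` (selected), `trace` (named numeric, k -> CH value),
#'   `labels` (flat labels at k*).
#' @export
select_k_calinski_harabasz <- function(profiles, clustering) {
  x <- unclass(profiles)
  if (nrow(unique(x)) < 2) stop("all profiles identical; CH undefined")
  trace <- vapply(seq_along(clustering$k_range), function(ii) {
    calinski_harabasz(x, clustering$labels_by_k[, ii])
  }, numeric(1))
  names(trace) <- as.character(clustering$k_range)
  best <- which.max(trace)
  list(k = clustering$k_range[best], trace = trace,
       labels = stats::setNames(clustering$labels_by_k[, best], rownames(x)))
}

calinski_harabasz <- function(x, labels) {
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    ssb <- ssb + nrow(xg) * sum((cg - grand)^2)
    ssw <- ssw + sum(sweep(xg, 2, cg)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Associate subject clusters with clinical outcomes
#'
#' Per binary outcome: a k x 2 contingency table with a chi-squared test
#' (no Yates correction; Monte-Carlo p-value when any expected count is
#' below 5) and a per-cluster odds ratio of the outcome for membership of
#' that cluster versus all remaining participants, with Wald 95% CI on
#' the log scale (`SE = sqrt(1/a + 1/b + 1/c + 1/d)`); zero cells get the
#' Haldane-Anscombe 0.5 correction and are flagged. Per continuous
#' outcome: a Kruskal-Wallis test across clusters.
#'
#' @param labels named integer cluster labels (names = participant ids).
#' @param outcomes data.frame with `participant_id` and outcome columns.
#' @param binary_cols,continuous_cols outcome columns to test; defaults
#'   pick the standard binary flags present and every other numeric
#'   column as continuous.
#' @param or_reference "rest" (default: each cluster versus all other
#'   retained participants) or a specific cluster label to use as the
#'   reference group.
#' @return list of class `association_report` with `binary` (per outcome:
#'   `table`, `chisq`, `odds_ratios`) and `continuous` (per outcome:
#'   `kruskal`).
#' @export
associate_outcomes <- function(labels, outcomes,
                               binary_cols = NULL, continuous_cols = NULL,
                               or_reference = "rest") {
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by participant id")
  m <- match(ids, outcomes$participant_id)
  if (anyNA(m)) stop("participants missing from outcome table: ",
                     paste(utils::head(ids[is.na(m)]), collapse = ", "))
  oc <- outcomes[m, , drop = FALSE]
  std_binary <- c("asthma", "wheeze", "rhinitis", "AD")
  if (is.null(binary_cols)) binary_cols <- intersect(std_binary, names(oc))
  if (is.null(continuous_cols)) {
    continuous_cols <- setdiff(names(oc)[vapply(oc, is.numeric, logical(1))],
                               c(binary_cols, "participant_id"))
  }
  out <- list(binary = list(), continuous = list())
  for (cl in binary_cols) {
    y <- oc[[cl]]
    ok <- !is.na(y)
    tab <- table(cluster = labels[ok], outcome = factor(y[ok], levels = 0:1))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ch <- stats::chisq.test(tab, simulate.p.value = TRUE, B = 2000)
    } else {
      ch <- stats::chisq.test(tab, correct = FALSE)
    }
    ors <- lapply(sort(unique(labels[ok])), function(g) {
      in_g <- labels[ok] == g
      ref <- if (identical(or_reference, "rest")) !in_g else labels[ok] == or_reference
      odds_ratio_wald(a = sum(in_g & y[ok] == 1), b = sum(in_g & y[ok] == 0),
                      c = sum(ref & y[ok] == 1), d = sum(ref & y[ok] == 0))
    })
    names(ors) <- paste0("cluster_", sort(unique(labels[ok])))
    out$binary[[cl]] <- list(table = tab,
                             chisq = list(statistic = unname(ch$statistic),
                                          p = ch$p.value),
                             odds_ratios = ors)
  }
  for (cl in continuous_cols) {
    v <- oc[[cl]]
    ok <- !is.na(v)
    kw <- stats::kruskal.test(v[ok], factor(labels[ok]))
    out$continuous[[cl]] <- list(kruskal = list(statistic = unname(kw$statistic),
                                                df = unname(kw$parameter),
                                                p = kw$p.value))
  }
  class(out) <- "association_report"
  out
}

#' Odds ratio with Wald 95% confidence interval
#'
#' `OR = (a * d) / (b * c)` for exposed cases `a`, exposed non-cases `b`,
#' reference cases `c`, reference non-cases `d`. Any zero cell triggers
#' the Haldane-Anscombe 0.5 continuity correction (flagged in the
#' result).
#'
#' @param a,b,c,d cell counts.
#' @return list: `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
odds_ratio_wald <- function(a, b, c, d) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       corrected = corrected)
}
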