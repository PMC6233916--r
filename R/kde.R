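#' Bivariate Gaussian product-kernel density estimate
#'
#' Product kernel with an independent bandwidth per dimension from the
#' requested rule, computed on the supplied points only. For two
#' dimensions Scott's and Silverman's multivariate rules coincide at
#' `h_j = sd_j * m^(-1/6)`; a fixed bandwidth can be supplied instead.
#' Near-constant dimensions (sd below 1e-8 — e.g. a component all-zero
#' within one class) get a small fallback bandwidth of 1e-3 so the
#' density stays evaluable.
#'
#' @param points numeric matrix with two columns, at least 5 rows.
#' @param bandwidth_rule "scott", "silverman" or "fixed".
#' @param fixed_h length-2 bandwidths when `bandwidth_rule = "fixed"`.
#' @param label identifier used in error messages (e.g. "pair Der p 1 /
#'   Der p 2, class 1").
#' @return object of class `pair_density` with `$train`, `$h`; evaluate
#'   with [evaluate_density()].
#' @export
fit_pair_density <- function(points, bandwidth_rule = c("scott", "silverman", "fixed"),
                             fixed_h = NULL, label = "pair") {
  bandwidth_rule <- match.arg(bandwidth_rule)
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two columns")
  if (nrow(points) < 5) {
    stop("too few points (", nrow(points), " < 5) to fit a density for ", label)
  }
  h <- if (bandwidth_rule == "fixed") {
    stopifnot(length(fixed_h) == 2, all(fixed_h > 0))
    as.numeric(fixed_h)
  } else {
    kde_bandwidth(points)
  }
  structure(list(train = points, h = h), class = "pair_density")
}

kde_bandwidth <- function(points) {
  m <- nrow(points)
  s <- apply(points, 2, stats::sd)
  s[s < 1e-8] <- 1e-3 * m^(1 / 6)   # fallback for degenerate dimensions
  s * m^(-1 / 6)
}

#' Evaluate a fitted pair density, floored away from zero
#'
#' @param model a `pair_density`.
#' @param query matrix of evaluation points (two columns).
#' @param floor lower bound applied to the estimate (default 1e-10);
#'   keeps log density ratios finite at the edge of the support.
#' @return numeric vector of floored density values.
#' @export
evaluate_density <- function(model, query, floor = 1e-10) {
  query <- as.matrix(query)
  stopifnot(ncol(query) == 2)
  h <- model$h
  k1 <- stats::dnorm(outer(query[, 1], model$train[, 1], "-") / h[1]) / h[1]
  k2 <- stats::dnorm(outer(query[, 2], model$train[, 2], "-") / h[2]) / h[2]
  pmax(rowMeans(k1 * k2), floor)
}

# All class-conditional pair densities of a training half, stored
# compactly: per-component training columns + per-component bandwidths.
# Pair (i, j) densities are evaluated from per-component kernel matrices,
# which are shared across the p(p-1)/2 pairs.
fit_pair_density_model <- function(x, y, bandwidth_rule = "scott",
                                   fixed_h = NULL) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% 0:1))
  if (length(unique(y)) < 2 || min(table(y)) < 5) {
    stop("fewer than 5 training points in a class")
  }
  pairs <- utils::combn(ncol(x), 2)
  comp_h <- function(xt) {
    m <- nrow(xt)
    if (!is.null(fixed_h)) return(rep_len(fixed_h, ncol(xt)))
    s <- apply(xt, 2, stats::sd)
    s[s < 1e-8] <- 1e-3 * m^(1 / 6)
    s * m^(-1 / 6)
  }
  x0 <- x[y == 0, , drop = FALSE]
  x1 <- x[y == 1, , drop = FALSE]
  structure(list(train0 = x0, train1 = x1,
                 h0 = comp_h(x0), h1 = comp_h(x1),
                 pairs = pairs, component_ids = colnames(x)),
            class = "pair_density_model")
}

#' Log density-ratio features for all component pairs
#'
#' For each pair (i, j), in lexicographic order, the feature is
#' `log f1_ij(x_i, x_j) - log f0_ij(x_i, x_j)` under the class-conditional
#' product-kernel densities of the supplied model, with both densities
#' floored (so a point far outside both supports yields 0).
#'
#' @param model a `pair_density_model` (internal to [jdinac_fit()], but
#'   exposed for inspection via `fit_pair_density_model`).
#' @param x evaluation matrix, same components (columns) as the model's
#'   training data.
#' @param floor density floor before taking logs, default 1e-10.
#' @return n x n_pairs matrix; columns named "comp_i|comp_j".
#' @export
density_ratio_features <- function(model, x, floor = 1e-10) {
  stopifnot(inherits(model, "pair_density_model"))
  x <- as.matrix(x)
  if (!is.null(model$component_ids) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$component_ids)) {
    stop("component mismatch between evaluation matrix and density model")
  }
  if (ncol(x) != ncol(model$train0)) {
    stop("evaluation matrix has wrong number of components")
  }
  lf1 <- pair_log_density(model$train1, model$h1, model$pairs, x, floor)
  lf0 <- pair_log_density(model$train0, model$h0, model$pairs, x, floor)
  out <- lf1 - lf0
  colnames(out) <- paste(model$component_ids[model$pairs[1, ]],
                         model$component_ids[model$pairs[2, ]], sep = "|")
  out
}

pair_log_density <- function(train, h, pairs, x, floor) {
  p <- ncol(train)
  n <- nrow(x)
  K <- vector("list", p)
  for (k in seq_len(p)) {
    K[[k]] <- stats::dnorm(outer(x[, k], train[, k], "-") / h[k]) / h[k]
  }
  out <- matrix(0, n, ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    out[, q] <- log(pmax(rowMeans(K[[pairs[1, q]]] * K[[pairs[2, q]]]), floor))
  }
  out
}
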