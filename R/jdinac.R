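#' JDINAC: differential interaction network classification
#'
#' Joint density-based nonparametric differential interaction network
#' analysis and classification. The model is a logistic regression of the
#' outcome on per-pair log ratios of class-conditional bivariate kernel
#' densities,
#' `logit(P) = a0 + sum_{i<j} b_ij * log(f1_ij(G_i, G_j) / f0_ij(G_i, G_j))`,
#' with an L1 constraint on the coefficients. Estimation uses multiple
#' splitting with prediction averaging: each of `T` repetitions draws a
#' stratified half-split, estimates the pair densities on one half, fits
#' a class-weighted L1-penalised logistic regression on density-ratio
#' features of the other half (penalty chosen by inner cross-validated
#' deviance, largest-lambda-within-1-SE), records which coefficients are
#' nonzero, predicts the held-out (density) half, then swaps the halves.
#' A pair's differential weight is the number of the `2T` fitted models
#' in which its coefficient was nonzero; per-participant probabilities
#' are averaged over the fits in which the participant was not in the
#' regression half.
#'
#' @param x numeric matrix (participants x components) of
#'   log1-transformed ISU values (apply [log1_transform()] first; values
#'   are used as-is).
#' @param y binary outcome vector (0/1), both classes present.
#' @param T number of split-swap repetitions (2T fitted models), default
#'   25 so that the total model count matches a 50-repetition protocol.
#' @param bandwidth_rule KDE bandwidth rule per class per dimension,
#'   computed on the density-training half only: "scott" (default),
#'   "silverman" or "fixed".
#' @param fixed_h bandwidth when `bandwidth_rule = "fixed"`.
#' @param penalty "1se" (default) or "min" rule on the inner
#'   cross-validated deviance path.
#' @param nfolds_inner inner CV folds for penalty selection, default 5.
#' @param class_weights if `TRUE` (default) observations are weighted by
#'   inverse class frequency, normalised to mean 1.
#' @param floor density floor before logs, default 1e-10.
#' @param seed master seed; per-repetition sub-streams are derived from
#'   it deterministically.
#' @return object of class `jdinac_fit`: `differential_weight` (named,
#'   per pair), `n_models` (= 2T), `prob` (averaged out-of-half
#'   probabilities per participant), `fits` (per-model intercept, sparse
#'   coefficients, lambda, split indices), plus the training data needed
#'   by [predict.jdinac_fit()].
#' @export
jdinac_fit <- function(x, y, T = 25, bandwidth_rule = "scott", fixed_h = NULL,
                       penalty = c("1se", "min"), nfolds_inner = 5,
                       class_weights = TRUE, floor = 1e-10, seed = 1L) {
  penalty <- match.arg(penalty)
  x <- as.matrix(x)
  y <- as.integer(y)
  T <- as.integer(T)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1), ncol(x) >= 2)
  if (length(unique(y)) < 2 || min(table(y)) < 10) {
    stop("need at least 10 participants per class")
  }
  n <- nrow(x)
  pair_idx <- utils::combn(ncol(x), 2)
  pair_names <- paste(colnames(x)[pair_idx[1, ]], colnames(x)[pair_idx[2, ]],
                      sep = "|")
  npairs <- ncol(pair_idx)

  weight_total <- stats::setNames(numeric(npairs), pair_names)
  beta_sum <- stats::setNames(numeric(npairs), pair_names)
  prob_sum <- numeric(n)
  prob_cnt <- numeric(n)
  fits <- vector("list", 2L * T)

  for (t in seq_len(T)) {
    set.seed(sub_seed(seed, t))
    halves <- stratified_half_split(y)
    for (s in 1:2) {
      dens_idx <- if (s == 1) halves$a else halves$b
      lr_idx <- if (s == 1) halves$b else halves$a
      model <- fit_pair_density_model(x[dens_idx, , drop = FALSE], y[dens_idx],
                                      bandwidth_rule = bandwidth_rule,
                                      fixed_h = fixed_h)
      f_lr <- density_ratio_features(model, x[lr_idx, , drop = FALSE],
                                     floor = floor)
      w <- if (class_weights) inverse_class_weights(y[lr_idx]) else rep(1, length(lr_idx))
      cvfit <- cv_l1_logistic(f_lr, y[lr_idx], weights = w,
                              nfolds = nfolds_inner, penalty = penalty)
      beta <- cvfit$beta
      nz <- beta != 0
      weight_total[nz] <- weight_total[nz] + 1
      beta_sum <- beta_sum + beta
      f_out <- density_ratio_features(model, x[dens_idx, , drop = FALSE],
                                      floor = floor)
      pr <- stats::plogis(cvfit$a0 + drop(f_out %*% beta))
      prob_sum[dens_idx] <- prob_sum[dens_idx] + pr
      prob_cnt[dens_idx] <- prob_cnt[dens_idx] + 1
      fits[[2L * (t - 1L) + s]] <- list(
        dens_idx = dens_idx, a0 = cvfit$a0,
        beta_nz = beta[nz], lambda = cvfit$lambda
      )
    }
  }

  structure(list(
    differential_weight = weight_total,
    beta_mean_nz = ifelse(weight_total > 0, beta_sum / pmax(weight_total, 1), 0),
    n_models = 2L * T, T = T,
    prob = stats::setNames(ifelse(prob_cnt > 0, prob_sum / pmax(prob_cnt, 1), NA_real_),
                           rownames(x)),
    y = y, x = x, pair_idx = pair_idx, pair_names = pair_names,
    fits = fits, bandwidth_rule = bandwidth_rule, fixed_h = fixed_h,
    floor = floor, penalty = penalty, class_weights = class_weights,
    seed = seed
  ), class = "jdinac_fit")
}

#' @export
print.jdinac_fit <- function(x, ...) {
  cat(sprintf("JDINAC fit: n=%d, %d pairs, %d models (T=%d); %d pairs ever selected\n",
              length(x$y), length(x$differential_weight), x$n_models, x$T,
              sum(x$differential_weight > 0)))
  invisible(x)
}

# deterministic sub-stream seed, kept within 32-bit integer range
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

stratified_half_split <- function(y) {
  a <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    a <- c(a, sample(idx, floor(length(idx) / 2)))
  }
  list(a = sort(a), b = setdiff(seq_along(y), a))
}

inverse_class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab[as.character(y)]))
  w / mean(w)
}

# L1 logistic with penalty chosen by stratified inner CV deviance
cv_l1_logistic <- function(x, y, weights, nfolds = 5, penalty = "1se") {
  foldid <- stratified_folds(y, nfolds)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          weights = weights, foldid = foldid,
                          type.measure = "deviance", standardize = TRUE)
  s <- if (penalty == "1se") cv$lambda.1se else cv$lambda.min
  co <- stats::coef(cv, s = s)
  list(a0 = co[1, 1], beta = co[-1, 1], lambda = s)
}

stratified_folds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}

#' Extract the differential network from a JDINAC fit
#'
#' Pairs whose coefficient was nonzero in at least `min_fraction` of the
#' fitted models form the differential network. Edge direction is the
#' sign of the mean of the nonzero coefficient estimates: positive means
#' the pair's case-density dominance raises asthma risk ("risk"),
#' negative "protective".
#'
#' @param fit a [jdinac_fit()].
#' @param min_fraction inclusion threshold on
#'   `differential_weight / n_models`, default 0.25.
#' @return data.frame of class `differential_network`: `comp_i`, `comp_j`,
#'   `differential_weight`, `inclusion_fraction`, `direction`,
#'   `mean_beta`. May have zero rows.
#' @export
extract_network <- function(fit, min_fraction = 0.25) {
  frac <- fit$differential_weight / fit$n_models
  keep <- which(frac >= min_fraction)
  comp <- do.call(rbind, strsplit(fit$pair_names[keep], "|", fixed = TRUE))
  out <- data.frame(
    comp_i = if (length(keep)) comp[, 1] else character(0),
    comp_j = if (length(keep)) comp[, 2] else character(0),
    differential_weight = as.integer(fit$differential_weight[keep]),
    inclusion_fraction = unname(frac[keep]),
    mean_beta = unname(fit$beta_mean_nz[keep]),
    stringsAsFactors = FALSE
  )
  out$direction <- ifelse(out$mean_beta >= 0, "risk", "protective")
  out <- out[order(-out$inclusion_fraction), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_network", "data.frame")
  out
}

#' Predict case probabilities for new participants
#'
#' Averages over every fitted model: each model's density half rebuilds
#' its pair densities, features of the new data are computed under them,
#' and the model's coefficients give a probability.
#'
#' @param object a [jdinac_fit()].
#' @param newx matrix with the same components (columns, same order and
#'   names) as the training matrix, log1-transformed.
#' @param ... unused.
#' @return named vector of averaged probabilities in `[0, 1]`.
#' @export
predict.jdinac_fit <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (!identical(colnames(newx), colnames(object$x))) {
    stop("component mismatch: new data must have the same components in the same order")
  }
  acc <- numeric(nrow(newx))
  for (f in object$fits) {
    model <- fit_pair_density_model(object$x[f$dens_idx, , drop = FALSE],
                                    object$y[f$dens_idx],
                                    bandwidth_rule = object$bandwidth_rule,
                                    fixed_h = object$fixed_h)
    eta <- rep(f$a0, nrow(newx))
    if (length(f$beta_nz) > 0) {
      cols <- match(names(f$beta_nz), object$pair_names)
      pairs_sub <- object$pair_idx[, cols, drop = FALSE]
      feats <- density_ratio_features_subset(model, pairs_sub, newx, object$floor)
      eta <- eta + drop(feats %*% f$beta_nz)
    }
    acc <- acc + stats::plogis(eta)
  }
  stats::setNames(acc / length(object$fits), rownames(newx))
}

# features for a subset of pairs only (prediction path)
density_ratio_features_subset <- function(model, pairs, x, floor) {
  lf1 <- pair_log_density(model$train1, model$h1, pairs, x, floor)
  lf0 <- pair_log_density(model$train0, model$h0, pairs, x, floor)
  lf1 - lf0
}

#' Write differential-network outputs
#'
#' @param network a `differential_network` from [extract_network()].
#' @param fit the corresponding [jdinac_fit()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_jdinac_outputs <- function(network, fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges_path <- file.path(dir, "differential_edges.tsv")
  utils::write.table(as.data.frame(network)[, c("comp_i", "comp_j",
                       "differential_weight", "inclusion_fraction", "direction")],
                     edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
  prob_path <- file.path(dir, "jdinac_probabilities.csv")
  utils::write.csv(data.frame(participant_id = names(fit$prob),
                              prob_asthma = unname(fit$prob)),
                   prob_path, row.names = FALSE)
  meta_path <- file.path(dir, "jdinac_meta.json")
  jsonlite::write_json(list(T = fit$T, n_models = fit$n_models,
                            bandwidth_rule = fit$bandwidth_rule,
                            penalty = fit$penalty,
                            class_weights = fit$class_weights,
                            seed = fit$seed),
                       meta_path, auto_unbox = TRUE, pretty = TRUE)
  if (nrow(network) > 0) {
    g <- igraph::graph_from_data_frame(network[, c("comp_i", "comp_j")],
                                       directed = FALSE)
    igraph::E(g)$weight <- network$differential_weight
    igraph::E(g)$direction <- network$direction
    igraph::write_graph(g, file.path(dir, "differential_network.graphml"),
                        format = "graphml")
  }
  invisible(dir)
}
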