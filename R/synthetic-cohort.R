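#' Configuration for the synthetic zero-inflated ISU cohort generator
#'
#' The generator draws a Gaussian-copula latent matrix with a shared
#' "atopy" factor plus component blocks, maps it through per-component
#' log-normal marginals truncated at zero (`ISU = max(exp(mu + sigma*z) -
#' shift, 0)`), and optionally masks entries to structural zeros. Class
#' outcomes are attached under one of three signal regimes:
#' \describe{
#'   \item{null}{outcomes Bernoulli(`outcome_prevalence`), independent of
#'     the matrix.}
#'   \item{marginal}{outcomes logistic in the log1 values of
#'     `marginal_components` (intercept solved so the realised prevalence
#'     matches `outcome_prevalence`).}
#'   \item{interaction_only}{cases and controls share identical marginals
#'     but the latent correlation of each planted `differential_pairs` row
#'     differs by class — only dependency structure carries signal.}
#' }
#'
#' @param n_participants,n_components cohort dimensions.
#' @param block_spec list of `list(size =, r =)` giving planted component
#'   blocks (consecutive components, from the first) and their
#'   within-block latent correlation; sizes must sum to <= `n_components`.
#' @param background_r latent correlation shared by all components
#'   (a single atopy-like factor); default 0.
#' @param mu,sigma log-normal location/scale, recycled per component.
#' @param shift subtracted from `exp(mu + sigma z)` before truncation at
#'   zero; with `shift = 1`, `log1p(ISU)` recovers the latent Gaussian on
#'   the positive part.
#' @param zero_inflation per-component probability of an extra structural
#'   zero mask, recycled; default 0 (truncation already yields zeros).
#' @param outcome_prevalence case fraction in (0, 1).
#' @param signal_regime "null", "marginal" or "interaction_only".
#' @param marginal_components,marginal_beta components (indices) and slope
#'   for the marginal regime.
#' @param differential_pairs data.frame with columns `i`, `j`, `r_case`,
#'   `r_control` (latent correlations per class) for the
#'   interaction_only regime.
#' @param loadings optional per-component loading overrides on the shared
#'   factor (correlation scale, i.e. `loadings[k]^2` replaces
#'   `background_r` for component k in off-block entries).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants, n_components,
                          block_spec = list(),
                          background_r = 0,
                          mu = 0.5, sigma = 1, shift = 1,
                          zero_inflation = 0,
                          outcome_prevalence = 0.3,
                          signal_regime = c("null", "marginal", "interaction_only"),
                          marginal_components = integer(),
                          marginal_beta = 1,
                          differential_pairs = NULL,
                          loadings = NULL,
                          seed = 1L) {
  signal_regime <- match.arg(signal_regime)
  sizes <- vapply(block_spec, function(b) as.integer(b$size), integer(1))
  rs <- vapply(block_spec, function(b) as.numeric(b$r), numeric(1))
  if (sum(sizes) > n_components) stop("block sizes sum exceeds n_components")
  if (any(rs <= -1 | rs >= 1)) stop("block correlations must lie in (-1, 1)")
  if (outcome_prevalence <= 0 || outcome_prevalence >= 1) {
    stop("outcome_prevalence must lie in (0, 1)")
  }
  if (!is.null(differential_pairs)) {
    differential_pairs <- as.data.frame(differential_pairs)
    stopifnot(all(c("i", "j", "r_case", "r_control") %in% names(differential_pairs)))
    if (any(abs(c(differential_pairs$r_case, differential_pairs$r_control)) >= 1)) {
      stop("differential pair correlations must lie in (-1, 1)")
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_components = as.integer(n_components),
    block_spec = block_spec,
    background_r = background_r,
    mu = rep_len(mu, n_components),
    sigma = rep_len(sigma, n_components),
    shift = shift,
    zero_inflation = rep_len(zero_inflation, n_components),
    outcome_prevalence = outcome_prevalence,
    signal_regime = signal_regime,
    marginal_components = marginal_components,
    marginal_beta = marginal_beta,
    differential_pairs = differential_pairs,
    loadings = loadings,
    component_ids = paste0("sIgE_", sprintf("%03d", seq_len(n_components))),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

latent_correlation <- function(cfg) {
  p <- cfg$n_components
  load <- rep(sqrt(max(cfg$background_r, 0)), p)
  if (!is.null(cfg$loadings)) load <- cfg$loadings
  R <- outer(load, load)
  sizes <- vapply(cfg$block_spec, function(b) as.integer(b$size), integer(1))
  start <- cumsum(c(1L, sizes))[seq_along(sizes)]
  blocklab <- integer(p)
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b] + sizes[b] - 1L)
    R[idx, idx] <- cfg$block_spec[[b]]$r
    blocklab[idx] <- b
  }
  diag(R) <- 1
  list(R = R, block_labels = blocklab)
}

check_psd <- function(R, label) {
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop("infeasible (non-PSD) latent correlation matrix for ", label,
         " (min eigenvalue ", signif(ev, 3), ")")
  }
  invisible(ev)
}

draw_latent <- function(n, R) {
  # chol with a tiny jitter only to absorb numerically-zero eigenvalues;
  # genuine infeasibility has already been rejected by check_psd()
  ch <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-8, nrow(R))))
  matrix(stats::rnorm(n * nrow(R)), n, nrow(R)) %*% ch
}

#' Generate a synthetic CRD cohort
#'
#' @param cfg a [cohort_config()].
#' @return list with `crd` ([crd_matrix()]), `outcomes` (data.frame with
#'   `participant_id`, `asthma`), and `truth` (planted block labels,
#'   differential pairs, and — for the marginal regime — the causal
#'   components).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_participants
  p <- cfg$n_components
  lat <- latent_correlation(cfg)
  R <- lat$R

  if (cfg$signal_regime == "interaction_only" &&
      !is.null(cfg$differential_pairs) && nrow(cfg$differential_pairs) > 0) {
    R1 <- R; R0 <- R
    for (k in seq_len(nrow(cfg$differential_pairs))) {
      dp <- cfg$differential_pairs[k, ]
      R1[dp$i, dp$j] <- R1[dp$j, dp$i] <- dp$r_case
      R0[dp$i, dp$j] <- R0[dp$j, dp$i] <- dp$r_control
    }
    check_psd(R1, "case class (differential pairs)")
    check_psd(R0, "control class (differential pairs)")
    y <- stats::rbinom(n, 1L, cfg$outcome_prevalence)
    Z <- matrix(0, n, p)
    if (any(y == 1L)) Z[y == 1L, ] <- draw_latent(sum(y == 1L), R1)
    if (any(y == 0L)) Z[y == 0L, ] <- draw_latent(sum(y == 0L), R0)
  } else {
    check_psd(R, "latent block structure")
    Z <- draw_latent(n, R)
    y <- NULL
  }

  X <- pmax(exp(sweep(sweep(Z, 2, cfg$sigma, "*"), 2, cfg$mu, "+")) - cfg$shift, 0)
  zi <- cfg$zero_inflation
  if (any(zi > 0)) {
    mask <- matrix(stats::rbinom(n * p, 1L, rep(zi, each = n)), n, p)
    X[mask == 1L] <- 0
  }

  if (is.null(y)) {
    if (cfg$signal_regime == "marginal" && length(cfg$marginal_components) > 0) {
      lp <- log1p(X[, cfg$marginal_components, drop = FALSE]) %*%
        rep_len(cfg$marginal_beta, length(cfg$marginal_components))
      b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) - cfg$outcome_prevalence,
                           c(-30, 30))$root
      y <- stats::rbinom(n, 1L, stats::plogis(b0 + lp))
    } else {
      y <- stats::rbinom(n, 1L, cfg$outcome_prevalence)
    }
  }

  ids <- paste0("P", sprintf("%04d", seq_len(n)))
  crd <- crd_matrix(X, participant_ids = ids, component_ids = cfg$component_ids)
  truth <- list(
    component_blocks = ifelse(lat$block_labels == 0L, NA_integer_, lat$block_labels),
    differential_pairs = cfg$differential_pairs,
    marginal_components = cfg$marginal_components
  )
  list(crd = crd,
       outcomes = data.frame(participant_id = ids, asthma = y,
                             stringsAsFactors = FALSE),
       truth = truth)
}

#' Canned configuration emulating the study cohort's shape
#'
#' 112 components: seven blocks of sizes (4, 3, 4, 6, 8, 4, 4) named after
#' house-dust-mite, peanut, lipocalin, grass, PR-10, tree and profilin
#' allergen families, 11 active singleton components, and 68 rare
#' components below the activity threshold; n = 461 participants; a shared
#' atopy factor (latent r = 0.76) with within-block latent r = 0.90.
#' Positivity rates are set so that ~44 components exceed the 5%
#' activity rule and ~46% of participants are sensitised to at least one
#' active component; outcome prevalence 0.34 so that asthma prevalence
#' among sensitised participants matches the study (~34%).
#'
#' When `plant_differential = TRUE` (default) three differential pairs are
#' planted among the higher-prevalence active singletons: those six
#' components get a slightly reduced atopy loading (latent r 0.60) so the
#' class-conditional pair correlations (0.95 in cases, 0.20 in controls)
#' stay feasible, and the outcome regime is interaction_only. The loading
#' reduction is deliberately mild: sensitised participants are selected on
#' having at least one positive component, which truncates the shared
#' atopy factor, and components too detached from that factor would shift
#' the selected subset's correlation structure.
#'
#' @param seed integer seed.
#' @param plant_differential plant the three differential singleton pairs.
#' @return a [cohort_config()].
#' @export
emulate_paper_shape <- function(seed = 1L, plant_differential = TRUE) {
  bl <- c(4L, 3L, 4L, 6L, 8L, 4L, 4L)
  block_r <- 0.90
  r0 <- 0.74
  sig <- 1.5
  q_block <- rep(c(0.157, 0.078, 0.088, 0.167, 0.118, 0.078, 0.069), bl)
  q_single <- seq(0.069, 0.108, length.out = 11)
  q_rare <- rep(0.015, 68)
  q <- c(q_block, q_single, q_rare)
  p <- length(q)
  # positivity P(ISU > 0.30) = q  =>  mu = log(1.3) - sigma * qnorm(1 - q)
  mu <- log(1.3) - sig * stats::qnorm(1 - q)
  names_block <- c("Der p 1", "Der p 2", "Der f 1", "Der f 2",
                   "Ara h 1", "Ara h 2", "Ara h 6",
                   "Fel d 4", "Equ c 1", "Can f 1", "Mus m 1",
                   "Phl p 1", "Phl p 2", "Phl p 4", "Phl p 5", "Phl p 6", "Cyn d 1",
                   "Gly m 4", "Mal d 1", "Aln g 1", "Bet v 1", "Pru p 1",
                   "Cor a 1.04", "Ara h 8", "Cor a 1.01",
                   "Cup a 1", "Jug r 2", "Pla a 2", "Cry j 1",
                   "Mer a 1", "Bet v 2", "Hev b 8", "Phl p 12")
  names_single <- c("Der p 10", "Lep d 2", "Fel d 1", "Blo t 5", "Gal d 3",
                    "Phl p 11", "Mux f 3", "Che a 1", "Ole e 1", "Can f 5",
                    "Alt a 1")
  comp_ids <- c(names_block, names_single,
                paste0("rare_", sprintf("%02d", seq_len(68))))

  loadings <- rep(sqrt(r0), p)
  diff_pairs <- NULL
  regime <- "null"
  if (plant_differential) {
    single_idx <- sum(bl) + seq_len(11)         # components 34..44
    planted <- single_idx[c(11, 10, 9, 8, 7, 6)] # highest-prevalence singletons
    loadings[planted] <- sqrt(0.60)
    q[planted] <- 0.15
    mu <- log(1.3) - sig * stats::qnorm(1 - q)
    diff_pairs <- data.frame(
      i = planted[c(1, 3, 5)], j = planted[c(2, 4, 6)],
      r_case = 0.95, r_control = 0.20
    )
    regime <- "interaction_only"
  }
  cfg <- cohort_config(
    n_participants = 461L, n_components = p,
    block_spec = lapply(bl, function(s) list(size = s, r = block_r)),
    background_r = r0, mu = mu, sigma = sig, shift = 1,
    zero_inflation = 0, outcome_prevalence = 0.34,
    signal_regime = regime, differential_pairs = diff_pairs,
    loadings = loadings, seed = seed
  )
  cfg$component_ids <- comp_ids
  if (!is.null(cfg$differential_pairs)) {
    cfg$differential_pairs$comp_i <- comp_ids[cfg$differential_pairs$i]
    cfg$differential_pairs$comp_j <- comp_ids[cfg$differential_pairs$j]
  }
  cfg
}

#' Truth labels for component clustering on a generated cohort
#'
#' Maps planted block labels onto a component subset, giving every
#' non-block component its own singleton label so the result can be
#' compared to a flat clustering with [rand_index()].
#'
#' @param truth `truth` element from [generate_cohort()].
#' @param components character vector of component ids (in the cohort's
#'   naming), or indices.
#' @param component_ids full component id vector of the cohort.
#' @return integer labels, one per requested component.
#' @export
truth_component_labels <- function(truth, components, component_ids) {
  idx <- if (is.character(components)) match(components, component_ids) else components
  lab <- truth$component_blocks[idx]
  nb <- is.na(lab)
  lab[nb] <- max(0L, lab[!nb], 0L) + seq_len(sum(nb)) + 1000L
  as.integer(lab)
}

#' Generate binary sensitisation profiles from four archetypes
#'
#' Emulates the participant-level structure used for sensitisation
#' clustering: multiple sensitisation (positive across all component
#' groups), a dust-mite-like archetype, a grass/tree-like archetype, and
#' lower-grade sensitisation (few scattered positives), with independent
#' bit-flip noise. All-zero profiles are redrawn (the analysis only ever
#' clusters sensitised participants).
#'
#' @param n number of participants.
#' @param flip bit-flip noise probability per entry, default 0.05.
#' @param weights archetype mixing proportions.
#' @param seed integer seed.
#' @return list with `profile` (binary matrix), `archetype` (true labels
#'   1..4).
#' @export
generate_archetype_profiles <- function(n = 300, flip = 0.05,
                                        weights = c(0.25, 0.3, 0.25, 0.2),
                                        seed = 1L) {
  set.seed(seed)
  p <- 20L
  arch <- rbind(
    multiple   = as.integer(seq_len(p) <= 16),
    hdm        = as.integer(seq_len(p) %in% 1:5),
    grass_tree = as.integer(seq_len(p) %in% 6:12),
    low_grade  = as.integer(seq_len(p) %in% 13:14)
  )
  lab <- sample.int(4L, n, replace = TRUE, prob = weights / sum(weights))
  prof <- matrix(0L, n, p,
                 dimnames = list(paste0("P", sprintf("%03d", seq_len(n))),
                                 paste0("c", sprintf("%02d", seq_len(p)))))
  for (i in seq_len(n)) {
    repeat {
      row <- arch[lab[i], ]
      flips <- stats::rbinom(p, 1L, flip)
      row <- as.integer(xor(row, flips))
      if (sum(row) > 0L) break
    }
    prof[i, ] <- row
  }
  class(prof) <- c("binary_profile", "matrix", "array")
  list(profile = prof, archetype = lab)
}
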