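#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with its study default: 0.30 ISU
#' positivity, 5% activity prevalence, 0.40 dissimilarity cut, 25% network
#' inclusion fraction, 10-fold / 50-repetition CV for the baseline, and
#' T = 25 JDINAC split-swap repetitions (50 fitted models).
#'
#' @param seed mandatory integer seed for every stochastic stage.
#' @param isu_threshold positivity threshold (ISU), default 0.30.
#' @param min_prevalence active-component rule, default 0.05.
#' @param cut_height component-cluster cut on 1 - dCor, default 0.40.
#' @param network_min_fraction differential-network inclusion fraction,
#'   default 0.25.
#' @param cv_folds,cv_repetitions baseline CV protocol, defaults 10 / 50.
#' @param jdinac_T JDINAC repetitions, default 25.
#' @param k_range candidate subject-cluster counts, default 2:8.
#' @param edge_min_dcor display threshold for connectivity-graph edges.
#' @param dcor_log1 compute dCor on log1 values (default TRUE; FALSE uses
#'   raw ISU).
#' @param na_to_zero map missing input cells to 0 on read.
#' @param or_reference odds-ratio reference group ("rest" or a cluster).
#' @param bandwidth_rule,penalty passed to [jdinac_fit()] and
#'   [penalised_lr_fit()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            isu_threshold = 0.30,
                            min_prevalence = 0.05,
                            cut_height = 0.40,
                            network_min_fraction = 0.25,
                            cv_folds = 10,
                            cv_repetitions = 50,
                            jdinac_T = 25,
                            k_range = 2:8,
                            edge_min_dcor = 0.3,
                            dcor_log1 = TRUE,
                            na_to_zero = FALSE,
                            or_reference = "rest",
                            bandwidth_rule = "scott",
                            penalty = "1se") {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(isu_threshold > 0, min_prevalence > 0, min_prevalence < 1,
            cut_height >= 0, cut_height <= 1,
            network_min_fraction > 0, cv_folds >= 2, jdinac_T >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: dichotomise and filter -> component dissimilarity, clustering
#' (average linkage plus DIANA/PAM comparators and Rand agreement) and
#' connectivity graph -> subject clustering (Jaccard/Ward,
#' Calinski-Harabasz) with outcome associations -> JDINAC versus
#' penalised logistic regression -> differential network and bipartite
#' views. Every stage writes its outputs under `outdir`; a manifest with
#' MD5 checksums and a summary JSON (deterministic given the seed;
#' timings live only in the manifest) complete the run.
#'
#' @param crd a [crd_matrix()] of raw ISU values.
#' @param outcomes data.frame with `participant_id` and `asthma` (plus
#'   optional binary/continuous outcome columns).
#' @param config a [pipeline_config()].
#' @param outdir run directory (created).
#' @return invisibly, a list with the key stage objects (`filter`,
#'   `component_clustering`, `subject_k`, `jdinac`, `lr_report`,
#'   `jdinac_report`, `network`, `summary`).
#' @export
run_pipeline <- function(crd, outcomes, config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", outdir, ")", call. = FALSE)
    })
    timings[[name]] <<- round(tic() - t0, 3)
    res
  }

  flt <- stage("filter", {
    b <- dichotomise(crd, threshold = config$isu_threshold)
    f <- filter_active(b, m = crd, min_prevalence = config$min_prevalence)
    write_crd(f$crd, file.path(outdir, "filtered_isu.csv"))
    write_filter_report(f, file.path(outdir, "filter_report.json"))
    f
  })
  xlog <- log1_transform(flt$crd)

  comp <- stage("component_clusters", {
    d <- dissimilarity_matrix(flt$crd, log1 = config$dcor_log1)
    cl <- agglomerative_cluster(d, cut_height = config$cut_height)
    rd <- rp <- NA_real_
    if (cl$k >= 2 && cl$k <= nrow(d) - 1) {
      rd <- rand_index(cl$labels, divisive_cluster(d, cl$k))
      rp <- rand_index(cl$labels, pam_cluster(d, cl$k))
    }
    g <- build_connectivity_graph(d, cl, edge_min_dcor = config$edge_min_dcor)
    write_component_outputs(cl, g, file.path(outdir, "components"))
    utils::write.csv(as.data.frame(unclass(d)),
                     file.path(outdir, "components", "dissimilarity.csv"))
    list(d = d, clustering = cl, rand_diana = rd, rand_pam = rp, graph = g)
  })

  subj <- stage("subject_clusters", {
    dj <- jaccard_matrix(flt$profile)
    wc <- ward_cluster(dj, k_range = config$k_range)
    sel <- select_k_calinski_harabasz(flt$profile, wc)
    assoc <- associate_outcomes(sel$labels, outcomes,
                                or_reference = config$or_reference)
    dir.create(file.path(outdir, "subjects"), showWarnings = FALSE)
    utils::write.csv(data.frame(participant_id = names(sel$labels),
                                cluster_id = unname(sel$labels)),
                     file.path(outdir, "subjects", "subject_clusters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(association_report_json(assoc),
                         file.path(outdir, "subjects", "associations.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(selection = sel, assoc = assoc)
  })

  y <- outcomes$asthma[match(rownames(xlog), outcomes$participant_id)]
  if (anyNA(y)) stop("retained participants missing asthma outcome")

  fit <- stage("jdinac", {
    jdinac_fit(unclass(xlog), y, T = config$jdinac_T,
               bandwidth_rule = config$bandwidth_rule,
               penalty = config$penalty, seed = config$seed)
  })
  jd_report <- performance_report(fit$prob, y,
                                  protocol = list(model = "jdinac",
                                                  folds = NA, repetitions = fit$T,
                                                  seed = config$seed,
                                                  mode = "split-swap averaged out-of-half"))

  lr_report <- stage("penalised_lr", {
    repeated_cv_evaluate(penalised_lr_spec(penalty = config$penalty),
                         unclass(xlog), y,
                         folds = config$cv_folds,
                         repetitions = config$cv_repetitions,
                         seed = config$seed)
  })

  net <- stage("network", {
    nw <- extract_network(fit, min_fraction = config$network_min_fraction)
    write_jdinac_outputs(nw, fit, file.path(outdir, "jdinac"))
    nw
  })

  stage("bipartite", {
    bg <- build_bipartite(flt$profile, subj$selection$labels,
                          comp$clustering$labels, outcomes)
    write_bipartite_outputs(bg, file.path(outdir, "bipartite"))
    bg
  })

  dir.create(file.path(outdir, "objects"), showWarnings = FALSE)
  saveRDS(fit, file.path(outdir, "objects", "jdinac_fit.rds"))

  summary <- list(
    n_before = flt$report$n_before, n_after = flt$report$n_after,
    p_before = flt$report$p_before, p_after = flt$report$p_after,
    n_component_clusters = comp$clustering$k,
    n_component_singletons = sum(table(comp$clustering$labels) == 1L),
    active_components = flt$active_components,
    rand_diana = comp$rand_diana, rand_pam = comp$rand_pam,
    subject_k = subj$selection$k,
    jdinac_auc = jd_report$auc, lr_auc = lr_report$auc,
    jdinac_sensitivity = jd_report$sensitivity,
    jdinac_specificity = jd_report$specificity,
    n_differential_edges = nrow(net),
    differential_edges = if (nrow(net)) paste(net$comp_i, net$comp_j, sep = "|") else character(0),
    config = config[setdiff(names(config), "k_range")],
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(outdir, timings)

  invisible(list(filter = flt, component = comp, subject = subj,
                 jdinac = fit, jdinac_report = jd_report,
                 lr_report = lr_report, network = net, summary = summary,
                 outdir = outdir))
}

association_report_json <- function(assoc) {
  list(
    binary = lapply(assoc$binary, function(b) {
      list(table = as.data.frame.matrix(b$table), chisq = b$chisq,
           odds_ratios = b$odds_ratios)
    }),
    continuous = assoc$continuous
  )
}

write_manifest <- function(outdir, timings) {
  files <- setdiff(list.files(outdir, recursive = TRUE),
                   c("manifest.json"))
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(
    files = data.frame(path = files, md5 = unname(sums),
                       stringsAsFactors = FALSE),
    stage_timings_s = timings,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Verify a run directory against its manifest
#'
#' @param outdir run directory with `manifest.json`.
#' @return TRUE if every checksum matches; otherwise an error naming the
#'   first mismatch.
#' @export
verify_manifest <- function(outdir) {
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                             simplifyVector = TRUE)
  cur <- tools::md5sum(file.path(outdir, man$files$path))
  bad <- which(unname(cur) != man$files$md5)
  if (length(bad)) stop("checksum mismatch: ", man$files$path[bad[1]])
  TRUE
}

#' Validate the frozen pipeline on a second dataset
#'
#' Re-runs filtering and fitting from scratch on the new data (the
#' validation set keeps its own active-component set, as an external
#' narrow validation requires), then compares the resulting differential
#' edge list with the frozen run's by Jaccard overlap of edges. A
#' separate "apply" mode instead scores the new data with the frozen
#' JDINAC model for prospective use.
#'
#' @param frozen_dir run directory of the frozen (training) analysis.
#' @param crd,outcomes the validation dataset.
#' @param config a [pipeline_config()] for the re-run.
#' @param outdir output directory for the validation run.
#' @param mode "refit" (default) or "apply".
#' @return list: for "refit", the validation `run` plus `edge_jaccard`
#'   and both edge lists; for "apply", a `performance_report`.
#' @export
validate_pipeline <- function(frozen_dir, crd, outcomes, config, outdir,
                              mode = c("refit", "apply")) {
  mode <- match.arg(mode)
  frozen_edges <- utils::read.table(
    file.path(frozen_dir, "jdinac", "differential_edges.tsv"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  frozen_summary <- jsonlite::read_json(file.path(frozen_dir, "summary.json"),
                                        simplifyVector = TRUE)
  if (mode == "apply") {
    fit <- readRDS(file.path(frozen_dir, "objects", "jdinac_fit.rds"))
    common <- intersect(colnames(fit$x), colnames(crd))
    if (length(common) == 0) stop("no components in common with the frozen model")
    if (!identical(sort(common), sort(colnames(fit$x)))) {
      stop("frozen model components missing from validation data: ",
           paste(setdiff(colnames(fit$x), common), collapse = ", "))
    }
    xv <- log1p(unclass(crd)[, colnames(fit$x), drop = FALSE])
    prob <- predict(fit, xv)
    y <- outcomes$asthma[match(rownames(xv), outcomes$participant_id)]
    return(performance_report(prob, y,
                              protocol = list(model = "jdinac-frozen",
                                              folds = NA, repetitions = fit$T,
                                              seed = config$seed,
                                              mode = "apply frozen model")))
  }
  common <- intersect(colnames(crd), unlist(frozen_summary$active_components))
  if (length(common) == 0) {
    stop("no components in common between validation data and the frozen active set")
  }
  message("validate: ", length(common), " components shared with the frozen active set")
  run <- run_pipeline(crd, outcomes, config, outdir)
  new_edges <- run$network
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  k1 <- if (nrow(frozen_edges)) key(frozen_edges$comp_i, frozen_edges$comp_j) else character(0)
  k2 <- if (nrow(new_edges)) key(new_edges$comp_i, new_edges$comp_j) else character(0)
  un <- union(k1, k2)
  jac <- if (length(un) == 0) NA_real_ else length(intersect(k1, k2)) / length(un)
  list(run = run, edge_jaccard = jac,
       frozen_edges = k1, validation_edges = k2)
}
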