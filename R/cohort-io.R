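#' Construct a CRD matrix of component-specific IgE values
#'
#' A CRD (component-resolved diagnostics) matrix holds continuous
#' specific-IgE measurements in ISAC Standardised Units (ISU): rows are
#' participants, columns are allergen components (e.g. "Der p 1").
#' Values must be non-negative and complete; identifiers must be unique.
#'
#' @param values numeric matrix, participants x components, entries >= 0.
#' @param participant_ids character vector of unique participant ids
#'   (defaults to existing rownames).
#' @param component_ids character vector of unique component names
#'   (defaults to existing colnames).
#' @return a numeric matrix of class `crd_matrix` with row/column names set.
#' @export
crd_matrix <- function(values, participant_ids = rownames(values),
                       component_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(participant_ids)) {
    participant_ids <- paste0("P", seq_len(nrow(values)))
  }
  if (is.null(component_ids)) {
    component_ids <- paste0("C", seq_len(ncol(values)))
  }
  participant_ids <- as.character(participant_ids)
  component_ids <- as.character(component_ids)
  if (length(participant_ids) != nrow(values)) {
    stop("participant_ids length does not match number of rows")
  }
  if (length(component_ids) != ncol(values)) {
    stop("component_ids length does not match number of columns")
  }
  if (anyDuplicated(participant_ids)) stop("duplicate participant ids")
  if (anyDuplicated(component_ids)) stop("duplicate component ids")
  if (anyNA(values)) stop("missing values in CRD matrix; see `na_to_zero` in read_crd()")
  if (any(values < 0)) stop("negative ISU values are not allowed")
  dimnames(values) <- list(participant_ids, component_ids)
  class(values) <- c("crd_matrix", "matrix", "array")
  values
}

#' @export
print.crd_matrix <- function(x, ...) {
  cat(sprintf("CRD matrix: %d participants x %d components (ISU)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Read a CRD matrix from delimited text
#'
#' The first column holds participant identifiers; the header row holds
#' component names. The delimiter (comma or tab) is sniffed from the
#' header line.
#'
#' @param path file path.
#' @param na_to_zero if `TRUE`, missing cells are mapped to 0 (ISAC
#'   reports below-detection as 0) and a message is emitted; if `FALSE`
#'   (default) missing cells are an error. Silent imputation hides data
#'   problems, so the flag is explicit.
#' @param sep field delimiter; `NULL` (default) sniffs "," vs tab from the
#'   header line.
#' @return a [crd_matrix()].
#' @export
read_crd <- function(path, na_to_zero = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0L) stop("no participants in ", path)
  if (ncol(df) < 2L) stop("no components in ", path)
  ids <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  bad <- which(is.na(num) & !is.na(body) & body != "" &
                 toupper(body) != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at row %d (participant '%s'), column '%s': '%s'",
                 bad[1, 1], ids[bad[1, 1]], colnames(body)[bad[1, 2]],
                 body[bad[1, 1], bad[1, 2]]))
  }
  if (anyNA(num)) {
    if (na_to_zero) {
      message(sum(is.na(num)), " missing cells mapped to 0 ISU")
      num[is.na(num)] <- 0
    } else {
      stop("missing cells in ", path, "; set na_to_zero = TRUE to map them to 0")
    }
  }
  m <- crd_matrix(num, participant_ids = ids,
                  component_ids = colnames(body))
  message(sprintf("read_crd: n=%d participants, p=%d components", nrow(m), ncol(m)))
  m
}

#' Write a CRD matrix (or binary profile) as CSV
#'
#' Round-trips through [read_crd()] at full double precision.
#'
#' @param m matrix with participant rownames and component colnames.
#' @param path output path.
#' @export
write_crd <- function(m, path) {
  df <- data.frame(participant_id = rownames(m), as.data.frame(unclass(m),
                   check.names = FALSE), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a participant outcomes table
#'
#' Expects a participant-id first column and binary outcome columns
#' (asthma, optionally wheeze/rhinitis/AD) coded 0/1; any additional
#' numeric columns are treated as continuous (e.g. lung function).
#'
#' @param path file path; delimiter sniffed as in [read_crd()].
#' @param binary_cols columns validated as binary; only those present are
#'   checked.
#' @return data.frame with `participant_id` plus outcome columns.
#' @export
read_outcomes <- function(path,
                          binary_cols = c("asthma", "wheeze", "rhinitis", "AD")) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, quote = "\"")
  names(df)[1L] <- "participant_id"
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id)) stop("duplicate participant ids in outcomes")
  for (cl in intersect(binary_cols, names(df))) {
    v <- df[[cl]]
    if (!all(v %in% c(0, 1, NA))) stop("outcome column '", cl, "' is not binary 0/1")
  }
  df
}

#' Dichotomise ISU values into a binary sensitisation profile
#'
#' Positivity is *strictly* greater than the threshold: the manufacturer
#' cut-off 0.30 ISU itself is negative.
#'
#' @param m a [crd_matrix()].
#' @param threshold positivity cut-off in ISU, default 0.30.
#' @return integer 0/1 matrix of class `binary_profile`, same axes as `m`.
#' @export
dichotomise <- function(m, threshold = 0.30) {
  stopifnot(threshold > 0)
  b <- (unclass(m) > threshold) * 1L
  dimnames(b) <- dimnames(m)
  class(b) <- c("binary_profile", "matrix", "array")
  b
}

#' Filter to active components and sensitised participants
#'
#' A component is *active* when positive (ISU above threshold) in at least
#' `min_prevalence` of the participants supplied (inclusive, denominator =
#' pre-filter participant count). Participants are retained when positive
#' to at least one active component. Axis order is preserved.
#'
#' @param b a `binary_profile` from [dichotomise()].
#' @param m optional paired [crd_matrix()] filtered to the same axes.
#' @param min_prevalence minimum positive fraction, default 0.05.
#' @return list with `active_components`, `retained_participants`,
#'   filtered `profile` (and `crd` when `m` given), and `report`
#'   (n/p before and after, dropped components).
#' @export
filter_active <- function(b, m = NULL, min_prevalence = 0.05) {
  stopifnot(nrow(b) >= 1L)
  prev <- colMeans(unclass(b))
  keep_c <- prev >= min_prevalence
  if (!any(keep_c)) stop("no active components at min_prevalence = ", min_prevalence)
  bk <- unclass(b)[, keep_c, drop = FALSE]
  keep_p <- rowSums(bk) > 0L
  if (!any(keep_p)) stop("no participants positive to any active component")
  prof <- bk[keep_p, , drop = FALSE]
  class(prof) <- c("binary_profile", "matrix", "array")
  out <- list(
    active_components = colnames(b)[keep_c],
    retained_participants = rownames(b)[keep_p],
    profile = prof,
    report = list(
      n_before = nrow(b), n_after = sum(keep_p),
      p_before = ncol(b), p_after = sum(keep_c),
      dropped_components = colnames(b)[!keep_c]
    )
  )
  if (!is.null(m)) {
    stopifnot(identical(dimnames(m), dimnames(b)))
    out$crd <- crd_matrix(unclass(m)[keep_p, keep_c, drop = FALSE])
  }
  out
}

#' log(x + 1) transform of a CRD matrix
#'
#' The transform applied before distance-correlation, density and
#' regression modelling; invertible via `expm1`.
#'
#' @param m a [crd_matrix()].
#' @return transformed `crd_matrix`.
#' @export
log1_transform <- function(m) {
  if (any(m < 0)) stop("negative values cannot be log1-transformed")
  out <- log1p(unclass(m))
  dimnames(out) <- dimnames(m)
  class(out) <- class(m)
  out
}

#' Write a filter report as JSON
#'
#' @param flt result of [filter_active()].
#' @param path output path.
#' @export
write_filter_report <- function(flt, path) {
  jsonlite::write_json(flt$report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
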