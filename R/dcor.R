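#' Distance correlation between two numeric vectors
#'
#' Szekely's sample distance correlation: pairwise absolute-distance
#' matrices are double-centred (subtract row means and column means, add
#' the grand mean), the squared distance covariance is the mean of the
#' entrywise product, and the correlation normalises by the distance
#' variances. Sensitive to nonlinear dependence; 0 iff independence in
#' the population version. If either vector is constant its distance
#' variance is zero and the statistic is defined as 0 here (0/0 case).
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return dCor value in `[0, 1]`.
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  stopifnot(n >= 2)
  A <- dc_center(x)
  B <- dc_center(y)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  dcov2 <- mean(A * B)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# double-centred absolute-distance matrix of a vector
dc_center <- function(x) {
  d <- abs(outer(x, x, "-"))
  d - rowMeans(d) - rep(colMeans(d), each = length(x)) + mean(d)
}

#' Pairwise distance-correlation dissimilarity of CRD components
#'
#' Entry (i, j) is `1 - dCor(column i, column j)`. By default the matrix
#' is computed on log(x+1)-transformed ISU values (consistent with the
#' modelling stages; heavy right tails otherwise dominate the pairwise
#' distances); set `log1 = FALSE` to use raw values. Constant columns
#' yield dCor 0 (dissimilarity 1) against everything and a warning.
#'
#' All double-centred distance matrices are stacked column-wise so every
#' pairwise distance covariance is one crossproduct — O(p^2 n^2) but BLAS
#' bound, comfortably fast at cohort scale.
#'
#' @param m a [crd_matrix()] with p >= 2 components.
#' @param log1 apply [log1_transform()] first (default TRUE).
#' @return symmetric p x p matrix of class `dissimilarity_matrix` with
#'   zero diagonal and component dimnames.
#' @export
dissimilarity_matrix <- function(m, log1 = TRUE) {
  stopifnot(ncol(m) >= 2)
  x <- unclass(m)
  if (log1) x <- log1p(x)
  n <- nrow(x)
  p <- ncol(x)
  centred <- matrix(0, n * n, p)
  for (k in seq_len(p)) centred[, k] <- dc_center(x[, k])
  V <- crossprod(centred) / (n * n)    # V[i,j] = dCov^2(i, j)
  dv <- diag(V)
  const <- dv <= 0
  if (any(const)) {
    warning("constant component(s): ", paste(colnames(m)[const], collapse = ", "),
            "; dCor with these set to 0")
  }
  denom <- sqrt(outer(dv, dv))
  dcor <- matrix(0, p, p)
  ok <- denom > 0
  dcor[ok] <- sqrt(pmax(V[ok], 0)) / sqrt(denom[ok])
  dcor[dcor > 1] <- 1
  out <- 1 - dcor
  diag(out) <- 0
  out <- (out + t(out)) / 2
  dimnames(out) <- list(colnames(m), colnames(m))
  class(out) <- c("dissimilarity_matrix", "matrix", "array")
  out
}

#' Distance-correlation matrix (similarity form)
#'
#' @param m a [crd_matrix()].
#' @param log1 apply the log1 transform first.
#' @return symmetric p x p dCor matrix with unit diagonal.
#' @export
dcor_matrix <- function(m, log1 = TRUE) {
  d <- unclass(dissimilarity_matrix(m, log1 = log1))
  out <- 1 - d
  dimnames(out) <- dimnames(d)
  out
}
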