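# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, textbook formulas) so they cannot
# share code paths with the package implementation.

# distance correlation via the double-centering definition, element by element
dcor_oracle <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-"))
  b <- abs(outer(y, y, "-"))
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  dvarx <- sum(A * A) / n^2
  dvary <- sum(B * B) / n^2
  if (dvarx <= 0 || dvary <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvarx * dvary))
}

# Rand index by enumerating all object pairs
rand_oracle <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / choose(n, 2)
}

# Pearson chi-squared statistic from first principles
chisq_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# Kruskal-Wallis H with tie correction, textbook formula
kw_oracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(rg) sum(rg)^2 / length(rg))) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# two-point-kernel bivariate KDE evaluated longhand
kde_oracle <- function(train, h, query) {
  vapply(seq_len(nrow(query)), function(i) {
    mean(vapply(seq_len(nrow(train)), function(t) {
      dnorm((query[i, 1] - train[t, 1]) / h[1]) / h[1] *
        dnorm((query[i, 2] - train[t, 2]) / h[2]) / h[2]
    }, numeric(1)))
  }, numeric(1))
}

# small raw-ISU matrix with named axes for io tests
toy_crd <- function(values = c(0, 0.5, 1.2, 0, 0, 2.0), n = 3, p = 2) {
  crd_matrix(matrix(values, n, p),
             participant_ids = paste0("P", 1:n),
             component_ids = paste0("C", 1:p))
}
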