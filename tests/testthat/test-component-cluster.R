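block_dissim <- function(sizes, within = 0, between = 1) {
  p <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between, p, p)
  for (g in seq_along(sizes)) d[lab == g, lab == g] <- within
  diag(d) <- 0
  dimnames(d) <- list(paste0("C", 1:p), paste0("C", 1:p))
  class(d) <- c("dissimilarity_matrix", "matrix", "array")
  d
}

test_that("a duplicated pair plus an orthogonal component yields pair + singleton", {
  d <- block_dissim(c(2, 1))
  cl <- agglomerative_cluster(d, cut_height = 0.4)
  expect_identical(cl$k, 2L)
  expect_identical(unname(cl$labels[1]), unname(cl$labels[2]))
  expect_false(cl$labels[3] == cl$labels[1])
  expect_identical(unname(cl$singleton), c(FALSE, FALSE, TRUE))
})

test_that("cutting at zero makes everything a singleton unless duplicated", {
  set.seed(8)
  m <- crd_matrix(matrix(rexp(6 * 30), 30, 6))
  d <- dissimilarity_matrix(m)
  cl <- agglomerative_cluster(d, cut_height = 0)
  expect_identical(cl$k, 6L)
})

test_that("average-linkage merge heights never invert", {
  set.seed(12)
  for (rep in 1:5) {
    m <- crd_matrix(matrix(rexp(8 * 25), 25, 8))
    cl <- agglomerative_cluster(dissimilarity_matrix(m))
    expect_false(is.unsorted(cl$tree$height))
  }
})

test_that("DIANA and PAM recover perfectly separated blocks and respect their contracts", {
  d <- block_dissim(c(3, 4))
  truth <- rep(1:2, c(3, 4))
  expect_equal(rand_index(divisive_cluster(d, 2), truth), 1)
  pc <- pam_cluster(d, 2)
  expect_equal(rand_index(pc, truth), 1)
  med <- attr(pc, "medoids")
  expect_true(all(pc[med] == pc[med]))  # medoids exist among labelled points
  expect_true(all(med %in% names(pc)))
  expect_error(divisive_cluster(d, 1), "k must lie")
  expect_error(pam_cluster(d, 8), "k must lie")
})

test_that("Rand index agrees with pair enumeration and its identities", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3, tolerance = 1e-12)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               rand_oracle(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  expect_identical(rand_index(1:4, rep(1, 4)), 0)          # no pair agrees
  set.seed(3)
  a <- sample(1:3, 12, replace = TRUE)
  b <- sample(1:4, 12, replace = TRUE)
  expect_equal(rand_index(a, b), rand_oracle(a, b), tolerance = 1e-12)
  expect_equal(rand_index(a, b), rand_index(b, a))
  expect_equal(rand_index(a, a), 1)
  # invariant to relabelling
  expect_equal(rand_index(a, b), rand_index(4 - a, b))
  expect_error(rand_index(1:3, 1:4), "length")
})

test_that("planted latent blocks are recovered by the 0.40 cut across seeds", {
  hits <- 0
  n_seeds <- 20
  for (s in 1:n_seeds) {
    cfg <- cohort_config(n_participants = 500, n_components = 12,
                         block_spec = list(list(size = 4, r = 0.9),
                                           list(size = 4, r = 0.9),
                                           list(size = 4, r = 0.9)),
                         background_r = 0, mu = 1, sigma = 1, seed = s)
    coh <- generate_cohort(cfg)
    d <- dissimilarity_matrix(coh$crd)
    cl <- agglomerative_cluster(d, cut_height = 0.40)
    truth <- coh$truth$component_blocks
    hits <- hits + (rand_index(cl$labels, truth) >= 0.999)
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("connectivity graph scales the hub to 1 and filters edges monotonically", {
  # hub: component 1 strongly associated with everything, others mutually weak
  p <- 6
  dcor <- matrix(0.05, p, p)
  dcor[1, ] <- dcor[, 1] <- 0.8
  diag(dcor) <- 1
  d <- 1 - dcor
  dimnames(d) <- list(paste0("C", 1:p), paste0("C", 1:p))
  class(d) <- c("dissimilarity_matrix", "matrix", "array")
  g <- build_connectivity_graph(d, edge_min_dcor = 0.3)
  sc <- igraph::V(g)$scaled_connectivity
  names(sc) <- igraph::V(g)$name
  expect_equal(unname(sc["C1"]), 1)
  expect_true(all(sc[-1] < 1))
  expect_equal(igraph::degree(g)[["C1"]], p - 1)
  g2 <- build_connectivity_graph(d, edge_min_dcor = 0.9)
  expect_lte(igraph::ecount(g2), igraph::ecount(g))
  # two components: both ends carry scaled connectivity 1 by symmetry
  g3 <- build_connectivity_graph(block_dissim(c(1, 1), between = 0.4))
  expect_equal(igraph::V(g3)$scaled_connectivity, c(1, 1))
})

test_that("hierarchical, divisive and medoid partitions agree on well-separated planted blocks", {
  rands <- c()
  for (s in 1:5) {
    cfg <- cohort_config(n_participants = 400, n_components = 9,
                         block_spec = list(list(size = 3, r = 0.9),
                                           list(size = 3, r = 0.9),
                                           list(size = 3, r = 0.9)),
                         mu = 1, seed = s + 40)
    coh <- generate_cohort(cfg)
    d <- dissimilarity_matrix(coh$crd)
    cl <- agglomerative_cluster(d)
    rands <- c(rands,
               rand_index(cl$labels, divisive_cluster(d, cl$k)),
               rand_index(cl$labels, pam_cluster(d, cl$k)))
  }
  expect_gte(mean(rands), 0.9)
})
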