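test_that("Jaccard distance counts intersections over unions", {
  expect_equal(jaccard_distance(c(1, 0, 1), c(1, 1, 0)), 1 - 1 / 3,
               tolerance = 1e-12)
  expect_identical(jaccard_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_identical(jaccard_distance(c(1, 1, 0), c(0, 0, 1)), 1)
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), "all-zero")
  expect_error(jaccard_distance(c(1, 0), c(1, 0, 1)), "length")
})

test_that("Jaccard distance satisfies the triangle inequality on random triples", {
  set.seed(71)
  for (rep in 1:200) {
    v <- matrix(rbinom(30, 1, 0.4), 3, 10)
    if (any(rowSums(v) == 0)) next
    d12 <- jaccard_distance(v[1, ], v[2, ])
    d13 <- jaccard_distance(v[1, ], v[3, ])
    d23 <- jaccard_distance(v[2, ], v[3, ])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("the distance matrix agrees with the pairwise definition", {
  set.seed(6)
  b <- matrix(rbinom(40, 1, 0.5), 8, 5)
  b[rowSums(b) == 0, 1] <- 1L
  rownames(b) <- paste0("P", 1:8)
  dm <- as.matrix(jaccard_matrix(b))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(dm[i, j], jaccard_distance(b[i, ], b[j, ]), tolerance = 1e-12)
  }
})

test_that("Ward clustering separates distinct profiles and has monotone heights", {
  b <- rbind(P1 = c(1, 0, 0), P2 = c(0, 1, 0), P3 = c(0, 0, 1))
  wc <- ward_cluster(jaccard_matrix(b), k_range = 2)
  expect_false(is.unsorted(wc$tree$height))
  expect_error(ward_cluster(jaccard_matrix(b), k_range = 3), "k_range")
  set.seed(13)
  bb <- matrix(rbinom(300, 1, 0.4), 30, 10)
  bb[rowSums(bb) == 0, 1] <- 1L
  rownames(bb) <- paste0("P", 1:30)
  wc2 <- ward_cluster(jaccard_matrix(bb), k_range = 2:6)
  expect_false(is.unsorted(wc2$tree$height))
})

test_that("cluster labels are invariant to participant order", {
  gen <- generate_archetype_profiles(n = 120, seed = 31)
  d <- jaccard_matrix(gen$profile)
  sel <- select_k_calinski_harabasz(gen$profile, ward_cluster(d, 2:6))
  set.seed(99)
  perm <- sample(nrow(gen$profile))
  pp <- gen$profile[perm, ]
  class(pp) <- class(gen$profile)
  sel2 <- select_k_calinski_harabasz(pp, ward_cluster(jaccard_matrix(pp), 2:6))
  expect_identical(sel2$k, sel$k)
  expect_equal(rand_index(sel$labels[rownames(pp)], sel2$labels), 1)
})

test_that("Calinski-Harabasz selects the planted number of archetypes", {
  gen <- generate_archetype_profiles(n = 300, flip = 0.05, seed = 17)
  sel <- select_k_calinski_harabasz(gen$profile,
                                    ward_cluster(jaccard_matrix(gen$profile), 2:8))
  expect_identical(sel$k, 4L)
  expect_gte(rand_index(sel$labels, gen$archetype), 0.9)
  # two archetypes only
  two <- generate_archetype_profiles(n = 200, weights = c(0.5, 0.5, 0, 0), seed = 3)
  sel2 <- select_k_calinski_harabasz(two$profile,
                                     ward_cluster(jaccard_matrix(two$profile), 2:6))
  expect_identical(sel2$k, 2L)
  # k = 1 never appears in the trace
  expect_false("1" %in% names(sel$trace))
  # degenerate input
  ident <- matrix(1L, 10, 4, dimnames = list(paste0("P", 1:10), NULL))
  expect_error(select_k_calinski_harabasz(ident, ward_cluster(stats::dist(ident), 2)),
               "identical")
})

test_that("association layer reproduces hand-computed statistics", {
  # chi-squared on a printed 3x2 table
  tab <- matrix(c(20, 10, 5, 10, 15, 20), nrow = 3,
                dimnames = list(1:3, 0:1))
  labels <- setNames(rep(1:3, times = rowSums(tab)), paste0("P", 1:80))
  y <- unlist(mapply(function(zeros, ones) c(rep(0, zeros), rep(1, ones)),
                     tab[, 1], tab[, 2]))
  outcomes <- data.frame(participant_id = names(labels), asthma = unname(y))
  rep1 <- associate_outcomes(labels, outcomes)
  expect_equal(rep1$binary$asthma$chisq$statistic, chisq_oracle(tab),
               tolerance = 1e-10)
  # Kruskal-Wallis against the textbook formula on distinct values
  set.seed(23)
  outcomes$fev1 <- rnorm(80)
  rep2 <- associate_outcomes(labels, outcomes)
  expect_equal(rep2$continuous$fev1$kruskal$statistic,
               kw_oracle(outcomes$fev1, unname(labels)), tolerance = 1e-10)
})

test_that("odds ratios follow the 2x2 formula with Wald intervals", {
  est <- odds_ratio_wald(10, 10, 5, 20)
  expect_identical(est$or, 4)
  expect_false(est$corrected)
  expect_lt(est$ci_low, 4); expect_gt(est$ci_high, 4)
  sym <- odds_ratio_wald(7, 7, 7, 7)
  expect_identical(sym$or, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)
  zc <- odds_ratio_wald(5, 0, 3, 4)
  expect_true(zc$corrected)
  expect_true(is.finite(zc$or) && is.finite(zc$ci_high))
})

test_that("cluster odds ratios use the cluster-vs-rest contrast by default", {
  labels <- setNames(c(rep(1, 20), rep(2, 25)), paste0("P", 1:45))
  y <- c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 20))
  outcomes <- data.frame(participant_id = names(labels), asthma = y)
  rep1 <- associate_outcomes(labels, outcomes)
  expect_equal(rep1$binary$asthma$odds_ratios$cluster_1$or, (10 * 20) / (10 * 5))
  alt <- associate_outcomes(labels, outcomes, or_reference = 2)
  expect_equal(alt$binary$asthma$odds_ratios$cluster_1$or, (10 * 20) / (10 * 5))
})
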