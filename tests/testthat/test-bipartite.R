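bip_fixture <- function() {
  b <- rbind(P1 = c(1L, 0L, 1L), P2 = c(0L, 1L, 0L), P3 = c(1L, 1L, 0L))
  colnames(b) <- c("A", "B", "C")
  class(b) <- c("binary_profile", "matrix", "array")
  list(b = b,
       sc = setNames(c(1L, 2L, 1L), rownames(b)),
       cc = setNames(c(1L, 1L, 2L), colnames(b)),
       outcomes = data.frame(participant_id = rownames(b),
                             asthma = c(1L, 0L, 0L)))
}

test_that("edge weights count positives and conserve the profile total", {
  f <- bip_fixture()
  bg <- build_bipartite(f$b, f$sc, f$cc, f$outcomes)
  expect_identical(sum(bg$edges$weight), sum(f$b))
  # per-component column sums equal prevalence counts
  comp_tot <- tapply(bg$edges$weight, bg$edges$component, sum)
  expect_equal(as.vector(comp_tot[colnames(f$b)]),
               as.vector(colSums(f$b)))
  # a single positive subject yields a single unit edge
  one <- f$b[1, , drop = FALSE] * 0L; one[1, 2] <- 1L
  class(one) <- class(f$b)
  bg1 <- build_bipartite(one, f$sc[1], f$cc, f$outcomes[1, ])
  expect_identical(nrow(bg1$edges), 1L)
  expect_identical(bg1$edges$weight, 1L)
})

test_that("aggregation is invariant to subject order and rejects unlabelled subjects", {
  f <- bip_fixture()
  bg <- build_bipartite(f$b, f$sc, f$cc, f$outcomes)
  perm <- f$b[c(3, 1, 2), ]
  class(perm) <- class(f$b)
  bg2 <- build_bipartite(perm, f$sc, f$cc, f$outcomes)
  key <- function(e) e[order(e$group, e$component), ]
  expect_identical(key(bg$edges), key(bg2$edges))
  expect_error(build_bipartite(f$b, f$sc[1:2], f$cc, f$outcomes), "unlabelled")
})

test_that("group nodes carry sizes and asthma status; groups partition subjects", {
  f <- bip_fixture()
  bg <- build_bipartite(f$b, f$sc, f$cc, f$outcomes)
  v <- igraph::as_data_frame(bg$graph, what = "vertices")
  gv <- v[v$type == "group", ]
  expect_identical(sum(gv$size), nrow(f$b))
  expect_setequal(gv$asthma_status, c(0L, 1L))
})

test_that("archetype groups connect most strongly to their own component block", {
  gen <- generate_archetype_profiles(n = 300, seed = 51)
  lab <- setNames(gen$archetype, rownames(gen$profile))
  cc <- setNames(rep(1:4, each = 5), colnames(gen$profile))
  outcomes <- data.frame(participant_id = rownames(gen$profile),
                         asthma = rbinom(300, 1, 0.3))
  bg <- build_bipartite(gen$profile, lab, cc, outcomes)
  # HDM-like archetype (2) is positive on components 1..5 only
  hdm_edges <- bg$edges[grepl("^SC2_", bg$edges$group), ]
  in_block <- hdm_edges$component %in% paste0("c", sprintf("%02d", 1:5))
  expect_gt(sum(hdm_edges$weight[in_block]), sum(hdm_edges$weight[!in_block]))
})

test_that("multi-positivity strata report rising odds under a planted monotone effect", {
  set.seed(61)
  n <- 600
  counts <- rbinom(n, 6, 0.4)
  y <- rbinom(n, 1, plogis(-2 + 0.8 * counts))
  b <- t(sapply(counts, function(k) as.integer(seq_len(6) <= k)))
  b <- cbind(b, anchor = 1L)  # keeps every subject sensitised
  rownames(b) <- paste0("P", 1:n)
  colnames(b)[1:6] <- paste0("s", 1:6)
  class(b) <- c("binary_profile", "matrix", "array")
  outcomes <- data.frame(participant_id = rownames(b), asthma = y)
  tab <- multi_positivity_risk(b, outcomes, paste0("s", 1:6),
                               breaks = c(0, 2, 4))
  expect_identical(nrow(tab), 3L)
  expect_true(is.na(tab$or[1]))
  expect_gt(tab$or[3], tab$or[2])
  expect_gt(tab$or[2], 1)
  # single stratum: no comparison possible
  tab1 <- multi_positivity_risk(b, outcomes, "anchor", breaks = c(0))
  expect_identical(nrow(tab1), 1L)
  expect_true(is.na(tab1$or[1]))
  expect_error(multi_positivity_risk(b, outcomes, character(0)), "length")
  expect_error(multi_positivity_risk(b, outcomes, "nope"), "unknown components")
})

test_that("null multi-positivity strata keep the null inside their intervals", {
  set.seed(62)
  cover <- 0
  n_sim <- 60
  for (s in 1:n_sim) {
    n <- 300
    counts <- rbinom(n, 5, 0.5)
    y <- rbinom(n, 1, 0.3)
    b <- t(sapply(counts, function(k) as.integer(seq_len(5) <= k)))
    b <- cbind(b, anchor = 1L)
    rownames(b) <- paste0("P", 1:n)
    colnames(b)[1:5] <- paste0("s", 1:5)
    class(b) <- c("binary_profile", "matrix", "array")
    outcomes <- data.frame(participant_id = rownames(b), asthma = y)
    tab <- multi_positivity_risk(b, outcomes, paste0("s", 1:5), breaks = c(0, 3))
    cover <- cover + (tab$ci_low[2] <= 1 && tab$ci_high[2] >= 1)
  }
  expect_gte(cover / n_sim, 0.9)
})
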