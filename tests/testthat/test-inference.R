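test_that("permutation null is reproducible and preserves per-node geometry", {
  set.seed(5)
  V <- matrix(abs(rnorm(8 * 6, 1, 0.4)), nrow = 8)
  g <- rnorm(6, 0.1, 0.3)
  fm <- small_field_matrix(V)
  plan <- permutation_plan(n_perm = 50, seed = 99)
  null1 <- permutation_null(fm, g, plan)
  null2 <- permutation_null(fm, g, plan)
  expect_identical(null1, null2)
  expect_equal(dim(null1), c(8L, 50L))
  # a different seed gives a different ensemble
  null3 <- permutation_null(fm, g, permutation_plan(n_perm = 50, seed = 100))
  expect_false(identical(null1, null3))
  # every null column is a PEC map of some reordering of g: bounded by the
  # extreme over all permutations (exhaustive reference)
  ex <- permutation_null(fm, g, plan, exhaustive = TRUE)
  expect_true(all(null1 <= apply(ex, 1, max) + 1e-12))
  expect_true(all(null1 >= apply(ex, 1, min) - 1e-12))
})

test_that("exhaustive null enumerates exactly the m! permutation PEC values", {
  V <- rbind(c(0.3, 0.9, 0.2, 0.7), c(0.8, 0.1, 0.5, 0.4))
  g <- c(-0.1, 0.2, 0.05, 0.4)
  fm <- small_field_matrix(V)
  null <- permutation_null(fm, g, permutation_plan(n_perm = 1, seed = 1),
                           exhaustive = TRUE)
  expect_equal(ncol(null), factorial(4))
  # brute-force reference: loop every permutation, naive Pearson per node
  perms <- pecmap:::enumerate_permutations(4)
  for (node in 1:2) {
    ref <- sort(vapply(perms, function(p) naive_pearson(V[node, ], g[p]), 0))
    expect_equal(sort(null[node, ]), ref, tolerance = 1e-12)
  }
})

test_that("add-one p-values have the right range, extremes and sidedness", {
  obs <- pecmap:::new_pec_map(c(0.9, -0.5, 0.1), rep(FALSE, 3), 10, "all",
                              "pearson", NULL)
  null <- rbind(seq(-0.5, 0.5, length.out = 10),
                seq(-0.5, 0.5, length.out = 10),
                seq(-0.5, 0.5, length.out = 10))
  plan <- permutation_plan(n_perm = 10, seed = 1)
  pv <- permutation_pvalues(obs, null, plan)
  # above every null value -> minimum p = 1/(n_perm + 1)
  expect_equal(pv$p[1], 1 / 11)
  # below every null value, one-sided -> p = 1
  expect_equal(pv$p[2], 1)
  expect_true(all(pv$p > 0 & pv$p <= 1))
  # two-sided uses |.|: -0.5 ties the largest |null| values
  plan2 <- permutation_plan(n_perm = 10, seed = 1, sidedness = "two_sided")
  pv2 <- permutation_pvalues(obs, null, plan2)
  expect_equal(pv2$p[2], (1 + sum(abs(null[2, ]) >= 0.5)) / 11)
  # degenerate nodes are forced to p = 1
  obs_d <- pecmap:::new_pec_map(c(0.9, 0), c(FALSE, TRUE), 10, "all",
                                "pearson", NULL)
  pv3 <- permutation_pvalues(obs_d, null[1:2, ], plan)
  expect_equal(pv3$p[2], 1)
  expect_error(permutation_pvalues(obs, null[1:2, ], plan),
               class = "pecmap_alignment_error")
})

test_that("one-sided p is monotone decreasing in the observed PEC", {
  set.seed(21)
  null_row <- matrix(rnorm(200), nrow = 1)
  plan <- permutation_plan(n_perm = 200, seed = 1)
  obs_vals <- seq(-2, 2, length.out = 41)
  p <- vapply(obs_vals, function(v) {
    m <- pecmap:::new_pec_map(v, FALSE, 10, "all", "pearson", NULL)
    permutation_pvalues(m, null_row, plan)$p
  }, 0)
  expect_true(all(diff(p) <= 0))
})

test_that("Monte-Carlo p over the enumerated group matches exact rank-based p", {
  # toy matrix with <= 6 outcomes: feed the fully enumerated permutation set
  # through the Monte-Carlo estimator and compare with the exact p computed
  # by brute force
  set.seed(31)
  V <- matrix(abs(rnorm(5 * 5, 1, 0.4)), nrow = 5)
  g <- rnorm(5, 0.1, 0.3)
  fm <- small_field_matrix(V)
  map <- compute_pec(fm, g)
  null <- permutation_null(fm, g, permutation_plan(n_perm = 1, seed = 1),
                           exhaustive = TRUE)
  plan <- permutation_plan(n_perm = factorial(5), seed = 1)
  pv <- permutation_pvalues(map, null, plan)
  perms <- pecmap:::enumerate_permutations(5)
  for (node in 1:5) {
    null_ref <- vapply(perms, function(p) naive_pearson(V[node, ], g[p]), 0)
    # same tie convention as the estimator: the identity permutation (a
    # bitwise near-tie across the two computation routes) counts as >=
    exact <- (1 + sum(null_ref >= map$pec[node] - 1e-12)) / (factorial(5) + 1)
    expect_equal(pv$p[node], exact, tolerance = 1e-12)
  }
})

test_that("parcel rule reproduces hand-computed interpolated 75th percentiles", {
  labels <- rep(c("A", "B"), each = 8)
  parcellation <- pecmap:::new_parcellation(labels)
  p_a <- c(rep(0.01, 7), 0.2)        # p75 = 0.01 -> significant
  p_b <- c(rep(0.01, 6), 0.2, 0.3)   # p75 = 0.0575 -> not significant
  obs <- pecmap:::new_pec_map(rep(0.5, 16), rep(FALSE, 16), 10, "all",
                              "pearson", NULL)
  pv <- structure(
    tibble::tibble(node_id = 0:15, pec = 0.5, p = c(p_a, p_b),
                   significant = c(p_a, p_b) < 0.05,
                   degenerate = FALSE),
    sidedness = "one_sided_positive", n_perm = 1000, alpha = 0.05,
    subset = "all", class = c("pec_pvalues", "tbl_df", "tbl", "data.frame"))
  tab <- parcel_significance(pv, parcellation)
  expect_equal(tab$p75[tab$parcel == "A"], 0.01)
  expect_true(tab$significant[tab$parcel == "A"])
  expect_equal(tab$p75[tab$parcel == "B"], 0.0575)
  expect_false(tab$significant[tab$parcel == "B"])
  expect_equal(tab$frac_sig[tab$parcel == "A"], 7 / 8)
  # independent quantile cross-check
  expect_equal(tab$p75, c(naive_quantile(p_a, 0.75), naive_quantile(p_b, 0.75)))
  # all-ones parcel is never significant
  pv_null <- pv; pv_null$p <- rep(1, 16); pv_null$significant <- FALSE
  tab2 <- parcel_significance(pv_null, parcellation)
  expect_false(any(tab2$significant))
})

test_that("degenerate nodes are excluded and emptied parcels warn, not error", {
  labels <- c(rep("A", 4), rep("B", 2))
  parcellation <- pecmap:::new_parcellation(labels)
  pv <- structure(
    tibble::tibble(node_id = 0:5, pec = 0.1,
                   p = c(0.01, 0.02, 0.03, 0.04, 1, 1),
                   significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                   degenerate = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)),
    sidedness = "one_sided_positive", n_perm = 1000, alpha = 0.05,
    subset = "all", class = c("pec_pvalues", "tbl_df", "tbl", "data.frame"))
  expect_warning(tab <- parcel_significance(pv, parcellation), "no usable nodes")
  expect_true(tab$empty[tab$parcel == "B"])
  expect_false(tab$significant[tab$parcel == "B"])
  expect_equal(tab$n_used[tab$parcel == "A"], 4L)
  expect_true(tab$significant[tab$parcel == "A"])
})
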