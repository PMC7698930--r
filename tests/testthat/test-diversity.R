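test_that("baselga_partition matches hand-computed and degenerate cases", {
  # identical communities
  bp <- baselga_partition(letters[1:10], letters[1:10])
  expect_equal(c(bp$beta_sor, bp$beta_sim, bp$beta_sne), c(0, 0, 0))
  expect_identical(c(bp$a, bp$b, bp$c), c(10L, 0L, 0L))

  # complete turnover
  bp <- baselga_partition(paste0("x", 1:5), paste0("y", 1:7))
  expect_equal(c(bp$beta_sor, bp$beta_sim, bp$beta_sne), c(1, 1, 0))

  # a = 2, b = 1, c = 3
  bp <- baselga_partition(c("s1", "s2", "u1"), c("s1", "s2", "v1", "v2", "v3"))
  expect_identical(c(bp$a, bp$b, bp$c), c(2L, 1L, 3L))
  expect_equal(bp$beta_sor, 0.5)
  expect_equal(bp$beta_sim, 1 / 3)
  expect_equal(bp$beta_sne, 1 / 6)

  # one empty community: all dissimilarity is nestedness-resultant
  bp <- baselga_partition(character(0), c("a", "b"))
  expect_equal(c(bp$beta_sor, bp$beta_sim, bp$beta_sne), c(1, 0, 1))

  expect_snh_error(baselga_partition(character(0), character(0)),
                   "snh_domain_error")
})

test_that("partition invariants hold on fuzzed pairs and match the oracle", {
  set.seed(42)
  pool <- paste0("t", 1:40)
  for (i in 1:500) {
    A <- sample(pool, sample(0:25, 1))
    B <- sample(pool, sample(1:25, 1))
    bp <- baselga_partition(A, B)
    or <- oracle_beta(A, B)
    expect_identical(c(bp$a, bp$b, bp$c), as.integer(c(or$a, or$b, or$c)))
    expect_equal(bp$beta_sor, or$beta_sor, tolerance = 1e-14)
    expect_equal(bp$beta_sim, or$beta_sim, tolerance = 1e-14)
    # additivity, range, symmetry, component ordering
    expect_lt(abs(bp$beta_sor - bp$beta_sim - bp$beta_sne), 1e-12)
    expect_true(all(c(bp$beta_sor, bp$beta_sim, bp$beta_sne) >= 0))
    expect_true(all(c(bp$beta_sor, bp$beta_sim, bp$beta_sne) <= 1))
    expect_lte(bp$beta_sim, bp$beta_sor)
    rev <- baselga_partition(B, A)
    expect_equal(rev$beta_sor, bp$beta_sor)
    expect_equal(rev$beta_sim, bp$beta_sim)
    if (length(setdiff(A, B)) == length(setdiff(B, A)))
      expect_equal(bp$beta_sne, 0)
  }
})

test_that("beta_sor agrees with vegan's Sorensen dissimilarity", {
  skip_if_not_installed("vegan")
  set.seed(7)
  pool <- paste0("t", 1:30)
  for (i in 1:25) {
    A <- sample(pool, sample(1:20, 1)); B <- sample(pool, sample(1:20, 1))
    m <- rbind(as.integer(pool %in% A), as.integer(pool %in% B))
    ref <- as.numeric(vegan::vegdist(m, method = "bray", binary = TRUE))
    expect_equal(baselga_partition(A, B)$beta_sor, ref, tolerance = 1e-12)
  }
})

test_that("pooled_habitat_community unions point communities", {
  ds <- dataset_from_communities(
    list(p1 = c("x", "y"), p2 = c("y", "z"), p3 = "w"),
    habitats = c("hedgerow", "hedgerow", "grassland"))
  expect_identical(pooled_habitat_community(ds, "hedgerow", "bees"),
                   c("x", "y", "z"))
  expect_warning(out <- pooled_habitat_community(ds, "forest_edge", "bees"),
                 "empty")
  expect_length(out, 0)
})

test_that("pairwise_beta_within reproduces hand computations", {
  ds <- dataset_from_communities(
    list(p1 = c("x", "y"), p2 = c("y", "z"), p3 = c("x", "z")),
    habitats = rep("grassland", 3))
  pw <- pairwise_beta_within(ds, "grassland")
  expect_identical(nrow(pw$pairs), 3L)
  expect_true(all(pw$pairs$a == 1 & pw$pairs$b == 1 & pw$pairs$c == 1))
  expect_equal(pw$pairs$beta_sor, rep(0.5, 3))
  expect_equal(pw$median_beta_sor, 0.5)

  same <- dataset_from_communities(
    list(p1 = c("x", "y"), p2 = c("x", "y"), p3 = c("x", "y")),
    habitats = rep("hedgerow", 3))
  expect_equal(pairwise_beta_within(same, "hedgerow")$median_beta_sor, 0)

  disj <- dataset_from_communities(
    list(p1 = "x", p2 = "y", p3 = "z"), habitats = rep("hedgerow", 3))
  expect_equal(pairwise_beta_within(disj, "hedgerow")$median_beta_sor, 1)

  # empty-empty pairs are excluded, not an error, while empty-nonempty count
  mix <- dataset_from_communities(
    list(p1 = c("x", "y"), p2 = character(0), p3 = character(0),
         p4 = c("x", "z")),
    habitats = rep("grassland", 4))
  pw <- pairwise_beta_within(mix, "grassland")
  expect_identical(pw$n_excluded_pairs, 1L)
  expect_identical(nrow(pw$pairs), 5L)

  one <- dataset_from_communities(list(p1 = "x", p2 = character(0)),
                                  habitats = rep("grassland", 2))
  expect_snh_error(pairwise_beta_within(one, "grassland"), "snh_domain_error")
})

test_that("interpolated rarefaction equals brute-force subsample enumeration", {
  # boundary identities first
  av <- abundance_vector(c(a = 4, b = 2, c = 1))
  rc <- rarefaction_curve(av, m_grid = c(1, 7), n_boot = 10, seed = 1)
  expect_equal(rc$curve$expected_richness[1], 1)
  expect_equal(rc$curve$expected_richness[2], av$S_obs)

  # spec'd toy: x = (2, 1), m = 2 -> 5/3
  rc <- rarefaction_curve(abundance_vector(c(a = 2, b = 1)), m_grid = 2,
                          n_boot = 10, seed = 1)
  expect_equal(rc$curve$expected_richness, 5 / 3, tolerance = 1e-12)

  # every composition with n <= 8 against exhaustive enumeration
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    parts <- diff(c(0, sort(sample(seq_len(n - 1), sample(0:(n - 1), 1))), n))
    counts <- stats::setNames(parts, paste0("s", seq_along(parts)))
    rc <- rarefaction_curve(abundance_vector(counts), m_grid = seq_len(n),
                            n_boot = 5, seed = 1)
    for (m in seq_len(n))
      expect_equal(rc$curve$expected_richness[m], oracle_rarefaction(counts, m),
                   tolerance = 1e-10)
  }
})

test_that("rarefaction curves are nondecreasing, concave, and extrapolate sanely", {
  set.seed(3)
  counts <- table(sample(paste0("s", 1:30), 120, replace = TRUE,
                         prob = 1 / seq_len(30)))
  av <- abundance_vector(stats::setNames(as.integer(counts), names(counts)))
  rc <- rarefaction_curve(av, n_boot = 50, seed = 9)
  e <- rc$curve$expected_richness
  expect_true(all(diff(e) > -1e-10))
  interp <- rc$curve$m <= av$n
  expect_true(all(diff(diff(e[interp]) / diff(rc$curve$m[interp])) < 1e-8))
  expect_true(all(rc$curve$ci_low <= e + 1e-12))
  expect_true(all(rc$curve$ci_high >= e - 1e-12))
  expect_true(all(rc$curve$method[rc$curve$m > av$n] == "extrapolated"))
  # extrapolation approaches S_obs + Chao1's undetected-species estimate
  expect_gt(max(e), av$S_obs)

  expect_snh_error(rarefaction_curve(av, m_grid = c(0, 5)), "snh_domain_error")
  expect_snh_error(abundance_vector(c(a = -1)), "snh_domain_error")
})

test_that("permutation null test has the documented extremes and add-one p", {
  # identical pooled communities: observed dissimilarity is at its floor
  ds <- dataset_from_communities(
    list(p1 = c("x", "y"), p2 = c("x", "y"), p3 = c("x", "y"),
         p4 = c("x", "y")),
    habitats = c("grassland", "grassland", "hedgerow", "hedgerow"))
  nt <- beta_null_test(ds, c("grassland", "hedgerow"), "bees",
                       n_perm = 49, seed = 1)
  expect_equal(nt$observed, 0)
  expect_equal(nt$p_value, 1)

  # disjoint habitat pools with full detection: observed is maximal and no
  # permutation can tie it, so p hits its add-one floor
  gen <- generate_dataset(simulation_config(
    n_landscapes = 10, pool_overlap = 0, detection_prob = 1,
    plant_pool_size = 10, bee_pool_size = 8,
    pollen_richness_probs = 1, seed = 5))
  nt <- beta_null_test(gen$dataset, c("grassland", "hedgerow"), "bees",
                       n_perm = 99, seed = 2)
  expect_equal(nt$observed, 1)
  expect_equal(nt$p_value, 1 / 100)
  expect_length(nt$null_values, 99)

  expect_snh_error(beta_null_test(ds, c("grassland", "hedgerow"), "bees",
                                  n_perm = 0), "snh_domain_error")
})

test_that("richness_abundance_summary counts per point and habitat", {
  ds <- toy_dataset()
  s <- richness_abundance_summary(ds)
  expect_equal(s$per_point$abundance[s$per_point$point_id == "p1"], 2)
  expect_equal(s$per_point$richness[s$per_point$point_id == "p3"], 1)
  expect_equal(s$per_habitat$median_abundance[
    s$per_habitat$habitat == "grassland"], 2)
  # empty point
  ds2 <- dataset_from_communities(list(p1 = c("x", "x"), p2 = character(0)),
                                  habitats = c("grassland", "hedgerow"))
  s2 <- richness_abundance_summary(ds2)
  expect_equal(s2$per_point$abundance[2], 0)
  expect_equal(s2$per_point$richness[2], 0)
})
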