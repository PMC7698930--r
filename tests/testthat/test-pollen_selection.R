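test_that("pollen availability counts occurrence records among included taxa", {
  ds <- bee_dataset(
    sites = data.frame(point_id = c("p1", "p2"), landscape_id = "L1",
                       habitat = c("grassland", "hedgerow")),
    bees = data.frame(bee_id = "b1", point_id = "p1", species = "s"),
    plants = data.frame(point_id = c("p1", "p2", "p1"),
                        taxon = c("A", "A", "B"), entomophilous = TRUE),
    pollen = data.frame(bee_id = character(0), pollen_taxon = character(0)))
  pa <- pollen_availability(ds, c("A", "B"))
  expect_equal(pa$PA[pa$taxon == "A"], 2 / 3)
  expect_equal(pa$PA[pa$taxon == "B"], 1 / 3)
  expect_equal(sum(pa$PA), 1, tolerance = 1e-12)

  # single taxon, single point
  pa1 <- pollen_availability(ds, "B")
  expect_equal(pa1$PA, 1)

  # included taxon with zero flora records gets PA = 0 and does not disturb
  # the denominator
  pa0 <- pollen_availability(ds, c("A", "B", "Z"))
  expect_equal(pa0$PA[pa0$taxon == "Z"], 0)
  expect_equal(sum(pa0$PA), 1, tolerance = 1e-12)

  expect_snh_error(pollen_availability(ds, character(0)), "snh_domain_error")
  expect_snh_error(pollen_availability(ds, "Z"), "snh_domain_error")
})

test_that("a taxon occurring in several layers at one point counts once", {
  ds <- bee_dataset(
    sites = data.frame(point_id = "p1", landscape_id = "L1",
                       habitat = "hedgerow"),
    bees = data.frame(bee_id = "b1", point_id = "p1", species = "s"),
    plants = data.frame(point_id = c("p1", "p1", "p1"),
                        taxon = c("A", "A", "B"),
                        layer = c("herbaceous", "shrub", "herbaceous"),
                        entomophilous = TRUE),
    pollen = data.frame(bee_id = character(0), pollen_taxon = character(0)))
  pa <- pollen_availability(ds, c("A", "B"))
  expect_equal(pa$n_occurrences, c(1L, 1L))
  expect_equal(pa$PA, c(0.5, 0.5))
})

test_that("harvest rate follows the hand count under both denominators", {
  ds <- bee_dataset(
    sites = data.frame(point_id = "p1", landscape_id = "L1",
                       habitat = "grassland"),
    bees = data.frame(bee_id = paste0("b", 1:4), point_id = "p1",
                      species = "s", kept_for_pollen = TRUE),
    plants = data.frame(point_id = "p1", taxon = c("A", "B"),
                        entomophilous = TRUE),
    pollen = data.frame(bee_id = c("b1", "b2", "b2", "b3"),
                        pollen_taxon = c("A", "A", "B", "B")))
  hr <- harvest_rate(ds, "records")
  expect_equal(hr$HR[hr$taxon == "A"], 2 / 4)
  expect_equal(hr$HR[hr$taxon == "B"], 2 / 4)
  expect_equal(sum(hr$HR), 1, tolerance = 1e-12)

  # per-bee convention: 4 bees examined (b4 carried nothing but counts)
  hrb <- harvest_rate(ds, "bees")
  expect_equal(hrb$HR, c(2 / 4, 2 / 4))

  # all bees carry only A
  ds2 <- ds
  ds2$pollen <- data.frame(bee_id = paste0("b", 1:4), pollen_taxon = "A")
  ds2 <- bee_dataset(ds2$sites, ds2$bees, ds2$plants, ds2$pollen)
  expect_equal(harvest_rate(ds2, "records")$HR, 1)
  # taxa never carried are absent from the table
  expect_false("B" %in% harvest_rate(ds2)$taxon)

  ds3 <- ds
  ds3$pollen <- ds3$pollen[0, ]
  expect_snh_error(harvest_rate(ds3), "snh_domain_error")
})

test_that("Jacobs' index matches direct evaluation and its properties", {
  expect_equal(jacobs_index(0.3, 0.3), 0)
  expect_equal(jacobs_index(0, 0.2), -1)
  expect_equal(jacobs_index(0.2, 0), 1)
  expect_equal(jacobs_index(0.009, 0.001), 0.008 / 0.009982, tolerance = 1e-12)
  expect_equal(round(jacobs_index(0.009, 0.001), 4), 0.8014)

  expect_snh_error(jacobs_index(0, 0), "snh_domain_error")
  expect_snh_error(jacobs_index(1, 1), "snh_domain_error")
  expect_snh_error(jacobs_index(1.2, 0.5), "snh_domain_error")

  g <- seq(0.02, 0.98, length.out = 25)
  grid <- expand.grid(HR = g, PA = g)
  D <- jacobs_index(grid$HR, grid$PA)
  expect_true(all(D >= -1 & D <= 1))
  # antisymmetry
  expect_equal(D, -jacobs_index(grid$PA, grid$HR), tolerance = 1e-12)
  # strictly increasing in HR at fixed PA, decreasing in PA at fixed HR
  Dm <- matrix(D, length(g), length(g))
  expect_true(all(apply(Dm, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(Dm, 1, function(row) all(diff(row) < 0))))
})

test_that("bootstrap_selection is deterministic, symmetric case is neutral", {
  # every bee carries every taxon and PA is uniform: D = 0 for all taxa
  ds <- bee_dataset(
    sites = data.frame(point_id = c("p1", "p2"), landscape_id = "L1",
                       habitat = c("grassland", "hedgerow")),
    bees = data.frame(bee_id = paste0("b", 1:6),
                      point_id = rep(c("p1", "p2"), 3), species = "s",
                      kept_for_pollen = TRUE),
    plants = data.frame(point_id = rep(c("p1", "p2"), each = 3),
                        taxon = rep(c("A", "B", "C"), 2),
                        entomophilous = TRUE),
    pollen = expand.grid(bee_id = paste0("b", 1:6),
                         pollen_taxon = c("A", "B", "C"),
                         stringsAsFactors = FALSE))
  sel <- bootstrap_selection(ds, n_boot = 100, seed = 3)
  expect_equal(sel$results$D, rep(0, 3))
  expect_true(all(sel$results$selection_class == "neutral"))
  expect_true(all(sel$results$ci_low <= 0 & sel$results$ci_high >= 0))

  sel2 <- bootstrap_selection(ds, n_boot = 100, seed = 3)
  expect_identical(sel$results, sel2$results)

  expect_snh_error(bootstrap_selection(ds, n_boot = 1), "snh_domain_error")
})

test_that("pollen taxa absent from the flora are excluded from D", {
  ds <- toy_dataset()
  ds$pollen <- rbind(ds$pollen,
                     data.frame(bee_id = "b3", pollen_taxon = "Tilia europaea"))
  ds <- bee_dataset(ds$sites, ds$bees, ds$plants, ds$pollen)
  sel <- bootstrap_selection(ds, n_boot = 50, seed = 1)
  expect_identical(sel$excluded_taxa, "Tilia europaea")
  expect_false("Tilia europaea" %in% sel$results$taxon)
  # classification rule: over iff ci_low > 0, under iff ci_high < 0
  r <- sel$results
  expect_identical(r$selection_class,
                   ifelse(r$ci_low > 0, "over_selected",
                          ifelse(r$ci_high < 0, "under_selected", "neutral")))
})

test_that("CI width shrinks as the number of bees grows", {
  width_at <- function(n_bees, seed) {
    set.seed(seed)
    pts <- data.frame(point_id = c("p1", "p2"), landscape_id = "L1",
                      habitat = c("grassland", "hedgerow"))
    bees <- data.frame(bee_id = sprintf("b%04d", seq_len(n_bees)),
                       point_id = sample(c("p1", "p2"), n_bees, TRUE),
                       species = "s", kept_for_pollen = TRUE)
    plants <- data.frame(point_id = rep(c("p1", "p2"), each = 4),
                         taxon = rep(c("A", "B", "C", "D"), 2),
                         entomophilous = TRUE)
    pollen <- data.frame(bee_id = bees$bee_id,
                         pollen_taxon = sample(c("A", "B", "C", "D"), n_bees,
                                               TRUE, prob = c(4, 2, 1, 1)))
    ds <- bee_dataset(pts, bees, plants, pollen)
    sel <- bootstrap_selection(ds, n_boot = 300, seed = 11)
    mean(sel$results$ci_high - sel$results$ci_low)
  }
  w <- vapply(c(50, 200, 800), width_at, numeric(1), seed = 21)
  expect_true(all(diff(w) < 0))
})
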