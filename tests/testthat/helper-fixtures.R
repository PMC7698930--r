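# Fixtures are built in code; tests stay text-only and self-contained.

options(snhbees.verbose = FALSE)

HABITATS <- c("hedgerow", "forest_edge", "grassland")

# Minimal well-formed survey: 3 points, 5 bees, 6 plant rows, 4 pollen rows.
toy_dataset <- function() {
  bee_dataset(
    sites = data.frame(
      point_id = c("p1", "p2", "p3"),
      landscape_id = c("L1", "L1", "L2"),
      habitat = c("hedgerow", "forest_edge", "grassland")),
    bees = data.frame(
      bee_id = paste0("b", 1:5),
      point_id = c("p1", "p1", "p2", "p3", "p3"),
      species = c("Sp one", "Sp two", "Sp one", "Sp three", "Sp three"),
      kept_for_pollen = TRUE),
    plants = data.frame(
      point_id = c("p1", "p1", "p2", "p2", "p3", "p3"),
      taxon = c("Ranunculus acris", "Trifolium repens", "Ranunculus acris",
                "Quercus robur", "Trifolium repens", "Lotus corniculatus"),
      layer = c("herbaceous", "herbaceous", "herbaceous", "tree",
                "herbaceous", "herbaceous"),
      abundance_code = c("+", "2", "r", "1", "3", "+"),
      entomophilous = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)),
    pollen = data.frame(
      bee_id = c("b1", "b2", "b4", "b5"),
      pollen_taxon = c("Ranunculus acris", "Trifolium repens",
                       "Trifolium repens", "Lotus corniculatus")))
}

# The hand-computable two-habitat network: grassland holds edges
# (b1,A),(b2,B), the hedgerow holds (b1,A),(b3,C).
toy_network_dataset <- function() {
  bee_dataset(
    sites = data.frame(
      point_id = c("g", "h"), landscape_id = c("L1", "L1"),
      habitat = c("grassland", "hedgerow")),
    bees = data.frame(
      bee_id = paste0("bee", 1:4),
      point_id = c("g", "g", "h", "h"),
      species = c("b1", "b2", "b1", "b3"),
      kept_for_pollen = TRUE),
    plants = data.frame(
      point_id = c("g", "g", "h"),
      taxon = c("A", "B", "C"),
      entomophilous = TRUE),
    pollen = data.frame(
      bee_id = paste0("bee", 1:4),
      pollen_taxon = c("A", "B", "A", "C")))
}

# Dataset whose per-point bee communities are given explicitly; plants and
# pollen left empty. `comms` is a named list point_id -> species vector,
# `habitats` a same-length vector of habitat types.
dataset_from_communities <- function(comms, habitats) {
  pts <- names(comms)
  bees <- do.call(rbind, lapply(seq_along(comms), function(i) {
    if (!length(comms[[i]])) return(NULL)
    data.frame(point_id = pts[i], species = comms[[i]])
  }))
  if (is.null(bees)) bees <- data.frame(point_id = character(0),
                                        species = character(0))
  bees <- data.frame(bee_id = sprintf("b%03d", seq_len(nrow(bees))), bees)
  bee_dataset(
    sites = data.frame(point_id = pts, landscape_id = pts,
                       habitat = habitats),
    bees = bees,
    plants = data.frame(point_id = character(0), taxon = character(0)),
    pollen = data.frame(bee_id = character(0), pollen_taxon = character(0)))
}

# Independent set-algebra oracle for the beta partition: represents the two
# communities as incidence vectors over the union and re-derives a/b/c and
# the three dissimilarities from first principles.
oracle_beta <- function(A, B) {
  u <- union(unique(A), unique(B))
  ia <- as.integer(u %in% A); ib <- as.integer(u %in% B)
  a <- sum(ia == 1 & ib == 1)
  only_a <- sum(ia == 1 & ib == 0); only_b <- sum(ia == 0 & ib == 1)
  b <- min(only_a, only_b); cc <- max(only_a, only_b)
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- if (a + b == 0) 0 else b / (a + b)
  list(a = a, b = b, c = cc, beta_sor = sor, beta_sim = sim,
       beta_sne = sor - sim)
}

# Brute-force rarefaction oracle: enumerate every m-subset of the
# individual-level sample and average the richness.
oracle_rarefaction <- function(counts, m) {
  individuals <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(individuals), m)
  mean(apply(subs, 2, function(idx) length(unique(individuals[idx]))))
}

expect_snh_error <- function(expr, class) expect_error(expr, class = class)
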