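#' Filter a dataset to the abundant bee species
#'
#' Keeps bee records (and their pollen loads) of species captured more than
#' `min_individuals - 1` times across the whole dataset, i.e. the default
#' keeps species with more than 4 individuals. Rare species are dropped
#' because their pollen loads confound specific diets with habitat effects.
#'
#' @param ds a `bee_dataset`.
#' @param min_individuals minimum total captures for a species to be kept
#'   (default 5, equivalently "more than 4 individuals").
#' @return The filtered `bee_dataset` (sites and plants unchanged).
#' @export
abundant_species_filter <- function(ds, min_individuals = 5L) {
  stopifnot(inherits(ds, "bee_dataset"))
  counts <- table(ds$bees$species)
  keep_sp <- names(counts)[counts >= min_individuals]
  ds$bees <- ds$bees[ds$bees$species %in% keep_sp, , drop = FALSE]
  ds$pollen <- ds$pollen[ds$pollen$bee_id %in% ds$bees$bee_id, , drop = FALSE]
  validate_dataset(ds)
  ds
}

#' Build the bee-pollen bipartite network
#'
#' One edge per unique (bee species, pollen taxon) pair observed anywhere in
#' the dataset; the edge frequency counts the supporting pollen records and
#' the edge's habitat set collects the habitats of the sampling points where
#' the interaction was observed. Node provenance is derived the same way.
#'
#' @param ds a `bee_dataset`, usually after [abundant_species_filter()].
#' @return Object of class `bee_network`: `edges` (data.frame `bee_species`,
#'   `pollen_taxon`, `frequency`, `habitats` comma-separated), `bee_nodes`
#'   and `plant_nodes` (data.frames with `name`, `degree`, `habitats`).
#' @export
build_network <- function(ds) {
  recs <- pollen_records_with_context(ds)
  if (nrow(recs) == 0L)
    stop(errorCondition("no pollen records: empty network",
                        class = c("snh_domain_error", "error")))
  key <- paste(recs$bee_species, recs$pollen_taxon, sep = "\r")
  agg_hab <- function(h) paste(sort(unique(h)), collapse = ",")
  edges <- data.frame(
    bee_species = tapply(recs$bee_species, key, `[`, 1),
    pollen_taxon = tapply(recs$pollen_taxon, key, `[`, 1),
    frequency = as.integer(tapply(recs$bee_species, key, length)),
    habitats = tapply(recs$habitat, key, agg_hab),
    row.names = NULL, stringsAsFactors = FALSE)
  edges <- edges[order(edges$bee_species, edges$pollen_taxon), , drop = FALSE]
  bee_nodes <- data.frame(
    name = sort(unique(edges$bee_species)), stringsAsFactors = FALSE)
  bee_nodes$degree <- vapply(bee_nodes$name, function(x)
    sum(edges$bee_species == x), 0L)
  bee_nodes$habitats <- vapply(bee_nodes$name, function(x)
    agg_hab(recs$habitat[recs$bee_species == x]), character(1))
  plant_nodes <- data.frame(
    name = sort(unique(edges$pollen_taxon)), stringsAsFactors = FALSE)
  plant_nodes$degree <- vapply(plant_nodes$name, function(x)
    sum(edges$pollen_taxon == x), 0L)
  plant_nodes$habitats <- vapply(plant_nodes$name, function(x)
    agg_hab(recs$habitat[recs$pollen_taxon == x]), character(1))
  structure(list(edges = edges, bee_nodes = bee_nodes,
                 plant_nodes = plant_nodes),
            class = "bee_network")
}

# Pollen records joined to bee species and sampling-point habitat.
pollen_records_with_context <- function(ds) {
  i <- match(ds$pollen$bee_id, ds$bees$bee_id)
  out <- data.frame(
    bee_id = ds$pollen$bee_id,
    bee_species = ds$bees$species[i],
    pollen_taxon = ds$pollen$pollen_taxon,
    point_id = ds$bees$point_id[i],
    stringsAsFactors = FALSE)
  out$habitat <- ds$sites$habitat[match(out$point_id, ds$sites$point_id)]
  out
}

#' @export
print.bee_network <- function(x, ...) {
  cat(sprintf("bipartite bee-pollen network: %d unique interactions, %d bee species, %d pollen taxa\n",
              nrow(x$edges), nrow(x$bee_nodes), nrow(x$plant_nodes)))
  cat(sprintf("  median links per bee species: %s\n",
              format(stats::median(x$bee_nodes$degree))))
  invisible(x)
}

#' Share of interactions unique to a habitat group
#'
#' Fraction of network edges observed only at sampling points of the given
#' habitats (their habitat set is a subset of `habitat_group`).
#'
#' @param network a `bee_network`.
#' @param habitat_group character vector of habitats (may be empty).
#' @return A fraction in `[0, 1]`.
#' @export
unique_interaction_share <- function(network, habitat_group) {
  stopifnot(inherits(network, "bee_network"))
  if (nrow(network$edges) == 0L)
    stop(errorCondition("empty network", class = c("snh_domain_error", "error")))
  if (length(habitat_group))
    habitat_group <- vapply(habitat_group, match.arg, "", choices = HABITATS)
  hsets <- strsplit(network$edges$habitats, ",", fixed = TRUE)
  mean(vapply(hsets, function(h) all(h %in% habitat_group), logical(1)))
}

#' Network robustness to removal of one habitat type
#'
#' Quantifies how much of the bee-pollen network survives when all sampling
#' points of one habitat type are removed, under equal sampling effort.
#' Because the habitats have unequal numbers of sampling points, each
#' replicate first draws `subsample_size` points per habitat without
#' replacement (a habitat with exactly `subsample_size` points enters
#' as-is), builds the full network on those points, then the reduced network
#' excluding the removed habitat's points. Remnant percentages are relative
#' to the per-replicate full network: a species counts as remaining only if
#' it retains at least one interaction.
#'
#' @param ds a `bee_dataset`, usually after [abundant_species_filter()].
#' @param removed_habitat habitat to remove, or a character vector of
#'   habitats removed together.
#' @param n_boot number of replicates (default 5000).
#' @param subsample_size points drawn per habitat (default 24). `NULL`
#'   disables subsampling (all points used; replicates are then identical).
#' @param seed integer seed.
#' @param replace draw points with replacement instead (default `FALSE`,
#'   i.e. subsampling without replacement).
#' @return Object of class `removal_result`: `replicates` (data.frame with
#'   per-replicate `pct_remnant_interactions`, `pct_remnant_plants`,
#'   `pct_remnant_bees`, `pct_unique_to_removed`), `summary` (mean and sd of
#'   each percentage), plus the call parameters.
#' @export
habitat_removal_robustness <- function(ds, removed_habitat, n_boot = 5000L,
                                       subsample_size = 24L, seed = 1L,
                                       replace = FALSE) {
  stopifnot(inherits(ds, "bee_dataset"))
  removed_habitat <- unique(vapply(removed_habitat, match.arg, "",
                                   choices = HABITATS))
  recs <- pollen_records_with_context(ds)
  if (nrow(recs) == 0L)
    stop(errorCondition("no pollen records: empty network",
                        class = c("snh_domain_error", "error")))

  # integer encodings so each replicate is a set union over point indices
  edge_key <- paste(recs$bee_species, recs$pollen_taxon, sep = "\r")
  edge_id <- match(edge_key, unique(edge_key))
  bee_id <- match(recs$bee_species, unique(recs$bee_species))
  plant_id <- match(recs$pollen_taxon, unique(recs$pollen_taxon))
  pts <- ds$sites$point_id
  by_point <- function(ids) lapply(stats::setNames(pts, pts), function(p)
    unique(ids[recs$point_id == p]))
  edges_of <- by_point(edge_id)
  bees_of <- by_point(bee_id)
  plants_of <- by_point(plant_id)

  pts_by_hab <- split(ds$sites$point_id, factor(ds$sites$habitat, HABITATS))
  if (!is.null(subsample_size)) {
    short <- vapply(pts_by_hab, length, 0L) < subsample_size
    if (any(short))
      stop(errorCondition(paste0(
        "habitat(s) with fewer than subsample_size points: ",
        paste(names(pts_by_hab)[short], collapse = ", ")),
        class = c("snh_domain_error", "error")))
  }

  pct <- function(kept, total) if (total == 0L) 100 else 100 * kept / total
  one_rep <- function() {
    sel <- if (is.null(subsample_size)) pts else
      unlist(lapply(pts_by_hab, function(p)
        if (!replace && length(p) == subsample_size) p
        else sample(p, subsample_size, replace = replace)),
        use.names = FALSE)
    sel_keep <- sel[!ds$sites$habitat[match(sel, pts)] %in% removed_habitat]
    full_e <- unique(unlist(edges_of[sel], use.names = FALSE))
    red_e <- unique(unlist(edges_of[sel_keep], use.names = FALSE))
    full_b <- unique(unlist(bees_of[sel], use.names = FALSE))
    red_b <- unique(unlist(bees_of[sel_keep], use.names = FALSE))
    full_p <- unique(unlist(plants_of[sel], use.names = FALSE))
    red_p <- unique(unlist(plants_of[sel_keep], use.names = FALSE))
    c(pct(length(red_e), length(full_e)),
      pct(length(red_p), length(full_p)),
      pct(length(red_b), length(full_b)))
  }
  snh_log("habitat_removal_robustness(%s): n_boot=%d subsample=%s seed=%d",
          paste(removed_habitat, collapse = "+"), n_boot,
          ifelse(is.null(subsample_size), "none", subsample_size), seed)
  set.seed(seed)
  mat <- t(vapply(seq_len(n_boot), function(i) one_rep(), numeric(3)))
  replicates <- data.frame(
    pct_remnant_interactions = mat[, 1],
    pct_remnant_plants = mat[, 2],
    pct_remnant_bees = mat[, 3],
    pct_unique_to_removed = 100 - mat[, 1])
  summ <- data.frame(
    metric = c("pct_remnant_interactions", "pct_remnant_plants",
               "pct_remnant_bees"),
    mean = colMeans(mat), sd = apply(mat, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(removed_habitat = removed_habitat, replicates = replicates,
                 summary = summ, n_boot = n_boot,
                 subsample_size = subsample_size, seed = seed,
                 replace = replace),
            class = "removal_result")
}

#' @export
print.removal_result <- function(x, ...) {
  cat(sprintf("habitat removal: %s (%d replicates, subsample %s)\n",
              paste(x$removed_habitat, collapse = "+"), x$n_boot,
              ifelse(is.null(x$subsample_size), "off", x$subsample_size)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-26s mean %.1f%% lost %.1f%% (sd %.2f)\n",
                s$metric[i], s$mean[i], 100 - s$mean[i], s$sd[i]))
  invisible(x)
}

#' Plot a bipartite bee-pollen network
#'
#' Simple deterministic two-column layout: bee species on the left, pollen
#' taxa on the right, link width proportional to interaction frequency.
#' Node colour distinguishes taxa found only in grasslands from taxa found
#' (also) in wooded habitats.
#'
#' @param x a `bee_network`.
#' @param ... ignored.
#' @export
plot.bee_network <- function(x, ...) {
  nb <- nrow(x$bee_nodes); np <- nrow(x$plant_nodes)
  yb <- seq(0, 1, length.out = max(nb, 2))[seq_len(nb)]
  yp <- seq(0, 1, length.out = max(np, 2))[seq_len(np)]
  graphics::plot(NA, xlim = c(-0.7, 1.7), ylim = c(-0.02, 1.02), axes = FALSE,
                 xlab = "", ylab = "", main = "bee-pollen interaction network")
  w <- 0.5 + 2 * x$edges$frequency / max(x$edges$frequency)
  for (i in seq_len(nrow(x$edges))) {
    graphics::segments(0, yb[match(x$edges$bee_species[i], x$bee_nodes$name)],
                       1, yp[match(x$edges$pollen_taxon[i], x$plant_nodes$name)],
                       lwd = w[i], col = grDevices::adjustcolor("grey40", 0.5))
  }
  col_of <- function(h) ifelse(h == "grassland", "steelblue", "forestgreen")
  graphics::points(rep(0, nb), yb, pch = 15, col = col_of(x$bee_nodes$habitats))
  graphics::points(rep(1, np), yp, pch = 15, col = col_of(x$plant_nodes$habitats))
  graphics::text(rep(-0.05, nb), yb, x$bee_nodes$name, cex = 0.5, adj = 1)
  graphics::text(rep(1.05, np), yp, x$plant_nodes$name, cex = 0.5, adj = 0)
  invisible(NULL)
}

#' Boxplot of remnant-interaction percentages
#'
#' @param results list of `removal_result` objects (one per removed habitat).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_removal_boxplot <- function(results, ...) {
  stopifnot(all(vapply(results, inherits, TRUE, "removal_result")))
  vals <- lapply(results, function(r) r$replicates$pct_remnant_interactions)
  names(vals) <- vapply(results, function(r)
    paste(r$removed_habitat, collapse = "+"), character(1))
  graphics::boxplot(vals, ylab = "% remnant interactions",
                    xlab = "removed habitat", ...)
  invisible(NULL)
}
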