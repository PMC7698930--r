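#' Partition pairwise beta diversity into turnover and nestedness
#'
#' Decomposes total Sorensen dissimilarity between two presence/absence
#' communities into spatial turnover (Simpson dissimilarity) and a
#' nestedness-resultant component:
#' \deqn{\beta_{sor} = \frac{b+c}{2a+b+c}, \quad
#'       \beta_{sim} = \frac{b}{a+b}, \quad
#'       \beta_{sne} = \frac{c-b}{2a+b+c}\cdot\frac{a}{a+b}}
#' where `a` is the number of taxa shared by the two communities, `b` the
#' number unique to the poorer community (the one with fewer unique taxa)
#' and `c` the number unique to the richer one. The identity
#' `beta_sor = beta_sim + beta_sne` holds exactly.
#'
#' @param community_a,community_b character vectors of taxon names
#'   (duplicates ignored; presence/absence only).
#' @return An object of class `beta_partition`: a list with integer counts
#'   `a`, `b`, `c` and dissimilarities `beta_sor`, `beta_sim`, `beta_sne`,
#'   all in `[0, 1]`.
#' @details When one community is empty (`a = b = 0`, `c > 0`) the turnover
#'   component is taken as 0 and all dissimilarity is nestedness-resultant
#'   (`beta_sor = beta_sne = 1`); the 0/0 in the Simpson formula is resolved
#'   to 0 because no species is replaced. Two empty communities have no
#'   defined dissimilarity and raise an error.
#' @examples
#' baselga_partition(c("x", "y", "z"), c("y", "z", "w"))
#' @export
baselga_partition <- function(community_a, community_b) {
  A <- unique(as.character(community_a))
  B <- unique(as.character(community_b))
  A <- A[!is.na(A)]; B <- B[!is.na(B)]
  a <- length(intersect(A, B))
  u <- c(length(setdiff(A, B)), length(setdiff(B, A)))
  b <- min(u); cc <- max(u)
  if (a + b + cc == 0L)
    stop(errorCondition("both communities are empty: dissimilarity undefined",
                        class = c("snh_domain_error", "error")))
  beta_sor <- (b + cc) / (2 * a + b + cc)
  beta_sim <- if (a + b == 0L) 0 else b / (a + b)
  beta_sne <- beta_sor - beta_sim
  structure(list(a = a, b = b, c = cc, beta_sor = beta_sor,
                 beta_sim = beta_sim, beta_sne = beta_sne),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("beta partition: a=%d b=%d c=%d | bsor=%.4f = bsim=%.4f + bsne=%.4f\n",
              x$a, x$b, x$c, x$beta_sor, x$beta_sim, x$beta_sne))
  invisible(x)
}

#' Pooled community of one habitat type
#'
#' Unions taxa over all sampling points of a habitat (presence/absence).
#' For `taxa_source = "plants"` only entomophilous taxa are pooled by
#' default, matching how the botanical data enter every downstream analysis.
#'
#' @param ds a `bee_dataset`.
#' @param habitat one of `"hedgerow"`, `"forest_edge"`, `"grassland"`.
#' @param taxa_source `"bees"` (bee species) or `"plants"` (plant taxa).
#' @param entomophilous_only for plants, drop non-entomophilous taxa
#'   (default `TRUE`).
#' @return Character vector of taxa (possibly empty, with a warning if the
#'   habitat has no records).
#' @export
pooled_habitat_community <- function(ds, habitat,
                                     taxa_source = c("bees", "plants"),
                                     entomophilous_only = TRUE) {
  taxa_source <- match.arg(taxa_source)
  habitat <- match.arg(habitat, HABITATS)
  pts <- ds$sites$point_id[ds$sites$habitat == habitat]
  taxa <- point_communities(ds, taxa_source, entomophilous_only)
  out <- sort(unique(unlist(taxa[names(taxa) %in% pts], use.names = FALSE)))
  if (!length(out))
    warning(sprintf("habitat '%s' has no %s records: empty community",
                    habitat, taxa_source))
  out
}

# Per-sampling-point presence lists, named by point_id (all points present,
# possibly with empty communities).
point_communities <- function(ds, taxa_source = c("bees", "plants"),
                              entomophilous_only = TRUE) {
  taxa_source <- match.arg(taxa_source)
  if (taxa_source == "bees") {
    tab <- data.frame(point_id = ds$bees$point_id, taxon = ds$bees$species)
  } else {
    pl <- ds$plants
    if (entomophilous_only) pl <- pl[pl$entomophilous, , drop = FALSE]
    tab <- data.frame(point_id = pl$point_id, taxon = pl$taxon)
  }
  out <- lapply(stats::setNames(ds$sites$point_id, ds$sites$point_id),
                function(p) unique(tab$taxon[tab$point_id == p]))
  out
}

#' Pairwise beta diversity between sampling points within one habitat
#'
#' Computes the Baselga partition for every unordered pair of sampling
#' points of the given habitat. Pairs in which both points have empty
#' communities are excluded (and counted); a point with an empty community
#' paired with a non-empty one contributes full dissimilarity.
#'
#' @inheritParams pooled_habitat_community
#' @return A list with `pairs` (data.frame: `point_1`, `point_2`, `a`, `b`,
#'   `c`, `beta_sor`, `beta_sim`, `beta_sne`), `median_beta_sor`, and
#'   `n_excluded_pairs`.
#' @export
pairwise_beta_within <- function(ds, habitat,
                                 taxa_source = c("bees", "plants"),
                                 entomophilous_only = TRUE) {
  taxa_source <- match.arg(taxa_source)
  habitat <- match.arg(habitat, HABITATS)
  pts <- ds$sites$point_id[ds$sites$habitat == habitat]
  comm <- point_communities(ds, taxa_source, entomophilous_only)[pts]
  usable <- pts[vapply(comm[pts], length, 0L) > 0L]
  if (length(usable) < 2L)
    stop(errorCondition(sprintf(
      "habitat '%s': need >= 2 sampling points with >= 1 taxon, found %d",
      habitat, length(usable)), class = c("snh_domain_error", "error")))
  idx <- utils::combn(length(pts), 2L)
  keep <- logical(ncol(idx))
  rows <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    p1 <- pts[idx[1, k]]; p2 <- pts[idx[2, k]]
    if (length(comm[[p1]]) == 0L && length(comm[[p2]]) == 0L) next
    bp <- baselga_partition(comm[[p1]], comm[[p2]])
    keep[k] <- TRUE
    rows[[k]] <- data.frame(point_1 = p1, point_2 = p2, a = bp$a, b = bp$b,
                            c = bp$c, beta_sor = bp$beta_sor,
                            beta_sim = bp$beta_sim, beta_sne = bp$beta_sne,
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows[keep])
  n_excl <- sum(!keep)
  if (n_excl) snh_log("pairwise_beta_within(%s): excluded %d empty-empty pair(s)",
                      habitat, n_excl)
  list(habitat = habitat, pairs = pairs,
       median_beta_sor = stats::median(pairs$beta_sor),
       n_excluded_pairs = n_excl)
}

#' Abundance vector of a community
#'
#' @param counts named integer vector (taxon -> number of individuals) or a
#'   character vector of individual-level taxon labels, which is tabulated.
#' @return An object of class `abundance_vector` with elements `counts`,
#'   `n` (total individuals), `S_obs`, `f1` and `f2` (singleton/doubleton
#'   counts).
#' @export
abundance_vector <- function(counts) {
  if (is.character(counts) || is.factor(counts)) {
    counts <- table(as.character(counts))
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  if (is.null(names(counts))) names(counts) <- paste0("sp", seq_along(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop(errorCondition("counts must be nonnegative integers",
                        class = c("snh_domain_error", "error")))
  counts <- counts[counts > 0]
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 n = sum(counts), S_obs = length(counts),
                 f1 = sum(counts == 1L), f2 = sum(counts == 2L)),
            class = "abundance_vector")
}

# Exact hypergeometric interpolation: expected richness in a random
# subsample of m individuals (m <= n), computed on the log scale.
rarefy_interpolate <- function(counts, m) {
  n <- sum(counts)
  vapply(m, function(mm) {
    if (mm == 0) return(0)
    miss <- exp(lchoose(n - counts, mm) - lchoose(n, mm))
    miss[n - counts < mm] <- 0
    length(counts) - sum(miss)
  }, numeric(1))
}

# Chao1 estimate of undetected richness, with the standard bias correction
# and the f2 = 0 small-sample fallback.
chao1_f0 <- function(n, f1, f2) {
  if (n <= 1 || f1 == 0) return(0)
  if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2)
  else ((n - 1) / n) * f1 * (f1 - 1) / 2
}

# Extrapolated richness at n + mstar individuals (mstar >= 0).
rarefy_extrapolate <- function(counts, mstar) {
  n <- sum(counts); S <- length(counts)
  f1 <- sum(counts == 1L); f2 <- sum(counts == 2L)
  f0 <- chao1_f0(n, f1, f2)
  if (f0 == 0) return(rep(S, length(mstar)))
  S + f0 * (1 - (1 - f1 / (n * f0 + f1))^mstar)
}

#' Individual-based rarefaction and extrapolation curve
#'
#' Expected species richness as a function of the number of individuals
#' sampled. Interpolated values (`m <= n`) use the exact hypergeometric
#' formula \eqn{E[S_m] = S_{obs} - \sum_i \binom{n-x_i}{m}/\binom{n}{m}};
#' extrapolated values (`m > n`) use the Chao1-based estimator of
#' undetected richness. Confidence bands are bootstrap percentile intervals
#' over resampled abundance vectors (multinomial resampling of `n`
#' individuals from the observed relative abundances).
#'
#' The default confidence level of 0.84 follows the rule that
#' non-overlapping 84% intervals between two curves correspond to a
#' pairwise test at an error rate of about 0.05.
#'
#' @param av an [abundance_vector()] (or something coercible to one).
#' @param m_grid integer vector of sample sizes; default 40 knots from 1 to
#'   `2n` (extrapolation bounded at twice the observed sample size).
#' @param conf confidence level for the bootstrap band (default 0.84).
#' @param n_boot number of bootstrap resamples (default 200).
#' @param seed integer seed for the bootstrap.
#' @return Object of class `rarefaction_curve`: data.frame `curve` with
#'   columns `m`, `method` (`"interpolated"`/`"observed"`/`"extrapolated"`),
#'   `expected_richness`, `ci_low`, `ci_high`; plus `n`, `S_obs`, `conf`,
#'   `n_boot`, `seed`.
#' @export
rarefaction_curve <- function(av, m_grid = NULL, conf = 0.84,
                              n_boot = 200L, seed = 1L) {
  if (!inherits(av, "abundance_vector")) av <- abundance_vector(av)
  counts <- av$counts; n <- av$n
  if (n < 1L) stop(errorCondition("community has no individuals",
                                  class = c("snh_domain_error", "error")))
  if (is.null(m_grid)) {
    m_grid <- unique(round(seq(1, 2 * n, length.out = min(40, 2 * n))))
  }
  m_grid <- sort(unique(as.integer(m_grid)))
  if (any(m_grid <= 0L))
    stop(errorCondition("m_grid values must be >= 1",
                        class = c("snh_domain_error", "error")))
  est_curve <- function(cts) {
    ntot <- sum(cts)
    lo <- m_grid[m_grid <= ntot]; hi <- m_grid[m_grid > ntot]
    c(rarefy_interpolate(cts, lo), rarefy_extrapolate(cts, hi - ntot))
  }
  expected <- est_curve(counts)
  snh_log("rarefaction_curve: n=%d S_obs=%d n_boot=%d seed=%d",
          n, av$S_obs, n_boot, seed)
  set.seed(seed)
  p <- counts / n
  boot <- matrix(NA_real_, n_boot, length(m_grid))
  for (b in seq_len(n_boot)) {
    res <- stats::rmultinom(1, n, p)[, 1]
    boot[b, ] <- est_curve(res[res > 0])
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  method <- ifelse(m_grid < n, "interpolated",
                   ifelse(m_grid == n, "observed", "extrapolated"))
  structure(list(
    curve = data.frame(m = m_grid, method = method,
                       expected_richness = expected,
                       ci_low = pmin(ci[1, ], expected),
                       ci_high = pmax(ci[2, ], expected)),
    n = n, S_obs = av$S_obs, conf = conf, n_boot = n_boot, seed = seed),
    class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("rarefaction curve: n=%d, S_obs=%d, %d knots, %.0f%% CI (%d boot)\n",
              x$n, x$S_obs, nrow(x$curve), 100 * x$conf, x$n_boot))
  print(utils::head(x$curve, 6))
  invisible(x)
}

#' Permutation null model for habitat effect on pooled beta diversity
#'
#' Tests whether the Sorensen dissimilarity between the pooled communities
#' of two habitats exceeds what random assortment of sampling points would
#' produce. The null distribution is built by permuting the point-to-habitat
#' labels (points, not taxa, are shuffled), keeping the number of points per
#' habitat fixed, and recomputing the pooled dissimilarity. The p-value uses
#' the add-one convention `p = (1 + #(null >= obs)) / (1 + n_perm)` and is
#' one-sided (observed dissimilarity larger than expected).
#'
#' @param ds a `bee_dataset`.
#' @param habitat_pair character vector of two habitats.
#' @param taxa_source `"bees"` or `"plants"`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return Object of class `null_model_result`: `observed`, `null_values`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
beta_null_test <- function(ds, habitat_pair, taxa_source = c("bees", "plants"),
                           n_perm = 999L, seed = 1L) {
  taxa_source <- match.arg(taxa_source)
  stopifnot(length(habitat_pair) == 2L)
  habitat_pair <- vapply(habitat_pair, match.arg, "", choices = HABITATS)
  if (n_perm < 1L) stop(errorCondition("n_perm must be >= 1",
                                       class = c("snh_domain_error", "error")))
  comm <- point_communities(ds, taxa_source)
  pts1 <- ds$sites$point_id[ds$sites$habitat == habitat_pair[1]]
  pts2 <- ds$sites$point_id[ds$sites$habitat == habitat_pair[2]]
  if (!length(pts1) || !length(pts2))
    stop(errorCondition("both habitats need >= 1 sampling point",
                        class = c("snh_domain_error", "error")))
  pool_beta <- function(g1, g2) {
    baselga_partition(unlist(comm[g1], use.names = FALSE),
                      unlist(comm[g2], use.names = FALSE))$beta_sor
  }
  observed <- pool_beta(pts1, pts2)
  all_pts <- c(pts1, pts2); n1 <- length(pts1)
  snh_log("beta_null_test(%s~%s, %s): n_perm=%d seed=%d",
          habitat_pair[1], habitat_pair[2], taxa_source, n_perm, seed)
  set.seed(seed)
  null_values <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(all_pts)
    pool_beta(perm[seq_len(n1)], perm[-seq_len(n1)])
  }, numeric(1))
  p <- (1 + sum(null_values >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, n_perm = n_perm, seed = seed,
                 habitat_pair = habitat_pair, taxa_source = taxa_source),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("permutation null model (%s ~ %s, %s): observed bsor = %.4f, p = %.4g (%d perms)\n",
              x$habitat_pair[1], x$habitat_pair[2], x$taxa_source,
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Per-point and per-habitat abundance and richness summaries
#'
#' Bee abundance (number of captures) and species richness per sampling
#' point, with per-habitat medians, and a Kruskal-Wallis rank test for
#' habitat differences delegated to [stats::kruskal.test()].
#'
#' @param ds a `bee_dataset`.
#' @return A list with `per_point` (point_id, habitat, abundance, richness),
#'   `per_habitat` (medians and point counts), `kruskal` (the two `htest`
#'   results for abundance and richness) and `pairwise` (Bonferroni-adjusted
#'   pairwise Wilcoxon post-hoc tables); the test entries are `NULL` when
#'   fewer than two habitats are present.
#' @export
richness_abundance_summary <- function(ds) {
  pts <- ds$sites$point_id
  ab <- vapply(pts, function(p) sum(ds$bees$point_id == p), 0L)
  ri <- vapply(pts, function(p) length(unique(ds$bees$species[ds$bees$point_id == p])), 0L)
  per_point <- data.frame(point_id = pts, habitat = ds$sites$habitat,
                          abundance = ab, richness = ri,
                          stringsAsFactors = FALSE, row.names = NULL)
  agg <- function(v) vapply(HABITATS, function(h)
    stats::median(v[per_point$habitat == h]), numeric(1))
  per_habitat <- data.frame(
    habitat = HABITATS,
    n_points = vapply(HABITATS, function(h) sum(per_point$habitat == h), 0L),
    median_abundance = agg(per_point$abundance),
    median_richness = agg(per_point$richness),
    row.names = NULL, stringsAsFactors = FALSE)
  kr <- ph <- NULL
  if (length(unique(per_point$habitat)) >= 2L) {
    kr <- list(
      abundance = stats::kruskal.test(per_point$abundance,
                                      factor(per_point$habitat)),
      richness = stats::kruskal.test(per_point$richness,
                                     factor(per_point$habitat)))
    # post-hoc pairwise comparisons, Bonferroni-adjusted; delegated to the
    # standard routine rather than re-implemented
    ph <- suppressWarnings(list(
      abundance = stats::pairwise.wilcox.test(
        per_point$abundance, factor(per_point$habitat),
        p.adjust.method = "bonferroni"),
      richness = stats::pairwise.wilcox.test(
        per_point$richness, factor(per_point$habitat),
        p.adjust.method = "bonferroni")))
  }
  list(per_point = per_point, per_habitat = per_habitat, kruskal = kr,
       pairwise = ph)
}
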