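#' Pollen availability index (PA)
#'
#' Availability of each plant taxon across the study site, on
#' presence/absence data. An occurrence record is a (taxon, sampling point)
#' pair: a taxon present at a point counts once regardless of vegetation
#' layer or cover code. For taxon `i`,
#' `PA_i = (occurrence records of i) / (total occurrence records among the
#' included taxa)`, so the PA values of the included taxa sum to 1.
#'
#' @param ds a harmonized `bee_dataset`.
#' @param included_taxa taxa defining the denominator. Default `"carried"`:
#'   the harmonized plant taxa actually found on captured bees (the taxa that
#'   supply the pollen). `"entomophilous"` widens the denominator to all
#'   entomophilous taxa in the botanical survey. A character vector gives an
#'   explicit set.
#' @return data.frame `taxon`, `n_occurrences`, `PA` (rows sorted by taxon;
#'   included taxa with zero flora records appear with `PA = 0`).
#' @export
pollen_availability <- function(ds, included_taxa = c("carried", "entomophilous")) {
  occ <- plant_occurrence_records(ds)
  if (is.character(included_taxa) && length(included_taxa) >= 1 &&
      all(included_taxa %in% c("carried", "entomophilous"))) {
    included_taxa <- switch(match.arg(included_taxa),
      carried = sort(unique(ds$pollen$pollen_taxon)),
      entomophilous = sort(unique(occ$taxon)))
  }
  included_taxa <- norm_taxon(included_taxa)
  if (!length(included_taxa))
    stop(errorCondition("included_taxa is empty",
                        class = c("snh_domain_error", "error")))
  occ <- occ[occ$taxon %in% included_taxa, , drop = FALSE]
  denom <- nrow(occ)
  if (denom == 0L)
    stop(errorCondition("no plant occurrence records among included taxa",
                        class = c("snh_domain_error", "error")))
  n_occ <- vapply(included_taxa, function(t) sum(occ$taxon == t), 0L)
  data.frame(taxon = included_taxa, n_occurrences = n_occ,
             PA = n_occ / denom, row.names = NULL, stringsAsFactors = FALSE)
}

# Unique (point, taxon) presence records among entomophilous plants; the
# layer-collapsed view used by PA and by habitat provenance.
plant_occurrence_records <- function(ds) {
  pl <- ds$plants[ds$plants$entomophilous, c("point_id", "taxon"), drop = FALSE]
  unique(pl)
}

#' Pollen harvest rate (HR)
#'
#' Frequency with which each pollen taxon is carried by the sampled bees.
#' A pollen record is a distinct (bee, taxon) pair, so a taxon counts once
#' per bee however much of it the bee carried.
#'
#' @param ds a harmonized `bee_dataset`.
#' @param denominator `"records"` (default): total number of pollen records,
#'   so the HR values sum to 1; or `"bees"`: number of bees examined for
#'   pollen (bees flagged `kept_for_pollen`, falling back to all bees when
#'   the flag is absent), so HR is the fraction of examined bees carrying
#'   the taxon.
#' @return data.frame `taxon`, `n_bees_carrying`, `HR`. Taxa never carried
#'   do not appear.
#' @export
harvest_rate <- function(ds, denominator = c("records", "bees")) {
  denominator <- match.arg(denominator)
  if (nrow(ds$pollen) == 0L)
    stop(errorCondition("no pollen records",
                        class = c("snh_domain_error", "error")))
  taxa <- sort(unique(ds$pollen$pollen_taxon))
  n_carry <- vapply(taxa, function(t)
    length(unique(ds$pollen$bee_id[ds$pollen$pollen_taxon == t])), 0L)
  denom <- switch(denominator,
    records = nrow(ds$pollen),
    bees = length(examined_bees(ds)))
  data.frame(taxon = taxa, n_bees_carrying = n_carry, HR = n_carry / denom,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Bees examined for pollen: those flagged kept_for_pollen when the flag is
# informative, otherwise every captured bee. Bees carrying no pollen stay in
# this set — they carry information for the per-bee HR convention and for
# the bootstrap.
examined_bees <- function(ds) {
  flag <- ds$bees$kept_for_pollen
  if (any(!is.na(flag) & flag)) ds$bees$bee_id[!is.na(flag) & flag]
  else ds$bees$bee_id
}

#' Jacobs' selection index
#'
#' \deqn{D = \frac{HR - PA}{HR + PA - 2\,HR\,PA}}
#' `D` lies in `[-1, 1]`: positive when a taxon is harvested more than
#' expected from its availability (over-selected), negative when harvested
#' less (under-selected), 0 when use matches availability. Vectorized.
#'
#' @param HR harvest rate(s) in `[0, 1]`.
#' @param PA availability value(s) in `[0, 1]`.
#' @return Numeric vector of D values.
#' @export
jacobs_index <- function(HR, PA) {
  if (any(HR < 0 | HR > 1 | PA < 0 | PA > 1, na.rm = TRUE))
    stop(errorCondition("HR and PA must lie in [0, 1]",
                        class = c("snh_domain_error", "error")))
  degenerate <- (HR == 0 & PA == 0) | (HR == 1 & PA == 1)
  if (any(degenerate, na.rm = TRUE))
    stop(errorCondition("Jacobs' index undefined when HR = PA = 0 or HR = PA = 1",
                        class = c("snh_domain_error", "error")))
  (HR - PA) / (HR + PA - 2 * HR * PA)
}

#' Pollen selection analysis with bootstrap confidence intervals
#'
#' Computes Jacobs' selection index D for every pollen taxon found in the
#' flora, with bootstrap percentile confidence intervals. Each replicate
#' resamples the examined bees with replacement, carrying each bee's whole
#' pollen load (loads within a bee are dependent, so the bee is the
#' resampling unit); HR is recomputed per replicate while PA stays fixed
#' (the botanical survey is not resampled). A taxon is classified
#' `over_selected` when its lower CI bound is above 0, `under_selected`
#' when its upper bound is below 0, and `neutral` otherwise.
#'
#' Pollen taxa absent from the (harmonized) flora cannot receive an
#' availability value; they are excluded from D and listed in
#' `$excluded_taxa`.
#'
#' @param ds a harmonized `bee_dataset`.
#' @param n_boot number of bootstrap replicates (default 5000).
#' @param seed integer seed.
#' @param conf_level central CI mass (default 0.95, i.e. the 2.5% and 97.5%
#'   percentiles).
#' @param hr_denominator,pa_denominator conventions passed to
#'   [harvest_rate()] and [pollen_availability()].
#' @return Object of class `selection_table`: data.frame `results` with
#'   `taxon`, `PA`, `HR`, `D`, `ci_low`, `ci_high`, `selection_class`,
#'   `habitat_provenance` (comma-separated habitats where the taxon occurred
#'   in the flora), `unstable` (taxon absent from more than half of the
#'   replicates); plus `excluded_taxa`, `n_boot`, `seed`.
#' @export
bootstrap_selection <- function(ds, n_boot = 5000L, seed = 1L,
                                conf_level = 0.95,
                                hr_denominator = c("records", "bees"),
                                pa_denominator = c("carried", "entomophilous")) {
  hr_denominator <- match.arg(hr_denominator)
  pa_denominator <- match.arg(pa_denominator)
  if (n_boot < 2L) stop(errorCondition("n_boot must be >= 2",
                                       class = c("snh_domain_error", "error")))
  ds <- harmonize_taxa(ds, ds$taxon_map)  # ensure absent-from-flora is current
  excluded <- ds$absent_from_flora
  pollen <- ds$pollen[!ds$pollen$pollen_taxon %in% excluded, , drop = FALSE]
  if (nrow(pollen) == 0L)
    stop(errorCondition("no pollen records matching the flora",
                        class = c("snh_domain_error", "error")))
  taxa <- sort(unique(pollen$pollen_taxon))

  pa_tab <- pollen_availability(ds, pa_denominator)
  PA <- stats::setNames(rep(0, length(taxa)), taxa)
  hit <- taxa %in% pa_tab$taxon
  PA[hit] <- pa_tab$PA[match(taxa[hit], pa_tab$taxon)]

  bees <- examined_bees(ds)
  # integer representation: per bee, the integer codes of taxa it carries
  load_by_bee <- split(match(pollen$pollen_taxon, taxa),
                       factor(pollen$bee_id, levels = bees))
  n_bees <- length(bees)
  n_records_total <- nrow(pollen)

  hr_from_bees <- function(idx) {
    codes <- unlist(load_by_bee[idx], use.names = FALSE)
    cnt <- tabulate(codes, nbins = length(taxa))
    denom <- switch(hr_denominator, records = length(codes), bees = length(idx))
    if (denom == 0L) rep(NA_real_, length(taxa)) else cnt / denom
  }
  HR <- hr_from_bees(seq_len(n_bees))
  D <- jacobs_index(HR, PA)  # degenerate pairs impossible: HR > 0, PA may be 0

  snh_log("bootstrap_selection: %d taxa, %d bees, n_boot=%d seed=%d (HR/%s, PA/%s)",
          length(taxa), n_bees, n_boot, seed, hr_denominator, pa_denominator)
  set.seed(seed)
  Dboot <- matrix(NA_real_, n_boot, length(taxa))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_bees, n_bees, replace = TRUE)
    HRb <- hr_from_bees(idx)
    present <- HRb > 0 | PA > 0
    Db <- rep(NA_real_, length(taxa))
    Db[present] <- jacobs_index(HRb[present], PA[present])
    Dboot[b, ] <- Db
  }
  alpha <- (1 - conf_level) / 2
  ci <- apply(Dboot, 2, function(v)
    stats::quantile(v, probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE))
  n_missing <- colSums(is.na(Dboot))
  class_of <- function(lo, hi) {
    if (lo > 0) "over_selected" else if (hi < 0) "under_selected" else "neutral"
  }
  prov <- habitat_provenance(ds, taxa)
  results <- data.frame(
    taxon = taxa, PA = unname(PA), HR = HR, D = D,
    ci_low = ci[1, ], ci_high = ci[2, ],
    selection_class = mapply(class_of, ci[1, ], ci[2, ]),
    habitat_provenance = prov,
    unstable = n_missing > n_boot / 2,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(results = results, excluded_taxa = excluded,
                 n_boot = n_boot, seed = seed, conf_level = conf_level,
                 n_bees = n_bees, n_pollen_records = n_records_total,
                 hr_denominator = hr_denominator,
                 pa_denominator = pa_denominator),
            class = "selection_table")
}

# Comma-separated habitats in whose flora each taxon occurred.
habitat_provenance <- function(ds, taxa) {
  occ <- plant_occurrence_records(ds)
  occ$habitat <- ds$sites$habitat[match(occ$point_id, ds$sites$point_id)]
  vapply(taxa, function(t) {
    h <- sort(unique(occ$habitat[occ$taxon == t]))
    paste(h, collapse = ",")
  }, character(1))
}

#' @export
print.selection_table <- function(x, ...) {
  cat(sprintf("pollen selection: %d taxa (%d excluded, absent from flora), %d bees, %d boot\n",
              nrow(x$results), length(x$excluded_taxa), x$n_bees, x$n_boot))
  tab <- table(x$results$selection_class)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Plot Jacobs' selection indices
#'
#' Horizontal bar chart of D sorted descending, with taxa whose confidence
#' interval excludes zero drawn in colour and the rest in grey.
#'
#' @param x a `selection_table`.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot.selection_table <- function(x, ...) {
  r <- x$results[order(x$results$D, decreasing = TRUE), ]
  sig <- r$selection_class != "neutral"
  mid <- graphics::barplot(r$D, names.arg = r$taxon, las = 2,
    col = ifelse(sig, "purple3", "grey70"), border = NA,
    ylab = "Jacobs' selection index D", cex.names = 0.55, ...)
  graphics::abline(h = 0)
  invisible(mid)
}
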