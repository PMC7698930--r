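# The three semi-natural habitat (SNH) types surveyed in the sampling design.
HABITATS <- c("hedgerow", "forest_edge", "grassland")

# Vegetation layers of the botanical releves.
LAYERS <- c("herbaceous", "shrub", "tree")

# Braun-Blanquet cover-abundance codes accepted on plant rows. They are only
# ever used as presence markers, never quantitatively.
BB_CODES <- c("r", "+", "1", "2", "3", "4", "5")

#' Construct a validated survey dataset
#'
#' Bundles the four long-format survey tables — sampling points, individual
#' bee captures, plant occurrences and per-bee pollen loads — into a single
#' validated object that every analysis stage consumes.
#'
#' @param sites data.frame with columns `point_id`, `landscape_id`,
#'   `habitat`. `habitat` must be one of `"hedgerow"`, `"forest_edge"`,
#'   `"grassland"`.
#' @param bees data.frame with columns `bee_id`, `point_id`, `species` and
#'   optionally `kept_for_pollen` (logical: individual retained for pollen
#'   sampling). One row per captured individual.
#' @param plants data.frame with columns `point_id`, `taxon` and optionally
#'   `layer`, `abundance_code`, `entomophilous`. Any Braun-Blanquet code
#'   (including `"+"` and `"r"`) counts as presence.
#' @param pollen data.frame with columns `bee_id`, `pollen_taxon`; one row
#'   per pollen taxon found on a bee.
#' @param taxon_map optional named character vector mapping raw taxon names
#'   to harmonized names (typically genus-level merges).
#'
#' @return An object of class `bee_dataset`: a list with elements `sites`,
#'   `bees`, `plants`, `pollen`, `taxon_map` and `absent_from_flora` (pollen
#'   taxa with no match in the botanical data, populated by
#'   [harmonize_taxa()]).
#' @seealso [read_dataset()], [harmonize_taxa()]
#' @export
bee_dataset <- function(sites, bees, plants, pollen,
                        taxon_map = character(0)) {
  sites  <- as.data.frame(sites,  stringsAsFactors = FALSE)
  bees   <- as.data.frame(bees,   stringsAsFactors = FALSE)
  plants <- as.data.frame(plants, stringsAsFactors = FALSE)
  pollen <- as.data.frame(pollen, stringsAsFactors = FALSE)

  if (!"kept_for_pollen" %in% names(bees)) {
    bees$kept_for_pollen <- rep(NA, nrow(bees))
  }
  bees$kept_for_pollen <- as.logical(bees$kept_for_pollen)
  if (!"layer" %in% names(plants))
    plants$layer <- rep(NA_character_, nrow(plants))
  if (!"abundance_code" %in% names(plants))
    plants$abundance_code <- rep(NA_character_, nrow(plants))
  if (!"entomophilous" %in% names(plants))
    plants$entomophilous <- rep(TRUE, nrow(plants))
  plants$entomophilous <- as_flag(plants$entomophilous)

  for (col in c("point_id", "landscape_id")) sites[[col]] <- as.character(sites[[col]])
  sites$habitat <- as.character(sites$habitat)
  for (col in c("bee_id", "point_id", "species")) bees[[col]] <- as.character(bees[[col]])
  plants$point_id <- as.character(plants$point_id)
  plants$taxon <- norm_taxon(plants$taxon)
  plants$layer <- as.character(plants$layer)
  plants$abundance_code <- as.character(plants$abundance_code)
  pollen$bee_id <- as.character(pollen$bee_id)
  pollen$pollen_taxon <- norm_taxon(pollen$pollen_taxon)

  ds <- structure(
    list(sites = sites, bees = bees, plants = plants, pollen = pollen,
         taxon_map = taxon_map, absent_from_flora = character(0)),
    class = "bee_dataset")
  validate_dataset(ds)
  ds
}

# Coerce CSV-ish truthy encodings to logical.
as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes", "y")
}

# Whitespace-normalized, case-folded taxon names keep matching between the
# botanical and pollen tables robust to data-entry noise. Display casing is
# "Genus species"-style: first letter upper, rest as given.
norm_taxon <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  low <- tolower(x)
  ok <- !is.na(low) & nzchar(low)
  low[ok] <- paste0(toupper(substr(low[ok], 1, 1)), substr(low[ok], 2, nchar(low[ok])))
  low
}

#' Validate a survey dataset
#'
#' Checks the structural invariants: unique identifiers, legal habitat and
#' layer values, and referential integrity (every bee record points to a
#' known sampling point, every pollen record to a known bee). Violations are
#' reported with the offending identifiers and row numbers.
#'
#' @param ds a [bee_dataset()] object.
#' @return `ds`, invisibly, if valid. Otherwise an error of class
#'   `snh_validation_error` is thrown.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "bee_dataset"))
  fail <- function(msg) stop(errorCondition(msg,
    class = c("snh_validation_error", "error")))

  dup <- ds$sites$point_id[duplicated(ds$sites$point_id)]
  if (length(dup)) fail(paste0("duplicated point_id: ", head_ids(dup)))
  bad <- !ds$sites$habitat %in% HABITATS
  if (any(bad)) fail(paste0("unknown habitat value(s) in sites rows ",
    head_ids(which(bad)), ": ", head_ids(unique(ds$sites$habitat[bad])),
    " (expected one of ", paste(HABITATS, collapse = ", "), ")"))

  dup <- ds$bees$bee_id[duplicated(ds$bees$bee_id)]
  if (length(dup)) fail(paste0("duplicated bee_id: ", head_ids(dup)))
  orphan <- !ds$bees$point_id %in% ds$sites$point_id
  if (any(orphan)) fail(paste0("bee rows ", head_ids(which(orphan)),
    " reference unknown point_id: ", head_ids(unique(ds$bees$point_id[orphan]))))

  orphan <- !ds$plants$point_id %in% ds$sites$point_id
  if (any(orphan)) fail(paste0("plant rows ", head_ids(which(orphan)),
    " reference unknown point_id: ", head_ids(unique(ds$plants$point_id[orphan]))))
  badlay <- !is.na(ds$plants$layer) & !ds$plants$layer %in% LAYERS
  if (any(badlay)) fail(paste0("unknown layer value(s): ",
    head_ids(unique(ds$plants$layer[badlay]))))
  key <- paste(ds$plants$point_id, ds$plants$taxon, ds$plants$layer, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) fail(paste0("duplicated (point_id, taxon, layer) at plant rows ",
    head_ids(dup)))

  orphan <- !ds$pollen$bee_id %in% ds$bees$bee_id
  if (any(orphan)) fail(paste0("pollen rows ", head_ids(which(orphan)),
    " reference unknown bee_id: ", head_ids(unique(ds$pollen$bee_id[orphan]))))
  key <- paste(ds$pollen$bee_id, ds$pollen$pollen_taxon, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) fail(paste0("duplicated (bee_id, pollen_taxon) at pollen rows ",
    head_ids(dup)))

  invisible(ds)
}

head_ids <- function(x, k = 5) {
  x <- as.character(x)
  if (length(x) > k) paste0(paste(x[seq_len(k)], collapse = ", "), ", ...")
  else paste(x, collapse = ", ")
}

#' @export
print.bee_dataset <- function(x, ...) {
  cat("<bee_dataset>\n")
  cat(sprintf("  sampling points: %d (%s)\n", nrow(x$sites),
    paste(sprintf("%s=%d", HABITATS, tabulate(match(x$sites$habitat, HABITATS), 3)),
          collapse = ", ")))
  cat(sprintf("  bees:   %d individuals, %d species\n", nrow(x$bees),
    length(unique(x$bees$species))))
  cat(sprintf("  plants: %d occurrence rows, %d taxa\n", nrow(x$plants),
    length(unique(x$plants$taxon))))
  cat(sprintf("  pollen: %d records, %d taxa\n", nrow(x$pollen),
    length(unique(x$pollen$pollen_taxon))))
  if (length(x$absent_from_flora))
    cat(sprintf("  pollen taxa absent from flora: %d\n", length(x$absent_from_flora)))
  invisible(x)
}

#' Read a survey dataset from CSV files
#'
#' Reads the four long-format tables (UTF-8, comma-delimited, header row
#' mandatory) and returns a validated [bee_dataset()].
#'
#' Expected columns:
#' \describe{
#'   \item{sites.csv}{`point_id, landscape_id, habitat`}
#'   \item{bees.csv}{`bee_id, point_id, species` (optional `kept_for_pollen`)}
#'   \item{plants.csv}{`point_id, taxon` (optional `layer, abundance_code,
#'     entomophilous`)}
#'   \item{pollen.csv}{`bee_id, pollen_taxon`}
#' }
#'
#' @param sites,bees,plants,pollen paths to the four CSV files.
#' @param genus_merges optional named character vector passed on to
#'   [harmonize_taxa()] after reading.
#' @return A validated `bee_dataset`.
#' @export
read_dataset <- function(sites, bees, plants, pollen,
                         genus_merges = NULL) {
  ds <- bee_dataset(
    sites  = read_table_checked(sites,  c("point_id", "landscape_id", "habitat")),
    bees   = read_table_checked(bees,   c("bee_id", "point_id", "species")),
    plants = read_table_checked(plants, c("point_id", "taxon")),
    pollen = read_table_checked(pollen, c("bee_id", "pollen_taxon")))
  if (!is.null(genus_merges)) ds <- harmonize_taxa(ds, genus_merges)
  ds
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop(errorCondition(
    paste0("input file not found: ", path),
    class = c("snh_format_error", "error")))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop(errorCondition(
    paste0(path, ": missing required column(s): ",
           paste(missing, collapse = ", ")),
    class = c("snh_format_error", "error")))
  df
}

#' Write a survey dataset to CSV files
#'
#' Inverse of [read_dataset()]: writes the four tables into `dir` as
#' `sites.csv`, `bees.csv`, `plants.csv`, `pollen.csv`.
#'
#' @param ds a `bee_dataset`.
#' @param dir output directory (created if absent).
#' @return The four file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "bee_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("sites.csv", "bees.csv", "plants.csv", "pollen.csv"))
  utils::write.csv(ds$sites,  paths[1], row.names = FALSE)
  utils::write.csv(ds$bees,   paths[2], row.names = FALSE)
  utils::write.csv(ds$plants, paths[3], row.names = FALSE)
  utils::write.csv(ds$pollen, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Harmonize plant and pollen taxon names
#'
#' Applies genus-level merges so that pollen taxa (often only determined to
#' genus) can be matched against the botanical survey. After harmonization,
#' pollen taxa with no matching plant taxon are flagged as absent from the
#' flora and excluded downstream from selection-index calculations.
#'
#' @param ds a `bee_dataset`.
#' @param genus_merges named character vector `c(raw_name = harmonized_name)`.
#'   Matching is case-insensitive after whitespace normalization. The mapping
#'   must be idempotent: a harmonized name must not itself be remapped to a
#'   different name.
#' @return The harmonized `bee_dataset`; `$absent_from_flora` holds the
#'   pollen taxa (harmonized names) not found in the plant table, and
#'   `$taxon_map` the normalized mapping applied.
#' @export
harmonize_taxa <- function(ds, genus_merges = character(0)) {
  stopifnot(inherits(ds, "bee_dataset"))
  if (length(genus_merges)) {
    if (is.null(names(genus_merges)))
      stop(errorCondition("genus_merges must be a named character vector",
                          class = c("snh_config_error", "error")))
    from <- norm_taxon(names(genus_merges))
    to <- norm_taxon(unname(genus_merges))
    if (anyDuplicated(from)) {
      conf <- from[duplicated(from)]
      stop(errorCondition(paste0("conflicting merges for: ", head_ids(conf)),
                          class = c("snh_config_error", "error")))
    }
    # a target that is itself remapped to something else makes the map
    # non-idempotent (a chain or cycle)
    chained <- to %in% from & vapply(to, function(t)
      to[match(t, from)] != t, logical(1))
    if (any(chained)) stop(errorCondition(
      paste0("cyclic or chained merges via: ", head_ids(to[chained])),
      class = c("snh_config_error", "error")))
    map <- stats::setNames(to, from)
    remap <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
    ds$plants$taxon <- remap(ds$plants$taxon)
    ds$pollen$pollen_taxon <- remap(ds$pollen$pollen_taxon)
    # merges can create duplicate presence rows; presence is idempotent
    ds$plants <- unique(ds$plants[!duplicated(
      paste(ds$plants$point_id, ds$plants$taxon, ds$plants$layer, sep = "\r")), ,
      drop = FALSE])
    ds$pollen <- ds$pollen[!duplicated(
      paste(ds$pollen$bee_id, ds$pollen$pollen_taxon, sep = "\r")), , drop = FALSE]
    ds$taxon_map <- map
  }
  ds$absent_from_flora <-
    sort(setdiff(unique(ds$pollen$pollen_taxon), unique(ds$plants$taxon)))
  validate_dataset(ds)
  ds
}

#' Read a pipeline configuration file
#'
#' Configuration is a JSON document of key-value pairs: `seed`, `n_boot`,
#' `n_perm`, `min_individuals`, `subsample_size`, `hr_denominator`
#' (`"records"` or `"bees"`), `pa_denominator` (`"carried"` or
#' `"entomophilous"`), `genus_merges` (object mapping raw to harmonized
#' names), and input paths. Unknown keys are kept and passed through.
#'
#' @param path path to a JSON config file.
#' @return A named list with defaults filled in.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    seed = 1L, n_boot = 5000L, n_perm = 999L,
    min_individuals = 5L, subsample_size = 24L,
    conf_rarefaction = 0.84, n_boot_rarefaction = 200L,
    hr_denominator = "records", pa_denominator = "carried",
    genus_merges = character(0))
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop(errorCondition(
    paste0("config file not found: ", path),
    class = c("snh_config_error", "error")))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(user$genus_merges))
    user$genus_merges <- unlist(user$genus_merges)
  utils::modifyList(defaults, user)
}

# Structured logging to stderr; every stochastic stage logs its seed here.
snh_log <- function(fmt, ..., verbose = getOption("snhbees.verbose", TRUE)) {
  if (isTRUE(verbose)) message(sprintf(paste0("[snhbees] ", fmt), ...))
}
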