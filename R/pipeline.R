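#' Run the full analysis pipeline
#'
#' Chains every stage on real or simulated data: read/validate and
#' harmonize, diversity analyses (pooled inter-habitat beta partition with
#' permutation null tests, intra-habitat pairwise beta, rarefaction per
#' habitat, abundance/richness summaries), pollen-selection analysis, and
#' the network robustness analysis. Writes tidy CSV outputs plus a JSON run
#' manifest recording the configuration, seeds and input checksums, so every
#' stochastic result is traceable.
#'
#' @param config a configuration list from [read_config()], or a path to a
#'   JSON config file. Recognised keys: either `simulate = TRUE` (use the
#'   study-design preset) or `sites`/`bees`/`plants`/`pollen` file paths;
#'   plus `seed`, `n_boot`, `n_perm`, `min_individuals`, `subsample_size`,
#'   `hr_denominator`, `pa_denominator`, `genus_merges`.
#' @param out_dir directory for outputs (created).
#' @param verbose log progress to standard error.
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = read_config(), out_dir = "snh_output",
                         verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  old <- options(snhbees.verbose = verbose); on.exit(options(old))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages_run <- character(0)
  outputs <- character(0)
  checksums <- list()

  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    snh_log("stage: %s", name)
    res <- tryCatch(expr, error = function(e) stop(errorCondition(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("snh_stage_error", "error"))))
    stages_run <<- c(stages_run, name)
    res
  }

  # --- input --------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    ds <- stage("simulate", {
      sim <- emulate_study_design(seed = config$seed)
      write_dataset(sim$dataset, file.path(out_dir, "simulated_input"))
      jsonlite::write_json(sim$ground_truth[c("plant_pools", "bee_pools",
                                              "expected_beta")],
                           file.path(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      sim$dataset
    })
  } else {
    paths <- unlist(config[c("sites", "bees", "plants", "pollen")])
    missing <- setdiff(c("sites", "bees", "plants", "pollen"), names(paths))
    if (length(missing)) stop(errorCondition(
      paste0("config must name input CSVs; missing: ",
             paste(missing, collapse = ", ")),
      class = c("snh_config_error", "error")))
    checksums <- lapply(paths, function(p)
      unname(tools::md5sum(path.expand(p))))
    ds <- stage("read", read_dataset(paths["sites"], paths["bees"],
                                     paths["plants"], paths["pollen"]))
    ds <- stage("harmonize", harmonize_taxa(ds, config$genus_merges))
  }

  # --- diversity ----------------------------------------------------------
  stage("diversity", {
    pairs <- utils::combn(HABITATS, 2)
    rows <- list()
    for (src in c("bees", "plants")) {
      for (k in seq_len(ncol(pairs))) {
        h1 <- pairs[1, k]; h2 <- pairs[2, k]
        bp <- baselga_partition(pooled_habitat_community(ds, h1, src),
                                pooled_habitat_community(ds, h2, src))
        nt <- beta_null_test(ds, c(h1, h2), src, n_perm = config$n_perm,
                             seed = config$seed)
        rows[[length(rows) + 1L]] <- data.frame(
          taxa_source = src, habitat_1 = h1, habitat_2 = h2,
          a = bp$a, b = bp$b, c = bp$c, beta_sor = bp$beta_sor,
          beta_sim = bp$beta_sim, beta_sne = bp$beta_sne,
          null_p_value = nt$p_value, stringsAsFactors = FALSE)
      }
    }
    emit(do.call(rbind, rows), "beta_between_habitats.csv")

    within <- lapply(HABITATS, function(h)
      tryCatch(pairwise_beta_within(ds, h, "bees"), error = function(e) NULL))
    within <- within[!vapply(within, is.null, TRUE)]
    if (length(within)) {
      emit(do.call(rbind, lapply(within, function(w)
        cbind(habitat = w$habitat, w$pairs))), "beta_within_habitats.csv")
    }

    curves <- lapply(HABITATS, function(h) {
      sp <- ds$bees$species[ds$bees$point_id %in%
                              ds$sites$point_id[ds$sites$habitat == h]]
      if (!length(sp)) return(NULL)
      rc <- rarefaction_curve(abundance_vector(sp),
                              conf = config$conf_rarefaction,
                              n_boot = config$n_boot_rarefaction,
                              seed = config$seed)
      cbind(habitat = h, rc$curve)
    })
    emit(do.call(rbind, curves[!vapply(curves, is.null, TRUE)]),
         "rarefaction.csv")

    summ <- richness_abundance_summary(ds)
    emit(summ$per_point, "abundance_richness_per_point.csv")
    emit(summ$per_habitat, "abundance_richness_per_habitat.csv")
  })

  # --- pollen selection ---------------------------------------------------
  if (nrow(ds$pollen)) {
    sel <- stage("selection", bootstrap_selection(
      ds, n_boot = config$n_boot, seed = config$seed,
      hr_denominator = config$hr_denominator,
      pa_denominator = config$pa_denominator))
    emit(sel$results, "pollen_selection.csv")
    grDevices::pdf(file.path(out_dir, "selection_barplot.pdf"), 10, 5)
    plot(sel); grDevices::dev.off()
    outputs <- c(outputs, file.path(out_dir, "selection_barplot.pdf"))
  }

  # --- network ------------------------------------------------------------
  sub <- abundant_species_filter(ds, config$min_individuals)
  if (nrow(sub$pollen)) {
    stage("network", {
      net <- build_network(sub)
      emit(net$edges, "network_edges.csv")
      can_sub <- all(vapply(HABITATS, function(h)
        sum(sub$sites$habitat == h), 0L) >= config$subsample_size)
      rem <- lapply(HABITATS, function(h) habitat_removal_robustness(
        sub, h, n_boot = config$n_boot,
        subsample_size = if (can_sub) config$subsample_size else NULL,
        seed = config$seed))
      emit(do.call(rbind, lapply(rem, function(r)
        cbind(removed_habitat = paste(r$removed_habitat, collapse = "+"),
              r$summary))), "removal_robustness.csv")
      grDevices::pdf(file.path(out_dir, "network.pdf"), 10, 8)
      plot(net); plot_removal_boxplot(rem); grDevices::dev.off()
      outputs <- c(outputs, file.path(out_dir, "network.pdf"))
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("snhbees")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "genus_merges")],
    genus_merges = as.list(config$genus_merges),
    seed = config$seed,
    input_checksums = checksums,
    stages_run = stages_run,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  snh_log("pipeline complete: %d outputs in %s", length(outputs), out_dir)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `beta`, `rarefy`, `selection`,
#' `network` and `run`. Invoke from a shell as, e.g.,
#' \preformatted{Rscript -e 'snhbees::snh_cli()' run --config config.json --out-dir out}
#'
#' Global flags: `--config`, `--seed`, `--n-boot`, `--out-dir`, `--verbose`.
#' `simulate` writes the four survey CSVs plus the ground truth; the other
#' subcommands run the corresponding stage on the configured inputs; `run`
#' chains everything.
#'
#' @param args character vector of command-line arguments (default: the
#'   actual command line).
#' @return Exit status 0 on success (invisibly); errors terminate with a
#'   nonzero status under `Rscript`.
#' @export
snh_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: snh_cli <simulate|beta|rarefy|selection|network|run> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--n-boot", type = "integer", default = NULL,
                          dest = "n_boot"),
    optparse::make_option("--out-dir", type = "character",
                          default = "snh_output", dest = "out_dir"),
    optparse::make_option("--verbose", action = "store_true",
                          default = TRUE)))
  opt <- optparse::parse_args(parser, args = args[-1])
  config <- read_config(opt$config)
  if (!is.null(opt$seed)) config$seed <- opt$seed
  if (!is.null(opt$n_boot)) config$n_boot <- opt$n_boot
  old <- options(snhbees.verbose = isTRUE(opt$verbose))
  on.exit(options(old), add = TRUE)

  load_input <- function() {
    ds <- read_dataset(config$sites, config$bees, config$plants,
                       config$pollen)
    harmonize_taxa(ds, config$genus_merges)
  }
  switch(cmd,
    simulate = {
      sim <- emulate_study_design(seed = config$seed)
      dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_dataset(sim$dataset, opt$out_dir)
      jsonlite::write_json(
        sim$ground_truth[c("plant_pools", "bee_pools", "expected_beta")],
        file.path(opt$out_dir, "ground_truth.json"),
        auto_unbox = TRUE, digits = NA)
      snh_log("simulate: wrote dataset + ground_truth.json to %s", opt$out_dir)
    },
    beta = {
      ds <- load_input()
      pairs <- utils::combn(HABITATS, 2)
      rows <- lapply(seq_len(ncol(pairs)), function(k) {
        bp <- baselga_partition(
          pooled_habitat_community(ds, pairs[1, k], "bees"),
          pooled_habitat_community(ds, pairs[2, k], "bees"))
        data.frame(habitat_1 = pairs[1, k], habitat_2 = pairs[2, k],
                   a = bp$a, b = bp$b, c = bp$c, beta_sor = bp$beta_sor,
                   beta_sim = bp$beta_sim, beta_sne = bp$beta_sne)
      })
      dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(do.call(rbind, rows),
                       file.path(opt$out_dir, "beta_between_habitats.csv"),
                       row.names = FALSE)
    },
    rarefy = {
      ds <- load_input()
      rows <- lapply(HABITATS, function(h) {
        sp <- ds$bees$species[ds$bees$point_id %in%
                                ds$sites$point_id[ds$sites$habitat == h]]
        if (!length(sp)) return(NULL)
        cbind(habitat = h,
              rarefaction_curve(abundance_vector(sp),
                                conf = config$conf_rarefaction,
                                n_boot = config$n_boot_rarefaction,
                                seed = config$seed)$curve)
      })
      dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
                       file.path(opt$out_dir, "rarefaction.csv"),
                       row.names = FALSE)
    },
    selection = {
      if (is.null(config$pollen)) stop(errorCondition(
        "selection stage requested but config names no pollen.csv",
        class = c("snh_config_error", "error")))
      ds <- load_input()
      sel <- bootstrap_selection(ds, n_boot = config$n_boot,
                                 seed = config$seed,
                                 hr_denominator = config$hr_denominator,
                                 pa_denominator = config$pa_denominator)
      dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(sel$results,
                       file.path(opt$out_dir, "pollen_selection.csv"),
                       row.names = FALSE)
    },
    network = {
      ds <- abundant_species_filter(load_input(), config$min_individuals)
      net <- build_network(ds)
      dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(net$edges,
                       file.path(opt$out_dir, "network_edges.csv"),
                       row.names = FALSE)
      rem <- lapply(HABITATS, function(h) habitat_removal_robustness(
        ds, h, n_boot = config$n_boot,
        subsample_size = config$subsample_size, seed = config$seed))
      utils::write.csv(do.call(rbind, lapply(rem, function(r)
        cbind(removed_habitat = r$removed_habitat, r$summary))),
        file.path(opt$out_dir, "removal_robustness.csv"), row.names = FALSE)
    },
    run = run_pipeline(config, out_dir = opt$out_dir,
                       verbose = isTRUE(opt$verbose)),
    stop(errorCondition(paste0("unknown subcommand: ", cmd),
                        class = c("snh_config_error", "error"))))
  invisible(0L)
}
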