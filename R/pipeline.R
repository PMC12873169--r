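# End-to-end pipeline: simulate -> core -> jaccard -> taylor -> robustness
# -> compare, with one master seed and a JSON manifest sufficient to re-run
# bit-identically.

#' Pipeline configuration
#'
#' Bundles the stage parameters of [run_pipeline()]. Stage seeds are derived
#' from the single master `seed` through named sub-streams.
#'
#' @param seed master integer seed.
#' @param cohort named list of [cohort_config()] overrides.
#' @param genome named list of [genome_content_config()] overrides.
#' @param detection detection threshold used by all presence calls.
#' @param core_thresholds prevalence thresholds (default `c(1, 0.8, 0.5)`).
#' @param bin_width Jaccard time-bin width in days (default 60).
#' @param taylor_reference reference group for standardization (default
#'   `"A"`).
#' @param confidence confidence levels of the healthy window (default
#'   `c(0.68, 0.98)`).
#' @param robustness named list: `levels` (default
#'   `c("global", "superpathway")`), `magnitudes`, `reps`, `n_null`,
#'   `samples` (`"first"` = first sample of each individual, `"all"`, or a
#'   character vector of sample ids).
#' @param compare_adjust `"none"` or `"bh"` for the group contrasts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = list(),
                            genome = list(),
                            detection = 1e-4,
                            core_thresholds = c(1, 0.8, 0.5),
                            bin_width = 60,
                            taylor_reference = "A",
                            confidence = c(0.68, 0.98),
                            robustness = list(),
                            compare_adjust = "none") {
  rob <- utils::modifyList(
    list(levels = c("global", "superpathway"),
         magnitudes = seq(0.05, 0.75, by = 0.05),
         reps = 20, n_null = 100, samples = "first"),
    robustness)
  structure(list(seed = as.integer(seed), cohort = cohort, genome = genome,
                 detection = detection, core_thresholds = core_thresholds,
                 bin_width = bin_width, taylor_reference = taylor_reference,
                 confidence = confidence, robustness = rob,
                 compare_adjust = compare_adjust),
            class = "pipeline_config")
}

simulate_inputs <- function(config, out_dir = NULL) {
  ccfg <- do.call(cohort_config, utils::modifyList(
    config$cohort,
    list(seed = substream_seed(config$seed, "cohort"),
         detection = config$detection)))
  gcfg_over <- utils::modifyList(
    config$genome, list(seed = substream_seed(config$seed, "genome")))
  if (is.null(gcfg_over$n_taxa)) gcfg_over$n_taxa <- ccfg$n_taxa
  gcfg <- do.call(genome_content_config, gcfg_over)
  table <- generate_cohort(ccfg)
  content <- generate_genome_content(gcfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_abundance_table(table, file.path(out_dir, "abundance.tsv"),
                          file.path(out_dir, "metadata.tsv"))
    write_genome_content(content, file.path(out_dir, "genome_content.tsv"),
                         file.path(out_dir, "rrn.tsv"),
                         file.path(out_dir, "pathway_map.tsv"))
    jsonlite::write_json(list(cohort = unclass(ccfg), genome = unclass(gcfg)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = table, content = content, cohort_config = ccfg,
       genome_config = gcfg)
}

robustness_sample_ids <- function(table, samples) {
  if (identical(samples, "all")) return(table$samples$sample_id)
  if (identical(samples, "first")) {
    meta <- table$samples
    firsts <- vapply(split(seq_len(nrow(meta)), meta$individual_id),
                     function(idx) idx[which.min(meta$collection_day[idx])],
                     integer(1))
    return(meta$sample_id[sort(firsts)])
  }
  as.character(samples)
}

#' Run the full analysis pipeline
#'
#' Generates (or takes) a cohort and genome content, then runs every stage:
#' core microbiota at the configured thresholds with the age-group
#' partition, within-individual Jaccard pairs and 60-day binned decay per
#' group, Jaccard-core-index trajectories against each group's 50% core with
#' group contrasts, per-individual Taylor fits with standardization and
#' healthy-window classification, taxa-function robustness scores on a
#' subset of samples with group contrasts, and writes all result TSVs plus
#' the run manifest into `out_dir`.
#'
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param table,content optional pre-built [abundance_table()] /
#'   [genome_content()]; by default they are simulated from the config.
#' @return invisibly, a named list of all in-memory results.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         table = NULL, content = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  det <- config$detection
  if (is.null(table) || is.null(content)) {
    sim <- simulate_inputs(config, out_dir = out_dir)
    table <- table %||% sim$table
    content <- content %||% sim$content
  }
  results <- list()

  # core microbiota
  ca <- core_analysis(table, thresholds = config$core_thresholds,
                      detection = det)
  for (key in names(ca$cores)) {
    for (g in names(ca$cores[[key]])) {
      results[[sprintf("core_%s_p%d", g, round(100 * as.numeric(key)))]] <-
        as.data.frame(ca$cores[[key]][[g]])
    }
    results[[sprintf("core_partition_p%d", round(100 * as.numeric(key)))]] <-
      ca$partitions[[key]]
  }

  # temporal similarity
  pairs <- pairwise_within_individual(table, detection = det)
  results$jaccard_pairs <- pairs
  binned <- lapply(split(pairs, pairs$age_group), bin_series,
                   width = config$bin_width)
  results$jaccard_binned <- do.call(rbind, lapply(names(binned), function(g) {
    cbind(age_group = g, binned[[g]], stringsAsFactors = FALSE)
  }))
  cores50 <- lapply(stats::setNames(age_group_levels, age_group_levels),
                    function(g) {
                      extract_core(compute_prevalence(table, g, det), 0.5)
                    })
  jci <- jci_age_trajectory(table, cores = cores50, detection = det)
  results$jci <- jci
  results$jci_comparisons <- do.call(rbind, lapply(age_group_levels,
    function(ref) {
      sub <- jci[jci$reference_group == ref, ]
      cmp <- compare_groups(sub$jci, sub$age_group,
                            metric = paste0("jci_ref_", ref),
                            adjust = config$compare_adjust)
      cmp
    }))

  # Taylor stability
  fits <- fit_taylor_cohort(table, detection = det)
  results$taylor_fits <- as.data.frame(fits)
  space <- standardize_fits(fits, reference = config$taylor_reference)
  results$taylor_space <- as.data.frame(space)
  results$taylor_window <- do.call(rbind, lapply(config$confidence,
    function(p) cbind(confidence = p, classify_window(space, p))))

  # taxa-function robustness
  rob_ids <- robustness_sample_ids(table, config$robustness$samples)
  rob_rows <- list()
  for (sid in rob_ids) {
    ab <- table$values[, sid]
    for (lvl in config$robustness$levels) {
      rob_rows[[paste(sid, lvl)]] <- pathway_robustness(
        ab, content, level = lvl,
        magnitudes = config$robustness$magnitudes,
        reps = config$robustness$reps,
        n_null = config$robustness$n_null,
        seed = substream_seed(config$seed, paste0("robustness.", sid)),
        sample_id = sid)
    }
  }
  rob <- do.call(rbind, rob_rows)
  rownames(rob) <- NULL
  results$robustness_scores <- as.data.frame(rob)

  # group contrasts on global attenuation / buffering
  glob <- rob[rob$scope == "global", , drop = FALSE]
  if (nrow(glob)) {
    grp <- table$samples$age_group[match(glob$sample_id,
                                         table$samples$sample_id)]
    cmp_rows <- list()
    for (metric in c("attenuation", "buffering")) {
      vals <- glob[[metric]]
      cmp_rows[[metric]] <- compare_groups(vals, grp, metric = metric,
                                           adjust = config$compare_adjust)
    }
    results$robustness_comparisons <- do.call(rbind, cmp_rows)
  }

  write_result_tables(results, out_dir, config = unclass(config),
                      seed = config$seed)
  invisible(results)
}

#' Re-run a pipeline from its manifest
#'
#' Reads the configuration and seed recorded in a `manifest.json` written by
#' [run_pipeline()] and re-executes the pipeline; with the same package
#' version the outputs are bit-identical.
#'
#' @param manifest_path path to `manifest.json`.
#' @param out_dir output directory for the re-run.
#' @return invisibly, the re-run's results list.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  config <- pipeline_config(
    seed = cfg$seed,
    cohort = as.list(cfg$cohort),
    genome = as.list(cfg$genome),
    detection = cfg$detection,
    core_thresholds = cfg$core_thresholds,
    bin_width = cfg$bin_width,
    taylor_reference = cfg$taylor_reference,
    confidence = cfg$confidence,
    robustness = as.list(cfg$robustness),
    compare_adjust = cfg$compare_adjust)
  run_pipeline(out_dir, config)
}
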