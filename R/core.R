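# Prevalence-threshold core microbiota: per-group taxon prevalences at a
# detection limit, core extraction at 100/80/50% thresholds, and the
# seven-region membership partition across the three age groups.

#' Per-taxon prevalence within an age group
#'
#' Prevalence of a taxon is the fraction of the group's *samples* (pooled
#' across individuals, so individuals with more samples weigh more) in which
#' its relative abundance is strictly greater than the detection threshold.
#'
#' @param table an [abundance_table()].
#' @param group age group, one of `"I"`, `"A"`, `"E"`.
#' @param detection detection threshold (default 1e-4).
#' @return object of class `prevalence_profile`: data.frame with columns
#'   `taxon_id`, `prevalence`; attributes `age_group`, `n_samples`,
#'   `detection`.
#' @export
compute_prevalence <- function(table, group, detection = 1e-4) {
  stopifnot(inherits(table, "abundance_table"))
  group <- as.character(as_age_group(group))
  validate_detection(detection)
  idx <- which(as.character(table$samples$age_group) == group)
  if (!length(idx)) stopf("age group '%s' has no samples", group)
  pres <- table$values[, idx, drop = FALSE] > detection
  prof <- data.frame(taxon_id = table$taxa,
                     prevalence = rowMeans(pres),
                     stringsAsFactors = FALSE)
  structure(prof, class = c("prevalence_profile", "data.frame"),
            age_group = group, n_samples = length(idx),
            detection = detection)
}

#' Extract the core set at a prevalence threshold
#'
#' Core membership is "at least": taxa with prevalence `>= threshold`.
#'
#' @param profile a [compute_prevalence()] result.
#' @param threshold prevalence threshold in `(0, 1]` (the conventional levels
#'   are 1.0, 0.8, 0.5).
#' @return object of class `core_set`: data.frame with columns `taxon_id`,
#'   `prevalence` (members only); attributes `age_group`,
#'   `prevalence_threshold`, `detection`, `n_samples`.
#' @export
extract_core <- function(profile, threshold) {
  stopifnot(inherits(profile, "prevalence_profile"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stopf("threshold must be a single number in (0, 1]")
  }
  members <- profile[profile$prevalence >= threshold, , drop = FALSE]
  rownames(members) <- NULL
  structure(as.data.frame(members),
            class = c("core_set", "data.frame"),
            age_group = attr(profile, "age_group"),
            prevalence_threshold = threshold,
            detection = attr(profile, "detection"),
            n_samples = attr(profile, "n_samples"))
}

#' Core taxa ids of a core set
#' @param core a `core_set`.
#' @return character vector of member taxon ids.
#' @export
core_members <- function(core) {
  stopifnot(inherits(core, "core_set"))
  core$taxon_id
}

#' Partition core membership across the three age groups
#'
#' Given one core per age group at a common threshold and detection limit,
#' returns the seven-region set partition (I-only, A-only, E-only, the three
#' pairwise-exclusive intersections, and the triple intersection). Regions
#' are pairwise disjoint and their union is the union of the three cores.
#'
#' @param cores named list with elements `I`, `A`, `E`, each a `core_set`
#'   built at the same `prevalence_threshold` and `detection`.
#' @return data.frame with columns `region` (e.g. `"I"`, `"I&A"`,
#'   `"I&A&E"`), `n_taxa`, `members` (comma-separated ids); attribute
#'   `prevalence_threshold`.
#' @export
core_partition <- function(cores) {
  if (!all(age_group_levels %in% names(cores))) {
    stopf("'cores' must be a named list with elements I, A, E")
  }
  cores <- cores[age_group_levels]
  for (co in cores) stopifnot(inherits(co, "core_set"))
  thr <- vapply(cores, attr, numeric(1), "prevalence_threshold")
  det <- vapply(cores, attr, numeric(1), "detection")
  if (length(unique(thr)) != 1L || length(unique(det)) != 1L) {
    stopf("cores must share one prevalence threshold and one detection threshold")
  }
  sets <- lapply(cores, core_members)
  all_taxa <- unique(unlist(sets))
  in_i <- all_taxa %in% sets$I
  in_a <- all_taxa %in% sets$A
  in_e <- all_taxa %in% sets$E
  region_of <- function(i, a, e) {
    paste(c("I", "A", "E")[c(i, a, e)], collapse = "&")
  }
  regions <- c("I", "A", "E", "I&A", "I&E", "A&E", "I&A&E")
  lab <- mapply(region_of, in_i, in_a, in_e)
  out <- data.frame(
    region = regions,
    n_taxa = vapply(regions, function(r) sum(lab == r), integer(1)),
    members = vapply(regions, function(r) {
      paste(sort(all_taxa[lab == r]), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, prevalence_threshold = thr[[1]], detection = det[[1]])
}

#' Cores at several thresholds for all age groups
#'
#' Convenience wrapper running [compute_prevalence()] once per group and
#' [extract_core()] at each threshold.
#'
#' @param table an [abundance_table()].
#' @param thresholds numeric vector of prevalence thresholds (default
#'   `c(1.0, 0.8, 0.5)`).
#' @param detection detection threshold (default 1e-4).
#' @return nested list: `cores[[as.character(threshold)]][[group]]` is a
#'   `core_set`; plus `partitions[[as.character(threshold)]]`.
#' @export
core_analysis <- function(table, thresholds = c(1.0, 0.8, 0.5),
                          detection = 1e-4) {
  profiles <- lapply(stats::setNames(age_group_levels, age_group_levels),
                     function(g) compute_prevalence(table, g, detection))
  cores <- list()
  partitions <- list()
  for (thr in thresholds) {
    key <- as.character(thr)
    cores[[key]] <- lapply(profiles, extract_core, threshold = thr)
    partitions[[key]] <- core_partition(cores[[key]])
  }
  list(profiles = profiles, cores = cores, partitions = partitions)
}
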