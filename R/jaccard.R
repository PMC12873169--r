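# Within-individual temporal similarity: presence-set Jaccard between sample
# pairs of the same individual as a function of time lapse (60-day binning),
# and the Jaccard core index of single samples against a fixed 50%-prevalence
# reference core.

presence_set <- function(abundance, detection = 1e-4) {
  names(abundance)[abundance > detection]
}

#' Jaccard similarity of two samples' presence sets
#'
#' `J = |S_a intersect S_b| / |S_a union S_b|` where a taxon belongs to a
#' sample's set iff its abundance is strictly greater than the detection
#' threshold. Two empty sets are identically empty: `J = 1` with a warning,
#' never a silent drop.
#'
#' @param sample_a,sample_b named numeric abundance vectors over the same
#'   taxa (columns of one [abundance_table()]).
#' @param detection detection threshold (default 1e-4).
#' @return Jaccard similarity in `[0, 1]`.
#' @export
jaccard_presence <- function(sample_a, sample_b, detection = 1e-4) {
  validate_detection(detection)
  a <- sample_a > detection
  b <- sample_b > detection
  union_n <- sum(a | b)
  if (union_n == 0) {
    warnf("both presence sets empty; Jaccard defined as 1")
    return(1)
  }
  sum(a & b) / union_n
}

#' All within-individual sample pairs with their Jaccard similarities
#'
#' Enumerates every unordered pair of samples belonging to the same
#' individual; between-individual pairs are never formed. Individuals with a
#' single sample contribute nothing.
#'
#' @param table an [abundance_table()].
#' @param detection detection threshold (default 1e-4).
#' @return data.frame with columns `individual_id`, `age_group`, `sample_a`,
#'   `sample_b`, `day_gap`, `jaccard` (zero rows if no individual has two
#'   samples).
#' @export
pairwise_within_individual <- function(table, detection = 1e-4) {
  stopifnot(inherits(table, "abundance_table"))
  validate_detection(detection)
  meta <- table$samples
  pres <- table$values > detection
  out <- list()
  for (ind in unique(meta$individual_id)) {
    idx <- which(meta$individual_id == ind)
    if (length(idx) < 2) next
    pairs <- utils::combn(idx, 2)
    inter <- crossprod(pres[, idx, drop = FALSE])
    uni <- outer(colSums(pres[, idx, drop = FALSE]),
                 colSums(pres[, idx, drop = FALSE]), "+") - inter
    local <- match(pairs, idx)
    dim(local) <- dim(pairs)
    j <- inter[t(local)] / uni[t(local)]
    j[!is.finite(j)] <- 1  # empty-vs-empty convention
    out[[ind]] <- data.frame(
      individual_id = ind,
      age_group = as.character(meta$age_group[idx[1]]),
      sample_a = meta$sample_id[pairs[1, ]],
      sample_b = meta$sample_id[pairs[2, ]],
      day_gap = abs(meta$collection_day[pairs[2, ]] -
                      meta$collection_day[pairs[1, ]]),
      jaccard = as.numeric(j),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(individual_id = character(0), age_group = character(0),
                      sample_a = character(0), sample_b = character(0),
                      day_gap = integer(0), jaccard = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bin similarity pairs by time lapse
#'
#' Pairs with gap `g` fall in the half-open bin `[k*width, (k+1)*width)`,
#' i.e. `k = floor(g / width)`. The representative gap of bin `k` is its
#' midpoint `k*width + width/2`. The per-bin standard deviation uses the
#' sample (n-1) denominator and is `NA` for single-pair bins.
#'
#' @param pairs data.frame from [pairwise_within_individual()], optionally
#'   pre-filtered (e.g. by age group).
#' @param width bin width in days (default 60).
#' @return data.frame with columns `bin`, `gap_mid`, `mean_jaccard`,
#'   `sd_jaccard`, `n_pairs`, sorted by bin.
#' @export
bin_series <- function(pairs, width = 60) {
  if (!is_count(width) || width < 1) stopf("bin width must be an integer >= 1")
  if (!nrow(pairs)) {
    return(data.frame(bin = integer(0), gap_mid = numeric(0),
                      mean_jaccard = numeric(0), sd_jaccard = numeric(0),
                      n_pairs = integer(0)))
  }
  k <- floor(pairs$day_gap / width)
  agg <- split(pairs$jaccard, k)
  bins <- as.integer(names(agg))
  out <- data.frame(
    bin = bins,
    gap_mid = bins * width + width / 2,
    mean_jaccard = vapply(agg, mean, numeric(1)),
    sd_jaccard = vapply(agg, function(v) {
      if (length(v) > 1) stats::sd(v) else NA_real_
    }, numeric(1)),
    n_pairs = vapply(agg, length, integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard core index of one sample against a fixed reference core
#'
#' With `C` the reference core members and `S` the sample's presence set at
#' the detection threshold, the index is
#' `JCI = |C and S| / (|C| + |S| - |C and S|)` - the Jaccard similarity of
#' the two sets, with the reference core held fixed. The reference is a
#' 50%-prevalence core of one age group.
#'
#' @param abundance named numeric abundance vector (one table column).
#' @param core a `core_set` built at the 50% prevalence threshold.
#' @param detection detection threshold (default 1e-4; the same one used to
#'   build the core).
#' @return JCI in `[0, 1]`.
#' @export
jaccard_core_index <- function(abundance, core, detection = 1e-4) {
  stopifnot(inherits(core, "core_set"))
  validate_detection(detection)
  C <- core_members(core)
  if (!length(C)) stopf("reference core is empty: index undefined")
  S <- presence_set(abundance, detection)
  common <- length(intersect(C, S))
  common / (length(C) + length(S) - common)
}

#' Jaccard core index trajectories against each age group's reference core
#'
#' Computes one JCI per (sample, reference group) pair, carrying the
#' subject's age at collection for trajectory plots; group contrasts on the
#' resulting values are delegated to [compare_groups()].
#'
#' @param table an [abundance_table()] with `subject_age_years` metadata.
#' @param cores named list (`I`, `A`, `E`) of 50%-threshold `core_set`s; by
#'   default they are computed from `table` itself.
#' @param detection detection threshold (default 1e-4).
#' @return data.frame with columns `sample_id`, `individual_id`,
#'   `age_group`, `subject_age_years`, `reference_group`, `jci` (3 rows per
#'   sample).
#' @export
jci_age_trajectory <- function(table, cores = NULL, detection = 1e-4) {
  stopifnot(inherits(table, "abundance_table"))
  missing_age <- table$samples$sample_id[is.na(table$samples$subject_age_years)]
  if (length(missing_age)) {
    stopf("subject_age_years missing for sample(s): %s",
          paste(missing_age, collapse = ", "))
  }
  if (is.null(cores)) {
    cores <- lapply(stats::setNames(age_group_levels, age_group_levels),
                    function(g) {
                      extract_core(compute_prevalence(table, g, detection), 0.5)
                    })
  }
  for (co in cores) {
    stopifnot(inherits(co, "core_set"))
    if (abs(attr(co, "prevalence_threshold") - 0.5) > 1e-12) {
      stopf("reference cores must be built at the 50%% prevalence threshold")
    }
  }
  meta <- table$samples
  out <- list()
  for (ref in age_group_levels) {
    jci <- vapply(seq_len(ncol(table$values)), function(j) {
      jaccard_core_index(table$values[, j], cores[[ref]], detection)
    }, numeric(1))
    out[[ref]] <- data.frame(
      sample_id = meta$sample_id,
      individual_id = meta$individual_id,
      age_group = as.character(meta$age_group),
      subject_age_years = meta$subject_age_years,
      reference_group = ref,
      jci = jci,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
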