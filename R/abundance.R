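# The abundance_table container: a taxa x samples relative-abundance matrix
# joined to per-sample metadata. Every downstream stage consumes this type.

#' Construct and validate an abundance table
#'
#' An `abundance_table` holds genus-level (or any fixed-rank) relative
#' abundances as a taxa-by-samples matrix together with per-sample metadata:
#' sample id, individual id, age group (`I`/`A`/`E` for Infant/Adult/Elder),
#' collection day and subject age in years. Collection days are re-based per
#' individual so each individual's first sample is day 0.
#'
#' Columns must sum to 1: columns off by more than `renorm_tol` are
#' renormalized with a warning, smaller drift is repaired silently. Negative
#' entries and all-zero columns are hard errors, as is a sample column with no
#' metadata row.
#'
#' @param values numeric matrix, taxa in rows (rownames = taxon ids), samples
#'   in columns (colnames = sample ids).
#' @param metadata data.frame with columns `sample_id`, `individual_id`,
#'   `age_group`, `collection_day`, `subject_age_years`.
#' @param compositional logical; enforce unit column sums (default `TRUE`).
#'   The synthetic generator's diagnostic "noiseless" mode disables closure to
#'   preserve exact designed moments.
#' @param renorm_tol numeric; deviation from 1 above which renormalization is
#'   reported with a warning (default `1e-6`).
#' @return an object of class `abundance_table`: list with elements `values`
#'   (matrix), `taxa` (character), `samples` (metadata data.frame ordered as
#'   the matrix columns).
#' @export
abundance_table <- function(values, metadata, compositional = TRUE,
                            renorm_tol = 1e-6) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("'values' must carry taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stopf("taxon ids must be unique")
  if (anyDuplicated(colnames(values))) stopf("sample ids must be unique")
  if (any(!is.finite(values))) stopf("non-finite abundance values")
  if (any(values < 0)) {
    bad <- colnames(values)[apply(values < 0, 2, any)][1]
    stopf("negative abundance in sample '%s'", bad)
  }

  required <- c("sample_id", "individual_id", "age_group", "collection_day",
                "subject_age_years")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stopf("metadata lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) {
    stopf("duplicated sample_id in metadata")
  }
  absent <- setdiff(colnames(values), metadata$sample_id)
  if (length(absent)) {
    stopf("metadata lacks row(s) for sample(s): %s",
          paste(absent, collapse = ", "))
  }
  meta <- metadata[match(colnames(values), metadata$sample_id), required,
                   drop = FALSE]
  rownames(meta) <- NULL
  meta$sample_id <- as.character(meta$sample_id)
  meta$individual_id <- as.character(meta$individual_id)
  meta$age_group <- as_age_group(meta$age_group)
  meta$collection_day <- as.integer(meta$collection_day)
  meta$subject_age_years <- as.numeric(meta$subject_age_years)
  if (any(is.na(meta$collection_day)) || any(meta$collection_day < 0)) {
    stopf("collection_day must be a non-negative integer")
  }

  # age group must be constant within an individual
  grp_by_ind <- tapply(as.character(meta$age_group), meta$individual_id,
                       function(g) length(unique(g)))
  if (any(grp_by_ind > 1)) {
    stopf("age_group differs within individual(s): %s",
          paste(names(grp_by_ind)[grp_by_ind > 1], collapse = ", "))
  }

  # re-base collection days so each individual starts at day 0
  first_day <- tapply(meta$collection_day, meta$individual_id, min)
  meta$collection_day <- meta$collection_day -
    as.integer(first_day[meta$individual_id])

  if (compositional) {
    csums <- colSums(values)
    if (any(csums == 0)) {
      stopf("sample '%s' has zero total abundance",
            colnames(values)[csums == 0][1])
    }
    off <- abs(csums - 1) > renorm_tol
    if (any(off)) {
      warnf("renormalized %d sample column(s) not summing to 1 (max deviation %.3g)",
            sum(off), max(abs(csums - 1)))
    }
    drift <- abs(csums - 1) > 1e-9
    if (any(drift)) {
      values[, drift] <- sweep(values[, drift, drop = FALSE], 2,
                               csums[drift], "/")
    }
    if (any(values > 1)) stopf("abundance above 1 after renormalization")
  }

  structure(
    list(values = values, taxa = rownames(values), samples = meta),
    class = "abundance_table",
    compositional = compositional
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  n_ind <- length(unique(x$samples$individual_id))
  cat(sprintf("abundance_table: %d taxa x %d samples (%d individuals)\n",
              length(x$taxa), nrow(x$samples), n_ind))
  tab <- table(x$samples$age_group)
  cat("  samples per age group:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  collection day range: %d..%d\n",
              min(x$samples$collection_day), max(x$samples$collection_day)))
  invisible(x)
}

#' Number of samples in an abundance table
#' @param x an `abundance_table`.
#' @return integer.
#' @export
n_samples <- function(x) ncol(x$values)

#' Subset an abundance table by samples
#'
#' @param table an `abundance_table`.
#' @param sample_ids character vector of sample ids to keep (order preserved).
#' @return an `abundance_table` restricted to those samples. Columns are not
#'   renormalized (they already sum to 1) and collection days are *not*
#'   re-based, so time structure within individuals is preserved.
#' @export
subset_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "abundance_table"))
  missing <- setdiff(sample_ids, table$samples$sample_id)
  if (length(missing)) {
    stopf("unknown sample id(s): %s", paste(missing, collapse = ", "))
  }
  idx <- match(sample_ids, table$samples$sample_id)
  meta <- table$samples[idx, , drop = FALSE]
  rownames(meta) <- NULL
  structure(
    list(values = table$values[, idx, drop = FALSE], taxa = table$taxa,
         samples = meta),
    class = "abundance_table",
    compositional = attr(table, "compositional")
  )
}

#' Presence/absence call at a detection threshold
#'
#' A taxon is present in a sample iff its relative abundance is strictly
#' greater than the detection threshold. The strict inequality is the single
#' convention used by cores, prevalence and all Jaccard computations.
#'
#' @param abundance numeric vector (or matrix) of relative abundances.
#' @param detection numeric detection threshold in `[0, 1)`; default `1e-4`.
#' @return logical of the same shape as `abundance`.
#' @export
is_present <- function(abundance, detection = 1e-4) {
  validate_detection(detection)
  abundance > detection
}

validate_detection <- function(detection) {
  if (!is.numeric(detection) || length(detection) != 1L || is.na(detection) ||
      detection < 0 || detection >= 1) {
    stopf("detection threshold must be a single number in [0, 1)")
  }
  invisible(detection)
}

#' Read an abundance table and its sample metadata from TSV files
#'
#' Expects the tidy microbiome export layout: abundances with taxa as rows,
#' first column `taxon_id`, one column per sample; metadata as a separate TSV
#' keyed by `sample_id`. Columns not summing to 1 within `1e-6` are
#' renormalized with a warning; a sample missing from the metadata or a
#' negative abundance is a hard error.
#'
#' @param path path to the abundance TSV.
#' @param metadata_path path to the metadata TSV.
#' @return a validated [abundance_table()].
#' @export
read_abundance_table <- function(path, metadata_path) {
  for (p in c(path, metadata_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  ab <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(ab)[1] != "taxon_id") {
    stopf("abundance TSV must have first column 'taxon_id'")
  }
  values <- as.matrix(ab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(ab$taxon_id)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  abundance_table(values, meta)
}

#' Write an abundance table and its metadata to TSV files
#'
#' Inverse of [read_abundance_table()]; numbers are serialized with 10
#' significant digits so that read-write round trips are bit-stable.
#'
#' @param table an `abundance_table`.
#' @param path abundance TSV output path.
#' @param metadata_path metadata TSV output path.
#' @return invisibly, `c(path, metadata_path)`.
#' @export
write_abundance_table <- function(table, path, metadata_path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(taxon_id = table$taxa,
                   apply(table$values, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
  meta <- table$samples
  meta$subject_age_years <- fmt_num(meta$subject_age_years)
  meta$age_group <- as.character(meta$age_group)
  write_tsv_raw(meta, metadata_path)
  invisible(c(path, metadata_path))
}
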