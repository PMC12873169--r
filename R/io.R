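# Result serialization: TSV writers/readers with a fixed numeric format so
# that write -> read -> write round trips are byte-identical, plus the JSON
# run manifest.

# 10 significant digits: enough to round-trip the doubles we produce through
# text without decimal noise.
fmt_num <- function(x) {
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_raw <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Read a result TSV written by the pipeline
#'
#' Plain tab-separated read with `check.names = FALSE`; numeric columns come
#' back as doubles parsed from the 10-significant-digit serialization.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# Convert one result object to (filename stem, data.frame) pairs.
result_frames <- function(name, x) {
  if (inherits(x, "core_set")) {
    df <- as.data.frame(x)
    stem <- sprintf("core_%s_p%d", attr(x, "age_group"),
                    round(100 * attr(x, "prevalence_threshold")))
    return(stats::setNames(list(df), stem))
  }
  if (inherits(x, "abundance_table")) {
    stop("use write_abundance_table() for abundance tables")
  }
  if (is.data.frame(x)) return(stats::setNames(list(x), name))
  if (is.list(x)) {
    out <- list()
    for (i in seq_along(x)) {
      nm <- names(x)[i] %||% as.character(i)
      sub <- result_frames(paste0(name, "_", nm), x[[i]])
      out <- c(out, sub)
    }
    return(out)
  }
  stopf("cannot serialize result '%s' of class %s", name, class(x)[1])
}

format_result_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) df[[j]] <- fmt_num(df[[j]])
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
    if (is.logical(df[[j]])) df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                                               ifelse(df[[j]], "TRUE", "FALSE"))
  }
  df
}

#' Write a family of result tables plus a JSON run manifest
#'
#' Each element of `results` becomes one TSV named after its list name (core
#' sets get conventional `core_<group>_p<threshold>` stems). A
#' `manifest.json` records the written files, the configuration and seed of
#' the run and the package/R versions, which is sufficient to re-run the
#' pipeline bit-identically.
#'
#' @param results named list of result objects (data.frames, `core_set`s, or
#'   nested named lists thereof). May be empty: then only the manifest is
#'   written.
#' @param out_dir output directory (created if needed).
#' @param config optional configuration list echoed into the manifest.
#' @param seed optional integer seed echoed into the manifest.
#' @return character vector of written file paths (manifest last).
#' @export
write_result_tables <- function(results, out_dir, config = NULL, seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stopf("output directory '%s' is not writable", out_dir)
  }
  if (length(results) && is.null(names(results))) {
    stopf("'results' must be a named list")
  }
  frames <- list()
  for (nm in names(results)) {
    frames <- c(frames, result_frames(nm, results[[nm]]))
  }
  paths <- character(0)
  for (stem in names(frames)) {
    p <- file.path(out_dir, paste0(stem, ".tsv"))
    write_tsv_raw(format_result_df(frames[[stem]]), p)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "corestab",
    version = as.character(utils::packageVersion("corestab")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    files = basename(paths)
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, mpath))
}
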