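# Genome content: taxa x gene-family copy numbers, per-taxon 16S (rrn) copy
# numbers, and the two-level function -> pathway -> superpathway map. This is
# the PICRUSt2-style input that projects taxonomy into function space.

#' Construct and validate a genome-content object
#'
#' @param copy_numbers non-negative numeric matrix, taxa in rows (rownames =
#'   taxon ids), gene families in columns (colnames = function ids).
#' @param rrn named numeric vector of per-taxon 16S copy numbers (>= 1),
#'   names matching the matrix rownames.
#' @param pathway_map data.frame with columns `function_id`, `pathway_id`,
#'   `superpathway_id`; every function id maps to exactly one pathway and
#'   every pathway to exactly one superpathway.
#' @return object of class `genome_content`.
#' @export
genome_content <- function(copy_numbers, rrn, pathway_map) {
  if (!is.matrix(copy_numbers) || !is.numeric(copy_numbers)) {
    stopf("'copy_numbers' must be a numeric matrix")
  }
  if (is.null(rownames(copy_numbers)) || is.null(colnames(copy_numbers))) {
    stopf("'copy_numbers' must carry taxon rownames and function colnames")
  }
  if (any(copy_numbers < 0)) stopf("negative copy numbers")
  taxa <- rownames(copy_numbers)
  if (!all(taxa %in% names(rrn))) {
    stopf("rrn copy numbers missing for taxa: %s",
          paste(setdiff(taxa, names(rrn)), collapse = ", "))
  }
  rrn <- rrn[taxa]
  if (any(rrn < 1)) stopf("rrn copy numbers must be >= 1")

  required <- c("function_id", "pathway_id", "superpathway_id")
  if (!all(required %in% names(pathway_map))) {
    stopf("pathway_map must have columns %s", paste(required, collapse = ", "))
  }
  pathway_map <- pathway_map[, required]
  pathway_map[] <- lapply(pathway_map, as.character)
  if (anyDuplicated(pathway_map$function_id)) {
    stopf("a function id maps to more than one pathway")
  }
  pw_super <- tapply(pathway_map$superpathway_id, pathway_map$pathway_id,
                     function(s) length(unique(s)))
  if (any(pw_super > 1)) {
    stopf("pathway(s) map to more than one superpathway: %s",
          paste(names(pw_super)[pw_super > 1], collapse = ", "))
  }
  fns <- colnames(copy_numbers)
  unmapped <- setdiff(fns, pathway_map$function_id)
  if (length(unmapped)) {
    stopf("function id(s) absent from pathway map: %s",
          paste(unmapped, collapse = ", "))
  }
  structure(
    list(copy_numbers = copy_numbers, taxa = taxa, functions = fns,
         rrn = rrn, pathway_map = pathway_map),
    class = "genome_content"
  )
}

#' @export
print.genome_content <- function(x, ...) {
  cat(sprintf(
    "genome_content: %d taxa x %d gene families (%d pathways, %d superpathways)\n",
    length(x$taxa), length(x$functions),
    length(unique(x$pathway_map$pathway_id)),
    length(unique(x$pathway_map$superpathway_id))))
  invisible(x)
}

#' Functions belonging to one scope
#'
#' @param content a `genome_content`.
#' @param scope `"global"`, `"pathway:<id>"` or `"superpathway:<id>"`.
#' @return character vector of function ids in the scope (in matrix column
#'   order); error if the scope names no functions.
#' @export
scope_functions <- function(content, scope) {
  stopifnot(inherits(content, "genome_content"))
  if (identical(scope, "global")) return(content$functions)
  parts <- strsplit(scope, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("pathway", "superpathway")) {
    stopf("invalid scope '%s' (use 'global', 'pathway:<id>' or 'superpathway:<id>')",
          scope)
  }
  map <- content$pathway_map
  ids <- if (parts[1] == "pathway") {
    map$function_id[map$pathway_id == parts[2]]
  } else {
    map$function_id[map$superpathway_id == parts[2]]
  }
  ids <- intersect(content$functions, ids)
  if (!length(ids)) stopf("scope '%s' contains no functions", scope)
  ids
}

#' Read genome content from its three TSV files
#'
#' @param content_path taxa x functions copy-number TSV (first column
#'   `taxon_id`).
#' @param rrn_path TSV with columns `taxon_id`, `rrn_copies`.
#' @param pathway_path TSV with columns `function_id`, `pathway_id`,
#'   `superpathway_id`.
#' @return a validated [genome_content()].
#' @export
read_genome_content <- function(content_path, rrn_path, pathway_path) {
  for (p in c(content_path, rrn_path, pathway_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  cn <- utils::read.delim(content_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(cn)[1] != "taxon_id") {
    stopf("genome content TSV must have first column 'taxon_id'")
  }
  m <- as.matrix(cn[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(cn$taxon_id)
  rrn_df <- utils::read.delim(rrn_path, stringsAsFactors = FALSE)
  rrn <- stats::setNames(as.numeric(rrn_df$rrn_copies),
                         as.character(rrn_df$taxon_id))
  map <- utils::read.delim(pathway_path, stringsAsFactors = FALSE)
  genome_content(m, rrn, map)
}

#' Write genome content to its three TSV files
#'
#' @param content a `genome_content`.
#' @param content_path,rrn_path,pathway_path output TSV paths.
#' @return invisibly, the three paths.
#' @export
write_genome_content <- function(content, content_path, rrn_path,
                                 pathway_path) {
  stopifnot(inherits(content, "genome_content"))
  df <- data.frame(taxon_id = content$taxa, content$copy_numbers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_raw(df, content_path)
  write_tsv_raw(data.frame(taxon_id = content$taxa,
                           rrn_copies = content$rrn,
                           stringsAsFactors = FALSE), rrn_path)
  write_tsv_raw(content$pathway_map, pathway_path)
  invisible(c(content_path, rrn_path, pathway_path))
}
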