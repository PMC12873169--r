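# Shared fixtures, all built in code.

# abundance_table from a plain matrix; metadata auto-generated: sample ids
# are the column names "IND_Tk", one row per column.
make_table <- function(values, individual = NULL, group = NULL, days = NULL,
                       ages = NULL, ...) {
  n <- ncol(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(n))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("t%02d", seq_len(nrow(values)))
  }
  meta <- data.frame(
    sample_id = colnames(values),
    individual_id = individual %||% rep("X01", n),
    age_group = group %||% rep("A", n),
    collection_day = days %||% seq(0, by = 30, length.out = n),
    subject_age_years = ages %||% rep(35, n),
    stringsAsFactors = FALSE)
  abundance_table(values, meta, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# column-stochastic random matrix
random_composition <- function(n_taxa, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n_taxa * n_samples), n_taxa, n_samples)
  sweep(m, 2, colSums(m), "/")
}

# identity genome content: n taxa, n functions, copy number 1 on the
# diagonal, all rrn = 1 -> functional profile equals the composition
identity_content <- function(n = 10) {
  taxa <- sprintf("g%03d", seq_len(n))
  fns <- sprintf("fn%04d", seq_len(n))
  m <- diag(n)
  dimnames(m) <- list(taxa, fns)
  genome_content(m, stats::setNames(rep(1, n), taxa),
                 data.frame(function_id = fns,
                            pathway_id = rep(c("pw01", "pw02"), length.out = n),
                            superpathway_id = rep("sp1", n)))
}

# all taxa share one identical genome row
uniform_content <- function(n_taxa = 10, n_functions = 6) {
  taxa <- sprintf("g%03d", seq_len(n_taxa))
  fns <- sprintf("fn%04d", seq_len(n_functions))
  m <- matrix(rep(seq_len(n_functions), each = n_taxa), n_taxa, n_functions,
              dimnames = list(taxa, fns))
  genome_content(m, stats::setNames(rep(1, n_taxa), taxa),
                 data.frame(function_id = fns,
                            pathway_id = rep("pw01", n_functions),
                            superpathway_id = rep("sp1", n_functions)))
}

# uniform community over the content's taxa
uniform_community <- function(content) {
  n <- length(content$taxa)
  stats::setNames(rep(1 / n, n), content$taxa)
}

# brute-force two-sided Mann-Whitney p-value by enumerating all group
# assignments (independent oracle for the exact path)
brute_force_wilcoxon_p <- function(x, y) {
  n_a <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n, n_a)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}
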