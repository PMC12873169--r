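# Taxa-function robustness. A community's functional profile is the
# rrn-corrected projection of its taxonomic composition through a
# genome-content matrix. Random taxon-knockout perturbations of increasing
# magnitude yield (d_T, d_F) pairs - Bray-Curtis shifts in taxonomic and in
# functional space - whose hinge-curve fit d_F = s * max(0, d_T - b)
# summarizes the response: the slope s is the rate at which functional shift
# grows, the offset b the size of taxonomic perturbation tolerated before a
# functional shift appears. Standardizing (s, b) against a shuffled-genome
# null gives the attenuation and buffering scores: attenuation > 0 means the
# functional response is flatter than expected under random taxa-function
# assignment, buffering > 0 means a larger perturbation is tolerated.

#' Bray-Curtis dissimilarity
#'
#' `BC = 1 - sum(min(x_i, y_i))` for non-negative vectors summing to 1
#' (general inputs use `1 - 2*sum(min)/(sum(x)+sum(y))`). Symmetric, in
#' `[0, 1]`.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stopf("negative entries")
  tot <- sum(x) + sum(y)
  if (tot == 0) return(0)
  1 - 2 * sum(pmin(x, y)) / tot
}

# column-wise Bray-Curtis of a reference vector against each matrix column;
# all inputs assumed column-normalized to sum 1
bc_cols <- function(ref, m) {
  # first argument to pmin must be the matrix so dims are preserved
  1 - colSums(pmin(m, ref))
}

#' Project a community composition into function space
#'
#' Each taxon's relative abundance is divided by its 16S (rrn) copy number
#' (the PICRUSt2 correction), renormalized, multiplied through the
#' copy-number matrix, and the resulting function vector renormalized to
#' sum 1.
#'
#' @param abundance named numeric abundance vector; names must be a subset
#'   of the content's taxa.
#' @param content a [genome_content()].
#' @return named function-abundance vector summing to 1; error if no taxon
#'   with positive abundance carries any function.
#' @export
functional_profile <- function(abundance, content) {
  stopifnot(inherits(content, "genome_content"))
  a <- align_abundance(abundance, content)
  f <- profile_cols(matrix(a, ncol = 1, dimnames = list(content$taxa, "x")),
                    content)[, 1]
  if (sum(f) == 0) stopf("all-zero functional projection: no abundant taxon carries any function")
  f
}

# map an abundance vector onto the content's taxon order and renormalize
align_abundance <- function(abundance, content) {
  if (is.null(names(abundance))) stopf("abundance vector must be named")
  unknown <- setdiff(names(abundance)[abundance > 0], content$taxa)
  if (length(unknown)) {
    stopf("abundant taxa absent from genome content: %s",
          paste(unknown, collapse = ", "))
  }
  a <- stats::setNames(numeric(length(content$taxa)), content$taxa)
  keep <- intersect(names(abundance), content$taxa)
  a[keep] <- abundance[keep]
  if (sum(a) == 0) stopf("abundance vector is all zero")
  a / sum(a)
}

# function profiles (columns sum to 1, or to 0 if the projection is empty)
# of each column of a taxa-by-n abundance matrix
profile_cols <- function(A, content, copy_numbers = content$copy_numbers,
                         rrn = content$rrn) {
  W <- A / rrn
  ws <- colSums(W)
  ws[ws == 0] <- 1
  W <- sweep(W, 2, ws, "/")
  f <- crossprod(copy_numbers, W)
  fs <- colSums(f)
  nz <- fs > 0
  f[, nz] <- sweep(f[, nz, drop = FALSE], 2, fs[nz], "/")
  f
}

#' Knock out random taxa up to a target perturbation magnitude
#'
#' Taxa are removed in uniformly random order until the cumulative removed
#' relative abundance first reaches `m` (the final removed taxon may
#' overshoot); survivors are renormalized. `m = 0` returns the input. If a
#' draw would empty the community the order is resampled once, then it is an
#' error. Uses the current RNG stream.
#'
#' @param abundance named non-negative abundance vector.
#' @param m target magnitude in `[0, 0.95]`.
#' @return perturbed abundance vector summing to 1 (removed taxa at 0).
#' @export
perturb <- function(abundance, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m > 0.95) {
    stopf("magnitude m must lie in [0, 0.95]")
  }
  rel <- abundance / sum(abundance)
  if (m == 0) return(rel)
  for (attempt in 1:2) {
    pool <- which(rel > 0)
    ord <- pool[sample.int(length(pool))]
    k <- which(cumsum(rel[ord]) >= m)[1]
    removed <- ord[seq_len(k)]
    if (length(removed) < length(pool)) {
      out <- rel
      out[removed] <- 0
      return(out / sum(out))
    }
  }
  stopf("perturbation at magnitude %.2f would empty the community", m)
}

# curve-level wrapper: a knockout that would empty the community (a dominant
# taxon drawn last) is redrawn up to `tries` times; a magnitude for which no
# removal order works (no subset of mass in [m, 1)) still errors
perturb_retry <- function(abundance, m, tries = 20) {
  for (i in seq_len(tries)) {
    out <- tryCatch(perturb(abundance, m), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stopf("no feasible knockout at magnitude %.2f after %d draws", m, tries)
}

#' Perturbation response curve of one sample
#'
#' For each magnitude on the grid and each replicate, one knockout
#' perturbation is drawn; `d_T` is the Bray-Curtis shift between original
#' and perturbed taxonomic compositions, `d_F` the Bray-Curtis shift between
#' their functional profiles restricted to the scope's functions and
#' renormalized within the scope. Both shifts come from the same
#' perturbation event. Deterministic under a fixed seed.
#'
#' @param abundance named abundance vector (one sample column).
#' @param content a [genome_content()].
#' @param scope `"global"`, `"pathway:<id>"` or `"superpathway:<id>"`.
#' @param magnitudes perturbation magnitude grid (default
#'   `seq(0.05, 0.75, by = 0.05)`).
#' @param reps replicates per magnitude (default 20).
#' @param seed integer master seed (perturbations use the `"perturb"`
#'   sub-stream).
#' @param sample_id label carried into outputs.
#' @return object of class `perturbation_curve`: list with `points`
#'   (data.frame `magnitude`, `rep`, `d_T`, `d_F`), the perturbed community
#'   matrix, the aligned original composition, `scope`, `seed`, `sample_id`.
#' @export
perturbation_curve <- function(abundance, content, scope = "global",
                               magnitudes = seq(0.05, 0.75, by = 0.05),
                               reps = 20, seed = 1L, sample_id = "sample") {
  stopifnot(inherits(content, "genome_content"))
  if (!is_count(reps) || reps < 1) stopf("reps must be an integer >= 1")
  scope_fns <- scope_functions(content, scope)
  a <- align_abundance(abundance, content)
  P <- with_seed(substream_seed(seed, "perturb"), {
    cols <- lapply(rep(magnitudes, each = reps),
                   function(m) perturb_retry(a, m))
    do.call(cbind, cols)
  })
  rownames(P) <- content$taxa
  d_T <- bc_cols(a, P)
  d_F <- scoped_dF(a, P, content, scope_fns)
  points <- data.frame(magnitude = rep(magnitudes, each = reps),
                       rep = rep(seq_len(reps), times = length(magnitudes)),
                       d_T = d_T, d_F = d_F)
  structure(list(points = points, perturbed = P, abundance = a,
                 scope = scope, seed = as.integer(seed),
                 sample_id = sample_id),
            class = "perturbation_curve")
}

# d_F of each perturbed column within a scope, given the aligned original.
# The original's scope projection being empty is an error; a perturbed
# community that lost the whole scope scores d_F = 1 (total shift).
scoped_dF <- function(a, P, content, scope_fns,
                      copy_numbers = content$copy_numbers,
                      rrn = content$rrn) {
  F_all <- profile_cols(cbind(P, a), content, copy_numbers, rrn)
  n <- ncol(P)
  f0 <- F_all[scope_fns, n + 1]
  s0 <- sum(f0)
  if (s0 == 0) return(rep(NA_real_, n))
  f0 <- f0 / s0
  Fp <- F_all[scope_fns, seq_len(n), drop = FALSE]
  sp <- colSums(Fp)
  out <- rep(1, n)
  nz <- sp > 0
  Fp <- sweep(Fp[, nz, drop = FALSE], 2, sp[nz], "/")
  out[nz] <- bc_cols(f0, Fp)
  # shifts below 1e-12 are floating-point dust (identical-profile case)
  out[out < 1e-12] <- 0
  out
}

#' Fit the hinge response model to a perturbation curve
#'
#' Least squares fit of `d_F = s * max(0, d_T - b)` by grid search on the
#' offset `b` over `[0, max d_T]` in steps of 0.005, with the closed-form
#' optimal (non-negative) slope at each offset; ties in residual sum of
#' squares break toward the smaller offset.
#'
#' @param curve a [perturbation_curve()] or a data.frame with columns `d_T`,
#'   `d_F` (>= 10 points; all `d_T = 0` is an error).
#' @param b_step offset grid step (default 0.005).
#' @return object of class `hinge_fit`: list with slope `s`, offset `b`,
#'   `rss`, `n_points`.
#' @export
fit_hinge <- function(curve, b_step = 0.005) {
  points <- if (inherits(curve, "perturbation_curve")) curve$points else curve
  x <- points$d_T
  y <- points$d_F
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10) stopf("hinge fit needs at least 10 points")
  if (all(x == 0)) stopf("all taxonomic shifts are zero; hinge undefined")
  grid <- seq(0, max(x), by = b_step)
  best <- list(s = 0, b = 0, rss = Inf)
  sum_y2 <- sum(y^2)
  for (b in grid) {
    xb <- pmax(0, x - b)
    sxx <- sum(xb^2)
    s <- if (sxx > 0) max(0, sum(xb * y) / sxx) else 0
    rss <- sum_y2 - 2 * s * sum(xb * y) + s^2 * sxx
    if (rss < best$rss - 1e-12) best <- list(s = s, b = b, rss = rss)
  }
  structure(c(best, list(n_points = length(x))), class = "hinge_fit")
}

#' Null-standardized robustness scores for one perturbation curve
#'
#' The null model permutes the assignment of whole genome rows (with their
#' rrn copy numbers) to taxa, preserving genome-content marginals and the
#' community itself, and refits the hinge on the *same* perturbation events
#' (`d_T` unchanged, `d_F` recomputed). Attenuation
#' `A = (mean(s_null) - s_obs) / sd(s_null)` and buffering
#' `B = (b_obs - mean(b_null)) / sd(b_null)`; a degenerate null (sd = 0)
#' flags the score undefined (`NA`) and the run continues.
#'
#' @param curve a [perturbation_curve()].
#' @param content the [genome_content()] the curve was computed against.
#' @param n_null number of null permutations (>= 20; default 100).
#' @param seed integer master seed (nulls use the `"null"` sub-stream;
#'   defaults to the curve's seed).
#' @return one-row data.frame of class `robustness_score`: `sample_id`,
#'   `scope`, `attenuation`, `buffering`, `attenuation_defined`,
#'   `buffering_defined`, `s_obs`, `b_obs`, null means/sds, `n_null`.
#' @export
robustness_scores <- function(curve, content, n_null = 100, seed = NULL) {
  stopifnot(inherits(curve, "perturbation_curve"),
            inherits(content, "genome_content"))
  if (!is_count(n_null) || n_null < 20) stopf("n_null must be an integer >= 20")
  seed <- seed %||% curve$seed
  obs <- fit_hinge(curve)
  scope_fns <- scope_functions(content, curve$scope)
  perms <- with_seed(substream_seed(seed, "null"), {
    lapply(seq_len(n_null), function(i) sample.int(length(content$taxa)))
  })
  d_T <- curve$points$d_T
  s_null <- b_null <- rep(NA_real_, n_null)
  for (i in seq_len(n_null)) {
    p <- perms[[i]]
    cn <- content$copy_numbers[p, , drop = FALSE]
    rownames(cn) <- content$taxa
    rr <- stats::setNames(content$rrn[p], content$taxa)
    d_F <- scoped_dF(curve$abundance, curve$perturbed, content, scope_fns,
                     copy_numbers = cn, rrn = rr)
    if (all(is.na(d_F))) next
    fit <- fit_hinge(data.frame(d_T = d_T, d_F = d_F))
    s_null[i] <- fit$s
    b_null[i] <- fit$b
  }
  ok <- is.finite(s_null)
  if (sum(ok) < 2) stopf("null distribution empty for scope '%s'", curve$scope)
  sm <- mean(s_null[ok]); ssd <- stats::sd(s_null[ok])
  bm <- mean(b_null[ok]); bsd <- stats::sd(b_null[ok])
  a_def <- ssd > 0
  b_def <- bsd > 0
  if (!a_def) cs_log("info", sprintf(
    "degenerate null slope distribution for scope '%s': attenuation undefined",
    curve$scope))
  if (!b_def) cs_log("info", sprintf(
    "degenerate null offset distribution for scope '%s': buffering undefined",
    curve$scope))
  out <- data.frame(
    sample_id = curve$sample_id, scope = curve$scope,
    attenuation = if (a_def) (sm - obs$s) / ssd else NA_real_,
    buffering = if (b_def) (obs$b - bm) / bsd else NA_real_,
    attenuation_defined = a_def, buffering_defined = b_def,
    s_obs = obs$s, b_obs = obs$b,
    s_null_mean = sm, s_null_sd = ssd,
    b_null_mean = bm, b_null_sd = bsd,
    n_null = sum(ok),
    stringsAsFactors = FALSE)
  class(out) <- c("robustness_score", "data.frame")
  out
}

#' Robustness scores per pathway or superpathway
#'
#' Runs the perturbation, hinge fit and null standardization once per scope
#' at the requested level, sharing one set of perturbation events and one
#' set of null genome permutations across scopes (so that per-scope scores
#' of one sample are comparable). Empty scopes are skipped with a warning.
#'
#' @param abundance named abundance vector (one sample column).
#' @param content a [genome_content()].
#' @param level `"superpathway"` (default), `"pathway"`, or `"global"`.
#' @param magnitudes,reps,n_null,seed,sample_id as in
#'   [perturbation_curve()] / [robustness_scores()].
#' @return data.frame of class `robustness_score`, one row per scope.
#' @export
pathway_robustness <- function(abundance, content,
                               level = c("superpathway", "pathway", "global"),
                               magnitudes = seq(0.05, 0.75, by = 0.05),
                               reps = 20, n_null = 100, seed = 1L,
                               sample_id = "sample") {
  level <- match.arg(level)
  stopifnot(inherits(content, "genome_content"))
  if (!is_count(n_null) || n_null < 20) stopf("n_null must be an integer >= 20")
  scopes <- switch(level,
    global = "global",
    pathway = paste0("pathway:", unique(content$pathway_map$pathway_id)),
    superpathway = paste0("superpathway:",
                          unique(content$pathway_map$superpathway_id)))
  a <- align_abundance(abundance, content)
  P <- with_seed(substream_seed(seed, "perturb"), {
    do.call(cbind, lapply(rep(magnitudes, each = reps),
                          function(m) perturb_retry(a, m)))
  })
  rownames(P) <- content$taxa
  d_T <- bc_cols(a, P)
  perms <- with_seed(substream_seed(seed, "null"), {
    lapply(seq_len(n_null), function(i) sample.int(length(content$taxa)))
  })

  scope_fn_list <- list()
  for (sc in scopes) {
    fns <- tryCatch(scope_functions(content, sc), error = function(e) NULL)
    if (is.null(fns)) {
      warnf("scope '%s' contains no functions; skipped", sc)
      next
    }
    scope_fn_list[[sc]] <- fns
  }

  # observed fits per scope
  obs <- list()
  for (sc in names(scope_fn_list)) {
    d_F <- scoped_dF(a, P, content, scope_fn_list[[sc]])
    obs[[sc]] <- if (all(is.na(d_F))) NULL else
      fit_hinge(data.frame(d_T = d_T, d_F = d_F))
    if (is.null(obs[[sc]])) {
      warnf("scope '%s' carried by no abundant taxon; skipped", sc)
      scope_fn_list[[sc]] <- NULL
    }
  }

  s_null <- b_null <- matrix(NA_real_, n_null, length(scope_fn_list),
                             dimnames = list(NULL, names(scope_fn_list)))
  for (i in seq_len(n_null)) {
    p <- perms[[i]]
    cn <- content$copy_numbers[p, , drop = FALSE]
    rownames(cn) <- content$taxa
    rr <- stats::setNames(content$rrn[p], content$taxa)
    F_all <- profile_cols(cbind(P, a), content, copy_numbers = cn, rrn = rr)
    for (sc in names(scope_fn_list)) {
      fns <- scope_fn_list[[sc]]
      f0 <- F_all[fns, ncol(P) + 1]
      s0 <- sum(f0)
      if (s0 == 0) next
      fp <- F_all[fns, seq_len(ncol(P)), drop = FALSE]
      sp <- colSums(fp)
      d_F <- rep(1, ncol(P))
      nz <- sp > 0
      d_F[nz] <- bc_cols(f0 / s0, sweep(fp[, nz, drop = FALSE], 2, sp[nz], "/"))
      d_F[d_F < 1e-12] <- 0
      fit <- fit_hinge(data.frame(d_T = d_T, d_F = d_F))
      s_null[i, sc] <- fit$s
      b_null[i, sc] <- fit$b
    }
  }

  rows <- list()
  for (sc in names(scope_fn_list)) {
    sn <- s_null[, sc]; bn <- b_null[, sc]
    ok <- is.finite(sn)
    if (sum(ok) < 2) {
      warnf("null distribution empty for scope '%s'; skipped", sc)
      next
    }
    sm <- mean(sn[ok]); ssd <- stats::sd(sn[ok])
    bm <- mean(bn[ok]); bsd <- stats::sd(bn[ok])
    rows[[sc]] <- data.frame(
      sample_id = sample_id, scope = sc,
      attenuation = if (ssd > 0) (sm - obs[[sc]]$s) / ssd else NA_real_,
      buffering = if (bsd > 0) (obs[[sc]]$b - bm) / bsd else NA_real_,
      attenuation_defined = ssd > 0, buffering_defined = bsd > 0,
      s_obs = obs[[sc]]$s, b_obs = obs[[sc]]$b,
      s_null_mean = sm, s_null_sd = ssd,
      b_null_mean = bm, b_null_sd = bsd,
      n_null = sum(ok),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("robustness_score", "data.frame")
  out
}
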