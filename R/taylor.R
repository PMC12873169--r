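# Taylor's power-law stability analysis. For each individual, the temporal
# mean mu_i and standard deviation sigma_i of every taxon's relative
# abundance are regressed on the log-log scale: log10 sigma = log10 sqrt(V)
# + beta * log10 mu, so that sigma^2 = V * mu^(2*beta). beta = 1/2 is the
# Poisson limiting class, beta = 1 the exponential class; V is the variance
# a hypothetical dominant taxon (mu ~ 1) would attain, so larger V means a
# less stable community ranking. Fits are standardized to a reference group
# (Adults) and classified against circular confidence regions (the "healthy
# window").

#' Per-taxon temporal moments for one individual
#'
#' Mean and sample (n-1 denominator) standard deviation of each taxon's
#' relative abundance across the individual's time points. Zero observations
#' count for taxa detected in at least one time point; taxa never detected
#' (strictly above the detection threshold) are dropped.
#'
#' @param table an [abundance_table()].
#' @param individual_id individual to extract (needs >= 2 samples).
#' @param detection detection threshold used for the "ever detected" filter
#'   (default 1e-4).
#' @return object of class `taxon_moments`: data.frame with columns
#'   `taxon_id`, `mu`, `sigma`; attributes `individual_id`, `n_timepoints`,
#'   `age_group`.
#' @export
taxon_moments <- function(table, individual_id, detection = 1e-4) {
  stopifnot(inherits(table, "abundance_table"))
  idx <- which(table$samples$individual_id == individual_id)
  if (length(idx) < 2) {
    stopf("individual '%s' has fewer than 2 samples", individual_id)
  }
  x <- table$values[, idx, drop = FALSE]
  detected <- rowSums(x > detection) >= 1
  x <- x[detected, , drop = FALSE]
  out <- data.frame(taxon_id = rownames(x),
                    mu = rowMeans(x),
                    sigma = apply(x, 1, stats::sd),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("taxon_moments", "data.frame"),
            individual_id = individual_id,
            n_timepoints = length(idx),
            age_group = as.character(table$samples$age_group[idx[1]]))
}

#' Build a taxon_moments object from raw mean/sd pairs
#'
#' Escape hatch for fitting Taylor's law to externally computed moments
#' (e.g. count series).
#'
#' @param mu,sigma numeric vectors of per-taxon means and standard
#'   deviations.
#' @param individual_id label (default `"series"`).
#' @param n_timepoints number of time points the moments came from.
#' @return a `taxon_moments` object.
#' @export
moments_from_values <- function(mu, sigma, individual_id = "series",
                                n_timepoints = NA_integer_) {
  stopifnot(length(mu) == length(sigma))
  if (any(mu < 0) || any(sigma < 0)) stopf("moments must be non-negative")
  out <- data.frame(taxon_id = sprintf("t%04d", seq_along(mu)),
                    mu = as.numeric(mu), sigma = as.numeric(sigma),
                    stringsAsFactors = FALSE)
  structure(out, class = c("taxon_moments", "data.frame"),
            individual_id = individual_id,
            n_timepoints = as.integer(n_timepoints),
            age_group = NA_character_)
}

#' Fit Taylor's power law to one individual's taxon moments
#'
#' Ordinary least squares of `log10 sigma` on `log10 mu`. The slope is
#' `beta`; the intercept `a` gives `V = 10^(2a)`, so that
#' `sigma^2 = V * mu^(2*beta)` and a taxon at `mu = 1` has variance `V`.
#' Taxa with `mu = 0` or `sigma = 0` (constant series) cannot enter the log
#' regression and are excluded with a logged count; at least 3 usable taxa
#' are required. Fits from only 2 time points are flagged low-confidence.
#'
#' @param moments a [taxon_moments()] object.
#' @return one-row data.frame of class `taylor_fit`: `individual_id`,
#'   `age_group`, `V`, `beta`, `se_logV`, `se_beta`, `r2`, `n_taxa_fit`,
#'   `n_dropped`, `n_timepoints`, `low_confidence`.
#' @export
fit_taylor <- function(moments) {
  stopifnot(inherits(moments, "taxon_moments"))
  usable <- moments$mu > 0 & moments$sigma > 0
  n_drop <- sum(!usable)
  if (n_drop > 0) {
    cs_log("debug", sprintf("fit_taylor: dropped %d taxa with zero mean or sd",
                            n_drop))
  }
  m <- moments[usable, , drop = FALSE]
  if (nrow(m) < 3) {
    stopf("fewer than 3 taxa with positive mean and sd for individual '%s'",
          attr(moments, "individual_id"))
  }
  fit <- stats::lm(log10(sigma) ~ log10(mu), data = m)
  # summary.lm warns on exact-law (R^2 = 1) input; that case is legitimate
  # here (noiseless oracle cohorts)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  coefs <- sm$coefficients
  intercept <- coefs[1, 1]
  beta <- coefs[2, 1]
  n_tp <- attr(moments, "n_timepoints")
  out <- data.frame(
    individual_id = attr(moments, "individual_id"),
    age_group = attr(moments, "age_group") %||% NA_character_,
    V = 10^(2 * intercept),
    beta = beta,
    se_logV = 2 * coefs[1, 2],  # log10 V = 2 * intercept
    se_beta = coefs[2, 2],
    r2 = sm$r.squared,
    n_taxa_fit = nrow(m),
    n_dropped = n_drop,
    n_timepoints = n_tp,
    low_confidence = !is.na(n_tp) && n_tp < 3,
    stringsAsFactors = FALSE)
  class(out) <- c("taylor_fit", "data.frame")
  out
}

#' Taylor fits for every individual in a cohort
#'
#' @param table an [abundance_table()].
#' @param detection detection threshold for the per-individual moment filter.
#' @param min_samples individuals with fewer samples are skipped with a log
#'   message (default 2).
#' @return data.frame of class `taylor_fits`, one row per fitted individual.
#' @export
fit_taylor_cohort <- function(table, detection = 1e-4, min_samples = 2) {
  stopifnot(inherits(table, "abundance_table"))
  inds <- unique(table$samples$individual_id)
  rows <- list()
  for (ind in inds) {
    n <- sum(table$samples$individual_id == ind)
    if (n < min_samples) {
      cs_log("info", sprintf("skipping individual '%s' (%d sample(s))", ind, n))
      next
    }
    rows[[ind]] <- fit_taylor(taxon_moments(table, ind, detection))
  }
  if (!length(rows)) stopf("no individual has >= %d samples", min_samples)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("taylor_fits", "data.frame")
  out
}

#' Standardize Taylor fits to a reference group
#'
#' Per-individual coordinates `(log10 V, beta)` are z-scored against the
#' reference group's mean and (n-1) standard deviation per axis, so
#' reference individuals have mean 0 and sd 1 on both axes; per-individual
#' standard errors are divided by the same reference sds. The amplitude axis
#' is `log10 V` because V is a multiplicative amplitude.
#'
#' @param fits a `taylor_fits` data.frame (needs `age_group`).
#' @param reference reference age group (default `"A"`, Adults).
#' @return data.frame of class `taylor_space` with columns `individual_id`,
#'   `age_group`, `z_V`, `z_beta`, `se_z_V`, `se_z_beta`; attributes
#'   `reference`, `ref_mean`, `ref_sd`.
#' @export
standardize_fits <- function(fits, reference = "A") {
  stopifnot(is.data.frame(fits))
  reference <- as.character(as_age_group(reference))
  ref <- fits[fits$age_group == reference, , drop = FALSE]
  if (nrow(ref) < 2) stopf("reference group '%s' has fewer than 2 fits",
                           reference)
  ref_mean <- c(logV = mean(log10(ref$V)), beta = mean(ref$beta))
  ref_sd <- c(logV = stats::sd(log10(ref$V)), beta = stats::sd(ref$beta))
  if (any(ref_sd == 0)) stopf("reference group has zero variance on an axis")
  out <- data.frame(
    individual_id = fits$individual_id,
    age_group = fits$age_group,
    z_V = (log10(fits$V) - ref_mean["logV"]) / ref_sd["logV"],
    z_beta = (fits$beta - ref_mean["beta"]) / ref_sd["beta"],
    se_z_V = fits$se_logV / ref_sd["logV"],
    se_z_beta = fits$se_beta / ref_sd["beta"],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("taylor_space", "data.frame"),
            reference = reference, ref_mean = ref_mean, ref_sd = ref_sd)
}

#' Radius of the circular confidence region in standardized Taylor space
#'
#' For a standard bivariate normal the circle of radius
#' `r = sqrt(-2 * ln(1 - p))` contains probability `p`; `p = 0.68` and
#' `p = 0.98` give the inner and outer rings of the healthy window.
#'
#' @param p coverage probability in `(0, 1)`.
#' @return radius (same length as `p`).
#' @export
confidence_radius <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stopf("p must lie strictly between 0 and 1")
  }
  sqrt(-2 * log(1 - p))
}

#' Classify individuals against the healthy window
#'
#' An individual is inside the window at level `p` iff its standardized
#' radial distance `sqrt(z_V^2 + z_beta^2)` is `<=` the confidence radius
#' (boundary points count as inside).
#'
#' @param space a [standardize_fits()] result.
#' @param p coverage probability (default 0.68).
#' @return data.frame with columns `individual_id`, `age_group`, `distance`,
#'   `radius`, `inside`.
#' @export
classify_window <- function(space, p = 0.68) {
  stopifnot(inherits(space, "taylor_space"))
  r <- confidence_radius(p)
  d <- sqrt(space$z_V^2 + space$z_beta^2)
  data.frame(individual_id = space$individual_id,
             age_group = space$age_group,
             distance = d,
             radius = r,
             inside = d <= r,
             stringsAsFactors = FALSE)
}
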