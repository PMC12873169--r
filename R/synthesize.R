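# Synthetic cohort and genome-content generators. These stand in for the
# deposited sequencing data: they emulate a three-age-group longitudinal
# cohort (Infant/Adult/Elder, up to 8 irregularly spaced samples per
# individual) whose within-individual temporal fluctuations follow Taylor's
# power law sigma^2 = V * mu^(2*beta), with a core/transient prevalence
# structure, and PICRUSt2-style genome-content matrices with a tunable
# functional-redundancy knob.

# Enrollment age ranges (years) per group, matching the cohort design the
# generator emulates: Infants 2-5, Adults 27-44, Elders 69-81.
.age_ranges <- list(I = c(2, 5), A = c(27, 44), E = c(69, 81))

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the emulated study design: 10 individuals per age group,
#' a target of 8 samples per individual at irregular ~75-day intervals
#' (total follow-up ~360-750 days), 60 genus-level taxa, and Taylor's-law
#' fluctuations with amplitude `taylor_V = 0.3` and index
#' `taylor_beta = 0.75` (midway between the Poisson and exponential limiting
#' classes).
#'
#' @param n_individuals_per_group individuals per age group (default 10).
#' @param n_timepoints target samples per individual (default 8).
#' @param interval_days_mean,interval_days_sd mean/sd of the jittered
#'   between-sample interval in days (defaults 75/25; intervals are floored
#'   at 1 day).
#' @param n_taxa number of taxa (default 60).
#' @param core_fraction fraction of taxa given high prevalence in all groups
#'   (default 0.4). Core taxa also occupy the top abundance ranks.
#' @param core_prevalence per-sample presence probability of core taxa
#'   (default 0.95).
#' @param transient_prevalence baseline presence probability of transient
#'   taxa in the Adult group (default 0.45).
#' @param group_prevalence_trend additive presence-probability shift per age
#'   group step for transient taxa (default 0.1): with a positive trend the
#'   expected prevalence is ordered Infant < Adult < Elder, so core size
#'   grows with age.
#' @param taylor_V fluctuation amplitude V > 0 (default 0.3).
#' @param taylor_beta power-law index in `[0.5, 1]` (default 0.75).
#' @param mean_abundance_range range of the geometric rank-abundance ladder
#'   of per-taxon mean relative abundances, before closure (default
#'   `c(1e-3, 0.15)`).
#' @param detection relative-abundance detection threshold (default 1e-4).
#'   Present taxa are floored just above it (see Details).
#' @param fluctuation `"gamma"` (default) or `"truncnorm"`. Both target
#'   standard deviation `sqrt(taylor_V) * mu^taylor_beta`; the gamma draw
#'   has exactly the designed mean and sd on positive support, whereas the
#'   zero-truncated normal distorts both whenever `sigma` is comparable to
#'   `mu` (which at `V = 0.3` is most taxa), and is retained only for
#'   comparison.
#' @param noiseless logical; diagnostic mode producing exact designed
#'   moments (see Details). Default `FALSE`.
#' @param seed integer seed; the generator is bit-reproducible from it.
#'
#' @details
#' In stochastic mode each taxon's abundance at a time point is, when the
#' taxon is present, a draw centred on its subject-level mean `mu` with
#' standard deviation `sqrt(taylor_V) * mu^taylor_beta`, floored at
#' `3 * detection` so that a "present" draw is actually detectable (making
#' realized prevalence equal the configured presence probability); absent
#' draws are 0; the sample column is then renormalized to sum 1.
#'
#' In noiseless mode (requires an even `n_timepoints`) the fluctuation is
#' applied deterministically as an alternating +/- `sigma * sqrt((n-1)/n)`
#' around `mu`, all taxa are always present, and columns are *not*
#' renormalized: the per-taxon sample mean and (n-1)-denominator standard
#' deviation then equal `mu` and `sigma` exactly, giving an exact oracle for
#' the Taylor estimator at the cost of exact compositional closure.
#'
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals_per_group = 10,
                          n_timepoints = 8,
                          interval_days_mean = 75,
                          interval_days_sd = 25,
                          n_taxa = 60,
                          core_fraction = 0.4,
                          core_prevalence = 0.95,
                          transient_prevalence = 0.45,
                          group_prevalence_trend = 0.1,
                          taylor_V = 0.3,
                          taylor_beta = 0.75,
                          mean_abundance_range = c(1e-3, 0.15),
                          detection = 1e-4,
                          fluctuation = c("gamma", "truncnorm"),
                          noiseless = FALSE,
                          seed = 1L) {
  fluctuation <- match.arg(fluctuation)
  cfg <- list(n_individuals_per_group = n_individuals_per_group,
              n_timepoints = n_timepoints,
              interval_days_mean = interval_days_mean,
              interval_days_sd = interval_days_sd,
              n_taxa = n_taxa,
              core_fraction = core_fraction,
              core_prevalence = core_prevalence,
              transient_prevalence = transient_prevalence,
              group_prevalence_trend = group_prevalence_trend,
              taylor_V = taylor_V,
              taylor_beta = taylor_beta,
              mean_abundance_range = mean_abundance_range,
              detection = detection,
              fluctuation = fluctuation,
              noiseless = noiseless,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$taylor_beta < 0.5 || cfg$taylor_beta > 1) {
    stopf("taylor_beta must lie in [0.5, 1]")
  }
  if (cfg$taylor_V <= 0) stopf("taylor_V must be positive")
  if (cfg$core_fraction < 0 || cfg$core_fraction > 1) {
    stopf("core_fraction must lie in [0, 1]")
  }
  if (cfg$interval_days_mean <= 0 || cfg$interval_days_sd <= 0) {
    stopf("interval parameters must be positive")
  }
  if (cfg$n_timepoints < 2) stopf("n_timepoints must be >= 2")
  if (cfg$n_taxa < 3) stopf("n_taxa must be >= 3")
  if (cfg$noiseless && cfg$n_timepoints %% 2 != 0) {
    stopf("noiseless mode requires an even n_timepoints")
  }
  validate_detection(cfg$detection)
  invisible(cfg)
}

#' Generate a synthetic longitudinal cohort
#'
#' See [cohort_config()] for the generative model. Taxa `g001 ...` are
#' ordered by decreasing design mean abundance; the first
#' `round(core_fraction * n_taxa)` are core taxa. Individuals are labelled
#' `I01..`, `A01..`, `E01..`.
#'
#' @param config a [cohort_config()].
#' @return an [abundance_table()]; in noiseless mode the table carries
#'   `compositional = FALSE` (see [cohort_config()] Details).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_taxa <- cfg$n_taxa
  taxa <- sprintf("g%03d", seq_len(n_taxa))
  n_core <- round(cfg$core_fraction * n_taxa)
  is_core <- seq_len(n_taxa) <= n_core

  # geometric rank-abundance ladder for the design means (before closure)
  lo <- log10(cfg$mean_abundance_range[1])
  hi <- log10(cfg$mean_abundance_range[2])
  base_log10 <- seq(hi, lo, length.out = n_taxa)

  floor_val <- 3 * cfg$detection
  n_tp <- cfg$n_timepoints
  sd_amp <- sqrt(cfg$taylor_V)

  cols <- list()
  meta <- list()
  for (gidx in seq_along(age_group_levels)) {
    grp <- age_group_levels[gidx]
    p_transient <- min(1, max(0.02, cfg$transient_prevalence +
                                cfg$group_prevalence_trend * (gidx - 2)))
    p_present <- ifelse(is_core, cfg$core_prevalence, p_transient)
    rng <- .age_ranges[[grp]]
    for (i in seq_len(cfg$n_individuals_per_group)) {
      ind <- sprintf("%s%02d", grp, i)
      age0 <- stats::runif(1, rng[1], rng[2])
      gaps <- pmax(1, round(stats::rnorm(n_tp - 1, cfg$interval_days_mean,
                                         cfg$interval_days_sd)))
      days <- c(0L, as.integer(cumsum(gaps)))

      if (cfg$noiseless) {
        # Diagnostic ladder lifted to [0.1, 0.5] and not closed to sum 1:
        # the alternating two-point fluctuation needs mu - sigma > 0, which
        # closure to 60 taxa cannot provide at V ~ 0.3.
        mu <- 10^(seq(log10(0.5), log10(0.1), length.out = n_taxa))
        sigma <- sd_amp * mu^cfg$taylor_beta
        amp <- sigma * sqrt((n_tp - 1) / n_tp)
        if (any(mu - amp < 0)) {
          stopf("noiseless mode infeasible: sqrt(V)*mu^beta exceeds mu for the rarest taxa")
        }
        x <- matrix(0, n_taxa, n_tp)
        for (t in seq_len(n_tp)) {
          sign_t <- (-1)^(t + seq_len(n_taxa))
          x[, t] <- mu + sign_t * amp
        }
      } else {
        # subject-level means: ladder + individual lognormal effect, closed to 1
        mu <- 10^(base_log10 + stats::rnorm(n_taxa, 0, 0.5))
        mu <- mu / sum(mu)
        sigma <- sd_amp * mu^cfg$taylor_beta
        present <- matrix(stats::runif(n_taxa * n_tp), n_taxa, n_tp) <=
          p_present
        draws <- if (cfg$fluctuation == "gamma") {
          # gamma with matched (mu, sigma): positive support, exact designed
          # moments at every mean, unlike the truncated normal
          matrix(stats::rgamma(n_taxa * n_tp, shape = rep((mu / sigma)^2, n_tp),
                               rate = rep(mu / sigma^2, n_tp)), n_taxa, n_tp)
        } else {
          matrix(pmax(stats::rnorm(n_taxa * n_tp, mean = mu, sd = sigma), 0),
                 n_taxa, n_tp)
        }
        # present draws are floored just above the detection limit so the
        # configured presence probabilities are realized exactly
        x <- ifelse(present, pmax(draws, floor_val), 0)
        x <- sweep(x, 2, colSums(x), "/")
      }
      colnames(x) <- sprintf("%s_T%d", ind, seq_len(n_tp))
      cols[[ind]] <- x
      meta[[ind]] <- data.frame(
        sample_id = colnames(x),
        individual_id = ind,
        age_group = grp,
        collection_day = days,
        subject_age_years = age0 + days / 365.25,
        stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- taxa
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  tab <- abundance_table(values, metadata,
                         compositional = !cfg$noiseless)
  attr(tab, "core_taxa") <- taxa[is_core]
  attr(tab, "config") <- cfg
  tab
}

#' Configuration for the synthetic genome-content generator
#'
#' @param n_taxa number of taxa (default 60; must match the cohort when used
#'   together).
#' @param n_functions number of gene families (default 120).
#' @param redundancy fraction in `[0, 1]` of gene families shared identically
#'   by all taxa. `0` gives taxa pairwise-disjoint function sets, `1` gives
#'   all taxa identical genome rows.
#' @param rrn_min,rrn_max range of the uniform integer 16S copy numbers
#'   (defaults 1/15).
#' @param n_pathways,n_superpathways sizes of the two-level KEGG-style
#'   grouping (defaults 12/4).
#' @param seed integer seed.
#' @return a validated list of class `genome_content_config`.
#' @export
genome_content_config <- function(n_taxa = 60, n_functions = 120,
                                  redundancy = 0.5,
                                  rrn_min = 1, rrn_max = 15,
                                  n_pathways = 12, n_superpathways = 4,
                                  seed = 1L) {
  cfg <- list(n_taxa = n_taxa, n_functions = n_functions,
              redundancy = redundancy, rrn_min = rrn_min, rrn_max = rrn_max,
              n_pathways = n_pathways, n_superpathways = n_superpathways,
              seed = as.integer(seed))
  if (cfg$redundancy < 0 || cfg$redundancy > 1) {
    stopf("redundancy must lie in [0, 1]")
  }
  if (cfg$rrn_min < 1 || cfg$rrn_max < cfg$rrn_min) {
    stopf("rrn copy-number range invalid (need 1 <= rrn_min <= rrn_max)")
  }
  if (cfg$n_functions < cfg$n_pathways) {
    stopf("n_functions must be >= n_pathways")
  }
  if (cfg$n_pathways < cfg$n_superpathways) {
    stopf("n_pathways must be >= n_superpathways")
  }
  structure(cfg, class = "genome_content_config")
}

#' Generate a synthetic genome-content table
#'
#' `round(redundancy * n_functions)` gene families are "shared": present in
#' every taxon with a common copy number. The remaining families are
#' "specific": each is carried by exactly one taxon (the first `n_taxa`
#' specific families cover every taxon once, so no taxon has an empty genome
#' when `n_functions * (1 - redundancy) >= n_taxa`). Copy numbers are small
#' integers (1-3); 16S copy numbers are uniform integers in
#' `[rrn_min, rrn_max]`. Functions are partitioned into pathways and
#' pathways into superpathways round-robin.
#'
#' @param config a [genome_content_config()].
#' @return a [genome_content()].
#' @export
generate_genome_content <- function(config) {
  stopifnot(inherits(config, "genome_content_config"))
  with_seed(config$seed, generate_genome_content_impl(config))
}

generate_genome_content_impl <- function(cfg) {
  taxa <- sprintf("g%03d", seq_len(cfg$n_taxa))
  fns <- sprintf("fn%04d", seq_len(cfg$n_functions))
  n_shared <- round(cfg$redundancy * cfg$n_functions)
  shared_idx <- if (n_shared > 0) sample(cfg$n_functions, n_shared) else
    integer(0)
  specific_idx <- setdiff(seq_len(cfg$n_functions), shared_idx)

  m <- matrix(0, cfg$n_taxa, cfg$n_functions, dimnames = list(taxa, fns))
  if (length(shared_idx)) {
    m[, shared_idx] <- rep(sample(1:3, length(shared_idx), replace = TRUE),
                           each = cfg$n_taxa)
  }
  if (length(specific_idx)) {
    n_spec <- length(specific_idx)
    owners <- if (n_spec >= cfg$n_taxa) {
      c(sample(cfg$n_taxa), sample(cfg$n_taxa, n_spec - cfg$n_taxa,
                                   replace = TRUE))
    } else {
      sample(cfg$n_taxa, n_spec)
    }
    m[cbind(owners, specific_idx)] <- sample(1:3, n_spec, replace = TRUE)
  }
  rrn <- stats::setNames(
    as.numeric(sample(seq(cfg$rrn_min, cfg$rrn_max), cfg$n_taxa,
                      replace = TRUE)), taxa)

  pw_of_fn <- rep_len(seq_len(cfg$n_pathways), cfg$n_functions)
  sp_of_pw <- rep_len(seq_len(cfg$n_superpathways), cfg$n_pathways)
  map <- data.frame(
    function_id = fns,
    pathway_id = sprintf("pw%02d", pw_of_fn),
    superpathway_id = sprintf("sp%d", sp_of_pw[pw_of_fn]),
    stringsAsFactors = FALSE)

  genome_content(m, rrn, map)
}
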