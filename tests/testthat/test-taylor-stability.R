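# Taylor's power-law fitting, standardization, and the healthy window

test_that("taxon moments follow the stated conventions", {
  v <- cbind(S1 = c(0.2, 0.0, 0.4, 0.4),
             S2 = c(0.4, 0.0, 0.4, 0.2))
  rownames(v) <- c("a", "absent", "const", "d")
  tab <- make_table(v, individual = c("A01", "A01"), days = c(0, 30))
  m <- taxon_moments(tab, "A01")
  expect_false("absent" %in% m$taxon_id)  # never detected: dropped
  expect_equal(m$mu[m$taxon_id == "a"], 0.3)
  expect_equal(m$sigma[m$taxon_id == "a"], stats::sd(c(0.2, 0.4)))
  expect_equal(m$sigma[m$taxon_id == "const"], 0)  # kept, excluded at fit
  expect_error(taxon_moments(tab, "nope"), "fewer than 2")
})

test_that("exact power-law points are recovered exactly", {
  mu <- c(0.1, 0.2, 0.4)
  m <- moments_from_values(mu, 0.5 * mu^0.8, n_timepoints = 5)
  fit <- fit_taylor(m)
  expect_equal(fit$beta, 0.8, tolerance = 1e-10)
  expect_equal(fit$V, 0.25, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_false(fit$low_confidence)
})

test_that("common rescaling shifts V by c^(2-2*beta) and leaves beta", {
  set.seed(3)
  mu <- runif(20, 0.01, 0.5)
  sigma <- 0.5 * mu^0.8 * exp(rnorm(20, 0, 0.1))
  f1 <- fit_taylor(moments_from_values(mu, sigma))
  cc <- 3.7
  f2 <- fit_taylor(moments_from_values(cc * mu, cc * sigma))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
  expect_equal(f2$V, f1$V * cc^(2 - 2 * f1$beta), tolerance = 1e-8)
})

test_that("fits are invariant to taxon order and duplication", {
  set.seed(4)
  mu <- runif(15, 0.01, 0.5)
  sigma <- 0.6 * mu^0.7 * exp(rnorm(15, 0, 0.1))
  f1 <- fit_taylor(moments_from_values(mu, sigma))
  perm <- sample(15)
  f2 <- fit_taylor(moments_from_values(mu[perm], sigma[perm]))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f2$V, f1$V, tolerance = 1e-12)
  f3 <- fit_taylor(moments_from_values(rep(mu, 2), rep(sigma, 2)))
  expect_equal(f3$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f3$V, f1$V, tolerance = 1e-12)
})

test_that("degenerate moment sets are rejected", {
  expect_error(fit_taylor(moments_from_values(c(0.1, 0.2), c(0.01, 0.02))),
               "fewer than 3")
  # constant taxa (sigma = 0) don't count toward the minimum
  expect_error(fit_taylor(moments_from_values(c(0.1, 0.2, 0.3, 0.4),
                                              c(0.01, 0.02, 0, 0))),
               "fewer than 3")
})

test_that("standardization centers and scales on the reference group", {
  fits <- data.frame(
    individual_id = c("A1", "A2", "A3", "I1"),
    age_group = c("A", "A", "A", "I"),
    V = c(0.1, 0.2, 0.4, 0.8),
    beta = c(0.6, 0.7, 0.8, 0.9),
    se_logV = rep(0.1, 4), se_beta = rep(0.05, 4))
  sp <- standardize_fits(fits, reference = "A")
  ref <- sp[sp$age_group == "A", ]
  expect_equal(mean(ref$z_V), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ref$z_V), 1, tolerance = 1e-12)
  expect_equal(mean(ref$z_beta), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ref$z_beta), 1, tolerance = 1e-12)
  # an individual sitting at the reference mean lands at the origin
  at_mean <- fits[1, ]
  at_mean$individual_id <- "X"
  at_mean$age_group <- "E"
  at_mean$V <- 10^mean(log10(fits$V[1:3]))
  at_mean$beta <- mean(fits$beta[1:3])
  sp2 <- standardize_fits(rbind(fits, at_mean))
  expect_equal(sp2$z_V[sp2$individual_id == "X"], 0, tolerance = 1e-12)
  expect_equal(sp2$z_beta[sp2$individual_id == "X"], 0, tolerance = 1e-12)
  # two reference sds above the mean on the V axis
  two_up <- at_mean
  two_up$individual_id <- "Y"
  two_up$V <- 10^(mean(log10(fits$V[1:3])) + 2 * stats::sd(log10(fits$V[1:3])))
  sp3 <- standardize_fits(rbind(fits, two_up))
  expect_equal(sp3$z_V[sp3$individual_id == "Y"], 2, tolerance = 1e-10)
  # degenerate reference
  degen <- fits; degen$V <- 0.2
  expect_error(standardize_fits(degen), "zero variance")
})

test_that("confidence radii follow the bivariate-normal closed form", {
  expect_equal(confidence_radius(0.68), sqrt(-2 * log(0.32)))
  expect_equal(confidence_radius(0.98), sqrt(-2 * log(0.02)))
  # r -> 0 as p -> 0
  expect_lt(confidence_radius(1e-9), 1e-4)
  expect_error(confidence_radius(1), "between 0 and 1")
  expect_error(confidence_radius(0), "between 0 and 1")
})

test_that("window classification is radial with an inclusive boundary", {
  sp <- structure(
    data.frame(individual_id = c("o", "far", "edge"),
               age_group = c("A", "I", "E"),
               z_V = c(0, 3, confidence_radius(0.98)),
               z_beta = c(0, 0, 0),
               se_z_V = 0.1, se_z_beta = 0.1),
    class = c("taylor_space", "data.frame"),
    reference = "A", ref_mean = c(logV = 0, beta = 0),
    ref_sd = c(logV = 1, beta = 1))
  cl <- classify_window(sp, 0.98)
  expect_true(cl$inside[cl$individual_id == "o"])
  expect_false(cl$inside[cl$individual_id == "far"])   # 3 > 2.797
  expect_true(cl$inside[cl$individual_id == "edge"])   # boundary is inside
})

test_that("classification is invariant to affine rescaling of raw parameters", {
  tab <- generate_cohort(cohort_config(seed = 12,
                                       n_individuals_per_group = 4,
                                       n_timepoints = 4, n_taxa = 30))
  fits <- fit_taylor_cohort(tab)
  cl1 <- classify_window(standardize_fits(fits), 0.68)
  fits2 <- fits
  fits2$V <- fits2$V * 7.3          # multiplicative on V = affine on log10 V
  fits2$beta <- 2 + 0.5 * fits2$beta
  fits2$se_logV <- fits2$se_logV
  fits2$se_beta <- 0.5 * fits2$se_beta
  cl2 <- classify_window(standardize_fits(fits2), 0.68)
  expect_equal(cl1$inside, cl2$inside)
  expect_equal(cl1$distance, cl2$distance, tolerance = 1e-10)
})

test_that("fitted beta stays below 1 on cohorts designed with beta < 1", {
  tab <- generate_cohort(cohort_config(seed = 10))
  fits <- fit_taylor_cohort(tab)
  expect_true(mean(fits$beta) < 1)
  expect_true(all(fits$r2 > 0.5))
})
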