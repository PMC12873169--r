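# taxa-function robustness: projection, perturbation, hinge fit, nulls

test_that("functional profiles follow the rrn-corrected projection", {
  ic <- identity_content(4)
  a <- stats::setNames(c(0.4, 0.3, 0.2, 0.1), ic$taxa)
  expect_equal(unname(functional_profile(a, ic)), unname(a))

  # identical genome rows: profile independent of how abundance splits
  uc <- uniform_content(3, 5)
  p1 <- functional_profile(stats::setNames(c(0.8, 0.1, 0.1), uc$taxa), uc)
  p2 <- functional_profile(stats::setNames(c(0.1, 0.2, 0.7), uc$taxa), uc)
  expect_equal(p1, p2, tolerance = 1e-12)

  # rrn = (2, 1), equal abundances, identity matrix -> (1/3, 2/3)
  taxa <- c("g001", "g002"); fns <- c("fn0001", "fn0002")
  m <- diag(2); dimnames(m) <- list(taxa, fns)
  gc2 <- genome_content(m, c(g001 = 2, g002 = 1),
                        data.frame(function_id = fns, pathway_id = "p1",
                                   superpathway_id = "s1"))
  expect_equal(unname(functional_profile(c(g001 = 0.5, g002 = 0.5), gc2)),
               c(1 / 3, 2 / 3))

  # no abundant taxon carries any function
  m0 <- m; m0["g001", ] <- 0
  gc0 <- genome_content(m0, c(g001 = 1, g002 = 1),
                        data.frame(function_id = fns, pathway_id = "p1",
                                   superpathway_id = "s1"))
  expect_error(functional_profile(c(g001 = 1, g002 = 0), gc0), "all-zero")
})

test_that("knockout perturbation walks the cumulative-mass rule", {
  a <- stats::setNames(rep(0.1, 10), sprintf("g%03d", 1:10))
  set.seed(1)
  expect_identical(perturb(a, 0), a)
  p <- perturb(a, 0.3)
  expect_equal(sum(p == 0), 3)          # exactly 3 equal-mass taxa removed
  expect_equal(sum(p), 1)
  expect_error(perturb(a, 0.96), "magnitude")
  # a magnitude no removal order can satisfy empties the community
  b <- stats::setNames(c(0.5, 0.5), c("x", "y"))
  set.seed(2)
  expect_error(perturb(b, 0.6), "empty")
})

test_that("Bray-Curtis matches its definition and an independent oracle", {
  x <- c(0.5, 0.5, 0); y <- c(0.25, 0.25, 0.5)
  expect_equal(bray_curtis(x, x), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(x, y), 0.5)
  expect_equal(bray_curtis(x, y), bray_curtis(y, x))
  expect_error(bray_curtis(c(-0.1, 0.6, 0.5), y), "negative")
  # oracle: vegan::vegdist on random compositions
  set.seed(5)
  for (i in 1:20) {
    u <- rexp(8); u <- u / sum(u)
    v <- rexp(8); v <- v / sum(v)
    expect_equal(bray_curtis(u, v),
                 as.numeric(vegan::vegdist(rbind(u, v), method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("perturbation curves have the stated geometry and cardinality", {
  ic <- identity_content(12)
  a <- stats::setNames(rep(1 / 12, 12), ic$taxa)
  cv <- perturbation_curve(a, ic, magnitudes = seq(0.1, 0.5, 0.1), reps = 4,
                           seed = 3)
  expect_equal(nrow(cv$points), 20)
  # identity content: functional shift equals taxonomic shift pointwise
  expect_lt(max(abs(cv$points$d_F - cv$points$d_T)), 1e-12)
  # determinism
  cv2 <- perturbation_curve(a, ic, magnitudes = seq(0.1, 0.5, 0.1), reps = 4,
                            seed = 3)
  expect_identical(cv$points, cv2$points)

  # identical genomes: function space is blind to composition
  uc <- uniform_content(12, 6)
  cvu <- perturbation_curve(a, uc, magnitudes = seq(0.1, 0.5, 0.1), reps = 4,
                            seed = 3)
  expect_true(all(cvu$points$d_F == 0))
})

test_that("scope restriction reduces to the global computation when full", {
  gc <- generate_genome_content(genome_content_config(
    n_taxa = 10, n_functions = 20, redundancy = 0.4, n_pathways = 4,
    n_superpathways = 1, seed = 6))
  a <- stats::setNames(rep(0.1, 10), gc$taxa)
  cv_g <- perturbation_curve(a, gc, scope = "global",
                             magnitudes = c(0.2, 0.4), reps = 5, seed = 9)
  cv_s <- perturbation_curve(a, gc, scope = "superpathway:sp1",
                             magnitudes = c(0.2, 0.4), reps = 5, seed = 9)
  expect_equal(cv_g$points$d_F, cv_s$points$d_F, tolerance = 1e-12)
  expect_error(perturbation_curve(a, gc, scope = "pathway:nope"),
               "no functions")
})

test_that("hinge fits recover designed curves to grid precision", {
  x <- seq(0.02, 0.8, length.out = 40)
  f1 <- fit_hinge(data.frame(d_T = x, d_F = 0.6 * pmax(0, x - 0.1)))
  expect_equal(f1$s, 0.6, tolerance = 1e-6)
  expect_equal(f1$b, 0.1, tolerance = 0.005)
  f2 <- fit_hinge(data.frame(d_T = x, d_F = x))
  expect_equal(f2$s, 1, tolerance = 1e-10)
  expect_equal(f2$b, 0)
  f3 <- fit_hinge(data.frame(d_T = x, d_F = rep(0, 40)))
  expect_equal(f3$s, 0)
  expect_equal(f3$b, 0)  # flat data ties break to the smallest offset
  expect_error(fit_hinge(data.frame(d_T = x[1:5], d_F = x[1:5])), "10 points")
  expect_error(fit_hinge(data.frame(d_T = rep(0, 12), d_F = rep(0, 12))),
               "shifts are zero")
})

test_that("degenerate nulls flag attenuation undefined and runs continue", {
  uc <- uniform_content(10, 6)
  a <- uniform_community(uc)
  cv <- perturbation_curve(a, uc, magnitudes = seq(0.1, 0.6, 0.1), reps = 4,
                           seed = 2)
  sc <- robustness_scores(cv, uc, n_null = 20)
  expect_false(sc$attenuation_defined)
  expect_true(is.na(sc$attenuation))
  expect_equal(sc$s_obs, 0)
  expect_error(robustness_scores(cv, uc, n_null = 5), "n_null")
})

test_that("robustness scores are invariant to taxon relabeling", {
  gc <- generate_genome_content(genome_content_config(
    n_taxa = 8, n_functions = 16, redundancy = 0.3, n_pathways = 4,
    n_superpathways = 2, seed = 7))
  a <- stats::setNames(c(0.3, 0.2, 0.15, 0.1, 0.1, 0.05, 0.05, 0.05),
                       gc$taxa)
  cv <- perturbation_curve(a, gc, magnitudes = seq(0.1, 0.6, 0.1), reps = 5,
                           seed = 4)
  sc <- robustness_scores(cv, gc, n_null = 30)

  # relabel taxa consistently everywhere (same order, new names)
  new <- sprintf("tax_%02d", 1:8)
  gc2 <- gc
  rownames(gc2$copy_numbers) <- new
  gc2$taxa <- new
  names(gc2$rrn) <- new
  a2 <- stats::setNames(unname(a), new)
  cv2 <- perturbation_curve(a2, gc2, magnitudes = seq(0.1, 0.6, 0.1),
                            reps = 5, seed = 4)
  sc2 <- robustness_scores(cv2, gc2, n_null = 30)
  expect_equal(sc$attenuation, sc2$attenuation, tolerance = 1e-10)
  expect_equal(sc$buffering, sc2$buffering, tolerance = 1e-10)
})

test_that("per-pathway scores cover scopes and are deterministic", {
  gc <- generate_genome_content(genome_content_config(
    n_taxa = 10, n_functions = 20, redundancy = 0.4, n_pathways = 4,
    n_superpathways = 2, seed = 8))
  a <- stats::setNames(rep(0.1, 10), gc$taxa)
  r1 <- pathway_robustness(a, gc, level = "superpathway",
                           magnitudes = seq(0.1, 0.6, 0.1), reps = 5,
                           n_null = 20, seed = 11, sample_id = "s1")
  expect_equal(nrow(r1), 2)  # one row per superpathway
  expect_setequal(r1$scope, c("superpathway:sp1", "superpathway:sp2"))
  r2 <- pathway_robustness(a, gc, level = "superpathway",
                           magnitudes = seq(0.1, 0.6, 0.1), reps = 5,
                           n_null = 20, seed = 11, sample_id = "s1")
  expect_identical(r1, r2)

  # a scope carried identically by all taxa has d_F = 0 regardless of the
  # global structure around it
  m <- gc$copy_numbers
  shared_fns <- gc$pathway_map$function_id[gc$pathway_map$pathway_id == "pw01"]
  m[, shared_fns] <- 2
  gc3 <- genome_content(m, gc$rrn, gc$pathway_map)
  cvp <- perturbation_curve(a, gc3, scope = "pathway:pw01",
                            magnitudes = seq(0.1, 0.6, 0.1), reps = 5,
                            seed = 12)
  expect_true(all(cvp$points$d_F == 0))
})
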