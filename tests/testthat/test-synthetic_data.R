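test_that("synthetic_truth splits class totals over the compound catalog", {
  truth <- synthetic_truth()
  cat_tab <- truth$catalog
  by_class <- tapply(cat_tab$basal, cat_tab$compound_class, sum)
  expect_equal(as.numeric(by_class[BVOC_CLASSES]),
               unname(truth$class_basal[BVOC_CLASSES]))
  by_class_i <- tapply(cat_tab$induction, cat_tab$compound_class, sum)
  expect_equal(as.numeric(by_class_i[BVOC_CLASSES]),
               unname(truth$class_induction[BVOC_CLASSES]))
  expect_equal(truth$total_induction, sum(truth$class_induction))
  # dominant compound carries dominant_share of its class
  mt <- cat_tab[cat_tab$compound_class == "MT", ]
  expect_equal(max(mt$basal) / sum(mt$basal), 0.6)
})

test_that("synthetic_truth validates its arguments", {
  expect_error(synthetic_truth(class_basal = c(MT = 1)),
               class = "bvoc_config_error")
  expect_error(synthetic_truth(loading_low = 1.5))
  expect_error(synthetic_truth(noise_cv = -1))
})

test_that("study presets differ in design and damage intensity", {
  a1 <- study_truth("Abisko1")
  tr <- study_truth("Tromso")
  expect_equal(a1$density_levels, c(0, 5, 15, 30, 50))
  expect_equal(tr$density_levels, c(0, 5, 15, 30))
  expect_equal(tr$replicates, 5)
  expect_gt(tr$damage_slope, a1$damage_slope)
  # overrides pass through
  expect_equal(study_truth("Abisko2", replicates = 7)$replicates, 7)
})

test_that("simulation is reproducible from the seed", {
  truth <- synthetic_truth()
  s1 <- simulate_experiment(truth, seed = 5)
  s2 <- simulate_experiment(truth, seed = 5)
  expect_identical(s1$emissions, s2$emissions)
  expect_identical(unclass(s1$data$peaks), unclass(s2$data$peaks))
  expect_identical(s1$data$leaves, s2$data$leaves)
  s3 <- simulate_experiment(truth, seed = 6)
  expect_false(identical(s1$emissions, s3$emissions))
})

test_that("simulated experiments have a valid design and metadata", {
  truth <- synthetic_truth(replicates = 3)
  sim <- simulate_experiment(truth, seed = 8)
  expect_s3_class(sim$data, "bvoc_dataset")
  branch <- sim$data$samples[sim$data$samples$sample_type == "branch", ]
  expect_equal(nrow(branch), 15)
  # randomized complete block: every density once per block
  expect_true(all(table(branch$larval_density, branch$block_id) == 1))
  expect_equal(sum(sim$data$samples$sample_type == "blank"), truth$n_blanks)
  # blanks carry exactly the blank contamination level
  blanks <- unclass(sim$data$peaks)[sim$data$samples$sample_type == "blank", ]
  expect_true(all(blanks == truth$blank_level))
  # leaf areas respect the configured range (before feeding loss)
  lv <- sim$data$leaves
  la0 <- lv$leaf_area_total + lv$leaf_area_eaten
  expect_true(all(la0 >= truth$leaf_area_range[1] &
                    la0 <= truth$leaf_area_range[2]))
  # damage groups are the documented classification of realised damage
  expect_identical(sim$groups,
                   classify_damage(lv$percent_eaten, truth$group_threshold))
})

test_that("feeding damage increases with larval density", {
  truth <- synthetic_truth()
  sim <- simulate_experiment(truth, seed = 9)
  dens <- sim$data$samples$larval_density[
    sim$data$samples$sample_type == "branch"]
  pct <- sim$data$leaves$percent_eaten
  expect_gt(cor(dens, pct, method = "spearman"), 0.5)
  expect_true(all(pct >= 0 & pct <= truth$damage_max))
})

test_that("a noise-free simulation is recovered exactly by the pipeline math", {
  truth <- synthetic_truth(noise_cv = 0, blank_level = 0,
                           damage_noise = c(base = 0, prop = 0))
  sim <- simulate_experiment(truth, seed = 10)
  d <- sim$data
  is_blank <- d$samples$sample_type == "blank"
  sub <- subtract_blanks(
    peak_table(unclass(d$peaks)[!is_blank, , drop = FALSE]),
    unclass(d$peaks)[is_blank, , drop = FALSE])
  d2 <- bvoc_dataset(sub, d$samples, d$leaves, d$compounds)
  em <- build_emission_matrix(d2)
  expect_equal(em, sim$emissions, tolerance = 1e-12)
  # and the true emissions are exactly the deterministic dose response
  pct <- d$leaves$percent_eaten
  mu <- outer(pct, truth$catalog$induction) +
    matrix(truth$catalog$basal, length(pct), nrow(truth$catalog),
           byrow = TRUE)
  expect_equal(unname(sim$emissions), unname(mu), tolerance = 1e-12)
})

test_that("class-total dose response matches the generating inductions", {
  truth <- synthetic_truth(noise_cv = 0, blank_level = 0,
                           damage_noise = c(base = 0, prop = 0))
  sim <- simulate_experiment(truth, seed = 12)
  ct <- aggregate_groups(sim$emissions, sim$data$compounds)
  pct <- sim$data$leaves$percent_eaten
  for (g in BVOC_CLASSES) {
    # lm warns about the (intentionally) perfect noise-free fit
    fit <- suppressWarnings(regress_on_damage(ct[[g]], pct))
    expect_equal(fit$slope, unname(truth$class_induction[[g]]),
                 tolerance = 1e-8)
  }
  expect_equal(suppressWarnings(regress_on_damage(ct$total, pct))$slope,
               truth$total_induction, tolerance = 1e-8)
})

test_that("theoretical_integration gives the equicorrelated closed form", {
  truth <- synthetic_truth()
  p <- nrow(truth$catalog)
  expect_equal(as.numeric(theoretical_integration(truth, "low")),
               p * truth$loading_low^4)
  expect_equal(as.numeric(theoretical_integration(truth, "high")),
               p * truth$loading_high^4)
  R <- attr(theoretical_integration(truth, "low"), "R_true")
  expect_equal(unique(R[upper.tri(R)]), truth$loading_low^2)
  expect_equal(as.numeric(integration_index(R)),
               as.numeric(theoretical_integration(truth, "low")),
               tolerance = 1e-10)
  # no latent factor means no integration
  expect_equal(as.numeric(theoretical_integration(
    synthetic_truth(loading_low = 0), "low")), 0)
})

test_that("large-sample latent-factor draws converge to the theoretical index", {
  truth <- synthetic_truth()
  p <- nrow(truth$catalog)
  lam <- truth$loading_low
  set.seed(131)
  n <- 10000
  f <- rnorm(n)
  z <- matrix(rnorm(n * p), n, p)
  x <- lam * f + sqrt(1 - lam^2) * z
  ii <- as.numeric(integration_index(cor(x)))
  th <- as.numeric(theoretical_integration(truth, "low"))
  expect_lt(abs(ii - th) / th, 0.02)
})

test_that("within-experiment integration is higher under low damage", {
  truth <- synthetic_truth()
  ok <- vapply(1:25, function(s) {
    sim <- simulate_experiment(truth, seed = 400 + s)
    lo <- sim$groups == "low"
    if (sum(lo) < 5 || sum(!lo) < 5) return(NA)
    gl <- suppressMessages(integrate_group(sim$emissions[lo, ], "low"))
    gh <- suppressMessages(integrate_group(sim$emissions[!lo, ], "high"))
    gl$int_relative > gh$int_relative
  }, logical(1))
  expect_gte(mean(ok, na.rm = TRUE), 0.9)
})
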