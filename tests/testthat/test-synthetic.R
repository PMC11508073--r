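test_that("simulation configs validate their stochastic parameters", {
  crv <- fish_curve()
  expect_error(simulation_config(crv, doses = 1, cells_per_dose = 0, seed = 1),
               "positive integers")
  expect_error(simulation_config(crv, doses = 1, cells_per_dose = 10),
               "seed")
  expect_error(simulation_config(crv, doses = c(1, 1), cells_per_dose = 10,
                                 seed = 1), "unique")
  expect_error(simulation_config(crv, doses = 1, cells_per_dose = 10,
                                 dispersion = "neg_binomial", seed = 1),
               "nb_size")
  expect_error(simulation_config(crv, doses = 1, cells_per_dose = 10,
                                 dispersion = "partial_body", seed = 1,
                                 fraction_irradiated = 1.5),
               "fraction_irradiated")
  expect_error(simulation_config(list(not_a_class = crv), doses = 1,
                                 cells_per_dose = 10, seed = 1),
               "named by aberration class")
})

test_that("simulation is seed-deterministic and zero at zero dose with no background", {
  crv <- calibration_curve(0, 0.021, 0.387)
  cfg <- simulation_config(crv, doses = c(0, 2), cells_per_dose = 100,
                           seed = 321)
  a <- simulate_score_sheet(cfg)
  b <- simulate_score_sheet(cfg)
  expect_identical(a, b)
  other <- simulate_score_sheet(
    simulation_config(crv, doses = c(0, 2), cells_per_dose = 100, seed = 322))
  expect_false(identical(a, other))

  zero_point <- a$points[[1]]
  expect_identical(class_total(zero_point, "dicentric_equivalents"), 0L)
  expect_identical(sum(total_aberrations(zero_point$cells)), 0L)
})

test_that("simulated yields match the generating curve within Monte Carlo error", {
  crv <- calibration_curve(0, 0.021, 0.387)
  cfg <- simulation_config(crv, doses = 1, cells_per_dose = 10000, seed = 99)
  sheet <- simulate_score_sheet(cfg)
  y <- summarize_sheet(sheet)$yield
  expect_lt(abs(y - 0.408), 3 * sqrt(0.408 / 10000))
})

test_that("the Poisson model is equidispersed and the alternatives are overdispersed", {
  crv <- calibration_curve(0.005, 0.05, 0.08)
  vm <- vapply(1:500, function(i) {
    cfg <- simulation_config(crv, doses = 2, cells_per_dose = 200,
                             seed = 10000 + i)
    summarize_sheet(simulate_score_sheet(cfg))$dispersion
  }, 1)
  mc_se <- sd(vm) / sqrt(length(vm))
  expect_lt(abs(mean(vm) - 1), 3 * mc_se)

  vm_nb <- vapply(1:100, function(i) {
    cfg <- simulation_config(crv, doses = 2, cells_per_dose = 200,
                             dispersion = "neg_binomial", nb_size = 2,
                             seed = 20000 + i)
    summarize_sheet(simulate_score_sheet(cfg))$dispersion
  }, 1)
  expect_gt(mean(vm_nb), 1.05)

  vm_pb <- vapply(1:100, function(i) {
    cfg <- simulation_config(crv, doses = 4, cells_per_dose = 200,
                             dispersion = "partial_body",
                             fraction_irradiated = 0.5, seed = 30000 + i)
    summarize_sheet(simulate_score_sheet(cfg))$dispersion
  }, 1)
  expect_gt(mean(vm_pb), 1.2)
})

test_that("multi-arm studies demand a shared dose grid and distinct arms", {
  crv <- fish_curve()
  c1 <- simulation_config(crv, doses = c(1, 3), cells_per_dose = 20, seed = 1,
                          donor = "d1", preparation = "METAPHASE")
  c2 <- simulation_config(crv, doses = c(1, 5), cells_per_dose = 20, seed = 2,
                          donor = "d1", preparation = "G2_PCC")
  expect_error(simulate_study(list(c1, c2)), "same dose grid")
  c3 <- simulation_config(crv, doses = c(1, 3), cells_per_dose = 20, seed = 3,
                          donor = "d1", preparation = "METAPHASE")
  expect_error(simulate_study(list(c1, c3)), "appear once")

  c4 <- simulation_config(crv, doses = c(1, 3), cells_per_dose = 20, seed = 4,
                          donor = "d1", preparation = "G2_PCC")
  study <- simulate_study(list(c1, c4))
  expect_length(study$sheets, 2)
  expect_s3_class(study$design, "spectrum_design")
  expect_identical(sort(unique(study$design$g2)), c(0L, 1L))
})

test_that("null studies give uniform interaction p-values; shifted spectra are detected", {
  spectrum_curves <- function(compound_beta) {
    list(dicentric_equivalents = calibration_curve(0.001, 0.02, 0.06),
         compound_fragments = calibration_curve(0.001, 0.03, compound_beta),
         terminal_fragments = calibration_curve(0.001, 0.01, 0.03))
  }
  run_study <- function(seed, compound_beta_g2) {
    configs <- list()
    k <- 0
    for (donor in c("d1", "d2")) for (prep in c("METAPHASE", "G2_PCC")) {
      k <- k + 1
      beta <- if (prep == "G2_PCC") compound_beta_g2 else 0.09
      configs[[k]] <- simulation_config(
        spectrum_curves(beta), doses = c(1, 3, 5), cells_per_dose = 300,
        seed = seed * 10 + k, donor = donor, preparation = prep)
    }
    # only three classes carry curves, so the empty-category warning is
    # expected by construction
    fit <- suppressWarnings(fit_spectrum_model(simulate_study(configs)$design))
    fit$interaction[fit$interaction$category == "dicentric_equivalents", ]
  }

  null_runs <- lapply(1:200, run_study, compound_beta_g2 = 0.09)
  p_null <- vapply(null_runs, function(r) r$p, 1)
  ks <- suppressWarnings(stats::ks.test(p_null, "punif"))
  expect_lt(unname(ks$statistic), 0.1)

  shifted <- lapply(1:200, function(s) run_study(100000 + s,
                                                 compound_beta_g2 = 0.15))
  sign_neg <- vapply(shifted, function(r) r$estimate < 0, TRUE)
  expect_gte(mean(sign_neg), 0.95)
})

test_that("simulate -> fit -> estimate recovers a known dose inside its interval", {
  truth <- fish_curve()
  hits <- vapply(1:200, function(i) {
    cal_cfg <- simulation_config(truth, doses = c(0, 0.5, 1, 2, 3, 4),
                                 cells_per_dose = 500, seed = 50000 + i)
    cal <- fit_lq_poisson(simulate_score_sheet(cal_cfg))
    set.seed(60000 + i)
    x <- rpois(1, 50 * evaluate_curve(truth, 2))
    e <- estimate_dose(cal, x, 50)
    e$lcl <= 2 && 2 <= e$ucl
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})
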