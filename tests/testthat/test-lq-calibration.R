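test_that("curve evaluation and JSON serialization behave", {
  crv <- fish_curve()
  expect_equal(evaluate_curve(crv, 0), 0.008)
  expect_equal(evaluate_curve(crv, 2), 0.008 + 0.088 * 2 + 0.095 * 4)
  cabas <- calibration_curve(0, 0.021, 0.387)
  expect_equal(evaluate_curve(cabas, 1), 0.408)
  expect_error(evaluate_curve(crv, -1), "non-negative")
  expect_error(calibration_curve(-0.1, 0.1, 0.1), "non-negative")

  f <- withr::local_tempfile(fileext = ".json")
  write_curve(crv, f)
  back <- read_curve(f)
  expect_equal(back$c, crv$c)
  expect_equal(back$alpha, crv$alpha)
  expect_equal(back$beta, crv$beta)
  expect_equal(back$se, crv$se)
})

test_that("single-dose fit with background and alpha fixed hits the closed form", {
  fit <- fit_lq_poisson(data.frame(dose_gy = 2, n_cells = 100, total = 40),
                        fix_c = TRUE, fix_alpha = TRUE)
  expect_equal(fit$beta, 40 / (100 * 4), tolerance = 1e-10)
  expect_identical(fit$c, 0)
  expect_identical(fit$alpha, 0)
})

test_that("noiseless data on an LQ curve are recovered essentially exactly", {
  truth <- calibration_curve(0.01, 0.05, 0.06)
  D <- c(0, 1, 2, 4)
  N <- 1e6
  pts <- data.frame(dose_gy = D, n_cells = N,
                    total = round(N * evaluate_curve(truth, D)))
  fit <- fit_lq_poisson(pts)
  expect_equal(c(fit$c, fit$alpha, fit$beta), c(0.01, 0.05, 0.06),
               tolerance = 1e-6)
  gof <- goodness_of_fit(fit, pts)
  expect_lt(gof$deviance, 1e-6)
})

test_that("seeded Poisson data: estimates near truth and likelihood beats a grid search", {
  set.seed(90210)
  truth <- c(c = 0.001, alpha = 0.02, beta = 0.06)
  D <- c(0, 0.5, 1, 2, 3, 5)
  N <- rep(5000, length(D))
  lam <- truth[1] + truth[2] * D + truth[3] * D^2
  X <- rpois(length(D), N * lam)
  fit <- fit_lq_poisson(data.frame(dose_gy = D, n_cells = N, total = X))
  est <- c(fit$c, fit$alpha, fit$beta)
  se <- fit$se
  expect_true(all(is.na(se) | abs(est - truth) <= 3 * se))

  # grid-search ML oracle on a lattice around the truth
  grid <- expand.grid(
    c = seq(0, 0.004, length.out = 17),
    alpha = seq(0.001, 0.04, length.out = 17),
    beta = seq(0.05, 0.07, length.out = 17))
  ll_grid <- apply(as.matrix(grid), 1,
                   function(th) lq_loglik_oracle(th, D = D, N = N, X = X))
  expect_gte(fit$fit$loglik, max(ll_grid) - 1e-6)

  # score equations vanish at the reported optimum
  lam_hat <- evaluate_curve(fit, D)
  for (z in list(rep(1, length(D)), D, D^2)) {
    expect_lt(abs(sum(N * (X / (N * lam_hat) - 1) * z)), 1e-6 * (1 + sum(X)))
  }
})

test_that("the fit is invariant to dose-point order and to splitting a dose point", {
  set.seed(5)
  D <- c(0, 1, 2, 3, 5)
  N <- rep(400, 5)
  X <- rpois(5, N * (0.005 + 0.03 * D + 0.07 * D^2))
  base <- fit_lq_poisson(data.frame(dose_gy = D, n_cells = N, total = X))
  perm <- sample(5)
  shuffled <- fit_lq_poisson(data.frame(dose_gy = D[perm], n_cells = N[perm],
                                        total = X[perm]))
  expect_equal(c(shuffled$c, shuffled$alpha, shuffled$beta),
               c(base$c, base$alpha, base$beta), tolerance = 1e-8)

  # split the 2 Gy point into two halves carrying the same totals
  split_df <- data.frame(
    dose_gy = c(D[-3], 2, 2), n_cells = c(N[-3], 150, 250),
    total = c(X[-3], 10, X[3] - 10))
  split_fit <- fit_lq_poisson(split_df)
  expect_equal(c(split_fit$c, split_fit$alpha, split_fit$beta),
               c(base$c, base$alpha, base$beta), tolerance = 1e-8)
})

test_that("our Newton fitter agrees with an identity-link Poisson GLM", {
  # interior optimum (background well identified by the 0 Gy point), so the
  # unconstrained GLM and the projected Newton fit target the same maximum
  set.seed(1401)
  truth <- c(0.02, 0.05, 0.08)
  d <- data.frame(dose = c(0, 0.5, 1, 2, 3, 5), n = 2000)
  d$x <- rpois(6, d$n * (truth[1] + truth[2] * d$dose + truth[3] * d$dose^2))
  ours <- fit_lq_poisson(data.frame(dose_gy = d$dose, n_cells = d$n,
                                    total = d$x))
  glm_fit <- stats::glm(x ~ 0 + n + I(n * dose) + I(n * dose^2), data = d,
                        family = stats::poisson(link = "identity"),
                        start = truth)
  expect_equal(unname(stats::coef(glm_fit)),
               c(ours$c, ours$alpha, ours$beta), tolerance = 1e-5)
})

test_that("goodness of fit: saturated and simulated-at-truth behaviour", {
  # as many free parameters as dose points: deviance ~ 0, df = 0
  sat_df <- data.frame(dose_gy = c(1, 2, 4), n_cells = 500,
                       total = c(50, 145, 485))  # exactly on (0.01, 0.04, 0.05)
  sat <- fit_lq_poisson(sat_df)
  gof <- goodness_of_fit(sat, sat_df)
  expect_lt(gof$deviance, 1e-6)
  expect_identical(gof$df, 0L)
  expect_true(is.na(gof$p_value))

  set.seed(777)
  # interior truth with the background pinned by a 0 Gy point, so the
  # nonnegativity constraint stays inactive and the deviance is chi-square
  D <- c(0, 0.5, 1, 2, 3, 5)
  N <- rep(2000, 6)
  lam <- 0.02 + 0.05 * D + 0.08 * D^2
  ratio <- replicate(200, {
    X <- rpois(6, N * lam)
    df <- data.frame(dose_gy = D, n_cells = N, total = X)
    fit <- fit_lq_poisson(df)
    g <- goodness_of_fit(fit, df)
    g$deviance / g$df
  })
  mc_se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * mc_se)
})

test_that("degenerate inputs are refused with diagnostics", {
  expect_error(fit_lq_poisson(data.frame(dose_gy = c(0, 1, 2), n_cells = 100,
                                         total = 0)),
               "degenerate")
  expect_error(fit_lq_poisson(data.frame(dose_gy = c(1, 2), n_cells = 100,
                                         total = c(5, 20))),
               "at least as many dose points")
})
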