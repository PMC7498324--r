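test_that("binding models reproduce their closed-form values", {
  expect_equal(competition_model(0, 500, 0.10, 0.20), 0.20)
  expect_equal(competition_model(500, 500, 0.10, 0.20), 0.15)
  expect_equal(competition_model(1500, 500, 0.10, 0.20), 0.125)
  expect_equal(saturation_model(0, 250, 0.05, 0.25), 0.05)
  expect_equal(saturation_model(250, 250, 0.05, 0.25), 0.15)
  expect_equal(saturation_model(1e9, 250, 0.05, 0.25), 0.25, tolerance = 1e-6)
  expect_error(competition_model(10, -5, 0.1, 0.2),
               class = "racetails_validation_error")
  expect_error(saturation_model(10, 0, 0.1, 0.2),
               class = "racetails_validation_error")
})

test_that("model identities, monotonicity and bounds hold on random draws", {
  withr::local_seed(101)
  grid <- sort(c(0, 10^runif(30, -1, 6)))
  for (i in 1:1000) {
    ic50 <- 10^runif(1, 0, 6)
    a_free <- runif(1, 0, 0.5)
    a_bound <- runif(1, 0, 0.5)
    vals <- competition_model(grid, ic50, a_free, a_bound)
    expect_equal(vals[1], a_bound, tolerance = 1e-12)
    expect_equal(competition_model(ic50, ic50, a_free, a_bound),
                 (a_free + a_bound) / 2, tolerance = 1e-12)
    expect_true(all(vals >= min(a_free, a_bound) - 1e-12 &
                      vals <= max(a_free, a_bound) + 1e-12))
    if (a_bound > a_free) {
      expect_true(all(diff(vals) < 0))
    } else if (a_bound < a_free) {
      expect_true(all(diff(vals) > 0))
    }
    sat <- saturation_model(grid, ic50, a_free, a_bound)
    if (a_bound > a_free) expect_true(all(diff(sat) > 0))
  }
})

test_that("saturation fit recovers noiseless parameters to 1e-6", {
  d <- titration_design("saturation", noise_sd = 0,
                        truth = list(kd = 250, a_free = 0.05, a_max = 0.25))
  fit <- fit_saturation(simulate_saturation(d))
  expect_true(fit$converged)
  expect_lt(abs(fit$kd - 250) / 250, 1e-6)
  expect_lt(abs(fit$a_free - 0.05), 1e-8)
  expect_lt(abs(fit$a_max - 0.25), 1e-8)
})

test_that("saturation fit rejects underdetermined and flags degenerate input", {
  two <- tibble::tibble(concentration_nM = c(5, 5, 3000, 3000),
                        anisotropy = c(0.05, 0.05, 0.2, 0.2))
  expect_error(fit_saturation(two),
               class = "racetails_underdetermined_error")
  flat <- tibble::tibble(concentration_nM = c(5, 50, 500, 3000),
                         anisotropy = rep(0.1, 4))
  fit <- fit_saturation(flat)
  expect_false(fit$converged)
  expect_true(fit$degenerate)
})

test_that("saturation fit is accurate and calibrated under noise", {
  d <- titration_design("saturation", replicates = 3, noise_sd = 0.002,
                        truth = list(kd = 250, a_free = 0.05, a_max = 0.25),
                        seed = 31)
  fit <- fit_saturation(simulate_saturation(d))
  expect_lt(abs(fit$kd - 250) / 250, 0.1)
  expect_gt(fit$se[["kd"]], 0)
})

test_that("global competition fit recovers noiseless parameters to 1e-6", {
  d <- titration_design("competition", replicates = 3, noise_sd = 0,
                        truth = list(ic50 = 500,
                                     a_free = c(0.10, 0.09, 0.11),
                                     a_bound = c(0.20, 0.21, 0.19)))
  fit <- fit_competition_global(simulate_competition(d))
  expect_true(fit$identifiable)
  expect_lt(abs(fit$ic50 - 500) / 500, 1e-6)
  expect_equal(unname(fit$a_free), c(0.10, 0.09, 0.11), tolerance = 1e-6)
  expect_equal(unname(fit$a_bound), c(0.20, 0.21, 0.19), tolerance = 1e-6)
})

test_that("single-experiment global fit equals an independent profile fit", {
  # noiseless: both routes must land on the truth
  d0 <- titration_design("competition", replicates = 1, noise_sd = 0,
                         truth = list(ic50 = 500, a_free = 0.10,
                                      a_bound = 0.20))
  m0 <- simulate_competition(d0)
  g0 <- fit_competition_global(m0)
  p0 <- profile_competition_fit(m0$concentration_nM, m0$anisotropy)
  expect_lt(abs(g0$ic50 - p0$ic50) / p0$ic50, 1e-8)
  expect_lt(abs(unname(g0$a_free) - p0$a_free), 1e-8)
  expect_lt(abs(unname(g0$a_bound) - p0$a_bound), 1e-8)

  # noisy: both routes must find the same least-squares optimum
  d1 <- titration_design("competition", replicates = 1, noise_sd = 0.002,
                         truth = list(ic50 = 500, a_free = 0.10,
                                      a_bound = 0.20), seed = 41)
  m1 <- simulate_competition(d1)
  g1 <- fit_competition_global(m1)
  p1 <- profile_competition_fit(m1$concentration_nM, m1$anisotropy)
  expect_lt(abs(g1$ic50 - p1$ic50) / p1$ic50, 1e-6)
  expect_lt(abs(unname(g1$a_free) - p1$a_free), 1e-8)
  expect_lt(abs(unname(g1$a_bound) - p1$a_bound), 1e-8)
})

test_that("competition fit errors on single-concentration experiments", {
  bad <- tibble::tibble(experiment_id = c("a", "a", "b", "b"),
                        concentration_nM = c(50, 500, 100, 100),
                        anisotropy = c(0.2, 0.15, 0.2, 0.2),
                        replicate = 1L)
  expect_error(fit_competition_global(bad),
               class = "racetails_underdetermined_error")
})

test_that("flat competition data yields identifiable = FALSE, not an error", {
  d <- titration_design("competition", replicates = 2, noise_sd = 0,
                        truth = list(ic50 = 500, a_free = 0.15,
                                     a_bound = 0.15))
  fit <- fit_competition_global(simulate_competition(d))
  expect_false(fit$identifiable)
})

test_that("IC50 standard error shrinks roughly as n^(-1/2)", {
  ses <- vapply(c(3, 12, 48), function(reps) {
    d <- titration_design("competition", replicates = reps, noise_sd = 0.002,
                          truth = list(ic50 = 500, a_free = 0.10,
                                       a_bound = 0.20), seed = 71)
    fit_competition_global(simulate_competition(d))$se_ic50
  }, 0)
  expect_lt(ses[2], ses[1])
  expect_lt(ses[3], ses[2])
  # factor-of-4 replication should shrink the SE about twofold
  expect_lt(ses[3] / ses[1], 0.5)
  expect_gt(ses[3] / ses[1], 0.1)
})

test_that("delta-method band covers the fitted curve and tightens at the data", {
  d <- titration_design("competition", replicates = 3, noise_sd = 0.002,
                        truth = list(ic50 = 500, a_free = 0.10,
                                     a_bound = 0.20), seed = 61)
  fit <- fit_competition_global(simulate_competition(d))
  grid <- 10^seq(1, 6, length.out = 50)
  bd <- fit$band(grid, experiment = fit$experiments[1])
  expect_true(all(bd$lower <= bd$fit & bd$fit <= bd$upper))
  truth_curve <- competition_model(grid, 500, 0.10, 0.20)
  expect_gt(mean(bd$lower <= truth_curve & truth_curve <= bd$upper), 0.8)
  expect_error(fit$band(grid, experiment = "nope"),
               class = "racetails_validation_error")
})
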