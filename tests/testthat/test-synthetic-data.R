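test_that("deterministic tail models sample exactly as specified", {
  expect_equal(sample_tails(cc_model(), 5), rep("CC", 5))
  zero <- tail_model(c(`0` = 1), c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(sample_tails(zero, 3), rep("", 3))
})

test_that("sampled base fractions match the model within binomial error", {
  m <- tail_model(c(`1` = 1), c(A = 0.5, C = 0.5, G = 0, T = 0))
  tails <- withr::with_seed(7, sample_tails(m, 10000))
  frac_c <- mean(tails == "C")
  expect_lt(abs(frac_c - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("sampled length distribution matches length_probs within 4 SE", {
  m <- mixed_model()
  n <- 20000
  tails <- withr::with_seed(11, sample_tails(m, n))
  emp <- table(factor(nchar(tails), levels = 0:4)) / n
  for (len in 0:4) {
    p <- m$length_probs[[as.character(len)]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(emp[[as.character(len)]] - p), 4 * se)
  }
})

test_that("expected_composition matches exhaustive enumeration to 1e-12", {
  models <- list(cc_model(), mixed_model(), default_tail_model())
  for (m in models) {
    got <- expected_composition(m)
    oracle <- enum_composition(m)
    expect_equal(got$coverage, oracle$coverage, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got$overall, oracle$overall, tolerance = 1e-12)
    expect_equal(got$per_position, oracle$per_position, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got$mean_length, oracle$mean_length, tolerance = 1e-12)
  }
})

test_that("expected_composition handles boundary cases per contract", {
  got <- expected_composition(cc_model())
  expect_equal(unname(got$per_position["C", ]), c(1, 1))
  expect_equal(unname(got$coverage), c(1, 1))

  m <- tail_model(c(`1` = 0.9, `2` = 0.1), c(A = 0, C = 1, G = 0, T = 0))
  expect_equal(unname(expected_composition(m)$coverage), c(1.0, 0.1))

  # a zero-probability intermediate length keeps its position defined via
  # longer tails; an unreachable position is NA, not zero
  sparse <- tail_model(c(`0` = 0.5, `2` = 0.5),
                       c(A = 1, C = 0, G = 0, T = 0))
  ec <- expected_composition(sparse)
  expect_false(anyNA(ec$per_position))
})

test_that("tail model validation rejects malformed probability inputs", {
  expect_error(tail_model(c(`1` = 0.5), c(A = 1, C = 0, G = 0, T = 0)),
               class = "racetails_validation_error")
  expect_error(tail_model(c(`1` = 1), c(A = 0.5, C = 0.6, G = 0, T = 0)),
               class = "racetails_validation_error")
  expect_error(contaminant_model(0.6, 0.6),
               class = "racetails_validation_error")
  expect_error(contaminant_model(long_insert_length = 100),
               class = "racetails_validation_error")
})

test_that("simulate_reads builds clean reads by construction", {
  s <- toy_substrate(); a <- toy_adapter()
  sim <- simulate_reads(s, a, mixed_model(), n_reads = 100, seed = 1)
  expect_equal(nrow(sim$reads), 100L)
  expect_true(all(sim$truth$class == "clean"))
  expect_true(all(startsWith(sim$reads$sequence, s$prefix)))
  expect_true(all(endsWith(sim$reads$sequence, a$sequence)))
  expect_equal(nchar(sim$reads$sequence), nchar(sim$reads$quality))
})

test_that("contaminant classes are allocated exactly as round(fraction*n)", {
  s <- toy_substrate(); a <- toy_adapter()
  cm <- contaminant_model(fraction_no_adapter = 0.1)
  sim <- simulate_reads(s, a, mixed_model(), 1000, cm, seed = 2)
  expect_equal(sum(sim$truth$class == "no_adapter"), 100L)
  expect_equal(sum(sim$truth$class == "clean"), 900L)

  cm2 <- contaminant_model(0.031, 0.049, 0.02, 0.011)
  sim2 <- simulate_reads(s, a, mixed_model(), 777, cm2, seed = 3)
  counts <- table(sim2$truth$class)
  expect_equal(unname(counts[["no_prefix"]]), round(0.031 * 777))
  expect_equal(unname(counts[["no_adapter"]]), round(0.049 * 777))
  expect_equal(unname(counts[["long_insert"]]), round(0.02 * 777))
  expect_equal(unname(counts[["junk"]]), round(0.011 * 777))
})

test_that("read simulation is bit-reproducible under a fixed seed", {
  s <- toy_substrate(); a <- toy_adapter()
  cm <- contaminant_model(0.05, 0.05, 0.02, 0.02)
  sim1 <- simulate_reads(s, a, default_tail_model(), 500, cm, seed = 99)
  sim2 <- simulate_reads(s, a, default_tail_model(), 500, cm, seed = 99)
  expect_identical(sim1, sim2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim1$reads, f1)
  write_fastq(sim2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulated saturation obeys the one-site identities when noiseless", {
  tr <- list(kd = 250, a_free = 0.05, a_max = 0.25)
  d <- titration_design("saturation", concentrations = c(0, 250, 3000),
                        replicates = 1, noise_sd = 0, truth = tr)
  m <- simulate_saturation(d)
  expect_equal(m$anisotropy[m$concentration_nM == 0], 0.05)
  expect_equal(m$anisotropy[m$concentration_nM == 250], (0.05 + 0.25) / 2)
})

test_that("simulated competition obeys the displacement identities", {
  tr <- list(ic50 = 500, a_free = 0.10, a_bound = 0.20)
  d <- titration_design("competition", concentrations = c(0, 500, 5e5),
                        replicates = 2, noise_sd = 0, truth = tr)
  m <- simulate_competition(d)
  expect_equal(unique(m$anisotropy[m$concentration_nM == 0]), 0.20)
  expect_equal(unique(m$anisotropy[m$concentration_nM == 500]), 0.15)
  expect_equal(length(unique(m$experiment_id)), 2L)
  expect_identical(simulate_competition(titration_design(
    "competition", replicates = 3, noise_sd = 0.01, truth = tr, seed = 5)),
    simulate_competition(titration_design(
      "competition", replicates = 3, noise_sd = 0.01, truth = tr, seed = 5)))
})

test_that("titration designs validate their truth parameters", {
  expect_error(titration_design("saturation", truth = list(kd = -1,
                                                           a_free = 0, a_max = 1)),
               class = "racetails_validation_error")
  expect_error(titration_design("competition", truth = list(ic50 = 0,
                                                            a_free = 0, a_bound = 1)),
               class = "racetails_validation_error")
  expect_error(titration_design("saturation", concentrations = c(5, 5),
                                truth = list(kd = 1, a_free = 0, a_max = 1)),
               class = "racetails_validation_error")
})
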