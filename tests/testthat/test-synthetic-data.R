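# Ground-truth generator: library structure, emission, determinism and
# recovery metrics.

test_that("generation is deterministic given the seed", {
  lib1 <- make_library(n = 40, seed = 31)
  lib2 <- make_library(n = 40, seed = 31)
  expect_identical(lib1, lib2)
  d <- make_design(varieties = c("A", "B"), regions = "R",
                   vintages = 2020, n_rep = 3)
  s1 <- emit_peaklists(lib1, d, seed = 32)
  s2 <- emit_peaklists(lib2, d, seed = 32)
  expect_identical(s1, s2)
  expect_false(identical(s1, emit_peaklists(lib1, d, seed = 33)))
})

test_that("homologous series step by exact CH2 and glycosyl masses", {
  lib <- make_library(n = 60, seed = 34, n_series = 4,
                      series_length = 3)
  for (s in unique(na.omit(lib$series))) {
    mem <- lib[!is.na(lib$series) & lib$series == s, ]
    mem <- mem[order(mem$neutral_mass), ]
    step <- if (grepl("CH2", s)) 14.015650 else 162.052824
    expect_equal(diff(mem$neutral_mass), rep(step, nrow(mem) - 1),
                 tolerance = 1e-6)
  }
  # repeated glycosylation of glucose lands on the expected neutrals
  glc <- parse_formula("C6H12O6")
  steps <- vapply(0:2, function(k) {
    monoisotopic_mass(glc + k * parse_formula("C6H10O5"))
  }, numeric(1))
  expect_equal(steps, c(180.063388, 342.116212, 504.169036),
               tolerance = 5e-7)
})

test_that("class proportions are honoured at large n", {
  mix <- c(CHO = 0.7, CHNO = 0.2, CHOS = 0.1)
  lib <- make_library(n = 1000, seed = 35, class_mix = mix,
                      n_series = 0, pollutant = FALSE)
  realised <- table(lib$class)[names(mix)] / nrow(lib)
  expect_true(all(abs(realised - mix) < 0.02))
  expect_error(make_library(n = 10, class_mix = c(CHO = 0)),
               "infeasible")
})

test_that("noiseless emission reproduces theoretical masses exactly", {
  lib <- make_library(n = 20, seed = 36, pollutant = FALSE)
  d <- make_design(varieties = "A", regions = "R", vintages = 2020,
                   n_rep = 2)
  quiet <- noise_spec(di_ppm_sd = 0, lc_ppm_sd = 0, rt_sd = 0,
                      intensity_cv = 0, batch_log_sd = 0,
                      dropout_mid = -Inf)
  sim <- emit_peaklists(lib, d, noise = quiet, seed = 37)
  expect_identical(sort(sim$di[[1]]$mz), sort(lib$ion_mz))
  expect_identical(sort(unique(sim$lc[[1]]$mz)), sort(lib$ion_mz))
  # conservation: one LC peak per (detection, isomer)
  expect_identical(nrow(sim$lc[[1]]), sum(lib$n_isomers))
  expect_identical(sum(vapply(sim$lc, nrow, integer(1))),
                   sum(sim$truth$n_isomers))
})

test_that("the sugar pollutant elutes at 13 distinct retention times", {
  lib <- make_library(n = 30, seed = 38)
  poll <- lib[lib$is_pollutant, ]
  expect_identical(poll$adduct, "chloride")
  expect_identical(poll$n_isomers, 13L)
  expect_identical(length(unique(poll$rts[[1]])), 13L)
  d <- make_design(varieties = "A", regions = "R", vintages = 2020,
                   n_rep = 1)
  sim <- emit_peaklists(lib, d, noise = noise_spec(dropout_mid = -Inf),
                        seed = 39)
  near <- abs(sim$lc[[1]]$mz - poll$ion_mz) / poll$ion_mz * 1e6 < 5
  expect_identical(sum(near), 13L)
})

test_that("the DI mass-error distribution matches the configured noise", {
  lib <- make_library(n = 60, seed = 40, pollutant = FALSE)
  d <- make_design(varieties = c("A", "B"), regions = "R",
                   vintages = 2020:2021, n_rep = 3)
  sim <- emit_peaklists(lib, d, noise = noise_spec(dropout_mid = -Inf),
                        seed = 41)
  err <- (sim$truth$obs_mz_di - sim$truth$true_mz) /
    sim$truth$true_mz * 1e6
  expect_equal(sd(err), 0.1, tolerance = 0.1)
  expect_gt(shapiro.test(sample(err, 500))$p.value, 0.01)
})

test_that("alignment recall degrades as mass noise outgrows the window", {
  lib <- make_library(n = 60, seed = 42, pollutant = FALSE)
  d <- make_design(varieties = c("A", "B"), regions = "R",
                   vintages = 2020, n_rep = 5)
  recall <- vapply(c(0.1, 0.6, 1.2, 2.0), function(sd_ppm) {
    sim <- emit_peaklists(lib, d,
                          noise = noise_spec(di_ppm_sd = sd_ppm,
                                             lc_ppm_sd = max(sd_ppm, 1),
                                             dropout_mid = -Inf),
                          seed = 43)
    fm <- align_samples(sim$di, window = 0.5)
    truth_report(sim, features = fm, window = 0.5)$alignment_recall
  }, numeric(1))
  expect_equal(recall[1], 1)
  expect_true(all(diff(recall) <= 0.02))
  expect_lt(recall[4], recall[1])
})

test_that("truth_report scores a perfect pipeline as 1 and checks ids", {
  lib <- make_library(n = 25, seed = 44, pollutant = FALSE)
  d <- make_design(varieties = "A", regions = "R", vintages = 2020,
                   n_rep = 2)
  quiet <- noise_spec(di_ppm_sd = 0, lc_ppm_sd = 0, rt_sd = 0,
                      intensity_cv = 0, batch_log_sd = 0,
                      dropout_mid = -Inf)
  sim <- emit_peaklists(lib, d, noise = quiet, seed = 45)
  fm <- align_samples(sim$di)
  asg <- assign_peaks(fm$features$mz)
  rep <- truth_report(sim, features = fm, assignments = asg)
  expect_identical(rep$alignment_precision, 1)
  expect_identical(rep$alignment_recall, 1)
  expect_gte(rep$assignment_accuracy, 0.95)
  attr(fm, "dataset_id") <- "gm-999"
  expect_error(truth_report(sim, features = fm), "different dataset")
})

test_that("the calibrated factor simulator hits its target fractions", {
  pm <- simulate_factor_matrix(n = 108, p = 40,
                               fractions = c(variety = 0.25), seed = 46)
  v <- pm$factors$variety
  r2 <- mean(vapply(seq_len(ncol(pm$x)), function(j) {
    summary(lm(pm$x[, j] ~ v))$adj.r.squared
  }, numeric(1)))
  expect_lt(abs(r2 - 0.25), 0.02)
})
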