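# Bounded enumeration and mass-difference-network assignment.

small_bounds <- list(C = c(1L, 30L), H = c(1L, 60L), N = c(0L, 3L),
                     O = c(0L, 15L), S = c(0L, 2L))

test_that("enumeration equals the exhaustive brute-force oracle", {
  oracle <- make_brute_oracle(small_bounds)
  cfg <- assignment_config(bounds = small_bounds)
  set.seed(3)
  mzs <- runif(25, 92, 520)
  for (mz in mzs) {
    got <- candidate_keys(enumerate_formulas(mz, cfg))
    expect_identical(got, oracle(mz), label = paste("mz", mz))
  }
})

test_that("anchor peaks are assigned their printed compositions", {
  first <- enumerate_formulas(215.03279,
                              assignment_config(adduct_set = "chloride"))
  expect_identical(first$formula[1], "C6H12O6")
  expect_identical(first$adduct[1], "chloride")
  dep <- enumerate_formulas(203.08257,
                            assignment_config(adduct_set = "deprotonated"))
  expect_true("C11H12N2O2" %in% dep$formula)
  expect_error(enumerate_formulas(12.0, assignment_config()),
               "mass range")
})

test_that("candidates are sorted by |error| with documented tie-breaks", {
  cfg <- assignment_config(tolerance_ppm = 3, bounds = small_bounds)
  out <- enumerate_formulas(341.10894, cfg)
  expect_true(nrow(out) > 1)
  expect_true(!is.unsorted(abs(out$error_ppm)))
  expect_true(all(abs(out$error_ppm) <= 3))
})

test_that("widening tolerance or bounds never drops a candidate", {
  set.seed(9)
  for (mz in runif(6, 100, 600)) {
    narrow <- enumerate_formulas(mz, assignment_config(
      tolerance_ppm = 0.5, bounds = small_bounds))
    wide_tol <- enumerate_formulas(mz, assignment_config(
      tolerance_ppm = 2, bounds = small_bounds))
    big <- list(C = c(1L, 40L), H = c(1L, 80L), N = c(0L, 5L),
                O = c(0L, 25L), S = c(0L, 3L))
    wide_bounds <- enumerate_formulas(mz, assignment_config(
      tolerance_ppm = 0.5, bounds = big))
    expect_true(all(candidate_keys(narrow) %in% candidate_keys(wide_tol)))
    expect_true(all(candidate_keys(narrow) %in%
                      candidate_keys(wide_bounds)))
  }
})

test_that("network propagation walks a glycosyl step from a seed", {
  peaks <- c(ion_mz("C6H12O6"), ion_mz("C12H22O11"))
  seeds <- data.frame(name = "glucose", formula = "C6H12O6",
                      adduct = "deprotonated",
                      mz = ion_mz("C6H12O6"), stringsAsFactors = FALSE)
  edges <- data.frame(name = "glycosyl", formula = "C6H10O5",
                      delta = monoisotopic_mass("C6H10O5"),
                      stringsAsFactors = FALSE)
  out <- assign_by_network(peaks, assignment_config(), seeds, edges)
  expect_identical(out$formula, c("C6H12O6", "C12H22O11"))
  expect_identical(out$provenance, c("seed", "network"))
  # the disaccharide neutral mass is one glycosyl unit above glucose
  expect_equal(monoisotopic_mass("C12H22O11"), 342.116212,
               tolerance = 5e-7)
})

test_that("a seed with no matching edges assigns only itself", {
  peaks <- c(ion_mz("C6H12O6"), 500.123)
  seeds <- default_seeds()[1, ]
  edges <- default_edges()[1, ]  # H2 does not bridge these peaks
  out <- assign_by_network(peaks, assignment_config(), seeds, edges)
  expect_identical(out$formula, "C6H12O6")
})

test_that("inconsistent seeds and edges are rejected at load", {
  peaks <- ion_mz("C6H12O6")
  bad_seed <- data.frame(formula = "C6H12O6", adduct = "deprotonated",
                         mz = ion_mz("C6H12O6") + 0.01)
  expect_error(assign_by_network(peaks, assignment_config(), bad_seed,
                                 default_edges()), "seed")
  bad_edge <- data.frame(name = "x", formula = "CH2", delta = 14.0)
  expect_error(assign_by_network(peaks, assignment_config(),
                                 default_seeds(), bad_edge),
               "inconsistent")
})

test_that("network assignments are a subset of enumeration and are
           order-invariant", {
  # chain glucose -> +CH2 -> +glycosyl with small mass noise
  chain <- c("C6H12O6", "C7H14O6", "C13H24O11")
  mzs <- vapply(chain, function(f) ion_mz(f), numeric(1))
  set.seed(21)
  peaks <- mzs * (1 + rnorm(3, 0, 0.05) * 1e-6)
  cfg <- assignment_config()
  out <- assign_by_network(peaks, cfg, default_seeds(), default_edges())
  expect_identical(out$formula, chain)
  for (i in seq_len(nrow(out))) {
    cand <- enumerate_formulas(out$mz[i], cfg)
    expect_true(out$formula[i] %in% cand$formula)
  }
  out_perm <- assign_by_network(rev(peaks), cfg, default_seeds(),
                                default_edges())
  expect_identical(out_perm, out)
})

test_that("adduct-priority cascade resolves cross-adduct ambiguity", {
  asg <- assign_peaks(c(215.03279, ion_mz("C11H12N2O2")),
                      assignment_config())
  expect_identical(asg$adduct, c("chloride", "deprotonated"))
  expect_identical(asg$formula, c("C6H12O6", "C11H12N2O2"))
})

test_that("assignment summaries count classes and adducts", {
  empty <- assignment_summary(assign_peaks(numeric(0)))
  expect_identical(empty$n_assigned, 0L)
  expect_true(all(empty$by_class == 0))
  df <- data.frame(formula = c("a", "b", "c"),
                   class = c("CHO", "CHO", "CHNOS"),
                   adduct = c("deprotonated", "deprotonated", "chloride"),
                   stringsAsFactors = FALSE)
  s <- assignment_summary(df, n_peaks = 4)
  expect_identical(as.vector(s$by_class[c("CHO", "CHNOS")]), c(2L, 1L))
  expect_identical(s$assigned_fraction, 0.75)
})
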