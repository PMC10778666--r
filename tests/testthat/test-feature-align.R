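# Feature-matrix construction, presence filtering, isobar grouping and
# cross-dataset alignment.

pk <- function(mz, intensity = 100, snr = 10, rt = NULL) {
  df <- data.frame(mz = mz, intensity = intensity, snr = snr)
  if (!is.null(rt)) df$rt <- rt
  df
}

test_that("identical masses collapse to one feature across samples", {
  fm <- align_samples(list(s1 = pk(300), s2 = pk(300)), window = 0.5)
  expect_identical(ncol(fm$intensity), 1L)
  expect_true(all(fm$intensity > 0))
})

test_that("peaks 1 ppm apart split under a 0.5-ppm window", {
  fm <- align_samples(list(s1 = pk(300.00000), s2 = pk(300.00030)),
                      window = 0.5)
  expect_identical(ncol(fm$intensity), 2L)
})

test_that("a ladder of 0.4-ppm-spaced peaks cannot chain past the window", {
  mzs <- 400 * cumprod(c(1, rep(1 + 0.4e-6, 7)))
  lists <- setNames(lapply(mzs, pk), paste0("s", seq_along(mzs)))
  fm <- align_samples(lists, window = 0.5)
  expect_gt(ncol(fm$intensity), 1L)
  # max pairwise ppm spread inside any feature stays within the window
  for (f in seq_len(ncol(fm$intensity))) {
    members <- mzs[fm$intensity[, f] > 0]
    if (length(members) > 1) {
      spread <- (max(members) - min(members)) / min(members) * 1e6
      expect_lte(spread, 0.5)
    }
  }
})

test_that("alignment is invariant to sample and peak order", {
  set.seed(5)
  base <- runif(20, 100, 900)
  lists <- lapply(1:4, function(i) {
    idx <- sample(20, 15)
    pk(base[idx] * (1 + rnorm(15, 0, 0.05) * 1e-6),
       intensity = runif(15, 10, 1000))
  })
  names(lists) <- paste0("s", 1:4)
  fm1 <- align_samples(lists, window = 0.5)
  shuffled <- lapply(lists, function(df) df[sample(nrow(df)), ])
  fm2 <- align_samples(shuffled[c(3, 1, 4, 2)], window = 0.5)
  expect_equal(fm1$features$mz, fm2$features$mz)
  expect_equal(fm1$intensity[rownames(fm2$intensity), ],
               fm2$intensity)
})

test_that("low-S/N peaks are excluded and duplicate peaks keep the max", {
  lists <- list(s1 = pk(c(300, 300.00001, 500), c(50, 80, 10),
                        snr = c(10, 10, 2)))
  fm <- align_samples(lists, window = 0.5, min_snr = 3)
  expect_identical(ncol(fm$intensity), 1L)   # S/N 2 peak dropped
  expect_identical(unname(fm$intensity[1, 1]), 80)
})

test_that("presence filter keeps 'at least' semantics and ceilings", {
  intens <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 10, 1)
  feats <- data.frame(feature_id = "F1", mz = 100)
  fm <- feature_matrix(feats, intens)
  expect_identical(ncol(presence_filter(fm, 4)$intensity), 0L)  # 3 < 4
  intens4 <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), 10, 1)
  fm4 <- feature_matrix(feats, intens4)
  expect_identical(ncol(presence_filter(fm4, 4)$intensity), 1L)
  # 33% of 10 samples rounds up to 4
  expect_identical(ncol(presence_filter(fm4, min_fraction = 0.33)$
                          intensity), 1L)
  fm3 <- feature_matrix(feats, matrix(c(1, 1, 1, rep(0, 7)), 10, 1))
  expect_identical(ncol(presence_filter(fm3, min_fraction = 0.33)$
                          intensity), 0L)
})

test_that("isobar grouping merges within 2 ppm on the unweighted mean", {
  feats <- data.frame(feature_id = c("A", "B", "C"),
                      mz = c(400.0000, 400.0006, 410),
                      rt = c(60, 180, 60))
  fm <- feature_matrix(feats, matrix(1, 2, 3,
                                     dimnames = list(c("s1", "s2"), NULL)))
  g <- group_isobars(fm, window = 2)
  expect_identical(nrow(g), 2L)
  expect_equal(g$mean_mz[1], 400.0003)
  expect_identical(g$multiplicity[1], 2L)
  expect_identical(g$multiplicity[2], 1L)
})

test_that("cross-platform alignment applies the 5-ppm window and tie rules", {
  di <- data.frame(feature_id = "D1", mz = 400.0000)
  lcg <- data.frame(group_id = "G1", mean_mz = 400.0016,
                    multiplicity = 2L)
  map <- cross_align(di, lcg, window = 5)
  expect_identical(nrow(map), 1L)
  expect_equal(map$error_ppm, 4, tolerance = 1e-3)
  # equidistant candidates resolve to the lower m/z
  di2 <- data.frame(feature_id = c("D1", "D2"),
                    mz = c(400.0000, 400.0024))
  lcg2 <- data.frame(group_id = "G1", mean_mz = 400.0012,
                     multiplicity = 1L)
  map2 <- cross_align(di2, lcg2, window = 5)
  expect_identical(map2$di_id, "D1")
  # disjoint ranges give an empty map
  expect_identical(nrow(cross_align(di, data.frame(group_id = "G9",
    mean_mz = 900, multiplicity = 1L), window = 5)), 0L)
})

test_that("LC-LC alignment enforces the 10-s RT tolerance", {
  A <- data.frame(feature_id = "A1", mz = 400, rt = 100)
  B11 <- data.frame(feature_id = "B1", mz = 400, rt = 111)
  expect_identical(nrow(lc_lc_align(A, B11, rt_tol = 10)), 0L)
  Bsame <- data.frame(feature_id = "B1", mz = 400, rt = 100)
  m <- lc_lc_align(A, Bsame, rt_tol = 10)
  expect_identical(m$error_ppm, 0)
  # RT delta outranks mass error in the tie cascade
  B2 <- data.frame(feature_id = c("B1", "B2"),
                   mz = c(400.0012, 400.0000), rt = c(101, 108))
  m2 <- lc_lc_align(A, B2, window = 5, rt_tol = 10)
  expect_identical(m2$id_b, "B1")
})

test_that("alignment maps are one-to-at-most-one", {
  set.seed(8)
  di <- data.frame(feature_id = paste0("D", 1:30),
                   mz = sort(runif(30, 100, 900)))
  lcg <- data.frame(group_id = paste0("G", 1:40),
                    mean_mz = sort(runif(40, 100, 900)) *
                      (1 + rnorm(40, 0, 2) * 1e-6),
                    multiplicity = 1L)
  map <- cross_align(di, lcg, window = 5)
  expect_lte(nrow(map), 30L)
  expect_false(anyDuplicated(map$di_id) > 0)
  expect_false(anyDuplicated(map$lc_group) > 0)
})

test_that("isobar statistics aggregate per class", {
  map <- data.frame(di_id = c("D1", "D2"), lc_group = c("G1", "G2"),
                    multiplicity = c(2L, 4L))
  asg <- data.frame(feature_id = c("D1", "D2"),
                    formula = c("C6H12O6", "C11H12N2O2"),
                    class = c("CHO", "CHNO"))
  tab <- isobar_statistics(map, asg)
  cho <- tab[tab$class == "CHO", ]
  expect_identical(cho$n, 1L)
  expect_equal(cho$isobar_mean, 2)
  expect_identical(c(cho$isobar_min, cho$isobar_max), c(2L, 2L))
  expect_equal(tab$isobar_mean[tab$class == "total"], 3)
  empty <- isobar_statistics(map[0, ], asg)
  expect_identical(nrow(empty), 0L)
})

test_that("coverage patterns report shared and unique features", {
  intens <- cbind(F1 = c(rep(5, 5), rep(0, 5)),      # unique to A
                  F2 = rep(3, 10),                    # shared
                  F3 = c(rep(0, 5), rep(2, 5)))       # unique to B
  feats <- data.frame(feature_id = c("F1", "F2", "F3"),
                      mz = c(100, 200, 300))
  fm <- feature_matrix(feats, intens)
  groups <- rep(c("A", "B"), each = 5)
  v <- coverage_venn(fm, groups, min_samples_per_group = 4)
  expect_identical(v$n_union, 3L)
  expect_equal(sum(v$pattern$pct), 100, tolerance = 0.1)
  expect_identical(v$pattern$n[v$pattern$pattern == "A&B"], 1L)
  # identical groups share everything
  v2 <- coverage_venn(fm, rep(c("A", "B"), 5), min_samples_per_group = 2)
  expect_identical(v2$pattern$pattern, "A&B")
  expect_equal(v2$pattern$pct, 100)
})

test_that("feature matrices round-trip through wide TSV bit-exactly", {
  set.seed(12)
  feats <- data.frame(feature_id = c("F1", "F2"),
                      mz = c(180.0633881, 342.1162119),
                      rt = c(NA_real_, NA_real_))
  intens <- matrix(rlnorm(6, 10, 2), 3, 2,
                   dimnames = list(paste0("s", 1:3), feats$feature_id))
  fm <- feature_matrix(feats, intens,
                       data.frame(sample_id = paste0("s", 1:3),
                                  variety = c("a", "b", "a")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_identical(back$features$mz, fm$features$mz)
  expect_identical(unname(back$intensity), unname(fm$intensity))
  expect_identical(back$samples$variety, fm$samples$variety)
})

test_that("peak-list reader requires a header with an mz column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("intensity\tsnr", "1\t2"), path)
  expect_error(read_peaklist(path), "mz")
  write_peaklist(pk(c(100.5, 200.25)), path)
  back <- read_peaklist(path)
  expect_identical(back$mz, c(100.5, 200.25))
})
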