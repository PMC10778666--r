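# Feature-matrix construction from per-sample peak lists, presence
# filtering, isobar grouping, and cross-dataset alignment.

#' Construct a feature matrix object
#'
#' Container for aligned features: a feature descriptor table, a
#' samples-by-features intensity matrix (0 = not detected), and sample
#' metadata.
#'
#' @param features Data frame with at least `feature_id` and `mz`
#'   (consensus m/z); optionally `rt` (seconds) and annotation columns
#'   (`formula`, `class`).
#' @param intensity Numeric matrix, rows = samples, columns = features;
#'   `dimnames` must carry sample ids and feature ids.
#' @param samples Data frame of sample metadata with a `sample_id`
#'   column, one row per intensity row.
#' @return An object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(features, intensity, samples = NULL) {
  stopifnot(is.data.frame(features), all(c("feature_id", "mz") %in%
                                           names(features)))
  stopifnot(is.matrix(intensity), ncol(intensity) == nrow(features))
  if (is.null(samples)) {
    ids <- rownames(intensity)
    if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(intensity)))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(samples) == nrow(intensity), "sample_id" %in%
              names(samples))
  if (is.unsorted(features$mz)) {
    stop("features must be ordered by increasing consensus m/z",
         call. = FALSE)
  }
  colnames(intensity) <- features$feature_id
  rownames(intensity) <- samples$sample_id
  structure(list(features = features, intensity = intensity,
                 samples = samples), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x$intensity), " samples x ",
      ncol(x$intensity), " features\n", sep = "")
  cat("  m/z range ", format(min(x$features$mz)), "-",
      format(max(x$features$mz)),
      if ("rt" %in% names(x$features) && any(!is.na(x$features$rt)))
        " (with retention times)" else "", "\n", sep = "")
  det <- mean(x$intensity > 0)
  cat("  detected cells: ", sprintf("%.1f%%", 100 * det), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensity)

#' Extract the intensity matrix
#' @param fm A [feature_matrix()].
#' @return Numeric samples-by-features matrix.
#' @export
intensities <- function(fm) fm$intensity

# Single m/z sweep used for both DI alignment and isobar grouping.
# Sorts by mass and opens a new cluster whenever the incoming peak is
# more than `window` ppm above the running (unweighted) mean of the
# current cluster.  Deterministic and independent of input order;
# because membership is always tested against the cluster mean, chains
# of peaks each within the window of its neighbour cannot extend a
# cluster without bound.  Membership deliberately ignores intensity:
# weighting the membership centroid by log-normal intensities lets a
# single bright peak drag the centroid and split a genuine feature
# (the consensus m/z reported afterwards IS intensity-weighted).
.sweep_cluster <- function(mz, window) {
  ord <- order(mz)
  mzs <- mz[ord]
  cl <- integer(length(mzs))
  cur <- 0L
  centroid <- -Inf
  n_in <- 0L
  for (i in seq_along(mzs)) {
    if (cur == 0L ||
        (mzs[i] - centroid) / centroid * 1e6 > window) {
      cur <- cur + 1L
      centroid <- mzs[i]
      n_in <- 1L
    } else {
      n_in <- n_in + 1L
      centroid <- centroid + (mzs[i] - centroid) / n_in
    }
    cl[i] <- cur
  }
  out <- integer(length(mz))
  out[ord] <- cl
  out
}

#' Read a peak list
#'
#' Delimited text with a header; recognised columns are `mz` (Da,
#' required), `rt` (seconds), `intensity` and `snr`.  Extra columns are
#' kept.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Data frame of peaks.
#' @export
read_peaklist <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"mz" %in% names(df)) {
    stop("peak list '", path, "' has no 'mz' column (header required; ",
         "RT, when present, is in seconds under column 'rt')",
         call. = FALSE)
  }
  if (any(df$mz <= 0)) stop("non-positive m/z in '", path, "'",
                            call. = FALSE)
  df
}

#' Write a peak list
#' @param peaks Data frame of peaks.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path, sep = "\t") {
  utils::write.table(.format_numeric(peaks), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Full-precision numeric formatting so that TSV round trips are
# bit-exact (17 significant digits reproduce any double).
.format_numeric <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- "NA"
      df[[j]] <- v
    }
  }
  df
}

#' Align per-sample peak lists into a feature matrix
#'
#' Pools all peaks, sorts by mass and clusters them with a single sweep:
#' a new feature opens when the incoming peak lies more than `window`
#' ppm above the running intensity-weighted centroid of the current
#' feature.  When peaks carry retention times (LC data), each m/z
#' cluster is further split by RT gaps larger than `rt_tol` so isomers
#' stay distinct.  Peaks below `min_snr` (when an `snr` column exists)
#' are discarded before clustering.  If one sample contributes several
#' peaks to a feature, the maximum intensity is kept.
#'
#' @param peaklists Named list of peak data frames (see
#'   [read_peaklist()]); names become sample ids.
#' @param window Alignment window in ppm (> 0; default 0.5, the
#'   FT-ICR-style window).
#' @param min_snr Minimum signal-to-noise ratio (default 3); ignored
#'   when no `snr` column is present.
#' @param rt_tol RT gap (seconds) beyond which an m/z cluster is split
#'   into distinct features (default 10); only used when peaks carry
#'   `rt`.
#' @param samples Optional sample metadata data frame (`sample_id`
#'   column) joined onto the result.
#' @return A [feature_matrix()]; consensus m/z is the intensity-weighted
#'   mean of the contributing peaks, consensus RT the intensity-weighted
#'   mean RT.
#' @export
align_samples <- function(peaklists, window = 0.5, min_snr = 3,
                          rt_tol = 10, samples = NULL) {
  stopifnot(length(peaklists) >= 1L, window > 0)
  if (is.null(names(peaklists)) || anyDuplicated(names(peaklists))) {
    stop("peaklists must be a uniquely named list (names = sample ids)",
         call. = FALSE)
  }
  sample_ids <- names(peaklists)
  pooled <- do.call(rbind, lapply(sample_ids, function(s) {
    df <- peaklists[[s]]
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    if ("snr" %in% names(df) && !is.null(min_snr)) {
      df <- df[is.na(df$snr) | df$snr >= min_snr, , drop = FALSE]
    }
    if (nrow(df) == 0L) return(NULL)
    data.frame(sample = s, mz = df$mz,
               intensity = if ("intensity" %in% names(df)) df$intensity
                           else 1,
               rt = if ("rt" %in% names(df)) df$rt else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    feats <- data.frame(feature_id = character(0), mz = numeric(0),
                        rt = numeric(0))
    intens <- matrix(0, length(sample_ids), 0,
                     dimnames = list(sample_ids, NULL))
    return(feature_matrix(feats, intens, samples))
  }
  cl <- .sweep_cluster(pooled$mz, window)
  has_rt <- any(!is.na(pooled$rt))
  if (has_rt) {
    # split each m/z cluster at RT gaps > rt_tol (sorted sweep)
    key <- paste0(cl, "/")
    for (g in unique(cl)) {
      idx <- which(cl == g)
      rts <- pooled$rt[idx]
      ordr <- order(rts)
      sub <- integer(length(idx))
      cur <- 1L
      for (k in seq_along(ordr)) {
        if (k > 1L && (rts[ordr[k]] - rts[ordr[k - 1L]]) > rt_tol) {
          cur <- cur + 1L
        }
        sub[ordr[k]] <- cur
      }
      key[idx] <- paste0(g, "/", sub)
    }
    cl <- match(key, unique(key[order(pooled$mz,
                                      ifelse(is.na(pooled$rt), 0,
                                             pooled$rt))]))
  }
  groups <- split(seq_len(nrow(pooled)), cl)
  cons <- lapply(groups, function(idx) {
    w <- pooled$intensity[idx]
    w[w <= 0 | is.na(w)] <- .Machine$double.eps
    c(mz = sum(pooled$mz[idx] * w) / sum(w),
      rt = if (has_rt) sum(pooled$rt[idx] * w) / sum(w) else NA_real_)
  })
  cons <- do.call(rbind, cons)
  ord <- order(cons[, "mz"], cons[, "rt"], na.last = TRUE)
  groups <- groups[ord]
  cons <- cons[ord, , drop = FALSE]
  nfeat <- length(groups)
  feats <- data.frame(
    feature_id = sprintf("F%05d", seq_len(nfeat)),
    mz = cons[, "mz"],
    rt = cons[, "rt"],
    stringsAsFactors = FALSE)
  intens <- matrix(0, length(sample_ids), nfeat,
                   dimnames = list(sample_ids, feats$feature_id))
  for (f in seq_len(nfeat)) {
    idx <- groups[[f]]
    agg <- tapply(pooled$intensity[idx], pooled$sample[idx], max)
    intens[names(agg), f] <- agg
  }
  fm <- feature_matrix(feats, intens, samples)
  attr(fm, "window_ppm") <- window
  fm
}

#' Presence filter
#'
#' Keeps features detected (nonzero) in at least `min_samples` samples,
#' or in at least a `min_fraction` of the samples
#' (`ceiling(n * min_fraction)`; a stated lower bound, so fractional
#' thresholds round up).
#'
#' @param fm A [feature_matrix()].
#' @param min_samples Minimum number of samples (default 4).
#' @param min_fraction Alternative fractional threshold in (0, 1];
#'   overrides `min_samples` when given.
#' @return Filtered [feature_matrix()] with attributes `n_removed` and
#'   `n_retained`.
#' @export
presence_filter <- function(fm, min_samples = 4, min_fraction = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is.null(min_fraction)) {
    stopifnot(min_fraction > 0, min_fraction <= 1)
    min_samples <- ceiling(nrow(fm$intensity) * min_fraction)
  }
  stopifnot(min_samples > 0)
  present <- colSums(fm$intensity > 0) >= min_samples
  out <- feature_matrix(fm$features[present, , drop = FALSE],
                        fm$intensity[, present, drop = FALSE],
                        fm$samples)
  attr(out, "n_removed") <- sum(!present)
  attr(out, "n_retained") <- sum(present)
  out
}

#' Group LC features into isobar groups
#'
#' Features whose m/z agree within `window` ppm are merged into one
#' group keyed by the unweighted mean m/z; the group keeps all member
#' retention times sorted ascending, and its isobar multiplicity is the
#' number of distinct RTs.
#'
#' @param fm LC [feature_matrix()] whose features carry `rt`.
#' @param window Grouping window in ppm (default 2).
#' @return Data frame with `group_id`, `mean_mz`, `multiplicity`,
#'   `n_features`, `rts` (list column, sorted) and `members` (list of
#'   feature ids).
#' @export
group_isobars <- function(fm, window = 2) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!"rt" %in% names(fm$features) || all(is.na(fm$features$rt))) {
    stop("group_isobars() needs LC features with retention times",
         call. = FALSE)
  }
  cl <- .sweep_cluster(fm$features$mz, window)
  groups <- split(seq_len(nrow(fm$features)), cl)
  res <- lapply(groups, function(idx) {
    rts <- sort(fm$features$rt[idx])
    data.frame(mean_mz = mean(fm$features$mz[idx]),
               multiplicity = length(unique(rts)),
               n_features = length(idx))
  })
  out <- do.call(rbind, res)
  ord <- order(out$mean_mz)
  out <- out[ord, , drop = FALSE]
  groups <- groups[ord]
  out$group_id <- sprintf("G%05d", seq_len(nrow(out)))
  out$rts <- lapply(groups, function(idx) sort(fm$features$rt[idx]))
  out$members <- lapply(groups, function(idx) fm$features$feature_id[idx])
  rownames(out) <- NULL
  out[, c("group_id", "mean_mz", "multiplicity", "n_features", "rts",
          "members")]
}

# Greedy one-to-at-most-one matching over a candidate pair table already
# sorted by the tie cascade; returns logical keep vector.
.greedy_pairs <- function(a_id, b_id) {
  keep <- logical(length(a_id))
  used_a <- character(0)
  used_b <- character(0)
  for (i in seq_along(a_id)) {
    if (!(a_id[i] %in% used_a) && !(b_id[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, a_id[i])
      used_b <- c(used_b, b_id[i])
    }
  }
  keep
}

#' Align LC isobar groups to direct-infusion features
#'
#' Each LC group (keyed by its mean m/z) is matched to at most one DI
#' feature whose m/z agrees within `window` ppm.  Among multiple
#' candidates the tie cascade is: smallest absolute ppm error, then
#' smallest RT delta (when both sides carry RT), then the lower m/z.
#'
#' @param di_features DI [feature_matrix()] (or its `$features` table).
#' @param lc_groups Isobar group table from [group_isobars()].
#' @param window Matching window in ppm (default 5).
#' @return Alignment map: data frame with `di_id`, `lc_group`,
#'   `di_mz`, `lc_mz`, `error_ppm` (signed, LC group mean vs DI mass,
#'   in ppm of the LC mean), `multiplicity`.
#' @export
cross_align <- function(di_features, lc_groups, window = 5) {
  feats <- if (inherits(di_features, "feature_matrix"))
    di_features$features else di_features
  cand <- NULL
  for (i in seq_len(nrow(lc_groups))) {
    gm <- lc_groups$mean_mz[i]
    err <- ppm_error(gm, feats$mz)   # LC observed vs DI reference
    hit <- which(abs(err) <= window)
    if (!length(hit)) next
    cand <- rbind(cand, data.frame(
      di_id = feats$feature_id[hit], lc_group = lc_groups$group_id[i],
      di_mz = feats$mz[hit], lc_mz = gm, error_ppm = err[hit],
      multiplicity = lc_groups$multiplicity[i],
      stringsAsFactors = FALSE))
  }
  empty <- data.frame(di_id = character(0), lc_group = character(0),
                      di_mz = numeric(0), lc_mz = numeric(0),
                      error_ppm = numeric(0), multiplicity = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(cand)) return(empty)
  cand <- cand[order(abs(cand$error_ppm), cand$di_mz, cand$lc_group), ,
               drop = FALSE]
  out <- cand[.greedy_pairs(cand$di_id, cand$lc_group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align two LC feature sets
#'
#' A match requires mass agreement within `window` ppm AND an RT
#' difference of at most `rt_tol` seconds.  Ties are resolved by the
#' smallest RT delta first, then the smallest absolute ppm error, then
#' the lower m/z; matching is one-to-at-most-one.
#'
#' @param fa,fb LC [feature_matrix()] objects (or `$features` tables)
#'   carrying `rt`.
#' @param window Matching window in ppm (default 5).
#' @param rt_tol RT tolerance in seconds (default 10).
#' @return Alignment map: data frame with `id_a`, `id_b`, `mz_a`,
#'   `mz_b`, `error_ppm`, `rt_delta`.
#' @export
lc_lc_align <- function(fa, fb, window = 5, rt_tol = 10) {
  A <- if (inherits(fa, "feature_matrix")) fa$features else fa
  B <- if (inherits(fb, "feature_matrix")) fb$features else fb
  stopifnot("rt" %in% names(A), "rt" %in% names(B))
  cand <- NULL
  for (i in seq_len(nrow(A))) {
    err <- ppm_error(A$mz[i], B$mz)
    dt <- abs(A$rt[i] - B$rt)
    hit <- which(abs(err) <= window & dt <= rt_tol)
    if (!length(hit)) next
    cand <- rbind(cand, data.frame(
      id_a = A$feature_id[i], id_b = B$feature_id[hit],
      mz_a = A$mz[i], mz_b = B$mz[hit],
      error_ppm = err[hit], rt_delta = dt[hit],
      stringsAsFactors = FALSE))
  }
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      mz_a = numeric(0), mz_b = numeric(0),
                      error_ppm = numeric(0), rt_delta = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$rt_delta, abs(cand$error_ppm),
                     pmin(cand$mz_a, cand$mz_b)), , drop = FALSE]
  out <- cand[.greedy_pairs(cand$id_a, cand$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-class isobar statistics of an alignment map
#'
#' For each compound class of the matched DI features: how many
#' compositions found LC hits, the mean isobar multiplicity (average
#' number of retention times per composition) and its min-max range.
#'
#' @param map Alignment map from [cross_align()].
#' @param assignments Assignment table with `formula` and `class` for
#'   the DI features, carrying a `feature_id` column (or rows aligned
#'   with `map$di_id`).
#' @return Data frame, one row per class plus a `"total"` row:
#'   `class`, `n`, `pct`, `isobar_mean`, `isobar_min`, `isobar_max`.
#' @export
isobar_statistics <- function(map, assignments) {
  if (nrow(map) == 0L) {
    return(data.frame(class = character(0), n = integer(0),
                      pct = numeric(0), isobar_mean = numeric(0),
                      isobar_min = integer(0), isobar_max = integer(0),
                      stringsAsFactors = FALSE))
  }
  if ("feature_id" %in% names(assignments)) {
    cls <- assignments$class[match(map$di_id, assignments$feature_id)]
  } else {
    stopifnot(nrow(assignments) == nrow(map))
    cls <- assignments$class
  }
  ok <- !is.na(cls)
  cls <- cls[ok]
  mult <- map$multiplicity[ok]
  lv <- intersect(c("CHO", "CHNO", "CHOS", "CHNOS", "unclassified"),
                  unique(cls))
  rows <- lapply(lv, function(cl) {
    m <- mult[cls == cl]
    data.frame(class = cl, n = length(m), pct = 100 * length(m) /
                 length(mult), isobar_mean = mean(m),
               isobar_min = min(m), isobar_max = max(m),
               stringsAsFactors = FALSE)
  })
  tot <- data.frame(class = "total", n = length(mult), pct = 100,
                    isobar_mean = mean(mult), isobar_min = min(mult),
                    isobar_max = max(mult), stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), tot)
  rownames(out) <- NULL
  out
}

#' Feature-coverage comparison between sample groups
#'
#' A feature counts as present in a group when it is detected in at
#' least `min_samples_per_group` samples of that group.  For each
#' presence pattern across groups the count and percentage (of features
#' present in at least one group) are reported; for two groups this is
#' the shared/unique Venn breakdown and the percentages sum to 100.
#'
#' @param fm A [feature_matrix()].
#' @param groups Factor or character vector of group labels, one per
#'   sample.
#' @param min_samples_per_group Detection threshold per group
#'   (default 4).
#' @return List with `pattern` (data frame: one row per presence
#'   pattern with a count and percentage), `presence` (logical
#'   features-by-groups matrix) and `n_union`.
#' @export
coverage_venn <- function(fm, groups, min_samples_per_group = 4) {
  stopifnot(inherits(fm, "feature_matrix"))
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(fm$intensity), nlevels(groups) >= 2)
  small <- levels(groups)[table(groups) < min_samples_per_group]
  if (length(small)) {
    warning("group(s) with fewer samples than the detection threshold: ",
            paste(small, collapse = ", "))
  }
  presence <- sapply(levels(groups), function(g) {
    colSums(fm$intensity[groups == g, , drop = FALSE] > 0) >=
      min_samples_per_group
  })
  if (is.null(dim(presence))) presence <- matrix(presence, nrow = 1)
  rownames(presence) <- fm$features$feature_id
  in_any <- rowSums(presence) > 0
  pat <- apply(presence[in_any, , drop = FALSE], 1L, function(r) {
    paste(colnames(presence)[r], collapse = "&")
  })
  tab <- table(pat)
  pattern <- data.frame(pattern = names(tab), n = as.integer(tab),
                        pct = 100 * as.integer(tab) / sum(in_any),
                        stringsAsFactors = FALSE)
  pattern <- pattern[order(-pattern$n, pattern$pattern), , drop = FALSE]
  rownames(pattern) <- NULL
  list(pattern = pattern, presence = presence,
       n_union = sum(in_any))
}

#' Write / read a feature matrix as wide TSV
#'
#' Features as rows: `feature_id`, `mz`, `rt`, annotation columns, then
#' one intensity column per sample.  Numeric values are written with 17
#' significant digits so the round trip is bit-exact.  Sample metadata
#' goes to `<path>.samples.tsv` when present.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  wide <- cbind(fm$features, as.data.frame(t(fm$intensity)))
  utils::write.table(.format_numeric(wide), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (ncol(fm$samples) > 1L) {
    utils::write.table(.format_numeric(fm$samples),
                       paste0(path, ".samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  wide <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("feature_id", "mz", "rt", "formula", "class",
                           "adduct", "error_ppm"), names(wide))
  sample_cols <- setdiff(names(wide), meta_cols)
  feats <- wide[, meta_cols, drop = FALSE]
  intens <- t(as.matrix(wide[, sample_cols, drop = FALSE]))
  colnames(intens) <- feats$feature_id
  meta_path <- paste0(path, ".samples.tsv")
  samples <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else NULL
  feature_matrix(feats, intens, samples)
}

#' Write an alignment map
#' @param map Alignment map from [cross_align()] or [lc_lc_align()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_map <- function(map, path) {
  utils::write.table(.format_numeric(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
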