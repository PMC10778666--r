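# Feature-matrix preprocessing: zero imputation, log10 + Pareto
# scaling, two-stage batch correction, and univariate screening.

# Accept either a feature_matrix or a plain samples-by-features matrix.
.as_intensity <- function(x) {
  if (inherits(x, "feature_matrix")) x$intensity
  else if (is.matrix(x)) x
  else stop("expected a feature_matrix or a samples-by-features matrix",
            call. = FALSE)
}

.restore <- function(x, m) {
  if (inherits(x, "feature_matrix")) {
    x$intensity <- m
    x
  } else m
}

#' Replace zero intensities
#'
#' Zeros (not-detected cells) are replaced, per feature, by
#' `factor` times the minimum nonzero intensity of that feature; nonzero
#' cells are never altered.  All-zero features are rejected: they must
#' be removed by the presence filter first.
#'
#' @param x A [feature_matrix()] or samples-by-features matrix.
#' @param factor Fraction of the per-feature minimum used as the
#'   imputed value, in (0, 1] (default 2/3).
#' @return Object of the same type with zeros imputed.
#' @examples
#' m <- matrix(c(0, 0.9, 1.2), 3, 1)
#' impute_zeros(m)  # 0 -> 0.6
#' @export
impute_zeros <- function(x, factor = 2 / 3) {
  stopifnot(factor > 0, factor <= 1)
  m <- .as_intensity(x)
  if (any(m < 0, na.rm = TRUE)) stop("negative intensities", call. = FALSE)
  zero_cols <- which(colSums(m > 0) == 0)
  if (length(zero_cols)) {
    stop("all-zero feature(s) at column(s) ",
         paste(utils::head(zero_cols, 5), collapse = ", "),
         "; apply presence_filter() first", call. = FALSE)
  }
  for (j in seq_len(ncol(m))) {
    z <- m[, j] == 0
    if (any(z)) m[z, j] <- factor * min(m[!z, j])
  }
  .restore(x, m)
}

#' Log10 transform and Pareto scaling
#'
#' Each cell is log10-transformed, then each feature is mean-centred
#' and divided by the square root of its standard deviation (Pareto
#' scaling), giving heavy features less dominance than no scaling but
#' more than unit-variance scaling.  Constant features scale to all
#' zeros.  The result is tagged with attribute `scaled = TRUE`;
#' applying the transform twice is an error.
#'
#' @param x A [feature_matrix()] or samples-by-features matrix with all
#'   entries > 0 (impute first).
#' @return Object of the same type, scaled, with attribute `"scaled"`.
#' @export
transform_scale <- function(x) {
  m <- .as_intensity(x)
  if (isTRUE(attr(x, "scaled")) || isTRUE(attr(m, "scaled"))) {
    stop("matrix is already log/Pareto scaled; refusing to scale twice",
         call. = FALSE)
  }
  if (any(m <= 0)) {
    bad <- which(colSums(m <= 0) > 0)[1]
    stop("non-positive entry in feature column ", bad,
         "; impute zeros before transforming", call. = FALSE)
  }
  lm10 <- log10(m)
  mu <- colMeans(lm10)
  sdv <- apply(lm10, 2L, stats::sd)
  sc <- sqrt(sdv)
  sc[sdv == 0] <- 1  # constant feature -> centred zeros
  out <- sweep(sweep(lm10, 2L, mu, "-"), 2L, sc, "/")
  res <- .restore(x, out)
  attr(res, "scaled") <- TRUE
  res
}

#' Two-stage batch correction
#'
#' Per feature, a location/scale adjustment estimated by least squares:
#' stage 1 removes per-batch mean offsets (re-centring every batch on
#' the grand mean), stage 2 rescales each batch's residual spread to
#' the pooled within-batch standard deviation.  After correction the
#' per-batch means of every feature agree with the grand mean to
#' numerical precision, and applying the correction twice is a no-op.
#' Batches with a single sample get the location step only (with a
#' warning): a scale is not estimable from one observation.
#'
#' @param x A [feature_matrix()] or samples-by-features matrix.
#' @param batch Factor or vector of batch labels, one per sample
#'   (>= 2 batches).
#' @return Object of the same type, batch-corrected.
#' @export
batch_correct <- function(x, batch) {
  m <- .as_intensity(x)
  batch <- as.factor(batch)
  stopifnot(length(batch) == nrow(m), nlevels(batch) >= 2)
  singleton <- levels(batch)[table(batch) < 2]
  if (length(singleton)) {
    warning("singleton batch(es) ", paste(singleton, collapse = ", "),
            ": scale step skipped for them")
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    grand <- mean(v)
    centred <- v
    sds <- numeric(nlevels(batch))
    for (bi in seq_len(nlevels(batch))) {
      idx <- batch == levels(batch)[bi]
      centred[idx] <- v[idx] - mean(v[idx])
      sds[bi] <- if (sum(idx) >= 2) stats::sd(v[idx]) else NA_real_
    }
    # pooled within-batch sd over batches where it is estimable
    ns <- table(batch)
    est <- !is.na(sds)
    pooled <- sqrt(sum((ns[est] - 1) * sds[est]^2) / sum(ns[est] - 1))
    for (bi in seq_len(nlevels(batch))) {
      idx <- batch == levels(batch)[bi]
      scale_b <- if (!is.na(sds[bi]) && sds[bi] > 0 && pooled > 0)
        pooled / sds[bi] else 1
      out[idx, j] <- grand + centred[idx] * scale_b
    }
  }
  .restore(x, out)
}

# Dunn's post hoc z statistic on the rank scale with tie correction.
.dunn_pairwise <- function(v, g) {
  g <- droplevels(as.factor(g))
  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  n <- table(g)
  ties <- table(r)
  tiesum <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - tiesum / (12 * (N - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             stringsAsFactors = FALSE)
}

#' Univariate feature screening
#'
#' For three or more groups: Kruskal-Wallis per feature, followed by
#' Dunn's rank-based post hoc pairwise comparison.  For two groups: a
#' Student t-test when both groups pass a Shapiro-Wilk normality check
#' at `shapiro_alpha`, otherwise a Mann-Whitney U test.  Feature-level
#' p-values are Benjamini-Hochberg adjusted across features.  Fold
#' changes are computed on the raw (unlogged, imputed) intensities as
#' the ratio of group means; for more than two groups the max/min group
#' mean ratio is reported.  Constant features get p = 1 and are
#' flagged.
#'
#' @param x Raw-scale (imputed) [feature_matrix()] or
#'   samples-by-features matrix.
#' @param groups Factor of group labels, one per sample; every group
#'   needs n >= 3.
#' @param alpha FDR significance level recorded in the result
#'   (default 0.05).
#' @param shapiro_alpha Level of the normality pre-test in the
#'   two-group rule (default 0.05).
#' @return List of class `"univariate_result"`: `table` (per feature:
#'   statistic, test, p, p_adj, fold_change, log2_fc, group means,
#'   flag), `posthoc` (Dunn pairwise table per feature, >= 3 groups
#'   only), `alpha`.
#' @export
univariate_screen <- function(x, groups, alpha = 0.05,
                              shapiro_alpha = 0.05) {
  m <- .as_intensity(x)
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(m), nlevels(groups) >= 2)
  if (any(table(groups) < 3)) {
    stop("every group needs at least 3 samples", call. = FALSE)
  }
  k <- nlevels(groups)
  nfeat <- ncol(m)
  stat <- p <- fc <- numeric(nfeat)
  test <- character(nfeat)
  flag <- character(nfeat)
  gmeans <- matrix(NA_real_, nfeat, k,
                   dimnames = list(NULL, paste0("mean_", levels(groups))))
  posthoc <- vector("list", nfeat)
  for (j in seq_len(nfeat)) {
    v <- m[, j]
    gm <- tapply(v, groups, mean)
    gmeans[j, ] <- gm
    fc[j] <- if (k == 2L) gm[[1]] / gm[[2]] else max(gm) / min(gm)
    if (stats::sd(v) == 0) {
      stat[j] <- NA_real_; p[j] <- 1; test[j] <- "none"
      flag[j] <- "constant"
      next
    }
    flag[j] <- ""
    if (k >= 3L) {
      kw <- stats::kruskal.test(v, groups)
      stat[j] <- unname(kw$statistic); p[j] <- kw$p.value
      test[j] <- "kruskal-wallis"
      posthoc[[j]] <- .dunn_pairwise(v, groups)
    } else {
      g1 <- v[groups == levels(groups)[1]]
      g2 <- v[groups == levels(groups)[2]]
      normal <- function(g) {
        if (stats::sd(g) == 0) return(FALSE)
        stats::shapiro.test(g)$p.value >= shapiro_alpha
      }
      if (normal(g1) && normal(g2)) {
        tt <- stats::t.test(g1, g2)
        stat[j] <- unname(tt$statistic); p[j] <- tt$p.value
        test[j] <- "t-test"
      } else {
        wt <- stats::wilcox.test(g1, g2, exact = FALSE)
        stat[j] <- unname(wt$statistic); p[j] <- wt$p.value
        test[j] <- "mann-whitney"
      }
    }
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(
    feature = if (inherits(x, "feature_matrix"))
      x$features$feature_id else
        (colnames(m) %||% paste0("V", seq_len(nfeat))),
    statistic = stat, test = test, p = p, p_adj = p_adj,
    fold_change = fc,
    log2_fc = ifelse(fc > 0, suppressWarnings(log2(fc)), NA_real_),
    gmeans, flag = flag,
    stringsAsFactors = FALSE)
  names(posthoc) <- tab$feature
  structure(list(table = tab, posthoc = posthoc, alpha = alpha),
            class = "univariate_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.univariate_result <- function(x, ...) {
  sig <- sum(x$table$p_adj < x$alpha, na.rm = TRUE)
  cat("univariate screen: ", nrow(x$table), " features, ",
      sig, " significant at FDR ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Write a univariate screening table
#' @param result A `univariate_result` from [univariate_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_univariate <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
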