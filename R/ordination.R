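# Unsupervised ordination and constrained variance decomposition.

#' Principal component analysis of a feature matrix
#'
#' Eigen decomposition of the column-centred matrix (no rescaling:
#' apply [transform_scale()] first).
#'
#' @param x Transformed/scaled samples-by-features matrix or
#'   [feature_matrix()].
#' @param n_comp Number of components to keep (default 2); truncated
#'   with a warning when it exceeds the matrix rank.
#' @return List with `scores` (samples x n_comp), `loadings`
#'   (features x n_comp, orthonormal) and `explained`
#'   (variance ratios, descending, summing to <= 1).
#' @export
feature_pca <- function(x, n_comp = 2) {
  m <- .as_intensity(x)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_comp > rank) {
    warning("n_comp = ", n_comp, " exceeds rank ", rank,
            "; truncating")
    n_comp <- rank
  }
  list(scores = pc$x[, seq_len(n_comp), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_comp), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_comp)])
}

#' Canonical eigenvalues of a redundancy analysis
#'
#' Constrained ordination of the (centred) response matrix on the
#' dummy-coded explanatory factors; the eigenvalues of the fitted
#' values' covariance.  Thin wrapper around [vegan::rda()].
#'
#' @param x Samples-by-features response matrix or [feature_matrix()].
#' @param factors Data frame of explanatory factors.
#' @return Numeric vector of canonical eigenvalues (variance scale,
#'   i.e. sums of squares divided by n - 1).
#' @export
constrained_eigen <- function(x, factors) {
  m <- .as_intensity(x)
  fit <- vegan::rda(m ~ ., data = as.data.frame(factors))
  unname(fit$CCA$eig)
}

#' RDA variance partitioning across design factors
#'
#' Decomposes the variance of the response matrix into unique and
#' shared fractions attributable to 2 or 3 design factors, using
#' adjusted R-squared (Ezekiel correction) of the all-subsets partial
#' redundancy-analysis models, plus a permutation test (pseudo-F) of
#' each factor's marginal model.  Built on [vegan::varpart()],
#' [vegan::rda()] and [vegan::anova.cca()].
#'
#' @param x Transformed/scaled samples-by-features matrix or
#'   [feature_matrix()].
#' @param factors Data frame of 2 or 3 factors (e.g. variety, region,
#'   vintage), one row per sample.  Constant columns are dropped with a
#'   warning.
#' @param n_perm Permutations for the significance tests
#'   (default 1000).
#' @param seed Mandatory integer seed for the permutation schemes.
#' @return Object of class `"variance_partition"`: `unique` (named
#'   adjusted fractions per factor), `shared` (named pairwise/triple
#'   fractions), `unexplained`, `significance` (per-factor marginal
#'   pseudo-F and p), `n_perm`.  Fractions plus unexplained sum to 1.
#' @export
rda_varpart <- function(x, factors, n_perm = 1000, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  m <- .as_intensity(x)
  factors <- as.data.frame(factors, stringsAsFactors = TRUE)
  stopifnot(nrow(factors) == nrow(m))
  keep <- vapply(factors, function(f) length(unique(f)) > 1, logical(1))
  if (!all(keep)) {
    warning("dropping constant factor(s): ",
            paste(names(factors)[!keep], collapse = ", "))
    factors <- factors[, keep, drop = FALSE]
  }
  nf <- ncol(factors)
  if (nf < 2 || nf > 3) {
    stop("rda_varpart() supports 2 or 3 (non-constant) factors, got ",
         nf, call. = FALSE)
  }
  n_dummy <- sum(vapply(factors, function(f)
    length(unique(f)) - 1, numeric(1)))
  if (nrow(m) <= n_dummy + 2) {
    stop("too few samples for the number of dummy-coded factor levels",
         call. = FALSE)
  }
  fml <- lapply(names(factors), function(nm) stats::as.formula(
    paste("~", nm)))
  set.seed(seed)
  vp <- if (nf == 2) {
    vegan::varpart(m, fml[[1]], fml[[2]], data = factors)
  } else {
    vegan::varpart(m, fml[[1]], fml[[2]], fml[[3]], data = factors)
  }
  ind <- vp$part$indfract
  adj <- ind$Adj.R.square
  if (nf == 2) {
    unique_fr <- stats::setNames(adj[1:2], names(factors))
    shared <- c(adj[3])
    names(shared) <- paste(names(factors), collapse = "&")
    unexplained <- adj[4]
  } else {
    unique_fr <- stats::setNames(adj[1:3], names(factors))
    shared <- adj[4:7]
    names(shared) <- c(paste(names(factors)[c(1, 2)], collapse = "&"),
                       paste(names(factors)[c(2, 3)], collapse = "&"),
                       paste(names(factors)[c(1, 3)], collapse = "&"),
                       paste(names(factors), collapse = "&"))
    unexplained <- adj[8]
  }
  sig <- do.call(rbind, lapply(names(factors), function(nm) {
    others <- setdiff(names(factors), nm)
    f <- stats::as.formula(paste("m ~", nm, "+ Condition(",
                                 paste(others, collapse = " + "), ")"))
    fit <- vegan::rda(f, data = factors)
    an <- vegan::anova.cca(fit, permutations = n_perm)
    data.frame(factor = nm, pseudo_F = an$F[1], p = an$`Pr(>F)`[1],
               stringsAsFactors = FALSE)
  }))
  structure(list(unique = unique_fr, shared = shared,
                 unexplained = unexplained, significance = sig,
                 n_perm = n_perm, seed = seed),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("RDA variance partition (adjusted R-squared fractions)\n")
  for (nm in names(x$unique)) {
    p <- x$significance$p[x$significance$factor == nm]
    cat(sprintf("  %-12s unique %6.1f%%  (marginal p = %.4g)\n", nm,
                100 * x$unique[[nm]], p))
  }
  for (nm in names(x$shared)) {
    cat(sprintf("  %-12s shared %6.1f%%\n", nm, 100 * x$shared[[nm]]))
  }
  cat(sprintf("  unexplained %9.1f%%\n", 100 * x$unexplained))
  invisible(x)
}
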