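# Two-class OPLS-DA: orthogonal-signal-corrected PLS with one
# predictive component, cross-validated Q2, permutation validation and
# OPLS VIP scores.
#
# Model (on the centred data): orthogonal components are extracted by
# deflating X with the part of its loading that is uncorrelated with
# the class vector (Trygg-Wold orthogonal projection to latent
# structures); the single predictive component is then an ordinary
# PLS1 component of the filtered X.  With 0 orthogonal components the
# fit is numerically identical to 1-component PLS-DA.

.opls_core <- function(X, y, n_ortho) {
  # X, y already centred.  Returns weights/scores/loadings.
  W_o <- P_o <- NULL
  T_o <- NULL
  Xf <- X
  k <- 0L
  while (k < n_ortho) {
    w <- crossprod(Xf, y)
    w <- w / sqrt(sum(w^2))
    t_p <- Xf %*% w
    p <- crossprod(Xf, t_p) / sum(t_p^2)
    w_o <- p - as.numeric(crossprod(w, p)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-10) break  # no orthogonal variation left
    w_o <- w_o / nrm
    t_o <- Xf %*% w_o
    p_o <- crossprod(Xf, t_o) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
    k <- k + 1L
  }
  w <- crossprod(Xf, y)
  w <- w / sqrt(sum(w^2))
  t_p <- Xf %*% w
  p <- crossprod(Xf, t_p) / sum(t_p^2)
  q <- as.numeric(crossprod(y, t_p) / sum(t_p^2))
  list(w = w, t = t_p, p = p, q = q, W_o = W_o, P_o = P_o, T_o = T_o,
       n_ortho = k)
}

# Filter and project new (already centred) data through a fitted core.
.opls_project <- function(core, Xnew) {
  Xf <- Xnew
  if (!is.null(core$W_o)) {
    for (k in seq_len(ncol(core$W_o))) {
      t_o <- Xf %*% core$W_o[, k]
      Xf <- Xf - tcrossprod(t_o, core$P_o[, k])
    }
  }
  drop(Xf %*% core$w)
}

# Stratified fold assignment, deterministic given the RNG state.
.stratified_folds <- function(y01, k) {
  fold <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# One full Q2 evaluation (k-fold CV) for a given label vector.
.opls_q2 <- function(X, y_num, n_ortho, folds) {
  press <- ss <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    mu_x <- colMeans(X[tr, , drop = FALSE])
    mu_y <- mean(y_num[tr])
    Xtr <- sweep(X[tr, , drop = FALSE], 2L, mu_x)
    ytr <- y_num[tr] - mu_y
    core <- .opls_core(Xtr, ytr, n_ortho)
    Xte <- sweep(X[!tr, , drop = FALSE], 2L, mu_x)
    yhat <- .opls_project(core, Xte) * core$q
    yte <- y_num[!tr] - mu_y
    press <- press + sum((yte - yhat)^2)
    ss <- ss + sum(yte^2)
  }
  1 - press / ss
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis with one
#' predictive component and `n_ortho` orthogonal (class-uncorrelated)
#' components, fitted on an already transformed/scaled
#' samples-by-features matrix.  Reports R2X, R2Y, a k-fold
#' cross-validated Q2, a label-permutation p-value for Q2, and OPLS VIP
#' scores combining the predictive and orthogonal parts.
#'
#' The permutation p-value is `(1 + #\{Q2_perm >= Q2\}) / (n_perm + 1)`,
#' each permuted model refitted and cross-validated exactly like the
#' observed one.  VIP for feature j is
#' `sqrt(p * (s_p w_j^2 + sum_k s_k w_ok^2) / (s_p + sum_k s_k))` with
#' normalised weight vectors and `s_p`, `s_k` the Y sum of squares
#' explained by the predictive and k-th orthogonal component (the
#' standard PLS VIP weighting), so that the mean squared VIP over
#' features is exactly 1.
#'
#' @param x Numeric samples-by-features matrix (transform/scale first)
#'   or [feature_matrix()].
#' @param y Two-level factor (or coercible) of class labels.
#' @param n_ortho Number of orthogonal components (default 1); may come
#'   out lower if no orthogonal variation remains.
#' @param cv_folds Cross-validation folds, stratified by class
#'   (default 7).
#' @param n_perm Label permutations for the validation test
#'   (default 500).
#' @param seed Mandatory integer seed governing fold assignment and
#'   permutations.
#' @return Object of class `"opls_da"` with scores, loadings, weights,
#'   `R2X`, `R2Y`, `Q2`, `p_perm`, `vip`, and the fitted centring
#'   vectors needed by [predict.opls_da()].
#' @export
opls_da <- function(x, y, n_ortho = 1, cv_folds = 7, n_perm = 500,
                    seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  X <- .as_intensity(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) {
    stop("opls_da() needs exactly two classes, got ", nlevels(y),
         call. = FALSE)
  }
  n_by_class <- table(y)
  if (min(n_by_class) < cv_folds) {
    stop("each class needs at least cv_folds (= ", cv_folds,
         ") samples", call. = FALSE)
  }
  if (max(n_by_class) / min(n_by_class) > 10) {
    warning("severe class imbalance (> 10:1)")
  }
  y01 <- as.integer(y) - 1L
  y_num <- as.numeric(y01)
  set.seed(seed)
  folds <- .stratified_folds(y01, cv_folds)
  mu_x <- colMeans(X)
  mu_y <- mean(y_num)
  Xc <- sweep(X, 2L, mu_x)
  yc <- y_num - mu_y
  core <- .opls_core(Xc, yc, n_ortho)
  ssx <- sum(Xc^2)
  ssy <- sum(yc^2)
  ssx_pred <- sum(core$t^2) * sum(core$p^2)
  ssx_orth <- if (is.null(core$T_o)) numeric(0) else
    vapply(seq_len(ncol(core$T_o)), function(k) {
      sum(core$T_o[, k]^2) * sum(core$P_o[, k]^2)
    }, numeric(1))
  yhat <- core$t * core$q
  R2Y <- 1 - sum((yc - yhat)^2) / ssy
  R2X <- (ssx_pred + sum(ssx_orth)) / ssx
  Q2 <- .opls_q2(X, y_num, n_ortho, folds)
  # permutation validation
  q2_perm <- numeric(n_perm)
  if (n_perm > 0) {
    for (b in seq_len(n_perm)) {
      yp <- sample(y_num)
      fp <- .stratified_folds(as.integer(yp), cv_folds)
      q2_perm[b] <- .opls_q2(X, yp, n_ortho, fp)
    }
    p_perm <- (1 + sum(q2_perm >= Q2)) / (n_perm + 1)
  } else {
    p_perm <- NA_real_
  }
  # combined OPLS VIP: every component (predictive and orthogonal) is
  # weighted by the Y sum of squares it explains, the standard PLS VIP
  # weighting; orthogonal components are class-uncorrelated by
  # construction, so their residual contribution is tiny
  s_p <- sum(core$t^2) * core$q^2             # SSY explained (predictive)
  s_o <- if (is.null(core$T_o)) numeric(0) else
    vapply(seq_len(ncol(core$T_o)), function(k) {
      t_o <- core$T_o[, k]
      as.numeric(crossprod(yc, t_o))^2 / sum(t_o^2)
    }, numeric(1))
  p_feat <- ncol(X)
  num <- s_p * core$w^2
  if (length(s_o)) {
    for (k in seq_along(s_o)) num <- num + s_o[k] * core$W_o[, k]^2
  }
  vip <- sqrt(p_feat * num / (s_p + sum(s_o)))
  vip <- drop(vip)
  names(vip) <- colnames(X) %||% paste0("V", seq_len(p_feat))
  structure(list(
    levels = levels(y), y = y, scores = drop(core$t),
    scores_ortho = core$T_o, weights = drop(core$w),
    loadings = drop(core$p), q = core$q,
    weights_ortho = core$W_o, loadings_ortho = core$P_o,
    n_ortho = core$n_ortho, R2X = R2X, R2Y = R2Y, Q2 = Q2,
    p_perm = p_perm, q2_perm = q2_perm, vip = vip,
    mu_x = mu_x, mu_y = mu_y, cv_folds = cv_folds, n_perm = n_perm,
    seed = seed, core = core), class = "opls_da")
}

#' @export
print.opls_da <- function(x, ...) {
  cat("OPLS-DA (", x$levels[1], " vs ", x$levels[2], "): 1 predictive + ",
      x$n_ortho, " orthogonal component(s)\n", sep = "")
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %.3f", x$R2X, x$R2Y, x$Q2))
  if (!is.na(x$p_perm)) {
    cat(sprintf("  p(perm, n=%d) = %.4g", x$n_perm, x$p_perm))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.opls_da <- function(object, ...) {
  print(object)
  cat("  samples: ", paste(table(object$y), collapse = " / "),
      "; features: ", length(object$vip), "\n", sep = "")
  cat("  VIP > 1: ", sum(object$vip > 1), " features; top 5: ",
      paste(names(sort(object$vip, decreasing = TRUE))[1:5],
            collapse = ", "), "\n", sep = "")
  invisible(object)
}

#' @export
coef.opls_da <- function(object, ...) {
  # regression vector on the centred feature scale
  b <- object$core$w * object$q
  stats::setNames(drop(b), names(object$vip))
}

#' Predict classes from a fitted OPLS-DA model
#'
#' New samples are centred with the training means, filtered through
#' the orthogonal components, and scored on the predictive component;
#' the class boundary is the midpoint of the fitted class codes.
#'
#' @param object An `opls_da` fit.
#' @param newdata Samples-by-features matrix (or [feature_matrix()])
#'   with the same feature columns, on the same transformed scale.
#' @param type `"class"` (default) or `"score"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or numeric predictive scores.
#' @export
predict.opls_da <- function(object, newdata, type = c("class", "score"),
                            ...) {
  type <- match.arg(type)
  X <- .as_intensity(newdata)
  Xc <- sweep(X, 2L, object$mu_x)
  t_new <- .opls_project(object$core, Xc)
  if (type == "score") return(t_new)
  yhat <- t_new * object$q + object$mu_y
  factor(object$levels[ifelse(yhat >= 0.5, 2L, 1L)],
         levels = object$levels)
}

#' @export
residuals.opls_da <- function(object, ...) {
  y_num <- as.numeric(as.integer(object$y) - 1L)
  (y_num - object$mu_y) - object$scores * object$q
}

#' Score plot of an OPLS-DA model
#'
#' Predictive score against the first orthogonal score (or sample index
#' when the model has no orthogonal component), coloured by class.
#'
#' @param x An `opls_da` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.opls_da <- function(x, ...) {
  t2 <- if (!is.null(x$scores_ortho)) x$scores_ortho[, 1] else
    seq_along(x$scores)
  cols <- c("#1f77b4", "#d62728")[as.integer(x$y)]
  graphics::plot(x$scores, t2, col = cols, pch = 19,
                 xlab = "t (predictive)",
                 ylab = if (!is.null(x$scores_ortho)) "t_o1 (orthogonal)"
                        else "sample index", ...)
  graphics::legend("topright", legend = x$levels, col =
                     c("#1f77b4", "#d62728"), pch = 19, bty = "n")
  invisible(x)
}

#' VIP-ranked marker table
#'
#' Features whose VIP exceeds the threshold, ranked by VIP, with
#' formula/class annotation when available and the per-class percentage
#' breakdown of the VIP set.
#'
#' @param model An `opls_da` fit.
#' @param assignments Optional assignment table with `feature_id`,
#'   `formula`, `class` columns.
#' @param threshold VIP cutoff (default 1; features strictly above it
#'   are selected).
#' @return List with `markers` (ranked data frame) and
#'   `class_breakdown` (percentages summing to 100 over annotated
#'   markers).
#' @export
vip_ranking <- function(model, assignments = NULL, threshold = 1) {
  stopifnot(inherits(model, "opls_da"))
  sel <- which(model$vip > threshold)
  ord <- sel[order(model$vip[sel], decreasing = TRUE)]
  markers <- data.frame(feature_id = names(model$vip)[ord],
                        vip = unname(model$vip[ord]),
                        stringsAsFactors = FALSE)
  if (!is.null(assignments)) {
    i <- match(markers$feature_id, assignments$feature_id)
    markers$formula <- assignments$formula[i]
    markers$class <- assignments$class[i]
  }
  breakdown <- if (!is.null(markers$class) && any(!is.na(markers$class))) {
    tb <- table(markers$class[!is.na(markers$class)])
    100 * tb / sum(tb)
  } else NULL
  list(markers = markers, class_breakdown = breakdown)
}
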