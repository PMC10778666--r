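# Ground-truthed synthetic data: a metabolite library spanning the van
# Krevelen plane (with homologous series and a sugar "pollutant"
# eluting at many retention times), a study design, and per-sample
# direct-infusion and LC peak lists with controlled mass error, RT
# jitter, intensity noise, batch offsets and dropout.  Every emitted
# peak traces back to one (metabolite, adduct, isomer, sample) tuple.

# Draw one random plausible neutral composition of a given class.
.random_composition <- function(class, cfg) {
  for (attempt in 1:200) {
    C <- sample(6:40, 1L)
    hc <- stats::runif(1, 0.8, 2.0)
    oc <- stats::runif(1, 0.15, 1.0)
    H <- max(2L, round(hc * C))
    O <- max(1L, round(oc * C))
    N <- if (class %in% c("CHNO", "CHNOS")) sample(1:3, 1L) else 0L
    S <- if (class %in% c("CHOS", "CHNOS")) sample(1:2, 1L) else 0L
    if ((H + N) %% 2L == 1L) H <- H + 1L  # integer RDBE
    cnt <- c(C = C, H = H, N = N, O = O, S = S)
    cnt_m <- matrix(cnt, 1, dimnames = list(NULL, names(cnt)))
    if (!.plausible(cnt_m, cfg)) next
    mz <- tryCatch(ion_mz(cnt, "deprotonated"), error = function(e) NA)
    if (is.na(mz) || mz < cfg$mass_range[1] || mz > cfg$mass_range[2]) next
    return(cnt)
  }
  NULL
}

# Distinct retention times with a minimum separation, inside [rt_min,
# rt_max] seconds.
.draw_rts <- function(n, rt_min = 60, rt_max = 600, min_sep = 30) {
  grid <- seq(rt_min, rt_max, by = min_sep)
  sort(sample(grid, n) + stats::runif(n, 0, min_sep / 3))
}

#' Generate a ground-truth metabolite library
#'
#' Random CHNOS compositions inside the assignment element bounds and
#' van Krevelen envelope, in requested class proportions, plus
#' homologous series (CH2 alkylation steps and C6H10O5 glycosylation
#' steps) and, optionally, a glucose-like "sugar pollutant" emitted as
#' its chloride adduct at many distinct retention times.  Pairwise
#' ion-m/z separation of at least `min_gap_ppm` is enforced
#' (rejection), emulating peaks resolvable at the platform windows.
#'
#' @param n Number of metabolites (>= 1).
#' @param seed Integer seed.
#' @param class_mix Named proportions over CHO/CHNO/CHOS/CHNOS.
#' @param n_series Number of homologous series to plant (half CH2, half
#'   glycosyl; each of length `series_length`), counted inside `n`.
#' @param series_length Members per series.
#' @param pollutant Plant the 13-RT chloride-adduct sugar pollutant
#'   (default TRUE).
#' @param pollutant_rts Number of distinct pollutant retention times
#'   (default 13).
#' @param isomer_probs Probabilities of a metabolite having 1, 2, ...
#'   distinct RT isomers.
#' @param min_gap_ppm Minimum pairwise ion separation (default 2).
#' @param config [assignment_config()] supplying bounds and
#'   plausibility envelope.
#' @return Data frame of class `"gm_library"`: `id`, `formula`, element
#'   counts, `class`, `adduct`, `neutral_mass`, `ion_mz`,
#'   `base_intensity`, `n_isomers`, `rts` (list column), `series`,
#'   `is_pollutant`.
#' @export
make_library <- function(n = 300, seed = 1,
                         class_mix = c(CHO = 0.70, CHNO = 0.20,
                                       CHOS = 0.08, CHNOS = 0.02),
                         n_series = 6, series_length = 3,
                         pollutant = TRUE, pollutant_rts = 13,
                         isomer_probs = c(0.70, 0.20, 0.07, 0.03),
                         min_gap_ppm = 2,
                         config = assignment_config()) {
  stopifnot(n >= 1)
  if (any(class_mix < 0) || abs(sum(class_mix)) < 1e-12) {
    stop("infeasible class mix", call. = FALSE)
  }
  class_mix <- class_mix / sum(class_mix)
  set.seed(seed)
  rows <- list()
  seen <- character(0)
  add_row <- function(cnt, series = NA_character_, adduct = "deprotonated",
                      n_iso = NULL, rts = NULL, pollutant = FALSE) {
    f <- format_formula(cnt)
    if (f %in% seen) return(FALSE)
    mz <- tryCatch(ion_mz(cnt, adduct), error = function(e) NA_real_)
    if (is.na(mz) || mz < config$mass_range[1] ||
        mz > config$mass_range[2]) return(FALSE)
    if (is.null(n_iso)) {
      n_iso <- sample(seq_along(isomer_probs), 1L, prob = isomer_probs)
    }
    if (is.null(rts)) rts <- .draw_rts(n_iso)
    row <- data.frame(
      formula = f, C = cnt[["C"]], H = cnt[["H"]], N = cnt[["N"]],
      O = cnt[["O"]], S = cnt[["S"]],
      class = chemical_class(cnt), adduct = adduct,
      neutral_mass = monoisotopic_mass(cnt), ion_mz = mz,
      base_intensity = stats::rlnorm(1, log(1e6), 1),
      n_isomers = as.integer(n_iso), series = series,
      is_pollutant = pollutant,
      stringsAsFactors = FALSE)
    row$rts <- list(rts)
    rows[[length(rows) + 1L]] <<- row
    seen <<- c(seen, f)
    TRUE
  }
  # homologous series
  n_planted <- 0L
  for (s in seq_len(n_series)) {
    step <- if (s %% 2L == 1L) c(C = 1L, H = 2L) else
      c(C = 6L, H = 10L, O = 5L)
    kind <- if (s %% 2L == 1L) "CH2" else "glycosyl"
    for (attempt in 1:50) {
      base <- .random_composition("CHO", config)
      if (is.null(base)) next
      members <- lapply(seq_len(series_length) - 1L, function(k) {
        x <- base
        x[names(step)] <- x[names(step)] + k * step
        x
      })
      ok <- all(vapply(members, function(x) {
        mzx <- tryCatch(ion_mz(x, "deprotonated"),
                        error = function(e) NA_real_)
        !is.na(mzx) && mzx >= config$mass_range[1] &&
          mzx <= config$mass_range[2] &&
          .plausible(matrix(x[c("C","H","N","O","S")], 1,
                     dimnames = list(NULL, c("C","H","N","O","S"))),
                     config)
      }, logical(1)))
      if (!ok) next
      added <- vapply(members, add_row,
                      logical(1), series = paste0(kind, "-", s))
      n_planted <- n_planted + sum(added)
      break
    }
  }
  # random fill to n
  target <- max(0L, n - n_planted - as.integer(pollutant))
  cls <- sample(names(class_mix), target, replace = TRUE,
                prob = class_mix)
  for (cl in cls) {
    for (attempt in 1:50) {
      cnt <- .random_composition(cl, config)
      if (!is.null(cnt) && add_row(cnt)) break
    }
  }
  if (pollutant) {
    add_row(parse_formula("C6H12O6"), adduct = "chloride",
            n_iso = pollutant_rts,
            rts = .draw_rts(pollutant_rts, 60, 600, 42),
            pollutant = TRUE)
  }
  lib <- do.call(rbind, rows)
  # enforce min pairwise ion gap: planted series and the pollutant are
  # protected; random fill metabolites near a protected ion, or near an
  # earlier kept ion, are dropped
  protected <- lib$is_pollutant | !is.na(lib$series)
  keep <- rep(TRUE, nrow(lib))
  for (i in which(!protected)) {
    d <- abs(ppm_error(lib$ion_mz[i], lib$ion_mz[protected]))
    if (length(d) && min(d) < min_gap_ppm) keep[i] <- FALSE
  }
  ord <- order(lib$ion_mz)
  last_kept <- NA_real_
  for (i in ord) {
    if (!keep[i]) next
    if (protected[i]) {
      last_kept <- lib$ion_mz[i]
    } else if (!is.na(last_kept) &&
               (lib$ion_mz[i] - last_kept) / last_kept * 1e6 <
                 min_gap_ppm) {
      keep[i] <- FALSE
    } else {
      last_kept <- lib$ion_mz[i]
    }
  }
  lib <- lib[keep, , drop = FALSE]
  lib$id <- sprintf("M%04d", seq_len(nrow(lib)))
  rownames(lib) <- NULL
  class(lib) <- c("gm_library", "data.frame")
  lib
}

#' Generate a balanced study design
#'
#' Coarse emulation of a multi-vineyard sampling: varieties crossed
#' with regions, vintages and pseudo-replicates, with batches assigned
#' round-robin so every batch is balanced across classes.
#'
#' @param varieties,regions,vintages Factor levels.
#' @param n_rep Pseudo-replicates per cell (default 2).
#' @param n_batches Number of measurement batches (default 2).
#' @param preparation Preparation label (default "SPE").
#' @return Data frame with `sample_id`, `variety`, `region`, `vintage`,
#'   `batch`, `preparation`.
#' @export
make_design <- function(varieties = c("Chardonnay", "PinotNoir",
                                      "Meunier", "Aligote"),
                        regions = c("Burgundy", "Languedoc", "UcoValley"),
                        vintages = 2019:2021, n_rep = 2, n_batches = 2,
                        preparation = "SPE") {
  d <- expand.grid(rep = seq_len(n_rep), vintage = vintages,
                   region = regions, variety = varieties,
                   stringsAsFactors = FALSE)
  d <- d[, c("variety", "region", "vintage", "rep")]
  d$batch <- paste0("B", (seq_len(nrow(d)) - 1L) %% n_batches + 1L)
  d$preparation <- preparation
  d$sample_id <- sprintf("S%03d", seq_len(nrow(d)))
  d[, c("sample_id", "variety", "region", "vintage", "batch",
        "preparation")]
}

#' Noise specification for the peak-list generator
#'
#' Defaults reflect the two platforms' accuracy regimes: sub-ppm mass
#' error for direct infusion (sd 0.1 ppm), few-ppm for LC (sd 1.0 ppm),
#' 2 s RT jitter, 30% intensity CV, a mild per-batch multiplicative
#' offset, and a logistic detection-dropout in log10 intensity.
#'
#' @param di_ppm_sd,lc_ppm_sd Mass error sd in ppm per platform
#'   (DI must be smaller than LC).
#' @param rt_sd RT jitter sd in seconds.
#' @param intensity_cv Multiplicative intensity coefficient of
#'   variation.
#' @param batch_log_sd Sd of the per-batch log10 offset (0 = no batch
#'   effect).
#' @param dropout_mid,dropout_scale Logistic dropout: detection
#'   probability `plogis((log10(I) - dropout_mid)/dropout_scale)`;
#'   `dropout_mid = -Inf` disables dropout.
#' @return List of class `"gm_noise"`.
#' @export
noise_spec <- function(di_ppm_sd = 0.1, lc_ppm_sd = 1.0, rt_sd = 2,
                       intensity_cv = 0.3, batch_log_sd = 0.1,
                       dropout_mid = 3.5, dropout_scale = 0.4) {
  stopifnot(di_ppm_sd >= 0, di_ppm_sd <= lc_ppm_sd)
  structure(list(di_ppm_sd = di_ppm_sd, lc_ppm_sd = lc_ppm_sd,
                 rt_sd = rt_sd, intensity_cv = intensity_cv,
                 batch_log_sd = batch_log_sd, dropout_mid = dropout_mid,
                 dropout_scale = dropout_scale), class = "gm_noise")
}

#' Emit per-sample peak lists from a library and design
#'
#' For every sample, each detected (metabolite, adduct) yields one
#' direct-infusion peak with multiplicative mass error
#' `Normal(0, di_ppm_sd)` and one LC peak per isomer with RT jitter;
#' intensities are log-normal around the metabolite's base intensity,
#' scaled by marker fold changes and per-batch offsets, and dropout is
#' applied per (sample, metabolite).  Fully reproducible from the seed.
#'
#' @param library A [make_library()] table.
#' @param design A [make_design()] table.
#' @param noise A [noise_spec()].
#' @param markers Optional marker specification: data frame with
#'   `formula`, `variety` (the up-regulated class) and `fold_change`.
#' @param seed Integer seed.
#' @return List of class `"gm_dataset"`: `di` and `lc` (named lists of
#'   per-sample peak data frames), `design`, `library`, `markers`,
#'   `noise`, `truth` (long table of every emitted peak with its
#'   provenance), `dataset_id`.
#' @export
emit_peaklists <- function(library, design, noise = noise_spec(),
                           markers = NULL, seed = 1) {
  stopifnot(nrow(design) >= 1)
  set.seed(seed)
  nmet <- nrow(library)
  nsam <- nrow(design)
  sdlog <- sqrt(log(1 + noise$intensity_cv^2))
  batches <- sort(unique(design$batch))
  batch_off <- stats::setNames(
    stats::rnorm(length(batches), 0, noise$batch_log_sd), batches)
  mfc <- rep(1, nmet)
  mvariety <- rep(NA_character_, nmet)
  if (!is.null(markers)) {
    i <- match(markers$formula, library$formula)
    if (any(is.na(i))) stop("marker formula(s) not in library",
                            call. = FALSE)
    mfc[i] <- markers$fold_change
    mvariety[i] <- markers$variety
  }
  di <- lc <- stats::setNames(vector("list", nsam), design$sample_id)
  truth <- list()
  for (s in seq_len(nsam)) {
    fc_s <- ifelse(!is.na(mvariety) & mvariety == design$variety[s],
                   mfc, 1)
    inten <- library$base_intensity * fc_s *
      10^batch_off[[design$batch[s]]] *
      stats::rlnorm(nmet, 0, sdlog)
    p_det <- stats::plogis((log10(inten) - noise$dropout_mid) /
                             noise$dropout_scale)
    detected <- stats::runif(nmet) < p_det
    mz_di <- library$ion_mz *
      (1 + stats::rnorm(nmet, 0, noise$di_ppm_sd) * 1e-6)
    di[[s]] <- data.frame(mz = mz_di[detected],
                          intensity = inten[detected],
                          snr = inten[detected] / 1e3)
    lcrows <- list()
    for (m in which(detected)) {
      rts <- library$rts[[m]]
      k <- length(rts)
      lcrows[[length(lcrows) + 1L]] <- data.frame(
        mz = library$ion_mz[m] *
          (1 + stats::rnorm(k, 0, noise$lc_ppm_sd) * 1e-6),
        rt = rts + stats::rnorm(k, 0, noise$rt_sd),
        intensity = inten[m] / k * stats::rlnorm(k, 0, sdlog / 2),
        metabolite = library$id[m], isomer = seq_len(k),
        stringsAsFactors = FALSE)
    }
    lc_s <- if (length(lcrows)) do.call(rbind, lcrows) else
      data.frame(mz = numeric(0), rt = numeric(0),
                 intensity = numeric(0), metabolite = character(0),
                 isomer = integer(0))
    lc[[s]] <- lc_s[, c("mz", "rt", "intensity")]
    truth[[s]] <- data.frame(
      sample = design$sample_id[s],
      metabolite = library$id[detected],
      formula = library$formula[detected],
      adduct = library$adduct[detected],
      true_mz = library$ion_mz[detected],
      obs_mz_di = mz_di[detected],
      intensity = inten[detected],
      n_isomers = library$n_isomers[detected],
      stringsAsFactors = FALSE)
  }
  structure(list(di = di, lc = lc, design = design, library = library,
                 markers = markers, noise = noise,
                 truth = do.call(rbind, truth),
                 dataset_id = sprintf("gm-%d", seed)),
            class = "gm_dataset")
}

#' Simulate a feature matrix with calibrated factor effects
#'
#' Matrix-level generator for variance-partition studies: standardised
#' noise plus per-factor level effects calibrated analytically so each
#' factor explains a requested fraction of the total population
#' variance (for factor k with L_k balanced levels and level effects
#' drawn N(0, tau_k^2), tau_k^2 = f_k / ((1 - sum f) (1 - 1/L_k))).
#'
#' @param n Samples.
#' @param p Features.
#' @param fractions Named target variance fractions, e.g.
#'   `c(variety = 0.16, region = 0.10)`.
#' @param levels Named list of level labels per factor (extra factors
#'   with no entry in `fractions` get zero effect).
#' @param seed Integer seed.
#' @return List: `x` (n x p matrix), `factors` (data frame),
#'   `fractions` (the targets).
#' @export
simulate_factor_matrix <- function(n = 100, p = 50,
                                   fractions = c(variety = 0.16,
                                                 region = 0.10),
                                   levels = list(
                                     variety = c("Chardonnay",
                                                 "PinotNoir"),
                                     region = c("Burgundy", "Languedoc",
                                                "UcoValley"),
                                     vintage = c("2019", "2020", "2021")),
                                   seed = 1) {
  stopifnot(sum(fractions) < 1)
  set.seed(seed)
  # crossed systematic design: factors are mutually (near-)orthogonal
  idx <- seq_len(n) - 1L
  div <- 1L
  factors <- list()
  for (nm in names(levels)) {
    L <- length(levels[[nm]])
    factors[[nm]] <- levels[[nm]][(idx %/% div) %% L + 1L]
    div <- div * L
  }
  factors <- as.data.frame(factors, stringsAsFactors = TRUE)
  x <- matrix(stats::rnorm(n * p), n, p)
  for (nm in names(levels)) {
    f <- if (nm %in% names(fractions)) fractions[[nm]] else 0
    if (f <= 0) next
    lv <- levels[[nm]]
    w <- table(factors[[nm]])[lv] / n
    v_target <- f / (1 - sum(fractions))
    eff <- matrix(stats::rnorm(length(lv) * p), length(lv), p,
                  dimnames = list(lv, NULL))
    # centre and rescale each feature's level effects so the planted
    # between-level variance is exactly the target
    eff <- sweep(eff, 2L, colSums(eff * as.numeric(w)))
    s <- sqrt(colSums(eff^2 * as.numeric(w)) / v_target)
    eff <- sweep(eff, 2L, s, "/")
    x <- x + eff[as.character(factors[[nm]]), , drop = FALSE]
  }
  colnames(x) <- sprintf("F%04d", seq_len(p))
  list(x = x, factors = factors, fractions = fractions)
}

#' Recovery metrics against the generator's ground truth
#'
#' Compares pipeline outputs with the traceable truth of a
#' [emit_peaklists()] dataset: alignment precision/recall of a DI
#' feature matrix (a feature is a true positive when its consensus m/z
#' matches an emitted ion within `window` ppm), formula-assignment
#' accuracy on matched features, planted-marker recovery in a VIP set,
#' and residual batch effect.  All metrics lie in [0, 1].
#'
#' @param sim A `gm_dataset` from [emit_peaklists()].
#' @param features Optional DI [feature_matrix()] built from
#'   `sim$di`.  If it carries a `dataset_id` attribute it must match
#'   the simulation's.
#' @param assignments Optional [assign_peaks()]-style table aligned
#'   with the features (`feature_id` column or row order).
#' @param vip_features Optional character vector of feature ids
#'   selected as markers.
#' @param corrected Optional batch-corrected matrix to score residual
#'   batch R-squared on.
#' @param window Match window in ppm (default 0.5).
#' @return Named list of metrics (subset depending on inputs).
#' @export
truth_report <- function(sim, features = NULL, assignments = NULL,
                         vip_features = NULL, corrected = NULL,
                         window = 0.5) {
  stopifnot(inherits(sim, "gm_dataset"))
  out <- list()
  ions <- unique(sim$truth[, c("metabolite", "formula", "true_mz")])
  match_feature <- function(mz) {
    d <- abs(ppm_error(mz, ions$true_mz))
    i <- which.min(d)
    if (d[i] <= window) i else NA_integer_
  }
  if (!is.null(features)) {
    fid <- attr(features, "dataset_id")
    if (!is.null(fid) && !identical(fid, sim$dataset_id)) {
      stop("feature matrix comes from a different dataset (",
           fid, " vs ", sim$dataset_id, ")", call. = FALSE)
    }
    hits <- vapply(features$features$mz, match_feature, integer(1))
    out$alignment_precision <- mean(!is.na(hits))
    out$alignment_recall <- length(unique(hits[!is.na(hits)])) /
      nrow(ions)
    if (!is.null(assignments)) {
      truth_formula <- ions$formula[hits]
      got <- assignments$formula
      ok <- !is.na(hits) & !is.na(got)
      out$assignment_accuracy <- if (any(ok))
        mean(got[ok] == truth_formula[ok]) else NA_real_
    }
  }
  if (!is.null(vip_features) && !is.null(sim$markers) &&
      !is.null(features)) {
    hits <- vapply(features$features$mz, match_feature, integer(1))
    marker_feats <- features$features$feature_id[
      !is.na(hits) & ions$formula[hits] %in% sim$markers$formula]
    out$marker_recovery <- if (length(marker_feats))
      mean(marker_feats %in% vip_features) else NA_real_
  }
  if (!is.null(corrected)) {
    b <- as.factor(sim$design$batch)
    r2 <- vapply(seq_len(ncol(corrected)), function(j) {
      summary(stats::lm(corrected[, j] ~ b))$r.squared
    }, numeric(1))
    out$batch_r2 <- mean(r2)
  }
  stopifnot(all(unlist(out) >= 0 & unlist(out) <= 1, na.rm = TRUE))
  out
}
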