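# End-to-end orchestration: one configuration object, one seeded run
# chaining simulate -> align -> assign -> preprocess -> discriminate ->
# report, with per-stage counts and TSV/JSON outputs.

#' Pipeline configuration
#'
#' Collects every stage parameter with the platform defaults: 0.5 ppm
#' DI alignment/assignment window, 2 ppm isobar grouping, 5 ppm
#' cross-platform window, 10 s RT tolerance, S/N >= 3, presence in >= 4
#' samples (descriptive) and >= 33% of samples (multivariate), 2/3
#' minimum imputation, log10 + Pareto, 500 OPLS-DA permutations, 1000
#' RDA permutations.  All randomness flows from the single top-level
#' seed (stage seeds are derived from it by fixed offsets).
#'
#' @param seed Top-level integer seed.
#' @param n_metabolites Library size for the simulation stage.
#' @param n_markers,marker_fc Planted variety markers: how many, and
#'   their fold change.
#' @param di_window,isobar_window,cross_window Alignment windows (ppm).
#' @param rt_tol RT tolerance in seconds.
#' @param min_snr Minimum S/N for DI peaks.
#' @param min_samples Presence threshold (samples) for description.
#' @param min_fraction Presence threshold (fraction) for multivariate
#'   analysis.
#' @param impute_factor Zero-imputation factor.
#' @param tolerance_ppm Formula-assignment tolerance.
#' @param n_ortho,cv_folds,opls_perm OPLS-DA settings.
#' @param rda_perm RDA permutation count.
#' @param classes The two variety labels contrasted by OPLS-DA.
#' @param noise A [noise_spec()].
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, n_metabolites = 200,
                            n_markers = 20, marker_fc = 3,
                            di_window = 0.5, isobar_window = 2,
                            cross_window = 5, rt_tol = 10, min_snr = 3,
                            min_samples = 4, min_fraction = 0.33,
                            impute_factor = 2 / 3, tolerance_ppm = 0.5,
                            n_ortho = 1, cv_folds = 7, opls_perm = 500,
                            rda_perm = 1000,
                            classes = c("Chardonnay", "PinotNoir"),
                            noise = noise_spec()) {
  stopifnot(tolerance_ppm > 0, di_window > 0, isobar_window > 0,
            cross_window > 0, rt_tol >= 0, min_fraction > 0,
            min_fraction <= 1, impute_factor > 0, impute_factor <= 1,
            length(classes) == 2)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline configuration (seed ", x$seed, ")\n", sep = "")
  cat("  windows: DI ", x$di_window, " ppm, isobar ", x$isobar_window,
      " ppm, cross ", x$cross_window, " ppm, RT ", x$rt_tol, " s\n",
      sep = "")
  cat("  filters: S/N >= ", x$min_snr, ", presence >= ", x$min_samples,
      " samples / >= ", round(100 * x$min_fraction), "%\n", sep = "")
  cat("  models: OPLS-DA ", x$opls_perm, " perms, RDA ", x$rda_perm,
      " perms; contrast ", paste(x$classes, collapse = " vs "), "\n",
      sep = "")
  invisible(x)
}

# jsonlite-serialisable view of a config (noise spec flattened).
.config_as_list <- function(config) {
  out <- unclass(config)
  out$noise <- unclass(out$noise)
  out
}

#' Run the full pipeline on a seeded synthetic dataset
#'
#' Chains the whole processing chain on generated ground-truthed data:
#' simulate peak lists, align the DI samples, assign formulas, build
#' and group the LC features, align the platforms, preprocess
#' (presence filter, imputation, batch correction, log10 + Pareto),
#' run univariate screening, OPLS-DA between the configured varieties,
#' PCA and RDA variance partitioning, and score everything against the
#' generator's truth.  When `out_dir` is given every table is written
#' there (TSV/JSON) together with the effective configuration and a
#' manifest of per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param quiet Suppress per-stage messages.
#' @return List with the intermediate and final objects (`sim`,
#'   `di_features`, `assignments`, `lc_features`, `isobars`,
#'   `alignment`, `isobar_stats`, `venn`, `matrix` (scaled),
#'   `univariate`, `opls`, `pca`, `varpart`, `recovery`, `counts`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  counts <- list()
  seed <- config$seed

  say("[simulate] library of ", config$n_metabolites, " metabolites")
  lib <- make_library(n = config$n_metabolites, seed = seed,
                      config = assignment_config(
                        tolerance_ppm = config$tolerance_ppm))
  design <- make_design()
  cand <- lib$formula[lib$class == "CHO" & !lib$is_pollutant]
  markers <- data.frame(
    formula = utils::head(cand, config$n_markers),
    variety = config$classes[2], fold_change = config$marker_fc,
    stringsAsFactors = FALSE)
  sim <- emit_peaklists(lib, design, noise = config$noise,
                        markers = markers, seed = seed)
  counts$metabolites <- nrow(lib)
  counts$samples <- nrow(design)
  counts$di_peaks <- sum(vapply(sim$di, nrow, integer(1)))
  counts$lc_peaks <- sum(vapply(sim$lc, nrow, integer(1)))
  say("[simulate] ", counts$di_peaks, " DI peaks, ", counts$lc_peaks,
      " LC peaks over ", counts$samples, " samples")

  say("[align] DI window ", config$di_window, " ppm, S/N >= ",
      config$min_snr)
  di_fm <- align_samples(sim$di, window = config$di_window,
                         min_snr = config$min_snr, samples = design)
  attr(di_fm, "dataset_id") <- sim$dataset_id
  di_fm <- presence_filter(di_fm, min_samples = config$min_samples)
  counts$di_features <- ncol(di_fm$intensity)
  say("[align] ", counts$di_features, " DI features after presence filter")

  say("[assign] enumeration at ", config$tolerance_ppm, " ppm")
  acfg <- assignment_config(tolerance_ppm = config$tolerance_ppm)
  assignments <- assign_peaks(di_fm$features$mz, acfg)
  assignments$feature_id <- di_fm$features$feature_id
  di_fm$features$formula <- assignments$formula
  di_fm$features$class <- assignments$class
  counts$assigned <- sum(!is.na(assignments$formula))
  counts$unambiguous <- sum(!is.na(assignments$formula) &
                              !assignments$ambiguous)
  say("[assign] ", counts$assigned, " assigned (",
      counts$unambiguous, " unambiguous)")

  say("[align] LC features, isobar grouping at ", config$isobar_window,
      " ppm, cross-platform at ", config$cross_window, " ppm")
  lc_fm <- align_samples(sim$lc, window = config$cross_window,
                         min_snr = NULL, rt_tol = config$rt_tol,
                         samples = design)
  isob <- group_isobars(lc_fm, window = config$isobar_window)
  amap <- cross_align(di_fm, isob, window = config$cross_window)
  istats <- isobar_statistics(amap, assignments)
  counts$lc_features <- ncol(lc_fm$intensity)
  counts$isobar_groups <- nrow(isob)
  counts$matched <- nrow(amap)
  say("[align] ", counts$lc_features, " LC features, ",
      counts$isobar_groups, " isobar groups, ", counts$matched,
      " cross-platform matches")

  venn <- coverage_venn(di_fm, di_fm$samples$variety,
                        min_samples_per_group = config$min_samples)

  say("[preprocess] presence >= ", round(100 * config$min_fraction),
      "%, impute ", round(config$impute_factor, 3),
      " x min, batch correction, log10 + Pareto")
  fm2 <- presence_filter(di_fm, min_fraction = config$min_fraction)
  fm2 <- impute_zeros(fm2, factor = config$impute_factor)
  fm2 <- batch_correct(fm2, fm2$samples$batch)
  scaled <- transform_scale(fm2)
  counts$model_features <- ncol(scaled$intensity)

  say("[discriminate] univariate, OPLS-DA (", config$opls_perm,
      " perms), PCA, RDA (", config$rda_perm, " perms)")
  uni <- univariate_screen(fm2, fm2$samples$variety)
  sel <- scaled$samples$variety %in% config$classes
  x_sel <- scaled$intensity[sel, , drop = FALSE]
  y_sel <- factor(scaled$samples$variety[sel], levels = config$classes)
  opls <- opls_da(x_sel, y_sel, n_ortho = config$n_ortho,
                  cv_folds = config$cv_folds,
                  n_perm = config$opls_perm, seed = seed + 1L)
  pca <- feature_pca(scaled$intensity, n_comp = 2)
  vp <- rda_varpart(x_sel,
                    scaled$samples[sel, c("variety", "region", "vintage")],
                    n_perm = config$rda_perm, seed = seed + 2L)
  vr <- vip_ranking(opls, assignments)
  recovery <- truth_report(
    sim, features = di_fm, assignments = assignments,
    vip_features = vr$markers$feature_id,
    corrected = fm2$intensity, window = config$di_window)
  counts$vip_markers <- nrow(vr$markers)
  say("[discriminate] Q2 = ", round(opls$Q2, 3), ", perm p = ",
      signif(opls$p_perm, 3))

  res <- list(config = config, sim = sim, di_features = di_fm,
              assignments = assignments, lc_features = lc_fm,
              isobars = isob, alignment = amap, isobar_stats = istats,
              venn = venn, matrix = scaled, univariate = uni,
              opls = opls, vip = vr, pca = pca, varpart = vp,
              recovery = recovery, counts = counts)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dirs <- file.path(out_dir, c("simulate", "align", "assign",
                               "preprocess", "discriminate", "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.config_as_list(res$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in names(res$sim$di)) {
    write_peaklist(res$sim$di[[s]],
                   file.path(out_dir, "simulate",
                             paste0(s, ".di.tsv")))
    write_peaklist(res$sim$lc[[s]],
                   file.path(out_dir, "simulate",
                             paste0(s, ".lc.tsv")))
  }
  utils::write.table(res$sim$design,
                     file.path(out_dir, "simulate", "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_matrix(res$di_features,
                       file.path(out_dir, "align", "di_features.tsv"))
  write_feature_matrix(res$lc_features,
                       file.path(out_dir, "align", "lc_features.tsv"))
  write_alignment_map(res$alignment,
                      file.path(out_dir, "align", "alignment_map.tsv"))
  write_assignments(res$assignments,
                    file.path(out_dir, "assign", "assignments.tsv"))
  write_feature_matrix(res$matrix,
                       file.path(out_dir, "preprocess", "scaled.tsv"))
  write_univariate(res$univariate,
                   file.path(out_dir, "discriminate", "univariate.tsv"))
  utils::write.table(res$vip$markers,
                     file.path(out_dir, "discriminate", "vip.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$isobar_stats,
                     file.path(out_dir, "report", "isobar_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$venn$pattern,
                     file.path(out_dir, "report", "venn.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    opls = list(R2X = res$opls$R2X, R2Y = res$opls$R2Y,
                Q2 = res$opls$Q2, p_perm = res$opls$p_perm,
                n_ortho = res$opls$n_ortho, seed = res$opls$seed),
    varpart = list(unique = as.list(res$varpart$unique),
                   shared = as.list(res$varpart$shared),
                   unexplained = res$varpart$unexplained),
    pca_explained = res$pca$explained,
    recovery = res$recovery,
    counts = res$counts),
    file.path(out_dir, "report", "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
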