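# Elemental-composition assignment of observed m/z values: bounded
# brute-force mass decomposition, and propagation along a library of
# exact biochemical mass differences from trusted seed formulas.

#' Configuration for formula assignment
#'
#' Bundles the tolerance, element bounds, adduct set and
#' chemical-plausibility filters used by [enumerate_formulas()] and
#' [assign_by_network()].
#'
#' Default bounds (C 1-70, H 1-130, N 0-10, O 0-45, S 0-4) cover the
#' 92-1000 Da working range of negative-mode small-molecule profiling
#' with headroom; plausibility windows are 0 <= RDBE <= 40,
#' 0.2 <= H/C <= 3.1, O/C <= 1.5, plus the even-electron rule that a
#' neutral's RDBE must be a whole number.
#'
#' @param tolerance_ppm Assignment window in ppm (> 0, default 0.5).
#' @param mass_range Allowed observed m/z range in Da (default 92-1000).
#' @param bounds Named list of `c(min, max)` integer count bounds per
#'   element (C, H, N, O, S).
#' @param adduct_set Character vector of adduct names considered
#'   (see [adducts()]).
#' @param rdbe_range,hc_range,oc_range Plausibility windows for RDBE,
#'   H/C and O/C of the neutral candidate.
#' @param electron Include the electron mass in ion m/z (default TRUE).
#' @return An object of class `"assignment_config"`.
#' @export
assignment_config <- function(tolerance_ppm = 0.5,
                              mass_range = c(92, 1000),
                              bounds = list(C = c(1L, 70L), H = c(1L, 130L),
                                            N = c(0L, 10L), O = c(0L, 45L),
                                            S = c(0L, 4L)),
                              adduct_set = c("deprotonated",
                                             "deprotonated-dehydrated",
                                             "chloride"),
                              rdbe_range = c(0, 40),
                              hc_range = c(0.2, 3.1),
                              oc_range = c(0, 1.5),
                              electron = TRUE) {
  stopifnot(is.numeric(tolerance_ppm), length(tolerance_ppm) == 1L,
            tolerance_ppm > 0)
  stopifnot(length(mass_range) == 2L, all(mass_range > 0),
            mass_range[1] < mass_range[2])
  stopifnot(all(c("C", "H", "N", "O", "S") %in% names(bounds)))
  for (b in bounds) stopifnot(length(b) == 2L, all(b >= 0), b[1] <= b[2])
  for (a in adduct_set) .match_adduct(a)
  structure(list(tolerance_ppm = tolerance_ppm,
                 mass_range = as.numeric(mass_range),
                 bounds = lapply(bounds, as.integer),
                 adduct_set = adduct_set,
                 rdbe_range = as.numeric(rdbe_range),
                 hc_range = as.numeric(hc_range),
                 oc_range = as.numeric(oc_range),
                 electron = isTRUE(electron)),
            class = "assignment_config")
}

#' @export
print.assignment_config <- function(x, ...) {
  cat("Formula assignment configuration\n")
  cat("  tolerance: ", x$tolerance_ppm, " ppm; mass range ",
      x$mass_range[1], "-", x$mass_range[2], " Da\n", sep = "")
  b <- vapply(names(x$bounds),
              function(el) paste0(el, " ", x$bounds[[el]][1], "-",
                                  x$bounds[[el]][2]),
              character(1))
  cat("  bounds:   ", paste(b, collapse = ", "), "\n", sep = "")
  cat("  adducts:  ", paste(x$adduct_set, collapse = ", "), "\n", sep = "")
  cat("  filters:  RDBE ", x$rdbe_range[1], "-", x$rdbe_range[2],
      " (integer), H/C ", x$hc_range[1], "-", x$hc_range[2],
      ", O/C <= ", x$oc_range[2], "\n", sep = "")
  invisible(x)
}

# Plausibility filter on a candidate count matrix (columns C,H,N,O,S).
.plausible <- function(cnt, config) {
  rdbe <- cnt[, "C"] - cnt[, "H"] / 2 + cnt[, "N"] / 2 + 1
  hc <- cnt[, "H"] / cnt[, "C"]
  oc <- cnt[, "O"] / cnt[, "C"]
  rdbe >= config$rdbe_range[1] & rdbe <= config$rdbe_range[2] &
    abs(rdbe - round(rdbe)) < 1e-9 &
    hc >= config$hc_range[1] & hc <= config$hc_range[2] &
    oc >= config$oc_range[1] & oc <= config$oc_range[2]
}

.candidate_frame <- function(mz, cnt, adduct, theo, config, provenance) {
  if (nrow(cnt) == 0L) {
    return(data.frame(mz = numeric(0), formula = character(0),
                      adduct = character(0), theo_mz = numeric(0),
                      error_ppm = numeric(0), C = integer(0), H = integer(0),
                      N = integer(0), O = integer(0), S = integer(0),
                      class = character(0), o_to_c = numeric(0),
                      h_to_c = numeric(0), rdbe = numeric(0),
                      provenance = character(0),
                      stringsAsFactors = FALSE))
  }
  form <- apply(cnt, 1L, function(r) {
    format_formula(c(C = r[["C"]], H = r[["H"]], N = r[["N"]],
                     O = r[["O"]], S = r[["S"]]))
  })
  cls <- ifelse(cnt[, "N"] > 0 & cnt[, "S"] > 0, "CHNOS",
         ifelse(cnt[, "N"] > 0, "CHNO",
         ifelse(cnt[, "S"] > 0, "CHOS", "CHO")))
  cls[cnt[, "O"] == 0] <- "unclassified"
  data.frame(mz = mz, formula = form, adduct = adduct, theo_mz = theo,
             error_ppm = ppm_error(mz, theo),
             C = cnt[, "C"], H = cnt[, "H"], N = cnt[, "N"],
             O = cnt[, "O"], S = cnt[, "S"],
             class = cls,
             o_to_c = cnt[, "O"] / cnt[, "C"],
             h_to_c = cnt[, "H"] / cnt[, "C"],
             rdbe = cnt[, "C"] - cnt[, "H"] / 2 + cnt[, "N"] / 2 + 1,
             provenance = provenance,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Deterministic candidate ordering: |error| ascending, then fewer
# heteroatoms (N+O+S), then formula string.
.order_candidates <- function(df) {
  df[order(abs(df$error_ppm), df$N + df$O + df$S, df$formula), ,
     drop = FALSE]
}

#' Enumerate candidate formulas for an observed m/z
#'
#' Exhaustive bounded decomposition: for every adduct in the
#' configuration, every CHNOS composition inside the element bounds whose
#' ion m/z falls within the ppm tolerance of the observed mass, and which
#' passes the plausibility filters, is returned.  An empty result is a
#' valid outcome (unassigned peak).
#'
#' @param mz Observed m/z in Da; must lie inside the configured mass
#'   range.
#' @param config An [assignment_config()].
#' @return Data frame of candidates sorted by absolute ppm error
#'   (ties: fewer heteroatoms, then formula), with columns `mz`,
#'   `formula` (neutral, Hill order), `adduct`, `theo_mz`, `error_ppm`,
#'   element counts, `class`, `o_to_c`, `h_to_c`, `rdbe`, `provenance`.
#' @examples
#' cfg <- assignment_config(adduct_set = "chloride")
#' enumerate_formulas(215.03279, cfg)[1, c("formula", "adduct")]
#' @export
enumerate_formulas <- function(mz, config = assignment_config()) {
  stopifnot(is.numeric(mz), length(mz) == 1L)
  if (mz < config$mass_range[1] || mz > config$mass_range[2]) {
    stop("mz ", mz, " outside configured mass range [",
         config$mass_range[1], ", ", config$mass_range[2], "]",
         call. = FALSE)
  }
  b <- config$bounds
  tol_da <- config$tolerance_ppm * 1e-6 * mz
  m <- .MONOISOTOPIC
  out <- vector("list", length(config$adduct_set))
  for (k in seq_along(config$adduct_set)) {
    a <- .match_adduct(config$adduct_set[k])
    target <- mz - a$delta - if (config$electron) .ELECTRON_MASS else 0
    # grid over N, S, O; solve H per C from the residual mass
    grid <- expand.grid(N = b$N[1]:b$N[2], S = b$S[1]:b$S[2],
                        O = b$O[1]:b$O[2])
    rem0 <- target - grid$N * m[["N"]] - grid$S * m[["S"]] -
      grid$O * m[["O"]]
    keep0 <- rem0 >= b$C[1] * m[["C"]] + b$H[1] * m[["H"]] - tol_da
    grid <- grid[keep0, , drop = FALSE]
    rem0 <- rem0[keep0]
    hits <- vector("list", b$C[2] - b$C[1] + 1L)
    for (C in b$C[1]:b$C[2]) {
      remH <- rem0 - C * m[["C"]]
      H <- as.integer(round(remH / m[["H"]]))
      ok <- H >= b$H[1] & H <= b$H[2]
      if (!any(ok)) next
      theo_neutral <- C * m[["C"]] + H[ok] * m[["H"]] +
        grid$N[ok] * m[["N"]] + grid$O[ok] * m[["O"]] +
        grid$S[ok] * m[["S"]]
      theo <- theo_neutral + a$delta +
        if (config$electron) .ELECTRON_MASS else 0
      close <- abs(mz - theo) <= tol_da
      if (!any(close)) next
      cnt <- cbind(C = C, H = H[ok][close], N = grid$N[ok][close],
                   O = grid$O[ok][close], S = grid$S[ok][close])
      hits[[C - b$C[1] + 1L]] <- list(cnt = cnt, theo = theo[close])
    }
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (!length(hits)) next
    cnt <- do.call(rbind, lapply(hits, `[[`, "cnt"))
    theo <- unlist(lapply(hits, `[[`, "theo"))
    # adduct feasibility on the neutral, then plausibility
    feas <- cnt[, "H"] >= a$min_H & cnt[, "O"] >= a$min_O
    keep <- feas & .plausible(cnt, config)
    out[[k]] <- .candidate_frame(mz, cnt[keep, , drop = FALSE], a$name,
                                 theo[keep], config, "enumeration")
  }
  res <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                          list(.candidate_frame(mz, matrix(0, 0, 5,
                            dimnames = list(NULL, c("C","H","N","O","S"))),
                            character(0), numeric(0), config,
                            character(0)))))
  # final tolerance in ppm of the observed mass (exact window)
  res <- res[abs(res$error_ppm) <= config$tolerance_ppm + 1e-12, ,
             drop = FALSE]
  .order_candidates(res)
}

#' Assign many peaks by enumeration
#'
#' Runs [enumerate_formulas()] over a vector of observed m/z values and
#' reports, per peak, the best candidate together with the number of
#' surviving candidates.  A peak is "unambiguous" when exactly one
#' candidate survives the filters at the configured tolerance;
#' multi-candidate peaks keep their best candidate but are flagged.
#'
#' With the default `"cascade"` strategy the adducts in
#' `config$adduct_set` are tried in order and a later adduct is only
#' consulted for peaks that found no candidate at the earlier ones --
#' deprotonation dominates negative-mode electrospray, so `[M-H]-`
#' readings take priority and chloride attachment is a fallback.  This
#' also avoids the systematic double reading of every ion as both
#' `[M-H]-` of Y and `[M-H-H2O]-` of Y+H2O, which have identical
#' theoretical m/z.  `"pooled"` ranks candidates from all adducts
#' together purely by mass error.
#'
#' @param mzs Numeric vector of observed m/z values.
#' @param config An [assignment_config()].
#' @param strategy `"cascade"` (adduct priority, default) or
#'   `"pooled"`.
#' @return Data frame with one row per input m/z: the best candidate's
#'   columns (NA if unassigned), `n_candidates` and `ambiguous`.
#' @export
assign_peaks <- function(mzs, config = assignment_config(),
                         strategy = c("cascade", "pooled")) {
  strategy <- match.arg(strategy)
  rows <- lapply(mzs, function(mz) {
    if (mz < config$mass_range[1] || mz > config$mass_range[2]) {
      cand <- NULL
    } else if (strategy == "pooled") {
      cand <- enumerate_formulas(mz, config)
    } else {
      cand <- NULL
      for (a in config$adduct_set) {
        cfg_a <- config
        cfg_a$adduct_set <- a
        cand <- enumerate_formulas(mz, cfg_a)
        if (nrow(cand) > 0L) break
      }
    }
    n <- if (is.null(cand)) 0L else nrow(cand)
    if (n == 0L) {
      data.frame(mz = mz, formula = NA_character_, adduct = NA_character_,
                 theo_mz = NA_real_, error_ppm = NA_real_,
                 class = NA_character_, o_to_c = NA_real_,
                 h_to_c = NA_real_, rdbe = NA_real_,
                 provenance = NA_character_, n_candidates = 0L,
                 ambiguous = FALSE, stringsAsFactors = FALSE)
    } else {
      cbind(cand[1L, c("mz", "formula", "adduct", "theo_mz", "error_ppm",
                       "class", "o_to_c", "h_to_c", "rdbe", "provenance")],
            n_candidates = n, ambiguous = n > 1L)
    }
  })
  if (!length(rows)) {
    return(data.frame(mz = numeric(0), formula = character(0),
                      adduct = character(0), theo_mz = numeric(0),
                      error_ppm = numeric(0), class = character(0),
                      o_to_c = numeric(0), h_to_c = numeric(0),
                      rdbe = numeric(0), provenance = character(0),
                      n_candidates = integer(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Default seed assignments for network propagation
#'
#' Trusted grape-juice metabolites used as starting points: glucose,
#' fructose, tartaric acid, malic acid and tryptophan, as their
#' deprotonated ions.
#'
#' @return Data frame with columns `name`, `formula`, `adduct`, `mz`.
#' @export
default_seeds <- function() {
  s <- data.frame(
    name = c("glucose", "fructose", "tartaric acid", "malic acid",
             "tryptophan"),
    formula = c("C6H12O6", "C6H12O6", "C4H6O6", "C4H6O5", "C11H12N2O2"),
    adduct = "deprotonated",
    stringsAsFactors = FALSE)
  s$mz <- vapply(seq_len(nrow(s)),
                 function(i) ion_mz(s$formula[i], s$adduct[i]), numeric(1))
  s
}

#' Default mass-difference edge library
#'
#' Roughly thirty exact biochemical mass differences used to propagate
#' compositions through a peak network: homologation (H2, CH2, CH2O,
#' C2H2O, C2H4O2), small in/organic losses (O, CO, CO2, H2O, NH, NH3, S,
#' SO3, HPO3 is out of scope -- no P), the glycosyl unit C6H10O5,
#' deoxyhexose/pentose units, and amino-acid residue masses.
#'
#' @return Data frame with columns `name`, `formula` (composition delta)
#'   and `delta` (monoisotopic mass difference in Da).
#' @export
default_edges <- function() {
  e <- data.frame(
    name = c("H2", "CH2", "O", "CO", "CO2", "H2O", "NH", "NH3", "S",
             "SO3", "CH2O", "C2H2O", "C2H4O2", "glycosyl C6H10O5",
             "deoxyhexosyl C6H10O4", "pentosyl C5H8O4",
             "Gly residue", "Ala residue", "Ser residue", "Pro residue",
             "Val residue", "Thr residue", "Cys residue", "Leu/Ile residue",
             "Asn residue", "Asp residue", "Gln residue", "Glu residue",
             "Lys residue", "Met residue", "His residue", "Phe residue",
             "Arg residue", "Tyr residue", "Trp residue"),
    formula = c("H2", "CH2", "O", "CO", "CO2", "H2O", "NH", "NH3", "S",
                "SO3", "CH2O", "C2H2O", "C2H4O2", "C6H10O5", "C6H10O4",
                "C5H8O4",
                "C2H3NO", "C3H5NO", "C3H5NO2", "C5H7NO", "C5H9NO",
                "C4H7NO2", "C3H5NOS", "C6H11NO", "C4H6N2O2", "C4H5NO3",
                "C5H8N2O2", "C5H7NO3", "C6H12N2O", "C5H9NOS", "C6H7N3O",
                "C9H9NO", "C6H12N4O", "C9H9NO2", "C11H10N2O"),
    stringsAsFactors = FALSE)
  e$delta <- vapply(e$formula, monoisotopic_mass, numeric(1),
                    USE.NAMES = FALSE)
  e
}

#' Assign formulas by mass-difference-network propagation
#'
#' Builds a graph on the observed peaks (edges connect peak pairs whose
#' mass difference matches a library delta within the ppm tolerance,
#' evaluated on the heavier mass) and propagates compositions
#' breadth-first from the seed assignments.  A propagated candidate is
#' accepted only if its counts stay inside the configured element bounds,
#' it passes the plausibility filters, and its theoretical ion m/z
#' reproduces the peak's observed m/z within tolerance -- so error cannot
#' accumulate along paths.  Peaks reachable with conflicting compositions
#' are flagged `"conflict"` and report the first composition reached in
#' breadth-first (mass-sorted) order.
#'
#' @param peaks Numeric vector of observed m/z values.
#' @param config An [assignment_config()]; its tolerance governs both
#'   edge matching and acceptance.
#' @param seeds Data frame like [default_seeds()] (columns `formula`,
#'   `adduct`); each seed must match an observed peak within tolerance,
#'   and a seed whose stated m/z is inconsistent with its formula is
#'   rejected.
#' @param edges Data frame like [default_edges()]; stated deltas are
#'   checked against `monoisotopic_mass(formula)`.
#' @return Data frame of assignments (same columns as
#'   [enumerate_formulas()] plus `flag`), `provenance` `"seed"` or
#'   `"network"`, sorted by m/z.
#' @export
assign_by_network <- function(peaks, config = assignment_config(),
                              seeds = default_seeds(),
                              edges = default_edges()) {
  stopifnot(is.numeric(peaks), length(peaks) >= 1L)
  tol <- config$tolerance_ppm
  # validate edge library internal consistency
  for (i in seq_len(nrow(edges))) {
    if (abs(edges$delta[i] - monoisotopic_mass(edges$formula[i])) > 1e-6) {
      stop("edge '", edges$name[i], "': stated mass delta inconsistent ",
           "with its composition delta", call. = FALSE)
    }
  }
  ord <- order(peaks)
  mz <- peaks[ord]
  n <- length(mz)
  comp <- vector("list", n)       # assigned neutral counts
  adt <- character(n)
  prov <- character(n)
  flag <- rep("ok", n)
  queue <- integer(0)
  # seed matching
  for (i in seq_len(nrow(seeds))) {
    theo <- ion_mz(seeds$formula[i], seeds$adduct[i],
                   electron = config$electron)
    if (!is.null(seeds$mz) && abs(ppm_error(seeds$mz[i], theo)) > tol) {
      stop("seed '", seeds$formula[i], "': stated m/z ", seeds$mz[i],
           " is beyond tolerance of its theoretical ion m/z ", theo,
           call. = FALSE)
    }
    hit <- which(abs(ppm_error(mz, theo)) <= tol)
    for (j in hit) {
      cand <- as_composition(seeds$formula[i])
      if (is.null(comp[[j]])) {
        comp[[j]] <- cand; adt[j] <- seeds$adduct[i]; prov[j] <- "seed"
        queue <- c(queue, j)
      } else if (!identical(unname(comp[[j]]), unname(cand))) {
        flag[j] <- "conflict"
      }
    }
  }
  if (!length(queue)) {
    stop("no seed matches any observed peak within tolerance",
         call. = FALSE)
  }
  b <- config$bounds
  in_bounds <- function(x) {
    x[["C"]] >= b$C[1] && x[["C"]] <= b$C[2] &&
      x[["H"]] >= b$H[1] && x[["H"]] <= b$H[2] &&
      x[["N"]] >= b$N[1] && x[["N"]] <= b$N[2] &&
      x[["O"]] >= b$O[1] && x[["O"]] <= b$O[2] &&
      x[["S"]] >= b$S[1] && x[["S"]] <= b$S[2] && x[["Cl"]] == 0L
  }
  edge_comps <- lapply(edges$formula, as_composition)
  head_i <- 1L
  while (head_i <= length(queue)) {
    j <- queue[head_i]; head_i <- head_i + 1L
    base <- comp[[j]]
    for (k in seq_len(nrow(edges))) {
      for (sgn in c(1, -1)) {
        target_mz <- mz[j] + sgn * edges$delta[k]
        heavier <- pmax(mz, target_mz)
        hits <- which(abs(mz - target_mz) <= tol * 1e-6 * heavier)
        if (!length(hits)) next
        cand <- base + sgn * edge_comps[[k]]
        if (any(cand < 0L)) next
        if (!in_bounds(cand)) next
        cnt <- matrix(cand[c("C", "H", "N", "O", "S")], 1,
                      dimnames = list(NULL, c("C", "H", "N", "O", "S")))
        if (!.plausible(cnt, config)) next
        a <- .match_adduct(adt[j])
        if (cand[["H"]] < a$min_H || cand[["O"]] < a$min_O) next
        theo <- ion_mz(cand, adt[j], electron = config$electron)
        for (h in hits) {
          if (abs(ppm_error(mz[h], theo)) > tol) next
          if (is.null(comp[[h]])) {
            comp[[h]] <- cand; adt[h] <- adt[j]; prov[h] <- "network"
            queue <- c(queue, h)
          } else if (!identical(unname(comp[[h]]), unname(cand))) {
            flag[h] <- "conflict"
          }
        }
      }
    }
  }
  assigned <- which(!vapply(comp, is.null, logical(1)))
  if (!length(assigned)) {
    out <- .candidate_frame(numeric(0), matrix(0, 0, 5,
             dimnames = list(NULL, c("C","H","N","O","S"))),
             character(0), numeric(0), config, character(0))
    out$flag <- character(0)
    return(out)
  }
  cnt <- do.call(rbind, lapply(comp[assigned],
                               function(x) x[c("C", "H", "N", "O", "S")]))
  colnames(cnt) <- c("C", "H", "N", "O", "S")
  theo <- vapply(assigned, function(j) {
    ion_mz(comp[[j]], adt[j], electron = config$electron)
  }, numeric(1))
  out <- .candidate_frame(mz[assigned], cnt, adt[assigned], theo, config,
                          prov[assigned])
  out$flag <- flag[assigned]
  out[order(out$mz), , drop = FALSE]
}

#' Summarise a set of assignments
#'
#' Counts per compound class and per adduct, plus the assigned fraction
#' when the total number of peaks submitted is supplied.
#'
#' @param assignments Data frame from [enumerate_formulas()],
#'   [assign_peaks()] or [assign_by_network()] (rows with `NA` formula
#'   count as unassigned).
#' @param n_peaks Optional total number of peaks the assignments came
#'   from; defaults to `nrow(assignments)`.
#' @return List with `n_assigned`, `by_class`, `by_adduct`,
#'   `assigned_fraction`.
#' @export
assignment_summary <- function(assignments, n_peaks = NULL) {
  ok <- assignments[!is.na(assignments$formula), , drop = FALSE]
  if (is.null(n_peaks)) n_peaks <- nrow(assignments)
  list(n_assigned = nrow(ok),
       by_class = table(factor(ok$class,
                               levels = c("CHO", "CHNO", "CHOS", "CHNOS",
                                          "unclassified"))),
       by_adduct = table(factor(ok$adduct, levels = .ADDUCTS$name)),
       assigned_fraction = if (n_peaks > 0) nrow(ok) / n_peaks else NA_real_)
}

#' Write an assignment table
#'
#' Tab-delimited text with columns m/z, neutral formula (Hill order),
#' adduct, ppm error, class, O/C, H/C and provenance.
#'
#' @param assignments Assignment data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  cols <- intersect(c("mz", "formula", "adduct", "theo_mz", "error_ppm",
                      "class", "o_to_c", "h_to_c", "rdbe", "provenance",
                      "flag", "n_candidates", "ambiguous"),
                    names(assignments))
  utils::write.table(assignments[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
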