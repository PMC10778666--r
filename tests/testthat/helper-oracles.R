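# Independent oracles kept deliberately separate from the package's
# implementation paths.

# Published monoisotopic masses, retyped here independently of the
# package's frozen table.
ORACLE_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                 O = 15.9949146196, S = 31.97207100, Cl = 34.96885268)
ORACLE_ELECTRON <- 0.000548579909
ORACLE_ADDUCT_DELTA <- c(
  "deprotonated" = -ORACLE_MASS[["H"]],
  "deprotonated-dehydrated" = -3 * ORACLE_MASS[["H"]] - ORACLE_MASS[["O"]],
  "chloride" = ORACLE_MASS[["Cl"]])

# Exhaustive nested enumeration over every (C,H,N,O,S) tuple inside the
# bounds: the brute-force reference for enumerate_formulas().  Builds
# the full tuple lattice once (masses are mz-independent) and reuses it
# across masses.
make_brute_oracle <- function(bounds) {
  grid <- expand.grid(C = bounds$C[1]:bounds$C[2],
                      H = bounds$H[1]:bounds$H[2],
                      N = bounds$N[1]:bounds$N[2],
                      O = bounds$O[1]:bounds$O[2],
                      S = bounds$S[1]:bounds$S[2])
  grid$mass <- grid$C * ORACLE_MASS[["C"]] + grid$H * ORACLE_MASS[["H"]] +
    grid$N * ORACLE_MASS[["N"]] + grid$O * ORACLE_MASS[["O"]] +
    grid$S * ORACLE_MASS[["S"]]
  grid$rdbe <- grid$C - grid$H / 2 + grid$N / 2 + 1
  grid$ok <- grid$rdbe >= 0 & grid$rdbe <= 40 &
    abs(grid$rdbe - round(grid$rdbe)) < 1e-9 &
    grid$H / grid$C >= 0.2 & grid$H / grid$C <= 3.1 &
    grid$O / grid$C <= 1.5
  function(mz, tolerance_ppm = 0.5,
           adduct_set = c("deprotonated", "deprotonated-dehydrated",
                          "chloride")) {
    hits <- list()
    for (a in adduct_set) {
      theo <- grid$mass + ORACLE_ADDUCT_DELTA[[a]] + ORACLE_ELECTRON
      feas <- switch(a,
        "deprotonated" = grid$H >= 1,
        "deprotonated-dehydrated" = grid$H >= 3 & grid$O >= 1,
        "chloride" = rep(TRUE, nrow(grid)))
      sel <- abs((mz - theo) / mz * 1e6) <= tolerance_ppm & grid$ok & feas
      if (any(sel)) {
        g <- grid[sel, c("C", "H", "N", "O", "S")]
        hits[[a]] <- paste0("C", g$C, "H", g$H, "N", g$N, "O", g$O,
                            "S", g$S, "@", a)
      }
    }
    sort(as.character(unlist(hits, use.names = FALSE)))
  }
}

# Canonical key for comparing candidate sets with the oracle.
candidate_keys <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste0("C", df$C, "H", df$H, "N", df$N, "O", df$O, "S", df$S,
              "@", df$adduct))
}

# Single-component NIPALS PLS1, the reference the 0-orthogonal OPLS fit
# must reduce to.
nipals_pls1 <- function(X, y) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  w <- crossprod(Xc, yc)
  w <- w / sqrt(sum(w^2))
  t1 <- Xc %*% w
  list(scores = drop(t1), weights = drop(w))
}

# Mean silhouette of a 1-d score split into two known groups.
silhouette_1d <- function(x, g) {
  g <- as.integer(as.factor(g))
  s <- vapply(seq_along(x), function(i) {
    own <- abs(x[i] - x[g == g[i]])
    a <- sum(own) / (length(own) - 1)
    b <- mean(abs(x[i] - x[g != g[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
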