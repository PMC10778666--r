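---
title: "grapemet: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{grapemet: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapemet)
```

`grapemet` processes untargeted negative-mode mass-spectrometry data
of grape juice from two platforms: direct-infusion FT-ICR-MS (DI;
ultra-high mass accuracy, no chromatography) and RP-UHPLC-Q-ToF-MS
(LC; retention times, few-ppm accuracy). This vignette is the
package's own account of the methods: what each stage computes, which
defaults matter and why, where the design was genuinely open and how
it was settled, and what the synthetic-data tests do and do not show.

## Exact-mass arithmetic

All m/z values derive from one frozen table of monoisotopic atomic
masses (`mass_constants()`; IUPAC/CODATA values, carbon-12 exactly 12)
plus the electron mass. A singly charged anion carries one extra
electron, and the package **includes the electron mass by default** in
`ion_mz()`: for the chloride adduct of glucose the electron term moves
the theoretical m/z from 215.03224 to 215.03279 — a 2.5-ppm shift,
five times the assignment window, so omitting it would misassign
essentially every peak. The toggle (`electron = FALSE`) exists for
comparison with software that reports neutral-basis masses.

Three adducts are modelled — `[M-H]-`, `[M-H-H2O]-`, `[M+Cl]-` — and
every annotation reports the **neutral** composition plus an adduct
tag, never bare ion stoichiometry. This avoids a classic trap: the
deprotonated reading of Y and the dehydrated-deprotonated reading of
Y+H2O have *identical* theoretical m/z, so an ion-stoichiometry label
is ambiguous where the (neutral, adduct) pair is not.

Relative mass error is `(mz1 - mz2)/mz1 * 1e6` ppm with the
experimental mass as reference; all windows below are expressed in it.

## Formula assignment

`enumerate_formulas()` decomposes an observed m/z over C/H/N/O/S by
exhaustive search inside element bounds (defaults C 1–70, H 1–130,
N 0–10, O 0–45, S 0–4; masses 92–1000 Da), with a 0.5-ppm window and
chemical-plausibility filters: 0 ≤ RDBE ≤ 40, 0.2 ≤ H/C ≤ 3.1,
O/C ≤ 1.5, and — a filter the package adds on its own — *integer*
RDBE, since an even-electron neutral cannot have a half-integer ring-
plus-double-bond count. The bounds cover the mass range with headroom
and are fully configurable. Candidates are ordered by absolute ppm
error, then fewer heteroatoms, then formula string, so output order is
reproducible to the byte.

`assign_peaks()` ranks candidates per peak. Its default **adduct
cascade** tries `[M-H]-` first and consults later adducts only for
peaks with no deprotonated candidate. The rationale is ionization
chemistry, not convenience: deprotonation dominates negative
electrospray, and a pooled ranking across adducts lets a chloride
reading of a genuinely deprotonated ion win on mass error alone —
in simulations this misassigned roughly 40% of ions, while the cascade
assigns >99% correctly and still recognises genuine chloride species
(the glucose pollutant at 215.03279 has no deprotonated candidate and
falls through to `[M+Cl]-`). A `strategy = "pooled"` mode preserves
the pure mass-error ranking. "Unambiguous" means exactly one surviving
candidate; multi-candidate peaks keep their best candidate and a flag.

`assign_by_network()` re-specifies the mass-difference-network idea
(the original in-house tool is unpublished): seed metabolites known to
be present (glucose, fructose, tartaric and malic acid, tryptophan, as
`[M-H]-`) propagate compositions breadth-first along ~35 exact
biochemical deltas (H2, CH2, O, CO, CO2, H2O, NH, NH3, S, SO3,
acetyl/glycosyl/pentosyl units, amino-acid residues). Edge matching
uses the ppm window of the heavier mass. Crucially, a propagated
composition is only accepted if its own theoretical ion m/z reproduces
the peak within the window — so error cannot accumulate along paths —
and peaks reachable with conflicting compositions are flagged rather
than silently overwritten. The network route is validated against the
brute-force enumerator, not against any external tool.

## Feature alignment

`align_samples()` pools all samples' peaks, sorts by mass, and sweeps
once: a peak opens a new feature when it lies more than the window
(0.5 ppm for DI) above the running mean of the current cluster. The
running-mean test prevents single-linkage chaining: a ladder of peaks
each 0.4 ppm from its neighbour cannot stretch a feature beyond the
window. Membership deliberately uses the *unweighted* mean even though
the reported consensus m/z is intensity-weighted: metabolomic
intensities are log-normal, and letting one bright sample drag the
membership centroid splits genuine features (we observed exactly this
with weighted membership). When peaks carry retention times, each m/z
cluster is further split at RT gaps larger than the RT tolerance so
isomers stay distinct. One sample contributing two peaks to a feature
keeps the larger intensity.

LC features are grouped into **isobar groups** within 2 ppm, keyed by
the unweighted group mean, with multiplicity = number of distinct
retention times; groups are matched to DI features within 5 ppm.
Tie cascades are explicit and configurable: cross-platform matching
minimises |ppm|, then RT delta, then takes the lower mass; LC–LC
matching (10 s RT tolerance) puts the RT delta first. Matching is
one-to-at-most-one, resolved greedily in cascade order. The LC–LC
mass window has no single canonical value; the package reuses the
5-ppm cross-platform window by default.

Presence filters implement "at least n samples" (inclusive) and "at
least a fraction f" as `ceiling(n_samples * f)` — a stated lower
bound rounds up. Coverage comparisons call a feature present in a
group when detected in ≥ 4 samples of that group and report
shared/unique pattern counts whose percentages sum to 100.

## Preprocessing and univariate statistics

The pipeline order is fixed as: presence filter → zero imputation
(2/3 of the per-feature minimum nonzero) → batch correction → log10 →
Pareto scaling → models. Batch correction could equally run before
the presence filter; it runs after, on the imputed raw scale, which
keeps zeros from dominating the location estimates, and the order is
configurable for sensitivity analysis.
Pareto scaling divides each centred log-feature by the square root of
its standard deviation; a feature with log-sd 4 scales to sd 2.
Scaling is stateful — the result carries a `scaled` attribute and a
second `transform_scale()` call is an error, because double scaling is
a silent and common mistake.

`batch_correct()` is a two-stage per-feature linear adjustment:
remove per-batch means (recentre on the grand mean), then rescale each
batch's residuals to the pooled within-batch standard deviation. It is
idempotent to 1e-9 and removes a planted constant offset exactly. The
scale stage's fold-change distortion is pure sampling error of the
per-batch sd estimates (≈ 1/sqrt(2 n_b) relative); with 20-sample
batches the worst feature out of 100 can shift ~6%, with 60-sample
batches ~3%. Singleton batches get the location step only.

The univariate screen uses Kruskal–Wallis plus Dunn's rank post hoc
(hand-implemented with tie correction; no packaged Dunn test is
available here) for ≥ 3 groups, and for 2 groups a Student t-test when
both groups pass Shapiro–Wilk at α = 0.05, otherwise Mann–Whitney.
Feature-level p-values are Benjamini–Hochberg adjusted; fold changes
are ratios of raw (imputed) group means with log2 alongside. Constant
features report p = 1 with a flag rather than NA.

## Chemometrics

PCA is the eigendecomposition of the centred scaled matrix
(`stats::prcomp`). **OPLS-DA** is hand-implemented (no orthogonal-PLS
implementation is available in the dependency set): orthogonal
components are extracted by deflating X with the part of its loading
uncorrelated with the class vector, then one predictive PLS1 component
is fitted on the filtered matrix. With zero orthogonal components the
fit is numerically identical to 1-component PLS-DA, which the tests
check against an independent NIPALS implementation. Q2 uses
stratified k-fold cross-validation (default 7 folds, a declared
convention of this package); the permutation p-value is `(1 + #{Q2_perm ≥ Q2})/(n+1)`
with every permuted model refitted and cross-validated identically
(default 500 permutations). Seeds are mandatory arguments; there is no
hidden RNG state.

VIP scores combine the predictive and orthogonal components, each
weighted by the Y sum of squares it explains, with normalised weight
vectors — the standard PLS VIP weighting, stated explicitly because
VIP variants differ. Under it the mean squared VIP is exactly 1, and
orthogonal (class-uncorrelated) variation contributes only its tiny
residual Y covariance; weighting orthogonal parts by *X* variance
instead was tried and rejected, as it drowns class-predictive weights
in class-orthogonal variance and breaks marker ranking.

**RDA variance partitioning** wraps vegan (`rda`, `varpart`,
`anova.cca`): unique and shared fractions are Ezekiel-adjusted
R-squared values from all-subsets partial models, marginal
significance comes from permutation pseudo-F tests of each factor
given the others, and fractions plus the unexplained remainder sum to
one. Adjusted fractions may be slightly negative under the null;
that is expected behaviour, not an error.

## The synthetic-data generator

`make_library()` draws plausible CHNOS compositions across the van
Krevelen envelope in configurable class proportions, plants homologous
series (CH2 and glycosyl C6H10O5 steps), gives each metabolite 1–4
retention-time isomers, and adds a "sugar pollutant": a glucose
chloride adduct eluting at 13 distinct retention times, emulating a
carbohydrate-rich matrix in which sugars bleed through the whole
chromatogram. Pollutant RTs are spaced ≥ 42 s over 60–600 s so that
the 13 isomers remain resolvable by the 10-s RT split rule once many
samples' 2-s RT jitter is pooled. A minimum pairwise ion separation
(default 2 ppm) is enforced on the library, emulating peaks a
12-T FT-ICR instrument would resolve.

`emit_peaklists()` generates, per sample, a DI peak per detected
(metabolite, adduct) with multiplicative Gaussian mass error (default
sd 0.1 ppm DI / 1.0 ppm LC — sub-ppm vs few-ppm regimes) and an LC
peak per isomer with RT jitter (sd 2 s); intensities are log-normal
(CV 30%) around the metabolite's base intensity, scaled by marker
fold changes, per-batch offsets, and a logistic detection dropout in
log-intensity (a statistical proxy for ionization competition). The
defaults were chosen so the processing windows (0.5/2/5 ppm, 10 s)
are neither trivially loose nor unachievable. Every peak traces to one
(metabolite, adduct, isomer, sample) tuple, and identical seeds give
byte-identical output. The default design coarsely mirrors a
multi-vineyard sampling (4 varieties × 3 regions × 3 vintages × 2
replicates, 2 balanced batches) and is fully parameterised.

`simulate_factor_matrix()` is a separate matrix-level generator for
variance-partition studies: a crossed systematic design (factors
mutually orthogonal) with per-feature level effects rescaled so each
factor explains an exact target fraction of the population variance
(for factor k with L balanced levels, the planted between-level
variance is f_k/(1 - Σf)). This makes "inject a 16% variety fraction"
a calibrated statement rather than a hopeful one.

What the generator does **not** emulate: chromatographic peak shapes,
isotopologue envelopes, correlated (structured) noise, retention-time
drift between batches, and real ionization-suppression physics.
Passing tests therefore demonstrate algorithmic correctness under the
stated noise model, not instrument-grade robustness; on real data the
alignment windows and the dropout pattern would be the first things to
re-examine.

## Numerical and testing choices

Degenerate inputs have defined behaviour: empty peak lists give
all-zero rows; an unassignable peak is a valid empty result; all-zero
features are rejected by imputation (the presence filter must run
first); constant features scale to zero columns and test as p = 1.
TSV writers emit 17 significant digits so feature matrices round-trip
bit-exactly. The test suite sizes are deliberate: oracle equivalence
of the enumerator is checked on 100 random masses under reduced
bounds (an exhaustive ~1M-tuple reference lattice); alignment
recovery on a 150-ion, 50-sample set; the OPLS acceptance design uses
40 samples per class, 50 planted 3× markers and 500 permutations; the
null false-positive rate is measured over 10,000 feature tests; batch
correction is scored on 60-sample batches. One fixed-seed recovery
realization contains a 5.1σ mass-error outlier whose peak lands
outside the 0.5-ppm window; the aligner correctly gives it its own
single-sample feature and the ≥ 4-samples presence rule removes it —
the behaviour a practitioner would want.

## Known limitations

Only singly charged negative-mode ions and three adduct species; no
isotopologue scoring (which real workflows use to break candidate
ties); formula space limited to C/H/N/O/S (no P, no halogens beyond
the chloride adduct); two-class OPLS-DA only; no retention-time
warping across LC batches; the network assigner depends on seed
coverage — a disconnected compound class is simply left to the
enumerator. The batch model is location/scale per batch; drift within
a batch is out of scope.
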