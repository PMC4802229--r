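---
title: "Mapping kinase genetic dependencies from arrayed siRNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping kinase genetic dependencies from arrayed siRNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinasedep)
library(data.table)
```

## The problem

Profiling which kinases a tumor cell line depends on — by silencing each of
several hundred kinase genes with arrayed siRNA and measuring viability —
produces a map of *kinase genetic dependencies* (KGDs). Crossed with the
lines' molecular annotations (tumor histotype, driver-gene mutation and
copy-number calls, pathway membership), such a map generates hypotheses of
the form "mutation in driver *A* creates a dependency on kinase *B*", the
raw material for biomarker-driven drug targets. kinasedep implements that
analysis end to end: plate normalization and robust standardization, screen
quality control, dependency calling, permutation-based association testing,
interaction-network integration and drug-sensitivity comparison, plus a
ground-truth simulator that makes every stage testable.

## From raw plates to robust Z scores

A screen is one cell line assayed in triplicate plates (384- or 96-well).
Each library well's signal is divided by the **median signal of library
wells on its plate** (one factor per plate and replicate), which removes
plate- and replicate-level intensity effects; control wells are carried
through flagged but never contribute to the scaling. Replicates are
summarized per target by their **median**, and each screen is standardized
with a robust Z score over library targets:

$$Z_i = \frac{x_i - \mathrm{median}(x)}{1.4826 \cdot \mathrm{MAD}(x)}.$$

The 1.4826 constant makes the denominator a consistent estimate of the
standard deviation under normality, so Z values are comparable across lines
and to ordinary Z scores. Control wells (notably the killing positive
control) are excluded from the location/scale estimates, which they would
otherwise bias. `robust_z()` refuses fewer than 10 non-NA values by default
(a MAD over a handful of points is too unstable for screen use); the
`min_values` argument exists for small worked examples. Failed wells are NA
and are dropped per test, never imputed.

Screen-level QC combines two filters, both configurable:

* **Z'-factor** from control wells,
  $Z' = 1 - 3(\sigma_{pos} + \sigma_{neg}) / |\mu_{pos} - \mu_{neg}|$,
  a dynamic-range statistic (1 = ideal separation). Default floor: 0.3.
* **Replicate correlation**: the median pairwise Pearson correlation
  between replicate library-well vectors. Default floor: 0.7. (Pearson r is
  invariant to each replicate's affine Z transform, so the correlation is
  computed on normalized signals directly.)

A (line, target) pair with $Z \le -2$ is called a KGD. The threshold is
applied inclusively; the boundary case is a set of measure zero either way.

Cell lines are clustered on their dependency profiles with average-linkage
hierarchical clustering on the distance $1 - r$ (Pearson, pairwise-complete)
after restricting to the 20% most variable targets (ties at the variance
cutoff are all kept).

## The median-permutation (MP) test

The core statistic. For a binary grouping of cell lines (a histotype, a
driver alteration, a pathway grouping) and one siRNA target, the observed
effect is the difference of group medians,
$\Delta = \mathrm{median}(Z_{\text{interest}}) -
\mathrm{median}(Z_{\text{other}})$, and its significance is assessed
against random re-assignments of the group labels at fixed group sizes.
The test is **one-sided toward sensitization** ($\Delta < 0$): every
reported dependency is a loss of viability in the interest group. The
empirical p-value uses the standard finite-permutation guard,

$$p = \frac{1 + \#\{\Delta_{perm} \le \Delta_{obs}\}}{N + 1},$$

so $p = 0$ is impossible and $p \ge 1/(N+1)$ always. Full-scale runs use
$N = 10^6$ permutations; the test suite and the bundled analyses use
$10^3$–$10^4$, which changes only the resolution of small p-values.

Implementation notes that matter for reproducibility:

* Each (feature, target) pair gets its **own seeded permutation stream**,
  derived by hashing the global seed with the feature and target names.
  Results are therefore independent of test order and trivially
  parallelizable; seeded runs are bit-reproducible.
* The permutation kernel (C++) sorts the Z vector once and reads both group
  medians off order statistics, so a permutation costs $O(k \log k)$ in the
  interest-group size $k$ rather than two $O(n)$ selections. Median
  arithmetic matches `stats::median` exactly, including the mean-of-middles
  rule for even sizes.
* `mp_test_exact()` enumerates all $\binom{n}{k}$ label assignments and is
  the oracle the sampled test is validated against on small instances.

Multiple testing uses Benjamini–Hochberg, applied **within each feature
across its targets** (each feature's target-wide scan is treated as its own
family; a global mode is available via `bh_scope = "global"`). Histotype
scans use FDR 0.1; the driver focus set uses the deliberately permissive
FDR 0.5 of a hypothesis-generating screen, and nominal p ≤ 0.05 flags are
kept for the exploratory analyses. Dependencies nominally significant in
two or more within-histotype scopes are reported as recurrent
(`recurrent_dependencies()`).

## Feature construction

* **Histotype features** are one-hot; a histotype needs at least 2 lines on
  each side of the contrast to be testable. Subtype contrasts (e.g. clear
  cell vs other ovarian) are expressed by NA-ing out lines outside the
  scope (`scope_restrict()`).
* **Driver features** come from a binary alteration matrix that is an
  *input* (variant classification is out of scope). The testability rule is
  at least 7 altered and 7 unaltered lines (`min_altered_lines`),
  within-histotype runs relax this to 3/3.
* **Pathway groupings** OR together the member genes' alteration columns: a
  line is pathway-altered if any member is altered; NA propagates only when
  every member is NA. The shipped
  `inst/extdata/pathways15_synthetic.gmt` and
  `drivers_focus21_synthetic.tsv` are clearly-labelled synthetic stand-ins
  with the structure such curated lists have, and are meant to be replaced
  by the user's own definitions.
* The **better-predictor filter** keeps a pathway-level association only
  when |Spearman rho| between pathway membership and Z strictly exceeds
  that of every individual member gene. Ties go to the single gene — the
  more parsimonious explanation — which also makes a single-member pathway
  never "better".

## Network integration

The typed interaction graph holds four edge classes: `ppi` (undirected),
`kinase_substrate` and `regulatory` (directed), and `functional`
(STRING-like, undirected, scored). Functional edges are kept only at
combined score **strictly greater than 0.7** (the usual high-confidence
cutoff). A gene pair may carry several edge types.

* **Direct links** between a driver and a dependency are matched ignoring
  direction — a kinase acting on the driver and a substrate of the driver
  are both "previously reported relationships".
* **Shortest paths** are computed only for pairs *without* a direct link
  (pairs with one are length 1 by annotation, which keeps the two
  annotations consistent). Traversal treats ppi as bidirectional and the
  directed types as one-way, uses only the three typed classes (not the
  functional layer), and breaks ties among equal-length paths by always
  taking the lexicographically smallest admissible predecessor, so output
  is deterministic. Pairs at distance 2 with no direct link are the
  "one intermediate connection" class.
* **Connectivity enrichment** asks whether a driver's dependency set
  carries more within-set functional edges than uniformly drawn same-size
  sets from the screened background (genes on the array present in the
  graph). The null is deliberately the simplest "expected by chance" model
  — uniform sets without degree matching; parallel edges count once. The
  empirical p again uses the $+1/(N+1)$ guard.

## Drug sensitivity

Dose-response viabilities (8 log-spaced concentrations by default) are
summarized as the **trapezoidal mean of viability over the log-dose grid**,
clipped to [0, 1] before integration (values above 1 are growth
stimulation), so AUC = 1 means untouched and AUC = 0 fully killed at all
doses; lower = more sensitive. No sigmoid is fitted — the statistic
operates on AUC directly, which is monotone in pointwise viability and
scale-free across drugs. Group comparisons use a one-sided Mann–Whitney U
test (interest group more sensitive = lower AUC), exact for small samples
without ties, normal approximation with tie correction otherwise.
`exclusion_rerun()` repeats a test after removing a specified subset (e.g.
amplified lines) to show an effect is not carried by them. AUCs computed
under different normalization conventions (e.g. external compendia) are not
comparable and are never mixed.

## The synthetic-data generator

`generate_screen()` and friends produce fully specified inputs with known
ground truth. The default panel mirrors the study conditions this package
is built around: **117 lines from 10 histotypes (uneven sizes, breast
largest), 714 library targets, triplicate 384-well plates** with siPLK1
positive controls at ~10% of negative-control signal and ≥16 control wells
per plate.

The signal model is multiplicative log-normal, as appropriate for
luminescence intensity data: per-(plate, replicate) scaling factors
(log-sd 0.15), a per-(line, target) biological effect (log-sd
`bio_sd` = 0.18) and per-well replicate noise (log-sd `noise_sd` = 0.05,
screens still pass default QC at 0.1). Planted dependencies multiply the
affected viabilities by $(1 + \delta \kappa)$ where
$\kappa = \sqrt{\sigma_{bio}^2 + 0.449\,\sigma_{noise}^2}$ is the analytic
$1.4826 \cdot \mathrm{MAD}$ of summarized normalized viability (0.449 is
the variance deflation of a median of three). A multiplicative injection on
the viability scale — rather than an additive shift of log-viability — is
what keeps the *realized* robust Z shift within ±10% of the requested
$\delta$ even at $\delta = -5$; a log-scale shift misses by ~25% there
because of the curvature of $e^x$. The calibration degrades when planted
targets stop being a negligible fraction of the library (they then inflate
the per-line MAD); at the default 714-target library with ~14 planted
targets the bias is ~2%.

What the generator does *not* emulate: spatial within-plate effects (edge
wells), siRNA off-target structure, correlated dependencies between related
kinases, and real cell lines' profiles. Tests passing on synthetic screens
therefore demonstrate the statistical machinery — calibration, power,
error control — not robustness to those artifacts.

Other generators: `generate_alterations()` (Bernoulli columns, or exact
designed counts, optional co-mutation), `generate_network()` (Erdős–Rényi
background, planted dense module, sub-threshold decoy edges, verbatim typed
paths), `generate_dose_response()` (Hill curves, h = 1.5, per-line log-IC50
spread 0.35 ≈ 0.1 AUC spread; the sensitive group's IC50 centre is solved
numerically so the noiseless mean AUC gap equals the requested shift).
Every generator is a pure function of its seed and restores the caller's
RNG state.

## Problem sizes and numerical choices

* The bundled analyses and the acceptance script run the full 117 × 714
  panel with 2 × 10^3 permutations per test; statistical validation uses
  10^4–10^5 permutations on small instances and 100 simulation replicates
  for recovery/FDR checks. These sizes were chosen so the whole suite runs
  comfortably on a laptop; the statistics are identical at 10^6
  permutations, only small-p resolution changes.
* Degenerate inputs fail loudly: zero plate medians, MAD = 0 screens,
  constant Z vectors in clustering or Spearman steps, equal control means
  in Z', groups emptied by NA removal. Nothing is silently coerced.
* BH is `stats::p.adjust(method = "BH")` behind a validating surface;
  Mann–Whitney is `stats::wilcox.test`; medians/MAD are `stats::median` /
  `stats::mad` with the 1.4826 constant.

## Known limitations

* The connectivity null ignores degree structure; hub-rich dependency sets
  can look "connected" for degree reasons alone. A degree-aware null is the
  natural extension.
* BH within feature assumes the per-feature scans are the meaningful
  families; a global correction is stricter and available but not default.
* The MP test has no covariate adjustment (e.g. histotype as a confounder
  of a driver association is handled only by the within-histotype scans).
* Negative results are weak evidence: transient silencing and single-assay
  viability put a ceiling on the negative predictive value of any screen
  this pipeline processes.
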