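---
title: "Methods behind soilq: soil quality, enzyme stoichiometry, and driver analysis for manure-substitution trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind soilq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilq)
```

## The experimental setting

soilq analyzes field trials in which part of the chemical nitrogen
fertilizer of a maize system is replaced by organic (dairy) manure. The
canonical design the package emulates has five treatments — a full-chemical
control (CK) and 25%, 50%, 75% and 100% manure-N substitution — in a
randomized complete block design with three replicate plots, sampled at two
depth layers (0–20 and 20–40 cm). Total N is held constant across
treatments (187.5 kg N ha⁻¹ yr⁻¹, with the design table rounding to 187);
`fertilizer_table()` carries the canonical rates and `plan_for_rate()`
interpolates plans for intermediate substitution fractions, linear in
manure N with manure P and K scaled by the full-substitution nutrient
ratios. The canonical rows are a lookup, not a recomputation, because the
published rates carry inconsistent rounding (0.25 × 187.5 = 46.875 is
listed as 47.0) and reproducing the design exactly matters more than
arithmetic purity. Note the protocol states 187.5 kg N while the design
table prints 187; the package keeps the table's 187 in the canonical rows
and uses 187.5 for interpolation, and both appear in the documentation
rather than silently resolving the discrepancy.

## The radar-area soil quality index

Each indicator is first rescaled to a linear score in [0, 1]. Only "linear
score" is conventional here; soilq uses min–max scoring,

$$SL_i = \frac{x_i - \min x}{\max x - \min x}$$

(or its reflection for "less-is-better" indicators), computed **within one
depth layer** across all samples of that layer. Per-depth normalization was
chosen because the index is reported and compared per depth; pooling layers
would let the (systematically different) subsoil values compress the
topsoil scores. A constant column carries no ranking information; its
scores are set to the neutral 0.5 with a warning, rather than dropping the
indicator, so the spoke count `n` stays identical across depths.

The per-sample index is the radar-chart area

$$SQI = 0.5 \sum_i^{n} SL_i^2 \sin(2\pi/n),$$

in which every spoke contributes its own squared score. A literal polygon
area would use adjacent products $SL_i\,SL_{i+1}$ and depend on spoke
order; the squared-spoke form is the published convention and is
order-invariant, so it is the default, with the polygon variant available
behind `method = "polygon"` for sensitivity analysis. The index is bounded
by $0.5\,n\sin(2\pi/n)$ and strictly increasing in every nonzero score;
the test suite checks these properties plus agreement with a naive
loop-summation oracle to 1e-12 over 1000 random score vectors.

Two genuinely open choices are surfaced as arguments rather than baked in.
First, scoring directions: it is defensible to treat bulk density (and
perhaps dissolved organic N) as "less-is-better", but no direction
assignment can be recovered from published group means alone, so the
default scores every indicator "more-is-better" and `directions = c(BD =
"less")` runs the alternative. Second, the indicator set defaults to every
soil variable present at both depths — the eleven physicochemical
indicators plus the six enzymes — and is fully configurable.

## Ecoenzymatic stoichiometry vectors

With $C = BG + CB + XYL$ (C-acquisition), $N = NAG + LAP$ and $P = ALP$,
the proportions $x = C/(C+P)$ and $y = C/(C+N)$ define a point whose
polar summary is the stoichiometry vector: length $\sqrt{x^2+y^2}$
(relative microbial C demand) and angle $\mathrm{Degrees}(\mathrm{atan2}$
applied with the C-vs-P proportion as the x-coordinate$)$. Two conventions
required a decision:

* The length formula is sometimes printed without an explicit square root
  (a rendering artifact of the sum-of-squares form); soilq implements the
  standard rooted length and also returns the unrooted `length_sq` as a
  diagnostic.
* Math libraries take `atan2(y, x)` while spreadsheets take
  `ATAN2(x, y)`. soilq fixes the convention so that the first listed
  proportion (C vs P) is the x-coordinate: more phosphatase activity
  (P demand) shrinks $x$ and pushes the angle **above** 45°, more
  N-acquisition pushes it below. `ACP` is accepted as an input alias for
  `ALP` (the same phosphatase measured at different pH), and `CE`/`BX`
  for `CB`/`XYL`.

The vector is homogeneous of degree zero in the activities (scale
invariant), lives in angle ∈ (0°, 90°) and length ∈ (0, √2], and reflects
about 45° when P- and N-acquisition are swapped — all property-tested.
The conventional interpretive thresholds (length ∝ C limitation, 45° as
the N/P boundary) are a community reading, not a package claim.

## Treatment statistics

One-way ANOVA from raw data delegates to `stats::aov`. The distinctive
piece is `anova_from_summary()`, which reconstructs the identical ANOVA
from a printed summary table: for k equal-n groups,
$MSB = n\sum(m_i-\bar m)^2/(k-1)$ and $MSW = \sum SD_i^2/k$, with
$F = MSB/MSW$ on $(k-1,\,k(n-1))$ degrees of freedom. For balanced raw
data the two paths agree to machine precision (property-tested via
moment-matched constructions), which also fixes the degenerate rules:
$MSW=0$ with $MSB>0$ reports $F=\infty,\ p=0$; both zero report
$F=0,\ p=1$. Reconstruction from a published five-treatment trait table
reproduces its printed p-values (yield < 0.001, root length 0.004, root
surface area 0.008, root volume 0.004) — with one caveat: the root-biomass
row recomputes to 0.004 from the printed (rounded) moments while the
source prints 0.005, presumably computed from unrounded data. soilq
asserts only the reproducible rows.

Letter displays use Tukey's HSD by default: groups differ when their mean
gap exceeds $q_{1-\alpha,k,\nu}\sqrt{MSW/n}$, and the compact letter
display is built by the insert-and-absorb algorithm so two groups share a
letter exactly when their pairwise test is non-significant (verified
against a brute-force pairwise matrix on random instances). Fisher's LSD
is available because regional agronomy practice varies and the test family
behind published letter displays is often unnamed. Published letter
strings are generally **not** exactly recoverable from rounded summary
tables under any standard family; soilq therefore treats p-values, not
letters, as the reproduction target.

Two-way ANOVA (treatment × depth, fixed effects) mirrors the published
analysis; block (replicate) effects are omitted by default, matching the
one/two-way analysis convention for these trials even though the field
layout is a randomized complete block — the generator can inject an
additive block term (`block_sd`) to probe the consequences. Normality
checking wraps `stats::shapiro.test`.

## Community summaries

The community module starts from a taxon × sample count table with a
taxon → phylum map; read-level processing is out of scope. Phylum names are
normalized through an alias table (Actinobacteriota/Actinomycetota,
Proteobacteria/Pseudomonadota, …) because taxonomies mix pre- and
post-2021 nomenclature. Diversity uses the Gini–Simpson form
$1-\sum p_i^2$ — chosen because substitution trials report the index
*increasing* with diversity gains, which is the behaviour of $1-D$, not of
the dominance form — with inverse Simpson behind a flag. Bray–Curtis
dissimilarity is computed on within-sample relative abundances (no
rarefaction, which is deliberately out of scope) via `vegan::vegdist`, and
group differences in community structure are tested by PERMANOVA
(`vegan::adonis2` behind `permanova()`), a stand-in made explicit because
published reports often claim "structure was significantly altered"
without naming a test.

## Driver analysis

`mantel_test()` is implemented in the package: the correlation (Pearson or
Spearman) of the upper-triangle entries of two distance matrices, with a
null built by simultaneous row/column permutation of the second matrix and
the add-one rule $p = (1 + \#\{r^\ast \ge r\})/(1 + n_{perm})$, so p can
never be zero. An explicit permutation matrix can replace random sampling,
which the tests use for exact enumeration on 4 × 4 problems. Feature blocks
are turned into distances by Euclidean distance on z-scored columns — a
choice that has to be made somewhere, since published Mantel analyses
rarely state their metric.

Feature importance follows the response-permutation ("rfPermute-style")
scheme: a random forest regression (base learner delegated to
`randomForest`) supplies each feature's permutation importance as the mean
increase in out-of-bag MSE when that feature is shuffled, and significance
comes from refitting the forest `n_null` times with the **response**
permuted — a stricter null than shuffling features one at a time, because
it destroys all feature–response structure at once. p-values again use the
add-one rule. With `n_null` refits the attainable p-values are the grid
$k/(n_{null}+1)$, so the null rejection rate at level α is
$\lfloor \alpha(n_{null}+1)\rfloor/(n_{null}+1)$ — slightly below α —
which the calibration tests account for. Raw p-values are reported with
conventional significance stars (0.05/0.01/0.001) and no multiplicity
correction by default, matching reporting practice in this literature;
`p.adjust` can be applied downstream.

`driver_report()` assembles, per depth, the feature matrix
(physicochemical + enzymes + vector length/angle), and runs featurewise
correlations, the Mantel test, and permutation importance for each
response (grain yield, replicated over layers since it is a plot-level
trait, and the per-sample SQI).

## The synthetic-data generator

No public dataset accompanies the trial this package emulates, so the
generator is a first-class module that encodes the study conditions:

* **Design**: 5 treatments × 3 replicates × 2 depths, balanced.
* **Indicators and enzymes**: independent Gaussians per variable,
  `mean = CK mean × treatment effect` per depth, `SD = CV × mean`
  (CV 0.08 for physicochemical indicators, 0.10 for enzymes — typical
  plot-scale variability for these assays). CK baselines use the measured
  site values where available (SOC 21.9 g kg⁻¹, AHN 99.8 mg kg⁻¹, BD
  1.58 g cm⁻³) and typical Mollisol cropland values otherwise. Treatment
  effects are parameterized from the published per-depth percent-change
  ranges (e.g. topsoil MBC +28–42%, subsoil AP −42–60%, topsoil CB
  +138–239%), interpolated linearly from the 25% to the 100% rate;
  variables with no reported response get effect 1. Negative draws are
  truncated at zero — at these CVs the truncation probability is
  vanishing, so the documented bias is negligible.
* **Yield and root traits**: drawn directly from the published
  per-treatment means and SDs (plot-level, no depth).
* **Community**: per-sample phylum proportions are
  Dirichlet(concentration × mean vector) with concentration 200, counts
  multinomial at 10,000 reads — the count structure of amplicon data
  without modeling reads. Phylum means start from a typical cropland
  topsoil profile and apply the published enrichment/depletion directions
  (topsoil Actinomycetota +14–28%, Gemmatimonadota +64–88%, Bacteroidota
  −21–57%, …; subsoil Actinomycetota −12–20%, …), renormalized. Each
  phylum is split into 5 synthetic taxa by a fixed within-phylum Dirichlet
  draw.

Independent Gaussians match the ANOVA the analysis assumes;
cross-indicator correlation and block effects are configurable off by
default so power analyses can inject known structure. Each plot × depth is
one observation — within-plot compositing is not modeled because no
sampling detail at that level is available.

What the generator does **not** emulate: spatial autocorrelation between
plots, non-Gaussian tails and measurement censoring, depth-profile
continuity (layers are independent), taxon-level phylogenetic structure,
and sequencing artifacts. Passing tests on this generator therefore
validate the *statistical machinery* — not field-scale claims about real
soils.

With the shipped defaults and seed, the generated trial reproduces the
qualitative headline of such experiments: every substitution treatment
scores a higher mean SQI than CK in the 0–20 cm layer and a lower one in
the 20–40 cm layer. The published *magnitudes* (e.g. topsoil SQI +44–55%)
are not reproducible without the underlying raw data and are deliberately
not asserted; the generated topsoil gains are larger than the published
ones because min–max scores respond strongly to the monotone treatment
effects the defaults encode.

## Numerical and testing choices

* Problem sizes: property suites use 300–1000 random cases; permutation
  null calibrations use 500 simulated datasets at 99–199 permutations;
  forest-based checks use 30-sample, 10-feature fixtures with 100–200
  trees and 10–60 null refits, 50–200 runs. These sizes give stable
  verdicts for the statistical checks while keeping the default suite in
  the low minutes on one core.
* All stochastic stages are seeded; `simulate_trial`, `permanova`,
  `mantel_test`, `permutation_importance` and `run_all` reproduce exactly
  under a fixed seed, and `run_all` writes a manifest recording it.
* Depth labels are normalized to ASCII (`"0-20"`, `"20-40"`) on input
  because source tables mix hyphens and en-dashes.
* Equal-n is required for the summary-statistics ANOVA (its formulas
  assume it); unbalanced raw data routes through the general `aov`
  decomposition.

## Known limitations

* The SQI scoring direction question (BD/DON) is unresolvable from
  published group means; both settings are one argument away, but the
  default is a choice, not a finding.
* Letter displays from rounded summary tables can disagree with displays
  computed from raw data; only p-values are treated as reproducible.
* Mixed-effects models for the depth factor (plots as subjects) are out
  of scope; the fixed-effects two-way ANOVA mirrors the published
  analysis.
* The driver analysis ranks associations; it makes no causal claim.
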