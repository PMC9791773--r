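---
title: "Scoring and validating preschooler diet quality with cpdi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating preschooler diet quality with cpdi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdi)
library(dplyr)
```

## The index

The Chinese Preschooler Dietary Index (CPDI) summarizes the overall diet
quality of a child aged 2--5 years as a single 0--90 score built from 11
components: five *adequacy* components that should be eaten sufficiently
(vegetables, fruits, dairy, soybeans, aquatic products; 0--10 points each),
five *moderation* components that should be eaten in a target range
(cereals, eggs, red meat and poultry; 0--10 points each; vitamin A and iron,
0--2.5 points each, down-weighted to limit collinearity with the food
groups), and one *limitation* component that should be minimized
(high-sugar/high-fat snacks, 0--5 points).

Everything is scored on **densities** -- amounts per 1000 kcal of energy
intake -- so the index measures dietary *quality* rather than quantity, and a
small eater is not penalized for eating less of everything. Because daily
energy requirements differ between completed ages 2--3 (1000--1200 kcal/day)
and 4--5 (1200--1400 kcal/day), every component has age-group-specific
cutoffs. The full cutoff table ships as data
(`inst/extdata/cpdi_standard.yaml`); `cpdi_standard()` loads it, and variant
standards in the same schema can be loaded with `read_standard()` without
touching code.

## The three scoring rules

Write $d$ for a component's density, $m$ for its maximum score.

**Adequacy** (recommended density $r$): full marks at or above the
recommendation, proportional below it,

$$s(d) = \min(d / r,\, 1)\, m.$$

**Moderation** (max-score interval $[l, u]$): full marks inside the
interval; 0 at $d = 0$ and for $d > 2u$; linear against the *nearest* bound
in between,

$$s(d) = \left(1 - \left|1 - d/b\right|\right) m, \qquad
b = \begin{cases} l & 0 < d < l \\ u & u < d \le 2u. \end{cases}$$

The definition names "the upper limit or the lower limit" as the denominator
without saying which applies when; the nearest-bound reading is the only one
that is continuous at both interval ends and reproduces the published
worked example (cereals at 150 g/1000 kcal for a 2--3-year-old scoring
$(1 - |1 - 150/100|)\times 10 = 5$). Under it the rule rises linearly from 0
to $m$ on $(0, l]$, plateaus on $[l, u]$, and falls linearly back to 0 at
$2u$, which is exactly the tabulated minimum-score criterion ("0 or more
than twice the upper limit"). The only discontinuity candidate, $d = 0$, is
in fact a removable one: the below-interval branch tends to 0 as
$d \to 0^+$.

**Limitation** (limit density $L$): full marks at zero intake, 0 at or above
the limit,

$$s(d) = \max(1 - d/L,\, 0)\, m.$$

For snacks $L$ is fixed at 100 g/1000 kcal for both age groups. The German
Optimized Mixed Diet's "tolerated foods" allowance that motivates a snack
cap is stated per day (50 g/d), and no per-day-to-per-1000-kcal conversion
is published; we store only the density cutoff that the worked example
($(1 - 45/100) \times 5 = 2.75$) and the tabulated zero criterion
($> 100$ g/1000 kcal) jointly force, and note the unexplained relationship
here rather than invent one.

All three rules are clamped to $[0, m]$ to guard floating-point edges;
scores carry full precision internally and are rounded only in report
writers (2 decimals for scores, 1 for densities).

```{r worked}
score_density(200, "dairy", "4-5")   # adequacy worked example
score_density(150, "cereals", "2-3") # moderation worked example
score_density(45, "snacks", "4-5")   # limitation worked example
```

## From recall records to a score

Dietary input is one row per subject-day: `energy_kcal` plus grams (or
nutrient units) per component, as produced by a 24-h recall converted
through a food-composition table (`convert_foods_to_nutrients()` implements
the per-100-g standard-serving conversion; a small synthetic table ships for
exercising that path, since real national tables are copyrighted).

Choices a scorer must make, and what this package does:

* **Averaging order.** Intakes are averaged over the (typically 3) recall
  days first, then densified: density = mean daily amount / mean daily
  energy x 1000 (a ratio of means). Averaging three daily scores instead is
  *not* equivalent; the ratio-of-means convention matches scoring each child
  once on averaged intakes. If you want the alternative, score each day as
  its own record set and average the totals yourself.
* **Boundary semantics.** Max-score criteria are inclusive (`>=`);
  minimum-score criteria are strict (`> 2u`, `>= L` gives 0 only because the
  limitation formula itself reaches 0 exactly at $L$). The plausible-energy
  filter excludes subjects with mean daily energy strictly below 400 or
  strictly above 4000 kcal/day; exactly 400 or 4000 is kept.
* **Ages** are completed years: fractional ages are floored before group
  assignment, and the index is undefined outside ages 2--5 (an error for
  single subjects, a reject entry in cohort scoring).
* **Missing components** in the records are scored as zero consumption and
  flagged, never silently skipped -- skipping would shrink the 0--90 scale.
* **Units** are declared per component in the standard (grams for foods,
  ug RAE for vitamin A, mg for iron) and are the caller's responsibility;
  no retinol/beta-carotene conversion is attempted because conversion
  factors are specific to each food-composition table.

`score_cohort()` applies all of this per subject, collects per-subject
failures in `rejects()`, and keeps the densities it scored in
`densities()` as an audit trail.

## Cohort statistics

* **Categories.** Diet quality is split at the cohort's empirical 25th and
  75th percentiles into low / medium / high, with the medium interval
  inclusive at both cuts. Percentile definitions differ across software; we
  fix the linear-interpolation convention (`stats::quantile()` type 7,
  numpy's default "linear"). Counts near the boundaries can therefore
  differ by a subject or two from analyses done under other conventions
  (e.g. SAS's default definition 5).
* **Nutrient adequacy ratio.** actual / recommended daily intake, truncated
  at 1, so oversupply of one nutrient cannot mask shortfalls.
* **Item-rest correlations.** Spearman (midrank ties) between each
  component's subscore and the total minus that component; a zero-variance
  component yields a flagged `NA`, never a fabricated value.
* **Cronbach's alpha.** Published "standard and nonstandard" alphas rarely
  define their terms, so both conventions are always reported side by side:
  raw $\alpha = \frac{k}{k-1}\left(1 - \sum_j \sigma_j^2 / \sigma_T^2\right)$
  and standardized $\alpha = k\bar r / (1 + (k-1)\bar r)$ with $\bar r$ the
  mean pairwise Pearson correlation.
* **Dimensionality.** Eigen-decomposition of the subscore *correlation*
  matrix (components have unequal ranges -- 10 vs 2.5 points -- so covariance
  would let the wide components dominate), retaining factors with
  eigenvalue > 1 (Kaiser's rule) and reporting their cumulative variance
  share. Constant columns are dropped with a warning.

A low alpha is expected and is not a defect of the code: a diet-quality
index is formative, not reflective -- its components are meant to carry
independent information, which is exactly what near-zero inter-component
correlations and several eigenvalues near 1 express.

## The synthetic cohort generator

No individual-level survey data ships with the package, so
`simulate_cohort()` generates cohorts with known ground truth in the same
CSV dialect the scorer reads. The model, chosen once at design time:

* demographics drawn to mirror the surveyed population's structure (age mix
  22.5/24.7/25.0/27.8% over ages 2--5, 54.1% boys, 28% urban, income bands
  41.2/27.5/21.0/5.7/4.6%);
* per-child true densities from a **zero-inflated log-normal** per
  component -- log-normal for nonnegativity and right skew, a point mass at
  zero for the documented non-consumption phenomenon (the default dairy
  zero-probability is 0.693, matching the reported share of children who
  consumed no dairy across three recall days);
* urban residence and each income-band step shift log-densities additively
  (the configured effect directions make urban, higher-income children score
  higher, reproducing the published gradients qualitatively);
* mean daily energy log-normal around the child's age-band midpoint
  (sdlog 0.20), three recall days, and day-to-day log-normal noise of scale
  0.25 (mean 1) on both daily energy and amounts; `day_sd = 0` gives
  noiseless records whose densified values equal the ground truth exactly;
* one random stream split hierarchically -- per-subject seeds are drawn
  up front -- so enlarging a cohort never perturbs earlier subjects.

The location/scale defaults per component were set so that typical intake
patterns (insufficient fruits/dairy/aquatic products, cereal and red-meat
excess, adequate iron, near-zero snacking) emerge and the mean total lands
in the published 35--45-point ballpark; that is a plausibility default, not
a calibration claim. What the generator deliberately does **not** emulate:
food-item-level composition (densities are drawn at component level),
within-year seasonality, weekday/weekend structure, measurement error in
recalls, and survey clustering. Tests passing on synthetic cohorts
therefore validate the *algorithms*, not any cohort-level statistic of real
data.

```{r demo}
coh <- simulate_cohort(500, seed = 1)
kept <- filter_plausible_energy(coh$records)$kept
scores <- score_cohort(kept, coh$profiles)
glance(scores)
glance(reliability_report(scores))
head(categorize_quality(scores))
```

## Validation design

The test suite checks the implementation against independent oracles rather
than against itself: a scalar, literal transcription of the verbal scoring
rules evaluated on 10,000-point density grids per component and age group
(agreement to 1e-9 points, plus monotonicity and a slope-bound continuity
check); density invariance under per-subject rescaling of all intakes and
energy (1000 subjects, random factors $e^{\pm 2}$); and reliability
recovery on one-factor subscore matrices where standardized alpha has the
Spearman--Brown closed form $k\lambda^2/(1+(k-1)\lambda^2)$ -- at
$n = 5000$, $k = 11$, $\lambda = 0.6$ the estimate must land within
$\pm 0.03$ of 0.861, and independent columns must give all correlation
eigenvalues in $(0.9, 1.1)$. Those problem sizes keep each property
informative while the whole suite runs in about a minute.

## Limitations

* Cohort-level published statistics (mean score, alphas, the three-factor
  variance share, demographic trend tests) require the original survey
  data, which is not redistributable; this package reproduces the *methods*
  and demonstrates the same report layout on synthetic cohorts.
* No usual-intake (measurement-error) modelling, recall-day imputation, or
  seasonal adjustment: scores describe the recorded days.
* Trend tests across categories and regression modelling of score
  predictors are ordinary statistics any environment provides; the scores
  CSV is written in a shape (one row per child, one column per subscore)
  that feeds them directly.
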