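---
title: "Landmark-normalized radial nerve safe zones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-normalized radial nerve safe zones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsafe)
```

## The problem

The radial nerve (RN) runs obliquely across the posterior humerus in
the radial groove, directly on the periosteum, which makes it the
nerve most often injured in humeral-shaft fracture surgery — both by
the fracture itself and by plates inserted against the bone. Absolute
distances from the nerve to palpable landmarks vary with arm length,
so they transfer poorly between patients.

`radsafe` works with a landmark-*normalized* description instead.
Three palpable bony landmarks define a triangle on the posterior
arm: the Acromial Angle (AA, proximal), the Olecranon (Ol,
distal-medial) and the Lateral Epicondyle of the Humerus (LEH,
distal-lateral). The nerve's projections onto the two long edges are
Intersection Point A (on AA–Ol) and Intersection Point B (on
AA–LEH). The two quantities the whole analysis runs on are the edge
fractions

$$r_a = \frac{|IPA - Ol|}{|AA - Ol|}, \qquad
  r_b = \frac{|IPB - LEH|}{|AA - LEH|},$$

both measured from the distal landmark toward AA. Being ratios, they
are invariant under uniform rescaling of the arm, so one cohort's
fractions apply to any patient's triangle.

## Safe-zone definitions

Each specimen's nerve is idealized as the chord joining its two
crossing points. For a cohort of $n$ limbs:

* **Absolute safe zone** — the quadrilateral
  $[Ol,\; p(f_a),\; p(f_b),\; LEH]$ with $f_a = \min_i r_{a,i}$ and
  $f_b = \min_i r_{b,i}$, where $p(f)$ is the point at fraction $f$
  along the edge. By construction no observed chord crosses its open
  interior; chords touching the boundary do not count
  (`zone_violation_rate()` is exactly 0 on the defining cohort).
* **Relative safe zone** — the same construction with $f_a, f_b$ the
  empirical $\alpha$-quantiles (default $\alpha = 0.05$) of the two
  fractions, i.e. fewer than $\alpha + 1/n$ of the observed nerves
  cross below the boundary *on each edge*.

The relative zone is deliberately a *per-edge marginal* construction,
which is what published boundary percentages correspond to. The
chord-level probability of a nerve entering the zone through either
edge is larger than $\alpha$ unless the two fractions are perfectly
correlated: under a bivariate-normal ratio model with the default
correlation 0.557 it is about 8.6% rather than 5%
(1 − 0.95² ≈ 9.75% under independence). `violation_probability_model()`
computes this number so users can see exactly what "5%" does and does
not promise.

```{r joint-risk}
f_a <- qnorm(0.05, 0.599, 0.062)
f_b <- qnorm(0.05, 0.429, 0.066)
violation_probability_model(0.599, 0.062, 0.429, 0.066, 0.557,
                            f_a, f_b, n_mc = 1e5, seed = 1)
```

Quantiles default to linear interpolation between order statistics at
position $\alpha(n-1)+1$ (`stats::quantile` type 7). Published
boundaries rarely state their convention; the `type` argument makes
it explicit and configurable. At $n = 60$ the difference between
common conventions is a fraction of a percentage point, well inside
sampling noise.

The Ol–LEH base width of the triangle is not part of standard
measurement protocols (default 5 cm, configurable). Only polygon
*coordinates* depend on it; the boundary fractions never do.

## The synthetic cohort generator

Raw per-specimen data are rarely redistributable, so the package
ships a seeded generator (`simulate_cohort()`) whose defaults
reproduce the published cohort's structure: 30 cadavers (20 male, 10
female), both limbs each. Per limb it draws:

* **Segment lengths** (cm): sex-stratified truncated normals — males
  AA–Ol 29.54 ± 1.77, AA–LEH 29.34 ± 2.33; females 27.48 ± 1.61,
  26.98 ± 1.44 — truncated at mean ± 4 sd (and > 0), which moves the
  moments by well under 0.1%. Within a limb the two lengths correlate
  at 0.9, and a shared-cadaver random effect gives a left/right
  correlation of 0.5; neither value is reported anywhere, both are
  plausible for skeletal dimensions, and both are configurable (they
  do not affect any headline quantity, which depend only on the
  ratio marginals).
* **Crossing fractions**: $(r_a, r_b)$ jointly normal with means
  0.599/0.429, SDs 0.062/0.066, correlation 0.557, truncated to
  (0.05, 0.95). The correlation is *derived*, not printed: an OLS
  slope of 0.593 for $r_b$ on $r_a$ with those SDs implies
  $\rho = 0.593 \times 0.062 / 0.066 = 0.557$, and that direction of
  regression is the only one consistent with the published
  $t = 5.107$ (`implied_slope_t(0.593, 0.062, 0.066, 60)` = 5.108).
  The fractions are modeled as sex- and side-invariant, which matches
  the published group comparisons (no significant difference for
  either ratio).
* **Distal angle** $\beta$ (degrees): gamma, moment-matched to
  7.283 ± 6.165 via `derive_gamma_params()` (shape 1.396, scale
  5.219). The gamma's skewness $2/\sqrt{\text{shape}} \approx 1.69$
  overshoots the reported 1.372 somewhat; it is accepted as an
  approximation of the right-skewed, non-normal angle, and a
  truncated-normal alternative is selectable
  (`beta_model = "truncnorm"`).
* **Auxiliary distances** IPA–IPB (4.785 ± 1.656 cm) and IPB–BPC
  (8.568 ± 2.322 cm): truncated normals.

Crossing distances are constructed as $ipa\_ol = r_a \cdot aa\_ol$,
so the stored table is internally consistent by construction. Output
distances are rounded to 0.1 cm (and $\beta$ to 0.1°), matching a
±0.5 mm precision ruler; `round = FALSE` gives the unrounded values.
The number of male cadavers is the deterministic rounding of
`male_fraction * n_cadavers`, not a random draw, so small cohorts
always have the intended composition.

What the generator does **not** emulate: real joint dependence
between arm length and crossing fractions (assumed independent),
fixation shrinkage, measurement error beyond rounding, and any
paired-limb correlation in the *ratios*. Tests that pass on synthetic
cohorts therefore validate the pipeline's arithmetic and its
statistical calibration under the stated model — not the anatomy of
any new population.

## Measurement precision

Duplicate readings of the two segment lengths (12 limbs, measured
twice by one investigator; embedded as `table1_fixture()`) feed three
standard anthropometric precision statistics:

$$TEM = \sqrt{\frac{\sum_i d_i^2}{2n}}, \qquad
  rTEM = 100 \cdot \frac{TEM}{\bar{x}}, \qquad
  R = 1 - \frac{TEM^2}{SD^2},$$

with $d_i$ the within-pair difference, $\bar{x}$ the mean and $SD$
the standard deviation (n − 1 denominator) of all $2n$ readings. The
SD convention is a documented choice — the source formula says only
"standard deviation of all measurements".

```{r precision}
precision_table(table1_fixture())
```

Two reproducibility notes. First, the published precision table's
TEM/%TEM cells (0.05–0.08 / 0.32–0.56%) cannot be obtained from the
printed duplicate readings under the stated formula (our values are
0.000–0.082 cm); the formula, not the table, is treated as
authoritative, and no attempt is made to guess the original pairing.
Second, "R = 1.00 for all variables" holds for three of the four
sets; the left AA–LEH set gives R = 0.9948, which rounds to 0.99.
The headline claim — reliability indistinguishable from 1 at two
decimals for the AA–Ol reference measurement — reproduces exactly.

## Cohort statistics

* **Descriptives** (`describe()`): SD with n − 1 denominator,
  adjusted Fisher–Pearson skewness and bias-corrected excess kurtosis
  (the SPSS/Excel conventions, via `e1071` type 2), so values are
  directly comparable with published tables.
* **Normality** (`lilliefors_normality()`): the composite-normality
  K–S test with mean and SD estimated from the sample. The plain K–S
  null distribution is badly conservative in this situation, and the
  published D = 0.095 with p = 0.195 at n = 60 is only consistent
  with a Lilliefors-corrected p-value. Rather than interpolating
  published critical-value tables, the p-value is Monte-Carlo:
  the fraction of seeded standard-normal samples of the same size
  whose refitted D reaches the observed one (default 10 000
  replicates; `lilliefors_null()` lets callers share one null table
  across many tests of the same n). Calibration is itself tested:
  under the null the rejection rate at 0.05 stays within 0.05 ± 0.01
  over 2000 replicates.
* **Approximate-normality fallback** (`classify_normality()`): items
  failing the test but with |skewness| < 3 and |kurtosis| < 10 are
  classified `approximately_normal` and retained for moment-based
  analysis; this screening rule is how right-skewed-but-mild items
  stay in the t-test stage while $\beta$'s behaviour flags the nerve
  as unpredictable distal to the AA–LEH line.
* **Group comparisons** (`compare_groups()`,
  `compare_from_summaries()`): pooled-variance Student's t with
  df = n₁ + n₂ − 2, the convention behind published summary tables
  (Welch available via `var_equal = FALSE`). The summary-based twin
  exists so printed tables can be checked without raw data; both
  routes agree to 1e-9 on identical inputs. No multiple-testing
  correction is applied across the nine items, matching the source
  analysis; users comparing many items should keep that in mind.
* **Regression** (`fit_ratio_regression()`): OLS of $r_b$ on $r_a$.
  A zero-residual fit is flagged (`perfect_fit`) rather than
  reporting a meaningless t statistic.

## Numerical and degenerate-input choices

* Triangle construction solves the circle–circle intersection in
  closed form and refuses non-strict triangle inequalities.
* Boundary contact ($r$ exactly equal to $f$) is not a violation:
  the zone's interior is open. Ties in the minimum are harmless.
* Cohort validation recomputes ratios from distances; stored ratio
  columns may deviate by at most 0.005 (the worst case for distances
  rounded to 0.1 cm) before a row is rejected.
* Empty cohorts are writable (header-only CSV) and readable with a
  warning, but every estimator requires a non-empty cohort; the
  relative zone additionally requires $n \ge 1/\alpha$ so that the
  quantile is interior.
* Reliability is clamped to [0, 1]; TEM of fewer than two pairs,
  zero grand mean and zero SD are errors, not NaNs.
* The SVG renderer writes elements itself with fixed number
  formatting, so identical inputs give byte-identical files.

## Problem sizes

The shipped tests run the generator at up to 15 000 cadavers for
moment-recovery checks, 2000-replicate calibration studies for the
Monte-Carlo p-value, and 1000-chord geometric cross-checks; the
whole suite completes in well under a minute. The acceptance script
(`scripts/acceptance.R`) uses one 30-cadaver cohort (the study's
size) for the relative-zone boundaries and one 5000-cadaver cohort
for generator recovery.

## Known limitations

* The cohort behind the default parameters is 60 formalin-fixed
  limbs from one (elderly, Chinese) donor population; the defaults
  inherit that scope.
* The relative zone controls per-edge marginal risk, not chord-level
  risk (see above) — surgical interpretation should use the joint
  number from `violation_probability_model()`.
* The nerve is modeled as a straight chord inside the triangle and
  not at all distal to the AA–LEH line, where the measured angle
  $\beta$ is right-skewed and non-normal — i.e. the course there is
  genuinely variable and no zone is claimed.
* XLSX supplements are ingested by converting to the documented CSV
  schema externally; the package reads CSV only.
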