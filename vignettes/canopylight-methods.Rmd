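---
title: "Methods: light-profile modelling along forest chronosequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: light-profile modelling along forest chronosequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopylight)
```

## The scientific problem

During tropical secondary succession the canopy rises, stands accumulate
basal area and crown mass, and tree sizes differentiate. These structural
changes reshape the light environment: the height at which most light is
intercepted moves upward, the steepness of light extinction changes, and
the amount and patchiness of light reaching the forest floor — where seeds
germinate — declines. `canopylight` quantifies these changes from two
standard field data sets per stand: an individual-tree inventory and a grid
of relative light intensity (RLI) measurements, taken at the centre of each
of 16 subplots (5 × 5 m) of a 40 × 10 m plot, at 1 m steps from 1 to 22 m.

## The sigmoid light-profile model

Vertical RLI profiles are summarized with the logistic sigmoid

$$Y(x) = \frac{100}{1 + e^{-a (x - b)}}$$

with the asymptote fixed at 100%. The two parameters are directly
ecological: $b$ (m) is the height of the inflection point (HIP), where 50%
of above-canopy light remains, and $a$ (per m) is the slope at that point,
the light attenuation rate. Fixing the asymptote keeps predictions inside
the physically meaningful 0–100% band; no lower offset is estimated, so the
curve approaches 0% at the ground asymptotically. The same curve is fitted
to cumulative structural profiles (attribute accumulated over trees ranked
by increasing height, as percent of the plot total), giving the HIP and
accumulation slope of basal area, height, crown area and crown length.

We report the raw parameter $a$ as "the slope at the inflection point"
rather than the curve derivative there ($25a$ for asymptote 100); the two
differ only by a constant factor, so trends and standardized coefficients
are unaffected, and $a$ is the quantity users can plug back into the
formula.

### Fitting protocol

The model is fitted by bounded nonlinear least squares
(`minpack.lm::nlsLM`):

* initial $b$: the height where the profile first crosses 50%, by linear
  interpolation between bracketing measurements (mid-range when the profile
  never crosses 50);
* initial $a$: $4 / \mathrm{range}(x)$, the slope a sigmoid needs to
  traverse the measured height range;
* bounds $a \in [10^{-3}, 20]$, $b \in [0, 2\max(x)]$;
* parameter tolerance $10^{-8}$, up to five extra restarts from a fixed
  schedule of perturbed initials (deterministic, so fitting never touches
  the caller's random-number stream); the converged restart with the lowest
  RSS wins.

Contracts: a profile whose fitted slope pins at the positivity bound is
rejected (light must decrease towards the ground); a profile with less than
1 percent point of range is flagged degenerate rather than fitted; $b$
above the measured range sets an `extrapolated` flag — this happens when
the canopy is taller than the measurement rod, and the fixed asymptote
makes the extrapolation explicit instead of hiding it. On noiseless
sigmoid data the protocol recovers $(a, b)$ to below $10^{-6}$ relative
error across $a \in [0.2, 2]$, $b \in [2, 20]$; with 5% multiplicative
noise the median HIP error stays within 0.5 m (both are exercised in the
test suite).

## Heterogeneity metrics

* **Relative HIP** = $100\,b / H_{\max}$, with $H_{\max}$ the tallest tree
  of the *whole plot* (light in a subplot is shaped by neighbours rooted
  elsewhere). It may exceed 100% when the fit is extrapolated.
* **Understorey RLI** is the raw 1 m measurement (mean over subplots), not
  the fitted value — closest to where regeneration happens and free of
  model error where the sigmoid fits worst.
* **Horizontal light heterogeneity (HLH)** at a height is the sample SD
  (n−1) of RLI across the 16 subplots, in percent points — absolute SD,
  because plants respond to absolute differences in light. Its peak height
  (ties resolved to the lowest height) marks where the canopy is patchiest.
* **Structural CVs** use $100 \times SD/\text{mean}$ over the 16 subplot
  totals — relative, so stands of very different absolute size remain
  comparable. Sample SD is used throughout: the 16 subplots are a sample
  of the stand, not the population.
* Plot means of HIP, relative HIP and attenuation rate average the
  converged, non-degenerate subplot fits only; exclusions are counted and
  surfaced in the run manifest, never silent.

Conventions the data model fixes: diameters in cm, lengths in m, basal
area in cm², crown area in m²; multi-stemmed trees enter as one individual
with effective DBH $\sqrt{\sum d_i^2}$ (preserving basal area), and the
1 cm inclusion threshold applies to that effective DBH; subplot membership
comes from the stem base coordinate in half-open 5 m cells, and trees
rooted outside the plot are dropped with a warning; ties in the height
ranking of cumulative profiles keep input order (any stable order yields
the same curve up to relabeling of coincident points).

## Trend inference

Each metric is regressed on stand age. Subplot-replicated metrics use a
linear mixed model with plot random intercepts (REML, `lme4`); plot-level
metrics reduce to OLS. The association is reported as
$\mathrm{sign}(\hat\beta)\sqrt{R^2_{marginal}}$, the correlation
attributable to the fixed age effect — with marginal $R^2$ computed as the
fixed-effect variance over the total (fixed + random + residual) variance.
Parametric assumptions are checked on the residuals: Shapiro–Wilk for
normality and Breusch–Pagan against age for homoscedasticity, both at
$\alpha = 0.05$. If either fails, inference switches to the nonparametric
route: the Mann–Kendall test (tie-corrected variance, continuity-corrected
normal approximation, tau-b) on plot means ordered by age, with Sen's
protocol — median of pairwise slopes, intercept as the median of
$y - \hat\beta x$ — for the regression line. Singular or degenerate mixed
fits degrade to OLS with a warning rather than aborting a pipeline run. No
multiple-testing correction is applied across metrics; each trend is
reported as-is.

## Path models

Structure is linked to light with chains of standardized regressions:
age → $s_1$, age → $s_2$, light ~ $s_1 + s_2$, all variables z-scored so
coefficients are comparable path strengths; $R^2$ is reported for the
final light response only. The two structural predictors are selected by
rule: first the candidate most strongly correlated (|r|) with the light
descriptor, then, among the rest, the one least correlated with the first
— a collinearity-avoidance heuristic; if the chosen pair is still
collinear (|r| > 0.99 is a hard error), the pipeline walks down the
candidate order. Candidate pools mirror the mechanism being tested:
structure HIPs for the HIP of light, structure accumulation slopes (on a
natural-log scale, which improves normality for rate-like quantities) for
the attenuation rate, plot totals for understorey RLI, and structural CVs
for understorey HLH — the latter with a direct age → light edge, since
age affects understorey patchiness through gap dynamics not captured by
the structural CVs. This is deliberately a chain of component
regressions: no d-separation testing or global fit statistic is computed.

## The synthetic chronosequence generator

The generator exists so that every stage of the analysis can be exercised,
calibrated and property-tested without field data. It emulates the study
design (14 stands, ages 8–32; 40 × 10 m plots; 16 subplots; light at
1–22 m) with the following mechanics, chosen once and fixed in
`inst/extdata/default_config.yaml`:

* **Stem density** declines with age as $600\,e^{-0.05\,\text{age}}$
  expected stems per plot (Poisson), i.e. roughly 10,000/ha of stems over
  1 cm DBH in young fallows thinning to ~3,000/ha by year 32 —
  self-thinning at field-plausible magnitudes.
* **Tree sizes** are reverse-J: DBH ~ 1 cm + Weibull(shape 1.1, scale
  growing linearly with age). Many small and few large trees at every age,
  with the large-tree tail extending as the stand ages.
* **Height** follows a power-law allometry $3.6\,D^{0.55}$ m (capped at
  35 m) with lognormal scatter that *grows* with age (0.04 + 0.005/yr) —
  stand differentiation. The power law, rather than an age-driven height
  distribution, is what makes the emergent vertical structure right: young
  stands are crowded with short trees whose crowns sit low (so the HIP of
  light is low and extinction steep), while old stands carry tall,
  large-crowned canopy trees that intercept light high up.
* **Crowns** are vertical elliptic cylinders: width $1.2 + 0.6 D^{0.75}$ m
  with lognormal noise on the two orthogonal diameters, occupying a
  fraction ~0.55 of tree height. Cylinders, not ellipsoids, keep vertical
  path lengths exact and cheap; profile shapes are insensitive to the
  difference at the 1 m height resolution of the design.
* **Site effects**: each plot draws a lognormal jitter (SD 0.12) of the
  Weibull shape and a slope (SD 0.20) of crown ratio against size rank.
  Stands of the same age therefore differ structurally, as real sites do;
  without this, the four structural HIPs are collinear at |r| > 0.99 and
  no valid path-model predictor pair exists.
* **Light** is Beer–Lambert along vertical rays: optical depth
  $\tau = k \cdot \text{LAD} \cdot \sum \text{crown path lengths}$ with
  $k \cdot \text{LAD} = 0.19$ per m of crown path, plus a scalar diffuse
  floor $\epsilon = 1.2\%$ standing in for lateral diffuse light, and
  mean-one lognormal measurement noise (SD 0.20 on the log), clipped to
  [0, 100]. Noiseless fields are monotone non-increasing downward and
  bounded below by $100\,\epsilon$; doubling LAD doubles every $\tau$
  exactly.
* **Reproducibility**: all randomness flows from a master seed through
  per-(age, stream) child seeds, so adding an age to the design never
  reshuffles other plots, and a fixed seed gives byte-identical output.
  All simulation routines save and restore the caller's RNG state.

Calibration targets, set once: youngest stands top out near 12–15 m and
the oldest near 27–30 m; understorey RLI means stay within the
field-plausible 0.05–16% band at every age; and the canonical successional
signs (HIP and relative HIP rising, attenuation rate falling, understorey
RLI falling) are recoverable from the default configuration.

What the generator does **not** emulate: species identity and composition,
within-crown foliage clumping, lateral light transport beyond the scalar
floor (no hemispherical integration, no sunflecks), gap creation as an
explicit mortality process (bright understorey patches arise only from
random crown placement), and temporal dynamics within a stand. Passing
tests on synthetic chronosequences therefore demonstrate that the
estimators recover the structure the generator encodes — monotone
successional trends, Beer–Lambert vertical profiles, structure–light
coupling — not that field data obey that structure.

## Numerical choices and degenerate inputs

* RLI values above 100 after relativization are clipped to 100 with a
  warning (sensor/reference mismatch is expected in the field), never
  discarded.
* Empty inventories are valid (zero totals); zero-total attributes and
  near-constant light profiles raise explicit degenerate-input errors or
  flags rather than producing numbers.
* CSV interchange uses '.' decimals, comma separators and 6 significant
  digits; read∘write is the identity at that precision.
* Tests and examples run at the design's natural size (14 plots × 16
  subplots × 22 heights); simulation-based checks use 20–200 replicates,
  sizes at which the checked contrasts are decisive.

## Known limitations

The mixed-model association measure is one of several reasonable
"correlation from a mixed model" constructions; tau and Sen slopes are the
more robust quantities for small chronosequences (n = 14 plots). The
fixed-asymptote sigmoid cannot represent profiles that plateau below 100%
(e.g. a measurement ladder that never clears the canopy) except through
the extrapolation flag. And a chronosequence is a space-for-time design:
the trend machinery quantifies association with stand age, not within-site
temporal change.
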