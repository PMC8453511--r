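# canopylight

Light is the resource that structures closed tropical forests: who gets it,
at what height it is intercepted, and how patchy it is near the ground
decide which species can regenerate during secondary succession.
`canopylight` is an R package for quantifying **vertical and horizontal
light heterogeneity along secondary-forest chronosequences** and linking it
to forest structure. It is aimed at forest ecologists working with paired
tree inventories (DBH, height, crown dimensions) and vertical profiles of
relative light intensity (RLI, % of above-canopy irradiance) measured on a
subplot grid.

## The model at the core

A vertical light profile is summarized by the two-parameter logistic
sigmoid

    Y(x) = 100 / (1 + exp(-a (x - b)))

where `Y` is RLI (%), `x` is height (m), `a` (per m) is the slope at the
inflection point — the **light attenuation rate** — and `b` (m) is the
**height of the inflection point (HIP)**, the height where exactly 50% of
above-canopy light remains. By construction `Y(b) = 50` for every `a`.
The same curve fitted to cumulative structural profiles (basal area, crown
area, crown length, height accumulated over trees ranked by height) gives
the height where each structural attribute is concentrated.

Around this model the package provides:

- **Inventory**: effective DBH of multi-stemmed trees
  (root-sum-of-squares), basal area `0.25 π DBH²`, elliptical crown area
  `0.25 π d₁ d₂`, crown length, plot totals, horizontal CVs over the 16
  subplots, and cumulative vertical profiles.
- **Light**: relativization of PPFD readings, per-subplot sigmoid fits,
  relative HIP (% of maximum canopy height), understorey RLI at 1 m, and
  horizontal light heterogeneity (HLH, the SD of RLI across subplots at
  each height) with its peak height.
- **Trends**: linear mixed models (plot random intercepts) with a
  Mann–Kendall + Sen's-slope fallback when parametric assumptions fail,
  and standardized path models for age → structure → light chains.
- **Simulator**: an individual-tree stand generator (reverse-J size
  distributions, power-law allometries, self-thinning) with a
  Beer–Lambert light field over the 16-subplot × 1–22 m measurement grid,
  so the whole pipeline can be exercised without field data.

## Worked example

Fit a light profile measured at 1–22 m:

```r
library(canopylight)
h <- 1:22
rli <- c(2.1, 2.4, 3.1, 4.4, 6.6, 10.1, 15.6, 23.4, 33.8, 46.3, 59.6, 71.8,
         81.6, 88.6, 93.2, 96.0, 97.7, 98.7, 99.2, 99.6, 99.8, 99.9)
fit <- fit_sigmoid(h, rli)
fit
#> Logistic sigmoid profile fit (asymptote fixed at 100)
#>   a (slope at inflection, per m): 0.5288
#>   b (height of inflection, m):    10.2313
#>   RSS: 7.807 on 22 points
```

Half of the above-canopy light is gone by 10.2 m, and light decays at
0.53 per m around that height (`predict(fit, newdata = fit$b)` returns
exactly 50).

Run the full pipeline on a simulated 14-stand chronosequence (ages 8–32):

```r
run <- run_pipeline(sim_config(seed = 1))
subset(run$trends, metric %in%
       c("hip", "relative_hip", "attenuation_rate", "rli_1m"))
#>            metric           method   slope intercept association  p_value  n
#>               hip mann_kendall_sen  0.7147      1.19       0.758 0.000197 14
#>      relative_hip mann_kendall_sen  0.8567     44.36       0.473 0.021489 14
#>  attenuation_rate mann_kendall_sen -0.0177      0.98      -0.714 0.000459 14
#>            rli_1m mann_kendall_sen -0.0856      4.80      -0.187 0.381074 14
```

The successional signature is visible directly: the HIP climbs by about
0.7 m per year (light is intercepted ever higher as the canopy rises), the
attenuation rate declines (light is absorbed more gradually in older,
better-differentiated stands), and understorey light at 1 m slowly fades.
The path models then attribute these light changes to structure, e.g.

```r
run$paths$mean_hip
#> Standardized path model for mean_hip
#>   age -> hip_basal_area: beta = +0.916 (p = 4.34e-06) *
#>   age -> hip_crown_length: beta = +0.957 (p = 8.21e-08) *
#>   hip_basal_area -> mean_hip: beta = +1.266 (p = 0.000678) *
#>   hip_crown_length -> mean_hip: beta = -0.343 (p = 0.231)
#>   R^2 (mean_hip) = 0.904, n = 14
```

— the height where basal area accumulates is what carries the HIP of
light upward.

A command-line front end with `simulate`, `analyze`, `trends` and `all`
subcommands lives in `inst/scripts/canopylight-cli.R`:

```sh
Rscript inst/scripts/canopylight-cli.R all --seed 1 --out-dir out/
```

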