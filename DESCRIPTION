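Package: canopylight
Title: Vertical and Horizontal Light Heterogeneity Along Tropical Secondary
    Forest Chronosequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how light availability and its spatial
    heterogeneity change during tropical secondary forest succession.
    Fits logistic sigmoid curves to vertical profiles of relative light
    intensity to extract the height of the inflection point (HIP, the height
    where 50% of above-canopy light remains) and the light attenuation rate;
    summarizes horizontal light heterogeneity as the standard deviation of
    relative light intensity across subplots; computes per-tree and per-plot
    forest structural attributes (effective diameter of multi-stemmed trees,
    basal area, crown area and length) and their cumulative vertical
    profiles; estimates successional trends with linear mixed models and a
    Mann-Kendall/Sen nonparametric fallback; and chains structure and light
    through standardized path models. Includes an individual-tree stand
    simulator with a Beer-Lambert light field that generates chronosequence
    data with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml,
    lme4,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
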