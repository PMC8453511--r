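#' Reference successional regression lines
#'
#' Regression lines of light-heterogeneity descriptors against stand age
#' reported for a published 8--32 year tropical secondary-forest
#' chronosequence (14 stands, 16 subplots each, light measured from 1 to
#' 22 m). They serve as external consistency benchmarks for the scale and
#' direction of the successional trends this package estimates; they are
#' inputs, not outputs, of the package.
#'
#' Forms: `linear` means `y = slope * age + intercept`; `log` means
#' `y = slope * log(age) + intercept` (natural log).
#'
#' @return Data frame with `metric`, `form`, `slope`, `intercept`, `units`.
#' @seealso [evaluate_reference_trend()]
#' @export
reference_trend_lines <- function() {
  data.frame(
    metric = c("mean_hip", "mean_relative_hip", "mean_attenuation_rate",
               "rli_1m", "hlh_peak_abs", "hlh_peak_rel", "hlh_1m"),
    form = c("log", "log", "linear", "linear", "linear", "linear", "log"),
    slope = c(8.31, 21.11, -0.024, -0.083, 0.49, 1.03, -1.34),
    intercept = c(-13.56, -9.62, 1.09, 4.22, 1.48, 35.78, 5.70),
    units = c("m", "%", "per m", "%", "m", "%", "% points"))
}

#' Evaluate a reference regression line at a stand age
#'
#' @param metric One of the metric names of [reference_trend_lines()].
#' @param age Stand age(s), years.
#' @return Predicted metric value(s) on the reference line.
#' @export
#' @examples
#' evaluate_reference_trend("rli_1m", c(8, 32))  # understorey RLI endpoints
evaluate_reference_trend <- function(metric, age) {
  ref <- reference_trend_lines()
  row <- ref[ref$metric == metric, ]
  if (nrow(row) != 1) stop("unknown reference metric: ", metric)
  x <- if (row$form == "log") log(age) else age
  row$slope * x + row$intercept
}
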