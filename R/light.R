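#' Relative light intensity from paired irradiance readings
#'
#' Standardizes an in-canopy PPFD reading by the simultaneously measured
#' above-canopy (or nearby open-area) reference irradiance:
#' `100 * measured / reference`, in percent. Values above 100 — expected
#' occasionally under field conditions from sensor/reference mismatch — are
#' clipped to 100 with a warning rather than discarded.
#'
#' @param measured In-canopy PPFD reading(s); non-negative.
#' @param reference Reference PPFD; positive, recycled against `measured`.
#' @return Relative light intensity (percent, in \[0, 100\]).
#' @export
relativize <- function(measured, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference irradiance must be positive")
  if (any(!is.finite(measured)) || any(measured < 0))
    stop("measured irradiance must be non-negative")
  rli <- 100 * measured / reference
  if (any(rli > 100)) {
    warning(sum(rli > 100),
            " reading(s) exceeded the reference; clipped to 100%")
    rli <- pmin(rli, 100)
  }
  rli
}

#' Assemble a light grid
#'
#' A `light_grid` holds the relative light intensity (percent) measured at
#' the centre of each subplot over a ladder of heights — the standard design
#' being 16 subplots and heights 1 to 22 m at 1 m intervals.
#'
#' @param rli Numeric matrix, subplots in rows, heights in columns, percent
#'   values in \[0, 100\].
#' @param heights Strictly increasing measurement heights (m); length must
#'   match `ncol(rli)`.
#' @param plot_id Plot identifier.
#' @param age Stand age (years).
#' @return A `light_grid` object.
#' @export
light_grid <- function(rli, heights = 1:22, plot_id = NA, age = NA) {
  rli <- as.matrix(rli)
  stopifnot(ncol(rli) == length(heights), !is.unsorted(heights, strictly = TRUE))
  if (any(!is.finite(rli)) || any(rli < 0) || any(rli > 100))
    stop("rli values must lie in [0, 100]")
  dimnames(rli) <- list(subplot = seq_len(nrow(rli)) - 1L, height = heights)
  structure(list(plot_id = plot_id, age = age,
                 heights = as.numeric(heights), rli = rli),
            class = "light_grid")
}

#' @export
print.light_grid <- function(x, ...) {
  cat("Light grid: plot ", format(x$plot_id), " (age ", format(x$age),
      " yr), ", nrow(x$rli), " subplots x ", length(x$heights),
      " heights [", min(x$heights), "-", max(x$heights), " m]\n", sep = "")
  invisible(x)
}

#' Fit the vertical light sigmoid for one subplot
#'
#' Thin wrapper around [fit_sigmoid()] with the light-profile contract:
#' relative light intensity in \[0, 100\] against measurement height, the
#' asymptote fixed at 100, and the positive-slope requirement (light must
#' decrease towards the ground).
#'
#' @param heights Measurement heights (m), at least 4.
#' @param rli Relative light intensity (percent) at those heights.
#' @return A `sigmoid_fit` whose `b` is the HIP and `a` the attenuation rate.
#' @export
fit_light_sigmoid <- function(heights, rli) {
  if (any(rli < 0 | rli > 100)) stop("rli must lie in [0, 100]")
  fit_sigmoid(heights, rli, asym = 100)
}

#' Light attenuation rate of a fitted profile
#'
#' Accessor with a contract: the attenuation rate is the sigmoid slope
#' parameter `a` at the inflection point, defined only for a converged fit.
#'
#' @param fit A `sigmoid_fit`.
#' @return `a` (per m).
#' @export
attenuation_rate <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!isTRUE(fit$converged))
    stop("attenuation rate undefined: fit did not converge (", fit$message, ")")
  fit$a
}

#' Relative height of the inflection point
#'
#' Expresses the HIP as a percentage of the maximum canopy height of the
#' whole plot, making stands of different stature comparable. May exceed 100
#' when the fitted inflection sits above the tallest tree (extrapolated fit).
#'
#' @param b HIP (m).
#' @param max_canopy_height Height of the tallest tree in the plot (m), > 0.
#' @return Relative HIP (percent).
#' @export
relative_hip <- function(b, max_canopy_height) {
  if (any(!is.finite(max_canopy_height)) || any(max_canopy_height <= 0))
    stop("max canopy height must be positive")
  100 * b / max_canopy_height
}

#' Understorey relative light intensity
#'
#' The raw measurements at 1 m — the closest level to the forest floor where
#' seeds germinate — not the fitted curve.
#'
#' @param grid A [light_grid()] that includes a 1 m level.
#' @param height Understorey reference height (m, default 1).
#' @return List with `per_subplot` (percent, one per subplot) and `mean`.
#' @export
understorey_rli <- function(grid, height = 1) {
  stopifnot(inherits(grid, "light_grid"))
  j <- match(height, grid$heights)
  if (is.na(j)) stop("no measurement at ", height, " m in this grid")
  v <- grid$rli[, j]
  list(per_subplot = v, mean = mean(v))
}

#' Horizontal light heterogeneity profile
#'
#' At each reference height, the horizontal light heterogeneity (HLH) is the
#' sample standard deviation of relative light intensity across the subplots.
#' The profile's peak marks the height where the canopy is patchiest; ties
#' resolve to the lowest height.
#'
#' @param grid A [light_grid()] with at least 2 subplots.
#' @param max_canopy_height Tallest tree of the plot (m), used to relativize
#'   the peak height.
#' @return An `hlh_profile`: list with `heights`, `hlh` (percent points),
#'   `peak_height_abs` (m), `peak_height_rel` (percent of canopy height),
#'   `hlh_at_1m`, and ids.
#' @export
hlh_profile <- function(grid, max_canopy_height) {
  stopifnot(inherits(grid, "light_grid"))
  if (nrow(grid$rli) < 2)
    stop("HLH undefined with a single subplot")
  hlh <- apply(grid$rli, 2, stats::sd)
  peak <- grid$heights[which.max(hlh)]   # which.max: first (lowest) on ties
  structure(list(
    plot_id = grid$plot_id, age = grid$age,
    heights = grid$heights, hlh = unname(hlh),
    peak_height_abs = peak,
    peak_height_rel = relative_hip(peak, max_canopy_height),
    hlh_at_1m = if (1 %in% grid$heights)
      unname(hlh[match(1, grid$heights)]) else NA_real_),
    class = "hlh_profile")
}

#' @export
print.hlh_profile <- function(x, ...) {
  cat("HLH profile: plot ", format(x$plot_id),
      sprintf(" | peak %.1f m (%.1f%% of canopy) | HLH at 1 m: %.2f\n",
              x$peak_height_abs, x$peak_height_rel, x$hlh_at_1m), sep = "")
  invisible(x)
}

#' Plot-level vertical light summary
#'
#' Fits the light sigmoid in every subplot of a grid and averages HIP,
#' relative HIP and attenuation rate over the converged, non-degenerate fits
#' (failed or degenerate subplots are excluded and counted). The maximum
#' canopy height is the tallest tree of the whole plot, because light in a
#' subplot is shaped by neighbouring trees rooted elsewhere.
#'
#' @param grid A [light_grid()].
#' @param inv The matching [stand_inventory()] (source of the maximum canopy
#'   height), or a positive number giving that height directly.
#' @return A `vertical_light_summary`: list with per-subplot `fits`,
#'   `mean_hip` (m), `mean_relative_hip` (percent), `mean_attenuation_rate`
#'   (per m), `rli_at_1m_mean` (percent), `max_canopy_height` (m), and
#'   `n_excluded` (subplots whose fit failed or was degenerate).
#' @export
summarize_plot <- function(grid, inv) {
  stopifnot(inherits(grid, "light_grid"))
  max_h <- if (inherits(inv, "stand_inventory")) {
    if (nrow(inv) == 0) stop("empty inventory: no canopy height")
    max(inv$height)
  } else {
    as.numeric(inv)
  }
  if (!is.finite(max_h) || max_h <= 0) stop("max canopy height must be positive")

  fits <- lapply(seq_len(nrow(grid$rli)), function(i)
    fit_light_sigmoid(grid$heights, grid$rli[i, ]))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no subplot light fit converged for plot ",
                     format(grid$plot_id))
  b <- vapply(fits[ok], `[[`, numeric(1), "b")
  a <- vapply(fits[ok], `[[`, numeric(1), "a")
  structure(list(
    plot_id = grid$plot_id, age = grid$age, fits = fits,
    mean_hip = mean(b),
    mean_relative_hip = mean(relative_hip(b, max_h)),
    mean_attenuation_rate = mean(a),
    rli_at_1m_mean = understorey_rli(grid)$mean,
    max_canopy_height = max_h,
    n_excluded = sum(!ok)),
    class = "vertical_light_summary")
}

#' @export
print.vertical_light_summary <- function(x, ...) {
  cat("Vertical light summary: plot ", format(x$plot_id), " (age ",
      format(x$age), " yr)\n", sep = "")
  cat(sprintf("  mean HIP: %.2f m (%.1f%% of %.1f m canopy)\n",
              x$mean_hip, x$mean_relative_hip, x$max_canopy_height))
  cat(sprintf("  mean attenuation rate: %.3f per m\n", x$mean_attenuation_rate))
  cat(sprintf("  mean RLI at 1 m: %.2f%%\n", x$rli_at_1m_mean))
  if (x$n_excluded > 0)
    cat("  ", x$n_excluded, " subplot fit(s) excluded\n", sep = "")
  invisible(x)
}
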