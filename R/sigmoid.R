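#' Logistic sigmoid light-profile value
#'
#' Evaluates the two-parameter logistic sigmoid
#' \deqn{Y = A / (1 + \exp(-a (x - b)))}
#' used to describe vertical profiles of relative light intensity (RLI) and
#' cumulative forest structural attributes. `a` is the slope at the inflection
#' point (the light attenuation rate when fitted to an RLI profile) and `b` is
#' the height of the inflection point (HIP), the height where the curve equals
#' half of the asymptote `A` (50% RLI for the default `asym = 100`).
#'
#' @param x Height (m), possibly a vector.
#' @param a Slope at the inflection point (per m).
#' @param b Height of the inflection point (m).
#' @param asym Upper asymptote (default 100, i.e. full above-canopy light).
#' @return Numeric vector of curve values in `(0, asym)`.
#' @export
#' @examples
#' sigmoid_curve(10, a = 0.96, b = 10)  # exactly 50 at x = b
sigmoid_curve <- function(x, a, b, asym = 100) {
  asym / (1 + exp(-a * (x - b)))
}

#' Fit the logistic sigmoid to a vertical profile
#'
#' Fits \eqn{Y = 100 / (1 + \exp(-a (x - b)))} to a profile of relative light
#' intensity (or cumulative structure, in percent) against height by bounded
#' nonlinear least squares. The asymptote is fixed at 100 so that predictions
#' stay within the physically meaningful 0--100% band.
#'
#' The fitting protocol is: initial `b` is the height where the profile first
#' crosses 50 (by linear interpolation between bracketing measurement heights,
#' falling back to the mid-range when the profile never crosses 50); initial
#' `a` is `4 / diff(range(x))`; parameters are bounded to
#' `a` in \[1e-3, 20\] and `b` in \[0, 2 max(x)\]; up to five restarts from
#' deterministically perturbed initial values are attempted and the converged
#' fit with the lowest residual sum of squares is kept; the parameter
#' tolerance is 1e-8.
#'
#' A fit is rejected (`converged = FALSE`) when the optimizer fails on every
#' restart or when the estimated slope is pinned at the lower bound, which is
#' how a profile that increases *downward* (negative true slope) manifests
#' under the positivity bound. A near-constant profile (range of `y` below
#' 1 percent point) is flagged degenerate and not fitted.
#'
#' @param x Measurement heights (m), at least 4 distinct values.
#' @param y Profile values in percent (same length as `x`).
#' @param asym Fixed upper asymptote (default 100).
#' @param max_restarts Maximum number of perturbed restarts after the first
#'   attempt (default 5).
#' @return An object of class `sigmoid_fit`: a list with elements `a`, `b`,
#'   `rss`, `converged`, `degenerate`, `extrapolated` (`b > max(x)`),
#'   `message`, and the data used. Methods: [coef.sigmoid_fit()],
#'   [predict.sigmoid_fit()], [residuals.sigmoid_fit()], `fitted`, `print`,
#'   `summary`, `plot`.
#' @seealso [attenuation_rate()], [relative_hip()]
#' @export
#' @examples
#' h <- 1:22
#' rli <- sigmoid_curve(h, a = 1, b = 10)
#' fit <- fit_sigmoid(h, rli)
#' coef(fit)
#' predict(fit, newdata = coef(fit)[["b"]])  # 50 by construction
fit_sigmoid <- function(x, y, asym = 100, max_restarts = 5) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct heights to fit the sigmoid")

  out <- structure(
    list(a = NA_real_, b = NA_real_, asym = asym, rss = NA_real_,
         converged = FALSE, degenerate = FALSE, extrapolated = FALSE,
         message = "", x = x, y = y),
    class = "sigmoid_fit")

  if (diff(range(y)) < 1) {
    out$degenerate <- TRUE
    out$message <- "near-constant profile (range < 1 percent point)"
    return(out)
  }

  half <- asym / 2
  b0 <- .init_half_crossing(x, y, half)
  a0 <- 4 / diff(range(x))
  lower <- c(a = 1e-3, b = 0)
  upper <- c(a = 20, b = 2 * max(x))
  # deterministic perturbation schedule (no RNG: fits must not disturb the
  # caller's random-number stream)
  a_mult <- c(1, 0.5, 2, 0.25, 4, 8)
  b_mult <- c(1, 0.7, 1.3, 0.4, 1.6, 1)

  best <- NULL
  n_try <- min(max_restarts + 1L, length(a_mult))
  for (i in seq_len(n_try)) {
    st <- c(a = min(max(a0 * a_mult[i], lower[1]), upper[1]),
            b = min(max(b0 * b_mult[i], lower[2]), upper[2]))
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ asym / (1 + exp(-a * (x - b))),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ptol = 1e-8, ftol = 1e-8, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(cand)) next
    rss <- sum(stats::residuals(cand)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = cand, rss = rss)
    if (rss < 1e-16) break
  }

  if (is.null(best)) {
    out$message <- "no restart converged"
    return(out)
  }
  cf <- stats::coef(best$fit)
  if (cf[["a"]] <= lower[["a"]] * (1 + 1e-6)) {
    # slope pinned at the positivity bound: the profile wants a non-positive
    # slope (light increasing downward) and the fit is rejected
    out$message <- "slope at lower bound; non-increasing profile rejected"
    return(out)
  }
  out$a <- unname(cf[["a"]])
  out$b <- unname(cf[["b"]])
  out$rss <- best$rss
  out$converged <- TRUE
  out$extrapolated <- out$b > max(x)
  out
}

# height where the profile first crosses `half`, scanning upward from the
# lowest height; linear interpolation between the bracketing measurements
.init_half_crossing <- function(x, y, half) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  below <- y < half
  cross <- which(below[-length(y)] != below[-1])
  if (length(cross) == 0) return(mean(range(x)))
  i <- cross[1]
  x0 <- x[i]; x1 <- x[i + 1]; y0 <- y[i]; y1 <- y[i + 1]
  if (y1 == y0) return((x0 + x1) / 2)
  x0 + (half - y0) * (x1 - x0) / (y1 - y0)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' Predict from a fitted sigmoid profile
#'
#' @param object A `sigmoid_fit`.
#' @param newdata Heights (m) at which to evaluate the fitted curve; defaults
#'   to the heights used in fitting.
#' @param ... Unused.
#' @return Predicted profile values (percent).
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed sigmoid fit")
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  sigmoid_curve(x, object$a, object$b, object$asym)
}

#' @export
fitted.sigmoid_fit <- function(object, ...) predict(object)

#' @export
residuals.sigmoid_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Logistic sigmoid profile fit (asymptote fixed at ",
      format(x$asym), ")\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate: ", x$message, "\n", sep = "")
  } else if (!x$converged) {
    cat("  FAILED: ", x$message, "\n", sep = "")
  } else {
    cat(sprintf("  a (slope at inflection, per m): %.4f\n", x$a))
    cat(sprintf("  b (height of inflection, m):    %.4f%s\n", x$b,
                if (x$extrapolated) "  [extrapolated above measured range]" else ""))
    cat(sprintf("  RSS: %.4g on %d points\n", x$rss, length(x$x)))
  }
  invisible(x)
}

#' @export
summary.sigmoid_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.sigmoid_fit")
}

#' @export
print.summary.sigmoid_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$converged) {
    r <- stats::residuals(x$fit)
    cat(sprintf("  residuals: min %.3f, median %.3f, max %.3f\n",
                min(r), stats::median(r), max(r)))
  }
  invisible(x)
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  graphics::plot(x$y, x$x, xlab = "Relative light intensity (%)",
                 ylab = "Height (m)", xlim = c(0, x$asym), ...)
  if (x$converged) {
    hh <- seq(min(x$x), max(x$x), length.out = 200)
    graphics::lines(sigmoid_curve(hh, x$a, x$b, x$asym), hh)
    graphics::abline(h = x$b, lty = 2)
  }
  invisible(x)
}
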