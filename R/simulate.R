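# run expr with a private RNG state seeded at `seed`; the caller's stream
# is untouched
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# deterministic per-age child seed: depends only on (master, age), so adding
# an age to the chronosequence never reshuffles the other plots
.child_seed <- function(master, age, stream = 0L) {
  (as.numeric(master) * 69069 + round(age) * 2654435 + stream * 97) %% 2147483647
}

#' Simulation configuration for a synthetic chronosequence
#'
#' Bundles the study design (14 stand ages spanning 8--32 years, 40 x 10 m
#' plots with 16 subplots of 5 x 5 m, light measured at 1 m steps from 1 to
#' 22 m) with the allometric and optical constants of the generator. The
#' calibration constants live in a plain-text YAML file shipped with the
#' package (`inst/extdata/default_config.yaml`); any value can be overridden
#' through `...`.
#'
#' @param ages Stand ages (years); default 14 values spanning 8--32.
#' @param seed Master seed; per-plot seeds are derived deterministically.
#' @param config_file YAML file of generator constants; defaults to the
#'   packaged file.
#' @param ... Named overrides for top-level entries (`allometry` and `light`
#'   may be given as partial lists; unnamed members keep their defaults).
#' @return A `sim_config` list with elements `ages`, `seed`, `plot_length`,
#'   `plot_width`, `n_subplots`, `heights`, `allometry`, `light`.
#' @export
sim_config <- function(ages = NULL, seed = 1,
                       config_file = system.file("extdata",
                                                 "default_config.yaml",
                                                 package = "canopylight"),
                       ...) {
  cfg <- yaml::read_yaml(config_file)
  if (!is.null(ages)) cfg$ages <- ages
  cfg$seed <- seed
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("allometry", "light") && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg$ages <- as.numeric(cfg$ages)
  cfg$heights <- as.numeric(cfg$heights[1]):as.numeric(cfg$heights[2])
  stopifnot(all(cfg$ages > 0))
  structure(cfg, class = "sim_config")
}

#' Simulate one secondary-forest stand
#'
#' Generates an individual-tree inventory for a stand of the given age.
#' Stem density declines with age (self-thinning); tree sizes follow a
#' reverse-J diameter distribution whose scale grows with age, so stands
#' differentiate: young stands are crowded with small, short-crowned trees
#' while older stands carry a few large-crowned canopy trees over many small
#' ones. Height follows a saturating height-diameter allometry with
#' lognormal scatter; crown width scales as a power of DBH; the crown
#' occupies a roughly constant fraction of tree height. A fraction of trees
#' is multi-stemmed; the inclusion rule (effective DBH > 1 cm) is applied by
#' [stand_inventory()].
#'
#' @param age Stand age (years).
#' @param config A [sim_config()].
#' @param seed Integer seed (default derived from the config master seed and
#'   the age).
#' @param plot_id Plot identifier (default `P<age>`).
#' @return A [stand_inventory()] (possibly empty, with a warning).
#' @export
simulate_stand <- function(age, config = sim_config(),
                           seed = .child_seed(config$seed, age),
                           plot_id = sprintf("P%02d", round(age))) {
  al <- config$allometry
  .with_seed(seed, {
    n <- stats::rpois(1, al$stems_init * exp(-al$thinning_rate * age))
    if (n == 0) {
      warning("empty stand simulated at age ", age)
      empty <- data.frame(x = numeric(), y = numeric(), height = numeric(),
                          crown_base = numeric(), crown_d1 = numeric(),
                          crown_d2 = numeric(), dbh = numeric())
      return(stand_inventory(empty, plot_id, age,
                             config$plot_length, config$plot_width))
    }
    # plot-level random effects: stands of the same age differ in their
    # size-distribution shape and in how crown ratio scales with tree size
    # (site-to-site scatter of a real chronosequence)
    shape_p <- al$dbh_weibull_shape * exp(stats::rnorm(1, 0, al$site_shape_sd))
    cr_slope_p <- stats::rnorm(1, 0, al$site_crown_slope_sd)
    scale_age <- max(al$dbh_scale_base + al$dbh_scale_rate * age, 0.2)
    d_eff <- 1 + stats::rweibull(n, shape_p, scale_age)
    # a fraction of trees is multi-stemmed; stems partition the squared
    # effective diameter so the combined DBH reproduces d_eff
    n_stems <- 1L + stats::rbinom(n, 2L, al$multi_stem_prob)
    stems <- lapply(seq_len(n), function(i) {
      k <- n_stems[i]
      if (k == 1) return(d_eff[i])
      w <- stats::rgamma(k, 2)
      sqrt(d_eff[i]^2 * w / sum(w))
    })
    # stand differentiation: height scatter around the allometry widens
    # with age, spreading the foliage over a deeper profile in old stands
    sd_h <- al$height_noise_sd + al$height_disp_rate * age
    height <- al$height_coef * d_eff^al$height_exp *
      exp(stats::rnorm(n, 0, sd_h))
    height <- pmin(pmax(height, 1.5), al$height_max)
    size_rank <- (rank(height, ties.method = "average") - 0.5) / n
    cr <- pmin(pmax(stats::rnorm(n, al$crown_ratio_mean, al$crown_ratio_sd) +
                      cr_slope_p * (size_rank - 0.5), 0.05), 0.95)
    cw <- al$crown_width_base + al$crown_width_coef * d_eff^al$crown_width_exp
    trees <- data.frame(
      x = stats::runif(n, 0, config$plot_length),
      y = stats::runif(n, 0, config$plot_width),
      height = height,
      crown_base = height * (1 - cr),
      crown_d1 = cw * exp(stats::rnorm(n, 0, al$crown_width_noise_sd)),
      crown_d2 = cw * exp(stats::rnorm(n, 0, al$crown_width_noise_sd)))
    trees$stem_diameters <- stems
    stand_inventory(trees, plot_id, age,
                    config$plot_length, config$plot_width)
  })
}

#' Vertical path length through one tree crown
#'
#' Crowns are modelled as vertical elliptic cylinders spanning the crown
#' length, with semi-axes half the two crown diameters, centred on the stem.
#' The function returns how much of the vertical ray above `from_height`
#' lies inside the crown: zero when the column misses the elliptical
#' footprint, otherwise the overlap of `[max(from_height, crown_base),
#' height]`.
#'
#' @param tree A list or one-row data frame with `x`, `y`, `height`,
#'   `crown_base`, `crown_d1`, `crown_d2`.
#' @param column_x,column_y Coordinates of the vertical measurement column
#'   (m).
#' @param from_height Lower end of the ray (m).
#' @return Path length inside the crown (m, `>= 0`).
#' @export
crown_path_length <- function(tree, column_x, column_y, from_height) {
  r1 <- tree$crown_d1 / 2
  r2 <- tree$crown_d2 / 2
  if (r1 <= 0 || r2 <= 0) return(0)
  if (((column_x - tree$x) / r1)^2 + ((column_y - tree$y) / r2)^2 > 1)
    return(0)
  max(0, tree$height - max(from_height, tree$crown_base))
}

# path lengths for all trees of `inv` through the column at (cx, cy), for a
# vector of from-heights; returns total path per height (vectorized form of
# crown_path_length summed over trees)
.column_paths <- function(inv, cx, cy, heights) {
  if (nrow(inv) == 0) return(numeric(length(heights)))
  r1 <- inv$crown_d1 / 2
  r2 <- inv$crown_d2 / 2
  inside <- r1 > 0 & r2 > 0 &
    ((cx - inv$x) / r1)^2 + ((cy - inv$y) / r2)^2 <= 1
  if (!any(inside)) return(numeric(length(heights)))
  top <- inv$height[inside]
  base <- inv$crown_base[inside]
  vapply(heights, function(h) sum(pmax(0, top - pmax(h, base))),
         numeric(1))
}

#' Subplot-centre coordinates of the measurement grid
#'
#' @param config A [sim_config()].
#' @return Data frame with `subplot` (0--15), `x`, `y` (m), matching the
#'   indexing of [subplot_index()].
#' @export
subplot_centers <- function(config = sim_config()) {
  ncol_cells <- as.integer(config$plot_length / 5)
  idx <- 0:(config$n_subplots - 1)
  data.frame(subplot = idx,
             x = 2.5 + 5 * (idx %% ncol_cells),
             y = 2.5 + 5 * (idx %/% ncol_cells))
}

#' Simulate the light grid of a stand
#'
#' Beer-Lambert light field: at each subplot centre and measurement height
#' `h`, the optical depth is `tau = k * lad * sum(crown path lengths above
#' h)` and the noiseless relative light intensity is
#' `100 * (eps + (1 - eps) * exp(-tau))`, where `eps` is a diffuse floor
#' standing in for lateral diffuse light. Multiplicative lognormal
#' measurement noise (mean 1) is applied and values are clipped to
#' \[0, 100\].
#'
#' @param inv A [stand_inventory()].
#' @param config A [sim_config()] (source of the optical constants and the
#'   measurement design).
#' @param seed Integer seed (default derived from the config master seed and
#'   the stand age).
#' @param noise Apply measurement noise (default `TRUE`); `FALSE` gives the
#'   deterministic field.
#' @return A [light_grid()].
#' @export
simulate_light_grid <- function(inv, config = sim_config(),
                                seed = .child_seed(config$seed,
                                                   attr(inv, "age"), 1L),
                                noise = TRUE) {
  lp <- config$light
  centers <- subplot_centers(config)
  heights <- config$heights
  tau <- t(vapply(seq_len(nrow(centers)), function(i)
    lp$k * lp$lad_multiplier *
      .column_paths(inv, centers$x[i], centers$y[i], heights),
    numeric(length(heights))))
  rli <- 100 * (lp$epsilon + (1 - lp$epsilon) * exp(-tau))
  if (noise && lp$noise_sd > 0) {
    rli <- .with_seed(seed, {
      sdl <- lp$noise_sd
      rli * exp(stats::rnorm(length(rli), -sdl^2 / 2, sdl))
    })
  }
  rli <- pmin(pmax(rli, 0), 100)
  light_grid(rli, heights, plot_id = attr(inv, "plot_id"),
             age = attr(inv, "age"))
}

#' Simulate a full chronosequence
#'
#' One stand and one light grid per configured age, with per-age seeds
#' derived deterministically from the master seed (adding an age never
#' changes the other plots). Optionally writes the inventory and light CSV
#' files.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, `inventory.csv` and
#'   `light.csv` are written there via [write_inventory()] and
#'   [write_light()].
#' @return A named list (one element per age) of lists with `inventory` and
#'   `grid`.
#' @export
simulate_chronosequence <- function(config = sim_config(), out_dir = NULL) {
  out <- lapply(config$ages, function(age) {
    inv <- simulate_stand(age, config)
    list(inventory = inv, grid = simulate_light_grid(inv, config))
  })
  names(out) <- vapply(out, function(p) attr(p$inventory, "plot_id"), "")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_inventory(lapply(out, `[[`, "inventory"),
                    file.path(out_dir, "inventory.csv"))
    write_light(lapply(out, `[[`, "grid"), file.path(out_dir, "light.csv"))
  }
  out
}
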