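#' Structural and light metrics for one plot
#'
#' Computes the per-plot quantities of the analysis: structural totals and
#' their horizontal CVs, the sigmoid HIP and slope of each cumulative
#' structural profile, the vertical light summary and the horizontal light
#' heterogeneity descriptors.
#'
#' @param inv A [stand_inventory()].
#' @param grid The matching [light_grid()].
#' @return One-row data frame of plot metrics (NA where a structure fit
#'   failed), plus the count of excluded subplot light fits.
#' @export
plot_metrics <- function(inv, grid) {
  tot <- stand_totals(inv)
  cvs <- vapply(c(.structural_attributes, "tree_count"), function(at)
    tryCatch(structural_cv(inv, at), error = function(e) NA_real_),
    numeric(1))
  names(cvs) <- paste0("cv_", names(cvs))

  sf <- lapply(.structural_attributes, function(at) {
    f <- tryCatch(fit_structure_sigmoid(cumulative_profile(inv, at)),
                  error = function(e) NULL)
    if (is.null(f) || !isTRUE(f$converged))
      c(hip = NA_real_, slope = NA_real_)
    else c(hip = f$b, slope = f$a)
  })
  sf <- unlist(sf)
  names(sf) <- as.vector(outer(c("hip_", "slope_"), .structural_attributes,
                               paste0))

  vl <- summarize_plot(grid, inv)
  hh <- hlh_profile(grid, vl$max_canopy_height)

  cbind(tot,
        as.data.frame(as.list(cvs)),
        as.data.frame(as.list(sf)),
        data.frame(mean_hip = vl$mean_hip,
                   mean_relative_hip = vl$mean_relative_hip,
                   mean_attenuation_rate = vl$mean_attenuation_rate,
                   rli_1m = vl$rli_at_1m_mean,
                   hlh_peak_abs = hh$peak_height_abs,
                   hlh_peak_rel = hh$peak_height_rel,
                   hlh_1m = hh$hlh_at_1m,
                   n_excluded_fits = vl$n_excluded))
}

#' Per-subplot light metrics for one plot
#'
#' The subplot-level replicates behind the plot means: HIP, relative HIP and
#' attenuation rate from each converged subplot fit, and the raw 1 m RLI.
#'
#' @param inv A [stand_inventory()].
#' @param grid The matching [light_grid()].
#' @return Data frame with one row per converged subplot fit.
#' @export
subplot_metrics <- function(inv, grid) {
  vl <- summarize_plot(grid, inv)
  ok <- vapply(vl$fits, function(f) isTRUE(f$converged), logical(1))
  b <- vapply(vl$fits[ok], `[[`, numeric(1), "b")
  a <- vapply(vl$fits[ok], `[[`, numeric(1), "a")
  u <- understorey_rli(grid)$per_subplot
  data.frame(plot_id = vl$plot_id, age = vl$age,
             subplot = (seq_along(vl$fits) - 1L)[ok],
             hip = b, relative_hip = relative_hip(b, vl$max_canopy_height),
             attenuation_rate = a, rli_1m = u[ok])
}

#' Analyse a chronosequence of stands and light grids
#'
#' @param plots List with one element per plot, each a list holding
#'   `inventory` and `grid` (the shape returned by
#'   [simulate_chronosequence()]).
#' @return List of class `chronosequence_analysis` with `plot_metrics` (one
#'   row per plot) and `subplot_metrics` (one row per converged subplot
#'   fit).
#' @export
analyze_chronosequence <- function(plots) {
  pm <- do.call(rbind, lapply(plots, function(p)
    plot_metrics(p$inventory, p$grid)))
  sm <- do.call(rbind, lapply(plots, function(p)
    subplot_metrics(p$inventory, p$grid)))
  rownames(pm) <- rownames(sm) <- NULL
  structure(list(plot_metrics = pm, subplot_metrics = sm),
            class = "chronosequence_analysis")
}

#' @export
print.chronosequence_analysis <- function(x, ...) {
  cat("Chronosequence analysis: ", nrow(x$plot_metrics), " plots, ages ",
      min(x$plot_metrics$age), "-", max(x$plot_metrics$age), " yr\n",
      sep = "")
  invisible(x)
}

# metrics whose replicates live at the subplot level
.subplot_level_metrics <- c("hip", "relative_hip", "attenuation_rate",
                            "rli_1m")
.plot_level_metrics <- c("mean_hip", "mean_relative_hip",
                         "mean_attenuation_rate", "rli_1m",
                         "hlh_peak_abs", "hlh_peak_rel", "hlh_1m",
                         "tree_count", "total_basal_area",
                         "total_crown_area", "total_crown_length",
                         "max_height")

#' Successional trends of the light and structure metrics
#'
#' Runs [trend_with_age()] for every light-heterogeneity descriptor:
#' subplot-replicated metrics (HIP, relative HIP, attenuation rate, RLI at
#' 1 m) use the mixed model with plot random intercepts; plot-level metrics
#' (HLH descriptors, structural totals) reduce to OLS — each with the
#' Mann-Kendall + Sen fallback when parametric assumptions fail.
#'
#' @param analysis A [analyze_chronosequence()] result.
#' @param fallback Passed to [trend_with_age()].
#' @return Data frame with one row per metric: method, slope, intercept,
#'   association, p-value.
#' @export
chronosequence_trends <- function(analysis,
                                  fallback = c("auto", "mk", "lmm")) {
  fallback <- match.arg(fallback)
  sm <- analysis$subplot_metrics
  pm <- analysis$plot_metrics
  one <- function(metric, values, ages, plots) {
    tr <- trend_with_age(values, ages, plots, fallback)
    data.frame(metric = metric, method = tr$method, slope = tr$slope,
               intercept = tr$intercept, association = tr$association,
               p_value = tr$p_value, n = tr$n)
  }
  rows <- c(
    lapply(.subplot_level_metrics, function(m)
      one(m, sm[[m]], sm$age, sm$plot_id)),
    lapply(setdiff(.plot_level_metrics,
                   c("mean_hip", "mean_relative_hip",
                     "mean_attenuation_rate", "rli_1m")),
           function(m) one(m, pm[[m]], pm$age, pm$plot_id)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the four light responses and their candidate structural predictor pools
.path_specs <- function(pm) {
  list(
    mean_hip = list(
      candidates = pm[, paste0("hip_", .structural_attributes)],
      log = FALSE, age_edge = FALSE),
    mean_attenuation_rate = list(
      candidates = pm[, paste0("slope_", .structural_attributes)],
      log = TRUE, age_edge = FALSE),
    rli_1m = list(
      candidates = pm[, c("tree_count", "total_basal_area",
                          "total_crown_area", "total_crown_length")],
      log = FALSE, age_edge = FALSE),
    hlh_1m = list(
      candidates = pm[, paste0("cv_", c(.structural_attributes,
                                        "tree_count"))],
      log = FALSE, age_edge = TRUE))
}

#' Path models linking age, forest structure and light
#'
#' For each of the four light descriptors (mean HIP, mean attenuation rate,
#' RLI at 1 m, HLH at 1 m) the two structural predictors are chosen by
#' [select_predictors()] from the matching candidate pool (structure HIPs,
#' structure slopes, plot totals, structure CVs respectively), then the
#' standardized [path_model()] is fitted on plot-level data. The
#' attenuation-rate model is fitted on log-transformed variables; the HLH
#' model carries a direct age edge.
#'
#' @param analysis A [analyze_chronosequence()] result.
#' @return Named list of [path_model()] results (entries are `NULL` with a
#'   warning when a response had too few complete cases).
#' @export
chronosequence_paths <- function(analysis) {
  pm <- analysis$plot_metrics
  specs <- .path_specs(pm)
  out <- lapply(names(specs), function(resp) {
    sp <- specs[[resp]]
    cand <- sp$candidates
    ok <- stats::complete.cases(cand, pm[[resp]], pm$age)
    if (sum(ok) < 5) {
      warning("too few complete cases for path model of ", resp)
      return(NULL)
    }
    cl <- vapply(names(cand), function(nm)
      stats::cor(cand[[nm]][ok], pm[[resp]][ok]), numeric(1))
    cb <- stats::cor(as.matrix(cand[ok, ]))
    first <- select_predictors(cl, cb)[1]
    # second predictor: weakest correlation with the first; if that pair is
    # still collinear, walk down the candidate order
    rest <- setdiff(names(cand), first)
    rest <- rest[order(abs(cb[rest, first]), rest)]
    fit <- NULL
    for (second in rest) {
      fit <- tryCatch(
        path_model(pm$age[ok], cand[[first]][ok], cand[[second]][ok],
                   pm[[resp]][ok],
                   names = c("age", first, second, resp),
                   log_transform = sp$log, include_age_edge = sp$age_edge),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      warning("no usable predictor pair for path model of ", resp)
    fit
  })
  names(out) <- names(specs)
  out
}

#' Run the full chronosequence pipeline
#'
#' Chains simulation (or file input), per-plot analysis, successional
#' trends and the four path models, writing tidy CSV outputs and a
#' plain-text run manifest recording the seed and any excluded subplot
#' fits. With a fixed seed the run is deterministic: repeated runs produce
#' numerically identical outputs.
#'
#' @param config A [sim_config()] (used when `inventory_csv` is `NULL`).
#' @param inventory_csv,light_csv Optional paths to field-format input CSVs;
#'   when given they replace simulation.
#' @param out_dir Output directory (created); `NULL` to skip writing.
#' @param fallback Trend fallback policy, see [trend_with_age()].
#' @return List of class `canopylight_run` with `plots`, `analysis`,
#'   `trends`, `paths`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), inventory_csv = NULL,
                         light_csv = NULL, out_dir = NULL,
                         fallback = "auto") {
  if (is.null(inventory_csv) != is.null(light_csv))
    stop("provide both inventory_csv and light_csv, or neither")
  plots <- if (is.null(inventory_csv)) {
    simulate_chronosequence(config)
  } else {
    invs <- read_inventory(inventory_csv)
    grids <- read_light(light_csv)
    ids <- names(invs)
    if (!setequal(ids, vapply(grids, `[[`, "", "plot_id")))
      stop("inventory and light files cover different plots")
    grids <- grids[match(ids, vapply(grids, `[[`, "", "plot_id"))]
    stats::setNames(
      lapply(seq_along(invs), function(i)
        list(inventory = invs[[i]], grid = grids[[i]])), ids)
  }
  analysis <- analyze_chronosequence(plots)
  trends <- chronosequence_trends(analysis, fallback)
  paths <- chronosequence_paths(analysis)

  manifest <- c(
    paste0("seed: ", if (is.null(inventory_csv)) config$seed else "NA (file input)"),
    paste0("package_version: ", as.character(utils::packageVersion("canopylight"))),
    paste0("n_plots: ", nrow(analysis$plot_metrics)),
    paste0("excluded_subplot_fits: ",
           sum(analysis$plot_metrics$n_excluded_fits)),
    paste0("fallback: ", fallback),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(d, f) {
      d[] <- lapply(d, function(col)
        if (is.numeric(col)) signif(col, 6) else col)
      utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
    }
    wcsv(analysis$plot_metrics, "plot_metrics.csv")
    wcsv(analysis$subplot_metrics, "subplot_metrics.csv")
    wcsv(trends, "trends.csv")
    pe <- do.call(rbind, lapply(names(paths), function(nm) {
      if (is.null(paths[[nm]])) return(NULL)
      cbind(response = nm, paths[[nm]]$edges,
            r_squared = paths[[nm]]$r_squared)
    }))
    if (!is.null(pe)) wcsv(pe, "path_edges.csv")
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  structure(list(plots = plots, analysis = analysis, trends = trends,
                 paths = paths, manifest = manifest),
            class = "canopylight_run")
}

#' @export
print.canopylight_run <- function(x, ...) {
  print(x$analysis)
  cat("Trends:\n")
  print(x$trends, digits = 3)
  invisible(x)
}
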