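#' Effective DBH of a multi-stemmed tree
#'
#' Collapses the stems of a multi-stemmed tree into a single effective
#' diameter at breast height: the square root of the sum of squared stem
#' diameters. This preserves total basal area, and reduces to the measured
#' diameter for a single-stemmed tree.
#'
#' @param stem_diameters Numeric vector of per-stem diameters at breast
#'   height (cm); non-empty, all positive.
#' @return Effective DBH (cm).
#' @export
#' @examples
#' combine_multistem_dbh(c(3, 4))  # 5
combine_multistem_dbh <- function(stem_diameters) {
  if (length(stem_diameters) == 0 || !is.numeric(stem_diameters))
    stop("stem_diameters must be a non-empty numeric vector")
  if (any(!is.finite(stem_diameters)) || any(stem_diameters <= 0))
    stop("all stem diameters must be positive and finite")
  sqrt(sum(stem_diameters^2))
}

#' Tree basal area from DBH
#'
#' @param dbh Diameter at breast height (cm); vectorized.
#' @return Basal area (cm^2), `0.25 * pi * dbh^2`.
#' @export
tree_basal_area <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh < 0)) stop("dbh must be non-negative")
  0.25 * pi * dbh^2
}

#' Tree crown area from two orthogonal crown diameters
#'
#' Ellipse area spanned by the north-south and east-west crown diameters.
#'
#' @param d1,d2 Orthogonal crown diameters (m); vectorized.
#' @return Crown area (m^2), `0.25 * pi * d1 * d2`.
#' @export
tree_crown_area <- function(d1, d2) {
  if (any(!is.finite(d1)) || any(!is.finite(d2)) || any(d1 < 0) || any(d2 < 0))
    stop("crown diameters must be non-negative")
  0.25 * pi * d1 * d2
}

#' Tree crown length
#'
#' @param height Total tree height (m); vectorized.
#' @param crown_base_height Height of the lowest live branch (m).
#' @return Crown length (m), `height - crown_base_height`.
#' @export
tree_crown_length <- function(height, crown_base_height) {
  if (any(!is.finite(height)) || any(!is.finite(crown_base_height)))
    stop("heights must be finite")
  if (any(crown_base_height < 0) || any(crown_base_height > height))
    stop("crown base must lie between the ground and the tree top")
  height - crown_base_height
}

#' Subplot index of a stem position
#'
#' Assigns a tree to one of the 16 subplots of the 40 x 10 m plot
#' (a grid of 5 x 5 m cells, 8 along the plot length and 2 across its
#' width). Cells are half-open, `[x0, x0 + 5) x [y0, y0 + 5)`, indexed
#' 0--15 row-major along the length. Stems rooted outside the plot get `NA`.
#'
#' @param x,y Stem base coordinates (m) within the plot.
#' @param plot_length,plot_width Plot dimensions (m); defaults 40 and 10.
#' @param cell Subplot cell size (m); default 5.
#' @return Integer subplot indices in 0--15 (or `NA` outside the plot).
#' @export
subplot_index <- function(x, y, plot_length = 40, plot_width = 10, cell = 5) {
  ncol_cells <- as.integer(plot_length / cell)
  idx <- floor(x / cell) + ncol_cells * floor(y / cell)
  idx[x < 0 | x >= plot_length | y < 0 | y >= plot_width] <- NA_integer_
  as.integer(idx)
}

#' Assemble a validated stand inventory
#'
#' Builds a `stand_inventory` object: a data frame with one row per tree
#' (DBH > 1 cm inclusion rule applied to the effective multi-stem DBH) plus
#' plot metadata. Trees rooted outside the plot are dropped with a warning.
#'
#' @param trees Data frame with columns `x`, `y` (stem coordinates, m),
#'   `height` (m), `crown_base` (m), `crown_d1`, `crown_d2` (m), and either
#'   `dbh` (cm) or a list-column `stem_diameters` of per-stem diameters (cm).
#'   An optional `tree_id` column is kept.
#' @param plot_id Plot identifier.
#' @param age Stand age (years since abandonment), positive.
#' @param plot_length,plot_width Plot dimensions (m).
#' @param min_dbh Inclusion threshold (cm); trees with effective DBH at or
#'   below it are excluded (default 1).
#' @return A `stand_inventory`: the tree table with derived columns
#'   `dbh`, `subplot`, `basal_area` (cm^2), `crown_area` (m^2),
#'   `crown_length` (m), and attributes `plot_id`, `age`, `plot_length`,
#'   `plot_width`.
#' @export
stand_inventory <- function(trees, plot_id, age,
                            plot_length = 40, plot_width = 10, min_dbh = 1) {
  stopifnot(is.data.frame(trees), age > 0)
  tr <- as.data.frame(trees)
  if (is.null(tr$dbh)) {
    if (is.null(tr$stem_diameters))
      stop("trees must carry either 'dbh' or 'stem_diameters'")
    tr$dbh <- vapply(tr$stem_diameters, combine_multistem_dbh, numeric(1))
  }
  if (nrow(tr) > 0) {
    with(tr, {
      if (any(height <= 0)) stop("tree heights must be positive")
      if (any(crown_base < 0 | crown_base > height))
        stop("crown base must lie between the ground and the tree top")
      if (any(crown_d1 < 0 | crown_d2 < 0))
        stop("crown diameters must be non-negative")
    })
  }
  tr$subplot <- subplot_index(tr$x, tr$y, plot_length, plot_width)
  if (nrow(tr) > 0 && anyNA(tr$subplot)) {
    warning(sum(is.na(tr$subplot)), " tree(s) rooted outside the plot excluded")
    tr <- tr[!is.na(tr$subplot), , drop = FALSE]
  }
  tr <- tr[tr$dbh > min_dbh, , drop = FALSE]
  if (is.null(tr$tree_id)) tr$tree_id <- seq_len(nrow(tr))
  tr$basal_area <- tree_basal_area(tr$dbh)
  tr$crown_area <- tree_crown_area(tr$crown_d1, tr$crown_d2)
  tr$crown_length <- tree_crown_length(tr$height, tr$crown_base)
  rownames(tr) <- NULL
  structure(tr, plot_id = plot_id, age = age,
            plot_length = plot_length, plot_width = plot_width,
            class = c("stand_inventory", "data.frame"))
}

.structural_attributes <- c("basal_area", "height", "crown_area", "crown_length")

# per-tree values of a named structural attribute
.tree_attribute <- function(inv, attribute) {
  attribute <- match.arg(attribute, .structural_attributes)
  inv[[attribute]]
}

#' Plot-level structural totals
#'
#' Counts trees (DBH > 1 cm rule already applied by [stand_inventory()]) and
#' sums basal area, crown area and crown length over the plot. An empty
#' inventory yields zero totals.
#'
#' @param inv A `stand_inventory`.
#' @return One-row data frame: `plot_id`, `age`, `tree_count`,
#'   `total_basal_area` (cm^2), `total_crown_area` (m^2),
#'   `total_crown_length` (m), `max_height` (m; 0 when empty).
#' @export
stand_totals <- function(inv) {
  stopifnot(inherits(inv, "stand_inventory"))
  data.frame(
    plot_id = attr(inv, "plot_id"),
    age = attr(inv, "age"),
    tree_count = nrow(inv),
    total_basal_area = sum(inv$basal_area),
    total_crown_area = sum(inv$crown_area),
    total_crown_length = sum(inv$crown_length),
    max_height = if (nrow(inv)) max(inv$height) else 0)
}

#' Horizontal heterogeneity of a structural attribute
#'
#' Coefficient of variation, `100 * SD / mean`, of the per-subplot totals of
#' a structural attribute over the 16 subplots (empty subplots contribute
#' zero). The sample SD (n - 1 denominator) is used: the subplots are treated
#' as a sample of the stand.
#'
#' @param inv A `stand_inventory`.
#' @param attribute One of `"basal_area"`, `"height"`, `"crown_area"`,
#'   `"crown_length"`, or `"tree_count"`.
#' @param n_subplots Number of subplot cells (default 16).
#' @return CV in percent.
#' @export
structural_cv <- function(inv, attribute, n_subplots = 16) {
  stopifnot(inherits(inv, "stand_inventory"))
  per_tree <- if (identical(attribute, "tree_count")) {
    rep(1, nrow(inv))
  } else {
    .tree_attribute(inv, attribute)
  }
  sums <- numeric(n_subplots)
  if (nrow(inv) > 0) {
    agg <- tapply(per_tree, factor(inv$subplot, levels = 0:(n_subplots - 1)), sum)
    agg[is.na(agg)] <- 0
    sums <- as.numeric(agg)
  }
  m <- mean(sums)
  if (m <= 0) stop("undefined CV: subplot mean is zero for ", attribute)
  100 * stats::sd(sums) / m
}

#' Cumulative vertical profile of a structural attribute
#'
#' Ranks trees in increasing order of height (ties keep input order) and
#' accumulates the attribute, expressed as percent of the plot total, against
#' tree height. This is the stand's vertical distribution of the attribute;
#' its sigmoid fit ([fit_structure_sigmoid()]) gives the height where most of
#' the attribute is concentrated (its HIP) and how steeply it accumulates.
#'
#' @param inv A `stand_inventory` with at least one tree.
#' @param attribute One of `"basal_area"`, `"height"`, `"crown_area"`,
#'   `"crown_length"`.
#' @return A `cumulative_profile`: data frame with `height` (m, ascending)
#'   and `cumulative_percent` (non-decreasing, ending at 100), with the
#'   attribute name stored as an attribute.
#' @export
cumulative_profile <- function(inv, attribute) {
  stopifnot(inherits(inv, "stand_inventory"))
  vals <- .tree_attribute(inv, attribute)
  if (nrow(inv) == 0 || sum(vals) <= 0)
    stop("degenerate profile: zero total ", attribute)
  o <- order(inv$height)           # stable: height ties keep input order
  structure(
    data.frame(height = inv$height[o],
               cumulative_percent = 100 * cumsum(vals[o]) / sum(vals)),
    attribute = attribute,
    class = c("cumulative_profile", "data.frame"))
}

#' Sigmoid fit of a cumulative structural profile
#'
#' Fits the same logistic sigmoid used for light profiles to a cumulative
#' structural curve. The fitted `b` is the HIP of the attribute (the height
#' below which half of the plot total lies) and `a` is the slope of its
#' accumulation at that height.
#'
#' @param profile A [cumulative_profile()].
#' @return A [fit_sigmoid()] object.
#' @export
fit_structure_sigmoid <- function(profile) {
  stopifnot(inherits(profile, "cumulative_profile"))
  if (length(unique(profile$height)) < 4)
    stop("need at least 4 distinct tree heights to fit the profile")
  fit_sigmoid(profile$height, profile$cumulative_percent)
}
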