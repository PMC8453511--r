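# canonical CSV dialects: '.' decimal separator, ',' field separator,
# floats at 6 significant digits

.inv_cols <- c("plot_id", "age_yr", "x_m", "y_m", "stem_diameters_cm",
               "height_m", "crown_base_m", "crown_d1_m", "crown_d2_m")

.fmt6 <- function(x) {
  if (is.numeric(x)) as.character(signif(x, 6)) else as.character(x)
}

#' Write stand inventories to the inventory CSV dialect
#'
#' One row per tree; multi-stem diameters are semicolon-joined in the
#' `stem_diameters_cm` field; floats carry 6 significant digits.
#'
#' @param invs A `stand_inventory` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(invs, path) {
  if (inherits(invs, "stand_inventory")) invs <- list(invs)
  rows <- lapply(invs, function(inv) {
    if (nrow(inv) == 0) return(NULL)
    stems <- if (!is.null(inv$stem_diameters)) {
      vapply(inv$stem_diameters,
             function(s) paste(signif(s, 6), collapse = ";"), "")
    } else {
      as.character(signif(inv$dbh, 6))
    }
    data.frame(plot_id = attr(inv, "plot_id"), age_yr = attr(inv, "age"),
               x_m = .fmt6(inv$x), y_m = .fmt6(inv$y),
               stem_diameters_cm = stems,
               height_m = .fmt6(inv$height),
               crown_base_m = .fmt6(inv$crown_base),
               crown_d1_m = .fmt6(inv$crown_d1),
               crown_d2_m = .fmt6(inv$crown_d2))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read stand inventories from the inventory CSV dialect
#'
#' All-or-nothing load with row-level validation: any malformed field or
#' invariant violation (non-positive height, crown base above the tree top,
#' negative crown diameter, non-positive stem diameter) aborts with a
#' message citing the offending data row.
#'
#' @param path CSV path conforming to the inventory dialect (header
#'   required).
#' @return Named list of [stand_inventory()] objects, one per plot.
#' @export
read_inventory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(sort(names(df)), sort(.inv_cols)))
    stop("malformed inventory header: expected columns ",
         paste(.inv_cols, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad) || anyNA(v))
      stop("non-numeric '", col, "' in inventory row(s) ",
           paste(utils::head(unique(c(bad, which(is.na(v)))), 5),
                 collapse = ", "))
    v
  }
  age <- num("age_yr"); x <- num("x_m"); y <- num("y_m")
  height <- num("height_m"); cb <- num("crown_base_m")
  d1 <- num("crown_d1_m"); d2 <- num("crown_d2_m")
  stems <- lapply(strsplit(df$stem_diameters_cm, ";", fixed = TRUE),
                  function(s) suppressWarnings(as.numeric(s)))
  for (i in seq_along(stems)) {
    s <- stems[[i]]
    if (length(s) == 0 || anyNA(s) || any(s <= 0))
      stop("invalid stem_diameters_cm in inventory row ", i)
    if (height[i] <= 0)
      stop("non-positive height in inventory row ", i)
    if (cb[i] < 0 || cb[i] > height[i])
      stop("crown base outside [0, height] in inventory row ", i)
    if (d1[i] < 0 || d2[i] < 0)
      stop("negative crown diameter in inventory row ", i)
  }
  out <- lapply(split(seq_len(nrow(df)), df$plot_id), function(rows) {
    ages <- unique(age[rows])
    if (length(ages) != 1)
      stop("plot ", df$plot_id[rows[1]], " has inconsistent ages")
    tr <- data.frame(x = x[rows], y = y[rows], height = height[rows],
                     crown_base = cb[rows], crown_d1 = d1[rows],
                     crown_d2 = d2[rows])
    tr$stem_diameters <- stems[rows]
    stand_inventory(tr, df$plot_id[rows[1]], ages)
  })
  out[order(vapply(out, function(i) attr(i, "age"), numeric(1)))]
}

#' Write light grids to the relativized light CSV dialect
#'
#' One row per plot x subplot x height with `rli_percent` at 6 significant
#' digits.
#'
#' @param grids A `light_grid` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_light <- function(grids, path) {
  if (inherits(grids, "light_grid")) grids <- list(grids)
  rows <- lapply(grids, function(g) {
    expand <- expand.grid(subplot = seq_len(nrow(g$rli)) - 1L,
                          height_m = g$heights)
    data.frame(plot_id = g$plot_id, age_yr = g$age,
               subplot = expand$subplot, height_m = expand$height_m,
               rli_percent = .fmt6(as.vector(g$rli)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read light grids from CSV (raw or relativized dialect)
#'
#' Auto-detects the dialect from the header: the raw dialect carries `ppfd`
#' and `reference_ppfd` columns and is passed through [relativize()]; the
#' relativized dialect carries `rli_percent`. A file carrying both is
#' rejected. Each plot must cover the full subplot x height crossing; any
#' missing cell aborts with the gap locations.
#'
#' @param path CSV path.
#' @return Named list of [light_grid()] objects, one per plot, ordered by
#'   age.
#' @export
read_light <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base_cols <- c("plot_id", "age_yr", "subplot", "height_m")
  if (!all(base_cols %in% names(df)))
    stop("malformed light header: need columns ",
         paste(base_cols, collapse = ", "))
  has_raw <- all(c("ppfd", "reference_ppfd") %in% names(df))
  has_rel <- "rli_percent" %in% names(df)
  if (has_raw && has_rel)
    stop("mixed light dialects: file carries both ppfd and rli_percent")
  if (!has_raw && !has_rel)
    stop("unknown light dialect: need ppfd + reference_ppfd or rli_percent")
  rli_all <- if (has_raw) relativize(df$ppfd, df$reference_ppfd)
             else as.numeric(df$rli_percent)
  if (anyNA(rli_all)) stop("non-numeric light values in ", path)

  out <- lapply(split(seq_len(nrow(df)), df$plot_id), function(rows) {
    heights <- sort(unique(df$height_m[rows]))
    subplots <- sort(unique(df$subplot[rows]))
    full <- expand.grid(subplot = subplots, height_m = heights)
    key <- paste(df$subplot[rows], df$height_m[rows])
    missing <- full[!paste(full$subplot, full$height_m) %in% key, ]
    if (nrow(missing) > 0)
      stop("incomplete light grid for plot ", df$plot_id[rows[1]],
           ": missing (subplot, height) cells ",
           paste(sprintf("(%s, %s)", missing$subplot, missing$height_m),
                 collapse = ", "))
    m <- matrix(NA_real_, length(subplots), length(heights))
    m[cbind(match(df$subplot[rows], subplots),
            match(df$height_m[rows], heights))] <- rli_all[rows]
    light_grid(m, heights, plot_id = df$plot_id[rows[1]],
               age = unique(df$age_yr[rows])[1])
  })
  out[order(vapply(out, function(g) g$age, numeric(1)))]
}
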