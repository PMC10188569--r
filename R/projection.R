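#' Project a fitted model onto a raster stack
#'
#' Predicts the cloglog suitability (or raw/link value) of every jointly
#' valid cell; nodata propagates.
#'
#' @param model a [maxent()] fit.
#' @param stack a [raster_stack()] supplying every model variable.
#' @param type output scale, see [predict.maxent()].
#' @param clamp clamp cell values to the training bounds.
#' @return a [raster_grid()] of predictions.
#' @export
project_map <- function(model, stack, type = "cloglog", clamp = model$clamp) {
  stopifnot(inherits(stack, "raster_stack"))
  missing <- setdiff(model$defs$variables, names(stack$layers))
  if (length(missing))
    stop(sprintf("stack lacks model variable layer(s): %s",
                 paste(missing, collapse = ", ")))
  ref <- stack$layers[[1]]
  out <- matrix(NA_real_, ref$nrows, ref$ncols)
  vals <- stack_cell_values(stack)
  if (nrow(vals))
    out[attr(vals, "cell_index")] <- predict(model, vals, type = type, clamp = clamp)
  raster_grid(out, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize,
              nodata = ref$nodata)
}

#' Cellwise unweighted mean of aligned suitability maps
#'
#' Used to average projections across climate-model (GCM) ensembles. A
#' cell is nodata in the result when any input map is nodata there.
#'
#' @param maps list of aligned [raster_grid()] objects.
#' @return a [raster_grid()].
#' @export
ensemble_mean <- function(maps) {
  if (!length(maps)) stop("ensemble_mean needs at least one map")
  ref <- maps[[1]]
  for (g in maps)
    if (g$nrows != ref$nrows || g$ncols != ref$ncols ||
        abs(g$xll - ref$xll) > 1e-9 || abs(g$yll - ref$yll) > 1e-9 ||
        abs(g$cellsize - ref$cellsize) > 1e-12)
      stop("ensemble maps are not aligned")
  acc <- Reduce(`+`, lapply(maps, function(g) g$values))
  raster_grid(acc / length(maps), xll = ref$xll, yll = ref$yll,
              cellsize = ref$cellsize, nodata = ref$nodata)
}

#' Classify a suitability map into five classes
#'
#' Breaks are multiples of the threshold: `(t, 2t, 3t, 4t)`, giving codes
#' 0 (unsuitable, `v < t`), 1 (low), 2 (moderate), 3 (optimum) and
#' 4 (high, `v >= 4t`). Explicit breaks may be supplied instead; the
#' multiple-of-t rule requires `0 < t < 0.25` so the top break stays
#' below 1.
#'
#' @param map cloglog suitability [raster_grid()] (values in `[0, 1]`).
#' @param t classification threshold (typically the training maxSSS
#'   threshold).
#' @param breaks optional explicit break vector (length 4, strictly
#'   increasing, in `(0, 1)`).
#' @return object of class `classified_map`: `grid` (codes 0-4 or
#'   nodata), `breaks`, `t`.
#' @export
classify_suitability <- function(map, t = NULL, breaks = NULL) {
  stopifnot(inherits(map, "raster_grid"))
  if (is.null(breaks)) {
    if (is.null(t)) stop("supply a threshold t or explicit breaks")
    if (t <= 0 || t >= 0.25)
      stop("t must lie in (0, 0.25) so that the break 4t stays below 1")
    breaks <- t * (1:4)
  } else {
    if (length(breaks) != 4 || any(diff(breaks) <= 0) ||
        breaks[1] <= 0 || breaks[4] >= 1)
      stop("breaks must be 4 strictly increasing values in (0, 1)")
    if (is.null(t)) t <- breaks[1]
  }
  v <- map$values
  codes <- matrix(NA_real_, map$nrows, map$ncols)
  fin <- is.finite(v)
  codes[fin] <- findInterval(v[fin], breaks)
  structure(list(grid = raster_grid(codes, xll = map$xll, yll = map$yll,
                                    cellsize = map$cellsize, nodata = map$nodata),
                 breaks = breaks, t = t),
            class = "classified_map")
}

#' @export
print.classified_map <- function(x, ...) {
  cat(sprintf("classified_map: breaks (%s), t = %g\n",
              paste(sprintf("%.4g", x$breaks), collapse = ", "), x$t))
  tab <- table(factor(x$grid$values, levels = 0:4))
  cat("  cells per class (0=unsuitable .. 4=high):",
      paste(as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

# km^2 area of each cell of a geographic grid, by matrix row: a cell in
# the latitude band [phi1, phi2] spans R^2 * dlon_rad * (sin phi2 - sin phi1)
cell_area_by_row <- function(grid, radius_km = 6371.0088) {
  i <- seq_len(grid$nrows)                     # row 1 = north
  lat_top <- grid$yll + (grid$nrows - i + 1) * grid$cellsize
  lat_bot <- lat_top - grid$cellsize
  radius_km^2 * (grid$cellsize * pi / 180) *
    (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
}

#' Per-class area of a classified map
#'
#' Spherical-Earth cell areas (authalic radius 6371.0088 km): a cell in
#' latitude band `[phi1, phi2]` with width `dlon` radians covers
#' `R^2 dlon (sin phi2 - sin phi1)` km^2. Nodata cells are excluded from
#' all classes and from the total.
#'
#' @param classified a [classify_suitability()] result (or a bare code
#'   [raster_grid()]).
#' @param radius_km spherical Earth radius in km.
#' @return data frame with `class` (0-4), `label`, `area_km2`; total land
#'   area in attribute `total_km2`.
#' @export
class_areas <- function(classified, radius_km = 6371.0088) {
  grid <- if (inherits(classified, "classified_map")) classified$grid else classified
  a_row <- cell_area_by_row(grid, radius_km)
  area_mat <- matrix(a_row, grid$nrows, grid$ncols)
  labels <- c("unsuitable", "low", "moderate", "optimum", "high")
  areas <- vapply(0:4, function(k)
    sum(area_mat[which(grid$values == k)]), numeric(1))
  out <- data.frame(class = 0:4, label = labels, area_km2 = areas)
  attr(out, "total_km2") <- sum(area_mat[is.finite(grid$values)])
  out
}

#' Decimal half-up rounding
#'
#' Rounds half away from zero on the decimal representation (0.1945 to
#' three decimals is 0.195), the convention used when reporting
#' classification break values; base [round()] rounds half to even. A tiny
#' epsilon guards against binary representation error.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-class percentage change between two area tables
#'
#' `denominator = "present"` gives `100 (A_f - A_p) / A_p` (positive =
#' expansion); `"future"` gives `100 (A_f - A_p) / A_f`. A class empty in
#' the denominator scenario but occupied in the other reports `Inf` rather
#' than a number.
#'
#' @param present,future [class_areas()] tables with the same class
#'   scheme.
#' @param denominator `"present"` or `"future"`.
#' @return data frame with `class`, `label`, `change_pct`; the convention
#'   is recorded in attribute `denominator`.
#' @export
change_table <- function(present, future, denominator = c("present", "future")) {
  denominator <- match.arg(denominator)
  if (!identical(present$class, future$class))
    stop("area tables use different class schemes")
  den <- if (denominator == "present") present$area_km2 else future$area_km2
  diff <- future$area_km2 - present$area_km2
  pct <- ifelse(den > 0, 100 * diff / den, ifelse(diff == 0, 0, Inf * sign(diff)))
  out <- data.frame(class = present$class, label = present$label,
                    change_pct = pct)
  attr(out, "denominator") <- denominator
  out
}
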