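#' Construct a raster grid
#'
#' A `raster_grid` is a single gridded layer in geographic (WGS84 degree)
#' coordinates with square cells, row 1 being the northernmost row. Missing
#' cells are stored as `NA` internally; `nodata` records the sentinel used
#' on disk.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid
#'   (degrees).
#' @param cellsize cell edge length in degrees; cells are square.
#' @param nodata numeric sentinel written for missing cells.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!(is.numeric(cellsize) && length(cellsize) == 1L && cellsize > 0))
    stop("cellsize must be a single positive number")
  values[!is.finite(values)] <- NA_real_
  structure(list(nrows = nrow(values), ncols = ncol(values),
                 xll = as.numeric(xll), yll = as.numeric(yll),
                 cellsize = as.numeric(cellsize), nodata = as.numeric(nodata),
                 values = values),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g deg\n", x$nrows, x$ncols, x$cellsize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              x$xll, x$xll + x$ncols * x$cellsize,
              x$yll, x$yll + x$nrows * x$cellsize))
  v <- x$values[is.finite(x$values)]
  cat(sprintf("  valid cells: %d/%d", length(v), x$nrows * x$ncols))
  if (length(v)) cat(sprintf("; range [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line ESRI ASCII header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`) followed by row-major cell values, northernmost row
#' first. The `*center` dialect is converted to corner coordinates by
#' subtracting half a cell. Cells equal to the NODATA sentinel (and any
#' non-finite values) become `NA`.
#'
#' @param path path to a `.asc` file.
#' @return a [raster_grid()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list(); i <- 1L
  repeat {
    if (i > length(lines)) break
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- tok[2]; i <- i + 1L
    } else break
  }
  need1 <- c("ncols", "nrows", "cellsize")
  for (k in need1) if (is.null(hdr[[k]]))
    stop(sprintf("malformed ESRI ASCII header: missing key '%s'", k))
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  cellsize <- as.numeric(hdr$cellsize)
  if (is.na(ncols) || is.na(nrows) || is.na(cellsize))
    stop("malformed ESRI ASCII header: non-numeric ncols/nrows/cellsize")
  if (!is.null(hdr$xllcorner)) xll <- as.numeric(hdr$xllcorner)
  else if (!is.null(hdr$xllcenter)) xll <- as.numeric(hdr$xllcenter) - cellsize / 2
  else stop("malformed ESRI ASCII header: missing key 'xllcorner'")
  if (!is.null(hdr$yllcorner)) yll <- as.numeric(hdr$yllcorner)
  else if (!is.null(hdr$yllcenter)) yll <- as.numeric(hdr$yllcenter) - cellsize / 2
  else stop("malformed ESRI ASCII header: missing key 'yllcorner'")
  nodata <- if (!is.null(hdr$nodata_value)) as.numeric(hdr$nodata_value) else -9999

  data_lines <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  if (length(data_lines) != nrows)
    stop(sprintf("expected %d data rows, found %d", nrows, length(data_lines)))
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    row <- as.numeric(strsplit(trimws(data_lines[r]), "\\s+")[[1]])
    if (length(row) != ncols)
      stop(sprintf("row %d has %d values, expected %d", r, length(row), ncols))
    vals[r, ] <- row
  }
  vals[!is.finite(vals) | vals == nodata] <- NA_real_
  raster_grid(vals, xll = xll, yll = yll, cellsize = cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_esri_ascii()]: header integers round-trip exactly and
#' cell values to better than 1e-10 relative precision.
#'
#' @param grid a [raster_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))
  hdr <- c(sprintf("ncols %d", grid$ncols),
           sprintf("nrows %d", grid$nrows),
           sprintf("xllcorner %.15g", grid$xll),
           sprintf("yllcorner %.15g", grid$yll),
           sprintf("cellsize %.15g", grid$cellsize),
           sprintf("NODATA_value %.15g", grid$nodata))
  writeLines(hdr, con)
  v <- grid$values
  v[!is.finite(v)] <- grid$nodata
  for (r in seq_len(grid$nrows))
    writeLines(paste(sprintf("%.15g", v[r, ]), collapse = " "), con)
  invisible(path)
}

#' Bundle aligned raster layers into a stack
#'
#' All layers must share grid geometry (`nrows`, `ncols`, origin, cellsize).
#' A cell is *valid* only where no layer is missing.
#'
#' @param layers named list of [raster_grid()] objects.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  if (inherits(layers, "raster_grid")) layers <- list(layer = layers)
  if (!length(layers)) stop("raster_stack needs at least one layer")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("layer", seq_along(layers))
  ref <- layers[[1]]
  for (nm in names(layers)) {
    g <- layers[[nm]]
    if (!inherits(g, "raster_grid")) stop(sprintf("layer '%s' is not a raster_grid", nm))
    if (g$nrows != ref$nrows || g$ncols != ref$ncols ||
        abs(g$xll - ref$xll) > 1e-9 || abs(g$yll - ref$yll) > 1e-9 ||
        abs(g$cellsize - ref$cellsize) > 1e-12)
      stop(sprintf("layer '%s' is not aligned with the first layer", nm))
  }
  structure(list(layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  ref <- x$layers[[1]]
  cat(sprintf("raster_stack: %d layers, %d x %d cells\n",
              length(x$layers), ref$nrows, ref$ncols))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname raster_stack
#' @param x a `raster_stack`.
#' @export
n_layers <- function(x) length(x$layers)

#' Jointly valid cells of a stack
#'
#' @param stack a [raster_stack()].
#' @return logical matrix, `TRUE` where every layer holds a finite value.
#' @export
valid_mask <- function(stack) {
  stopifnot(inherits(stack, "raster_stack"))
  m <- Reduce(`&`, lapply(stack$layers, function(g) is.finite(g$values)))
  m
}

# cell values of every jointly valid cell, one row per cell (column-major
# cell order, i.e. down columns of the value matrices)
stack_cell_values <- function(stack, mask = valid_mask(stack)) {
  keep <- which(as.vector(mask))
  out <- vapply(stack$layers, function(g) g$values[keep], numeric(length(keep)))
  if (length(keep) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(stack$layers)))
  df <- as.data.frame(out)
  attr(df, "cell_index") <- keep
  df
}

# cell index (matrix row from top, col) containing a lon/lat point under the
# half-open membership rule [edge, edge + cellsize); returns NA when outside
point_to_cell <- function(grid, lon, lat) {
  jf <- floor((lon - grid$xll) / grid$cellsize)
  ib <- floor((lat - grid$yll) / grid$cellsize)  # row index from the bottom, 0-based
  ok <- jf >= 0 & jf < grid$ncols & ib >= 0 & ib < grid$nrows
  row <- ifelse(ok, grid$nrows - ib, NA_integer_)
  col <- ifelse(ok, jf + 1, NA_integer_)
  cbind(row = as.integer(row), col = as.integer(col))
}

# centre coordinates of matrix cell (row from top, col)
cell_center <- function(grid, row, col) {
  cbind(lon = grid$xll + (col - 0.5) * grid$cellsize,
        lat = grid$yll + (grid$nrows - row + 0.5) * grid$cellsize)
}

#' Construct an occurrence set
#'
#' @param lon,lat numeric vectors of coordinates in degrees.
#' @param species species label.
#' @return data frame of class `occurrences` with columns `lon`, `lat`.
#' @export
occurrences <- function(lon, lat, species = "species") {
  stopifnot(length(lon) == length(lat))
  df <- data.frame(lon = as.numeric(lon), lat = as.numeric(lat))
  attr(df, "species") <- species
  class(df) <- c("occurrences", "data.frame")
  df
}

#' Read an occurrence CSV
#'
#' Expects a header with species, longitude and latitude columns (names
#' configurable). Rows outside the grid's bounding box are dropped with a
#' message; with `dedupe_per_cell` at most one record is kept per grid cell
#' (the first encountered wins).
#'
#' @param path CSV path.
#' @param grid optional [raster_grid()] used for bounds filtering and
#'   per-cell de-duplication.
#' @param dedupe_per_cell drop all but the first record in each grid cell.
#' @param lon_col,lat_col,species_col column names in the file.
#' @return an [occurrences()] data frame.
#' @export
read_occurrences_csv <- function(path, grid = NULL, dedupe_per_cell = TRUE,
                                 lon_col = "longitude", lat_col = "latitude",
                                 species_col = "species") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c(lon_col, lat_col))
    if (!cn %in% names(df)) stop(sprintf("occurrence file lacks column '%s'", cn))
  lon <- suppressWarnings(as.numeric(df[[lon_col]]))
  lat <- suppressWarnings(as.numeric(df[[lat_col]]))
  bad <- which(is.na(lon) | is.na(lat))
  if (length(bad))
    stop(sprintf("non-numeric coordinate at data row %d", bad[1]))
  sp <- if (species_col %in% names(df)) df[[species_col]][1] else "species"
  occ <- occurrences(lon, lat, species = sp)
  if (!is.null(grid)) occ <- filter_occurrences(occ, grid, dedupe_per_cell)
  occ
}

#' Bounds-filter and optionally thin occurrences to one per cell
#'
#' @param occ an [occurrences()] set.
#' @param grid reference [raster_grid()].
#' @param dedupe_per_cell keep only the first record per cell.
#' @export
filter_occurrences <- function(occ, grid, dedupe_per_cell = TRUE) {
  rc <- point_to_cell(grid, occ$lon, occ$lat)
  inside <- !is.na(rc[, 1])
  if (any(!inside))
    message(sprintf("dropping %d occurrence(s) outside the grid bounds", sum(!inside)))
  occ2 <- occ[inside, , drop = FALSE]
  rc <- rc[inside, , drop = FALSE]
  if (dedupe_per_cell && nrow(occ2)) {
    key <- (rc[, 1] - 1L) * grid$ncols + rc[, 2]
    keep <- !duplicated(key)
    if (any(!keep))
      message(sprintf("dropping %d duplicate occurrence(s) sharing a grid cell", sum(!keep)))
    occ2 <- occ2[keep, , drop = FALSE]
  }
  class(occ2) <- c("occurrences", "data.frame")
  attr(occ2, "species") <- attr(occ, "species")
  occ2
}

#' Write occurrences to CSV
#' @param occ an [occurrences()] set.
#' @param path output path.
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(data.frame(species = attr(occ, "species") %||% "species",
                              longitude = occ$lon, latitude = occ$lat),
                   path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract per-point predictor values from a stack
#'
#' Each point takes the value of the cell containing it; cell membership is
#' half-open (a point on a shared edge belongs to the cell whose left/lower
#' edge it touches). Points falling on a cell that is nodata in any layer
#' are dropped with a message.
#'
#' @param stack a [raster_stack()].
#' @param points an [occurrences()] set (or data frame with `lon`, `lat`).
#' @param provenance label stored on the result (`"presence"` or
#'   `"background"`).
#' @return data frame, one row per retained point, one column per layer.
#' @export
extract_samples <- function(stack, points, provenance = "presence") {
  stopifnot(inherits(stack, "raster_stack"))
  ref <- stack$layers[[1]]
  rc <- point_to_cell(ref, points$lon, points$lat)
  inside <- !is.na(rc[, 1])
  if (any(!inside))
    message(sprintf("extract_samples: %d point(s) outside grid bounds dropped", sum(!inside)))
  rc <- rc[inside, , drop = FALSE]
  vals <- vapply(stack$layers, function(g) g$values[cbind(rc[, 1], rc[, 2])],
                 numeric(nrow(rc)))
  if (nrow(rc) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(stack$layers)))
  ok <- if (nrow(rc)) rowSums(!is.finite(vals)) == 0 else logical(0)
  if (any(!ok))
    message(sprintf("extract_samples: %d point(s) on nodata cells dropped", sum(!ok)))
  out <- as.data.frame(vals[ok, , drop = FALSE])
  if (!nrow(out)) stop("no valid samples: every point fell outside the grid or on nodata")
  attr(out, "provenance") <- provenance
  out
}
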