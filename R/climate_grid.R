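#' The seven bioclimatic variables used throughout the package
#'
#' Annual precipitation (mm), precipitation of the driest and wettest month
#' (mm), mean annual temperature, temperature annual range, and the maximum
#' and minimum mean monthly temperature (all degrees C). These are the
#' covariates every climate stack must carry.
#'
#' @return Character vector of the seven canonical variable names.
#' @export
climate_variables <- function() {
  c("annual_precip", "driest_month_precip", "wettest_month_precip",
    "mean_annual_temp", "temp_annual_range",
    "max_monthly_temp", "min_monthly_temp")
}

#' Construct a single-variable climate grid
#'
#' A `climate_grid` is a rectangular raster of one climate variable with
#' cell-center registration. Cells are half-open intervals
#' `[left, right) x [bottom, top)`, so point-to-cell assignment is
#' deterministic on shared edges. Row 1 of `values` is the *top* (northmost)
#' row, matching ESRI ASCII grid file order; `origin` is the lower-left
#' corner of the grid. Missing cells are `NA`.
#'
#' @param values Numeric matrix (row 1 = top row).
#' @param variable Variable name; one of [climate_variables()] or a
#'   `"monthly_*"` name for raw monthly inputs.
#' @param cell_size Positive cell edge length (degrees or km).
#' @param origin Length-2 numeric `(x, y)` of the lower-left corner.
#' @return An object of class `climate_grid`.
#' @export
#' @examples
#' g <- climate_grid(matrix(1:6, 2, 3), "mean_annual_temp", cell_size = 1)
climate_grid <- function(values, variable, cell_size = 1, origin = c(0, 0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.character(variable), length(variable) == 1L,
            length(cell_size) == 1L, cell_size > 0,
            length(origin) == 2L, is.finite(origin))
  if (!(variable %in% climate_variables() || startsWith(variable, "monthly_")))
    stop("unknown climate variable: ", variable)
  if (any(!is.finite(values) & !is.na(values)))
    stop("grid values must be finite or NA")
  structure(
    list(variable = variable, values = values,
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %s: %d x %d cells of %g, origin (%g, %g), %d missing\n",
              x$variable, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$values)

## geometry equality to a small tolerance
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

grid_extent <- function(g) {
  c(xmin = g$origin[1], xmax = g$origin[1] + ncol(g$values) * g$cell_size,
    ymin = g$origin[2], ymax = g$origin[2] + nrow(g$values) * g$cell_size)
}

## Point -> (row, col) under half-open [left,right) x [bottom,top) cells.
## Returns NA for points outside the extent.
point_cell <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  cx <- floor((x - g$origin[1]) / g$cell_size)
  cy <- floor((y - g$origin[2]) / g$cell_size)
  inside <- cx >= 0 & cx < nc & cy >= 0 & cy < nr
  row <- ifelse(inside, nr - cy, NA_integer_)
  col <- ifelse(inside, cx + 1L, NA_integer_)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read a gridded climate layer
#'
#' Reads a single-band raster as a [climate_grid()]. ESRI ASCII grids are
#' parsed natively (header `ncols/nrows/xllcorner/yllcorner/cellsize` with an
#' optional `NODATA_value`, which is mapped to `NA`). GeoTIFF input is read
#' through the `tiff` package, which exposes pixel values but not
#' georeferencing tags, so `cell_size` and `origin` must be supplied by the
#' caller for that format.
#'
#' @param path File path.
#' @param format `"ascii_grid"` or `"geotiff"`.
#' @param variable Variable name for the resulting grid.
#' @param cell_size,origin Geometry, used (and required to be meaningful)
#'   for `format = "geotiff"`; ignored for ASCII grids, whose header wins.
#' @return A [climate_grid()].
#' @export
read_grid <- function(path, format = c("ascii_grid", "geotiff"),
                      variable = "mean_annual_temp",
                      cell_size = 1, origin = c(0, 0)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "ascii_grid") {
    read_ascii_grid(path, variable)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read GeoTIFF input")
    v <- tiff::readTIFF(path, as.is = TRUE)
    if (is.list(v)) stop("multi-image TIFF is unsupported input")
    if (length(dim(v)) == 3L) {
      if (dim(v)[3] > 1L) stop("multi-band GeoTIFF is unsupported input")
      v <- v[, , 1L]
    }
    climate_grid(v, variable, cell_size = cell_size, origin = origin)
  }
}

read_ascii_grid <- function(path, variable) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("not a valid ESRI ASCII grid: ", path)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "cellsize", "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
    if (i > length(lines)) break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header incomplete in ", path,
         " (xllcenter registration is not supported)")
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[i:length(lines)]), "\\s+"))))
  vals <- vals[!is.na(vals) | seq_along(vals) <= hdr$ncols * hdr$nrows]
  if (length(vals) != hdr$ncols * hdr$nrows || anyNA(vals))
    stop("ASCII grid body does not match header dimensions in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  climate_grid(m, variable, cell_size = hdr$cellsize,
               origin = c(hdr$xllcorner, hdr$yllcorner))
}

#' Write a climate grid as an ESRI ASCII grid
#'
#' Values are written with 6 significant digits; `NA` cells become the
#' `NODATA_value` (-9999). A write/read cycle at this precision is
#' byte-stable.
#'
#' @param grid A [climate_grid()].
#' @param path Output file path.
#' @param nodata No-data sentinel written to the file.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "climate_grid"))
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %s", format(grid$origin[1], digits = 10)),
           sprintf("yllcorner %s", format(grid$origin[2], digits = 10)),
           sprintf("cellsize %s", format(grid$cell_size, digits = 10)),
           sprintf("NODATA_value %s", format(nodata)))
  body <- apply(v, 1L, function(r)
    paste(formatC(signif(r, 6), format = "g", digits = 6), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Block-aggregate a grid to a coarser resolution
#'
#' Each output cell is the mean of the non-missing cells in a
#' `factor x factor` block of the input (an all-missing block stays
#' missing), emulating resampling ~4 km climate surfaces to the ~40 km
#' spacing of survey routes. Dimensions not divisible by `factor` are
#' truncated at the top/right edge with a warning.
#'
#' @param grid A [climate_grid()].
#' @param factor Positive integer block edge; default 10 (4 km -> 40 km).
#' @return A [climate_grid()] with `cell_size * factor`.
#' @export
aggregate_grid <- function(grid, factor = 10L) {
  stopifnot(inherits(grid, "climate_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor <= 0L) stop("aggregation factor must be a positive integer")
  if (factor == 1L) return(grid)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  keep_r <- (nr %/% factor) * factor
  keep_c <- (nc %/% factor) * factor
  if (keep_r == 0L || keep_c == 0L)
    stop("grid smaller than one aggregation block")
  if (keep_r < nr || keep_c < nc) {
    warning(sprintf("grid %dx%d not divisible by %d; truncating %d row(s) at top, %d col(s) at right",
                    nr, nc, factor, nr - keep_r, nc - keep_c))
    ## row 1 is the top edge: drop the excess there so the origin is preserved
    v <- v[(nr - keep_r + 1L):nr, 1:keep_c, drop = FALSE]
  }
  onr <- keep_r %/% factor; onc <- keep_c %/% factor
  out <- matrix(NA_real_, onr, onc)
  for (i in seq_len(onr)) {
    rows <- ((i - 1L) * factor + 1L):(i * factor)
    for (j in seq_len(onc)) {
      block <- v[rows, ((j - 1L) * factor + 1L):(j * factor)]
      if (!all(is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
    }
  }
  climate_grid(out, grid$variable, cell_size = grid$cell_size * factor,
               origin = grid$origin)
}
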