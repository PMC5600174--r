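#' Single-band regular raster grid
#'
#' Minimal raster container used throughout the pipeline: a numeric matrix in
#' raster convention (row 1 is the northernmost row), a cell size in metres,
#' and the projected coordinates of the lower-left corner of the grid. Nodata
#' cells are `NA` in `values`.
#'
#' The centre of cell `(row, col)` is at
#' `x = x0 + (col - 0.5) * cell_size`,
#' `y = y0 + (nrow - row + 0.5) * cell_size`.
#'
#' @param values numeric matrix (NA = nodata)
#' @param cell_size cell edge length in metres (> 0)
#' @param origin numeric length-2, `(x0, y0)` of the lower-left grid corner
#' @return an object of class `raster_grid`
#' @export
raster_grid <- function(values, cell_size = 50, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be numeric of length 2")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%s, %s], %d nodata\n",
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Coordinates of all cell centres
#'
#' @param r a [raster_grid()]
#' @return data.frame with `row`, `col`, `x`, `y` for every cell
#' @export
cell_centres <- function(r) {
  stopifnot(is_raster_grid(r))
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  g$x <- r$origin[1] + (g$col - 0.5) * cs
  g$y <- r$origin[2] + (nr - g$row + 0.5) * cs
  g
}

#' Slope and aspect components from a digital elevation model
#'
#' Horn's 8-neighbour finite-difference method (the default of common GIS
#' slope/aspect tools). Slope is returned in percent (100 * rise/run). Aspect
#' (the downhill azimuth, clockwise from geographic north) is decomposed into
#' `northness = cos(aspect)` and `westness = -sin(aspect)`, both in
#' `[-1, 1]`. On flat cells (zero gradient) both components are 0. Border
#' cells and cells with any nodata neighbour are nodata.
#'
#' @param dem a [raster_grid()] of elevations (m), at least 3 x 3
#' @return list with raster_grids `slope_pct`, `northness`, `westness`
#' @export
slope_aspect <- function(dem) {
  stopifnot(is_raster_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3 x 3 cells")
  cs <- dem$cell_size
  sl <- no <- we <- matrix(NA_real_, nr, nc)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  # Horn kernel on the interior, vectorized with shifted submatrices.
  a <- z[ri - 1, ci - 1]; b <- z[ri - 1, ci]; cc <- z[ri - 1, ci + 1]
  d <- z[ri,     ci - 1];                      f <- z[ri,     ci + 1]
  g <- z[ri + 1, ci - 1]; h <- z[ri + 1, ci]; i <- z[ri + 1, ci + 1]
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)   # east
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)   # north
  grad <- sqrt(dzdx^2 + dzdy^2)
  sl[ri, ci] <- 100 * grad
  az <- atan2(-dzdx, -dzdy)                    # downhill azimuth from north
  n_int <- cos(az); w_int <- -sin(az)
  flat <- grad == 0
  n_int[flat] <- 0; w_int[flat] <- 0
  no[ri, ci] <- n_int; we[ri, ci] <- w_int
  list(slope_pct = raster_grid(sl, cs, dem$origin),
       northness = raster_grid(no, cs, dem$origin),
       westness  = raster_grid(we, cs, dem$origin))
}

#' Block-mean aggregation of a raster
#'
#' Aggregates `factor x factor` blocks to single cells by the mean of their
#' non-nodata members; a block that is entirely nodata stays nodata. Trailing
#' rows/columns that do not fill a block are dropped with a message.
#'
#' @param r a [raster_grid()]
#' @param factor positive integer block edge
#' @return a [raster_grid()] with `cell_size * factor`
#' @export
aggregate_mean <- function(r, factor) {
  stopifnot(is_raster_grid(r))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(r)
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  nro <- nr %/% factor; nco <- nc %/% factor
  if (nro < 1L || nco < 1L) stop("grid smaller than one aggregation block")
  if (nr %% factor || nc %% factor)
    message(sprintf("aggregate_mean: dropping %d trailing row(s), %d trailing column(s)",
                    nr %% factor, nc %% factor))
  v <- v[seq_len(nro * factor), seq_len(nco * factor), drop = FALSE]
  # fold into (factor, nro, factor, nco) and average over block dims
  a <- array(v, dim = c(factor, nro, factor * nco))
  a <- array(aperm(a, c(2, 1, 3)), dim = c(nro, factor, factor, nco))
  out <- apply(a, c(1, 4), function(b) {
    m <- mean(b, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  })
  # origin of the output: same lower-left x; y shifts up by dropped rows
  y0 <- r$origin[2] + (nr - nro * factor) * r$cell_size
  raster_grid(out, r$cell_size * factor, c(r$origin[1], y0))
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format. `write_raster()` then `read_raster()`
#' reproduces values, cell size, origin and the nodata mask exactly (values
#' are written with full precision). GeoTIFF is not supported (no GDAL
#' binding is available); files must be ESRI ASCII (.asc).
#'
#' @param path file path
#' @return `read_raster()`: a [raster_grid()]
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ESRI ASCII grid header, missing field: ",
         paste(miss, collapse = ", "))
  if (!is.null(hdr$xllcenter) || !is.null(hdr$yllcenter)) {
    hdr$xllcorner <- (hdr$xllcenter %||% 0) - hdr$cellsize / 2
    hdr$yllcorner <- (hdr$yllcenter %||% 0) - hdr$cellsize / 2
  }
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ESRI ASCII grid body has %d values, expected nrows*ncols = %d",
                 length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, hdr$cellsize,
              c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0))
}

#' @param r a [raster_grid()]
#' @param nodata value written for nodata cells
#' @rdname read_raster
#' @export
write_raster <- function(r, path, nodata = -9999) {
  stopifnot(is_raster_grid(r))
  v <- r$values
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel value ", nodata,
         "; choose another")
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2]),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  writeLines(apply(v, 1L, function(row)
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' Read a CSV of point coordinates
#'
#' Expects a header with at least `x` and `y` columns in projected metres.
#'
#' @param path CSV file path
#' @return data.frame with numeric `x`, `y` (plus any extra columns)
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) stop("points file not found: ", path)
  d <- read.csv(path)
  for (col in c("x", "y")) {
    if (!col %in% names(d))
      stop("points CSV is missing required column `", col, "`: ", path)
    if (!is.numeric(d[[col]]))
      stop("points CSV column `", col, "` is not numeric: ", path)
  }
  d
}

#' Map point coordinates to cell indices of a raster
#'
#' @param r a [raster_grid()]
#' @param xy data.frame/matrix with columns x, y (metres)
#' @return data.frame with `row`, `col`, `cell` (column-major index)
#' @export
cells_at_points <- function(r, xy) {
  stopifnot(is_raster_grid(r))
  xy <- as.data.frame(xy)
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  col <- floor((xy$x - r$origin[1]) / cs) + 1L
  row <- nr - floor((xy$y - r$origin[2]) / cs)
  if (any(col < 1L | col > nc | row < 1L | row > nr))
    stop("point(s) outside the raster extent")
  data.frame(row = row, col = col, cell = (col - 1L) * nr + row)
}
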