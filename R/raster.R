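#' Regular planar raster surface
#'
#' A minimal raster container for covariate grids (digestible energy,
#' predator relative use, utilization distributions) on one planar,
#' metre-based coordinate system. Values are stored as a matrix with rows
#' indexed south-to-north, so `values[r, c]` is the cell whose centre is at
#' `origin + (c - 1/2, r - 1/2) * cell_size`. Cell-centre registration,
#' x east / y north.
#'
#' @param values numeric matrix of cell values (row 1 = southernmost row).
#' @param origin_x,origin_y coordinates (m) of the lower-left corner of the
#'   grid (the corner of the cell, not its centre).
#' @param cell_size cell edge length in metres; cells are square.
#' @param nodata_flag sentinel used on disk for missing cells; cells equal to
#'   it are read back as `NA`.
#' @return an object of class `raster_surface`.
#' @export
raster_surface <- function(values, origin_x = 0, origin_y = 0,
                           cell_size = 1, nodata_flag = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (nrow(values) < 1 || ncol(values) < 1) stop("raster must have >= 1 cell")
  structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, n_rows = nrow(values), n_cols = ncol(values),
         nodata_flag = nodata_flag),
    class = "raster_surface")
}

#' @export
print.raster_surface <- function(x, ...) {
  cat(sprintf("raster_surface: %d x %d cells, %g m, extent x [%g, %g] y [%g, %g]\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$origin_x, x$origin_x + x$n_cols * x$cell_size,
              x$origin_y, x$origin_y + x$n_rows * x$cell_size))
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat(sprintf("  values: [%g, %g], mean %g\n",
                             min(v), max(v), mean(v)))
  invisible(x)
}

#' Cell-centre coordinates of a raster
#'
#' @param r a [raster_surface()].
#' @return list with vectors `x` (length `n_cols`) and `y` (length `n_rows`).
#' @export
raster_coords <- function(r) {
  list(x = r$origin_x + (seq_len(r$n_cols) - 0.5) * r$cell_size,
       y = r$origin_y + (seq_len(r$n_rows) - 0.5) * r$cell_size)
}

raster_extent <- function(r) {
  c(xmin = r$origin_x, xmax = r$origin_x + r$n_cols * r$cell_size,
    ymin = r$origin_y, ymax = r$origin_y + r$n_rows * r$cell_size)
}

# row/col of the cell containing each point; points on a cell boundary
# resolve to the lower-index cell.
raster_cell_index <- function(r, x, y) {
  ext <- raster_extent(r)
  out <- which(x < ext["xmin"] | x > ext["xmax"] |
               y < ext["ymin"] | y > ext["ymax"] |
               !is.finite(x) | !is.finite(y))
  if (length(out)) {
    stop(sprintf("point (%.6g, %.6g) lies outside the raster extent",
                 x[out[1]], y[out[1]]))
  }
  fx <- (x - r$origin_x) / r$cell_size
  fy <- (y - r$origin_y) / r$cell_size
  col <- pmin(pmax(ceiling(fx), 1L), r$n_cols)
  row <- pmin(pmax(ceiling(fy), 1L), r$n_rows)
  # exact boundary: ceiling() already assigns the lower-index cell for
  # interior boundaries (fx integer -> that column); fx == 0 handled by pmax.
  cbind(row = row, col = col)
}

#' Look up raster values at points
#'
#' Nearest-cell lookup by default; `method = "bilinear"` interpolates the
#' four surrounding cell centres (clamped at the edges).
#'
#' @param r a [raster_surface()].
#' @param x,y point coordinates (m).
#' @param method `"nearest"` or `"bilinear"`.
#' @return numeric vector of values; an error names the first point outside
#'   the extent or on a nodata cell.
#' @export
raster_lookup <- function(r, x, y, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (method == "nearest") {
    idx <- raster_cell_index(r, x, y)
    v <- r$values[cbind(idx[, "row"], idx[, "col"])]
  } else {
    ext <- raster_extent(r)
    bad <- which(x < ext["xmin"] | x > ext["xmax"] |
                 y < ext["ymin"] | y > ext["ymax"])
    if (length(bad)) {
      stop(sprintf("point (%.6g, %.6g) lies outside the raster extent",
                   x[bad[1]], y[bad[1]]))
    }
    # fractional position relative to cell centres
    gx <- (x - r$origin_x) / r$cell_size - 0.5
    gy <- (y - r$origin_y) / r$cell_size - 0.5
    c0 <- pmin(pmax(floor(gx) + 1, 1L), r$n_cols); c1 <- pmin(c0 + 1L, r$n_cols)
    r0 <- pmin(pmax(floor(gy) + 1, 1L), r$n_rows); r1 <- pmin(r0 + 1L, r$n_rows)
    tx <- pmin(pmax(gx - (c0 - 1L), 0), 1)
    ty <- pmin(pmax(gy - (r0 - 1L), 0), 1)
    v00 <- r$values[cbind(r0, c0)]; v01 <- r$values[cbind(r0, c1)]
    v10 <- r$values[cbind(r1, c0)]; v11 <- r$values[cbind(r1, c1)]
    v <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
         ty * ((1 - tx) * v10 + tx * v11)
  }
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop(sprintf("point (%.6g, %.6g) falls on a nodata cell",
                 x[bad[1]], y[bad[1]]))
  }
  v
}

#' Extract model covariates at points
#'
#' Returns digestible energy raw (kcal/g) and predator covariates as the
#' natural logarithm of the predator relative-use surfaces. Predator values
#' are floored at the smallest positive value in their raster before the log
#' so that zero cells do not map to `-Inf`.
#'
#' @param x,y point coordinates (m), equal length.
#' @param de,lion,wolf [raster_surface()] objects: digestible energy and the
#'   (pre-log) mountain lion and wolf relative-use surfaces.
#' @param method lookup method passed to [raster_lookup()].
#' @return data.frame with columns `de`, `ml`, `wf`, one row per point.
#' @export
extract_covariates <- function(x, y, de, lion, wolf,
                               method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  log_floored <- function(r) {
    v <- raster_lookup(r, x, y, method)
    pos <- r$values[is.finite(r$values) & r$values > 0]
    if (!length(pos)) stop("predator raster has no positive values")
    log(pmax(v, min(pos)))
  }
  data.frame(de = raster_lookup(de, x, y, method),
             ml = log_floored(lion),
             wf = log_floored(wolf))
}

#' Read an ESRI ASCII grid
#'
#' Supports the standard header (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, optional `nodata_value`). Data rows
#' in the file run north to south and are flipped into the south-first
#' internal convention.
#'
#' @param path file path.
#' @return a [raster_surface()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list(); n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2]); n_hdr <- n_hdr + 1L
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize))
    stop("not an ESRI ASCII grid: ", path)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII grid has wrong number of cells")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[hdr$nrows:1, , drop = FALSE]          # north-first on disk
  m[m == nodata] <- NA_real_
  ox <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
        else hdr$xllcenter - hdr$cellsize / 2
  oy <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
        else hdr$yllcenter - hdr$cellsize / 2
  raster_surface(m, ox, oy, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param r a [raster_surface()].
#' @param path output path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(r, path, digits = 8) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", r$n_cols),
               sprintf("nrows %d", r$n_rows),
               sprintf("xllcorner %.10g", r$origin_x),
               sprintf("yllcorner %.10g", r$origin_y),
               sprintf("cellsize %.10g", r$cell_size),
               sprintf("nodata_value %.10g", r$nodata_flag)), con)
  m <- r$values[r$n_rows:1, , drop = FALSE]
  m[!is.finite(m)] <- r$nodata_flag
  writeLines(apply(formatC(m, format = "g", digits = digits), 1, paste,
                   collapse = " "), con)
  invisible(path)
}
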