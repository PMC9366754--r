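# Kernel utilization distributions and isopleth home ranges.
#
# The UD is a fixed-kernel (single global bandwidth, Gaussian product kernel)
# density evaluated on a regular grid; isopleths are level sets that enclose
# a stated fraction of the UD mass, polygonized by marching-squares
# contouring of the gridded density.

#' Reference bandwidth for a fixed-kernel UD
#'
#' The ad hoc ("reference") rule applied per axis: `h = sd * n^(-1/6)`.
#'
#' @param x,y location coordinates.
#' @return numeric length-2 vector `c(hx, hy)`.
#' @export
reference_bandwidth <- function(x, y) {
  n <- length(x)
  c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
}

#' Estimate a kernel utilization distribution
#'
#' Evaluates the Gaussian fixed-kernel density of a point set on a regular
#' grid and normalizes it so that grid mass (density times cell area) sums
#' to one.
#'
#' @param locations telemetry `data.frame`, or any data.frame with `x`, `y`.
#' @param bandwidth kernel standard deviation in metres, scalar or
#'   `c(hx, hy)`; default is the per-axis reference rule
#'   ([reference_bandwidth()]).
#' @param grid_resolution cell size of the UD grid (m).
#' @param pad extent margin in bandwidths beyond the data range.
#' @param owner label stored with the UD (`animal_id` or `"population"`).
#' @return a [raster_surface()] of densities with attributes `bandwidth`,
#'   `n_locations` and `owner`.
#' @export
estimate_kde_ud <- function(locations, bandwidth = NULL,
                            grid_resolution = 250, pad = 4, owner = NA) {
  x <- locations$x; y <- locations$y
  if (length(x) < 5)
    stop("insufficient data: at least 5 locations are required for a UD")
  if (is.null(bandwidth)) bandwidth <- reference_bandwidth(x, y)
  h <- rep_len(bandwidth, 2L)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("bandwidth must be positive; supply one explicitly for degenerate point sets")
  x0 <- floor((min(x) - pad * h[1]) / grid_resolution) * grid_resolution
  y0 <- floor((min(y) - pad * h[2]) / grid_resolution) * grid_resolution
  nc <- ceiling((max(x) + pad * h[1] - x0) / grid_resolution)
  nr <- ceiling((max(y) + pad * h[2] - y0) / grid_resolution)
  gx <- x0 + (seq_len(nc) - 0.5) * grid_resolution
  gy <- y0 + (seq_len(nr) - 0.5) * grid_resolution
  # separable product kernel: density = (Ky %*% t(Kx)) / n
  Kx <- outer(gx, x, function(g, p) stats::dnorm(g, p, h[1])) # nc x n
  Ky <- outer(gy, y, function(g, p) stats::dnorm(g, p, h[2])) # nr x n
  dens <- tcrossprod(Ky, Kx) / length(x)                      # nr x nc
  mass <- sum(dens) * grid_resolution^2
  if (mass <= 0) stop("degenerate UD: zero mass on grid")
  ud <- raster_surface(dens / mass, x0, y0, grid_resolution)
  attr(ud, "bandwidth") <- h
  attr(ud, "n_locations") <- length(x)
  attr(ud, "owner") <- owner
  ud
}

#' Home-range polygon set
#'
#' Container for one or more simple planar rings. Built by
#' [extract_isopleth()], or directly from rings for availability polygons of
#' known shape. Rings are 2-column matrices; containment is tested with
#' even-odd crossing counts, so a ring nested inside another acts as a hole.
#'
#' @param polygons list of 2-column matrices (closed or open rings).
#' @param isopleth_level fraction of UD mass the range was cut at, or `NA`.
#' @param bandwidth,grid_resolution provenance of the parent UD, if any.
#' @param owner animal id or `"population"`.
#' @param area enclosed area in m^2; computed by shoelace (sum over rings) if
#'   omitted.
#' @return an object of class `home_range`.
#' @export
home_range <- function(polygons, isopleth_level = NA, bandwidth = NA,
                       grid_resolution = NA, owner = NA, area = NULL) {
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3)
    if (any(p[1, ] != p[nrow(p), ])) p <- rbind(p, p[1, ])
    unname(p)
  })
  if (is.null(area)) area <- sum(vapply(polygons, ring_area, 0))
  structure(list(polygons = polygons, isopleth_level = isopleth_level,
                 bandwidth = bandwidth, grid_resolution = grid_resolution,
                 owner = owner, area = area),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range (%s): %d ring(s), area %.4g km^2, isopleth %s\n",
              x$owner, length(x$polygons), x$area / 1e6,
              ifelse(is.na(x$isopleth_level), "-",
                     format(x$isopleth_level))))
  invisible(x)
}

ring_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

hr_boundary <- function(hr) {
  do.call(rbind, lapply(seq_along(hr$polygons), function(i) {
    if (i == 1) hr$polygons[[i]] else rbind(c(NA, NA), hr$polygons[[i]])
  }))
}

hr_bbox <- function(hr) {
  b <- do.call(rbind, hr$polygons)
  c(xmin = min(b[, 1]), xmax = max(b[, 1]),
    ymin = min(b[, 2]), ymax = max(b[, 2]))
}

#' Test point containment in a home range
#' @param hr a [home_range()].
#' @param x,y point coordinates.
#' @return logical vector (even-odd rule across all rings).
#' @export
hr_contains <- function(hr, x, y) {
  mgcv::in.out(hr_boundary(hr), cbind(x, y))
}

#' Extract an isopleth home range from a UD
#'
#' Finds the density threshold whose superlevel set encloses the requested
#' fraction of UD mass on the grid, and polygonizes it by marching-squares
#' contouring. `level = 1` returns the support of the density (all cells with
#' positive mass).
#'
#' @param ud a UD [raster_surface()] from [estimate_kde_ud()].
#' @param level fraction of UD mass in (0, 1]; the conventional home range
#'   uses 0.99.
#' @param owner label for the resulting range (defaults to the UD's owner).
#' @return a [home_range()]; its `area` is the grid area of enclosed cells
#'   and attribute `mass` holds the actually enclosed UD mass.
#' @export
extract_isopleth <- function(ud, level = 0.99, owner = NULL) {
  if (!is.finite(level) || level <= 0 || level > 1)
    stop("isopleth level must be in (0, 1]")
  v <- as.vector(ud$values)
  a <- ud$cell_size^2
  o <- order(v, decreasing = TRUE)
  cm <- cumsum(v[o]) * a
  k <- which(cm >= min(level, cm[length(cm)]))[1]
  if (is.na(k)) k <- length(v)
  thr <- v[o][k]
  if (level >= 1) thr <- min(v[v > 0])
  mask <- ud$values >= thr & ud$values > 0
  mass <- sum(ud$values[mask]) * a
  co <- raster_coords(ud)
  if (thr <= min(v)) {
    ext <- raster_extent(ud)
    rings <- list(cbind(ext[c(1, 2, 2, 1, 1)], ext[c(3, 3, 4, 4, 3)]))
  } else {
    cl <- grDevices::contourLines(co$x, co$y, t(ud$values),
                                  levels = thr * (1 - 1e-12))
    if (!length(cl)) stop("isopleth contouring failed (threshold outside grid range)")
    rings <- lapply(cl, function(s) cbind(s$x, s$y))
  }
  hr <- home_range(rings, isopleth_level = level,
                   bandwidth = attr(ud, "bandwidth"),
                   grid_resolution = ud$cell_size,
                   owner = if (is.null(owner)) attr(ud, "owner") else owner,
                   area = sum(mask) * a)
  attr(hr, "mass") <- mass
  attr(hr, "threshold") <- thr
  hr
}

#' Sample points uniformly inside a home range
#'
#' Rejection sampling from the bounding box; bitwise reproducible for a
#' given seed.
#'
#' @param hr a [home_range()].
#' @param n number of points (>= 0).
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return data.frame with columns `x`, `y` and `n` rows.
#' @export
sample_uniform_in_polygon <- function(hr, n, seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (hr$area <= 0) stop("degenerate polygon: zero area")
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  bb <- hr_bbox(hr)
  if (bb["xmax"] <= bb["xmin"] || bb["ymax"] <= bb["ymin"])
    stop("degenerate polygon: empty bounding box")
  local_seed(seed)
  out <- matrix(NA_real_, 0, 2)
  bnd <- hr_boundary(hr)
  guard <- 0L
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 64L)
    cand <- cbind(stats::runif(m, bb["xmin"], bb["xmax"]),
                  stats::runif(m, bb["ymin"], bb["ymax"]))
    keep <- mgcv::in.out(bnd, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed: polygon area too small relative to its bounding box")
  }
  data.frame(x = out[seq_len(n), 1], y = out[seq_len(n), 2])
}

#' Clip a home range to a rectangular extent
#'
#' Sutherland-Hodgman clipping of each ring against the (convex) rectangle;
#' used to restrict kernel isopleths to the mapped study area before
#' availability sampling, since the kernel smooths density beyond the
#' covariate rasters.
#'
#' @param hr a [home_range()].
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)` (a
#'   `raster_surface` extent works).
#' @return the clipped [home_range()]; rings falling fully outside are
#'   dropped, and an error is raised if nothing remains.
#' @export
hr_clip <- function(hr, extent) {
  ex <- unname(extent[c("xmin", "xmax", "ymin", "ymax")])
  if (any(is.na(ex))) ex <- unname(extent[1:4])
  rings <- lapply(hr$polygons, clip_ring_rect, ex)
  rings <- rings[vapply(rings, function(p) !is.null(p) && nrow(p) >= 3,
                        TRUE)]
  if (!length(rings)) stop("home range lies entirely outside the extent")
  out <- home_range(rings, isopleth_level = hr$isopleth_level,
                    bandwidth = hr$bandwidth,
                    grid_resolution = hr$grid_resolution, owner = hr$owner)
  attr(out, "clipped_to") <- ex
  out
}

# clip one ring against axis-aligned rectangle c(xmin,xmax,ymin,ymax)
clip_ring_rect <- function(p, ex) {
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  inside <- list(function(q) q[, 1] >= ex[1], function(q) q[, 1] <= ex[2],
                 function(q) q[, 2] >= ex[3], function(q) q[, 2] <= ex[4])
  edge_val <- c(ex[1], ex[2], ex[3], ex[4])
  edge_axis <- c(1, 1, 2, 2)
  for (e in 1:4) {
    if (!nrow(p)) return(NULL)
    keep <- inside[[e]](p)
    out <- matrix(NA_real_, 0, 2)
    n <- nrow(p)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a <- p[i, ]; b <- p[j, ]
      ain <- keep[i]; bin <- keep[j]
      if (ain) out <- rbind(out, a)
      if (xor(ain, bin)) {
        ax <- edge_axis[e]
        t <- (edge_val[e] - a[ax]) / (b[ax] - a[ax])
        out <- rbind(out, a + t * (b - a))
      }
    }
    p <- out
  }
  if (nrow(p) < 3) return(NULL)
  rbind(p, p[1, ])
}

#' Export a home range as WKT
#'
#' Each ring becomes one polygon of a `MULTIPOLYGON` (hole association is
#' not reconstructed).
#'
#' @param hr a [home_range()].
#' @return WKT string.
#' @export
hr_to_wkt <- function(hr) {
  rings <- vapply(hr$polygons, function(p) {
    paste0("((", paste(sprintf("%.6g %.6g", p[, 1], p[, 2]), collapse = ", "),
           "))")
  }, "")
  paste0("MULTIPOLYGON(", paste(rings, collapse = ", "), ")")
}
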