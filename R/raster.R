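#' Grid geometry for a north-up raster
#'
#' Describes a regular, axis-aligned raster grid in world coordinates
#' (metres). Row 1 is the north edge; columns increase eastward. All raster
#' objects in this package (single-band rasters, band stacks, masks, label
#' layers) carry one of these.
#'
#' @param xmin x coordinate (m) of the west edge of the grid.
#' @param ymax y coordinate (m) of the north edge of the grid.
#' @param px pixel size (m); pixels are square.
#' @param nrow,ncol raster dimensions.
#' @return A `grid_geom` object.
#' @export
grid_geom <- function(xmin, ymax, px, nrow, ncol) {
  stopifnot(is.numeric(px), length(px) == 1L, px > 0,
            nrow >= 1, ncol >= 1)
  structure(list(xmin = xmin, ymax = ymax, px = px,
                 nrow = as.integer(nrow), ncol = as.integer(ncol)),
            class = "grid_geom")
}

#' @export
print.grid_geom <- function(x, ...) {
  cat(sprintf("<grid_geom> %d x %d px @ %.4g m, origin (%.3f, %.3f)\n",
              x$nrow, x$ncol, x$px, x$xmin, x$ymax))
  invisible(x)
}

geom_equal <- function(a, b, tol = 1e-9) {
  abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$px - b$px) < tol && a$nrow == b$nrow && a$ncol == b$ncol
}

#' Pixel-centre coordinates of a grid
#'
#' @param geom a [grid_geom()].
#' @return `pixel_centers_x`: x coordinates of column centres (length
#'   `ncol`); `pixel_centers_y`: y coordinates of row centres (length
#'   `nrow`, north to south).
#' @keywords internal
pixel_centers_x <- function(geom) geom$xmin + (seq_len(geom$ncol) - 0.5) * geom$px

#' @rdname pixel_centers_x
#' @keywords internal
pixel_centers_y <- function(geom) geom$ymax - (seq_len(geom$nrow) - 0.5) * geom$px

#' Single-band raster
#'
#' A numeric matrix plus its [grid_geom()]. `NA` marks nodata.
#'
#' @param values numeric matrix (`geom$nrow` x `geom$ncol`).
#' @param geom a [grid_geom()].
#' @export
cp_raster <- function(values, geom) {
  values <- as.matrix(values)
  if (nrow(values) != geom$nrow || ncol(values) != geom$ncol)
    stop("raster values do not match grid geometry", call. = FALSE)
  structure(list(values = values, geom = geom), class = "cp_raster")
}

#' @export
print.cp_raster <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<cp_raster> %d x %d px @ %.4g m, range [%.4g, %.4g]\n",
              x$geom$nrow, x$geom$ncol, x$geom$px, rng[1], rng[2]))
  invisible(x)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised crossing-number test. Points on the left/bottom boundary of an
#' axis-aligned rectangle count as inside, points on the right/top do not,
#' so adjacent plots partition the pixels with no sharing.
#'
#' @param px,py point coordinates (equal-length vectors).
#' @param poly n x 2 matrix of polygon vertices (closed implicitly).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' Rasterize a plot polygon to pixel indices
#'
#' Returns the (column-major) cell indices of all pixels whose centres fall
#' inside the polygon, under the half-open boundary convention of
#' [point_in_polygon()]. A polygon that misses the grid entirely yields an
#' empty index set, not an error.
#'
#' @param polygon n x 2 matrix of vertices in world coordinates (m).
#' @param geom the target [grid_geom()].
#' @return integer vector of cell indices into a `geom$nrow` x `geom$ncol`
#'   matrix.
#' @export
rasterize_plot <- function(polygon, geom) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3)
  cx <- pixel_centers_x(geom)
  cy <- pixel_centers_y(geom)
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  cols <- which(cx >= xr[1] - geom$px & cx <= xr[2] + geom$px)
  rows <- which(cy >= yr[1] - geom$px & cy <= yr[2] + geom$px)
  if (!length(cols) || !length(rows)) return(integer(0))
  grid <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  keep <- point_in_polygon(cx[grid$col], cy[grid$row], polygon)
  sort(as.integer((grid$col[keep] - 1L) * geom$nrow + grid$row[keep]))
}

rect_polygon <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Block-average resampling between grids
#'
#' Aggregates a fine raster onto a coarser target grid by averaging all fine
#' pixels whose centres fall in each coarse cell. Coarse cells receiving no
#' fine pixel are `NA`.
#'
#' @param r a [cp_raster()] on the fine grid.
#' @param geom_to target [grid_geom()].
#' @return a [cp_raster()] on `geom_to`.
#' @export
resample_block_mean <- function(r, geom_to) {
  gx <- pixel_centers_x(r$geom)
  gy <- pixel_centers_y(r$geom)
  col_to <- floor((gx - geom_to$xmin) / geom_to$px) + 1L
  row_to <- floor((geom_to$ymax - gy) / geom_to$px) + 1L
  okc <- col_to >= 1L & col_to <= geom_to$ncol
  okr <- row_to >= 1L & row_to <= geom_to$nrow
  idx_fine <- which(outer(okr, okc, `&`))
  rows_f <- ((idx_fine - 1L) %% r$geom$nrow) + 1L
  cols_f <- ((idx_fine - 1L) %/% r$geom$nrow) + 1L
  cell_to <- (col_to[cols_f] - 1L) * geom_to$nrow + row_to[rows_f]
  vals <- r$values[idx_fine]
  means <- rowsum(vals, cell_to, na.rm = TRUE) /
    rowsum(as.numeric(!is.na(vals)), cell_to)
  out <- matrix(NA_real_, geom_to$nrow, geom_to$ncol)
  out[as.integer(rownames(means))] <- means[, 1]
  out[!is.finite(out)] <- NA_real_
  cp_raster(out, geom_to)
}

shift_matrix <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 - dr):min(nr, nr - dr)
  sc <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(sr) && length(sc) && sr[1] <= sr[length(sr)] && sc[1] <= sc[length(sc)])
    out[sr, sc] <- m[sr + dr, sc + dc]
  out
}
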