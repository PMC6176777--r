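#' Excess green index map
#'
#' ExG = 2 rho_green - rho_red - rho_blue, computed per pixel from the
#' visible bands of a reflectance stack. Nodata propagates.
#'
#' @param stack a [band_stack()] containing `blue`, `green`, `red`.
#' @return A [cp_raster()] of ExG values.
#' @export
compute_exg <- function(stack) {
  need <- c("blue", "green", "red")
  missing <- setdiff(need, names(stack$bands))
  if (length(missing))
    stop("missing band(s) for ExG: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cp_raster(2 * stack$bands$green - stack$bands$red - stack$bands$blue,
            stack$geom)
}

#' Sunlit-vegetation mask by excess-green thresholding
#'
#' Pixels with ExG strictly above the threshold are classed as sunlit
#' vegetation. Both bare soil and cast shadow fall below the threshold:
#' shadow attenuates the visible bands roughly proportionally, scaling ExG
#' down with them, so a single threshold removes soil and shadow together.
#' The default 0.046 matches the segmentation threshold used with this
#' camera's reflectance products. Nodata pixels are never vegetation.
#'
#' @param stack a [band_stack()].
#' @param threshold ExG threshold (finite).
#' @return A `veg_mask`: logical matrix plus geometry.
#' @export
sunlit_vegetation_mask <- function(stack, threshold = 0.046) {
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be numeric", call. = FALSE)
  exg <- compute_exg(stack)
  m <- !is.na(exg$values) & exg$values > threshold
  structure(list(values = m, geom = stack$geom, threshold = threshold),
            class = "veg_mask")
}

#' @export
print.veg_mask <- function(x, ...) {
  cat(sprintf("<veg_mask> %d / %d pixels sunlit vegetation (threshold %g)\n",
              sum(x$values), length(x$values), x$threshold))
  invisible(x)
}

#' Confusion counts of a mask against simulator labels
#'
#' Quality control for the segmentation stage on simulated scenes: a 2 x 4
#' table of mask state (vegetation / other) against the four simulator
#' pixel classes.
#'
#' @param mask a `veg_mask`.
#' @param labels a [cp_raster()] of [label_codes()] on the same grid.
#' @return 2 x 4 integer matrix, rows `mask_veg`/`mask_other`, columns the
#'   label classes.
#' @export
mask_statistics <- function(mask, labels) {
  if (!geom_equal(mask$geom, labels$geom))
    stop("mask and label geometries differ", call. = FALSE)
  lc <- label_codes()
  out <- matrix(0L, 2, length(lc),
                dimnames = list(c("mask_veg", "mask_other"), names(lc)))
  for (j in seq_along(lc)) {
    sel <- labels$values == lc[j]
    out[1, j] <- sum(mask$values & sel)
    out[2, j] <- sum(!mask$values & sel)
  }
  out
}
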