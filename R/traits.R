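#' Estimate the terrain model from soil margin strips
#'
#' The bare-soil strips flanking the field east and west expose the ground
#' surface; assuming only a gentle west-east trend, the terrain under the
#' crop is reconstructed per raster row by taking the median surface
#' elevation inside each strip and linearly interpolating between the two
#' strip centres, with constant extrapolation outside them.
#'
#' @param dsm a [cp_raster()] surface model.
#' @param margin_strips list with polygons `west` and `east` (n x 2 vertex
#'   matrices, world metres).
#' @return A [cp_raster()] terrain model on the same grid.
#' @export
estimate_dtm <- function(dsm, margin_strips) {
  g <- dsm$geom
  strip_cols <- lapply(margin_strips[c("west", "east")], function(poly) {
    idx <- rasterize_plot(poly, g)
    sort(unique(((idx - 1L) %/% g$nrow) + 1L))
  })
  cx <- pixel_centers_x(g)
  centers <- vapply(strip_cols, function(cols) mean(cx[cols]), numeric(1))
  dtm <- matrix(NA_real_, g$nrow, g$ncol)
  for (r in seq_len(g$nrow)) {
    med <- vapply(strip_cols, function(cols) {
      v <- dsm$values[r, cols]
      stats::median(v[!is.na(v)])
    }, numeric(1))
    if (anyNA(med))
      stop("no valid soil-strip pixels on raster row ", r, call. = FALSE)
    dtm[r, ] <- stats::approx(centers, med, xout = cx, rule = 2)$y
  }
  cp_raster(dtm, g)
}

#' Canopy height model (cm) from DSM minus DTM
#'
#' Height = (DSM - DTM) x 100 cm; small negative differences from terrain
#' interpolation error are clipped to zero.
#'
#' @param dsm,dtm [cp_raster()]s on the same grid (m).
#' @return A [cp_raster()] of heights in cm.
#' @export
height_map <- function(dsm, dtm) {
  if (!geom_equal(dsm$geom, dtm$geom))
    stop("DSM and DTM geometries differ", call. = FALSE)
  cp_raster(pmax((dsm$values - dtm$values) * 100, 0), dsm$geom)
}

#' Plot height percentile
#'
#' The q-th percentile of all height pixels whose centres fall in the plot
#' boundary — vegetation and soil alike — with linear interpolation between
#' order statistics.
#'
#' @param heights a [cp_raster()] of heights (cm).
#' @param plot_pixels integer cell indices from [rasterize_plot()].
#' @param q percentile in (0, 100\].
#' @return height (cm).
#' @export
plot_height_percentile <- function(heights, plot_pixels, q) {
  v <- heights$values[plot_pixels]
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty plot pixel set", call. = FALSE)
  unname(stats::quantile(v, q / 100, type = 7))
}

#' Canopy cover of a plot
#'
#' Ratio of sunlit-vegetation pixels to all pixels in the plot.
#'
#' @param mask a `veg_mask` from [sunlit_vegetation_mask()].
#' @param plot_pixels integer cell indices.
#' @return fraction in \[0, 1\].
#' @export
canopy_cover <- function(mask, plot_pixels) {
  if (!length(plot_pixels)) stop("empty plot pixel set", call. = FALSE)
  sum(mask$values[plot_pixels]) / length(plot_pixels)
}

VI_NAMES <- c("ExG", "NDVI", "RDVI", "GNDVI", "CI_Green", "CI_RedEdge",
              "NDRE", "RGBVI")

#' Compute a vegetation index raster
#'
#' The eight indices: ExG = 2G - R - B; NDVI = (NIR - R)/(NIR + R);
#' RDVI = (NIR - R)/sqrt(NIR + R); GNDVI = (NIR - G)/(NIR + G);
#' CI_Green = NIR/G - 1; CI_RedEdge = NIR/RE - 1;
#' NDRE = (NIR - RE)/(NIR + RE); RGBVI = (G^2 - B R)/(G^2 + B R).
#' Division by zero yields nodata at the affected pixel.
#'
#' RDVI here is the renormalized difference index with the square-root
#' denominator of its original definition, which is what distinguishes its
#' behaviour from NDVI; `rdvi_compat = TRUE` selects the NDVI-identical
#' variant occasionally seen in printed index tables.
#'
#' @param stack a [band_stack()].
#' @param name one of ExG, NDVI, RDVI, GNDVI, CI_Green, CI_RedEdge, NDRE,
#'   RGBVI.
#' @param rdvi_compat use the NDVI-identical RDVI variant.
#' @return A [cp_raster()].
#' @export
compute_vi <- function(stack, name, rdvi_compat = FALSE) {
  if (!name %in% VI_NAMES)
    stop("unknown vegetation index: ", name, call. = FALSE)
  b <- stack$bands
  v <- switch(name,
    ExG = 2 * b$green - b$red - b$blue,
    NDVI = (b$nir - b$red) / (b$nir + b$red),
    RDVI = if (rdvi_compat) (b$nir - b$red) / (b$nir + b$red)
           else (b$nir - b$red) / sqrt(b$nir + b$red),
    GNDVI = (b$nir - b$green) / (b$nir + b$green),
    CI_Green = b$nir / b$green - 1,
    CI_RedEdge = b$nir / b$rededge - 1,
    NDRE = (b$nir - b$rededge) / (b$nir + b$rededge),
    RGBVI = (b$green^2 - b$blue * b$red) / (b$green^2 + b$blue * b$red))
  v[!is.finite(v)] <- NA_real_
  cp_raster(v, stack$geom)
}

#' Plot-mean vegetation index over sunlit vegetation
#'
#' Arithmetic mean of the index over pixels that are both inside the plot
#' and sunlit vegetation. A plot with no sunlit pixel yields `NA` (flagged
#' downstream), not an error.
#'
#' @param vi a [cp_raster()] index map.
#' @param mask a `veg_mask`.
#' @param plot_pixels integer cell indices.
#' @return mean index value, or `NA` if no sunlit pixel.
#' @export
plot_mean_vi <- function(vi, mask, plot_pixels) {
  sel <- plot_pixels[mask$values[plot_pixels]]
  if (!length(sel)) return(NA_real_)
  mean(vi$values[sel], na.rm = TRUE)
}

#' Extract per-plot morphological and spectral traits
#'
#' For every plot: the 90/93/95/98th height percentiles from the canopy
#' height model (all in-plot pixels), canopy cover, and the mean of each of
#' the eight vegetation indices over sunlit vegetation pixels. Plots with
#' zero sunlit pixels are flagged (`n_sunlit = 0`, VI means `NA`).
#'
#' @param stack a [band_stack()] (multispectral grid).
#' @param dsm a [cp_raster()] surface model (may be a finer grid).
#' @param dtm matching terrain model, or margin-strip polygons to estimate
#'   it from (list with `west`/`east`).
#' @param mask a `veg_mask` on the stack grid.
#' @param plots a [plot_set()].
#' @param percentiles height percentiles to report.
#' @return tibble: `plot_id`, `ph90` ... , `cc`, eight VI columns
#'   (lower-case), `n_pixels`, `n_sunlit`.
#' @export
extract_plot_traits <- function(stack, dsm, dtm, mask, plots,
                                percentiles = c(90, 93, 95, 98)) {
  if (!geom_equal(stack$geom, mask$geom))
    stop("stack and mask geometries differ", call. = FALSE)
  if (!inherits(dtm, "cp_raster")) dtm <- estimate_dtm(dsm, dtm)
  hts <- height_map(dsm, dtm)
  vis <- lapply(VI_NAMES, function(nm) compute_vi(stack, nm))
  names(vis) <- VI_NAMES
  n <- nrow(plots)
  ph <- matrix(NA_real_, n, length(percentiles))
  cc <- numeric(n); npix <- integer(n); nsun <- integer(n)
  vimeans <- matrix(NA_real_, n, length(VI_NAMES))
  for (i in seq_len(n)) {
    poly <- plots$geometry[[i]]
    idx_h <- rasterize_plot(poly, hts$geom)
    idx_m <- rasterize_plot(poly, stack$geom)
    npix[i] <- length(idx_m)
    if (!length(idx_h) || !length(idx_m)) next
    ph[i, ] <- vapply(percentiles, function(q)
      plot_height_percentile(hts, idx_h, q), numeric(1))
    cc[i] <- canopy_cover(mask, idx_m)
    nsun[i] <- sum(mask$values[idx_m])
    vimeans[i, ] <- vapply(vis, function(v)
      plot_mean_vi(v, mask, idx_m), numeric(1))
  }
  out <- tibble::tibble(plot_id = plots$plot_id)
  for (j in seq_along(percentiles))
    out[[paste0("ph", percentiles[j])]] <- ph[, j]
  out$cc <- cc
  cols <- c(ExG = "exg", NDVI = "ndvi", RDVI = "rdvi", GNDVI = "gndvi",
            CI_Green = "ci_green", CI_RedEdge = "ci_rededge", NDRE = "ndre",
            RGBVI = "rgbvi")
  for (nm in VI_NAMES) out[[cols[[nm]]]] <- vimeans[, match(nm, VI_NAMES)]
  out$n_pixels <- npix
  out$n_sunlit <- nsun
  out
}

#' Select the height percentile best matching manual measurements
#'
#' Correlates each extracted height-percentile column with manually
#' measured plot heights and returns the percentile with the highest
#' Pearson r (ties broken toward the lower percentile).
#'
#' @param traits trait table from [extract_plot_traits()].
#' @param measured data frame with `plot_id` and `height_cm`.
#' @return list: `percentile` (numeric), `r_table` (tibble of percentile,
#'   r).
#' @export
select_height_percentile <- function(traits, measured) {
  merged <- merge(traits, measured, by = "plot_id")
  if (nrow(merged) < 3)
    stop("need at least 3 plots with both values", call. = FALSE)
  if (stats::sd(merged$height_cm) == 0)
    stop("measured heights are constant; correlation undefined", call. = FALSE)
  cols <- grep("^ph[0-9]+$", names(traits), value = TRUE)
  qs <- as.numeric(sub("ph", "", cols))
  rs <- unname(vapply(cols, function(cl)
    stats::cor(merged[[cl]], merged$height_cm), numeric(1)))
  ord <- order(qs)
  qs <- qs[ord]; rs <- rs[ord]
  best <- qs[which.max(rs)]   # which.max takes the first (lowest q) on ties
  list(percentile = best, r_table = tibble::tibble(percentile = qs, r = rs))
}

#' Band-average a hyperspectral spectrum to camera bands
#'
#' Convolves a leaf-level reflectance spectrum with a Gaussian spectral
#' response per band (sd = FWHM / 2 sqrt(2 ln 2)), truncated at +/- 1.5
#' FWHM around the band centre, using trapezoidal weights on the spectrum's
#' own wavelength grid.
#'
#' @param wavelength_nm,reflectance the spectrum (sorted wavelengths).
#' @param bands band definitions, as [micasense_bands()].
#' @return named numeric vector of band reflectances.
#' @export
resample_spectrum_to_bands <- function(wavelength_nm, reflectance,
                                       bands = micasense_bands()) {
  stopifnot(length(wavelength_nm) == length(reflectance))
  ord <- order(wavelength_nm)
  wl <- wavelength_nm[ord]; rf <- reflectance[ord]
  out <- numeric(nrow(bands))
  for (i in seq_len(nrow(bands))) {
    c0 <- bands$center_nm[i]; fw <- bands$fwhm_nm[i]
    lo <- c0 - 1.5 * fw; hi <- c0 + 1.5 * fw
    if (wl[1] > lo || wl[length(wl)] < hi)
      stop("spectrum does not cover band ", bands$name[i], call. = FALSE)
    sel <- which(wl >= lo & wl <= hi)
    if (length(sel) < 2 || max(diff(wl[sel])) > fw)
      stop("spectrum gap inside band support of ", bands$name[i],
           call. = FALSE)
    w <- wl[sel]; r <- rf[sel]
    sigma <- fw / (2 * sqrt(2 * log(2)))
    g <- exp(-0.5 * ((w - c0) / sigma)^2)
    dw <- diff(w)
    trap <- c(dw / 2, 0) + c(0, dw / 2)   # trapezoid quadrature weights
    out[i] <- sum(g * trap * r) / sum(g * trap)
  }
  stats::setNames(out, bands$name)
}
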