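#' Label codes of the simulated pixel-class raster
#'
#' @return named integer vector: `soil_sunlit = 1`, `soil_shaded = 2`,
#'   `veg_sunlit = 3`, `veg_shaded = 4`.
#' @export
label_codes <- function() {
  c(soil_sunlit = 1L, soil_shaded = 2L, veg_sunlit = 3L, veg_shaded = 4L)
}

#' Noise parameters of the scene simulator
#'
#' @param biomass_log_sd sd of the multiplicative log-normal noise applied
#'   to generated biomass (log scale, unitless).
#' @param reflectance_sd sd of additive reflectance noise per band per pixel.
#' @param height_sd_m sd (m) of within-plot canopy height jitter.
#' @return A `noise_params` list.
#' @export
noise_params <- function(biomass_log_sd = 0.05, reflectance_sd = 0.005,
                         height_sd_m = 0.05) {
  if (biomass_log_sd < 0 || reflectance_sd < 0 || height_sd_m < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  structure(list(biomass_log_sd = biomass_log_sd,
                 reflectance_sd = reflectance_sd,
                 height_sd_m = height_sd_m), class = "noise_params")
}

#' Latent-trait distribution parameters of the simulator
#'
#' Controls the per-plot draws of true height, cover, and the NDVI/NDRE
#' spectral latents, plus the correlation targets linking leaf nitrogen and
#' chlorophyll to the NDRE latent. High-nitrogen plots receive a positive
#' mean shift on the NDRE latent (`ndre_treat_shift`), reflecting the
#' nitrogen signal carried by red-edge indices.
#'
#' @param height_line_range range (cm) of per-line mean heights.
#' @param height_treat_shift high-N height increment (cm).
#' @param height_plot_sd per-plot height sd (cm).
#' @param cover_line_range,cover_treat_shift,cover_plot_sd canopy cover
#'   fraction analogues.
#' @param ndvi_range,ndvi_sd per-line NDVI latent base range and plot sd.
#' @param ndre_mean_low low-N NDRE latent mean; `ndre_treat_shift` is added
#'   for high-N plots; `ndre_sd` is the plot sd.
#' @param ndre_treat_shift high-N shift on the NDRE latent.
#' @param ndre_sd plot sd of the NDRE latent.
#' @param leafN_mean,leafN_sd,leafN_corr leaf N (%) marginal moments and
#'   target Pearson correlation with the NDRE latent.
#' @param chl_mean,chl_sd,chl_corr leaf chlorophyll (relative units)
#'   analogues.
#' @return A `latent_params` list.
#' @export
latent_params <- function(height_line_range = c(340, 440),
                          height_treat_shift = 20, height_plot_sd = 15,
                          cover_line_range = c(0.55, 0.90),
                          cover_treat_shift = 0.05, cover_plot_sd = 0.03,
                          ndvi_range = c(0.70, 0.88), ndvi_sd = 0.02,
                          ndre_mean_low = 0.30, ndre_treat_shift = 0.08,
                          ndre_sd = 0.04,
                          leafN_mean = 1.8, leafN_sd = 0.4, leafN_corr = 0.6,
                          chl_mean = 30, chl_sd = 8, chl_corr = 0.6) {
  structure(as.list(environment()), class = "latent_params")
}

#' Canopy and soil spectral parameters
#'
#' Fixed soil reflectance spectrum and the fixed canopy blue/green/NIR
#' reflectances; per-plot canopy red and red-edge reflectances are derived
#' from each plot's NDVI and NDRE latents so the rendered indices equal the
#' latents exactly in the noiseless case.
#'
#' @param soil named reflectances of the five bands for sunlit soil.
#' @param veg_blue,veg_green,veg_nir fixed canopy reflectances.
#' @return A `spectra_params` list.
#' @export
spectra_params <- function(soil = c(blue = 0.11, green = 0.09, red = 0.07,
                                    rededge = 0.18, nir = 0.26),
                           veg_blue = 0.06, veg_green = 0.13, veg_nir = 0.50) {
  structure(list(soil = soil, veg_blue = veg_blue, veg_green = veg_green,
                 veg_nir = veg_nir), class = "spectra_params")
}

#' Canopy band reflectances implied by NDVI / NDRE latents
#'
#' Inverts the normalized-difference definitions: with NIR fixed,
#' red = NIR (1 - NDVI)/(1 + NDVI) and red-edge = NIR (1 - NDRE)/(1 + NDRE).
#'
#' @param ndvi,ndre latent index values (vectors).
#' @param spectra a [spectra_params()].
#' @return list of five reflectance vectors named as the bands.
#' @export
veg_spectrum_from_latents <- function(ndvi, ndre, spectra = spectra_params()) {
  nir <- spectra$veg_nir
  list(blue = rep(spectra$veg_blue, length(ndvi)),
       green = rep(spectra$veg_green, length(ndvi)),
       red = nir * (1 - ndvi) / (1 + ndvi),
       rededge = nir * (1 - ndre) / (1 + ndre),
       nir = rep(nir, length(ndvi)))
}

#' Default generative biomass models
#'
#' The three-predictor (plant height, canopy cover, NDRE) exponential
#' models used by the simulator as the trait-to-biomass link, for fresh and
#' dry above-ground biomass (kg per plot).
#'
#' @return list with elements `fresh` and `dry`, each an
#'   [exponential_model()].
#' @export
default_generative_models <- function() {
  list(
    fresh = exponential_model(10.63, c(PH = 0.003, CC = 0.6, NDRE = 1.728),
                              response = "fresh_biomass_kg"),
    dry = exponential_model(3.90, c(PH = 0.003, CC = 0.345, NDRE = 0.87),
                            response = "dry_biomass_kg")
  )
}

#' Configuration of a simulated field scene
#'
#' Defaults reproduce the study layout: 24 lines x 2 nitrogen treatments x
#' 8 replicates in a randomized complete block design, 3 m x 3 m plots of
#' four rows at 0.76 m spacing, multispectral ground sampling distance
#' 0.020 m and surface-model GSD 0.013 m, and an excess-green segmentation
#' threshold of 0.046.
#'
#' @param n_lines,n_treatments,n_reps design counts.
#' @param plot_size_m plot side length (m).
#' @param row_spacing_m crop row spacing within a plot (m).
#' @param rows_per_plot crop rows per plot.
#' @param gsd_ms_m multispectral pixel size (m).
#' @param gsd_rgb_m surface-model pixel size (m).
#' @param margin_strip_m width (m) of the bare-soil strips flanking the
#'   field on its east and west edges (used for terrain interpolation).
#' @param sun_azimuth_deg sun azimuth, degrees clockwise from north.
#' @param sun_elevation_deg sun elevation above horizon, (0, 90].
#' @param exg_threshold excess-green threshold separating sunlit vegetation
#'   from soil and shadow.
#' @param attenuation named factors (`visible`, `nir`) multiplying
#'   blue/green/red and rededge/NIR reflectance inside cast shadows.
#' @param shadow_min_prominence minimum height (m) an occluder must rise
#'   above the sun ray to cast shadow; a crude penumbra/diffuse-fill stand-in
#'   that also keeps centimetre-scale canopy roughness from self-shading
#'   whole plots.
#' @param dtm_base_m,dtm_slope base terrain elevation (m) and west-to-east
#'   slope (m per m).
#' @param noise a [noise_params()].
#' @param latents a [latent_params()].
#' @param spectra a [spectra_params()].
#' @param models generative biomass models, as
#'   [default_generative_models()].
#' @param seed root integer seed; all stages draw from named substreams of
#'   it.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(n_lines = 24, n_treatments = 2, n_reps = 8,
                         plot_size_m = 3.0, row_spacing_m = 0.76,
                         rows_per_plot = 4, gsd_ms_m = 0.020,
                         gsd_rgb_m = 0.013, margin_strip_m = 2.0,
                         sun_azimuth_deg = 135, sun_elevation_deg = 70,
                         exg_threshold = 0.046,
                         attenuation = c(visible = 0.2, nir = 0.7),
                         shadow_min_prominence = 0.25,
                         dtm_base_m = 100, dtm_slope = 0.004,
                         noise = noise_params(), latents = latent_params(),
                         spectra = spectra_params(),
                         models = default_generative_models(), seed = 1L) {
  cfg <- as.list(environment())
  if (any(c(n_lines, n_treatments, n_reps, rows_per_plot) < 1))
    stop("design counts must be >= 1", call. = FALSE)
  if (gsd_ms_m <= 0 || gsd_rgb_m <= 0 || plot_size_m <= 0)
    stop("pixel and plot sizes must be positive", call. = FALSE)
  if (sun_elevation_deg <= 0 || sun_elevation_deg > 90)
    stop("sun_elevation_deg must lie in (0, 90]", call. = FALSE)
  stopifnot(inherits(noise, "noise_params"))
  structure(cfg, class = "scene_config")
}

# Deterministic substream seeds below 2^31, derived from the root seed and
# a stage name so stages are independently reproducible.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 1009)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Build the randomized complete block field design
#'
#' Lays out `n_reps` blocks stacked north to south; within each block the
#' line x treatment combinations are randomized over an
#' `n_treatments`-row x `n_lines`-column grid of `plot_size_m` square
#' plots. Bare-soil margin strips of width `margin_strip_m` flank the
#' field east and west.
#'
#' @param config a [scene_config()].
#' @param seed integer seed (defaults to the design substream of
#'   `config$seed`).
#' @return A [plot_set()] with attributes `extent` (xmin, xmax, ymin, ymax)
#'   and `margins` (west/east strip polygons).
#' @export
build_field_design <- function(config, seed = derive_seed(config$seed, "design")) {
  n_lines <- config$n_lines; n_trt <- config$n_treatments; n_reps <- config$n_reps
  ps <- config$plot_size_m; m <- config$margin_strip_m
  width <- 2 * m + n_lines * ps
  height <- n_reps * n_trt * ps
  combos <- expand.grid(line = sprintf("L%02d", seq_len(n_lines)),
                        treatment = c("low_N", "high_N")[seq_len(min(n_trt, 2))],
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (n_trt > 2)
    combos <- expand.grid(line = sprintf("L%02d", seq_len(n_lines)),
                          treatment = sprintf("T%d", seq_len(n_trt)),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- with_seed(seed, {
    out <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      ord <- sample.int(nrow(combos))
      blk <- combos[ord, , drop = FALSE]
      blk$rep <- r
      blk$cell <- seq_len(nrow(blk)) - 1L
      out[[r]] <- blk
    }
    out
  })
  df <- do.call(rbind, rows)
  col <- df$cell %% n_lines
  row_in_block <- df$cell %/% n_lines
  df$xmin <- m + col * ps
  df$ymax <- height - ((df$rep - 1L) * n_trt + row_in_block) * ps
  geoms <- lapply(seq_len(nrow(df)), function(i)
    rect_polygon(df$xmin[i], df$ymax[i] - ps, df$xmin[i] + ps, df$ymax[i]))
  plots <- plot_set(sprintf("P%03d", seq_len(nrow(df))),
                    df$line, df$treatment, df$rep, geoms)
  attr(plots, "extent") <- c(xmin = 0, xmax = width, ymin = 0, ymax = height)
  attr(plots, "margins") <- list(
    west = rect_polygon(0, 0, m, height),
    east = rect_polygon(width - m, 0, width, height))
  attr(plots, "plot_size_m") <- ps
  plots
}

#' Simulate per-plot ground truth
#'
#' Draws per-plot true height, canopy cover and NDVI/NDRE spectral latents
#' (line effects plus a positive high-nitrogen NDRE shift), derives the
#' full set of latent vegetation-index values from the implied canopy
#' spectrum, computes fresh and dry biomass from the generative exponential
#' models under multiplicative log-normal noise, and draws leaf nitrogen
#' and chlorophyll with the configured correlation to the NDRE latent.
#'
#' @param design a [plot_set()] from [build_field_design()].
#' @param models generative models (list `fresh`, `dry` of
#'   [exponential_model()]).
#' @param noise a [noise_params()].
#' @param seed integer seed.
#' @param latents a [latent_params()].
#' @param spectra a [spectra_params()].
#' @return tibble of per-plot truth (one row per plot).
#' @export
simulate_plot_truths <- function(design, models = default_generative_models(),
                                 noise = noise_params(), seed = 1L,
                                 latents = latent_params(),
                                 spectra = spectra_params()) {
  stopifnot(inherits(noise, "noise_params"))
  for (m in models) if (m$a <= 0)
    stop("generative models need a positive multiplicative coefficient",
         call. = FALSE)
  n <- nrow(design)
  lp <- latents
  with_seed(seed, {
    lines <- sort(unique(design$line))
    line_h <- stats::runif(length(lines), lp$height_line_range[1],
                           lp$height_line_range[2])
    line_c <- stats::runif(length(lines), lp$cover_line_range[1],
                           lp$cover_line_range[2])
    line_v <- stats::runif(length(lines), lp$ndvi_range[1], lp$ndvi_range[2])
    names(line_h) <- names(line_c) <- names(line_v) <- lines
    high <- design$treatment == "high_N"
    h <- unname(line_h[design$line]) + ifelse(high, lp$height_treat_shift, 0) +
      stats::rnorm(n, 0, lp$height_plot_sd)
    h <- pmin(pmax(h, 0), 480)
    cc <- unname(line_c[design$line]) + ifelse(high, lp$cover_treat_shift, 0) +
      stats::rnorm(n, 0, lp$cover_plot_sd)
    cc <- pmin(pmax(cc, 0.05), 0.98)
    ndvi <- pmin(pmax(unname(line_v[design$line]) +
                        stats::rnorm(n, 0, lp$ndvi_sd), 0.55), 0.93)
    ndre <- lp$ndre_mean_low + ifelse(high, lp$ndre_treat_shift, 0) +
      stats::rnorm(n, 0, lp$ndre_sd)
    ndre <- pmin(pmax(ndre, 0.10), 0.55)
    spec <- veg_spectrum_from_latents(ndvi, ndre, spectra)
    vis <- latent_vi_table(spec)
    preds <- tibble::tibble(PH = h, CC = cc)
    preds <- cbind(preds, vis)
    eps_f <- exp(stats::rnorm(n, 0, noise$biomass_log_sd))
    eps_d <- exp(stats::rnorm(n, 0, noise$biomass_log_sd))
    fresh <- predict(models$fresh, preds) * eps_f
    dry <- predict(models$dry, preds) * eps_d
    dry <- pmin(dry, 0.95 * fresh)  # dry mass can never exceed fresh mass
    z <- as.numeric(scale(ndre))
    leafN <- lp$leafN_mean + lp$leafN_sd *
      (lp$leafN_corr * z + sqrt(1 - lp$leafN_corr^2) * stats::rnorm(n))
    chl <- lp$chl_mean + lp$chl_sd *
      (lp$chl_corr * z + sqrt(1 - lp$chl_corr^2) * stats::rnorm(n))
    tibble::tibble(plot_id = design$plot_id, line = design$line,
                   treatment = design$treatment, rep = design$rep,
                   true_height_cm = h, true_cover = cc,
                   ndvi_latent = ndvi, ndre_latent = ndre,
                   fresh_biomass_kg = fresh, dry_biomass_kg = dry,
                   leaf_N_pct = pmax(leafN, 0.1),
                   chlorophyll = pmax(chl, 1))
  })
}

# All eight latent VI values implied by a canopy spectrum.
latent_vi_table <- function(spec) {
  with(spec, tibble::tibble(
    ExG = 2 * green - red - blue,
    NDVI = (nir - red) / (nir + red),
    RDVI = (nir - red) / sqrt(nir + red),
    GNDVI = (nir - green) / (nir + green),
    CI_Green = nir / green - 1,
    CI_RedEdge = nir / rededge - 1,
    NDRE = (nir - rededge) / (nir + rededge),
    RGBVI = (green^2 - blue * red) / (green^2 + blue * red)))
}

# Per-grid vegetation pattern: plot membership and crop-row canopy strips.
# Rows run north-south; per plot the strip width is cover * plot / rows so
# the vegetated pixel fraction matches true_cover.
render_field_masks <- function(design, truth, config, geom) {
  plot_index <- matrix(0L, geom$nrow, geom$ncol)
  veg <- matrix(FALSE, geom$nrow, geom$ncol)
  cx <- pixel_centers_x(geom)
  ps <- config$plot_size_m
  offs <- (seq_len(config$rows_per_plot) -
             (config$rows_per_plot + 1) / 2) * config$row_spacing_m
  for (i in seq_len(nrow(design))) {
    poly <- design$geometry[[i]]
    idx <- rasterize_plot(poly, geom)
    if (!length(idx)) stop("plot ", design$plot_id[i],
                           " lies outside the raster extent", call. = FALSE)
    plot_index[idx] <- i
    centers <- mean(range(poly[, 1])) + offs
    px_x <- cx[((idx - 1L) %/% geom$nrow) + 1L]
    dmin <- do.call(pmin, lapply(centers, function(cc) abs(px_x - cc)))
    # grow the row strips outward until exactly round(cover * n) pixels
    # are canopy, so the vegetated fraction matches true_cover to 1 pixel
    n_veg <- round(truth$true_cover[i] * length(idx))
    if (n_veg > 0) veg[idx[order(dmin, idx)[seq_len(n_veg)]]] <- TRUE
  }
  list(plot_index = plot_index, veg = veg)
}

#' Render a scene from a design and its ground truth
#'
#' Produces the five-band reflectance stack and pixel labels on the
#' multispectral grid, and the surface/terrain models on the finer
#' surface-model grid. Canopies are flat-topped per-plot row strips with
#' small height jitter; the canopy spectrum of each plot follows its
#' NDVI/NDRE latents; additive reflectance noise is applied before shadow
#' casting.
#'
#' @param design a [plot_set()] from [build_field_design()].
#' @param truth truth table from [simulate_plot_truths()].
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @return A `canophen_scene`: list with `bands` ([band_stack()]), `labels`,
#'   `dsm`, `dtm_true` ([cp_raster()]s), `plots`, `truth`, `config`.
#' @export
render_scene <- function(design, truth, config,
                         seed = derive_seed(config$seed, "render")) {
  if (!all(design$plot_id %in% truth$plot_id))
    stop("truth table does not cover all plots", call. = FALSE)
  truth <- truth[match(design$plot_id, truth$plot_id), ]
  ext <- attr(design, "extent")
  geom_ms <- grid_geom(ext["xmin"], ext["ymax"], config$gsd_ms_m,
                       round((ext["ymax"] - ext["ymin"]) / config$gsd_ms_m),
                       round((ext["xmax"] - ext["xmin"]) / config$gsd_ms_m))
  geom_sm <- grid_geom(ext["xmin"], ext["ymax"], config$gsd_rgb_m,
                       round((ext["ymax"] - ext["ymin"]) / config$gsd_rgb_m),
                       round((ext["xmax"] - ext["xmin"]) / config$gsd_rgb_m))
  ms <- render_field_masks(design, truth, config, geom_ms)
  sm <- render_field_masks(design, truth, config, geom_sm)

  dtm_vals <- function(geom) {
    x <- matrix(pixel_centers_x(geom), geom$nrow, geom$ncol, byrow = TRUE)
    config$dtm_base_m + config$dtm_slope * x
  }
  dtm_sm <- dtm_vals(geom_sm)
  heights <- matrix(0, geom_sm$nrow, geom_sm$ncol)
  vi <- which(sm$veg)
  heights[vi] <- truth$true_height_cm[sm$plot_index[vi]] / 100
  spec <- veg_spectrum_from_latents(truth$ndvi_latent, truth$ndre_latent,
                                    config$spectra)
  with_seed(seed, {
    if (config$noise$height_sd_m > 0 && length(vi)) {
      jit <- stats::rnorm(length(vi), 0, config$noise$height_sd_m)
      heights[vi] <- pmax(heights[vi] + jit, 0.5 * heights[vi])
    }
    bands <- list()
    vms <- which(ms$veg)
    pm <- ms$plot_index[vms]
    for (b in BAND_NAMES) {
      m <- matrix(config$spectra$soil[[b]], geom_ms$nrow, geom_ms$ncol)
      m[vms] <- spec[[b]][pm]
      if (config$noise$reflectance_sd > 0)
        m <- m + matrix(stats::rnorm(length(m), 0, config$noise$reflectance_sd),
                        nrow(m), ncol(m))
      bands[[b]] <- pmax(m, 0)
    }
  })
  labels <- matrix(label_codes()[["soil_sunlit"]], geom_ms$nrow, geom_ms$ncol)
  labels[ms$veg] <- label_codes()[["veg_sunlit"]]
  structure(list(bands = band_stack(bands, geom_ms),
                 labels = cp_raster(labels, geom_ms),
                 dsm = cp_raster(dtm_sm + heights, geom_sm),
                 dtm_true = cp_raster(dtm_sm, geom_sm),
                 plots = design, truth = truth, config = config),
            class = "canophen_scene")
}

#' @export
print.canophen_scene <- function(x, ...) {
  cat(sprintf("<canophen_scene> %d plots | MS %d x %d px | DSM %d x %d px\n",
              nrow(x$plots), x$bands$geom$nrow, x$bands$geom$ncol,
              x$dsm$geom$nrow, x$dsm$geom$ncol))
  invisible(x)
}

# Binary shadow mask by ray casting on a DSM: a pixel is shaded when any
# surface element along the ray toward the sun rises more than min_prom
# above the ray.
shadow_mask <- function(dsm, azimuth_deg, elevation_deg, min_prom = 0.15) {
  g <- dsm$geom
  if (elevation_deg >= 90) return(matrix(FALSE, g$nrow, g$ncol))
  tan_e <- tan(elevation_deg * pi / 180)
  az <- azimuth_deg * pi / 180
  dx <- sin(az); dy <- cos(az)
  z <- dsm$values
  zrange <- max(z, na.rm = TRUE) - min(z, na.rm = TRUE)
  K <- ceiling((zrange - min_prom) / (g$px * tan_e))
  shade <- matrix(FALSE, g$nrow, g$ncol)
  if (K < 1) return(shade)
  for (k in seq_len(K)) {
    dr <- as.integer(round(-k * dy))   # row decreases northward
    dc <- as.integer(round(k * dx))
    occ <- shift_matrix(z, dr, dc, fill = -Inf)
    shade <- shade | (occ > z + k * g$px * tan_e + min_prom)
  }
  shade
}

#' Cast shadows onto a rendered scene
#'
#' Projects shadows from the configured sun azimuth/elevation by ray
#' casting on the surface model (block-averaged to the multispectral grid),
#' relabels shaded pixels, and attenuates their reflectance — visible bands
#' more strongly than red-edge/NIR. The asymmetric attenuation makes shaded
#' pixels show a higher NDVI than sunlit canopy while their excess green
#' drops below the segmentation threshold, reproducing the shadow artifact
#' the segmentation stage must remove.
#'
#' @param scene a `canophen_scene` from [render_scene()].
#' @param config a [scene_config()] (defaults to the scene's own).
#' @return The scene with updated `bands` and `labels`.
#' @export
cast_shadows <- function(scene, config = scene$config) {
  if (is.null(scene$labels))
    stop("scene has no label raster; render it first", call. = FALSE)
  dsm_ms <- resample_block_mean(scene$dsm, scene$bands$geom)
  shade <- shadow_mask(dsm_ms, config$sun_azimuth_deg,
                       config$sun_elevation_deg,
                       config$shadow_min_prominence)
  if (!any(shade)) return(scene)
  att <- config$attenuation
  for (b in c("blue", "green", "red"))
    scene$bands$bands[[b]][shade] <- scene$bands$bands[[b]][shade] * att[["visible"]]
  for (b in c("rededge", "nir"))
    scene$bands$bands[[b]][shade] <- scene$bands$bands[[b]][shade] * att[["nir"]]
  lab <- scene$labels$values
  lc <- label_codes()
  lab[shade & lab == lc[["soil_sunlit"]]] <- lc[["soil_shaded"]]
  lab[shade & lab == lc[["veg_sunlit"]]] <- lc[["veg_shaded"]]
  scene$labels <- cp_raster(lab, scene$labels$geom)
  scene
}

#' Simulate a complete scene
#'
#' Runs design, truth simulation, rendering and shadow casting from one
#' root seed via named substreams.
#'
#' @param config a [scene_config()].
#' @return A `canophen_scene`.
#' @export
simulate_scene <- function(config = scene_config()) {
  design <- build_field_design(config)
  truth <- simulate_plot_truths(design, config$models, config$noise,
                                derive_seed(config$seed, "truths"),
                                config$latents, config$spectra)
  scene <- render_scene(design, truth, config)
  cast_shadows(scene, config)
}

#' Write / read scene artifacts
#'
#' Writes `bands.tif` (16-bit DN encoding), `dsm.tif`, `dtm.tif`,
#' `labels.tif`, `plots.geojson`, `truth.csv` and a checksum manifest.
#'
#' @param scene a `canophen_scene`.
#' @param dir output directory (created if missing).
#' @return the directory (write) or a `canophen_scene` (read), invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_multiband_raster(scene$bands, file.path(dir, "bands.tif"), "uint16_dn")
  write_raster(scene$dsm, file.path(dir, "dsm.tif"), "float32")
  write_raster(scene$dtm_true, file.path(dir, "dtm.tif"), "float32")
  write_raster(scene$labels, file.path(dir, "labels.tif"), "uint8")
  write_plot_polygons(scene$plots, file.path(dir, "plots.geojson"))
  write_table_csv(scene$truth, file.path(dir, "truth.csv"))
  saveRDS_free_manifest(dir)
  invisible(dir)
}

saveRDS_free_manifest <- function(dir) {
  files <- setdiff(list.files(dir), "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  jsonlite::write_json(as.list(sums), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  plots <- read_plot_polygons(file.path(dir, "plots.geojson"))
  bands <- read_multiband_raster(file.path(dir, "bands.tif"))
  g <- bands$geom
  ext <- c(xmin = g$xmin, xmax = g$xmin + g$ncol * g$px,
           ymin = g$ymax - g$nrow * g$px, ymax = g$ymax)
  xs <- range(unlist(lapply(plots$geometry, function(gm) gm[, 1])))
  attr(plots, "extent") <- ext
  attr(plots, "margins") <- list(
    west = rect_polygon(ext["xmin"], ext["ymin"], xs[1], ext["ymax"]),
    east = rect_polygon(xs[2], ext["ymin"], ext["xmax"], ext["ymax"]))
  structure(list(
    bands = bands,
    labels = read_raster(file.path(dir, "labels.tif")),
    dsm = read_raster(file.path(dir, "dsm.tif")),
    dtm_true = read_raster(file.path(dir, "dtm.tif")),
    plots = plots,
    truth = read_table_csv(file.path(dir, "truth.csv")),
    config = NULL), class = "canophen_scene")
}
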