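make_strips <- function(width, height, strip) {
  list(west = cbind(c(0, strip, strip, 0), c(0, 0, height, height)),
       east = cbind(c(width - strip, width, width, width - strip),
                    c(0, 0, height, height)))
}

test_that("terrain estimation interpolates between the margin strips", {
  g <- grid_geom(0, 10, 1, 10, 102)
  strips <- make_strips(102, 10, 2)
  flat <- cp_raster(matrix(100, 10, 102), g)
  expect_equal(estimate_dtm(flat, strips)$values,
               matrix(100, 10, 102), tolerance = 1e-12)
  # west strip at 100 m, east at 102 m, centred 100 px apart
  ramp <- matrix(100, 10, 102)
  ramp[, 101:102] <- 102
  dtm <- estimate_dtm(cp_raster(ramp, g), strips)
  centers <- pixel_centers_x(g)
  mid <- which.min(abs(centers - 51))
  expect_equal(dtm$values[5, mid], 100 + 2 * (centers[mid] - 1) / 100,
               tolerance = 1e-9)   # linear ramp between strip centres
  expect_equal(stats::coef(stats::lm(dtm$values[5, 10:90] ~
                                       centers[10:90]))[[2]], 2 / 100,
               tolerance = 1e-9)
  # shift equivariance
  dtm5 <- estimate_dtm(cp_raster(ramp + 5, g), strips)
  expect_equal(dtm5$values, dtm$values + 5, tolerance = 1e-9)
})

test_that("height map converts, clips and validates geometry", {
  g <- grid_geom(0, 2, 1, 2, 2)
  dsm <- cp_raster(matrix(c(103.5, 100, 99.98, 100), 2), g)
  dtm <- cp_raster(matrix(100, 2, 2), g)
  h <- height_map(dsm, dtm)
  expect_equal(h$values[1, 1], 350)
  expect_equal(h$values[1, 2], 0)      # -0.02 m clipped
  expect_equal(h$values[2, 1], 0)
  expect_error(height_map(dsm, cp_raster(matrix(0, 3, 3),
                                         grid_geom(0, 3, 1, 3, 3))),
               "geometries differ")
})

test_that("plot height percentiles match a sort-and-interpolate oracle", {
  g100 <- grid_geom(0, 10, 0.1, 100, 100)
  set.seed(11)
  for (n in c(10, 137, 4000)) {
    vals <- matrix(0, 100, 100)
    idx <- sample.int(10000, n)
    vals[idx] <- rexp(n, 1 / 150)
    r <- cp_raster(vals, g100)
    for (q in c(90, 93, 95, 98))
      expect_equal(plot_height_percentile(r, idx, q),
                   oracle_percentile(vals[idx], q), tolerance = 1e-10)
    expect_gte(plot_height_percentile(r, idx, 98),
               plot_height_percentile(r, idx, 90))
  }
  const <- cp_raster(matrix(200, 100, 100), g100)
  expect_equal(plot_height_percentile(const, 1:500, 93), 200)
  expect_error(plot_height_percentile(const, integer(0), 90), "empty")
})

test_that("canopy cover is the sunlit pixel ratio", {
  g <- grid_geom(0, 1, 0.1, 10, 10)
  mask <- structure(list(values = matrix(FALSE, 10, 10), geom = g,
                         threshold = 0), class = "veg_mask")
  expect_equal(canopy_cover(mask, 1:100), 0)
  mask$values[1:50] <- TRUE
  expect_equal(canopy_cover(mask, 1:100), 0.5)
  mask$values[] <- TRUE
  expect_equal(canopy_cover(mask, 1:100), 1)
  expect_error(canopy_cover(mask, integer(0)), "empty")
})

test_that("vegetation index formulas give their closed-form values", {
  g <- grid_geom(0, 0.1, 0.1, 1, 1)
  mk <- function(v) matrix(v, 1, 1)
  st <- function(b, g_, r, re, n)
    band_stack(list(blue = mk(b), green = mk(g_), red = mk(r),
                    rededge = mk(re), nir = mk(n)), g)
  val <- function(stack, vi, ...) compute_vi(stack, vi, ...)$values[1, 1]
  expect_equal(val(st(0.1, 0.1, 0.5, 0.3, 0.5), "NDVI"), 0)
  expect_equal(val(st(0.1, 0.1, 0.2, 0.3, 0.8), "NDVI"), 0.6)
  expect_equal(val(st(0.1, 0.1, 0.2, 0.3, 0.8), "RDVI"), 0.6 / sqrt(1.0))
  expect_equal(val(st(0.1, 0.1, 0.2, 0.3, 0.8), "RDVI", rdvi_compat = TRUE),
               0.6)
  expect_equal(val(st(0.1, 0.2, 0.3, 0.3, 0.6), "GNDVI"), 0.5)
  expect_equal(val(st(0.1, 0.2, 0.3, 0.3, 0.6), "CI_Green"), 2)
  expect_equal(val(st(0.1, 0.2, 0.3, 0.3, 0.6), "CI_RedEdge"), 1)
  expect_equal(val(st(0.1, 0.2, 0.3, 0.3, 0.6), "NDRE"), 1 / 3)
  expect_equal(val(st(0.1, 0.2, 0.4, 0.3, 0.6), "RGBVI"), 0)  # G^2 = B R
  expect_equal(val(st(0.05, 0.20, 0.08, 0.3, 0.6), "ExG"), 0.27)
  expect_error(compute_vi(st(0.1, 0.1, 0.1, 0.1, 0.1), "EVI"), "unknown")
  # division by zero becomes nodata
  expect_true(is.na(val(st(0.1, 0, 0.1, 0.1, 0.3), "CI_Green")))
})

test_that("normalized-difference indices are bounded and scale-invariant", {
  st <- random_stack(30, seed = 9)
  doubled <- st
  for (b in names(doubled$bands)) doubled$bands[[b]] <- doubled$bands[[b]] * 2.7
  for (vi in c("NDVI", "GNDVI", "NDRE", "RGBVI")) {
    v <- compute_vi(st, vi)$values
    expect_true(all(v >= -1 & v <= 1, na.rm = TRUE))
  }
  for (vi in c("NDVI", "GNDVI", "NDRE", "CI_Green", "CI_RedEdge", "RGBVI"))
    expect_equal(compute_vi(doubled, vi)$values, compute_vi(st, vi)$values,
                 tolerance = 1e-12)
})

test_that("plot VI means honour the sunlit mask", {
  g <- grid_geom(0, 1, 0.5, 2, 2)
  vi <- cp_raster(matrix(c(0.2, 0.9, 0.2, 0.9), 2), g)
  mask <- structure(list(values = matrix(c(TRUE, FALSE, TRUE, FALSE), 2),
                         geom = g, threshold = 0), class = "veg_mask")
  expect_equal(plot_mean_vi(vi, mask, 1:4), 0.2)
  mask$values[] <- FALSE
  expect_true(is.na(plot_mean_vi(vi, mask, 1:4)))
  const <- cp_raster(matrix(0.7, 2, 2), g)
  mask$values[] <- TRUE
  expect_equal(plot_mean_vi(const, mask, 1:4), 0.7)
})

test_that("shadow masking lowers the plot NDVI mean below the naive mean", {
  scene <- default_small_scene()
  mask <- sunlit_vegetation_mask(scene$bands, 0.046)
  ndvi <- compute_vi(scene$bands, "NDVI")
  lc <- label_codes()
  veg_any <- scene$labels$values %in% lc[c("veg_sunlit", "veg_shaded")]
  shaded_any <- scene$labels$values %in% lc[c("soil_shaded", "veg_shaded")]
  for (i in seq_len(nrow(scene$plots))) {
    idx <- rasterize_plot(scene$plots$geometry[[i]], scene$bands$geom)
    if (!any(shaded_any[idx])) next
    masked <- plot_mean_vi(ndvi, mask, idx)
    naive <- mean(ndvi$values[idx][veg_any[idx] | shaded_any[idx]])
    expect_lte(masked, naive)
  }
})

test_that("traits extracted from a noiseless scene recover the truth", {
  cfg <- small_scene_config(noise = noise_params(0, 0, 0),
                            sun_elevation_deg = 90)
  scene <- simulate_scene(cfg)
  mask <- sunlit_vegetation_mask(scene$bands, cfg$exg_threshold)
  traits <- extract_plot_traits(scene$bands, scene$dsm,
                                attr(scene$plots, "margins"), mask,
                                scene$plots)
  expect_equal(nrow(traits), nrow(scene$plots))
  cmp <- merge(traits, scene$truth, by = "plot_id")
  expect_lt(max(abs(cmp$ph90 - cmp$true_height_cm)), 1)
  expect_lt(max(abs(cmp$cc - cmp$true_cover)), 1 / min(cmp$n_pixels) + 1e-9)
  expect_lt(max(abs(cmp$ndvi - cmp$ndvi_latent)), 1e-6)
  expect_lt(max(abs(cmp$ndre - cmp$ndre_latent)), 1e-6)
  expect_equal(cmp$cc, cmp$n_sunlit / cmp$n_pixels)
})

test_that("traits track truth within tolerance on noisy shadowed scenes", {
  ok_cc <- ok_ph <- c()
  for (s in 1:3) {
    scene <- default_small_scene(seed = s)
    mask <- sunlit_vegetation_mask(scene$bands, 0.046)
    traits <- extract_plot_traits(scene$bands, scene$dsm,
                                  attr(scene$plots, "margins"), mask,
                                  scene$plots)
    cmp <- merge(traits, scene$truth, by = "plot_id")
    ok_ph <- c(ok_ph, abs(cmp$ph90 - cmp$true_height_cm) /
                 cmp$true_height_cm < 0.10)
    ok_cc <- c(ok_cc, abs(cmp$cc - cmp$true_cover) < 0.05)
  }
  expect_gte(mean(ok_ph), 0.90)
  expect_gte(mean(ok_cc), 0.90)
})

test_that("the best height percentile is selected by correlation", {
  scene <- default_small_scene()
  mask <- sunlit_vegetation_mask(scene$bands, 0.046)
  traits <- extract_plot_traits(scene$bands, scene$dsm,
                                attr(scene$plots, "margins"), mask,
                                scene$plots)
  measured <- data.frame(plot_id = traits$plot_id,
                         height_cm = traits$ph90)
  sel <- select_height_percentile(traits, measured)
  expect_equal(sel$percentile, 90)
  expect_equal(sel$r_table$r[sel$r_table$percentile == 90], 1.0)
  set.seed(4)
  measured95 <- data.frame(plot_id = traits$plot_id,
                           height_cm = traits$ph95 + rnorm(nrow(traits), 0, 0.5))
  expect_equal(select_height_percentile(traits, measured95)$percentile, 95)
  expect_error(select_height_percentile(
    traits, data.frame(plot_id = traits$plot_id, height_cm = 1)),
    "constant")
})

test_that("spectral band averaging matches a fine quadrature oracle", {
  wl <- seq(350, 2500, by = 1)
  flat <- resample_spectrum_to_bands(wl, rep(0.5, length(wl)))
  expect_equal(unname(flat), rep(0.5, 5), tolerance = 1e-12)
  lin <- resample_spectrum_to_bands(wl, 0.0002 * wl)
  expect_equal(unname(lin), 0.0002 * micasense_bands()$center_nm,
               tolerance = 1e-6)
  # step spectrum against brute-force 0.1 nm quadrature
  step_fun <- function(w) ifelse(w < 700, 0.1, 0.6)
  got <- resample_spectrum_to_bands(wl, step_fun(wl))
  bands <- micasense_bands()
  for (i in seq_len(nrow(bands))) {
    wf <- seq(bands$center_nm[i] - 1.5 * bands$fwhm_nm[i],
              bands$center_nm[i] + 1.5 * bands$fwhm_nm[i], by = 0.1)
    sigma <- bands$fwhm_nm[i] / (2 * sqrt(2 * log(2)))
    gw <- exp(-0.5 * ((wf - bands$center_nm[i]) / sigma)^2)
    want <- sum(gw * step_fun(wf)) / sum(gw)
    expect_lt(abs(got[[i]] - want), 1e-4)
  }
  expect_error(resample_spectrum_to_bands(seq(500, 600), rep(0.5, 101)),
               "does not cover")
  gap <- wl[wl < 800 | wl > 880]
  expect_error(resample_spectrum_to_bands(gap, step_fun(gap)), "gap")
})
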