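#' Run configuration for the end-to-end pipeline
#'
#' A single configuration object (optionally loaded from YAML) drives
#' simulate, extract and model stages.
#'
#' @param scene a [scene_config()], or a list of its fields.
#' @param exg_threshold segmentation threshold.
#' @param height_percentile which height percentile feeds models as PH.
#' @param responses truth columns to model.
#' @param k cross-validation folds.
#' @param test_fraction held-out fraction for the train/test split.
#' @param screen_predictors if `TRUE`, multi-predictor sets violating the
#'   admissibility bound on the data's own correlation matrix are skipped
#'   (with the reason logged).
#' @param admissibility_threshold bound used when screening.
#' @param seed root seed for split and CV.
#' @return A `run_config` list.
#' @export
run_config <- function(scene = scene_config(), exg_threshold = 0.046,
                       height_percentile = 90,
                       responses = c("fresh_biomass_kg", "dry_biomass_kg"),
                       k = 10, test_fraction = 0.2,
                       screen_predictors = FALSE,
                       admissibility_threshold = 0.69, seed = 1L) {
  if (!inherits(scene, "scene_config")) scene <- do.call(scene_config, scene)
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unspecified fields take the [run_config()] defaults; the `scene` block
#' maps to [scene_config()] fields, with `noise` and `latents` sub-blocks.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scene)) {
    sc <- y$scene
    if (!is.null(sc$noise)) sc$noise <- do.call(noise_params, sc$noise)
    if (!is.null(sc$latents)) sc$latents <- do.call(latent_params, sc$latents)
    y$scene <- do.call(scene_config, sc)
  }
  do.call(run_config, y)
}

log_msg <- function(...) message(sprintf(...))

#' Simulate a scene and write its artifacts
#'
#' @param config a `run_config` (or path to a YAML one).
#' @param out_dir output directory for the scene files.
#' @return the scene, invisibly; artifacts and a checksum manifest are
#'   written to `out_dir`.
#' @export
cmd_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  scene <- simulate_scene(config$scene)
  write_scene(scene, out_dir)
  log_msg("simulated %d plots -> %s", nrow(scene$plots), out_dir)
  invisible(scene)
}

#' Segment and extract plot traits from scene artifacts
#'
#' Reads the scene from `scene_dir` (or takes an in-memory scene), builds
#' the sunlit-vegetation mask, estimates the terrain model from the margin
#' strips, extracts per-plot traits and writes `mask.tif` and
#' `traits.csv`. Plots flagged for zero sunlit pixels are counted in the
#' log.
#'
#' @param scene a `canophen_scene` or a directory written by
#'   [cmd_simulate()].
#' @param out_dir output directory.
#' @param exg_threshold segmentation threshold.
#' @return the trait table, invisibly.
#' @export
cmd_extract <- function(scene, out_dir, exg_threshold = 0.046) {
  if (is.character(scene)) scene <- read_scene(scene)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mask <- sunlit_vegetation_mask(scene$bands, exg_threshold)
  margins <- attr(scene$plots, "margins")
  traits <- extract_plot_traits(scene$bands, scene$dsm, margins, mask,
                                scene$plots)
  write_raster(cp_raster(mask$values * 1, mask$geom),
               file.path(out_dir, "mask.tif"), "uint8")
  write_table_csv(traits, file.path(out_dir, "traits.csv"))
  n_flag <- sum(traits$n_sunlit == 0)
  log_msg("extracted %d plots (%d flagged with zero sunlit pixels) -> %s",
          nrow(traits), n_flag, out_dir)
  invisible(traits)
}

trait_column_for <- function(pred, height_percentile) {
  switch(pred,
         PH = paste0("ph", height_percentile), CC = "cc", NDVI = "ndvi",
         NDRE = "ndre", RDVI = "rdvi", RGBVI = "rgbvi", ExG = "exg",
         GNDVI = "gndvi", CI_Green = "ci_green", CI_RedEdge = "ci_rededge",
         stop("unknown predictor: ", pred, call. = FALSE))
}

#' Fit and evaluate the configured biomass models
#'
#' Merges traits with ground truth, splits 4:1, fits every configured
#' simple and multiple exponential model on the training set, runs k-fold
#' cross-validation, evaluates on the test set, runs the nitrogen-treatment
#' t-tests on CI_Green / CI_RedEdge / NDRE, and correlates VIs with the lab
#' traits. Writes `models.csv`, `cv.csv`, `test.csv`, `ttests.csv`,
#' `vi_lab_corr.csv`.
#'
#' @param traits trait table (or path to `traits.csv`).
#' @param truth truth table (or path) with responses and, when present,
#'   `treatment`, `leaf_N_pct`, `chlorophyll`.
#' @param out_dir report directory.
#' @param config a `run_config`.
#' @param predictor_sets list of predictor-name vectors; default the six
#'   single predictors plus the ten investigated combinations.
#' @return list of the report tables, invisibly.
#' @export
cmd_model <- function(traits, truth, out_dir, config = run_config(),
                      predictor_sets = NULL) {
  if (is.character(traits)) traits <- read_table_csv(traits)
  if (is.character(truth)) truth <- read_table_csv(truth)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(predictor_sets))
    predictor_sets <- c(as.list(c("PH", "CC", "NDVI", "NDRE", "RDVI",
                                  "RGBVI")),
                        reference_predictor_sets())
  if (!length(predictor_sets) || any(!lengths(predictor_sets)))
    stop("empty predictor list", call. = FALSE)
  dat <- merge(traits, truth, by = "plot_id")
  dat <- dat[dat$n_sunlit > 0, ]
  excluded <- setdiff(truth$plot_id, dat$plot_id)
  if (length(excluded))
    log_msg("excluded %d plot(s) with no usable traits: %s",
            length(excluded), paste(utils::head(excluded, 5), collapse = ", "))
  hp <- config$height_percentile
  all_preds <- unique(unlist(predictor_sets))
  pred_cols <- vapply(all_preds, trait_column_for, character(1),
                      height_percentile = hp)
  X_all <- stats::setNames(dat[pred_cols], all_preds)

  keep <- predictor_sets
  if (isTRUE(config$screen_predictors)) {
    cm <- correlation_matrix(X_all, threshold = config$admissibility_threshold)
    keep <- list()
    for (s in predictor_sets) {
      if (length(s) == 1) { keep[[length(keep) + 1L]] <- s; next }
      adm <- admissible_predictor_sets(cm, config$admissibility_threshold,
                                       extra_sets = list(s))
      rej <- attr(adm, "rejected")
      if (nrow(rej)) log_msg("skipped model %s: %s", rej$set, rej$reason)
      else keep[[length(keep) + 1L]] <- s
    }
  }

  split <- train_test_split(nrow(dat), config$test_fraction,
                            derive_seed(config$seed, "split"))
  models <- list(); cv <- list(); test <- list()
  for (resp in config$responses) {
    y <- dat[[resp]]
    for (s in keep) {
      X <- X_all[s]
      fit <- fit_exponential(X[split$train, , drop = FALSE], y[split$train],
                             response = resp)
      cvres <- kfold_cv(X[split$train, , drop = FALSE], y[split$train],
                        k = config$k, seed = derive_seed(config$seed, "cv"))
      ev <- evaluate_on_test(fit, X[split$test, , drop = FALSE],
                             y[split$test])
      tag <- paste(s, collapse = "+")
      mt <- if (length(s) == 1) "SER" else "MER"
      mrow <- tibble::tibble(response = resp, model_type = mt,
                             predictors = tag, a = fit$a)
      for (p in c("PH", "CC", "NDVI", "NDRE", "RDVI", "RGBVI", "ExG",
                  "GNDVI", "CI_Green", "CI_RedEdge"))
        if (p %in% names(fit$b)) mrow[[paste0("b_", p)]] <- fit$b[[p]]
      models[[length(models) + 1L]] <- mrow
      cv[[length(cv) + 1L]] <- tibble::tibble(
        response = resp, predictors = tag, rmse = cvres$rmse,
        std = cvres$std, k = cvres$k)
      test[[length(test) + 1L]] <- tibble::tibble(
        response = resp, predictors = tag, rmse = ev$rmse, r = ev$r,
        p_value = ev$p_value, n = ev$n)
    }
  }
  bind_ragged <- function(lst) {
    cols <- unique(unlist(lapply(lst, names)))
    do.call(rbind, lapply(lst, function(d) {
      for (cl in setdiff(cols, names(d))) d[[cl]] <- NA_real_
      d[cols]
    }))
  }
  report <- list(models = bind_ragged(models), cv = do.call(rbind, cv),
                 test = do.call(rbind, test))

  if ("treatment" %in% names(dat) && length(unique(dat$treatment)) == 2) {
    tt <- lapply(c("ci_green", "ci_rededge", "ndre"), function(v) {
      res <- treatment_ttest(dat[[v]], dat$treatment)
      tibble::tibble(vi = v, t = res$t, p_value = res$p_value,
                     mean_group1 = res$group_means[1],
                     mean_group2 = res$group_means[2],
                     n1 = res$group_sizes[1], n2 = res$group_sizes[2])
    })
    report$ttests <- do.call(rbind, tt)
  }
  lab_cols <- intersect(c("chlorophyll", "leaf_N_pct"), names(truth))
  if (length(lab_cols))
    report$vi_lab_corr <- correlate_vi_with_lab(
      traits, truth[c("plot_id", lab_cols)], lab_cols = lab_cols)

  write_table_csv(report$models, file.path(out_dir, "models.csv"))
  write_table_csv(report$cv, file.path(out_dir, "cv.csv"))
  write_table_csv(report$test, file.path(out_dir, "test.csv"))
  if (!is.null(report$ttests))
    write_table_csv(report$ttests, file.path(out_dir, "ttests.csv"))
  if (!is.null(report$vi_lab_corr))
    write_table_csv(report$vi_lab_corr, file.path(out_dir, "vi_lab_corr.csv"))
  invisible(report)
}

#' One-shot end-to-end demonstration on a reduced field
#'
#' Simulates a 4-line x 2-treatment x 2-replicate field (16 plots) at a
#' coarse ground sampling distance, extracts traits, fits the biomass
#' models, and prints the recovered three-predictor dry-biomass
#' coefficients next to the generating values.
#'
#' @param seed integer seed.
#' @param dir working directory (default a session temp dir).
#' @return list with `scene`, `traits`, `report`, invisibly.
#' @export
run_demo <- function(seed = 1L, dir = file.path(tempdir(), "canophen_demo")) {
  cfg <- run_config(
    scene = scene_config(n_lines = 4, n_treatments = 2, n_reps = 2,
                         gsd_ms_m = 0.05, gsd_rgb_m = 0.04,
                         margin_strip_m = 1, seed = seed),
    k = 5, seed = seed)
  scene <- cmd_simulate(cfg, file.path(dir, "scene"))
  traits <- cmd_extract(scene, file.path(dir, "extract"),
                        cfg$exg_threshold)
  report <- cmd_model(traits, scene$truth, file.path(dir, "report"), cfg)
  gen <- cfg$scene$models$dry
  fitted <- report$models[report$models$response == "dry_biomass_kg" &
                            report$models$predictors == "PH+CC+NDRE", ]
  cat("Three-predictor dry-biomass model (PH + CC + NDRE):\n")
  cat(sprintf("  generating: a = %.3f, b = (%.4f, %.3f, %.3f)\n",
              gen$a, gen$b[["PH"]], gen$b[["CC"]], gen$b[["NDRE"]]))
  cat(sprintf("  recovered:  a = %.3f, b = (%.4f, %.3f, %.3f)\n",
              fitted$a, fitted$b_PH, fitted$b_CC, fitted$b_NDRE))
  invisible(list(scene = scene, traits = traits, report = report))
}
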