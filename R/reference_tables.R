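#' Published exponential biomass model coefficients
#'
#' The simple (SER) and multiple (MER) exponential regression coefficients
#' reported for late-season sorghum fresh and dry above-ground biomass (kg
#' per plot) as functions of plant height (PH, cm), canopy cover (CC,
#' fraction) and vegetation indices. These serve as generative ground truth
#' for parameter-recovery simulations and as a layout reference for model
#' reports.
#'
#' @param response `"fresh"` or `"dry"`.
#' @return tibble: `model_type` (SER/MER), `predictors` (plus-joined
#'   names), `a`, and rate coefficient columns `b_PH`, `b_CC`, `b_NDVI`,
#'   `b_NDRE`, `b_RDVI`, `b_RGBVI` (NA where absent).
#' @export
reference_biomass_models <- function(response = c("fresh", "dry")) {
  response <- match.arg(response)
  row <- function(type, preds, a, ...) {
    b <- c(...)
    out <- tibble::tibble(model_type = type,
                          predictors = paste(names(b), collapse = "+"),
                          a = a, b_PH = NA_real_, b_CC = NA_real_,
                          b_NDVI = NA_real_, b_NDRE = NA_real_,
                          b_RDVI = NA_real_, b_RGBVI = NA_real_)
    for (nm in names(b)) out[[paste0("b_", nm)]] <- b[[nm]]
    out
  }
  fresh <- rbind(
    row("SER", NULL, 21.22, PH = 0.005),
    row("SER", NULL, 22.47, CC = 1.618),
    row("SER", NULL, 0.31, NDVI = 7.03),
    row("SER", NULL, 14.02, NDRE = 3.813),
    row("SER", NULL, 2.04, RDVI = 6.973),
    row("SER", NULL, 6.41, RGBVI = 3.68),
    row("MER", NULL, 18.70, PH = 0.004, CC = 0.246),
    row("MER", NULL, 0.26, NDVI = 6.637, RGBVI = 0.706),
    row("MER", NULL, 1.36, NDRE = 3.605, RGBVI = 3.571),
    row("MER", NULL, 1.32, RDVI = 6.41, RGBVI = 1.069),
    row("MER", NULL, 16.54, PH = 0.004, NDRE = 1.166),
    row("MER", NULL, 9.37, PH = 0.004, RGBVI = 1.370),
    row("MER", NULL, 0.31, CC = 0.584, NDVI = 6.447),
    row("MER", NULL, 5.86, CC = 1.336, NDRE = 3.486),
    row("MER", NULL, 1.96, CC = 0.434, RDVI = 6.412),
    row("MER", NULL, 10.63, PH = 0.003, CC = 0.6, NDRE = 1.728))
  dry <- rbind(
    row("SER", NULL, 5.63, PH = 0.004),
    row("SER", NULL, 6.50, CC = 1.42),
    row("SER", NULL, 0.22, NDVI = 5.679),
    row("SER", NULL, 4.46, NDRE = 3.272),
    row("SER", NULL, 0.91, RDVI = 5.869),
    row("SER", NULL, 3.04, RGBVI = 2.726),
    row("MER", NULL, 5.15, PH = 0.004, CC = 0.169),
    row("MER", NULL, 0.22, NDVI = 5.607, RGBVI = 0.130),
    row("MER", NULL, 0.86, NDRE = 3.125, RGBVI = 2.522),
    row("MER", NULL, 0.77, RDVI = 5.664, RGBVI = 0.392),
    row("MER", NULL, 5.03, PH = 0.004, NDRE = 0.545),
    row("MER", NULL, 4.47, PH = 0.004, RGBVI = 0.384),
    row("MER", NULL, 0.22, CC = 0.61, NDVI = 5.085),
    row("MER", NULL, 1.94, CC = 1.222, NDRE = 3.041),
    row("MER", NULL, 0.86, CC = 0.472, RDVI = 5.278),
    row("MER", NULL, 3.90, PH = 0.003, CC = 0.345, NDRE = 0.87))
  if (response == "fresh") fresh else dry
}

#' Turn a reference-model row into an exponential model object
#'
#' @param row one row of [reference_biomass_models()].
#' @param response response name for the model object.
#' @return An [exponential_model()].
#' @export
reference_model_as_object <- function(row, response = "biomass_kg") {
  bcols <- grep("^b_", names(row), value = TRUE)
  b <- unlist(row[bcols])
  b <- b[!is.na(b)]
  names(b) <- sub("^b_", "", names(b))
  exponential_model(row$a, b, response = response)
}

#' Published correlation matrix of candidate biomass predictors
#'
#' Pairwise Pearson correlations among plant height, canopy cover, NDVI,
#' NDRE, RDVI and RGBVI over the field plots, used for predictor
#' admissibility screening at |r| < 0.69.
#'
#' @return 6 x 6 symmetric [correlation_matrix()].
#' @export
reference_predictor_correlations <- function() {
  nms <- c("PH", "CC", "NDVI", "NDRE", "RDVI", "RGBVI")
  m <- diag(6)
  dimnames(m) <- list(nms, nms)
  lower <- list(
    c("CC", "PH", 0.61),
    c("NDVI", "PH", 0.74), c("NDVI", "CC", 0.54),
    c("NDRE", "PH", 0.68), c("NDRE", "CC", 0.25), c("NDRE", "NDVI", 0.90),
    c("RDVI", "PH", 0.80), c("RDVI", "CC", 0.57), c("RDVI", "NDVI", 0.96),
    c("RDVI", "NDRE", 0.89),
    c("RGBVI", "PH", 0.54), c("RGBVI", "CC", 0.75), c("RGBVI", "NDVI", 0.64),
    c("RGBVI", "NDRE", 0.26), c("RGBVI", "RDVI", 0.59))
  for (e in lower) {
    m[e[1], e[2]] <- as.numeric(e[3])
    m[e[2], e[1]] <- as.numeric(e[3])
  }
  structure(m, class = c("correlation_matrix", class(m)), threshold = 0.69)
}

#' The ten investigated multi-predictor combinations
#'
#' The nine admissible pairs under |r| < 0.69 plus the three-predictor set
#' (PH, CC, NDRE) whose internal pairs are all admissible.
#'
#' @return list of character vectors.
#' @export
reference_predictor_sets <- function() {
  list(c("PH", "CC"), c("NDVI", "RGBVI"), c("NDRE", "RGBVI"),
       c("RDVI", "RGBVI"), c("PH", "NDRE"), c("PH", "RGBVI"),
       c("CC", "NDVI"), c("CC", "NDRE"), c("CC", "RDVI"),
       c("PH", "CC", "NDRE"))
}
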