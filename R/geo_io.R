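#' Band definitions of the five-band multispectral camera
#'
#' Centre wavelength and FWHM bandwidth of the blue, green, red, red-edge
#' and near-infrared bands of the RedEdge-class multispectral camera.
#'
#' @return A tibble with columns `name`, `center_nm`, `fwhm_nm`.
#' @export
micasense_bands <- function() {
  tibble::tibble(
    name      = c("blue", "green", "red", "rededge", "nir"),
    center_nm = c(475, 560, 668, 717, 840),
    fwhm_nm   = c(20, 20, 10, 10, 40)
  )
}

BAND_NAMES <- c("blue", "green", "red", "rededge", "nir")
DN_SCALE <- 32768

#' Convert 16-bit digital numbers to reflectance
#'
#' The camera vendor's convention encodes 100% reflectance as digital
#' number 32768, so reflectance = DN / 32768 (values above 32768 encode
#' reflectance above 1, up to 65535/32768).
#'
#' @param dn integer digital numbers in \[0, 65535\].
#' @return numeric reflectance.
#' @export
scale_dn_to_reflectance <- function(dn) {
  if (any(!is.na(dn) & (dn < 0 | dn > 65535)))
    stop("digital numbers must lie in [0, 65535]", call. = FALSE)
  dn / DN_SCALE
}

#' Co-registered five-band reflectance stack
#'
#' @param bands named list of numeric matrices (`blue`, `green`, `red`,
#'   `rededge`, `nir`), reflectance units, `NA` = nodata.
#' @param geom shared [grid_geom()].
#' @return A `band_stack`.
#' @export
band_stack <- function(bands, geom) {
  stopifnot(is.list(bands), !is.null(names(bands)))
  dims <- c(geom$nrow, geom$ncol)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!all(dim(b) == dims))
      stop("band '", nm, "' does not match the grid geometry", call. = FALSE)
    if (any(b < 0, na.rm = TRUE))
      stop("band '", nm, "' contains negative reflectance", call. = FALSE)
  }
  structure(list(bands = bands, geom = geom), class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  cat(sprintf("<band_stack> %s | %d x %d px @ %.4g m\n",
              paste(names(x$bands), collapse = ", "),
              x$geom$nrow, x$geom$ncol, x$geom$px))
  invisible(x)
}

world_file_path <- function(path) sub("\\.tiff?$", ".tfw", path)
sidecar_path <- function(path) paste0(path, ".json")

write_world_file <- function(geom, path) {
  lines <- c(geom$px, 0, 0, -geom$px,
             geom$xmin + geom$px / 2, geom$ymax - geom$px / 2)
  writeLines(format(lines, digits = 15), world_file_path(path))
}

geom_to_list <- function(geom) geom[c("xmin", "ymax", "px", "nrow", "ncol")]
geom_from_list <- function(l) grid_geom(l$xmin, l$ymax, l$px, l$nrow, l$ncol)

# Internal storage model: multi-page TIFF (one page per band). uint16_dn
# pages hold DN/65535 so the 16-bit sample is the DN itself (bit-exact).
# float32 pages hold value/scale with the scale recorded in the JSON
# sidecar, because 32-bit float TIFF samples are only well defined in
# [0, 1] by the writer; round-trip accuracy is float32 precision of the
# scaled value. Nodata is carried as an extra validity page when present.
write_pages <- function(pages, path, bits) {
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
}

#' Write a multiband reflectance raster
#'
#' @param stack a [band_stack()].
#' @param path output TIFF path; a `.tfw` world file and a `.json` sidecar
#'   (geometry, band names, encoding) are written alongside.
#' @param encoding `"uint16_dn"` (DN = reflectance x 32768, clamped to
#'   \[0, 65535\] and rounded) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_multiband_raster <- function(stack, path, encoding = c("uint16_dn", "float32")) {
  encoding <- match.arg(encoding)
  bands <- stack$bands
  has_na <- any(vapply(bands, anyNA, logical(1)))
  meta <- list(geom = geom_to_list(stack$geom), band_names = names(bands),
               encoding = encoding, nodata_page = has_na)
  if (encoding == "uint16_dn") {
    pages <- lapply(bands, function(b) {
      dn <- round(pmin(pmax(b, 0), 65535 / DN_SCALE) * DN_SCALE)
      dn[is.na(dn)] <- 0
      dn / 65535
    })
    bits <- 16L
  } else {
    scale <- max(1, max(unlist(lapply(bands, max, na.rm = TRUE)), na.rm = TRUE))
    meta$scale <- scale
    pages <- lapply(bands, function(b) { b[is.na(b)] <- 0; b / scale })
    bits <- 32L
  }
  if (has_na) {
    valid <- Reduce(`&`, lapply(bands, function(b) !is.na(b)))
    pages <- c(pages, list(valid * 1))
  }
  write_pages(pages, path, bits)
  write_world_file(stack$geom, path)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multiband reflectance raster
#'
#' @param path TIFF written by [write_multiband_raster()].
#' @param band_order expected bands, as from [micasense_bands()]; the file
#'   must contain exactly this many bands.
#' @return A [band_stack()] in reflectance units.
#' @export
read_multiband_raster <- function(path, band_order = micasense_bands()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  n_expect <- nrow(band_order)
  n_bands <- length(pages) - isTRUE(meta$nodata_page)
  if (n_bands != n_expect)
    stop(sprintf("band-count mismatch: file has %d bands, expected %d",
                 n_bands, n_expect), call. = FALSE)
  if (is.null(meta$geom))
    stop("missing georeferencing sidecar for ", path, call. = FALSE)
  geom <- geom_from_list(meta$geom)
  bands <- lapply(pages[seq_len(n_bands)], function(p) {
    if (identical(meta$encoding, "uint16_dn")) round(p * 65535) / DN_SCALE
    else p * meta$scale
  })
  names(bands) <- band_order$name
  if (isTRUE(meta$nodata_page)) {
    invalid <- pages[[length(pages)]] < 0.5
    bands <- lapply(bands, function(b) { b[invalid] <- NA_real_; b })
  }
  band_stack(bands, geom)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing sidecar metadata: ", sp, call. = FALSE)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read a single-band raster
#'
#' Elevation and similar unbounded rasters are stored as normalized float32
#' with offset/scale in the sidecar; label rasters as 8-bit categories.
#'
#' @param r a [cp_raster()].
#' @param path TIFF path.
#' @param kind `"float32"` or `"uint8"` (integer categories 0-255).
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, kind = c("float32", "uint8")) {
  kind <- match.arg(kind)
  v <- r$values
  has_na <- anyNA(v)
  meta <- list(geom = geom_to_list(r$geom), kind = kind, nodata_page = has_na)
  if (kind == "uint8") {
    page <- v; page[is.na(page)] <- 0
    stopifnot(all(page >= 0 & page <= 255))
    pages <- list(page / 255)
    bits <- 8L
  } else {
    offset <- min(v, na.rm = TRUE)
    scale <- max(v, na.rm = TRUE) - offset
    if (!is.finite(scale) || scale == 0) scale <- 1
    meta$offset <- offset; meta$scale <- scale
    page <- (v - offset) / scale
    page[is.na(page)] <- 0
    pages <- list(page)
    bits <- 32L
  }
  if (has_na) pages <- c(pages, list((!is.na(v)) * 1))
  write_pages(pages, path, bits)
  write_world_file(r$geom, path)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- pages[[1]]
  v <- if (identical(meta$kind, "uint8")) round(v * 255)
       else v * meta$scale + meta$offset
  if (isTRUE(meta$nodata_page)) v[pages[[2]] < 0.5] <- NA_real_
  cp_raster(v, geom_from_list(meta$geom))
}

#' Plot polygon set with metadata
#'
#' @param plot_id character vector of unique identifiers.
#' @param line,treatment,rep metadata vectors (recycled to length).
#' @param geometry list of n x 2 vertex matrices (world metres).
#' @return A tibble of class `plot_set` with a `geometry` list-column.
#' @export
plot_set <- function(plot_id, line, treatment, rep, geometry) {
  if (anyDuplicated(plot_id))
    stop("duplicate plot_id in plot set", call. = FALSE)
  ps <- tibble::tibble(plot_id = as.character(plot_id),
                       line = line, treatment = treatment, rep = rep,
                       geometry = geometry)
  class(ps) <- c("plot_set", class(ps))
  ps
}

#' Write plot polygons as GeoJSON
#'
#' @param plots a [plot_set()].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_plot_polygons <- function(plots, path) {
  features <- lapply(seq_len(nrow(plots)), function(i) {
    poly <- plots$geometry[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(plot_id = plots$plot_id[i], line = plots$line[i],
                        treatment = plots$treatment[i], rep = plots$rep[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) ring[j, ])))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read plot polygons from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection of polygon features, each with a
#'   unique `plot_id` property (and optional `line`, `treatment`, `rep`).
#' @return A [plot_set()].
#' @export
read_plot_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  feats <- gj$features
  if (!length(feats))
    return(plot_set(character(0), character(0), character(0), integer(0), list()))
  ids <- character(length(feats)); lines <- character(length(feats))
  trts <- character(length(feats)); reps <- integer(length(feats))
  geoms <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon"))
      stop("non-polygon feature at index ", i, call. = FALSE)
    props <- f$properties
    if (is.null(props$plot_id))
      stop("feature ", i, " lacks a plot_id property", call. = FALSE)
    ids[i] <- as.character(props$plot_id)
    lines[i] <- if (is.null(props$line)) NA_character_ else as.character(props$line)
    trts[i] <- if (is.null(props$treatment)) NA_character_ else as.character(props$treatment)
    reps[i] <- if (is.null(props$rep)) NA_integer_ else as.integer(props$rep)
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    geoms[[i]] <- m
  }
  if (anyDuplicated(ids))
    stop("duplicate plot_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  plot_set(ids, lines, trts, reps, geoms)
}

#' Write / read a plain-text table (CSV, UTF-8, '.' decimal)
#'
#' @param df data frame.
#' @param path CSV path.
#' @return the table (read) or `path` invisibly (write).
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8",
                                    stringsAsFactors = FALSE))
}
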