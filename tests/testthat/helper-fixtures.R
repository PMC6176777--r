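# Small simulated scenes shared across tests (built once per run).

small_scene_config <- function(seed = 1L, ...) {
  scene_config(n_lines = 3, n_treatments = 2, n_reps = 2,
               gsd_ms_m = 0.05, gsd_rgb_m = 0.04, margin_strip_m = 1,
               seed = seed, ...)
}

.scene_cache <- new.env(parent = emptyenv())

default_small_scene <- function(seed = 1L) {
  key <- paste0("scene", seed)
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- simulate_scene(small_scene_config(seed = seed))
  .scene_cache[[key]]
}

# A flat random reflectance stack for property tests.
random_stack <- function(n = 20, seed = 42) {
  set.seed(seed)
  g <- grid_geom(0, n * 0.1, 0.1, n, n)
  band_stack(list(blue = matrix(runif(n^2, 0, 0.4), n),
                  green = matrix(runif(n^2, 0, 0.5), n),
                  red = matrix(runif(n^2, 0, 0.5), n),
                  rededge = matrix(runif(n^2, 0.05, 0.6), n),
                  nir = matrix(runif(n^2, 0.05, 0.9), n)), g)
}

# ---- independent oracles -------------------------------------------------

# Percentile by explicit sort-and-interpolate (linear between closest order
# statistics), written directly from the definition.
oracle_percentile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Pearson r from the covariance/variance sums.
oracle_pearson <- function(m, p) {
  sum((m - mean(m)) * (p - mean(p))) /
    sqrt(sum((m - mean(m))^2) * sum((p - mean(p))^2))
}

# Pooled-variance two-sample t statistic from the textbook formula.
oracle_student_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Convex-polygon membership by half-plane tests (CCW orientation).
oracle_in_convex <- function(px, py, poly) {
  area2 <- sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                 c(poly[-1, 1], poly[1, 1]) * poly[, 2])
  if (area2 < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  ok <- rep(TRUE, length(px))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cross <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    ok <- ok & cross > 0
  }
  ok
}
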