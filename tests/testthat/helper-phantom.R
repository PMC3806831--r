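# Shared fixtures, all generated in code.

# A small, quick cohort for unit tests: 4 patients x 2 slices, guaranteed
# lipid lesion so every training fold carries both classes.
tiny_params <- function(n_patients = 4, slices = 2, seed = 11, ...) {
  phantom_params(
    n_patients = n_patients, slices_per_patient = slices,
    lesions = list(lipid = list(mean = 142.0, sd = 115.8, prevalence = 1)),
    seed = seed, ...
  )
}

tiny_cohort <- function(...) generate_cohort(tiny_params(...))

# random simple (star-shaped) polygon around a center, vertices in mm
random_star_polygon <- function(n_vertices = 12, center = c(5, 5),
                                r_range = c(1, 4)) {
  # jittered regular angles keep every angular gap below pi, so the polygon
  # is star-shaped about `center` and therefore simple
  th <- 2 * pi * (seq_len(n_vertices) - 1 +
                    stats::runif(n_vertices, 0, 0.9)) / n_vertices
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# The full-sweep study conditions (15 patients x 5 slices, nine weightings)
# are expensive, so tests needing them share one evaluation.
.sweep_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.sweep_env$cohort)) {
    .sweep_env$cohort <- preprocess_cohort(generate_cohort(phantom_params()))
  }
  .sweep_env$cohort
}

default_sweep <- function() {
  if (is.null(.sweep_env$sweep)) {
    .sweep_env$sweep <- evaluate_combinations(default_cohort())
  }
  .sweep_env$sweep
}

# independently sampled Gaussian-derivative kernels (same calibration rules,
# assembled by the test, not by the package)
oracle_kernels <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_px^2))
  g0 <- g / sum(g)
  k1 <- x * g; k1 <- k1 / sum(x * k1)
  k2 <- (x^2 / sigma_px^4 - 1 / sigma_px^2) * g
  k2 <- k2 - mean(k2); k2 <- k2 / (sum(x^2 * k2) / 2)
  list(g0 = g0, k1 = k1, k2 = k2, radius = r)
}

# brute-force dense 2D correlation at selected output pixels, with the same
# edge-mirroring convention, via explicit patch sums
dense_conv_at <- function(image, k2d, rows, cols) {
  r <- (nrow(k2d) - 1L) / 2L
  mi <- function(n) c(rev(seq_len(r)), seq_len(n), seq(n, by = -1,
                                                       length.out = r))
  pad <- image[mi(nrow(image)), mi(ncol(image))]
  out <- matrix(NA_real_, length(rows), length(cols))
  for (ii in seq_along(rows)) {
    for (jj in seq_along(cols)) {
      patch <- pad[rows[ii]:(rows[ii] + 2 * r), cols[jj]:(cols[jj] + 2 * r)]
      out[ii, jj] <- sum(patch * k2d)
    }
  }
  out
}
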