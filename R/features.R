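#' Gaussian scale-space feature specification
#'
#' Per channel, the feature vector holds the normalized signal intensity plus
#' the Gaussian jet at each scale. The full 2D jet per scale is
#' {L, Lx, Ly, Lxx, Lxy, Lyy}: the zero-order (smoothed) image, both first
#' derivatives and the three second derivatives, all in physical units
#' (per mm, per mm^2). A rotation-invariant reduced jet
#' {L, |grad L|, Laplacian} is available as an option. Default scales are
#' 0.25, 0.5, 1.0 and 2.0 mm.
#'
#' @param scales strictly increasing positive Gaussian scales in mm.
#' @param jet `"full"` (6 operators per scale) or `"rotation_invariant"`
#'   (3 per scale).
#' @param include_raw include the normalized intensity itself (default TRUE).
#' @return A `feature_spec`; with defaults, 1 + 6 x 4 = 25 features per
#'   channel.
#' @export
feature_spec <- function(scales = c(0.25, 0.5, 1.0, 2.0),
                         jet = c("full", "rotation_invariant"),
                         include_raw = TRUE) {
  jet <- match.arg(jet)
  if (length(scales) < 1 || any(scales <= 0) ||
      any(diff(scales) <= 0)) {
    stop("scales must be strictly positive and strictly increasing (mm)",
         call. = FALSE)
  }
  ops <- switch(jet,
    full = c("L", "Lx", "Ly", "Lxx", "Lxy", "Lyy"),
    rotation_invariant = c("L", "gradmag", "laplacian")
  )
  structure(list(scales = scales, jet = jet, operators = ops,
                 include_raw = include_raw),
            class = "feature_spec")
}

#' Number of features per channel implied by a spec
#' @param spec a [feature_spec()].
#' @return Integer count.
#' @export
n_features_per_channel <- function(spec) {
  as.integer(spec$include_raw) + length(spec$operators) * length(spec$scales)
}

# sampled Gaussian and Gaussian-derivative correlation kernels, calibrated so
# constants, ramps and quadratics are reproduced exactly (in pixel units)
gaussian_kernels <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  x <- seq(-r, r)
  g <- stats::dnorm(x, 0, sigma_px)
  g0 <- g / sum(g)
  k1 <- x * g                      # correlation form: G'(-j) ~ +j g(j)
  k1 <- k1 / sum(x * k1)
  k2 <- (x^2 / sigma_px^4 - 1 / sigma_px^2) * g
  k2 <- k2 - mean(k2)
  k2 <- k2 / (sum(x^2 * k2) / 2)
  list(g0 = g0, k1 = k1, k2 = k2, radius = r)
}

# symmetric (edge-repeating) padding indices for length n, pad r
mirror_index <- function(n, r) {
  if (r >= n) {
    stop(sprintf("kernel radius %d too large for image extent %d", r, n),
         call. = FALSE)
  }
  c(rev(seq_len(r)), seq_len(n), seq(n, by = -1, length.out = r))
}

# band matrix realizing 1D correlation with kernel k after padding by r
band_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  m <- matrix(0, n, n + 2L * r)
  for (t in seq_along(k)) m[cbind(seq_len(n), seq_len(n) + t - 1L)] <- k[t]
  m
}

# separable correlation with mirror boundary: ky along rows (y), kx along
# columns (x)
convolve_sep <- function(image, ky, kx) {
  ry <- (length(ky) - 1L) / 2L
  rx <- (length(kx) - 1L) / 2L
  p <- image[mirror_index(nrow(image), ry), mirror_index(ncol(image), rx),
             drop = FALSE]
  band_matrix(nrow(image), ky) %*% p %*% t(band_matrix(ncol(image), kx))
}

#' Gaussian derivative jet of an image at one scale
#'
#' Computes the zero-, first- and second-order Gaussian derivatives at
#' standard deviation `scale_mm`, expressed in physical units: the kernel is
#' applied at `sigma_px = scale_mm / spacing_mm` and first/second derivatives
#' are divided by `spacing_mm` / `spacing_mm^2`. Image borders are handled by
#' mirror reflection. x runs along columns, y along rows.
#'
#' @param image numeric matrix.
#' @param scale_mm Gaussian scale in mm (> 0). Scales below half a pixel are
#'   computed with a warning (the sampled kernel is then a poor
#'   discretization).
#' @param spacing_mm pixel spacing in mm.
#' @return Named list of matrices `L`, `Lx`, `Ly`, `Lxx`, `Lxy`, `Lyy`.
#' @export
gaussian_derivative_stack <- function(image, scale_mm, spacing_mm) {
  stopifnot(is.matrix(image), scale_mm > 0, spacing_mm > 0)
  sigma <- scale_mm / spacing_mm
  if (sigma < 0.5) {
    warning(sprintf("scale %.3g mm is below half a pixel (%.3g px)",
                    scale_mm, sigma))
  }
  k <- gaussian_kernels(sigma)
  s1 <- spacing_mm
  list(
    L   = convolve_sep(image, k$g0, k$g0),
    Lx  = convolve_sep(image, k$g0, k$k1) / s1,
    Ly  = convolve_sep(image, k$k1, k$g0) / s1,
    Lxx = convolve_sep(image, k$g0, k$k2) / s1^2,
    Lxy = convolve_sep(image, k$k1, k$k1) / s1^2,
    Lyy = convolve_sep(image, k$k2, k$g0) / s1^2
  )
}

feature_suffixes <- function(spec) {
  c(if (spec$include_raw) "raw",
    as.vector(t(outer(spec$operators, spec$scales,
                      function(op, s) sprintf("%s.s%g", op, s)))))
}

channel_feature_stack <- function(image, spec, spacing_mm) {
  out <- list()
  if (spec$include_raw) out[["raw"]] <- image
  stacks <- lapply(spec$scales, gaussian_derivative_stack, image = image,
                   spacing_mm = spacing_mm)
  for (op in spec$operators) {
    for (si in seq_along(spec$scales)) {
      st <- stacks[[si]]
      img <- switch(op,
        gradmag = sqrt(st$Lx^2 + st$Ly^2),
        laplacian = st$Lxx + st$Lyy,
        st[[op]]
      )
      out[[sprintf("%s.s%g", op, spec$scales[si])]] <- img
    }
  }
  out
}

#' Extract per-pixel feature vectors for a weighting subset
#'
#' Builds the feature matrix over every vessel-wall pixel of the supplied
#' (preprocessed) studies: for each selected weighting, the normalized
#' intensity plus the Gaussian jet per scale. Columns are ordered
#' deterministically by weighting (canonical protocol order), then operator,
#' then scale. Labels distinguish soft-plaque pixels from all other wall
#' tissue. Beyond choosing the weighting subset there is no feature
#' selection.
#'
#' @param studies a [patient_study()] or list of them; must have passed
#'   through [preprocess_study()] (features are only ever computed on
#'   normalized channels).
#' @param weightings character vector: the contrast-weighting subset.
#' @param spec a [feature_spec()].
#' @return A `feature_matrix`: list with `values` (n_pixels x n_features),
#'   `pixels` (tibble: patient_id, slice, row, col), `labels` (factor
#'   not_soft_plaque/soft_plaque), `feature_names`, `weightings`, `spec`.
#' @export
extract_features <- function(studies, weightings, spec = feature_spec()) {
  if (inherits(studies, "patient_study")) studies <- list(studies)
  weightings <- validate_weightings(weightings)
  weightings <- intersect(contrast_weightings(), weightings)
  stopifnot(inherits(spec, "feature_spec"))

  rows <- list(); pix <- list(); labs <- list()
  for (study in studies) {
    for (si in seq_along(study$slices)) {
      sl <- study$slices[[si]]
      if (!isTRUE(attr(sl, "preprocessed"))) {
        stop("features must be computed on preprocessed (normalized) slices; ",
             "run preprocess_study() first", call. = FALSE)
      }
      missing <- setdiff(weightings, names(sl$channels))
      if (length(missing) > 0) {
        stop("study ", study$patient_id, " is missing channel(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      idx <- which(sl$wall)
      blocks <- lapply(weightings, function(w) {
        imgs <- channel_feature_stack(sl$channels[[w]], spec,
                                      sl$geometry$spacing)
        vapply(imgs, function(m) m[idx], numeric(length(idx)))
      })
      rows[[length(rows) + 1L]] <- do.call(cbind, blocks)
      rc <- arrayInd(idx, dim(sl$wall))
      pix[[length(pix) + 1L]] <- tibble::tibble(
        patient_id = study$patient_id, slice = si,
        row = rc[, 1], col = rc[, 2]
      )
      labs[[length(labs) + 1L]] <- sl$labels[idx] == 2L
    }
  }
  values <- do.call(rbind, rows)
  feature_names <- as.vector(t(outer(weightings, feature_suffixes(spec),
                                     paste, sep = ".")))
  colnames(values) <- feature_names
  structure(
    list(values = values,
         pixels = dplyr::bind_rows(pix),
         labels = factor(ifelse(unlist(labs), "soft_plaque",
                                "not_soft_plaque"),
                         levels = c("not_soft_plaque", "soft_plaque")),
         feature_names = feature_names,
         weightings = weightings,
         spec = spec),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d pixels x %d features (%s; %d per channel); %d soft-plaque\n",
    nrow(x$values), ncol(x$values), paste(x$weightings, collapse = ", "),
    n_features_per_channel(x$spec), sum(x$labels == "soft_plaque")))
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  cbind(as.data.frame(x$pixels), label = x$labels,
        as.data.frame(x$values))
}

#' Tidy a feature matrix into a tibble
#' @param x a `feature_matrix`.
#' @param ... unused.
#' @return Tibble with pixel provenance, label and one column per feature.
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Write a feature matrix as CSV for inspection
#' @param x a `feature_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# column indices of a weighting sub-block within a wider feature matrix
feature_columns <- function(feature_names, weightings) {
  w <- sub("\\..*$", "", feature_names)
  which(w %in% weightings)
}
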