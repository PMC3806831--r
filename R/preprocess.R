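#' Median-ROI normalization specification
#'
#' Signal intensities are normalized by the median of a 4 x 4 cm region of
#' interest centered on the lumen, which makes channels comparable across
#' sequences of one subject and across subjects. The ROI is clipped to the
#' image bounds; the median is taken over the clipped pixel set.
#'
#' @param center length-2 numeric (x, y) ROI center in mm, normally the lumen
#'   contour centroid.
#' @param roi_width,roi_height ROI size in mm (default 40 x 40).
#' @return A `normalization_spec` object.
#' @export
normalization_spec <- function(center, roi_width = 40, roi_height = 40) {
  stopifnot(length(center) == 2, is.finite(center),
            roi_width > 0, roi_height > 0)
  structure(list(center = as.numeric(center), roi_width = roi_width,
                 roi_height = roi_height),
            class = "normalization_spec")
}

roi_pixels <- function(geometry, spec) {
  ctr <- pixel_centers(geometry)
  jx <- which(abs(ctr$x - spec$center[1]) <= spec$roi_width / 2)
  iy <- which(abs(ctr$y - spec$center[2]) <= spec$roi_height / 2)
  if (length(jx) == 0 || length(iy) == 0) {
    stop("normalization ROI clipped to the image contains no pixels",
         call. = FALSE)
  }
  list(rows = iy, cols = jx)
}

#' Normalize a channel by its ROI median
#'
#' Divides the image by the median intensity of the ROI, so the output is
#' scale invariant: `normalize_channel(c * I) == normalize_channel(I)` for
#' any c > 0. Applied per channel and per slice, before any derivative
#' filtering.
#'
#' @param image numeric matrix.
#' @param geometry a [slice_geometry()] describing `image`.
#' @param spec a [normalization_spec()].
#' @return Normalized matrix, with attribute `normalized = TRUE`.
#' @export
normalize_channel <- function(image, geometry, spec) {
  stopifnot(is.matrix(image), inherits(geometry, "slice_geometry"),
            inherits(spec, "normalization_spec"),
            all(dim(image) == c(geometry$rows, geometry$cols)))
  idx <- roi_pixels(geometry, spec)
  med <- stats::median(image[idx$rows, idx$cols])
  if (!is.finite(med) || med <= 0) {
    stop(sprintf("ROI median is %.4g; cannot normalize a non-positive channel",
                 med), call. = FALSE)
  }
  out <- image / med
  attr(out, "normalized") <- TRUE
  out
}

#' Apparent diffusion coefficient map from two b-values
#'
#' Mono-exponential two-point fit: `ADC = log(s_b0 / s_bw) / (b_high - b_low)`
#' per pixel, in mm^2/s. Pixels with non-positive signal in either input are
#' set to 0 and flagged in the `invalid` attribute.
#'
#' @param s_b0 image at the low b-value (b = 0 s/mm^2 in the reference
#'   protocol).
#' @param s_bw diffusion-weighted image at the high b-value (b = 500 s/mm^2).
#' @param b_low,b_high b-values in s/mm^2 with `b_high > b_low >= 0`.
#' @return ADC matrix (mm^2/s) with logical attribute `invalid`.
#' @export
#' @examples
#' s0 <- matrix(100, 4, 4)
#' compute_adc(s0, s0 * exp(-0.5), 0, 500)[1, 1]  # 1e-3 mm^2/s
compute_adc <- function(s_b0, s_bw, b_low = 0, b_high = 500) {
  stopifnot(is.matrix(s_b0), is.matrix(s_bw), all(dim(s_b0) == dim(s_bw)))
  if (!(b_high > b_low && b_low >= 0)) {
    stop("need b_high > b_low >= 0", call. = FALSE)
  }
  bad <- !(s_b0 > 0 & s_bw > 0)
  adc <- matrix(0, nrow(s_b0), ncol(s_b0))
  adc[!bad] <- log(s_b0[!bad] / s_bw[!bad]) / (b_high - b_low)
  attr(adc, "invalid") <- bad
  adc
}

#' Preprocess a study: derive ADC and normalize every channel
#'
#' Runs the two preprocessing stages on each slice: (1) if the study carries
#' both diffusion channels (DWT2 at b=0, DWI at b=500 s/mm^2) and no ADC
#' channel yet, the ADC map is computed and appended; (2) every channel is
#' normalized by the median of a 4 x 4 cm ROI centered on the lumen contour
#' centroid of that slice.
#'
#' @param study a [patient_study()].
#' @param b_low,b_high b-values (s/mm^2) of the diffusion pair.
#' @param roi_width,roi_height normalization ROI size in mm.
#' @return The preprocessed [patient_study()]; its slices gain the attribute
#'   `preprocessed = TRUE`.
#' @export
preprocess_study <- function(study, b_low = 0, b_high = 500,
                             roi_width = 40, roi_height = 40) {
  stopifnot(inherits(study, "patient_study"))
  slices <- lapply(study$slices, function(sl) {
    ch <- sl$channels
    if (all(c("DWT2", "DWI") %in% names(ch)) && !("ADC" %in% names(ch))) {
      ch$ADC <- compute_adc(ch$DWT2, ch$DWI, b_low, b_high)
    }
    spec <- normalization_spec(polygon_centroid(sl$lumen$vertices),
                               roi_width, roi_height)
    ch <- lapply(ch, normalize_channel, geometry = sl$geometry, spec = spec)
    ch <- ch[intersect(contrast_weightings(), names(ch))]
    out <- vessel_slice(ch, sl$geometry, sl$lumen, sl$outer_wall,
                        plaque_mask = sl$labels == 2L, .wall = sl$wall)
    attr(out, "adc_truth") <- attr(sl, "adc_truth")
    attr(out, "preprocessed") <- TRUE
    out
  })
  out <- patient_study(study$patient_id, slices)
  attributes(out) <- utils::modifyList(attributes(study),
                                       attributes(out))
  out
}

#' Preprocess every study of a cohort
#' @param studies list of [patient_study()] objects.
#' @inheritParams preprocess_study
#' @return List of preprocessed studies.
#' @export
preprocess_cohort <- function(studies, b_low = 0, b_high = 500,
                              roi_width = 40, roi_height = 40) {
  lapply(studies, preprocess_study, b_low = b_low, b_high = b_high,
         roi_width = roi_width, roi_height = roi_height)
}
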