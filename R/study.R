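#' One aligned multi-contrast vessel-wall slice
#'
#' Bundles the per-weighting channel images (all pre-aligned on the shared
#' reference grid), the manually-delineated-style lumen and outer-wall
#' contours, and the reference soft-plaque labels. The label mask codes
#' 0 = background, 1 = wall tissue, 2 = soft plaque; soft-plaque labels can
#' only occur on wall pixels.
#'
#' @param channels named list of rows x cols numeric matrices; names are
#'   contrast weightings (see [contrast_weightings()]).
#' @param geometry a [slice_geometry()].
#' @param lumen,outer_wall [contour()] objects.
#' @param plaque_contours optional list of soft-plaque [contour()]s.
#' @param plaque_mask optional logical matrix of reference soft-plaque pixels
#'   (used instead of `plaque_contours` when the lesion is defined directly
#'   on the grid, as the phantom does); clipped to the wall.
#' @param .wall precomputed wall mask (internal fast path; must equal
#'   `wall_mask(lumen, outer_wall, geometry)`).
#' @return A `vessel_slice` object with elements `channels`, `geometry`,
#'   `lumen`, `outer_wall`, `plaque_contours`, `wall`, `labels`.
#' @export
vessel_slice <- function(channels, geometry, lumen, outer_wall,
                         plaque_contours = list(), plaque_mask = NULL,
                         .wall = NULL) {
  stopifnot(inherits(geometry, "slice_geometry"),
            inherits(lumen, "contour"), inherits(outer_wall, "contour"))
  if (length(channels) == 0 || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("channels must be a named list of image matrices", call. = FALSE)
  }
  validate_weightings(names(channels))
  dims <- c(geometry$rows, geometry$cols)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !all(dim(ch) == dims)) {
      stop(sprintf("channel '%s' does not match the %d x %d slice grid",
                   nm, dims[1], dims[2]), call. = FALSE)
    }
  }
  wall <- .wall %||% wall_mask(lumen, outer_wall, geometry)
  plaque <- matrix(FALSE, dims[1], dims[2])
  for (pc in plaque_contours) {
    stopifnot(inherits(pc, "contour"))
    plaque <- plaque | rasterize_contour(pc, geometry)
  }
  if (!is.null(plaque_mask)) {
    stopifnot(is.logical(plaque_mask), all(dim(plaque_mask) == dims))
    plaque <- plaque | plaque_mask
  }
  plaque <- plaque & wall
  labels <- matrix(0L, dims[1], dims[2])
  labels[wall] <- 1L
  labels[plaque] <- 2L
  structure(
    list(channels = channels, geometry = geometry, lumen = lumen,
         outer_wall = outer_wall, plaque_contours = plaque_contours,
         wall = wall, labels = labels),
    class = "vessel_slice"
  )
}

#' @export
print.vessel_slice <- function(x, ...) {
  cat(sprintf(
    "<vessel_slice> %d x %d px, channels: %s; %d wall px (%d soft plaque)\n",
    x$geometry$rows, x$geometry$cols,
    paste(names(x$channels), collapse = ", "),
    sum(x$wall), sum(x$labels == 2L)))
  invisible(x)
}

#' One patient's study: an ordered stack of vessel-wall slices
#'
#' @param patient_id character scalar.
#' @param slices list of [vessel_slice()] objects sharing one geometry and
#'   one channel set.
#' @return A `patient_study` object.
#' @export
patient_study <- function(patient_id, slices) {
  stopifnot(is.character(patient_id), length(patient_id) == 1,
            length(slices) >= 1)
  ch0 <- names(slices[[1]]$channels)
  g0 <- slices[[1]]$geometry
  for (s in slices) {
    stopifnot(inherits(s, "vessel_slice"))
    if (!identical(names(s$channels), ch0)) {
      stop("all slices of a study must carry the same channel set",
           call. = FALSE)
    }
    if (!identical(unclass(s$geometry), unclass(g0))) {
      stop("all slices of a study must share one geometry", call. = FALSE)
    }
  }
  structure(list(patient_id = patient_id, slices = slices),
            class = "patient_study")
}

#' @export
print.patient_study <- function(x, ...) {
  cat(sprintf("<patient_study> %s: %d slices, channels: %s\n",
              x$patient_id, length(x$slices),
              paste(names(x$slices[[1]]$channels), collapse = ", ")))
  invisible(x)
}

#' Channel names of a study
#' @param study a [patient_study()].
#' @return Character vector.
#' @export
study_channels <- function(study) names(study$slices[[1]]$channels)

#' Reference soft-plaque masks of a study
#' @param study a [patient_study()].
#' @return List of logical matrices, one per slice.
#' @export
reference_masks <- function(study) {
  lapply(study$slices, function(s) s$labels == 2L)
}
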