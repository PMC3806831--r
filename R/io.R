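#' Write a patient study to disk
#'
#' Layout, one patient per set of files inside `dir`:
#' * `<id>_<WEIGHTING>.nii.gz` - one NIfTI volume per channel
#'   (rows x cols x slices, float64, pixdim = spacing/spacing/thickness);
#' * `<id>_labels.nii.gz` - label volume, 0 = background, 1 = wall,
#'   2 = soft plaque;
#' * `<id>_slice<k>_contours.txt` - per-slice plain-text polygons: a role
#'   line (`lumen`, `outer_wall` or `soft_plaque`) followed by `x y` vertex
#'   lines in mm, one block per contour separated by blank lines.
#'
#' @param study a [patient_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "patient_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- study$slices[[1]]$geometry
  id <- study$patient_id
  files <- character()
  pd <- c(g$spacing, g$spacing, g$thickness)

  for (w in study_channels(study)) {
    arr <- vapply(study$slices, function(sl) sl$channels[[w]],
                  matrix(0, g$rows, g$cols))
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- pd
    f <- file.path(dir, sprintf("%s_%s.nii.gz", id, w))
    RNifti::writeNifti(im, f, datatype = "double")
    files <- c(files, f)
  }

  lab <- vapply(study$slices, function(sl) sl$labels,
                matrix(0L, g$rows, g$cols))
  im <- RNifti::asNifti(lab)
  RNifti::pixdim(im) <- pd
  f <- file.path(dir, sprintf("%s_labels.nii.gz", id))
  RNifti::writeNifti(im, f, datatype = "int16")
  files <- c(files, f)

  for (k in seq_along(study$slices)) {
    sl <- study$slices[[k]]
    f <- file.path(dir, sprintf("%s_slice%d_contours.txt", id, k))
    con <- file(f, "w")
    for (ct in c(list(sl$lumen, sl$outer_wall), sl$plaque_contours)) {
      writeLines(ct$role, con)
      writeLines(sprintf("%.17g %.17g", ct$vertices[, 1], ct$vertices[, 2]),
                 con)
      writeLines("", con)
    }
    close(con)
    files <- c(files, f)
  }
  invisible(files)
}

read_contour_file <- function(path) {
  lines <- trimws(readLines(path))
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "") { i <- i + 1; next }
    role <- lines[i]
    if (!role %in% c("lumen", "outer_wall", "soft_plaque")) {
      stop("contour file ", path, ": unknown role '", role, "'",
           call. = FALSE)
    }
    i <- i + 1
    verts <- list()
    while (i <= length(lines) && lines[i] != "") {
      verts[[length(verts) + 1L]] <- as.numeric(strsplit(lines[i],
                                                         "\\s+")[[1]])
      i <- i + 1
    }
    out[[length(out) + 1L]] <- contour(do.call(rbind, verts), role = role)
  }
  out
}

#' Read a patient study from disk
#'
#' Reads the layout written by [write_study()]. All channel volumes must
#' share one grid; a mismatch raises a geometry error. If a requested channel
#' has no file, a missing-channel error names the weighting. Reference
#' soft-plaque labels are taken from the label volume when present, else from
#' `soft_plaque` contours.
#'
#' @param dir directory holding the files.
#' @param patient_id patient identifier embedded in the filenames.
#' @param channels channels to load (default: all files found).
#' @return A [patient_study()].
#' @export
read_study <- function(dir, patient_id, channels = NULL) {
  all_files <- list.files(dir, pattern = paste0(
    "^", patient_id, "_[A-Z0-9]+\\.nii(\\.gz)?$"))
  found <- sub("\\.nii(\\.gz)?$", "",
               sub(paste0("^", patient_id, "_"), "", all_files))
  found <- setdiff(found, "labels")
  bad <- setdiff(found, contrast_weightings())
  if (length(bad) > 0) {
    stop("unknown weighting name(s) in files for ", patient_id, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  channels <- channels %||% intersect(contrast_weightings(), found)
  missing <- setdiff(channels, found)
  if (length(missing) > 0) {
    stop("study ", patient_id, " is missing channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  vols <- lapply(channels, function(w) {
    f <- Sys.glob(file.path(dir, sprintf("%s_%s.nii*", patient_id, w)))[1]
    RNifti::readNifti(f)
  })
  names(vols) <- channels
  dims <- lapply(vols, dim)
  if (length(unique(lapply(dims, as.integer))) != 1) {
    stop("geometry mismatch: channel volumes of ", patient_id,
         " have different grid shapes", call. = FALSE)
  }
  d <- dims[[1]]
  if (length(d) == 2) d <- c(d, 1L)
  pd <- RNifti::pixdim(vols[[1]])
  if (abs(pd[1] - pd[2]) > 1e-9) {
    stop("anisotropic in-plane spacing is not supported", call. = FALSE)
  }
  g <- slice_geometry(d[1], d[2], spacing = pd[1], thickness = pd[3])

  lab_file <- Sys.glob(file.path(dir, sprintf("%s_labels.nii*", patient_id)))
  labels <- if (length(lab_file) > 0) {
    lv <- RNifti::readNifti(lab_file[1])
    if (!all(dim(lv)[1:2] == d[1:2])) {
      stop("geometry mismatch: label volume of ", patient_id,
           " does not match the channel grid", call. = FALSE)
    }
    lv
  } else NULL

  slices <- lapply(seq_len(d[3]), function(k) {
    cf <- file.path(dir, sprintf("%s_slice%d_contours.txt", patient_id, k))
    if (!file.exists(cf)) {
      stop("missing contour file for ", patient_id, " slice ", k,
           call. = FALSE)
    }
    cts <- read_contour_file(cf)
    roles <- vapply(cts, `[[`, "", "role")
    if (sum(roles == "lumen") != 1 || sum(roles == "outer_wall") != 1) {
      stop("contour file ", cf,
           " must contain exactly one lumen and one outer_wall contour",
           call. = FALSE)
    }
    ch <- lapply(vols, function(v) {
      m <- if (length(dim(v)) == 3) v[, , k] else v[, ]
      matrix(as.numeric(m), d[1], d[2])
    })
    pm <- if (!is.null(labels)) {
      lk <- if (length(dim(labels)) == 3) labels[, , k] else labels[, ]
      matrix(lk == 2, d[1], d[2])
    } else NULL
    vessel_slice(ch, g,
                 lumen = cts[[which(roles == "lumen")]],
                 outer_wall = cts[[which(roles == "outer_wall")]],
                 plaque_contours = cts[roles == "soft_plaque"],
                 plaque_mask = pm)
  })
  patient_study(patient_id, slices)
}

#' Write a cohort plus a manifest
#'
#' @param studies list of [patient_study()] objects.
#' @param dir output directory.
#' @param extra named list merged into the manifest (e.g. seed, parameters).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(studies, dir, extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (st in studies) write_study(st, dir)
  manifest <- c(list(
    patients = vapply(studies, `[[`, "", "patient_id"),
    slices_per_patient = length(studies[[1]]$slices),
    channels = study_channels(studies[[1]])
  ), extra)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory containing `manifest.json`.
#' @return List of [patient_study()] objects.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::fromJSON(mf)
  lapply(manifest$patients, function(id) read_study(dir, id))
}
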