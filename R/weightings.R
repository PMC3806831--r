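#' Contrast weightings of the carotid vessel-wall protocol
#'
#' The protocol acquires six pulse sequences from which nine contrast
#' weightings are derived: TOF angiography; fat-suppressed T1W; a dual-echo
#' acquisition yielding both T2W and PDW; STIR; MR direct thrombus imaging
#' (MRDTI); and a diffusion acquisition yielding the b=0 image (DWT2), the
#' diffusion-weighted image (DWI) and, after post-processing, the apparent
#' diffusion coefficient map (ADC).
#'
#' @return Character vector of the nine weighting names, in canonical order.
#' @export
#' @examples
#' contrast_weightings()
contrast_weightings <- function() {
  c("TOF", "T1W", "T2W", "PDW", "STIR", "MRDTI", "DWT2", "DWI", "ADC")
}

#' Check and normalize a set of weighting names
#'
#' @param weightings character vector of weighting names.
#' @return The validated character vector.
#' @keywords internal
validate_weightings <- function(weightings) {
  if (length(weightings) == 0) {
    stop("at least one contrast weighting is required", call. = FALSE)
  }
  bad <- setdiff(weightings, contrast_weightings())
  if (length(bad) > 0) {
    stop("unknown contrast weighting(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(weightings)) {
    stop("duplicated contrast weighting(s) in subset", call. = FALSE)
  }
  weightings
}

#' Pulse-sequence scan-time table
#'
#' Maps each contrast weighting to its source pulse sequence and each
#' sequence to its acquisition time in decimal minutes. Several weightings
#' share one acquisition: the dual-echo sequence yields both T2W and PDW, and
#' the diffusion acquisition yields DWT2, DWI and (by post-processing) ADC, so
#' a shared sequence is only acquired - and only billed - once per protocol.
#'
#' Default times are 0:48 (TOF), 5:22 (T1W), 8:24 (T2W/PDW), 5:36 (STIR),
#' 2:09 (MRDTI) and 4:42 (DWT2/DWI) converted to decimal minutes.
#'
#' @return A tibble with columns `weighting`, `sequence`, `minutes`.
#' @seealso [scan_duration()]
#' @export
#' @examples
#' sequence_time_table()
sequence_time_table <- function() {
  seq_minutes <- c(
    "TOF"       = 48 / 60,
    "T1W"       = 5 + 22 / 60,
    "T2W/PDW"   = 8 + 24 / 60,
    "STIR"      = 5 + 36 / 60,
    "MRDTI"     = 2 + 9 / 60,
    "DWT2/DWI"  = 4 + 42 / 60
  )
  w2s <- c(
    TOF = "TOF", T1W = "T1W", T2W = "T2W/PDW", PDW = "T2W/PDW",
    STIR = "STIR", MRDTI = "MRDTI",
    DWT2 = "DWT2/DWI", DWI = "DWT2/DWI", ADC = "DWT2/DWI"
  )
  tibble::tibble(
    weighting = names(w2s),
    sequence  = unname(w2s),
    minutes   = unname(seq_minutes[w2s])
  )
}

#' Total scan duration of a weighting subset
#'
#' Sums acquisition minutes over the *distinct* source pulse sequences the
#' subset requires: choosing both T2W and PDW costs one dual-echo
#' acquisition, and any of DWT2, DWI, ADC costs the single diffusion
#' acquisition. Durations are reported rounded half-up to one decimal minute
#' (so 2.95 prints as 3.0); set `round = FALSE` for the exact sum.
#'
#' @param subset character vector of contrast weighting names.
#' @param table a sequence-time table as from [sequence_time_table()].
#' @param round logical; round half-up to 1 decimal (default `TRUE`).
#' @return Scan duration in minutes.
#' @export
#' @examples
#' scan_duration(c("TOF"))
#' scan_duration(c("TOF", "MRDTI", "ADC"))
#' scan_duration(c("T2W", "PDW")) # one dual-echo acquisition
scan_duration <- function(subset, table = sequence_time_table(), round = TRUE) {
  subset <- validate_weightings(subset)
  rows <- table[match(subset, table$weighting), , drop = FALSE]
  if (anyNA(rows$sequence)) {
    stop("weighting(s) missing from sequence time table: ",
         paste(subset[is.na(rows$sequence)], collapse = ", "), call. = FALSE)
  }
  keep <- !duplicated(rows$sequence)
  total <- sum(rows$minutes[keep])
  if (round) round_half_up(total, 1) else total
}
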