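#' Round half away from zero
#'
#' Base `round()` rounds half to even (2.95 to one decimal gives 2.9 on some
#' inputs); printed scan durations use conventional half-up rounding, so
#' 2.95 -> 3.0 and 7.65 -> 7.7.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just below .5 (7.65 is
  # 7.6499999... in binary) still round the way their decimal form reads
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Derive a child RNG seed below 2^31
#' @keywords internal
derive_seed <- function(master, index) {
  v <- (as.numeric(master) %% 1000003) * 2011 + as.numeric(index) * 7919 + 17
  as.integer(v %% 2147483629)
}
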