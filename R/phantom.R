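#' Class-conditional tissue intensity model for the phantom
#'
#' Defines, per contrast weighting, the Gaussian signal model of the three
#' tissue classes the phantom draws from: background (everything outside the
#' outer wall, lumen included), normal wall tissue, and soft plaque
#' (pooled lipid-rich necrotic core / intraplaque hemorrhage). Class
#' separations are specified in pooled-SD units and encode the qualitative
#' informativeness tiers of the weightings: TOF, MRDTI and ADC carry strong
#' soft-plaque contrast; T1W, T2W and PDW moderate contrast; STIR and the
#' raw b=0 diffusion image (DWT2) almost none. A weighting is tiered `high`
#' at separation >= 2 pooled SDs and `low` at <= 0.5.
#'
#' The diffusion channels are generated through a mono-exponential forward
#' model: a per-pixel true ADC field (mm^2/s) is drawn class-conditionally,
#' the b=0 image DWT2 is drawn from its own signal model, and
#' DWI = DWT2 * exp(-(b_high - b_low) * ADC). The ADC map itself is therefore
#' never generated directly; it is recovered by [compute_adc()] during
#' preprocessing, and the DWI separation is whatever the forward model
#' induces.
#'
#' @param separations named numeric vector of class separations (pooled-SD
#'   units) for the directly generated weightings plus `ADC`; defaults shown
#'   above. Partial overrides are merged over the defaults.
#' @return A list with `channels` (tibble: weighting, tier, bg_mean,
#'   wall_mean, plaque_mean, sd) and `diffusion` (b-values and ADC field
#'   parameters).
#' @export
#' @examples
#' tissue_intensity_model()$channels
#' # a strongly separable variant for the informative weightings:
#' tissue_intensity_model(c(TOF = 4, MRDTI = 4, ADC = 4))$channels
tissue_intensity_model <- function(separations = NULL) {
  sep <- c(TOF = 2.6, T1W = 1.0, T2W = 0.85, PDW = 0.85, STIR = 0.3,
           MRDTI = 2.2, DWT2 = 0.2, ADC = 2.05)
  if (!is.null(separations)) {
    validate_weightings(names(separations))
    sep[names(separations)] <- separations
  }
  direct <- c("TOF", "T1W", "T2W", "PDW", "STIR", "MRDTI", "DWT2")
  bg <- c(TOF = 40, T1W = 50, T2W = 60, PDW = 60, STIR = 50, MRDTI = 30,
          DWT2 = 60)
  sd <- 20
  channels <- tibble::tibble(
    weighting   = direct,
    bg_mean     = unname(bg[direct]),
    wall_mean   = 100,
    plaque_mean = 100 + unname(sep[direct]) * sd,
    sd          = sd
  )
  adc_sd <- 0.15e-3
  diffusion <- list(
    b_low = 0, b_high = 500,                      # s/mm^2
    adc_bg = 1.8e-3, adc_wall = 1.0e-3,           # mm^2/s
    adc_plaque = 1.0e-3 + sep[["ADC"]] * adc_sd,
    adc_sd_bg = 0.3e-3, adc_sd_wall = adc_sd, adc_sd_plaque = adc_sd
  )
  channels$tier <- tier_of(abs(channels$plaque_mean - channels$wall_mean) /
                             channels$sd)
  list(channels = channels, diffusion = diffusion)
}

tier_of <- function(sep) {
  ifelse(sep >= 2, "high", ifelse(sep <= 0.5, "low", "medium"))
}

#' Class separation per weighting implied by an intensity model
#'
#' @param model a [tissue_intensity_model()].
#' @return Tibble with `weighting`, `separation` (pooled-SD units), `tier`,
#'   covering the directly generated channels and the ADC field.
#' @export
class_separation <- function(model) {
  ch <- model$channels
  d <- model$diffusion
  out <- tibble::tibble(
    weighting = c(ch$weighting, "ADC"),
    separation = c(abs(ch$plaque_mean - ch$wall_mean) / ch$sd,
                   abs(d$adc_plaque - d$adc_wall) / d$adc_sd_wall)
  )
  out$tier <- tier_of(out$separation)
  out
}

#' Phantom cohort parameters
#'
#' Study conditions of the synthetic cohort: 15 patients with 5 slices each
#' on the 0.39 mm / 3 mm reference grid. Per-patient soft-plaque burden
#' follows the reference population: a lipid-like lesion present in 14/15
#' patients with volume log-normal of mean 142.0 and SD 115.8 mm^3, and a
#' hemorrhage-like lesion in 4/15 patients with mean 75.6 and SD 48.3 mm^3;
#' both are pooled into one soft-plaque class. Diseased walls are thick
#' (outer radius 3.8-5.0 mm over a 1.3-2.2 mm lumen) so that drawn volumes
#' fit the crescent geometry.
#'
#' @param n_patients number of patients (>= 2).
#' @param slices_per_patient slices per study.
#' @param geometry a [slice_geometry()].
#' @param lumen_radius,outer_radius length-2 mm ranges; lumen max must be
#'   below outer min.
#' @param lesions named list of lesion settings, each a list with `mean`,
#'   `sd` (mm^3, log-normal moments) and `prevalence` in \[0, 1\].
#' @param model a [tissue_intensity_model()].
#' @param channels which measured weightings to generate (ADC is derived in
#'   preprocessing and needs both DWT2 and DWI).
#' @param gain_sd log-SD of the per-sequence multiplicative receiver gain
#'   (one gain per acquisition per patient; 0 disables).
#' @param biovar between-patient biological variability: each patient's
#'   class means are shifted by independent N(0, biovar * sd) draws per
#'   channel and class. This is what makes weakly separated channels
#'   unreliable across a cohort even though pixel noise averages out; 0
#'   disables.
#' @param bias_amplitude amplitude of an optional smooth multiplicative
#'   in-plane bias field (0 disables, the default).
#' @param seed master seed; each patient derives an independent sub-seed.
#' @return A `phantom_params` object.
#' @export
phantom_params <- function(n_patients = 15L,
                           slices_per_patient = 5L,
                           geometry = slice_geometry(),
                           lumen_radius = c(1.3, 2.2),
                           outer_radius = c(3.8, 5.0),
                           lesions = list(
                             lipid = list(mean = 142.0, sd = 115.8,
                                          prevalence = 14 / 15),
                             hemorrhage = list(mean = 75.6, sd = 48.3,
                                               prevalence = 4 / 15)
                           ),
                           model = tissue_intensity_model(),
                           channels = c("TOF", "T1W", "T2W", "PDW", "STIR",
                                        "MRDTI", "DWT2", "DWI"),
                           gain_sd = 0.2,
                           biovar = 0.6,
                           bias_amplitude = 0,
                           seed = 1L) {
  stopifnot(inherits(geometry, "slice_geometry"))
  n_patients <- as.integer(n_patients)
  slices_per_patient <- as.integer(slices_per_patient)
  stopifnot(n_patients >= 1, slices_per_patient >= 1)
  if (!(length(lumen_radius) == 2 && length(outer_radius) == 2 &&
        all(lumen_radius > 0) && diff(lumen_radius) >= 0 &&
        diff(outer_radius) >= 0 &&
        max(lumen_radius) < min(outer_radius))) {
    stop("invalid radii: lumen range must be positive and below the outer range",
         call. = FALSE)
  }
  for (nm in names(lesions)) {
    l <- lesions[[nm]]
    if (!(l$mean > 0 && l$sd > 0 && l$prevalence >= 0 && l$prevalence <= 1)) {
      stop("invalid lesion settings for '", nm, "'", call. = FALSE)
    }
  }
  channels <- validate_weightings(channels)
  if ("ADC" %in% channels) {
    stop("ADC is a derived map: generate DWT2 and DWI and run preprocess_study()",
         call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, slices_per_patient = slices_per_patient,
         geometry = geometry, lumen_radius = lumen_radius,
         outer_radius = outer_radius, lesions = lesions, model = model,
         channels = channels, gain_sd = gain_sd, biovar = biovar,
         bias_amplitude = bias_amplitude, seed = as.integer(seed)),
    class = "phantom_params"
  )
}

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# area (mm^2) of {x : u.x >= d} intersected with the annulus rl < |x| < ro
crescent_area <- function(d, rl, ro) {
  seg <- function(R, d) {
    if (d >= R) return(0)
    if (d <= -R) return(pi * R^2)
    R^2 * acos(d / R) - d * sqrt(R^2 - d^2)
  }
  seg(ro, d) - seg(rl, d)
}

# chord offset d achieving a requested crescent area
solve_chord_offset <- function(area, rl, ro) {
  stopifnot(area > 0, area < pi * (ro^2 - rl^2))
  stats::uniroot(function(d) crescent_area(d, rl, ro) - area,
                 lower = -ro * (1 - 1e-9), upper = ro * (1 - 1e-9),
                 tol = 1e-10)$root
}

#' Generate one synthetic patient study
#'
#' Builds an annular vessel wall (concentric circles with a jittered center),
#' plants crescent-shaped soft-plaque lesions whose analytic volume is drawn
#' from the configured log-normal distributions, and fills every channel with
#' class-conditional Gaussian intensities, per-sequence receiver gains and
#' (optionally) a smooth bias field. A lesion spans a contiguous run of
#' slices; its per-slice crescent (the region of the annulus beyond a chord
#' at a random angle) is solved analytically so the target volume is exact up
#' to grid discretization. Deterministic given `patient_seed`.
#'
#' The generated study carries attributes used by validation code:
#' `target_volumes` (analytic lesion volumes, mm^3) and, per slice, the true
#' `adc_truth` field driving the diffusion forward model.
#'
#' @param params a [phantom_params()].
#' @param patient_seed integer seed for this patient.
#' @param patient_id identifier; defaults to the seed.
#' @return A [patient_study()].
#' @export
generate_patient <- function(params, patient_seed,
                             patient_id = sprintf("P%06d", patient_seed %% 1000000L)) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(patient_seed, generate_patient_impl(params, patient_id))
}

generate_patient_impl <- function(params, patient_id) {
  g <- params$geometry
  n_sl <- params$slices_per_patient
  rl <- stats::runif(1, params$lumen_radius[1], params$lumen_radius[2])
  ro <- stats::runif(1, params$outer_radius[1], params$outer_radius[2])
  fov <- c(g$cols, g$rows) * g$spacing
  center <- fov / 2 + stats::runif(2, -1, 1)
  lumen <- circle_contour(center, rl, role = "lumen")
  outer <- circle_contour(center, ro, role = "outer_wall")
  wall <- wall_mask(lumen, outer, g)

  ctr <- pixel_centers(g)
  px <- matrix(rep(ctr$x, each = g$rows), g$rows, g$cols) - center[1]
  py <- matrix(rep(ctr$y, times = g$cols), g$rows, g$cols) - center[2]
  rad <- sqrt(px^2 + py^2)
  annulus_area <- pi * (ro^2 - rl^2)

  # lesion plan: contiguous slice runs of analytically controlled crescents
  plaque_masks <- replicate(n_sl, matrix(FALSE, g$rows, g$cols),
                            simplify = FALSE)
  target_volumes <- stats::setNames(numeric(length(params$lesions)),
                                    names(params$lesions))
  base_angle <- stats::runif(1, 0, 2 * pi)
  li <- 0
  for (nm in names(params$lesions)) {
    li <- li + 1
    les <- params$lesions[[nm]]
    if (stats::runif(1) >= les$prevalence) next
    sdlog <- sqrt(log(1 + (les$sd / les$mean)^2))
    meanlog <- log(les$mean) - sdlog^2 / 2
    vol <- stats::rlnorm(1, meanlog, sdlog)
    a_cap <- 0.9 * annulus_area
    k <- max(2L, ceiling(vol / (g$thickness * 0.6 * annulus_area)))
    k <- min(k, n_sl)
    a_slice <- vol / (g$thickness * k)
    if (a_slice > a_cap) {            # very large draw: clip to the geometry
      a_slice <- a_cap
      vol <- a_slice * g$thickness * k
    }
    start <- sample.int(n_sl - k + 1L, 1)
    theta <- base_angle + (li - 1) * pi +
      stats::runif(1, -pi / 4, pi / 4)
    d <- solve_chord_offset(a_slice, rl, ro)
    u <- c(cos(theta), sin(theta))
    beyond <- (px * u[1] + py * u[2]) >= d
    crescent <- beyond & rad >= rl & rad <= ro
    for (s in start:(start + k - 1L)) {
      plaque_masks[[s]] <- plaque_masks[[s]] | crescent
    }
    target_volumes[[nm]] <- vol
  }

  # per-sequence receiver gains shared by weightings of one acquisition
  tt <- sequence_time_table()
  seqs <- unique(tt$sequence)
  gains <- stats::setNames(exp(stats::rnorm(length(seqs), 0, params$gain_sd)),
                           seqs)
  gain_of <- stats::setNames(gains[tt$sequence], tt$weighting)

  ch_tab <- params$model$channels
  dif <- params$model$diffusion

  # between-patient biological variability: per-channel, per-class mean shifts
  bv <- params$biovar
  shift <- function(sd) if (bv > 0) stats::rnorm(1, 0, bv * sd) else 0
  ch_tab$wall_mean <- ch_tab$wall_mean +
    vapply(ch_tab$sd, shift, 0)
  ch_tab$plaque_mean <- ch_tab$plaque_mean +
    vapply(ch_tab$sd, shift, 0)
  dif$adc_wall <- dif$adc_wall + shift(dif$adc_sd_wall)
  dif$adc_plaque <- dif$adc_plaque + shift(dif$adc_sd_plaque)

  slices <- vector("list", n_sl)
  for (s in seq_len(n_sl)) {
    cls <- matrix(1L, g$rows, g$cols)          # 1 bg, 2 wall, 3 plaque
    cls[wall] <- 2L
    cls[plaque_masks[[s]] & wall] <- 3L
    bias <- if (params$bias_amplitude > 0) {
      phase <- stats::runif(2, 0, 2 * pi)
      1 + params$bias_amplitude *
        sin(2 * pi * outer(ctr$y, rep(1, g$cols)) / fov[2] + phase[1]) *
        cos(2 * pi * outer(rep(1, g$rows), ctr$x) / fov[1] + phase[2])
    } else 1

    channels <- list()
    for (w in intersect(params$channels,
                        c("TOF", "T1W", "T2W", "PDW", "STIR", "MRDTI"))) {
      row <- ch_tab[ch_tab$weighting == w, ]
      mu <- c(row$bg_mean, row$wall_mean, row$plaque_mean)[cls]
      img <- matrix(mu + stats::rnorm(length(cls), 0, row$sd),
                    g$rows, g$cols)
      channels[[w]] <- img * bias * gain_of[[w]]
    }

    need_dwi <- any(c("DWT2", "DWI") %in% params$channels)
    adc_field <- NULL
    if (need_dwi) {
      adc_mu <- c(dif$adc_bg, dif$adc_wall, dif$adc_plaque)[cls]
      adc_sd <- c(dif$adc_sd_bg, dif$adc_sd_wall, dif$adc_sd_plaque)[cls]
      adc_field <- matrix(pmax(adc_mu + stats::rnorm(length(cls), 0, adc_sd),
                               1e-5), g$rows, g$cols)
      row <- ch_tab[ch_tab$weighting == "DWT2", ]
      mu <- c(row$bg_mean, row$wall_mean, row$plaque_mean)[cls]
      s0 <- matrix(pmax(mu + stats::rnorm(length(cls), 0, row$sd), 1e-3),
                   g$rows, g$cols) * bias
      if ("DWT2" %in% params$channels) {
        channels[["DWT2"]] <- s0 * gain_of[["DWT2"]]
      }
      if ("DWI" %in% params$channels) {
        channels[["DWI"]] <- s0 * exp(-(dif$b_high - dif$b_low) * adc_field) *
          gain_of[["DWI"]]
      }
    }

    channels <- channels[intersect(contrast_weightings(), names(channels))]
    sl <- vessel_slice(channels, g, lumen, outer,
                       plaque_mask = plaque_masks[[s]], .wall = wall)
    attr(sl, "adc_truth") <- adc_field
    slices[[s]] <- sl
  }

  study <- patient_study(patient_id, slices)
  attr(study, "target_volumes") <- target_volumes
  study
}

#' Generate a synthetic cohort
#'
#' @param params a [phantom_params()]; `params$seed` drives independent
#'   per-patient sub-seeds, so the cohort is a pure function of its params.
#' @return List of [patient_study()] objects.
#' @export
#' @examples
#' cohort <- generate_cohort(phantom_params(n_patients = 2, seed = 7))
#' length(cohort)
generate_cohort <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  if (params$n_patients < 2) {
    stop("cohort too small: leave-one-out evaluation needs >= 2 patients",
         call. = FALSE)
  }
  lapply(seq_len(params$n_patients), function(i) {
    generate_patient(params, derive_seed(params$seed, i),
                     patient_id = sprintf("P%02d", i))
  })
}
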