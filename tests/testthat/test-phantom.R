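test_that("cohort generation is deterministic and sized correctly", {
  p <- tiny_params(seed = 3)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
  expect_length(a, 4)
  expect_length(a[[1]]$slices, 2)

  full <- phantom_params()
  expect_equal(full$n_patients, 15)
  expect_equal(full$slices_per_patient, 5)

  # different master seed: same schema, different intensities
  c2 <- generate_cohort(tiny_params(seed = 4))
  expect_identical(names(a[[1]]$slices[[1]]$channels),
                   names(c2[[1]]$slices[[1]]$channels))
  expect_false(identical(a[[1]]$slices[[1]]$channels$TOF,
                         c2[[1]]$slices[[1]]$channels$TOF))
})

test_that("lesion prevalence zero yields plaque-free studies", {
  p <- phantom_params(
    n_patients = 2, slices_per_patient = 2,
    lesions = list(lipid = list(mean = 142, sd = 115.8, prevalence = 0)),
    seed = 5
  )
  co <- generate_cohort(p)
  for (st in co) for (sl in st$slices) expect_false(any(sl$labels == 2L))
})

test_that("a one-patient cohort is refused (LOO undefined)", {
  expect_error(generate_cohort(phantom_params(n_patients = 1)),
               "too small")
})

test_that("invalid radii and lesion settings are rejected", {
  expect_error(phantom_params(lumen_radius = c(4, 5),
                              outer_radius = c(3, 3.5)), "radii")
  expect_error(phantom_params(lesions = list(
    lipid = list(mean = -1, sd = 1, prevalence = 0.5))), "lesion")
  expect_error(phantom_params(channels = c("TOF", "ADC")), "derived")
})

test_that("label-mask volume tracks the analytic crescent volume", {
  # tolerance: one boundary pixel layer around the crescent per slice
  p <- tiny_params(n_patients = 6, slices = 5, seed = 21)
  co <- generate_cohort(p)
  g <- co[[1]]$slices[[1]]$geometry
  for (st in co) {
    target <- sum(attr(st, "target_volumes"))
    measured <- plaque_volume(reference_masks(st), g)
    layer <- 2 * pi * 5.0 * g$spacing * g$thickness *
      length(st$slices)
    expect_lt(abs(measured - target), layer)
  }
})

test_that("pooled plaque volumes follow the configured log-normal", {
  # lipid-only cohort: mean of nonzero per-patient volumes near 142 mm^3
  p <- phantom_params(
    n_patients = 1000, slices_per_patient = 5,
    lesions = list(lipid = list(mean = 142.0, sd = 115.8, prevalence = 1)),
    channels = "TOF", gain_sd = 0, biovar = 0, seed = 17
  )
  vols <- vapply(seq_len(p$n_patients), function(i) {
    st <- generate_patient(p, plaqopt:::derive_seed(p$seed, i))
    plaque_volume(reference_masks(st), st$slices[[1]]$geometry)
  }, 0)
  vols <- vols[vols > 0]
  expect_gt(length(vols), 990)
  expect_lt(abs(mean(vols) - 142.0) / 142.0, 0.10)
})

test_that("class-conditional intensities match the configured Gaussians", {
  p <- phantom_params(n_patients = 2, slices_per_patient = 30,
                      lesions = list(lipid = list(mean = 200, sd = 50,
                                                  prevalence = 1)),
                      gain_sd = 0, biovar = 0, seed = 31)
  st <- generate_patient(p, 12345)
  model <- p$model$channels
  for (w in c("TOF", "MRDTI")) {
    row <- model[model$weighting == w, ]
    wallpix <- unlist(lapply(st$slices, function(sl)
      sl$channels[[w]][sl$labels == 1L]))
    expect_gt(length(wallpix), 1e4)
    ks <- stats::ks.test(wallpix, "pnorm", row$wall_mean, row$sd)
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("intensity tiers encode the configured separations", {
  sep <- class_separation(tissue_intensity_model())
  high <- sep$weighting[sep$tier == "high"]
  expect_setequal(high, c("TOF", "MRDTI", "ADC"))
  expect_true(all(sep$separation[sep$tier == "high"] >= 2))
  expect_true(all(sep$separation[sep$tier == "low"] <= 0.5))
  # overrides propagate
  sep4 <- class_separation(tissue_intensity_model(c(STIR = 4)))
  expect_equal(sep4$separation[sep4$weighting == "STIR"], 4)
})
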