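test_that("constant and linear images have the expected jets", {
  img <- matrix(5, 32, 32)
  st <- gaussian_derivative_stack(img, scale_mm = 1, spacing_mm = 0.5)
  expect_equal(st$L, img)
  for (d in c("Lx", "Ly", "Lxx", "Lxy", "Lyy")) {
    expect_lt(max(abs(st[[d]])), 1e-10)
  }

  # ramp in physical x: I = a * x_mm; Lx = a, Lxx = 0 away from borders
  a <- 2.3
  spacing <- 0.5
  xs <- (seq_len(32) - 0.5) * spacing
  ramp <- matrix(rep(a * xs, each = 32), 32, 32)
  st <- gaussian_derivative_stack(ramp, scale_mm = 1, spacing_mm = spacing)
  interior <- 10:22
  expect_equal(st$Lx[interior, interior],
               matrix(a, 13, 13), tolerance = 1e-8)
  expect_lt(max(abs(st$Lxx[interior, interior])), 1e-8)
  expect_lt(max(abs(st$Ly[interior, interior])), 1e-8)
})

test_that("separable filtering matches dense 2D convolution in the interior", {
  set.seed(123)
  img <- matrix(stats::rnorm(64 * 64), 64, 64)
  spacing <- 0.39
  scale <- 1.0
  k <- oracle_kernels(scale / spacing)
  st <- gaussian_derivative_stack(img, scale, spacing)
  rows <- 25:40; cols <- 22:37
  cases <- list(
    L   = list(outer(k$g0, k$g0), 1),
    Lx  = list(outer(k$g0, k$k1), spacing),
    Ly  = list(outer(k$k1, k$g0), spacing),
    Lxx = list(outer(k$g0, k$k2), spacing^2),
    Lxy = list(outer(k$k1, k$k1), spacing^2),
    Lyy = list(outer(k$k2, k$g0), spacing^2)
  )
  for (nm in names(cases)) {
    oracle <- dense_conv_at(img, cases[[nm]][[1]], rows, cols) /
      cases[[nm]][[2]]
    got <- st[[nm]][rows, cols]
    rel <- max(abs(got - oracle)) / max(abs(oracle))
    expect_lt(rel, 1e-3)
  }
})

test_that("tiny scales warn but still compute", {
  img <- matrix(stats::rnorm(16 * 16), 16, 16)
  expect_warning(gaussian_derivative_stack(img, 0.1, 0.39), "half a pixel")
})

test_that("feature dimensions follow the 1 + 6 x scales formula", {
  expect_equal(n_features_per_channel(feature_spec()), 25)
  expect_equal(n_features_per_channel(feature_spec(jet = "rotation_invariant")),
               13)
  expect_equal(n_features_per_channel(
    feature_spec(scales = c(0.5, 1), include_raw = FALSE)), 12)
  expect_error(feature_spec(scales = c(1, 0.5)), "increasing")
  expect_error(feature_spec(scales = -1), "positive")

  co <- preprocess_cohort(tiny_cohort(n_patients = 2, slices = 1, seed = 2))
  fm1 <- extract_features(co[[1]], "TOF")
  expect_equal(ncol(fm1$values), 25)
  expect_equal(nrow(fm1$values), sum(co[[1]]$slices[[1]]$wall))

  fm9 <- extract_features(co, contrast_weightings())
  expect_equal(ncol(fm9$values), 225)
  expect_equal(length(fm9$feature_names), 225)
})

test_that("feature rows are invariant to study order", {
  co <- preprocess_cohort(tiny_cohort(n_patients = 3, slices = 1, seed = 6))
  a <- extract_features(co, c("TOF", "MRDTI"))
  b <- extract_features(rev(co), c("TOF", "MRDTI"))
  key_a <- paste(a$pixels$patient_id, a$pixels$slice, a$pixels$row,
                 a$pixels$col)
  key_b <- paste(b$pixels$patient_id, b$pixels$slice, b$pixels$row,
                 b$pixels$col)
  expect_setequal(key_a, key_b)
  expect_equal(a$values[order(key_a), ], b$values[order(key_b), ])
})

test_that("raw, unnormalized studies are refused", {
  co <- tiny_cohort(n_patients = 2, slices = 1, seed = 8)
  expect_error(extract_features(co, "TOF"), "preprocess")
  pre <- preprocess_cohort(co)
  expect_error(extract_features(pre, c("TOF", "BAD")), "unknown")
  expect_error(extract_features(pre, character(0)), "at least one")
})
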