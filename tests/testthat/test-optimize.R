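test_that("subset enumeration is exhaustive, unique and ordered", {
  s9 <- enumerate_subsets(contrast_weightings())
  expect_length(s9, 511)
  expect_equal(anyDuplicated(vapply(s9, paste, "", collapse = "-")), 0)
  expect_equal(vapply(s9, length, 0L), sort(vapply(s9, length, 0L)))

  expect_length(enumerate_subsets("TOF"), 1)

  # 3 elements against a brute-force bitmask oracle
  w <- c("TOF", "T1W", "ADC")
  got <- lapply(enumerate_subsets(w), sort)
  oracle <- list()
  for (mask in 1:7) {
    oracle[[mask]] <- sort(w[as.logical(bitwAnd(mask, c(1, 2, 4)))])
  }
  expect_setequal(vapply(got, paste, "", collapse = "-"),
                  vapply(oracle, paste, "", collapse = "-"))

  expect_error(enumerate_subsets(character(0)), "empty")
})

test_that("scan durations reproduce the printed protocol times", {
  expect_equal(scan_duration("TOF"), 0.8)
  expect_equal(scan_duration(c("TOF", "MRDTI")), 3.0)
  expect_equal(scan_duration(c("TOF", "MRDTI", "ADC")), 7.7)
  expect_equal(scan_duration(c("TOF", "MRDTI", "ADC", "T2W")), 16.1)
  expect_equal(scan_duration(c("TOF", "MRDTI", "ADC", "PDW", "T1W")), 21.4)
  # shared acquisitions are billed once
  expect_equal(scan_duration(c("T2W", "PDW")), 8.4)
  expect_equal(scan_duration(c("DWT2", "DWI", "ADC")), 4.7)
  expect_equal(
    scan_duration(c("TOF", "MRDTI", "ADC", "PDW", "T1W", "DWI", "DWT2",
                    "T2W")), 21.4)
  expect_error(scan_duration(character(0)), "at least one")
  expect_error(scan_duration("XYZ"), "unknown")
})

test_that("scan duration is monotone under subset inclusion", {
  subsets <- enumerate_subsets(contrast_weightings())
  for (s in subsets) {
    d <- scan_duration(s, round = FALSE)
    for (w in setdiff(contrast_weightings(), s)) {
      expect_gte(scan_duration(c(s, w), round = FALSE), d)
    }
  }
})

test_that("plaque volume is pixel count times voxel volume", {
  g <- slice_geometry(64, 64, spacing = 0.39, thickness = 3)
  expect_equal(plaque_volume(matrix(FALSE, 64, 64), g), 0)
  m <- matrix(FALSE, 64, 64); m[1:10, 1:10] <- TRUE
  expect_equal(plaque_volume(m, g), 100 * 0.39^2 * 3)
  expect_equal(plaque_volume(list(m, m), g), 2 * 100 * 0.1521 * 3)
})

test_that("pearson_with_ci matches the closed-form statistics", {
  x <- c(10, 20, 30, 40, 55)
  perfect <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(perfect$r, 1)

  set.seed(314)
  for (i in 1:20) {
    a <- stats::rnorm(15); b <- stats::rnorm(15)
    got <- pearson_with_ci(a, b)
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(got$r, r, tolerance = 1e-12)
    z <- atanh(r); se <- 1 / sqrt(12)
    expect_equal(got$ci_low, tanh(z - stats::qnorm(0.975) * se),
                 tolerance = 1e-10)
    expect_equal(got$ci_high, tanh(z + stats::qnorm(0.975) * se),
                 tolerance = 1e-10)
    tstat <- r * sqrt(13) / sqrt(1 - r^2)
    expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), 13),
                 tolerance = 1e-10)
  }

  expect_error(pearson_with_ci(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_with_ci(1:2, 1:2), "at least 3")
})

test_that("leave-one-out keeps test patients out of their own folds", {
  co <- preprocess_cohort(tiny_cohort(n_patients = 3, slices = 2, seed = 37))
  res <- loo_cross_validate(co, c("TOF", "MRDTI"))
  expect_equal(nrow(res), 3)

  # corrupting the held-out patient's labels must not change its predictions
  corrupted <- co
  sl <- corrupted[[2]]$slices[[1]]
  flipped <- vessel_slice(sl$channels, sl$geometry, sl$lumen, sl$outer_wall,
                          plaque_mask = sl$wall)  # label everything plaque
  attr(flipped, "preprocessed") <- TRUE
  corrupted[[2]]$slices[[1]] <- flipped
  res2 <- loo_cross_validate(corrupted, c("TOF", "MRDTI"))
  m1 <- attr(res, "masks")[[co[[2]]$patient_id]]
  m2 <- attr(res2, "masks")[[co[[2]]$patient_id]]
  expect_identical(m1, m2)
})

test_that("two patients give two folds trained on each other", {
  co <- preprocess_cohort(tiny_cohort(n_patients = 2, slices = 2, seed = 41))
  res <- loo_cross_validate(co, "TOF")
  expect_equal(nrow(res), 2)
  expect_setequal(res$patient_id, c("P01", "P02"))
})

test_that("plaque-free training folds are reported as degenerate", {
  p <- phantom_params(
    n_patients = 2, slices_per_patient = 2,
    lesions = list(lipid = list(mean = 140, sd = 100, prevalence = 0)),
    seed = 43
  )
  co <- preprocess_cohort(generate_cohort(p))
  expect_error(loo_cross_validate(co, "TOF"), "degenerate")
})

test_that("the sweep's sufficient-statistic path equals the naive LOO path", {
  co <- preprocess_cohort(tiny_cohort(n_patients = 4, slices = 2, seed = 47))
  res <- evaluate_combinations(co, weightings = c("TOF", "MRDTI", "ADC"))
  expect_equal(nrow(res), 7)
  for (i in seq_len(nrow(res))) {
    sub <- strsplit(res$subset[i], "-")[[1]]
    naive <- loo_cross_validate(co, sub)
    ct <- pearson_with_ci(naive$reference_volume, naive$predicted_volume)
    expect_equal(res$volumes[[i]]$predicted_volume,
                 naive$predicted_volume, tolerance = 1e-8)
    expect_equal(res$r[i], ct$r, tolerance = 1e-8)
  }
})

test_that("a perfect predictor yields r = 1", {
  co <- tiny_cohort(n_patients = 5, slices = 2, seed = 53)
  ref <- reference_volumes(co)
  perfect <- pearson_with_ci(ref$reference_volume, ref$reference_volume)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
})

test_that("ranking modes order and break ties as documented", {
  res <- tibble::tibble(
    subset = c("A", "B", "C", "D"),
    n_weightings = c(2L, 1L, 1L, 3L),
    r = c(0.9, 0.9, 0.8, 0.95),
    ci_low = 0, ci_high = 1, p_value = 0.01,
    scan_minutes = c(5, 3, 1, 9),
    status = "ok",
    volumes = list(tibble::tibble())
  )
  class(res) <- c("combination_results", class(res))
  top <- rank_combinations(res, "by_correlation", top_k = 3)
  expect_equal(top$subset, c("D", "B", "A"))  # tie 0.9: fewer weightings
  bc <- rank_combinations(res, "by_count")
  expect_equal(bc$subset, c("B", "A", "D"))
  single <- rank_combinations(res[1, ], "by_correlation")
  expect_equal(single$subset, "A")
})

test_that("results tables round-trip through CSV", {
  co <- preprocess_cohort(tiny_cohort(n_patients = 3, slices = 1, seed = 59))
  res <- evaluate_combinations(co, weightings = c("TOF", "T1W"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, path)
  back <- read_results_csv(path)
  expect_equal(back$r, res$r, tolerance = 1e-12)
  expect_equal(back$subset, res$subset)
  expect_s3_class(back, "combination_results")
})
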