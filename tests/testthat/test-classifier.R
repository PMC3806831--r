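fake_features <- function(X, y) {
  list(values = X,
       labels = factor(y, levels = c("not_soft_plaque", "soft_plaque")))
}

two_clouds <- function(n = 50, d = 3, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n * d), n, d),
             matrix(stats::rnorm(n * d, mean = sep), n, d))
  colnames(X) <- paste0("f", seq_len(d))
  fake_features(X, rep(c("not_soft_plaque", "soft_plaque"), each = n))
}

test_that("fitted means and covariances match their defining formulas", {
  ff <- two_clouds(n = 250, d = 10, seed = 42)
  m <- fit_mahalanobis(ff, cov_mode = "per_class", lambda = 0)
  for (k in m$classes) {
    Xk <- ff$values[ff$labels == k, ]
    expect_equal(m$mu[[k]], colMeans(Xk), tolerance = 1e-12)
    # brute-force covariance: centered outer products over n - 1
    Xc <- sweep(Xk, 2, colMeans(Xk))
    S <- matrix(0, 10, 10)
    for (i in seq_len(nrow(Xc))) S <- S + tcrossprod(Xc[i, ])
    expect_equal(m$cov[[k]], S / (nrow(Xk) - 1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # pooled mode equals the weighted within-class covariance
  mp <- fit_mahalanobis(ff, cov_mode = "pooled", lambda = 0)
  S1 <- stats::cov(ff$values[ff$labels == m$classes[1], ])
  S2 <- stats::cov(ff$values[ff$labels == m$classes[2], ])
  expect_equal(mp$cov[[1]], (249 * S1 + 249 * S2) / 498, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("shrinkage rescues singular covariances", {
  # duplicated samples: each class is 3 copies of 2 points (rank-1 scatter)
  X <- matrix(rep(c(0, 0, 1, 2), 3), ncol = 2, byrow = TRUE)
  X <- rbind(X, X + 5)
  ff <- fake_features(X, rep(c("not_soft_plaque", "soft_plaque"), each = 6))
  m <- fit_mahalanobis(ff, cov_mode = "per_class", lambda = 1e-4)
  expect_s3_class(m, "mahalanobis_model")
  # and the regularized fit predicts its own training data sensibly
  expect_equal(as.character(predict(m, X[7, , drop = FALSE])),
               "soft_plaque")
})

test_that("training with a missing class is refused", {
  X <- matrix(stats::rnorm(20), 10, 2)
  expect_error(fit_mahalanobis(fake_features(X, rep("soft_plaque", 10))),
               "degenerate")
})

test_that("mahalanobis distance matches the explicit-inverse oracle", {
  set.seed(99)
  for (i in 1:120) {
    d <- sample(2:6, 1)
    A <- matrix(stats::rnorm(d * d), d)
    S <- crossprod(A) + diag(d) * 0.5
    mu <- stats::rnorm(d)
    x <- stats::rnorm(d)
    mine <- mahalanobis_dist2(x, mu, S)
    oracle <- drop(t(x - mu) %*% solve(S) %*% (x - mu))
    expect_equal(mine, oracle, tolerance = 1e-10)
    expect_equal(mine, unname(stats::mahalanobis(rbind(x), mu, S)),
                 tolerance = 1e-10)
  }
  # identity covariance reduces to squared Euclidean distance
  expect_equal(mahalanobis_dist2(c(3, 4), c(0, 0), diag(2)), 25)
  expect_equal(mahalanobis_dist2(c(1, 2, 3), c(1, 2, 3), diag(3)), 0)
})

test_that("prediction is argmin distance with a conservative tie rule", {
  ff <- two_clouds(n = 40, d = 2, sep = 5, seed = 7)
  m <- fit_mahalanobis(ff, cov_mode = "pooled", lambda = 0)
  # class means map to their own class
  expect_equal(as.character(predict(m, rbind(m$mu[[2]]))), "soft_plaque")

  # mirror-symmetric classes give mu2 = -mu1 exactly, so x = 0 is an exact
  # tie, which the rule resolves conservatively
  set.seed(77)
  X1 <- matrix(stats::rnorm(80, mean = 2), 40, 2)
  ffm <- fake_features(rbind(X1, -X1),
                       rep(c("not_soft_plaque", "soft_plaque"), each = 40))
  mm <- fit_mahalanobis(ffm, cov_mode = "pooled", lambda = 0)
  expect_equal(mm$mu[[2]], -mm$mu[[1]])
  expect_equal(as.character(predict(mm, rbind(c(0, 0)))), "not_soft_plaque")

  set.seed(8)
  Xt <- matrix(stats::rnorm(200 * 2, mean = 2.5), 200, 2)
  pred <- predict(m, Xt)
  oracle <- apply(Xt, 1, function(x) {
    d1 <- stats::mahalanobis(rbind(x), m$mu[[1]], m$cov[[1]])
    d2 <- stats::mahalanobis(rbind(x), m$mu[[2]], m$cov[[2]])
    if (d2 < d1) "soft_plaque" else "not_soft_plaque"
  })
  expect_equal(as.character(pred), oracle)

  expect_error(predict(m, matrix(0, 2, 5)), "mismatch")
})

test_that("pooled-covariance predictions are affine invariant (lambda = 0)", {
  ff <- two_clouds(n = 60, d = 3, sep = 4, seed = 21)
  set.seed(22)
  Xt <- matrix(stats::rnorm(300, mean = 2), 100, 3)
  A <- matrix(stats::rnorm(9), 3) + diag(3) * 2   # well-conditioned map
  b <- stats::rnorm(3)
  m0 <- fit_mahalanobis(ff, cov_mode = "pooled", lambda = 0)
  ff2 <- fake_features(ff$values %*% t(A) + rep(b, each = nrow(ff$values)),
                       ff$labels)
  m1 <- fit_mahalanobis(ff2, cov_mode = "pooled", lambda = 0)
  expect_equal(predict(m0, Xt),
               predict(m1, Xt %*% t(A) + rep(b, each = nrow(Xt))))
})

test_that("pooled mode reproduces a linear-discriminant oracle", {
  # equal class sizes, pooled covariance: the boundary is the hyperplane
  # w'x = w'(mu1+mu2)/2 with w = Sigma^-1 (mu2 - mu1)
  ff <- two_clouds(n = 80, d = 4, sep = 3, seed = 31)
  m <- fit_mahalanobis(ff, cov_mode = "pooled", lambda = 0)
  set.seed(32)
  Xt <- matrix(stats::rnorm(400, mean = 1.5), 100, 4)
  w <- solve(m$cov[[1]], m$mu[[2]] - m$mu[[1]])
  thresh <- sum(w * (m$mu[[1]] + m$mu[[2]])) / 2
  oracle <- ifelse(Xt %*% w > thresh, "soft_plaque", "not_soft_plaque")
  expect_equal(as.character(predict(m, Xt)), as.vector(oracle))
})

test_that("training accuracy beats a naive distance-to-mean baseline", {
  set.seed(51)
  n <- 150
  # anisotropic clouds where the euclidean nearest-mean rule is suboptimal
  X1 <- cbind(stats::rnorm(n, 0, 4), stats::rnorm(n, 0, 0.3))
  X2 <- cbind(stats::rnorm(n, 2, 4), stats::rnorm(n, 1.2, 0.3))
  X <- rbind(X1, X2); colnames(X) <- c("f1", "f2")
  ff <- fake_features(X, rep(c("not_soft_plaque", "soft_plaque"), each = n))
  m <- fit_mahalanobis(ff, cov_mode = "pooled")
  acc <- mean(predict(m, X) == ff$labels)
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  base <- mean(ifelse(
    rowSums(sweep(X, 2, mu2)^2) < rowSums(sweep(X, 2, mu1)^2),
    "soft_plaque", "not_soft_plaque") == ff$labels)
  expect_gte(acc, base)
})

test_that("models serialize to JSON and back without changing predictions", {
  ff <- two_clouds(n = 30, d = 3, sep = 4, seed = 61)
  m <- fit_mahalanobis(ff)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  m2 <- model_from_json(path)
  expect_equal(m2$mu, m$mu, tolerance = 1e-12)
  set.seed(62)
  Xt <- matrix(stats::rnorm(60, 2), 20, 3)
  expect_equal(predict(m2, Xt), predict(m, Xt))
})

test_that("tidy and glance summarize a fitted model", {
  ff <- two_clouds(n = 25, d = 2, seed = 71)
  m <- fit_mahalanobis(ff)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)  # 2 classes x 2 features
  expect_named(td, c("class", "feature", "mean", "variance"))
  gl <- glance(m)
  expect_equal(gl$n_features, 2)
  expect_equal(gl$cov_mode, "pooled")
})
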