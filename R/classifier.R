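#' Fit a two-class Mahalanobis-distance classifier
#'
#' Learns per-class mean vectors and covariance statistics from labeled wall
#' pixels. A pixel is later assigned to the class with the smaller squared
#' Mahalanobis distance `(x - mu_k)' Sigma_k^-1 (x - mu_k)`; no prior or
#' log-determinant term enters the rule. The default metric is the pooled
#' within-class covariance (the classical Mahalanobis classifier, giving a
#' linear decision boundary); per-class covariances are available as an
#' option but are fragile when between-patient variability inflates one
#' class's covariance. Covariances are shrunk toward their diagonal,
#' `Sigma_reg = (1 - lambda) Sigma + lambda diag(Sigma)`, which keeps the fit
#' invertible despite strongly collinear scale-space features.
#'
#' @param features a [extract_features()] result, or a list with `values`
#'   (numeric matrix) and `labels` (factor with levels not_soft_plaque,
#'   soft_plaque).
#' @param cov_mode `"pooled"` (default) or `"per_class"`.
#' @param lambda shrinkage weight in \[0, 1).
#' @return A `mahalanobis_model`.
#' @export
fit_mahalanobis <- function(features, cov_mode = c("pooled", "per_class"),
                            lambda = 1e-4) {
  cov_mode <- match.arg(cov_mode)
  stopifnot(lambda >= 0, lambda < 1)
  X <- features$values
  y <- features$labels
  stopifnot(is.matrix(X), nrow(X) == length(y))
  classes <- c("not_soft_plaque", "soft_plaque")
  n_k <- table(factor(y, levels = classes))
  if (any(n_k < 2)) {
    stop("degenerate training set: class(es) ",
         paste(classes[n_k < 2], collapse = ", "),
         " have fewer than 2 samples", call. = FALSE)
  }
  stats <- lapply(classes, function(k) {
    Xk <- X[y == k, , drop = FALSE]
    list(n = nrow(Xk), sum = colSums(Xk), scatter = crossprod(Xk))
  })
  names(stats) <- classes
  fit_from_stats(stats, cov_mode, lambda,
                 colnames(X) %||% paste0("f", seq_len(ncol(X))))
}

# core fit from per-class sufficient statistics (n, sum, X'X)
fit_from_stats <- function(stats, cov_mode, lambda, feature_names) {
  classes <- names(stats)
  mu <- lapply(stats, function(s) s$sum / s$n)
  centered_scatter <- mapply(function(s, m) s$scatter - s$n * tcrossprod(m),
                             stats, mu, SIMPLIFY = FALSE)
  covs <- if (cov_mode == "pooled") {
    n_tot <- sum(vapply(stats, `[[`, 0, "n"))
    pooled <- Reduce(`+`, centered_scatter) / (n_tot - length(classes))
    rep(list(pooled), length(classes))
  } else {
    mapply(function(cs, s) cs / (s$n - 1), centered_scatter, stats,
           SIMPLIFY = FALSE)
  }
  names(covs) <- classes
  chols <- lapply(covs, function(S) {
    S <- (S + t(S)) / 2
    Sreg <- (1 - lambda) * S + lambda * diag(diag(S), nrow(S))
    ch <- tryCatch(chol(Sreg), error = function(e) NULL)
    if (is.null(ch)) {
      stop("regularized covariance is not positive definite; ",
           "increase lambda or remove constant features", call. = FALSE)
    }
    ch
  })
  structure(
    list(classes = classes, mu = mu, cov = covs, chol = chols,
         cov_mode = cov_mode, lambda = lambda,
         n_features = length(feature_names),
         feature_names = feature_names,
         n_train = vapply(stats, `[[`, 0, "n")),
    class = "mahalanobis_model"
  )
}

#' @export
print.mahalanobis_model <- function(x, ...) {
  cat(sprintf(
    "<mahalanobis_model> %d features, %s covariance, lambda=%g; n = %s\n",
    x$n_features, x$cov_mode, x$lambda,
    paste(sprintf("%s:%d", x$classes, x$n_train), collapse = ", ")))
  invisible(x)
}

#' Squared Mahalanobis distance
#'
#' `d2 = (x - mu)' Sigma^-1 (x - mu)`, computed through the Cholesky factor
#' of the (regularized) covariance.
#'
#' @param x numeric vector, or matrix with one observation per row.
#' @param mu mean vector.
#' @param sigma positive-definite covariance matrix.
#' @return Non-negative numeric vector of squared distances.
#' @export
mahalanobis_dist2 <- function(x, mu, sigma) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(mu)) {
    stop(sprintf("feature length mismatch: expected %d, got %d",
                 length(mu), ncol(x)), call. = FALSE)
  }
  ch <- tryCatch(chol((sigma + t(sigma)) / 2), error = function(e) {
    stop("covariance is not positive definite: ", conditionMessage(e),
         call. = FALSE)
  })
  dist2_from_chol(x, mu, ch)
}

dist2_from_chol <- function(X, mu, ch) {
  z <- backsolve(ch, t(X) - mu, transpose = TRUE)
  colSums(z^2)
}

#' Predict soft-plaque labels for wall pixels
#'
#' Assigns each pixel to the class with the smaller squared Mahalanobis
#' distance; exact ties go to `not_soft_plaque` (conservative plaque calls).
#'
#' @param object a [fit_mahalanobis()] model.
#' @param features a `feature_matrix` or plain numeric matrix with matching
#'   columns.
#' @param ... unused.
#' @return Factor of predicted labels (levels not_soft_plaque, soft_plaque),
#'   aligned with the rows of `features`.
#' @export
predict.mahalanobis_model <- function(object, features, ...) {
  X <- if (is.matrix(features)) features else features$values
  if (ncol(X) != object$n_features) {
    stop(sprintf("feature length mismatch: model expects %d features, got %d",
                 object$n_features, ncol(X)), call. = FALSE)
  }
  d_not <- dist2_from_chol(X, object$mu[[1]], object$chol[[1]])
  d_sp  <- dist2_from_chol(X, object$mu[[2]], object$chol[[2]])
  factor(ifelse(d_sp < d_not, "soft_plaque", "not_soft_plaque"),
         levels = object$classes)
}

#' Rebuild per-slice predicted plaque masks from pixel predictions
#'
#' @param features the `feature_matrix` that was predicted on.
#' @param labels factor of predicted labels aligned with `features`.
#' @param studies the studies the features came from (for grid dimensions).
#' @return Named list (by patient) of lists of logical matrices, one per
#'   slice.
#' @export
prediction_masks <- function(features, labels, studies) {
  if (inherits(studies, "patient_study")) studies <- list(studies)
  names(studies) <- vapply(studies, `[[`, "", "patient_id")
  out <- lapply(studies, function(st) {
    lapply(st$slices, function(sl) matrix(FALSE, sl$geometry$rows,
                                          sl$geometry$cols))
  })
  px <- features$pixels
  hit <- labels == "soft_plaque"
  for (i in which(hit)) {
    out[[px$patient_id[i]]][[px$slice[i]]][px$row[i], px$col[i]] <- TRUE
  }
  out
}

#' Serialize a Mahalanobis model to JSON
#' @param model a `mahalanobis_model`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- list(
    classes = model$classes, mu = model$mu,
    cov = lapply(model$cov, function(S) unclass(S)),
    cov_mode = model$cov_mode, lambda = model$lambda,
    feature_names = model$feature_names,
    n_train = as.list(model$n_train)
  )
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a Mahalanobis model from JSON
#' @param path file path or JSON string from [model_to_json()].
#' @return A `mahalanobis_model`.
#' @export
model_from_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  mu <- lapply(p$mu, function(v) stats::setNames(as.numeric(v),
                                                p$feature_names))
  covs <- lapply(p$cov, function(S) matrix(unlist(S), length(mu[[1]])))
  chols <- lapply(covs, function(S) {
    lam <- p$lambda
    chol((1 - lam) * (S + t(S)) / 2 + lam * diag(diag(S), nrow(S)))
  })
  structure(
    list(classes = p$classes, mu = mu, cov = covs, chol = chols,
         cov_mode = p$cov_mode, lambda = p$lambda,
         n_features = length(mu[[1]]),
         feature_names = p$feature_names,
         n_train = unlist(p$n_train)),
    class = "mahalanobis_model"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-class feature means of a fitted model
#' @param x a `mahalanobis_model`.
#' @param ... unused.
#' @return Tibble with columns `class`, `feature`, `mean`, `variance`.
#' @export
tidy.mahalanobis_model <- function(x, ...) {
  purrr::map_dfr(x$classes, function(k) {
    tibble::tibble(class = k, feature = x$feature_names,
                   mean = x$mu[[k]], variance = diag(x$cov[[k]]))
  })
}

#' One-row summary of a fitted model
#' @param x a `mahalanobis_model`.
#' @param ... unused.
#' @return One-row tibble.
#' @export
glance.mahalanobis_model <- function(x, ...) {
  tibble::tibble(
    n_features = x$n_features, cov_mode = x$cov_mode, lambda = x$lambda,
    n_not_soft_plaque = unname(x$n_train[1]),
    n_soft_plaque = unname(x$n_train[2])
  )
}
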