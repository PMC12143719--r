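# Multivariate k-nearest-neighbour imputation with inverse-distance
# weighting.
#
# Prediction for a query p is the weighted mean of the k nearest
# training plots in the standardized feature space,
#     y_hat_p = sum_l w_l y_l,   w_l proportional to 1 / d_l,
# computed jointly for all three responses (vol, agb, dcp) from the
# same neighbour set.  The per-query uncertainty is the standard
# deviation of the neighbour responses about the prediction,
#     s_p = sqrt( sum_l (y_l - y_hat_p)^2 / k ),
# with unweighted deviations and divisor k.  Distances are floored at
# a small epsilon so that a query coinciding with a training plot is
# dominated by that plot.

#' Fit a k-nearest-neighbour imputation model
#'
#' @param training a [build_feature_matrix()] `training_set` (mapping
#'   plots only).
#' @param k neighbour count (default 7).
#' @param epsilon distance floor in standardized feature units applied
#'   before inverse-distance weighting (default 1e-9); must be > 0.
#' @return An object of class `forest_knn`.
#' @export
fit_knn <- function(training, k = 7L, epsilon = 1e-9) {
  stopifnot(inherits(training, "training_set"), k >= 1L, epsilon > 0)
  n <- nrow(training$X)
  if (n < 1L) stop("empty training set")
  if (n < k)
    stop(sprintf("training set has %d plots but k = %d", n, k))
  structure(list(X = training$X, Y = training$Y,
                 scaler = training$scaler,
                 feature_names = training$feature_names,
                 location_mode = training$location_mode,
                 plot_ids = training$plot_ids,
                 k = as.integer(k), epsilon = epsilon),
            class = "forest_knn")
}

#' @export
print.forest_knn <- function(x, ...) {
  cat(sprintf(paste0("<forest_knn> k = %d, Euclidean distance, inverse-",
                     "distance weights\n  %d training plots, features: %s\n"),
              x$k, nrow(x$X), paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' @export
summary.forest_knn <- function(object, ...) {
  ym <- colMeans(object$Y)
  cat(sprintf("k-nearest-neighbour imputation model (k = %d)\n", object$k))
  cat(sprintf("  training plots: %d\n", nrow(object$X)))
  cat(sprintf("  features (%d): %s\n", length(object$feature_names),
              paste(object$feature_names, collapse = ", ")))
  cat(sprintf("  mean responses: vol %.1f m3/ha, agb %.1f t/ha, dcp %.1f %%\n",
              ym["vol"], ym["agb"], ym["dcp"]))
  invisible(object)
}

# exhaustive neighbour search.  Distances accumulate squared
# per-feature differences in fixed column order so that results are
# bitwise reproducible; ties (exactly equal distances) are broken
# towards the lower training-row index.
knn_search <- function(model, Q, k = model$k) {
  X <- model$X
  nq <- nrow(Q); nt <- nrow(X)
  D <- matrix(0, nq, nt)
  for (f in seq_len(ncol(X)))
    D <- D + (outer(Q[, f], X[, f], "-"))^2
  idx <- matrix(0L, nq, k)
  dst <- matrix(0, nq, k)
  rows <- seq_len(nq)
  for (l in seq_len(k)) {
    j <- max.col(-D, ties.method = "first")
    idx[, l] <- j
    dst[, l] <- D[cbind(rows, j)]
    D[cbind(rows, j)] <- Inf
  }
  list(idx = idx, dist = sqrt(dst))
}

standardize_features <- function(model, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model$feature_names))
    stop(sprintf("feature dimension mismatch: got %d, model expects %d (%s)",
                 ncol(X), length(model$feature_names),
                 paste(model$feature_names, collapse = ", ")))
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_names))
    X <- X[, model$feature_names, drop = FALSE]
  sweep(sweep(X, 2, model$scaler$center, "-"), 2, model$scaler$scale, "/")
}

#' Predict forest attributes for feature vectors
#'
#' Applies the fitted kNN imputation to one or more query feature rows,
#' returning for each the inverse-distance-weighted prediction and the
#' neighbour standard deviation for all three responses.  Batch
#' prediction is row-wise identical to repeated single-row calls and
#' order-preserving.
#'
#' @param object a [fit_knn()] model.
#' @param newdata matrix or data frame of raw (unstandardized) feature
#'   rows in the model's column layout.
#' @param standardized set `TRUE` if `newdata` is already standardized
#'   with the model's scaler.
#' @param details also return neighbour indices, distances and weights.
#' @param ... unused.
#' @return A `data.frame` with columns `vol`, `agb`, `dcp`,
#'   `stdev_vol`, `stdev_agb`, `stdev_dcp`; with `details = TRUE` a
#'   list also holding `idx`, `dist`, `weights`.
#' @export
predict.forest_knn <- function(object, newdata, standardized = FALSE,
                               details = FALSE, ...) {
  Q <- if (standardized) {
    if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
    newdata
  } else standardize_features(object, newdata)
  ns <- knn_search(object, Q)
  k <- object$k
  d <- pmax(ns$dist, object$epsilon)
  w <- 1 / d
  w <- w / rowSums(w)
  out <- matrix(0, nrow(Q), 6,
                dimnames = list(NULL, c("vol", "agb", "dcp",
                                        "stdev_vol", "stdev_agb",
                                        "stdev_dcp")))
  for (j in 1:3) {
    yk <- matrix(object$Y[ns$idx, j], nrow(Q), k)
    yhat <- rowSums(w * yk)
    out[, j] <- yhat
    out[, j + 3] <- sqrt(rowSums((yk - yhat)^2) / k)
  }
  pred <- as.data.frame(out)
  if (details) list(prediction = pred, idx = ns$idx, dist = ns$dist,
                    weights = w)
  else pred
}

#' Leave-one-out residuals of a kNN model
#'
#' Each training plot is predicted from its k nearest neighbours
#' excluding itself (and any other row at exactly zero distance is
#' retained — only the row's own index is removed), giving honest
#' in-sample residuals `observed - predicted`.
#'
#' @param object a [fit_knn()] model.
#' @param ... unused.
#' @return A `data.frame` of residuals with columns `vol`, `agb`, `dcp`.
#' @export
residuals.forest_knn <- function(object, ...) {
  loo <- loo_predict(object)
  as.data.frame(object$Y - as.matrix(loo[, c("vol", "agb", "dcp")]))
}

loo_predict <- function(model) {
  n <- nrow(model$X)
  ns <- knn_search(model, model$X, k = min(model$k + 1L, n))
  k <- model$k
  keep <- t(vapply(seq_len(n), function(i) {
    cand <- which(ns$idx[i, ] != i)
    cand[seq_len(min(k, length(cand)))]
  }, integer(min(k, n - 1L))))
  idx <- matrix(ns$idx[cbind(rep(seq_len(n), each = ncol(keep)),
                             as.vector(t(keep)))],
                n, ncol(keep), byrow = TRUE)
  dst <- matrix(ns$dist[cbind(rep(seq_len(n), each = ncol(keep)),
                              as.vector(t(keep)))],
                n, ncol(keep), byrow = TRUE)
  d <- pmax(dst, model$epsilon)
  w <- 1 / d; w <- w / rowSums(w)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("vol", "agb", "dcp")))
  for (j in 1:3) {
    yk <- matrix(model$Y[idx, j], n, ncol(idx))
    out[, j] <- rowSums(w * yk)
  }
  as.data.frame(out)
}

#' Observed versus leave-one-out predicted plot
#'
#' @param x a [fit_knn()] model.
#' @param variable which response to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.forest_knn <- function(x, variable = c("agb", "vol", "dcp"), ...) {
  variable <- match.arg(variable)
  loo <- loo_predict(x)
  obs <- x$Y[, variable]
  unit <- c(vol = "m3/ha", agb = "t/ha", dcp = "%")[variable]
  graphics::plot(obs, loo[[variable]],
                 xlab = sprintf("observed %s (%s)", variable, unit),
                 ylab = sprintf("LOO predicted %s (%s)", variable, unit),
                 pch = 16, col = grDevices::adjustcolor("forestgreen", 0.4),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Save / load a fitted model
#'
#' Round-trip serialization of a `forest_knn` model to a single file.
#'
#' @param model a [fit_knn()] model.
#' @param path file path.
#' @return `path` invisibly; `load_knn()` returns the model.
#' @export
save_knn <- function(model, path) {
  stopifnot(inherits(model, "forest_knn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_knn
#' @export
load_knn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "forest_knn"))
    stop("file does not contain a forest_knn model")
  model
}
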