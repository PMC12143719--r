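# The kNN imputation core: neighbour search, inverse-distance
# weighting, the neighbour-standard-deviation uncertainty, and the
# model object's methods.

toy_training <- function(X, Y) {
  structure(list(X = X, Y = Y,
                 scaler = list(center = rep(0, ncol(X)),
                               scale = rep(1, ncol(X))),
                 plot_ids = sprintf("t%d", seq_len(nrow(X))),
                 feature_names = colnames(X) %||%
                   paste0("f", seq_len(ncol(X))),
                 location_mode = "none"),
            class = "training_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("single-neighbour and hand-worked two-neighbour cases", {
  X <- matrix(c(0, 1, 4, 9), ncol = 1)
  Y <- cbind(vol = c(10, 20, 30, 40), agb = c(1, 2, 3, 4),
             dcp = c(0, 50, 100, 25))
  m1 <- fit_knn(toy_training(X, Y), k = 1)
  p <- predict(m1, matrix(3.9), standardized = TRUE)
  expect_equal(unlist(p[c("vol", "agb", "dcp")]),
               c(vol = 30, agb = 3, dcp = 100))
  expect_equal(unlist(p[c("stdev_vol", "stdev_agb", "stdev_dcp")]),
               c(stdev_vol = 0, stdev_agb = 0, stdev_dcp = 0))

  # equidistant neighbours with responses {0, 2}: prediction 1, s = 1
  X2 <- matrix(c(-1, 1), ncol = 1)
  Y2 <- cbind(vol = c(0, 2), agb = c(0, 2), dcp = c(0, 2))
  m2 <- fit_knn(toy_training(X2, Y2), k = 2)
  p2 <- predict(m2, matrix(0), standardized = TRUE)
  expect_equal(p2$agb, 1)
  expect_equal(p2$stdev_agb, 1)
  expect_equal(p2$vol, 1)

  # a query on a training plot is dominated through the epsilon floor
  m4 <- fit_knn(toy_training(X, Y), k = 4)
  p4 <- predict(m4, matrix(1), standardized = TRUE)
  expect_equal(p4$vol, 20, tolerance = 1e-6)
  # but s still measures neighbour spread, not the match
  expect_gt(p4$stdev_vol, 0)
})

test_that("fit_knn validates inputs and k = n uses every plot", {
  X <- matrix(rnorm(14), 7, 2)
  Y <- cbind(vol = 1:7, agb = 1:7, dcp = 1:7)
  expect_error(fit_knn(toy_training(X[1:3, ], Y[1:3, ]), k = 7),
               "3 plots but k = 7")
  m <- fit_knn(toy_training(X, Y), k = 7)
  det <- predict(m, matrix(rnorm(2), 1), standardized = TRUE,
                 details = TRUE)
  expect_setequal(as.vector(det$idx), 1:7)
  expect_equal(sum(det$weights), 1)
})

test_that("neighbour sets and predictions equal the exhaustive oracle", {
  set.seed(101)
  n <- 1000; q <- 100; p <- 11
  X <- matrix(rnorm(n * p), n, p)
  # include exact duplicate rows to exercise the index tie-break
  X[2, ] <- X[1, ]
  X[500, ] <- X[499, ]
  Y <- cbind(vol = rexp(n, 1 / 200), agb = rexp(n, 1 / 120),
             dcp = runif(n, 0, 100))
  Q <- matrix(rnorm(q * p), q, p)
  Q[1, ] <- X[1, ]            # query coinciding with a training plot
  m <- fit_knn(toy_training(X, Y), k = 7)
  got <- predict(m, Q, standardized = TRUE, details = TRUE)
  oracle <- knn_oracle(X, Y, Q, k = 7)
  expect_identical(got$idx, oracle$idx)
  expect_equal(got$dist, oracle$dist, tolerance = 0)
  expect_equal(as.matrix(got$prediction[, c("vol", "agb", "dcp")]),
               oracle$yhat, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(as.matrix(got$prediction[, c("stdev_vol", "stdev_agb",
                                            "stdev_dcp")]),
               oracle$s, ignore_attr = TRUE, tolerance = 1e-12)
  # distances non-decreasing; weights positive and normalized
  expect_true(all(apply(got$dist, 1, function(d) all(diff(d) >= 0))))
  expect_true(all(got$weights > 0))
  expect_equal(rowSums(got$weights), rep(1, q))
})

test_that("predictions are convex combinations of neighbour responses", {
  set.seed(55)
  X <- matrix(rnorm(600), 200, 3)
  Y <- cbind(vol = rexp(200, 1 / 300), agb = rexp(200, 1 / 150),
             dcp = runif(200, 0, 100))
  m <- fit_knn(toy_training(X, Y), k = 7)
  Q <- matrix(rnorm(150), 50, 3)
  got <- predict(m, Q, standardized = TRUE, details = TRUE)
  for (j in c("vol", "agb", "dcp")) {
    yn <- matrix(Y[got$idx, j], 50, 7)
    expect_true(all(got$prediction[[j]] >= apply(yn, 1, min) - 1e-12))
    expect_true(all(got$prediction[[j]] <= apply(yn, 1, max) + 1e-12))
  }
  # s >= 0, and s = 0 iff all neighbour responses equal
  expect_true(all(got$prediction$stdev_vol >= 0))
  Yc <- Y; Yc[, "agb"] <- 42
  mc <- fit_knn(toy_training(X, Yc), k = 7)
  expect_equal(predict(mc, Q, standardized = TRUE)$stdev_agb,
               rep(0, 50))
})

test_that("the uncertainty statistic is translation- and scale-consistent", {
  set.seed(66)
  X <- matrix(rnorm(300), 100, 3)
  Y <- cbind(vol = rexp(100, 1 / 300), agb = rexp(100, 1 / 150),
             dcp = runif(100, 0, 100))
  Q <- matrix(rnorm(30), 10, 3)
  m <- fit_knn(toy_training(X, Y), k = 5)
  base <- predict(m, Q, standardized = TRUE)
  shifted <- Y; shifted[, "agb"] <- shifted[, "agb"] + 1000
  ms <- fit_knn(toy_training(X, shifted), k = 5)
  ps <- predict(ms, Q, standardized = TRUE)
  expect_equal(ps$stdev_agb, base$stdev_agb, tolerance = 1e-9)
  expect_equal(ps$agb, base$agb + 1000, tolerance = 1e-9)
  scaled <- Y; scaled[, "agb"] <- scaled[, "agb"] * 3
  mm <- fit_knn(toy_training(X, scaled), k = 5)
  pm <- predict(mm, Q, standardized = TRUE)
  expect_equal(pm$stdev_agb, base$stdev_agb * 3, tolerance = 1e-9)
})

test_that("batch prediction is order-preserving and equals single calls", {
  set.seed(9)
  X <- matrix(rnorm(200), 50, 4)
  Y <- cbind(vol = rexp(50, 1 / 300), agb = rexp(50, 1 / 150),
             dcp = runif(50, 0, 100))
  m <- fit_knn(toy_training(X, Y), k = 3)
  Q <- matrix(rnorm(40), 10, 4)
  batch <- predict(m, Q, standardized = TRUE)
  singles <- do.call(rbind, lapply(seq_len(10), function(i)
    predict(m, Q[i, , drop = FALSE], standardized = TRUE)))
  expect_equal(batch, singles, ignore_attr = TRUE)
  perm <- sample(10)
  expect_equal(predict(m, Q[perm, ], standardized = TRUE),
               batch[perm, ], ignore_attr = TRUE)
  expect_error(predict(m, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("models round-trip through serialization and expose methods", {
  fx <- make_test_model(seed = 23, n_plots = 120, extent = 2000, k = 5)
  f <- withr::local_tempfile(fileext = ".rds")
  save_knn(fx$model, f)
  back <- load_knn(f)
  expect_equal(back, fx$model)
  Xv <- signature_features(fx$validation, "both_axes")
  expect_equal(predict(back, Xv), predict(fx$model, Xv))
  expect_output(print(fx$model), "k = 5")
  expect_output(summary(fx$model), "training plots")
  r <- residuals(fx$model)
  expect_equal(names(r), c("vol", "agb", "dcp"))
  expect_equal(nrow(r), nrow(fx$model$X))
  expect_gt(sd(r$agb), 0)   # honest leave-one-out, not self-matching
  saveRDS(list(1), f)
  expect_error(load_knn(f), "forest_knn")
})
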