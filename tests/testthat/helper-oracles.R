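# Shared oracles and fixtures.  Oracles are deliberately naive and
# independent of the package internals they check.

# Supersampling oracle for circle-pixel overlap weights: about n x n
# sample points over the circle's bounding box on a lattice aligned
# with (and offset from) the pixel edges, so that pixel assignment is
# exact and only the circular arc is sampled.  The weight of a cell is
# the fraction of in-circle points falling in it.
supersample_footprint <- function(easting, northing, transform, dim,
                                  radius = FOOTPRINT_RADIUS, n = 1000L) {
  tr <- transform
  s <- ceiling(tr$px * n / (2 * radius))   # subdivisions per pixel
  hx <- tr$px / s; hy <- tr$py / s
  kx <- floor((easting - radius - tr$x0) / hx):
    ceiling((easting + radius - tr$x0) / hx)
  ky <- floor((tr$y0 - (northing + radius)) / hy):
    ceiling((tr$y0 - (northing - radius)) / hy)
  xs <- tr$x0 + (kx + 0.5) * hx
  ys <- tr$y0 - (ky + 0.5) * hy
  pts <- expand.grid(x = xs, y = ys)
  inside <- (pts$x - easting)^2 + (pts$y - northing)^2 <= radius^2
  pts <- pts[inside, ]
  row <- floor((tr$y0 - pts$y) / tr$py) + 1
  col <- floor((pts$x - tr$x0) / tr$px) + 1
  tab <- table(paste(row, col))
  key <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(row = as.integer(key[, 1]), col = as.integer(key[, 2]),
             weight = as.numeric(tab) / sum(tab))
}

# Brute-force kNN oracle: per-query loop, distances via colSums of
# squared feature differences, ties broken by training-row index.
knn_oracle <- function(X, Y, Q, k, epsilon = 1e-9) {
  nq <- nrow(Q)
  idx <- matrix(0L, nq, k); dst <- matrix(0, nq, k)
  yhat <- matrix(0, nq, ncol(Y)); s <- matrix(0, nq, ncol(Y))
  for (i in seq_len(nq)) {
    d2 <- numeric(nrow(X))
    for (f in seq_len(ncol(X))) d2 <- d2 + (Q[i, f] - X[, f])^2
    d <- sqrt(d2)
    ord <- order(d, seq_along(d))[seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- d[ord]
    w <- 1 / pmax(d[ord], epsilon)
    w <- w / sum(w)
    for (j in seq_len(ncol(Y))) {
      yh <- sum(w * Y[ord, j])
      yhat[i, j] <- yh
      s[i, j] <- sqrt(sum((Y[ord, j] - yh)^2) / k)
    }
  }
  list(idx = idx, dist = dst, yhat = yhat, s = s)
}

# Small deterministic raster stack with hand-set values.
make_test_stack <- function(nr = 20, nc = 20, origin = c(4000000, 2700000),
                            seed = 99, cloud_cells = NULL,
                            loss_cells = NULL, loss_year = 2019) {
  set.seed(seed)
  bands <- list()
  for (nm in c("B2", "B3", "B4", "B5", "B8", "B11", "B12"))
    bands[[nm]] <- matrix(runif(nr * nc, 200, 3000), nr, nc)
  bands$TCD <- matrix(runif(nr * nc, 0, 100), nr, nc)
  bands$FTY <- matrix(sample(c(FTY_CONIFEROUS, FTY_BROADLEAVED), nr * nc,
                             replace = TRUE), nr, nc)
  bands$QUALITY <- matrix(8000, nr, nc)
  if (!is.null(cloud_cells)) bands$QUALITY[cloud_cells] <- 1000
  tr <- geotransform(origin[1], origin[2], 10)
  n30 <- ceiling(nr * 10 / 30)
  gfc <- matrix(0, n30, ceiling(nc * 10 / 30))
  if (!is.null(loss_cells)) gfc[loss_cells] <- loss_year
  raster_stack(bands, tr, gfc = gfc,
               gfc_transform = geotransform(origin[1], origin[2], 30))
}

# A small fitted model on synthetic plots, reused by several files.
make_test_model <- function(seed = 11, n_plots = 400, extent = 2000,
                            location_mode = "both_axes", k = 7) {
  params <- scene_params(extent = extent, seed = seed,
                         cloud_fraction = 0, loss_fraction = 0)
  sc <- suppressWarnings(simulate_scene(params, n_plots = n_plots))
  sig <- screen_plots(extract_signatures(sc$plots, sc$stack))
  sp <- split_validation(kept_plots(sig))
  area <- area_config("test", "XX", location_mode)
  forest_map <- !is.na(sp$validation$FTY) &
    sp$validation$FTY != FTY_NONFOREST
  ts <- build_feature_matrix(sp$mapping, area)
  list(model = fit_knn(ts, k = k), training = ts, area = area,
       mapping = sp$mapping, validation = sp$validation[forest_map, ],
       scene = sc)
}
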