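# The synthetic-scene generator: determinism, ground-truth consistency
# and parameter recovery.

test_that("landscapes are deterministic and respect degenerate params", {
  p <- scene_params(extent = 1000, seed = 5)
  l1 <- generate_landscape(p)
  l2 <- generate_landscape(p)
  expect_identical(l1$agb, l2$agb)
  expect_identical(l1$dcp, l2$dcp)
  expect_equal(l1$vol, p$vol_ratio * l1$agb)
  expect_true(all(l1$agb >= 0))
  expect_true(all(l1$dcp >= 0 & l1$dcp <= 100))

  # zero-sd fields collapse to the stated means
  pc <- scene_params(extent = 500, seed = 1, agb_sd = 0, conifer_sd = 0,
                     agb_mean = 150, conifer_mean = 40)
  lc <- generate_landscape(pc)
  expect_true(all(lc$agb == 150))
  expect_true(all(lc$dcp == 40))
  expect_error(scene_params(extent = -1), "positive")
})

test_that("realized field moments track the targets over seeds", {
  # parameters where zero-clipping is immaterial, so the configured
  # mean is the field mean
  means <- vapply(1:20, function(s) {
    p <- scene_params(extent = 2000, seed = s, agb_mean = 150,
                      agb_sd = 40, agb_corr_len = 150)
    mean(generate_landscape(p)$agb)
  }, numeric(1))
  se <- sd(means) / sqrt(20)
  expect_lt(abs(mean(means) - 150), 3 * se + 1e-9)
})

test_that("rendered stacks are consistent with the ground truth", {
  pc <- scene_params(extent = 500, seed = 2, agb_sd = 0,
                     conifer_sd = 0, agb_mean = 120, noise_sd = 0,
                     tcd_noise_sd = 0, cloud_fraction = 0,
                     loss_fraction = 0)
  lc <- generate_landscape(pc)
  st <- render_stack(lc)
  for (nm in names(pc$band_model)) {
    bm <- pc$band_model[[nm]]
    expect_equal(unique(as.vector(st$bands[[nm]])),
                 bm$a * exp(-120 / bm$b) + bm$c, tolerance = 1e-12)
  }
  expect_equal(unique(as.vector(st$bands$TCD)),
               100 * (1 - exp(-120 / pc$tcd_scale)))
  # no pixel fails the quality screen without clouds
  expect_true(all(st$bands$QUALITY > 4000))
  expect_true(all(st$gfc == 0))

  # forest typing follows conifer share and the biomass threshold
  p2 <- scene_params(extent = 1000, seed = 3, cloud_fraction = 0,
                     loss_fraction = 0)
  l2 <- generate_landscape(p2)
  s2 <- render_stack(l2)
  con <- l2$dcp > 50 & l2$agb >= p2$forest_agb_threshold
  nf <- l2$agb < p2$forest_agb_threshold
  expect_true(all(s2$bands$FTY[con] == FTY_CONIFEROUS))
  expect_true(all(s2$bands$FTY[nf] == FTY_NONFOREST))

  # cloud and loss fractions are approximately honoured
  p3 <- scene_params(extent = 2000, seed = 4, cloud_fraction = 0.2,
                     loss_fraction = 0.1)
  s3 <- render_stack(generate_landscape(p3))
  expect_equal(mean(s3$bands$QUALITY <= 4000), 0.2, tolerance = 0.01)
  expect_equal(mean(s3$gfc > 0), 0.1, tolerance = 0.05)
})

test_that("the saturating band response is recoverable at zero noise", {
  p <- scene_params(extent = 2000, seed = 6, noise_sd = 0,
                    cloud_fraction = 0, loss_fraction = 0)
  l <- generate_landscape(p)
  s <- render_stack(l)
  set.seed(10)
  pick <- sample(length(l$agb), 2000)
  agb <- as.vector(l$agb)[pick]
  v <- as.vector(s$bands$B4)[pick]
  bm <- p$band_model$B4
  fit <- stats::nls(v ~ a * exp(-agb / b) + c,
                    start = list(a = 700, b = 100, c = 150),
                    algorithm = "port",
                    lower = c(a = 1, b = 10, c = 0))
  expect_lt(abs(coef(fit)[["b"]] - bm$b) / bm$b, 0.1)
})

test_that("sampled plots reproduce the footprint-weighted ground truth", {
  p <- scene_params(extent = 1000, seed = 7)
  l <- generate_landscape(p)
  plots <- sample_plots(l, 40, seed = 8)
  expect_identical(sample_plots(l, 40, seed = 8), plots)
  # margins: no footprint leaves the scene
  expect_true(all(plots$easting >= p$origin[1] + FOOTPRINT_RADIUS))
  expect_true(all(plots$northing <= p$origin[2] - FOOTPRINT_RADIUS))
  # responses equal the extraction oracle on the truth grids
  for (i in c(1, 17, 40)) {
    fw <- circle_footprint(plots$easting[i], plots$northing[i],
                           l$transform, dim(l$agb))
    expect_equal(plots$agb[i], weighted_mean_band(l$agb, fw),
                 tolerance = 1e-6)
    expect_equal(plots$vol[i], weighted_mean_band(l$vol, fw),
                 tolerance = 1e-6)
  }
  # constant landscape: plot responses equal the constants
  pc <- scene_params(extent = 500, seed = 1, agb_sd = 0,
                     conifer_sd = 0, agb_mean = 150, conifer_mean = 40)
  lc <- generate_landscape(pc)
  p1 <- sample_plots(lc, 1, seed = 2)
  expect_equal(p1$agb, 150, tolerance = 1e-9)
  expect_equal(p1$vol, 150 * pc$vol_ratio, tolerance = 1e-9)
  expect_equal(p1$dcp, 40, tolerance = 1e-9)
  expect_warning(sample_plots(lc, 5000, seed = 1), "density cap")
})

test_that("screening removes exactly the engineered disturbed plots", {
  # a clear scene, then hand-placed cloud and loss patches under three
  # known plots
  params <- scene_params(extent = 1000, seed = 9, cloud_fraction = 0,
                         loss_fraction = 0)
  sc <- simulate_scene(params, n_plots = 30)
  stack <- sc$stack
  tr <- stack$transform
  # pin the three disturbed plots and keep the rest clear of the patches
  sc$plots$easting[1:3] <- tr$x0 + c(150, 450, 750)
  sc$plots$northing[1:3] <- tr$y0 - c(150, 450, 750)
  for (i in 4:30) {
    too_close <- function(e, n) any(abs(e - sc$plots$easting[1:3]) < 80 &
                                      abs(n - sc$plots$northing[1:3]) < 80)
    while (too_close(sc$plots$easting[i], sc$plots$northing[i])) {
      sc$plots$easting[i] <-
        tr$x0 + 10 + (sc$plots$easting[i] - tr$x0 + 137) %% 980
      sc$plots$northing[i] <-
        tr$y0 - 10 - (tr$y0 - sc$plots$northing[i] + 211) %% 980
    }
  }
  cells <- lapply(1:3, function(i)
    point_cell(tr, sc$plots$easting[i], sc$plots$northing[i]))
  clamp <- function(v, hi) pmin(pmax(v, 1), hi)
  for (i in 1:2) {
    r <- cells[[i]]$row; cc <- cells[[i]]$col
    stack$bands$QUALITY[clamp((r - 2):(r + 2), 100),
                        clamp((cc - 2):(cc + 2), 100)] <- 1000
  }
  g <- point_cell(stack$gfc_transform, sc$plots$easting[3],
                  sc$plots$northing[3])
  stack$gfc[clamp((g$row - 1):(g$row + 1), nrow(stack$gfc)),
            clamp((g$col - 1):(g$col + 1), ncol(stack$gfc))] <- 2020
  sig <- screen_plots(extract_signatures(sc$plots, stack))
  expect_equal(sig$screen_status[1:3],
               c("excluded_cloud", "excluded_cloud", "excluded_change"))
  expect_true(all(sig$screen_status[4:30] == "kept"))
})
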