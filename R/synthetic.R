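# Synthetic forest scenes with a known ground truth.
#
# The generator emulates the inputs of the mapping workflow: a smooth
# above-ground-biomass field (kernel-smoothed Gaussian noise, clipped
# at zero), a conifer-proportion field, volume proportional to biomass,
# and a rendered raster stack in which each spectral band follows a
# saturating exponential response  value = a * exp(-agb / b) + c  plus
# additive Gaussian noise.  The saturation reproduces the optical
# saturation mechanism that causes overestimation of low and
# underestimation of high biomass in the mapped product.  Tree-cover
# density increases with biomass; forest type is conifer where the
# conifer share exceeds 50 %, non-forest where biomass is below a
# threshold; a quality band marks a random fraction of pixels as
# cloud-contaminated; a 30 m loss-year layer marks a random fraction
# of blocks as disturbed.

DEFAULT_BAND_MODEL <- list(
  B2  = list(a =  400, b = 150, c = 250),
  B3  = list(a =  500, b = 150, c = 350),
  B4  = list(a =  900, b = 130, c = 200),
  B5  = list(a =  900, b = 160, c = 500),
  B8  = list(a = -1200, b = 180, c = 3300),
  B11 = list(a = 1500, b = 160, c = 900),
  B12 = list(a = 1200, b = 140, c = 500)
)

#' Synthetic scene parameters
#'
#' Defaults describe an 8 x 8 km temperate-forest landscape: biomass
#' mean 180 t/ha with strong spatial variation (sd 140 t/ha, clipped at
#' zero) so that both near-zero and > 500 t/ha stands occur; volume at
#' 1.7 m3 per t of biomass; conifer share centred at 50 %; spectral
#' bands saturating at 130-180 t/ha with additive noise sd 30 (band
#' units); 5 % cloud cover and 2 % disturbed 30 m blocks.
#'
#' @param extent scene side length (m).
#' @param resolution pixel size (m); the workflow convention is 10 m.
#' @param origin top-left corner `c(easting, northing)` (m).
#' @param agb_mean,agb_sd,agb_corr_len biomass field moments (t/ha) and
#'   spatial correlation length (m).
#' @param conifer_mean,conifer_sd,conifer_corr_len conifer-share field
#'   (percent, clipped to \[0, 100\]).
#' @param vol_ratio m3 of volume per t of biomass.
#' @param band_model per-band list of `a`, `b`, `c` for the saturating
#'   response `a * exp(-agb/b) + c`.
#' @param noise_sd additive band noise standard deviation (band units).
#' @param tcd_scale biomass scale (t/ha) of the tree-cover-density
#'   response `100 * (1 - exp(-agb / tcd_scale))`.
#' @param tcd_noise_sd additive TCD noise sd (percentage points).
#' @param forest_agb_threshold biomass (t/ha) below which a pixel is
#'   non-forest.
#' @param quality_good,quality_cloud composite-quality values for clear
#'   and cloudy pixels (the screening threshold is 4000).
#' @param cloud_fraction fraction of pixels marked cloudy; clouds are
#'   spatially coherent patches, not independent pixels.
#' @param cloud_corr_len correlation length of the cloud field (m).
#' @param loss_fraction fraction of 30 m blocks with canopy loss.
#' @param loss_years calendar years losses are drawn from.
#' @param crs_epsg projected CRS code.
#' @param seed integer seed controlling the whole scene.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(extent = 8000, resolution = 10,
                         origin = c(4000000, 2700000),
                         agb_mean = 180, agb_sd = 140,
                         agb_corr_len = 300,
                         conifer_mean = 50, conifer_sd = 35,
                         conifer_corr_len = 500,
                         vol_ratio = 1.7,
                         band_model = DEFAULT_BAND_MODEL,
                         noise_sd = 30,
                         tcd_scale = 60, tcd_noise_sd = 5,
                         forest_agb_threshold = 2,
                         quality_good = 10000, quality_cloud = 2000,
                         cloud_fraction = 0.05,
                         cloud_corr_len = 200,
                         loss_fraction = 0.02,
                         loss_years = 2001:2021,
                         crs_epsg = 3035,
                         seed = 1L) {
  if (extent <= 0) stop("extent must be positive")
  stopifnot(agb_sd >= 0, conifer_sd >= 0, noise_sd >= 0,
            cloud_fraction >= 0, cloud_fraction <= 1,
            loss_fraction >= 0, loss_fraction <= 1)
  structure(as.list(environment()), class = "scene_params")
}

# stationary Gaussian random field on an n x n grid via FFT circular
# convolution of white noise with a Gaussian kernel; standardized to
# exactly zero mean and unit sd before scaling
gaussian_field <- function(nr, nc, corr_len_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len_px > 0) {
    kr <- stats::dnorm(pmin(0:(nr - 1), nr - (0:(nr - 1))), sd = corr_len_px)
    kc <- stats::dnorm(pmin(0:(nc - 1), nc - (0:(nc - 1))), sd = corr_len_px)
    kern <- outer(kr, kc)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
      (nr * nc)
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate the ground-truth landscape
#'
#' @param params a [scene_params()].
#' @return List of class `landscape`: matrices `agb` (t/ha), `vol`
#'   (m3/ha), `dcp` (%), with the scene `transform` and `crs_epsg`.
#' @export
generate_landscape <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  n <- as.integer(round(params$extent / params$resolution))
  cl_agb <- params$agb_corr_len / params$resolution
  cl_con <- params$conifer_corr_len / params$resolution
  agb <- params$agb_mean +
    if (params$agb_sd > 0) params$agb_sd * gaussian_field(n, n, cl_agb)
    else 0
  agb <- pmax(agb, 0)
  dcp <- params$conifer_mean +
    if (params$conifer_sd > 0)
      params$conifer_sd * gaussian_field(n, n, cl_con)
    else 0
  dcp <- pmin(pmax(dcp, 0), 100)
  if (!is.matrix(agb)) agb <- matrix(agb, n, n)
  if (!is.matrix(dcp)) dcp <- matrix(dcp, n, n)
  vol <- params$vol_ratio * agb
  tr <- geotransform(params$origin[1], params$origin[2],
                     params$resolution)
  structure(list(agb = agb, vol = vol, dcp = dcp, transform = tr,
                 crs_epsg = params$crs_epsg, params = params),
            class = "landscape")
}

#' Render the raster stack of a landscape
#'
#' @param landscape a [generate_landscape()] result.
#' @param params a [scene_params()]; defaults to the landscape's own.
#' @return A [raster_stack()] consistent with the ground truth.
#' @export
render_stack <- function(landscape, params = landscape$params) {
  set.seed(params$seed + 1L)
  agb <- landscape$agb
  n <- nrow(agb)
  bands <- list()
  for (nm in names(params$band_model)) {
    bm <- params$band_model[[nm]]
    v <- bm$a * exp(-agb / bm$b) + bm$c
    if (params$noise_sd > 0)
      v <- v + matrix(stats::rnorm(length(agb), sd = params$noise_sd),
                      n, n)
    bands[[nm]] <- v
  }
  tcd <- 100 * (1 - exp(-agb / params$tcd_scale))
  if (params$tcd_noise_sd > 0)
    tcd <- tcd + matrix(stats::rnorm(length(agb),
                                     sd = params$tcd_noise_sd), n, n)
  bands$TCD <- pmin(pmax(tcd, 0), 100)
  fty <- matrix(FTY_BROADLEAVED, n, n)
  fty[landscape$dcp > 50] <- FTY_CONIFEROUS
  fty[agb < params$forest_agb_threshold] <- FTY_NONFOREST
  bands$FTY <- fty
  quality <- matrix(params$quality_good, n, n)
  if (params$cloud_fraction > 0) {
    cf <- gaussian_field(n, n, params$cloud_corr_len / params$resolution)
    cloudy <- cf > stats::quantile(cf, 1 - params$cloud_fraction)
    quality[cloudy] <- params$quality_cloud
  }
  bands$QUALITY <- quality
  n30 <- as.integer(ceiling(params$extent / 30))
  gfc <- matrix(0, n30, n30)
  if (params$loss_fraction > 0) {
    hit <- stats::runif(n30 * n30) < params$loss_fraction
    gfc[hit] <- sample(params$loss_years, sum(hit), replace = TRUE)
  }
  gfc_tr <- geotransform(params$origin[1], params$origin[2], 30)
  raster_stack(bands, landscape$transform, gfc = gfc,
               gfc_transform = gfc_tr, crs_epsg = params$crs_epsg)
}

#' Sample field plots from the ground truth
#'
#' Plot centres are uniform over the scene, kept at least one footprint
#' radius inside the extent; responses are the area-weighted ground
#' truth over the 100 m2 circular footprint (the same geometry used for
#' signature extraction).
#'
#' @param landscape a [generate_landscape()] result.
#' @param n number of plots.
#' @param seed sampling seed (independent of the scene seed).
#' @param year,country recorded measurement year and country code.
#' @return A plot-record `data.frame` (see [read_plot_table()]).
#' @export
sample_plots <- function(landscape, n, seed, year = 2020,
                         country = "XX") {
  stopifnot(n >= 1)
  params <- landscape$params
  dens_cap <- 0.5 * (params$extent / 100)^2   # one plot per 2 ha
  if (n > dens_cap)
    warning(sprintf("n = %d exceeds the plot density cap (%d) for this extent",
                    n, as.integer(dens_cap)), call. = FALSE)
  set.seed(seed)
  m <- FOOTPRINT_RADIUS
  tr <- landscape$transform
  ext <- params$extent
  e <- tr$x0 + m + stats::runif(n) * (ext - 2 * m)
  no <- tr$y0 - m - stats::runif(n) * (ext - 2 * m)
  d <- dim(landscape$agb)
  vol <- agb <- dcp <- numeric(n)
  for (i in seq_len(n)) {
    fw <- circle_footprint(e[i], no[i], tr, d)
    vol[i] <- weighted_mean_band(landscape$vol, fw)
    agb[i] <- weighted_mean_band(landscape$agb, fw)
    dcp[i] <- weighted_mean_band(landscape$dcp, fw)
  }
  data.frame(plot_id = sprintf("P%05d", seq_len(n)),
             easting = e, northing = no, year = as.integer(year),
             country = country, vol = vol, agb = agb,
             dcp = pmin(pmax(dcp, 0), 100))
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper: ground truth, rendered stack and sampled plot
#' table in one call.
#'
#' @param params a [scene_params()].
#' @param n_plots number of field plots.
#' @param plot_seed seed for plot sampling (default derived from the
#'   scene seed).
#' @return List with `landscape`, `stack`, `plots` and `params`.
#' @export
simulate_scene <- function(params = scene_params(), n_plots = 1000,
                           plot_seed = params$seed + 2L) {
  landscape <- generate_landscape(params)
  stack <- render_stack(landscape, params)
  plots <- sample_plots(landscape, n_plots, seed = plot_seed)
  list(landscape = landscape, stack = stack, plots = plots,
       params = params)
}
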