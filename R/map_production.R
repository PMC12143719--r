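# Wall-to-wall map production: per-pixel feature assembly, windowed
# kNN prediction over a raster stack, forest masking, and emission of
# the six encoded output layers as GeoTIFF tiles.

#' Assemble per-pixel feature rows from a raster stack
#'
#' Builds one raw feature row per pixel in the model's column layout:
#' spectral bands, TCD, the forest-type indicator and, per the area's
#' `location_mode`, the pixel-centre coordinates snapped to the 1 km
#' grid.  Pixels with any nodata input or composite quality not above
#' the threshold are marked invalid.
#'
#' @param stack a [raster_stack()].
#' @param area an [area_config()].
#' @param quality_threshold quality screening threshold (default 4000,
#'   strict, as at training time).
#' @param rows optional row window (integer vector of raster rows).
#' @return List with `X` (one row per pixel of the window, pixel order
#'   column-major as in R matrices), `valid` and `forest` logical
#'   vectors in the same order.
#' @export
pixel_features <- function(stack, area, quality_threshold = 4000,
                           rows = NULL) {
  d <- stack_dim(stack)
  rows <- rows %||% seq_len(d[1])
  nc <- d[2]
  sub <- function(b) b[rows, , drop = FALSE]
  cont <- lapply(stack$bands[c(SPECTRAL_BANDS, "TCD")], sub)
  fty <- sub(stack$bands$FTY)
  quality <- sub(stack$bands$QUALITY)
  X <- cbind(do.call(cbind, lapply(cont, as.vector)),
             as.vector(as.numeric(fty == FTY_CONIFEROUS)))
  colnames(X) <- c(SPECTRAL_BANDS, "TCD", "FTY")
  if (area$location_mode != "none") {
    tr <- stack$transform
    cells <- expand.grid(row = rows, col = seq_len(nc))
    ctr <- pixel_center(tr, cells$row, cells$col)
    g <- snap_to_1km_grid(ctr$x, ctr$y)
    if (area$location_mode == "both_axes")
      X <- cbind(X, easting_1km = g$easting, northing_1km = g$northing)
    else
      X <- cbind(X, northing_1km = g$northing)
  }
  valid <- !apply(X, 1, anyNA) & !is.na(as.vector(quality)) &
    as.vector(quality) > quality_threshold & !is.na(as.vector(fty))
  forest <- !is.na(as.vector(fty)) & as.vector(fty) != FTY_NONFOREST
  list(X = X, valid = valid, forest = forest)
}

#' Predict a full tile of forest attributes
#'
#' Applies a fitted kNN model to every valid forest pixel of a stack,
#' producing the six output grids (three attributes and their
#' neighbour-standard-deviation uncertainty layers) plus the validity
#' and forest masks.  Non-forest pixels are never predicted: they can
#' only ever be the non-forest sentinel in the encoded product.
#' Processing is windowed over blocks of rows; the window size does not
#' affect the result.
#'
#' @param model a [fit_knn()] model.
#' @param stack a [raster_stack()].
#' @param area an [area_config()] matching the model's feature layout.
#' @param quality_threshold quality screening threshold.
#' @param window_rows rows per processing window (default 256).
#' @return An object of class `prediction_tile`: list of matrices
#'   `Vol`, `stdev_vol`, `AGB`, `stdev_agb`, `P_agb_conifers`,
#'   `stdev_P_agb_conifers` (NA outside valid forest), plus `valid`,
#'   `forest`, `transform`, `crs_epsg`.
#' @export
predict_tile <- function(model, stack, area, quality_threshold = 4000,
                         window_rows = 256L) {
  if (!identical(feature_names_for(area$location_mode),
                 model$feature_names))
    stop("area location_mode does not match the model's feature layout")
  d <- stack_dim(stack)
  grids <- lapply(seq_len(6), function(i)
    matrix(NA_real_, d[1], d[2]))
  names(grids) <- MAP_VARIABLES
  valid <- matrix(FALSE, d[1], d[2])
  forest <- matrix(FALSE, d[1], d[2])
  starts <- seq(1L, d[1], by = window_rows)
  for (s in starts) {
    rows <- s:min(s + window_rows - 1L, d[1])
    pf <- pixel_features(stack, area, quality_threshold, rows = rows)
    valid[rows, ] <- pf$valid
    forest[rows, ] <- pf$forest
    sel <- pf$valid & pf$forest
    if (!any(sel)) next
    pred <- predict(model, pf$X[sel, , drop = FALSE])
    grids$Vol[rows, ][sel] <- pred$vol
    grids$stdev_vol[rows, ][sel] <- pred$stdev_vol
    grids$AGB[rows, ][sel] <- pred$agb
    grids$stdev_agb[rows, ][sel] <- pred$stdev_agb
    grids$P_agb_conifers[rows, ][sel] <- pred$dcp
    grids$stdev_P_agb_conifers[rows, ][sel] <- pred$stdev_dcp
  }
  structure(c(grids, list(valid = valid, forest = forest,
                          transform = stack$transform,
                          crs_epsg = stack$crs_epsg)),
            class = "prediction_tile")
}

#' Produce encoded map tiles from a prediction
#'
#' Encodes each of the six output grids to uint16 (no-data 65535,
#' non-forest 65534) and writes one GeoTIFF per variable, named
#' `{year}_{variable}_{tile}.tif` after the tile containing the stack's
#' lower-left corner.  A run manifest (inputs, configuration hash,
#' per-variable cell accounting) is written alongside.
#'
#' @param tile a [predict_tile()] result.
#' @param year map reference year.
#' @param out_dir output directory.
#' @param variables subset of variables to write (default all six).
#' @param manifest_extra named list merged into the run manifest.
#' @return Character vector of written file paths (the manifest path as
#'   the `"manifest"` attribute).
#' @export
produce_maps <- function(tile, year, out_dir,
                         variables = MAP_VARIABLES,
                         manifest_extra = list()) {
  stopifnot(inherits(tile, "prediction_tile"))
  bad <- setdiff(variables, MAP_VARIABLES)
  if (length(bad)) stop("unknown map variable(s): ",
                        paste(bad, collapse = ", "))
  d <- dim(tile$valid)
  tr <- tile$transform
  ll <- c(easting = tr$x0, northing = tr$y0 - d[1] * tr$py)
  tile_lab <- tile_id_for(ll["easting"], ll["northing"])
  paths <- character(0)
  accounting <- list()
  for (v in variables) {
    enc <- encode_uint16(tile[[v]], tile$forest, tile$valid)
    spec <- map_tile_spec(year, v, tile_lab)
    p <- write_map_tile(spec, enc, out_dir, transform = tr,
                        crs_epsg = tile$crs_epsg)
    paths <- c(paths, p)
    accounting[[v]] <- list(value = sum(enc <= MAX_VALUE_U16),
                            nonforest = sum(enc == NONFOREST_U16),
                            nodata = sum(enc == NODATA_U16))
  }
  manifest <- c(list(year = year, tile = tile_lab,
                     dimensions = as.integer(d),
                     crs_epsg = tile$crs_epsg,
                     variables = variables,
                     cells = accounting),
                manifest_extra)
  mpath <- file.path(out_dir, sprintf("%d_manifest_%s.yaml", year,
                                      tile_lab))
  yaml::write_yaml(manifest, mpath)
  attr(paths, "manifest") <- mpath
  paths
}
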