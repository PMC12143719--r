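# In-memory raster stack: the 10 m covariate layers used for signature
# extraction and map production, plus the 30 m canopy-loss-year layer
# carried on its own grid.

#' Forest-type category codes
#'
#' The categorical forest-type layer uses integer codes: 0 = non-forest,
#' 1 = coniferous forest, 2 = broadleaved forest.
#' @export
FTY_NONFOREST <- 0L
#' @rdname FTY_NONFOREST
#' @export
FTY_CONIFEROUS <- 1L
#' @rdname FTY_NONFOREST
#' @export
FTY_BROADLEAVED <- 2L

STACK_BANDS_10M <- c("B2", "B3", "B4", "B5", "B8", "B11", "B12",
                     "TCD", "FTY", "QUALITY")
SPECTRAL_BANDS <- c("B2", "B3", "B4", "B5", "B8", "B11", "B12")

#' Raster stack constructor
#'
#' Bundles the co-registered 10 m covariate layers (seven spectral
#' bands, tree-cover density `TCD` in percent, forest type `FTY`,
#' composite quality `QUALITY`) with the 30 m canopy-loss-year layer
#' `GFC` (0 = no loss, otherwise the calendar year of loss).
#'
#' @param bands named list of matrices, one per 10 m layer; all must
#'   share dimensions.  Required names: B2, B3, B4, B5, B8, B11, B12,
#'   TCD, FTY, QUALITY.
#' @param transform [geotransform()] of the 10 m grid.
#' @param gfc matrix of canopy-loss years on the 30 m grid, or `NULL`.
#' @param gfc_transform [geotransform()] of the 30 m grid.
#' @param crs_epsg EPSG code of the shared projected CRS.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(bands, transform, gfc = NULL, gfc_transform = NULL,
                         crs_epsg = 3035) {
  stopifnot(is.list(bands), inherits(transform, "geotransform"))
  missing <- setdiff(STACK_BANDS_10M, names(bands))
  if (length(missing))
    stop("missing bands: ", paste(missing, collapse = ", "))
  dims <- lapply(bands[STACK_BANDS_10M], dim)
  if (length(unique(dims)) != 1L)
    stop("all 10 m bands must share dimensions")
  fty <- bands$FTY
  bad <- !(fty %in% c(FTY_NONFOREST, FTY_CONIFEROUS, FTY_BROADLEAVED) |
             is.na(fty))
  if (any(bad)) stop("FTY contains codes outside {0, 1, 2}")
  tcd <- bands$TCD
  if (any(tcd < 0 | tcd > 100, na.rm = TRUE))
    stop("TCD must lie in [0, 100]")
  if (!is.null(gfc) && is.null(gfc_transform))
    stop("a GFC layer needs its own geotransform")
  structure(list(bands = bands[STACK_BANDS_10M], transform = transform,
                 gfc = gfc, gfc_transform = gfc_transform,
                 crs_epsg = crs_epsg),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<raster_stack> %d x %d pixels at %g m, EPSG:%s\n",
              d[1], d[2], x$transform$px, x$crs_epsg))
  cat("  bands:", paste(names(x$bands), collapse = ", "), "\n")
  if (!is.null(x$gfc))
    cat(sprintf("  GFC: %d x %d at %g m\n", nrow(x$gfc), ncol(x$gfc),
                x$gfc_transform$px))
  invisible(x)
}

stack_dim <- function(stack) dim(stack$bands[[1]])

#' Write a raster stack as per-band GeoTIFF files
#'
#' Each layer is written to `<dir>/<NAME>.tif` (float64); the 30 m
#' loss-year layer keeps its own georeferencing.
#'
#' @param stack a [raster_stack()].
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$bands))
    write_geotiff(file.path(dir, paste0(nm, ".tif")), stack$bands[[nm]],
                  stack$transform, crs_epsg = stack$crs_epsg,
                  nodata = -9999, datatype = "float64")
  if (!is.null(stack$gfc))
    write_geotiff(file.path(dir, "GFC.tif"), stack$gfc,
                  stack$gfc_transform, crs_epsg = stack$crs_epsg,
                  nodata = -9999, datatype = "float64")
  invisible(dir)
}

#' Read a raster stack from per-band GeoTIFF files
#'
#' @param dir directory holding `<NAME>.tif` files as written by
#'   [write_stack()].
#' @return A [raster_stack()].
#' @export
read_stack <- function(dir) {
  bands <- list()
  tr <- NULL; crs <- NULL
  for (nm in STACK_BANDS_10M) {
    f <- file.path(dir, paste0(nm, ".tif"))
    if (!file.exists(f)) stop("missing band file: ", f)
    g <- read_geotiff(f, na_nodata = TRUE)
    bands[[nm]] <- g$values
    tr <- tr %||% g$transform
    crs <- crs %||% g$crs_epsg
  }
  gfc <- NULL; gfc_tr <- NULL
  f <- file.path(dir, "GFC.tif")
  if (file.exists(f)) {
    g <- read_geotiff(f, na_nodata = TRUE)
    gfc <- g$values; gfc_tr <- g$transform
  }
  raster_stack(bands, tr, gfc = gfc, gfc_transform = gfc_tr,
               crs_epsg = crs)
}
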