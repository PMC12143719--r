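# 500 km output tiling, uint16 sentinel encoding and map-tile files.
#
# Output maps are delivered as 500 x 500 km tiles in an equal-area
# projection (default ETRS89-LAEA, EPSG:3035).  Tile labels name the
# lower-left corner in units of 100 km, e.g. the tile with lower-left
# corner E 3 900 000 m / N 2 400 000 m is "E39_N24".  Corners are
# multiples of 100 km; the 500 km partition is anchored so that this
# published corner is itself a tile corner (tile corners are congruent
# to 400 000 m modulo 500 000 m on both axes).

TILE_SIZE <- 500000
TILE_ANCHOR <- 400000

MAP_VARIABLES <- c("Vol", "stdev_vol", "AGB", "stdev_agb",
                   "P_agb_conifers", "stdev_P_agb_conifers")

NODATA_U16 <- 65535
NONFOREST_U16 <- 65534
MAX_VALUE_U16 <- 65533

#' Tile label containing a coordinate
#'
#' Maps a projected coordinate to the label of the 500 km tile that
#' contains it.  Tiles are half-open squares \[corner, corner + 500 km)
#' on both axes, so a tile's lower-left corner belongs to the tile it
#' names.
#'
#' @param easting,northing coordinates (m) in the map CRS.
#' @param anchor grid anchor offset (m modulo 500 km); default places a
#'   tile corner at E 3 900 000 / N 2 400 000.
#' @return Character vector of labels such as `"E39_N24"`.
#' @export
tile_id_for <- function(easting, northing, anchor = TILE_ANCHOR) {
  corner <- function(v)
    floor((v - anchor) / TILE_SIZE) * TILE_SIZE + anchor
  ee <- corner(easting) / 100000
  nn <- corner(northing) / 100000
  sprintf("E%d_N%d", as.integer(ee), as.integer(nn))
}

#' Lower-left corner of a tile label
#'
#' @param tile label such as `"E39_N24"`.
#' @return Named numeric vector `c(easting, northing)` in metres.
#' @export
tile_corner <- function(tile) {
  m <- regmatches(tile, regexec("^E(-?[0-9]+)_N(-?[0-9]+)$", tile))[[1]]
  if (length(m) != 3L) stop("malformed tile label: ", tile)
  c(easting = as.numeric(m[2]) * 100000,
    northing = as.numeric(m[3]) * 100000)
}

#' Map tile specification
#'
#' @param year map reference year.
#' @param variable one of `Vol`, `stdev_vol`, `AGB`, `stdev_agb`,
#'   `P_agb_conifers`, `stdev_P_agb_conifers`.
#' @param tile tile label (see [tile_id_for()]).
#' @return An object of class `map_tile_spec`.
#' @export
map_tile_spec <- function(year, variable, tile) {
  if (!variable %in% MAP_VARIABLES)
    stop("unknown map variable: ", variable, "; expected one of ",
         paste(MAP_VARIABLES, collapse = ", "))
  tile_corner(tile)  # validates the label
  structure(list(year = as.integer(year), variable = variable,
                 tile = tile), class = "map_tile_spec")
}

#' Output file name for a map tile
#'
#' File names follow the pattern `{year}_{variable}_{tile}.tif`.
#'
#' @param spec a [map_tile_spec()].
#' @return File name string.
#' @export
output_filename <- function(spec) {
  stopifnot(inherits(spec, "map_tile_spec"))
  sprintf("%d_%s_%s.tif", spec$year, spec$variable, spec$tile)
}

#' Parse a map tile file name
#'
#' Inverse of [output_filename()].
#'
#' @param filename file name such as `"2020_stdev_vol_E39_N24.tif"`.
#' @return A [map_tile_spec()].
#' @export
parse_output_filename <- function(filename) {
  base <- sub("\\.tif$", "", basename(filename))
  m <- regmatches(base,
                  regexec("^([0-9]{4})_(.+)_(E-?[0-9]+_N-?[0-9]+)$", base))[[1]]
  if (length(m) != 4L) stop("malformed map file name: ", filename)
  map_tile_spec(as.integer(m[2]), m[3], m[4])
}

#' Encode a physical-unit grid as uint16 with sentinel values
#'
#' Invalid cells become 65535 (no-data), valid non-forest cells 65534,
#' and remaining cells are rounded half away from zero and clamped to
#' \[0, 65533\].
#'
#' @param values numeric matrix in physical units (m3/ha, t/ha or %).
#' @param forest_mask logical matrix, `TRUE` where forest.
#' @param valid_mask logical matrix, `TRUE` where the prediction inputs
#'   were valid.
#' @return Integer matrix of uint16 codes.
#' @export
encode_uint16 <- function(values, forest_mask, valid_mask) {
  stopifnot(identical(dim(values), dim(forest_mask)),
            identical(dim(values), dim(valid_mask)))
  fill <- valid_mask & forest_mask
  v <- values[fill]
  if (any(v < 0, na.rm = TRUE))
    stop("negative physical value passed to encode_uint16(); ",
         "predictions are convex combinations of non-negative responses")
  if (anyNA(v))
    stop("NA value on a valid forest cell passed to encode_uint16()")
  out <- matrix(NODATA_U16, nrow(values), ncol(values))
  out[valid_mask & !forest_mask] <- NONFOREST_U16
  out[fill] <- pmin(floor(v + 0.5), MAX_VALUE_U16)
  storage.mode(out) <- "integer"
  out
}

#' Decode a uint16 grid back to physical units
#'
#' @param encoded integer matrix as produced by [encode_uint16()].
#' @return List with `values` (numeric matrix, `NA` at both sentinels),
#'   `forest_mask` and `valid_mask`.
#' @export
decode_uint16 <- function(encoded) {
  valid <- encoded != NODATA_U16
  forest <- valid & encoded != NONFOREST_U16
  values <- matrix(NA_real_, nrow(encoded), ncol(encoded))
  values[forest] <- as.numeric(encoded[forest])
  list(values = values, forest_mask = forest, valid_mask = valid)
}

#' Write an encoded map tile as GeoTIFF
#'
#' Writes a single-band uint16 GeoTIFF with nodata tag 65535, named per
#' [output_filename()] and georeferenced at the tile's corner (or at a
#' supplied reduced-extent transform for testing).
#'
#' @param spec a [map_tile_spec()].
#' @param encoded integer matrix from [encode_uint16()].
#' @param out_dir output directory.
#' @param transform optional [geotransform()]; by default the grid is
#'   assumed to start at the tile's upper-left corner with 10 m pixels.
#' @param crs_epsg EPSG code; required.
#' @return The written file path, invisibly.
#' @export
write_map_tile <- function(spec, encoded, out_dir, transform = NULL,
                           crs_epsg = 3035) {
  stopifnot(inherits(spec, "map_tile_spec"))
  if (is.null(crs_epsg) || !is.finite(crs_epsg))
    stop("an output CRS must be configured to write map tiles")
  if (is.null(transform)) {
    corner <- tile_corner(spec$tile)
    transform <- geotransform(corner["easting"],
                              corner["northing"] + TILE_SIZE, 10)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, output_filename(spec))
  write_geotiff(path, encoded, transform, crs_epsg = crs_epsg,
                nodata = NODATA_U16, datatype = "uint16")
  invisible(path)
}

#' Read a map tile written by [write_map_tile()]
#'
#' @param path file path.
#' @return List with the [map_tile_spec()], the decoded grids of
#'   [decode_uint16()], the raw `encoded` matrix and the `transform`.
#' @export
read_map_tile <- function(path) {
  g <- read_geotiff(path)
  spec <- parse_output_filename(path)
  c(list(spec = spec, encoded = g$values, transform = g$transform,
         crs_epsg = g$crs_epsg), decode_uint16(g$values))
}
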