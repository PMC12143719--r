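# Minimal single-band GeoTIFF codec (little-endian, uncompressed, one
# sample per pixel).  Supports uint16 and float64 payloads plus the
# georeferencing tags needed here: ModelPixelScale, ModelTiepoint, a
# GeoKey directory carrying the projected CRS EPSG code, and the GDAL
# nodata tag.  Written because the map tiles must be self-describing
# GeoTIFF files; it is not a general TIFF implementation.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)

#' Geotransform constructor
#'
#' A geotransform anchors a north-up raster grid in a projected CRS:
#' `x0`, `y0` are the coordinates of the grid's top-left (north-west)
#' corner and `px`, `py` the pixel width and height in metres (both
#' positive; rows run southwards).
#'
#' @param x0,y0 top-left corner easting / northing (m).
#' @param px,py pixel width and height (m), both positive.
#' @return An object of class `geotransform`.
#' @export
geotransform <- function(x0, y0, px = 10, py = px) {
  stopifnot(is.finite(x0), is.finite(y0), px > 0, py > 0)
  structure(list(x0 = x0, y0 = y0, px = px, py = py),
            class = "geotransform")
}

# pixel-center coordinates of (row, col); row 1 is the northernmost row
pixel_center <- function(tr, row, col) {
  list(x = tr$x0 + (col - 0.5) * tr$px,
       y = tr$y0 - (row - 0.5) * tr$py)
}

# inverse of pixel_center: the cell containing a point under the
# half-open convention [edge, edge + pixel) on both axes
point_cell <- function(tr, x, y) {
  list(row = floor((tr$y0 - y) / tr$py) + 1,
       col = floor((x - tr$x0) / tr$px) + 1)
}

u16_to_signed <- function(v) {
  v <- as.integer(round(v))
  v[v > 32767L] <- v[v > 32767L] - 65536L
  v
}

#' Write a single-band GeoTIFF
#'
#' @param path output file path.
#' @param values numeric matrix, row 1 = northernmost row.
#' @param transform a [geotransform()].
#' @param crs_epsg EPSG code of the projected CRS (stored in the GeoKey
#'   directory; default 3035, ETRS89-extended / LAEA Europe).
#' @param nodata optional nodata value recorded in the GDAL nodata tag;
#'   `NA` cells are written as this value.
#' @param datatype `"uint16"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(path, values, transform, crs_epsg = 3035,
                          nodata = NULL, datatype = c("float64", "uint16")) {
  datatype <- match.arg(datatype)
  stopifnot(is.matrix(values), inherits(transform, "geotransform"))
  if (is.null(crs_epsg) || !is.finite(crs_epsg))
    stop("a projected CRS (EPSG code) is required to write a GeoTIFF")
  h <- nrow(values); w <- ncol(values)
  v <- as.vector(t(values))            # row-major
  if (!is.null(nodata)) v[is.na(v)] <- nodata
  if (anyNA(v)) stop("NA cells present but no nodata value given")
  if (datatype == "uint16") {
    if (any(v < 0 | v > 65535)) stop("uint16 values must lie in [0, 65535]")
    bits <- 16L; fmt <- 1L; bpp <- 2L
  } else {
    bits <- 64L; fmt <- 3L; bpp <- 8L
  }

  entries <- list()
  add <- function(tag, type, count, value, offset_block = NULL) {
    entries[[length(entries) + 1L]] <<- list(tag = tag, type = type,
                                             count = count, value = value,
                                             block = offset_block)
  }
  ps_block <- writeBin(c(transform$px, transform$py, 0),
                       raw(), size = 8, endian = "little")
  tp_block <- writeBin(c(0, 0, 0, transform$x0, transform$y0, 0),
                       raw(), size = 8, endian = "little")
  geokeys <- c(1L, 1L, 0L, 3L,            # version, rev, minor, n keys
               1024L, 0L, 1L, 1L,          # GTModelType = projected
               1025L, 0L, 1L, 1L,          # GTRasterType = PixelIsArea
               3072L, 0L, 1L, as.integer(crs_epsg))
  gk_block <- writeBin(u16_to_signed(geokeys), raw(), size = 2,
                       endian = "little")
  nd_block <- NULL
  if (!is.null(nodata)) {
    nd_str <- format(nodata, scientific = FALSE, trim = TRUE)
    nd_block <- c(charToRaw(nd_str), as.raw(0L))
  }

  add(256L, 4L, 1L, w)                      # ImageWidth
  add(257L, 4L, 1L, h)                      # ImageLength
  add(258L, 3L, 1L, bits)                   # BitsPerSample
  add(259L, 3L, 1L, 1L)                     # Compression = none
  add(262L, 3L, 1L, 1L)                     # Photometric = BlackIsZero
  add(273L, 4L, 1L, NA)                     # StripOffsets (patched)
  add(277L, 3L, 1L, 1L)                     # SamplesPerPixel
  add(278L, 4L, 1L, h)                      # RowsPerStrip
  add(279L, 4L, 1L, h * w * bpp)            # StripByteCounts
  add(284L, 3L, 1L, 1L)                     # PlanarConfiguration
  add(339L, 3L, 1L, fmt)                    # SampleFormat
  add(33550L, 12L, 3L, NA, ps_block)        # ModelPixelScale
  add(33922L, 12L, 6L, NA, tp_block)        # ModelTiepoint
  add(34735L, 3L, length(geokeys), NA, gk_block)  # GeoKeyDirectory
  if (!is.null(nd_block))
    add(42113L, 2L, length(nd_block), NA, nd_block)  # GDAL_NODATA

  n_entries <- length(entries)
  ifd_offset <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  aux_offset <- ifd_offset + ifd_size
  # lay out auxiliary blocks
  cur <- aux_offset
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (!is.null(e$block)) {
      entries[[i]]$value <- cur
      cur <- cur + length(e$block)
    }
  }
  if (cur %% 2L == 1L) cur <- cur + 1L
  data_offset <- cur
  entries[[6L]]$value <- data_offset      # StripOffsets

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(n_entries, con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(u16_to_signed(e$tag), con, size = 2, endian = "little")
    writeBin(e$type, con, size = 2, endian = "little")
    writeBin(as.integer(e$count), con, size = 4, endian = "little")
    size <- TIFF_TYPE_SIZES[[as.character(e$type)]] * e$count
    if (is.null(e$block) && size <= 4L) {
      # inline, left-justified little-endian
      val_raw <- if (e$type == 3L)
        writeBin(u16_to_signed(e$value), raw(), size = 2, endian = "little")
      else
        writeBin(as.integer(e$value), raw(), size = 4, endian = "little")
      writeBin(c(val_raw, raw(4L - length(val_raw))), con)
    } else {
      writeBin(as.integer(e$value), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")   # next IFD
  for (e in entries) if (!is.null(e$block)) writeBin(e$block, con)
  aux_end <- aux_offset +
    sum(vapply(entries, function(e) length(e$block %||% raw()), 1L))
  if (data_offset > aux_end) writeBin(raw(data_offset - aux_end), con)
  if (datatype == "uint16") {
    writeBin(u16_to_signed(v), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(v), con, size = 8, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a single-band GeoTIFF written by [write_geotiff()]
#'
#' @param path file path.
#' @param na_nodata replace cells equal to the nodata tag with `NA`
#'   (default `FALSE`; map tiles keep their sentinel codes).
#' @return A list with `values` (matrix), `transform`, `crs_epsg`,
#'   `nodata` and `datatype`.
#' @export
read_geotiff <- function(path, na_nodata = FALSE) {
  rawv <- readBin(path, "raw", file.info(path)$size)
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(rawv[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = "little")
  if (rawToChar(rawv[1:2]) != "II")
    stop("only little-endian TIFF is supported")
  ifd <- rd(4L, "integer", 1L, 4L)
  n_entries <- rd(ifd, "integer", 1L, 2L, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- rd(off, "integer", 1L, 2L, signed = FALSE)
    type <- rd(off + 2L, "integer", 1L, 2L, signed = FALSE)
    count <- rd(off + 4L, "integer", 1L, 4L)
    size <- TIFF_TYPE_SIZES[[as.character(type)]] * count
    voff <- if (size <= 4L) off + 8L else rd(off + 8L, "integer", 1L, 4L)
    value <- switch(as.character(type),
      `1` = rd(voff, "integer", count, 1L, signed = FALSE),
      `2` = rawToChar(rawv[(voff + 1):(voff + count - 1L)]),
      `3` = rd(voff, "integer", count, 2L, signed = FALSE),
      `4` = rd(voff, "integer", count, 4L),
      `12` = rd(voff, "double", count, 8L),
      stop("unsupported TIFF field type: ", type))
    tags[[as.character(tag)]] <- value
  }
  need <- function(tag) tags[[as.character(tag)]] %||%
    stop("missing required TIFF tag ", tag)
  w <- need(256L); h <- need(257L); bits <- need(258L)
  if ((tags[["259"]] %||% 1L) != 1L) stop("compressed TIFF not supported")
  fmt <- tags[["339"]] %||% 1L
  strip_off <- need(273L)
  rows_per_strip <- tags[["278"]] %||% h
  bpp <- bits / 8L
  if (bits == 16L && fmt == 1L) {
    datatype <- "uint16"
    read_strip <- function(off, npix) rd(off, "integer", npix, 2L,
                                         signed = FALSE)
  } else if (bits == 64L && fmt == 3L) {
    datatype <- "float64"
    read_strip <- function(off, npix) rd(off, "double", npix, 8L)
  } else stop("unsupported sample layout: ", bits, "-bit format ", fmt)
  v <- numeric(0)
  row0 <- 0L
  for (s in seq_along(strip_off)) {
    nr <- min(rows_per_strip, h - row0)
    v <- c(v, read_strip(strip_off[s], nr * w))
    row0 <- row0 + nr
  }
  values <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
  if (datatype == "uint16") storage.mode(values) <- "integer"
  ps <- tags[["33550"]]; tp <- tags[["33922"]]
  if (is.null(ps) || is.null(tp))
    stop("file lacks georeferencing tags; not a GeoTIFF?")
  tr <- geotransform(tp[4], tp[5], ps[1], ps[2])
  crs_epsg <- NA_integer_
  gk <- tags[["34735"]]
  if (!is.null(gk) && length(gk) >= 4L) {
    nk <- gk[4]
    for (j in seq_len(nk)) {
      key <- gk[4L * j + 1L]
      if (key == 3072L) crs_epsg <- gk[4L * j + 4L]
    }
  }
  nodata <- if (!is.null(tags[["42113"]]))
    as.numeric(tags[["42113"]]) else NULL
  if (na_nodata && !is.null(nodata)) values[values == nodata] <- NA
  list(values = values, transform = tr, crs_epsg = crs_epsg,
       nodata = nodata, datatype = datatype)
}
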