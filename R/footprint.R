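# Plot signature extraction: area-weighted raster statistics over a
# 100 m2 circular footprint centred on each field plot, and the two
# screening rules (composite quality, post-measurement canopy loss).

#' Radius of the 100 m2 plot footprint (m)
#' @export
FOOTPRINT_RADIUS <- sqrt(100 / pi)

# Sutherland-Hodgman clip of a polygon against one axis-aligned
# half-plane.  `coord` selects the axis (1 = x, 2 = y); keep side is
# coord >= bound (dir = 1) or coord <= bound (dir = -1).
clip_halfplane <- function(x, y, axis, bound, dir) {
  n <- length(x)
  if (n == 0L) return(list(x = x, y = y))
  p <- if (axis == 1L) x else y
  inside <- dir * (p - bound) >= 0
  j <- c(2:n, 1L)
  ins_i <- inside; ins_j <- inside[j]
  # parametric intersection with the clip line
  denom <- p[j] - p
  t <- (bound - p) / ifelse(denom == 0, NA, denom)
  ix <- x + t * (x[j] - x)
  iy <- y + t * (y[j] - y)
  if (axis == 1L) ix <- rep(bound, n) else iy <- rep(bound, n)
  # per input edge emit up to two vertices, preserving order
  e1x <- ifelse(ins_i & ins_j, x[j], ifelse(ins_i & !ins_j, ix, ifelse(!ins_i & ins_j, ix, NA)))
  e1y <- ifelse(ins_i & ins_j, y[j], ifelse(ins_i & !ins_j, iy, ifelse(!ins_i & ins_j, iy, NA)))
  e2x <- ifelse(!ins_i & ins_j, x[j], NA)
  e2y <- ifelse(!ins_i & ins_j, y[j], NA)
  ox <- as.vector(rbind(e1x, e2x)); oy <- as.vector(rbind(e1y, e2y))
  keep <- !is.na(ox)
  list(x = ox[keep], y = oy[keep])
}

polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# area of polygon clipped to [xmin,xmax] x [ymin,ymax]
clipped_area <- function(x, y, xmin, xmax, ymin, ymax) {
  p <- clip_halfplane(x, y, 1L, xmin, 1)
  p <- clip_halfplane(p$x, p$y, 1L, xmax, -1)
  p <- clip_halfplane(p$x, p$y, 2L, ymin, 1)
  p <- clip_halfplane(p$x, p$y, 2L, ymax, -1)
  polygon_area(p$x, p$y)
}

#' Pixel weights of the circular plot footprint
#'
#' Computes, for a circle of given area centred on a plot, the fraction
#' of the circle's area falling in each intersected pixel of a raster
#' grid.  The circle is approximated by a regular polygon (512 vertices
#' by default) clipped against each pixel square; weights are
#' normalised by the polygon's own area so that they sum to exactly 1
#' when the footprint lies inside the grid.
#'
#' @param easting,northing footprint centre (m).
#' @param transform [geotransform()] of the target grid.
#' @param dim grid dimensions `c(nrow, ncol)`.
#' @param radius circle radius (m); default the 100 m2 footprint.
#' @param n_vertices polygon approximation order (>= 256).
#' @return List with `cells` (data.frame of row, col, weight) and
#'   `offgrid` (`TRUE` when the circle extends beyond the grid, in
#'   which case `cells` is empty).
#' @export
circle_footprint <- function(easting, northing, transform, dim,
                             radius = FOOTPRINT_RADIUS,
                             n_vertices = 512L) {
  stopifnot(n_vertices >= 256L)
  tr <- transform
  ang <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  px <- easting + radius * cos(ang)
  py <- northing + radius * sin(ang)
  # candidate cells from the circle's bounding box
  cmin <- point_cell(tr, easting - radius, northing + radius)
  cmax <- point_cell(tr, easting + radius, northing - radius)
  if (cmin$row < 1L || cmin$col < 1L || cmax$row > dim[1] ||
      cmax$col > dim[2])
    return(list(cells = data.frame(row = integer(), col = integer(),
                                   weight = numeric()), offgrid = TRUE))
  grid <- expand.grid(row = cmin$row:cmax$row, col = cmin$col:cmax$col)
  area <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    xmin <- tr$x0 + (grid$col[i] - 1) * tr$px
    ymax <- tr$y0 - (grid$row[i] - 1) * tr$py
    area[i] <- clipped_area(px, py, xmin, xmin + tr$px,
                            ymax - tr$py, ymax)
  }
  keep <- area > 0
  w <- area[keep] / polygon_area(px, py)
  list(cells = data.frame(row = grid$row[keep], col = grid$col[keep],
                          weight = w),
       offgrid = FALSE)
}

#' Area-weighted mean of a band over a footprint
#'
#' @param band numeric matrix.
#' @param fw footprint weights from [circle_footprint()].
#' @return The weighted mean, or `NA` if any contributing pixel is
#'   nodata (`NA`).
#' @export
weighted_mean_band <- function(band, fw) {
  v <- band[cbind(fw$cells$row, fw$cells$col)]
  if (anyNA(v)) return(NA_real_)
  sum(fw$cells$weight * v)
}

#' Area-weighted mode of a categorical band over a footprint
#'
#' Returns the category with the greatest summed weight; exact ties are
#' broken deterministically towards the lowest category code.
#'
#' @inheritParams weighted_mean_band
#' @return The modal category code, or `NA` if any contributing pixel
#'   is nodata.
#' @export
weighted_mode_band <- function(band, fw) {
  v <- band[cbind(fw$cells$row, fw$cells$col)]
  if (anyNA(v)) return(NA_real_)
  tot <- tapply(fw$cells$weight, v, sum)
  cats <- as.numeric(names(tot))
  ord <- order(-tot, cats)          # max weight, then lowest code
  cats[ord[1]]
}

#' Extract plot signatures from a raster stack
#'
#' For each plot, computes the area-weighted mean of the continuous
#' layers (spectral bands, TCD, QUALITY) and the area-weighted mode of
#' the categorical layers (FTY on the 10 m grid; the canopy-loss year
#' GFC directly on its 30 m grid) over the 100 m2 circular footprint.
#' Plots whose footprint leaves the grid are flagged `excluded_offgrid`.
#'
#' @param plots plot records (see [read_plot_table()]).
#' @param stack a [raster_stack()].
#' @param radius footprint radius (m).
#' @return A `data.frame` with one row per plot: the plot columns, the
#'   extracted signature columns (B2..B12, TCD, FTY, QUALITY, GFC) and
#'   a `screen_status` column (`"kept"` or `"excluded_offgrid"` at this
#'   stage; see [screen_plots()]).
#' @export
extract_signatures <- function(plots, stack, radius = FOOTPRINT_RADIUS) {
  n <- nrow(plots)
  d10 <- stack_dim(stack)
  cont <- c(SPECTRAL_BANDS, "TCD", "QUALITY")
  sig <- matrix(NA_real_, n, length(cont) + 2L,
                dimnames = list(NULL, c(cont, "FTY", "GFC")))
  status <- rep("kept", n)
  for (i in seq_len(n)) {
    fw <- circle_footprint(plots$easting[i], plots$northing[i],
                           stack$transform, d10, radius = radius)
    off <- fw$offgrid
    gw <- NULL
    if (!off && !is.null(stack$gfc)) {
      gw <- circle_footprint(plots$easting[i], plots$northing[i],
                             stack$gfc_transform, dim(stack$gfc),
                             radius = radius)
      off <- off || gw$offgrid
    }
    if (off) { status[i] <- "excluded_offgrid"; next }
    for (b in cont) sig[i, b] <- weighted_mean_band(stack$bands[[b]], fw)
    sig[i, "FTY"] <- weighted_mode_band(stack$bands$FTY, fw)
    sig[i, "GFC"] <- if (is.null(gw)) 0
                     else weighted_mode_band(stack$gfc, gw)
  }
  out <- cbind(plots, as.data.frame(sig))
  out$screen_status <- status
  rownames(out) <- NULL
  out
}

#' Screen plot signatures
#'
#' Applies the two screening rules to extracted signatures:
#' cloud-contaminated observations (footprint-mean composite quality
#' not greater than the threshold) are `excluded_cloud`, and plots with
#' canopy loss detected since 2018 — or since the year before the
#' earliest plot measurement, whichever is earlier — are
#' `excluded_change`.  Screening is a pure filter: every input row is
#' returned with its `screen_status` set and no other field altered.
#'
#' @param signatures output of [extract_signatures()].
#' @param earliest_year earliest plot measurement year (defaults to
#'   `min(signatures$year)`).
#' @param quality_threshold quality values must exceed this to be kept
#'   (default 4000; the comparison is strict).
#' @return The signatures with `screen_status` in `kept`,
#'   `excluded_cloud`, `excluded_change`, `excluded_offgrid`; category
#'   counts in `attr(, "screen_counts")`.
#' @export
screen_plots <- function(signatures, earliest_year = NULL,
                         quality_threshold = 4000) {
  earliest_year <- earliest_year %||% min(signatures$year)
  loss_cut <- min(2018, earliest_year - 1)
  st <- signatures$screen_status
  open <- st != "excluded_offgrid"
  cloud <- open & (is.na(signatures$QUALITY) |
                     signatures$QUALITY <= quality_threshold)
  st[cloud] <- "excluded_cloud"
  change <- open & !cloud & !is.na(signatures$GFC) &
    signatures$GFC > 0 & signatures$GFC >= loss_cut
  st[change] <- "excluded_change"
  st[open & !cloud & !change] <- "kept"
  signatures$screen_status <- st
  counts <- table(factor(st, levels = c("kept", "excluded_cloud",
                                        "excluded_change",
                                        "excluded_offgrid")))
  attr(signatures, "screen_counts") <- counts
  signatures
}

#' Kept rows of a screened signature table
#'
#' @param signatures output of [screen_plots()].
#' @return The rows with `screen_status == "kept"`.
#' @export
kept_plots <- function(signatures) {
  out <- signatures[signatures$screen_status == "kept", , drop = FALSE]
  rownames(out) <- NULL
  out
}
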