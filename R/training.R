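# Training-set assembly: the deterministic every-third validation
# split, plot pooling across countries of a processing area, location
# features on the 1 km reference grid, and feature standardization.

#' Processing-area configuration
#'
#' A processing area is mapped with one pooled set of training plots.
#' Areas containing inventory plots use both 1 km grid coordinates as
#' location features (`both_axes`); plot-free areas borrowing plots
#' from ecologically similar regions use `none` (or `northing_only` for
#' the one documented exception).
#'
#' @param area_id identifier.
#' @param contributing_countries country codes whose plots are pooled.
#' @param location_mode `"both_axes"`, `"northing_only"` or `"none"`.
#' @param member_tiles optional tile labels covered by the area.
#' @param has_plots whether the area itself contains inventory plots;
#'   `both_axes` requires it.
#' @return An object of class `area_config`.
#' @export
area_config <- function(area_id, contributing_countries,
                        location_mode = c("both_axes", "northing_only",
                                          "none"),
                        member_tiles = character(), has_plots = TRUE) {
  location_mode <- match.arg(location_mode)
  if (location_mode == "both_axes" && !has_plots)
    stop("location_mode 'both_axes' requires in-area plots")
  structure(list(area_id = area_id,
                 contributing_countries = contributing_countries,
                 location_mode = location_mode,
                 member_tiles = member_tiles,
                 has_plots = has_plots),
            class = "area_config")
}

#' Snap coordinates to the 1 km reference grid
#'
#' Plot locations enter the feature space generalized to the origin of
#' their 1 km grid cell (coordinates floored to the km).
#'
#' @param easting,northing projected coordinates (m).
#' @return List with `easting` and `northing` of the cell origin.
#' @export
snap_to_1km_grid <- function(easting, northing) {
  list(easting = floor(easting / 1000) * 1000,
       northing = floor(northing / 1000) * 1000)
}

#' Every-third validation split
#'
#' Sorts plots by increasing volume (ties broken by `plot_id`) and
#' assigns every third plot (1-based positions 3, 6, 9, ...) to the
#' validation set; the remaining two thirds are the mapping set.  The
#' validation set size is therefore `floor(n / 3)`.
#'
#' @param plots screened plot rows with `vol` and `plot_id` columns.
#' @return List with `mapping` and `validation` data frames.
#' @export
split_validation <- function(plots) {
  n <- nrow(plots)
  if (n < 3L)
    warning("fewer than 3 plots; validation set is empty", call. = FALSE)
  ord <- order(plots$vol, plots$plot_id)
  pos <- seq_len(n)
  val_idx <- ord[pos %% 3L == 0L]
  map_idx <- ord[pos %% 3L != 0L]
  mapping <- plots[sort(map_idx), , drop = FALSE]
  validation <- plots[sort(val_idx), , drop = FALSE]
  rownames(mapping) <- rownames(validation) <- NULL
  list(mapping = mapping, validation = validation)
}

#' Pool plots for a processing area
#'
#' Concatenates the plot tables of every country contributing to an
#' area.  A plot appearing in several inputs (e.g. via overlapping
#' image tiles) is retained as distinct rows.
#'
#' @param area an [area_config()].
#' @param tables named list of per-country plot data frames.
#' @return One pooled data frame.
#' @export
pool_plots_for_area <- function(area, tables) {
  missing <- setdiff(area$contributing_countries, names(tables))
  if (length(missing))
    stop("no plot table for country code(s): ",
         paste(missing, collapse = ", "))
  out <- do.call(rbind, c(tables[area$contributing_countries],
                          list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

feature_names_for <- function(location_mode) {
  base <- c(SPECTRAL_BANDS, "TCD", "FTY")
  switch(location_mode,
         none = base,
         northing_only = c(base, "northing_1km"),
         both_axes = c(base, "easting_1km", "northing_1km"))
}

#' Raw feature rows for signature tables
#'
#' Assembles the unstandardized kNN feature matrix (the model applies
#' its own scaler at prediction time) for plots carrying signature
#' columns, e.g. to predict validation plots.
#'
#' @param plots plot rows with signature columns (B2..B12, TCD, FTY)
#'   and coordinates.
#' @param location_mode `"both_axes"`, `"northing_only"` or `"none"`;
#'   must match the model's feature layout.
#' @return Numeric matrix, one row per plot.
#' @export
signature_features <- function(plots, location_mode) {
  need <- c(SPECTRAL_BANDS, "TCD", "FTY")
  for (f in need) {
    if (is.null(plots[[f]])) stop("missing signature field: ", f)
    if (anyNA(plots[[f]])) {
      bad <- plots$plot_id[which(is.na(plots[[f]]))[1]]
      stop(sprintf("missing signature value for field '%s' (plot %s)",
                   f, bad))
    }
  }
  X <- cbind(as.matrix(plots[SPECTRAL_BANDS]), TCD = plots$TCD,
             FTY = as.numeric(plots$FTY == FTY_CONIFEROUS))
  if (location_mode != "none") {
    g <- snap_to_1km_grid(plots$easting, plots$northing)
    if (location_mode == "both_axes")
      X <- cbind(X, easting_1km = g$easting, northing_1km = g$northing)
    else
      X <- cbind(X, northing_1km = g$northing)
  }
  colnames(X) <- feature_names_for(location_mode)
  X
}

#' Build the feature and response matrices for a processing area
#'
#' Assembles the kNN feature matrix from pooled mapping plots: the
#' seven spectral bands, tree-cover density, forest type as a binary
#' indicator (coniferous = 1, broadleaved = 0) and, depending on the
#' area's `location_mode`, the 1 km grid coordinates.  Plots whose
#' footprint signature is non-forest are excluded.  With
#' `scaling = "standardize"` (default) every feature is centred and
#' scaled to unit variance using the statistics of these plots, giving
#' all features equal weight in the Euclidean distance;
#' `scaling = "none"` keeps raw units.
#'
#' @param plots pooled, screened mapping plots with signature columns.
#' @param area an [area_config()].
#' @param scaling `"standardize"` or `"none"`.
#' @param scaler optional previously fitted scaler (list of `center`,
#'   `scale`), e.g. to place validation plots in a mapping-set feature
#'   space; overrides `scaling`.
#' @return An object of class `training_set`: `X` (feature matrix),
#'   `Y` (response matrix vol/agb/dcp), `scaler`, `plot_ids`,
#'   `feature_names`, `location_mode`.
#' @export
build_feature_matrix <- function(plots, area, scaling = c("standardize",
                                                          "none"),
                                 scaler = NULL) {
  scaling <- match.arg(scaling)
  nf <- !is.na(plots$FTY) & plots$FTY == FTY_NONFOREST
  if (any(nf)) plots <- plots[!nf, , drop = FALSE]
  X <- signature_features(plots, area$location_mode)
  if (is.null(scaler)) {
    if (scaling == "standardize") {
      center <- colMeans(X)
      scale <- apply(X, 2, stats::sd)
      zero <- !is.finite(scale) | scale == 0
      if (any(zero)) {
        warning("zero-variance feature(s): ",
                paste(colnames(X)[zero], collapse = ", "),
                "; scale set to 1", call. = FALSE)
        scale[zero] <- 1
      }
    } else {
      center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
      names(center) <- names(scale) <- colnames(X)
    }
    scaler <- list(center = center, scale = scale)
  }
  Xs <- sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
  Y <- cbind(vol = plots$vol, agb = plots$agb, dcp = plots$dcp)
  structure(list(X = Xs, Y = Y, scaler = scaler,
                 plot_ids = plots$plot_id,
                 feature_names = colnames(X),
                 location_mode = area$location_mode,
                 n_excluded_nonforest = sum(nf)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d plots x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}
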