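# Field-plot tables: one row per inventory plot with projected
# coordinates (m, equal-area CRS), measurement year, country code and
# the three response variables (vol m3/ha, agb t/ha, dcp %).

PLOT_COLUMNS <- c("plot_id", "easting", "northing", "year", "country",
                  "vol", "agb", "dcp")
PLOT_NUMERIC <- c("easting", "northing", "year", "vol", "agb", "dcp")

#' Read and validate a field-plot table
#'
#' Reads a delimited plot table (CSV with header) and validates each
#' row: `vol` and `agb` must be finite and non-negative, `dcp` (conifer
#' share of above-ground biomass, percent) must lie in \[0, 100\], and
#' `plot_id` must be unique.  Rows violating the range invariants are
#' dropped with row-level diagnostics attached as the `"rejected"`
#' attribute; structural problems (missing columns, non-numeric values)
#' are errors.
#'
#' @param path CSV file with columns plot_id, easting, northing, year,
#'   country, vol, agb, dcp.
#' @return A validated `data.frame` of plot records; rejected rows (with
#'   a `reason` column) in `attr(, "rejected")`.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) stop("plot table not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing <- setdiff(PLOT_COLUMNS, names(raw))
  if (length(missing))
    stop("plot table lacks required column(s): ",
         paste(missing, collapse = ", "))
  df <- raw[PLOT_COLUMNS]
  for (col in PLOT_NUMERIC) {
    conv <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(conv) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' in row(s) %s", col,
                   paste(utils::head(bad, 10), collapse = ", ")))
    df[[col]] <- conv
  }
  df$year <- as.integer(df$year)
  validate_plot_records(df)
}

#' Validate plot records
#'
#' Applies the row invariants of [read_plot_table()] to an in-memory
#' `data.frame`.
#'
#' @param df plot records.
#' @return The valid rows, with rejects in `attr(, "rejected")`.
#' @export
validate_plot_records <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(!is.finite(df$vol) | df$vol < 0, "vol must be finite and >= 0")
  flag(!is.finite(df$agb) | df$agb < 0, "agb must be finite and >= 0")
  flag(!is.finite(df$dcp) | df$dcp < 0 | df$dcp > 100,
       "dcp must lie in [0, 100]")
  flag(!is.finite(df$easting) | !is.finite(df$northing),
       "coordinates must be finite")
  flag(duplicated(df$plot_id), "duplicate plot_id")
  bad <- !is.na(reason)
  rejected <- df[bad, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[bad]
    warning(sprintf("rejected %d plot record(s); see attr(, 'rejected')",
                    nrow(rejected)), call. = FALSE)
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a plot table to CSV
#'
#' @param plots plot records as returned by [read_plot_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(plots, path) {
  utils::write.csv(plots[intersect(c(PLOT_COLUMNS,
                                     setdiff(names(plots), PLOT_COLUMNS)),
                                   names(plots))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
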