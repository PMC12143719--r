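# Structured run configuration (YAML): processing areas, kNN
# parameters, feature scaling and output settings.

#' Read a run configuration file
#'
#' The YAML file has an `areas:` list (each with `area_id`,
#' `contributing_countries`, `location_mode`, optional `member_tiles`
#' and `has_plots`), an optional `knn:` block (`k`, `epsilon`), an
#' optional `scaling:` flag (`standardize` or `none`) and an optional
#' `output:` block (`year`, `crs_epsg`, `dir`).
#'
#' @param path YAML file path.
#' @return List of class `run_config` with `areas` (named list of
#'   [area_config()]), `knn`, `scaling` and `output`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$areas) || !length(cfg$areas))
    stop("configuration must define at least one processing area")
  areas <- lapply(cfg$areas, function(a) {
    if (is.null(a$area_id)) stop("each area needs an area_id")
    area_config(a$area_id,
                contributing_countries = unlist(a$contributing_countries),
                location_mode = a$location_mode %||% "both_axes",
                member_tiles = unlist(a$member_tiles) %||% character(),
                has_plots = a$has_plots %||% TRUE)
  })
  names(areas) <- vapply(areas, function(a) as.character(a$area_id),
                         character(1))
  tiles <- unlist(lapply(areas, function(a) a$member_tiles))
  if (anyDuplicated(tiles))
    stop("tile(s) assigned to more than one processing area: ",
         paste(unique(tiles[duplicated(tiles)]), collapse = ", "))
  knn <- cfg$knn %||% list()
  scaling <- cfg$scaling %||% "standardize"
  if (!scaling %in% c("standardize", "none"))
    stop("scaling must be 'standardize' or 'none'")
  structure(list(areas = areas,
                 knn = list(k = knn$k %||% 7L,
                            epsilon = knn$epsilon %||% 1e-9),
                 scaling = scaling,
                 output = cfg$output %||% list()),
            class = "run_config")
}
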