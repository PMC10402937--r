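# Grid-to-ZIP exposure aggregation.
#
# Gridded pollutant predictions are aggregated to ZIP level by averaging
# the predictions at grid cells whose centroids fall inside the ZIP
# polygon; ZIPs without a polygon representation (points: large
# buildings, military bases, post offices) take the value of the nearest
# grid centroid. Point-in-polygon tests use mgcv::in.out().

#' Aggregate gridded predictions to ZIP-year exposures
#'
#' @param grids Tibble of grid-cell predictions with columns `x`, `y`,
#'   `year`, `pollutant`, `value` (one row per cell-year-pollutant).
#' @param zips ZIP geometry list: a named list (names = ZIP codes) whose
#'   elements are either a two-column matrix/data frame of polygon
#'   vertices (`x`, `y`; simple, non-self-intersecting) or a length-two
#'   numeric `c(x, y)` for point ZIPs.
#' @return Tibble with one row per (`zip`, `year`, `pollutant`):
#'   `zip`, `year`, `pollutant`, `conc`, `n_cells` (number of contained
#'   centroids; 1 with `method = "nearest"`), `method` (`"polygon_mean"`
#'   or `"nearest"`). A polygon ZIP containing no centroid falls back to
#'   the nearest grid with a warning.
#' @export
aggregate_grid_to_zip <- function(grids, zips) {
  if (nrow(grids) == 0) abort("empty grid table")
  if (length(zips) == 0 || is.null(names(zips))) {
    abort("zips must be a named list of geometries")
  }
  grids <- tibble::as_tibble(grids)
  if (!"pollutant" %in% names(grids)) grids$pollutant <- "value"
  cells <- grids %>%
    dplyr::distinct(.data$x, .data$y) %>%
    as.data.frame()

  assign_cells <- purrr::imap(zips, function(geom, zip) {
    if (is.null(geom)) abort(paste0("zip ", zip, " has no geometry"))
    if (is.numeric(geom) && length(geom) == 2 && is.null(dim(geom))) {
      i <- which.min((cells$x - geom[1])^2 + (cells$y - geom[2])^2)
      return(tibble::tibble(
        zip = zip, x = cells$x[i], y = cells$y[i], method = "nearest"
      ))
    }
    poly <- as.matrix(as.data.frame(geom)[, 1:2])
    inside <- mgcv::in.out(poly, as.matrix(cells))
    if (!any(inside)) {
      warn(paste0(
        "zip ", zip, " contains no grid centroid; falling back to nearest grid"
      ))
      cx <- mean(poly[, 1])
      cy <- mean(poly[, 2])
      i <- which.min((cells$x - cx)^2 + (cells$y - cy)^2)
      return(tibble::tibble(
        zip = zip, x = cells$x[i], y = cells$y[i], method = "nearest"
      ))
    }
    tibble::tibble(
      zip = zip, x = cells$x[inside], y = cells$y[inside],
      method = "polygon_mean"
    )
  }) %>% dplyr::bind_rows()

  assign_cells %>%
    dplyr::inner_join(grids, by = c("x", "y"), relationship = "many-to-many") %>%
    dplyr::summarise(
      conc = mean(.data$value),
      n_cells = dplyr::n(),
      method = .data$method[1],
      .by = c("zip", "year", "pollutant")
    ) %>%
    dplyr::arrange(.data$zip, .data$year, .data$pollutant)
}
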