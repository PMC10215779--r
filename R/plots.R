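# Map figures: report point maps and predicted-distribution maps in the
# global equirectangular composition (suitable habitat shaded, reports as
# points). ggplot2 objects are returned for the analysis scripts to save.

#' Global map of occurrence reports
#'
#' @param reports Report tibble.
#' @param env Optional `env_field_set` whose land mask is drawn as
#'   background.
#' @return A ggplot object.
#' @export
plot_report_map <- function(reports, env = NULL) {
  g <- ggplot2::ggplot()
  if (!is.null(env)) {
    land <- which(env$mask, arr.ind = TRUE)
    land_df <- tibble::tibble(lat = env$lat[land[, 1]], lon = env$lon[land[, 2]])
    g <- g + ggplot2::geom_tile(data = land_df,
                                ggplot2::aes(x = .data$lon, y = .data$lat),
                                fill = "grey85")
  }
  g +
    ggplot2::geom_point(data = reports,
                        ggplot2::aes(x = .data$longitude, y = .data$latitude,
                                     colour = .data$genus),
                        size = 0.5, alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-90, 90), expand = FALSE) +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = "Genus") +
    ggplot2::theme_minimal()
}

#' Predicted-distribution map for one genus
#'
#' Suitable cells shaded, with optional report points (squares) and legacy
#' points (circles) overlaid.
#'
#' @param map A `suitability_map`.
#' @param reports,legacy Optional report tibbles for the genus.
#' @return A ggplot object.
#' @export
plot_suitability_map <- function(map, reports = NULL, legacy = NULL) {
  suit <- static_mask(map)
  ix <- which(suit, arr.ind = TRUE)
  suit_df <- tibble::tibble(lat = map$lat[ix[, 1]], lon = map$lon[ix[, 2]])
  land <- which(!map$ocean, arr.ind = TRUE)
  land_df <- tibble::tibble(lat = map$lat[land[, 1]], lon = map$lon[land[, 2]])
  g <- ggplot2::ggplot() +
    ggplot2::geom_tile(data = land_df,
                       ggplot2::aes(x = .data$lon, y = .data$lat), fill = "grey85") +
    ggplot2::geom_tile(data = suit_df,
                       ggplot2::aes(x = .data$lon, y = .data$lat),
                       fill = "steelblue4", alpha = 0.7)
  if (!is.null(reports) && nrow(reports) > 0) {
    g <- g + ggplot2::geom_point(
      data = reports,
      ggplot2::aes(x = .data$longitude, y = .data$latitude),
      shape = 15, size = 0.7, colour = "deeppink3"
    )
  }
  if (!is.null(legacy) && nrow(legacy) > 0) {
    g <- g + ggplot2::geom_point(
      data = legacy,
      ggplot2::aes(x = .data$longitude, y = .data$latitude),
      shape = 16, size = 0.9, colour = "dodgerblue"
    )
  }
  g +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-90, 90), expand = FALSE) +
    ggplot2::labs(title = map$genus, x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}
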