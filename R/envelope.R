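# Environmental-envelope habitat prediction: suitable habitat is the hard
# box in environmental space bounded by the central 90% interval (5th-95th
# percentile) of the positive reports' values on the forest-selected
# predictors, mapped back to the grid.

#' Build a percentile environmental envelope
#'
#' Per selected predictor, the central `central_fraction` interval of the
#' positive profiles' values, using linear-interpolation quantiles
#' (`type = 7`) — the quantile convention is pinned because definitions
#' differ across ecosystems.
#'
#' @param positive_profiles Data frame of environmental profiles for rows
#'   where the genus is present (>= 2 rows).
#' @param selected Character vector of predictor names (the forest
#'   selection).
#' @param central_fraction Central probability mass enclosed (default 0.90,
#'   i.e. bounds at the 5th and 95th percentiles); 1 gives (min, max).
#' @param genus Optional genus label carried along.
#' @return An `envelope`: list with `genus`, `bounds` (tibble `predictor`,
#'   `lower`, `upper`), `central_fraction`.
#' @export
build_envelope <- function(positive_profiles, selected, central_fraction = 0.90,
                           genus = NULL) {
  if (nrow(positive_profiles) < 2) stop("need at least 2 positive profiles")
  if (central_fraction <= 0 || central_fraction > 1) {
    stop("central_fraction must be in (0, 1]")
  }
  probs <- c((1 - central_fraction) / 2, (1 + central_fraction) / 2)
  rows <- lapply(selected, function(p) {
    if (!p %in% names(positive_profiles)) {
      stop("selected predictor absent from profiles: ", p)
    }
    v <- positive_profiles[[p]]
    v <- v[is.finite(v)]
    if (length(v) == 0) stop("selected predictor entirely missing among positives: ", p)
    q <- quantile(v, probs, type = 7, names = FALSE)
    tibble::tibble(predictor = p, lower = q[1], upper = q[2])
  })
  structure(list(genus = genus, bounds = dplyr::bind_rows(rows),
                 central_fraction = central_fraction),
            class = "envelope")
}

#' Predict suitable habitat from an envelope
#'
#' A cell is suitable when every selected predictor at that cell falls
#' within its envelope bounds — in at least one month (`any_month`, the
#' default, matching a static global map) or month by month (`per_month`).
#' Land cells are never suitable.
#'
#' @param env An `env_field_set`.
#' @param envelope An `envelope`.
#' @param month_mode `"any_month"` or `"per_month"`.
#' @return A `suitability_map`: list with `genus`, `lat`, `lon`, `ocean`
#'   (logical matrix), `month_mode`, and `suitable` — a lat x lon logical
#'   matrix (`any_month`) or lat x lon x month array (`per_month`).
#' @export
predict_suitable <- function(env, envelope, month_mode = c("any_month", "per_month")) {
  month_mode <- match.arg(month_mode)
  b <- envelope$bounds
  missing_p <- setdiff(b$predictor, names(env$fields))
  if (length(missing_p) > 0) {
    stop("envelope predictors absent from environment: ",
         paste(missing_p, collapse = ", "))
  }
  dims <- c(length(env$lat), length(env$lon), length(env$months))
  ok <- array(TRUE, dim = dims)
  for (i in seq_len(nrow(b))) {
    f <- env$fields[[b$predictor[i]]]
    ok <- ok & !is.na(f) & f >= b$lower[i] & f <= b$upper[i]
  }
  suitable <- if (month_mode == "any_month") apply(ok, c(1, 2), any) else ok
  structure(list(genus = envelope$genus, lat = env$lat, lon = env$lon,
                 ocean = !env$mask, month_mode = month_mode,
                 suitable = suitable),
            class = "suitability_map")
}

#' Two-dimensional kernel density surface of occurrence points
#'
#' Gaussian kernel density on the lat/lon plane over a regular grid,
#' renormalized to integrate to 1 over the grid. Default bandwidth is
#' Scott's rule per axis (`sd * n^(-1/6)`), floored at half a degree.
#'
#' @param latitude,longitude Point coordinates (>= 1 point).
#' @param bandwidth Kernel standard deviation in degrees (length 1 or 2,
#'   lon then lat); `NULL` for the Scott default.
#' @param gridsize Number of grid nodes per axis.
#' @param lims Grid limits `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return List with `lat`, `lon` (grid node vectors), `density` (lat x lon
#'   matrix integrating to 1), `bandwidth`.
#' @export
density_surface <- function(latitude, longitude, bandwidth = NULL,
                            gridsize = c(180, 90),
                            lims = c(-180, 180, -90, 90)) {
  n <- length(latitude)
  if (n == 0) stop("need at least one point")
  stopifnot(length(longitude) == n)
  if (is.null(bandwidth)) {
    bandwidth <- c(sd(longitude), sd(latitude)) * n^(-1 / 6)
    bandwidth[!is.finite(bandwidth) | bandwidth < 0.5] <- 0.5
  }
  bandwidth <- rep(bandwidth, length.out = 2)
  # MASS::kde2d uses sd = h/4, so pass 4x the intended kernel sd
  kd <- MASS::kde2d(longitude, latitude, h = 4 * bandwidth,
                    n = gridsize, lims = lims)
  dx <- kd$x[2] - kd$x[1]; dy <- kd$y[2] - kd$y[1]
  z <- kd$z / (sum(kd$z) * dx * dy)
  list(lat = kd$y, lon = kd$x, density = t(z), bandwidth = bandwidth)
}
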