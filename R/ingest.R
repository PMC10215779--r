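# Reading, validating, and normalizing occurrence tables: the
# citizen-science export dialect and the legacy literature dialect.

#' The ten rhizostome genera modelled by default
#'
#' @return Character vector of ten genus labels (the default whitelist).
#' @export
rhizostome_genera <- function() {
  c("Cassiopea", "Catostylus", "Cotylorhiza", "Eupilema", "Lobonema",
    "Lychnorhiza", "Pseudorhiza", "Rhizostoma", "Rhopilema", "Stomolophus")
}

default_column_map <- function(source) {
  if (source == "inaturalist") {
    list(taxon = "taxon_name", latitude = "latitude", longitude = "longitude",
         date = "observed_on", id = "id")
  } else {
    list(taxon = "genus", latitude = "latitude", longitude = "longitude",
         year = "year", id = NULL)
  }
}

#' Read and validate an occurrence table
#'
#' Reads a CSV in the citizen-science export dialect (default headers
#' `taxon_name`, `latitude`, `longitude`, `observed_on`) or the legacy
#' literature dialect (`genus, species, region, latitude, longitude,
#' reference, year`). Rows with missing or out-of-range coordinates, or (for
#' citizen-science input) unparseable observation dates, are rejected and
#' logged with a reason. The genus is the first whitespace-delimited token of
#' the taxon string: every record is treated at genus rank.
#'
#' @param path CSV path.
#' @param source `"inaturalist"` or `"legacy"`. Legacy records carry no
#'   observation date; their `month` is `NA` (they are only used for spatial
#'   evaluation, never for monthly pairing).
#' @param column_map Optional named list overriding the default column names
#'   (`taxon`, `latitude`, `longitude`, `date`/`year`, `id`).
#' @return List with `reports` (validated tibble) and `rejected` (tibble of
#'   dropped rows with a `reason` column). `nrow(input) = nrow(reports) +
#'   nrow(rejected)` always.
#' @export
read_reports <- function(path, source = c("inaturalist", "legacy"),
                         column_map = NULL) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("missing input: ", path)
  cm <- utils::modifyList(default_column_map(source), column_map %||% list())
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))

  mandatory <- c(cm$taxon, cm$latitude, cm$longitude,
                 if (source == "inaturalist") cm$date)
  for (col in mandatory) {
    if (!col %in% names(d)) stop("missing mandatory column: ", col)
  }

  n <- nrow(d)
  lat <- suppressWarnings(as.numeric(d[[cm$latitude]]))
  lon <- suppressWarnings(as.numeric(d[[cm$longitude]]))
  reason <- rep(NA_character_, n)
  reason[is.na(lat)] <- "latitude missing"
  reason[is.na(reason) & (lat < -90 | lat > 90)] <- "latitude out of range"
  reason[is.na(reason) & is.na(lon)] <- "longitude missing"
  reason[is.na(reason) & (lon < -180 | lon > 180)] <- "longitude out of range"

  if (source == "inaturalist") {
    date <- suppressWarnings(as.Date(d[[cm$date]]))
    reason[is.na(reason) & is.na(date)] <- "date unparseable"
    month <- as.integer(format(date, "%m"))
    year <- as.integer(format(date, "%Y"))
  } else {
    month <- rep(NA_integer_, n)
    year <- if (!is.null(cm$year) && cm$year %in% names(d)) {
      suppressWarnings(as.integer(d[[cm$year]]))
    } else rep(NA_integer_, n)
  }

  taxon <- d[[cm$taxon]]
  reason[is.na(reason) & (is.na(taxon) | trimws(taxon) == "")] <- "taxon missing"
  genus <- vapply(strsplit(trimws(taxon), "\\s+"),
                  function(x) if (length(x) == 0) NA_character_ else x[1],
                  character(1))

  ids <- if (!is.null(cm$id) && cm$id %in% names(d)) d[[cm$id]] else
    sprintf("%s-%06d", source, seq_len(n))

  all_rows <- tibble::tibble(
    report_id = as.character(ids), genus = genus, latitude = lat,
    longitude = lon, month = month, year = year, source = source,
    reason = reason
  )
  keep <- is.na(all_rows$reason)
  list(
    reports = dplyr::select(all_rows[keep, ], -"reason"),
    rejected = all_rows[!keep, ]
  )
}

#' Filter reports to a genus whitelist
#'
#' Matching is case-insensitive; retained genera are normalized to the
#' whitelist's casing. Idempotent. The number of removals is attached as
#' attribute `n_removed`.
#'
#' @param reports Report tibble.
#' @param whitelist Character vector of genus labels (default the ten
#'   rhizostome genera).
#' @return Filtered report tibble.
#' @export
filter_taxonomy <- function(reports, whitelist = rhizostome_genera()) {
  if (length(whitelist) == 0) stop("whitelist must be non-empty")
  idx <- match(tolower(reports$genus), tolower(whitelist))
  out <- reports[!is.na(idx), ]
  out$genus <- whitelist[idx[!is.na(idx)]]
  attr(out, "n_removed") <- sum(is.na(idx))
  out
}

#' Round coordinates half-away-from-zero
#'
#' Deterministic decimal rounding with halves moving away from zero,
#' avoiding banker's-rounding platform differences in coordinate binning.
#'
#' @param lat,lon Numeric vectors.
#' @param digits Decimal digits (default 1, i.e. tenths of a degree).
#' @return List with rounded `lat` and `lon`.
#' @export
round_coordinate <- function(lat, lon, digits = 1) {
  list(lat = round_half_away(lat, digits), lon = round_half_away(lon, digits))
}

#' Round the coordinates of a report table in place
#'
#' @param reports Report tibble.
#' @param digits Decimal digits.
#' @return Report tibble with rounded `latitude`/`longitude`.
#' @export
round_reports <- function(reports, digits = 1) {
  rc <- round_coordinate(reports$latitude, reports$longitude, digits)
  reports$latitude <- rc$lat
  reports$longitude <- rc$lon
  reports
}
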