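# Spatiotemporal pairing of reports with climatology: every grid cell whose
# center lies within +/- window degrees of the report in both axes, in the
# report's month, contributes; matches are averaged per (variable, depth).
# The generous box accommodates land-based reports (beachings) near the
# coast. Longitude wraps across the antimeridian; latitude clamps at poles.

# Profile of one report: named 28-vector of means plus matched-cell counts.
pair_one <- function(lat_r, lon_r, month_r, env, window) {
  ii <- which(abs(env$lat - lat_r) <= window + 1e-9)
  jj <- which(lon_distance(env$lon, lon_r) <= window + 1e-9)
  mi <- match(month_r, env$months)
  keys <- names(env$fields)
  values <- stats::setNames(rep(NA_real_, length(keys)), keys)
  ncells <- stats::setNames(rep(0L, length(keys)), keys)
  if (length(ii) == 0 || length(jj) == 0 || is.na(mi)) {
    return(list(values = values, n_cells = ncells))
  }
  for (key in keys) {
    v <- env$fields[[key]][ii, jj, mi]
    ok <- !is.na(v)
    ncells[key] <- sum(ok)
    if (any(ok)) values[key] <- mean(v[ok])
  }
  list(values = values, n_cells = ncells)
}

#' Pair one report with the climatology
#'
#' @param report Single-row report tibble (must have a month).
#' @param env An `env_field_set`.
#' @param window Half-width of the pairing box in degrees (default 2, i.e.
#'   +/- 2 degrees in latitude and longitude).
#' @return An `environmental_profile`: list with `values` (named 28-vector,
#'   `NA` where no ocean cell matched), `n_cells` (matches per entry), and
#'   `unpairable` (`TRUE` if every entry is missing).
#' @export
pair_report <- function(report, env, window = 2) {
  if (is.na(report$month)) stop("report has no month; cannot pair with monthly climatology")
  p <- pair_one(report$latitude, report$longitude, report$month, env, window)
  p$unpairable <- all(is.na(p$values))
  class(p) <- "environmental_profile"
  p
}

#' Pair many reports with the climatology
#'
#' @param reports Report tibble.
#' @param env An `env_field_set`.
#' @param window Pairing half-width in degrees.
#' @return List with `values` (reports x 28 matrix), `n_cells` (same shape),
#'   and logical `unpairable` per report.
#' @export
pair_reports <- function(reports, env, window = 2) {
  keys <- names(env$fields)
  n <- nrow(reports)
  values <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
  ncells <- matrix(0L, n, length(keys), dimnames = list(NULL, keys))
  for (i in seq_len(n)) {
    if (is.na(reports$month[i])) next
    p <- pair_one(reports$latitude[i], reports$longitude[i],
                  reports$month[i], env, window)
    values[i, ] <- p$values
    ncells[i, ] <- p$n_cells
  }
  list(values = values, n_cells = ncells,
       unpairable = apply(values, 1, function(r) all(is.na(r))))
}

#' Assemble the curated multivariate abundance and environmental dataframe
#'
#' Pairs every report, drops unpairable ones, snaps reports to `map_step`
#' degree cells, accumulates genus counts per cell (and month, unless
#' collapsed), and averages the member reports' environmental profiles per
#' row.
#'
#' @param reports Report tibble (months required).
#' @param env An `env_field_set`.
#' @param map_step Mapping resolution in degrees (1 or 2 in the analysis).
#' @param window Pairing half-width in degrees.
#' @param collapse_months If `TRUE`, rows are cells; otherwise cell x month
#'   (the default, since pairing is month-specific).
#' @return A `curated_frame` tibble: `mapped_lat`, `mapped_lon`, optional
#'   `month`, `n_reports`, one count column per genus, then the 28 predictor
#'   columns. Attributes: `genera`, `predictors`, `n_unpairable`.
#' @export
build_frame <- function(reports, env, map_step = 2, window = 2,
                        collapse_months = FALSE) {
  if (map_step <= 0) stop("map_step must be positive")
  if (nrow(reports) == 0) {
    return(structure(tibble::tibble(), class = c("curated_frame", "tbl_df", "tbl", "data.frame"),
                     genera = character(), predictors = predictor_ids(),
                     n_unpairable = 0L))
  }
  paired <- pair_reports(reports, env, window)
  keep <- !paired$unpairable
  n_unpairable <- sum(!keep)
  reports <- reports[keep, ]
  vals <- paired$values[keep, , drop = FALSE]

  snap <- function(x, lo) lo + (floor((x - lo) / map_step) + 0.5) * map_step
  mapped_lat <- clamp(snap(reports$latitude, -90), -90 + map_step / 2, 90 - map_step / 2)
  mapped_lon <- snap(((reports$longitude + 180) %% 360) - 180, -180)

  key <- if (collapse_months) {
    paste(mapped_lat, mapped_lon, sep = "|")
  } else {
    paste(mapped_lat, mapped_lon, reports$month, sep = "|")
  }
  genera <- sort(unique(reports$genus))
  grp <- split(seq_len(nrow(reports)), key)
  # deterministic row order: by lat, lon (, month)
  ord <- order(vapply(grp, function(ix) mapped_lat[ix[1]], double(1)),
               vapply(grp, function(ix) mapped_lon[ix[1]], double(1)),
               vapply(grp, function(ix) if (collapse_months) 0L else reports$month[ix[1]], integer(1)))
  grp <- grp[ord]

  rows <- lapply(grp, function(ix) {
    counts <- table(factor(reports$genus[ix], levels = genera))
    prof <- colMeans(vals[ix, , drop = FALSE], na.rm = TRUE)
    prof[is.nan(prof)] <- NA_real_
    c(list(mapped_lat = mapped_lat[ix[1]], mapped_lon = mapped_lon[ix[1]]),
      if (!collapse_months) list(month = reports$month[ix[1]]),
      list(n_reports = length(ix)),
      as.list(as.integer(counts)) |> stats::setNames(genera),
      as.list(prof))
  })
  frame <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  structure(frame, class = c("curated_frame", class(frame)),
            genera = genera, predictors = names(env$fields),
            n_unpairable = n_unpairable)
}

#' Median-impute missing predictor entries for model fitting
#'
#' Forests and GLMs need complete rows; entries that failed to pair are
#' filled with the per-column median across the frame. An `.imputed` audit
#' column records rows touched, and attribute `imputation` tabulates counts
#' per predictor, so imputation is never silent.
#'
#' @param frame A `curated_frame`.
#' @return The frame with complete predictor columns.
#' @export
impute_frame <- function(frame) {
  preds <- intersect(attr(frame, "predictors") %||% predictor_ids(), names(frame))
  touched <- rep(FALSE, nrow(frame))
  audit <- integer(0)
  for (p in preds) {
    miss <- is.na(frame[[p]])
    if (any(miss)) {
      med <- median(frame[[p]], na.rm = TRUE)
      frame[[p]][miss] <- med
      touched <- touched | miss
      audit[p] <- sum(miss)
    }
  }
  frame$.imputed <- touched
  attr(frame, "imputation") <- audit
  frame
}
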