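# Evaluation of predicted distributions against the independent legacy
# dataset: percent of legacy records whose grid cell is predicted suitable.
# Because near-global envelopes trivially inflate this percentage, the
# suitable-ocean-area fraction is always reported alongside it.

# Nearest-cell indices for a set of points on the map grid (lon wraps).
cell_index <- function(map, latitude, longitude) {
  ilat <- vapply(latitude, function(x) which.min(abs(map$lat - x)), integer(1))
  ilon <- vapply(longitude, function(x) which.min(lon_distance(map$lon, x)), integer(1))
  cbind(ilat, ilon)
}

# Collapse a per-month suitability array to a static any-month mask.
static_mask <- function(map) {
  if (length(dim(map$suitable)) == 3) apply(map$suitable, c(1, 2), any) else map$suitable
}

#' Score a predicted distribution against legacy occurrences
#'
#' A legacy report counts as inside the predicted distribution when its
#' containing grid cell — or any cell within `tolerance` cells of it
#' (Chebyshev radius, longitude wrapping) — is suitable. Accuracy is
#' `100 * n_inside / n_legacy`, rounded to 0.1.
#'
#' @param map A `suitability_map`.
#' @param legacy_reports Report tibble for one genus (>= 1 row).
#' @param tolerance Cell radius for the inclusion rule (default 0: the
#'   containing cell itself).
#' @return A one-row tibble: `genus`, `n_legacy`, `n_inside`,
#'   `accuracy_pct`.
#' @export
legacy_accuracy <- function(map, legacy_reports, tolerance = 0) {
  n <- nrow(legacy_reports)
  if (n == 0) stop("no legacy data for genus")
  suit <- static_mask(map)
  nlat <- nrow(suit); nlon <- ncol(suit)
  idx <- cell_index(map, legacy_reports$latitude, legacy_reports$longitude)
  inside <- logical(n)
  offs <- -tolerance:tolerance
  for (r in seq_len(n)) {
    ii <- clamp(idx[r, 1] + offs, 1, nlat)
    jj <- ((idx[r, 2] + offs - 1) %% nlon) + 1
    inside[r] <- any(suit[ii, jj])
  }
  genus <- map$genus %||% unique(legacy_reports$genus)[1]
  tibble::tibble(genus = genus, n_legacy = n, n_inside = sum(inside),
                 accuracy_pct = round(100 * sum(inside) / n, 1))
}

#' Summarize distribution accuracy across genera
#'
#' Joins per-genus legacy accuracies with each map's suitable-ocean-area
#' fraction and flags genera whose predicted distribution is so wide that
#' the accuracy percentage is inflation-prone.
#'
#' @param accuracies Tibble of rows from [legacy_accuracy()].
#' @param maps Named list of `suitability_map`, keyed by genus.
#' @param area_flag_threshold Suitable-area fraction above which a genus is
#'   flagged (default 0.5).
#' @return Tibble `genus, n_legacy, n_inside, accuracy_pct, area_fraction,
#'   flag`, with `accuracy_min`/`accuracy_max` attributes.
#' @export
accuracy_report <- function(accuracies, maps, area_flag_threshold = 0.5) {
  if (nrow(accuracies) == 0) stop("no genera evaluated")
  area <- vapply(as.character(accuracies$genus), function(g) {
    m <- maps[[g]]
    if (is.null(m)) return(NA_real_)
    suit <- static_mask(m)
    sum(suit & m$ocean) / sum(m$ocean)
  }, double(1), USE.NAMES = FALSE)
  out <- accuracies
  out$area_fraction <- area
  out$flag <- !is.na(area) & area > area_flag_threshold
  attr(out, "accuracy_min") <- min(out$accuracy_pct)
  attr(out, "accuracy_max") <- max(out$accuracy_pct)
  out
}
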