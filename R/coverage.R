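# Coordinate-level abundance and rarefied sample-coverage screening.
# A genus is analysed further only if its report data are "saturated":
# estimated sample coverage strictly greater than the threshold (0.95).

#' Coordinate-level abundance vector for one genus
#'
#' Collapses a genus' reports to the count of reports per distinct rounded
#' coordinate, ordered by latitude then longitude.
#'
#' @param reports Report tibble with coordinates already rounded (see
#'   [round_reports()]).
#' @param genus Genus label.
#' @return An `abundance_vector`: list with `genus` and integer `counts`
#'   (possibly empty).
#' @export
abundance_from_reports <- function(reports, genus) {
  sub <- reports[reports$genus == genus, c("latitude", "longitude")]
  if (nrow(sub) == 0) {
    return(structure(list(genus = genus, counts = integer(0)),
                     class = "abundance_vector"))
  }
  tab <- dplyr::count(sub, .data$latitude, .data$longitude, name = "n")
  tab <- dplyr::arrange(tab, .data$latitude, .data$longitude)
  structure(list(genus = genus, counts = as.integer(tab$n)),
            class = "abundance_vector")
}

#' Abundance-based sample-coverage estimator
#'
#' The Chao–Jost coverage estimator at the observed sample size:
#' \deqn{\hat C = 1 - \frac{f_1}{n}\cdot\frac{(n-1)f_1}{(n-1)f_1 + 2f_2}}
#' with \eqn{n} the total count, \eqn{f_1} the number of coordinates seen
#' exactly once and \eqn{f_2} exactly twice. When \eqn{f_2 = 0} and
#' \eqn{f_1 > 0} the bias-corrected form replaces \eqn{f_1} by
#' \eqn{f_1 - 1} inside the correction factor. Conventions: \eqn{f_1 = 0}
#' gives coverage 1 (no singletons, sample saturated); a single report
#' (\eqn{n = 1}) gives coverage 0, since one observation carries no
#' information about unseen coordinates.
#'
#' @param av An `abundance_vector` or a bare vector of positive counts.
#' @return Coverage estimate in [0, 1].
#' @export
sample_coverage <- function(av) {
  counts <- if (inherits(av, "abundance_vector")) av$counts else as.integer(av)
  if (length(counts) == 0) stop("no reports")
  if (any(counts < 1)) stop("abundance counts must be positive integers")
  n <- sum(counts)
  if (n == 1) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f1 == 0) return(1)
  A <- if (f2 > 0) {
    (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  } else {
    (n - 1) * (f1 - 1) / ((n - 1) * (f1 - 1) + 2)
  }
  1 - (f1 / n) * A
}

#' Screen genera by rarefied sample coverage
#'
#' Computes the coordinate-level abundance vector and coverage estimate for
#' every genus present, retaining those with coverage strictly greater than
#' the threshold.
#'
#' @param reports Rounded report tibble.
#' @param threshold Retention threshold in (0, 1); comparison is strict.
#' @return Tibble with one row per genus: `genus`, `n` (reports), `n_coords`
#'   (distinct coordinates), `sc`, `retained`.
#' @export
retain_genera <- function(reports, threshold = 0.95) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  genera <- sort(unique(reports$genus))
  rows <- lapply(genera, function(g) {
    av <- abundance_from_reports(reports, g)
    sc <- sample_coverage(av)
    tibble::tibble(genus = g, n = sum(av$counts),
                   n_coords = length(av$counts), sc = sc,
                   retained = sc > threshold)
  })
  dplyr::bind_rows(rows)
}
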