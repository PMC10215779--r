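# Synthetic study system: gridded monthly ocean climatology, genus-specific
# environmental niches, geographically biased citizen-science sampling, and an
# independent legacy sample. The generator mimics the statistical structure
# the downstream analysis assumes (smooth autocorrelated fields, land mask,
# niche-driven occurrence, effort bias), not any real ocean product.

# Per-variable construction parameters: a latitudinal base profile, depth and
# seasonal terms, and the amplitude of the smoothed noise field. Units follow
# ocean-climatology convention (degC, PSU, mg/L, %, umol/L).
env_variable_params <- function() {
  list(
    temperature       = list(fun = function(a, d, s) 29 - 31 * a^1.8 - 0.10 * d + 3.5 * s,  noise = 1.2),
    salinity          = list(fun = function(a, d, s) 35.5 - 2.8 * a^3 + 0.015 * d + 0.3 * s, noise = 0.25),
    dissolved_oxygen  = list(fun = function(a, d, s) 4.5 + 4.5 * a^1.5 + 0.01 * d - 0.4 * s, noise = 0.35),
    oxygen_saturation = list(fun = function(a, d, s) 95 + 8 * a - 0.08 * d + 1.0 * s,        noise = 1.5),
    silicate          = list(fun = function(a, d, s) 3 + 95 * a^4 + 0.35 * d - 2.0 * s,      noise = 4.0),
    phosphate         = list(fun = function(a, d, s) 0.25 + 1.9 * a^2.5 + 0.012 * d - 0.08 * s, noise = 0.09),
    nitrate           = list(fun = function(a, d, s) 1.5 + 28 * a^3 + 0.18 * d - 1.2 * s,    noise = 1.3)
  )
}

# Separable Gaussian blur on a lat x lon matrix; longitude wraps, latitude
# clamps at the poles.
smooth_grid <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- ceiling(3 * sd_cells)
  k <- dnorm(-half:half, sd = sd_cells)
  k <- k / sum(k)
  nlat <- nrow(m); nlon <- ncol(m)
  out <- matrix(0, nlat, nlon)
  for (o in -half:half) {                       # longitude pass (wrap)
    idx <- ((seq_len(nlon) + o - 1) %% nlon) + 1
    out <- out + k[o + half + 1] * m[, idx, drop = FALSE]
  }
  out2 <- matrix(0, nlat, nlon)
  for (o in -half:half) {                       # latitude pass (clamp)
    idx <- clamp(seq_len(nlat) + o, 1, nlat)
    out2 <- out2 + k[o + half + 1] * out[idx, , drop = FALSE]
  }
  out2
}

#' Generate a synthetic gridded monthly ocean climatology
#'
#' Builds smooth global fields for the 7 climatology variables at 4 depths
#' (0, 5, 10, 20 m) across the requested months. Each field is a latitudinal
#' base profile plus depth and seasonal terms plus low-frequency spatial
#' noise, with a shared synthetic land mask applied to every slice. The
#' result is bit-reproducible for a fixed seed.
#'
#' @param seed Integer seed controlling all randomness.
#' @param lat_step Grid resolution in degrees; must divide 180 evenly.
#' @param months Integer vector, subset of 1:12.
#' @param land_fraction Fraction of grid cells masked as land, in [0, 1).
#' @param smooth_cells Gaussian smoothing bandwidth (grid cells) for the
#'   noise and mask fields; controls spatial autocorrelation length.
#' @param noise_amp Multiplier on each variable's noise amplitude.
#' @return An `env_field_set`: list with `lat`, `lon` (cell centers),
#'   `months`, `resolution`, `mask` (lat x lon logical, `TRUE` = land), and
#'   `fields`, a named list of 28 `lat x lon x month` arrays keyed by
#'   `predictor_ids()`.
#' @export
make_environment <- function(seed, lat_step = 2, months = 1:12,
                             land_fraction = 0.3, smooth_cells = 3,
                             noise_amp = 1) {
  if (!is.numeric(lat_step) || length(lat_step) != 1 || lat_step <= 0 ||
      abs(180 / lat_step - round(180 / lat_step)) > 1e-9) {
    stop("lat_step must be a positive number dividing 180 evenly, got ", lat_step)
  }
  months <- as.integer(months)
  if (length(months) == 0 || !all(months %in% 1:12)) {
    stop("months must be a non-empty subset of 1:12")
  }
  if (land_fraction < 0 || land_fraction >= 1) stop("land_fraction must be in [0, 1)")

  nlat <- as.integer(180 / lat_step)
  nlon <- as.integer(360 / lat_step)
  lat <- -90 + lat_step * (seq_len(nlat) - 0.5)
  lon <- -180 + lat_step * (seq_len(nlon) - 0.5)

  withr::with_seed(seed, {
    mask_field <- smooth_grid(matrix(runif(nlat * nlon), nlat, nlon), smooth_cells)
    mask <- mask_field > quantile(mask_field, 1 - land_fraction)

    params <- env_variable_params()
    a <- abs(lat) / 90                      # normalized absolute latitude
    hemi <- tanh(outer(lat, rep(1, nlon)) / 25)  # seasonal sign by hemisphere

    fields <- list()
    for (v in ENV_VARIABLES) {
      pv <- params[[v]]
      for (d in ENV_DEPTHS) {
        noise <- smooth_grid(matrix(rnorm(nlat * nlon), nlat, nlon), smooth_cells) *
          pv$noise * noise_amp * (smooth_cells + 1)  # rescale: blur shrinks variance
        arr <- array(NA_real_, dim = c(nlat, nlon, length(months)))
        for (mi in seq_along(months)) {
          s <- cos(2 * pi * (months[mi] - 8) / 12) * hemi
          base <- matrix(rep(a, nlon), nlat, nlon)  # placeholder for vectorized call
          slice <- pv$fun(base, d, s) + noise
          slice[mask] <- NA_real_
          arr[, , mi] <- slice
        }
        fields[[paste0(v, "_", d, "m")]] <- arr
      }
    }

    structure(
      list(lat = lat, lon = lon, months = months, resolution = lat_step,
           mask = mask, fields = fields),
      class = "env_field_set"
    )
  })
}

#' @export
print.env_field_set <- function(x, ...) {
  cat(sprintf(
    "<env_field_set> %d x %d grid at %g deg, %d months, %d fields, %.0f%% land\n",
    length(x$lat), length(x$lon), x$resolution, length(x$months),
    length(x$fields), 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Define a genus-specific environmental niche
#'
#' A niche is a product of independent Gaussian suitability kernels over a
#' set of informative predictors; occurrence intensity at a cell-month is
#' proportional to that product (times sampling effort).
#'
#' @param genus Genus label.
#' @param optima Named list, one entry per informative predictor id, each a
#'   numeric `c(mean, sd)` in predictor units.
#' @param informative Character vector of predictor ids that drive
#'   occurrence; defaults to `names(optima)`. Must be non-empty and a subset
#'   of `predictor_ids()`.
#' @param base_rate Expected reports per maximally suitable cell-month, used
#'   when sampling without a fixed target count.
#' @return A `niche_spec` object.
#' @export
niche_spec <- function(genus, optima, informative = names(optima), base_rate = 0.5) {
  stopifnot(is.character(genus), length(genus) == 1)
  if (length(informative) == 0) stop("informative_set must be non-empty")
  bad <- setdiff(informative, predictor_ids())
  if (length(bad) > 0) stop("unknown predictor ids: ", paste(bad, collapse = ", "))
  if (!all(informative %in% names(optima))) stop("every informative predictor needs an optimum")
  for (p in informative) {
    o <- optima[[p]]
    if (length(o) != 2 || !is.finite(o[2]) || o[2] <= 0) {
      stop("optimum for ", p, " must be c(mean, sd) with sd > 0")
    }
  }
  structure(list(genus = genus, optima = optima, informative = informative,
                 base_rate = base_rate),
            class = "niche_spec")
}

#' Default synthetic niches for the ten rhizostome genera
#'
#' Gaussian niche optima placed in realistic parts of the synthetic fields'
#' ranges: tropical shallow-water genera keyed to warm surface temperature,
#' temperate genera to cooler water, and the nutrient-associated genus
#' (Lychnorhiza) to silicate/phosphate, echoing the contrast the analysis is
#' meant to recover.
#'
#' @return Named list of `niche_spec`, one per genus.
#' @export
default_niches <- function() {
  n <- list(
    Cassiopea   = niche_spec("Cassiopea",   list(temperature_0m = c(27, 2))),
    Catostylus  = niche_spec("Catostylus",  list(temperature_5m = c(21, 2.5), salinity_0m = c(35.2, 0.6))),
    Cotylorhiza = niche_spec("Cotylorhiza", list(temperature_20m = c(24, 2), salinity_0m = c(35.3, 0.5))),
    Eupilema    = niche_spec("Eupilema",    list(temperature_10m = c(18, 2))),
    Lobonema    = niche_spec("Lobonema",    list(temperature_0m = c(28, 1.5), phosphate_0m = c(0.5, 0.3))),
    Lychnorhiza = niche_spec("Lychnorhiza", list(silicate_10m = c(25, 8), phosphate_20m = c(1.2, 0.4))),
    Pseudorhiza = niche_spec("Pseudorhiza", list(temperature_10m = c(16, 2.5))),
    Rhizostoma  = niche_spec("Rhizostoma",  list(temperature_0m = c(13, 3))),
    Rhopilema   = niche_spec("Rhopilema",   list(temperature_20m = c(22, 2.5), nitrate_0m = c(4, 3))),
    Stomolophus = niche_spec("Stomolophus", list(temperature_20m = c(24, 2), salinity_5m = c(34.8, 0.8)))
  )
  n
}

#' Sampling-effort surface over the environment grid
#'
#' Citizen-science effort is not only geographically biased but extremely
#' patchy: reports originate from a sparse set of access points (popular
#' beaches, marinas) whose popularity is heavy-tailed. The `"western"`
#' surface therefore combines three layers: high base effort over boxes
#' approximating North America, Europe/Mediterranean, and Australia; a
#' sparse seeded mask of active reporting cells (a small fraction of cells,
#' denser inside the boxes); and a lognormal popularity multiplier per
#' active cell. This patchiness is what lets report data saturate
#' (sample coverage > 0.95) at realistic sample sizes. The `"uniform"`
#' surface (used for the legacy literature sample) is dense and flat.
#'
#' @param env An `env_field_set`.
#' @param type `"western"` or `"uniform"`.
#' @param base Background effort weight outside the high-effort boxes.
#' @param active_fraction Fraction of in-box cells that are active
#'   reporting sites (out-of-box cells use a tenth of this).
#' @param hotspot_sdlog Lognormal sd of the per-cell popularity multiplier.
#' @param seed Seed for the sparsity and popularity draws.
#' @return A `participation_surface`: list with `weight`, a lat x lon matrix
#'   in [0, 1] with at least one positive cell.
#' @export
participation_surface <- function(env, type = c("western", "uniform"), base = 0.1,
                                  active_fraction = 0.05, hotspot_sdlog = 1,
                                  seed = 7) {
  type <- match.arg(type)
  w <- matrix(1, length(env$lat), length(env$lon))
  if (type == "western") {
    w[] <- base
    boxes <- list(c(8, 60, -130, -60),    # North America
                  c(30, 62, -12, 40),     # Europe / Mediterranean
                  c(-45, -10, 110, 155))  # Australia
    for (b in boxes) {
      ii <- env$lat >= b[1] & env$lat <= b[2]
      jj <- env$lon >= b[3] & env$lon <= b[4]
      w[ii, jj] <- 1
    }
    withr::with_seed(seed, {
      p_active <- ifelse(w > 0.5, active_fraction, active_fraction / 10)
      active <- matrix(runif(length(w)) < p_active, nrow(w))
      if (!any(active)) active[which.max(w)] <- TRUE
      w <- w * active * matrix(stats::rlnorm(length(w), 0, hotspot_sdlog), nrow(w))
      w <- w / max(w)
    })
  }
  stopifnot(all(w >= 0 & w <= 1), any(w > 0))
  structure(list(weight = w), class = "participation_surface")
}

# Suitability intensity array (lat x lon x month) for one niche: product of
# Gaussian kernels over the informative predictors; land (NA) cells get 0.
niche_intensity <- function(niche, env, effort_weight) {
  dims <- c(length(env$lat), length(env$lon), length(env$months))
  intensity <- array(1, dim = dims)
  for (p in niche$informative) {
    o <- niche$optima[[p]]
    f <- env$fields[[p]]
    k <- exp(-0.5 * ((f - o[1]) / o[2])^2)
    k[is.na(k)] <- 0
    intensity <- intensity * k
  }
  intensity * as.vector(effort_weight)   # weight recycles across months
}

sample_reports_one <- function(niche, env, effort, n_target, source,
                               sites_per_cell = 1) {
  intensity <- niche_intensity(niche, env, effort$weight)
  tot <- sum(intensity)
  if (tot == 0) {
    warning("niche for genus '", niche$genus, "' has zero total intensity; no reports drawn")
    return(empty_reports())
  }
  lam <- if (is.null(n_target)) {
    niche$base_rate * intensity / max(intensity)
  } else {
    n_target * intensity / tot
  }
  counts <- array(rpois(length(lam), lam), dim = dim(lam))
  nz <- which(counts > 0)
  if (length(nz) == 0) return(empty_reports())
  idx <- arrayInd(nz, dim(counts))
  k <- counts[nz]
  half <- env$resolution / 2
  ilat <- rep(idx[, 1], k); ilon <- rep(idx[, 2], k)
  lat0 <- env$lat[ilat]; lon0 <- env$lon[ilon]
  month <- rep(env$months[idx[, 3]], k)
  n <- length(lat0)
  if (is.null(sites_per_cell)) {
    # fully diffuse reporting: uniform jitter anywhere in the cell
    latitude <- clamp(lat0 + runif(n, -half, half), -90, 90)
    longitude <- lon0 + runif(n, -half, half)
  } else {
    # reports cluster at a few fixed access points per cell (shared across
    # months), so rounded coordinates repeat as they do in real report data
    cell <- paste(ilat, ilon)
    ucell <- unique(cell)
    site_lat <- matrix(runif(length(ucell) * sites_per_cell, -half, half),
                       nrow = length(ucell))
    site_lon <- matrix(runif(length(ucell) * sites_per_cell, -half, half),
                       nrow = length(ucell))
    ci <- match(cell, ucell)
    si <- sample.int(sites_per_cell, n, replace = TRUE)
    latitude <- clamp(lat0 + site_lat[cbind(ci, si)], -90, 90)
    longitude <- lon0 + site_lon[cbind(ci, si)]
  }
  tibble::tibble(
    report_id = sprintf("%s-%s-%05d", source, niche$genus, seq_len(n)),
    genus = niche$genus,
    latitude = latitude,
    longitude = longitude,
    month = as.integer(month),
    year = 2022L,
    source = source
  )
}

empty_reports <- function() {
  tibble::tibble(report_id = character(), genus = character(),
                 latitude = double(), longitude = double(),
                 month = integer(), year = integer(), source = character())
}

#' Sample niche-driven occurrence reports
#'
#' Draws Poisson counts per cell-month with intensity proportional to the
#' niche's Gaussian suitability kernel times the participation weight, then
#' jitters coordinates uniformly within the cell. Only ocean cells can yield
#' reports. A niche with zero total intensity is flagged with a warning and
#' contributes no reports.
#'
#' @param niches List of `niche_spec`.
#' @param env An `env_field_set`.
#' @param effort A `participation_surface`.
#' @param n_target Expected number of reports per genus (total intensity is
#'   normalized to this); if `NULL`, each niche's `base_rate` scales the
#'   per-cell-month intensity instead.
#' @param seed Integer seed.
#' @param sites_per_cell Number of fixed reporting sites per occupied cell
#'   that report coordinates snap to (coordinate reuse, as in real report
#'   data); `NULL` jitters every report uniformly within its cell instead.
#' @return Tibble of reports (`report_id`, `genus`, `latitude`, `longitude`,
#'   `month`, `year`, `source = "inaturalist"`).
#' @export
sample_reports <- function(niches, env, effort, n_target = 600, seed = 1,
                           sites_per_cell = 1) {
  if (!is.null(n_target) && n_target < 1) stop("n_target must be >= 1")
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(niches, sample_reports_one, env = env,
                            effort = effort, n_target = n_target,
                            source = "inaturalist",
                            sites_per_cell = sites_per_cell))
  })
}

#' Sample an independent legacy occurrence dataset
#'
#' Like [sample_reports()] but with uniform sampling effort (literature
#' records are assumed far less geographically biased than citizen reports)
#' and `source = "legacy"`.
#'
#' @param niches List of `niche_spec`.
#' @param env An `env_field_set`.
#' @param n Expected number of records per genus; `n = 0` gives an empty set.
#' @param seed Integer seed.
#' @param sites_per_cell As in [sample_reports()].
#' @return Tibble of reports with `source = "legacy"`.
#' @export
sample_legacy <- function(niches, env, n = 60, seed = 1, sites_per_cell = 1) {
  if (n == 0) return(empty_reports())
  uniform <- participation_surface(env, "uniform")
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(niches, sample_reports_one, env = env,
                            effort = uniform, n_target = n,
                            source = "legacy",
                            sites_per_cell = sites_per_cell))
  })
}

#' Write reports in the citizen-science export dialect
#'
#' Columns: `id`, `taxon_name` (genus + epithet placeholder), `latitude`,
#' `longitude`, `observed_on` (ISO date built from year/month).
#' @param reports Report tibble.
#' @param path Output CSV path.
#' @export
write_reports_csv <- function(reports, path) {
  out <- tibble::tibble(
    id = reports$report_id,
    taxon_name = paste(reports$genus, "sp."),
    latitude = reports$latitude,
    longitude = reports$longitude,
    observed_on = sprintf("%04d-%02d-15", reports$year, reports$month)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a legacy-literature style occurrence table
#'
#' Columns: `genus, species, region, latitude, longitude, reference, year`.
#' @param reports Report tibble.
#' @param path Output CSV path.
#' @export
write_legacy_csv <- function(reports, path) {
  out <- tibble::tibble(
    genus = reports$genus,
    species = "sp.",
    region = "synthetic",
    latitude = reports$latitude,
    longitude = reports$longitude,
    reference = "synthetic-generator",
    year = reports$year
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write climatology in the long-format CSV dialect
#'
#' One row per (variable, depth, month, cell): columns `variable, depth_m,
#' month, lat, lon, value` with empty values on land. This dialect is the
#' package's climatology interchange format.
#' @param env An `env_field_set`.
#' @param path Output CSV path.
#' @export
write_climatology_csv <- function(env, path) {
  nlat <- length(env$lat); nlon <- length(env$lon); nm <- length(env$months)
  chunks <- lapply(names(env$fields), function(key) {
    vd <- strsplit(key, "_(?=[0-9]+m$)", perl = TRUE)[[1]]
    tibble::tibble(
      variable = vd[1],
      depth_m = as.numeric(sub("m$", "", vd[2])),
      month = rep(env$months, each = nlat * nlon),
      lat = rep(env$lat, times = nlon * nm),
      lon = rep(rep(env$lon, each = nlat), times = nm),
      value = as.vector(env$fields[[key]])
    )
  })
  readr::write_csv(dplyr::bind_rows(chunks), path)
  invisible(path)
}

#' Read climatology from the long-format CSV dialect
#'
#' Inverse of [write_climatology_csv()]; reconstructs the grid geometry and
#' the shared land mask (cells missing in every field/month).
#' @param path CSV path.
#' @return An `env_field_set`.
#' @export
read_climatology_csv <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("variable", "depth_m", "month", "lat", "lon", "value")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) stop("climatology CSV missing column(s): ", paste(miss, collapse = ", "))
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  months <- sort(unique(d$month))
  res <- if (length(lat) > 1) lat[2] - lat[1] else 360 / length(lon)
  nlat <- length(lat); nlon <- length(lon); nm <- length(months)
  fields <- list()
  for (key in predictor_ids()) {
    vd <- strsplit(key, "_(?=[0-9]+m$)", perl = TRUE)[[1]]
    sub <- d[d$variable == vd[1] & d$depth_m == as.numeric(sub("m$", "", vd[2])), ]
    if (nrow(sub) == 0) next
    arr <- array(NA_real_, dim = c(nlat, nlon, nm))
    ii <- match(sub$lat, lat)
    jj <- match(sub$lon, lon)
    mm <- match(sub$month, months)
    arr[cbind(ii, jj, mm)] <- sub$value
    fields[[key]] <- arr
  }
  mask <- Reduce(`&`, lapply(fields, function(a) apply(is.na(a), c(1, 2), all)))
  structure(list(lat = lat, lon = lon, months = as.integer(months),
                 resolution = res, mask = mask, fields = fields),
            class = "env_field_set")
}
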