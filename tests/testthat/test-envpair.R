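one_report <- function(lat, lon, month = 1L) {
  tibble::tibble(report_id = "r1", genus = "G", latitude = lat,
                 longitude = lon, month = month, year = 2022L,
                 source = "inaturalist")
}

test_that("pairing averages matching non-missing cells per variable-depth", {
  env <- uniform_env(10, lat_step = 5)
  r <- one_report(0.5, 0.5)
  prof <- pair_report(r, env, window = 5)
  expect_false(prof$unpairable)
  expect_true(all(prof$values == 10))

  # a field with exactly two matching cells, values 10 and 20 -> mean 15
  f <- env$fields$temperature_0m
  f[] <- NA_real_
  f[which(env$lat == 2.5), which(env$lon == 2.5), 1] <- 20
  f[which(env$lat == -2.5), which(env$lon == -2.5), 1] <- 10
  env$fields$temperature_0m <- f
  prof <- pair_report(r, env, window = 5)
  expect_equal(unname(prof$values["temperature_0m"]), 15)
  expect_identical(unname(prof$n_cells["temperature_0m"]), 2L)
  expect_equal(unname(prof$values["salinity_0m"]), 10)
})

test_that("longitude window wraps across the antimeridian (brute-force check)", {
  env <- tiny_env()
  r <- one_report(0.5, 179.5, month = 2L)
  w <- 12
  prof <- pair_report(r, env, w)
  # brute force over all cells, circular longitude distance
  cells <- expand.grid(i = seq_along(env$lat), j = seq_along(env$lon))
  dlon <- abs(((env$lon[cells$j] - r$longitude + 180) %% 360) - 180)
  keep <- abs(env$lat[cells$i] - r$latitude) <= w & dlon <= w
  mi <- match(2L, env$months)
  for (k in c("temperature_0m", "nitrate_20m")) {
    v <- env$fields[[k]][, , mi][as.matrix(cells[keep, ])]
    expect_equal(unname(prof$values[k]), mean(v, na.rm = TRUE))
  }
  # the kept set includes cells on the other side of the antimeridian
  expect_true(any(env$lon[cells$j[keep]] < -170))
})

test_that("pairing is translation-consistent under whole-cell longitude shifts", {
  env <- tiny_env()
  k <- 4   # cells
  shifted <- env
  idx <- ((seq_along(env$lon) - 1 - k) %% length(env$lon)) + 1
  for (f in names(env$fields)) shifted$fields[[f]] <- env$fields[[f]][, idx, , drop = FALSE]
  shifted$mask <- env$mask[, idx]
  r0 <- one_report(15, 20, month = 1L)
  r1 <- one_report(15, 20 + k * env$resolution, month = 1L)
  p0 <- pair_report(r0, env, window = 12)
  p1 <- pair_report(r1, shifted, window = 12)
  expect_equal(p0$values, p1$values)
})

test_that("widening the window only adds matched cells", {
  env <- tiny_env()
  r <- one_report(35.5, -20.2, month = 1L)
  narrow <- pair_report(r, env, window = 5)
  wide <- pair_report(r, env, window = 15)
  expect_true(all(wide$n_cells >= narrow$n_cells))
})

test_that("a report matching no ocean cell anywhere is flagged unpairable", {
  env <- uniform_env(10, lat_step = 5)
  for (f in names(env$fields)) env$fields[[f]][] <- NA_real_
  r <- one_report(0.5, 0.5)
  expect_true(pair_report(r, env, window = 5)$unpairable)
})

test_that("curated frame conserves report counts and refines with map_step", {
  env <- tiny_env()
  niches <- default_niches()[c("Cassiopea", "Rhizostoma")]
  reports <- round_reports(sample_reports(niches, env, uniform_effort(env),
                                          n_target = 150, seed = 31,
                                          sites_per_cell = NULL))
  fr2 <- build_frame(reports, env, map_step = 2, window = 10)
  paired_n <- nrow(reports) - attr(fr2, "n_unpairable")
  expect_identical(sum(fr2$Cassiopea) + sum(fr2$Rhizostoma), paired_n)
  expect_identical(sum(fr2$Cassiopea),
                   sum(reports$genus == "Cassiopea") -
                     sum(pair_reports(reports, env, 10)$unpairable &
                           reports$genus == "Cassiopea"))
  expect_true(all(fr2$Cassiopea + fr2$Rhizostoma >= 1))

  fr1 <- build_frame(reports, env, map_step = 1, window = 10)
  expect_gte(nrow(fr1), nrow(fr2))

  # two reports of one genus snapped to one cell-month accumulate there
  two <- dplyr::bind_rows(one_report(10.2, 10.2), one_report(10.4, 10.4))
  two$genus <- "Cassiopea"; two$report_id <- c("a", "b")
  f <- build_frame(two, env, map_step = 2, window = 10)
  expect_identical(nrow(f), 1L)
  expect_identical(f$Cassiopea, 2L)
})

test_that("row profiles equal the mean of member report profiles (brute force)", {
  env <- tiny_env()
  niches <- default_niches()["Cassiopea"]
  reports <- round_reports(sample_reports(niches, env, uniform_effort(env),
                                          n_target = 80, seed = 32,
                                          sites_per_cell = NULL))
  fr <- build_frame(reports, env, map_step = 2)
  paired <- pair_reports(reports, env, 2)
  keep <- !paired$unpairable
  reports <- reports[keep, ]; vals <- paired$values[keep, , drop = FALSE]
  snap <- function(x, lo, step) lo + (floor((x - lo) / step) + 0.5) * step
  mlat <- pmin(pmax(snap(reports$latitude, -90, 2), -89), 89)
  mlon <- snap(((reports$longitude + 180) %% 360) - 180, -180, 2)
  for (i in head(seq_len(nrow(fr)), 5)) {
    members <- which(mlat == fr$mapped_lat[i] & mlon == fr$mapped_lon[i] &
                       reports$month == fr$month[i])
    manual <- colMeans(vals[members, , drop = FALSE], na.rm = TRUE)
    manual[is.nan(manual)] <- NA_real_
    expect_equal(unlist(fr[i, names(manual)]), manual, tolerance = 1e-12)
  }
})

test_that("imputation completes predictor columns and records an audit trail", {
  fr <- synthetic_frame(50)
  fr$temperature_0m[c(3, 7)] <- NA
  imp <- impute_frame(fr)
  expect_false(anyNA(imp$temperature_0m))
  expect_equal(imp$temperature_0m[3], median(fr$temperature_0m, na.rm = TRUE))
  expect_identical(which(imp$.imputed), c(3L, 7L))
  expect_identical(attr(imp, "imputation"), c(temperature_0m = 2L))
})
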