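test_that("environment generator produces the requested grid geometry", {
  env <- make_environment(1, lat_step = 2, months = 1L, land_fraction = 0.3)
  expect_length(env$lat, 90)
  expect_length(env$lon, 180)
  expect_length(env$fields, 28)
  expect_identical(dim(env$fields$temperature_0m), c(90L, 180L, 1L))
  expect_setequal(names(env$fields), predictor_ids())

  expect_error(make_environment(1, lat_step = 7), "lat_step")
  expect_error(make_environment(1, months = integer(0)), "months")
})

test_that("environment generation is bit-reproducible and masks land everywhere", {
  a <- make_environment(5, lat_step = 10, months = 1:2)
  b <- make_environment(5, lat_step = 10, months = 1:2)
  expect_identical(a, b)

  env <- tiny_env()
  masked <- which(env$mask)
  for (k in names(env$fields)) {
    for (m in seq_along(env$months)) {
      slice <- env$fields[[k]][, , m]
      expect_true(all(is.na(slice[masked])), info = k)
      expect_true(all(!is.na(slice[-masked])), info = k)
    }
  }
})

test_that("fields vary across depth and month", {
  env <- tiny_env()
  expect_gt(max(abs(env$fields$temperature_0m - env$fields$temperature_20m),
                na.rm = TRUE), 0.5)
  expect_gt(max(abs(env$fields$temperature_0m[, , 1] -
                    env$fields$temperature_0m[, , 2]), na.rm = TRUE), 0.1)
})

test_that("report sampling is seeded, ocean-only, and intensity-driven", {
  env <- tiny_env()
  niches <- list(niche_spec("Testus", list(temperature_0m = c(25, 3))))
  eff <- uniform_effort(env)

  r1 <- sample_reports(niches, env, eff, n_target = 200, seed = 9)
  r2 <- sample_reports(niches, env, eff, n_target = 200, seed = 9)
  expect_identical(r1, r2)
  expect_gt(nrow(r1), 0)
  expect_true(all(r1$source == "inaturalist"))
  expect_true(all(r1$month %in% env$months))

  # no report may come from a land cell
  ilat <- findInterval(r1$latitude, seq(-90, 90, by = env$resolution),
                       rightmost.closed = TRUE)
  ilon <- findInterval(r1$longitude, seq(-180, 180, by = env$resolution),
                       rightmost.closed = TRUE)
  expect_false(any(env$mask[cbind(ilat, ilon)]))

  # all-zero effort: zero intensity, flagged, no reports
  dead <- structure(list(weight = matrix(0, length(env$lat), length(env$lon))),
                    class = "participation_surface")
  expect_warning(r0 <- sample_reports(niches, env, dead, n_target = 50, seed = 1),
                 "zero total intensity")
  expect_identical(nrow(r0), 0L)
})

test_that("reports concentrate within the niche kernel (~2 sd contains >= 90%)", {
  env <- tiny_env()
  niches <- list(niche_spec("Testus", list(temperature_20m = c(25, 1))))
  r <- sample_reports(niches, env, uniform_effort(env), n_target = 600,
                      seed = 11, sites_per_cell = NULL)
  expect_gt(nrow(r), 300)
  ilat <- findInterval(r$latitude, seq(-90, 90, by = env$resolution),
                       rightmost.closed = TRUE)
  ilon <- findInterval(r$longitude, seq(-180, 180, by = env$resolution),
                       rightmost.closed = TRUE)
  im <- match(r$month, env$months)
  temp <- env$fields$temperature_20m[cbind(ilat, ilon, im)]
  expect_gte(mean(abs(temp - 25) <= 2), 0.90)
})

test_that("expected report counts increase with base_rate", {
  env <- tiny_env()
  eff <- uniform_effort(env)
  total_for <- function(rate) {
    niches <- list(niche_spec("Testus", list(temperature_0m = c(25, 3)),
                              base_rate = rate))
    sum(vapply(1:5, function(s) {
      nrow(sample_reports(niches, env, eff, n_target = NULL, seed = s))
    }, double(1)))
  }
  expect_lt(total_for(0.2), total_for(1.0))
})

test_that("legacy sampling is uniform-effort, tagged, and empty at n = 0", {
  env <- tiny_env()
  niches <- default_niches()[c("Cassiopea", "Rhizostoma")]
  expect_identical(nrow(sample_legacy(niches, env, n = 0, seed = 1)), 0L)
  leg <- sample_legacy(niches, env, n = 100, seed = 3)
  expect_true(all(leg$source == "legacy"))
  expect_setequal(unique(leg$genus), c("Cassiopea", "Rhizostoma"))
})

test_that("legacy records mostly fall inside an envelope built from report data", {
  env <- tiny_env()
  sel <- c("temperature_0m", "salinity_0m")
  niches <- list(niche_spec("Testus",
                            list(temperature_0m = c(24, 2), salinity_0m = c(34.8, 0.4))))
  cellvals <- function(r) {
    ilat <- findInterval(r$latitude, seq(-90, 90, by = env$resolution),
                         rightmost.closed = TRUE)
    ilon <- findInterval(r$longitude, seq(-180, 180, by = env$resolution),
                         rightmost.closed = TRUE)
    im <- match(r$month, env$months)
    data.frame(temperature_0m = env$fields$temperature_0m[cbind(ilat, ilon, im)],
               salinity_0m = env$fields$salinity_0m[cbind(ilat, ilon, im)])
  }
  train <- sample_reports(niches, env, uniform_effort(env), n_target = 800,
                          seed = 21, sites_per_cell = NULL)
  envp <- build_envelope(cellvals(train), sel)
  leg <- sample_legacy(niches, env, n = 500, seed = 22, sites_per_cell = NULL)
  v <- cellvals(leg)
  inside <- v$temperature_0m >= envp$bounds$lower[1] &
    v$temperature_0m <= envp$bounds$upper[1] &
    v$salinity_0m >= envp$bounds$lower[2] &
    v$salinity_0m <= envp$bounds$upper[2]
  # expectation >= 0.9^2 for two independent central-90% marginals;
  # allow Monte-Carlo slack at this sample size
  expect_gte(mean(inside), 0.78)
})

test_that("climatology CSV dialect round-trips the field set", {
  env <- make_environment(3, lat_step = 30, months = 1:2, land_fraction = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_climatology_csv(env, path)
  back <- read_climatology_csv(path)
  expect_equal(back$lat, env$lat)
  expect_equal(back$lon, env$lon)
  expect_equal(back$months, env$months)
  expect_equal(back$mask, env$mask, ignore_attr = TRUE)
  expect_equal(back$fields$nitrate_20m, env$fields$nitrate_20m, tolerance = 1e-12)
})
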