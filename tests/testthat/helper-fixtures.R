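# Shared fixtures, built once per test run. Small grids keep the suite fast;
# anything statistical uses fixed seeds.

# Coarse global environment: 18 x 36 cells at 10 degrees, 3 months.
tiny_env <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_environment(42, lat_step = 10, months = 1:3,
                                                   land_fraction = 0.2)
    cache
  }
})

# Environment with every field constant (ocean) — handy for exact pairing
# and envelope arithmetic.
uniform_env <- function(value = 10, lat_step = 10, months = 1L,
                        land_fraction = 0) {
  env <- make_environment(1, lat_step = lat_step, months = months,
                          land_fraction = land_fraction, noise_amp = 0)
  for (k in names(env$fields)) {
    f <- env$fields[[k]]
    f[!is.na(f)] <- value
    env$fields[[k]] <- f
  }
  env
}

uniform_effort <- function(env) participation_surface(env, "uniform")

# Hand-built curated frame: `n` rows, genus count columns driven by the
# named predictors, remaining predictors pure noise.
synthetic_frame <- function(n = 200, genera = c("Alpha", "Beta", "Gamma"),
                            seed = 1) {
  withr::with_seed(seed, {
    preds <- predictor_ids()
    X <- as.data.frame(matrix(rnorm(n * length(preds)), n,
                              dimnames = list(NULL, preds)))
    counts <- lapply(seq_along(genera), function(k) {
      mu <- exp(0.5 + 0.8 * X[[preds[k]]])
      as.integer(MASS::rnegbin(n, mu = mu, theta = 2))
    })
    names(counts) <- genera
    frame <- tibble::as_tibble(cbind(
      data.frame(mapped_lat = round(runif(n, -80, 80)),
                 mapped_lon = round(runif(n, -170, 170)), month = 1L,
                 n_reports = 1L),
      as.data.frame(counts), X
    ))
    # guarantee the frame invariant: every row has a positive count somewhere
    allzero <- rowSums(as.data.frame(counts)) == 0
    frame[[genera[1]]][allzero] <- 1L
    structure(frame, genera = genera, predictors = preds)
  })
}
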