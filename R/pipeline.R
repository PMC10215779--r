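# End-to-end orchestration: configuration, seeded execution of every stage,
# artifact serialization, and the 1 vs 2 degree robustness comparison.
# Every filter logs counts, because occurrence bookkeeping drifts easily.

#' Build a run configuration
#'
#' All tunables and every seed for the pipeline, as a plain list that
#' round-trips through YAML unchanged.
#'
#' @param ... Overrides of the defaults (see the returned object's names).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seeds = list(synth = 101L, legacy = 102L, split = 202L, rf = 303L, perm = 404L),
    lat_step = 2, months = 1:12, land_fraction = 0.3, smooth_cells = 3,
    effort = "western", n_target = 600, n_legacy = 60,
    genera = rhizostome_genera(),
    window = 2, map_step = 2, collapse_months = FALSE,
    sc_threshold = 0.95,
    n_resamples = 199, alpha = 0.05, p_adjust = "none",
    n_trees = 500, train_fraction = 0.8,
    central_fraction = 0.90, month_mode = "any_month",
    tolerance = 0, area_flag_threshold = 0.5,
    reports_csv = NULL, legacy_csv = NULL, climatology_csv = NULL
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML path.
#' @return `read_config()` returns the `run_config`; writing returns the
#'   path invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  structure(yaml::read_yaml(path), class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (unless input CSVs are configured) -> ingest ->
#' coverage screening -> environmental pairing -> multivariate GLM niche
#' test -> random forests -> envelopes and suitability -> legacy
#' evaluation, writing every intermediate artifact and a machine-readable
#' manifest into `out_dir`. Fully deterministic for a fixed config: a rerun
#' reproduces the CSV outputs byte for byte.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the main in-memory results and artifact
#'   paths.
#' @export
run_all <- function(config, out_dir) {
  # normalize path fields that YAML/JSON round trips may turn into empty lists
  for (f in c("reports_csv", "legacy_csv", "climatology_csv")) {
    if (!is.character(config[[f]]) || length(config[[f]]) != 1) config[f] <- list(NULL)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "input"), showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  env <- with_stage("environment", {
    if (!is.null(config$climatology_csv)) {
      read_climatology_csv(config$climatology_csv)
    } else {
      make_environment(config$seeds$synth, lat_step = config$lat_step,
                       months = config$months,
                       land_fraction = config$land_fraction,
                       smooth_cells = config$smooth_cells)
    }
  })

  with_stage("simulate", {
    if (is.null(config$reports_csv)) {
      niches <- default_niches()[config$genera]
      effort <- participation_surface(env, config$effort)
      reports_raw <- sample_reports(niches, env, effort,
                                    n_target = config$n_target,
                                    seed = config$seeds$synth)
      legacy_raw <- sample_legacy(niches, env, n = config$n_legacy,
                                  seed = config$seeds$legacy)
      write_reports_csv(reports_raw, p("input", "reports.csv"))
      write_legacy_csv(legacy_raw, p("input", "legacy.csv"))
      config$reports_csv <- p("input", "reports.csv")
      config$legacy_csv <- p("input", "legacy.csv")
    }
  })

  ing <- with_stage("ingest", {
    if (!file.exists(config$reports_csv)) stop("missing input: ", config$reports_csv)
    rr <- read_reports(config$reports_csv, "inaturalist")
    reports <- round_reports(filter_taxonomy(rr$reports, config$genera))
    lr <- read_reports(config$legacy_csv, "legacy")
    legacy <- round_reports(filter_taxonomy(lr$reports, config$genera))
    list(reports = reports, legacy = legacy,
         n_rejected = nrow(rr$rejected), n_rejected_legacy = nrow(lr$rejected))
  })

  coverage <- with_stage("coverage", {
    cov <- retain_genera(ing$reports, threshold = config$sc_threshold)
    readr::write_csv(cov, p("coverage.csv"))
    cov
  })
  retained <- coverage$genus[coverage$retained]
  if (length(retained) < 2) stop("stage 'coverage' retained fewer than 2 genera")
  reports <- ing$reports[ing$reports$genus %in% retained, ]

  frame <- with_stage("envpair", {
    fr <- impute_frame(build_frame(reports, env, map_step = config$map_step,
                                   window = config$window,
                                   collapse_months = config$collapse_months))
    readr::write_csv(fr, p("curated_frame.csv"))
    fr
  })

  glm_res <- with_stage("niche_glm", {
    mv <- manyglm_test(frame, n_resamples = config$n_resamples,
                       seed = config$seeds$perm)
    bp <- niche_biplot(mv)
    lat_groups <- kruskal_dunn_letters(reports$latitude, reports$genus,
                                       alpha = config$alpha,
                                       p_adjust = config$p_adjust)
    lon_groups <- kruskal_dunn_letters(reports$longitude, reports$genus,
                                       alpha = config$alpha,
                                       p_adjust = config$p_adjust)
    readr::write_csv(tibble::as_tibble(mv$coefficients, rownames = "genus"),
                     p("glm_coefficients.csv"))
    write_json_artifact(list(
      statistic = mv$statistic, p_value = mv$p_value,
      n_resamples = mv$n_resamples, warnings = mv$warnings,
      latitude = list(chisq = lat_groups$chisq, p_value = lat_groups$p_value,
                      letters = as.list(lat_groups$letters)),
      longitude = list(chisq = lon_groups$chisq, p_value = lon_groups$p_value,
                       letters = as.list(lon_groups$letters))
    ), p("glm_summary.json"))
    list(mv = mv, biplot = bp, lat = lat_groups, lon = lon_groups)
  })

  rf <- with_stage("rfm", {
    lt <- build_labels(frame)
    res <- rfm_all(lt, split_seed = config$seeds$split,
                   rf_seed = config$seeds$rf, n_trees = config$n_trees,
                   train_fraction = config$train_fraction)
    readr::write_csv(res$summary, p("rf_summary.csv"))
    readr::write_csv(res$importance, p("rf_importance.csv"))
    write_json_artifact(res$selected, p("rf_selected.json"))
    res
  })

  pred <- with_stage("envelope", {
    envelopes <- list(); maps <- list()
    for (g in names(rf$selected)) {
      sel <- rf$selected[[g]]
      if (length(sel) == 0) next
      pos <- frame[frame[[g]] > 0, , drop = FALSE]
      envelopes[[g]] <- build_envelope(pos, sel,
                                       central_fraction = config$central_fraction,
                                       genus = g)
      maps[[g]] <- predict_suitable(env, envelopes[[g]],
                                    month_mode = config$month_mode)
    }
    env_tab <- dplyr::bind_rows(lapply(envelopes, function(e) {
      dplyr::mutate(e$bounds, genus = e$genus, .before = 1)
    }))
    readr::write_csv(env_tab, p("envelopes.csv"))
    suit_tab <- dplyr::bind_rows(lapply(maps, function(m) {
      s <- static_mask(m)
      ix <- which(s, arr.ind = TRUE)
      tibble::tibble(genus = m$genus, lat = m$lat[ix[, 1]], lon = m$lon[ix[, 2]])
    }))
    readr::write_csv(suit_tab, p("suitability.csv"))
    list(envelopes = envelopes, maps = maps)
  })

  acc <- with_stage("evaluate", {
    rows <- list()
    for (g in names(pred$maps)) {
      leg <- ing$legacy[ing$legacy$genus == g, ]
      if (nrow(leg) == 0) next
      rows[[g]] <- legacy_accuracy(pred$maps[[g]], leg, tolerance = config$tolerance)
    }
    rep <- accuracy_report(dplyr::bind_rows(rows), pred$maps,
                           area_flag_threshold = config$area_flag_threshold)
    readr::write_csv(rep, p("accuracy.csv"))
    rep
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("rhizoniche")),
    config = unclass(config),
    counts = list(
      reports_read = nrow(ing$reports) + ing$n_rejected,
      reports_rejected = ing$n_rejected,
      reports_after_taxonomy = nrow(ing$reports),
      legacy_records = nrow(ing$legacy),
      genera_screened = nrow(coverage),
      genera_retained = length(retained),
      reports_retained_genera = nrow(reports),
      frame_rows = nrow(frame),
      frame_rows_imputed = sum(frame$.imputed),
      reports_unpairable = attr(frame, "n_unpairable") %||% 0L,
      genera_modelled = length(pred$maps),
      genera_evaluated = nrow(acc)
    )
  )
  write_json_artifact(manifest, p("manifest.json"))

  invisible(list(env = env, reports = reports, legacy = ing$legacy,
                 coverage = coverage, frame = frame, glm = glm_res,
                 rf = rf, envelopes = pred$envelopes, maps = pred$maps,
                 accuracy = acc, manifest = manifest, out_dir = out_dir))
}

#' Compare niche models at 1 vs 2 degree mapping
#'
#' Rebuilds the curated frame at both mapping resolutions from the same
#' reports, fits the multivariate GLM at each, and reports the Procrustes
#' correlation between the two biplot configurations alongside both
#' permutation p-values. A correlation near 1 means the coarser mapping
#' does not change the niche-model interpretation.
#'
#' @param config A `run_config` (its `map_step` is ignored; 1 and 2 are
#'   used).
#' @return List with `correlation` (Procrustes), `p_value_1deg`,
#'   `p_value_2deg`, `biplots`, and the two `mv_glm_result`s.
#' @export
robustness_check <- function(config) {
  env <- make_environment(config$seeds$synth, lat_step = config$lat_step,
                          months = config$months,
                          land_fraction = config$land_fraction,
                          smooth_cells = config$smooth_cells)
  niches <- default_niches()[config$genera]
  effort <- participation_surface(env, config$effort)
  reports <- round_reports(sample_reports(niches, env, effort,
                                          n_target = config$n_target,
                                          seed = config$seeds$synth))
  fit_at <- function(step) {
    frame <- impute_frame(build_frame(reports, env, map_step = step,
                                      window = config$window,
                                      collapse_months = config$collapse_months))
    if (nrow(frame) < 2) stop("degenerate frame at map_step = ", step,
                              " (", nrow(frame), " row)")
    mv <- manyglm_test(frame, n_resamples = config$n_resamples,
                       seed = config$seeds$perm)
    list(mv = mv, biplot = niche_biplot(mv))
  }
  r1 <- fit_at(1)
  r2 <- fit_at(2)
  common <- intersect(rownames(r1$biplot$scores), rownames(r2$biplot$scores))
  pro <- vegan::protest(r1$biplot$scores[common, ], r2$biplot$scores[common, ],
                        permutations = 199)
  list(correlation = unname(pro$t0), p_value_1deg = r1$mv$p_value,
       p_value_2deg = r2$mv$p_value,
       biplots = list(deg1 = r1$biplot, deg2 = r2$biplot),
       mv = list(deg1 = r1$mv, deg2 = r2$mv))
}
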