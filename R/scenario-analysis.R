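#' Configuration for one accessibility scenario
#'
#' A scenario is defined by which facilities may serve patients (the
#' observed provider subset in the actual scenario; every hospital and
#' clinic in the ideal scenario), how many Monte-Carlo patient-placement
#' trials to run, and the exceedance thresholds: 16 km, the reference limit
#' on home-visit travel distance in the national fee table, and 30 min of
#' travel time.
#'
#' @param name `"actual"`, `"ideal"`, or a custom label.
#' @param providers_only restrict to facilities with `is_provider = TRUE`;
#'   defaults to `TRUE` when `name == "actual"`, else `FALSE`.
#' @param n_trials number of repeated patient draws (default 10).
#' @param seed master seed for patient generation.
#' @param distance_threshold_km exceedance threshold on distance (km).
#' @param time_threshold_min exceedance threshold on time (minutes).
#' @param model a [cost_model()].
#' @param allocation_mode see [allocate_to_meshes()].
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name = c("actual", "ideal"),
                            providers_only = NULL,
                            n_trials = 10, seed = 1,
                            distance_threshold_km = 16,
                            time_threshold_min = 30,
                            model = cost_model(),
                            allocation_mode = "multinomial") {
  name <- if (is.character(name) && length(name) == 1) name else match.arg(name)
  if (is.null(providers_only)) providers_only <- identical(name, "actual")
  stopifnot(n_trials >= 1, distance_threshold_km > 0, time_threshold_min > 0)
  structure(
    list(name = name, providers_only = providers_only,
         n_trials = as.integer(n_trials), seed = seed,
         distance_threshold_km = distance_threshold_km,
         time_threshold_min = time_threshold_min,
         model = model, allocation_mode = allocation_mode),
    class = "scenario_config"
  )
}

select_facilities <- function(region, providers_only) {
  f <- region$facilities
  if (providers_only) f <- f[f$is_provider, , drop = FALSE]
  if (nrow(f) == 0) stop(region_error("scenario selects no facilities"))
  f
}

#' Run one scenario over repeated patient draws
#'
#' For each trial, generates hypothetical patients and computes each
#' patient's closest facility and travel cost against the scenario's
#' facility set; results are pooled across trials with trial labels.
#' Because patient draws depend only on (seed, trial, municipality), two
#' scenarios run with the same seed see identical patients, so their
#' contrast is a pure facility-set effect.
#'
#' @param region a `study_region`.
#' @param patient_counts per-municipality patient counts (named vector or
#'   tibble with `municipality_id`, `n_patients`).
#' @param config a [scenario_config()].
#' @return tibble of pooled access results, one row per patient x trial.
#' @export
run_scenario <- function(region, patient_counts, config = scenario_config()) {
  fac <- select_facilities(region, config$providers_only)
  res <- lapply(seq_len(config$n_trials), function(t) {
    pts <- generate_trial(region, patient_counts, t, config$seed,
                          mode = config$allocation_mode)
    nearest_facility(pts, fac, region$network, config$model)
  })
  dplyr::bind_rows(res)
}

#' Per-municipality accessibility summary
#'
#' Aggregates pooled access results into one row per municipality plus a
#' prefecture-wide row (`municipality_id = "(prefecture)"`): median and
#' 25-75 percentiles of travel distance (km) and time (min), computed by
#' linear interpolation (quantile type 7) over reachable observations
#' pooled across trials, and exceedance rates using strict inequality
#' ("over 16 km", "longer than 30 minutes"). Unreachable patients are
#' excluded from the percentiles but counted as exceeding any threshold in
#' the rate numerators and denominators; their count is reported.
#' Municipalities with no observations get a row of missing markers.
#'
#' @param results pooled access results from [run_scenario()] or
#'   [nearest_facility()] (must carry `municipality_id`).
#' @param region optional `study_region`; when given, every municipality
#'   appears in the output even with zero observations.
#' @param distance_threshold_km threshold for the distance exceedance rate.
#' @param time_threshold_min threshold for the time exceedance rate.
#' @return tibble with columns `municipality_id`, `n_patient_obs`,
#'   `n_unreachable`, `median_distance_km`, `p25_distance_km`,
#'   `p75_distance_km`, `median_time_min`, `p25_time_min`, `p75_time_min`,
#'   `rate_over_dist`, `rate_over_time`.
#' @export
summarize_access <- function(results, region = NULL,
                             distance_threshold_km = 16,
                             time_threshold_min = 30) {
  stopifnot(nrow(results) > 0)
  ids <- if (!is.null(region)) region$municipalities$id else
    sort(unique(results$municipality_id))
  one <- function(sub) {
    n <- nrow(sub)
    if (n == 0) {
      return(tibble::tibble(
        n_patient_obs = 0L, n_unreachable = 0L,
        median_distance_km = NA_real_, p25_distance_km = NA_real_,
        p75_distance_km = NA_real_, median_time_min = NA_real_,
        p25_time_min = NA_real_, p75_time_min = NA_real_,
        rate_over_dist = NA_real_, rate_over_time = NA_real_
      ))
    }
    reach <- sub[sub$reachable, , drop = FALSE]
    n_unreach <- n - nrow(reach)
    qd <- if (nrow(reach) > 0)
      quantile(reach$network_distance_m / 1000, c(.25, .5, .75),
               type = 7, names = FALSE) else rep(NA_real_, 3)
    qt <- if (nrow(reach) > 0)
      quantile(reach$travel_time_min, c(.25, .5, .75),
               type = 7, names = FALSE) else rep(NA_real_, 3)
    tibble::tibble(
      n_patient_obs = n, n_unreachable = n_unreach,
      median_distance_km = qd[2], p25_distance_km = qd[1],
      p75_distance_km = qd[3],
      median_time_min = qt[2], p25_time_min = qt[1], p75_time_min = qt[3],
      rate_over_dist =
        (sum(reach$network_distance_m / 1000 > distance_threshold_km) +
           n_unreach) / n,
      rate_over_time =
        (sum(reach$travel_time_min > time_threshold_min) + n_unreach) / n
    )
  }
  rows <- lapply(ids, function(id)
    one(results[results$municipality_id == id, , drop = FALSE]))
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(municipality_id = ids), out)
  pref <- dplyr::bind_cols(tibble::tibble(municipality_id = "(prefecture)"),
                           one(results))
  dplyr::bind_rows(out, pref)
}

#' Compare two scenario summaries
#'
#' Per-municipality differences (first summary minus second; by convention
#' actual minus ideal) for every summary statistic present in both tables,
#' ranked by the travel-time median difference where available. With the
#' provider set nested in the full facility set and identical patient
#' draws, every difference is non-negative: the gap measures how much
#' accessibility would improve if all facilities provided the service.
#'
#' @param summary_actual,summary_ideal tibbles with `municipality_id` and
#'   any of the statistic columns of [summarize_access()] (a minimal table
#'   with just `municipality_id` and `median_time_min` works).
#' @return tibble of `municipality_id` and `delta_*` columns, one per
#'   shared statistic, sorted by decreasing time-median difference.
#' @export
compare_scenarios <- function(summary_actual, summary_ideal) {
  a <- tibble::as_tibble(summary_actual)
  b <- tibble::as_tibble(summary_ideal)
  if (!setequal(a$municipality_id, b$municipality_id)) {
    stop(region_error("scenario summaries cover different municipalities"))
  }
  stats <- intersect(
    c("median_time_min", "median_distance_km",
      "rate_over_dist", "rate_over_time",
      "p25_time_min", "p75_time_min", "p25_distance_km", "p75_distance_km"),
    intersect(names(a), names(b))
  )
  if (length(stats) == 0) stop(region_error("no shared statistic columns to compare"))
  idx <- match(a$municipality_id, b$municipality_id)
  out <- tibble::tibble(municipality_id = a$municipality_id)
  for (s in stats) out[[paste0("delta_", s)]] <- a[[s]] - b[[s]][idx]
  key <- intersect(c("delta_median_time_min", paste0("delta_", stats[1])),
                   names(out))[1]
  out[order(-out[[key]]), , drop = FALSE]
}

#' Run the complete actual-vs-ideal accessibility study
#'
#' End-to-end driver: resolves the region and claims (from in-memory
#' objects, an input directory, or the built-in synthetic generator),
#' derives per-municipality patient counts from the claims, draws patients
#' for each trial once and evaluates both facility sets on the same draws,
#' then emits per-municipality summaries, the scenario comparison, the
#' usage table, and a run log. The patientwise monotonicity invariant
#' (ideal cost never exceeds actual cost) is asserted on every run.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   * `region` / `claims` — in-memory `study_region` and claims tibble, or
#'   * `input_dir` — directory with the region layers and `claims.csv`, or
#'   * `generator` — parameter list passed to [generator_params()];
#'   * `n_trials` (default 10), `seed` (default 1),
#'     `distance_threshold_km` (16), `time_threshold_min` (30),
#'     `objective` (`"time"`), `allocation_mode` (`"multinomial"`),
#'     `min_age` (75), `fiscal_year` (2019), `codes` (the eight defaults).
#' @param output_dir optional directory; when given, all tables are written
#'   as CSV together with `run_log.yaml`.
#' @return a list of class `study_report`: `usage`, `results` (pooled, with
#'   `scenario` column), `summary_actual`, `summary_ideal`,
#'   `summary_per_trial`, `comparison`, `log`.
#' @export
run_full_study <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(n_trials = 10, seed = 1, distance_threshold_km = 16,
         time_threshold_min = 30, objective = "time",
         allocation_mode = "multinomial", min_age = 75, fiscal_year = 2019,
         codes = home_care_service_codes()),
    config
  )

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(region_error(paste0("stage ", what, ": ", conditionMessage(e))))
    })
  }

  if (!is.null(cfg$region)) {
    region <- cfg$region; claims <- cfg$claims
  } else if (!is.null(cfg$input_dir)) {
    region <- stage("load_region", load_region(cfg$input_dir))
    claims <- stage("load_claims", readr::read_csv(
      file.path(cfg$input_dir, "claims.csv"),
      show_col_types = FALSE, progress = FALSE))
  } else if (!is.null(cfg$generator)) {
    gen <- stage("generate", {
      params <- do.call(generator_params, cfg$generator)
      r <- generate_region(params)
      list(region = r$region,
           claims = generate_claims(r$region, r$ground_truth, params))
    })
    region <- gen$region; claims <- gen$claims
  } else {
    stop(region_error("config must provide region/claims, input_dir, or generator"))
  }

  rule <- qualifying_rule(cfg$codes, cfg$min_age, cfg$fiscal_year)
  usage <- stage("usage_summary", usage_summary(claims, rule, region))
  counts <- usage[, c("municipality_id", "n_patients")]

  model <- cost_model(objective = cfg$objective)
  fac_actual <- select_facilities(region, providers_only = TRUE)
  fac_ideal <- select_facilities(region, providers_only = FALSE)

  res_a <- list(); res_i <- list()
  for (t in seq_len(cfg$n_trials)) {
    pts <- stage("generate_trial",
                 generate_trial(region, counts, t, cfg$seed,
                                mode = cfg$allocation_mode))
    res_a[[t]] <- nearest_facility(pts, fac_actual, region$network, model)
    res_i[[t]] <- nearest_facility(pts, fac_ideal, region$network, model)
  }
  res_a <- dplyr::bind_rows(res_a); res_i <- dplyr::bind_rows(res_i)

  obj_col <- if (cfg$objective == "time") "travel_time_min" else
    "network_distance_m"
  if (any(res_i[[obj_col]] > res_a[[obj_col]] + 1e-9)) {
    stop(region_error(
      "monotonicity violated: ideal cost exceeds actual cost for a patient"))
  }

  sum_a <- summarize_access(res_a, region, cfg$distance_threshold_km,
                            cfg$time_threshold_min)
  sum_i <- summarize_access(res_i, region, cfg$distance_threshold_km,
                            cfg$time_threshold_min)
  per_trial <- dplyr::bind_rows(lapply(seq_len(cfg$n_trials), function(t) {
    dplyr::bind_rows(
      dplyr::mutate(summarize_access(res_a[res_a$trial == t, ], region,
                                     cfg$distance_threshold_km,
                                     cfg$time_threshold_min),
                    scenario = "actual", trial = t),
      dplyr::mutate(summarize_access(res_i[res_i$trial == t, ], region,
                                     cfg$distance_threshold_km,
                                     cfg$time_threshold_min),
                    scenario = "ideal", trial = t)
    )
  }))
  comparison <- compare_scenarios(sum_a, sum_i)

  report <- structure(list(
    usage = usage,
    results = dplyr::bind_rows(
      dplyr::mutate(res_a, scenario = "actual"),
      dplyr::mutate(res_i, scenario = "ideal")
    ),
    summary_actual = sum_a,
    summary_ideal = sum_i,
    summary_per_trial = per_trial,
    comparison = comparison,
    log = list(
      seed = cfg$seed, n_trials = cfg$n_trials,
      objective = cfg$objective, allocation_mode = cfg$allocation_mode,
      distance_threshold_km = cfg$distance_threshold_km,
      time_threshold_min = cfg$time_threshold_min,
      n_facilities_actual = nrow(fac_actual),
      n_facilities_ideal = nrow(fac_ideal),
      n_patients_per_trial = sum(counts$n_patients),
      n_unreachable_actual = sum(!res_a$reachable),
      n_unreachable_ideal = sum(!res_i$reachable)
    )
  ), class = "study_report")

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    readr::write_csv(report$usage, file.path(output_dir, "usage.csv"), progress = FALSE)
    readr::write_csv(report$results, file.path(output_dir, "access_results.csv"), progress = FALSE)
    readr::write_csv(report$summary_actual, file.path(output_dir, "summary_actual.csv"), progress = FALSE)
    readr::write_csv(report$summary_ideal, file.path(output_dir, "summary_ideal.csv"), progress = FALSE)
    readr::write_csv(report$summary_per_trial, file.path(output_dir, "summary_per_trial.csv"), progress = FALSE)
    readr::write_csv(report$comparison, file.path(output_dir, "comparison.csv"), progress = FALSE)
    yaml::write_yaml(report$log, file.path(output_dir, "run_log.yaml"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  trials:", x$log$n_trials, " patients/trial:",
      x$log$n_patients_per_trial, "\n")
  cat("  facilities: actual", x$log$n_facilities_actual, "/ ideal",
      x$log$n_facilities_ideal, "\n")
  pref_a <- x$summary_actual[x$summary_actual$municipality_id == "(prefecture)", ]
  pref_i <- x$summary_ideal[x$summary_ideal$municipality_id == "(prefecture)", ]
  cat(sprintf("  prefecture median time: actual %.1f min / ideal %.1f min\n",
              pref_a$median_time_min, pref_i$median_time_min))
  top <- x$comparison[x$comparison$municipality_id != "(prefecture)", ][1, ]
  cat(sprintf("  largest time gap: %s (%.1f min)\n",
              top$municipality_id, top$delta_median_time_min))
  invisible(x)
}
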