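# End-to-end pipeline: (simulate or read) -> segment -> metrics -> curate ->
# statistics -> figures, with a manifest that fully determines a rerun on
# simulated inputs.

#' Curate a cohort
#'
#' Applies the quality-control rules, each fly independently (excluding one
#' triplet member never drops its partners): a fly is excluded when it was
#' inactive for strictly more than `inactivity_threshold` of the Pre-test
#' (a fly inactive exactly 90% of the time is retained), when its attribute
#' record is incomplete, or when a procedure error was flagged. Every
#' exclusion carries one primary reason, in that order of precedence.
#'
#' @param records Fly records (see [read_attributes()]).
#' @param metrics Session metrics from [metrics_table()]; every fly must
#'   have a Pre-test row.
#' @param inactivity_threshold Pre-test inactivity fraction above which a
#'   fly is excluded (strict inequality).
#' @return A `curation_report`: tibble with `fly_id`, `retained`, `reason`
#'   (NA when retained) and `pretest_activity`; the threshold is an
#'   attribute.
#' @export
curate <- function(records, metrics, inactivity_threshold = 0.90) {
  pre <- metrics[metrics$session == "Pre-test", c("fly_id", "activity_level")]
  missing_pre <- setdiff(records$fly_id, pre$fly_id)
  if (length(missing_pre))
    metrics_error(sprintf("fly '%s' has no Pre-test session", missing_pre[1]))
  rep <- dplyr::left_join(
    records[, c("fly_id", "attribute_complete", "procedure_error")],
    pre, by = "fly_id")
  rep <- dplyr::mutate(
    rep,
    reason = dplyr::case_when(
      (1 - .data$activity_level) > inactivity_threshold ~ "pretest-inactivity",
      !.data$attribute_complete ~ "attribute-missing",
      .data$procedure_error ~ "procedure-error-flag",
      TRUE ~ NA_character_
    ),
    retained = is.na(.data$reason)
  )
  out <- tibble::tibble(
    fly_id = rep$fly_id,
    retained = rep$retained,
    reason = rep$reason,
    pretest_activity = rep$activity_level
  )
  attr(out, "inactivity_threshold") <- inactivity_threshold
  class(out) <- c("curation_report", class(out))
  out
}

#' Pipeline run configuration
#'
#' Bundles all parameters of a run: simulator, protocol, analysis, cohort
#' size and seed, and (optionally) an input directory of recorded traces
#' instead of simulation.
#'
#' @param sim A [sim_config()].
#' @param protocol A [protocol_spec()].
#' @param analysis An [analysis_config()].
#' @param seed Root seed of the run.
#' @param n_triplets Cohort size when simulating.
#' @param input_dir Optional directory of trace CSVs; when given, traces are
#'   read instead of simulated.
#' @param attributes Attribute CSV path (defaults to
#'   `input_dir/attributes.csv`).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), protocol = protocol_spec(),
                       analysis = analysis_config(), seed = sim$seed,
                       n_triplets = sim$n_triplets,
                       input_dir = NULL, attributes = NULL) {
  structure(
    list(sim = sim, protocol = protocol, analysis = analysis,
         seed = as.integer(seed), n_triplets = as.integer(n_triplets),
         input_dir = input_dir,
         attributes = attributes %||%
           (if (!is.null(input_dir)) file.path(input_dir, "attributes.csv"))),
    class = "run_config"
  )
}

flatten_config <- function(config) {
  drop <- function(x, omit) x[setdiff(names(x), omit)]
  c(drop(unclass(config$sim), c("controller_latency", "seed", "n_triplets")),
    list(controller_latency_min = config$sim$controller_latency[1],
         controller_latency_max = config$sim$controller_latency[2]),
    drop(unclass(config$protocol), "session_order"),
    unclass(config$analysis),
    list(seed = config$seed, n_triplets = config$n_triplets,
         input_dir = config$input_dir %||% ""))
}

#' Read and write a flat key-value run configuration
#'
#' The file is a flat YAML mapping covering all simulator, protocol and
#' analysis fields; it fully determines a simulated run.
#'
#' @param path File path.
#' @return For `read_run_config()`, a [run_config()].
#' @export
read_run_config <- function(path) {
  kv <- yaml::read_yaml(path)
  take <- function(fn, extra = list()) {
    fml <- names(formals(fn))
    do.call(fn, c(kv[intersect(names(kv), fml)], extra))
  }
  lat <- c(kv$controller_latency_min %||% 0.3, kv$controller_latency_max %||% 0.8)
  sim <- take(sim_config, list(controller_latency = lat))
  protocol <- take(protocol_spec)
  analysis <- take(analysis_config)
  run_config(sim = sim, protocol = protocol, analysis = analysis,
             seed = kv$seed %||% sim$seed,
             n_triplets = kv$n_triplets %||% sim$n_triplets,
             input_dir = if (!is.null(kv$input_dir) && nzchar(kv$input_dir))
               kv$input_dir)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(flatten_config(config), path)
  invisible(path)
}

cohort_cad_curves <- function(traces, analysis) {
  grid <- seq(0, analysis$common_train_cut, by = 1)
  dplyr::bind_rows(lapply(traces, function(trace) {
    seg <- segment_trace(trace, speed_threshold = analysis$speed_threshold,
                         min_bout = analysis$min_bout)
    cc <- cad_curve_table(seg, session_windows(trace), grid)
    cc$fly_id <- attr(trace, "fly_id")
    cc
  }))
}

# Median CAD curve per group and Train session with bootstrap CI bands.
cad_band_table <- function(cad_curves, records, cut_used, seed,
                           n_resamples = 1000) {
  df <- dplyr::left_join(cad_curves,
                         records[, c("fly_id", "group")], by = "fly_id")
  df <- df[df$t <= cut_used, ]
  set.seed(seed)
  df |>
    dplyr::group_by(.data$group, .data$session, .data$t) |>
    dplyr::reframe({
      x <- .data$cad
      qs <- if (length(x) >= 2)
        quantile(boot_median_cpp(x, n_resamples), c(0.025, 0.975),
                 names = FALSE)
      else c(NA_real_, NA_real_)
      tibble::tibble(n = length(x), median = median(x),
                     ci_low = qs[1], ci_high = qs[2])
    })
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, segments every trace, computes the session
#' metrics and per-fly summaries, applies curation, and runs the inference
#' layer: group comparisons of Train-session CAD at the common cut, of
#' activity levels in each Test session, and of the activity differences;
#' plus, among yoked flies, the correlations of AD with total heat exposure
#' and with the exposure differential (per Train 1 and pooled over both
#' Train sessions).
#'
#' @param config A [run_config()].
#' @return An `operant_run` object: list with `metrics`, `fly_summary`,
#'   `curation`, `comparisons` (named `group_comparison` list),
#'   `correlations`, `cad_bands`, `records` and `manifest`.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(sim = sim_config(n_triplets = 6, seed = 7)))
#' glance(run)
#' }
run_pipeline <- function(config = run_config()) {
  analysis <- config$analysis
  digests <- character(0)
  if (is.null(config$input_dir)) {
    sm <- simulate_metrics(config$sim, config$protocol, analysis,
                           n_triplets = config$n_triplets, seed = config$seed)
    metrics <- sm$metrics; records <- sm$records; cad_curves <- sm$cad_curves
  } else {
    co <- read_cohort(config$input_dir, config$attributes,
                      chamber_length = config$protocol$chamber_length)
    records <- co$records
    metrics <- metrics_table(co$traces, records, analysis)
    cad_curves <- cohort_cad_curves(co$traces, analysis)
    files <- c(file.path(config$input_dir,
                         paste0(records$fly_id, ".csv")), config$attributes)
    digests <- tools::md5sum(files)
  }
  curation <- curate(records, metrics, analysis$inactivity_threshold)
  retained <- curation$fly_id[curation$retained]
  metrics_r <- metrics[metrics$fly_id %in% retained, ]
  attr(metrics_r, "common_cut_used") <- attr(metrics, "common_cut_used")
  summary <- fly_summary(metrics_r)
  small <- table(factor(summary$group, c("train", "yoked", "blank"))) < 2
  if (any(small))
    abort(sprintf("group '%s' has fewer than 2 retained flies",
                  names(small)[small][1]),
          class = "flyoperant_pipeline_error")
  cmp <- function(col, seed_off) {
    compare_groups(summary, !!rlang::sym(col), group,
                   n_resamples = analysis$n_resamples,
                   seed = config$seed + seed_off, adjust = analysis$adjust)
  }
  comparisons <- list(
    cad_train1 = cmp("cad_train1", 101),
    cad_train2 = cmp("cad_train2", 102),
    activity_pretest = cmp("activity_pretest", 103),
    activity_test1 = cmp("activity_test1", 104),
    activity_test2 = cmp("activity_test2", 105),
    ad_test1 = cmp("ad_test1", 106),
    ad_test2 = cmp("ad_test2", 107)
  )
  yoked <- summary[summary$group == "yoked", ]
  # degenerate cohorts (too few yoked flies, or no heat at all) yield NA
  # correlation rows rather than aborting the whole run
  safe_cor <- function(xcol, ycol, label) {
    out <- tryCatch(
      correlation_with_slope(yoked, !!rlang::sym(xcol), !!rlang::sym(ycol)),
      error = function(e) tibble::tibble(r = NA_real_, slope = NA_real_,
                                         intercept = NA_real_,
                                         p_value = NA_real_,
                                         n = nrow(yoked)))
    dplyr::mutate(out, contrast = label, .before = 1)
  }
  correlations <- dplyr::bind_rows(
    safe_cor("heat_exposure_total", "ad_test2", "ad_test2~heat_exposure"),
    safe_cor("ed_train1", "ad_test1", "ad_test1~ed_train1"),
    safe_cor("ed_all", "ad_test2", "ad_test2~ed_all")
  )
  correlations$stars <- p_stars(correlations$p_value)
  cut_used <- attr(metrics, "common_cut_used")
  cad_bands <- cad_band_table(
    cad_curves[cad_curves$fly_id %in% retained, ], records, cut_used,
    seed = config$seed + 108)
  manifest <- list(
    config = flatten_config(config),
    seed = config$seed,
    common_cut_used = cut_used,
    n_flies = nrow(records),
    n_retained = length(retained),
    package_version = as.character(packageVersion("flyoperant")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    input_digests = as.list(digests)
  )
  structure(
    list(metrics = metrics, fly_summary = summary, curation = curation,
         comparisons = comparisons, correlations = correlations,
         cad_bands = cad_bands, records = records, manifest = manifest),
    class = "operant_run"
  )
}

#' @export
print.operant_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<operant_run> %d flies (%d retained), seed %d, CAD cut %.1f s\n",
              m$n_flies, m$n_retained, m$seed, m$common_cut_used))
  med <- x$comparisons$ad_test2$group_summary
  cat("AD(Test2) group medians:\n")
  print(med)
  cat(sprintf("AD(Test2) Kruskal-Wallis p = %.4g %s\n",
              x$comparisons$ad_test2$omnibus$p_value,
              p_stars(x$comparisons$ad_test2$omnibus$p_value)))
  invisible(x)
}

#' Tidiers for pipeline runs
#'
#' @param x An `operant_run`.
#' @param ... Unused.
#' @return `tidy()`: the per-fly summary table; `glance()`: a one-row
#'   overview (cohort size, retention, seed, common cut, headline p-values).
#' @export
#' @method tidy operant_run
tidy.operant_run <- function(x, ...) x$fly_summary

#' @rdname tidy.operant_run
#' @export
#' @method glance operant_run
glance.operant_run <- function(x, ...) {
  tibble::tibble(
    n_flies = x$manifest$n_flies,
    n_retained = x$manifest$n_retained,
    seed = x$manifest$seed,
    common_cut_used = x$manifest$common_cut_used,
    p_cad_train2 = x$comparisons$cad_train2$omnibus$p_value,
    p_ad_test2 = x$comparisons$ad_test2$omnibus$p_value,
    r_ad_ed_all = x$correlations$r[x$correlations$contrast == "ad_test2~ed_all"]
  )
}

#' Write the outputs of a pipeline run
#'
#' Writes the numeric tables (metrics, per-fly summary, curation report,
#' correlations, CAD bands) as CSV, the statistics report and manifest as
#' JSON, and the figures as PNG (best-effort; figures are cosmetic, the
#' tables are the contract).
#'
#' @param run An `operant_run`.
#' @param dir Output directory (created if needed).
#' @param figures Write PNG figures.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, figures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$metrics, file.path(dir, "session_metrics.csv"),
                   progress = FALSE)
  readr::write_csv(run$fly_summary, file.path(dir, "fly_summary.csv"),
                   progress = FALSE)
  readr::write_csv(run$curation, file.path(dir, "curation_report.csv"),
                   progress = FALSE)
  readr::write_csv(run$correlations, file.path(dir, "correlations.csv"),
                   progress = FALSE)
  readr::write_csv(run$cad_bands, file.path(dir, "cad_bands.csv"),
                   progress = FALSE)
  stats_report(run$comparisons, file.path(dir, "stats_report.json"))
  writeLines(jsonlite::toJSON(run$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(dir, "manifest.json"))
  if (figures) {
    try({
      ggplot2::ggsave(file.path(dir, "cad_curves.png"), plot_cad_curves(run),
                      width = 8, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(dir, "activity_levels.png"),
                      plot_activity_levels(run), width = 7, height = 4,
                      dpi = 150)
      ggplot2::ggsave(file.path(dir, "ad_scatter.png"),
                      plot_ad_scatter(run), width = 9, height = 3.5,
                      dpi = 150)
    }, silent = TRUE)
  }
  invisible(dir)
}
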