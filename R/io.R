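#' Write a data frame as a UTF-8 CSV with a single header row
#'
#' Missing values are written as empty fields; column order is preserved.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path Input path.
#' @param logical_cols Columns to coerce back to logical.
#' @return A data frame; empty fields become \code{NA}.
#' @export
read_table_csv <- function(path, logical_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       fileEncoding = "UTF-8")
  for (col in intersect(logical_cols, names(x))) {
    x[[col]] <- as.logical(x[[col]])
  }
  x
}

logical_columns <- list(
  cohort = c("ics_use", "died"),
  daily_records = c("base_answered", "base_worse"),
  period_table = "ics_use"
)

#' Run the full monitoring study pipeline on a simulated cohort
#'
#' End-to-end driver: simulate the cohort (profiles, events, daily logs),
#' replay every patient's log through the zone engine, summarise app
#' usage, build the patient-period table, fit the four pre-post IRR
#' models for both outcomes, and test the CCQ time trend. All artifacts
#' are written to \code{out_dir} as CSV/JSON together with a run manifest
#' recording the seed and a digest of the configuration.
#'
#' @param config A [sim_config()], or the path of a JSON/YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the configuration seed.
#' @param goal_factor Step goal as a fraction of the assessed baseline,
#'   passed to [replay()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the simulated tables, the usage summary,
#'   the period table, the list of fitted models (\code{fits}), the CCQ
#'   trend and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("copdwatch_"),
                         seed = NULL, goal_factor = 1.0, quiet = FALSE) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (config$n_patients < 2) {
    stop("the pipeline needs at least 2 patients to fit rate models")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("simulating cohort (n = ", config$n_patients, ", seed = ",
      config$seed, ")")
  sim <- simulate_cohort(config, daily = TRUE)

  say("replaying daily logs through the zone engine")
  zone_parts <- lapply(split(sim$daily_records, sim$daily_records$patient_id),
                       function(r) {
                         r <- r[order(r$day), , drop = FALSE]
                         rep <- replay(r, goal_factor = goal_factor)
                         rep$zones$patient_id <- r$patient_id[1]
                         rep
                       })
  zones <- do.call(rbind, lapply(zone_parts, `[[`, "zones"))
  alerts <- do.call(rbind, lapply(zone_parts, `[[`, "alerts"))
  rownames(zones) <- rownames(alerts) <- NULL

  usage <- summarize_cohort_usage(sim$daily_records, goal_factor = goal_factor)
  cohort_summary <- lapply(
    usage[, setdiff(names(usage), "patient_id")],
    function(v) describe(v)[c("median", "q1", "q3", "mean", "sd")])

  say("fitting pre-post rate models")
  period_table <- build_period_table(sim$cohort, sim$events)
  fits <- list()
  for (outcome in c("hosp_days", "exacerbations")) {
    fam <- as.character(select_family(period_table, outcome))
    for (m in 1:4) {
      fit <- fit_irr(period_table, outcome, model_id = m, family = fam)
      fits[[paste0(outcome, "_model", m)]] <- fit
    }
  }
  fit_json <- lapply(fits, function(f) {
    list(outcome_name = f$outcome_name, model_id = f$model_id,
         coef = unname(f$coefficients[["intervention"]]),
         robust_se = f$robust_se, irr = f$irr,
         ci_low = f$ci_low, ci_high = f$ci_high,
         n_patients = f$n_patients, family = f$family,
         working_correlation = f$corstr)
  })

  ccq_long <- sim$daily_records[!is.na(sim$daily_records$ccq),
                                c("patient_id", "day", "ccq")]
  trend <- ccq_trend(ccq_long)

  paths <- c(cohort = "cohort.csv", events = "events.csv",
             daily_records = "daily_records.csv", zones = "zones.csv",
             alerts = "alerts.csv", usage = "usage_summary.csv",
             period_table = "period_table.csv")
  write_table_csv(sim$cohort, file.path(out_dir, paths["cohort"]))
  write_table_csv(sim$events, file.path(out_dir, paths["events"]))
  write_table_csv(sim$daily_records, file.path(out_dir, paths["daily_records"]))
  write_table_csv(zones, file.path(out_dir, paths["zones"]))
  write_table_csv(alerts, file.path(out_dir, paths["alerts"]))
  write_table_csv(usage, file.path(out_dir, paths["usage"]))
  write_table_csv(period_table, file.path(out_dir, paths["period_table"]))
  jsonlite::write_json(fit_json, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cohort_summary, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(trend, file.path(out_dir, "ccq_trend.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    command = "run_pipeline",
    config_hash = config_digest(config),
    seed = config$seed,
    timestamps = list(finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    output_paths = c(unname(paths), "fit.json", "cohort_summary.json",
                     "ccq_trend.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  say("wrote ", length(manifest$output_paths), " artifacts to ", out_dir)

  invisible(list(cohort = sim$cohort, events = sim$events,
                 daily_records = sim$daily_records, zones = zones,
                 alerts = alerts, usage = usage,
                 cohort_summary = cohort_summary,
                 period_table = period_table, fits = fits,
                 ccq_trend = trend, manifest = manifest, out_dir = out_dir))
}

# Stable digest of a configuration: serialised key=value pairs, summed as
# a simple 32-bit rolling hash (no external digest dependency).
config_digest <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
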