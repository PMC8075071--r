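#' Descriptive statistics in the reporting convention of the study tables
#'
#' Median, interquartile range, mean and SD of a numeric vector. Quartiles
#' use linear interpolation between order statistics (type 7, the
#' mainstream default), which the reported IQRs depend on.
#'
#' @param values Non-empty numeric vector; \code{NA}s are dropped.
#' @return A list with \code{median}, \code{q1}, \code{q3}, \code{mean},
#'   \code{sd} (\code{sd} is \code{NA} for a single value).
#' @export
#' @examples
#' describe(c(1, 2, 3, 4, 5))  # median 3, IQR 2-4
describe <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("describe() needs at least one non-missing value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3],
       mean = mean(values), sd = stats::sd(values))
}

#' Per-patient app-usage and zone summary
#'
#' Counts how a patient used the monitoring app and how much time was
#' spent in the escalation zones, in the shape of the study's usage
#' table: answered daily (BASE) questions, "worse" answers, on-demand
#' (PLUS) answers split by mapped zone class, days whose end-of-day
#' overall zone was orange or red, and the median daily step count.
#'
#' @param records Daily log for one patient (see
#'   [simulate_daily_records()] for the schema).
#' @param zone_series The \code{zones} data frame returned by [replay()]
#'   on the same records (optional: when omitted, [replay()] is run
#'   internally).
#' @param goal_factor Passed to [replay()] when \code{zone_series} is
#'   omitted.
#' @return A one-row data frame: \code{patient_id}, \code{n_base_answered},
#'   \code{n_base_yes}, \code{n_plus_answered}, \code{n_plus_orange},
#'   \code{n_plus_red}, \code{days_in_orange}, \code{days_in_red},
#'   \code{median_steps}.
#' @export
summarize_usage <- function(records, zone_series = NULL, goal_factor = 1.0) {
  pid <- if (nrow(records)) records$patient_id[1] else NA_character_
  if (nrow(records) && length(unique(records$patient_id)) > 1) {
    stop("summarize_usage() works on one patient at a time; got ids: ",
         paste(unique(records$patient_id), collapse = ", "))
  }
  if (is.null(zone_series)) {
    zone_series <- replay(records, goal_factor = goal_factor)$zones
  } else if (nrow(zone_series) != nrow(records)) {
    stop("zone series (", nrow(zone_series), " days) does not match the ",
         "records (", nrow(records), " days); replay the same log")
  }
  answered <- !is.na(records$base_worse)
  plus <- records$plus_answer[!is.na(records$plus_answer)]
  plus_class <- PLUS_ANSWERS[plus]
  data.frame(
    patient_id = pid,
    n_base_answered = sum(answered),
    n_base_yes = sum(records$base_worse[answered]),
    n_plus_answered = length(plus),
    n_plus_orange = sum(plus_class == "ORANGE"),
    n_plus_red = sum(plus_class == "RED"),
    days_in_orange = sum(zone_series$overall_zone == "ORANGE"),
    days_in_red = sum(zone_series$overall_zone == "RED"),
    median_steps = if (any(!is.na(records$steps))) {
      stats::median(records$steps, na.rm = TRUE)
    } else NA_real_,
    stringsAsFactors = FALSE)
}

#' Cohort-level usage summary
#'
#' Runs [replay()] and [summarize_usage()] per patient and stacks the
#' results.
#'
#' @param daily_records Daily logs for a whole cohort (column
#'   \code{patient_id} distinguishes patients).
#' @param goal_factor Passed to [replay()].
#' @return A data frame with one [summarize_usage()] row per patient.
#' @export
summarize_cohort_usage <- function(daily_records, goal_factor = 1.0) {
  parts <- lapply(split(daily_records, daily_records$patient_id),
                  function(r) {
                    r <- r[order(r$day), , drop = FALSE]
                    summarize_usage(r, goal_factor = goal_factor)
                  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}
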