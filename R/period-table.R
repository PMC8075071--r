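#' Build the patient-period count table for the pre-post analysis
#'
#' Collapses event histories into the analysis unit of the pre-post rate
#' comparison: one row per patient and period with the total exacerbation
#' count, total hospitalised days, and the exposure time. The pre period
#' is always 365 days (the year before inclusion); the post period runs
#' from inclusion to data extraction, or to death for patients who died.
#' Baseline covariates (age, sex, GOLD category, inhaled corticosteroid
#' use) are carried onto both rows for the adjusted models.
#'
#' @param profiles Cohort data frame from [generate_cohort()] (or any data
#'   frame with \code{patient_id}, \code{age}, \code{sex}, \code{gold},
#'   \code{ics_use}, \code{followup_post}).
#' @param events Event data frame with columns \code{patient_id},
#'   \code{period} (\code{"pre"}/\code{"post"}), \code{severity},
#'   \code{hosp_days}; alternatively pass pre- and post-period events
#'   separately via \code{pre_events}/\code{post_events}.
#' @param pre_events,post_events Optional separate event tables (used when
#'   \code{events} is missing); each needs \code{patient_id} and
#'   \code{hosp_days}.
#' @return Data frame with two rows per patient: \code{patient_id},
#'   \code{intervention} (0 = pre, 1 = post), \code{exposure_days},
#'   \code{n_exacerbations}, \code{n_hosp_days}, \code{age}, \code{sex}
#'   (factor, reference \code{male}), \code{gold}, \code{ics_use}. Sorted
#'   by patient then period.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 3, seed = 2), daily = FALSE)
#' build_period_table(sim$cohort, sim$events)
build_period_table <- function(profiles, events = NULL,
                               pre_events = NULL, post_events = NULL) {
  if (is.null(events)) {
    if (is.null(pre_events) || is.null(post_events)) {
      stop("provide either 'events' (with a period column) or both ",
           "'pre_events' and 'post_events'")
    }
    pre_events$period <- rep("pre", nrow(pre_events))
    post_events$period <- rep("post", nrow(post_events))
    events <- rbind(pre_events, post_events)
  }
  if (nrow(profiles) == 0) {
    stop("empty cohort: nothing to tabulate")
  }
  stray <- setdiff(unique(events$patient_id), profiles$patient_id)
  if (length(stray)) {
    stop("events reference patients absent from the cohort: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  if (any(!events$period %in% c("pre", "post"))) {
    stop("unknown period label in events: ",
         paste(setdiff(unique(events$period), c("pre", "post")), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    if (is.na(p$followup_post) || p$followup_post < 1) {
      stop("patient ", p$patient_id, " has no post period (follow-up < 1 day)")
    }
    ev <- events[events$patient_id == p$patient_id, , drop = FALSE]
    per_period <- function(period) {
      e <- ev[ev$period == period, , drop = FALSE]
      data.frame(patient_id = p$patient_id,
                 intervention = as.integer(period == "post"),
                 exposure_days = if (period == "pre") 365 else p$followup_post,
                 n_exacerbations = nrow(e),
                 n_hosp_days = sum(e$hosp_days),
                 age = p$age, sex = p$sex,
                 gold = ifelse(p$gold == "missing", NA_character_, p$gold),
                 ics_use = p$ics_use, stringsAsFactors = FALSE)
    }
    rbind(per_period("pre"), per_period("post"))
  })
  out <- do.call(rbind, rows)
  out$sex <- factor(out$sex, levels = c("male", "female"))
  out
}
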