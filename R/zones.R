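#' Zone levels of the monitoring traffic-light scheme
#'
#' Patients monitored by the program are always in exactly one of four
#' ordered zones: \code{GREEN} (steady state) < \code{YELLOW} (symptoms
#' worsened, adapt medication per the personal exacerbation plan) <
#' \code{ORANGE} (no improvement for 3 days, or a serious on-demand answer:
#' take emergency medication or contact a health care professional) <
#' \code{RED} (potentially life-threatening: the buddy is advised to call an
#' ambulance).
#'
#' @format Character vector of the four zone labels in escalation order.
#' @export
ZONES <- c("GREEN", "YELLOW", "ORANGE", "RED")

#' Advice codes attached to alerts
#'
#' @format Character vector of the recognised advice codes.
#' @export
ADVICE_CODES <- c("NONE", "READ_PLAN_ADAPT_MEDICATION",
                  "EMERGENCY_MEDICATION_OR_CONTACT_HCP", "CALL_AMBULANCE")

#' Answer categories of the on-demand (PLUS) severity question
#'
#' Three answers map to the orange zone, seven to the red zone, and
#' \code{NONE} leaves the state untouched.
#'
#' @format Named character vector mapping each answer to its zone class.
#' @export
PLUS_ANSWERS <- c(
  HEMOPTYSIS = "ORANGE", FEVER = "ORANGE", TOO_SICK_FOR_ACTIVITIES = "ORANGE",
  VERY_DYSPNEIC = "RED", CHEST_PAIN = "RED", CONFUSED = "RED",
  FORGETFULNESS = "RED", DIZZINESS = "RED", COLLAPSE_TENDENCY = "RED",
  LOSS_OF_CONSCIOUSNESS = "RED", NONE = "NONE"
)

zone_level <- function(zone) match(zone, ZONES)

zone_max <- function(a, b) ZONES[pmax(zone_level(a), zone_level(b))]

new_alert <- function(patient_id, day, from_zone, to_zone, recipient, advice) {
  data.frame(patient_id = patient_id, day = as.integer(day),
             from_zone = from_zone, to_zone = to_zone,
             recipient = recipient, advice = advice,
             stringsAsFactors = FALSE)
}

empty_alerts <- function() {
  new_alert(character(0), integer(0), character(0), character(0),
            character(0), character(0))
}

#' Initialise the monitoring state machine
#'
#' At the start of app use a patient is in the green zone (steady state):
#' both the symptom-driven and the step-driven component are \code{GREEN},
#' the consecutive-worse-day counter is zero and no step goal is set yet
#' (the goal is derived from a 3-week baseline, see
#' [assess_step_baseline()]).
#'
#' @param patient_id Identifier attached to emitted alerts.
#' @return An object of class \code{zone_state}: a list with components
#'   \code{symptom_zone}, \code{step_zone}, \code{overall_zone} (all zone
#'   labels), \code{consecutive_worse_days}, \code{step_goal},
#'   \code{baseline_steps} (\code{NA} until assessed), \code{day_index}
#'   (last processed day, \code{-1} initially) and \code{red_via_plus}
#'   (whether the current red symptom zone was reached through the
#'   on-demand question).
#' @export
#' @examples
#' st <- init_state()
#' st$overall_zone  # "GREEN"
init_state <- function(patient_id = "p1") {
  structure(list(
    patient_id = patient_id,
    symptom_zone = "GREEN",
    step_zone = "GREEN",
    overall_zone = "GREEN",
    consecutive_worse_days = 0L,
    step_goal = NA_real_,
    baseline_steps = NA_real_,
    day_index = -1L,
    red_via_plus = FALSE
  ), class = "zone_state")
}

#' @export
print.zone_state <- function(x, ...) {
  cat("<zone_state> patient", x$patient_id,
      "| overall:", x$overall_zone,
      "(symptoms:", x$symptom_zone, "/ steps:", paste0(x$step_zone, ")"),
      "| worse streak:", x$consecutive_worse_days,
      "| step goal:", ifelse(is.na(x$step_goal), "unset", x$step_goal), "\n")
  invisible(x)
}

refresh_overall <- function(state) {
  state$overall_zone <- zone_max(state$symptom_zone, state$step_zone)
  state
}

# Emit patient + buddy alerts for a change of the overall zone. The buddy
# is alerted on every change; the patient additionally receives the advice
# when there is one.
alerts_for_change <- function(state, day, from_zone, to_zone) {
  advice <- advice_for(state, to_zone)
  out <- new_alert(state$patient_id, day, from_zone, to_zone, "buddy", advice)
  if (advice != "NONE") {
    out <- rbind(out, new_alert(state$patient_id, day, from_zone, to_zone,
                                "patient", advice))
  }
  out
}

# Advice depends on the destination zone and, for red, on the pathway:
# only a red reached through the on-demand question carries the
# call-an-ambulance advice; a red reached through a 40% step decline is
# advised like orange.
advice_for <- function(state, to_zone) {
  switch(to_zone,
    GREEN = "NONE",
    YELLOW = "READ_PLAN_ADAPT_MEDICATION",
    ORANGE = "EMERGENCY_MEDICATION_OR_CONTACT_HCP",
    RED = if (state$red_via_plus) "CALL_AMBULANCE"
          else "EMERGENCY_MEDICATION_OR_CONTACT_HCP")
}

#' Process one answered daily (BASE) symptom question
#'
#' The daily question asks whether COPD symptoms worsened beyond
#' day-to-day variation. A first "worse" answer moves the patient from
#' green to yellow (advice: read the personal exacerbation plan and adapt
#' medication). Three consecutive "worse" answers escalate to orange
#' (advice: emergency medication or contact a health care professional).
#' Any "not worse" answer returns the symptom component to green and
#' resets the counter. Days without an answer must simply not be processed:
#' the counter is frozen, neither advanced nor reset.
#'
#' @param state A \code{zone_state}.
#' @param worse Logical, the answer to "did your symptoms worsen?".
#' @param day Integer day index; must be strictly greater than the last
#'   processed day.
#' @return A list with elements \code{state} (updated \code{zone_state})
#'   and \code{alerts} (data frame of [AlertEvent][replay] rows, one buddy
#'   alert per overall-zone change plus a patient advice row when advice is
#'   given).
#' @export
#' @examples
#' st <- init_state()
#' res <- process_base(st, worse = TRUE, day = 0)
#' res$state$overall_zone  # "YELLOW"
process_base <- function(state, worse, day = state$day_index + 1L) {
  stopifnot(inherits(state, "zone_state"), is.logical(worse), !is.na(worse))
  day <- as.integer(day)
  if (day <= state$day_index) {
    stop("out-of-order day index: day ", day,
         " after already processing day ", state$day_index)
  }
  prev_overall <- state$overall_zone
  if (worse) {
    state$consecutive_worse_days <- state$consecutive_worse_days + 1L
    candidate <- if (state$consecutive_worse_days >= 3L) "ORANGE" else "YELLOW"
    state$symptom_zone <- zone_max(state$symptom_zone, candidate)
  } else {
    state$symptom_zone <- "GREEN"
    state$consecutive_worse_days <- 0L
    state$red_via_plus <- FALSE
  }
  state$day_index <- day
  state <- refresh_overall(state)
  alerts <- if (state$overall_zone != prev_overall) {
    alerts_for_change(state, day, prev_overall, state$overall_zone)
  } else empty_alerts()
  list(state = state, alerts = alerts)
}

#' Process an on-demand (PLUS) severity answer
#'
#' The on-demand question can be filled out at any time by the patient or
#' the buddy when something serious is suspected. Serious but not
#' immediately life-threatening answers (hemoptysis, fever, too sick for
#' activities) raise the symptom zone to at least orange; answers flagging
#' a potentially life-threatening situation (very dyspneic, chest pain,
#' confusion, forgetfulness, dizziness, tendency to collapse, loss of
#' consciousness) raise it to red, with the buddy advised to call an
#' ambulance. An on-demand answer never lowers the zone.
#'
#' @param state A \code{zone_state}.
#' @param answer One of \code{names(PLUS_ANSWERS)}.
#' @param day Integer day index of the answer (may equal the current day:
#'   the question is on-demand, not once daily).
#' @return A list with \code{state} and \code{alerts} as in
#'   [process_base()].
#' @export
#' @examples
#' res <- process_plus(init_state(), "FEVER", day = 0)
#' res$state$overall_zone  # "ORANGE"
process_plus <- function(state, answer, day = max(state$day_index, 0L)) {
  stopifnot(inherits(state, "zone_state"))
  if (!answer %in% names(PLUS_ANSWERS)) {
    stop("unknown PLUS answer category: ", answer)
  }
  day <- as.integer(day)
  if (day < state$day_index) {
    stop("out-of-order day index: day ", day,
         " after already processing day ", state$day_index)
  }
  prev_overall <- state$overall_zone
  mapped <- PLUS_ANSWERS[[answer]]
  if (mapped != "NONE") {
    if (mapped == "RED" && zone_level(state$symptom_zone) < 4L) {
      state$red_via_plus <- TRUE
    }
    state$symptom_zone <- zone_max(state$symptom_zone, mapped)
  }
  state$day_index <- day
  state <- refresh_overall(state)
  alerts <- if (state$overall_zone != prev_overall) {
    alerts_for_change(state, day, prev_overall, state$overall_zone)
  } else empty_alerts()
  list(state = state, alerts = alerts)
}

#' Baseline activity level from the first three weeks of step counts
#'
#' During the first 3 weeks of app use the baseline activity level is
#' assessed; afterwards a step goal is set relative to it. The baseline is
#' the mean of the non-missing daily step counts in that window.
#'
#' @param first_days Numeric vector of exactly 21 daily step counts;
#'   \code{NA} marks days without a measurement.
#' @return The mean of the non-missing values, or \code{NA} if all 21 days
#'   are missing (the engine then stays in symptom-only mode).
#' @export
#' @examples
#' assess_step_baseline(rep(c(1000, 2000, 3000), each = 7))  # 2000
assess_step_baseline <- function(first_days) {
  if (length(first_days) != 21L) {
    stop("baseline assessment needs exactly 21 daily values, got ",
         length(first_days))
  }
  if (all(is.na(first_days))) return(NA_real_)
  mean(first_days, na.rm = TRUE)
}

#' Zone implied by a daily step count relative to the step goal
#'
#' Reaching the goal keeps the patient in the green zone. A decline of 20%
#' or more (steps at or below 80% of the goal) signals the orange zone; a
#' decline of 40% or more (at or below 60% of the goal) the red zone. Ties
#' go to the more severe zone. Between 80% and 100% of the goal the zone
#' stays green: the scheme defines no yellow step zone.
#'
#' @param steps Daily step count.
#' @param goal Step goal set after the baseline assessment; must be a
#'   positive number.
#' @return A zone label.
#' @export
#' @examples
#' step_zone_of(3900, 5000)  # "ORANGE" (22% below goal)
#' step_zone_of(2900, 5000)  # "RED"    (42% below goal)
step_zone_of <- function(steps, goal) {
  if (is.na(goal)) {
    stop("step goal is unset; assess the 3-week step baseline first")
  }
  stopifnot(goal > 0, steps >= 0)
  if (steps <= 0.6 * goal) "RED"
  else if (steps <= 0.8 * goal) "ORANGE"
  else "GREEN"
}

#' Is a health-status (CCQ) questionnaire due on a given day?
#'
#' The Clinical COPD Questionnaire is completed three times a week. The
#' schedule is anchored at inclusion: days 0, 2 and 4 of every 7-day week
#' (day indices are 0-based from the inclusion date).
#'
#' @param day Non-negative integer day index.
#' @return Logical (vectorised over \code{day}).
#' @export
#' @examples
#' ccq_due(0:6)  # TRUE FALSE TRUE FALSE TRUE FALSE FALSE
ccq_due <- function(day) {
  if (any(day < 0)) stop("day index must be non-negative")
  (day %% 7) %in% c(0, 2, 4)
}

#' Replay a daily monitoring log through the zone state machine
#'
#' Drives all monitoring rules over a patient's daily log. Days 0-20 form
#' the step-baseline window; from day 21 on the step goal is
#' \code{goal_factor} times the assessed baseline and daily step counts are
#' classified with [step_zone_of()]. Each day is evaluated atomically: the
#' answered daily symptom question (if any) and an on-demand answer (if
#' any) update the symptom component, the step count updates the step
#' component, the overall zone is the more severe of the two, and one buddy
#' alert is emitted per change of the end-of-day overall zone (with a
#' patient advice row whenever the new zone carries advice).
#'
#' @param records Data frame with columns \code{day} (sorted, 0-based),
#'   \code{base_answered} (logical), \code{base_worse} (logical, `NA` on
#'   unanswered days), \code{plus_answer} (answer category or `NA`) and
#'   \code{steps} (daily count or `NA`); optionally \code{patient_id}.
#' @param goal_factor Step goal as a fraction of the assessed baseline.
#'   The goal set in practice by a physiotherapist is not prescribed by the
#'   scheme; 1.0 (goal = baseline) is the default.
#' @return A list with \code{zones} (data frame: \code{day},
#'   \code{symptom_zone}, \code{step_zone}, \code{overall_zone}, one row
#'   per log day) and \code{alerts} (data frame: \code{patient_id},
#'   \code{day}, \code{from_zone}, \code{to_zone}, \code{recipient},
#'   \code{advice}).
#' @export
replay <- function(records, goal_factor = 1.0) {
  cols <- c("day", "base_answered", "base_worse", "plus_answer", "steps")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) {
    return(list(
      zones = data.frame(day = integer(0), symptom_zone = character(0),
                         step_zone = character(0), overall_zone = character(0),
                         stringsAsFactors = FALSE),
      alerts = empty_alerts()))
  }
  if (is.unsorted(records$day, strictly = TRUE)) {
    stop("records must be sorted by strictly increasing day")
  }
  pid <- if ("patient_id" %in% names(records)) records$patient_id[1] else "p1"
  state <- init_state(patient_id = pid)

  n <- nrow(records)
  zones <- data.frame(day = as.integer(records$day),
                      symptom_zone = character(n), step_zone = character(n),
                      overall_zone = character(n), stringsAsFactors = FALSE)
  alerts <- vector("list", n)
  prev_overall <- "GREEN"

  # days absent from the log count as missing in the 21-day window
  baseline_window <- records$steps[records$day <= 20L][
    match(0:20, records$day[records$day <= 20L])]

  for (i in seq_len(n)) {
    day <- as.integer(records$day[i])
    if (day == 21L || (i == 1L && day > 21L) ||
        (i > 1L && records$day[i - 1L] < 21L && day > 21L)) {
      state$baseline_steps <- assess_step_baseline(baseline_window)
      if (!is.na(state$baseline_steps)) {
        state$step_goal <- goal_factor * state$baseline_steps
      }
    }
    if (isTRUE(records$base_answered[i]) && !is.na(records$base_worse[i])) {
      state <- process_base(state, records$base_worse[i], day)$state
    } else {
      state$day_index <- day
    }
    pa <- records$plus_answer[i]
    if (!is.na(pa) && pa != "NONE") {
      state <- process_plus(state, pa, day)$state
    }
    if (!is.na(records$steps[i]) && !is.na(state$step_goal) && day > 20L) {
      state$step_zone <- step_zone_of(records$steps[i], state$step_goal)
      state <- refresh_overall(state)
    }
    zones$symptom_zone[i] <- state$symptom_zone
    zones$step_zone[i] <- state$step_zone
    zones$overall_zone[i] <- state$overall_zone
    if (state$overall_zone != prev_overall) {
      alerts[[i]] <- alerts_for_change(state, day, prev_overall,
                                       state$overall_zone)
      prev_overall <- state$overall_zone
    }
  }
  list(zones = zones, alerts = do.call(rbind, c(list(empty_alerts()),
                                                alerts[!vapply(alerts, is.null, logical(1))])))
}
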