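# Independent oracles used across the test files. Each is deliberately
# written as a direct transcription of the monitoring/analysis rules,
# separate from the package implementation.

# Brute-force zone interpreter: walks a daily log and recomputes, for
# every day, the symptom zone (streak of consecutive answered "worse"
# days; on-demand answers floor the zone; any "not worse" answer resets
# to green), the step zone (3-week mean baseline, then 20%/40% decline
# thresholds against goal_factor * baseline), the overall zone, and the
# alert sequence as the diffs of the end-of-day overall zones.
oracle_replay <- function(records, goal_factor = 1.0) {
  lvl <- c(GREEN = 1, YELLOW = 2, ORANGE = 3, RED = 4)
  plus_map <- c(HEMOPTYSIS = "ORANGE", FEVER = "ORANGE",
                TOO_SICK_FOR_ACTIVITIES = "ORANGE",
                VERY_DYSPNEIC = "RED", CHEST_PAIN = "RED", CONFUSED = "RED",
                FORGETFULNESS = "RED", DIZZINESS = "RED",
                COLLAPSE_TENDENCY = "RED", LOSS_OF_CONSCIOUSNESS = "RED",
                NONE = "NONE")
  base_win <- records$steps[records$day <= 20]
  baseline <- if (all(is.na(base_win)) || !length(base_win)) NA else
    mean(base_win, na.rm = TRUE)
  goal <- goal_factor * baseline

  symptom <- "GREEN"; streak <- 0; red_plus <- FALSE; step <- "GREEN"
  n <- nrow(records)
  overall <- symptom_z <- step_z <- character(n)
  for (i in seq_len(n)) {
    worse <- records$base_worse[i]
    if (isTRUE(records$base_answered[i]) && !is.na(worse)) {
      if (worse) {
        streak <- streak + 1
        cand <- if (streak >= 3) "ORANGE" else "YELLOW"
        if (lvl[cand] > lvl[symptom]) symptom <- cand
      } else {
        symptom <- "GREEN"; streak <- 0; red_plus <- FALSE
      }
    }
    pa <- records$plus_answer[i]
    if (!is.na(pa) && plus_map[pa] != "NONE") {
      if (plus_map[pa] == "RED" && lvl[symptom] < 4) red_plus <- TRUE
      if (lvl[plus_map[pa]] > lvl[symptom]) symptom <- plus_map[pa]
    }
    if (!is.na(records$steps[i]) && !is.na(goal) && records$day[i] > 20) {
      s <- records$steps[i]
      step <- if (s <= 0.6 * goal) "RED" else if (s <= 0.8 * goal) "ORANGE"
              else "GREEN"
    }
    symptom_z[i] <- symptom
    step_z[i] <- step
    overall[i] <- names(lvl)[max(lvl[symptom], lvl[step])]
  }
  prev <- c("GREEN", overall[-n])
  changes <- which(overall != prev)
  advice <- vapply(changes, function(i) {
    switch(overall[i],
           GREEN = "NONE",
           YELLOW = "READ_PLAN_ADAPT_MEDICATION",
           ORANGE = "EMERGENCY_MEDICATION_OR_CONTACT_HCP",
           RED = if (symptom_z[i] == "RED") "CALL_AMBULANCE"
                 else "EMERGENCY_MEDICATION_OR_CONTACT_HCP")
  }, character(1))
  list(zones = data.frame(day = records$day, symptom_zone = symptom_z,
                          step_zone = step_z, overall_zone = overall,
                          stringsAsFactors = FALSE),
       alerts = data.frame(day = records$day[changes],
                           from_zone = prev[changes],
                           to_zone = overall[changes], advice = advice,
                           stringsAsFactors = FALSE))
}

# Random daily log generator for property tests.
random_log <- function(n_days = 60, p_answer = 0.7, p_worse = 0.3,
                       p_plus = 0.15, p_step_missing = 0.2, goal = 4000) {
  day <- 0:(n_days - 1)
  answered <- runif(n_days) < p_answer
  worse <- ifelse(answered, runif(n_days) < p_worse, NA)
  plus <- rep(NA_character_, n_days)
  ask <- runif(n_days) < p_plus
  plus[ask] <- sample(names(copdwatch::PLUS_ANSWERS), sum(ask), replace = TRUE)
  steps <- ifelse(runif(n_days) < p_step_missing, NA_real_,
                  round(runif(n_days, 0.4, 1.3) * goal))
  data.frame(patient_id = "px", day = day, base_answered = answered,
             base_worse = worse, plus_answer = plus, steps = steps,
             stringsAsFactors = FALSE)
}

# Pooled-rate closed form: with only an intercept and the period
# indicator in a Poisson log-linear model with log-exposure offset, the
# rate-ratio estimate is the ratio of pooled rates.
oracle_pooled_irr <- function(table, outcome) {
  y <- if (outcome == "exacerbations") table$n_exacerbations else table$n_hosp_days
  post <- table$intervention == 1
  (sum(y[post]) / sum(table$exposure_days[post])) /
    (sum(y[!post]) / sum(table$exposure_days[!post]))
}

# Cohort for fixed-table GEE tests: small, deterministic.
fixed_period_table <- function(seed = 42, n = 40) {
  cfg <- copdwatch::sim_config(n_patients = n, seed = seed)
  sim <- copdwatch::simulate_cohort(cfg, daily = FALSE)
  copdwatch::build_period_table(sim$cohort, sim$events)
}
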