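#' Generate a synthetic COPD cohort
#'
#' Draws baseline covariates, latent event rates and post-period follow-up
#' for \code{n_patients} patients. Covariates are sampled independently
#' from the marginal distributions in the configuration (ages and FEV1 %
#' predicted normal, sex and inhaled corticosteroid use Bernoulli, GOLD
#' category multinomial including a missing class). Each patient carries a
#' latent pre-period exacerbation rate (shared, or gamma-frailty
#' heterogeneous when \code{rate_dispersion > 0}) and a latent
#' hospital-days intensity. Post-period follow-up is drawn from a
#' piecewise-linear quantile model matched to the configured median and
#' IQR; patients who die have their follow-up drawn from the lower half of
#' that distribution.
#'
#' Generation is deterministic given the configuration (including its
#' seed) and uses per-patient substreams, so the profile of patient i does
#' not depend on how many patients are generated.
#'
#' @param config A [sim_config()].
#' @return A data frame with one row per patient: \code{patient_id},
#'   \code{age}, \code{sex}, \code{gold}, \code{ics_use}, \code{fev1pp},
#'   \code{latent_pre_rate} (events/person-year),
#'   \code{latent_hosp_days_rate} (days/person-year, pre period),
#'   \code{followup_post} (days), \code{died}.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 5, seed = 7))
#' cohort[, c("patient_id", "age", "sex", "followup_post")]
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- as.integer(config$n_patients)
  if (n == 0L) return(empty_cohort())
  rows <- lapply(seq_len(n), function(i) generate_patient(i, config))
  do.call(rbind, rows)
}

empty_cohort <- function() {
  data.frame(patient_id = character(0), age = numeric(0), sex = character(0),
             gold = character(0), ics_use = logical(0), fev1pp = numeric(0),
             latent_pre_rate = numeric(0), latent_hosp_days_rate = numeric(0),
             followup_post = numeric(0), died = logical(0),
             stringsAsFactors = FALSE)
}

generate_patient <- function(i, config) {
  with_seed(substream_seed(config$seed, i, "profile"), {
    sev <- config$severity_probs
    frailty <- if (config$rate_dispersion > 0) {
      stats::rgamma(1, shape = 1 / config$rate_dispersion,
                    rate = 1 / config$rate_dispersion)
    } else 1
    rate <- config$pre_exac_rate * frailty
    died <- stats::runif(1) < config$mortality_prob
    data.frame(
      patient_id = sprintf("p%04d", i),
      age = stats::rnorm(1, config$age_mean, config$age_sd),
      sex = ifelse(stats::runif(1) < config$prop_female, "female", "male"),
      gold = sample(names(config$gold_probs), 1, prob = config$gold_probs),
      ics_use = stats::runif(1) < config$ics_prob,
      fev1pp = stats::rnorm(1, config$fev1pp_mean, config$fev1pp_sd),
      latent_pre_rate = rate,
      latent_hosp_days_rate = rate * sev[["severe"]] *
        config$hosp_days_per_severe_mean,
      followup_post = sample_followup(1, config, died = died),
      died = died,
      stringsAsFactors = FALSE)
  })
}

# Follow-up in days from a piecewise-linear inverse CDF through the
# configured (min, q25, median, q75, max). Deaths truncate follow-up:
# the quantile is drawn from the lower half.
sample_followup <- function(n, config, died = FALSE) {
  u <- stats::runif(n)
  u[died] <- u[died] / 2
  q <- c(config$followup_range[1], config$followup_iqr[1],
         config$followup_median, config$followup_iqr[2],
         config$followup_range[2])
  pmax(1, round(stats::approx(x = c(0, 0.25, 0.5, 0.75, 1), y = q,
                              xout = u, ties = "ordered")$y))
}

#' Simulate exacerbation events for one patient-period
#'
#' Events follow a homogeneous Poisson process over the period: 365 days
#' for the pre period, the patient's (possibly death-truncated) follow-up
#' for the post period. The post-period event rate is the latent pre rate
#' times the generative rate ratio \code{post_rate_ratio_exac}. Each event
#' is classified mild / moderate / severe by the configured severity mix;
#' severe events (hospital admissions) carry at least one hospital day,
#' with extra days Poisson-distributed. In the post period the mean
#' per-event hospital days are scaled by
#' \code{post_rate_ratio_hospdays / post_rate_ratio_exac} so that the day
#' totals carry their own generative rate ratio.
#'
#' @param profile One row of [generate_cohort()] output.
#' @param period \code{"pre"} or \code{"post"}.
#' @param config The [sim_config()] used for the cohort.
#' @return Data frame with one row per event: \code{patient_id},
#'   \code{period}, \code{day} (0-based, sorted, within the period),
#'   \code{severity}, \code{hosp_days}.
#' @export
simulate_events <- function(profile, period, config) {
  if (!period %in% c("pre", "post")) {
    stop("unknown period label: '", period, "' (expected \"pre\" or \"post\")")
  }
  validate_sim_config(config)
  idx <- patient_index(profile$patient_id)
  with_seed(substream_seed(config$seed, idx, paste0("events_", period)), {
    exposure <- if (period == "pre") 365 else profile$followup_post
    rate <- profile$latent_pre_rate *
      if (period == "post") config$post_rate_ratio_exac else 1
    n_events <- stats::rpois(1, rate * exposure / 365)
    if (n_events == 0) return(empty_events())
    days <- sort(sample.int(as.integer(exposure), n_events, replace = TRUE) - 1L)
    severity <- sample(names(config$severity_probs), n_events, replace = TRUE,
                       prob = config$severity_probs)
    mean_days <- config$hosp_days_per_severe_mean *
      if (period == "post") {
        config$post_rate_ratio_hospdays / config$post_rate_ratio_exac
      } else 1
    hosp_days <- integer(n_events)
    severe <- severity == "severe"
    # admissions last at least one day; extra days are Poisson
    hosp_days[severe] <- 1L + stats::rpois(sum(severe), max(mean_days - 1, 0))
    data.frame(patient_id = profile$patient_id, period = period, day = days,
               severity = severity, hosp_days = hosp_days,
               stringsAsFactors = FALSE)
  })
}

empty_events <- function() {
  data.frame(patient_id = character(0), period = character(0),
             day = integer(0), severity = character(0),
             hosp_days = integer(0), stringsAsFactors = FALSE)
}

patient_index <- function(patient_id) {
  idx <- suppressWarnings(as.integer(sub("^p", "", patient_id)))
  ifelse(is.na(idx), (sum(utf8ToInt(paste(patient_id, collapse = ""))) %% 99991L) + 1L, idx)
}

#' Simulate a daily monitoring log for one patient
#'
#' Produces one record per follow-up day (day 0 to
#' \code{followup_post - 1}). The daily symptom question is answered with
#' probability \code{adherence_prob}; an answered question reports
#' worsening with high probability inside the symptom window around each
#' post-period event (from \code{symptom_window[1]} days before onset to
#' \code{symptom_window[2]} days after) and with a low background
#' probability otherwise. On-demand severity answers occur only on days
#' with a "worse" answer. Daily steps fluctuate log-normally around the
#' patient's habitual level and drop by \code{exac_step_decline} inside
#' event windows. CCQ scores appear only on scheduled days
#' (see [ccq_due()]) that were adhered to.
#'
#' @param profile One row of [generate_cohort()] output.
#' @param events Post-period events for this patient, as returned by
#'   [simulate_events()].
#' @param config The [sim_config()] used for the cohort.
#' @return Data frame with one row per day: \code{patient_id}, \code{day},
#'   \code{base_answered}, \code{base_worse} (`NA` when unanswered),
#'   \code{plus_answer} (`NA` when absent), \code{steps}, \code{ccq}
#'   (`NA` off-schedule).
#' @export
simulate_daily_records <- function(profile, events, config) {
  validate_sim_config(config)
  n_days <- as.integer(profile$followup_post)
  if (n_days <= 0) return(empty_daily_records())
  idx <- patient_index(profile$patient_id)
  with_seed(substream_seed(config$seed, idx, "daily"), {
    day <- 0:(n_days - 1)
    in_window <- rep(FALSE, n_days)
    for (d in events$day) {
      lo <- max(0, d - config$symptom_window[1])
      hi <- min(n_days - 1, d + config$symptom_window[2])
      in_window[(lo:hi) + 1L] <- TRUE
    }
    answered <- stats::runif(n_days) < config$adherence_prob
    p_worse <- ifelse(in_window, config$event_worse_prob,
                      config$background_worse_prob)
    worse <- ifelse(answered, stats::runif(n_days) < p_worse, NA)

    plus <- rep(NA_character_, n_days)
    symptomatic <- !is.na(worse) & worse
    asks <- symptomatic & stats::runif(n_days) < config$plus_prob
    if (any(asks)) {
      u <- stats::runif(sum(asks))
      orange_pool <- c("HEMOPTYSIS", "FEVER", "TOO_SICK_FOR_ACTIVITIES")
      red_pool <- c("VERY_DYSPNEIC", "CHEST_PAIN", "CONFUSED", "FORGETFULNESS",
                    "DIZZINESS", "COLLAPSE_TENDENCY", "LOSS_OF_CONSCIOUSNESS")
      ans <- character(sum(asks))
      is_red <- u < config$plus_red_prob
      is_orange <- !is_red & u < config$plus_red_prob + config$plus_orange_prob
      ans[is_red] <- sample(red_pool, sum(is_red), replace = TRUE)
      ans[is_orange] <- sample(orange_pool, sum(is_orange), replace = TRUE)
      ans[!is_red & !is_orange] <- "NONE"
      plus[asks] <- ans
    }

    # habitual step level: log-normal across patients with the configured
    # mean and SD on the natural scale
    cv2 <- (config$steps_baseline_sd / config$steps_baseline_mean)^2
    sdlog <- sqrt(log1p(cv2))
    habitual <- stats::rlnorm(1, log(config$steps_baseline_mean) - sdlog^2 / 2,
                              sdlog)
    steps <- round(habitual * exp(stats::rnorm(n_days, 0, config$step_noise_sd)) *
                     ifelse(in_window, 1 - config$exac_step_decline, 1))

    ccq_base <- min(6, max(0, stats::rnorm(1, config$ccq_mean, config$ccq_sd)))
    ccq <- rep(NA_real_, n_days)
    due <- ccq_due(day) & answered
    ccq[due] <- pmin(6, pmax(0, ccq_base + stats::rnorm(sum(due), 0, 0.3)))

    data.frame(patient_id = profile$patient_id, day = day,
               base_answered = answered, base_worse = worse,
               plus_answer = plus, steps = as.numeric(steps),
               ccq = round(ccq, 1), stringsAsFactors = FALSE)
  })
}

empty_daily_records <- function() {
  data.frame(patient_id = character(0), day = integer(0),
             base_answered = logical(0), base_worse = logical(0),
             plus_answer = character(0), steps = numeric(0), ccq = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort: profiles, events and daily logs
#'
#' Convenience wrapper running [generate_cohort()], [simulate_events()]
#' for both periods and (optionally) [simulate_daily_records()] for every
#' patient.
#'
#' @param config A [sim_config()].
#' @param daily Also generate daily monitoring logs (the slowest part;
#'   rate analyses only need events).
#' @return A list with data frames \code{cohort}, \code{events} (column
#'   \code{period} distinguishes pre/post) and \code{daily_records}
#'   (empty if \code{daily = FALSE}).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 4, seed = 11), daily = FALSE)
#' table(sim$events$period)
simulate_cohort <- function(config, daily = TRUE) {
  cohort <- generate_cohort(config)
  ev <- lapply(seq_len(nrow(cohort)), function(i) {
    rbind(simulate_events(cohort[i, ], "pre", config),
          simulate_events(cohort[i, ], "post", config))
  })
  events <- do.call(rbind, c(list(empty_events()), ev))
  daily_records <- empty_daily_records()
  if (daily && nrow(cohort) > 0) {
    dr <- lapply(seq_len(nrow(cohort)), function(i) {
      post <- events[events$patient_id == cohort$patient_id[i] &
                       events$period == "post", , drop = FALSE]
      simulate_daily_records(cohort[i, ], post, config)
    })
    daily_records <- do.call(rbind, dr)
  }
  list(cohort = cohort, events = events, daily_records = daily_records)
}
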