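#' Configuration of the synthetic COPD cohort simulator
#'
#' Bundles every knob of the generative model into a validated list. The
#' defaults describe a secondary-care COPD population at high risk of
#' exacerbations: mean age 67.4 (SD 8.0) years, 45% women, FEV1 45.5
#' (SD 17.7) % predicted, mostly GOLD category D, a pre-intervention
#' exacerbation rate of 2.4 events per person-year (dominated by severe,
#' i.e. hospitalised, events), about 4 hospital days per severe event,
#' post-period follow-up with median 587 days (IQR 372-594), 10%
#' mortality, and imperfect daily questionnaire adherence (43%).
#'
#' @param n_patients Number of simulated patients.
#' @param seed Integer master seed; every random draw in the simulator is a
#'   deterministic function of it (per-patient substreams are derived from
#'   it, so results do not depend on call order).
#' @param age_mean,age_sd Age distribution (years).
#' @param prop_female Proportion of women.
#' @param fev1pp_mean,fev1pp_sd FEV1 as percent of predicted.
#' @param gold_probs Named probability vector over GOLD categories
#'   \code{A}, \code{B}, \code{C}, \code{D} and \code{missing}; must sum
#'   to 1.
#' @param ics_prob Probability of inhaled corticosteroid use.
#' @param pre_exac_rate Pre-period exacerbation rate, events/person-year.
#' @param severity_probs Named probability vector over \code{mild},
#'   \code{moderate}, \code{severe}; must sum to 1. Severe means
#'   hospitalised.
#' @param hosp_days_per_severe_mean Mean hospital days per severe event
#'   (days are 1 + Poisson, guaranteeing at least one day per admission).
#' @param post_rate_ratio_exac Generative post/pre rate ratio for
#'   exacerbation counts.
#' @param post_rate_ratio_hospdays Generative post/pre rate ratio for
#'   hospitalised days (induced by scaling per-event hospital days in the
#'   post period).
#' @param rate_dispersion Between-patient heterogeneity of the latent
#'   exacerbation rate: 0 gives a shared rate (marginally Poisson counts);
#'   a positive value d draws per-patient gamma frailties with shape 1/d
#'   (marginally negative binomial counts).
#' @param followup_median,followup_iqr Median and IQR (length-2 vector) of
#'   post-period follow-up in days.
#' @param followup_range Support (min, max) of the follow-up distribution.
#' @param mortality_prob Probability of death during follow-up; deaths
#'   truncate follow-up (drawn from the lower half of the distribution).
#' @param adherence_prob Daily probability of answering the symptom (BASE)
#'   question.
#' @param event_worse_prob,background_worse_prob Probability that an
#'   answered daily question reports worsening inside / outside an
#'   exacerbation window.
#' @param symptom_window Days around each event onset with elevated
#'   symptoms and depressed steps: \code{c(before, after)}.
#' @param plus_prob Probability that an on-demand (PLUS) question is filled
#'   out on a day with a "worse" answer.
#' @param plus_orange_prob,plus_red_prob Probability that a filled-out
#'   on-demand answer falls in the orange / red class (otherwise benign).
#' @param steps_baseline_mean,steps_baseline_sd Across-patient mean and SD
#'   of the habitual daily step count (log-normal).
#' @param step_noise_sd Day-to-day log-scale SD of steps around the
#'   habitual level.
#' @param exac_step_decline Fractional step decline during exacerbation
#'   windows.
#' @param ccq_mean,ccq_sd Across-patient distribution of the CCQ
#'   health-status score (0-6 scale).
#' @return A validated list of class \code{sim_config}.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 10, seed = 42)
#' cfg$pre_exac_rate
sim_config <- function(n_patients = 29L,
                       seed = 1L,
                       age_mean = 67.4, age_sd = 8.0,
                       prop_female = 0.45,
                       fev1pp_mean = 45.5, fev1pp_sd = 17.7,
                       gold_probs = c(A = 0, B = 1, C = 1, D = 21,
                                      missing = 6) / 29,
                       ics_prob = 0.55,
                       pre_exac_rate = 2.4,
                       severity_probs = c(mild = 0.05, moderate = 0.10,
                                          severe = 0.85),
                       hosp_days_per_severe_mean = 4,
                       post_rate_ratio_exac = 0.310,
                       post_rate_ratio_hospdays = 0.210,
                       rate_dispersion = 0,
                       followup_median = 587,
                       followup_iqr = c(372, 594),
                       followup_range = c(360, 600),
                       mortality_prob = 0.10,
                       adherence_prob = 0.43,
                       event_worse_prob = 0.90,
                       background_worse_prob = 0.08,
                       symptom_window = c(3, 7),
                       plus_prob = 0.5,
                       plus_orange_prob = 0.10,
                       plus_red_prob = 0.10,
                       steps_baseline_mean = 2500,
                       steps_baseline_sd = 1500,
                       step_noise_sd = 0.25,
                       exac_step_decline = 0.4,
                       ccq_mean = 3.0, ccq_sd = 1.2) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

check_prob <- function(cfg, field) {
  v <- cfg[[field]]
  if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1)) {
    stop("invalid configuration: '", field, "' must be a probability in [0, 1]",
         call. = FALSE)
  }
}

check_pos <- function(cfg, field, strict = TRUE) {
  v <- cfg[[field]]
  ok <- is.numeric(v) && !any(is.na(v)) && all(if (strict) v > 0 else v >= 0)
  if (!ok) {
    stop("invalid configuration: '", field, "' must be ",
         if (strict) "positive" else "non-negative", call. = FALSE)
  }
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients)) {
    stop("invalid configuration: 'n_patients' must be a non-negative integer",
         call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop("invalid configuration: 'seed' must be an integer", call. = FALSE)
  }
  for (f in c("prop_female", "ics_prob", "mortality_prob", "adherence_prob",
              "event_worse_prob", "background_worse_prob", "plus_prob",
              "plus_orange_prob", "plus_red_prob", "exac_step_decline")) {
    check_prob(cfg, f)
  }
  for (f in c("age_sd", "fev1pp_sd", "hosp_days_per_severe_mean",
              "post_rate_ratio_exac", "post_rate_ratio_hospdays",
              "followup_median", "steps_baseline_mean", "steps_baseline_sd",
              "step_noise_sd", "ccq_sd")) {
    check_pos(cfg, f)
  }
  for (f in c("pre_exac_rate", "rate_dispersion")) check_pos(cfg, f, strict = FALSE)
  for (f in c("gold_probs", "severity_probs")) {
    check_prob(cfg, f)
    if (abs(sum(cfg[[f]]) - 1) > 1e-8) {
      stop("invalid configuration: '", f, "' must sum to 1", call. = FALSE)
    }
  }
  if (length(cfg$gold_probs) != 5 ||
      !setequal(names(cfg$gold_probs), c("A", "B", "C", "D", "missing"))) {
    stop("invalid configuration: 'gold_probs' needs names A, B, C, D, missing",
         call. = FALSE)
  }
  if (length(cfg$followup_iqr) != 2 || diff(cfg$followup_iqr) < 0) {
    stop("invalid configuration: 'followup_iqr' must be c(q25, q75) with q25 <= q75",
         call. = FALSE)
  }
  q <- c(cfg$followup_range[1], cfg$followup_iqr[1], cfg$followup_median,
         cfg$followup_iqr[2], cfg$followup_range[2])
  if (is.unsorted(q)) {
    stop("invalid configuration: follow-up range, IQR and median must be ordered",
         call. = FALSE)
  }
  if (length(cfg$symptom_window) != 2 || any(cfg$symptom_window < 0)) {
    stop("invalid configuration: 'symptom_window' must be c(days_before, days_after), both >= 0",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients, seed", x$seed, "\n")
  cat("  pre exacerbation rate:", x$pre_exac_rate, "/person-year;",
      "post/pre rate ratios:", x$post_rate_ratio_exac, "(events),",
      x$post_rate_ratio_hospdays, "(hospital days)\n")
  cat("  follow-up median", x$followup_median, "days (IQR",
      paste(x$followup_iqr, collapse = "-"), "); mortality",
      x$mortality_prob, "; daily adherence", x$adherence_prob, "\n")
  invisible(x)
}

#' Read a simulator configuration from a JSON or YAML file
#'
#' Keys are the arguments of [sim_config()]; absent keys keep their
#' defaults. YAML files require the \pkg{yaml} package.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  for (f in c("gold_probs", "severity_probs")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, raw)
}

# Deterministic per-patient / per-purpose substream seed below 2^31,
# derived from the master seed so that generation is call-order invariant.
substream_seed <- function(seed, patient_index, tag) {
  tag_code <- sum(utf8ToInt(tag)) %% 1009L
  val <- (as.numeric(seed) %% 2147483647) * 69621 +
    patient_index * 75053 + tag_code * 30269
  as.integer(val %% 2147483647)
}

# Evaluate an expression under a local RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
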