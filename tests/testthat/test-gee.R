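make_table <- function(pre_counts, post_counts, pre_exp, post_exp) {
  n <- length(pre_counts)
  data.frame(patient_id = rep(sprintf("p%02d", 1:n), each = 2),
             intervention = rep(0:1, n),
             exposure_days = as.vector(rbind(pre_exp, post_exp)),
             n_exacerbations = as.vector(rbind(pre_counts, post_counts)),
             n_hosp_days = as.vector(rbind(pre_counts, post_counts)),
             age = rep(65, 2 * n), sex = factor(rep("male", 2 * n),
                                                levels = c("male", "female")),
             gold = rep("D", 2 * n), ics_use = rep(FALSE, 2 * n),
             stringsAsFactors = FALSE)
}

test_that("the intervention-only IRR equals the ratio of pooled rates", {
  tab <- make_table(pre_counts = c(2, 3, 1), post_counts = c(1, 0, 1),
                    pre_exp = rep(365, 3), post_exp = c(400, 500, 600))
  fit <- fit_irr(tab, "exacerbations", model_id = 1, family = "poisson",
                 corstr = "independence")
  expect_equal(fit$irr, (2 / 1500) / (6 / 1095), tolerance = 1e-8)
  expect_equal(fit$irr, oracle_pooled_irr(tab, "exacerbations"),
               tolerance = 1e-10)
  # GEEFit invariants
  expect_equal(fit$irr, exp(fit$coefficients[["intervention"]]))
  expect_equal(fit$ci_low, exp(log(fit$irr) - 1.96 * fit$robust_se))
  expect_equal(fit$ci_high, exp(log(fit$irr) + 1.96 * fit$robust_se))
  expect_lte(fit$ci_low, fit$irr)
  expect_lte(fit$irr, fit$ci_high)
})

test_that("a perfectly symmetric table gives IRR 1", {
  tab <- make_table(pre_counts = c(2, 0, 3, 1), post_counts = c(2, 0, 3, 1),
                    pre_exp = rep(365, 4), post_exp = rep(365, 4))
  fit <- fit_irr(tab, "exacerbations", model_id = 1, family = "poisson")
  expect_equal(fit$irr, 1.0, tolerance = 1e-8)
})

test_that("independence GEE coefficients match a Poisson GLM to 1e-6", {
  tab <- fixed_period_table(seed = 42, n = 40)
  for (m in c(1, 2, 4)) {
    terms <- switch(as.character(m),
                    `1` = ".y ~ intervention",
                    `2` = ".y ~ intervention + sex + age",
                    `4` = ".y ~ intervention + sex + age + gold + ics_use")
    fit <- fit_irr(tab, "exacerbations", model_id = m, family = "poisson",
                   corstr = "independence")
    d <- if (m == 4) tab[!is.na(tab$gold), ] else tab
    d$.y <- d$n_exacerbations
    ref <- glm(as.formula(paste(terms, "+ offset(log(exposure_days))")),
               data = d, family = poisson())
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
  }
})

test_that("robust standard errors match an independent cluster sandwich", {
  skip_if_not_installed("sandwich")
  tab <- fixed_period_table(seed = 7, n = 60)
  tab$.y <- tab$n_exacerbations
  fit <- gee_count(.y ~ intervention + offset(log(exposure_days)), tab,
                   id = patient_id, corstr = "independence")
  ref <- glm(.y ~ intervention + offset(log(exposure_days)), data = tab,
             family = poisson())
  vc <- sandwich::vcovCL(ref, cluster = tab$patient_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(sqrt(diag(fit$vcov)), sqrt(diag(vc)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("exchangeable and independence estimates agree closely on paired counts", {
  tab <- fixed_period_table(seed = 11, n = 80)
  f1 <- fit_irr(tab, "exacerbations", 1, family = "poisson",
                corstr = "exchangeable")
  f2 <- fit_irr(tab, "exacerbations", 1, family = "poisson",
                corstr = "independence")
  expect_equal(f1$irr, f2$irr, tolerance = 0.02)
  expect_true(abs(f1$alpha) < 0.5)
})

test_that("covariate adjustment is nearly inert in the within-patient design", {
  tab <- fixed_period_table(seed = 19, n = 300)
  f1 <- fit_irr(tab, "exacerbations", 1, family = "poisson")
  f2 <- fit_irr(tab, "exacerbations", 2, family = "poisson")
  expect_lt(abs(f1$irr - f2$irr), 0.02)
})

test_that("rescaling the post period leaves the intervention-only IRR unchanged", {
  tab <- make_table(pre_counts = c(4, 2, 5, 1), post_counts = c(1, 2, 0, 1),
                    pre_exp = rep(365, 4), post_exp = c(300, 450, 500, 380))
  f0 <- fit_irr(tab, "exacerbations", 1, family = "poisson",
                corstr = "independence")
  scaled <- tab
  post <- scaled$intervention == 1
  scaled$exposure_days[post] <- scaled$exposure_days[post] * 3
  scaled$n_exacerbations[post] <- scaled$n_exacerbations[post] * 3
  f1 <- fit_irr(scaled, "exacerbations", 1, family = "poisson",
                corstr = "independence")
  expect_equal(f0$irr, f1$irr, tolerance = 1e-8)
})

test_that("degenerate tables raise informative errors", {
  tab <- make_table(pre_counts = c(0, 0), post_counts = c(0, 0),
                    pre_exp = rep(365, 2), post_exp = rep(400, 2))
  expect_error(select_family(tab, "exacerbations"), "zero")
  one <- make_table(pre_counts = 2, post_counts = 1, pre_exp = 365,
                    post_exp = 400)
  expect_error(fit_irr(one, "exacerbations", 1, family = "poisson"),
               "2 patients|2 clusters")
  expect_error(fit_irr(tab, "exacerbations", 9), "model_id")
})

test_that("family selection separates equi- from over-dispersed counts", {
  set.seed(314)
  n <- 500
  pois_tab <- make_table(pre_counts = rpois(n, 2), post_counts = rpois(n, 2),
                         pre_exp = rep(365, n), post_exp = rep(365, n))
  sel <- select_family(pois_tab, "exacerbations")
  expect_equal(as.character(sel), "poisson")
  expect_lt(attr(sel, "dispersion"), 1.5)

  nb_tab <- make_table(pre_counts = rnbinom(n, size = 0.5, mu = 2),
                       post_counts = rnbinom(n, size = 0.5, mu = 2),
                       pre_exp = rep(365, n), post_exp = rep(365, n))
  sel2 <- select_family(nb_tab, "exacerbations")
  expect_equal(as.character(sel2), "negative_binomial")

  # NB GEE also runs and recovers the pooled ratio on such data
  nb_fit <- fit_irr(nb_tab, "exacerbations", 1, family = "negative_binomial")
  expect_equal(nb_fit$irr, oracle_pooled_irr(nb_tab, "exacerbations"),
               tolerance = 0.05)
})

test_that("CCQ trends respond to direction and stay calibrated under the null", {
  up <- do.call(rbind, lapply(1:8, function(p) {
    data.frame(patient_id = p, day = seq(0, 180, by = 30),
               ccq = 2 + 0.1 * (0:6))
  }))
  t_up <- ccq_trend(up)
  expect_gt(t_up$slope, 0)

  rev <- transform(up, day = max(up$day) - day)
  t_rev <- ccq_trend(rev)
  expect_equal(t_rev$slope, -t_up$slope, tolerance = 1e-10)

  expect_warning(t_flat <- ccq_trend(transform(up, ccq = 3)), "identical")
  expect_equal(t_flat$slope, 0)
  expect_error(ccq_trend(up[1:2, ]), "2 patients|at least 2")

  # type-I error under a null with patient-level heterogeneity
  set.seed(1847)
  reject <- replicate(400, {
    d <- do.call(rbind, lapply(1:200, function(p) {
      data.frame(patient_id = p, day = seq(0, 150, by = 30),
                 ccq = rnorm(1, 3, 1) + rnorm(6, 0, 0.4))
    }))
    ccq_trend(d)$p_value < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.025)
})

test_that("the GEE recovers a known generative log rate ratio", {
  # 30 cohorts of 500 patients; the mean log-IRR must sit within 3 MC
  # standard errors of the generative value and well inside +/-0.05
  reps <- 30
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_patients = 500, seed = 5000 + r)
    sim <- simulate_cohort(cfg, daily = FALSE)
    tab <- build_period_table(sim$cohort, sim$events)
    f <- fit_irr(tab, "exacerbations", 1, family = "poisson")
    est[r] <- log(f$irr)
    se[r] <- f$robust_se
  }
  beta <- log(0.310)
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - beta), 3 * mc_se + 0.01)
  expect_lt(abs(mean(est) - beta), 0.05)
})
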