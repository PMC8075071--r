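# copdwatch

Simulation and pre-post analysis of a zone-based ("traffic light")
telemonitoring action plan for chronic obstructive pulmonary disease
(COPD).

Remote-monitoring programs for exacerbation-prone COPD patients combine a
daily symptom questionnaire, an on-demand severity question, and a
wearable step counter. Answers and step counts map the patient onto
ordered zones — green (steady state), yellow (symptoms worsened: adapt
medication per the personal exacerbation plan), orange (no improvement in
3 days, or a serious on-demand answer: emergency medication or contact a
professional), red (life-threatening: the informal caregiver, the
"buddy", is advised to call an ambulance) — and every zone change alerts
the buddy. Evaluations of such programs are typically small,
single-centre, pre-post designs without a control group, so their
analysis pipeline deserves to be exercised and validated on data with a
*known* effect size. `copdwatch` provides exactly that: a calibrated
synthetic cohort generator, a deterministic implementation of the zone
rules, usage summaries, and the pre-post count analysis, with no patient
data involved.

## The model at the core

For patient *i* in period *j* (pre-inclusion year vs post-inclusion
follow-up), the outcome count $Y_{ij}$ (total exacerbations, or days
admitted to hospital) is modelled marginally as

$$\log E[Y_{ij}] = \log t_{ij} + \beta_0 + \beta_1 \cdot \text{post}_{ij} + \gamma' z_i$$

where $t_{ij}$ is the exposure time (365 days pre; follow-up until data
extraction or death post), $\text{post}_{ij}$ is the intervention
indicator and $z_i$ are optional baseline covariates (sex, age, GOLD
category, inhaled corticosteroid use). The two periods of a patient form
a cluster: coefficients are estimated by generalized estimating equations
(GEE) with an exchangeable working correlation and robust (sandwich)
standard errors, and $e^{\beta_1}$ is the post-vs-pre **incidence rate
ratio (IRR)**. A Pearson-dispersion check chooses between the Poisson and
negative binomial variance functions. The GEE fitter (`gee_count()`) is
implemented in the package; with an independence working correlation its
estimates coincide with a Poisson GLM, which the tests exploit as an
independent oracle.

The companion power calculation (`paired_sample_size()`) solves the
paired-means noncentral-*t* sample size for a targeted reduction in
admission days and inflates it for dropout.

## Worked example

```r
library(copdwatch)

# a 29-patient cohort under the default study conditions
res <- run_pipeline(sim_config(), out_dir = "demo", quiet = TRUE)

res$fits$exacerbations_model1
#> Pre-post IRR, outcome 'exacerbations', model 1 (poisson GEE, exchangeable)
#> IRR 0.274 (95% CI 0.191-0.395), 29 patients

res$fits$hosp_days_model1
#> Pre-post IRR, outcome 'hosp_days', model 1 (negative_binomial GEE, exchangeable)
#> IRR 0.177 (95% CI 0.103-0.305), 29 patients

median(res$usage$n_base_answered)   # 232 answered daily questions
median(res$usage$n_base_yes)        # 20 "worse" answers per patient

paired_sample_size(1.5, 0.75, 1.125, 0.56, correlation = 0.4,
                   dropout = 0.20)
#> [1] 40   (32 analysed patients inflated for 20% dropout)
```

The generative post/pre rate ratios behind this simulation are 0.310
(exacerbations) and 0.210 (hospital days); at n = 29 a single cohort
estimates them with wide uncertainty (the point of simulating), while
averaging over many 500-patient cohorts recovers them closely. The
crude exacerbation IRR of 0.274 above means the simulated post period
shows a 73% reduction in the exacerbation rate, with the 95% CI
excluding 1.

`run_pipeline()` also writes `cohort.csv`, `events.csv`,
`daily_records.csv`, the replayed `zones.csv` and `alerts.csv`, a
per-patient `usage_summary.csv`, the `period_table.csv` analysis table,
`fit.json` (all four adjustment models for both outcomes),
`cohort_summary.json`, `ccq_trend.json` and a `manifest.json` with the
seed and config digest.

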