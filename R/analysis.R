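# Survival analysis of simulated cohorts (Kaplan-Meier, Cox hazard ratios),
# drug-usage accounting, and the catalog of named experiment presets.
# Model fits delegate to the survival package; Efron tie handling and Wald
# 95% intervals are fixed as the contract.

#' Kaplan-Meier curve for one treatment arm
#'
#' Product-limit estimator with right censoring at the simulation horizon.
#'
#' @param records Data frame with columns `time_days` (or `time`) and
#'   `event`, one row per replicate.
#' @return Data frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `survival` at each distinct event or censoring time.
#' @export
kaplan_meier <- function(records) {
  records <- as_survival_records(records, need_arm = FALSE)
  if (nrow(records) == 0) stop("need at least one survival record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, survival = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Cox proportional-hazards comparison of two arms
#'
#' Fits a proportional-hazards model with a single arm indicator (Efron tie
#' handling) and reports the hazard ratio of the non-reference arm with its
#' Wald 95% confidence interval and p-value. HR < 1 means the experimental
#' arm progresses more slowly than the reference.
#'
#' @param records Data frame with columns `time_days` (or `time`), `event`
#'   and `arm` (exactly two distinct labels).
#' @param reference Arm label used as the baseline.
#' @return List of class `hr_estimate`: `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `arm`, `reference`, `n_events`.
#' @export
cox_hazard_ratio <- function(records, reference) {
  records <- as_survival_records(records, need_arm = TRUE)
  arms <- unique(records$arm)
  if (length(arms) != 2) stop("records must contain exactly two arms")
  if (!reference %in% arms) stop("reference arm not present in records")
  if (sum(records$event) == 0) stop("no events: hazard ratio inestimable")
  records$arm <- factor(records$arm, levels = c(reference, setdiff(arms, reference)))
  fit <- survival::coxph(survival::Surv(time, event) ~ arm, data = records,
                         ties = "efron")
  s <- summary(fit)
  structure(list(hr = unname(s$conf.int[1, "exp(coef)"]),
                 ci_low = unname(s$conf.int[1, "lower .95"]),
                 ci_high = unname(s$conf.int[1, "upper .95"]),
                 p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
                 arm = setdiff(arms, reference), reference = reference,
                 n_events = sum(records$event)),
            class = "hr_estimate")
}

# Normalize a survival table: accept `time_days` or `time`.
as_survival_records <- function(records, need_arm = TRUE) {
  records <- as.data.frame(records)
  if (!"time" %in% names(records)) {
    if (!"time_days" %in% names(records)) stop("records need a time or time_days column")
    records$time <- records$time_days
  }
  if (!"event" %in% names(records)) stop("records need an event column")
  if (need_arm && !"arm" %in% names(records)) stop("records need an arm column")
  records$event <- as.logical(records$event)
  records
}

#' Drug usage of an arm relative to standard treatment
#'
#' Mean cumulative administered dose of each drug in the arm, divided by the
#' same mean under the comparator cohort, accounted over the full simulated
#' horizon.
#'
#' @param arm_cohort,st_cohort [run_replicates()] cohorts (the experimental
#'   arm and the standard-treatment comparator).
#' @return Named numeric vector `c(drug1, drug2)` of usage fractions.
#' @export
drug_usage_fraction <- function(arm_cohort, st_cohort) {
  mean_dose <- function(cohort)
    colMeans(do.call(rbind, lapply(cohort$results, `[[`, "cumulative_dose")))
  st <- mean_dose(st_cohort)
  if (any(st == 0)) stop("comparator cohort administered no drug")
  mean_dose(arm_cohort) / st
}

#' Catalog of named experiment presets
#'
#' Full simulation configurations for the study conditions explored with the
#' model: the default parameters; the 3x fitness-cost variant (division
#' 0.04/0.03/0.03/0.02, so singly resistant cells grow twice as fast as
#' doubly resistant ones); low/high cell-turnover variants that halve or
#' double the death rate while preserving every phenotype's net growth rate
#' and doubling time; tenfold-slowed kinetics; replacement probabilities 0,
#' 0.5 and 1; Delta Tumor 5/10/20/40%; Delta Dose 25/50/75%; treatment
#' vacations at 10/50/80% of the initiation burden; FD-Intermittent stop
#' thresholds at 50/80/90/95% of the initiation burden; and the
#' no-reverse-mutation variant. Presets fix the biology and controller
#' parameters; set `protocol` (and `label`) on the returned configuration to
#' choose the treatment arm.
#'
#' @param ... Overrides forwarded to every preset (e.g. `duration`,
#'   `protocol`).
#' @return Named list of [sim_config()] objects.
#' @export
#' @examples
#' names(experiment_presets())
experiment_presets <- function(...) {
  base <- list(...)
  mk <- function(...) do.call(sim_config, modifyList(base, list(...)))
  list(
    defaults = mk(),
    cost_3x = mk(division_rates = c(0.04, 0.03, 0.03, 0.02)),
    low_turnover = mk(death_rate = 0.005,
                      division_rates = c(0.055, 0.035, 0.035, 0.015)),
    high_turnover = mk(death_rate = 0.02,
                       division_rates = c(0.07, 0.05, 0.05, 0.03)),
    tenfold_slow = mk(death_rate = 0.001,
                      division_rates = c(0.006, 0.004, 0.004, 0.002)),
    replacement_0 = mk(replacement_prob = 0),
    replacement_50 = mk(replacement_prob = 0.5),
    replacement_100 = mk(replacement_prob = 1),
    delta_tumor_5 = mk(delta_tumor = 0.05),
    delta_tumor_10 = mk(delta_tumor = 0.10),
    delta_tumor_20 = mk(delta_tumor = 0.20),
    delta_tumor_40 = mk(delta_tumor = 0.40),
    delta_dose_25 = mk(delta_dose = 0.25),
    delta_dose_50 = mk(delta_dose = 0.50),
    delta_dose_75 = mk(delta_dose = 0.75),
    vacation_10 = mk(vacation_threshold = 500),
    vacation_50 = mk(vacation_threshold = 2500),
    vacation_80 = mk(vacation_threshold = 4000),
    fd_stop_at_50 = mk(fd_stop_fraction = 0.50),
    fd_stop_at_80 = mk(fd_stop_fraction = 0.20),
    fd_stop_at_90 = mk(fd_stop_fraction = 0.10),
    fd_stop_at_95 = mk(fd_stop_fraction = 0.05),
    no_reverse = mk(allow_reverse = FALSE)
  )
}
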