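# Shared builders: deterministic toy tables and records. Everything is
# generated in code; no stored fixtures beyond the reference JSON tables.

# one participant row; defaults are the centered reference profile
make_record <- function(participant_id = "P1", trial_id = "T1",
                        trial_year = 2000, arm = "placebo",
                        age = 35, sex_male = 0, bmi = 20,
                        baseline_cdai = 300, crp = 10,
                        tnfi_history = 0, steroid_use = 0,
                        immunomodulator_use = 0, ileal_disease = 0,
                        cdai_visits = NA_character_,
                        cdai_week8 = NA_real_,
                        cdai_reduction = NA_real_,
                        week8_imputed = FALSE) {
  data.frame(participant_id = participant_id, trial_id = trial_id,
             trial_year = trial_year, arm = arm, age = age,
             sex_male = sex_male, bmi = bmi,
             baseline_cdai = baseline_cdai, crp = crp,
             tnfi_history = tnfi_history, steroid_use = steroid_use,
             immunomodulator_use = immunomodulator_use,
             ileal_disease = ileal_disease, cdai_visits = cdai_visits,
             cdai_week8 = cdai_week8, cdai_reduction = cdai_reduction,
             week8_imputed = week8_imputed,
             stringsAsFactors = FALSE)
}

# n rows of varied covariates over the given trials (deterministic given seed)
make_covariate_table <- function(n, trials = c("A", "B"),
                                 years = NULL, arm = "placebo",
                                 seed = 1) {
  set.seed(seed)
  if (is.null(years)) years <- 2000 + seq_along(trials)
  tid <- rep(trials, length.out = n)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    trial_id = tid,
    trial_year = years[match(tid, trials)],
    arm = arm,
    age = runif(n, 20, 60),
    sex_male = rbinom(n, 1, 0.5),
    bmi = runif(n, 18, 32),
    baseline_cdai = runif(n, 230, 430),
    crp = runif(n, 1, 40),
    tnfi_history = rbinom(n, 1, 0.4),
    steroid_use = rbinom(n, 1, 0.4),
    immunomodulator_use = rbinom(n, 1, 0.3),
    ileal_disease = rbinom(n, 1, 0.7),
    cdai_visits = NA_character_,
    cdai_week8 = NA_real_,
    cdai_reduction = NA_real_,
    week8_imputed = FALSE,
    stringsAsFactors = FALSE)
}

# a constant-intercept effect model (all other coefficients zero)
constant_model <- function(intercept, include_year = FALSE,
                           label = "drug_attributable:ADA") {
  sc <- covariate_scheme(include_year)
  beta <- setNames(rep(0, length(sc$terms)), sc$terms)
  beta["intercept"] <- intercept
  effect_model(beta, sc, label)
}

# arm data frame with a prescribed remission pattern (baseline 300;
# remitters get reduction 160 -> week-8 CDAI 140, others 100 -> 200)
remission_arm <- function(remitters, n, trial_id = "T1", arm = "placebo",
                          trial_year = 2005) {
  rem <- c(rep(TRUE, remitters), rep(FALSE, n - remitters))
  tab <- make_record(participant_id = sprintf("%s-%03d", trial_id,
                                              seq_len(n)),
                     trial_id = trial_id, trial_year = trial_year,
                     arm = arm)
  tab$cdai_reduction <- ifelse(rem, 160, 100)
  tab$cdai_week8 <- tab$baseline_cdai - tab$cdai_reduction
  tab
}
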