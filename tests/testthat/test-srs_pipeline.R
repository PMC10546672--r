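# srs_pipeline: partition, attributable fit, counterfactual simulation,
# exact test, emulation, validation battery

test_that("partition obeys the arithmetic contract", {
  m70 <- constant_model(70, include_year = TRUE,
                        label = "placebo_effect")
  arm <- rbind(
    make_record("P1", arm = "active:ADA", cdai_week8 = 180,
                cdai_reduction = 120),
    make_record("P2", arm = "active:ADA", cdai_week8 = 270,
                cdai_reduction = 30))
  part <- partition_drug_attributable(m70, trial_table(arm))
  expect_equal(part$drug_component, c(50, -40))  # negatives preserved
  expect_equal(part$observed_reduction,
               part$placebo_component + part$drug_component)
  expect_equal(attr(part, "mean_drug_component"), 5)

  expect_error(partition_drug_attributable(m70,
                                           trial_table(make_record())),
               "placebo-arm")
  expect_error(partition_drug_attributable(constant_model(70), arm),
               "include_year")
  noout <- make_record("P9", arm = "active:ADA")
  expect_error(partition_drug_attributable(m70, trial_table(noout)),
               "absent outcome")
})

test_that("a constant injected drug effect of 68 points is recovered", {
  sc_d <- covariate_scheme(FALSE)
  beta_drug <- setNames(rep(0, 10), sc_d$terms)
  beta_drug["intercept"] <- 68
  design <- data.frame(trial_id = c("D1", "D2", "D3"),
                       year = c(2002, 2006, 2015),
                       arm = "active:ADA", n = 200, p_tnfi = 0.3)
  truth <- synthetic_truth(beta_drug = list(ADA = beta_drug),
                           sigma_u_drug = 0, trial_design = design,
                           seed = 55)
  tab <- generate_ipd(truth)
  # partition against the TRUE placebo model (oracle = generator), with
  # the drawn trial effects removed via the echoed random effects
  true_placebo <- effect_model(truth$beta_placebo, covariate_scheme(TRUE),
                               "placebo_effect")
  part <- partition_drug_attributable(true_placebo, tab)
  u_p <- attr(tab, "random_effects")$u_placebo
  resid <- part$drug_component - unname(u_p[part$trial_id])
  n <- nrow(tab)
  expect_lt(abs(mean(resid) - 68), 3 * truth$sigma_e / sqrt(n))
})

test_that("attributable model recovers the generating age slope", {
  design <- data.frame(trial_id = c("D1", "D2", "D3"),
                       year = c(2002, 2006, 2015),
                       arm = "active:ADA", n = 220, p_tnfi = 0.3)
  truth <- synthetic_truth(sigma_u_drug = 5, sigma_u_placebo = 5,
                           trial_design = design, seed = 66)
  tab <- generate_ipd(truth)
  true_placebo <- effect_model(truth$beta_placebo, covariate_scheme(TRUE),
                               "placebo_effect")
  part <- partition_drug_attributable(true_placebo, tab)
  attrib <- fit_attributable_model(part, tab)
  expect_match(attrib$outcome_label, "^drug_attributable:ADA")
  z_age <- (attrib$coefficients[["age_c"]] - (-1.77)) /
    attrib$standard_errors[["age_c"]]
  expect_lt(abs(z_age), 3)

  expect_error(
    fit_attributable_model(part, tab, covariate_scheme(TRUE)),
    "include_year")
  one_trial <- part[part$trial_id == "D1", ]
  class(one_trial) <- class(part)
  expect_error(fit_attributable_model(one_trial, tab),
               "random intercept unidentifiable")
})

test_that("a near-constant drug component yields an intercept-only model", {
  set.seed(77)
  tab <- trial_table(make_covariate_table(120, trials = c("A", "B", "C"),
                                          arm = "active:ADA", seed = 77),
                     validate = FALSE)
  m70 <- constant_model(70, include_year = TRUE, label = "placebo_effect")
  tab$cdai_reduction <- 70 + 42 + rnorm(120, 0, 1e-7)
  tab$cdai_week8 <- tab$baseline_cdai - tab$cdai_reduction
  part <- partition_drug_attributable(m70, tab)
  attrib <- fit_attributable_model(part, tab)
  expect_lt(abs(attrib$coefficients[["intercept"]] - 42), 1e-6)
  expect_lt(max(abs(attrib$coefficients[-1])), 1e-6)
})

test_that("counterfactual add-back matches the fixture arithmetic", {
  ref <- reference_effect_models()
  rec <- make_record("P1", cdai_week8 = 260, cdai_reduction = 40)
  sim <- simulate_counterfactual_arm(ref$adalimumab, trial_table(rec))
  expect_equal(sim$counterfactual_reduction, 40 + 67.57,
               tolerance = 1e-9)
  expect_equal(sim$counterfactual_week8, 300 - 107.57, tolerance = 1e-9)
  expect_false(remission_status(sim$baseline_cdai,
                                sim$counterfactual_reduction))

  # all-zero attributable model: simulated arm = observed placebo arm
  zero <- constant_model(0)
  sim0 <- simulate_counterfactual_arm(zero, trial_table(rec))
  expect_equal(sim0$counterfactual_reduction, rec$cdai_reduction)
  expect_equal(sim0$counterfactual_week8, rec$cdai_week8)

  expect_error(
    simulate_counterfactual_arm(ref$adalimumab,
                                trial_table(make_record(arm = "active:UST",
                                                        cdai_week8 = 200))),
    "active-arm")
  expect_error(simulate_counterfactual_arm(ref$adalimumab,
                                           trial_table(rec),
                                           draw_trial_effect = TRUE),
               "sigma_u2")
  big <- make_record("P2", baseline_cdai = 250, cdai_week8 = 50,
                     cdai_reduction = 200)
  expect_warning(simulate_counterfactual_arm(ref$adalimumab,
                                             trial_table(big)),
                 "below 0")
})

test_that("partition followed by add-back is the identity", {
  design <- data.frame(trial_id = c("D1", "D2"), year = c(2003, 2009),
                       arm = "active:ADA", n = 80, p_tnfi = 0.3)
  tab <- generate_ipd(synthetic_truth(trial_design = design, seed = 88))
  true_placebo <- effect_model(
    reference_effect_models()$placebo$coefficients,
    covariate_scheme(TRUE), "placebo_effect")
  part <- partition_drug_attributable(true_placebo, tab)
  # add the placebo component back: must reproduce the observed outcome
  expect_equal(part$placebo_component + part$drug_component,
               tab$cdai_reduction, tolerance = 1e-10)
})

test_that("remission threshold is strict at CDAI 150", {
  expect_true(remission_status(300, 160))    # week-8 CDAI 140
  expect_false(remission_status(300, 150))   # boundary
  expect_false(remission_status(140, -20))   # worsening to 160
  expect_equal(remission_status(c(300, 300), c(160, 150)),
               c(TRUE, FALSE))
})

test_that("fisher_exact_2x2 matches enumeration and reference values", {
  expect_identical(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(1, 9, 9, 1), 202 / 184756,
               tolerance = 1e-12)
  expect_equal(round(fisher_exact_2x2(67, 82, 62, 73), 1), 0.9)
  expect_warning(p <- fisher_exact_2x2(0, 0, 3, 4), "zero margin")
  expect_identical(p, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")

  # dual route: independent reference implementation over random tables
  set.seed(101)
  for (i in 1:100) {
    N <- sample(4:40, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    cc <- sample(0:(N - a - b), 1); d <- N - a - b - cc
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
      next
    ours <- fisher_exact_2x2(a, b, cc, d)
    ref <- stats::fisher.test(matrix(c(a, b, cc, d), 2,
                                     byrow = TRUE))$p.value
    expect_equal(ours, min(1, ref), tolerance = 1e-9,
                 info = sprintf("table %d %d %d %d", a, b, cc, d))
  }
})

test_that("emulation builds the 2x2 and renders the reference row", {
  ust <- remission_arm(67, 149, trial_id = "U1", arm = "active:UST")
  ada <- remission_arm(62, 135, trial_id = "A1", arm = "placebo")
  res <- emulate_head_to_head(trial_table(ust), trial_table(ada),
                              arm_labels = c("UST", "ADA"))
  expect_s3_class(res, "emulation_result")
  expect_equal(c(res$a, res$b, res$c, res$d), c(67, 82, 62, 73))
  # 67/149 = 44.966% (the printed 44.9 is a truncation); 62/135 = 45.9%
  expect_equal(res$rate1, 67 / 149)
  expect_equal(round(100 * res$rate2, 1), 45.9)
  expect_equal(round(res$p_value, 1), 0.9)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)

  # identical arms: identical rates, p = 1
  res2 <- emulate_head_to_head(trial_table(ust), trial_table(ust))
  expect_equal(res2$rate1, res2$rate2)
  expect_identical(res2$p_value, 1)

  # inclusion predicate filters both arms; empty arm errors
  ust2 <- ust; ust2$tnfi_history <- 1
  expect_error(emulate_head_to_head(trial_table(ust2),
                                    trial_table(ada)),
               "empty arm")
  df <- as.data.frame(res)
  expect_equal(df$p_value, res$p_value)
  expect_equal(df$remitters1, 67)
})

test_that("validation battery produces all five tagged modes", {
  tab <- generate_ipd(synthetic_truth(seed = 5))
  bat <- suppressWarnings(run_validation_battery(tab, battery_config()))
  expect_named(bat, c("primary", "high_capture", "complete_case",
                      "information_leakage", "negative_control"))
  modes <- vapply(bat, function(r) r$mode, character(1))
  expect_equal(unname(modes),
               c("primary", "sensitivity:high_capture",
                 "sensitivity:complete_case",
                 "sensitivity:information_leakage", "negative_control"))
  rep <- battery_report(bat)
  expect_equal(nrow(rep), 5L)
  expect_true(all(rep$p_value > 0 & rep$p_value <= 1))
  # every arm-1 cohort is the same observed TNFi-naive UST cohort
  expect_equal(length(unique(rep$n1[rep$mode != "sensitivity:complete_case"])), 1L)
  # the negative control pools all raw active arms (larger cohort)
  expect_gt(rep$n2[rep$mode == "negative_control"],
            max(rep$n2[rep$mode == "primary"]))
})

test_that("a failing mode is reported without aborting the battery", {
  tab <- generate_ipd(synthetic_truth(seed = 6))
  cfg <- battery_config(active_trials = "NO_SUCH_TRIAL",
                        modes = c("primary", "negative_control"))
  bat <- run_validation_battery(tab, cfg)
  expect_true(inherits(bat$primary, "error"))
  expect_true(inherits(bat$negative_control, "error"))
  rep <- battery_report(bat)
  expect_true(all(!is.na(rep$error)))

  cfg2 <- battery_config(modes = c("primary", "negative_control"))
  bat2 <- suppressWarnings(run_validation_battery(tab, cfg2))
  expect_s3_class(bat2$primary, "emulation_result")
  expect_equal(length(bat2), 2L)
})

test_that("primary-mode p is not systematically small under equal drugs", {
  # identical attributable truths for both drugs and no trial-level drug
  # heterogeneity: the emulated endpoint must not reject systematically
  pvals <- vapply(1:24, function(s) {
    truth <- synthetic_truth(
      sigma_u_drug = 0,
      trial_design = default_trial_design(placebo_scale = 0.5,
                                          active_scale = 0.5),
      seed = 1000 + s)
    tab <- generate_ipd(truth)
    bat <- suppressWarnings(
      run_validation_battery(tab, battery_config(modes = "primary")))
    bat$primary$p_value
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 4)
  expect_gt(median(pvals), 0.2)
})

test_that("counterfactual arm mean matches the oracle within 3 SE", {
  # estimated counterfactual mean reduction vs observed placebo mean plus
  # the true mean drug effect over the same covariates
  truth <- synthetic_truth(
    sigma_u_drug = 0,
    trial_design = default_trial_design(placebo_scale = 2,
                                        active_scale = 2),
    seed = 31)
  tab <- generate_ipd(truth)
  placebo_model <- fit_random_intercept_lm(
    subset_table(tab, tab$arm == "placebo"), covariate_scheme(TRUE))
  active <- subset_table(tab, tab$arm == "active:ADA")
  part <- partition_drug_attributable(placebo_model, active)
  attrib <- fit_attributable_model(part, active)
  comp <- subset_table(tab, tab$arm == "placebo" &
                         tab$trial_id %in% c("CERTIFI", "UNITI1",
                                             "UNITI2"))
  sim <- suppressWarnings(simulate_counterfactual_arm(attrib, comp))
  true_effect <- drop(design_matrix(comp, covariate_scheme(FALSE)) %*%
                        truth$beta_drug$ADA)
  err <- mean(sim$counterfactual_reduction) -
    (mean(comp$cdai_reduction) + mean(true_effect))
  # conservative SE from the two fits' diagonal coefficient variances,
  # projected on the comparator cohort's mean design vector
  xbar_d <- colMeans(design_matrix(comp, covariate_scheme(FALSE)))
  xbar_p <- colMeans(design_matrix(comp, covariate_scheme(TRUE)))
  se <- sqrt(sum((xbar_d * attrib$standard_errors)^2) +
               sum((xbar_p * placebo_model$standard_errors)^2))
  expect_lt(abs(err), 3 * se)
})
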