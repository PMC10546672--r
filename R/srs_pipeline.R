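# The SRS core: partition active-arm outcomes into placebo- and
# drug-attributable components, model the residuals, simulate counterfactual
# comparator arms by conditional-mean add-back, and emulate a head-to-head
# remission endpoint with Fisher's exact test.

#' Partition active-arm outcomes into placebo and drug components
#'
#' Subtracts the placebo model's fixed-effects conditional mean from each
#' observed active-arm reduction. The residual is the drug-attributable
#' component; it may be negative and is never clamped. By construction
#' `observed_reduction = placebo_component + drug_component` exactly.
#'
#' @param placebo_model an [effect_model()] fitted with `include_year = TRUE`.
#' @param active_records `trial_table` of drug-assigned participants with
#'   complete covariates and observed (or LOCF-imputed) reductions.
#' @return data frame of class `partitioned_outcome`: `participant_id`,
#'   `trial_id`, `arm`, `observed_reduction`, `placebo_component`,
#'   `drug_component`; the mean drug component is attribute
#'   `"mean_drug_component"`.
#' @export
partition_drug_attributable <- function(placebo_model, active_records) {
  stopifnot(inherits(placebo_model, "effect_model"),
            is.data.frame(active_records))
  if (!isTRUE(placebo_model$scheme$include_year))
    stop("placebo model must be fitted with include_year = TRUE")
  if (any(active_records$arm == "placebo"))
    stop("placebo-arm record(s) in active_records; partition applies to ",
         "drug-assigned arms only")
  if (anyNA(active_records$cdai_reduction))
    stop("absent outcome(s); apply LOCF or complete-case filtering first")
  placebo_component <- predict_fixed(placebo_model, active_records)
  out <- data.frame(
    participant_id = active_records$participant_id,
    trial_id = active_records$trial_id,
    arm = active_records$arm,
    observed_reduction = active_records$cdai_reduction,
    placebo_component = placebo_component,
    drug_component = active_records$cdai_reduction - placebo_component)
  attr(out, "mean_drug_component") <- mean(out$drug_component)
  class(out) <- c("partitioned_outcome", "data.frame")
  out
}

#' Fit the drug-attributable model on partitioned residuals
#'
#' Regresses the drug-attributable component on the same centered
#' covariates (without the year term) with a trial random intercept.
#'
#' @param partitioned output of [partition_drug_attributable()].
#' @param covariates the `trial_table` carrying the active records'
#'   covariates (matched by `participant_id`).
#' @param scheme a [covariate_scheme()] with `include_year = FALSE`.
#' @return an [effect_model()] labelled `drug_attributable:<code>`, the
#'   code taken from the active arms.
#' @export
fit_attributable_model <- function(partitioned, covariates,
                                   scheme = covariate_scheme(FALSE)) {
  stopifnot(inherits(partitioned, "partitioned_outcome"),
            is.data.frame(covariates))
  if (isTRUE(scheme$include_year))
    stop("drug-attributable model uses include_year = FALSE")
  idx <- match(partitioned$participant_id, covariates$participant_id)
  if (anyNA(idx))
    stop("partitioned participant(s) missing from covariate table")
  tab <- covariates[idx, , drop = FALSE]
  codes <- unique(sub("^active:", "", partitioned$arm))
  label <- paste0("drug_attributable:", paste(codes, collapse = "+"))
  fit_random_intercept_lm(trial_table(as.data.frame(tab),
                                      validate = FALSE),
                          scheme,
                          outcome = partitioned$drug_component,
                          outcome_label = label)
}

#' Simulate a counterfactual active-treatment arm
#'
#' Adds the drug-attributable model's conditional mean (fixed effects only)
#' back onto each placebo participant's observed reduction — the outcomes
#' the placebo cohort would have had under active treatment. The simulation
#' is deterministic: no residual noise is drawn, one counterfactual outcome
#' per participant, and records keep their identity. Optionally a single
#' trial-level deviation `N(0, sigma_u^2)` per trial can be drawn for
#' uncertainty exploration (off by default).
#'
#' @param attrib_model a drug-attributable [effect_model()]
#'   (`include_year = FALSE`).
#' @param placebo_records `trial_table` of placebo-assigned participants
#'   with observed (post-LOCF) week-8 outcomes.
#' @param draw_trial_effect logical; add a random trial intercept draw
#'   (requires the model's `sigma_u2`).
#' @return data frame of class `simulated_arm`: the placebo records plus
#'   `drug_addback`, `counterfactual_reduction`, `counterfactual_week8`.
#'   Negative counterfactual week-8 CDAI values are kept (with a warning);
#'   clamping cannot change remission status.
#' @export
simulate_counterfactual_arm <- function(attrib_model, placebo_records,
                                        draw_trial_effect = FALSE) {
  stopifnot(inherits(attrib_model, "effect_model"),
            is.data.frame(placebo_records))
  if (isTRUE(attrib_model$scheme$include_year))
    stop("attributable model must have include_year = FALSE")
  if (any(placebo_records$arm != "placebo"))
    stop("active-arm record(s); counterfactual simulation applies to the ",
         "placebo cohort")
  if (anyNA(placebo_records$cdai_reduction))
    stop("absent outcome(s); apply LOCF or complete-case filtering first")
  addback <- predict_fixed(attrib_model, placebo_records)
  if (draw_trial_effect) {
    if (is.na(attrib_model$sigma_u2))
      stop("draw_trial_effect requires the model's sigma_u2")
    trials <- unique(placebo_records$trial_id)
    u <- setNames(rnorm(length(trials), 0, sqrt(attrib_model$sigma_u2)),
                  trials)
    addback <- addback + unname(u[placebo_records$trial_id])
  }
  out <- as.data.frame(placebo_records)
  out$drug_addback <- addback
  out$counterfactual_reduction <- out$cdai_reduction + addback
  out$counterfactual_week8 <- out$baseline_cdai -
    out$counterfactual_reduction
  if (any(out$counterfactual_week8 < 0))
    warning(sum(out$counterfactual_week8 < 0),
            " counterfactual week-8 CDAI value(s) below 0 (kept unclamped)")
  class(out) <- c("simulated_arm", "data.frame")
  out
}

#' Week-8 clinical remission status
#'
#' Remission is a week-8 CDAI strictly below 150:
#' `baseline_cdai - reduction < 150`.
#'
#' @param baseline_cdai,reduction numeric vectors (CDAI points).
#' @return logical vector.
#' @examples
#' remission_status(300, 160)  # TRUE  (week-8 CDAI 140)
#' remission_status(300, 150)  # FALSE (boundary is non-remission)
#' @export
remission_status <- function(baseline_cdai, reduction) {
  (baseline_cdai - reduction) < 150
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: with both margins
#' fixed, all tables whose hypergeometric point probability does not exceed
#' the observed table's (within relative tolerance 1e-7) are summed. The
#' result is capped at 1. A zero margin carries no information and returns
#' p = 1 with a warning.
#'
#' @param a,b first arm remitters / non-remitters.
#' @param c,d second arm remitters / non-remitters.
#' @return the two-sided p-value, in (0, 1].
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)      # 1
#' fisher_exact_2x2(67, 82, 62, 73)  # 0.9053...
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) {
    warning("a zero margin carries no information; p = 1")
    return(1)
  }
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Emulate a head-to-head efficacy trial
#'
#' Applies an inclusion predicate (default: TNFi-naive) to both arms,
#' determines per-arm week-8 remission, builds the 2x2 contingency table
#' and computes the two-sided exact p-value. The comparator arm may be a
#' [simulate_counterfactual_arm()] result (counterfactual outcomes) or a
#' plain `trial_table` (observed outcomes, as in the negative control).
#'
#' @param observed_arm `trial_table` of the observed active cohort.
#' @param comparator_arm `simulated_arm` or `trial_table`.
#' @param inclusion function of a data frame returning a logical vector
#'   (default `tnfi_history == 0`); `NULL` keeps everyone.
#' @param arm_labels length-2 character labels.
#' @param mode tag: `"primary"`, `"sensitivity:<name>"`, or
#'   `"negative_control"`.
#' @return object of class `emulation_result`: counts `a`, `b`, `c`, `d`,
#'   per-arm remission rates, `p_value`, `mode`.
#' @export
emulate_head_to_head <- function(observed_arm, comparator_arm,
                                 inclusion = function(x) x$tnfi_history == 0,
                                 arm_labels = c("observed", "comparator"),
                                 mode = "primary") {
  stopifnot(is.data.frame(observed_arm), is.data.frame(comparator_arm),
            length(arm_labels) == 2L)
  reduction_of <- function(x) {
    if (!is.null(x$counterfactual_reduction)) x$counterfactual_reduction
    else x$cdai_reduction
  }
  filt <- function(x) {
    if (is.null(inclusion)) return(x)
    keep <- inclusion(as.data.frame(x))
    x[keep & !is.na(keep), , drop = FALSE]
  }
  o <- filt(observed_arm); s <- filt(comparator_arm)
  if (nrow(o) == 0L || nrow(s) == 0L)
    stop("empty arm after inclusion filtering")
  rem_o <- remission_status(o$baseline_cdai, reduction_of(o))
  rem_s <- remission_status(s$baseline_cdai, reduction_of(s))
  a <- sum(rem_o); b <- sum(!rem_o)
  cc <- sum(rem_s); d <- sum(!rem_s)
  structure(
    list(arm_labels = arm_labels,
         a = a, b = b, c = cc, d = d,
         n1 = a + b, n2 = cc + d,
         rate1 = a / (a + b), rate2 = cc / (cc + d),
         p_value = fisher_exact_2x2(a, b, cc, d),
         mode = mode),
    class = "emulation_result")
}

#' @export
print.emulation_result <- function(x, ...) {
  cat(sprintf("[%s] %s %d/%d (%.1f%%) vs %s %d/%d (%.1f%%), p = %.4g\n",
              x$mode, x$arm_labels[1L], x$a, x$n1, 100 * x$rate1,
              x$arm_labels[2L], x$c, x$n2, 100 * x$rate2, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.emulation_result <- function(x, ...) {
  data.frame(mode = x$mode,
             arm1 = x$arm_labels[1L],
             remitters1 = x$a, n1 = x$n1, rate1 = x$rate1,
             arm2 = x$arm_labels[2L],
             remitters2 = x$c, n2 = x$n2, rate2 = x$rate2,
             p_value = x$p_value)
}

#' Default validation-battery configuration
#'
#' Trial-role assignments mirroring the bundled synthetic world: six
#' placebo-controlled trials train the placebo model, three adalimumab
#' trials provide the uncontrolled active arms, and the three ustekinumab
#' trials provide the observed comparator arm and the placebo cohort to
#' simulate.
#'
#' @param ... overrides of the default entries.
#' @return named list understood by [run_validation_battery()].
#' @export
battery_config <- function(...) {
  cfg <- list(
    placebo_trials = c("PRECISE1", "ENACT", "ENCORE", "CERTIFI",
                       "UNITI1", "UNITI2"),
    active_trials = c("CLASSIC", "EXTEND", "NCT02499783"),
    comparator_trials = c("CERTIFI", "UNITI1", "UNITI2"),
    drug_code = "ADA",
    comparator_drug = "UST",
    high_capture_drop = c("PRECISE1", "ENACT"),
    leakage_drop = c("CERTIFI", "UNITI1", "UNITI2"),
    modes = c("primary", "high_capture", "complete_case",
              "information_leakage", "negative_control"),
    tnfi_naive_only = TRUE)
  modifyList(cfg, list(...))
}

# run one battery mode end to end; `data` is the raw (pre-harmonization)
# table so the complete-case mode can skip LOCF
.run_mode <- function(data, cfg, mode) {
  tab <- harmonize(data, locf = mode != "complete_case")
  inclusion <- if (isTRUE(cfg$tnfi_naive_only))
    function(x) x$tnfi_history == 0 else NULL
  observed <- subset_table(
    tab, tab$arm == paste0("active:", cfg$comparator_drug) &
      tab$trial_id %in% cfg$comparator_trials)
  labels <- c(cfg$comparator_drug, cfg$drug_code)
  if (mode == "negative_control") {
    raw_active <- subset_table(
      tab, tab$arm == paste0("active:", cfg$drug_code) &
        tab$trial_id %in% cfg$active_trials)
    return(emulate_head_to_head(observed, raw_active, inclusion,
                                arm_labels = labels,
                                mode = "negative_control"))
  }
  train_trials <- cfg$placebo_trials
  if (mode == "high_capture")
    train_trials <- setdiff(train_trials, cfg$high_capture_drop)
  if (mode == "information_leakage")
    train_trials <- setdiff(train_trials, cfg$leakage_drop)
  placebo_train <- subset_table(
    tab, tab$arm == "placebo" & tab$trial_id %in% train_trials)
  placebo_model <- fit_random_intercept_lm(
    placebo_train, covariate_scheme(TRUE),
    outcome_label = "placebo_effect")
  active <- subset_table(
    tab, tab$arm == paste0("active:", cfg$drug_code) &
      tab$trial_id %in% cfg$active_trials)
  part <- partition_drug_attributable(placebo_model, active)
  attrib <- fit_attributable_model(part, active, covariate_scheme(FALSE))
  comparator_placebo <- subset_table(
    tab, tab$arm == "placebo" & tab$trial_id %in% cfg$comparator_trials)
  sim <- simulate_counterfactual_arm(attrib, comparator_placebo)
  tag <- if (mode == "primary") "primary" else paste0("sensitivity:", mode)
  emulate_head_to_head(observed, sim, inclusion, arm_labels = labels,
                       mode = tag)
}

#' Run the full validation battery
#'
#' Executes, in order: the primary analysis (full SRS pipeline), the
#' "high-capture" sensitivity (drops configured trials with poor outcome
#' capture from placebo training), the complete-case sensitivity (no LOCF;
#' records with absent week-8 outcomes dropped), the information-leakage
#' sensitivity (drops the comparator-sponsor trials from placebo training),
#' and the negative control (observed comparator arm against the raw,
#' un-normalized active arms). A failing mode is reported and does not
#' abort the battery.
#'
#' @param data raw `trial_table` (pre-harmonization; the battery harmonizes
#'   per mode).
#' @param config a [battery_config()].
#' @return object of class `validation_battery`: named list of
#'   `emulation_result`s (or error conditions) per mode.
#' @export
run_validation_battery <- function(data, config = battery_config()) {
  results <- lapply(config$modes, function(mode) {
    tryCatch(.run_mode(data, config, mode), error = function(e) e)
  })
  names(results) <- config$modes
  structure(results, class = "validation_battery", config = config)
}

#' @export
print.validation_battery <- function(x, ...) {
  cat("<validation_battery>\n")
  for (mode in names(x)) {
    if (inherits(x[[mode]], "error")) {
      cat(sprintf("[%s] FAILED: %s\n", mode,
                  conditionMessage(x[[mode]])))
    } else {
      print(x[[mode]])
    }
  }
  invisible(x)
}

#' Render a validation battery as a summary table
#'
#' @param battery a `validation_battery`.
#' @return data frame, one row per successful mode (failed modes carry
#'   `NA` counts and the error message).
#' @export
battery_report <- function(battery) {
  rows <- lapply(names(battery), function(mode) {
    r <- battery[[mode]]
    if (inherits(r, "error")) {
      data.frame(mode = mode, arm1 = NA, remitters1 = NA, n1 = NA,
                 rate1 = NA, arm2 = NA, remitters2 = NA, n2 = NA,
                 rate2 = NA, p_value = NA,
                 error = conditionMessage(r))
    } else {
      cbind(as.data.frame(r), error = NA_character_)
    }
  })
  do.call(rbind, rows)
}
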