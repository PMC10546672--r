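# Trial-random-intercept linear models of the week-8 CDAI reduction:
# fitting (REML via lme4), prediction with and without the trial BLUP,
# leave-one-trial-out diagnostics, residual normality, and RMSE comparison.

#' Construct a fitted effect model object
#'
#' Container for either the placebo-attributable or a drug-attributable
#' model: fixed-effect coefficients (CDAI points per unit of centered
#' covariate), Wald standard errors and p-values, per-trial random
#' intercepts (BLUPs), variance components and the intraclass correlation.
#' Usually produced by [fit_random_intercept_lm()]; the constructor is
#' exported so published coefficient tables can be loaded as fixtures
#' (see [reference_effect_models()]).
#'
#' @param coefficients named numeric vector; names must exactly match
#'   `scheme$terms`, in order.
#' @param scheme the [covariate_scheme()] the coefficients refer to.
#' @param outcome_label `"placebo_effect"` or `"drug_attributable:<code>"`.
#' @param standard_errors,p_values optional named vectors (same shape).
#' @param random_intercepts optional named per-trial numeric vector.
#' @param sigma_u2,sigma_e2 between-trial and residual variances (CDAI
#'   points squared); may be `NA` for fixture models.
#' @param icc intraclass correlation; computed from the variances when they
#'   are available (and then must agree), otherwise may be supplied.
#' @param n_obs,n_trials fit sizes.
#' @param method free-form fit tag (`"REML/lme4"`, `"fixture"`, ...).
#' @return object of class `effect_model`.
#' @export
effect_model <- function(coefficients, scheme, outcome_label,
                         standard_errors = NULL, p_values = NULL,
                         random_intercepts = NULL,
                         sigma_u2 = NA_real_, sigma_e2 = NA_real_,
                         icc = NA_real_,
                         n_obs = NA_integer_, n_trials = NA_integer_,
                         method = "fixture") {
  stopifnot(inherits(scheme, "covariate_scheme"))
  if (!identical(names(coefficients), scheme$terms))
    stop("coefficient names must match the scheme's design-vector order: ",
         paste(scheme$terms, collapse = ", "))
  if (!is.na(sigma_u2) && !is.na(sigma_e2)) {
    icc_calc <- sigma_u2 / (sigma_u2 + sigma_e2)
    if (!is.na(icc) && abs(icc - icc_calc) > 1e-12)
      stop("supplied icc inconsistent with variance components")
    icc <- icc_calc
  }
  structure(
    list(outcome_label = outcome_label, scheme = scheme,
         coefficients = coefficients, standard_errors = standard_errors,
         p_values = p_values, random_intercepts = random_intercepts,
         sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, icc = icc,
         n_obs = n_obs, n_trials = n_trials, method = method),
    class = "effect_model")
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model> ", x$outcome_label, " [", x$method, "]\n", sep = "")
  cat("  n_obs = ", x$n_obs, ", n_trials = ", x$n_trials,
      ", icc = ", signif(x$icc, 3), "\n", sep = "")
  tab <- data.frame(estimate = x$coefficients)
  if (!is.null(x$standard_errors)) tab$se <- x$standard_errors
  if (!is.null(x$p_values)) tab$p <- x$p_values
  print(round(tab, 4))
  if (!is.null(x$random_intercepts)) {
    cat("  trial random intercepts:\n")
    print(round(x$random_intercepts, 3))
  }
  invisible(x)
}

# resolve outcome argument: a column name or a numeric vector per record
.resolve_outcome <- function(table, outcome) {
  if (is.character(outcome) && length(outcome) == 1L) {
    y <- table[[outcome]]
    if (is.null(y)) stop("no such outcome column: ", outcome)
  } else {
    y <- outcome
  }
  if (length(y) != nrow(table)) stop("outcome length must equal nrow(table)")
  if (anyNA(y)) stop("outcome contains missing values; harmonize first")
  as.numeric(y)
}

#' Fit a trial-random-intercept linear model
#'
#' REML fit of `outcome = x'beta + u_trial + e` with
#' `u_trial ~ N(0, sigma_u^2)` and `e ~ N(0, sigma_e^2)`, where `x` is the
#' centered fixed-effect design vector of `scheme`. Trial enters only
#' through the random intercept; random intercepts are reported as BLUPs.
#' Standard errors and p-values are Wald with the normal reference.
#'
#' @param table a `trial_table` with complete covariates.
#' @param scheme a [covariate_scheme()].
#' @param outcome column name (default `"cdai_reduction"`) or numeric
#'   vector, one value per record.
#' @param outcome_label label stored on the model.
#' @return an [effect_model()].
#' @export
fit_random_intercept_lm <- function(table, scheme = covariate_scheme(),
                                    outcome = "cdai_reduction",
                                    outcome_label = "placebo_effect") {
  stopifnot(is.data.frame(table))
  y <- .resolve_outcome(table, outcome)
  trials <- unique(table$trial_id)
  if (length(trials) < 2L)
    stop("random intercept unidentifiable: need >= 2 distinct trials")
  if (var(y) == 0) stop("zero-variance outcome")
  X <- design_matrix(table, scheme)
  if (nrow(X) <= ncol(X) + 2L)
    stop("too few observations: need n_obs > design-vector length + 2")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- as.data.frame(X)
  df$.y <- y
  df$.trial <- factor(table$trial_id)
  fml <- stats::as.formula(paste(
    ".y ~ 0 +", paste(scheme$terms, collapse = " + "), "+ (1 | .trial)"))
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = df, REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8))),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w)))
        stop("REML fit failed to converge: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- lme4::fixef(fit)[scheme$terms]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[scheme$terms]
  pz <- 2 * pnorm(-abs(beta / se))
  re <- lme4::ranef(fit)$.trial
  u <- setNames(re[, 1L], rownames(re))
  vc <- lme4::VarCorr(fit)
  sigma_u2 <- as.numeric(vc$.trial)
  sigma_e2 <- stats::sigma(fit)^2
  effect_model(coefficients = beta, scheme = scheme,
               outcome_label = outcome_label,
               standard_errors = se, p_values = pz,
               random_intercepts = u,
               sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
               n_obs = nrow(df), n_trials = length(trials),
               method = "REML/lme4")
}

#' Predict the fixed-effects conditional mean
#'
#' `x'beta` with the trial random intercept set to zero — the prediction
#' used for participants from trials outside the model's training set.
#'
#' @param model an [effect_model()].
#' @param table a `trial_table` (or one-row record) with complete
#'   covariates.
#' @param scheme optional; when supplied it must match the model's scheme
#'   (`include_year` in particular).
#' @return numeric vector of CDAI-point predictions.
#' @export
predict_fixed <- function(model, table, scheme = NULL) {
  stopifnot(inherits(model, "effect_model"))
  if (!is.null(scheme) &&
      !identical(scheme$include_year, model$scheme$include_year))
    stop("scheme mismatch: model include_year = ", model$scheme$include_year)
  if (!is.data.frame(table)) table <- as.data.frame(table)
  X <- design_matrix(table, model$scheme)
  drop(X %*% model$coefficients)
}

#' Predict including the trial random intercept
#'
#' `x'beta + u_trial` for records whose trial was in the training set.
#'
#' @inheritParams predict_fixed
#' @return numeric vector of CDAI-point predictions.
#' @export
predict_with_trial <- function(model, table, scheme = NULL) {
  stopifnot(inherits(model, "effect_model"))
  if (is.null(model$random_intercepts))
    stop("model carries no trial random intercepts")
  if (!is.data.frame(table)) table <- as.data.frame(table)
  unknown <- setdiff(unique(table$trial_id),
                     names(model$random_intercepts))
  if (length(unknown))
    stop("trial(s) not among the model's fitted trials: ",
         paste(unknown, collapse = ", "),
         "; use predict_fixed() for out-of-sample trials")
  predict_fixed(model, table, scheme) +
    unname(model$random_intercepts[table$trial_id])
}

#' Leave-one-trial-out evaluation
#'
#' For each trial, refits the model on the remaining trials and predicts
#' the held-out trial with fixed effects only, reporting the trial-averaged
#' residual (observed minus predicted), its SD and n. A fold whose fit
#' fails is reported with its error message; remaining folds continue.
#'
#' @inheritParams fit_random_intercept_lm
#' @return data frame: `trial_id`, `n`, `mean_residual`, `sd_residual`,
#'   `error`.
#' @export
loto_evaluate <- function(table, scheme = covariate_scheme(),
                          outcome = "cdai_reduction") {
  stopifnot(is.data.frame(table))
  y <- .resolve_outcome(table, outcome)
  trials <- sort(unique(table$trial_id))
  if (length(trials) < 3L)
    stop("leave-one-trial-out needs >= 3 trials")
  rows <- lapply(trials, function(t) {
    held <- table$trial_id == t
    res <- tryCatch({
      m <- fit_random_intercept_lm(subset_table(table, !held),
                                   scheme, y[!held])
      r <- y[held] - predict_fixed(m, table[held, , drop = FALSE])
      data.frame(trial_id = t, n = sum(held), mean_residual = mean(r),
                 sd_residual = sd(r), error = NA_character_)
    }, error = function(e) {
      data.frame(trial_id = t, n = sum(held), mean_residual = NA_real_,
                 sd_residual = NA_real_, error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}

#' Shapiro-Wilk normality check of trial-averaged residuals
#'
#' @param residuals numeric vector of per-trial mean residuals (>= 3).
#' @return list: `statistic`, `p_value`, `n`, `degenerate` (`TRUE` when the
#'   input is constant and the statistic is undefined).
#' @export
residual_normality <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 3L)
    stop("need >= 3 residuals for a normality test")
  if (length(unique(residuals)) == 1L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                n = length(residuals), degenerate = TRUE))
  sw <- shapiro.test(residuals)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       n = length(residuals), degenerate = FALSE)
}

#' Built-in fit procedures for [rmse_compare()]
#'
#' `proc_mixed` is the trial-random-intercept model (predicting held-out
#' data with fixed effects only); `proc_intercept_only` predicts the
#' training mean — the no-covariate baseline.
#'
#' @param train,test `trial_table`s.
#' @param scheme a [covariate_scheme()].
#' @param outcome outcome column name or numeric vector for `train`.
#' @return numeric predictions for `test`.
#' @export
proc_mixed <- function(train, test, scheme, outcome = "cdai_reduction") {
  m <- fit_random_intercept_lm(train, scheme, outcome)
  predict_fixed(m, test)
}

#' @rdname proc_mixed
#' @export
proc_intercept_only <- function(train, test, scheme,
                                outcome = "cdai_reduction") {
  y <- .resolve_outcome(train, outcome)
  rep(mean(y), nrow(test))
}

#' Cross-validated RMSE comparison of fit procedures
#'
#' Leave-one-trial-out (by default) cross-validation of two or more fit
#' procedures, pooling squared errors across folds, with a paired bootstrap
#' interval (resampling folds) for each procedure's RMSE difference against
#' the first.
#'
#' @param procedures named list of functions
#'   `f(train, test, scheme, outcome)` returning predictions for `test`
#'   (see [proc_mixed()]).
#' @inheritParams fit_random_intercept_lm
#' @param folds optional factor/character grouping, one entry per record;
#'   defaults to `trial_id` (leave-one-trial-out).
#' @param n_boot bootstrap replicates for the difference interval.
#' @return list: `rmse` (named vector), `fold_rmse` (folds x procedures),
#'   `diff_vs_first` (data frame with bootstrap 95% intervals), `failures`.
#' @export
rmse_compare <- function(procedures, table, scheme = covariate_scheme(),
                         outcome = "cdai_reduction", folds = NULL,
                         n_boot = 500) {
  stopifnot(is.list(procedures), length(procedures) >= 2L,
            !is.null(names(procedures)), all(nzchar(names(procedures))))
  y <- .resolve_outcome(table, outcome)
  if (is.null(folds)) folds <- table$trial_id
  stopifnot(length(folds) == nrow(table))
  fold_ids <- sort(unique(folds))
  pnames <- names(procedures)
  sqerr <- matrix(NA_real_, length(fold_ids), length(pnames),
                  dimnames = list(fold_ids, pnames))
  fold_n <- integer(length(fold_ids))
  failures <- list()
  for (k in seq_along(fold_ids)) {
    held <- folds == fold_ids[k]
    fold_n[k] <- sum(held)
    train <- subset_table(table, !held)
    test <- table[held, , drop = FALSE]
    for (p in pnames) {
      pred <- tryCatch(procedures[[p]](train, test, scheme, y[!held]),
                       error = function(e) e)
      if (inherits(pred, "error")) {
        failures[[paste(fold_ids[k], p, sep = "/")]] <-
          conditionMessage(pred)
      } else {
        sqerr[k, p] <- mean((y[held] - pred)^2)
      }
    }
  }
  ok <- stats::complete.cases(sqerr)
  w <- fold_n[ok] / sum(fold_n[ok])
  rmse <- sqrt(colSums(sqerr[ok, , drop = FALSE] * w))
  diff_boot <- replicate(n_boot, {
    idx <- sample(which(ok), sum(ok), replace = TRUE)
    wb <- fold_n[idx] / sum(fold_n[idx])
    r <- sqrt(colSums(sqerr[idx, , drop = FALSE] * wb))
    r - r[1L]
  })
  diffs <- data.frame(
    procedure = pnames,
    rmse_diff_vs_first = rmse - rmse[1L],
    lo95 = apply(diff_boot, 1L, quantile, 0.025),
    hi95 = apply(diff_boot, 1L, quantile, 0.975))
  list(rmse = rmse, fold_rmse = sqrt(sqerr), diff_vs_first = diffs,
       failures = failures)
}

# ---- serialization ----------------------------------------------------------

#' Read / write an effect model as JSON
#'
#' @param model an [effect_model()].
#' @param path JSON file path.
#' @return `write_effect_model()`: `path`, invisibly;
#'   `read_effect_model()`: the reconstructed [effect_model()].
#' @export
write_effect_model <- function(model, path) {
  stopifnot(inherits(model, "effect_model"))
  payload <- list(
    outcome_label = model$outcome_label,
    include_year = model$scheme$include_year,
    coefficients = as.list(model$coefficients),
    standard_errors = as.list(model$standard_errors),
    p_values = as.list(model$p_values),
    random_intercepts = as.list(model$random_intercepts),
    sigma_u2 = model$sigma_u2, sigma_e2 = model$sigma_e2,
    icc = model$icc, n_obs = model$n_obs, n_trials = model$n_trials,
    method = model$method)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_effect_model
#' @export
read_effect_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  .effect_model_from_list(p)
}

.effect_model_from_list <- function(p) {
  scheme <- covariate_scheme(include_year = isTRUE(p$include_year))
  num <- function(x) if (is.null(x) || !length(x)) NULL else unlist(x)
  na_or <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  effect_model(
    coefficients = num(p$coefficients)[scheme$terms],
    scheme = scheme, outcome_label = p$outcome_label,
    standard_errors = num(p$standard_errors),
    p_values = num(p$p_values),
    random_intercepts = num(p$random_intercepts),
    sigma_u2 = na_or(p$sigma_u2), sigma_e2 = na_or(p$sigma_e2),
    icc = na_or(p$icc),
    n_obs = if (is.null(p$n_obs)) NA_integer_ else as.integer(p$n_obs),
    n_trials = if (is.null(p$n_trials)) NA_integer_
               else as.integer(p$n_trials),
    method = if (is.null(p$method)) "fixture" else p$method)
}
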