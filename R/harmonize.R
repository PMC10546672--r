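# Harmonization / quality-control rules: categorical case deletion, pooled
# median imputation of continuous covariates, LOCF for the week-8 outcome,
# and the baseline summary table.

#' Median-impute continuous covariates
#'
#' Replaces each absent value of the listed continuous covariates with the
#' median of the observed values of that field, pooled across all trials by
#' default (a per-trial option exists for sensitivity checks). Observed
#' values are never modified.
#'
#' @param table a `trial_table`.
#' @param fields continuous covariates to impute.
#' @param per_trial logical; compute medians within each trial instead of
#'   pooling (off by default).
#' @return the imputed `trial_table`, with an imputation report (counts and
#'   medians used per field) in attribute `"imputation_report"`.
#' @export
impute_continuous_median <- function(table,
                                     fields = c("age", "bmi",
                                                "baseline_cdai", "crp"),
                                     per_trial = FALSE) {
  stopifnot(is.data.frame(table))
  bad <- setdiff(fields, .continuous_covariates)
  if (length(bad))
    stop("not a continuous covariate: ", paste(bad, collapse = ", "))
  report <- data.frame(field = fields, n_imputed = 0L, median = NA_real_)
  for (k in seq_along(fields)) {
    f <- fields[k]
    v <- table[[f]]
    miss <- is.na(v)
    if (!any(miss)) {
      report$median[k] <- median(v)
      next
    }
    if (all(miss)) stop("field entirely absent, no median exists: ", f)
    if (per_trial) {
      for (tid in unique(table$trial_id[miss])) {
        in_trial <- table$trial_id == tid
        obs <- v[in_trial & !miss]
        if (!length(obs))
          stop("field '", f, "' entirely absent within trial ", tid,
               " (per-trial imputation)")
        v[in_trial & miss] <- median(obs)
      }
      report$median[k] <- NA_real_  # trial-specific
    } else {
      m <- median(v[!miss])
      v[miss] <- m
      report$median[k] <- m
    }
    report$n_imputed[k] <- sum(miss)
    table[[f]] <- v
  }
  out <- trial_table(as.data.frame(table),
                     provenance = attr(table, "provenance"),
                     validate = FALSE)
  attr(out, "imputation_report") <- report
  out
}

#' Drop participants with absent categorical covariates
#'
#' Case deletion for the five binary covariates (sex, TNFi history, steroid
#' use, immunomodulator use, ileal disease): any record with at least one
#' absent flag is removed.
#'
#' @param table a `trial_table`.
#' @return the filtered `trial_table`; attribute `"drop_report"` is a data
#'   frame of dropped `participant_id`s and the fields that were missing.
#' @export
drop_missing_categorical <- function(table) {
  stopifnot(is.data.frame(table))
  flags <- as.matrix(as.data.frame(table)[, .binary_covariates])
  missing_any <- rowSums(is.na(flags)) > 0
  report <- data.frame(
    participant_id = table$participant_id[missing_any],
    reason = vapply(which(missing_any), function(i) {
      paste0("missing: ",
             paste(.binary_covariates[is.na(flags[i, ])], collapse = ","))
    }, character(1))
  )
  out <- subset_table(table, !missing_any,
                      note = "drop_missing_categorical")
  if (nrow(out) == 0L && nrow(table) > 0L)
    warning("all records dropped: every participant missing a categorical ",
            "covariate")
  attr(out, "drop_report") <- report
  out
}

#' Last-observation-carried-forward for the week-8 outcome
#'
#' For a record with an absent week-8 CDAI, carries forward the CDAI of the
#' latest post-baseline visit before week 8. A participant with no
#' post-baseline visit gets the baseline carried forward (reduction 0), the
#' conservative intention-to-treat convention. The reduction is recomputed
#' and the record is flagged `week8_imputed`.
#'
#' @param record one-row `trial_table` slice (or compatible data frame row).
#' @return the record, with `cdai_week8`, `cdai_reduction`, `week8_imputed`
#'   updated. If the week-8 value is already present the record is returned
#'   unchanged with a warning (precondition violation).
#' @export
impute_locf_week8 <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  if (!is.na(record$cdai_week8)) {
    warning("cdai_week8 already present; LOCF is a no-op")
    return(record)
  }
  v <- parse_visits(record$cdai_visits)
  v <- v[v$week > 0 & v$week < 8, , drop = FALSE]
  record$cdai_week8 <- if (nrow(v)) v$cdai[nrow(v)] else record$baseline_cdai
  record$cdai_reduction <- record$baseline_cdai - record$cdai_week8
  record$week8_imputed <- TRUE
  record
}

#' Apply LOCF to every record with an absent outcome
#'
#' @param table a `trial_table`.
#' @return the table with all week-8 outcomes present; attribute
#'   `"locf_report"` counts carried-forward and baseline-carried-forward
#'   records.
#' @export
impute_locf_table <- function(table) {
  stopifnot(is.data.frame(table))
  miss <- which(is.na(table$cdai_week8))
  n_baseline <- 0L
  for (i in miss) {
    rec <- impute_locf_week8(table[i, , drop = FALSE])
    if (rec$cdai_reduction == 0 &&
        rec$cdai_week8 == rec$baseline_cdai) n_baseline <- n_baseline + 1L
    table$cdai_week8[i] <- rec$cdai_week8
    table$cdai_reduction[i] <- rec$cdai_reduction
    table$week8_imputed[i] <- TRUE
  }
  out <- trial_table(as.data.frame(table),
                     provenance = attr(table, "provenance"),
                     validate = FALSE)
  attr(out, "locf_report") <- list(n_imputed = length(miss),
                                   n_baseline_carried = n_baseline)
  out
}

#' Full harmonization pipeline
#'
#' Fixed order: drop missing categoricals, median-impute continuous
#' covariates, LOCF the week-8 outcome. Idempotent.
#'
#' @param table a raw `trial_table`.
#' @param locf logical; apply LOCF (disabled for complete-case analyses,
#'   in which case records with absent outcomes are dropped).
#' @return analysis-ready `trial_table` with the stage reports attached.
#' @export
harmonize <- function(table, locf = TRUE) {
  out <- drop_missing_categorical(table)
  drop_rep <- attr(out, "drop_report")
  out <- impute_continuous_median(out)
  imp_rep <- attr(out, "imputation_report")
  if (locf) {
    out <- impute_locf_table(out)
  } else {
    out <- subset_table(out, !is.na(out$cdai_week8),
                        note = "complete_case")
  }
  attr(out, "drop_report") <- drop_rep
  attr(out, "imputation_report") <- imp_rep
  out
}

#' Baseline characteristics summary
#'
#' Per-trial (and overall) baseline table: N, arm counts with percentages,
#' mean (SD) of the continuous covariates and of the week-8 CDAI reduction,
#' count (%) of the binary covariates. Sample SD uses the n-1 denominator.
#'
#' @param table an analysis-ready `trial_table`.
#' @return data frame, one row per trial plus an `"Overall"` row.
#' @export
summarize_baseline <- function(table) {
  stopifnot(is.data.frame(table))
  one <- function(sub, label) {
    n <- nrow(sub)
    act <- sum(grepl("^active:", sub$arm))
    row <- data.frame(
      trial_id = label, n = n,
      n_active = act, pct_active = round(100 * act / n, 1),
      n_placebo = n - act, pct_placebo = round(100 * (n - act) / n, 1))
    for (f in .continuous_covariates) {
      row[[paste0(f, "_mean")]] <- mean(sub[[f]], na.rm = TRUE)
      row[[paste0(f, "_sd")]] <- sd(sub[[f]], na.rm = TRUE)
    }
    for (f in .binary_covariates) {
      cnt <- sum(sub[[f]], na.rm = TRUE)
      row[[paste0(f, "_n")]] <- cnt
      row[[paste0(f, "_pct")]] <- round(100 * cnt / n, 1)
    }
    row$cdai_reduction_mean <- mean(sub$cdai_reduction, na.rm = TRUE)
    row$cdai_reduction_sd <- sd(sub$cdai_reduction, na.rm = TRUE)
    row
  }
  trials <- sort(unique(table$trial_id))
  rows <- lapply(trials,
                 function(t) one(table[table$trial_id == t, ], t))
  rows <- c(rows, list(one(table, "Overall")))
  do.call(rbind, rows)
}
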