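# Core IPD containers: participant-level schema, CSV I/O, covariate
# centering and design-vector construction.

# canonical column order of an analysis table; cdai_visits is serialized as
# "week:value;week:value" so a participant stays one CSV row
.ipd_columns <- c(
  "participant_id", "trial_id", "trial_year", "arm",
  "age", "sex_male", "bmi", "baseline_cdai", "crp",
  "tnfi_history", "steroid_use", "immunomodulator_use", "ileal_disease",
  "cdai_visits", "cdai_week8", "cdai_reduction", "week8_imputed"
)

.continuous_covariates <- c("age", "bmi", "baseline_cdai", "crp")
.binary_covariates <- c("sex_male", "tnfi_history", "steroid_use",
                        "immunomodulator_use", "ileal_disease")

#' Covariate centering scheme
#'
#' Defines the fixed centering offsets and the ordering of the fixed-effect
#' design vector shared by the placebo-attributable and drug-attributable
#' models. Centering puts the model intercept at a reference participant:
#' year 2000, baseline CDAI 300, age 35, BMI 20, CRP 10 mg/L, female, no
#' TNFi history, no steroids, no immunomodulators, no ileal disease.
#'
#' @param include_year logical; include the centered trial-year term
#'   (used by the placebo model, dropped for drug-attributable models).
#' @return An object of class `covariate_scheme`: offsets, term order and
#'   the `include_year` switch. The design vector has `10 + include_year`
#'   entries, the first being the intercept.
#' @examples
#' sc <- covariate_scheme(include_year = TRUE)
#' sc$terms
#' @export
covariate_scheme <- function(include_year = TRUE) {
  stopifnot(is.logical(include_year), length(include_year) == 1L)
  terms <- c("intercept",
             if (include_year) "year_c",
             "baseline_cdai_c", "age_c", "bmi_c", "crp_c",
             "sex_male", "tnfi_history", "steroid_use",
             "immunomodulator_use", "ileal_disease")
  structure(
    list(
      offsets = c(year = -2000, baseline_cdai = -300, age = -35,
                  bmi = -20, crp = -10),
      include_year = include_year,
      terms = terms
    ),
    class = "covariate_scheme"
  )
}

#' @export
print.covariate_scheme <- function(x, ...) {
  cat("<covariate_scheme> ", length(x$terms), " terms",
      if (x$include_year) " (with year)" else " (no year)", "\n", sep = "")
  cat("  order: ", paste(x$terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Center one participant's covariates into a design vector
#'
#' @param record a single participant: one-row data frame (or list) with the
#'   covariate fields of an IPD table.
#' @param scheme a [covariate_scheme()].
#' @return Named numeric vector in the scheme's term order; first entry is
#'   the intercept (always 1).
#' @examples
#' rec <- list(trial_year = 2000, baseline_cdai = 300, age = 45, bmi = 20,
#'             crp = 10, sex_male = 1, tnfi_history = 0, steroid_use = 0,
#'             immunomodulator_use = 0, ileal_disease = 0)
#' center_design_vector(rec, covariate_scheme())
#' @export
center_design_vector <- function(record, scheme = covariate_scheme()) {
  stopifnot(inherits(scheme, "covariate_scheme"))
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) stop("`record` must be a single row")
    record <- as.list(record)
  }
  off <- scheme$offsets
  need <- c(if (scheme$include_year) "trial_year",
            "baseline_cdai", "age", "bmi", "crp", .binary_covariates)
  for (f in need) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("absent covariate: ", f, " (impute upstream before centering)")
  }
  x <- c(intercept = 1)
  if (scheme$include_year)
    x <- c(x, year_c = record$trial_year + off[["year"]])
  x <- c(x,
         baseline_cdai_c = record$baseline_cdai + off[["baseline_cdai"]],
         age_c = record$age + off[["age"]],
         bmi_c = record$bmi + off[["bmi"]],
         crp_c = record$crp + off[["crp"]],
         sex_male = as.numeric(record$sex_male),
         tnfi_history = as.numeric(record$tnfi_history),
         steroid_use = as.numeric(record$steroid_use),
         immunomodulator_use = as.numeric(record$immunomodulator_use),
         ileal_disease = as.numeric(record$ileal_disease))
  x[scheme$terms]
}

#' Fixed-effect design matrix for a table
#'
#' Row-wise [center_design_vector()]; errors on any absent covariate.
#'
#' @param table a `trial_table` (or compatible data frame).
#' @inheritParams center_design_vector
#' @return numeric matrix, one row per record, columns in scheme order.
#' @export
design_matrix <- function(table, scheme = covariate_scheme()) {
  stopifnot(is.data.frame(table))
  need <- c(if (scheme$include_year) "trial_year",
            .continuous_covariates, .binary_covariates)
  for (f in need) {
    if (anyNA(table[[f]]))
      stop("absent covariate: ", f, " (impute upstream before centering)")
  }
  n <- nrow(table)
  X <- matrix(0, n, length(scheme$terms),
              dimnames = list(NULL, scheme$terms))
  X[, "intercept"] <- 1
  if (scheme$include_year)
    X[, "year_c"] <- table$trial_year + scheme$offsets[["year"]]
  X[, "baseline_cdai_c"] <- table$baseline_cdai + scheme$offsets[["baseline_cdai"]]
  X[, "age_c"] <- table$age + scheme$offsets[["age"]]
  X[, "bmi_c"] <- table$bmi + scheme$offsets[["bmi"]]
  X[, "crp_c"] <- table$crp + scheme$offsets[["crp"]]
  for (f in .binary_covariates) X[, f] <- as.numeric(table[[f]])
  X
}

# ---- visit-series serialization --------------------------------------------

#' Parse / format a CDAI visit series
#'
#' Visit series are stored as a compact string, `"week:value;week:value"`,
#' so one participant is one CSV row. Weeks must be strictly increasing and
#' at most 8.
#'
#' @param s character scalar (possibly `NA`/empty).
#' @return `parse_visits()`: a data frame with columns `week`, `cdai`
#'   (zero rows when absent). `format_visits()`: the string encoding.
#' @export
parse_visits <- function(s) {
  if (length(s) != 1L || is.na(s) || !nzchar(s))
    return(data.frame(week = numeric(0), cdai = numeric(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L, logical(1))
  if (any(bad)) stop("malformed visit series: ", s)
  out <- data.frame(week = as.numeric(vapply(parts, `[`, "", 1L)),
                    cdai = as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(out)) stop("malformed visit series: ", s)
  out
}

#' @rdname parse_visits
#' @param visits data frame with columns `week`, `cdai`.
#' @export
format_visits <- function(visits) {
  if (is.null(visits) || nrow(visits) == 0L) return(NA_character_)
  paste(sprintf("%g:%g", visits$week, visits$cdai), collapse = ";")
}

# ---- trial_table ------------------------------------------------------------

#' Construct a trial table
#'
#' A `trial_table` is a validated data frame of participant records (one row
#' each) with a per-trial index and provenance metadata attached as
#' attributes. Most users get one from [read_ipd_table()] or
#' [generate_ipd()].
#'
#' @param records data frame with the IPD columns (missing optional columns
#'   are added as `NA`; `week8_imputed` defaults to `FALSE`).
#' @param provenance list of free-form metadata (source file, filters).
#' @param validate logical; run table-level invariant checks.
#' @return a `trial_table`.
#' @export
trial_table <- function(records, provenance = list(), validate = TRUE) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in .ipd_columns) {
    if (is.null(records[[col]])) {
      records[[col]] <- switch(col,
        week8_imputed = FALSE,
        cdai_visits = NA_character_,
        participant_id = , trial_id = , arm = NA_character_,
        NA_real_)
    }
  }
  records <- records[, .ipd_columns]
  if (validate && nrow(records) > 0L) {
    yrs <- unique(records[, c("trial_id", "trial_year")])
    dup <- yrs$trial_id[duplicated(yrs$trial_id)]
    if (length(dup))
      stop("trial_year must be constant within a trial; violated by: ",
           paste(unique(dup), collapse = ", "))
    if (anyDuplicated(records$participant_id))
      stop("duplicate participant_id")
    if (any(!grepl("^(placebo|active:.+)$", records$arm)))
      stop("arm must be 'placebo' or 'active:<drug-code>'")
  }
  structure(records,
            provenance = provenance,
            class = c("trial_table", "data.frame"))
}

#' @export
print.trial_table <- function(x, ...) {
  cat("<trial_table> ", nrow(x), " participants, ",
      length(unique(x$trial_id)), " trials\n", sep = "")
  print(trial_index(x), row.names = FALSE)
  invisible(x)
}

#' Per-trial arm counts
#'
#' @param table a `trial_table`.
#' @return data frame: `trial_id`, `trial_year`, `arm`, `n`.
#' @export
trial_index <- function(table) {
  if (nrow(table) == 0L)
    return(data.frame(trial_id = character(0), trial_year = numeric(0),
                      arm = character(0), n = integer(0)))
  agg <- aggregate(list(n = table$participant_id),
                   by = list(trial_id = table$trial_id,
                             trial_year = table$trial_year,
                             arm = table$arm),
                   FUN = length)
  agg[order(agg$trial_id, agg$arm), ]
}

# subset rows, keeping class and provenance
subset_table <- function(table, keep, note = NULL) {
  prov <- attr(table, "provenance")
  if (!is.null(note)) prov$filters <- c(prov$filters, note)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  trial_table(out, provenance = prov, validate = FALSE)
}

# ---- row-level validation ---------------------------------------------------

# returns NULL if ok, else a reason string; warnings collected separately
.validate_row <- function(rec) {
  if (is.na(rec$participant_id) || !nzchar(rec$participant_id))
    return("invariant: participant_id present")
  if (is.na(rec$trial_id) || !nzchar(rec$trial_id))
    return("invariant: trial_id present")
  if (is.na(rec$arm) || !grepl("^(placebo|active:.+)$", rec$arm))
    return("invariant: arm is 'placebo' or 'active:<drug-code>'")
  if (is.na(rec$baseline_cdai)) return("invariant: baseline_cdai present")
  if (rec$baseline_cdai <= 0) return("invariant: baseline_cdai > 0")
  if (!is.na(rec$cdai_week8) && rec$cdai_week8 < 0)
    return("invariant: all CDAI values >= 0")
  v <- tryCatch(parse_visits(rec$cdai_visits), error = function(e) e)
  if (inherits(v, "error")) return(conditionMessage(v))
  if (nrow(v)) {
    if (any(v$cdai < 0)) return("invariant: all CDAI values >= 0")
    if (any(v$week > 8)) return("invariant: visit weeks <= 8")
    if (nrow(v) > 1L && any(diff(v$week) <= 0))
      return("invariant: visit weeks strictly increasing")
  }
  if (!is.na(rec$cdai_week8) && !is.na(rec$cdai_reduction) &&
      abs(rec$cdai_reduction - (rec$baseline_cdai - rec$cdai_week8)) > 1e-8)
    return("invariant: cdai_reduction = baseline_cdai - cdai_week8")
  NULL
}

#' Read an IPD table from CSV
#'
#' Reads a header CSV (missing values as empty fields), maps columns,
#' validates every row against the participant-record invariants, and
#' returns the accepted rows as a [trial_table()]. Rows violating a hard
#' invariant are rejected, never repaired; nothing is imputed at this stage.
#' `cdai_reduction` is derived (`baseline - week8`) when the week-8 value is
#' present and the reduction column is absent.
#'
#' @param path CSV file path.
#' @param scheme a [covariate_scheme()] (kept as provenance; centering is
#'   not applied here).
#' @param column_map optional named character vector mapping internal field
#'   names to file column names (defaults: identical names).
#' @param report_path optional path; the per-row rejection report is written
#'   there as JSON.
#' @return a `trial_table`; the rejection report is attached as attribute
#'   `"rejected"` (data frame: row, participant_id, reason).
#' @export
read_ipd_table <- function(path, scheme = covariate_scheme(),
                           column_map = NULL, report_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(raw) == 0L) stop("empty IPD file: ", path)
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      ext <- column_map[[internal]]
      if (!ext %in% names(raw))
        stop("mapped column missing from file: ", ext)
      names(raw)[names(raw) == ext] <- internal
    }
  }
  mandatory <- c("participant_id", "trial_id", "trial_year", "arm",
                 .continuous_covariates, .binary_covariates)
  absent <- setdiff(mandatory, names(raw))
  if (length(absent))
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))
  for (col in setdiff(.ipd_columns, names(raw))) {
    raw[[col]] <- if (col == "week8_imputed") FALSE
                  else if (col == "cdai_visits") NA_character_ else NA_real_
  }
  num_cols <- c("trial_year", .continuous_covariates, .binary_covariates,
                "cdai_week8", "cdai_reduction")
  rejected <- data.frame(row = integer(0), participant_id = character(0),
                         reason = character(0))
  for (col in num_cols) {
    if (!is.numeric(raw[[col]])) {
      coerced <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & is.na(coerced))
      for (i in bad)
        rejected <- rbind(rejected, data.frame(
          row = i, participant_id = as.character(raw$participant_id[i]),
          reason = paste0("unparseable numeric in column '", col, "'")))
      raw[[col]] <- coerced
    }
  }
  raw$participant_id <- as.character(raw$participant_id)
  raw$trial_id <- as.character(raw$trial_id)
  raw$arm <- as.character(raw$arm)
  derive <- !is.na(raw$cdai_week8) & is.na(raw$cdai_reduction) &
    !is.na(raw$baseline_cdai)
  raw$cdai_reduction[derive] <- raw$baseline_cdai[derive] -
    raw$cdai_week8[derive]
  for (i in seq_len(nrow(raw))) {
    if (i %in% rejected$row) next
    reason <- .validate_row(raw[i, ])
    if (!is.null(reason))
      rejected <- rbind(rejected, data.frame(
        row = i, participant_id = raw$participant_id[i], reason = reason))
  }
  high <- !is.na(raw$baseline_cdai) & raw$baseline_cdai > 600 |
    !is.na(raw$cdai_week8) & raw$cdai_week8 > 600
  high[rejected$row] <- FALSE
  if (any(high))
    warning(sum(high), " record(s) with CDAI above 600 (kept, flagged)")
  keep <- setdiff(seq_len(nrow(raw)), rejected$row)
  out <- trial_table(raw[keep, , drop = FALSE],
                     provenance = list(source = path,
                                       n_read = nrow(raw),
                                       n_rejected = nrow(rejected)))
  attr(out, "rejected") <- rejected
  if (!is.null(report_path))
    jsonlite::write_json(rejected, report_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  out
}

#' Write an IPD table to CSV
#'
#' Inverse of [read_ipd_table()]: accepted rows round-trip up to numeric
#' formatting. Missing values are written as empty fields.
#'
#' @param table a `trial_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ipd_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(as.data.frame(table)[, .ipd_columns], path,
            row.names = FALSE, na = "")
  invisible(path)
}
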