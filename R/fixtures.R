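# Bundled reference fixtures: published coefficient tables and remission
# counts, used for exact-arithmetic prediction checks and the acceptance
# report. No fitting is involved when these are used.

#' Published reference effect models
#'
#' Loads the bundled coefficient tables of the published
#' placebo-attributable and adalimumab-attributable models (estimates, Wald
#' SEs and p-values, per-trial random intercepts, ICC) as
#' [effect_model()] fixtures. Variance components were not published and
#' are `NA`; predictions from these models are exact arithmetic on the
#' printed estimates.
#'
#' @return named list with elements `placebo` and `adalimumab`.
#' @examples
#' ref <- reference_effect_models()
#' ref$placebo$coefficients[["intercept"]]  # 92.18
#' @export
reference_effect_models <- function() {
  path <- system.file("extdata", "reference_effect_models.json",
                      package = "srsim", mustWork = TRUE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(placebo = .effect_model_from_list(p$placebo),
       adalimumab = .effect_model_from_list(p$adalimumab))
}

#' Published reference remission counts
#'
#' The week-8 clinical remission 2x2 counts of the TNFi-naive ustekinumab
#' and adalimumab cohorts: the real head-to-head trial (SEAVUE), the
#' primary emulated comparison, three sensitivity analyses and the
#' no-normalization negative control, with the p-value each row printed.
#'
#' @return data frame: `id`, `label`, `ust_remitters`, `ust_n`,
#'   `ada_remitters`, `ada_n`, `printed_p`.
#' @export
reference_remission_counts <- function() {
  path <- system.file("extdata", "reference_remission_counts.json",
                      package = "srsim", mustWork = TRUE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- p$rows
  rows$printed_p <- as.numeric(rows$printed_p)
  rows
}
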