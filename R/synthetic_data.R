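# Synthetic multi-trial IPD generator with known ground truth. Emulates the
# structure of the real nine-trial Crohn's disease corpus (trial-level years
# and arm sizes, covariate marginals, outcome scale) so every pipeline stage
# is testable without the access-restricted data.

# truncated normal by rejection; bounds are loose in all defaults
.rtruncnorm <- function(n, mean, sd, min = -Inf, max = Inf) {
  if (min >= max) stop("unsatisfiable truncation bounds")
  out <- rnorm(n, mean, sd)
  bad <- which(out < min | out > max)
  tries <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < min | out[bad] > max]
    tries <- tries + 1L
    if (tries > 10000L) stop("unsatisfiable truncation bounds")
  }
  out
}

# log-normal matched to a target mean and SD, truncated below
.rlnorm_matched <- function(n, mean, sd, min = 0) {
  cv2 <- (sd / mean)^2
  sigma2 <- log(1 + cv2)
  mu <- log(mean) - sigma2 / 2
  out <- rlnorm(n, mu, sqrt(sigma2))
  out[out < min] <- min
  out
}

#' Default multi-trial design
#'
#' Trial identifiers, years, arm compositions and per-trial TNFi-history
#' rates mirroring the real corpus: six placebo-controlled trials (whose
#' placebo arms train the placebo model; the three ustekinumab trials also
#' contribute the observed comparator arm), and three uncontrolled
#' adalimumab trials.
#'
#' @param placebo_scale,active_scale multipliers applied to the placebo /
#'   active arm sizes (rounded), for scaled-up recovery studies.
#' @return data frame: `trial_id`, `year`, `arm`, `n`, `p_tnfi`.
#' @export
default_trial_design <- function(placebo_scale = 1, active_scale = 1) {
  d <- data.frame(
    trial_id = c("PRECISE1", "ENACT", "ENCORE", "CERTIFI", "UNITI1",
                 "UNITI2", "CERTIFI", "UNITI1", "UNITI2",
                 "CLASSIC", "EXTEND", "NCT02499783"),
    year = c(2003, 2001, 2004, 2008, 2011, 2011, 2008, 2011, 2011,
             2002, 2006, 2015),
    arm = c(rep("placebo", 6), rep("active:UST", 3), rep("active:ADA", 3)),
    n = c(299, 178, 237, 126, 263, 207, 126, 260, 209, 73, 64, 102),
    p_tnfi = c(0.27, 0.40, 0.46, 1.00, 0.99, 0.32, 1.00, 0.99, 0.32,
               0.03, 0.48, 0.00))
  scale <- ifelse(d$arm == "placebo", placebo_scale, active_scale)
  d$n <- pmax(1L, as.integer(round(d$n * scale)))
  d
}

#' Ground truth of a synthetic IPD world
#'
#' The generating parameters of a simulated multi-trial dataset. Defaults
#' are the published reference coefficient tables (placebo and adalimumab;
#' the ustekinumab-attributable truth defaults to the adalimumab truth,
#' since the two drugs were found indistinguishable and no ustekinumab
#' coefficients are published), residual SD 95 CDAI points (the scale of
#' the observed reduction SDs, ~100), and between-trial SDs chosen to match
#' the published ICCs (0.02 placebo, 0.05 drug) at that residual SD.
#' Covariates are drawn independently from marginals matching the baseline
#' table: age ~ N(38,12) truncated at 18, BMI ~ N(24,5) truncated at 14,
#' baseline CDAI ~ N(300,60) truncated to \[220,450\], CRP log-normal with
#' mean 18 / SD 24 mg/L truncated at 0.1, sex-male Bernoulli(0.45), flags
#' Bernoulli at baseline-table-like rates (TNFi history per trial).
#'
#' @param beta_placebo named vector in `covariate_scheme(TRUE)` order.
#' @param beta_drug named list of vectors (per drug code) in
#'   `covariate_scheme(FALSE)` order.
#' @param sigma_u_placebo,sigma_u_drug,sigma_e SDs in CDAI points.
#' @param covariate_spec per-covariate distribution parameters.
#' @param trial_design see [default_trial_design()].
#' @param seed integer seed; generation is fully reproducible from it.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(beta_placebo = NULL, beta_drug = NULL,
                            sigma_u_placebo = 95 * sqrt(0.02 / 0.98),
                            sigma_u_drug = 95 * sqrt(0.05 / 0.95),
                            sigma_e = 95,
                            covariate_spec = NULL,
                            trial_design = default_trial_design(),
                            seed = 1L) {
  ref <- reference_effect_models()
  if (is.null(beta_placebo)) beta_placebo <- ref$placebo$coefficients
  if (is.null(beta_drug))
    beta_drug <- list(ADA = ref$adalimumab$coefficients,
                      UST = ref$adalimumab$coefficients)
  spec <- list(
    age = list(mean = 38, sd = 12, min = 18),
    sex_male = list(p = 0.45),
    bmi = list(mean = 24, sd = 5, min = 14),
    baseline_cdai = list(mean = 300, sd = 60, min = 220, max = 450),
    crp = list(mean = 18, sd = 24, min = 0.1),
    tnfi_history = list(p = 0.40),
    steroid_use = list(p = 0.40),
    immunomodulator_use = list(p = 0.35),
    ileal_disease = list(p = 0.75))
  if (!is.null(covariate_spec)) spec <- modifyList(spec, covariate_spec)
  stopifnot(sigma_u_placebo >= 0, sigma_u_drug >= 0, sigma_e >= 0,
            all(trial_design$n >= 1))
  if (!identical(names(beta_placebo), covariate_scheme(TRUE)$terms))
    stop("beta_placebo must be named in covariate_scheme(TRUE) order")
  for (code in names(beta_drug))
    if (!identical(names(beta_drug[[code]]),
                   covariate_scheme(FALSE)$terms))
      stop("beta_drug[['", code,
           "']] must be named in covariate_scheme(FALSE) order")
  structure(
    list(beta_placebo = beta_placebo, beta_drug = beta_drug,
         sigma_u_placebo = sigma_u_placebo, sigma_u_drug = sigma_u_drug,
         sigma_e = sigma_e, covariate_spec = spec,
         trial_design = trial_design, seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' Generate synthetic multi-trial IPD
#'
#' Draws, for each trial, a placebo-level random intercept
#' `u^P ~ N(0, sigma_u_placebo^2)` and per-drug intercepts
#' `u^D ~ N(0, sigma_u_drug^2)`; then per participant draws covariates and
#' sets
#' `reduction = x'beta_placebo + u^P + [active] (x'beta_drug + u^D) + e`,
#' `e ~ N(0, sigma_e^2)`. The week-8 CDAI is `baseline - reduction`,
#' floored at 0 (the number of floored records is recorded and the
#' reduction adjusted so the derived-reduction invariant holds). A visit
#' series at weeks 0, 4 and 8 is attached (week 4 linearly interpolated
#' with measurement noise) so LOCF is exercisable. Fully reproducible from
#' the truth's seed.
#'
#' @param truth a [synthetic_truth()].
#' @return a `trial_table`; the truth echo is attribute `"truth"`, the
#'   drawn trial effects attribute `"random_effects"`, and the floored
#'   count attribute `"n_floored"`.
#' @export
generate_ipd <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  des <- truth$trial_design
  trials <- unique(des$trial_id)
  u_p <- setNames(rnorm(length(trials), 0, truth$sigma_u_placebo), trials)
  drugs <- names(truth$beta_drug)
  u_d <- lapply(drugs, function(code)
    setNames(rnorm(length(trials), 0, truth$sigma_u_drug), trials))
  names(u_d) <- drugs
  spec <- truth$covariate_spec
  sc_y <- covariate_scheme(TRUE)
  sc_n <- covariate_scheme(FALSE)
  counters <- setNames(integer(length(trials)), trials)
  blocks <- vector("list", nrow(des))
  for (i in seq_len(nrow(des))) {
    tid <- des$trial_id[i]; n <- des$n[i]; arm <- des$arm[i]
    p_tnfi <- if (!is.null(des$p_tnfi) && !is.na(des$p_tnfi[i]))
      des$p_tnfi[i] else spec$tnfi_history$p
    tab <- data.frame(
      participant_id = sprintf("%s-%04d", tid,
                               counters[tid] + seq_len(n)),
      trial_id = tid, trial_year = des$year[i], arm = arm,
      age = .rtruncnorm(n, spec$age$mean, spec$age$sd, spec$age$min),
      sex_male = rbinom(n, 1, spec$sex_male$p),
      bmi = .rtruncnorm(n, spec$bmi$mean, spec$bmi$sd, spec$bmi$min),
      baseline_cdai = .rtruncnorm(n, spec$baseline_cdai$mean,
                                  spec$baseline_cdai$sd,
                                  spec$baseline_cdai$min,
                                  spec$baseline_cdai$max),
      crp = .rlnorm_matched(n, spec$crp$mean, spec$crp$sd, spec$crp$min),
      tnfi_history = rbinom(n, 1, p_tnfi),
      steroid_use = rbinom(n, 1, spec$steroid_use$p),
      immunomodulator_use = rbinom(n, 1, spec$immunomodulator_use$p),
      ileal_disease = rbinom(n, 1, spec$ileal_disease$p))
    counters[tid] <- counters[tid] + n
    mu <- drop(design_matrix(tab, sc_y) %*% truth$beta_placebo) +
      u_p[[tid]]
    if (grepl("^active:", arm)) {
      code <- sub("^active:", "", arm)
      if (is.null(truth$beta_drug[[code]]))
        stop("no drug truth for arm code: ", code)
      mu <- mu + drop(design_matrix(tab, sc_n) %*%
                        truth$beta_drug[[code]]) + u_d[[code]][[tid]]
    }
    reduction <- mu + rnorm(n, 0, truth$sigma_e)
    week8 <- pmax(0, tab$baseline_cdai - reduction)
    tab$cdai_week8 <- week8
    tab$cdai_reduction <- tab$baseline_cdai - week8
    week4 <- pmax(0, (tab$baseline_cdai + week8) / 2 + rnorm(n, 0, 15))
    tab$cdai_visits <- sprintf("0:%.10g;4:%.10g;8:%.10g",
                               tab$baseline_cdai, week4, week8)
    tab$week8_imputed <- FALSE
    blocks[[i]] <- tab
  }
  all_rows <- do.call(rbind, blocks)
  n_floored <- sum(all_rows$cdai_week8 == 0)
  out <- trial_table(all_rows,
                     provenance = list(source = "generate_ipd",
                                       seed = truth$seed))
  attr(out, "truth") <- truth
  attr(out, "random_effects") <- list(u_placebo = u_p, u_drug = u_d)
  attr(out, "n_floored") <- n_floored
  out
}

#' Inject missingness completely at random
#'
#' Sets fields absent with the given per-field probabilities. Removing a
#' week-8 outcome also removes the derived reduction. The original values
#' are recorded in an oracle ledger so imputation can be tested against
#' the truth.
#'
#' @param table a `trial_table`.
#' @param rates named list/vector of probabilities in \[0,1\]; names are
#'   field names (continuous or binary covariates, or `cdai_week8`).
#' @param seed integer seed.
#' @return the table with missingness; attribute `"missingness_oracle"` is
#'   a data frame of `participant_id`, `field`, `original`.
#' @export
inject_missingness <- function(table, rates, seed = 1L) {
  stopifnot(is.data.frame(table), !is.null(names(rates)))
  rates <- unlist(rates)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  set.seed(seed)
  oracle <- list()
  for (f in names(rates)) {
    if (is.null(table[[f]])) stop("no such field: ", f)
    hit <- runif(nrow(table)) < rates[[f]]
    if (!any(hit)) next
    oracle[[f]] <- data.frame(participant_id = table$participant_id[hit],
                              field = f,
                              original = table[[f]][hit])
    table[[f]][hit] <- NA
    if (f == "cdai_week8") table$cdai_reduction[hit] <- NA
  }
  out <- trial_table(as.data.frame(table),
                     provenance = attr(table, "provenance"),
                     validate = FALSE)
  attr(out, "missingness_oracle") <-
    if (length(oracle)) do.call(rbind, oracle)
    else data.frame(participant_id = character(0), field = character(0),
                    original = numeric(0))
  out
}

#' Serialize / load a synthetic truth
#'
#' @param truth a [synthetic_truth()].
#' @param path JSON (or, with the yaml package installed, `.yaml`) path.
#' @return `write_synthetic_truth()`: `path` invisibly;
#'   `read_synthetic_truth()`: the reconstructed truth.
#' @export
write_synthetic_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- list(
    beta_placebo = as.list(truth$beta_placebo),
    beta_drug = lapply(truth$beta_drug, as.list),
    sigma_u_placebo = truth$sigma_u_placebo,
    sigma_u_drug = truth$sigma_u_drug,
    sigma_e = truth$sigma_e,
    covariate_spec = truth$covariate_spec,
    trial_design = truth$trial_design,
    seed = truth$seed)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package not installed; use a .json path")
    writeLines(yaml::as.yaml(payload), path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_synthetic_truth
#' @export
read_synthetic_truth <- function(path) {
  p <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package not installed; use a .json path")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  synthetic_truth(
    beta_placebo = unlist(p$beta_placebo),
    beta_drug = lapply(p$beta_drug, unlist),
    sigma_u_placebo = p$sigma_u_placebo,
    sigma_u_drug = p$sigma_u_drug,
    sigma_e = p$sigma_e,
    covariate_spec = p$covariate_spec,
    trial_design = as.data.frame(p$trial_design),
    seed = p$seed)
}
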