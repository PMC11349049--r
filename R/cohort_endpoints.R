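#' Endpoint analysis configuration
#'
#' Bundles the trial's endpoint definitions: the tumoral CD8 cutoff that
#' stratifies the cohort, the minimum stable-disease duration that counts as
#' disease control, the credible level, and the Beta prior used for the
#' response-rate posteriors.
#'
#' @param cd8_cutoff_pct CD8-high/low cutoff on the tumoral CD8 percentage
#'   scale. Default 15.
#' @param sd_min_duration_weeks Minimum SD duration (weeks) for disease
#'   control. Default 24.
#' @param ci_level Credible level for posterior intervals. Default 0.95.
#' @param dcr_orr_prior Length-2 positive numeric, the Beta(alpha0, beta0)
#'   prior for DCR/ORR intervals. Default `c(0.4, 1.6)`.
#' @param conversion_prior Prior reading for the conversion interval:
#'   `"improper_zero"` (posterior Beta(s, n-s)) or `"uniform"`
#'   (posterior Beta(s+1, n-s+1)).
#' @return A list of class `endpoint_config`.
#' @export
endpoint_config <- function(cd8_cutoff_pct = 15,
                            sd_min_duration_weeks = 24,
                            ci_level = 0.95,
                            dcr_orr_prior = c(0.4, 1.6),
                            conversion_prior = c("improper_zero", "uniform")) {
  conversion_prior <- match.arg(conversion_prior)
  stop_if_not(ci_level > 0 && ci_level < 1, "ci_level must be in (0, 1)")
  stop_if_not(length(dcr_orr_prior) == 2 && all(dcr_orr_prior > 0),
              "dcr_orr_prior must be two positive numbers")
  structure(list(cd8_cutoff_pct = cd8_cutoff_pct,
                 sd_min_duration_weeks = sd_min_duration_weeks,
                 ci_level = ci_level,
                 dcr_orr_prior = dcr_orr_prior,
                 conversion_prior = conversion_prior),
            class = "endpoint_config")
}

bor_levels <- c("CR", "PR", "SD", "PD", "NE")

#' Validate a patient record table
#'
#' Checks the columns and invariants of the patient table: CD8 percentages in
#' \[0, 100\], group consistent with the baseline CD8 cutoff, and SD duration
#' present exactly when the best overall response is SD.
#'
#' @param patients Data frame with columns `patient_id`, `group`
#'   (`"CD8_LOW"`/`"CD8_HIGH"`), `baseline_cd8_pct`, `on_treatment_cd8_pcts`
#'   (list column of numeric vectors, or pipe-separated strings),
#'   `best_overall_response` (CR/PR/SD/PD/NE), `sd_duration_weeks`.
#' @param cfg An [endpoint_config()].
#' @return The validated table, with `on_treatment_cd8_pcts` as a list column.
#' @export
validate_patients <- function(patients, cfg = endpoint_config()) {
  need <- c("patient_id", "group", "baseline_cd8_pct",
            "on_treatment_cd8_pcts", "best_overall_response")
  miss <- setdiff(need, names(patients))
  stop_if_not(length(miss) == 0, "patients table lacks columns: %s",
              paste(miss, collapse = ", "))
  stop_if_not(!anyDuplicated(patients$patient_id), "duplicated patient_id")
  if (!is.list(patients$on_treatment_cd8_pcts)) {
    patients$on_treatment_cd8_pcts <- lapply(
      strsplit(ifelse(is.na(patients$on_treatment_cd8_pcts), "",
                      as.character(patients$on_treatment_cd8_pcts)), "|",
               fixed = TRUE),
      function(v) as.numeric(v[nzchar(v)]))
  }
  stop_if_not(all(patients$group %in% c("CD8_LOW", "CD8_HIGH")),
              "group must be CD8_LOW or CD8_HIGH")
  stop_if_not(all(patients$best_overall_response %in% bor_levels),
              "best_overall_response must be one of %s",
              paste(bor_levels, collapse = "/"))
  cd8 <- c(patients$baseline_cd8_pct, unlist(patients$on_treatment_cd8_pcts))
  stop_if_not(all(cd8 >= 0 & cd8 <= 100), "CD8 percentages must lie in [0, 100]")
  low <- patients$baseline_cd8_pct < cfg$cd8_cutoff_pct
  stop_if_not(all((patients$group == "CD8_LOW") == low),
              "group labels inconsistent with baseline CD8 and cutoff %s",
              cfg$cd8_cutoff_pct)
  is_sd <- patients$best_overall_response == "SD"
  if (!"sd_duration_weeks" %in% names(patients)) {
    stop_if_not(!any(is_sd), "sd_duration_weeks required when BOR = SD")
    patients$sd_duration_weeks <- NA_real_
  }
  stop_if_not(!any(is_sd & is.na(patients$sd_duration_weeks)),
              "sd_duration_weeks missing for a BOR = SD patient")
  stop_if_not(all(patients$sd_duration_weeks[is_sd] >= 0),
              "sd_duration_weeks must be nonnegative")
  patients
}

#' Read a patient table from TSV
#'
#' On-treatment CD8 values are pipe-separated in the `on_treatment_cd8_pcts`
#' column; an empty string means no on-treatment biopsy.
#'
#' @inheritParams validate_patients
#' @param path Path to a tab-separated patient table.
#' @return Validated patient data frame.
#' @export
read_patients <- function(path, cfg = endpoint_config()) {
  validate_patients(utils::read.delim(path, stringsAsFactors = FALSE,
                                      na.strings = c("NA", "")), cfg)
}

#' Objective response classification
#'
#' A patient is an objective responder iff the best overall response is CR or
#' PR. NE (not evaluable) counts as non-responder, keeping the
#' intent-to-treat denominator.
#'
#' @param patients Validated patient table (or any data frame with a
#'   `best_overall_response` column).
#' @return Logical vector, one element per patient.
#' @export
classify_responder <- function(patients) {
  patients$best_overall_response %in% c("CR", "PR")
}

#' Disease control classification
#'
#' CR, PR, or SD sustained for at least `cfg$sd_min_duration_weeks` weeks.
#'
#' @inheritParams classify_responder
#' @param cfg An [endpoint_config()].
#' @return Logical vector.
#' @export
classify_disease_control <- function(patients, cfg = endpoint_config()) {
  is_sd <- patients$best_overall_response == "SD"
  stop_if_not(!any(is_sd & is.na(patients$sd_duration_weeks %||% NA_real_)),
              "sd_duration_weeks missing for a BOR = SD patient")
  classify_responder(patients) |
    (is_sd & !is.na(patients$sd_duration_weeks) &
       patients$sd_duration_weeks >= cfg$sd_min_duration_weeks)
}

#' CD8 conversion classification
#'
#' A CD8-low patient converts when any on-treatment biopsy reaches the
#' CD8-high cutoff; when several on-treatment biopsies exist the maximum
#' percentage is used. Patients without an on-treatment biopsy are not
#' evaluable. Conversion is defined only for the CD8-low group: CD8-high
#' records are an error.
#'
#' @inheritParams classify_disease_control
#' @return Character vector with values `"CONVERTER"`, `"NON_CONVERTER"`,
#'   `"NOT_EVALUABLE"`.
#' @export
classify_converter <- function(patients, cfg = endpoint_config()) {
  stop_if_not(all(patients$group == "CD8_LOW"),
              "conversion is defined only for CD8_LOW patients")
  vapply(patients$on_treatment_cd8_pcts, function(v) {
    if (length(v) == 0) return("NOT_EVALUABLE")
    if (max(v) >= cfg$cd8_cutoff_pct) "CONVERTER" else "NON_CONVERTER"
  }, character(1))
}

new_posterior_interval <- function(s, n, a, b, level) {
  q <- stats::qbeta(c((1 - level) / 2, 1 - (1 - level) / 2), a, b)
  structure(list(successes = s, trials = n,
                 posterior_alpha = a, posterior_beta = b, level = level,
                 point_estimate_pct = round_half_up(100 * s / n, 1),
                 lower = q[1], upper = q[2],          # unrounded, probability scale
                 lower_pct = round_half_up(100 * q[1], 1),
                 upper_pct = round_half_up(100 * q[2], 1)),
            class = "posterior_interval")
}

#' @export
print.posterior_interval <- function(x, ...) {
  cat(sprintf("%s/%s = %.1f%% (%.0f%% credible interval: %.1f-%.1f)\n",
              x$successes, x$trials, x$point_estimate_pct, 100 * x$level,
              x$lower_pct, x$upper_pct))
  invisible(x)
}

#' Beta-binomial posterior credible interval for a proportion
#'
#' Posterior is Beta(alpha0 + s, beta0 + n - s); the interval is the
#' equal-tailed pair of posterior quantiles, reported on the percent scale to
#' one decimal (half-up).
#'
#' @param s Number of successes.
#' @param n Number of trials.
#' @param prior Length-2 positive numeric `(alpha0, beta0)`.
#' @param level Credible level.
#' @return A `posterior_interval` object.
#' @export
beta_binomial_interval <- function(s, n, prior = c(0.4, 1.6), level = 0.95) {
  stop_if_not(n >= 1 && s >= 0 && s <= n && s == round(s) && n == round(n),
              "need integer counts with 0 <= s <= n, n >= 1")
  stop_if_not(all(prior > 0), "prior parameters must be positive")
  new_posterior_interval(s, n, prior[1] + s, prior[2] + n - s, level)
}

#' Conversion-rate credible interval "assuming no prior"
#'
#' Two readings are supported: the improper Beta(0, 0) prior, whose posterior
#' is Beta(s, n - s) and literally adds no pseudo-counts (the default and the
#' reading that reproduces the trial's printed interval), and the uniform
#' Beta(1, 1). Under the improper prior, s = 0 or s = n gives an improper
#' posterior and is an error; switch to `"uniform"` in that case.
#'
#' @inheritParams beta_binomial_interval
#' @param prior `"improper_zero"` or `"uniform"`.
#' @return A `posterior_interval` object.
#' @seealso [conversion_interval_both()] to report both readings side by side.
#' @export
conversion_interval <- function(s, n, prior = c("improper_zero", "uniform"),
                                level = 0.95) {
  prior <- match.arg(prior)
  stop_if_not(n >= 1 && s >= 0 && s <= n, "need 0 <= s <= n, n >= 1")
  if (prior == "improper_zero") {
    if (s == 0 || s == n)
      stop("posterior Beta(s, n-s) is improper at s = 0 or s = n; ",
           "use prior = \"uniform\"", call. = FALSE)
    new_posterior_interval(s, n, s, n - s, level)
  } else {
    new_posterior_interval(s, n, s + 1, n - s + 1, level)
  }
}

#' @rdname conversion_interval
#' @export
conversion_interval_both <- function(s, n, level = 0.95) {
  list(improper_zero = conversion_interval(s, n, "improper_zero", level),
       uniform = conversion_interval(s, n, "uniform", level))
}

#' Logistic regression with Wald test
#'
#' Univariable (or multivariable) logistic regression fit by iteratively
#' reweighted least squares with an intercept; two-sided Wald p-values from
#' the normal reference on each coefficient. Complete or quasi-complete
#' separation is flagged as a non-converged fit with a warning rather than
#' returned silently.
#'
#' @param outcome Binary 0/1 vector.
#' @param predictor Numeric vector or matrix/data.frame of predictors
#'   (no intercept column; one is added).
#' @return List of class `logistic_fit`: `coefficients`, `standard_errors`,
#'   `wald_z`, `p_values`, `converged`.
#' @export
fit_logistic_wald <- function(outcome, predictor) {
  stop_if_not(all(outcome %in% c(0, 1)), "outcome must be binary 0/1")
  X <- as.matrix(predictor)
  stop_if_not(length(outcome) >= 3 && nrow(X) == length(outcome),
              "need >= 3 observations matching the predictor length")
  stop_if_not(all(apply(X, 2, stats::var) > 0), "predictor is constant")
  fit <- suppressWarnings(
    stats::glm(outcome ~ X, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  co <- summary(fit)$coefficients
  # quasi-complete separation: fitted probabilities at the boundary and/or
  # exploding standard errors
  sep <- !fit$converged || any(fit$fitted.values < 1e-8) ||
    any(fit$fitted.values > 1 - 1e-8) || any(co[, 2] > 50)
  if (sep) warning("possible complete/quasi-complete separation; ",
                   "estimates unreliable", call. = FALSE)
  nm <- c("(Intercept)", colnames(X) %||% paste0("x", seq_len(ncol(X))))
  if (ncol(X) == 1 && is.null(colnames(X))) nm <- c("(Intercept)", "x")
  structure(list(coefficients = stats::setNames(co[, 1], nm),
                 standard_errors = stats::setNames(co[, 2], nm),
                 wald_z = stats::setNames(co[, 1] / co[, 2], nm),
                 p_values = stats::setNames(
                   2 * stats::pnorm(-abs(co[, 1] / co[, 2])), nm),
                 converged = !sep),
            class = "logistic_fit")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table. An empty margin returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts
#'   (rows = marker status, columns = responder status).
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stop_if_not(all(dim(tab) == 2) && all(tab >= 0) && all(tab == round(tab)),
              "need a 2x2 table of nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin; p = 1 by convention", call. = FALSE)
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Cohort endpoint summary
#'
#' Classifies every patient and reports, per CD8 group, the ORR and DCR with
#' beta-binomial credible intervals, and for the CD8-low group the conversion
#' rate among patients with an on-treatment biopsy under both readings of the
#' no-prior interval.
#'
#' @inheritParams classify_disease_control
#' @return Nested list with `cd8_low`, `cd8_high` (counts, `orr`, `dcr`) and
#'   `conversion` (counts, intervals under both priors).
#' @export
summarize_endpoints <- function(patients, cfg = endpoint_config()) {
  patients <- validate_patients(patients, cfg)
  resp <- classify_responder(patients)
  ctrl <- classify_disease_control(patients, cfg)
  per_group <- function(g) {
    idx <- patients$group == g
    n <- sum(idx)
    list(n = n, responders = sum(resp[idx]), disease_control = sum(ctrl[idx]),
         orr = beta_binomial_interval(sum(resp[idx]), n,
                                      cfg$dcr_orr_prior, cfg$ci_level),
         dcr = beta_binomial_interval(sum(ctrl[idx]), n,
                                      cfg$dcr_orr_prior, cfg$ci_level))
  }
  low <- patients[patients$group == "CD8_LOW", , drop = FALSE]
  conv <- classify_converter(low, cfg)
  n_eval <- sum(conv != "NOT_EVALUABLE")
  n_conv <- sum(conv == "CONVERTER")
  conv_int <- if (n_eval > 0 && n_conv > 0 && n_conv < n_eval) {
    conversion_interval_both(n_conv, n_eval, cfg$ci_level)
  } else NULL
  list(cd8_low = per_group("CD8_LOW"),
       cd8_high = per_group("CD8_HIGH"),
       conversion = list(
         evaluable = n_eval, converters = n_conv,
         rate_pct = if (n_eval > 0) round_half_up(100 * n_conv / n_eval, 1)
                    else NA_real_,
         intervals = conv_int,
         default_prior = cfg$conversion_prior))
}
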