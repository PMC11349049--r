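#' ctDNA positivity
#'
#' A plasma sample is ctDNA positive when at least 2 of the assayed
#' patient-specific SNVs are detected.
#'
#' @param snvs_detected Integer count(s) of detected SNVs.
#' @param snvs_assayed Number of SNVs in the personalized panel. Default 16.
#' @return Logical vector.
#' @export
ctdna_positive <- function(snvs_detected, snvs_assayed = 16) {
  stop_if_not(all(snvs_detected >= 0 & snvs_detected <= snvs_assayed &
                    snvs_detected == round(snvs_detected)),
              "snvs_detected must be integers in [0, snvs_assayed]")
  snvs_detected >= 2
}

#' Molecular response by 50 percent ctDNA decrease
#'
#' A patient's ctDNA is called decreased when the on-treatment concentration
#' is at most half of the pretreatment concentration (boundary inclusive).
#' A zero baseline makes the ratio undefined: the call is not evaluable.
#'
#' @param baseline_mtm,on_tx_mtm Nonnegative MTM/ml (mean tumor molecules
#'   per ml plasma) at baseline and on treatment; vectorized.
#' @return Data frame: `baseline_mtm`, `on_tx_mtm`, `evaluable`,
#'   `decreased_50` (NA when not evaluable).
#' @export
classify_decrease <- function(baseline_mtm, on_tx_mtm) {
  stop_if_not(all(baseline_mtm >= 0) && all(on_tx_mtm >= 0),
              "MTM/ml must be nonnegative")
  evaluable <- baseline_mtm > 0
  dec <- ifelse(evaluable, on_tx_mtm <= 0.5 * baseline_mtm, NA)
  data.frame(baseline_mtm = baseline_mtm, on_tx_mtm = on_tx_mtm,
             evaluable = evaluable, decreased_50 = dec)
}

#' Baseline-adjusted ctDNA comparison between response groups
#'
#' Per patient, the log10 on-treatment (C2D1) MTM/ml minus the log10
#' baseline MTM/ml; groups are compared with the equal-variance Student t.
#' Patients lacking a strictly positive value at either timepoint are
#' dropped with a warning.
#'
#' @param measurements Data frame with columns `patient_id`, `timepoint`
#'   (`"BL"` and `"C2D1"` used), `mtm_per_ml`.
#' @param labels Named character vector: response group (`"CRPR"`/`"PD"`)
#'   per patient id.
#' @param groups Length-2 character, the two labels compared.
#' @return List: `delta` (named per-patient log10 changes), `t`, `p`, `df`,
#'   `n_per_group`.
#' @export
baseline_adjusted_comparison <- function(measurements, labels,
                                         groups = c("CRPR", "PD")) {
  bl <- measurements[measurements$timepoint == "BL", ]
  ot <- measurements[measurements$timepoint == "C2D1", ]
  ids <- intersect(bl$patient_id, ot$patient_id)
  b <- bl$mtm_per_ml[match(ids, bl$patient_id)]
  o <- ot$mtm_per_ml[match(ids, ot$patient_id)]
  ok <- b > 0 & o > 0
  if (any(!ok))
    warning("dropping patients with nonpositive MTM/ml at BL or C2D1: ",
            paste(ids[!ok], collapse = ", "), call. = FALSE)
  ids <- ids[ok]
  delta <- stats::setNames(log10(o[ok]) - log10(b[ok]), ids)
  g <- labels[ids]
  a <- delta[g == groups[1] & !is.na(g)]
  c2 <- delta[g == groups[2] & !is.na(g)]
  stop_if_not(length(a) >= 2 && length(c2) >= 2,
              "need >= 2 evaluable patients per response group")
  tt <- student_t_two_sample(a, c2)
  list(delta = delta, t = tt$t, p = tt$p, df = tt$df,
       n_per_group = stats::setNames(c(length(a), length(c2)), groups))
}

#' Logistic association of baseline ctDNA with a binary outcome
#'
#' Logistic regression of the outcome on log10 baseline MTM/ml with a Wald
#' test on the slope. Zero baselines are shifted by half the smallest
#' positive observed value before the log.
#'
#' @param baseline_mtm Per-patient baseline MTM/ml.
#' @param outcome Binary 0/1 outcome (response or CD8 conversion).
#' @return A [fit_logistic_wald()] result.
#' @export
ctdna_response_association <- function(baseline_mtm, outcome) {
  stop_if_not(all(baseline_mtm >= 0), "MTM/ml must be nonnegative")
  x <- baseline_mtm
  if (any(x == 0)) {
    pos <- x[x > 0]
    stop_if_not(length(pos) > 0, "all baseline MTM/ml are zero")
    x <- x + min(pos) / 2
  }
  fit_logistic_wald(outcome, log10(x))
}
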