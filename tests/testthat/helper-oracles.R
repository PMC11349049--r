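# Independent oracles used by the unit and acceptance tests. These must not
# share code paths with the package implementation.

# Two-sided Fisher p by full enumeration over tables with fixed margins:
# sum of hypergeometric probabilities no larger than the observed one.
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Logistic MLE by coarse-to-fine grid search on the log-likelihood, plus a
# Wald p from a finite-difference Hessian at the grid optimum.
logistic_grid_oracle <- function(y, x) {
  nll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  b <- c(0, 0); width <- 8
  for (lev in 1:8) {
    g0 <- seq(b[1] - width, b[1] + width, length.out = 41)
    g1 <- seq(b[2] - width, b[2] + width, length.out = 41)
    vals <- outer(g0, g1, Vectorize(nll))
    idx <- arrayInd(which.min(vals), dim(vals))
    b <- c(g0[idx[1]], g1[idx[2]])
    width <- width / 8
  }
  h <- 1e-4
  H <- matrix(0, 2, 2)
  f0 <- nll(b[1], b[2])
  H[1, 1] <- (nll(b[1] + h, b[2]) - 2 * f0 + nll(b[1] - h, b[2])) / h^2
  H[2, 2] <- (nll(b[1], b[2] + h) - 2 * f0 + nll(b[1], b[2] - h)) / h^2
  H[1, 2] <- H[2, 1] <-
    (nll(b[1] + h, b[2] + h) - nll(b[1] + h, b[2] - h) -
       nll(b[1] - h, b[2] + h) + nll(b[1] - h, b[2] - h)) / (4 * h^2)
  se <- sqrt(diag(solve(H)))
  list(coef = b, se = se, p = 2 * pnorm(-abs(b / se)))
}

# Textbook pooled two-sample t for a hand check.
t_closed_form <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  list(t = tt, p = 2 * pt(-abs(tt), length(a) + length(b) - 2))
}

# OLS coefficients by explicit normal equations.
ols_oracle <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# Monte-Carlo posterior quantiles for a Beta posterior.
beta_mc_quantiles <- function(a, b, level = 0.95, n = 1e6) {
  draws <- rbeta(n, a, b)
  quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}

# Minimal patient-record constructor for rule tests.
patient_row <- function(id = "P1", group = "CD8_LOW", baseline = 5,
                        on_tx = "", bor = "PD", sd_weeks = NA,
                        tumor = "CRPC") {
  data.frame(patient_id = id, group = group, tumor_type = tumor,
             baseline_cd8_pct = baseline, on_treatment_cd8_pcts = on_tx,
             best_overall_response = bor, sd_duration_weeks = sd_weeks,
             prior_ici = FALSE, stringsAsFactors = FALSE)
}

# A cohort table reproducing printed group counts: responders get PR, extra
# disease controls get long SD, the rest PD; converters get an on-treatment
# value above the cutoff.
build_counts_cohort <- function(n_low = 72, resp_low = 14, dc_low = 18,
                                n_high = 7, resp_high = 1,
                                n_biopsy = 39, n_conv = 14) {
  bor_low <- c(rep("PR", resp_low), rep("SD", dc_low - resp_low),
               rep("PD", n_low - dc_low))
  sd_w <- ifelse(bor_low == "SD", 30, NA)
  on_tx <- c(rep("20", n_conv), rep("5", n_biopsy - n_conv),
             rep("", n_low - n_biopsy))
  low <- data.frame(patient_id = sprintf("L%02d", 1:n_low), group = "CD8_LOW",
                    tumor_type = "CRPC", baseline_cd8_pct = 5,
                    on_treatment_cd8_pcts = on_tx,
                    best_overall_response = bor_low,
                    sd_duration_weeks = sd_w, prior_ici = FALSE,
                    stringsAsFactors = FALSE)
  high <- data.frame(patient_id = sprintf("H%02d", 1:n_high),
                     group = "CD8_HIGH", tumor_type = "HNCA",
                     baseline_cd8_pct = 40, on_treatment_cd8_pcts = "",
                     best_overall_response = c(rep("PR", resp_high),
                                               rep("PD", n_high - resp_high)),
                     sd_duration_weeks = NA, prior_ici = FALSE,
                     stringsAsFactors = FALSE)
  rbind(low, high)
}
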