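feature_layers <- c("RNA_TPM", "NPX", "PCT_PARENT_CYTOF", "PCT_PARENT_X50",
                    "PCT_MIF")

#' Feature-by-sample matrix with layer semantics
#'
#' Thin container tying a numeric features x samples matrix to the assay
#' layer it came from (which fixes the differential-comparison rule preset)
#' and the scale its values live on.
#'
#' @param values Numeric matrix, features in rows, samples in columns, both
#'   dimnames set and unique.
#' @param layer One of `"RNA_TPM"`, `"NPX"`, `"PCT_PARENT_CYTOF"`,
#'   `"PCT_PARENT_X50"`, `"PCT_MIF"`.
#' @param scale `"LINEAR"` or `"LOG2"`.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, layer, scale = c("LINEAR", "LOG2")) {
  layer <- match.arg(layer, feature_layers)
  scale <- match.arg(scale)
  values <- as.matrix(values)
  stop_if_not(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values needs feature rownames and sample colnames")
  stop_if_not(!anyDuplicated(rownames(values)), "duplicated feature ids")
  stop_if_not(!anyDuplicated(colnames(values)), "duplicated sample ids")
  if (startsWith(layer, "PCT"))
    stop_if_not(all(values >= 0 & values <= 100, na.rm = TRUE),
                "percent-of-parent values must lie in [0, 100]")
  if (layer == "RNA_TPM" && scale == "LINEAR")
    stop_if_not(all(values >= 0, na.rm = TRUE), "linear TPM must be >= 0")
  structure(list(values = values, layer = layer, scale = scale),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples, layer %s, scale %s\n",
              nrow(x$values), ncol(x$values), x$layer, x$scale))
  invisible(x)
}

#' Differential-comparison rule
#'
#' A significance call in this pipeline is the conjunction of a raw p-value
#' gate and an effect-size gate. `layer_rule()` returns the preset for each
#' assay layer: RNA (p < 0.05, |log2FC| > 1), serum proteomics NPX (p < 0.05,
#' |log2FC| > 0.75), CyTOF percent-of-parent (p < 0.01, no effect gate), X50
#' flow percent-of-parent (p < 0.05, |mean difference| > 20 points), and mIF
#' percent-of-parent (p < 0.05, |mean difference| > 5 points).
#'
#' @param p_threshold Raw p-value threshold (strict `<`).
#' @param effect_metric `"LOG2FC"` or `"MEAN_DIFF"`.
#' @param effect_threshold Nonnegative; 0 disables the effect gate.
#' @return A `comparison_rule` list.
#' @export
comparison_rule <- function(p_threshold, effect_metric = c("LOG2FC", "MEAN_DIFF"),
                            effect_threshold = 0) {
  effect_metric <- match.arg(effect_metric)
  stop_if_not(p_threshold > 0 && p_threshold <= 1 && effect_threshold >= 0,
              "invalid rule thresholds")
  structure(list(p_threshold = p_threshold, effect_metric = effect_metric,
                 effect_threshold = effect_threshold),
            class = "comparison_rule")
}

#' @rdname comparison_rule
#' @param layer Assay layer name as in [feature_matrix()].
#' @export
layer_rule <- function(layer) {
  switch(match.arg(layer, feature_layers),
         RNA_TPM          = comparison_rule(0.05, "LOG2FC", 1),
         NPX              = comparison_rule(0.05, "LOG2FC", 0.75),
         PCT_PARENT_CYTOF = comparison_rule(0.01, "MEAN_DIFF", 0),
         PCT_PARENT_X50   = comparison_rule(0.05, "MEAN_DIFF", 20),
         PCT_MIF          = comparison_rule(0.05, "MEAN_DIFF", 5))
}

#' Equal-variance two-sample Student t-test
#'
#' Classic pooled-variance Student t with |a| + |b| - 2 degrees of freedom,
#' two-sided. Zero pooled variance makes the statistic undefined; such
#' features are flagged not-testable rather than erroring.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `p`, `df`, `testable`.
#' @export
student_t_two_sample <- function(a, b) {
  stop_if_not(length(a) >= 2 && length(b) >= 2,
              "each group needs at least 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (!is.finite(sp2) || sp2 <= 0)
    return(list(t = NA_real_, p = NA_real_,
                df = length(a) + length(b) - 2, testable = FALSE))
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), testable = TRUE)
}

#' Log2-transform a linear-scale matrix
#'
#' @param fm A LINEAR-scale [feature_matrix()].
#' @param pseudocount Added before the log; default 1 so zero maps to zero.
#' @return The matrix on LOG2 scale.
#' @export
log2_transform <- function(fm, pseudocount = 1) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  stop_if_not(fm$scale == "LINEAR", "matrix is already on LOG2 scale")
  fm$values <- log2(fm$values + pseudocount)
  fm$scale <- "LOG2"
  fm
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to the same distribution: the across-column
#' mean of order statistics. Ties within a column receive the mean of the
#' reference values they span.
#'
#' @param fm A [feature_matrix()] with >= 2 samples.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(fm) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  stop_if_not(ncol(fm$values) >= 2, "need >= 2 samples")
  fm$values <- limma::normalizeQuantiles(fm$values, ties = TRUE)
  fm
}

#' Baseline normalization within subject
#'
#' Subtracts each subject's baseline (timepoint `"BL"`) value from every
#' on-treatment sample of that subject and drops the baseline columns.
#' Subjects without a baseline sample are dropped with a warning.
#'
#' @param fm A [feature_matrix()].
#' @param meta Data frame with columns `sample_id`, `subject_id`, `timepoint`
#'   covering every sample in `fm`.
#' @return A feature_matrix of baseline-subtracted on-treatment samples.
#' @export
baseline_normalize <- function(fm, meta) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  sids <- colnames(fm$values)
  stop_if_not(all(sids %in% meta$sample_id), "metadata missing for samples")
  meta <- meta[match(sids, meta$sample_id), ]
  bl <- meta$timepoint == "BL"
  bl_of <- meta$subject_id[bl]
  stop_if_not(!anyDuplicated(bl_of), "more than one baseline sample per subject")
  keep <- !bl & meta$subject_id %in% bl_of
  if (any(!bl & !meta$subject_id %in% bl_of))
    warning("dropping on-treatment samples of subjects without baseline: ",
            paste(unique(meta$subject_id[!bl & !meta$subject_id %in% bl_of]),
                  collapse = ", "), call. = FALSE)
  bl_mat <- fm$values[, bl, drop = FALSE][, match(meta$subject_id[keep], bl_of),
                                          drop = FALSE]
  out <- fm$values[, keep, drop = FALSE] - bl_mat
  colnames(out) <- sids[keep]
  fm$values <- out
  fm
}

#' Two-group differential feature comparison
#'
#' One equal-variance Student t-test per feature between the two contrast
#' groups, with significance defined by the rule's p and effect gates. For
#' `LOG2FC` rules the matrix must already be on log2 scale and the effect is
#' the difference of group means on that scale; for `MEAN_DIFF` it is the
#' plain difference of group means.
#'
#' @param fm A [feature_matrix()].
#' @param group Character/factor over the samples of `fm` (in column order)
#'   with exactly two used levels; `NA` samples are dropped.
#' @param rule A [comparison_rule()]; default the preset for `fm$layer`.
#' @param contrast Optional length-2 character giving (numerator, reference)
#'   group; default the two levels in factor order. Effect = mean(numerator)
#'   - mean(reference).
#' @return Data frame sorted by p: `feature`, `mean_1`, `mean_2`, `effect`,
#'   `t`, `p`, `testable`, `significant`.
#' @export
differential_features <- function(fm, group, rule = layer_rule(fm$layer),
                                  contrast = NULL) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  if (rule$effect_metric == "LOG2FC")
    stop_if_not(fm$scale == "LOG2",
                "LOG2FC rule needs a LOG2-scale matrix; see log2_transform()")
  group <- as.character(group)
  stop_if_not(length(group) == ncol(fm$values),
              "group must have one label per sample")
  keep <- !is.na(group)
  vals <- fm$values[, keep, drop = FALSE]
  group <- group[keep]
  lev <- contrast %||% unique(group)
  stop_if_not(length(lev) == 2 && all(group %in% lev),
              "need exactly two contrast groups")
  ia <- group == lev[1]; ib <- group == lev[2]
  for (g in lev[c(sum(ia), sum(ib)) < 2])
    stop(sprintf("group '%s' has fewer than 2 samples", g), call. = FALSE)
  a <- vals[, ia, drop = FALSE]; b <- vals[, ib, drop = FALSE]
  # vectorized pooled t across features
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1); vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  df <- na + nb - 2
  p <- 2 * stats::pt(-abs(tt), df)
  testable <- is.finite(sp2) & sp2 > 0
  tt[!testable] <- NA_real_; p[!testable] <- NA_real_
  eff <- ma - mb
  sig <- testable & p < rule$p_threshold & abs(eff) > rule$effect_threshold
  out <- data.frame(feature = rownames(vals), mean_1 = ma, mean_2 = mb,
                    effect = eff, t = tt, p = p, testable = testable,
                    significant = sig, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p), ]
}

#' Gene-signature score per sample
#'
#' Each member feature is z-scored across the samples of the matrix and the
#' per-sample score is the mean of the member z-scores. Members absent from
#' the matrix or with zero variance are dropped with a warning.
#'
#' @param fm A [feature_matrix()] with >= 2 samples.
#' @param members Character vector of member feature ids.
#' @return Named numeric vector of per-sample scores (sums to ~0).
#' @export
signature_score <- function(fm, members) {
  stop_if_not(inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  stop_if_not(ncol(fm$values) >= 2, "need >= 2 samples")
  present <- intersect(members, rownames(fm$values))
  sub <- fm$values[present, , drop = FALSE]
  usable <- apply(sub, 1, stats::sd) > 0
  if (length(present) < length(members) || any(!usable))
    warning(sprintf("dropping %d absent and %d zero-variance set members",
                    length(members) - length(present), sum(!usable)),
            call. = FALSE)
  sub <- sub[usable, , drop = FALSE]
  stop_if_not(nrow(sub) >= 1, "no usable set members")
  z <- t(scale(t(sub)))
  colMeans(z)
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail p for observing at least the overlap between a
#' significant-feature set and a pathway, within a stated universe.
#'
#' @param significant Character vector of significant feature ids
#'   (must lie in `universe`).
#' @param pathway Character vector of pathway member ids.
#' @param universe Character vector of all testable feature ids.
#' @param p_cutoff Significance gate on the enrichment p. Default 0.01.
#' @return List: `overlap`, `expected`, `p`, `significant`, `testable`.
#' @export
overrepresentation_test <- function(significant, pathway, universe,
                                    p_cutoff = 0.01) {
  significant <- unique(significant); universe <- unique(universe)
  stop_if_not(all(significant %in% universe),
              "significant features must be a subset of the universe")
  path_u <- unique(intersect(pathway, universe))
  if (length(path_u) == 0)
    return(list(overlap = 0L, expected = 0, p = NA_real_,
                significant = FALSE, testable = FALSE))
  k <- length(intersect(significant, path_u))
  N <- length(universe); K <- length(path_u); n <- length(significant)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, expected = n * K / N, p = p,
       significant = p < p_cutoff, testable = TRUE)
}
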