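#' Chao1 repertoire richness
#'
#' Nonparametric richness estimate from clone abundances. The classic form
#' S_obs + f1^2 / (2 f2) is used when doubletons exist; when f2 = 0 the
#' bias-corrected form S_obs + f1 (f1 - 1) / 2 is used instead, and the
#' variant applied is recorded.
#'
#' @param counts Vector of positive integer clone abundances.
#' @return List of class `diversity_result`: `s_obs`, `f1`, `f2`, `chao1`,
#'   `variant` (`"CLASSIC"` or `"BIAS_CORRECTED"`).
#' @export
chao1 <- function(counts) {
  stop_if_not(length(counts) >= 1, "empty abundance vector")
  stop_if_not(all(counts >= 1 & counts == round(counts)),
              "abundances must be positive integers")
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    est <- s_obs + f1^2 / (2 * f2)
    variant <- "CLASSIC"
  } else {
    est <- s_obs + f1 * (f1 - 1) / 2
    variant <- "BIAS_CORRECTED"
  }
  structure(list(s_obs = s_obs, f1 = f1, f2 = f2, chao1 = est,
                 variant = variant), class = "diversity_result")
}

validate_clones <- function(clones) {
  need <- c("patient_id", "chain", "cdr3_aa", "count")
  stop_if_not(all(need %in% names(clones)), "clone table lacks columns: %s",
              paste(setdiff(need, names(clones)), collapse = ", "))
  stop_if_not(all(clones$chain %in% c("TRA", "TRB")),
              "chain must be TRA or TRB")
  stop_if_not(all(nzchar(clones$cdr3_aa)) &&
                all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", clones$cdr3_aa)),
              "cdr3_aa must be nonempty uppercase amino-acid strings")
  stop_if_not(all(clones$count >= 1), "counts must be >= 1")
  clones
}

#' Per-patient Chao1 diversity from a clone table
#'
#' Duplicate records of the same clone (same patient, chain, CDR3, and any
#' grouping columns present) are collapsed by summing counts before
#' estimation.
#'
#' @param clones Clone table with columns `patient_id`, `chain`, `cdr3_aa`,
#'   `count`, and optionally `compartment`, `timepoint`.
#' @param chain `"TRA"` or `"TRB"`.
#' @return Data frame: grouping columns, `s_obs`, `f1`, `f2`, `chao1`,
#'   `variant`.
#' @export
repertoire_diversity <- function(clones, chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  clones <- validate_clones(clones)
  clones <- clones[clones$chain == chain, , drop = FALSE]
  stop_if_not(nrow(clones) > 0, "no %s records", chain)
  grp_cols <- intersect(c("patient_id", "compartment", "timepoint"),
                        names(clones))
  key <- do.call(paste, c(clones[grp_cols], sep = "\r"))
  clone_key <- paste(key, clones$cdr3_aa, sep = "\r")
  counts <- tapply(clones$count, clone_key, sum)
  grp_of_clone <- sub("\r[^\r]*$", "", names(counts))
  rows <- lapply(unique(key), function(k) {
    d <- chao1(as.vector(counts[grp_of_clone == k]))
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    cbind(as.data.frame(as.list(stats::setNames(parts, grp_cols)),
                        stringsAsFactors = FALSE),
          data.frame(s_obs = d$s_obs, f1 = d$f1, f2 = d$f2, chao1 = d$chao1,
                     variant = d$variant, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Cross-patient clone sharing
#'
#' Clones are keyed by exact CDR3 amino-acid identity within a chain.
#' Returns the symmetric patient-by-patient matrix of shared-clone counts
#' (diagonal = each patient's richness) and the list of public clones
#' (carried by >= 2 patients) with their carrier sets.
#'
#' @inheritParams repertoire_diversity
#' @return List of class `sharing_result`: `sharing` (matrix), `public`
#'   (data frame `cdr3_aa`, `n_patients`, `patients`), `chain`.
#' @export
shared_clones <- function(clones, chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  clones <- validate_clones(clones)
  clones <- clones[clones$chain == chain, , drop = FALSE]
  stop_if_not(nrow(clones) > 0, "no %s records", chain)
  pairs <- unique(clones[c("patient_id", "cdr3_aa")])
  pats <- sort(unique(pairs$patient_id))
  cdrs <- unique(pairs$cdr3_aa)
  inc <- matrix(0L, nrow = length(pats), ncol = length(cdrs),
                dimnames = list(pats, cdrs))
  inc[cbind(match(pairs$patient_id, pats), match(pairs$cdr3_aa, cdrs))] <- 1L
  sharing <- tcrossprod(inc)
  carriers <- colSums(inc)
  pub <- which(carriers >= 2)
  public <- data.frame(
    cdr3_aa = cdrs[pub],
    n_patients = carriers[pub],
    patients = vapply(pub, function(j)
      paste(pats[inc[, j] == 1], collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(sharing = sharing, public = public, chain = chain),
            class = "sharing_result")
}

#' Blood-tumor repertoire overlap for one patient
#'
#' Distinct blood clones per peripheral subset and how many of them are also
#' found in the patient's tumor repertoire (exact CDR3 identity within
#' chain).
#'
#' @inheritParams repertoire_diversity
#' @param patient Patient id; must have records in both compartments, else
#'   the result is flagged not evaluable.
#' @return Data frame: `subset_label`, `n_blood`, `n_shared_with_tumor`,
#'   plus attribute `evaluable`.
#' @export
blood_tumor_overlap <- function(clones, patient, chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  clones <- validate_clones(clones)
  stop_if_not("compartment" %in% names(clones),
              "clone table lacks a compartment column")
  sub <- clones[clones$patient_id == patient & clones$chain == chain, ,
                drop = FALSE]
  blood <- sub[sub$compartment == "BLOOD", , drop = FALSE]
  tumor <- sub[sub$compartment == "TUMOR", , drop = FALSE]
  if (nrow(blood) == 0 || nrow(tumor) == 0) {
    out <- data.frame(subset_label = character(), n_blood = integer(),
                      n_shared_with_tumor = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "evaluable") <- FALSE
    return(out)
  }
  tumor_set <- unique(tumor$cdr3_aa)
  lab <- if ("subset_label" %in% names(blood) && !all(is.na(blood$subset_label)))
    blood$subset_label else rep("ALL", nrow(blood))
  rows <- lapply(unique(lab), function(l) {
    cl <- unique(blood$cdr3_aa[lab == l])
    data.frame(subset_label = l, n_blood = length(cl),
               n_shared_with_tumor = length(intersect(cl, tumor_set)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "evaluable") <- TRUE
  out
}
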