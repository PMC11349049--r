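#' Synthetic data generators
#'
#' Every generator in this file is a pure function of its arguments and
#' `seed`: the same call yields byte-identical output, and the caller's RNG
#' state is untouched. Each returns its tables together with a `truth` list
#' recording the latent variables and planted coefficients, sufficient to
#' compute every recovery metric the test suite uses. `write_simulation()`
#' serializes any of them to TSV + JSON.
#'
#' @name synthetic_data
NULL

tumor_type_weights_default <- c(CRPC = 0.25, OVCA = 0.14, UTCA = 0.10,
                                NECA = 0.08, HNCA = 0.07, BRCA = 0.07,
                                CVCX = 0.05, GSCA = 0.05, LUCA = 0.05,
                                PANC = 0.05, OTHER = 0.09)

#' Simulate a CD8-stratified basket-trial cohort
#'
#' Patients are stratified by baseline tumoral CD8 percentage at the 15%
#' cutoff. A latent inflammation score drives CD8 conversion (logistic
#' model) among CD8-low patients with an on-treatment biopsy, and objective
#' response is a logistic function of conversion and inflammation, so the
#' conversion-response association the endpoint analysis estimates is
#' planted with known coefficients.
#'
#' @param n_cd8low,n_cd8high Group sizes. Defaults 72 and 7 (the trial's
#'   enrolment).
#' @param biopsy_prob Probability a CD8-low patient has an on-treatment
#'   biopsy. Default 0.54.
#' @param conversion_coef `c(intercept, slope)` of the conversion logistic
#'   on the latent inflammation score.
#' @param response_coef `c(intercept, conversion, inflammation)` of the
#'   response logistic.
#' @param tumor_type_weights Named sampling weights.
#' @param prior_ici_prob Probability of prior checkpoint-inhibitor exposure.
#' @param seed Integer seed.
#' @return List: `patients` (validated patient table), `truth` (latent
#'   scores, true coefficients, conversion/response indicators).
#' @export
simulate_cohort <- function(n_cd8low = 72, n_cd8high = 7, biopsy_prob = 0.54,
                            conversion_coef = c(-0.6, 1.0),
                            response_coef = c(-2.2, 1.4, 0.5),
                            tumor_type_weights = tumor_type_weights_default,
                            prior_ici_prob = 0.35, seed = 1) {
  with_seed(seed, {
    n <- n_cd8low + n_cd8high
    group <- rep(c("CD8_LOW", "CD8_HIGH"), c(n_cd8low, n_cd8high))
    baseline <- ifelse(group == "CD8_LOW", 15 * stats::rbeta(n, 1.2, 2.5),
                       15 + 85 * stats::rbeta(n, 0.8, 5))
    baseline <- round(baseline, 1)
    baseline[group == "CD8_LOW" & baseline >= 15] <- 14.9
    inflammation <- stats::rnorm(n)
    has_biopsy <- stats::rbinom(n, 1, ifelse(group == "CD8_LOW",
                                             biopsy_prob, 0.57)) == 1
    p_conv <- stats::plogis(conversion_coef[1] +
                              conversion_coef[2] * inflammation)
    converted <- group == "CD8_LOW" & has_biopsy &
      stats::rbinom(n, 1, p_conv) == 1
    on_tx <- vector("list", n)
    for (i in seq_len(n)) {
      if (!has_biopsy[i]) next
      k <- sample(1:2, 1, prob = c(0.8, 0.2))
      if (group[i] == "CD8_HIGH") {
        v <- pmin(100, baseline[i] + stats::runif(k, 2, 20))
      } else if (converted[i]) {
        v <- c(15 + 26 * stats::rbeta(1, 1, 2),
               if (k > 1) pmax(0, baseline[i] + stats::rnorm(k - 1, 2, 3)))
      } else {
        v <- pmax(0, pmin(14.9, baseline[i] + stats::rnorm(k, 1, 3)))
      }
      on_tx[[i]] <- round(pmin(100, pmax(0, v)), 1)
    }
    p_resp <- stats::plogis(response_coef[1] + response_coef[2] * converted +
                              response_coef[3] * inflammation)
    responder <- stats::rbinom(n, 1, p_resp) == 1
    bor <- ifelse(responder,
                  ifelse(stats::runif(n) < 0.1, "CR", "PR"),
                  ifelse(stats::runif(n) < 0.25, "SD",
                         ifelse(stats::runif(n) < 0.05, "NE", "PD")))
    sd_dur <- ifelse(bor == "SD", round(stats::rgamma(n, 2, 1 / 14)), NA)
    patients <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      group = group,
      tumor_type = sample(names(tumor_type_weights), n, replace = TRUE,
                          prob = tumor_type_weights),
      baseline_cd8_pct = baseline,
      on_treatment_cd8_pcts = vapply(on_tx, paste, "", collapse = "|"),
      best_overall_response = bor,
      sd_duration_weeks = sd_dur,
      prior_ici = stats::rbinom(n, 1, prior_ici_prob) == 1,
      stringsAsFactors = FALSE)
    list(patients = validate_patients(patients),
         truth = list(seed = seed, inflammation = inflammation,
                      conversion_coef = conversion_coef,
                      response_coef = response_coef,
                      converted = converted, responder = responder))
  })
}

#' Simulate a feature-by-sample omics matrix with planted effects
#'
#' Two groups of samples; a configured fraction of features carries a mean
#' shift of `effect` in group A, the rest are null. Values are Gaussian
#' around per-feature baselines on the layer's working scale (log2 for
#' RNA/NPX, percent for the PCT layers, where values are clamped to
#' \[0, 100\]). Optional additive batch offsets.
#'
#' @param n_features Number of features. Default 1000.
#' @param n_per_group Samples per group. Default 10.
#' @param frac_true Fraction of features with a planted effect. Default 0.05.
#' @param effect Planted group-A minus group-B mean shift, on the working
#'   scale. Default 2.
#' @param noise_sd Residual sd. Default 0.5.
#' @param layer Assay layer (see [feature_matrix()]). Default `"RNA_TPM"`.
#' @param batch_offsets Optional numeric vector of per-batch additive
#'   offsets; samples are assigned to batches cyclically.
#' @param seed Integer seed.
#' @return List: `fm` (a [feature_matrix()], scale LOG2 for RNA/NPX),
#'   `meta` (sample_id, group, batch), `truth` (planted feature ids,
#'   effect, noise_sd).
#' @export
simulate_omics <- function(n_features = 1000, n_per_group = 10,
                           frac_true = 0.05, effect = 2, noise_sd = 0.5,
                           layer = "RNA_TPM", batch_offsets = NULL,
                           seed = 1) {
  with_seed(seed, {
    n_samp <- 2 * n_per_group
    pct <- startsWith(layer, "PCT")
    base <- if (pct) stats::runif(n_features, 10, 60)
            else stats::rnorm(n_features, 6, 2)
    n_true <- round(frac_true * n_features)
    planted <- if (n_true > 0) sort(sample.int(n_features, n_true))
               else integer(0)
    shift <- numeric(n_features)
    shift[planted] <- effect
    grp <- rep(c("A", "B"), each = n_per_group)
    mat <- base + outer(shift, as.numeric(grp == "A")) +
      matrix(stats::rnorm(n_features * n_samp, 0, noise_sd),
             n_features, n_samp)
    batch <- rep("b1", n_samp)
    if (!is.null(batch_offsets)) {
      batch <- paste0("b", rep_len(seq_along(batch_offsets), n_samp))
      mat <- mat + rep(batch_offsets[rep_len(seq_along(batch_offsets),
                                             n_samp)], each = n_features)
    }
    if (pct) mat <- pmin(pmax(mat, 0), 100)
    rownames(mat) <- sprintf("f%04d", seq_len(n_features))
    colnames(mat) <- sprintf("s%02d", seq_len(n_samp))
    fm <- feature_matrix(mat, layer, scale = if (pct) "LINEAR" else "LOG2")
    list(fm = fm,
         meta = data.frame(sample_id = colnames(mat), group = grp,
                           batch = batch, stringsAsFactors = FALSE),
         truth = list(seed = seed, planted = rownames(mat)[planted],
                      effect = effect, noise_sd = noise_sd))
  })
}

#' Simulate segmented-ROI pixel tables for mIF phenotyping
#'
#' Each image holds several ROIs of segmented cells; for each marker a cell
#' is planted positive with the marker's `pos_fraction` and its pixels are
#' drawn from the positive (else negative) Gaussian mode, truncated at 0.
#' Truth records each cell's planted memberships and the realized per-image
#' positive fractions.
#'
#' @param n_images Number of images. Default 50.
#' @param rois_per_image ROIs per image. Default 2.
#' @param cells_per_roi Poisson mean cell count per ROI. Default 80.
#' @param pixels_per_cell Length-2 integer range of pixels per cell.
#'   Default c(20, 40).
#' @param markers Named list; per marker a list with `neg_mean`, `neg_sd`,
#'   `pos_mean`, `pos_sd`, `pos_fraction`. Default one CD8-like channel
#'   with 5-sd mode separation and 30% positives.
#' @param seed Integer seed.
#' @return List: `cells` (long pixel table: image_id, roi_id, cell_id,
#'   marker, pixel_index, intensity), `truth` (per-cell memberships,
#'   realized per-image fractions, configured modes).
#' @export
simulate_roi_images <- function(n_images = 50, rois_per_image = 2,
                                cells_per_roi = 80,
                                pixels_per_cell = c(20, 40),
                                markers = list(CD8 = list(
                                  neg_mean = 2, neg_sd = 1,
                                  pos_mean = 7, pos_sd = 1,
                                  pos_fraction = 0.3)),
                                seed = 1) {
  with_seed(seed, {
    out <- vector("list", n_images)
    memb <- vector("list", n_images)
    for (im in seq_len(n_images)) {
      image_id <- sprintf("img%03d", im)
      n_cells <- pmax(1, stats::rpois(rois_per_image, cells_per_roi))
      roi_id <- rep(sprintf("roi%d", seq_len(rois_per_image)), n_cells)
      cell_id <- unlist(lapply(n_cells, function(k) sprintf("c%04d",
                                                            seq_len(k))))
      npix <- sample(pixels_per_cell[1]:pixels_per_cell[2],
                     sum(n_cells), replace = TRUE)
      per_marker <- lapply(names(markers), function(mk) {
        cfgm <- markers[[mk]]
        pos <- stats::rbinom(sum(n_cells), 1, cfgm$pos_fraction) == 1
        mu <- ifelse(pos, cfgm$pos_mean, cfgm$neg_mean)
        sdv <- ifelse(pos, cfgm$pos_sd, cfgm$neg_sd)
        px <- pmax(0, stats::rnorm(sum(npix), rep(mu, npix), rep(sdv, npix)))
        list(cells = data.frame(
               image_id = image_id,
               roi_id = rep(roi_id, npix),
               cell_id = rep(cell_id, npix),
               marker = mk,
               pixel_index = unlist(lapply(npix, seq_len)),
               intensity = px, stringsAsFactors = FALSE),
             member = data.frame(image_id = image_id, roi_id = roi_id,
                                 cell_id = cell_id, marker = mk,
                                 positive = pos, stringsAsFactors = FALSE))
      })
      out[[im]] <- do.call(rbind, lapply(per_marker, `[[`, "cells"))
      memb[[im]] <- do.call(rbind, lapply(per_marker, `[[`, "member"))
    }
    cells <- do.call(rbind, out)
    membership <- do.call(rbind, memb)
    frac <- stats::aggregate(positive ~ image_id + marker, membership, mean)
    names(frac)[names(frac) == "positive"] <- "true_fraction_pct"
    frac$true_fraction_pct <- 100 * frac$true_fraction_pct
    list(cells = cells,
         truth = list(seed = seed, membership = membership,
                      image_fractions = frac, markers = markers))
  })
}

curve_point <- function(t, family) {
  switch(family,
         line = cbind(t, t),
         arc = cbind(cos(t * pi / 2), sin(t * pi / 2)),
         scurve = cbind(t, 0.3 * sin(2 * pi * t)))
}

#' Simulate cells on a latent 1-D trajectory with planted gene programs
#'
#' Cells receive latent times t ~ Uniform(0, 1), are placed on the chosen
#' 2-D curve embedded in `d` dimensions, and perturbed by isotropic Gaussian
#' noise. Genes are linear functions of t with per-vendor offsets and
#' optional group x t interaction effects, plus Gaussian noise — exactly the
#' model the trajectory GLM fits, so every coefficient is recoverable.
#'
#' @param n_cells Number of cells. Default 500.
#' @param d Embedding dimension (curve lives in the first two; the rest are
#'   noise). Default 2.
#' @param curve `"line"`, `"arc"`, or `"scurve"`.
#' @param noise_sd Isotropic embedding noise sd (the curves have extent ~1).
#'   Default 0.05.
#' @param gene_coefs Named numeric vector of per-gene trajectory
#'   coefficients (zeros = null genes). Default 10 genes, half null, half
#'   with coefficient 2.
#' @param interaction_coefs Optional named numeric: per-gene group x t
#'   interaction coefficients (genes not named get 0).
#' @param vendors Character vector of vendor labels. Default two.
#' @param vendor_offsets Numeric per-vendor additive offsets on every gene.
#' @param gene_noise_sd Residual sd of gene expression. Default 0.5.
#' @param seed Integer seed.
#' @return List: `embedding` (n_cells x d), `genes` (n_cells x genes),
#'   `meta` (vendor, group, timepoint), `truth` (latent `t`, all
#'   coefficients).
#' @export
simulate_trajectory <- function(n_cells = 500, d = 2,
                                curve = c("scurve", "line", "arc"),
                                noise_sd = 0.05,
                                gene_coefs = stats::setNames(
                                  rep(c(0, 2), each = 5),
                                  sprintf("g%02d", 1:10)),
                                interaction_coefs = NULL,
                                vendors = c("vendorA", "vendorB"),
                                vendor_offsets = c(0, 0.5),
                                gene_noise_sd = 0.5, seed = 1) {
  curve <- match.arg(curve)
  stop_if_not(d >= 2, "need d >= 2")
  with_seed(seed, {
    t <- stats::runif(n_cells)
    base <- curve_point(t, curve)
    emb <- cbind(base, matrix(0, n_cells, d - 2)) +
      matrix(stats::rnorm(n_cells * d, 0, noise_sd), n_cells, d)
    colnames(emb) <- sprintf("comp%02d", seq_len(d))
    vendor <- sample(vendors, n_cells, replace = TRUE)
    group <- sample(c("PR", "PD"), n_cells, replace = TRUE)
    timepoint <- sample(c("C1D1", "C1D8"), n_cells, replace = TRUE)
    voff <- stats::setNames(vendor_offsets, vendors)[vendor]
    gnames <- names(gene_coefs)
    icoefs <- stats::setNames(rep(0, length(gnames)), gnames)
    if (!is.null(interaction_coefs))
      icoefs[names(interaction_coefs)] <- interaction_coefs
    gind <- as.numeric(group == "PR")
    genes <- vapply(gnames, function(g) {
      gene_coefs[g] * t + icoefs[g] * t * gind + voff +
        stats::rnorm(n_cells, 0, gene_noise_sd)
    }, numeric(n_cells))
    list(embedding = emb, genes = genes,
         meta = data.frame(vendor = vendor, group = group,
                           timepoint = timepoint, stringsAsFactors = FALSE),
         truth = list(seed = seed, t = t, curve = curve,
                      gene_coefs = gene_coefs, interaction_coefs = icoefs,
                      vendor_offsets = vendor_offsets,
                      gene_noise_sd = gene_noise_sd))
  })
}

# Fisher log-series abundance sampler (parameter 0 < p < 1)
rlogseries <- function(n, p, kmax = 10000) {
  k <- seq_len(kmax)
  prob <- p^k / k
  sample(k, n, replace = TRUE, prob = prob)
}

random_cdr3 <- function(n, len_range = c(8, 16)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
         function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
         character(1))
}

#' Simulate TCR clone tables with planted public clones
#'
#' Per-patient blood repertoires with log-series abundances; a shared pool
#' of public CDR3 sequences is sprinkled across patients with a fixed
#' sharing probability, and each patient's tumor repertoire is a subsample
#' of their blood clones at the configured overlap rate plus tumor-private
#' clones.
#'
#' @param n_patients Number of patients. Default 8.
#' @param clones_per_patient Distinct blood clones per patient. Default 300.
#' @param logseries_p Log-series abundance parameter in (0,1). Default 0.9.
#' @param public_pool_size Size of the shared public-clone pool. Default 50.
#' @param share_prob Probability each patient carries each public clone.
#'   Default 0.5.
#' @param overlap_rate Fraction of a patient's blood clones also found in
#'   tumor. Default 0.2.
#' @param chain Chain label for all records. Default `"TRB"`.
#' @param seed Integer seed.
#' @return List: `clones` (clone table), `truth` (public pool, per-patient
#'   overlap sets).
#' @export
simulate_clones <- function(n_patients = 8, clones_per_patient = 300,
                            logseries_p = 0.9, public_pool_size = 50,
                            share_prob = 0.5, overlap_rate = 0.2,
                            chain = "TRB", seed = 1) {
  with_seed(seed, {
    pool <- random_cdr3(public_pool_size)
    subsets <- c("Tnaive", "Tcm", "Tem", "Tte")
    rows <- list()
    overlap_truth <- list()
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%02d", i)
      n_pub <- if (public_pool_size > 0)
        sum(stats::rbinom(public_pool_size, 1, share_prob)) else 0
      pub <- if (n_pub > 0) sample(pool, n_pub) else character(0)
      priv <- random_cdr3(max(0, clones_per_patient - length(pub)))
      cdr3 <- unique(c(pub, priv))
      counts <- rlogseries(length(cdr3), logseries_p)
      tumor_sel <- stats::runif(length(cdr3)) < overlap_rate
      tumor_cdr3 <- c(cdr3[tumor_sel], random_cdr3(30))
      rows[[pid]] <- rbind(
        data.frame(patient_id = pid, chain = chain, cdr3_aa = cdr3,
                   count = counts, compartment = "BLOOD", timepoint = "BL",
                   subset_label = sample(subsets, length(cdr3),
                                         replace = TRUE),
                   stringsAsFactors = FALSE),
        data.frame(patient_id = pid, chain = chain, cdr3_aa = tumor_cdr3,
                   count = rlogseries(length(tumor_cdr3), logseries_p),
                   compartment = "TUMOR", timepoint = "BL",
                   subset_label = NA_character_, stringsAsFactors = FALSE))
      overlap_truth[[pid]] <- cdr3[tumor_sel]
    }
    list(clones = do.call(rbind, c(rows, make.row.names = FALSE)),
         truth = list(seed = seed, public_pool = pool,
                      blood_tumor_overlap = overlap_truth))
  })
}

#' Simulate longitudinal ctDNA measurements
#'
#' Log-normal baseline MTM/ml per patient; responders decline on treatment
#' with configured probability (decliners drop ~10-fold, non-decliners
#' drift). SNV detection counts scale with concentration.
#'
#' @param n_crpr,n_pd Patients per response group. Defaults 7 and 10.
#' @param decline_prob Named numeric, probability of a >= 50% decline per
#'   group. Default `c(CRPR = 0.85, PD = 0.2)`.
#' @param seed Integer seed.
#' @return List: `measurements` (patient_id, timepoint, snvs_detected,
#'   mtm_per_ml), `labels` (named group per patient), `truth` (decliner
#'   flags, planted log10 changes).
#' @export
simulate_ctdna <- function(n_crpr = 7, n_pd = 10,
                           decline_prob = c(CRPR = 0.85, PD = 0.2),
                           seed = 1) {
  with_seed(seed, {
    n <- n_crpr + n_pd
    pid <- sprintf("P%02d", seq_len(n))
    grp <- rep(c("CRPR", "PD"), c(n_crpr, n_pd))
    bl <- stats::rlnorm(n, meanlog = 1.5, sdlog = 1.2)
    decliner <- stats::rbinom(n, 1, decline_prob[grp]) == 1
    delta <- ifelse(decliner, stats::rnorm(n, -1.2, 0.3),
                    stats::rnorm(n, 0.2, 0.3))
    c2 <- bl * 10^delta
    snv <- function(m) pmin(16L, 2L + stats::rpois(length(m),
                                                   pmax(0, log10(m + 1)) * 4))
    measurements <- rbind(
      data.frame(patient_id = pid, timepoint = "BL",
                 snvs_detected = snv(bl), mtm_per_ml = bl,
                 stringsAsFactors = FALSE),
      data.frame(patient_id = pid, timepoint = "C2D1",
                 snvs_detected = snv(c2), mtm_per_ml = c2,
                 stringsAsFactors = FALSE))
    list(measurements = measurements,
         labels = stats::setNames(grp, pid),
         truth = list(seed = seed, decliner = decliner, delta_log10 = delta))
  })
}

#' Serialize a simulation result to disk
#'
#' Writes each data frame/matrix element as TSV and the `truth` element as
#' JSON into `out_dir`.
#'
#' @param sim A generator result list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(sim)) {
    el <- sim[[nm]]
    if (nm == "truth" || !(is.data.frame(el) || is.matrix(el))) next
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(as.data.frame(el), p, sep = "\t", quote = FALSE,
                       row.names = is.matrix(el))
    paths <- c(paths, p)
  }
  if (!is.null(sim$truth)) {
    p <- file.path(out_dir, "truth.json")
    jsonlite::write_json(sim$truth, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
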