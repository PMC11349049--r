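make_fm <- function(mat, layer = "NPX", scale = "LOG2") {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("f", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  feature_matrix(mat, layer, scale)
}

test_that("pooled Student t matches the closed form and brackets a permutation p", {
  same <- student_t_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5, 6)
  got <- student_t_two_sample(a, b)
  orc <- t_closed_form(a, b)
  expect_equal(got$t, orc$t, tolerance = 1e-12)
  expect_equal(got$p, orc$p, tolerance = 1e-12)
  expect_equal(got$df, 7)

  # exhaustive label-permutation p brackets the parametric p for
  # symmetric-noise data (small n: all C(8,4) relabelings)
  set.seed(406)
  x <- rnorm(8)
  ga <- x[1:4]; gb <- x[5:8]
  t_obs <- abs(student_t_two_sample(ga, gb)$t)
  combs <- combn(8, 4)
  perm_t <- apply(combs, 2, function(idx)
    abs(student_t_two_sample(x[idx], x[-idx])$t))
  p_perm <- mean(perm_t >= t_obs - 1e-12)
  p_par <- student_t_two_sample(ga, gb)$p
  expect_lt(abs(p_perm - p_par), 0.25)

  flat <- student_t_two_sample(c(2, 2, 2), c(2, 2, 2))
  expect_false(flat$testable)
  expect_error(student_t_two_sample(1, c(1, 2)), "at least 2")
})

test_that("log2 transform is monotone, anchored at the pseudocount, and scale-aware", {
  fm <- make_fm(matrix(c(0, 7, 1, 3), 2), layer = "RNA_TPM", scale = "LINEAR")
  lg <- log2_transform(fm, 1)
  expect_equal(unname(lg$values[1, 1]), 0)
  expect_equal(unname(lg$values[2, 1]), 3)
  expect_equal(lg$scale, "LOG2")
  expect_equal(order(fm$values), order(lg$values))
  expect_error(log2_transform(lg), "LOG2")
})

test_that("quantile normalization equalizes columns, handles the hand case, and is idempotent", {
  fm <- make_fm(cbind(c(1, 2, 3), c(4, 5, 6)))
  qn <- quantile_normalize(fm)
  expect_equal(unname(qn$values), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  set.seed(407)
  fm2 <- make_fm(matrix(rnorm(60, sd = 3), 10, 6))
  qn1 <- quantile_normalize(fm2)
  expect_equal(apply(qn1$values, 2, mean),
               rep(mean(qn1$values[, 1]), 6) |> setNames(colnames(qn1$values)))
  qn2 <- quantile_normalize(qn1)
  expect_equal(qn1$values, qn2$values, tolerance = 1e-12)

  ident <- make_fm(cbind(a = c(1, 5, 9), b = c(1, 5, 9)))
  expect_equal(quantile_normalize(ident)$values, ident$values)
})

test_that("baseline normalization subtracts the subject's pretreatment sample", {
  mat <- cbind(s1 = c(10, 0), s2 = c(12, 1), s3 = c(9, 2), s4 = c(5, 5))
  rownames(mat) <- c("fA", "fB")
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     subject_id = c("u1", "u1", "u1", "u2"),
                     timepoint = c("BL", "C2D1", "C3D1", "C2D1"))
  fm <- make_fm(mat)
  expect_warning(out <- baseline_normalize(fm, meta), "without baseline")
  expect_equal(colnames(out$values), c("s2", "s3"))
  expect_equal(unname(out$values[, "s2"]), c(2, 1))
  expect_equal(unname(out$values[, "s3"]), c(-1, 2))

  # all timepoints equal to baseline gives an all-zero output
  m2 <- cbind(s1 = c(3, 4), s2 = c(3, 4))
  rownames(m2) <- c("fA", "fB")
  meta2 <- data.frame(sample_id = c("s1", "s2"), subject_id = "u1",
                      timepoint = c("BL", "C2D1"))
  expect_true(all(baseline_normalize(make_fm(m2), meta2)$values == 0))
})

test_that("differential comparison applies the layer rules and contrast symmetry", {
  sim <- simulate_omics(n_features = 400, n_per_group = 10, frac_true = 0.1,
                        effect = 2, noise_sd = 0.5, seed = 21)
  res <- differential_features(sim$fm, sim$meta$group, layer_rule("RNA_TPM"))
  planted_hit <- sum(res$significant[res$feature %in% sim$truth$planted])
  expect_gte(planted_hit, 36)
  null_fp <- mean(res$significant[!res$feature %in% sim$truth$planted])
  expect_lte(null_fp, 0.07)
  expect_false(is.unsorted(res$p))
  expect_true(all(res$significant ==
                    (res$testable & res$p < 0.05 & abs(res$effect) > 1)))

  # swapping the contrast negates effects and keeps p-values
  swapped <- differential_features(sim$fm, sim$meta$group,
                                   layer_rule("RNA_TPM"),
                                   contrast = c("B", "A"))
  m <- match(res$feature, swapped$feature)
  expect_equal(res$effect, -swapped$effect[m], tolerance = 1e-12)
  expect_equal(res$p, swapped$p[m], tolerance = 1e-12)

  # identical groups: nothing significant, features not testable
  const <- make_fm(matrix(rep(c(1, 2, 3, 4), each = 6), 4, 6, byrow = TRUE))
  res0 <- differential_features(const, rep(c("A", "B"), 3))
  expect_false(any(res0$significant))

  expect_error(differential_features(sim$fm,
                                     c("A", rep("B", ncol(sim$fm$values) - 1))),
               "fewer than 2")
  lin <- make_fm(matrix(1:12, 3), layer = "RNA_TPM", scale = "LINEAR")
  expect_error(differential_features(lin, rep(c("A", "B"), 2),
                                     layer_rule("RNA_TPM")), "LOG2")
})

test_that("the p-gate alone is calibrated at 5% on null features", {
  sim <- simulate_omics(n_features = 10000, n_per_group = 10, frac_true = 0,
                        seed = 22)
  rule <- comparison_rule(0.05, "LOG2FC", 0)
  res <- differential_features(sim$fm, sim$meta$group, rule)
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("signature scores are mean member z-scores with the stated invariances", {
  set.seed(408)
  mat <- matrix(rnorm(40), 5, 8,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  fm <- make_fm(mat)
  one <- signature_score(fm, "g2")
  expect_equal(one, (mat["g2", ] - mean(mat["g2", ])) / sd(mat["g2", ]))

  sc <- signature_score(fm, c("g1", "g3", "g4"))
  expect_equal(sum(sc), 0, tolerance = 1e-9)

  # affine rescaling of a member leaves the score unchanged
  mat2 <- mat; mat2["g3", ] <- 5 * mat2["g3", ] + 100
  expect_equal(signature_score(make_fm(mat2), c("g1", "g3", "g4")), sc,
               tolerance = 1e-12)

  # union of disjoint sets = member-count-weighted mean of the two scores
  s1 <- signature_score(fm, c("g1", "g2"))
  s2 <- signature_score(fm, c("g3", "g4", "g5"))
  su <- signature_score(fm, paste0("g", 1:5))
  expect_equal(su, (2 * s1 + 3 * s2) / 5, tolerance = 1e-12)

  expect_warning(signature_score(fm, c("g1", "nope")), "absent")
  flatrow <- mat; flatrow["g1", ] <- 7
  expect_error(suppressWarnings(signature_score(make_fm(flatrow), "g1")),
               "usable")
})

test_that("over-representation p matches the hypergeometric closed form and enumeration", {
  u <- paste0("g", 1:20)
  expect_equal(overrepresentation_test(u[1:6], u, u)$p, 1)
  res <- overrepresentation_test(u[1:5], u[1:5], u)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(res$significant)

  # exhaustive enumeration over draws from a small universe
  set.seed(409)
  uni <- paste0("g", 1:12)
  for (rep in 1:10) {
    sig <- sample(uni, 5)
    path <- sample(uni, 4)
    got <- overrepresentation_test(sig, path, uni)
    draws <- combn(12, 5)
    exceed <- mean(apply(draws, 2, function(idx)
      length(intersect(uni[idx], path))) >= got$overlap)
    expect_equal(got$p, exceed, tolerance = 1e-12)
  }
  off <- overrepresentation_test(uni[1:3], c("zz1", "zz2"), uni)
  expect_false(off$testable)
})
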