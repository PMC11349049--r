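#' Center and scale an embedding or expression matrix
#'
#' Columns are shifted to mean 0 and scaled to sd 1; zero-variance columns
#' carry no ordering information and are dropped with a warning.
#'
#' @param mat Numeric matrix with >= 2 rows.
#' @return The scaled matrix (attributes stripped).
#' @export
scale_center <- function(mat) {
  mat <- as.matrix(mat)
  stop_if_not(nrow(mat) >= 2, "need >= 2 rows")
  v <- apply(mat, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(mat)[v == 0] %||% which(v == 0), collapse = ", "),
            call. = FALSE)
    mat <- mat[, v > 0, drop = FALSE]
  }
  out <- scale(mat)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# orthogonal projection of points X onto the polyline through `curve`;
# returns arc-length positions and squared distances
project_to_polyline <- function(X, curve) {
  n <- nrow(X)
  seg <- diff(curve)
  seglen2 <- rowSums(seg^2)
  seglen <- sqrt(seglen2)
  arc0 <- c(0, cumsum(seglen))
  best_d2 <- rep(Inf, n)
  best_arc <- numeric(n)
  for (s in seq_len(nrow(curve) - 1)) {
    if (seglen2[s] == 0) next
    diffs <- sweep(X, 2, curve[s, ])
    tt <- pmin(1, pmax(0, (diffs %*% seg[s, ]) / seglen2[s]))
    d2 <- rowSums((diffs - tcrossprod(tt, seg[s, ]))^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- arc0[s] + tt[upd] * seglen[s]
  }
  list(arc = best_arc, d2 = best_d2)
}

#' Principal-curve pseudotime
#'
#' Fits a principal curve to a cells x components embedding by the
#' alternating projection/smoothing iteration: pseudotime is initialized by
#' projection onto the first principal component, each coordinate is then
#' smoothed against pseudotime with a cubic smoothing spline (penalty chosen
#' by generalized cross-validation), points are re-projected onto the
#' discretized curve, and pseudotime is recomputed as arc length. Iteration
#' stops when the relative change in total squared orthogonal distance falls
#' below `tol`, when the distance would increase (the previous state is
#' kept, so the recorded distance trace is non-increasing), or at
#' `max_iter`. No start or end cell is required; the orientation of the
#' curve is arbitrary unless `orient_by` is given.
#'
#' @param X Numeric cells x d matrix, d >= 2, >= 10 cells.
#' @param max_iter Maximum iterations. Default 1000.
#' @param tol Relative-change convergence tolerance on the total squared
#'   distance. Default 1e-4.
#' @param grid_n Number of points used to discretize the curve for
#'   projection. Default 200.
#' @param orient_by Optional per-cell numeric (e.g. a naive-marker score
#'   expected to be high early); pseudotime is flipped so that its
#'   correlation with `orient_by` is negative-to-positive increasing.
#' @return List of class `principal_curve_fit`: `pseudotime` (min-max scaled
#'   to \[0,1\]), `lambda` (arc-length positions), `curve` (grid_n x d fitted
#'   points), `iterations`, `converged`, `total_dist2`, `dist_trace`,
#'   `flipped`.
#' @export
fit_principal_curve <- function(X, max_iter = 1000, tol = 1e-4,
                                grid_n = 200, orient_by = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stop_if_not(n >= 10 && d >= 2, "need >= 10 cells and >= 2 components")
  stop_if_not(all(is.finite(X)), "embedding contains non-finite values")
  cvar <- apply(X, 2, stats::var)
  stop_if_not(any(cvar > 0), "degenerate embedding: all components constant")

  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  lambda <- pc$x[, 1]
  center <- colMeans(X)
  curve <- outer(seq(min(lambda), max(lambda), length.out = grid_n),
                 pc$rotation[, 1]) + rep(center, each = grid_n)
  pr <- project_to_polyline(X, curve)
  lambda <- pr$arc
  dist2 <- sum(pr$d2)
  trace <- dist2
  converged <- dist2 == 0
  iters <- 0L

  while (!converged && iters < max_iter) {
    iters <- iters + 1L
    gl <- seq(min(lambda), max(lambda), length.out = grid_n)
    new_curve <- matrix(0, grid_n, d)
    for (j in seq_len(d)) {
      fitj <- tryCatch(
        stats::smooth.spline(lambda, X[, j]),  # GCV-selected penalty
        error = function(e) NULL)
      new_curve[, j] <- if (is.null(fitj)) {
        rep(mean(X[, j]), grid_n)
      } else stats::predict(fitj, gl)$y
    }
    pr <- project_to_polyline(X, new_curve)
    new_dist2 <- sum(pr$d2)
    if (new_dist2 > dist2) {                  # GCV jitter at the fixed point:
      converged <- TRUE                       # keep previous state, monotone
      break                                   # trace, declare convergence
    }
    rel <- if (dist2 > 0) (dist2 - new_dist2) / dist2 else 0
    curve <- new_curve
    lambda <- pr$arc
    dist2 <- new_dist2
    trace <- c(trace, dist2)
    if (rel < tol) converged <- TRUE
  }

  rng <- range(lambda)
  pt <- if (diff(rng) > 0) (lambda - rng[1]) / diff(rng) else rep(0.5, n)
  flipped <- FALSE
  if (!is.null(orient_by)) {
    rho <- suppressWarnings(stats::cor(pt, orient_by, method = "spearman"))
    if (is.finite(rho) && rho > 0) { pt <- 1 - pt; flipped <- TRUE }
  }
  structure(list(pseudotime = pt, lambda = lambda, curve = curve,
                 iterations = iters, converged = converged,
                 total_dist2 = dist2, dist_trace = trace, flipped = flipped),
            class = "principal_curve_fit")
}

#' Trajectory-association test configuration
#'
#' Cutoffs for calling a gene trajectory-associated: Bonferroni-adjusted
#' p <= 0.10 combined with an absolute coefficient cutoff of 1 on the
#' pseudotime term (TRAJECTORY mode) or 0.25 on the group/timepoint term
#' (GROUP/TIMEPOINT modes). Coefficients are on the z-scored gene scale.
#'
#' @param adjusted_p_cutoff Bonferroni-adjusted p cutoff. Default 0.10.
#' @param coef_cutoff_trajectory Coefficient magnitude cutoff, TRAJECTORY
#'   mode. Default 1.
#' @param coef_cutoff_group Coefficient magnitude cutoff, GROUP/TIMEPOINT
#'   modes. Default 0.25.
#' @param covariates Covariate columns of the cell metadata to adjust for.
#'   Default `"vendor"`.
#' @return A `trajectory_test_config` list.
#' @export
trajectory_test_config <- function(adjusted_p_cutoff = 0.10,
                                   coef_cutoff_trajectory = 1,
                                   coef_cutoff_group = 0.25,
                                   covariates = "vendor") {
  structure(list(adjusted_p_cutoff = adjusted_p_cutoff,
                 coef_cutoff_trajectory = coef_cutoff_trajectory,
                 coef_cutoff_group = coef_cutoff_group,
                 covariates = covariates),
            class = "trajectory_test_config")
}

#' Bonferroni adjustment
#'
#' @param p Vector of p-values in \[0,1\].
#' @return `pmin(1, length(p) * p)`.
#' @export
bonferroni_adjust <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0,1]")
  pmin(1, length(p) * p)
}

build_trajectory_design <- function(pt, meta, mode, cfg, interaction) {
  cols <- list(`(Intercept)` = rep(1, length(pt)), pseudotime = pt)
  for (cv in cfg$covariates) {
    if (is.null(meta[[cv]])) next
    f <- factor(meta[[cv]])
    if (nlevels(f) < 2) next
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(cv, levels(f)[-1])
    for (k in seq_len(ncol(mm))) cols[[colnames(mm)[k]]] <- mm[, k]
  }
  term <- "pseudotime"
  if (mode != "TRAJECTORY") {
    gcol <- if (mode == "GROUP") "group" else "timepoint"
    f <- factor(meta[[gcol]])
    stop_if_not(nlevels(f) == 2, "%s must have exactly two levels", gcol)
    gname <- paste0(gcol, levels(f)[2])
    cols[[gname]] <- as.numeric(f == levels(f)[2])
    if (interaction) {
      term <- paste0("pseudotime:", gname)
      cols[[term]] <- pt * cols[[gname]]
    } else {
      term <- gname
    }
  }
  list(X = do.call(cbind, cols), term = term)
}

#' Gaussian GLM trajectory-association tests
#'
#' For each gene, an ordinary-least-squares Gaussian GLM of (by default
#' z-scored) expression on pseudotime plus covariates; in GROUP/TIMEPOINT
#' mode the model adds the group (or timepoint) factor and, by default, its
#' pseudotime interaction, and that term is the one tested. p-values come
#' from the coefficient t statistic; Bonferroni adjustment is across the
#' genes tested in the call; a gene is significant when the adjusted p is at
#' most `cfg$adjusted_p_cutoff` and the coefficient magnitude exceeds the
#' mode's cutoff.
#'
#' @param genes Cells x genes numeric matrix (column names = gene ids).
#' @param fit A [fit_principal_curve()] result, or a numeric pseudotime
#'   vector.
#' @param meta Data frame of per-cell metadata (columns `vendor`, and
#'   `group`/`timepoint` as required by `mode`).
#' @param mode `"TRAJECTORY"`, `"GROUP"`, or `"TIMEPOINT"`.
#' @param cfg A [trajectory_test_config()].
#' @param scale_genes Z-score each gene across cells before fitting
#'   (default TRUE, the scale on which the coefficient cutoffs are defined).
#' @param interaction In GROUP/TIMEPOINT mode test the pseudotime x group
#'   interaction (default) rather than the group main effect.
#' @return Data frame: `gene`, `coef`, `se`, `p`, `p_adj`, `testable`,
#'   `significant`, `mode`, `term`.
#' @export
trajectory_tests <- function(genes, fit, meta = NULL,
                             mode = c("TRAJECTORY", "GROUP", "TIMEPOINT"),
                             cfg = trajectory_test_config(),
                             scale_genes = TRUE, interaction = TRUE) {
  mode <- match.arg(mode)
  pt <- if (inherits(fit, "principal_curve_fit")) fit$pseudotime else fit
  genes <- as.matrix(genes)
  stop_if_not(nrow(genes) == length(pt),
              "genes must have one row per cell")
  if (is.null(meta)) meta <- data.frame(row.names = seq_along(pt))
  des <- build_trajectory_design(pt, meta, mode, cfg, interaction)
  X <- des$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear design; involved columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "), call. = FALSE)
  gvar <- apply(genes, 2, stats::var)
  testable <- gvar > 0
  Y <- genes[, testable, drop = FALSE]
  if (scale_genes) Y <- scale(Y)
  cf <- qr.coef(qrX, Y)
  res <- Y - X %*% cf
  dfree <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dfree
  XtXinv_jj <- diag(chol2inv(qr.R(qrX)))[match(des$term, colnames(X))]
  est <- cf[des$term, ]
  se <- sqrt(sigma2 * XtXinv_jj)
  pval <- 2 * stats::pt(-abs(est / se), dfree)
  out <- data.frame(gene = colnames(genes), coef = NA_real_, se = NA_real_,
                    p = NA_real_, p_adj = NA_real_, testable = testable,
                    significant = FALSE, mode = mode, term = des$term,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$coef[testable] <- est
  out$se[testable] <- se
  out$p[testable] <- pval
  out$p_adj[testable] <- bonferroni_adjust(pval)
  cut <- if (mode == "TRAJECTORY") cfg$coef_cutoff_trajectory
         else cfg$coef_cutoff_group
  out$significant <- out$testable & !is.na(out$p_adj) &
    out$p_adj <= cfg$adjusted_p_cutoff & abs(out$coef) > cut
  out
}

#' @rdname trajectory_tests
#' @param expr Expression vector for a single gene.
#' @export
glm_trajectory_association <- function(expr, fit, meta = NULL,
                                       mode = c("TRAJECTORY", "GROUP",
                                                "TIMEPOINT"),
                                       cfg = trajectory_test_config(),
                                       scale_genes = TRUE,
                                       interaction = TRUE) {
  trajectory_tests(matrix(expr, ncol = 1, dimnames = list(NULL, "gene")),
                   fit, meta, mode, cfg, scale_genes, interaction)
}

#' Cell-density trends along pseudotime
#'
#' Gaussian kernel density of pseudotime per stratum, bandwidth by
#' Silverman's rule of thumb, evaluated on a 256-point grid over \[0,1\] with
#' boundary reflection at 0 and 1 so each curve integrates to 1. Strata with
#' fewer than `min_cells` cells are suppressed with a warning.
#'
#' @param fit A [fit_principal_curve()] result or pseudotime vector.
#' @param strata Factor/character of per-cell stratum labels (e.g.
#'   group x timepoint).
#' @param n_grid Grid size. Default 256.
#' @param min_cells Minimum stratum size. Default 20.
#' @return Data frame: `stratum`, `pseudotime`, `density`.
#' @export
density_trend <- function(fit, strata, n_grid = 256, min_cells = 20) {
  pt <- if (inherits(fit, "principal_curve_fit")) fit$pseudotime else fit
  strata <- as.factor(strata)
  stop_if_not(length(strata) == length(pt), "one stratum label per cell")
  grid <- seq(0, 1, length.out = n_grid)
  out <- lapply(levels(strata), function(lv) {
    x <- pt[strata == lv]
    if (length(x) < min_cells) {
      warning(sprintf("stratum '%s' has %d < %d cells; curve suppressed",
                      lv, length(x), min_cells), call. = FALSE)
      return(NULL)
    }
    bw <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
    if (!is.finite(bw) || bw <= 0) bw <- 1e-3   # degenerate (point-mass) stratum
    # reflected kernel: mass outside [0,1] folded back at both boundaries
    f <- vapply(grid, function(g) {
      mean(stats::dnorm(g - x, sd = bw) + stats::dnorm(g + x, sd = bw) +
             stats::dnorm(2 - g - x, sd = bw))
    }, numeric(1))
    data.frame(stratum = lv, pseudotime = grid, density = f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Smoothed signature score along pseudotime
#'
#' Cubic smoothing spline (GCV penalty) of a per-cell signature score
#' against pseudotime, evaluated on a grid.
#'
#' @param scores Per-cell numeric scores.
#' @param fit A [fit_principal_curve()] result or pseudotime vector.
#' @param n_grid Grid size. Default 100.
#' @return Data frame: `pseudotime`, `score`.
#' @export
signature_along_trajectory <- function(scores, fit, n_grid = 100) {
  pt <- if (inherits(fit, "principal_curve_fit")) fit$pseudotime else fit
  stop_if_not(all(is.finite(scores)), "scores must be finite")
  grid <- seq(min(pt), max(pt), length.out = n_grid)
  if (stats::var(scores) == 0)
    return(data.frame(pseudotime = grid, score = rep(scores[1], n_grid)))
  sm <- stats::smooth.spline(pt, scores)
  data.frame(pseudotime = grid, score = stats::predict(sm, grid)$y)
}
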