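#' Exact 1-D k-means by dynamic programming
#'
#' Globally optimal (minimum within-cluster sum of squares) partition of a
#' 1-D sample into `k` contiguous clusters of the sorted values, computed by
#' dynamic programming with divide-and-conquer optimization (the per-cluster
#' cost is concave-Monge, so the optimal split index is monotone). Ties in
#' SSE are broken toward the smallest boundary index, making the solution
#' deterministic.
#'
#' @param x Numeric vector with at least `k` distinct values.
#' @param k Number of clusters.
#' @return List: sorted `centers`, cluster `sizes`, total within-cluster
#'   `sse`, and `assignment` (cluster index per element of `x`, 1 = lowest).
#' @export
kmeans_1d_exact <- function(x, k = 3) {
  stop_if_not(length(unique(x)) >= k,
              "need at least %d distinct values", k)
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  s1 <- c(0, cumsum(xs))
  s2 <- c(0, cumsum(xs^2))
  # SSE of xs[j..i], vectorized over j
  cost <- function(j, i) {
    w <- i - j + 1
    s <- s1[i + 1] - s1[j]
    pmax(0, (s2[i + 1] - s2[j]) - s^2 / w)
  }
  D_prev <- cost(1, seq_len(n))
  J <- matrix(1L, nrow = k, ncol = n)
  if (k > 1) {
    for (m in 2:k) {
      D_cur <- rep(Inf, n)
      # divide-and-conquer over i in [m, n]; candidate split j in [jlo, jhi]
      stack <- list(c(m, n, m, n))
      while (length(stack)) {
        node <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        lo <- node[1]; hi <- node[2]; jlo <- node[3]; jhi <- node[4]
        if (lo > hi) next
        mid <- (lo + hi) %/% 2L
        js <- jlo:min(jhi, mid)
        vals <- D_prev[js - 1] + cost(js, mid)
        best <- which.min(vals)            # first minimum: smallest j
        D_cur[mid] <- vals[best]
        J[m, mid] <- js[best]
        stack[[length(stack) + 1]] <- c(lo, mid - 1L, jlo, J[m, mid])
        stack[[length(stack) + 1]] <- c(mid + 1L, hi, J[m, mid], jhi)
      }
      D_prev <- D_cur
    }
  }
  bounds <- integer(k + 1)                 # cluster m = xs[(bounds[m]+1)..bounds[m+1]]
  bounds[k + 1] <- n
  for (m in k:1) bounds[m] <- if (m == 1) 0L else J[m, bounds[m + 1]] - 1L
  centers <- sizes <- numeric(k)
  assign_sorted <- integer(n)
  for (m in seq_len(k)) {
    idx <- (bounds[m] + 1):bounds[m + 1]
    centers[m] <- mean(xs[idx])
    sizes[m] <- length(idx)
    assign_sorted[idx] <- m
  }
  assignment <- integer(n)
  assignment[ord] <- assign_sorted
  list(centers = centers, sizes = sizes, sse = D_prev[n],
       assignment = assignment)
}

#' Adaptive marker threshold from pooled pixel intensities
#'
#' The background threshold for one marker in one image: exact 3-means on
#' the pooled pixel intensities of all segmented cells in the image, with
#' the threshold set to the average of the two largest centers.
#'
#' @param pixels Numeric vector of pooled pixel intensities (>= 3 distinct
#'   values; fewer is an error, never a silent degenerate threshold).
#' @param image_id,marker Identifiers carried through for error messages and
#'   bookkeeping.
#' @return List of class `marker_threshold`: `image_id`, `marker`, sorted
#'   `centers`, `threshold`, `sse`, `n_pixels`, and `separation` (gap between
#'   the two largest centers divided by the summed sds of those two clusters
#'   — a QC score; values below ~2 arise when the marker distribution is
#'   effectively unimodal, the regime where positivity calls degrade toward
#'   chance).
#' @export
kmeans_threshold <- function(pixels, image_id = NA_character_,
                             marker = NA_character_) {
  if (length(unique(pixels)) < 3)
    stop(sprintf("image %s, marker %s: fewer than 3 distinct pixel values",
                 image_id, marker), call. = FALSE)
  km <- kmeans_1d_exact(pixels, 3)
  top_sds <- sum(vapply(2:3, function(m)
    stats::sd(pixels[km$assignment == m]), numeric(1)), na.rm = TRUE)
  structure(list(image_id = image_id, marker = marker,
                 centers = km$centers,
                 threshold = (km$centers[2] + km$centers[3]) / 2,
                 sse = km$sse, n_pixels = length(pixels),
                 separation = if (top_sds > 0)
                   (km$centers[3] - km$centers[2]) / top_sds else Inf),
            class = "marker_threshold")
}

#' Per-image, per-marker thresholds for a segmented-cell table
#'
#' Pools the pixels of all cells in all ROIs of each image (pixels inside
#' segmentation masks only) and computes the 3-means threshold per marker.
#'
#' @param cells Long-format data frame with columns `image_id`, `roi_id`,
#'   `cell_id`, `marker`, `intensity` — one row per pixel.
#' @return Data frame: `image_id`, `marker`, `center_1..3`, `threshold`,
#'   `n_pixels`, `separation`.
#' @export
mif_thresholds <- function(cells) {
  need <- c("image_id", "roi_id", "cell_id", "marker", "intensity")
  stop_if_not(all(need %in% names(cells)), "cells table lacks columns: %s",
              paste(setdiff(need, names(cells)), collapse = ", "))
  keys <- unique(cells[c("image_id", "marker")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- cells$image_id == keys$image_id[i] & cells$marker == keys$marker[i]
    th <- kmeans_threshold(cells$intensity[sel], keys$image_id[i],
                           keys$marker[i])
    data.frame(image_id = th$image_id, marker = th$marker,
               center_1 = th$centers[1], center_2 = th$centers[2],
               center_3 = th$centers[3], threshold = th$threshold,
               n_pixels = th$n_pixels, separation = th$separation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cell positivity call
#'
#' A cell is positive for a marker iff strictly more than half of its pixels
#' strictly exceed the threshold.
#'
#' @param pixels Pixel intensities of one cell in one channel.
#' @param threshold Marker threshold for the cell's image.
#' @return Logical.
#' @export
call_positive <- function(pixels, threshold) {
  stop_if_not(length(pixels) >= 1, "cell has no pixels in this channel")
  sum(pixels > threshold) > length(pixels) / 2
}

#' Positivity calls for every cell and marker
#'
#' @inheritParams mif_thresholds
#' @param thresholds Output of [mif_thresholds()].
#' @return Data frame: `image_id`, `roi_id`, `cell_id`, `marker`, `positive`.
#' @export
mif_cell_calls <- function(cells, thresholds) {
  rows <- lapply(seq_len(nrow(thresholds)), function(i) {
    sel <- cells$image_id == thresholds$image_id[i] &
      cells$marker == thresholds$marker[i]
    sub <- cells[sel, ]
    key <- paste(sub$roi_id, sub$cell_id, sep = "\r")
    above <- tapply(sub$intensity > thresholds$threshold[i], key, sum)
    npix <- tapply(sub$intensity, key, length)
    parts <- strsplit(names(above), "\r", fixed = TRUE)
    data.frame(image_id = thresholds$image_id[i],
               roi_id = vapply(parts, `[`, "", 1),
               cell_id = vapply(parts, `[`, "", 2),
               marker = thresholds$marker[i],
               positive = as.vector(above) > as.vector(npix) / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Phenotype definition and hierarchy
#'
#' A population is defined by required-positive markers, required-negative
#' markers, and a parent population (`"ROOT"` = all segmented cells). The
#' hierarchy must be acyclic and rooted.
#'
#' @param name Population name.
#' @param positive,negative Character vectors of marker names.
#' @param parent Parent population name or `"ROOT"`.
#' @return A `phenotype_definition` list.
#' @export
phenotype_definition <- function(name, positive = character(),
                                 negative = character(), parent = "ROOT") {
  structure(list(name = name, positive = positive, negative = negative,
                 parent = parent), class = "phenotype_definition")
}

# topological order of definitions; errors on cycles or dangling parents
order_definitions <- function(definitions) {
  nms <- vapply(definitions, `[[`, "", "name")
  stop_if_not(!anyDuplicated(nms), "duplicated population names")
  parents <- vapply(definitions, `[[`, "", "parent")
  stop_if_not(all(parents %in% c("ROOT", nms)),
              "parent population not defined: %s",
              paste(setdiff(parents, c("ROOT", nms)), collapse = ", "))
  ordered <- character(0)
  remaining <- nms
  while (length(remaining)) {
    ready <- remaining[parents[match(remaining, nms)] %in% c("ROOT", ordered)]
    stop_if_not(length(ready) > 0, "cyclic phenotype hierarchy")
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  definitions[match(ordered, nms)]
}

#' Hierarchical cell phenotyping
#'
#' A cell belongs to a population iff it is positive for every
#' required-positive marker, negative for every required-negative marker,
#' and belongs to the parent population.
#'
#' @param calls Output of [mif_cell_calls()].
#' @param definitions List of [phenotype_definition()] objects.
#' @return Data frame: `image_id`, `roi_id`, `cell_id`, one logical column
#'   per population.
#' @export
phenotype_cells <- function(calls, definitions) {
  definitions <- order_definitions(definitions)
  markers_needed <- unique(unlist(lapply(definitions,
                                         function(d) c(d$positive, d$negative))))
  stop_if_not(all(markers_needed %in% calls$marker),
              "no positivity calls (missing threshold?) for markers: %s",
              paste(setdiff(markers_needed, calls$marker), collapse = ", "))
  key <- paste(calls$image_id, calls$roi_id, calls$cell_id, sep = "\r")
  ukey <- unique(key)
  pos <- matrix(FALSE, nrow = length(ukey), ncol = length(markers_needed),
                dimnames = list(ukey, markers_needed))
  sel <- calls$marker %in% markers_needed
  pos[cbind(match(key[sel], ukey), match(calls$marker[sel], markers_needed))] <-
    calls$positive[sel]
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  out <- data.frame(image_id = vapply(parts, `[`, "", 1),
                    roi_id = vapply(parts, `[`, "", 2),
                    cell_id = vapply(parts, `[`, "", 3),
                    stringsAsFactors = FALSE)
  member <- list(ROOT = rep(TRUE, length(ukey)))
  for (d in definitions) {
    m <- member[[d$parent]]
    for (mk in d$positive) m <- m & pos[, mk]
    for (mk in d$negative) m <- m & !pos[, mk]
    member[[d$name]] <- m
    out[[d$name]] <- m
  }
  out
}

#' Percent-of-parent population table
#'
#' Per ROI: 100 x (cells in population) / (cells in parent population); per
#' image: the unweighted mean over ROIs whose parent population is nonempty
#' (empty-parent ROIs are excluded and recorded as not evaluable).
#'
#' @param membership Output of [phenotype_cells()].
#' @param definitions The same definitions list.
#' @return List of two data frames: `per_roi` (`image_id`, `roi_id`,
#'   `population`, `n_parent`, `n_child`, `percent`) and `per_image`
#'   (`image_id`, `population`, `percent`, `n_rois_evaluable`).
#' @export
percent_of_parent <- function(membership, definitions) {
  definitions <- order_definitions(definitions)
  roi_key <- paste(membership$image_id, membership$roi_id, sep = "\r")
  urois <- unique(roi_key)
  per_roi <- do.call(rbind, lapply(definitions, function(d) {
    parent <- if (d$parent == "ROOT") rep(TRUE, nrow(membership))
              else membership[[d$parent]]
    n_parent <- as.vector(tapply(parent, roi_key, sum)[urois])
    n_child <- as.vector(tapply(membership[[d$name]], roi_key, sum)[urois])
    parts <- strsplit(urois, "\r", fixed = TRUE)
    data.frame(image_id = vapply(parts, `[`, "", 1),
               roi_id = vapply(parts, `[`, "", 2),
               population = d$name, n_parent = n_parent, n_child = n_child,
               percent = ifelse(n_parent > 0, 100 * n_child / n_parent,
                                NA_real_),
               stringsAsFactors = FALSE)
  }))
  per_image <- stats::aggregate(percent ~ image_id + population,
                                data = per_roi, FUN = mean,
                                na.action = stats::na.omit)
  n_eval <- stats::aggregate(cbind(n_rois_evaluable = !is.na(percent)) ~
                               image_id + population,
                             data = per_roi, FUN = sum)
  per_image <- merge(per_image, n_eval, all.y = TRUE)
  if (any(per_image$n_rois_evaluable == 0)) {
    bad <- per_image[per_image$n_rois_evaluable == 0, ]
    warning("population(s) with empty parent in every ROI of an image: ",
            paste(unique(bad$population), collapse = ", "), call. = FALSE)
    per_image$percent[per_image$n_rois_evaluable == 0] <- NA_real_
  }
  list(per_roi = per_roi, per_image = per_image)
}

#' Group comparison of mIF population percentages
#'
#' Equal-variance Student t on image-level percent-of-parent values per
#' population, significant when p < 0.05 and the absolute difference of the
#' group means exceeds 5 percentage points.
#'
#' @param per_image `per_image` data frame from [percent_of_parent()].
#' @param groups Named character vector mapping `image_id` to group label
#'   (exactly two groups, >= 2 images each).
#' @param rule Comparison rule; default the mIF preset.
#' @return A [differential_features()] result table (one row per population).
#' @export
compare_mif_populations <- function(per_image, groups,
                                    rule = layer_rule("PCT_MIF")) {
  wide <- stats::reshape(per_image[c("image_id", "population", "percent")],
                         idvar = "population", timevar = "image_id",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^percent\\.", "", colnames(mat))
  rownames(mat) <- wide$population
  fm <- feature_matrix(mat, "PCT_MIF", "LINEAR")
  differential_features(fm, groups[colnames(mat)], rule)
}
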