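#' Dice similarity coefficient between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`.
#'
#' @param a,b Logical or 0/1 matrices of identical shape, not both empty.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  ma <- as_binary_matrix(a, "a"); mb <- as_binary_matrix(b, "b")
  if (!all(dim(ma) == dim(mb))) stop("masks must share a shape")
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) stop("Dice is undefined for two empty masks")
  2 * sum(ma & mb) / (sa + sb)
}

as_points <- function(x, arg) {
  p <- as.matrix(x)
  if (!nrow(p) || ncol(p) != 2)
    stop(sprintf("`%s` must be a non-empty matrix of (row, col) points", arg))
  storage.mode(p) <- "double"
  p
}

#' Average Hausdorff distance between two boundary point sets
#'
#' The symmetric mean of directed mean nearest-neighbour Euclidean
#' distances: `(mean_a min_b d + mean_b min_a d) / 2`. The `"max"` variant
#' takes the larger of the two directed means instead.
#'
#' @param a,b Non-empty matrices of `(row, col)` points (e.g. from
#'   [mask_to_contour()]).
#' @param variant `"mean"` (default) or `"max"` combination of the two
#'   directed mean distances.
#' @return Distance in pixels.
#' @export
average_hausdorff <- function(a, b, variant = c("mean", "max")) {
  variant <- match.arg(variant)
  pa <- as_points(a, "a"); pb <- as_points(b, "b")
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2
  da <- mean(sqrt(apply(d2, 1, min)))
  db <- mean(sqrt(apply(d2, 2, min)))
  if (variant == "mean") (da + db) / 2 else max(da, db)
}

#' Effective diameter of a reference region
#'
#' Diameter of the circle with the same area as the mask:
#' `2 * sqrt(area / pi)` with area the foreground pixel count.
#'
#' @param mask Non-empty logical or 0/1 matrix.
#' @return Diameter in pixels.
#' @export
effective_diameter <- function(mask) {
  m <- as_binary_matrix(mask)
  area <- sum(m)
  if (area == 0) stop("effective diameter is undefined for an empty mask")
  2 * sqrt(area / pi)
}

#' RHD-D: average Hausdorff distance over effective diameter
#'
#' Dimensionless boundary error, the average Hausdorff distance between
#' predicted and reference outlines normalised by the effective diameter of
#' the reference region. Zero for identical outlines; invariant under
#' simultaneous rescaling of both outlines and region.
#'
#' @param pred_contour,ref_contour Boundary point sets.
#' @param ref_mask Reference region mask (the expert outline's interior).
#' @param variant Passed to [average_hausdorff()].
#' @return Non-negative dimensionless ratio.
#' @export
rhd_d <- function(pred_contour, ref_contour, ref_mask,
                  variant = c("mean", "max")) {
  average_hausdorff(pred_contour, ref_contour, match.arg(variant)) /
    effective_diameter(ref_mask)
}

#' Per-mass segmentation metrics row
#'
#' Computes DSC, average Hausdorff distance (on traced contours), effective
#' diameter of the reference, and RHD-D for one predicted/reference mask
#' pair.
#'
#' @param pred_mask,ref_mask Logical or 0/1 matrices of identical shape.
#' @param mass_id Identifier copied into the row.
#' @return One-row data frame with columns `mass_id`, `dsc`, `hd`, `deq`,
#'   `rhd_d`.
#' @export
evaluate_mass <- function(pred_mask, ref_mask, mass_id = NA_character_) {
  pc <- mask_to_contour(pred_mask)
  rc <- mask_to_contour(ref_mask)
  hd <- average_hausdorff(pc, rc)
  deq <- effective_diameter(ref_mask)
  data.frame(mass_id = mass_id,
             dsc = dice(pred_mask, ref_mask),
             hd = hd, deq = deq, rhd_d = hd / deq,
             stringsAsFactors = FALSE)
}

#' Cohort summary: per-metric median with bootstrap confidence interval
#'
#' The 95% confidence interval of the median is a seeded percentile
#' bootstrap (resampling masses with replacement).
#'
#' @param rows Data frame of per-mass metric rows (at least 2 rows), e.g.
#'   stacked [evaluate_mass()] output.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return List with `summary` (data frame: metric, median, ci_lower,
#'   ci_upper), `n_masses`, `n_boot`, `seed`, `conf` and `ci_method`.
#' @export
summarize_cohort <- function(rows, n_boot = 2000, seed = 1L, conf = 0.95) {
  if (nrow(rows) < 2) stop("cohort summaries require at least 2 masses")
  metrics <- intersect(c("dsc", "hd", "deq", "rhd_d"), names(rows))
  alpha <- (1 - conf) / 2
  out <- local_seed(seed, {
    lapply(metrics, function(mt) {
      x <- rows[[mt]]
      boots <- vapply(seq_len(n_boot), function(i)
        median(x[sample.int(length(x), replace = TRUE)]), numeric(1))
      data.frame(metric = mt, median = median(x),
                 ci_lower = unname(quantile(boots, alpha)),
                 ci_upper = unname(quantile(boots, 1 - alpha)),
                 stringsAsFactors = FALSE)
    })
  })
  list(summary = do.call(rbind, out), n_masses = nrow(rows),
       n_boot = n_boot, seed = seed, conf = conf,
       ci_method = "percentile bootstrap of the median")
}
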