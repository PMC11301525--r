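#' Local entropy filter (3x3 neighbourhood)
#'
#' Shannon entropy in bits of the 256-bin intensity histogram of each
#' pixel's nine-pixel (3x3) neighbourhood, with mirror padding at the
#' borders. The filter emphasises the structure of echo texture: flat
#' (cystic) regions score 0, fully heterogeneous neighbourhoods approach
#' `log2(9) ~ 3.17` bits.
#'
#' @param image Numeric matrix in `[0, 1]`, at least 3x3.
#' @return Matrix of entropies in bits.
#' @export
entropy_filter <- function(image) {
  img <- as_gray_matrix(image)
  if (nrow(img) < 3 || ncol(img) < 3)
    stop("entropy filter requires an image of at least 3 x 3 pixels")
  entropy3_cpp(img)
}

#' Local standard-deviation filter (3x3 neighbourhood)
#'
#' Sample standard deviation (denominator n - 1 = 8) of each pixel's 3x3
#' neighbourhood, with mirror padding; emphasises the magnitude of local
#' echo variation.
#'
#' @inheritParams entropy_filter
#' @return Matrix of standard deviations.
#' @export
std_filter <- function(image) {
  img <- as_gray_matrix(image)
  if (nrow(img) < 3 || ncol(img) < 3)
    stop("std filter requires an image of at least 3 x 3 pixels")
  std3_cpp(img)
}

#' Build the three-channel texture feature stack for in-mass pixels
#'
#' The grayscale, entropy-filtered and standard-deviation-filtered channels
#' are computed over the full ROI (so border neighbourhoods see real image
#' context), restricted to in-mask pixels, and z-score standardised per
#' channel over those pixels. A channel with zero variance is left at 0.
#'
#' @param roi Numeric ROI matrix in `[0, 1]`.
#' @param mask Logical/0-1 mask of the same shape with >= 1 foreground
#'   pixel.
#' @return List of class `feature_stack`: `features` (n x 3 standardised
#'   matrix with columns `gray`, `entropy`, `std`), `idx` (n x 2 matrix of
#'   0-based `(row, col)` pixel positions), `raw_gray`, `center`, `scale`
#'   and `shape`.
#' @export
build_feature_stack <- function(roi, mask) {
  img <- as_gray_matrix(roi, "roi")
  m <- as_binary_matrix(mask)
  if (!all(dim(img) == dim(m))) stop("roi and mask must share a shape")
  if (sum(m) == 0) stop("cannot build features for an empty mask")
  keep <- which(m > 0)                      # column-major order
  raw <- cbind(gray = img[keep],
               entropy = entropy_filter(img)[keep],
               std = std_filter(img)[keep])
  center <- colMeans(raw)
  scale <- apply(raw, 2, sd)
  feats <- raw
  for (j in 1:3) {
    feats[, j] <- if (is.na(scale[j]) || scale[j] < 1e-12) 0
                  else (raw[, j] - center[j]) / scale[j]
  }
  idx <- cbind(row = (keep - 1) %% nrow(m), col = (keep - 1) %/% nrow(m))
  structure(list(features = feats, idx = idx, raw_gray = raw[, "gray"],
                 center = center, scale = scale, shape = dim(m)),
            class = "feature_stack")
}

#' Fuzzy c-means clustering
#'
#' Minimises `J = sum_i sum_k u_ik^m ||x_i - v_k||^2` by alternating
#' centroid and membership updates, from a seeded random row-normalised
#' membership initialisation, until the largest membership change falls
#' below `tol` or `max_iter` is reached. A point coinciding with a centroid
#' receives membership 1 for the first such centroid.
#'
#' @param x A `feature_stack` or a numeric matrix of observations (rows).
#' @param c Number of clusters.
#' @param m Fuzzifier (> 1).
#' @param tol Convergence tolerance on memberships.
#' @param max_iter Iteration cap.
#' @param seed Integer seed for the membership initialisation.
#' @return List of class `fcm_result`: `memberships` (n x c, rows sum to
#'   1), `centroids` (c x d), `objective_trace` (non-increasing), `m`,
#'   `seed`, `iterations`.
#' @export
fcm_cluster <- function(x, c = 2, m = 2, tol = 1e-5, max_iter = 300,
                        seed = 1L) {
  X <- if (inherits(x, "feature_stack")) x$features else as.matrix(x)
  n <- nrow(X)
  if (n < c) stop("fewer observations than clusters")
  if (m <= 1) stop("the fuzzifier m must exceed 1")
  u <- local_seed(seed, {
    u0 <- matrix(runif(n * c), n, c)
    u0 / rowSums(u0)
  })
  trace <- numeric(0)
  iter <- 0
  v <- NULL
  repeat {
    iter <- iter + 1
    um <- u^m
    cs <- colSums(um)
    v_new <- t(um) %*% X / cs                         # c x d centroids
    # a cluster with zero total membership keeps its previous centroid
    dead <- cs < 1e-300
    if (any(dead))
      v_new[dead, ] <- if (is.null(v)) matrix(colMeans(X), sum(dead), ncol(X),
                                              byrow = TRUE) else v[dead, ]
    v <- v_new
    d2 <- outer(rowSums(X^2), rep(1, c)) -
      2 * X %*% t(v) + outer(rep(1, n), rowSums(v^2))
    d2[d2 < 0] <- 0
    zero <- d2 < 1e-24
    u_new <- matrix(0, n, c)
    has0 <- rowSums(zero) > 0
    if (any(has0)) {
      first0 <- max.col(zero[has0, , drop = FALSE] * 1, ties.method = "first")
      u_new[cbind(which(has0), first0)] <- 1
    }
    if (any(!has0)) {
      dk <- d2[!has0, , drop = FALSE]^(-1 / (m - 1))  # (1/d^2)^(1/(m-1))
      u_new[!has0, ] <- dk / rowSums(dk)
    }
    trace <- c(trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol || iter >= max_iter) break
  }
  if (length(trace) > 1 && any(diff(trace) > 1e-6 * (1 + trace[-length(trace)])))
    warning("fuzzy c-means objective increased between iterations")
  structure(list(memberships = u, centroids = v, objective_trace = trace,
                 m = m, seed = seed, iterations = iter),
            class = "fcm_result")
}

#' Label clusters as hypo- and hyperechoic components
#'
#' Pixels are hard-assigned to their maximum-membership cluster (ties to
#' the lower cluster index); the cluster whose member pixels have the lower
#' mean original grayscale becomes the relative hypoechoic component, the
#' other the hyperechoic component. An empty cluster is ranked by the
#' grayscale coordinate of its centroid (de-standardised), with a warning.
#'
#' @param result An `fcm_result` with 2 clusters.
#' @param stack The `feature_stack` that was clustered.
#' @return List of class `component_labeling`: `labels` (matrix over the
#'   ROI: 0 background, 1 hypoechoic, 2 hyperechoic), `hypo_cluster`,
#'   `cluster_gray_means`, `pixel_counts`, `tie` flag.
#' @export
label_components <- function(result, stack) {
  stopifnot(inherits(result, "fcm_result"), inherits(stack, "feature_stack"))
  u <- result$memberships
  if (ncol(u) != 2) stop("component labeling expects exactly 2 clusters")
  hard <- max.col(u, ties.method = "first")
  counts <- tabulate(hard, 2)
  gmeans <- numeric(2)
  for (k in 1:2) {
    gmeans[k] <- if (counts[k] > 0) {
      mean(stack$raw_gray[hard == k])
    } else {
      warning(sprintf("cluster %d is empty after hard assignment; using its centroid grayscale", k))
      result$centroids[k, 1] * max(stack$scale[1], 1e-12) + stack$center[1]
    }
  }
  tie <- isTRUE(all.equal(gmeans[1], gmeans[2]))
  if (tie)
    warning("clusters have equal mean grayscale; labeling the lower-index cluster hypoechoic")
  hypo <- if (tie) 1L else which.min(gmeans)
  labels <- matrix(0L, stack$shape[1], stack$shape[2])
  labels[stack$idx[, "row"] + 1 + stack$idx[, "col"] * stack$shape[1]] <-
    ifelse(hard == hypo, 1L, 2L)
  structure(list(labels = labels, hypo_cluster = hypo,
                 cluster_gray_means = gmeans, pixel_counts = counts,
                 tie = tie),
            class = "component_labeling")
}

#' Separate in-mass pixels into hypo- and hyperechoic components
#'
#' End-to-end unsupervised stage: build the three-channel texture stack for
#' the in-mask pixels of an ROI, run two-cluster fuzzy c-means, and label
#' the clusters by relative mean grayscale.
#'
#' @param roi Numeric ROI matrix in `[0, 1]` (the image cropped to the mass
#'   bounding box).
#' @param mask Logical/0-1 mask of segmented in-mass pixels.
#' @param m,tol,max_iter,seed Passed to [fcm_cluster()].
#' @return A `component_labeling` (see [label_components()]) with the
#'   `fcm_result` attached as `$fcm`.
#' @export
segment_components <- function(roi, mask, m = 2, tol = 1e-5, max_iter = 300,
                               seed = 1L) {
  stack <- build_feature_stack(roi, mask)
  res <- fcm_cluster(stack, c = 2, m = m, tol = tol, max_iter = max_iter,
                     seed = seed)
  out <- label_components(res, stack)
  out$fcm <- res
  out
}
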