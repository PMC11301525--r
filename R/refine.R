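#' Parameters of the prediction-mask refinement chain
#'
#' @param smoothing_window Odd Gaussian window size in pixels.
#' @param threshold Probability threshold applied strictly (`> threshold`).
#' @param gaussian_sigma Gaussian sigma in pixels; the default
#'   `smoothing_window / 6` places +/- 3 sigma inside the window.
#' @return An object of class `refinement_params`.
#' @export
refinement_params <- function(smoothing_window = 15, threshold = 0.5,
                              gaussian_sigma = smoothing_window / 6) {
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop("smoothing_window must be odd and >= 1")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (gaussian_sigma <= 0) stop("gaussian_sigma must be positive")
  structure(list(smoothing_window = as.integer(smoothing_window),
                 threshold = threshold, gaussian_sigma = gaussian_sigma),
            class = "refinement_params")
}

#' Resample a prediction mask back to original ROI size
#'
#' Nearest-neighbour resampling of the network-resolution mask to the
#' bounding-box shape.
#'
#' @param mask Logical or 0/1 matrix (network resolution).
#' @param bbox The ROI [make_bbox()] whose shape to restore.
#' @return Logical matrix of the box's shape.
#' @export
resize_to_original <- function(mask, bbox) {
  sh <- bbox_shape(bbox)
  resize_image(mask > 0, sh[1], sh[2], method = "nearest")
}

#' Fill interior holes of a binary mask
#'
#' Background components not 4-connected to the image border become
#' foreground; everything else is unchanged. Idempotent.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix without holes.
#' @export
fill_holes <- function(mask) {
  m <- as_binary_matrix(mask)
  fill_holes_cpp(m) > 0
}

gaussian_kernel_1d <- function(window, sigma) {
  x <- seq.int(-(window - 1) / 2, (window - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian convolution with mirror border handling.
gaussian_smooth <- function(m, window, sigma) {
  k <- gaussian_kernel_1d(window, sigma)
  hw <- (window - 1) %/% 2
  p <- pad_mirror(m, hw)
  h <- nrow(m); w <- ncol(m)
  tmp <- matrix(0, h, ncol(p))
  for (i in seq_len(window))
    tmp <- tmp + k[i] * p[i - 1 + seq_len(h), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(window))
    out <- out + k[i] * tmp[, i - 1 + seq_len(w), drop = FALSE]
  out
}

#' Gaussian-smooth a binary mask and re-threshold
#'
#' The mask is cast to 0/1, convolved with a normalised 2-D Gaussian kernel
#' (applied separably; mirror border handling so masks touching the ROI
#' edge are not eroded), and thresholded strictly above `threshold`.
#'
#' @param mask Logical or 0/1 matrix.
#' @param params A [refinement_params()].
#' @return Logical matrix.
#' @export
smooth_and_threshold <- function(mask, params = refinement_params()) {
  m <- as_binary_matrix(mask)
  if (params$smoothing_window > min(dim(m)))
    stop("smoothing window exceeds the mask size")
  s <- gaussian_smooth(m, params$smoothing_window, params$gaussian_sigma)
  s > params$threshold
}

#' Full post-prediction refinement chain
#'
#' Applies, in order: resample to original ROI shape, hole filling,
#' Gaussian smoothing with strict thresholding, largest-component
#' selection, and contour tracing. The input may be the network probability
#' map (binarised at `params$threshold` first) or an already-hard mask.
#'
#' @param prob_or_mask Numeric probability map or logical/0-1 mask at
#'   network resolution.
#' @param bbox ROI box defining the original shape.
#' @param params A [refinement_params()].
#' @return List with `mask` (refined logical matrix, hole-free, single
#'   4-connected component) and `contour` (from [mask_to_contour()]).
#' @export
refine_mask <- function(prob_or_mask, bbox, params = refinement_params()) {
  m <- prob_or_mask
  if (!is.logical(m)) {
    if (any(!(m %in% c(0, 1)))) m <- m > params$threshold else m <- m > 0
  }
  m <- resize_to_original(m, bbox)
  m <- fill_holes(m)
  m <- smooth_and_threshold(m, params)
  if (!any(m))
    stop("no mass predicted: refinement produced an empty mask")
  m <- keep_largest_component(m)
  m <- fill_holes(m)  # largest-component selection cannot open holes, but
                      # smoothing a multi-component mask can; keep contract
  list(mask = m, contour = mask_to_contour(m))
}
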