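#' Patient-level stratified train/test split
#'
#' Within each pathology subtype, patients are shuffled (seeded) and
#' assigned to the training partition, whole patients at a time, until the
#' subtype's training mass count first reaches `ceil(goal * subtype size)`;
#' the rest go to the test partition. A patient whose masses span subtypes
#' is assigned with the first subtype encountered and counted in every
#' subtype it touches. Each subtype is guaranteed at least one training
#' mass, and at least one test mass whenever it is carried by two or more
#' patients. Because whole patients move together, realised proportions may
#' overshoot the goal.
#'
#' @param records Cohort list from [generate_cohort()] or a data frame with
#'   columns `mass_id`, `patient_id`, `subtype`.
#' @param goal_train_fraction Target training fraction in (0, 1).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `mass_id`, `patient_id`, `subtype`,
#'   `partition` (`"train"`/`"test"`), with the goal and seed as attributes.
#' @export
stratified_split <- function(records, goal_train_fraction = 0.65, seed = 1L) {
  if (goal_train_fraction <= 0 || goal_train_fraction >= 1)
    stop("goal_train_fraction must lie strictly between 0 and 1")
  df <- if (is.data.frame(records)) {
    records[, c("mass_id", "patient_id", "subtype")]
  } else {
    if (!length(records)) stop("no records to split")
    data.frame(mass_id = vapply(records, `[[`, "", "mass_id"),
               patient_id = vapply(records, `[[`, "", "patient_id"),
               subtype = vapply(records, `[[`, "", "subtype"),
               stringsAsFactors = FALSE)
  }
  if (!nrow(df)) stop("no records to split")
  subtypes <- unique(df$subtype)              # order of first appearance
  # first subtype encountered per patient, in record order
  first_sub <- tapply(df$subtype, df$patient_id, `[`, 1)
  assign_of <- stats::setNames(rep(NA_character_, length(unique(df$patient_id))),
                               unique(df$patient_id))

  local_seed(seed, {
    for (s in subtypes) {
      in_s <- df$subtype == s
      target <- ceiling(goal_train_fraction * sum(in_s))
      n_train_s <- function()
        sum(in_s & assign_of[df$patient_id] == "train", na.rm = TRUE)
      own <- names(first_sub)[first_sub == s]
      own <- own[is.na(assign_of[own])]
      own <- if (length(own) > 1) sample(own) else own
      for (p in own) {
        assign_of[p] <- if (n_train_s() < target) "train" else "test"
      }
      # guarantees: >= 1 training mass per subtype; >= 1 test mass when the
      # subtype is carried by >= 2 patients
      carriers <- unique(df$patient_id[in_s])
      if (n_train_s() == 0 && length(own))
        assign_of[own[1]] <- "train"
      n_test_s <- sum(in_s & assign_of[df$patient_id] == "test", na.rm = TRUE)
      if (n_test_s == 0 && length(carriers) >= 2 && length(own) >= 2)
        assign_of[own[length(own)]] <- "test"
    }
  })
  # patients never reached through their first subtype cannot remain: every
  # patient's first subtype is processed above, so all are assigned
  df$partition <- unname(assign_of[df$patient_id])
  attr(df, "goal_train_fraction") <- goal_train_fraction
  attr(df, "seed") <- seed
  df
}

#' Resize a 2-D image or mask
#'
#' Bilinear (for intensity images) or nearest-neighbour (for masks)
#' resampling on a corner-aligned grid: output pixel `i` samples input
#' coordinate `i * (n_in - 1) / (n_out - 1)`, so resampling to the same size
#' is the identity and corner pixels are preserved.
#'
#' @param image Numeric or logical matrix.
#' @param rows,cols Output shape.
#' @param method `"bilinear"` or `"nearest"`.
#' @return Matrix of shape `rows` x `cols` (logical input stays logical
#'   under `"nearest"`).
#' @export
resize_image <- function(image, rows, cols, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  was_logical <- is.logical(image)
  m <- image
  storage.mode(m) <- "double"
  hin <- nrow(m); win <- ncol(m)
  if (rows < 1 || cols < 1) stop("output shape must be positive")
  src <- function(n_out, n_in) {
    if (n_out == 1) return(rep(0, 1))
    (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  sr <- src(rows, hin); sc <- src(cols, win)
  if (method == "nearest") {
    out <- m[round(sr) + 1, round(sc) + 1, drop = FALSE]
    if (was_logical) out <- out > 0.5
    return(out)
  }
  r0 <- pmin(floor(sr), hin - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(sc), win - 2); c0 <- pmax(c0, 0)
  if (hin == 1) r0 <- rep(0, rows)
  if (win == 1) c0 <- rep(0, cols)
  wr <- sr - r0; wc <- sc - c0
  top <- m[r0 + 1, , drop = FALSE]
  bot <- m[pmin(r0 + 1, hin - 1) + 1, , drop = FALSE]
  mid <- top * (1 - wr) + bot * wr
  left <- mid[, c0 + 1, drop = FALSE]
  right <- mid[, pmin(c0 + 1, win - 1) + 1, drop = FALSE]
  sweep(left, 2, 1 - wc, `*`) + sweep(right, 2, wc, `*`)
}

#' Standardize an ROI to the network input size
#'
#' Crops the image to the bounding box and resamples to `size` x `size`
#' (bilinear for images, nearest-neighbour for masks so they stay binary).
#' [unstandardize_mask()] is the inverse mapping used by the refinement
#' chain to return predictions to original ROI scale.
#'
#' @param image Numeric matrix in `[0, 1]` (or logical mask).
#' @param bbox [make_bbox()] region within the image.
#' @param size Output side in pixels.
#' @param method Resampling method; defaults to bilinear for numeric input
#'   and nearest-neighbour for logical input.
#' @return `size` x `size` matrix.
#' @export
standardize_roi <- function(image, bbox, size = 256, method = NULL) {
  if (is.null(method)) method <- if (is.logical(image)) "nearest" else "bilinear"
  roi <- crop(image, bbox)
  resize_image(roi, size, size, method = method)
}

#' @rdname standardize_roi
#' @param mask `size` x `size` prediction mask.
#' @export
unstandardize_mask <- function(mask, bbox) {
  sh <- bbox_shape(bbox)
  resize_image(mask, sh[1], sh[2], method = "nearest")
}

rot90_ccw <- function(m) {
  t(m)[ncol(m):1, , drop = FALSE]
}

#' Apply one of the 12 augmentation transforms
#'
#' The transform family is \{identity, left-right flip, up-down flip\}
#' crossed with \{0, 90, 180, 270\} degree rotations, enumerated in that
#' nested order as `transform_id` 0-11 (flip state changes every 4 ids).
#' Every transform is a pixel bijection, so foreground counts are conserved.
#'
#' @param m Square matrix.
#' @param transform_id Integer 0-11.
#' @return Transformed matrix.
#' @export
apply_transform <- function(m, transform_id) {
  if (nrow(m) != ncol(m))
    stop("augmentation transforms require square inputs (rotation would change shape)")
  if (transform_id < 0 || transform_id > 11) stop("transform_id must be 0..11")
  f <- transform_id %/% 4
  k <- transform_id %% 4
  out <- switch(f + 1, m, m[, ncol(m):1, drop = FALSE], m[nrow(m):1, , drop = FALSE])
  for (i in seq_len(k)) out <- rot90_ccw(out)
  out
}

#' Twelve-fold flip/rotation augmentation of an image/mask pair
#'
#' @param image,mask Square matrices of identical shape.
#' @return List of 12 samples, each `list(image, mask, transform_id)`, in
#'   `transform_id` order (id 0 is the identity).
#' @export
augment_pair <- function(image, mask) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must share a shape")
  if (nrow(image) != ncol(image))
    stop("augmentation transforms require square inputs (rotation would change shape)")
  lapply(0:11, function(t)
    list(image = apply_transform(image, t),
         mask = apply_transform(mask, t),
         transform_id = t))
}
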