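#' Bounding box in pixel coordinates
#'
#' Boxes use the package-wide convention: `(row, col)` indexing, 0-based,
#' half-open, so a box covers rows `row_min .. row_max - 1` and columns
#' `col_min .. col_max - 1`.
#'
#' @param row_min,col_min,row_max,col_max Integer pixel indices (0-based,
#'   half-open).
#' @return An object of class `adx_bbox`.
#' @export
make_bbox <- function(row_min, col_min, row_max, col_max) {
  b <- list(row_min = as.integer(row_min), col_min = as.integer(col_min),
            row_max = as.integer(row_max), col_max = as.integer(col_max))
  if (anyNA(unlist(b))) stop("bounding box indices must be finite integers")
  if (b$row_min < 0 || b$col_min < 0)
    stop("bounding box indices must be non-negative")
  if (b$row_min >= b$row_max || b$col_min >= b$col_max)
    stop("bounding box must satisfy row_min < row_max and col_min < col_max")
  structure(b, class = "adx_bbox")
}

bbox_shape <- function(bbox) {
  c(bbox$row_max - bbox$row_min, bbox$col_max - bbox$col_min)
}

check_bbox_in <- function(bbox, image) {
  if (bbox$row_max > nrow(image) || bbox$col_max > ncol(image))
    stop(sprintf("bounding box (%d,%d,%d,%d) exceeds image of %d x %d pixels",
                 bbox$row_min, bbox$col_min, bbox$row_max, bbox$col_max,
                 nrow(image), ncol(image)))
  invisible(TRUE)
}

#' Read a grayscale image into a unit-interval intensity matrix
#'
#' PNG and TIFF are supported. Three-channel inputs are converted to
#' luminance with Rec. 601 weights (0.299 R + 0.587 G + 0.114 B); integer
#' images are rescaled by the maximum representable value of their bit depth
#' (handled by the underlying readers).
#'
#' @param path Path to a PNG or TIFF file.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images")
    tiff::readTIFF(path)
  } else {
    stop(sprintf("unsupported image format '%s' for %s", ext, path))
  }
  img <- if (length(dim(arr)) == 2) {
    arr
  } else if (dim(arr)[3] == 2) {       # gray + alpha
    arr[, , 1]
  } else if (dim(arr)[3] %in% c(3, 4)) {
    0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  } else {
    stop(sprintf("unsupported channel count in %s", path))
  }
  clip01(img)
}

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities in `[0, 1]` are quantized to 8 bits by the PNG writer.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @export
save_image <- function(image, path) {
  png::writePNG(as_gray_matrix(image), path)
  invisible(path)
}

#' Read / write small-integer label masks as PNG
#'
#' Labels (0/1 for binary masks, 0/1/2 for component maps) are stored in the
#' 8-bit gray channel.
#'
#' @param path PNG path.
#' @return Integer matrix of labels.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  m <- round(png::readPNG(path) * 255)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' @rdname load_mask
#' @param mask Integer (or logical) matrix of labels in `0..255`.
#' @export
save_mask <- function(mask, path) {
  if (is.logical(mask)) storage.mode(mask) <- "integer"
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Crop an image to a bounding box
#'
#' @param image Numeric or integer matrix.
#' @param bbox An [make_bbox()] object within the image.
#' @return The sub-matrix covered by the box; output pixel (0, 0) is input
#'   pixel (`row_min`, `col_min`).
#' @export
crop <- function(image, bbox) {
  check_bbox_in(bbox, image)
  image[(bbox$row_min + 1):bbox$row_max,
        (bbox$col_min + 1):bbox$col_max, drop = FALSE]
}

#' Paste a region back into an image at a bounding box origin
#'
#' Inverse of [crop()]: `region` must have the box's shape.
#'
#' @inheritParams crop
#' @param region Matrix of the box's shape.
#' @export
paste_region <- function(image, region, bbox) {
  check_bbox_in(bbox, image)
  sh <- bbox_shape(bbox)
  if (!all(dim(region) == sh))
    stop("`region` shape does not match the bounding box")
  image[(bbox$row_min + 1):bbox$row_max,
        (bbox$col_min + 1):bbox$col_max] <- region
  image
}

#' Trace the outline contour of a binary mask
#'
#' Boundary pixels of the largest 4-connected foreground component are
#' traced in clockwise order (Moore neighbourhood tracing starting from the
#' uppermost-leftmost pixel). A boundary pixel is a foreground pixel with at
#' least one 8-neighbour that is background or outside the image.
#'
#' @param mask Logical or 0/1 matrix with at least one foreground pixel.
#' @return Integer matrix with columns `row`, `col` (0-based) of ordered
#'   boundary pixels; attribute `n_components` reports how many 4-connected
#'   foreground components the mask had (only the largest is traced).
#' @export
mask_to_contour <- function(mask) {
  m <- as_binary_matrix(mask)
  if (sum(m) == 0) stop("cannot trace the contour of an empty mask")
  lab <- label4_cpp(m)
  ncomp <- length(lab$sizes)
  if (ncomp > 1) {
    keep <- which.max(lab$sizes)
    m <- matrix(as.integer(lab$labels == keep), nrow(m), ncol(m))
  }
  ctr <- trace_contour_cpp(m)
  # the clockwise walk can step diagonally past pixels that are exposed to
  # background only at a corner; splice those in next to an adjacent traced
  # pixel so the contour is exactly the 8-adjacency boundary set, in order
  bset <- boundary8_cpp(m)
  key <- function(p) p[, 1] + p[, 2] * nrow(m)
  miss <- bset[!(key(bset) %in% key(ctr)), , drop = FALSE]
  for (i in seq_len(nrow(miss))) {
    adj <- which(abs(ctr[, 1] - miss[i, 1]) <= 1 &
                 abs(ctr[, 2] - miss[i, 2]) <= 1)
    at <- if (length(adj)) adj[1] else nrow(ctr)
    ctr <- rbind(ctr[seq_len(at), , drop = FALSE], miss[i, ],
                 if (at < nrow(ctr)) ctr[(at + 1):nrow(ctr), , drop = FALSE])
  }
  colnames(ctr) <- c("row", "col")
  rownames(ctr) <- NULL
  attr(ctr, "n_components") <- ncomp
  ctr
}

#' Keep the largest 4-connected component of a mask
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix containing only the largest component (all
#'   `FALSE` if the input is empty).
#' @export
keep_largest_component <- function(mask) {
  m <- as_binary_matrix(mask)
  if (sum(m) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  lab <- label4_cpp(m)
  matrix(lab$labels == which.max(lab$sizes), nrow(m), ncol(m))
}

#' Export a contour as CSV of (row, col) pairs
#'
#' @param contour Matrix from [mask_to_contour()].
#' @param path Output CSV path.
#' @export
save_contour <- function(contour, path) {
  write.csv(as.data.frame(contour), path, row.names = FALSE)
  invisible(path)
}

manifest_columns <- c("patient_id", "mass_id", "subtype", "malignant",
                      "image_path", "mask_path",
                      "row_min", "col_min", "row_max", "col_max")

#' Read / write cohort manifests
#'
#' The manifest is a CSV with one row per mass and columns `patient_id`,
#' `mass_id`, `subtype`, `malignant`, `image_path`, `mask_path`, and the
#' bounding box as `row_min`, `col_min`, `row_max`, `col_max` (0-based,
#' half-open). Extra columns are preserved.
#'
#' @param path CSV path.
#' @return A data frame with one row per mass.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing))
    stop(sprintf("manifest %s is missing required columns: %s",
                 path, paste(missing, collapse = ", ")))
  df$patient_id <- as.character(df$patient_id)
  df$mass_id <- as.character(df$mass_id)
  df$subtype <- as.character(df$subtype)
  df$malignant <- as.logical(df$malignant)
  df
}

#' @rdname load_manifest
#' @param manifest Data frame with the required manifest columns.
#' @export
save_manifest <- function(manifest, path) {
  missing <- setdiff(manifest_columns, names(manifest))
  if (length(missing))
    stop(sprintf("manifest is missing required columns: %s",
                 paste(missing, collapse = ", ")))
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
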