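#' Specification of a synthetic adnexal-mass ultrasound phantom
#'
#' A phantom is a square speckle image containing one lobulated elliptical
#' "mass" whose interior is partitioned into a dark (hypoechoic, cystic-like)
#' region and bright (hyperechoic, solid-like) regions, with optional bright
#' septation lines and dark acoustic-shadow columns. Ground-truth mass and
#' component masks are produced alongside the image, so the phantom can stand
#' in for clinical data when training and evaluating the pipeline.
#'
#' @param canvas_size Side of the square canvas in pixels.
#' @param center Mass centre `(row, col)` in pixels (0-based); default is the
#'   canvas centre.
#' @param axes Ellipse semi-axes `(a, b)` in pixels; default
#'   `c(0.30, 0.22) * canvas_size`.
#' @param rotation Ellipse rotation in radians.
#' @param lobulation_amp Amplitude of the sinusoidal radial perturbation, as
#'   a fraction of the local radius.
#' @param n_lobes Number of lobes of the perturbation.
#' @param lobe_phase Phase of the perturbation in radians.
#' @param hypo_level,hyper_level,background_level Mean echo intensities in
#'   `[0, 1]`; `hypo_level < hyper_level` is required.
#' @param component_layout List of interior components. Each element is a
#'   list with `type = "blob"` (`center`, `axes` in normalised mass
#'   coordinates, optional `rotation`) or `type = "septation"` (`from`, `to`
#'   in normalised mass coordinates, `width` in pixels). Pixels covered by a
#'   component are hyperechoic; the remaining interior is hypoechoic.
#' @param shadow_columns List of acoustic shadows, each a list with
#'   `col_min`/`col_max` (0-based, half-open), `attenuation` in `(0, 1]` and
#'   optional `row_start` (0-based; default: the first row below the mass).
#' @param speckle Logical: apply multiplicative speckle?
#' @param speckle_shape Shape of the unit-mean Gamma speckle factor (larger
#'   is smoother).
#' @param speckle_blur Logical: 3x3 box-blur the speckle field to mimic
#'   laterally correlated speckle.
#' @param seed Integer RNG seed; fixed seed gives bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(canvas_size = 256,
                         center = NULL,
                         axes = NULL,
                         rotation = 0,
                         lobulation_amp = 0.1,
                         n_lobes = 3,
                         lobe_phase = 0,
                         hypo_level = 0.2,
                         hyper_level = 0.8,
                         background_level = 0.45,
                         component_layout = list(
                           list(type = "blob", center = c(0.30, -0.25),
                                axes = c(0.35, 0.40), rotation = 0)),
                         shadow_columns = list(),
                         speckle = TRUE,
                         speckle_shape = 4,
                         speckle_blur = TRUE,
                         seed = 1L) {
  n <- as.integer(canvas_size)
  if (is.null(center)) center <- c((n - 1) / 2, (n - 1) / 2)
  if (is.null(axes)) axes <- c(0.30, 0.22) * n
  spec <- list(canvas_size = n, center = as.numeric(center),
               axes = as.numeric(axes), rotation = as.numeric(rotation),
               lobulation_amp = as.numeric(lobulation_amp),
               n_lobes = as.integer(n_lobes),
               lobe_phase = as.numeric(lobe_phase),
               hypo_level = as.numeric(hypo_level),
               hyper_level = as.numeric(hyper_level),
               background_level = as.numeric(background_level),
               component_layout = component_layout,
               shadow_columns = shadow_columns,
               speckle = isTRUE(speckle),
               speckle_shape = as.numeric(speckle_shape),
               speckle_blur = isTRUE(speckle_blur),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  lv <- c(spec$hypo_level, spec$hyper_level, spec$background_level)
  if (any(lv < 0) || any(lv > 1))
    stop("echo levels must lie in [0, 1]")
  if (spec$hypo_level >= spec$hyper_level)
    stop("hypo_level must be smaller than hyper_level")
  if (spec$canvas_size < 16) stop("canvas_size is too small")
  rmax <- max(spec$axes) * (1 + abs(spec$lobulation_amp))
  lo <- spec$center - rmax
  hi <- spec$center + rmax
  if (any(lo < 5) || any(hi > spec$canvas_size - 6))
    stop(sprintf(paste0("mass of bounding radius %.1f px centred at ",
                        "(%.1f, %.1f) does not fit a %d px canvas with a ",
                        "5-pixel margin"),
                 rmax, spec$center[1], spec$center[2], spec$canvas_size))
  invisible(spec)
}

# Membership grid of a (possibly lobulated) rotated ellipse.
ellipse_mask <- function(n, center, axes, rotation,
                         lob_amp = 0, n_lobes = 0, phase = 0) {
  rr <- matrix(0:(n - 1), n, n)
  cc <- t(rr)
  dy <- rr - center[1]
  dx <- cc - center[2]
  xr <- dx * cos(rotation) + dy * sin(rotation)
  yr <- -dx * sin(rotation) + dy * cos(rotation)
  rho <- sqrt((xr / axes[1])^2 + (yr / axes[2])^2)
  if (lob_amp != 0 && n_lobes > 0) {
    theta <- atan2(yr, xr)
    rho <= 1 + lob_amp * sin(n_lobes * theta + phase)
  } else {
    rho <= 1
  }
}

# Distance-to-segment test for septation lines; endpoints in pixels.
segment_band <- function(n, p1, p2, width) {
  rr <- matrix(0:(n - 1), n, n)
  cc <- t(rr)
  v <- p2 - p1
  vv <- sum(v^2)
  wy <- rr - p1[1]
  wx <- cc - p1[2]
  t <- if (vv > 0) clip01((wy * v[1] + wx * v[2]) / vv) else 0
  dy <- wy - t * v[1]
  dx <- wx - t * v[2]
  sqrt(dy^2 + dx^2) <= width / 2
}

#' Render a phantom sample from its specification
#'
#' The mass is rendered as a lobulated ellipse, its interior partitioned
#' into hypo- and hyperechoic regions per the component layout, unit-mean
#' Gamma speckle applied multiplicatively, shadow columns attenuated, and
#' the image clipped to `[0, 1]`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_sample` with elements `image` (numeric
#'   matrix in `[0, 1]`), `mass_mask` (logical), `component_truth` (integer
#'   matrix: 0 background, 1 hypoechoic, 2 hyperechoic) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$canvas_size
  mask <- ellipse_mask(n, spec$center, spec$axes, spec$rotation,
                       spec$lobulation_amp, spec$n_lobes, spec$lobe_phase)

  truth <- matrix(0L, n, n)
  truth[mask] <- 1L
  rot <- function(p) {  # mass-normalised (u, v) -> pixel (row, col) offset
    x <- p[1] * spec$axes[1]
    y <- p[2] * spec$axes[2]
    c(y * cos(spec$rotation) + x * sin(spec$rotation),
      x * cos(spec$rotation) - y * sin(spec$rotation))
  }
  for (comp in spec$component_layout) {
    hit <- if (identical(comp$type, "blob")) {
      ctr <- spec$center + rot(comp$center)
      ellipse_mask(n, ctr, comp$axes * spec$axes,
                   spec$rotation + (comp$rotation %||% 0))
    } else if (identical(comp$type, "septation")) {
      segment_band(n, spec$center + rot(comp$from),
                   spec$center + rot(comp$to), comp$width %||% 3)
    } else {
      stop(sprintf("unknown component type '%s'", comp$type))
    }
    truth[hit & mask] <- 2L
  }

  img <- matrix(spec$background_level, n, n)
  img[truth == 1L] <- spec$hypo_level
  img[truth == 2L] <- spec$hyper_level

  local_seed(spec$seed, {
    if (spec$speckle) {
      noise <- matrix(rgamma(n * n, shape = spec$speckle_shape,
                             rate = spec$speckle_shape), n, n)
      if (spec$speckle_blur) noise <- box_blur3(noise)
      img <- img * noise
    }
  })

  if (length(spec$shadow_columns)) {
    mass_rows <- which(rowSums(mask) > 0)
    below <- if (length(mass_rows)) max(mass_rows) else 1  # 1-based
    for (sc in spec$shadow_columns) {
      r0 <- (sc$row_start %||% below) + 1  # to 1-based
      cols <- (sc$col_min + 1):sc$col_max
      cols <- cols[cols >= 1 & cols <= n]
      if (r0 <= n && length(cols))
        img[r0:n, cols] <- img[r0:n, cols] * sc$attenuation
    }
  }

  structure(list(image = clip01(img), mass_mask = mask,
                 component_truth = truth, spec = spec),
            class = "phantom_sample")
}

# 3x3 box blur with mirror padding (keeps a unit-mean field unit mean away
# from clipping).
box_blur3 <- function(m) {
  p <- pad_mirror(m, 1)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[dr + seq_len(h), dc + seq_len(w)]
  out / 9
}

#' Built-in phantom subtype profiles
#'
#' Named parameter ranges used by [generate_cohort()] to condition phantom
#' geometry on a pathology-subtype analogue. The nine defaults mirror the
#' composition of a mixed benign/malignant adnexal-mass cohort: mostly
#' cystic subtypes (few bright blobs, occasional septations), solid subtypes
#' (large bright content) and shadowing subtypes. Ranges are package
#' choices, exposed here so studies can substitute their own.
#'
#' @return Named list of profile lists.
#' @export
subtype_profiles <- function() {
  prof <- function(malignant, axes_frac = c(0.18, 0.30),
                   lob = c(0.04, 0.12), blobs = c(1, 2),
                   blob_size = c(0.25, 0.45), septation = 0,
                   shadow = 0, hypo = c(0.15, 0.25), hyper = c(0.7, 0.85),
                   background = c(0.4, 0.5)) {
    list(malignant = malignant, axes_frac = axes_frac, lob = lob,
         blobs = blobs, blob_size = blob_size, septation = septation,
         shadow = shadow, hypo = hypo, hyper = hyper,
         background = background)
  }
  list(
    functional_cyst      = prof(FALSE, blobs = c(0, 1), blob_size = c(0.15, 0.3)),
    endometrioma         = prof(FALSE, blobs = c(0, 1), hypo = c(0.2, 0.3)),
    benign_epithelial    = prof(FALSE, blobs = c(0, 2), septation = 0.6),
    sexcord_germ         = prof(FALSE, blobs = c(1, 2), blob_size = c(0.3, 0.5),
                                shadow = 0.5),
    extraovarian         = prof(FALSE, axes_frac = c(0.15, 0.25),
                                blobs = c(0, 1), septation = 0.5),
    borderline           = prof(TRUE, blobs = c(1, 3)),
    epithelial_invasive  = prof(TRUE, blobs = c(2, 3), blob_size = c(0.3, 0.5),
                                lob = c(0.08, 0.15)),
    nonepithelial_invasive = prof(TRUE, blobs = c(2, 3), blob_size = c(0.4, 0.55),
                                  lob = c(0.08, 0.15)),
    metastasis           = prof(TRUE, blobs = c(2, 3), blob_size = c(0.35, 0.5),
                                lob = c(0.1, 0.15))
  )
}

#' Default subtype mixture of the synthetic cohort
#'
#' Fractions mirror a 54-mass cohort with 36 benign and 18 malignant masses
#' spread over nine pathology subtypes.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
default_subtype_mix <- function() {
  c(functional_cyst = 6, endometrioma = 7, benign_epithelial = 10,
    sexcord_germ = 10, extraovarian = 3, borderline = 2,
    epithelial_invasive = 8, nonepithelial_invasive = 5,
    metastasis = 3) / 54
}

# Largest-remainder apportionment of n over fractions.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

guess_malignant <- function(subtype) {
  grepl("malig|borderline|invasive|cancer|metasta", subtype,
        ignore.case = TRUE)
}

#' Generate a seeded synthetic cohort of mass records
#'
#' Draws `n_masses` phantoms whose geometry is conditioned on a subtype
#' label, apportioned over `subtype_mix` by largest remainder so that the
#' realised counts match the requested fractions exactly. Each record gets a
#' unique patient id except for a configurable fraction of patients carrying
#' two masses, and a bounding box enclosing the mass with a random 2-10
#' pixel margin per side.
#'
#' @param n_masses Number of masses (>= 1).
#' @param subtype_mix Named vector of subtype fractions summing to 1.
#'   Subtypes without a built-in profile use a generic profile and a
#'   name-based malignancy guess.
#' @param seed Integer RNG seed.
#' @param canvas_size Phantom canvas side in pixels.
#' @param two_mass_fraction Fraction of masses that share a patient with one
#'   other mass (default mirrors one two-mass patient in a 54-mass cohort).
#' @return List of mass records, each with `patient_id`, `mass_id`,
#'   `subtype`, `malignant`, `image`, `expert_mask`, `component_truth`,
#'   `bbox` and the generating `spec`.
#' @export
generate_cohort <- function(n_masses, subtype_mix = default_subtype_mix(),
                            seed = 1L, canvas_size = 256,
                            two_mass_fraction = 1 / 54) {
  if (n_masses < 1) stop("n_masses must be >= 1")
  if (!length(subtype_mix)) stop("subtype_mix must not be empty")
  if (is.null(names(subtype_mix)) || any(!nzchar(names(subtype_mix))))
    stop("subtype_mix must be a named vector")
  if (abs(sum(subtype_mix) - 1) > 1e-9)
    stop("subtype_mix fractions must sum to 1")
  counts <- apportion(n_masses, subtype_mix)
  subtypes <- rep(names(subtype_mix), counts)
  profiles <- subtype_profiles()
  generic <- subtype_profiles()$benign_epithelial
  n <- as.integer(canvas_size)

  local_seed(seed, {
    # patient ids: a few patients carry two masses (possibly across subtypes)
    n_pairs <- min(round(two_mass_fraction * n_masses), n_masses %/% 2)
    patient_of <- integer(n_masses)
    if (n_pairs > 0) {
      paired <- sample.int(n_masses, 2 * n_pairs)
      for (k in seq_len(n_pairs)) {
        patient_of[paired[2 * k - 1]] <- k
        patient_of[paired[2 * k]] <- k
      }
    }
    nxt <- n_pairs
    for (i in seq_len(n_masses)) {
      if (patient_of[i] == 0L) {
        nxt <- nxt + 1
        patient_of[i] <- nxt
      }
    }

    records <- vector("list", n_masses)
    for (i in seq_len(n_masses)) {
      st <- subtypes[i]
      pr <- profiles[[st]] %||% generic
      mal <- if (st %in% names(profiles)) pr$malignant else guess_malignant(st)
      runifr <- function(r) runif(1, r[1], r[2])
      ax <- c(runifr(pr$axes_frac), runifr(pr$axes_frac) * runif(1, 0.6, 0.9)) * n
      rmax_allowed <- (n - 1) / 2 - 6
      lob <- runifr(pr$lob)
      if (max(ax) * (1 + lob) > rmax_allowed) ax <- ax * rmax_allowed / (max(ax) * (1 + lob))
      slack <- rmax_allowed - max(ax) * (1 + lob)
      ctr <- (n - 1) / 2 + runif(2, -1, 1) * min(slack, 0.08 * n)
      nb <- sample(pr$blobs[1]:pr$blobs[2], 1)
      layout <- list()
      if (nb > 0) {
        for (b in seq_len(nb)) {
          layout[[length(layout) + 1]] <- list(
            type = "blob",
            center = runif(2, -0.45, 0.45),
            axes = c(runifr(pr$blob_size), runifr(pr$blob_size)),
            rotation = runif(1, 0, pi))
        }
      }
      if (runif(1) < pr$septation) {
        ang <- runif(1, 0, pi)
        layout[[length(layout) + 1]] <- list(
          type = "septation",
          from = 0.9 * c(cos(ang), sin(ang)),
          to = -0.9 * c(cos(ang), sin(ang)),
          width = runif(1, 2, 4))
      }
      shadows <- list()
      if (runif(1) < pr$shadow) {
        w <- round(runif(1, 0.08, 0.15) * n)
        c0 <- round(ctr[2] + runif(1, -0.3, 0.1) * ax[1])
        shadows <- list(list(col_min = max(0, c0), col_max = min(n, c0 + w),
                             attenuation = 0.4,
                             row_start = round(ctr[1])))
      }
      spec <- phantom_spec(
        canvas_size = n, center = ctr, axes = ax,
        rotation = runif(1, 0, pi), lobulation_amp = lob,
        n_lobes = sample(3:5, 1), lobe_phase = runif(1, 0, 2 * pi),
        hypo_level = runifr(pr$hypo), hyper_level = runifr(pr$hyper),
        background_level = runifr(pr$background),
        component_layout = layout, shadow_columns = shadows,
        speckle = TRUE, speckle_shape = 4, speckle_blur = TRUE,
        seed = sample.int(.Machine$integer.max - 1, 1))
      ph <- generate_phantom(spec)

      rows <- which(rowSums(ph$mass_mask) > 0)
      cols <- which(colSums(ph$mass_mask) > 0)
      mg <- sample(2:10, 4, replace = TRUE)
      bbox <- make_bbox(max(0, min(rows) - 1 - mg[1]),
                        max(0, min(cols) - 1 - mg[2]),
                        min(n, max(rows) + mg[3]),
                        min(n, max(cols) + mg[4]))
      records[[i]] <- list(
        patient_id = sprintf("P%03d", patient_of[i]),
        mass_id = sprintf("M%03d", i),
        subtype = st, malignant = mal,
        image = ph$image, expert_mask = ph$mass_mask,
        component_truth = ph$component_truth,
        bbox = bbox, spec = spec)
    }
    records
  })
}

#' Write a cohort to disk (images, masks, truths, manifest, specs)
#'
#' @param records Cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
save_cohort <- function(records, dir) {
  for (d in file.path(dir, c("images", "masks", "truth", "specs")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    ip <- file.path("images", paste0(r$mass_id, ".png"))
    mp <- file.path("masks", paste0(r$mass_id, ".png"))
    tp <- file.path("truth", paste0(r$mass_id, ".png"))
    save_image(r$image, file.path(dir, ip))
    save_mask(r$expert_mask, file.path(dir, mp))
    save_mask(r$component_truth, file.path(dir, tp))
    sp <- r$spec
    sp$component_layout <- lapply(sp$component_layout, function(x)
      lapply(x, as.vector))
    yaml::write_yaml(unclass(sp),
                     file.path(dir, "specs", paste0(r$mass_id, ".yaml")))
    data.frame(patient_id = r$patient_id, mass_id = r$mass_id,
               subtype = r$subtype, malignant = r$malignant,
               image_path = ip, mask_path = mp, truth_path = tp,
               row_min = r$bbox$row_min, col_min = r$bbox$col_min,
               row_max = r$bbox$row_max, col_max = r$bbox$col_max,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  save_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Load a cohort written by [save_cohort()]
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @return List of mass records (images and masks read back from PNG).
#' @export
load_cohort <- function(dir) {
  manifest <- load_manifest(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    tryCatch(
      list(patient_id = row$patient_id, mass_id = row$mass_id,
           subtype = row$subtype, malignant = row$malignant,
           image = load_image(file.path(dir, row$image_path)),
           expert_mask = load_mask(file.path(dir, row$mask_path)) > 0,
           component_truth = if ("truth_path" %in% names(manifest))
             load_mask(file.path(dir, row$truth_path)) else NULL,
           bbox = make_bbox(row$row_min, row$col_min, row$row_max,
                            row$col_max)),
      error = function(e)
        stop(sprintf("failed to load mass %s: %s", row$mass_id,
                     conditionMessage(e)), call. = FALSE))
  })
}
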