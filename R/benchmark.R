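#' Scaled-down end-to-end segmentation benchmark
#'
#' Synthetic analogue of a clinical segmentation evaluation, at desk scale:
#' generate independent training and test phantom cohorts, train the
#' reduced-profile U-net on the 12-fold augmented training ROIs, refine the
#' test predictions, and score each test mass with DSC and RHD-D against
#' the phantom ground truth.
#'
#' @param n_train,n_test Cohort sizes.
#' @param canvas_size Phantom canvas side in pixels.
#' @param config U-net configuration; defaults to the reduced CPU profile
#'   matched to `canvas_size`.
#' @param params Refinement parameters.
#' @param seed Integer seed; train/test cohorts and training draws are
#'   derived from it.
#' @param verbose Print the training loss per epoch?
#' @return List with `metrics` (per-mass rows), `summary` (from
#'   [summarize_cohort()]), `model` and the cohort sizes.
#' @export
segmentation_benchmark <- function(n_train = 200, n_test = 40,
                                   canvas_size = 128,
                                   config = NULL,
                                   params = refinement_params(),
                                   seed = 1L, verbose = FALSE) {
  if (is.null(config)) config <- unet_test_profile(seed = seed + 2L)
  stopifnot(config$input_size == canvas_size)
  train_rec <- generate_cohort(n_train, seed = seed, canvas_size = canvas_size,
                               two_mass_fraction = 0)
  test_rec <- generate_cohort(n_test, seed = seed + 1L,
                              canvas_size = canvas_size,
                              two_mass_fraction = 0)
  samples <- vector("list", 12 * n_train)
  for (i in seq_along(train_rec)) {
    r <- train_rec[[i]]
    roi <- standardize_roi(r$image, r$bbox, config$input_size)
    msk <- standardize_roi(r$expert_mask, r$bbox, config$input_size)
    samples[(12 * i - 11):(12 * i)] <- augment_pair(roi, msk)
  }
  model <- unet_train(build_unet(config), samples, verbose = verbose)
  rows <- lapply(test_rec, function(r) {
    roi <- standardize_roi(r$image, r$bbox, config$input_size)
    pred <- unet_predict(model, roi)
    ref <- refine_mask(pred$mask, r$bbox, params)
    evaluate_mass(ref$mask, crop(r$expert_mask, r$bbox), r$mass_id)
  })
  metrics <- do.call(rbind, rows)
  list(metrics = metrics,
       summary = summarize_cohort(metrics, seed = seed + 3L),
       model = model, n_train = n_train, n_test = n_test)
}

#' Component-recovery benchmark for the unsupervised stage
#'
#' Renders seeded two-component phantoms (dark interior with a substantial
#' bright blob, default levels 0.2 / 0.8, Gamma speckle of shape 4), runs
#' the fuzzy c-means component separation on the true mass region, and
#' scores each component against the planted truth with Dice.
#'
#' @param n_phantoms Number of phantoms.
#' @param canvas_size Canvas side in pixels.
#' @param seed Integer seed; phantom `i` uses `seed + i`.
#' @return Data frame with one row per phantom: `seed`, `dice_hypo`,
#'   `dice_hyper`, `iterations`, `objective_monotone`, `max_row_sum_err`.
#' @export
component_recovery_benchmark <- function(n_phantoms = 20, canvas_size = 256,
                                         seed = 1L) {
  rows <- lapply(seq_len(n_phantoms), function(i) {
    sp <- phantom_spec(canvas_size = canvas_size,
                       component_layout = list(list(type = "blob",
                                                    center = c(0.25, -0.2),
                                                    axes = c(0.55, 0.6))),
                       seed = seed + i)
    ph <- generate_phantom(sp)
    lab <- segment_components(ph$image, ph$mass_mask, seed = seed + i)
    tr <- ph$component_truth
    trace <- lab$fcm$objective_trace
    data.frame(seed = seed + i,
               dice_hypo = dice(lab$labels == 1L, tr == 1L),
               dice_hyper = dice(lab$labels == 2L, tr == 2L),
               iterations = lab$fcm$iterations,
               objective_monotone = all(diff(trace) <=
                                          1e-6 * (1 + trace[-length(trace)])),
               max_row_sum_err = max(abs(rowSums(lab$fcm$memberships) - 1)))
  })
  do.call(rbind, rows)
}
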