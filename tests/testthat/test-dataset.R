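fake_records <- function(n_patients, subtype = "a", masses_per_patient = 1) {
  recs <- list()
  for (p in seq_len(n_patients)) {
    for (m in seq_len(masses_per_patient)) {
      recs[[length(recs) + 1]] <- list(
        mass_id = sprintf("M_%s_%03d_%d", subtype, p, m),
        patient_id = sprintf("P%03d", p),
        subtype = subtype)
    }
  }
  recs
}

test_that("single-subtype split hits the per-subtype ceiling", {
  sp <- stratified_split(fake_records(20), 0.65, seed = 1)
  expect_identical(sum(sp$partition == "train"), 13L)  # ceil(0.65 * 20)
  expect_identical(sum(sp$partition == "test"), 7L)
})

test_that("patients are never divided across partitions", {
  recs <- c(fake_records(6, "a", 2), fake_records(4, "b"))
  # give patient ids of the second group distinct names
  for (i in 13:16) recs[[i]]$patient_id <- sprintf("Q%03d", i)
  sp <- stratified_split(recs, 0.65, seed = 7)
  per_patient <- tapply(sp$partition, sp$patient_id, function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
  expect_identical(anyDuplicated(sp$mass_id), 0L)
})

test_that("a single-patient cohort goes entirely to training", {
  sp <- stratified_split(fake_records(1, masses_per_patient = 3), 0.65, seed = 1)
  expect_true(all(sp$partition == "train"))
})

test_that("every subtype reaches both partitions when it has two patients", {
  recs <- c(fake_records(2, "rare"), fake_records(10, "common"))
  for (i in 3:12) recs[[i]]$patient_id <- sprintf("R%03d", i)
  sp <- stratified_split(recs, 0.65, seed = 3)
  for (s in c("rare", "common")) {
    expect_true(any(sp$partition[sp$subtype == s] == "train"))
    expect_true(any(sp$partition[sp$subtype == s] == "test"))
  }
})

test_that("split is seed-deterministic and validates its goal", {
  recs <- fake_records(15)
  expect_identical(stratified_split(recs, 0.65, seed = 5),
                   stratified_split(recs, 0.65, seed = 5))
  expect_error(stratified_split(recs, 1.2), "between 0 and 1")
})

test_that("a cross-subtype patient is assigned once and counted in both", {
  recs <- c(fake_records(4, "a"), fake_records(4, "b"))
  for (i in 5:8) recs[[i]]$patient_id <- sprintf("S%03d", i)
  recs[[9]] <- list(mass_id = "MX_1", patient_id = "P001", subtype = "b")
  sp <- stratified_split(recs, 0.65, seed = 2)
  expect_identical(unique(sp$partition[sp$patient_id == "P001"]),
                   sp$partition[sp$mass_id == "MX_1"])
})

test_that("resize is corner-aligned: identity, constants, checkerboard corners", {
  img <- matrix(runif(36), 6, 6)
  expect_equal(resize_image(img, 6, 6), img, tolerance = 1e-12)
  cst <- resize_image(matrix(0.7, 5, 3), 8, 8)
  expect_true(all(abs(cst - 0.7) < 1e-12))
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  up <- resize_image(cb, 4, 4)
  expect_identical(up[c(1, 4), c(1, 4)], cb)
  # hand-interpolated interior value: 1/3 of the way between 0 and 1
  expect_equal(up[1, 2], 1 / 3, tolerance = 1e-12)
})

test_that("mask standardize/unstandardize round-trip keeps Dice high", {
  for (s in c(1, 6)) {
    ph <- generate_phantom(quiet_spec(canvas = 96, seed = s))
    bb <- mask_bbox(ph$mass_mask)
    std <- standardize_roi(ph$mass_mask, bb, 128)
    expect_type(std, "logical")
    back <- unstandardize_mask(std, bb)
    expect_gte(sum(crop(ph$mass_mask, bb)), 100)
    expect_gte(dice(back, crop(ph$mass_mask, bb)), 0.98)
  }
})

test_that("augmentation yields 12 bijective samples with the identity first", {
  img <- matrix(runif(64), 8, 8)
  msk <- matrix(FALSE, 8, 8); msk[2:5, 3:4] <- TRUE
  aug <- augment_pair(img, msk)
  expect_length(aug, 12)
  expect_identical(vapply(aug, `[[`, 0L, "transform_id"), 0:11)
  expect_identical(aug[[1]]$image, img)
  expect_identical(aug[[1]]$mask, msk)
  fg <- vapply(aug, function(a) sum(a$mask), 0L)
  expect_true(all(fg == sum(msk)))
  sums <- vapply(aug, function(a) sum(a$image), 0)
  expect_true(all(abs(sums - sum(img)) < 1e-9))
  expect_error(augment_pair(matrix(0, 4, 6), matrix(FALSE, 4, 6)), "square")
})

test_that("constant images are fixed points of every transform", {
  cst <- matrix(0.4, 6, 6)
  aug <- augment_pair(cst, matrix(TRUE, 6, 6))
  for (a in aug) expect_identical(a$image, cst)
})
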