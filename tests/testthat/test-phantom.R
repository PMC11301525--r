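test_that("noise-free phantom is piecewise constant and masks agree", {
  sp <- phantom_spec(canvas_size = 64, speckle = FALSE,
                     component_layout = list(), seed = 3)
  ph <- generate_phantom(sp)
  expect_setequal(unique(as.vector(ph$image)),
                  c(sp$background_level, sp$hypo_level))
  expect_true(all(ph$image[ph$mass_mask] == sp$hypo_level))
  expect_true(all(ph$image[!ph$mass_mask] == sp$background_level))
  # mass mask equals the rendered ellipse exactly
  expect_identical(ph$mass_mask,
                   adnexseg:::ellipse_mask(64, sp$center, sp$axes, sp$rotation,
                                           sp$lobulation_amp, sp$n_lobes,
                                           sp$lobe_phase))
})

test_that("same spec and seed give bit-identical phantoms", {
  sp <- phantom_spec(canvas_size = 64, seed = 11)
  expect_identical(generate_phantom(sp), generate_phantom(sp))
})

test_that("component truth partitions the mass; mask is one hole-free component", {
  for (s in c(2, 9, 40)) {
    ph <- generate_phantom(two_level_spec(canvas = 96, seed = s))
    hypo <- ph$component_truth == 1L
    hyper <- ph$component_truth == 2L
    expect_identical(hypo | hyper, ph$mass_mask)
    expect_false(any(hypo & hyper))
    m <- ph$mass_mask; storage.mode(m) <- "integer"
    expect_length(adnexseg:::label4_cpp(m)$sizes, 1)
    expect_identical(fill_holes(ph$mass_mask), ph$mass_mask)
  }
})

test_that("with speckle on, hypo regions are darker than hyper regions", {
  # Monte-Carlo over 100 seeds with the default 0.2 / 0.8 levels
  wins <- vapply(1:100, function(s) {
    ph <- generate_phantom(two_level_spec(canvas = 64, seed = s))
    mean(ph$image[ph$component_truth == 1L]) <
      mean(ph$image[ph$component_truth == 2L])
  }, logical(1))
  expect_gte(sum(wins), 99)
})

test_that("mass exceeding the canvas is rejected with an explanation", {
  expect_error(phantom_spec(canvas_size = 64, axes = c(40, 30)),
               "does not fit")
})

test_that("cohort apportionment is exact by largest remainder", {
  rec <- generate_cohort(54, c(benign = 36 / 54, malignant = 18 / 54),
                         seed = 21, canvas_size = 64)
  expect_length(rec, 54)
  expect_identical(sum(vapply(rec, `[[`, "", "subtype") == "benign"), 36L)
  expect_identical(sum(vapply(rec, `[[`, "", "subtype") == "malignant"), 18L)
  expect_false(any(vapply(rec, `[[`, TRUE, "malignant")[
    vapply(rec, `[[`, "", "subtype") == "benign"]))
  expect_true(all(vapply(rec, `[[`, TRUE, "malignant")[
    vapply(rec, `[[`, "", "subtype") == "malignant"]))
})

test_that("default subtype mix reproduces the 36/18 benign/malignant cohort shape", {
  rec <- generate_cohort(54, seed = 4, canvas_size = 64)
  mal <- vapply(rec, `[[`, TRUE, "malignant")
  expect_identical(sum(!mal), 36L)
  expect_identical(sum(mal), 18L)
  # default two-mass fraction: 53 unique patients carry the 54 masses
  expect_length(unique(vapply(rec, `[[`, "", "patient_id")), 53L)
})

test_that("bounding boxes strictly contain the mass with margin", {
  rec <- generate_cohort(1, c(benign = 1), seed = 3, canvas_size = 64)[[1]]
  msk <- rec$expert_mask
  inside <- crop(msk, rec$bbox)
  expect_identical(sum(inside), sum(msk))
  rows <- range(which(rowSums(msk) > 0)) - 1
  expect_gte(rows[1] - rec$bbox$row_min, 2)
  expect_gte(rec$bbox$row_max - 1 - rows[2], 2)
})

test_that("different cohort seeds draw different geometry", {
  a <- generate_cohort(3, c(benign = 1), seed = 1, canvas_size = 64)
  b <- generate_cohort(3, c(benign = 1), seed = 2, canvas_size = 64)
  expect_false(identical(lapply(a, `[[`, "spec"), lapply(b, `[[`, "spec")))
})

test_that("cohort input validation", {
  expect_error(generate_cohort(0, c(a = 1)), "n_masses")
  expect_error(generate_cohort(5, numeric(0)), "empty")
  expect_error(generate_cohort(5, c(a = 0.5, b = 0.4)), "sum to 1")
})

test_that("cohorts round-trip through disk", {
  dir <- withr::local_tempdir()
  rec <- generate_cohort(4, seed = 8, canvas_size = 64, two_mass_fraction = 0)
  manifest <- save_cohort(rec, dir)
  expect_identical(nrow(manifest), 4L)
  back <- load_cohort(dir)
  expect_identical(back[[2]]$expert_mask, rec[[2]]$expert_mask)
  expect_identical(back[[2]]$component_truth,
                   rec[[2]]$component_truth)
  expect_lt(max(abs(back[[2]]$image - rec[[2]]$image)), 1 / 255 + 1e-12)
  expect_identical(back[[3]]$bbox, rec[[3]]$bbox)
})
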