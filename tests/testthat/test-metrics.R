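test_that("Dice matches pixel-set arithmetic", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_identical(dice(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_identical(dice(a, b), 0)
  # two 10x10 squares overlapping in a 5x10 strip: 2*50/200
  c1 <- matrix(FALSE, 20, 20); c1[6:15, 1:10] <- TRUE
  expect_identical(dice(a, c1), 0.5)
  expect_error(dice(a, matrix(FALSE, 5, 5)), "share a shape")
  expect_error(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), "undefined")
})

test_that("average Hausdorff distance matches hand computations", {
  expect_identical(average_hausdorff(rbind(c(0, 0)), rbind(c(3, 0))), 3)
  expect_identical(average_hausdorff(rbind(c(0, 0), c(0, 1)), rbind(c(0, 0))),
                   0.25)
  a <- rbind(c(1, 2), c(5, 5))
  expect_identical(average_hausdorff(a, a), 0)
  expect_error(average_hausdorff(a, matrix(0, 0, 2)), "non-empty")
})

test_that("average Hausdorff equals the exhaustive pairwise oracle", {
  set.seed(17)
  for (i in 1:50) {
    na <- sample(500, 1); nb <- sample(500, 1)
    a <- cbind(runif(na, 0, 100), runif(na, 0, 100))
    b <- cbind(runif(nb, 0, 100), runif(nb, 0, 100))
    expect_lt(abs(average_hausdorff(a, b) - ah_oracle(a, b)), 1e-9)
    expect_identical(average_hausdorff(a, b), average_hausdorff(b, a))
  }
})

test_that("the max variant takes the larger directed mean", {
  a <- rbind(c(0, 0), c(0, 1)); b <- rbind(c(0, 0))
  expect_identical(average_hausdorff(a, b, variant = "max"), 0.5)
})

test_that("effective diameter inverts the circle-area relation", {
  m <- matrix(0L, 12, 12); m[1:100] <- 1L
  expect_equal(effective_diameter(m), 2 * sqrt(100 / pi), tolerance = 1e-12)
  one <- matrix(0L, 3, 3); one[2, 2] <- 1L
  expect_equal(effective_diameter(one), 2 * sqrt(1 / pi), tolerance = 1e-12)
  expect_error(effective_diameter(matrix(0L, 3, 3)), "empty")
})

test_that("RHD-D is zero at equality and ~offset/diameter for shifted disks", {
  d <- disk_mask(128, 50)
  ctr <- mask_to_contour(d)
  expect_identical(rhd_d(ctr, ctr, d), 0)
  # a 1-pixel translate leaves half the boundary pixels coincident, so the
  # discrete average Hausdorff is ~0.5 px against a 100 px diameter
  shifted <- disk_mask(128, 50, center = c(65.5, 64.5))
  r <- rhd_d(mask_to_contour(shifted), ctr, d)
  expect_gt(r, 0.25 * 1 / 100)
  expect_lt(r, 1.5 * 1 / 100)
})

test_that("RHD-D is scale-free within discretisation tolerance", {
  # same configuration at 1x and 2x magnification: offset and diameter both
  # double, so the ratio should agree up to pixelisation
  ref_s <- disk_mask(64, 12); pred_s <- disk_mask(64, 12, center = c(34.5, 32.5))
  ref_b <- disk_mask(128, 24); pred_b <- disk_mask(128, 24, center = c(68.5, 64.5))
  r1 <- rhd_d(mask_to_contour(pred_s), mask_to_contour(ref_s), ref_s)
  r2 <- rhd_d(mask_to_contour(pred_b), mask_to_contour(ref_b), ref_b)
  expect_gt(min(r1, r2), 0)
  expect_lt(abs(r2 - r1) / r1, 0.25)
})

test_that("RHD-D decreases monotonically as a shifted disk slides home", {
  ref <- disk_mask(160, 55)
  rc <- mask_to_contour(ref)
  vals <- vapply(10:1, function(off) {
    rhd_d(mask_to_contour(disk_mask(160, 55, center = c(80.5 + off, 80.5))),
          rc, ref)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("cohort summaries bootstrap the median reproducibly", {
  rows <- data.frame(mass_id = letters[1:3], dsc = c(0.8, 0.9, 1.0),
                     hd = c(1, 1, 1), deq = c(10, 10, 10),
                     rhd_d = c(0.1, 0.1, 0.1))
  s1 <- summarize_cohort(rows, n_boot = 200, seed = 4)
  s2 <- summarize_cohort(rows, n_boot = 200, seed = 4)
  expect_identical(s1, s2)
  sm <- s1$summary
  expect_identical(sm$median[sm$metric == "dsc"], 0.9)
  expect_true(all(sm$ci_lower <= sm$median & sm$median <= sm$ci_upper))
  # degenerate CI when all values agree
  expect_identical(sm$ci_lower[sm$metric == "hd"], 1)
  expect_identical(sm$ci_upper[sm$metric == "hd"], 1)
  expect_error(summarize_cohort(rows[1, ]), "at least 2")
})

test_that("evaluate_mass composes the metrics consistently", {
  ref <- disk_mask(96, 30)
  pred <- disk_mask(96, 30, center = c(50.5, 48.5))
  row <- evaluate_mass(pred, ref, "m1")
  expect_equal(row$rhd_d, row$hd / row$deq, tolerance = 1e-12)
  expect_true(row$dsc > 0.9 && row$dsc < 1)
})
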