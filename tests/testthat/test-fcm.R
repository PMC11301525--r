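test_that("entropy filter matches hand-computed neighbourhood histograms", {
  expect_true(all(entropy_filter(matrix(0.5, 6, 6)) == 0))
  cb <- outer(1:9, 1:9, function(i, j) (i + j) %% 2 * 0.5)
  e <- entropy_filter(cb)
  # interior neighbourhood: five of one value, four of the other
  expect_equal(e[5, 5], -(5 / 9) * log2(5 / 9) - (4 / 9) * log2(4 / 9),
               tolerance = 1e-12)
  # nine distinct bins reach the log2(9) ceiling
  nine <- matrix(seq(0, 1, length.out = 9), 3, 3)
  expect_equal(entropy_filter(nine)[2, 2], log2(9), tolerance = 1e-12)
  expect_true(max(entropy_filter(matrix(runif(100), 10, 10))) <= log2(9) + 1e-12)
  expect_error(entropy_filter(matrix(0.1, 2, 5)), "3 x 3")
})

test_that("std filter is the sample standard deviation over 9 pixels", {
  expect_true(all(std_filter(matrix(0.3, 5, 5)) == 0))
  cb <- outer(1:9, 1:9, function(i, j) (i + j) %% 2)
  s <- std_filter(cb * 1.0)
  expect_equal(s[5, 5], sqrt((5 * (4 / 9)^2 + 4 * (5 / 9)^2) / 8),
               tolerance = 1e-12)
  ramp <- matrix(rep(c(0, 0.5, 1), each = 3), 3, 3)  # columns 0, 0.5, 1
  expect_equal(std_filter(t(ramp))[2, 2] * 2, sqrt(6 / 8), tolerance = 1e-12)
})

test_that("feature stacks standardise channels and map indices back", {
  ph <- generate_phantom(two_level_spec(canvas = 64, seed = 4))
  st <- build_feature_stack(ph$image, ph$mass_mask)
  expect_identical(nrow(st$features), sum(ph$mass_mask))
  expect_lt(max(abs(colMeans(st$features))), 1e-9)
  expect_lt(max(abs(apply(st$features, 2, sd) - 1)), 1e-6)
  # index map round-trips exactly
  expect_identical(ph$image[st$idx[, "row"] + 1 + st$idx[, "col"] * 64],
                   unname(st$raw_gray))
  # constant ROI: every channel degenerates to 0
  cst <- build_feature_stack(matrix(0.5, 16, 16), matrix(TRUE, 16, 16))
  expect_true(all(cst$features == 0))
  expect_error(build_feature_stack(ph$image, ph$mass_mask * 0), "empty")
})

test_that("two-level phantom features form well-separated clusters", {
  ph <- generate_phantom(two_level_spec(canvas = 96, seed = 2))
  st <- build_feature_stack(ph$image, ph$mass_mask)
  lab <- ph$component_truth[ph$mass_mask]
  # mean silhouette against planted truth
  d1 <- st$features[lab == 1, , drop = FALSE]
  d2 <- st$features[lab == 2, , drop = FALSE]
  c1 <- colMeans(d1); c2 <- colMeans(d2)
  between <- sqrt(sum((c1 - c2)^2))
  within <- mean(c(sqrt(rowSums(sweep(d1, 2, c1)^2)),
                   sqrt(rowSums(sweep(d2, 2, c2)^2))))
  expect_gt(between / within, 1)
})

test_that("fuzzy c-means memberships follow the update rules at fixed points", {
  # point equidistant from two tight blobs stays at (0.5, 0.5)
  x <- rbind(matrix(rnorm(60, -5, 0.01), 30, 2),
             matrix(rnorm(60, 5, 0.01), 30, 2), c(0, 0))
  res <- fcm_cluster(x, seed = 3)
  expect_lt(max(abs(res$memberships[61, ] - 0.5)), 0.01)
  expect_lt(max(abs(rowSums(res$memberships) - 1)), 1e-9)
  # a point coinciding with a centroid gets a one-hot row
  y <- rbind(matrix(0, 10, 2), matrix(1, 10, 2))
  resy <- fcm_cluster(y, seed = 1)
  expect_true(all(sort(round(resy$memberships[1, ], 6)) %in% c(0, 1)))
})

test_that("planted clusters are recovered exactly across 10 seeds", {
  set.seed(99)
  x <- rbind(matrix(rnorm(100, 0, 0.05), 50, 2),
             matrix(rnorm(100, 10, 0.05), 50, 2))
  truth <- rep(1:2, each = 50)
  for (s in 1:10) {
    res <- fcm_cluster(x, seed = s)
    hard <- max.col(res$memberships)
    acc <- max(mean(hard == truth), mean(hard == 3 - truth))
    expect_identical(acc, 1)
    expect_true(all(diff(res$objective_trace) <=
                      1e-6 * (1 + res$objective_trace[-length(res$objective_trace)])))
  }
})

test_that("converged objective matches a coarse two-centroid grid search", {
  set.seed(5)
  x <- cbind(c(rnorm(12, 0, 0.1), rnorm(12, 3, 0.1)), 0)
  res <- fcm_cluster(x, seed = 2)
  # oracle: exhaustive grid over centroid pairs, memberships from the
  # analytic update, objective evaluated directly
  grid <- seq(-0.5, 3.5, by = 0.05)
  best <- Inf
  for (v1 in grid) for (v2 in grid) {
    d2 <- cbind((x[, 1] - v1)^2, (x[, 1] - v2)^2) + 1e-300
    u <- (1 / d2) / rowSums(1 / d2)
    best <- min(best, sum(u^2 * d2))
  }
  expect_lte(tail(res$objective_trace, 1), best + 1e-3)
})

test_that("labeling follows relative grayscale means with a tie rule", {
  ph <- generate_phantom(two_level_spec(canvas = 96, seed = 6))
  st <- build_feature_stack(ph$image, ph$mass_mask)
  res <- fcm_cluster(st, seed = 1)
  lab <- label_components(res, st)
  expect_lt(lab$cluster_gray_means[lab$hypo_cluster],
            max(lab$cluster_gray_means))
  # labels cover exactly the mask
  expect_identical(lab$labels > 0, ph$mass_mask)
  # labeling is independent of the initialisation seed
  for (s in 2:6) {
    labs <- label_components(fcm_cluster(st, seed = s), st)
    expect_identical(labs$labels, lab$labels)
  }
})

test_that("uniform regions collapse to a single flagged component", {
  warns <- capture_warnings(
    out <- segment_components(matrix(0.5, 20, 20), matrix(TRUE, 20, 20),
                              seed = 1))
  expect_true(any(grepl("equal mean grayscale|empty", warns)))
  expect_identical(unique(out$labels[out$labels > 0]), 1L)
})

test_that("phantom components are recovered with high Dice", {
  # full-size phantom with a substantial solid blob; residual hyperechoic
  # error is confined to the in-mask rim band, whose 3x3 neighbourhoods
  # straddle the mass edge and therefore carry high entropy/std
  ph <- generate_phantom(two_level_spec(canvas = 256, seed = 12))
  bb <- mask_bbox(ph$mass_mask)
  lab <- segment_components(crop(ph$image, bb), crop(ph$mass_mask, bb),
                            seed = 2)
  tr <- crop(ph$component_truth, bb)
  expect_gte(dice(lab$labels == 1, tr == 1), 0.95)
  expect_gte(dice(lab$labels == 2, tr == 2), 0.90)
  core <- erode1(erode1(crop(ph$mass_mask, bb)))
  expect_gte(dice(lab$labels == 2 & core, tr == 2 & core), 0.95)
})

test_that("a bright clot inside a dark cyst is labeled hyperechoic", {
  sp <- phantom_spec(canvas_size = 128, hypo_level = 0.15, hyper_level = 0.75,
                     component_layout = list(list(type = "blob",
                                                  center = c(0.2, 0.3),
                                                  axes = c(0.35, 0.35))),
                     seed = 7)
  ph <- generate_phantom(sp)
  lab <- segment_components(ph$image, ph$mass_mask, seed = 3)
  clot <- ph$component_truth == 2L
  expect_gt(mean(lab$labels[clot] == 2L), 0.9)
})

test_that("in-mass acoustic shadow pixels are labeled hypoechoic", {
  sp <- phantom_spec(canvas_size = 128, hypo_level = 0.6, hyper_level = 0.8,
                     component_layout = list(),
                     shadow_columns = list(list(col_min = 55, col_max = 70,
                                                attenuation = 0.4,
                                                row_start = 60)),
                     seed = 8)
  ph <- generate_phantom(sp)
  lab <- segment_components(ph$image, ph$mass_mask, seed = 3)
  shadowed <- matrix(FALSE, 128, 128)
  shadowed[61:128, 56:70] <- TRUE
  inmask <- shadowed & ph$mass_mask
  expect_gt(sum(inmask), 100)
  expect_gt(mean(lab$labels[inmask] == 1L), 0.85)
})
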