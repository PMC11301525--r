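test_that("configuration validates divisibility and positivity", {
  expect_error(unet_config(input_size = 100, depth = 3), "divisible")
  expect_error(unet_config(learning_rate = 0), "positive")
  expect_s3_class(unet_config(input_size = 64, depth = 2), "unet_config")
})

test_that("the minimal architecture has the hand-counted parameter total", {
  # depth 1, base 1: encoder 2 convs (10 + 10), bottleneck 1->2 and 2->2
  # convs (20 + 38), up-convolution 2->1 (9), decoder convs on the
  # 2-channel concatenation (19 + 10), final 1x1 to 2 classes (4) = 120
  cfg <- unet_config(input_size = 16, depth = 1, base_filters = 1)
  expect_identical(unet_param_count(cfg), 120L)
  expect_identical(unet_param_count(build_unet(cfg)), 120L)
})

test_that("two builds from the same config are identical; predictions deterministic", {
  cfg <- unet_config(input_size = 32, depth = 2, base_filters = 2, seed = 9)
  m1 <- build_unet(cfg); m2 <- build_unet(cfg)
  expect_identical(m1$weights, m2$weights)
  img <- matrix(runif(32 * 32), 32, 32)
  p1 <- unet_predict(m1, img); p2 <- unet_predict(m1, img)
  expect_identical(p1$prob, p2$prob)
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  expect_identical(p1$mask, p1$prob > 0.5)
  expect_error(unet_predict(m1, matrix(0, 16, 16)), "32 x 32")
})

test_that("training for zero epochs is a no-op with empty history", {
  cfg <- unet_config(input_size = 16, depth = 1, base_filters = 2)
  mod <- build_unet(cfg)
  out <- unet_train(mod, list(), epochs = 0)
  expect_identical(out$weights, mod$weights)
  expect_identical(nrow(out$history), 0L)
  expect_error(unet_train(mod, list(), epochs = 2), "empty sample list")
})

test_that("the network overfits a single sample to high Dice", {
  ph <- generate_phantom(phantom_spec(canvas_size = 64, seed = 5))
  cfg <- unet_config(input_size = 64, depth = 2, base_filters = 8,
                     max_epochs = 200, seed = 2)
  mod <- unet_train(build_unet(cfg),
                    list(list(image = ph$image, mask = ph$mass_mask)))
  pred <- unet_predict(mod, ph$image)
  expect_gte(dice(pred$mask, ph$mass_mask), 0.95)
})

test_that("training loss descends on a small phantom set (median over 3 seeds)", {
  rec <- generate_cohort(20, seed = 31, canvas_size = 64, two_mass_fraction = 0)
  samples <- lapply(rec, function(r)
    list(image = standardize_roi(r$image, r$bbox, 64),
         mask = standardize_roi(r$expert_mask, r$bbox, 64)))
  drops <- vapply(1:3, function(s) {
    cfg <- unet_config(input_size = 64, depth = 2, base_filters = 4, seed = s)
    mod <- unet_train(build_unet(cfg), samples, epochs = 10)
    mod$history$loss[10] - mod$history$loss[1]
  }, numeric(1))
  expect_lt(median(drops), 0)
})

test_that("training is reproducible for a fixed seed", {
  ph <- generate_phantom(phantom_spec(canvas_size = 48, seed = 8))
  samples <- list(list(image = ph$image, mask = ph$mass_mask))
  cfg <- unet_config(input_size = 48, depth = 1, base_filters = 2, seed = 5)
  m1 <- unet_train(build_unet(cfg), samples, epochs = 5)
  m2 <- unet_train(build_unet(cfg), samples, epochs = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  mod <- build_unet(unet_config(input_size = 16, depth = 1, base_filters = 1))
  p <- file.path(dir, "net.rds")
  save_unet(mod, p)
  expect_identical(load_unet(p)$weights, mod$weights)
})
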