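small_cfg <- function(scheme = "binary", epochs = 1L, seed = 7L,
                      encoder = "micro", size = c(64L, 32L)) {
  train_config(scheme, encoder_name = encoder, epochs = epochs, seed = seed,
               augmentation = augmentation_spec(resize_to = size))
}

tiny_samples <- function(n, seed = 3L) {
  make_samples(n, seed = seed, image_size = c(64L, 32L), count_range = c(3L, 5L))
}

test_that("dataset splitting follows the rounded fractions deterministically", {
  ids <- sprintf("im%02d", 1:10)
  sp <- split_dataset(ids, c(0.6, 0.2, 0.2), seed = 5)
  expect_length(sp$train, 6L)
  expect_length(sp$val, 2L)
  expect_length(sp$test, 2L)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(sp, split_dataset(ids, c(0.6, 0.2, 0.2), seed = 5))
  expect_false(identical(sp, split_dataset(ids, c(0.6, 0.2, 0.2), seed = 6)))

  # the full-corpus size rounds to 1047 / 349 / 349
  big <- split_dataset(seq_len(1745), seed = 1)
  expect_equal(lengths(big), c(train = 1047L, val = 349L, test = 349L))

  expect_error(split_dataset(c("a", "b")), "at least 3")
  expect_error(split_dataset(ids, c(0.5, 0.2, 0.2)), "summing to 1")

  # property: disjoint exhaustive partition across random sizes
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(3:200, 1)
    sp2 <- split_dataset(seq_len(n), seed = rep)
    expect_equal(sort(unlist(sp2, use.names = FALSE)), seq_len(n))
  }
})

test_that("configs validate loss/scheme compatibility and encoder names", {
  expect_error(train_config("binary", loss = "kldiv"), "incompatible")
  expect_error(train_config("gaussian", loss = "bce"), "incompatible")
  expect_equal(train_config("gaussian")$loss, "kldiv")
  expect_error(train_config("binary", encoder_name = "resnet50"), "unknown encoder")
  expect_error(train_config("binary", epochs = 0), ">= 1")
  expect_error(train_config("binary", split_fractions = c(0.5, 0.4, 0.2)),
               "sum to 1")
})

test_that("a one-epoch run on two tiny images satisfies the smoke contract", {
  samples <- tiny_samples(4)
  ds <- list(train = samples[1:2], val = samples[3:4])
  model <- train_segmentation_model(ds, small_cfg(epochs = 1L))
  expect_s3_class(model, "spikelet_model")
  expect_equal(nrow(model$history), 1L)
  expect_true(all(is.finite(model$history$train_loss)))

  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(back$params, model$params)
  img <- samples[[1]]$image
  expect_identical(predict_mask(back, img), predict_mask(model, img))

  lg <- withr::local_tempfile(fileext = ".csv")
  write_training_log(model, lg)
  expect_equal(names(utils::read.csv(lg)),
               c("epoch", "train_loss", "val_loss", "val_f1"))

  expect_error(train_segmentation_model(list(train = list(), val = samples[3:4]),
                                        small_cfg()), "non-empty")
})

test_that("training is deterministic given the seed", {
  samples <- tiny_samples(6)
  ds <- list(train = samples[1:4], val = samples[5:6])
  m1 <- train_segmentation_model(ds, small_cfg(epochs = 2L, seed = 11L))
  m2 <- train_segmentation_model(ds, small_cfg(epochs = 2L, seed = 11L))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("predicted maps respect their codomain contracts", {
  samples <- tiny_samples(4)
  ds <- list(train = samples[1:2], val = samples[3:4])
  mb <- train_segmentation_model(ds, small_cfg("binary", epochs = 1L))
  pb <- predict_mask(mb, samples[[1]]$image)
  expect_equal(dim(pb), c(64L, 32L))
  expect_true(all(pb >= 0 & pb <= 1))
  expect_identical(pb, predict_mask(mb, samples[[1]]$image))

  mg <- train_segmentation_model(ds, small_cfg("gaussian", epochs = 1L))
  pg <- predict_mask(mg, samples[[1]]$image)
  expect_true(all(pg >= 0))
  expect_equal(sum(pg), 1, tolerance = 1e-9)

  # prediction resamples back to the original geometry
  big <- array(0.5, c(96, 48, 3))
  pbig <- predict_mask(mb, big)
  expect_equal(dim(pbig), c(96L, 48L))
})

test_that("the network can overfit one image and recover its own annotations", {
  samples <- make_samples(1, seed = 21, image_size = c(64L, 32L),
                          count_range = c(4L, 4L))
  s <- samples[[1]]
  still <- augmentation_spec(resize_to = c(64L, 32L), hflip_p = 0, vflip_p = 0,
                             rotate_p = 0, blur_p = 0, noise_p = 0,
                             brightness_contrast_p = 0, rgb_shift_p = 0,
                             cj_p = 0, gray_p = 0)
  cfg <- train_config("binary", encoder_name = "micro", epochs = 150L,
                      seed = 5L, augmentation = still)
  model <- train_segmentation_model(list(train = list(s), val = list(s)), cfg)
  map <- predict_mask(model, s$image)
  ctr <- extract_centers(map, "binary", cfg$extraction, s$annotations$scale)
  mr <- match_centers(ctr, s$annotations$points, 2, s$annotations$scale)
  expect_equal(detection_metrics(mr)$f1, 1)
})
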