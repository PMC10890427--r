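test_that("augmentation reaches the target count without touching labels", {
  ds <- toy_labeled_set(n_per_class = 10, seed = 2)
  aug <- augment_dataset(ds, target_per_class = 40, seed = 9)
  expect_equal(sum(aug$labels == "with_microfracture"), 40L)
  expect_equal(sum(aug$labels == "without_microfracture"), 40L)
  expect_equal(length(aug$images), 80L)
  # originals retained, augmented copies traceable to a source index
  expect_identical(aug$images[1:20], ds$images)
  added <- aug$images[aug$provenance == "augmented"]
  src <- vapply(added, function(im) attr(im, "aug_source"), 0L)
  expect_true(all(src >= 1L & src <= 20L))
  # augmented copies of "with" images come from "with" sources
  lab_added <- as.character(aug$labels[aug$provenance == "augmented"])
  expect_equal(lab_added, as.character(ds$labels)[src])

  # identity when the target is already met; determinism under seed
  expect_identical(augment_dataset(ds, 10, seed = 1)$images, ds$images)
  aug2 <- augment_dataset(ds, target_per_class = 40, seed = 9)
  expect_identical(aug$images, aug2$images)
})

test_that("training separates a linearly separable toy and is reproducible", {
  ds <- toy_labeled_set(n_per_class = 20, seed = 1)
  cfg <- classifier_config(input_height = 32L, input_width = 32L,
                           epochs = 5L, seed = 1L)
  model <- train_classifier(ds, cfg)
  expect_equal(model$log$train_accuracy[5], 1.0)
  # loss decreases from its initial scale under a small learning rate
  expect_lt(model$log$loss[5], model$log$loss[1])
  expect_equal(evaluate_accuracy(model, ds)$accuracy, 1.0)

  model2 <- train_classifier(ds, cfg)
  expect_identical(model$net$dense$W, model2$net$dense$W)
  expect_identical(model$net$blocks[[1]]$conv$W, model2$net$blocks[[1]]$conv$W)

  single <- ds; single$labels[] <- "with_microfracture"
  expect_error(train_classifier(single, cfg), "both classes")
})

test_that("inference is normalized, deterministic and shape tolerant", {
  ds <- toy_labeled_set(n_per_class = 16, seed = 3)
  cfg <- classifier_config(input_height = 32L, input_width = 32L,
                           epochs = 8L, seed = 2L)
  model <- train_classifier(ds, cfg)

  blank <- matrix(20, 32, 32)
  res <- classify_image(model, blank)
  expect_equal(as.character(res$label), "without_microfracture")
  p <- microfract:::predict_probs(model, list(blank, ds$images[[1]]))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_identical(p, microfract:::predict_probs(model, list(blank, ds$images[[1]])))

  # a 64x64 input is rescaled into the 32x32 network
  big <- matrix(20, 64, 64); big[20:40, 20:40] <- 200
  expect_s3_class(classify_image(model, big)$label, "factor")

  ev <- evaluate_accuracy(model, ds)
  expect_equal(sum(ev$confusion), length(ds$images))
  expect_gte(ev$accuracy, 0.9)
})

test_that("checkpoints round-trip through the JSON format", {
  ds <- toy_labeled_set(n_per_class = 6, seed = 4)
  model <- train_classifier(ds, classifier_config(input_height = 16L,
                                                  input_width = 16L,
                                                  epochs = 2L, seed = 3L))
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(model, path)
  back <- load_classifier(path)
  expect_equal(back$net$dense$W, model$net$dense$W)
  expect_equal(back$net$blocks[[3]]$bn$run_mean,
               model$net$blocks[[3]]$bn$run_mean)
  img <- ds$images[[1]]
  expect_equal(classify_image(back, img)$score, classify_image(model, img)$score)
})

test_that("the CNN pre-screen and morphological detection agree on most images", {
  t5 <- shared_t5()
  idx <- seq_len(100) # subset keeps the check at desk scale
  meta <- stack_meta(um_per_px = 1.4)
  morph <- vapply(t5$test$images[idx], function(im) {
    any(detect_microfractures(im, meta = meta)$records$type == "microfracture")
  }, TRUE)
  cnn <- t5$eval$predictions[idx] == "with_microfracture"
  expect_gte(mean(morph == cnn), 0.9)
})
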