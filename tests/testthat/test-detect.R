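test_that("clip slicing partitions the image and inverts exactly", {
  img <- matrix(runif(128 * 512), 128, 512)
  g <- slice_clips(img)
  expect_equal(g$n_clips, 32L)
  expect_identical(clips_to_image(g), img)
  expect_equal(slice_clips(matrix(0, 20, 32))$n_clips, 2L)
  expect_error(slice_clips(matrix(0, 20, 33)), "re-crop")
})

test_that("clip labels follow the any-annotated-column rule", {
  s <- generate_scene(desk_scene_spec(ez_gap_fraction = 0), seed = 1)
  expect_true(all(clip_labels(s$annotation, "ez")))

  # hand-built gap spanning exactly clips 10-19 (columns 145..304)
  ann <- s$annotation
  ann$ez_trace[145:304] <- NA
  labs <- clip_labels(ann, "ez")
  expect_false(any(labs[10:19]))
  expect_true(all(labs[-(10:19)]))

  # gap covering half a clip keeps the clip positive
  ann2 <- s$annotation
  ann2$ez_trace[1:8] <- NA
  expect_true(clip_label(ann2, "ez", 1))

  expect_error(clip_labels(s$annotation, "rpe"), "unknown layer")
  expect_error(clip_label(s$annotation, "ez", 999), "out of range")
})

test_that("training validates its inputs", {
  clips <- lapply(1:8, function(i) matrix(runif(32 * 16), 32, 16))
  cfg <- clip_cnn_config(channels = c(2L, 2L, 2L, 2L), epochs = 1L)
  expect_error(train_clip_cnn(list(), logical(0), cfg), "empty training set")
  expect_error(train_clip_cnn(clips, rep(TRUE, 8), cfg),
               "both positive and negative")
  expect_error(clip_cnn_config(threshold = 1.5), "threshold")
  expect_error(clip_cnn_config(epochs = 0), "epochs")
})

test_that("detection output has one decision per clip and obeys the threshold", {
  m <- tiny_clip_model()
  img <- matrix(runif(32 * 160), 32, 160)
  res <- detect_layers(m, img)
  expect_length(res$probability, 10L)
  expect_length(res$presence, 10L)
  expect_true(all(res$probability >= 0 & res$probability <= 1))
  expect_identical(res$presence, res$probability >= 0.5)
  # threshold override flips the binarisation point
  res0 <- detect_layers(m, img, threshold = max(res$probability) + 1e-9)
  expect_false(any(res0$presence))
  # same input, same output (deterministic inference)
  expect_identical(res$probability, detect_layers(m, img)$probability)
  # offset + re-normalisation leaves a [0,1]-spanning image unchanged
  img2 <- img; img2[1] <- 0; img2[2] <- 1
  expect_equal(detect_layers(m, img2)$probability,
               detect_layers(m, minmax_normalize(img2 + 0.25))$probability,
               tolerance = 1e-9)
})
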