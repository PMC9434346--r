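tiny_fcn_set <- function(n = 3, H = 32L, W = 64L) {
  scenes <- lapply(seq_len(n), function(i)
    generate_scene(scene_spec(image_height = H, image_width = W,
                              speckle_sigma = 0), seed = i))
  list(images = lapply(scenes, `[[`, "image"),
       masks = lapply(scenes, function(s) s$annotation$lesion_mask),
       scenes = scenes)
}

test_that("training validates configuration and class coverage", {
  expect_error(fcn_config(epochs = 0), "epochs")
  expect_error(fcn_config(channels = 4L), "channels")
  ts <- tiny_fcn_set()
  expect_error(train_fcn(list(), list()), "non-empty")
  masks_no_ped <- lapply(ts$masks, function(m) { m[m == 4L] <- 0L; m })
  expect_error(train_fcn(ts$images, masks_no_ped, fcn_config(epochs = 1)),
               "PED")
})

test_that("a tiny trained FCN is deterministic and label-consistent", {
  ts <- tiny_fcn_set()
  cfg <- fcn_config(channels = c(4L, 8L), epochs = 3L, seed = 7L)
  m1 <- train_fcn(ts$images, ts$masks, cfg)
  m2 <- train_fcn(ts$images, ts$masks, cfg)
  s1 <- segment(m1, ts$images[[1]], return_prob = TRUE)
  s2 <- segment(m2, ts$images[[1]])
  expect_identical(s1$labels, s2$labels)          # seeded training
  expect_identical(s1$labels, segment(m1, ts$images[[1]])$labels)
  expect_true(all(s1$labels %in% 0:4))
  # probability maps normalise pixelwise and agree with the argmax
  sums <- apply(s1$prob, c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
  am <- apply(s1$prob, c(1, 2), which.max) - 1L
  expect_identical(unname(am), unname(s1$labels))
  expect_error(segment(m1, matrix(0, 33, 64)), "divisible")
  expect_gt(m1$loss_history[1], tail(m1$loss_history, 1))  # loss trend
})
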