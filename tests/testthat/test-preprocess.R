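test_that("crop_and_resize reshapes a raw frame to the working geometry", {
  raw <- matrix(runif(108 * 192), 108, 192)  # 1920 x 1080 scaled down 10x
  out <- crop_and_resize(raw, "auto", target_height = 64L, target_width = 160L)
  expect_identical(dim(out), c(64L, 160L))
  # identity geometry leaves values unchanged (interpolation identity)
  out2 <- crop_and_resize(raw, "auto", target_height = nrow(raw),
                          target_width = 192L)
  expect_equal(unclass(out2), raw, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(crop_and_resize(raw, c(1, 10, 1, 500)), "roi")
  expect_error(crop_and_resize(raw, c(0, 10, 1, 10)), "roi")
  expect_error(crop_and_resize(matrix(numeric(0), 0, 0)), "raw")
  expect_error(crop_and_resize(raw, "auto", target_width = 100L),
               "divisible by 16")
})

test_that("full-scale reshape 1080x1920 -> 256x1600 works", {
  raw <- matrix(runif(1080 * 1920), 1080, 1920)
  out <- crop_and_resize(raw)
  expect_identical(dim(out), c(256L, 1600L))
  expect_equal(attr(out, "pixel_size_mm"), 8 / 1600)
})

test_that("min-max normalisation follows the formula and is idempotent", {
  m <- matrix(c(2, 4, 6, 4), 2, 2)
  n <- minmax_normalize(m)
  expect_equal(sort(unique(as.numeric(n))), c(0, 0.5, 1))
  expect_equal(minmax_normalize(n), n)
  expect_warning(z <- minmax_normalize(matrix(5, 3, 3)), "constant")
  expect_true(all(z == 0))
})

test_that("augmentation is seeded, label-safe and bounded", {
  s <- generate_scene(desk_scene_spec(), seed = 4)
  tr <- list(ez = s$annotation$ez_trace, elm = s$annotation$elm_trace)
  a1 <- augment(s$image, s$annotation$lesion_mask, tr, seed = 9)
  a2 <- augment(s$image, s$annotation$lesion_mask, tr, seed = 9)
  expect_identical(a1, a2)
  expect_true(all(unique(as.integer(a1$mask)) %in%
                    unique(as.integer(s$annotation$lesion_mask))))
  expect_true(all(a1$image >= 0 & a1$image <= 1))
  rows <- unlist(lapply(a1$traces, function(v) v[!is.na(v)]))
  expect_true(all(rows >= 1 & rows <= nrow(s$image)))
  expect_error(augment(s$image, s$annotation$lesion_mask[1:10, , drop = FALSE]),
               "mask shape")
})

test_that("a pure flip is an involution", {
  img <- matrix(runif(64 * 96), 64, 96)
  f1 <- augment(img, seed = 1, flip_p = 1, crop_scale_min = 1, shift_max = 0)
  f2 <- augment(f1$image, seed = 2, flip_p = 1, crop_scale_min = 1,
                shift_max = 0)
  expect_equal(f2$image, img, tolerance = 1e-12)
})
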