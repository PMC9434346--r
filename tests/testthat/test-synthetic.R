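test_that("scene generation is seeded, consistent and validates its spec", {
  sp <- desk_scene_spec(ez_gap_fraction = 0.3)
  s1 <- generate_scene(sp, seed = 11)
  s2 <- generate_scene(sp, seed = 11)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$features, s2$features)
  s3 <- generate_scene(sp, seed = 12)
  expect_false(identical(s1$image, s3$image))

  # length rate = 1 - gap fraction within one clip of discretisation
  expect_lt(abs(s1$features[["ez_length_rate"]] - 0.7), 16 / 512 + 1e-9)
  expect_true(all(s1$image >= 0 & s1$image <= 1))

  # invalid specs name the offending field
  expect_error(scene_spec(image_width = 513), "image_width")
  expect_error(desk_scene_spec(ez_gap_fraction = 1.2), "ez_gap_fraction")
  expect_error(desk_scene_spec(ez_row = 5), "ez_row")
  expect_error(lesion_spec("IRF", "ellipse", c(10, 10), c(0, 4), 0.1), "axes")
  expect_error(lesion_spec("FOO", "ellipse", c(10, 10), c(2, 4), 0.1),
               "unknown lesion class")
})

test_that("empty lesion list gives an all-background mask and zero areas", {
  s <- generate_scene(desk_scene_spec(lesion_specs = list()), seed = 1)
  expect_true(all(s$annotation$lesion_mask == 0L))
  areas <- s$features[grep("_area_mm2$", names(s$features))]
  expect_true(all(areas == 0))
  expect_true(is.na(s$features[["ped_mean_intensity"]]))
})

test_that("noise-free render is piecewise constant exactly on the mask", {
  s <- generate_scene(desk_scene_spec(speckle_sigma = 0), seed = 2)
  m <- s$annotation$lesion_mask
  img <- s$image
  # within each lesion class, off-trace pixels carry one intensity
  ezr <- unique(stats::na.omit(s$annotation$ez_trace))
  elmr <- unique(stats::na.omit(s$annotation$elm_trace))
  line_rows <- c(ezr, ezr + 1, elmr, elmr + 1)  # lines are drawn on top
  for (k in 1:4) {
    sel <- m == k
    sel[line_rows, ] <- FALSE
    expect_length(unique(img[sel]), 1L)
  }
})

test_that("traces and gaps agree and lie inside the image", {
  s <- generate_scene(desk_scene_spec(ez_gap_fraction = 0.25), seed = 5)
  tr <- s$annotation$ez_trace
  expect_equal(sum(is.na(tr)), round(0.25 * 512))
  expect_true(all(stats::na.omit(tr) >= 1 & stats::na.omit(tr) <= 128))
  # gap is one contiguous interval
  r <- rle(is.na(tr))
  expect_lte(sum(r$values), 1L)
})

test_that("cohort generation is reproducible, labelled and validated", {
  expect_error(generate_cohort(0), "n_eyes")
  c1 <- generate_cohort(8, seed = 3, render = FALSE)
  c2 <- generate_cohort(8, seed = 3, render = FALSE)
  expect_identical(cohort_feature_table(c1), cohort_feature_table(c2))
  expect_named(c1[[1]]$visits, c("baseline", "month1", "month3", "month12"))
  expect_true(all(vapply(c1, `[[`, integer(1), "label") %in% 0:2))

  # degenerate rule: warning, all labels equal
  expect_warning(
    c0 <- generate_cohort(5, outcome_model = outcome_rule_constant(0),
                          seed = 1, render = FALSE),
    "single class")
  expect_true(all(vapply(c0, `[[`, integer(1), "label") == 0L))
})

test_that("default planted rule yields all three classes at n = 120", {
  coh <- generate_cohort(120, seed = 17, render = FALSE)
  counts <- attr(coh, "class_counts")
  expect_true(all(counts > 0))
  # labels are consistent with the realised month-3 features
  rule <- outcome_rule_default()
  for (rec in coh[seq(1, 120, by = 12)]) {
    expect_identical(rec$label,
                     rule(lapply(rec$visits, `[[`, "features")))
  }
})

test_that("ez_only cohorts put the class signal in the layer features", {
  coh <- generate_cohort(40, seed = 23, signal = "ez_only", render = FALSE)
  ft <- cohort_feature_table(coh)
  m3 <- ft[ft$visit == "month3", ]
  # the planted rule is exactly recoverable from the realised ez rate
  pred <- ifelse(m3$ez_length_rate < 0.6, 1L,
                 ifelse(m3$ez_length_rate >= 0.9, 2L, 0L))
  expect_identical(pred, m3$label)
})
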