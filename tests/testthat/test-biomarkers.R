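test_that("length rate is the fraction of positive clips", {
  expect_equal(layer_length_rate(rep(TRUE, 100)), 1.0)
  expect_equal(layer_length_rate(c(rep(TRUE, 60), rep(FALSE, 40))), 0.6)
  expect_equal(layer_length_rate(rep(FALSE, 100)), 0.0)
  expect_error(layer_length_rate(logical(0)), "empty")
})

test_that("area, diameter and intensity follow their raster definitions", {
  m <- matrix(0L, 40, 60)
  m[11:20, 21:40] <- 1L                       # 10 x 20 IRF rectangle
  expect_equal(region_area(m, "IRF", 0.005), 200 * 0.000025)
  expect_equal(region_max_diameter(m, "IRF", 0.005), 20 * 0.005)
  expect_equal(region_area(m, "SRF", 0.005), 0)
  expect_equal(region_max_diameter(m, "SRF", 0.005), 0)

  # two components: areas add, diameters take the max
  m2 <- matrix(0L, 30, 60)
  m2[5:9, 3:7] <- 2L      # width 5
  m2[20:23, 30:41] <- 2L  # width 12
  expect_equal(region_area(m2, "SRF", 1), (5 * 5) + (4 * 12))
  expect_equal(region_max_diameter(m2, "SRF", 1), 12)

  img <- matrix(0.5, 40, 60)
  m[11:20, 21:40] <- 3L
  expect_equal(region_mean_intensity(img, m, "SHRM"), 0.5)
  img[11:20, 21:30] <- 0.2; img[11:20, 31:40] <- 0.8
  expect_equal(region_mean_intensity(img, m, "SHRM"), 0.5)
  expect_true(is.na(region_mean_intensity(img, matrix(0L, 40, 60), "PED")))
  expect_error(region_mean_intensity(img, m, "IRF"), "SHRM and PED")
  expect_error(region_area(m, "XYZ", 1), "unknown lesion class")
})

test_that("diameter uses connected components, not the column projection", {
  # two stacked blobs overlapping in columns: projection would merge them
  m <- matrix(0L, 30, 30)
  m[2:4, 2:9] <- 1L     # width 8
  m[10:12, 6:11] <- 1L  # width 6, overlapping columns, disjoint rows
  expect_equal(region_max_diameter(m, "IRF", 1), 8)
})

test_that("extract_biomarkers assembles the 12 features and round-trips", {
  s <- generate_scene(desk_scene_spec(speckle_sigma = 0), seed = 21)
  f <- quantify_annotation(s)
  expect_named(f, biomarker_feature_names())
  expect_equal(f, s$features)

  # all-background mask + all-true presence
  empty <- matrix(0L, 128, 512)
  f2 <- extract_biomarkers(s$image, empty, rep(TRUE, 32), rep(TRUE, 32))
  expect_equal(f2[["ez_length_rate"]], 1)
  expect_true(all(f2[grep("area|diameter", names(f2))] == 0))
  expect_true(all(is.na(f2[grep("intensity", names(f2))])))

  expect_error(extract_biomarkers(s$image, empty[1:64, ],
                                  rep(TRUE, 32), rep(TRUE, 32)),
               "geometries differ")
})

test_that("features scale as dimensional analysis dictates", {
  s <- generate_scene(desk_scene_spec(speckle_sigma = 0), seed = 22)
  ann <- s$annotation
  f1 <- extract_biomarkers(s$image, ann$lesion_mask,
                           clip_labels(ann, "ez"), clip_labels(ann, "elm"),
                           pixel_size_mm = 0.005)
  f2 <- extract_biomarkers(s$image, ann$lesion_mask,
                           clip_labels(ann, "ez"), clip_labels(ann, "elm"),
                           pixel_size_mm = 0.010)
  areas <- grep("_area_mm2$", names(f1))
  diams <- grep("_max_diameter_mm$", names(f1))
  inv <- grep("rate|intensity", names(f1))
  expect_equal(f2[areas], f1[areas] * 4)
  expect_equal(f2[diams], f1[diams] * 2)
  expect_equal(f2[inv], f1[inv])
})
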