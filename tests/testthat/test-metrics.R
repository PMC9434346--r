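test_that("dice follows its definition and conventions", {
  a <- matrix(c(rep(1, 10), rep(0, 10)), 4, 5)
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, 1 - a), 0.0)
  expect_equal(dice(a, 1 - a), dice(1 - a, a))  # symmetry
  # 4-px prediction inside an 8-px truth region
  p <- matrix(0, 6, 6); t <- matrix(0, 6, 6)
  p[2:3, 2:3] <- 1; t[2:5, 2:3] <- 1
  expect_equal(dice(p, t), 2 * 4 / (4 + 8))
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1)  # empty-empty
  expect_error(dice(p, t[1:3, ]), "shapes differ")
})

test_that("confusion metrics handle stated counts and degenerate truths", {
  expect_equal(confusion_metrics(c(TRUE, FALSE), c(TRUE, FALSE)),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  # TP=8, FN=2, TN=85, FP=5
  pred <- c(rep(TRUE, 8), rep(FALSE, 2), rep(FALSE, 85), rep(TRUE, 5))
  truth <- c(rep(TRUE, 10), rep(FALSE, 90))
  cm <- confusion_metrics(pred, truth)
  expect_equal(unname(cm), c(0.93, 0.8, 85 / 90), tolerance = 1e-12)
  expect_true(is.na(confusion_metrics(c(FALSE, TRUE),
                                      c(FALSE, FALSE))[["sensitivity"]]))
  expect_error(confusion_metrics(c(TRUE), c(TRUE, FALSE)), "lengths differ")
})

test_that("accuracy decomposes by prevalence on random vectors", {
  set.seed(42)
  for (i in 1:25) {
    n <- 200
    pred <- runif(n) < runif(1)
    truth <- runif(n) < runif(1, 0.2, 0.8)
    cm <- confusion_metrics(pred, truth)
    prev <- mean(truth)
    expect_equal(cm[["accuracy"]],
                 prev * cm[["sensitivity"]] + (1 - prev) * cm[["specificity"]],
                 tolerance = 1e-12)
  }
})

test_that("bootstrap CI is seeded, degenerate-safe and covers the mean", {
  expect_equal(unname(bootstrap_ci(rep(0.7, 8), seed = 1)), c(0.7, 0.7))
  expect_error(bootstrap_ci(numeric(0)), "no samples")
  x <- runif(30)
  ci <- bootstrap_ci(x, n_boot = 1000, seed = 5)
  expect_identical(ci, bootstrap_ci(x, n_boot = 1000, seed = 5))
  expect_lte(ci[["low"]], mean(x))
  expect_gte(ci[["high"]], mean(x))
})

test_that("bootstrap CI has near-nominal coverage (Monte Carlo)", {
  set.seed(7)
  hits <- vapply(1:200, function(i) {
    x <- as.numeric(runif(200) < 0.9)
    ci <- bootstrap_ci(x, n_boot = 2000, seed = i)
    ci[["low"]] <= 0.9 && 0.9 <= ci[["high"]]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("AVG aggregation reproduces the reference table cells", {
  ref <- read.csv(system.file("extdata", "reference_metrics.csv",
                              package = "retquant"), check.names = FALSE)
  dice_row <- as.numeric(ref[ref$metric == "dice",
                             c("IRF", "SRF", "SHRM", "PED")])
  sens_row <- as.numeric(ref[ref$metric == "sensitivity",
                             c("IRF", "SRF", "SHRM", "PED", "EZ", "ELM")])
  spec_row <- as.numeric(ref[ref$metric == "specificity",
                             c("IRF", "SRF", "SHRM", "PED", "EZ", "ELM")])
  expect_equal(aggregate_average(dice_row), 0.873)
  expect_equal(aggregate_average(sens_row), 0.873)
  expect_equal(aggregate_average(spec_row), 0.922)
  expect_equal(aggregate_average(c(0.5, 0.5, 0.5)), 0.5)
  expect_error(aggregate_average(NA_real_), "no values")
})

test_that("cohort accounting reproduces the reference proportions", {
  expect_equal(unname(class_proportions(c(66, 47, 29), counts = TRUE)),
               c(46.48, 33.10, 20.42))
  expect_equal(unname(class_proportions(c(10, 0, 0), counts = TRUE)),
               c(100, 0, 0))
  expect_equal(unname(class_proportions(c(1, 1, 1), counts = TRUE)),
               c(33.33, 33.33, 33.33))
  expect_equal(unname(class_proportions(rep(0:2, c(2, 1, 1)))),
               c(50, 25, 25))
  expect_equal(visit_share(c(186, 186, 157, 142), 3), 23.4)
  expect_equal(visit_share(c(148, 148, 119, 104), 1), 28.5)
  expect_error(class_proportions(integer(0)), "empty")
})

test_that("segmentation report has the table layout with N/A dice for layers", {
  s1 <- generate_scene(desk_scene_spec(), seed = 1)
  s2 <- generate_scene(desk_scene_spec(), seed = 2)
  truth <- list(s1$annotation$lesion_mask, s2$annotation$lesion_mask)
  lay <- list(ez = list(clip_labels(s1$annotation, "ez"),
                        clip_labels(s2$annotation, "ez")),
              elm = list(clip_labels(s1$annotation, "elm"),
                         clip_labels(s2$annotation, "elm")))
  rep <- segmentation_report(truth, truth, lay, lay, n_boot = 50, seed = 3)
  expect_identical(colnames(rep$table),
                   c("IRF", "SRF", "SHRM", "PED", "EZ", "ELM", "AVG"))
  expect_true(all(rep$table["dice", c("IRF", "SRF", "SHRM", "PED")] == 1))
  expect_true(is.na(rep$table["dice", "EZ"]))
  expect_true(all(rep$table["accuracy", ] == 1))
  rendered <- write_segmentation_report(rep)
  expect_identical(rendered["dice", "EZ"], "N/A")
})
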