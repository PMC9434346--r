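planted_matrix <- function(n = 80, p_noise = 6, seed = 31) {
  set.seed(seed)
  x1 <- runif(2 * n)
  x1 <- x1[abs(x1 - 0.4) > 0.03 & abs(x1 - 0.8) > 0.03][seq_len(n)]
  y <- ifelse(x1 < 0.4, 1L, ifelse(x1 >= 0.8, 2L, 0L))
  x <- cbind(signal = x1,
             matrix(runif(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(x = x, y = y)
}

test_that("feature matrix composition follows the variant x horizon rule", {
  coh <- generate_cohort(10, seed = 2, render = FALSE)
  ft <- cohort_feature_table(coh)
  fm6 <- build_feature_matrix(ft, "six_metric", "month3")
  core <- grep("^miss_", colnames(fm6$x), invert = TRUE)
  expect_length(core, 60L)  # 12 features x 5 visit blocks
  fm2 <- build_feature_matrix(ft, "two_metric", "baseline")
  expect_identical(colnames(fm2$x),
                   c("ez_length_rate@baseline", "elm_length_rate@baseline"))
  fm4 <- build_feature_matrix(ft, "four_metric", "month1")
  expect_length(grep("^miss_", colnames(fm4$x), invert = TRUE), 30L)

  # identical visits -> zero deltas
  ft0 <- ft
  base <- ft[ft$visit == "baseline", ]
  for (f in biomarker_feature_names())
    ft0[[f]] <- base[[f]][match(ft0$eye_id, base$eye_id)]
  fmd <- build_feature_matrix(ft0, "six_metric", "month1")
  dcols <- grep("@d_", colnames(fmd$x))
  expect_true(all(fmd$x[, dcols] == 0))

  # missing visit is reported by eye id
  ft_bad <- ft[!(ft$eye_id == "eye003" & ft$visit == "month3"), ]
  expect_error(build_feature_matrix(ft_bad, "six_metric", "month3"), "eye003")
})

test_that("imputation of missing reflectivity adds indicator columns", {
  coh <- generate_cohort(12, seed = 4, render = FALSE)
  ft <- cohort_feature_table(coh)
  # cured eyes lose SHRM/PED by month 3 -> NA reflectivity -> indicators
  stopifnot(any(is.na(ft$ped_mean_intensity)))
  fm <- build_feature_matrix(ft, "six_metric", "month3")
  expect_true(any(grepl("^miss_", colnames(fm$x))))
  expect_false(any(is.na(fm$x)))
})

test_that("cross-validated forest recovers a planted single-feature rule", {
  pm <- planted_matrix()
  cfg <- forest_config(n_trees = 150, cv_folds = 5, seed = 9)
  rep <- fit_predict_cv(pm$x, pm$y, cfg)
  expect_gte(rep$accuracy, 0.9)
  expect_gt(rep$auc_macro, 0.95)
  expect_equal(sum(rep$importance), 1)
  expect_identical(rank_feature_importance(rep)$feature[1], "signal")
  # reproducible under the same seed
  rep2 <- fit_predict_cv(pm$x, pm$y, cfg)
  expect_identical(rep$oof_prob, rep2$oof_prob)
  expect_identical(rep$folds, rep2$folds)
})

test_that("grid search stays in [150, 800] and selects per fold", {
  pm <- planted_matrix(n = 60)
  cfg <- forest_config(trees_grid = c(150L, 200L), cv_folds = 3, seed = 2)
  rep <- fit_predict_cv(pm$x, pm$y, cfg)
  expect_true(all(rep$chosen_n_trees %in% c(150L, 200L)))
  expect_error(forest_config(trees_grid = c(100L, 200L)), "150")
  expect_error(forest_config(cv_folds = 1), "cv_folds")
})

test_that("degenerate inputs are rejected", {
  pm <- planted_matrix(n = 30)
  expect_error(fit_predict_cv(pm$x, rep(0L, 30),
                              forest_config(n_trees = 150, cv_folds = 3)),
               "single class")
  expect_error(fit_predict_cv(pm$x[1:4, ], pm$y[1:4],
                              forest_config(n_trees = 150, cv_folds = 10)),
               "fewer eyes")
  expect_error(rank_feature_importance(list()), "fitted")
})

test_that("pure-noise features get near-uniform importance", {
  set.seed(12)
  aucs <- ratios <- numeric(5)
  for (i in 1:5) {
    x <- matrix(runif(60 * 5), 60, dimnames = list(NULL, paste0("n", 1:5)))
    y <- sample(0:2, 60, replace = TRUE)
    rep <- fit_predict_cv(x, y, forest_config(n_trees = 150, cv_folds = 3,
                                              seed = i))
    ratios[i] <- max(rep$importance) / min(rep$importance)
    aucs[i] <- rep$auc_macro
  }
  expect_lt(max(ratios), 5)
  expect_true(all(aucs > 0.3 & aucs < 0.7))
})

test_that("one-vs-rest AUC matches the rank statistic", {
  s <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(FALSE, FALSE, TRUE, TRUE)
  # brute-force pair counting oracle
  pairs <- expand.grid(p = which(y), n = which(!y))
  oracle <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                        ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(s, y), oracle)
  expect_true(is.na(roc_auc(s, rep(TRUE, 4))))
})
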