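# Random-forest prediction of three-class one-year disease activity from
# longitudinal biomarker vectors.  CART trees (Gini impurity) with bagging
# and majority voting are implemented here directly; no forest package is
# assumed.  Model variants use the EZ/ELM pair (two-metric), the four
# lesion classes (four-metric) or all 12 features (six-metric), at the
# baseline / month-1 / month-3 horizons with signed later-minus-baseline
# deltas.

# ---- CART / forest internals -------------------------------------------

tree_grow <- function(X, y, K, mtry, max_depth = 25L, min_node = 2L) {
  p <- ncol(X)
  nodes <- list()
  importance <- numeric(p)
  n_total <- length(y)
  # stack of (node_id, rows, depth); children patched in after the fact
  new_node <- function() length(nodes) + 1L
  build <- function(rows, depth) {
    id <- new_node()
    nodes[[id]] <<- list(feat = 0L, thr = 0, left = 0L, right = 0L,
                         pred = 0L, n = length(rows))
    counts <- tabulate(y[rows], K)
    nodes[[id]]$pred <<- which.max(counts)
    gini_p <- 1 - sum((counts / length(rows))^2)
    if (depth >= max_depth || length(rows) < 2L * min_node || gini_p <= 0)
      return(id)
    best <- NULL
    for (j in sample.int(p, min(mtry, p))) {
      xv <- X[rows, j]
      ord <- order(xv, method = "radix")
      xs <- xv[ord]
      n <- length(xs)
      valid <- which(xs[-n] < xs[-1])
      valid <- valid[valid >= min_node & (n - valid) >= min_node]
      if (!length(valid)) next
      ys <- y[rows][ord]
      cl <- matrix(0, n, K)
      for (k in seq_len(K)) cl[, k] <- cumsum(ys == k)
      nl <- valid
      cnl <- cl[valid, , drop = FALSE]
      cnr <- matrix(cl[n, ], length(valid), K, byrow = TRUE) - cnl
      gl <- 1 - rowSums((cnl / nl)^2)
      gr <- 1 - rowSums((cnr / (n - nl))^2)
      w <- (nl * gl + (n - nl) * gr) / n
      b <- which.min(w)
      if (is.null(best) || w[b] < best$w) {
        best <- list(w = w[b], feat = j,
                     thr = (xs[valid[b]] + xs[valid[b] + 1L]) / 2,
                     decrease = gini_p - w[b])
      }
    }
    if (is.null(best) || best$decrease <= 1e-12) return(id)
    importance[best$feat] <<- importance[best$feat] +
      best$decrease * length(rows) / n_total
    sel <- X[rows, best$feat] <= best$thr
    lid <- build(rows[sel], depth + 1L)
    rid <- build(rows[!sel], depth + 1L)
    nodes[[id]]$feat <<- best$feat
    nodes[[id]]$thr <<- best$thr
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    id
  }
  build(seq_along(y), 0L)
  list(nodes = nodes, importance = importance)
}

tree_predict <- function(tree, X) {
  out <- integer(nrow(X))
  rec <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (nd$feat == 0L) { out[rows] <<- nd$pred; return(invisible()) }
    sel <- X[rows, nd$feat] <= nd$thr
    if (any(sel)) rec(nd$left, rows[sel])
    if (any(!sel)) rec(nd$right, rows[!sel])
  }
  if (nrow(X)) rec(1L, seq_len(nrow(X)))
  out
}

rf_fit <- function(X, y, n_trees, K = 3L, mtry = NULL, max_depth = 25L,
                   min_node = 2L) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- length(y)
  trees <- vector("list", n_trees)
  importance <- numeric(ncol(X))
  for (t in seq_len(n_trees)) {
    bi <- sample.int(n, n, replace = TRUE)
    tr <- tree_grow(X[bi, , drop = FALSE], y[bi], K, mtry, max_depth, min_node)
    trees[[t]] <- tr$nodes
    importance <- importance + tr$importance
  }
  list(trees = trees, importance = importance, K = K, mtry = mtry)
}

# n x T matrix of per-tree class predictions (for grid prefixes).
rf_predict_trees <- function(forest, X) {
  vapply(forest$trees, function(nodes)
    tree_predict(list(nodes = nodes), X), integer(nrow(X)))
}

votes_to_prob <- function(tree_preds, K) {
  if (is.null(dim(tree_preds))) tree_preds <- matrix(tree_preds, ncol = 1L)
  t(apply(tree_preds, 1, function(r) tabulate(r, K) / length(r)))
}

majority_vote <- function(prob) max.col(prob, ties.method = "first")

#' One-vs-rest ROC AUC
#'
#' Rank-based (Mann-Whitney) AUC of a score against a binary indicator.
#'
#' @param scores numeric scores
#' @param positive logical indicator
#' @return AUC in `[0,1]`, `NA` if a class is absent
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

macro_ovr_auc <- function(prob, y, K) {
  aucs <- vapply(seq_len(K), function(k) roc_auc(prob[, k], y == k), numeric(1))
  list(per_class = aucs, macro = mean(aucs, na.rm = TRUE))
}

# ---- feature matrix construction ---------------------------------------

variant_features <- function(variant) {
  switch(variant,
    two_metric = c("ez_length_rate", "elm_length_rate"),
    four_metric = setdiff(biomarker_feature_names(),
                          c("ez_length_rate", "elm_length_rate")),
    six_metric = biomarker_feature_names(),
    stop("unknown variant '", variant, "'", call. = FALSE))
}

horizon_blocks <- function(horizon) {
  switch(horizon,
    baseline = list(visits = "baseline", deltas = character(0)),
    month1 = list(visits = c("baseline", "month1"), deltas = "month1"),
    month3 = list(visits = c("baseline", "month1", "month3"),
                  deltas = c("month1", "month3")),
    stop("unknown horizon '", horizon, "'", call. = FALSE))
}

#' Build the design matrix for one variant x horizon model
#'
#' Column layout is deterministic: visit blocks in temporal order, then
#' delta blocks (signed later minus baseline), features in canonical order
#' within each block.  Missing reflectivity cells (empty SHRM/PED) are
#' imputed as 0 and flagged with an appended indicator column per affected
#' column.
#'
#' @param features_table long table from [cohort_feature_table()] (columns
#'   `eye_id`, `visit`, `label`, features)
#' @param variant `"two_metric"`, `"four_metric"` or `"six_metric"`
#' @param horizon `"baseline"`, `"month1"` or `"month3"`
#' @return list with `x` (numeric matrix), `y` (integer labels 0/1/2),
#'   `columns`, `eye_ids`
#' @export
build_feature_matrix <- function(features_table,
                                 variant = c("six_metric", "two_metric",
                                             "four_metric"),
                                 horizon = c("month3", "baseline", "month1")) {
  variant <- match.arg(variant)
  horizon <- match.arg(horizon)
  feats <- variant_features(variant)
  hb <- horizon_blocks(horizon)
  eyes <- unique(features_table$eye_id)
  need <- hb$visits
  have <- split(features_table$visit, features_table$eye_id)
  bad <- eyes[!vapply(eyes, function(e) all(need %in% have[[e]]), logical(1))]
  if (length(bad))
    stop("eyes missing required visits for horizon '", horizon, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  per_visit <- lapply(need, function(v) {
    sub <- features_table[features_table$visit == v, , drop = FALSE]
    m <- as.matrix(sub[match(eyes, sub$eye_id), feats, drop = FALSE])
    rownames(m) <- eyes
    m
  })
  names(per_visit) <- need
  miss <- lapply(per_visit, function(m) is.na(m))
  per_visit <- lapply(per_visit, function(m) { m[is.na(m)] <- 0; m })
  blocks <- list()
  for (v in need) {
    b <- per_visit[[v]]
    colnames(b) <- paste0(feats, "@", v)
    blocks[[length(blocks) + 1L]] <- b
  }
  for (v in hb$deltas) {
    b <- per_visit[[v]] - per_visit[["baseline"]]
    colnames(b) <- paste0(feats, "@d_", v)
    blocks[[length(blocks) + 1L]] <- b
  }
  x <- do.call(cbind, blocks)
  for (v in need) {
    mm <- miss[[v]]
    for (j in which(colSums(mm) > 0)) {
      ind <- as.numeric(mm[, j])
      x <- cbind(x, ind)
      colnames(x)[ncol(x)] <- paste0("miss_", feats[j], "@", v)
    }
  }
  lab <- features_table$label[match(eyes, features_table$eye_id)]
  list(x = x, y = as.integer(lab), columns = colnames(x), eye_ids = eyes)
}

# ---- cross-validated fitting -------------------------------------------

#' Forest configuration
#'
#' @param n_trees fixed number of trees, or `NULL` to grid-search
#'   `trees_grid` by inner-validation macro AUC within each training fold
#' @param trees_grid candidate tree counts (150..800 by 50)
#' @param cv_folds stratified outer folds (>= 2)
#' @param mtry features per split (default `floor(sqrt(p))`)
#' @param max_depth,min_node tree growth limits
#' @param inner_frac fraction of each training fold held out for the grid
#'   search
#' @param seed integer seed (controls folds, bagging and grid search)
#' @return a `forest_config` list
#' @export
forest_config <- function(n_trees = NULL, trees_grid = seq(150L, 800L, 50L),
                          cv_folds = 10L, mtry = NULL, max_depth = 25L,
                          min_node = 2L, inner_frac = 0.25, seed = 1L) {
  if (!is.null(n_trees) && n_trees < 1L) stop_field("n_trees", "must be >= 1")
  if (any(trees_grid < 150L) || any(trees_grid > 800L))
    stop_field("trees_grid", "grid must stay within [150, 800]")
  if (cv_folds < 2L) stop_field("cv_folds", "must be >= 2")
  structure(list(n_trees = n_trees, trees_grid = as.integer(trees_grid),
                 cv_folds = as.integer(cv_folds), mtry = mtry,
                 max_depth = as.integer(max_depth),
                 min_node = as.integer(min_node), inner_frac = inner_frac,
                 seed = as.integer(seed)),
            class = "forest_config")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated random-forest prediction of disease activity
#'
#' Stratified k-fold cross-validation; within each training fold the tree
#' count is optionally grid-searched on an inner stratified split (selection
#' by macro one-vs-rest AUC), then a forest is refit on the whole training
#' fold and its majority-vote predictions pooled out of fold.  Macro AUC is
#' the unweighted mean of one-vs-rest AUCs of the vote fractions; macro
#' sensitivity/specificity are unweighted means of the per-class one-vs-rest
#' values of the hard predictions.
#'
#' @param x numeric design matrix (eyes x columns)
#' @param y integer labels in `{0, 1, 2}`
#' @param config a [forest_config()]
#' @param column_names optional column names (defaults to `colnames(x)`)
#' @return a `pred_metrics_report`: list with `auc_macro`, `auc_per_class`,
#'   `accuracy`, `sensitivity_macro`, `specificity_macro`, `importance`
#'   (normalised, sums to 1), `oof_prob`, `oof_pred`, `folds`,
#'   `chosen_n_trees`
#' @export
fit_predict_cv <- function(x, y, config = forest_config(),
                           column_names = colnames(x)) {
  x <- as.matrix(x)
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("labels contain a single class; cannot fit", call. = FALSE)
  if (nrow(x) < config$cv_folds)
    stop("fewer eyes than cross-validation folds", call. = FALSE)
  K <- 3L
  y1 <- y + 1L  # internal 1-based classes
  with_seed(config$seed, {
    fold <- stratified_folds(y1, config$cv_folds)
    oof_prob <- matrix(NA_real_, nrow(x), K)
    importance <- numeric(ncol(x))
    chosen <- integer(config$cv_folds)
    for (f in seq_len(config$cv_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (!length(te)) next
      n_trees <- config$n_trees
      if (is.null(n_trees)) {
        grid <- config$trees_grid
        inner <- unlist(lapply(unique(y1[tr]), function(cls) {
          idx <- sample(tr[y1[tr] == cls])
          head(idx, max(1L, round(length(idx) * config$inner_frac)))
        }))
        itr <- setdiff(tr, inner)
        forest <- rf_fit(x[itr, , drop = FALSE], y1[itr], max(grid), K,
                         config$mtry, config$max_depth, config$min_node)
        preds <- rf_predict_trees(forest, x[inner, , drop = FALSE])
        score <- vapply(grid, function(g) {
          pr <- votes_to_prob(preds[, seq_len(g), drop = FALSE], K)
          macro_ovr_auc(pr, y1[inner], K)$macro
        }, numeric(1))
        n_trees <- grid[which.max(score)]
      }
      forest <- rf_fit(x[tr, , drop = FALSE], y1[tr], n_trees, K,
                       config$mtry, config$max_depth, config$min_node)
      preds <- rf_predict_trees(forest, x[te, , drop = FALSE])
      oof_prob[te, ] <- votes_to_prob(preds, K)
      importance <- importance + forest$importance
      chosen[f] <- n_trees
    }
    hard <- majority_vote(oof_prob) - 1L
    auc <- macro_ovr_auc(oof_prob, y1, K)
    sens <- vapply(classes, function(k)
      confusion_metrics(hard == k, y == k)[["sensitivity"]], numeric(1))
    spec <- vapply(classes, function(k)
      confusion_metrics(hard == k, y == k)[["specificity"]], numeric(1))
    if (sum(importance) > 0) importance <- importance / sum(importance)
    names(importance) <- if (is.null(column_names))
      paste0("x", seq_len(ncol(x))) else column_names
    structure(list(
      auc_macro = auc$macro, auc_per_class = auc$per_class,
      accuracy = mean(hard == y),
      sensitivity_macro = mean(sens, na.rm = TRUE),
      specificity_macro = mean(spec, na.rm = TRUE),
      importance = importance, oof_prob = oof_prob, oof_pred = hard,
      folds = fold, chosen_n_trees = chosen, config = config),
      class = "pred_metrics_report")
  })
}

#' Rank features by forest importance
#'
#' Impurity-decrease importances accumulated over the cross-validation
#' forests, normalised to sum to 1, sorted descending.
#'
#' @param report a `pred_metrics_report` from [fit_predict_cv()]
#' @param top_k number of features to report
#' @return data.frame `(feature, importance)`
#' @export
rank_feature_importance <- function(report, top_k = 24L) {
  if (!inherits(report, "pred_metrics_report") || is.null(report$importance))
    stop("need a fitted pred_metrics_report", call. = FALSE)
  imp <- sort(report$importance, decreasing = TRUE)
  data.frame(feature = names(imp), importance = as.numeric(imp),
             row.names = NULL)[seq_len(min(top_k, length(imp))), ]
}

#' Fit all variant x horizon models on one cohort
#'
#' Runs [fit_predict_cv()] for the 3 x 3 grid of feature-set variants and
#' horizons with a shared seed, so the fold assignment is identical across
#' variants and comparisons are paired.
#'
#' @param features_table long table from [cohort_feature_table()]
#' @param config a [forest_config()]
#' @param variants,horizons subsets of the 3 x 3 grid
#' @return list with `summary` (data.frame: variant, horizon, auc_macro,
#'   accuracy, sensitivity, specificity) and `reports` (named list)
#' @export
compare_variants <- function(features_table, config = forest_config(),
                             variants = c("two_metric", "four_metric",
                                          "six_metric"),
                             horizons = c("baseline", "month1", "month3")) {
  reports <- list()
  rows <- list()
  for (h in horizons) for (v in variants) {
    fm <- build_feature_matrix(features_table, v, h)
    rep <- fit_predict_cv(fm$x, fm$y, config, fm$columns)
    key <- paste(v, h, sep = ".")
    reports[[key]] <- rep
    rows[[key]] <- data.frame(variant = v, horizon = h,
                              auc_macro = rep$auc_macro,
                              accuracy = rep$accuracy,
                              sensitivity = rep$sensitivity_macro,
                              specificity = rep$specificity_macro)
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       reports = reports)
}
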