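# Segmentation / detection performance metrics, bootstrap CIs, the AVG
# aggregation used in the headline performance table, and cohort accounting.

#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`.  Defined as 1 when both masks are empty
#' (perfect agreement on absence).
#'
#' @param pred_mask,true_mask logical/0-1 arrays of identical shape
#' @return value in `[0, 1]`
#' @export
dice <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask)) ||
      length(pred_mask) != length(true_mask))
    stop("mask shapes differ", call. = FALSE)
  a <- pred_mask != 0; b <- true_mask != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Accuracy, sensitivity and specificity of a binary prediction
#'
#' `accuracy = (TP+TN)/N`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`.  An undefined denominator (no positives /
#' no negatives in the truth) yields `NA` for that entry.
#'
#' @param pred,truth logical/0-1 vectors of equal length (pixels for the
#'   blocky lesions, clips for EZ/ELM)
#' @return named numeric `(accuracy, sensitivity, specificity)`
#' @export
confusion_metrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("prediction and truth lengths differ", call. = FALSE)
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t); tn <- sum(!p & !t)
  fp <- sum(p & !t); fn <- sum(!p & t)
  c(accuracy = (tp + tn) / length(p),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Percentile bootstrap confidence interval of a mean over scans
#'
#' Resamples per-scan metric values with replacement and returns the
#' `alpha/2` and `1 - alpha/2` percentiles of the resampled means.
#'
#' @param samples numeric vector of per-scan metric values (>= 1)
#' @param n_boot number of bootstrap resamples
#' @param alpha two-sided level (0.05 for a 95% CI)
#' @param seed integer seed
#' @return numeric `(low, high)`
#' @export
bootstrap_ci <- function(samples, n_boot = 2000L, alpha = 0.05, seed = 1L) {
  samples <- samples[!is.na(samples)]
  if (!length(samples)) stop("no samples for bootstrap", call. = FALSE)
  with_seed(seed, {
    n <- length(samples)
    means <- vapply(seq_len(n_boot), function(i)
      mean(samples[sample.int(n, n, replace = TRUE)]), numeric(1))
    stats::setNames(as.numeric(quantile(means, c(alpha / 2, 1 - alpha / 2))),
                    c("low", "high"))
  })
}

#' Arithmetic mean across biomarkers (the AVG column)
#'
#' @param per_biomarker_values numeric vector of per-biomarker metric
#'   values (NA cells, e.g. dice for the linear layers, are dropped)
#' @param digits decimals of the reported mean (3, matching the reported
#'   precision)
#' @return rounded arithmetic mean
#' @export
aggregate_average <- function(per_biomarker_values, digits = 3L) {
  v <- per_biomarker_values[!is.na(per_biomarker_values)]
  if (!length(v)) stop("no values to aggregate", call. = FALSE)
  round(mean(v), digits)
}

#' Class proportions of prognosis labels, in percent
#'
#' @param labels vector of class labels, or a named/plain vector of counts
#'   when `counts = TRUE`
#' @param counts interpret `labels` as per-class counts
#' @param digits decimals (2, matching the reported precision)
#' @return numeric percentages summing to ~100
#' @export
class_proportions <- function(labels, counts = FALSE, digits = 2L) {
  if (counts) n <- as.numeric(labels)
  else {
    if (!length(labels)) stop("empty label vector", call. = FALSE)
    n <- as.numeric(table(factor(labels, levels = sort(unique(labels)))))
  }
  if (!length(n) || sum(n) == 0) stop("no observations", call. = FALSE)
  round(100 * n / sum(n), digits)
}

#' Share of scans contributed by one visit, in percent
#'
#' Cohort accounting helper: `100 * counts[visit] / sum(counts)` at one
#' decimal, e.g. the month-3 share of all annotated scans.
#'
#' @param visit_counts numeric vector of per-visit scan counts
#' @param visit index or name of the visit
#' @param digits decimals
#' @return percentage
#' @export
visit_share <- function(visit_counts, visit, digits = 1L) {
  if (!length(visit_counts) || sum(visit_counts) <= 0)
    stop("invalid visit counts", call. = FALSE)
  round(100 * visit_counts[[visit]] / sum(visit_counts), digits)
}

#' Per-biomarker segmentation/detection report with bootstrap CIs
#'
#' Builds the standard performance table: rows accuracy, sensitivity,
#' specificity, dice; columns IRF, SRF, SHRM, PED, EZ, ELM and AVG.  Blocky
#' lesion metrics are computed per scan at pixel level, layer metrics at
#' clip level; dice is not defined for the linear layers (N/A, as in the
#' source table).  Point estimates are means over scans; CIs are percentile
#' bootstrap over scans.
#'
#' @param pred_masks,true_masks lists of label matrices (codes 0..4)
#' @param pred_layers,true_layers lists with elements `ez` and `elm`, each a
#'   list of per-clip logical vectors (one per scan); may be `NULL` to skip
#'   the layer columns
#' @param n_boot,alpha,seed bootstrap settings
#' @return a `seg_metrics_report`: list with `table` (data.frame of points),
#'   `ci` (low/high arrays)
#' @export
segmentation_report <- function(pred_masks, true_masks, pred_layers = NULL,
                                true_layers = NULL, n_boot = 1000L,
                                alpha = 0.05, seed = 1L) {
  if (length(pred_masks) != length(true_masks))
    stop("prediction and truth lists differ in length", call. = FALSE)
  biomarkers <- c(LESION_CLASSES, if (!is.null(pred_layers)) LAYER_CLASSES)
  metrics <- c("accuracy", "sensitivity", "specificity", "dice")
  per_scan <- list()
  for (bm in biomarkers) {
    if (bm %in% LESION_CLASSES) {
      id <- LESION_LEVELS[[bm]]
      vals <- t(vapply(seq_along(pred_masks), function(i) {
        p <- as_label_mask(pred_masks[[i]]) == id
        t <- as_label_mask(true_masks[[i]]) == id
        c(confusion_metrics(p, t), dice = dice(p, t))
      }, numeric(4)))
    } else {
      key <- tolower(bm)
      vals <- t(vapply(seq_along(pred_layers[[key]]), function(i) {
        p <- as.logical(pred_layers[[key]][[i]])
        t <- as.logical(true_layers[[key]][[i]])
        c(confusion_metrics(p, t), dice = NA_real_)
      }, numeric(4)))
    }
    colnames(vals) <- metrics
    per_scan[[bm]] <- vals
  }
  point <- sapply(per_scan, function(v) colMeans(v, na.rm = TRUE))
  point["dice", !colnames(point) %in% LESION_CLASSES] <- NA_real_
  lo <- hi <- point
  k <- 0L
  for (bm in colnames(point)) for (me in metrics) {
    k <- k + 1L
    if (is.na(point[me, bm]) || all(is.na(per_scan[[bm]][, me]))) {
      lo[me, bm] <- hi[me, bm] <- NA_real_
    } else {
      ci <- bootstrap_ci(per_scan[[bm]][, me], n_boot, alpha,
                         seed = child_seed(seed, k))
      lo[me, bm] <- ci[["low"]]; hi[me, bm] <- ci[["high"]]
    }
  }
  avg <- apply(point, 1, function(r) aggregate_average(r))
  tab <- as.data.frame(cbind(point, AVG = avg))
  structure(list(table = tab, ci = list(low = lo, high = hi),
                 per_scan = per_scan),
            class = "seg_metrics_report")
}

#' Write a segmentation report as CSV (table layout) and JSON
#'
#' @param report a `seg_metrics_report`
#' @param csv_path,json_path output paths (`NULL` to skip either)
#' @return invisibly, the rendered character table
#' @export
write_segmentation_report <- function(report, csv_path = NULL,
                                      json_path = NULL) {
  tab <- report$table
  rendered <- tab
  for (j in seq_along(rendered)) {
    col <- colnames(tab)[j]
    rendered[[j]] <- vapply(rownames(tab), function(me) {
      pt <- tab[me, j]
      if (is.na(pt)) return("N/A")
      if (col == "AVG") sprintf("%.3f", pt)
      else sprintf("%.3f (%.3f-%.3f)", pt, report$ci$low[me, col],
                   report$ci$high[me, col])
    }, character(1))
  }
  if (!is.null(csv_path)) write.csv(rendered, csv_path)
  if (!is.null(json_path))
    jsonlite::write_json(list(point = tab,
                              ci_low = as.data.frame(report$ci$low),
                              ci_high = as.data.frame(report$ci$high)),
                         json_path, dataframe = "columns", na = "null",
                         digits = NA, pretty = TRUE)
  invisible(rendered)
}
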