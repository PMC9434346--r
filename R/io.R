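# File interfaces: 8-bit grayscale PNG for scans, indexed-by-value PNG for
# masks (pixel value = class code 0..4), CSV for traces and feature tables,
# YAML for configs, RDS for model checkpoints (runtime artifacts).

#' Read / write B-scan images and label masks as PNG
#'
#' Scans are written as 8-bit grayscale (intensities in `[0,1]` scaled to
#' 0..255); masks store the class code directly in the 8-bit channel
#' (0=background, 1=IRF, 2=SRF, 3=SHRM, 4=PED).
#'
#' @param img numeric matrix in `[0,1]`
#' @param mask integer label matrix
#' @param path file path
#' @name png_io
#' @export
write_scan_png <- function(img, path) {
  png::writePNG(clamp(unclass(img), 0, 1), path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_scan_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

#' @rdname png_io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(unclass(mask) / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Write / read EZ and ELM traces as CSV
#'
#' One row per image column: `col, ez_row, elm_row` (`NA` inside gaps).
#'
#' @param annotation annotation list with the two traces
#' @param path file path
#' @name trace_io
#' @export
write_traces_csv <- function(annotation, path) {
  df <- data.frame(col = seq_along(annotation$ez_trace),
                   ez_row = annotation$ez_trace,
                   elm_row = annotation$elm_trace)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_traces_csv <- function(path) {
  df <- read.csv(path)
  list(ez_trace = as.numeric(df$ez_row), elm_trace = as.numeric(df$elm_row))
}

#' Save / load a trained model handle
#'
#' Single-file checkpoint (weights + config), a runtime artifact.
#'
#' @param model a `clip_cnn` or `lesion_fcn`
#' @param path file path
#' @name checkpoint_io
#' @export
save_model <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname checkpoint_io
#' @export
load_model <- function(path) readRDS(path)

#' Write a long feature table as CSV (units are in the column names)
#'
#' @param features_table data.frame from [cohort_feature_table()] or
#'   assembled per scan
#' @param path file path
#' @export
write_feature_table <- function(features_table, path) {
  write.csv(features_table, path, row.names = FALSE)
  invisible(path)
}
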