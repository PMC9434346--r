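# ROI cropping, resizing, min-max normalisation and training augmentation.

# Bilinear resize via two sparse-ish interpolation matrices (rows then
# columns).  Half-pixel-centre coordinate convention.
interp_weights <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pos <- clamp(pos, 0, n_in - 1)
  lo <- floor(pos)
  frac <- pos - lo
  hi <- pmin(lo + 1, n_in - 1)
  Wm <- matrix(0, n_out, n_in)
  Wm[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
  Wm[cbind(seq_len(n_out), hi + 1)] <-
    Wm[cbind(seq_len(n_out), hi + 1)] + frac
  Wm
}

resize_bilinear <- function(img, h_out, w_out) {
  Rw <- interp_weights(nrow(img), h_out)
  Cw <- interp_weights(ncol(img), w_out)
  Rw %*% img %*% t(Cw)
}

nearest_index <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  clamp(round(pos), 0, n_in - 1) + 1L
}

resize_nearest <- function(img, h_out, w_out) {
  img[nearest_index(nrow(img), h_out), nearest_index(ncol(img), w_out),
      drop = FALSE]
}

#' Crop a region of interest and resize to the working geometry
#'
#' Crops `roi` from a raw scan and reshapes it (bilinear) to
#' `target_height x target_width`.  The defaults reproduce the working
#' resolution of 256 x 1600; aspect distortion is accepted (e.g. a raw
#' 1920 x 1080 frame is reshaped directly).
#'
#' @param raw numeric matrix (rows = depth, cols = lateral position)
#' @param roi `"auto"` (full frame) or `c(row0, row1, col0, col1)`,
#'   1-based inclusive
#' @param target_height,target_width output size; width must be divisible
#'   by 16 so the result can be clip-sliced
#' @param pixel_size_mm pixel size attached to the output
#' @return matrix of the requested size with attribute `pixel_size_mm`
#' @export
crop_and_resize <- function(raw, roi = "auto", target_height = 256L,
                            target_width = 1600L, pixel_size_mm = 8 / 1600) {
  raw <- check_matrix_image(raw, "raw")
  if (target_width %% 16L != 0L)
    stop_field("target_width", "must be divisible by 16")
  if (identical(roi, "auto")) roi <- c(1L, nrow(raw), 1L, ncol(raw))
  if (length(roi) != 4L || any(!is.finite(roi)))
    stop_field("roi", "must be \"auto\" or c(row0, row1, col0, col1)")
  roi <- as.integer(roi)
  if (roi[1] < 1L || roi[3] < 1L || roi[2] > nrow(raw) || roi[4] > ncol(raw) ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop_field("roi", "outside the raw image bounds")
  out <- resize_bilinear(raw[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE],
                         target_height, target_width)
  attr(out, "pixel_size_mm") <- pixel_size_mm
  out
}

#' Min-max normalise an image to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant image maps to all zeros with a
#' warning.  Idempotent on non-constant input.
#'
#' @param img numeric matrix
#' @return matrix in `[0, 1]`, attributes preserved
#' @export
minmax_normalize <- function(img) {
  x <- check_matrix_image(img)
  rng <- range(x)
  at <- attributes(img)
  if (rng[1] == rng[2]) {
    warning("constant image: min-max normalisation returns all zeros",
            call. = FALSE)
    out <- matrix(0, nrow(x), ncol(x))
  } else {
    out <- (x - rng[1]) / (rng[2] - rng[1])
  }
  if (!is.null(at$pixel_size_mm)) attr(out, "pixel_size_mm") <- at$pixel_size_mm
  out
}

#' Training-time augmentation of an image / mask / trace triple
#'
#' Applies, under one seeded draw: a horizontal flip with probability
#' `flip_p`; a random crop at scale in `[crop_scale_min, 1]` resized back to
#' the original geometry (bilinear for intensities, nearest-neighbour for
#' the label mask so the label alphabet is preserved); and an additive
#' intensity shift in `[-shift_max, shift_max]` clipped to `[0, 1]`.  The
#' identical geometric transform is applied to the mask and to the EZ/ELM
#' traces (trace rows are remapped and rounded; columns that leave the crop
#' become `NA`).
#'
#' @param img numeric matrix in `[0,1]`
#' @param mask integer label matrix, same shape (or `NULL`)
#' @param traces named list of per-column traces (or `NULL`)
#' @param seed integer seed
#' @param flip_p,crop_scale_min,shift_max augmentation magnitudes
#' @return list `(image, mask, traces)`
#' @export
augment <- function(img, mask = NULL, traces = NULL, seed = 1L,
                    flip_p = 0.5, crop_scale_min = 0.9, shift_max = 0.1) {
  img <- check_matrix_image(img)
  H <- nrow(img); W <- ncol(img)
  if (!is.null(mask) && !all(dim(mask) == c(H, W)))
    stop("mask shape does not match image", call. = FALSE)
  if (!is.null(traces) && any(vapply(traces, length, integer(1)) != W))
    stop("trace length does not match image width", call. = FALSE)
  with_seed(seed, {
    do_flip <- runif(1) < flip_p
    scale <- runif(1, crop_scale_min, 1)
    hc <- max(2L, round(H * scale)); wc <- max(2L, round(W * scale))
    r0 <- sample.int(H - hc + 1L, 1L); c0 <- sample.int(W - wc + 1L, 1L)
    shift <- runif(1, -shift_max, shift_max)
    if (do_flip) {
      img <- img[, W:1, drop = FALSE]
      if (!is.null(mask)) mask <- mask[, W:1, drop = FALSE]
      if (!is.null(traces)) traces <- lapply(traces, rev)
    }
    rows <- r0:(r0 + hc - 1L); cols <- c0:(c0 + wc - 1L)
    out_img <- clamp(resize_bilinear(img[rows, cols, drop = FALSE], H, W) +
                       shift, 0, 1)
    out_mask <- if (is.null(mask)) NULL
      else resize_nearest(mask[rows, cols, drop = FALSE], H, W)
    out_traces <- if (is.null(traces)) NULL else lapply(traces, function(tr) {
      src_col <- nearest_index(wc, W) + c0 - 1L
      v <- tr[src_col]
      # rows remap with the vertical crop scale (same convention as bilinear)
      v <- round((v - r0 + 0.5) * H / hc - 0.5)
      v[!is.na(v) & (v < 1 | v > H)] <- NA_real_
      v
    })
    list(image = out_img, mask = out_mask, traces = out_traces)
  })
}
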