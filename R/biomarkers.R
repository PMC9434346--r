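# Quantification: detections and segmentations -> the 12-feature biomarker
# vector (length rates, areas, maximum diameters, mean reflectivity).

#' Layer length rate from a per-clip presence vector
#'
#' The proportion of 16-px clips in which the layer was detected — the
#' clip-resolution integrity measure of EZ/ELM.
#'
#' @param presence logical vector (or a `layer_detection` object)
#' @return fraction in `[0, 1]`
#' @export
layer_length_rate <- function(presence) {
  if (inherits(presence, "layer_detection")) presence <- presence$presence
  if (!length(presence)) stop("empty presence vector", call. = FALSE)
  mean(as.logical(presence))
}

as_label_mask <- function(mask) {
  if (inherits(mask, "lesion_segmentation")) mask <- mask$labels
  if (is.list(mask) && !is.null(mask$lesion_mask)) mask <- mask$lesion_mask
  if (!is.matrix(mask)) stop("mask must be a label matrix", call. = FALSE)
  mask
}

#' Lesion area in mm^2
#'
#' Pixel count of the class (summed over all connected components) times
#' the squared pixel size.
#'
#' @param mask label matrix, `lesion_segmentation`, or annotation list
#' @param lesion_class one of `"IRF"`, `"SRF"`, `"SHRM"`, `"PED"`
#' @param pixel_size_mm isotropic pixel size in mm
#' @return area in mm^2 (0 for an absent class)
#' @export
region_area <- function(mask, lesion_class, pixel_size_mm) {
  mask <- as_label_mask(mask)
  cls <- match_lesion_class(lesion_class)
  mask_area_px(mask, LESION_LEVELS[[cls]]) * pixel_size_mm^2
}

#' Maximum lesion diameter in mm
#'
#' The maximum horizontal (column-wise) extent over the 4-connected
#' components of the class — the basal diameter convention for lesions on a
#' B-scan.  0 for an absent class.
#'
#' @inheritParams region_area
#' @return length in mm
#' @export
region_max_diameter <- function(mask, lesion_class, pixel_size_mm) {
  mask <- as_label_mask(mask)
  cls <- match_lesion_class(lesion_class)
  mask_max_diameter_px(mask, LESION_LEVELS[[cls]]) * pixel_size_mm
}

#' Mean reflectivity of SHRM or PED
#'
#' Mean of the (normalised) image intensity over the class pixels; `NA`
#' (missing flag) when the class is empty.  Only defined for the two
#' hyperreflective classes.
#'
#' @param img B-scan matrix (min-max normalised)
#' @param mask label matrix / segmentation / annotation
#' @param lesion_class `"SHRM"` or `"PED"`
#' @return mean intensity, or `NA_real_`
#' @export
region_mean_intensity <- function(img, mask, lesion_class) {
  cls <- match_lesion_class(lesion_class)
  if (!cls %in% c("SHRM", "PED"))
    stop("mean intensity is only quantified for SHRM and PED", call. = FALSE)
  img <- check_matrix_image(img)
  mask <- as_label_mask(mask)
  if (!all(dim(img) == dim(mask)))
    stop("image and mask geometries differ", call. = FALSE)
  mask_mean_intensity(img, mask, LESION_LEVELS[[cls]])
}

#' Assemble the 12-feature biomarker vector of one scan
#'
#' @param img B-scan matrix
#' @param segmentation label matrix / `lesion_segmentation` / annotation
#' @param detection_ez,detection_elm per-clip presence vectors or
#'   `layer_detection` objects
#' @param pixel_size_mm isotropic pixel size in mm; defaults to the image's
#'   `pixel_size_mm` attribute
#' @return named numeric vector, see [biomarker_feature_names()]; the two
#'   intensity features are `NA` when their class is absent
#' @export
extract_biomarkers <- function(img, segmentation, detection_ez, detection_elm,
                               pixel_size_mm = NULL) {
  img <- check_matrix_image(img)
  mask <- as_label_mask(segmentation)
  if (!all(dim(img) == dim(mask)))
    stop("image and segmentation geometries differ", call. = FALSE)
  if (is.null(pixel_size_mm)) pixel_size_mm <- attr(img, "pixel_size_mm")
  if (is.null(pixel_size_mm)) stop("pixel_size_mm is required", call. = FALSE)
  f <- c(ez_length_rate = layer_length_rate(detection_ez),
         elm_length_rate = layer_length_rate(detection_elm))
  for (cls in LESION_CLASSES) {
    f[[paste0(tolower(cls), "_area_mm2")]] <-
      region_area(mask, cls, pixel_size_mm)
    f[[paste0(tolower(cls), "_max_diameter_mm")]] <-
      region_max_diameter(mask, cls, pixel_size_mm)
  }
  f[["shrm_mean_intensity"]] <- region_mean_intensity(img, mask, "SHRM")
  f[["ped_mean_intensity"]] <- region_mean_intensity(img, mask, "PED")
  f[biomarker_feature_names()]
}

#' Biomarkers of a scan from its ground-truth annotation
#'
#' Convenience wrapper: clip labels from the traces serve as the presence
#' vectors and the annotation mask as the segmentation, i.e. quantification
#' with a perfect upstream stage.
#'
#' @param scene a scene as returned by [generate_scene()] (or a list with
#'   `image` and `annotation`)
#' @return named numeric vector of the 12 features
#' @export
quantify_annotation <- function(scene) {
  ann <- scene$annotation
  no_image <- is.null(scene$image)
  img <- if (no_image) matrix(0, nrow(ann$lesion_mask), ncol(ann$lesion_mask))
         else scene$image
  ps <- attr(scene$image, "pixel_size_mm")
  if (is.null(ps)) ps <- 8 / 1600
  f <- extract_biomarkers(img, ann$lesion_mask,
                          clip_labels(ann, "ez"), clip_labels(ann, "elm"),
                          pixel_size_mm = ps)
  if (no_image)  # reflectivity is undefined without the rendered image
    f[c("shrm_mean_intensity", "ped_mean_intensity")] <- NA_real_
  f
}
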