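#' Construct a lesion specification
#'
#' One lesion to be rasterised into a synthetic B-scan.  IRF/SRF/SHRM are
#' ellipses; PED is a dome sitting on the RPE band.
#'
#' @param class one of `"IRF"`, `"SRF"`, `"SHRM"`, `"PED"`
#' @param shape `"ellipse"` or `"dome"`
#' @param center numeric `(row, col)` in pixels (for a dome the row is
#'   ignored: its base is the top of the RPE band)
#' @param axes numeric `(semi_axis_rows, semi_axis_cols)` in pixels, both > 0
#' @param intensity reflectivity in `[0, 1]` painted inside the lesion
#' @return a `lesion_spec` list
#' @export
lesion_spec <- function(class, shape = c("ellipse", "dome"), center, axes,
                        intensity) {
  class <- match_lesion_class(class)
  shape <- match.arg(shape)
  if (length(axes) != 2L || any(!is.finite(axes)) || any(axes <= 0))
    stop_field("axes", "must be two positive numbers")
  if (length(center) != 2L || any(!is.finite(center)))
    stop_field("center", "must be (row, col)")
  if (!is.finite(intensity) || intensity < 0 || intensity > 1)
    stop_field("intensity", "must be in [0, 1]")
  structure(list(class = class, shape = shape, center = as.numeric(center),
                 axes = as.numeric(axes), intensity = as.numeric(intensity)),
            class = "lesion_spec")
}

#' Specification of one synthetic B-scan scene
#'
#' Describes a layered retina: dark vitreous above `retina_top`, a medium
#' reflectivity neuroretina, a bright RPE band ending at `retina_bottom`, a
#' dim choroid below, thin bright EZ and ELM lines with seeded contiguous
#' gaps, and a list of lesions.  Defaults give a 256 x 1600 scan at
#' 0.005 mm/px (so 1600 px span 8 mm, the radial macula line length); pass
#' `image_height = 128, image_width = 512` for the desk-scale profile used
#' in the tests.
#'
#' @param image_height,image_width pixels; width must be divisible by 16
#'   (the clip width used by the layer detector)
#' @param retina_top,retina_bottom first/last row of the retinal slab
#' @param ez_row,elm_row rows of the two photoreceptor lines; must lie in
#'   `[retina_top, retina_bottom]`
#' @param ez_gap_fraction,elm_gap_fraction fraction of the width over which
#'   each line is absent (one contiguous seeded interval), in `[0, 1]`
#' @param lesion_specs list of [lesion_spec()]; `NULL` gives one default
#'   lesion of each class, scaled to the image
#' @param speckle_sigma multiplicative speckle scale (>= 0)
#' @param pixel_size_mm isotropic pixel size in mm
#' @param line_px thickness of the EZ/ELM lines in pixels
#' @return a `scene_spec` list, validated
#' @export
scene_spec <- function(image_height = 256L, image_width = 1600L,
                       retina_top = NULL, retina_bottom = NULL,
                       ez_row = NULL, elm_row = NULL,
                       ez_gap_fraction = 0.3, elm_gap_fraction = 0.2,
                       lesion_specs = NULL, speckle_sigma = 0.08,
                       pixel_size_mm = 8 / 1600, line_px = NULL) {
  H <- as.integer(image_height); W <- as.integer(image_width)
  if (is.na(H) || H < 32L) stop_field("image_height", "must be >= 32")
  if (is.na(W) || W < 32L) stop_field("image_width", "must be >= 32")
  if (W %% 16L != 0L) stop_field("image_width", "must be divisible by 16")
  if (is.null(retina_top)) retina_top <- round(0.25 * H)
  if (is.null(retina_bottom)) retina_bottom <- round(0.82 * H)
  if (!(retina_top >= 1 && retina_top < retina_bottom && retina_bottom <= H))
    stop_field("retina_top", "need 1 <= retina_top < retina_bottom <= height")
  if (is.null(elm_row)) elm_row <- retina_bottom - round(0.14 * H)
  if (is.null(ez_row)) ez_row <- retina_bottom - round(0.09 * H)
  for (nm in c("ez_row", "elm_row")) {
    v <- get(nm)
    if (v < retina_top || v > retina_bottom)
      stop_field(nm, "must lie inside [retina_top, retina_bottom]")
  }
  for (nm in c("ez_gap_fraction", "elm_gap_fraction")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) stop_field(nm, "must be in [0, 1]")
  }
  if (!is.finite(speckle_sigma) || speckle_sigma < 0)
    stop_field("speckle_sigma", "must be >= 0")
  if (!is.finite(pixel_size_mm) || pixel_size_mm <= 0)
    stop_field("pixel_size_mm", "must be > 0")
  if (is.null(line_px)) line_px <- max(1L, round(H / 128))
  rpe_band <- max(2L, round(0.03 * H))
  rpe_top <- retina_bottom - rpe_band + 1L
  if (is.null(lesion_specs)) {
    lesion_specs <- list(
      lesion_spec("PED", "dome", c(rpe_top, 0.40 * W),
                  c(0.10 * H, 0.09 * W), 0.68),
      lesion_spec("SHRM", "ellipse", c(rpe_top - 0.035 * H, 0.78 * W),
                  c(0.03 * H, 0.05 * W), 0.82),
      lesion_spec("SRF", "ellipse", c(rpe_top - 0.05 * H, 0.60 * W),
                  c(0.04 * H, 0.08 * W), 0.08),
      lesion_spec("IRF", "ellipse",
                  c(retina_top + 0.35 * (elm_row - retina_top), 0.30 * W),
                  c(0.05 * H, 0.05 * W), 0.08))
  }
  if (!is.list(lesion_specs) ||
      !all(vapply(lesion_specs, inherits, logical(1), "lesion_spec")))
    stop_field("lesion_specs", "must be a list of lesion_spec objects")
  structure(list(
    image_height = H, image_width = W,
    retina_top = as.integer(retina_top), retina_bottom = as.integer(retina_bottom),
    rpe_top = as.integer(rpe_top), ez_row = as.integer(ez_row),
    elm_row = as.integer(elm_row),
    ez_gap_fraction = ez_gap_fraction, elm_gap_fraction = elm_gap_fraction,
    lesion_specs = lesion_specs, speckle_sigma = speckle_sigma,
    pixel_size_mm = pixel_size_mm, line_px = as.integer(line_px)),
    class = "scene_spec")
}

# Rasterise one lesion; returns logical matrix of covered pixels.
rasterize_lesion <- function(ls, spec) {
  H <- spec$image_height; W <- spec$image_width
  r0 <- ls$center[1]; c0 <- ls$center[2]
  ar <- ls$axes[1]; ac <- ls$axes[2]
  m <- matrix(FALSE, H, W)
  if (ls$shape == "dome") {
    base <- spec$rpe_top  # dome sits on top of the RPE band
    cols <- max(1L, ceiling(c0 - ac)):min(W, floor(c0 + ac))
    for (cc in cols) {
      h <- ar * sqrt(max(0, 1 - ((cc - c0) / ac)^2))
      if (h < 1) next
      top <- max(1L, ceiling(base - h))
      if (top <= base - 1L) m[top:(base - 1L), cc] <- TRUE
    }
  } else {
    rows <- max(1L, ceiling(r0 - ar)):min(H, floor(r0 + ar))
    cols <- max(1L, ceiling(c0 - ac)):min(W, floor(c0 + ac))
    rr <- ((rows - r0) / ar)^2
    cc <- ((cols - c0) / ac)^2
    m[rows, cols] <- outer(rr, cc, `+`) <= 1
  }
  m
}

# Core raster measurements shared with the quantification module.
mask_area_px <- function(mask, class_id) sum(mask == class_id)

mask_max_diameter_px <- function(mask, class_id) {
  comps <- label_components(mask == class_id)
  if (!length(comps)) return(0)
  max(vapply(comps, function(px) diff(range(px[, "col"])) + 1L, integer(1)))
}

mask_mean_intensity <- function(img, mask, class_id) {
  sel <- mask == class_id
  if (!any(sel)) return(NA_real_)
  mean(img[sel])
}

# Clip-resolution length rate of a trace (any annotated column makes the
# clip count as present) -- the same rule the detector labels use.
trace_length_rate <- function(trace, clip_width = 16L) {
  n_clips <- length(trace) %/% clip_width
  present <- vapply(seq_len(n_clips), function(k) {
    any(!is.na(trace[((k - 1L) * clip_width + 1L):(k * clip_width)]))
  }, logical(1))
  mean(present)
}

measure_ground_truth <- function(img, mask, ez_trace, elm_trace, pixel_size_mm) {
  s <- pixel_size_mm
  f <- c(
    ez_length_rate  = trace_length_rate(ez_trace),
    elm_length_rate = trace_length_rate(elm_trace))
  for (cls in LESION_CLASSES) {
    id <- LESION_LEVELS[[cls]]
    f[[paste0(tolower(cls), "_area_mm2")]] <- mask_area_px(mask, id) * s^2
    f[[paste0(tolower(cls), "_max_diameter_mm")]] <- mask_max_diameter_px(mask, id) * s
  }
  f[["shrm_mean_intensity"]] <- mask_mean_intensity(img, mask, LESION_LEVELS[["SHRM"]])
  f[["ped_mean_intensity"]] <- mask_mean_intensity(img, mask, LESION_LEVELS[["PED"]])
  f[biomarker_feature_names()]
}

#' Render one synthetic B-scan with analytic ground truth
#'
#' Rasterises the layered retina described by a [scene_spec()]: lesions are
#' painted (PED, SHRM, SRF, IRF order, so a later class wins ties), the EZ
#' and ELM lines are drawn on top with one contiguous seeded gap each, then
#' multiplicative Gaussian speckle `x * (1 + sigma * eps)` is applied and
#' intensities clipped to `[0, 1]`.  Ground-truth biomarkers are measured on
#' the noise-free rasterisation, so quantification on the emitted annotation
#' reproduces them exactly.
#'
#' @param spec a [scene_spec()]
#' @param seed integer seed; the same `(spec, seed)` gives a bit-identical
#'   scene
#' @return list with `image` (H x W matrix in `[0,1]` with attribute
#'   `pixel_size_mm`), `annotation` (list `lesion_mask` integer matrix coded
#'   0=background 1=IRF 2=SRF 3=SHRM 4=PED; `ez_trace`, `elm_trace` numeric
#'   per-column row index, `NA` inside gaps), and `features` (named numeric,
#'   see [biomarker_feature_names()])
#' @export
generate_scene <- function(spec, seed = 1L) {
  if (!inherits(spec, "scene_spec")) spec <- do.call(scene_spec, spec)
  with_seed(seed, {
    H <- spec$image_height; W <- spec$image_width
    img <- matrix(0.05, H, W)                      # vitreous
    img[spec$retina_top:spec$retina_bottom, ] <- 0.45   # neuroretina
    img[spec$rpe_top:spec$retina_bottom, ] <- 0.85      # RPE band
    if (spec$retina_bottom < H) img[(spec$retina_bottom + 1L):H, ] <- 0.25  # choroid
    mask <- matrix(0L, H, W)
    ord <- order(match(vapply(spec$lesion_specs, `[[`, "", "class"),
                 c("PED", "SHRM", "SRF", "IRF")))
    for (ls in spec$lesion_specs[ord]) {
      sel <- rasterize_lesion(ls, spec)
      mask[sel] <- LESION_LEVELS[[ls$class]]
      img[sel] <- ls$intensity
    }
    draw_line <- function(row, gap_fraction) {
      trace <- rep(as.numeric(row), W)
      gap_len <- round(gap_fraction * W)
      if (gap_len >= W) trace[] <- NA_real_
      else if (gap_len > 0) {
        start <- sample.int(W - gap_len + 1L, 1L)
        trace[start:(start + gap_len - 1L)] <- NA_real_
      }
      rows <- row:min(H, row + spec$line_px - 1L)
      img[rows, !is.na(trace)] <<- 0.95
      trace
    }
    ez_trace <- draw_line(spec$ez_row, spec$ez_gap_fraction)
    elm_trace <- draw_line(spec$elm_row, spec$elm_gap_fraction)
    features <- measure_ground_truth(img, mask, ez_trace, elm_trace,
                                     spec$pixel_size_mm)
    if (spec$speckle_sigma > 0) {
      img <- img * (1 + spec$speckle_sigma * matrix(rnorm(H * W), H, W))
      img <- pmin(pmax(img, 0), 1)
    }
    attr(img, "pixel_size_mm") <- spec$pixel_size_mm
    list(image = img,
         annotation = list(lesion_mask = mask, ez_trace = ez_trace,
                           elm_trace = elm_trace),
         features = features)
  })
}

#' Planted outcome rules for synthetic cohorts
#'
#' `outcome_rule_default()` classifies an eye from its realised month-3
#' features: cured (2) when fluid and lesions have both resolved, stable (0)
#' when fluid has resolved but PED/SHRM persist, PDA (1) otherwise.
#' `outcome_rule_ez()` ignores lesions and classifies on the month-3 EZ
#' length rate alone (PDA below `pda_below`, cured at/above `cured_at`).
#' `outcome_rule_constant()` always returns `class` (degenerate, for tests).
#'
#' Each returns a function mapping a named list of per-visit feature vectors
#' to a class in `{0, 1, 2}`.
#'
#' @param eps_mm2 area below which a lesion counts as resolved
#' @param pda_below,cured_at EZ length-rate thresholds
#' @param class fixed class for the constant rule
#' @name outcome_rules
#' @export
outcome_rule_default <- function(eps_mm2 = 1e-6) {
  force(eps_mm2)
  function(visits) {
    m3 <- visits$month3
    fluid <- m3[["irf_area_mm2"]] + m3[["srf_area_mm2"]]
    lesions <- m3[["ped_area_mm2"]] + m3[["shrm_area_mm2"]]
    if (fluid <= eps_mm2 && lesions <= eps_mm2) 2L
    else if (fluid <= eps_mm2) 0L
    else 1L
  }
}

#' @rdname outcome_rules
#' @export
outcome_rule_ez <- function(pda_below = 0.6, cured_at = 0.9) {
  force(pda_below); force(cured_at)
  function(visits) {
    r <- visits$month3[["ez_length_rate"]]
    if (r < pda_below) 1L else if (r >= cured_at) 2L else 0L
  }
}

#' @rdname outcome_rules
#' @export
outcome_rule_constant <- function(class = 0L) {
  force(class)
  function(visits) as.integer(class)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Per-eye trajectory draw.  Returns per-visit gap fractions and per-visit
# lesion scale factors, per signal mode.
draw_trajectory <- function(signal) {
  scales <- function(mult) lapply(VISITS, function(v) mult)
  if (signal == "ez_only") {
    # Lesion course independent of outcome; EZ/ELM integrity carries it all.
    r3 <- runif(1, 0.30, 1.0)
    gap3 <- 1 - r3
    gap0 <- clamp(gap3 + runif(1, -0.2, 0.2), 0, 0.7)
    gaps_ez <- c(gap0, (gap0 + gap3) / 2, gap3, gap3)
    gaps_elm <- clamp(gaps_ez * runif(1, 0.7, 1.1), 0, 1)
    les <- lapply(1:4, function(v)
      stats::setNames(runif(4, 0.2, 1.2), LESION_CLASSES))  # iid: no class info
    list(gaps_ez = gaps_ez, gaps_elm = gaps_elm, lesion_scales = les)
  } else {
    archetype <- sample(c("stable", "pda", "cured"), 1,
                        prob = c(0.4648, 0.3310, 0.2042))
    fluid_mult <- switch(archetype,
      cured  = c(1, 0.5, 0, 0),
      stable = c(1, 0.5, 0, 0),
      pda    = c(1, 0.8, runif(1, 0.6, 1.1), runif(1, 0.6, 1.1)))
    solid_mult <- switch(archetype,
      cured  = c(1, 0.6, 0, 0),
      stable = c(1, 0.9, runif(1, 0.6, 0.9), runif(1, 0.5, 0.9)),
      pda    = c(1, 1, runif(1, 0.8, 1.2), runif(1, 0.8, 1.2)))
    gap0 <- if (archetype == "pda") runif(1, 0.45, 0.6) else runif(1, 0.05, 0.3)
    gaps_ez <- if (archetype == "pda") clamp(gap0 + c(0, 0.02, 0.05, 0.05), 0, 0.8)
               else gap0 * c(1, 0.7, 0.4, 0.3)
    gaps_elm <- clamp(gaps_ez * runif(1, 0.7, 1.1), 0, 1)
    les <- lapply(1:4, function(v) {
      s <- c(IRF = fluid_mult[v], SRF = fluid_mult[v],
             SHRM = solid_mult[v], PED = solid_mult[v])
      s * runif(4, 0.9, 1.1)  # mild visit-level jitter
    })
    list(gaps_ez = gaps_ez, gaps_elm = gaps_elm, lesion_scales = les)
  }
}

#' Generate a seeded longitudinal cohort with a planted outcome
#'
#' Each eye gets four visits (baseline, month 1, month 3, month 12) whose
#' lesion sizes and EZ/ELM gap fractions follow a per-eye trajectory, and a
#' prognosis label in `{0 stable, 1 PDA, 2 cured}` obtained by applying
#' `outcome_model` to the *realised* (rasterised) features, so labels and
#' features are consistent by construction.  With `signal = "lesions"`
#' (default) trajectories follow resolve/persist archetypes drawn with the
#' stable/PDA/cured prevalences 46.5/33.1/20.4% and the default rule
#' recovers them; with `signal = "ez_only"` lesion courses are independent
#' of outcome and only the photoreceptor integrity carries class signal.
#'
#' @param n_eyes number of eyes (>= 1)
#' @param outcome_model function(visits) -> class; `NULL` picks
#'   [outcome_rule_default()] or [outcome_rule_ez()] to match `signal`
#' @param seed integer seed
#' @param image_height,image_width scene size (desk-scale default)
#' @param signal `"lesions"` or `"ez_only"` (see above)
#' @param render if `FALSE`, skip the speckled intensity image (annotation
#'   and features are still computed from the rasterisation)
#' @param speckle_sigma passed to [scene_spec()]
#' @return list of records `(eye_id, label, visits)` with attribute
#'   `class_counts`; each visit holds `image` (or `NULL`), `annotation`,
#'   `features`
#' @export
generate_cohort <- function(n_eyes, outcome_model = NULL, seed = 1L,
                            image_height = 128L, image_width = 512L,
                            signal = c("lesions", "ez_only"),
                            render = TRUE, speckle_sigma = 0.08) {
  signal <- match.arg(signal)
  if (!is.numeric(n_eyes) || length(n_eyes) != 1L || n_eyes < 1)
    stop_field("n_eyes", "must be >= 1")
  n_eyes <- as.integer(n_eyes)
  if (is.null(outcome_model))
    outcome_model <- if (signal == "ez_only") outcome_rule_ez()
                     else outcome_rule_default()
  base_spec <- scene_spec(image_height = image_height,
                          image_width = image_width,
                          speckle_sigma = speckle_sigma)
  records <- with_seed(seed, {
    lapply(seq_len(n_eyes), function(e) {
      traj <- draw_trajectory(signal)
      base_scale <- runif(4, 0.7, 1.3)  # per-eye anatomy
      # per-eye lesion centres jittered once, shared across visits
      # (follow-up mode scans the same location)
      templates <- base_spec$lesion_specs
      visit_seeds <- sample.int(2^30, length(VISITS))
      visits <- list()
      for (v in seq_along(VISITS)) {
        sc <- traj$lesion_scales[[v]]
        lesions <- list()
        for (ls in templates) {
          s <- base_scale[match(ls$class, LESION_CLASSES)] * sc[[ls$class]]
          ax <- ls$axes * s
          if (any(ax < 1)) next  # resolved below raster resolution
          lesions[[length(lesions) + 1L]] <-
            lesion_spec(ls$class, ls$shape, ls$center, ax, ls$intensity)
        }
        sp <- scene_spec(image_height = image_height, image_width = image_width,
                         ez_gap_fraction = traj$gaps_ez[v],
                         elm_gap_fraction = traj$gaps_elm[v],
                         lesion_specs = lesions,
                         speckle_sigma = if (render) speckle_sigma else 0)
        scene <- generate_scene(sp, seed = visit_seeds[v])
        if (!render) scene$image <- NULL
        visits[[VISITS[v]]] <- scene
      }
      label <- outcome_model(lapply(visits, `[[`, "features"))
      if (!label %in% 0:2) stop("outcome_model must return a class in {0,1,2}")
      list(eye_id = sprintf("eye%03d", e), label = as.integer(label),
           visits = visits)
    })
  })
  counts <- table(factor(vapply(records, `[[`, integer(1), "label"),
                         levels = 0:2))
  if (sum(counts > 0) == 1L)
    warning("planted outcome rule produced a single class", call. = FALSE)
  attr(records, "class_counts") <- counts
  records
}

#' Flatten a cohort into a long feature table
#'
#' @param cohort output of [generate_cohort()]
#' @return data.frame with columns `eye_id`, `visit`, `label` and the 12
#'   biomarker features
#' @export
cohort_feature_table <- function(cohort) {
  rows <- lapply(cohort, function(rec) {
    do.call(rbind, lapply(names(rec$visits), function(v) {
      data.frame(eye_id = rec$eye_id, visit = v, label = rec$label,
                 t(rec$visits[[v]]$features), check.names = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
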