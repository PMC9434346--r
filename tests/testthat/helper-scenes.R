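# Shared fixtures, all generated in code at test time (desk-scale profile:
# 128 x 512 scenes = 32 clips of 128 x 16).

desk_scene_spec <- function(..., speckle_sigma = 0) {
  scene_spec(image_height = 128L, image_width = 512L,
             speckle_sigma = speckle_sigma, ...)
}

# Scene with per-seed jittered lesion geometry and gap fractions, so a set
# of scenes is not 20 copies of one mask.
varied_scene <- function(seed, speckle_sigma = 0) {
  base <- desk_scene_spec()
  with_seed <- get("with_seed", asNamespace("retquant"))
  sp <- with_seed(seed * 131L + 7L, {
    les <- lapply(base$lesion_specs, function(ls) {
      lesion_spec(ls$class, ls$shape,
                  ls$center + c(runif(1, -4, 4), runif(1, -0.05, 0.05) * 512),
                  ls$axes * runif(2, 0.7, 1.3), ls$intensity)
    })
    desk_scene_spec(ez_gap_fraction = runif(1, 0.1, 0.4),
                    elm_gap_fraction = runif(1, 0.1, 0.4),
                    lesion_specs = les, speckle_sigma = speckle_sigma)
  })
  generate_scene(sp, seed = seed)
}

# A throwaway clip classifier trained for a few seconds on tiny clips;
# used where tests need *a* fitted model, not an accurate one.
tiny_clip_model <- function() {
  set.seed(3)
  clips <- lapply(1:24, function(i) matrix(runif(32 * 16), 32, 16))
  labs <- rep(c(TRUE, FALSE), 12)
  train_clip_cnn(clips, labs,
                 clip_cnn_config(channels = c(2L, 2L, 2L, 2L), epochs = 1L,
                                 batch_size = 8L, seed = 1L))
}
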