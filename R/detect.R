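# Clip-based detection of the EZ and ELM photoreceptor lines: each B-scan
# is sliced into vertical 16-px-wide clips, a small CNN classifies presence
# per clip, and per-image predictions are merged back in clip order
# ("clipping-training" / "clipping-predicting-merging-testing").

#' Slice a B-scan into vertical clips
#'
#' Non-overlapping 16-px-wide clips, left to right; concatenating them
#' reproduces the image bit-exactly.
#'
#' @param img numeric matrix with width divisible by 16
#' @param clip_width clip width in pixels (16 throughout)
#' @return a `clip_grid`: list with `clips` (array H x 16 x n_clips),
#'   `n_clips`, `clip_width`, `height`
#' @export
slice_clips <- function(img, clip_width = 16L) {
  img <- check_matrix_image(img)
  W <- ncol(img)
  if (W %% clip_width != 0L)
    stop(sprintf(
      "width %d is not divisible by %d; re-crop the scan (crop_and_resize) first",
      W, clip_width), call. = FALSE)
  n <- W %/% clip_width
  clips <- array(img, c(nrow(img), clip_width, n))  # column-major: exact slices
  structure(list(clips = clips, n_clips = n, clip_width = as.integer(clip_width),
                 height = nrow(img)), class = "clip_grid")
}

#' Reassemble a clip grid into the original image
#' @param grid a `clip_grid`
#' @return numeric matrix
#' @export
clips_to_image <- function(grid) {
  stopifnot(inherits(grid, "clip_grid"))
  matrix(grid$clips, grid$height, grid$clip_width * grid$n_clips)
}

match_layer <- function(layer) {
  l <- tolower(as.character(layer))
  if (length(l) != 1L || !l %in% c("ez", "elm"))
    stop(sprintf("unknown layer '%s' (expected \"ez\" or \"elm\")", layer),
         call. = FALSE)
  l
}

#' Ground-truth clip labels from an annotation
#'
#' A clip is positive when the layer's trace is present (non-`NA`) in at
#' least one of its 16 columns.
#'
#' @param annotation annotation list with `ez_trace` / `elm_trace`
#' @param layer `"ez"` or `"elm"`
#' @param clip_width clip width in pixels
#' @return logical vector of length `n_clips`
#' @export
clip_labels <- function(annotation, layer, clip_width = 16L) {
  layer <- match_layer(layer)
  trace <- annotation[[paste0(layer, "_trace")]]
  if (is.null(trace)) stop("annotation has no trace for layer ", layer)
  n <- length(trace) %/% clip_width
  vapply(seq_len(n), function(k)
    any(!is.na(trace[((k - 1L) * clip_width + 1L):(k * clip_width)])),
    logical(1))
}

#' @rdname clip_labels
#' @param clip_index 1-based clip index
#' @export
clip_label <- function(annotation, layer, clip_index, clip_width = 16L) {
  labs <- clip_labels(annotation, layer, clip_width)
  if (clip_index < 1L || clip_index > length(labs))
    stop("clip_index out of range", call. = FALSE)
  labs[[clip_index]]
}

#' Configuration of the clip classifier CNN
#'
#' Four blocks of (convolution, batch normalisation, ReLU, 2x2 max pooling)
#' followed by two fully connected layers ending in a sigmoid; trained with
#' stochastic gradient descent on binary cross-entropy.
#'
#' @param channels convolution channels per block (length = number of blocks)
#' @param kernel odd kernel size
#' @param fc_width width of the hidden fully connected layer
#' @param lr,momentum,epochs,batch_size SGD hyper-parameters
#' @param threshold positivity threshold on the clip probability
#' @param seed integer seed for initialisation and shuffling
#' @return a `clip_cnn_config` list
#' @export
clip_cnn_config <- function(channels = c(16L, 32L, 64L, 128L), kernel = 3L,
                            fc_width = 64L, lr = 0.05, momentum = 0.9,
                            epochs = 20L, batch_size = 32L, threshold = 0.5,
                            seed = 1L) {
  if (length(channels) < 1L || any(channels < 1L))
    stop_field("channels", "must be positive")
  if (kernel %% 2L != 1L) stop_field("kernel", "must be odd")
  if (threshold <= 0 || threshold >= 1) stop_field("threshold", "must be in (0,1)")
  if (epochs < 1L) stop_field("epochs", "must be >= 1")
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 fc_width = as.integer(fc_width), lr = lr, momentum = momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 threshold = threshold, seed = as.integer(seed)),
            class = "clip_cnn_config")
}

as_clip_array <- function(clips) {
  if (inherits(clips, "clip_grid")) return(clips$clips)
  if (is.list(clips)) {
    if (!length(clips)) stop("empty training set", call. = FALSE)
    d <- dim(clips[[1]])
    arr <- array(0, c(d[1], d[2], length(clips)))
    for (i in seq_along(clips)) arr[, , i] <- clips[[i]]
    return(arr)
  }
  if (is.array(clips) && length(dim(clips)) == 3L) return(clips)
  stop("clips must be a clip_grid, a list of matrices, or an H x w x n array",
       call. = FALSE)
}

clip_cnn_forward <- function(model, x, training = FALSE) {
  caches <- list()
  for (i in seq_along(model$blocks)) {
    bf <- nn_block_fwd(model$blocks[[i]], x, training)
    model$blocks[[i]] <- bf$blk
    pf <- .cpp_maxpool2_fwd(bf$y)
    caches[[i]] <- list(block = bf$cache, pool_idx = pf$idx,
                        pre_pool_dim = dim(bf$y))
    x <- pf$y
  }
  featdim <- dim(x)
  f <- matrix(x, ncol = featdim[4])
  z1 <- model$fc1$w %*% f + model$fc1$b
  a1 <- pmax(z1, 0)
  z2 <- model$fc2$w %*% a1 + model$fc2$b
  p <- as.numeric(nn_sigmoid(z2))
  list(model = model, p = p,
       cache = list(caches = caches, featdim = featdim, f = f, a1 = a1))
}

clip_cnn_backward <- function(model, cache, dz2) {
  grads <- list(blocks = vector("list", length(model$blocks)))
  grads$fc2 <- list(w = dz2 %*% t(cache$a1), b = rowSums(dz2))
  ga1 <- t(model$fc2$w) %*% dz2
  ga1[cache$a1 <= 0] <- 0
  grads$fc1 <- list(w = ga1 %*% t(cache$f), b = rowSums(ga1))
  gf <- t(model$fc1$w) %*% ga1
  g <- array(gf, cache$featdim)
  for (i in rev(seq_along(model$blocks))) {
    cc <- cache$caches[[i]]
    g <- .cpp_maxpool2_bwd(cc$pool_idx, g, as.integer(cc$pre_pool_dim))
    bb <- nn_block_bwd(model$blocks[[i]], cc$block, g)
    grads$blocks[[i]] <- bb$grads
    g <- bb$gx
  }
  grads
}

#' Train the clip classifier for one layer
#'
#' One independent binary model is trained per layer (EZ or ELM).  Requires
#' both labels in the training set.
#'
#' @param clips training clips: a `clip_grid`, list of H x 16 matrices, or
#'   H x 16 x n array (H divisible by 16 for the four pooling stages)
#' @param labels logical (or 0/1) vector, one per clip
#' @param config a [clip_cnn_config()]
#' @param verbose print the running loss per epoch
#' @return a fitted `clip_cnn` model handle
#' @export
train_clip_cnn <- function(clips, labels, config = clip_cnn_config(),
                           verbose = FALSE) {
  x <- as_clip_array(clips)
  n <- dim(x)[3]
  labels <- as.numeric(labels)
  if (n == 0L || length(labels) != n)
    stop("need one label per training clip (non-empty)", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training set must contain both positive and negative clips",
         call. = FALSE)
  H <- dim(x)[1]; Wc <- dim(x)[2]
  nb <- length(config$channels)
  if (H %% 2^nb != 0L || Wc %% 2^nb != 0L)
    stop_field("clips", sprintf("height/width must be divisible by %d", 2^nb))
  with_seed(config$seed, {
    blocks <- list()
    cin <- 1L
    for (ch in config$channels) {
      blocks[[length(blocks) + 1L]] <-
        list(conv = nn_conv_init(config$kernel, cin, ch), bn = nn_bn_init(ch))
      cin <- ch
    }
    feat <- (H / 2^nb) * (Wc / 2^nb) * cin
    model <- list(blocks = blocks, fc1 = nn_fc_init(feat, config$fc_width),
                  fc2 = nn_fc_init(config$fc_width, 1L), config = config,
                  input_dim = c(H, Wc))
    state <- NULL
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb_seen <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        bi <- idx[start:min(start + config$batch_size - 1L, n)]
        if (length(bi) < 2L) next  # batchnorm needs > 1 sample
        xb <- array(x[, , bi], c(H, Wc, 1L, length(bi)))
        y <- labels[bi]
        fw <- clip_cnn_forward(model, xb, training = TRUE)
        model <- fw$model
        p <- clamp(fw$p, 1e-7, 1 - 1e-7)
        ep_loss <- ep_loss - mean(y * log(p) + (1 - y) * log(1 - p))
        nb_seen <- nb_seen + 1
        dz2 <- matrix((fw$p - y) / length(bi), nrow = 1)
        grads <- clip_cnn_backward(model, fw$cache, dz2)
        st <- nn_sgd_step(model[c("blocks", "fc1", "fc2")],
                          grads[c("blocks", "fc1", "fc2")], state,
                          lr = config$lr, momentum = config$momentum)
        model[c("blocks", "fc1", "fc2")] <- st$params
        state <- st$state
      }
      if (verbose) message(sprintf("epoch %d  bce %.4f", ep, ep_loss / nb_seen))
    }
    structure(model, class = "clip_cnn")
  })
}

#' Detect layer presence on a B-scan
#'
#' Slices the scan, scores every clip with the trained classifier, binarises
#' at `threshold`, and merges the per-clip decisions into the per-image
#' presence vector (clip order).
#'
#' @param model a fitted `clip_cnn` (or a named list of them, e.g.
#'   `list(ez = ..., elm = ...)`, in which case a named list of results is
#'   returned)
#' @param img B-scan matrix, width divisible by 16
#' @param threshold overrides the config threshold if given
#' @return a `layer_detection`: list with `probability`, `presence`,
#'   `threshold`, `n_clips`
#' @export
detect_layers <- function(model, img, threshold = NULL) {
  if (!inherits(model, "clip_cnn") && is.list(model))
    return(lapply(model, detect_layers, img = img, threshold = threshold))
  stopifnot(inherits(model, "clip_cnn"))
  grid <- slice_clips(img)
  if (grid$height != model$input_dim[1])
    stop("image height does not match the trained model", call. = FALSE)
  thr <- if (is.null(threshold)) model$config$threshold else threshold
  x <- array(grid$clips, c(dim(grid$clips)[1:2], 1L, grid$n_clips))
  p <- clip_cnn_forward(model, x, training = FALSE)$p
  structure(list(probability = p, presence = p >= thr, threshold = thr,
                 n_clips = grid$n_clips), class = "layer_detection")
}
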