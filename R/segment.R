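# Fully convolutional multi-class segmentation of the blocky lesions
# (IRF, SRF, SHRM, PED) with a small U-shaped encoder-decoder trained by
# pixelwise softmax cross-entropy.  Stands in for the original large
# pretrained backbone at desk scale; no download is needed.

#' Configuration of the lesion segmenter
#'
#' A U-shaped fully convolutional network: `length(channels)` encoder
#' levels of (conv, batchnorm, ReLU, 2x2 max-pool), a bottleneck block, and
#' mirrored decoder levels with nearest-neighbour upsampling and skip
#' concatenation, ending in a 1x1 convolution over `n_classes` logits.
#'
#' @param channels encoder channels per resolution level
#' @param n_classes number of labels (background + 4 lesions)
#' @param kernel odd convolution kernel size
#' @param lr,momentum,epochs SGD hyper-parameters
#' @param seed integer seed
#' @param coord_channel add a normalised row-coordinate input channel
#'   (depth position disambiguates IRF vs SRF, which share reflectivity)
#' @param class_weights `"median"` (median-frequency balancing computed on
#'   the training masks), `"none"`, or a numeric vector of length
#'   `n_classes`
#' @return an `fcn_config` list
#' @export
fcn_config <- function(channels = c(8L, 16L, 32L), n_classes = 5L,
                       kernel = 3L, lr = 0.05, momentum = 0.9, epochs = 30L,
                       seed = 1L, coord_channel = TRUE,
                       class_weights = "median") {
  if (length(channels) < 2L || any(channels < 1L))
    stop_field("channels", "need at least two positive levels")
  if (epochs < 1L) stop_field("epochs", "must be >= 1")
  if (n_classes < 2L) stop_field("n_classes", "must be >= 2")
  structure(list(channels = as.integer(channels),
                 n_classes = as.integer(n_classes), kernel = as.integer(kernel),
                 lr = lr, momentum = momentum, epochs = as.integer(epochs),
                 seed = as.integer(seed), coord_channel = isTRUE(coord_channel),
                 class_weights = class_weights),
            class = "fcn_config")
}

fcn_input <- function(img, coord_channel) {
  H <- nrow(img); W <- ncol(img)
  cin <- if (coord_channel) 2L else 1L
  x <- array(0, c(H, W, cin, 1L))
  x[, , 1L, 1L] <- img
  if (coord_channel) x[, , 2L, 1L] <- matrix((seq_len(H) - 1) / (H - 1), H, W)
  x
}

fcn_forward <- function(model, x, training = FALSE) {
  L <- length(model$enc)
  caches <- list(enc = vector("list", L), dec = vector("list", L))
  acts <- vector("list", L)
  for (i in seq_len(L)) {
    bf <- nn_block_fwd(model$enc[[i]], x, training)
    model$enc[[i]] <- bf$blk
    acts[[i]] <- bf$y
    pf <- .cpp_maxpool2_fwd(bf$y)
    caches$enc[[i]] <- list(block = bf$cache, pool_idx = pf$idx,
                            pre_pool_dim = dim(bf$y))
    x <- pf$y
  }
  bf <- nn_block_fwd(model$bott, x, training)
  model$bott <- bf$blk
  caches$bott <- bf$cache
  cur <- bf$y
  for (i in rev(seq_len(L))) {
    up <- .cpp_upsample2_fwd(cur)
    cat <- nn_cat_ch(up, acts[[i]])
    bf <- nn_block_fwd(model$dec[[i]], cat, training)
    model$dec[[i]] <- bf$blk
    caches$dec[[i]] <- list(block = bf$cache, up_ch = dim(up)[3])
    cur <- bf$y
  }
  logits <- .cpp_conv2d_fwd(cur, model$head$w, model$head$b)
  caches$head_in <- cur
  list(model = model, logits = logits, caches = caches)
}

fcn_backward <- function(model, caches, glogits) {
  L <- length(model$enc)
  grads <- list(enc = vector("list", L), dec = vector("list", L))
  hb <- .cpp_conv2d_bwd(caches$head_in, model$head$w, glogits)
  grads$head <- list(w = hb$gw, b = hb$gb)
  g <- hb$gx
  skip_g <- vector("list", L)
  for (i in seq_len(L)) {   # decoder blocks, shallowest applied last
    bb <- nn_block_bwd(model$dec[[i]], caches$dec[[i]]$block, g)
    grads$dec[[i]] <- bb$grads
    sp <- nn_split_ch(bb$gx, caches$dec[[i]]$up_ch)
    skip_g[[i]] <- sp$b
    g <- .cpp_upsample2_bwd(sp$a)
  }
  bb <- nn_block_bwd(model$bott, caches$bott, g)
  grads$bott <- bb$grads
  g <- bb$gx
  for (i in rev(seq_len(L))) {
    gact <- .cpp_maxpool2_bwd(caches$enc[[i]]$pool_idx, g,
                              as.integer(caches$enc[[i]]$pre_pool_dim)) +
      skip_g[[i]]
    bb <- nn_block_bwd(model$enc[[i]], caches$enc[[i]]$block, gact)
    grads$enc[[i]] <- bb$grads
    g <- bb$gx
  }
  grads
}

#' Train the lesion segmenter
#'
#' @param images list of B-scan matrices (same size, height and width
#'   divisible by `2^levels`)
#' @param masks list of integer label matrices (0=background, 1=IRF, 2=SRF,
#'   3=SHRM, 4=PED); every lesion class must appear somewhere in the set
#' @param config an [fcn_config()]
#' @param verbose print epoch losses
#' @return a fitted `lesion_fcn` model handle (with `$loss_history`)
#' @export
train_fcn <- function(images, masks, config = fcn_config(), verbose = FALSE) {
  if (!length(images) || length(images) != length(masks))
    stop("need a non-empty paired set of images and masks", call. = FALSE)
  present <- sort(unique(unlist(lapply(masks, function(m) unique(as.integer(m))))))
  missing_cls <- setdiff(seq_len(4L), present)
  if (length(missing_cls))
    stop("no training pixels for class(es): ",
         paste(names(LESION_LEVELS)[match(missing_cls, LESION_LEVELS)],
               collapse = ", "), call. = FALSE)
  L <- length(config$channels)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  if (H %% 2^L != 0L || W %% 2^L != 0L)
    stop_field("images", sprintf("height/width must be divisible by %d", 2^L))
  K <- config$n_classes
  cw <- config$class_weights
  if (identical(cw, "median")) {
    freq <- numeric(K)
    for (m in masks) freq <- freq + tabulate(as.integer(m) + 1L, K)
    freq <- freq / sum(freq)
    cw <- ifelse(freq > 0, median(freq[freq > 0]) / freq, 0)
  } else if (identical(cw, "none")) cw <- rep(1, K)
  with_seed(config$seed, {
    cin <- if (config$coord_channel) 2L else 1L
    ch <- config$channels
    enc <- list(); p <- cin
    for (i in seq_len(L)) {
      enc[[i]] <- list(conv = nn_conv_init(config$kernel, p, ch[i]),
                       bn = nn_bn_init(ch[i]))
      p <- ch[i]
    }
    bott <- list(conv = nn_conv_init(config$kernel, ch[L], ch[L]),
                 bn = nn_bn_init(ch[L]))
    dec <- list(); cur <- ch[L]
    for (i in rev(seq_len(L))) {
      dout <- ch[max(i - 1L, 1L)]
      dec[[i]] <- list(conv = nn_conv_init(config$kernel, cur + ch[i], dout),
                       bn = nn_bn_init(dout))
      cur <- dout
    }
    head <- nn_conv_init(1L, cur, K)
    model <- list(enc = enc, bott = bott, dec = dec, head = head,
                  config = config, class_weights = cw)
    state <- NULL
    loss_hist <- numeric(0)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(images))
      ep_loss <- 0
      for (ii in ord) {
        x <- fcn_input(images[[ii]], config$coord_channel)
        fw <- fcn_forward(model, x, training = TRUE)
        model <- fw$model
        ce <- nn_softmax_ce(fw$logits, masks[[ii]], cw)
        ep_loss <- ep_loss + ce$loss
        grads <- fcn_backward(model, fw$caches, ce$grad)
        part <- c("enc", "bott", "dec", "head")
        st <- nn_sgd_step(model[part], grads[part], state,
                          lr = config$lr, momentum = config$momentum)
        model[part] <- st$params
        state <- st$state
      }
      loss_hist <- c(loss_hist, ep_loss / length(images))
      if (verbose) message(sprintf("epoch %d  ce %.4f", ep, tail(loss_hist, 1)))
    }
    model$loss_history <- loss_hist
    structure(model, class = "lesion_fcn")
  })
}

#' Segment lesions on a B-scan
#'
#' Deterministic given the trained weights: batch-normalisation uses its
#' running statistics and the label map is the per-pixel argmax.
#'
#' @param model a fitted `lesion_fcn`
#' @param img B-scan matrix; height and width divisible by `2^levels`
#' @param return_prob also return the per-class probability maps
#' @return a `lesion_segmentation`: list with `labels` (integer matrix,
#'   0..4) and optionally `prob` (H x W x K array, pixelwise sums to 1)
#' @export
segment <- function(model, img, return_prob = FALSE) {
  stopifnot(inherits(model, "lesion_fcn"))
  img <- check_matrix_image(img)
  L <- length(model$config$channels)
  if (nrow(img) %% 2^L != 0L || ncol(img) %% 2^L != 0L)
    stop(sprintf("image geometry must be divisible by %d", 2^L), call. = FALSE)
  x <- fcn_input(img, model$config$coord_channel)
  logits <- fcn_forward(model, x, training = FALSE)$logits
  K <- model$config$n_classes
  m <- matrix(logits, nrow = nrow(img) * ncol(img))  # columns = classes
  lab <- matrix(max.col(m, ties.method = "first") - 1L, nrow(img), ncol(img))
  out <- list(labels = lab)
  if (return_prob) {
    m <- m - apply(m, 1, max)
    em <- exp(m)
    out$prob <- array(em / rowSums(em), c(nrow(img), ncol(img), K))
  }
  structure(out, class = "lesion_segmentation")
}
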