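# Analytic gradients of the hand-rolled network primitives are checked
# against central finite differences (the independent oracle for the
# training code).

ns <- asNamespace("retquant")

numgrad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("convolution forward/backward match finite differences", {
  set.seed(1)
  x <- array(rnorm(6 * 8 * 2 * 2), c(6, 8, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3, sd = 0.5), c(3, 3, 2, 3))
  b <- rnorm(3)
  y <- ns$.cpp_conv2d_fwd(x, w, b)
  g <- ns$.cpp_conv2d_bwd(x, w, cos(y))
  loss_w <- function(w_) sum(sin(ns$.cpp_conv2d_fwd(x, w_, b)))
  loss_x <- function(x_) sum(sin(ns$.cpp_conv2d_fwd(x_, w, b)))
  loss_b <- function(b_) sum(sin(ns$.cpp_conv2d_fwd(x, w, b_)))
  expect_lt(max(abs(numgrad(loss_w, w) - g$gw)), 1e-6)
  expect_lt(max(abs(numgrad(loss_x, x) - g$gx)), 1e-6)
  expect_lt(max(abs(numgrad(loss_b, b) - g$gb)), 1e-6)
})

test_that("max pooling routes gradients to the argmax; upsampling is adjoint", {
  set.seed(2)
  x <- array(rnorm(4 * 6 * 2 * 2), c(4, 6, 2, 2))
  p <- ns$.cpp_maxpool2_fwd(x)
  expect_equal(dim(p$y), c(2, 3, 2, 2))
  gx <- ns$.cpp_maxpool2_bwd(p$idx, p$y, dim(x))
  expect_equal(sum(gx), sum(p$y))
  expect_true(all(gx[gx != 0] %in% p$y))
  u <- ns$.cpp_upsample2_fwd(x)
  yy <- array(rnorm(length(u)), dim(u))
  expect_equal(sum(u * yy), sum(x * ns$.cpp_upsample2_bwd(yy)),
               tolerance = 1e-10)
})

test_that("batchnorm and softmax cross-entropy gradients are correct", {
  set.seed(3)
  x <- array(rnorm(4 * 5 * 2 * 3), c(4, 5, 2, 3))
  bn <- ns$nn_bn_init(2)
  bn$gamma <- c(1.3, 0.7); bn$beta <- c(0.2, -0.1)
  o <- ns$nn_bn_fwd(bn, x, TRUE)
  gb <- ns$nn_bn_bwd(bn, o$cache, cos(o$y))
  loss_x <- function(x_) sum(sin(ns$nn_bn_fwd(bn, x_, TRUE)$y))
  expect_lt(max(abs(numgrad(loss_x, x) - gb$gx)), 1e-6)

  K <- 4
  lg <- array(rnorm(3 * 5 * K * 2), c(3, 5, K, 2))
  lab <- array(sample(0:(K - 1), 30, TRUE), c(3, 5, 2))
  cw <- c(1, 2, 0.5, 1)
  ce <- ns$nn_softmax_ce(lg, lab, cw)
  loss_l <- function(l_) ns$nn_softmax_ce(l_, lab, cw)$loss
  expect_lt(max(abs(numgrad(loss_l, lg, eps = 1e-5) - ce$grad)), 1e-6)
  # pixel probabilities normalise
  expect_equal(max(abs(colSums(ce$prob) - 1)), 0, tolerance = 1e-12)
})
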