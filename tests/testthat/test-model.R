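# segmentation model: contracts, primitive correctness, gradients, and
# a small training sanity fit

test_that("model honours the shape/range contract and feature-map side", {
  cfg <- train_config(patch_size = 96L, seed = 2)
  m <- build_segmenter(cfg, "desk")
  expect_equal(m$config$down_sample, 8L)
  set.seed(1)
  x <- array(runif(96 * 96 * 3 * 2), c(96, 96, 3, 2))
  fw <- ophiocount:::seg_forward(m, x)
  expect_equal(dim(fw$prob), c(96L, 96L, 1L, 2L))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # encoder feature side is patch/8 before context pooling
  expect_equal(dim(fw$cache$a_deep)[1:2], c(12L, 12L))
  cfg288 <- train_config(patch_size = 288L, seed = 2)
  m288 <- build_segmenter(cfg288, "desk")
  x1 <- array(runif(288 * 288 * 3), c(288, 288, 3, 1))
  fw288 <- ophiocount:::seg_forward(m288, x1)
  expect_equal(dim(fw288$cache$a_deep)[1:2], c(36L, 36L))
  # pyramid branches pool to sides 1, 2, 3, 6
  for (bn in c(1L, 2L, 3L, 6L))
    expect_equal(dim(fw$cache[[paste0("pooled_ppm", bn)]])[1:2], c(bn, bn))
  expect_error(build_segmenter(train_config(patch_size = 100L)),
               "divide")
})

test_that("convolution matches a naive direct-summation oracle", {
  set.seed(1)
  H <- 6; W <- 7; C <- 2; N <- 2; Cout <- 3; k <- 3
  for (s in c(1L, 2L)) {
    p <- 1L
    x <- array(rnorm(H * W * C * N), c(H, W, C, N))
    Wm <- matrix(rnorm(Cout * k * k * C), Cout, k * k * C)
    b <- rnorm(Cout)
    y <- ophiocount:::cpp_conv_fwd(x, H, W, C, N, Wm, b, k, k, s, p, FALSE)
    Ho <- (H + 2 * p - k) %/% s + 1
    Wo <- (W + 2 * p - k) %/% s + 1
    for (n in 1:N) for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- b[co]
      for (c in 1:C) for (kj in 1:k) for (ki in 1:k) {
        hi <- (ho - 1) * s - p + ki; wi <- (wo - 1) * s - p + kj
        v <- if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          x[hi, wi, c, n] else 0
        rr <- (ki - 1) + k * ((kj - 1) + k * (c - 1)) + 1
        acc <- acc + Wm[co, rr] * v
      }
      expect_equal(y[ho, wo, co, n], acc, tolerance = 1e-12)
    }
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- train_config(patch_size = 48L, dropout_rate = 0, seed = 3)
  m <- build_segmenter(cfg, "desk")
  set.seed(9)
  x <- array(runif(48 * 48 * 3 * 2), c(48, 48, 3, 2))
  y <- array(as.double(rbinom(48 * 48 * 2, 1, 0.3)), c(48, 48, 1, 2))
  loss_at <- function(model) {
    fw <- ophiocount:::seg_forward(model, x)
    ophiocount:::cpp_sigmoid_loss(fw$up, y, 48L * 48L, 2L, 1, 1, 1, 2,
                                  0.25)$loss
  }
  fw <- ophiocount:::seg_forward(m, x)
  sl <- ophiocount:::cpp_sigmoid_loss(fw$up, y, 48L * 48L, 2L, 1, 1, 1, 2,
                                      0.25)
  gr <- ophiocount:::seg_backward(m, fw$cache, sl$grad_logit)
  eps <- 1e-6
  set.seed(4)
  for (nm in names(m$params)) {
    i <- sample(length(m$params[[nm]]$W), 1)
    m2 <- m
    m2$params[[nm]]$W[i] <- m2$params[[nm]]$W[i] + eps
    l1 <- loss_at(m2)
    m2$params[[nm]]$W[i] <- m2$params[[nm]]$W[i] - 2 * eps
    l0 <- loss_at(m2)
    num <- (l1 - l0) / (2 * eps)
    expect_equal(gr[[nm]]$dW[i], num, tolerance = 1e-4)
  }
})

test_that("bilinear resize and adaptive pooling behave as expected", {
  # constant input stays constant under resize both ways
  x <- array(0.7, c(5, 5, 1, 1))
  up <- ophiocount:::cpp_bilinear_fwd(x, 5L, 5L, 1L, 1L, 13L, 13L)
  expect_true(all(abs(up - 0.7) < 1e-12))
  # adaptive pooling averages half-open bins
  v <- array(matrix(1:16, 4, 4), c(4, 4, 1, 1))
  p2 <- ophiocount:::cpp_avgpool_fwd(v, 4L, 4L, 1L, 1L, 2L)
  expect_equal(p2[1, 1, 1, 1], mean(matrix(1:16, 4, 4)[1:2, 1:2]))
  expect_equal(p2[2, 2, 1, 1], mean(matrix(1:16, 4, 4)[3:4, 3:4]))
  p1 <- ophiocount:::cpp_avgpool_fwd(v, 4L, 4L, 1L, 1L, 1L)
  expect_equal(p1[1, 1, 1, 1], mean(1:16))
})

test_that("binarize uses a strict threshold", {
  p <- matrix(c(0.4, 0.5, 0.6, 0.51), 2, 2)
  b <- binarize(p, 0.5)
  expect_equal(as.vector(b), c(0L, 0L, 1L, 1L))
  expect_true(all(binarize(matrix(0.6, 2, 2)) == 1L))
  expect_true(all(binarize(matrix(0.5, 2, 2)) == 0L))
  expect_error(binarize(p, 0), "threshold")
  expect_error(binarize(p, 1), "threshold")
})

test_that("short training decreases the loss and is seed-reproducible", {
  cfg <- train_config(patch_size = 64L, batch_size = 4L, seed = 5,
                      epochs = 8L)
  scfg <- scene_config(width = 64, height = 64, n_stars = 1,
                       disc_radius_range = c(7, 10),
                       arm_length_range = c(8, 14),
                       min_center_separation = 10, seed = 1)
  scenes <- generate_dataset(scfg, 16, seed = 21)
  tp <- make_training_patches(scenes, "disc", 64L, 64L)
  m <- build_segmenter(cfg, "desk")
  m1 <- train_segmenter(m, tp$images, tp$masks)
  h <- m1$loss_history
  expect_equal(nrow(h), 8)
  expect_lt(h[8, 1], h[1, 1])
  m2 <- train_segmenter(m, tp$images, tp$masks)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})

test_that("predict_mosaic equals a single forward pass on one-patch input", {
  cfg <- train_config(patch_size = 64L, stride = 32L, seed = 6)
  m <- build_segmenter(cfg, "desk")
  set.seed(2)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p1 <- predict_mosaic(m, img)
  x <- array(img, c(64, 64, 3, 1))
  p2 <- ophiocount:::seg_forward(m, x)$prob[, , 1, 1]
  expect_equal(p1, p2, tolerance = 1e-12)
  # smaller-than-patch input is padded and cropped back
  small <- img[1:40, 1:50, , drop = FALSE]
  ps <- predict_mosaic(m, small)
  expect_equal(dim(ps), c(40L, 50L))
  expect_true(all(ps > 0 & ps < 1))
})
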