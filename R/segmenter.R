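# The patch segmentation model: a fully convolutional encoder at a
# configurable output stride (default 8), a pyramid pooling context
# module over bins {1, 2, 3, 6}, 1x1 fusion with dropout, a 1x1 sigmoid
# head, and bilinear upsampling back to the input resolution. Forward
# and backward passes run on native GEMM convolution primitives; training
# uses Adam on the additive Jaccard + Focal loss.

#' Training configuration for the segmentation model
#'
#' Defaults: learning rate 0.00012,
#' batch size 8, patch size 288, stride 144, dropout 0.3, output stride
#' (down-sample) 8, sigmoid output. The loss is the additive combination
#' of soft Jaccard and binary focal terms with unit weights.
#'
#' @param learning_rate Adam learning rate
#' @param batch_size patches per weight update
#' @param patch_size square training patch side in pixels
#' @param stride sliding-window stride for patch extraction
#' @param dropout_rate dropout probability in the fusion layer, [0, 1)
#' @param down_sample encoder output stride; must divide `patch_size`
#' @param epochs training epochs
#' @param loss_weights `(w_jaccard, w_focal)` non-negative weights
#' @param focal_gamma,focal_alpha focal loss parameters
#' @param jaccard_smooth soft-Jaccard smoothing constant
#' @param threshold binarization threshold for predictions, in (0, 1)
#' @param seed RNG seed controlling initialization, shuffling and dropout
#' @param enhancement an [enhancement_spec()] applied to mosaics before
#'   patching
#' @return object of class `train_config`
#' @export
train_config <- function(learning_rate = 0.00012,
                         batch_size = 8L,
                         patch_size = 288L,
                         stride = 144L,
                         dropout_rate = 0.3,
                         down_sample = 8L,
                         epochs = 500L,
                         loss_weights = c(1, 1),
                         focal_gamma = 2,
                         focal_alpha = 0.25,
                         jaccard_smooth = 1,
                         threshold = 0.5,
                         seed = 1L,
                         enhancement = enhancement_spec("none")) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (patch_size %% down_sample != 0)
    stop("down_sample must divide patch_size")
  if (!(down_sample %in% c(2L, 4L, 8L, 16L)))
    stop("down_sample must be a power of two in {2, 4, 8, 16}")
  if (any(loss_weights < 0)) stop("loss weights must be non-negative")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    patch_size = as.integer(patch_size), stride = as.integer(stride),
    dropout_rate = dropout_rate, down_sample = as.integer(down_sample),
    epochs = as.integer(epochs), loss_weights = loss_weights,
    focal_gamma = focal_gamma, focal_alpha = focal_alpha,
    jaccard_smooth = jaccard_smooth, threshold = threshold,
    seed = as.integer(seed), enhancement = enhancement
  ), class = "train_config")
}

PPM_BINS <- c(1L, 2L, 3L, 6L)

profile_widths <- function(profile, n_down) {
  base <- switch(profile, desk = 12L, full = 32L,
                 stop("unknown channel profile '", profile, "'"))
  enc <- base * 2L^(seq_len(n_down) - 1L)
  list(encoder = enc,
       deep = enc[n_down],
       ppm = max(4L, enc[n_down] %/% 4L),
       fuse = switch(profile, desk = 32L, full = 128L))
}

he_init <- function(cout, fan_in) {
  matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
}

#' Build an untrained segmentation model
#'
#' The encoder is a stack of strided 3x3 convolutions reaching the
#' configured output stride, followed by one stride-1 3x3 convolution;
#' the pyramid pooling module average-pools the encoder feature map to
#' 1x1, 2x2, 3x3 and 6x6 context grids, projects each with a 1x1
#' convolution and bilinearly upsamples back; the concatenation is fused
#' by a 1x1 convolution with dropout, mapped to a single logit channel,
#' bilinearly upsampled by the output stride, and passed through a
#' sigmoid. The `"desk"` profile is a compact encoder trainable on a
#' CPU; `"full"` uses the same structure with wider layers.
#'
#' @param config a [train_config()]
#' @param channel_profile `"desk"` or `"full"`
#' @return object of class `seg_model` (untrained)
#' @export
build_segmenter <- function(config = train_config(),
                            channel_profile = c("desk", "full")) {
  channel_profile <- match.arg(channel_profile)
  n_down <- as.integer(round(log2(config$down_sample)))
  feat_side <- config$patch_size %/% config$down_sample
  if (feat_side < max(PPM_BINS))
    stop("patch_size/down_sample must be >= ", max(PPM_BINS),
         " for the pyramid bins")
  wd <- profile_widths(channel_profile, n_down)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  params <- list()
  cin <- 3L
  for (i in seq_len(n_down)) {
    params[[paste0("enc", i)]] <- list(
      W = he_init(wd$encoder[i], 9L * cin), b = rep(0, wd$encoder[i]),
      k = 3L, stride = 2L, pad = 1L, cin = cin, cout = wd$encoder[i])
    cin <- wd$encoder[i]
  }
  params[["deep"]] <- list(
    W = he_init(wd$deep, 9L * cin), b = rep(0, wd$deep),
    k = 3L, stride = 1L, pad = 1L, cin = cin, cout = wd$deep)
  cin <- wd$deep
  for (bn in PPM_BINS) {
    params[[paste0("ppm", bn)]] <- list(
      W = he_init(wd$ppm, cin), b = rep(0, wd$ppm),
      k = 1L, stride = 1L, pad = 0L, cin = cin, cout = wd$ppm)
  }
  cat_ch <- cin + length(PPM_BINS) * wd$ppm
  params[["fuse"]] <- list(
    W = he_init(wd$fuse, cat_ch), b = rep(0, wd$fuse),
    k = 1L, stride = 1L, pad = 0L, cin = cat_ch, cout = wd$fuse)
  params[["head"]] <- list(
    W = he_init(1L, wd$fuse), b = rep(0, 1L),
    k = 1L, stride = 1L, pad = 0L, cin = wd$fuse, cout = 1L)
  n_par <- sum(vapply(params, function(p) length(p$W) + length(p$b),
                      numeric(1)))
  structure(list(
    arch = list(profile = channel_profile, n_down = n_down,
                widths = wd, bins = PPM_BINS,
                down_sample = config$down_sample),
    params = params,
    config = config,
    loss_history = NULL,
    trained = FALSE,
    n_params = n_par
  ), class = "seg_model")
}

conv_apply <- function(x, p, relu = FALSE) {
  d <- dim(x)
  cpp_conv_fwd(x, d[1], d[2], d[3], d[4], p$W, p$b, p$k, p$k,
               p$stride, p$pad, relu)
}

# forward pass; returns probabilities and (optionally) the cache needed
# for the backward pass
seg_forward <- function(model, x, train = FALSE) {
  p <- model$params
  cfg <- model$config
  n_down <- model$arch$n_down
  cache <- list(x = x)
  a <- x
  for (i in seq_len(n_down)) {
    nm <- paste0("enc", i)
    a <- conv_apply(a, p[[nm]], relu = TRUE)
    cache[[paste0("a_", nm)]] <- a
  }
  feat <- conv_apply(a, p$deep, relu = TRUE)
  cache$a_deep <- feat
  fd <- dim(feat)
  branches <- list(feat)
  for (bn in model$arch$bins) {
    nm <- paste0("ppm", bn)
    pooled <- cpp_avgpool_fwd(feat, fd[1], fd[2], fd[3], fd[4], bn)
    aa <- conv_apply(pooled, p[[nm]], relu = TRUE)
    up <- cpp_bilinear_fwd(aa, bn, bn, p[[nm]]$cout, fd[4], fd[1], fd[2])
    cache[[paste0("pooled_", nm)]] <- pooled
    cache[[paste0("a_", nm)]] <- aa
    branches[[length(branches) + 1]] <- up
  }
  cat_ch <- sum(vapply(branches, function(b) dim(b)[3], numeric(1)))
  concat <- array(0, c(fd[1], fd[2], cat_ch, fd[4]))
  off <- 0L
  for (b in branches) {
    cb <- dim(b)[3]
    concat[, , off + seq_len(cb), ] <- b
    off <- off + cb
  }
  cache$concat <- concat
  af <- conv_apply(concat, p$fuse, relu = TRUE)
  if (train && cfg$dropout_rate > 0) {
    keep <- array(
      (runif(length(af)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate),
      dim(af))
    af <- af * keep
    cache$drop_mask <- keep
  }
  cache$a_fuse <- af
  logit <- conv_apply(af, p$head)
  ld <- dim(logit)
  up <- cpp_bilinear_fwd(logit, ld[1], ld[2], 1L, ld[4],
                         dim(x)[1], dim(x)[2])
  list(prob = 1 / (1 + exp(-up)), up = up, cache = cache)
}

conv_back <- function(x, p, dy, want_dx = TRUE) {
  d <- dim(x)
  cpp_conv_bwd(x, d[1], d[2], d[3], d[4], p$W, p$k, p$k, p$stride,
               p$pad, dy, want_dx)
}

# backward pass from dL/d(upsampled logits); returns gradients for
# every parameter
seg_backward <- function(model, cache, dup) {
  p <- model$params
  n_down <- model$arch$n_down
  grads <- list()
  xd <- dim(cache$x)
  fd <- dim(cache$a_deep)
  dlogit <- cpp_bilinear_bwd(dup, xd[1], xd[2], 1L, xd[4], fd[1], fd[2])
  bw <- conv_back(cache$a_fuse, p$head, dlogit)
  grads$head <- list(dW = bw$dW, db = bw$db)
  daf <- bw$dx
  if (!is.null(cache$drop_mask)) daf <- daf * cache$drop_mask
  daf <- daf * (cache$a_fuse > 0)
  bw <- conv_back(cache$concat, p$fuse, daf)
  grads$fuse <- list(dW = bw$dW, db = bw$db)
  dconcat <- bw$dx
  dfeat <- dconcat[, , seq_len(fd[3]), , drop = FALSE]
  dim(dfeat) <- c(fd[1], fd[2], fd[3], fd[4])
  off <- fd[3]
  for (bn in model$arch$bins) {
    nm <- paste0("ppm", bn)
    cb <- p[[nm]]$cout
    dup_b <- dconcat[, , off + seq_len(cb), , drop = FALSE]
    dim(dup_b) <- c(fd[1], fd[2], cb, fd[4])
    off <- off + cb
    daa <- cpp_bilinear_bwd(dup_b, fd[1], fd[2], cb, fd[4], bn, bn)
    daa <- daa * (cache[[paste0("a_", nm)]] > 0)
    bw <- conv_back(cache[[paste0("pooled_", nm)]], p[[nm]], daa)
    grads[[nm]] <- list(dW = bw$dW, db = bw$db)
    dfeat <- dfeat + cpp_avgpool_bwd(bw$dx, bn, p[[nm]]$cin, fd[4],
                                     fd[1], fd[2])
  }
  dfeat <- dfeat * (cache$a_deep > 0)
  a_prev <- if (n_down >= 1) cache[[paste0("a_enc", n_down)]] else cache$x
  bw <- conv_back(a_prev, p$deep, dfeat)
  grads$deep <- list(dW = bw$dW, db = bw$db)
  da <- bw$dx
  for (i in rev(seq_len(n_down))) {
    nm <- paste0("enc", i)
    da <- da * (cache[[paste0("a_", nm)]] > 0)
    a_prev <- if (i > 1) cache[[paste0("a_enc", i - 1)]] else cache$x
    bw <- conv_back(a_prev, p[[nm]], da, want_dx = i > 1)
    grads[[nm]] <- list(dW = bw$dW, db = bw$db)
    if (i > 1) da <- bw$dx
  }
  grads
}

#' Train a segmentation model
#'
#' Minimizes the additive Jaccard + Focal loss with Adam over shuffled
#' mini-batches. All randomness (shuffling, dropout) is controlled by
#' the model's config seed, so repeated runs with the same seed produce
#' identical loss histories.
#'
#' @param model a [build_segmenter()] model
#' @param images training patches: an H x W x 3 x N array, or a list of
#'   `ophio_scene` objects (patches are then extracted at the config's
#'   patch size/stride)
#' @param masks binary masks H x W x N matching `images`; ignored when
#'   `images` is a list of scenes
#' @param variant annotation variant used to build masks from scenes
#' @param epochs number of epochs (default: the config value)
#' @param verbose print per-epoch losses
#' @return the trained `seg_model`, with `loss_history` (one row per
#'   epoch: combined, jaccard, focal)
#' @export
train_segmenter <- function(model, images, masks = NULL,
                            variant = c("disc", "full"),
                            epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "seg_model"))
  cfg <- model$config
  variant <- match.arg(variant)
  if (is.list(images) && !is.array(images)) {
    tp <- make_training_patches(images, variant = variant,
                                patch_size = cfg$patch_size,
                                stride = cfg$patch_size)
    images <- tp$images
    masks <- tp$masks
  }
  d <- dim(images)
  if (length(d) != 4 || d[3] != 3)
    stop("images must be an H x W x 3 x N array")
  if (is.null(masks) || !identical(dim(masks), d[-3]))
    stop("masks must be an H x W x N array matching images")
  n_img <- d[4]
  if (n_img < 1) stop("empty training set")
  epochs <- as.integer(epochs %||% cfg$epochs)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed((cfg$seed + 1L) %% 2147483647L)
  # Adam state
  adam_m <- lapply(model$params, function(p)
    list(W = array(0, dim(p$W)), b = rep(0, length(p$b))))
  adam_v <- adam_m
  t_step <- 0L
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  history <- matrix(NA_real_, epochs, 3,
                    dimnames = list(NULL, c("loss", "jaccard", "focal")))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_img)
    ep_loss <- ep_j <- ep_f <- 0
    nb <- 0L
    for (start in seq(1, n_img, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n_img)]
      xb <- images[, , , idx, drop = FALSE]
      yb <- masks[, , idx, drop = FALSE]
      yb4 <- array(as.double(yb), c(d[1], d[2], 1, length(idx)))
      fw <- seg_forward(model, xb, train = TRUE)
      lg <- cpp_sigmoid_loss(fw$up, yb4, d[1] * d[2], length(idx),
                             cfg$loss_weights[1], cfg$loss_weights[2],
                             cfg$jaccard_smooth, cfg$focal_gamma,
                             cfg$focal_alpha)
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", ep,
             " (batch starting at ", start, "); last finite epoch loss: ",
             if (ep > 1) history[ep - 1, 1] else NA)
      grads <- seg_backward(model, fw$cache, lg$grad_logit)
      t_step <- t_step + 1L
      corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
      for (nm in names(model$params)) {
        g <- grads[[nm]]
        adam_m[[nm]]$W <- b1 * adam_m[[nm]]$W + (1 - b1) * g$dW
        adam_v[[nm]]$W <- b2 * adam_v[[nm]]$W + (1 - b2) * g$dW^2
        adam_m[[nm]]$b <- b1 * adam_m[[nm]]$b + (1 - b1) * g$db
        adam_v[[nm]]$b <- b2 * adam_v[[nm]]$b + (1 - b2) * g$db^2
        model$params[[nm]]$W <- model$params[[nm]]$W -
          cfg$learning_rate * corr * adam_m[[nm]]$W /
          (sqrt(adam_v[[nm]]$W) + aeps)
        model$params[[nm]]$b <- model$params[[nm]]$b -
          cfg$learning_rate * corr * adam_m[[nm]]$b /
          (sqrt(adam_v[[nm]]$b) + aeps)
      }
      ep_loss <- ep_loss + lg$loss
      ep_j <- ep_j + lg$jaccard
      ep_f <- ep_f + lg$focal
      nb <- nb + 1L
    }
    history[ep, ] <- c(ep_loss, ep_j, ep_f) / nb
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f (jaccard %.4f, focal %.4f)",
                      ep, epochs, history[ep, 1], history[ep, 2],
                      history[ep, 3]))
  }
  model$loss_history <- rbind(model$loss_history, history)
  model$trained <- TRUE
  model
}

#' Extract aligned (image, mask) training patches from scenes
#'
#' @param scenes list of `ophio_scene` objects
#' @param variant which annotation variant to rasterize into masks
#' @param patch_size,stride tiling parameters
#' @return list with `images` (ps x ps x 3 x K) and `masks` (ps x ps x K)
#' @export
make_training_patches <- function(scenes, variant = c("disc", "full"),
                                  patch_size = 288L, stride = 144L) {
  variant <- match.arg(variant)
  imgs <- list()
  msks <- list()
  for (sc in scenes) {
    stopifnot(inherits(sc, "ophio_scene"))
    H <- dim(sc$image)[1]; W <- dim(sc$image)[2]
    ann <- if (variant == "disc") sc$annotations_disc else sc$annotations_full
    mask <- rasterize_annotations(ann, H, W)
    grid <- plan_grid(H, W, patch_size, stride)
    imgs <- c(imgs, slice_patches(sc$image, grid))
    msks <- c(msks, slice_patches(mask, grid))
  }
  k <- length(imgs)
  ps <- as.integer(patch_size)
  images <- array(0, c(ps, ps, 3, k))
  masks <- array(0, c(ps, ps, k))
  for (i in seq_len(k)) {
    images[, , , i] <- imgs[[i]]
    masks[, , i] <- msks[[i]]
  }
  list(images = images, masks = masks)
}

#' Predict a probability map for a whole mosaic
#'
#' The mosaic is tiled with the config's patch size and stride, each
#' patch is passed through the network, and overlapping predictions are
#' merged by their per-pixel mean. Mosaics smaller than one patch are
#' reflection-padded and the result cropped back.
#'
#' @param model a trained `seg_model`
#' @param mosaic H x W x 3 array (or grayscale matrix) in [0, 1]
#' @param config optional [train_config()] override (defaults to the
#'   model's)
#' @return probability matrix H x W in [0, 1]
#' @export
predict_mosaic <- function(model, mosaic, config = model$config) {
  stopifnot(inherits(model, "seg_model"))
  if (length(dim(mosaic)) == 2)
    mosaic <- array(rep(mosaic, 3), c(dim(mosaic), 3))
  d <- dim(mosaic)
  ps <- config$patch_size
  if (d[1] < ps || d[2] < ps) {
    padded <- reflect_pad(mosaic, max(0, ps - d[1]), max(0, ps - d[2]))
    out <- predict_mosaic(model, padded, config)
    return(out[seq_len(d[1]), seq_len(d[2])])
  }
  grid <- plan_grid(d[1], d[2], ps, config$stride)
  patches <- slice_patches(mosaic, grid)
  k <- length(patches)
  probs <- vector("list", k)
  bs <- config$batch_size
  for (start in seq(1, k, by = bs)) {
    idx <- start:min(start + bs - 1, k)
    xb <- array(0, c(ps, ps, 3, length(idx)))
    for (j in seq_along(idx)) xb[, , , j] <- patches[[idx[j]]]
    pr <- seg_forward(model, xb, train = FALSE)$prob
    for (j in seq_along(idx)) probs[[idx[j]]] <- pr[, , 1, j]
  }
  reassemble(probs, grid)
}

reflect_pad <- function(img, pad_h, pad_w) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(H + pad_h)]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(W + pad_w)]
  img[ri, ci, , drop = FALSE]
}

#' Threshold a probability map into a binary mask
#'
#' Strictly greater than the threshold: a pixel exactly at the threshold
#' is background.
#'
#' @param prob probability matrix in [0, 1]
#' @param threshold scalar in (0, 1); default 0.5
#' @return integer 0/1 matrix
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  matrix(as.integer(prob > threshold), nrow(prob), ncol(prob))
}

#' @export
print.seg_model <- function(x, ...) {
  cat("<seg_model> profile:", x$arch$profile,
      " output stride:", x$arch$down_sample,
      " parameters:", format(x$n_params, big.mark = ","),
      if (x$trained) "(trained)" else "(untrained)", "\n")
  if (!is.null(x$loss_history))
    cat("  final loss:",
        format(x$loss_history[nrow(x$loss_history), 1], digits = 4),
        "after", nrow(x$loss_history), "epochs\n")
  invisible(x)
}

#' @export
summary.seg_model <- function(object, ...) {
  print(object)
  cat("  encoder widths:", paste(object$arch$widths$encoder, collapse = ", "),
      "| ppm:", object$arch$widths$ppm, "x bins",
      paste(object$arch$bins, collapse = ","),
      "| fuse:", object$arch$widths$fuse, "\n")
  cat("  patch:", object$config$patch_size, " stride:", object$config$stride,
      " lr:", object$config$learning_rate,
      " dropout:", object$config$dropout_rate, "\n")
  invisible(object)
}

#' @export
plot.seg_model <- function(x, ...) {
  if (is.null(x$loss_history)) stop("model has no training history")
  h <- x$loss_history
  plot(h[, 1], type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss", ...)
  lines(h[, 2], lty = 2)
  lines(h[, 3], lty = 3)
  legend("topright", c("combined", "jaccard", "focal"), lty = 1:3,
         bty = "n")
  invisible(x)
}

#' @export
predict.seg_model <- function(object, newdata, ...) {
  predict_mosaic(object, newdata)
}

#' Save / load a segmentation model
#'
#' The model is stored as an RDS plus a small JSON metadata sidecar
#' (architecture, config hash, loss summary).
#'
#' @param model a `seg_model`
#' @param path output `.rds` path
#' @return `path`, invisibly
#' @export
save_segmenter <- function(model, path) {
  saveRDS(model, path)
  meta <- list(
    profile = model$arch$profile,
    down_sample = model$arch$down_sample,
    n_params = model$n_params,
    trained = model$trained,
    epochs = if (is.null(model$loss_history)) 0L else nrow(model$loss_history),
    final_loss = if (is.null(model$loss_history)) NA else
      model$loss_history[nrow(model$loss_history), 1],
    config = unclass(model$config)[c("learning_rate", "batch_size",
                                     "patch_size", "stride",
                                     "dropout_rate", "down_sample",
                                     "seed")]
  )
  jsonlite::write_json(meta, sub("\\.rds$", "_meta.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "seg_model"))
  m
}
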