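# Segmentation training losses: soft Jaccard and binary focal loss, and
# their weighted additive combination. Inputs are probability arrays in
# [0, 1] and binary truth arrays of identical shape; both losses are
# scalars.

check_pair <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)))
    stop("pred and truth shapes differ")
  if (min(pred) < -1e-9 || max(pred) > 1 + 1e-9)
    stop("pred values must lie in [0, 1]")
  if (!is_binary(truth)) stop("truth must be binary")
  invisible(TRUE)
}

#' Soft Jaccard loss
#'
#' `1 - (I + s) / (U + s)` with soft intersection `I = sum(pred * truth)`
#' and union `U = sum(pred) + sum(truth) - I`; the smoothing term `s`
#' keeps the loss defined on empty patches. Zero for a perfect binary
#' prediction (up to smoothing), near one for a disjoint one.
#'
#' @param pred probability array in [0, 1]
#' @param truth binary array, same shape
#' @param smooth small positive smoothing constant
#' @return scalar loss in [0, 1)
#' @export
jaccard_loss <- function(pred, truth, smooth = 1) {
  check_pair(pred, truth)
  if (smooth <= 0) stop("smooth must be positive")
  i <- sum(pred * truth)
  u <- sum(pred) + sum(truth) - i
  1 - (i + smooth) / (u + smooth)
}

#' Binary focal loss
#'
#' Mean over pixels of `-alpha * (1 - p_t)^gamma * log(p_t)` where
#' `p_t = pred` on foreground truth pixels and `1 - pred` on background.
#' With `gamma = 0, alpha = 1` this reduces to mean binary cross-entropy.
#' Predictions are clipped away from 0/1 for numerical stability.
#'
#' @param pred probability array in [0, 1]
#' @param truth binary array, same shape
#' @param gamma focusing exponent (>= 0)
#' @param alpha balancing factor in (0, 1]
#' @param eps clipping bound for probabilities
#' @return scalar loss (>= 0)
#' @export
focal_loss <- function(pred, truth, gamma = 2, alpha = 0.25, eps = 1e-7) {
  check_pair(pred, truth)
  if (gamma < 0) stop("gamma must be non-negative")
  p <- pmin(pmax(pred, eps), 1 - eps)
  pt <- ifelse(truth > 0, p, 1 - p)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Additive Jaccard + Focal training loss
#'
#' `w_jaccard * jaccard_loss + w_focal * focal_loss` with the component
#' parameters taken from a [train_config()].
#'
#' @param pred probability array in [0, 1]
#' @param truth binary array, same shape
#' @param config a [train_config()]; supplies `loss_weights`,
#'   `jaccard_smooth`, `focal_gamma`, `focal_alpha`
#' @return scalar loss
#' @export
combined_loss <- function(pred, truth, config = train_config()) {
  w <- config$loss_weights
  if (any(w < 0)) stop("loss weights must be non-negative")
  w[1] * jaccard_loss(pred, truth, smooth = config$jaccard_smooth) +
    w[2] * focal_loss(pred, truth, gamma = config$focal_gamma,
                      alpha = config$focal_alpha)
}

# gradients of the combined loss w.r.t. pred, for the training loop.
# Jaccard is computed per sample (4th dim) and averaged; focal is a mean
# over all pixels.
combined_loss_grad <- function(pred, truth, config) {
  w <- config$loss_weights
  s <- config$jaccard_smooth
  g <- config$focal_gamma
  a <- config$focal_alpha
  eps <- 1e-7
  d <- dim(pred)
  n <- if (length(d) == 4) d[4] else 1
  grad <- array(0, dim(pred))
  loss_j <- 0
  if (w[1] > 0) {
    for (k in seq_len(n)) {
      pk <- if (length(d) == 4) pred[, , , k] else pred
      tk <- if (length(d) == 4) truth[, , , k] else truth
      i <- sum(pk * tk)
      u <- sum(pk) + sum(tk) - i
      loss_j <- loss_j + (1 - (i + s) / (u + s)) / n
      gk <- -(tk * (u + s) - (i + s) * (1 - tk)) / (u + s)^2 / n
      if (length(d) == 4) grad[, , , k] <- grad[, , , k] + w[1] * gk
      else grad <- grad + w[1] * gk
    }
  }
  loss_f <- 0
  if (w[2] > 0) {
    p <- pmin(pmax(pred, eps), 1 - eps)
    pt <- ifelse(truth > 0, p, 1 - p)
    loss_f <- mean(-a * (1 - pt)^g * log(pt))
    dpt <- if (g == 0) -a / pt else
      a * g * (1 - pt)^(g - 1) * log(pt) - a * (1 - pt)^g / pt
    sgn <- ifelse(truth > 0, 1, -1)
    grad <- grad + w[2] * array(dpt * sgn / length(pred), dim(pred))
  }
  list(loss = w[1] * loss_j + w[2] * loss_f, grad = grad,
       jaccard = loss_j, focal = loss_f)
}
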