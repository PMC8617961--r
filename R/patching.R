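# Sliding-window tiling of mosaics into fixed-size overlapping patches
# and mean-merge reassembly of per-patch probability outputs. Offsets are
# placed at multiples of the stride, plus a final flush offset at
# (dimension - patch_size) whenever the last strided position does not
# reach the border, so every pixel is covered.

axis_offsets <- function(dim, patch_size, stride) {
  pos <- seq(0L, dim - patch_size, by = stride)
  if (pos[length(pos)] != dim - patch_size)
    pos <- c(pos, dim - patch_size)
  as.integer(pos)
}

#' Plan a deterministic patch grid over an image
#'
#' @param height,width image dimensions in pixels
#' @param patch_size square patch side in pixels (default 288)
#' @param stride sliding-window stride in pixels (default 144)
#' @return object of class `patch_grid` with `offsets`, an n x 2 integer
#'   matrix of 0-based (row, col) top-left corners in row-major order
#' @export
plan_grid <- function(height, width, patch_size = 288L, stride = 144L) {
  if (patch_size > height || patch_size > width)
    stop("image (", height, "x", width, ") smaller than patch size ",
         patch_size, "; pad first")
  if (stride < 1 || stride > patch_size)
    stop("stride must satisfy 1 <= stride <= patch_size")
  rows <- axis_offsets(as.integer(height), as.integer(patch_size),
                       as.integer(stride))
  cols <- axis_offsets(as.integer(width), as.integer(patch_size),
                       as.integer(stride))
  offsets <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 offsets = offsets,
                 image_height = as.integer(height),
                 image_width = as.integer(width)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat("<patch_grid>", nrow(x$offsets), "patches of", x$patch_size,
      "px (stride", x$stride, ") over", x$image_height, "x",
      x$image_width, "\n")
  invisible(x)
}

#' Slice an image into the patches of a grid
#'
#' @param image matrix (H x W) or array (H x W x C) matching the grid
#'   dimensions
#' @param grid a [plan_grid()] result
#' @return list of patches (same dimensionality as `image`), one per
#'   grid offset, in grid order
#' @export
slice_patches <- function(image, grid) {
  d <- dim(image)
  if (d[1] != grid$image_height || d[2] != grid$image_width)
    stop("image dimensions do not match grid")
  ps <- grid$patch_size
  lapply(seq_len(nrow(grid$offsets)), function(i) {
    r <- grid$offsets[i, 1]; c <- grid$offsets[i, 2]
    if (length(d) == 2) image[r + seq_len(ps), c + seq_len(ps)]
    else image[r + seq_len(ps), c + seq_len(ps), , drop = FALSE]
  })
}

#' Reassemble per-patch probability outputs into a mosaic probability map
#'
#' Where patches overlap, the per-pixel arithmetic mean of all covering
#' patch predictions is used (symmetric and order-independent; the
#' binarization threshold is applied after merging).
#'
#' @param prob_patches list of numeric matrices, one per grid offset
#' @param grid the [plan_grid()] used to slice
#' @return numeric matrix `image_height` x `image_width` with values in
#'   [0, 1]
#' @export
reassemble <- function(prob_patches, grid) {
  if (length(prob_patches) != nrow(grid$offsets))
    stop("expected ", nrow(grid$offsets), " patches, got ",
         length(prob_patches))
  H <- grid$image_height; W <- grid$image_width; ps <- grid$patch_size
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_len(nrow(grid$offsets))) {
    p <- prob_patches[[i]]
    if (!all(dim(p)[1:2] == c(ps, ps)))
      stop("patch ", i, " has wrong dimensions")
    r <- grid$offsets[i, 1]; c <- grid$offsets[i, 2]
    acc[r + seq_len(ps), c + seq_len(ps)] <-
      acc[r + seq_len(ps), c + seq_len(ps)] + p
    cnt[r + seq_len(ps), c + seq_len(ps)] <-
      cnt[r + seq_len(ps), c + seq_len(ps)] + 1
  }
  acc / cnt
}
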