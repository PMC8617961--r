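# Optional pre-processing of mosaics before training/inference, via a
# registry of named enhancement operators. Built-ins: "none", gamma
# correction ("gc"), CLAHE ("clahe"), and a global percentile stretch
# ("stretch"). Further underwater-enhancement methods can be plugged in
# with register_enhancement(). Enhancement is applied to the whole
# mosaic before patching. All operators preserve shape and the [0, 1]
# range and are deterministic.

.enh_registry <- new.env(parent = emptyenv())

#' Register an enhancement operator
#'
#' @param name registry key
#' @param fn function `(image, params)` returning an image of identical
#'   shape with values in [0, 1]
#' @return `name`, invisibly
#' @export
register_enhancement <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .enh_registry)
  invisible(name)
}

#' List registered enhancement operators
#' @return character vector of registry keys
#' @export
list_enhancements <- function() sort(ls(.enh_registry))

#' Describe an enhancement to apply
#'
#' @param name registered operator name (`"none"`, `"gc"`, `"clahe"`,
#'   `"stretch"`, or a user-registered key)
#' @param ... operator parameters (e.g. `gamma` for `"gc"`)
#' @return object of class `enhancement_spec`
#' @export
enhancement_spec <- function(name = "none", ...) {
  structure(list(name = name, params = list(...)),
            class = "enhancement_spec")
}

#' Apply a named enhancement to an image
#'
#' @param image matrix or H x W x 3 array in [0, 1]
#' @param spec an [enhancement_spec()]
#' @return enhanced image, same shape, values in [0, 1]
#' @export
apply_enhancement <- function(image, spec) {
  stopifnot(inherits(spec, "enhancement_spec"))
  if (!exists(spec$name, envir = .enh_registry))
    stop("unknown enhancement '", spec$name, "'; registered: ",
         paste(list_enhancements(), collapse = ", "))
  fn <- get(spec$name, envir = .enh_registry)
  out <- fn(image, spec$params)
  clip01(out)
}

#' Gamma intensity correction
#'
#' Per-channel power law `out = in^gamma`; gamma < 1 brightens, gamma > 1
#' darkens, gamma = 1 is the identity. 0 and 1 are fixed points.
#'
#' @param image image in [0, 1]
#' @param gamma positive exponent
#' @return corrected image
#' @export
gamma_correct <- function(image, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a positive scalar")
  stopif_not_prob(image)
  image^gamma
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Equalizes the luminance (HSV value) channel tile-wise with clipped
#' histograms and bilinear tile interpolation; chroma is preserved by
#' rescaling the RGB channels with the luminance gain. Grayscale input
#' is equalized directly.
#'
#' @param image matrix or H x W x 3 array in [0, 1]
#' @param clip_limit positive histogram clip limit
#' @param tile_grid integer (rows, cols) tile grid
#' @return equalized image in [0, 1]
#' @export
clahe <- function(image, clip_limit = 2, tile_grid = c(8, 8)) {
  if (clip_limit <= 0) stop("clip_limit must be positive")
  tile_grid <- rep(as.integer(tile_grid), length.out = 2)
  if (any(tile_grid < 1)) stop("tile_grid entries must be >= 1")
  stopif_not_prob(image)
  eq <- function(v) {
    # no contrast to amplify: constant input maps to itself
    if (diff(range(v)) < 1e-12) return(v)
    # EBImage images are (x, y); transpose in and out
    out <- EBImage::clahe(t(v), nx = tile_grid[2], ny = tile_grid[1],
                          limit = clip_limit, keep.range = TRUE)
    t(as.matrix(out))
  }
  if (length(dim(image)) == 2) return(clip01(eq(image)))
  v <- pmax(image[, , 1], pmax(image[, , 2], image[, , 3]))
  v2 <- eq(v)
  gain <- ifelse(v > 0, v2 / v, 0)
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * gain
  clip01(out)
}

#' Global percentile contrast stretch
#'
#' Linearly maps each channel so its low/high percentiles hit 0/1, then
#' clips. A channel whose two percentiles coincide (flat channel) is
#' returned unchanged. This is a deliberately simple global stretch, not
#' the histogram-redistribution method used on underwater imagery
#' elsewhere.
#'
#' @param image matrix or H x W x 3 array in [0, 1]
#' @param low_pct,high_pct percentile bounds, `0 <= low < high <= 100`
#' @return stretched image in [0, 1]
#' @export
percentile_stretch <- function(image, low_pct = 1, high_pct = 99) {
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stop("need 0 <= low_pct < high_pct <= 100")
  stopif_not_prob(image)
  stretch1 <- function(ch) {
    q <- stats::quantile(ch, c(low_pct, high_pct) / 100, names = FALSE)
    if (q[2] - q[1] < 1e-12) return(ch)
    clip01((ch - q[1]) / (q[2] - q[1]))
  }
  if (length(dim(image)) == 2) return(stretch1(image))
  out <- image
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- stretch1(image[, , ch])
  out
}

register_builtin_enhancements <- function() {
  register_enhancement("none", function(image, params) image)
  register_enhancement("gc", function(image, params) {
    gamma_correct(image, params$gamma %||% 1)
  })
  register_enhancement("clahe", function(image, params) {
    clahe(image, clip_limit = params$clip_limit %||% 2,
          tile_grid = params$tile_grid %||% c(8, 8))
  })
  register_enhancement("stretch", function(image, params) {
    percentile_stretch(image, low_pct = params$low_pct %||% 1,
                       high_pct = params$high_pct %||% 99)
  })
}

.onLoad <- function(libname, pkgname) {
  register_builtin_enhancements()
  cpp_tune_allocator()
}
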