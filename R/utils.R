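# shared internal helpers

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_binary <- function(x) {
  u <- unique(as.vector(x))
  all(u %in% c(0, 1, TRUE, FALSE))
}

as_mask <- function(x) {
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  m
}

stopif_not_prob <- function(x, name = "image") {
  if (!is.numeric(x)) stop(name, " must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop(name, " contains non-finite values", call. = FALSE)
  rng <- range(x)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop(name, " values must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

# deterministic child seeds from a master seed, kept inside 32-bit range
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% 2147483647L))
  sample.int(2147483646L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Read an RGB image into a [0, 1] array
#'
#' Reads PNG, TIFF, or JPEG-free formats supported by the underlying
#' readers and returns an H x W x 3 numeric array in [0, 1]. Grayscale
#' images are replicated to three channels; an alpha channel is dropped.
#'
#' @param path file path (.png or .tif/.tiff)
#' @return numeric array, height x width x 3, values in [0, 1]
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path)
      x
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  clip01(img)
}

#' Write an image array to disk
#'
#' @param img matrix (grayscale) or H x W x 3 array in [0, 1]
#' @param path output path; `.png` writes 8-bit PNG, `.tif`/`.tiff`
#'   writes 32-bit float TIFF (used for probability maps)
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- clip01(img)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 32L),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

rgb_to_gray <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
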