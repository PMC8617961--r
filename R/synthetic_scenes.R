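# Synthetic benthic scene generator. Emulates seabed mosaic crops
# containing brittle stars: an elliptical central body disc with five
# radiating, curved, tapering arms on a low-frequency textured
# background, plus optional stitching-style artifacts (border clipping,
# duplicated instances, discs hidden under sediment). Every scene comes
# with exact polygon ground truth in both annotation variants: polygons
# are traced along pixel boundaries of the rasterized organism, so
# rasterizing the annotations reproduces the ground-truth mask exactly.

#' Configuration for synthetic seabed scenes
#'
#' Defaults describe a mid-density scene: organism geometry is scaled so
#' that every disc comfortably exceeds the 40 px minimal-area counting
#' filter (disc radii 9-16 px give areas above 230 px even at maximal
#' ellipse eccentricity) and the default centre separation of 60 px
#' clears the 55 px watershed seed separation, so counting the
#' ground-truth disc mask recovers the true count exactly.
#'
#' @param width,height scene dimensions in pixels
#' @param n_stars number of organisms: a single count or a `(min, max)`
#'   range sampled uniformly
#' @param disc_radius_range ellipse base radius range in pixels
#' @param n_arms arms per organism (brittle stars have five)
#' @param arm_length_range,arm_width_range arm length and base width
#'   ranges in pixels (arms taper towards the tip)
#' @param organism_intensity mean organism luminance in [0, 1]
#' @param background_mean mean background luminance in [0, 1]
#' @param background_texture_scale amplitude of the low-frequency
#'   background texture, in [0, 1] luminance units
#' @param noise_sd Gaussian pixel noise standard deviation
#' @param clip_at_border allow organisms to be clipped by the image
#'   border (stitching artifact)
#' @param duplicate_instance render one organism twice at a small offset
#'   while counting it once (stitching artifact)
#' @param hide_disc hide one organism's disc under the sediment: its
#'   disc is not rendered and it has no disc-variant annotation
#' @param min_center_separation minimal Euclidean distance between
#'   organism centres in pixels (ignored for the duplicated instance)
#' @param seed default random seed for [generate_scene()]
#' @return object of class `scene_config`
#' @export
scene_config <- function(width = 576, height = 576,
                         n_stars = c(8, 16),
                         disc_radius_range = c(9, 16),
                         n_arms = 5,
                         arm_length_range = c(25, 45),
                         arm_width_range = c(3, 6),
                         organism_intensity = 0.25,
                         background_mean = 0.6,
                         background_texture_scale = 0.08,
                         noise_sd = 0.03,
                         clip_at_border = FALSE,
                         duplicate_instance = FALSE,
                         hide_disc = FALSE,
                         min_center_separation = 60,
                         seed = 1L) {
  rng_ok <- function(r) length(r) %in% c(1, 2) && all(is.finite(r)) &&
    all(r > 0) && (length(r) == 1 || r[1] <= r[2])
  if (width < 16 || height < 16) stop("scene dimensions too small")
  if (!rng_ok(disc_radius_range)) stop("invalid disc_radius_range")
  if (!rng_ok(arm_length_range)) stop("invalid arm_length_range")
  if (!rng_ok(arm_width_range)) stop("invalid arm_width_range")
  if (length(n_stars) == 2 && n_stars[1] > n_stars[2])
    stop("n_stars range minimum exceeds maximum")
  if (any(n_stars < 0)) stop("n_stars must be non-negative")
  for (v in c(organism_intensity, background_mean,
              background_texture_scale))
    if (v < 0 || v > 1) stop("intensity parameters must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (min_center_separation < 0) stop("min_center_separation must be >= 0")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_stars = n_stars, disc_radius_range = rep(disc_radius_range, length.out = 2),
    n_arms = as.integer(n_arms),
    arm_length_range = rep(arm_length_range, length.out = 2),
    arm_width_range = rep(arm_width_range, length.out = 2),
    organism_intensity = organism_intensity,
    background_mean = background_mean,
    background_texture_scale = background_texture_scale,
    noise_sd = noise_sd,
    clip_at_border = isTRUE(clip_at_border),
    duplicate_instance = isTRUE(duplicate_instance),
    hide_disc = isTRUE(hide_disc),
    min_center_separation = min_center_separation,
    seed = as.integer(seed)
  ), class = "scene_config")
}

# rasterize one organism's geometry onto the scene canvas.
# Returns integer masks for the disc and the full shape (disc + arms).
draw_organism <- function(H, W, cx, cy, r, ecc, theta, n_arms,
                          arm_len, arm_w0) {
  disc <- matrix(0L, H, W)
  full <- matrix(0L, H, W)
  a <- r
  b <- r * (1 - ecc)
  # disc: filled rotated ellipse
  ext <- ceiling(a) + 1
  rr <- max(0, floor(cy - ext)):min(H - 1, ceiling(cy + ext))
  cc <- max(0, floor(cx - ext)):min(W - 1, ceiling(cx + ext))
  if (length(rr) > 0 && length(cc) > 0) {
    dx <- outer(rep(1, length(rr)), cc - cx)
    dy <- outer(rr - cy, rep(1, length(cc)))
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    inside <- (u * u + v * v) <= 1
    disc[rr + 1, cc + 1][inside] <- 1L
  }
  full[disc == 1L] <- 1L
  # arms: quadratic Bezier centrelines with linearly tapering half-width
  base_ang <- theta + 2 * pi * (seq_len(n_arms) - 1) / n_arms +
    runif(n_arms, -0.25, 0.25)
  for (k in seq_len(n_arms)) {
    phi <- base_ang[k]
    dirv <- c(cos(phi), sin(phi))
    # ellipse radius along phi (relative to rotation theta)
    rel <- phi - theta
    r_edge <- a * b / sqrt((b * cos(rel))^2 + (a * sin(rel))^2)
    L <- runif(1, arm_len[1], arm_len[2])
    w0 <- runif(1, arm_w0[1], arm_w0[2]) / 2
    p0 <- c(cx, cy) + 0.8 * r_edge * dirv
    p2 <- p0 + L * dirv
    perp <- c(-dirv[2], dirv[1])
    p1 <- (p0 + p2) / 2 + perp * runif(1, -0.25, 0.25) * L
    nt <- max(16L, ceiling(2 * L))
    tt <- seq(0, 1, length.out = nt)
    bx <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
    by <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
    hw <- w0 + (0.7 - w0) * tt
    hw[hw < 0.7] <- 0.7
    for (i in seq_len(nt)) {
      h <- hw[i]
      r0 <- max(0, floor(by[i] - h)):min(H - 1, ceiling(by[i] + h))
      c0 <- max(0, floor(bx[i] - h)):min(W - 1, ceiling(bx[i] + h))
      if (length(r0) == 0 || length(c0) == 0) next
      if (r0[1] > r0[length(r0)] || c0[1] > c0[length(c0)]) next
      ddx <- outer(rep(1, length(r0)), c0 - bx[i])
      ddy <- outer(r0 - by[i], rep(1, length(c0)))
      stamp <- (ddx * ddx + ddy * ddy) <= h * h
      full[r0 + 1, c0 + 1][stamp] <- 1L
    }
  }
  list(disc = disc, full = full)
}

# largest 4-connected component, preferring the one containing (cy, cx)
select_component <- function(mask, cy, cx) {
  lab <- cpp_label_components(mask, 4L)
  if (max(lab) == 0L) return(NULL)
  ri <- as.integer(round(cy)) + 1L
  ci <- as.integer(round(cx)) + 1L
  pick <- 0L
  if (ri >= 1 && ri <= nrow(lab) && ci >= 1 && ci <= ncol(lab) &&
      lab[ri, ci] > 0L) {
    pick <- lab[ri, ci]
  } else {
    sizes <- tabulate(lab[lab > 0L])
    pick <- which.max(sizes)
  }
  matrix(as.integer(lab == pick), nrow(lab), ncol(lab))
}

#' Generate one synthetic seabed scene with ground truth
#'
#' Organisms are placed by rejection sampling under the minimal centre
#' separation; infeasible configurations (too many stars for the area)
#' raise an error rather than silently undercounting. Annotation
#' polygons are traced along pixel boundaries so that
#' [rasterize_annotations()] reproduces the ground-truth masks exactly;
#' organism masks are the filled outer contours of the rasterized
#' shapes.
#'
#' @param config a [scene_config()]
#' @param seed integer seed; defaults to `config$seed`. Identical
#'   `(config, seed)` give bit-identical scenes.
#' @return object of class `ophio_scene`: a list with `image` (H x W x 3
#'   array in [0, 1]), `annotations_full` and `annotations_disc`
#'   ([annotation_set()]s), `true_count`, `seed`, and `config`
#' @export
generate_scene <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scene_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  H <- config$height; W <- config$width
  n <- if (length(config$n_stars) == 2)
    sample(config$n_stars[1]:config$n_stars[2], 1) else as.integer(config$n_stars)

  # per-organism geometry
  geom <- NULL
  if (n > 0) {
    geom <- data.frame(
      r = runif(n, config$disc_radius_range[1], config$disc_radius_range[2]),
      ecc = runif(n, 0.05, 0.25),
      theta = runif(n, 0, pi),
      arm_len = runif(n, config$arm_length_range[1], config$arm_length_range[2])
    )
    # placement with rejection sampling
    margin <- if (config$clip_at_border) rep(2, n)
      else geom$r + geom$arm_len + 2
    cxs <- numeric(0); cys <- numeric(0)
    budget <- 300L * n
    for (i in seq_len(n)) {
      lo_x <- margin[i]; hi_x <- W - 1 - margin[i]
      lo_y <- margin[i]; hi_y <- H - 1 - margin[i]
      if (hi_x <= lo_x || hi_y <= lo_y)
        stop("scene too small for organism extent; increase dimensions ",
             "or enable clip_at_border")
      placed <- FALSE
      while (budget > 0L) {
        budget <- budget - 1L
        cx <- runif(1, lo_x, hi_x)
        cy <- runif(1, lo_y, hi_y)
        if (length(cxs) == 0 ||
            all((cxs - cx)^2 + (cys - cy)^2 >=
                config$min_center_separation^2)) {
          cxs <- c(cxs, cx); cys <- c(cys, cy)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", n, " organisms with separation ",
             config$min_center_separation, " in ", W, "x", H,
           " after bounded retries")
    }
    geom$cx <- cxs; geom$cy <- cys
  }

  hidden_idx <- if (config$hide_disc && n > 0) sample(n, 1) else 0L
  dup_idx <- if (config$duplicate_instance && n > 0) sample(n, 1) else 0L

  polys_full <- vector("list", n)
  polys_disc <- vector("list", n)
  masks_full <- vector("list", n)
  masks_disc <- vector("list", n)
  render_extra <- NULL

  for (i in seq_len(n)) {
    g <- draw_organism(H, W, geom$cx[i], geom$cy[i], geom$r[i], geom$ecc[i],
                       geom$theta[i], config$n_arms,
                       rep(geom$arm_len[i], 2), config$arm_width_range)
    comp <- select_component(g$full, geom$cy[i], geom$cx[i])
    if (is.null(comp)) next  # fully clipped away (cannot happen: centre inside)
    poly_f <- cpp_trace_outer_boundary(comp)
    mask_f <- cpp_rasterize_polygons(list(poly_f), H, W)
    polys_full[[i]] <- poly_f
    masks_full[[i]] <- mask_f
    if (i != hidden_idx && sum(g$disc) > 0) {
      dcomp <- select_component(g$disc, geom$cy[i], geom$cx[i])
      if (!is.null(dcomp) && all(dcomp <= mask_f)) {
        poly_d <- cpp_trace_outer_boundary(dcomp)
        polys_disc[[i]] <- poly_d
        masks_disc[[i]] <- cpp_rasterize_polygons(list(poly_d), H, W)
      }
    }
    if (i == dup_idx) {
      off <- c(round(runif(1, 5, 10)), round(runif(1, 5, 10)))
      sh <- matrix(0L, H, W)
      src_r <- seq_len(H - off[1])
      src_c <- seq_len(W - off[2])
      sh[src_r + off[1], src_c + off[2]] <- mask_f[src_r, src_c]
      render_extra <- sh
    }
  }

  keep <- !vapply(masks_full, is.null, logical(1))
  true_count <- sum(keep)

  # render: low-frequency texture + noise background, organisms darker
  cell <- 24
  gh <- ceiling(H / cell) + 1; gw <- ceiling(W / cell) + 1
  coarse <- matrix(rnorm(gh * gw), gh, gw)
  tex <- cpp_bilinear_fwd(array(coarse, c(gh, gw, 1, 1)), gh, gw, 1L, 1L,
                          as.integer(H), as.integer(W))[, , 1, 1]
  lum <- config$background_mean + config$background_texture_scale * tex +
    rnorm(H * W, 0, config$noise_sd)
  org_tint <- c(1.06, 0.97, 0.90)
  bg_tint <- c(0.96, 1.03, 0.94)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- lum * bg_tint[ch]
  for (i in which(keep)) {
    vis <- masks_full[[i]]
    if (i == hidden_idx) {
      # disc polygon was not emitted; carve the geometric disc out of the
      # rendering so only arms are visible
      g <- draw_organism_disc_only(H, W, geom$cx[i], geom$cy[i], geom$r[i],
                                   geom$ecc[i], geom$theta[i])
      vis <- vis * (1L - g)
    }
    idx <- vis == 1L
    val <- config$organism_intensity + rnorm(1, 0, 0.02)
    for (ch in 1:3)
      img[, , ch][idx] <- val * org_tint[ch] +
        rnorm(sum(idx), 0, config$noise_sd)
  }
  if (!is.null(render_extra)) {
    idx <- render_extra == 1L
    val <- config$organism_intensity + rnorm(1, 0, 0.02)
    for (ch in 1:3)
      img[, , ch][idx] <- val * org_tint[ch] +
        rnorm(sum(idx), 0, config$noise_sd)
  }
  img <- clip01(img)

  mk_set <- function(polys, variant) {
    ps <- Filter(Negate(is.null), polys)
    annotation_set(
      mosaic_id = paste0("synthetic-", seed), variant = variant,
      annotator = "synthetic",
      polygons = lapply(ps, function(v)
        polygon_annotation(v, variant = variant))
    )
  }
  structure(list(
    image = img,
    annotations_full = mk_set(polys_full, "full"),
    annotations_disc = mk_set(polys_disc, "disc"),
    true_count = true_count,
    seed = as.integer(seed),
    config = config
  ), class = "ophio_scene")
}

draw_organism_disc_only <- function(H, W, cx, cy, r, ecc, theta) {
  a <- r; b <- r * (1 - ecc)
  disc <- matrix(0L, H, W)
  ext <- ceiling(a) + 1
  rr <- max(0, floor(cy - ext)):min(H - 1, ceiling(cy + ext))
  cc <- max(0, floor(cx - ext)):min(W - 1, ceiling(cx + ext))
  dx <- outer(rep(1, length(rr)), cc - cx)
  dy <- outer(rr - cy, rep(1, length(cc)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  disc[rr + 1, cc + 1][(u * u + v * v) <= 1] <- 1L
  disc
}

#' @export
print.ophio_scene <- function(x, ...) {
  cat("<ophio_scene>", x$config$width, "x", x$config$height,
      " organisms:", x$true_count,
      " (full:", length(x$annotations_full),
      ", disc:", length(x$annotations_disc), ") seed:", x$seed, "\n")
  invisible(x)
}

#' Generate a reproducible set of synthetic scenes
#'
#' Per-scene seeds are derived deterministically from the master seed, so
#' the same `(config, n_scenes, seed)` always yields bit-identical scene
#' lists.
#'
#' @param config a [scene_config()]
#' @param n_scenes number of scenes (>= 1)
#' @param seed master seed
#' @return list of `ophio_scene` objects
#' @export
generate_dataset <- function(config, n_scenes, seed = config$seed) {
  stopifnot(n_scenes >= 1)
  seeds <- derive_seeds(seed, n_scenes)
  lapply(seeds, function(s) generate_scene(config, seed = s))
}

#' Write a scene to disk (PNG image + annotation JSONs + manifest)
#'
#' @param scene an `ophio_scene`
#' @param dir output directory (created if needed)
#' @param prefix filename prefix
#' @return named character vector of written paths, invisibly
#' @export
write_scene <- function(scene, dir, prefix = sprintf("scene_%d", scene$seed)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    image = file.path(dir, paste0(prefix, ".png")),
    full = file.path(dir, paste0(prefix, "_full.json")),
    disc = file.path(dir, paste0(prefix, "_disc.json")),
    manifest = file.path(dir, paste0(prefix, "_manifest.json"))
  )
  write_image(scene$image, paths["image"])
  write_annotations(scene$annotations_full, paths["full"])
  write_annotations(scene$annotations_disc, paths["disc"])
  jsonlite::write_json(
    list(seed = scene$seed, true_count = scene$true_count,
         config = unclass(scene$config)),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
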