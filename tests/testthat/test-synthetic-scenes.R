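# synthetic scene generator: determinism, counts, artifacts, and the
# geometric guarantees downstream counting relies on

test_that("scene generation is deterministic and counts organisms by construction", {
  cfg <- scene_config(width = 640, height = 640, n_stars = 20,
                      min_center_separation = 60, seed = 7)
  sc <- generate_scene(cfg, seed = 7)
  expect_equal(sc$true_count, 20)
  expect_length(sc$annotations_full$polygons, 20)
  expect_length(sc$annotations_disc$polygons, 20)
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  sc2 <- generate_scene(cfg, seed = 7)
  expect_identical(sc, sc2)
  sc3 <- generate_scene(cfg, seed = 8)
  expect_false(identical(sc$image, sc3$image))
})

test_that("empty scene is a blank textured image with no annotations", {
  cfg <- scene_config(width = 128, height = 128, n_stars = 0, seed = 3)
  sc <- generate_scene(cfg)
  expect_equal(sc$true_count, 0)
  expect_length(sc$annotations_full$polygons, 0)
  expect_length(sc$annotations_disc$polygons, 0)
  m <- rasterize_annotations(sc$annotations_full, 128, 128)
  expect_equal(sum(m), 0)
})

test_that("hide_disc drops exactly one disc annotation but keeps the full one", {
  cfg <- scene_config(width = 512, height = 512, n_stars = 10,
                      hide_disc = TRUE, seed = 3)
  sc <- generate_scene(cfg, seed = 3)
  expect_length(sc$annotations_full$polygons, 10)
  expect_length(sc$annotations_disc$polygons, 9)
  expect_equal(sc$true_count, 10)
})

test_that("disc masks are contained in full masks and respect the area floor", {
  for (seed in c(2, 5, 9)) {
    cfg <- small_scene_config()
    sc <- generate_scene(cfg, seed = seed)
    H <- cfg$height; W <- cfg$width
    md <- rasterize_annotations(sc$annotations_disc, H, W)
    mf <- rasterize_annotations(sc$annotations_full, H, W)
    expect_true(all(md <= mf))
    # every disc polygon alone clears the 40 px minimal-area filter
    for (p in sc$annotations_disc$polygons) {
      a <- sum(rasterize_annotations(list(p), H, W))
      expect_gt(a, 40)
    }
  }
})

test_that("dataset generation is reproducible and seeds differ across scenes", {
  cfg <- small_scene_config()
  d1 <- generate_dataset(cfg, 3, seed = 1)
  d2 <- generate_dataset(cfg, 3, seed = 1)
  expect_identical(d1, d2)
  d3 <- generate_dataset(cfg, 3, seed = 2)
  expect_false(identical(d1[[1]]$image, d3[[1]]$image))
  cfg_fixed <- scene_config(width = 320, height = 320, n_stars = 5,
                            min_center_separation = 60)
  d4 <- generate_dataset(cfg_fixed, 5, seed = 4)
  expect_equal(sum(vapply(d4, `[[`, numeric(1), "true_count")), 25)
})

test_that("infeasible placement errors instead of undercounting", {
  cfg <- scene_config(width = 200, height = 200, n_stars = 40,
                      min_center_separation = 80, seed = 1)
  expect_error(generate_scene(cfg), "could not place|too small")
})

test_that("duplicated-instance artifact renders twice but counts once", {
  cfg <- scene_config(width = 448, height = 448, n_stars = 6,
                      duplicate_instance = TRUE, seed = 11)
  sc <- generate_scene(cfg, seed = 11)
  expect_equal(sc$true_count, 6)
  expect_length(sc$annotations_full$polygons, 6)
  # the rendered organism pixels must exceed the annotated ones (the
  # duplicate is painted but not annotated)
  mf <- rasterize_annotations(sc$annotations_full, 448, 448)
  lum <- 0.299 * sc$image[, , 1] + 0.587 * sc$image[, , 2] +
    0.114 * sc$image[, , 3]
  dark <- lum < 0.45
  expect_gt(sum(dark & mf == 0), 50)
})

test_that("scene round-trips through disk artifacts", {
  cfg <- small_scene_config()
  sc <- generate_scene(cfg, seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  img <- read_image(paths["image"])
  expect_equal(dim(img), dim(sc$image))
  expect_lt(max(abs(img - sc$image)), 1 / 254)  # 8-bit quantization
  ann <- read_annotations(paths["full"])
  expect_equal(length(ann), length(sc$annotations_full))
  expect_equal(ann$polygons[[1]]$vertices,
               sc$annotations_full$polygons[[1]]$vertices)
})
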