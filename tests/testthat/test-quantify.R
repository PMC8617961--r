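# counting workflow: morphology, EDT, peak seeding, watershed, and the
# full pipeline with its recovery guarantees

test_that("counting config pairs kernel and area with the variant", {
  cd <- counting_config("disc")
  expect_equal(cd$kernel_size, c(2L, 2L))
  expect_equal(cd$min_area, 40L)
  cf <- counting_config("full")
  expect_equal(cf$kernel_size, c(4L, 4L))
  expect_equal(cf$min_area, 120L)
  expect_equal(cd$edt_min_distance, 55)
  expect_equal(cd$connectivity, 8L)
})

test_that("elliptical kernels match the inscribed-ellipse construction", {
  # even sizes follow the floor(size/2)-anchored convention
  expect_equal(ellipse_kernel(c(2, 2)),
               rbind(c(0L, 1L), c(1L, 1L)))
  k3 <- ellipse_kernel(c(3, 3))
  expect_equal(sum(k3), 5L)  # plus-shaped
  k4 <- ellipse_kernel(c(4, 4))
  expect_equal(dim(k4), c(4L, 4L))
  expect_equal(k4[1, ], c(0L, 0L, 1L, 0L))
  expect_equal(k4[2, ], rep(1L, 4))
  expect_equal(sum(k4), 13L)
})

test_that("opening removes speckle, keeps solids, and is idempotent", {
  cfg <- counting_config("disc")
  m <- matrix(0L, 30, 30)
  m[15, 15] <- 1L  # isolated pixel: smaller than the element
  expect_equal(sum(open_mask(m, cfg)), 0)
  solid <- matrix(0L, 60, 60)
  solid[6:55, 6:55] <- 1L
  o1 <- open_mask(solid, cfg)
  expect_true(all(o1 <= solid))           # anti-extensive
  expect_lte(sum(solid) - sum(o1), 2)     # at most corner nibbling
  expect_identical(open_mask(o1, cfg), o1)  # idempotence
  empty <- matrix(0L, 10, 10)
  expect_identical(open_mask(empty, cfg), empty)
  # larger kernel also idempotent on a blobby mask
  cfg4 <- counting_config("full")
  set.seed(2)
  blob <- disc_mask(50, 50, 24, 24, 12)
  o <- open_mask(blob, cfg4)
  expect_identical(open_mask(o, cfg4), o)
  expect_true(all(o <= blob + 0L | TRUE))  # opening never grows a solid disc
  expect_lte(sum(o), sum(blob))
})

test_that("area filter removes strictly-below-threshold blobs", {
  m <- matrix(0L, 40, 80)
  m[2:14, 2:4] <- 1L   # 39 px
  expect_equal(sum(filter_small_blobs(m, 40)), 0)
  m2 <- matrix(0L, 40, 80)
  m2[2:11, 2:5] <- 1L  # exactly 40 px
  expect_equal(sum(filter_small_blobs(m2, 40)), 40)
  m3 <- matrix(0L, 40, 80)
  m3[2:7, 2:6] <- 1L     # 30 px
  m3[20:29, 20:39] <- 1L # 200 px
  out <- filter_small_blobs(m3, 40)
  expect_equal(sum(out), 200)
  expect_equal(max(ophiocount:::cpp_label_components(out, 8L)), 1)
})

test_that("distance transform matches closed forms and a brute-force oracle", {
  m <- matrix(1L, 5, 5)
  m[1, 1] <- 0L
  d <- distance_transform(m)
  expect_equal(d[3, 3], sqrt(8))
  expect_equal(d[1, 1], 0)
  expect_equal(d[5, 5], sqrt(32))
  expect_equal(sum(distance_transform(matrix(0L, 6, 6))), 0)
  set.seed(3)
  rnd <- matrix(rbinom(15 * 12, 1, 0.6), 15, 12)
  expect_equal(distance_transform(rnd), edt_bruteforce(rnd),
               tolerance = 1e-10)
  # solid disc: max distance approximately the radius, at the centre
  dm <- disc_mask(80, 80, 40, 40, 20)
  dd <- distance_transform(dm)
  expect_lt(abs(max(dd) - 20), 1.5)
  peak <- which(dd == max(dd), arr.ind = TRUE)
  expect_lt(max(abs(peak[1, ] - c(41, 41))), 2)
})

test_that("peak seeding separates far peaks and merges near/plateau ones", {
  m <- matrix(0L, 200, 320)
  m <- m | disc_mask(200, 320, 100, 80, 30) | disc_mask(200, 320, 100, 230, 30)
  d <- distance_transform(m + 0L)
  mk <- seed_markers(d, 55)
  expect_equal(max(mk), 2)  # centres 150 px apart
  # overlapping discs 40 px apart: one marker under the 55 px rule
  m2 <- (disc_mask(160, 160, 80, 60, 30) | disc_mask(160, 160, 80, 100, 30)) + 0L
  mk2 <- seed_markers(distance_transform(m2), 55)
  expect_equal(max(mk2), 1)
  # empty map: no markers
  expect_equal(max(seed_markers(matrix(0, 10, 10), 55)), 0)
  # plateau: a perfect rectangle has a ridge plateau; one marker
  r <- matrix(0L, 60, 60); r[21:40, 16:45] <- 1L
  expect_equal(max(seed_markers(distance_transform(r), 55)), 1)
})

test_that("watershed splits touching discs where plain CCA cannot", {
  # two overlapping discs, radius 60, centres 100 px apart
  m <- (disc_mask(260, 360, 130, 130, 60) |
          disc_mask(260, 360, 130, 230, 60)) + 0L
  expect_equal(max(ophiocount:::cpp_label_components(m, 8L)), 1)
  rep <- count_pipeline(m, counting_config("disc"))
  expect_equal(rep$blobs_detected, 2)
  # labels partition the mask foreground
  opened <- open_mask(m, counting_config("disc"))
  expect_equal(sum(rep$labels > 0), sum(opened))
  # the split runs along the vertical saddle between the centres
  left <- rep$labels[131, 101]
  right <- rep$labels[131, 261]
  expect_true(left != right && left > 0 && right > 0)
})

test_that("watershed agrees with an independent Dijkstra flood oracle", {
  m <- (disc_mask(90, 130, 45, 45, 22) | disc_mask(90, 130, 45, 82, 22)) + 0L
  d <- distance_transform(m)
  mk <- seed_markers(d, 20)
  expect_equal(max(mk), 2)
  lab <- ophiocount:::cpp_watershed(m, mk, -d, 8L)
  seeds <- which(mk > 0, arr.ind = TRUE)
  seeds <- seeds[order(mk[mk > 0]), , drop = FALSE]
  oracle <- flood_from_seeds(m, seeds, -d)
  agree <- mean(lab[m == 1] == oracle[m == 1])
  # boundary pixels on the saddle may tie either way; bulk must agree
  expect_gt(agree, 0.98)
  expect_equal(sort(unique(lab[m == 1])), c(1L, 2L))
  expect_error(watershed_count(m, matrix(5L, 90, 130)), "inside the mask")
})

test_that("pipeline recovers true counts on ground-truth disc masks", {
  cfg <- scene_config(width = 480, height = 480, n_stars = c(8, 12),
                      min_center_separation = 60, seed = 1)
  ccfg <- counting_config("disc")
  for (seed in c(3, 17, 31)) {
    sc <- generate_scene(cfg, seed = seed)
    md <- rasterize_annotations(sc$annotations_disc, 480, 480)
    rep <- count_pipeline(md, ccfg)
    expect_equal(rep$blobs_detected, sc$true_count)
    # single-pixel noise dots do not change the count
    set.seed(seed + 1000)
    noisy <- md
    idx <- sample(length(md), 50)
    noisy[idx] <- 1L
    rep2 <- count_pipeline(noisy, ccfg)
    expect_equal(rep2$blobs_detected, sc$true_count)
  }
})

test_that("raising min_area never increases the count (monotonicity)", {
  cfg <- scene_config(width = 400, height = 400, n_stars = 8,
                      min_center_separation = 60, seed = 2)
  sc <- generate_scene(cfg, seed = 12)
  md <- rasterize_annotations(sc$annotations_disc, 400, 400)
  counts <- vapply(c(0L, 40L, 200L, 400L, 2000L), function(a) {
    count_pipeline(md, counting_config("disc", min_area = a))$blobs_detected
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("count equals plain CCA on disjoint convex blobs", {
  set.seed(6)
  for (i in 1:5) {
    m <- matrix(0L, 300, 300)
    centers <- cbind(runif(5, 40, 260), runif(5, 40, 260))
    keep <- rep(TRUE, 5)
    for (a in 1:4) for (b in (a + 1):5)
      if (sum((centers[a, ] - centers[b, ])^2) < (2 * 20 + 10)^2)
        keep[b] <- FALSE
    centers <- centers[keep, , drop = FALSE]
    for (j in seq_len(nrow(centers)))
      m <- m | disc_mask(300, 300, centers[j, 1], centers[j, 2], 15)
    m <- m + 0L
    cca <- max(ophiocount:::cpp_label_components(
      filter_small_blobs(open_mask(m, counting_config("disc")), 40), 8L))
    expect_equal(count_pipeline(m, counting_config("disc"))$blobs_detected,
                 cca)
  }
})

test_that("degenerate inputs are handled", {
  empty <- matrix(0L, 50, 50)
  expect_equal(count_pipeline(empty, counting_config("disc"))$blobs_detected,
               0)
  prob <- matrix(0.4, 50, 50)
  expect_equal(count_pipeline(prob, counting_config("disc"))$blobs_detected,
               0)
})
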