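# IOU, count ratios, instance matching, and the forgiving re-evaluation

test_that("confusion counts enumerate correctly", {
  p <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  t <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  cc <- confusion_counts(p, t)
  expect_equal(cc$tp, 1); expect_equal(cc$fn, 1)
  expect_equal(cc$fp, 0); expect_equal(cc$tn, 2)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 4)
  same <- matrix(rbinom(25, 1, 0.5), 5, 5)
  cs <- confusion_counts(same, same)
  expect_equal(cs$fp + cs$fn, 0)
  allfg <- matrix(1L, 3, 3); allbg <- matrix(0L, 3, 3)
  expect_equal(confusion_counts(allfg, allbg)$fp, 9)
  expect_error(confusion_counts(allfg, matrix(0L, 2, 2)), "shapes")
})

test_that("iou follows TP/(TP+FN+FP) with its symmetry and edge cases", {
  mk <- function(tp, fp, fn, tn = 0)
    structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
              class = "confusion_counts")
  expect_equal(iou(mk(50, 25, 25)), 0.5)
  expect_equal(iou(mk(10, 0, 0)), 1)
  expect_equal(iou(mk(0, 5, 0)), 0)
  expect_equal(iou(mk(3, 7, 2)), iou(mk(3, 2, 7)))  # fp/fn symmetric
  expect_error(iou(mk(0, 0, 0)), "undefined")
  # matrix interface equals manual enumeration on 2x2 fixtures
  for (i in 0:15) {
    p <- matrix(as.integer(intToBits(i)[1:4]), 2, 2)
    for (j in 0:15) {
      t <- matrix(as.integer(intToBits(j)[1:4]), 2, 2)
      cc <- confusion_counts(p, t)
      if (cc$tp + cc$fp + cc$fn > 0)
        expect_equal(iou(cc), cc$tp / (cc$tp + cc$fp + cc$fn))
    }
  }
  expect_equal(iou(matrix(1L, 2, 2), matrix(1L, 2, 2)), 1)
})

test_that("count ratios truncate to three decimals", {
  expect_equal(count_ratio(393, 500), 0.786)
  expect_equal(count_ratio(337, 361), 0.933)
  expect_equal(count_ratio(377, 457), 0.824)
  expect_equal(count_ratio(342, 362), 0.944)
  expect_equal(count_ratio(100, 100), 1.000)
  expect_equal(count_ratio(433, 362), 1.196)  # above 1, not capped
  expect_error(count_ratio(5, 0), "positive")
})

test_that("instance matching is exact on a perfect label map", {
  cfg <- small_scene_config()
  sc <- generate_scene(cfg, seed = 8)
  md <- rasterize_annotations(sc$annotations_disc, cfg$height, cfg$width)
  rep <- count_pipeline(md, counting_config("disc"))
  im <- match_instances(rep$labels, sc$annotations_disc)
  expect_equal(im$strict$tp, sc$true_count)
  expect_equal(im$strict$fp, 0)
  expect_equal(im$strict$fn, 0)
})

test_that("spurious and split blobs classify as FP with greedy one-to-one", {
  truth <- annotation_set("m", "disc", "a",
                          list(rect_polygon(10, 10, 29, 29)))
  lab <- matrix(0L, 60, 60)
  lab[12:18, 12:28] <- 1L  # overlaps truth more
  lab[23:28, 12:28] <- 2L  # second blob inside the same annotation
  lab[45:52, 45:52] <- 3L  # background blob
  im <- match_instances(lab, truth)
  expect_equal(im$strict$tp, 1)
  expect_equal(im$strict$fp, 2)  # greedy one-to-one: larger overlap wins
  expect_equal(im$strict$fn, 0)
  expect_true(1 %in% setdiff(1:3, im$fp$blob))  # blob 1 is the match
  # no detections at all: everything is FN
  im0 <- match_instances(matrix(0L, 60, 60), truth)
  expect_equal(im0$strict$fn, 1)
  expect_equal(im0$strict$tp, 0)
})

test_that("forgiving evaluation excludes organism-adjacent FPs and invisible-disc FNs", {
  # organism: full shape covers a disc plus an "arm" strip; the disc
  # annotation covers only the disc
  full <- annotation_set("m", "full", "a", list(
    rect_polygon(10, 10, 49, 29, "full")))     # body + arm region
  disc <- annotation_set("m", "disc", "a", list(
    rect_polygon(10, 10, 29, 29, "disc")))
  # predicted blob on the arm (inside full, outside disc) -> FP, excluded
  lab <- matrix(0L, 80, 80)
  lab[16:24, 36:44] <- 1L
  im <- match_instances(lab, disc)
  expect_equal(im$strict$fp, 1)
  expect_equal(im$strict$fn, 1)
  adj <- forgiving_adjust(im, full, disc, visibility_min_area = 40)
  expect_equal(adj$forgiving$fp, 0)   # organism present: excluded
  expect_equal(adj$forgiving$fn, 1)   # disc clearly visible: kept
  expect_lte(adj$forgiving$fp, adj$strict$fp)
  expect_lte(adj$forgiving$fn, adj$strict$fn)
  # hidden-disc scene: the FN instance has no disc polygon -> excluded
  cfgh <- scene_config(width = 512, height = 512, n_stars = 6,
                       hide_disc = TRUE, seed = 5)
  sch <- generate_scene(cfgh, seed = 5)
  empty_pred <- matrix(0L, 512, 512)
  imh <- match_instances(empty_pred, sch$annotations_full)
  expect_equal(imh$strict$fn, 6)
  adjh <- forgiving_adjust(imh, sch$annotations_full,
                           sch$annotations_disc)
  expect_equal(adjh$forgiving$fn, 5)  # the hidden-disc organism excluded
  # a report with no errors is unchanged
  md <- rasterize_annotations(sch$annotations_disc, 512, 512)
  repd <- count_pipeline(md, counting_config("disc"))
  imd <- match_instances(repd$labels, sch$annotations_disc)
  adjd <- forgiving_adjust(imd, sch$annotations_full, sch$annotations_disc)
  expect_equal(adjd$forgiving$fp, adjd$strict$fp)
  expect_equal(adjd$forgiving$fn, adjd$strict$fn)
})

test_that("evaluate_prediction ties the pieces together", {
  cfg <- small_scene_config()
  sc <- generate_scene(cfg, seed = 13)
  md <- rasterize_annotations(sc$annotations_disc, cfg$height, cfg$width)
  # ground truth fed as prediction: IOU 1, ratio 1.000
  r <- evaluate_prediction(md, sc$annotations_disc,
                           full_truth = sc$annotations_full,
                           disc_truth = sc$annotations_disc)
  expect_equal(r$iou, 1)
  expect_equal(r$count_ratio, 1.000)
  expect_equal(r$instances$strict$fp, 0)
  # empty prediction: IOU 0, all FN
  r0 <- evaluate_prediction(matrix(0, cfg$height, cfg$width),
                            sc$annotations_disc)
  expect_equal(r0$iou, 0)
  expect_equal(r0$instances$strict$fn, sc$true_count)
  expect_equal(r0$blobs_detected, 0)
})
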