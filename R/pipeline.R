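# End-to-end experiment driver: simulate -> [enhance] -> train ->
# predict -> count -> evaluate, from a single config, with seeded
# reproducibility and persisted artifacts.

#' Experiment configuration
#'
#' @param scene a [scene_config()] for synthetic scenes
#' @param train a [train_config()]
#' @param counting optional [counting_config()]; defaults to the
#'   variant's standard parameters
#' @param variant annotation variant to train and evaluate on
#' @param split either `list(mode = "scenes", n_train, n_test)` for
#'   separate train/test scene sets, or `list(mode = "halves")` to
#'   train on the top half and test on the bottom half of one mosaic
#' @param profile segmenter channel profile
#' @param out_dir artifact directory (`NULL` for none)
#' @param seed master seed; scene and training seeds derive from it
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(scene = scene_config(),
                              train = train_config(),
                              counting = NULL,
                              variant = c("disc", "full"),
                              split = list(mode = "scenes",
                                           n_train = 20L, n_test = 5L),
                              profile = "desk",
                              out_dir = NULL,
                              seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(counting)) counting <- counting_config(variant)
  stopifnot(inherits(scene, "scene_config"),
            inherits(train, "train_config"),
            inherits(counting, "counting_config"))
  if (!split$mode %in% c("scenes", "halves"))
    stop("split mode must be 'scenes' or 'halves'")
  structure(list(scene = scene, train = train, counting = counting,
                 variant = variant, split = split, profile = profile,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Write / read an experiment config as YAML
#'
#' The YAML representation round-trips losslessly through
#' [read_experiment_config()].
#'
#' @param config an [experiment_config()]
#' @param path YAML file path
#' @return `path` / the restored config
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  obj <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  enh <- obj$train$enhancement
  tr <- obj$train
  tr$enhancement <- NULL
  tr$loss_weights <- as.numeric(unlist(obj$train$loss_weights))
  cfg <- experiment_config(
    scene = do.call(scene_config, obj$scene),
    train = do.call(train_config, c(tr, list(
      enhancement = do.call(enhancement_spec,
                            c(list(name = enh$name), enh$params))))),
    counting = do.call(counting_config, obj$counting),
    variant = obj$variant,
    split = obj$split,
    profile = obj$profile,
    out_dir = obj$out_dir,
    seed = obj$seed
  )
  cfg
}

#' Split a mosaic horizontally into training and testing halves
#'
#' The top rows `[0, H/2)` form the training half and the bottom rows
#' `[H/2, H)` the testing half. Annotation instances are assigned to the
#' half containing their polygon centroid; polygons are clipped to their
#' half and bottom-half coordinates are shifted into the half's frame.
#'
#' @param image H x W x 3 array (H at least twice the patch size for
#'   downstream training)
#' @param annotations an [annotation_set()], or a named list of sets
#'   (e.g. both variants); each is split with the same rule
#' @return list with `train` and `test`, each containing `image` and
#'   `annotations` (matching the input structure)
#' @export
split_halves <- function(image, annotations) {
  H <- dim(image)[1]
  if (H < 4) stop("image too small to split")
  mid <- H %/% 2
  split_set <- function(set) {
    stopifnot(inherits(set, "annotation_set"))
    top <- list(); bottom <- list()
    for (p in set$polygons) {
      cen <- polygon_centroid(p$vertices)
      if (cen[2] < mid) {
        v <- p$vertices
        v[, 2] <- pmin(v[, 2], mid - 0.5)
        top[[length(top) + 1]] <- polygon_annotation(
          v, p$label, p$variant, p$annotator)
      } else {
        v <- p$vertices
        v[, 2] <- pmax(v[, 2], mid - 0.5) - mid
        bottom[[length(bottom) + 1]] <- polygon_annotation(
          v, p$label, p$variant, p$annotator)
      }
    }
    list(train = annotation_set(paste0(set$mosaic_id, "-top"),
                                set$variant, set$annotator, top),
         test = annotation_set(paste0(set$mosaic_id, "-bottom"),
                               set$variant, set$annotator, bottom))
  }
  top_img <- image[seq_len(mid), , , drop = FALSE]
  bot_img <- image[(mid + 1):H, , , drop = FALSE]
  if (inherits(annotations, "annotation_set")) {
    s <- split_set(annotations)
    list(train = list(image = top_img, annotations = s$train),
         test = list(image = bot_img, annotations = s$test))
  } else {
    ss <- lapply(annotations, split_set)
    list(train = list(image = top_img,
                      annotations = lapply(ss, `[[`, "train")),
         test = list(image = bot_img,
                     annotations = lapply(ss, `[[`, "test")))
  }
}

#' Run an end-to-end segment-and-count experiment
#'
#' Generates seeded synthetic scenes, optionally enhances them, trains
#' the segmentation model on the training scenes, predicts probability
#' maps for the test scenes, counts blobs, and evaluates. With an
#' `out_dir`, scenes, the model, probability maps, count reports, the
#' evaluation report and a run log (seeds, configs) are persisted; the
#' persisted artifacts suffice to re-run evaluation without re-training.
#'
#' @param config an [experiment_config()]
#' @param epochs optional override of the training epochs
#' @param verbose print progress
#' @return object of class `experiment_result`: per-test-scene
#'   [evaluate_prediction()] reports, the pooled IOU and count ratio,
#'   the trained model, and artifact paths (if written)
#' @export
run_experiment <- function(config, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, 3)
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  enh <- config$train$enhancement
  apply_enh <- function(sc) {
    sc$image <- apply_enhancement(sc$image, enh)
    sc
  }
  if (config$split$mode == "scenes") {
    train_scenes <- stage("simulate", generate_dataset(
      config$scene, config$split$n_train, seed = seeds[1]))
    test_scenes <- stage("simulate", generate_dataset(
      config$scene, config$split$n_test, seed = seeds[2]))
  } else {
    mosaic <- stage("simulate", generate_scene(config$scene, seed = seeds[1]))
    halves <- split_halves(mosaic$image,
                           list(full = mosaic$annotations_full,
                                disc = mosaic$annotations_disc))
    mk_scene <- function(h, label) {
      structure(list(image = h$image,
                     annotations_full = h$annotations$full,
                     annotations_disc = h$annotations$disc,
                     true_count = length(h$annotations$full),
                     seed = mosaic$seed,
                     config = config$scene), class = "ophio_scene")
    }
    train_scenes <- list(mk_scene(halves$train, "top"))
    test_scenes <- list(mk_scene(halves$test, "bottom"))
  }
  train_scenes <- lapply(train_scenes, apply_enh)
  test_scenes <- lapply(test_scenes, apply_enh)
  if (!is.null(out)) {
    for (i in seq_along(train_scenes))
      write_scene(train_scenes[[i]], file.path(out, "scenes", "train"),
                  sprintf("train_%03d", i))
    for (i in seq_along(test_scenes))
      write_scene(test_scenes[[i]], file.path(out, "scenes", "test"),
                  sprintf("test_%03d", i))
  }
  tcfg <- config$train
  tcfg$seed <- as.integer(seeds[3] %% 2147483647)
  model <- stage("build", build_segmenter(tcfg, config$profile))
  model <- stage("train", train_segmenter(
    model, train_scenes, variant = config$variant, epochs = epochs,
    verbose = verbose))
  if (!is.null(out)) save_segmenter(model, file.path(out, "model.rds"))
  reports <- vector("list", length(test_scenes))
  agg <- list(tp = 0, fp = 0, fn = 0, tn = 0, blobs = 0, gt = 0)
  for (i in seq_along(test_scenes)) {
    sc <- test_scenes[[i]]
    prob <- stage("predict", predict_mosaic(model, sc$image))
    if (!is.null(out))
      write_image(prob, file.path(out, sprintf("prob_test_%03d.tif", i)))
    truth <- if (config$variant == "disc") sc$annotations_disc
      else sc$annotations_full
    rep <- stage("evaluate", evaluate_prediction(
      prob, truth, config = config$counting,
      threshold = config$train$threshold,
      full_truth = sc$annotations_full,
      disc_truth = sc$annotations_disc))
    reports[[i]] <- rep
    agg$tp <- agg$tp + rep$confusion$tp
    agg$fp <- agg$fp + rep$confusion$fp
    agg$fn <- agg$fn + rep$confusion$fn
    agg$tn <- agg$tn + rep$confusion$tn
    agg$blobs <- agg$blobs + rep$blobs_detected
    agg$gt <- agg$gt + rep$ground_truth_count
    if (!is.null(out))
      jsonlite::write_json(
        list(iou = rep$iou, blobs_detected = rep$blobs_detected,
             ground_truth = rep$ground_truth_count,
             ratio = rep$count_ratio,
             strict = rep$instances$strict,
             forgiving = rep$instances$forgiving),
        file.path(out, sprintf("eval_test_%03d.json", i)),
        auto_unbox = TRUE, digits = NA)
  }
  pooled_iou <- agg$tp / (agg$tp + agg$fp + agg$fn)
  pooled_ratio <- if (agg$gt > 0) count_ratio(agg$blobs, agg$gt) else NA
  result <- structure(list(
    reports = reports,
    iou = pooled_iou,
    blobs_detected = agg$blobs,
    ground_truth_count = agg$gt,
    count_ratio = pooled_ratio,
    model = model,
    config = config,
    out_dir = out
  ), class = "experiment_result")
  if (!is.null(out)) {
    jsonlite::write_json(
      list(seed = config$seed, derived_seeds = seeds,
           variant = config$variant,
           pooled_iou = pooled_iou,
           blobs_detected = agg$blobs, ground_truth = agg$gt,
           ratio = pooled_ratio,
           r_version = as.character(getRversion())),
      file.path(out, "experiment_report.json"),
      auto_unbox = TRUE, digits = NA)
    write_experiment_config(config, file.path(out, "config.yaml"))
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> variant:", x$config$variant,
      " test scenes:", length(x$reports), "\n")
  cat("  pooled IOU:", format(x$iou, digits = 4),
      " blobs:", x$blobs_detected, "/", x$ground_truth_count,
      " ratio:", format(x$count_ratio, nsmall = 3), "\n")
  invisible(x)
}
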