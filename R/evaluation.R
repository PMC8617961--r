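# Evaluation: pixel-level confusion counts and IOU, blob-count ratios
# with the truncate-to-3-decimals reporting convention, and
# instance-level strict/forgiving accounting of false positives and
# negatives.

#' Pixel confusion counts between prediction and ground truth
#'
#' @param pred,truth binary matrices of identical shape
#' @return object of class `confusion_counts` with `tp`, `fp`, `fn`,
#'   `tn`
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ")
  p <- pred != 0; t <- truth != 0
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> tp:", x$tp, " fp:", x$fp, " fn:", x$fn,
      " tn:", x$tn, "\n")
  invisible(x)
}

#' Intersection over union from confusion counts
#'
#' `IOU = TP / (TP + FN + FP)`; undefined (error) when prediction and
#' truth are both empty.
#'
#' @param counts a [confusion_counts()], or a binary prediction matrix
#'   (then `truth` must be supplied)
#' @param truth optional binary truth matrix
#' @return IOU in [0, 1]
#' @export
iou <- function(counts, truth = NULL) {
  if (!inherits(counts, "confusion_counts"))
    counts <- confusion_counts(counts, truth)
  denom <- counts$tp + counts$fn + counts$fp
  if (denom == 0)
    stop("IOU undefined: prediction and ground truth are both empty")
  counts$tp / denom
}

#' Blob-count ratio, truncated to three decimals
#'
#' `detected / ground_truth`, truncated (not rounded) to 3 decimals —
#' the reporting convention under which 337/361 prints as 0.933 and
#' 377/457 as 0.824. Values above 1 are possible and not capped.
#'
#' @param detected number of detected blobs
#' @param ground_truth number of annotated instances (> 0)
#' @return truncated ratio
#' @export
count_ratio <- function(detected, ground_truth) {
  if (ground_truth <= 0) stop("ground_truth must be positive")
  floor(detected / ground_truth * 1000 + 1e-9) / 1000
}

#' Match predicted blobs to ground-truth instances
#'
#' A predicted blob is a true positive when its centroid pixel lies
#' inside a ground-truth instance not already matched; candidate pairs
#' are assigned greedily by decreasing pixel overlap, one-to-one.
#' Unmatched blobs are false positives, unmatched instances false
#' negatives.
#'
#' @param pred_labels integer label map of predicted blobs (e.g. from
#'   [count_pipeline()])
#' @param truth an [annotation_set()] in the same mosaic frame
#' @return object of class `instance_match_report`: matched pairs,
#'   per-blob FP records (with centroids), per-instance FN records, and
#'   `strict = list(tp, fp, fn)` totals
#' @export
match_instances <- function(pred_labels, truth) {
  stopifnot(inherits(truth, "annotation_set"))
  H <- nrow(pred_labels); W <- ncol(pred_labels)
  n_truth <- length(truth$polygons)
  truth_lab <- matrix(0L, H, W)
  for (i in seq_len(n_truth)) {
    m <- rasterize_annotations(truth$polygons[i], H, W)
    sel <- m == 1L & truth_lab == 0L
    truth_lab[sel] <- i
  }
  ids <- sort(unique(pred_labels[pred_labels > 0L]))
  n_blob <- length(ids)
  cent <- matrix(NA_real_, n_blob, 2)
  cand_truth <- integer(n_blob)
  overlap <- numeric(n_blob)
  for (b in seq_len(n_blob)) {
    idx <- which(pred_labels == ids[b])
    rr <- (idx - 1L) %% H + 1L
    cc <- (idx - 1L) %/% H + 1L
    cr <- round(mean(rr)); cl <- round(mean(cc))
    cent[b, ] <- c(cr, cl)
    ti <- truth_lab[cr, cl]
    cand_truth[b] <- ti
    if (ti > 0L) overlap[b] <- sum(truth_lab[idx] == ti)
  }
  ord <- order(-overlap, ids)
  matched_blob <- integer(0)
  matched_truth <- integer(0)
  pairs <- list()
  for (b in ord) {
    ti <- cand_truth[b]
    if (ti == 0L || ti %in% matched_truth || ids[b] %in% matched_blob)
      next
    matched_blob <- c(matched_blob, ids[b])
    matched_truth <- c(matched_truth, ti)
    pairs[[length(pairs) + 1]] <- c(blob = ids[b], truth = ti)
  }
  fp_ids <- setdiff(ids, matched_blob)
  fn_ids <- setdiff(seq_len(n_truth), matched_truth)
  structure(list(
    pairs = pairs,
    fp = data.frame(blob = fp_ids,
                    centroid_row = cent[match(fp_ids, ids), 1],
                    centroid_col = cent[match(fp_ids, ids), 2],
                    excluded = rep(FALSE, length(fp_ids))),
    fn = data.frame(truth = fn_ids,
                    excluded = rep(FALSE, length(fn_ids))),
    strict = list(tp = length(pairs), fp = length(fp_ids),
                  fn = length(fn_ids)),
    forgiving = NULL,
    truth_variant = truth$variant,
    truth_polygons = truth$polygons,
    frame = c(H, W)
  ), class = "instance_match_report")
}

#' @export
print.instance_match_report <- function(x, ...) {
  cat("<instance_match_report> strict: TP", x$strict$tp, "FP",
      x$strict$fp, "FN", x$strict$fn)
  if (!is.null(x$forgiving))
    cat("  | forgiving: FP", x$forgiving$fp, "FN", x$forgiving$fn)
  cat("\n")
  invisible(x)
}

#' Forgiving re-evaluation of instance errors
#'
#' Re-classifies instance errors the way a forgiving expert review
#' would: a false positive is excluded when its blob centroid falls
#' inside a full-shape instance (the organism is present even though its
#' disc was not correctly detected); a false negative is excluded when
#' the instance has no distinguishable central disc — its disc polygon
#' is missing or rasterizes to fewer than `visibility_min_area` pixels.
#' Forgiving totals never exceed strict totals.
#'
#' @param report an [match_instances()] report
#' @param full_truth full-shape [annotation_set()]
#' @param disc_truth disc [annotation_set()]
#' @param visibility_min_area disc visibility threshold in pixels
#'   (default: the disc counting filter's 40 px)
#' @return the report with per-error exclusion flags and a
#'   `forgiving = list(fp, fn)` total
#' @export
forgiving_adjust <- function(report, full_truth, disc_truth,
                             visibility_min_area = 40) {
  stopifnot(inherits(report, "instance_match_report"))
  if (is.null(full_truth) || is.null(disc_truth))
    stop("both full-shape and disc annotation sets are required")
  H <- report$frame[1]; W <- report$frame[2]
  full_mask <- rasterize_annotations(full_truth, H, W)
  if (nrow(report$fp) > 0) {
    inside <- full_mask[cbind(report$fp$centroid_row,
                              report$fp$centroid_col)] == 1L
    report$fp$excluded <- inside
  }
  if (nrow(report$fn) > 0) {
    disc_areas <- vapply(seq_len(nrow(report$fn)), function(i) {
      ti <- report$fn$truth[i]
      cen <- polygon_centroid(report$truth_polygons[[ti]]$vertices)
      # find the disc polygon containing this instance's centroid
      for (dp in disc_truth$polygons) {
        m <- rasterize_annotations(list(dp), H, W)
        r <- round(cen[2]) + 1L; c <- round(cen[1]) + 1L
        if (r >= 1 && r <= H && c >= 1 && c <= W && m[r, c] == 1L)
          return(sum(m))
      }
      0
    }, numeric(1))
    report$fn$excluded <- disc_areas < visibility_min_area
  }
  report$forgiving <- list(
    fp = sum(!report$fp$excluded),
    fn = sum(!report$fn$excluded)
  )
  report
}

#' Evaluate a predicted probability map against ground truth
#'
#' Binarizes the prediction, computes pixel confusion counts and IOU,
#' runs the counting workflow, reports the truncated count ratio, and
#' performs instance matching (plus the forgiving re-evaluation when
#' both annotation variants are supplied).
#'
#' @param pred_prob probability matrix in [0, 1] (or an already binary
#'   mask)
#' @param truth [annotation_set()] used as ground truth
#' @param config a [counting_config()]; defaults to the truth variant's
#' @param threshold binarization threshold
#' @param full_truth,disc_truth optional annotation sets enabling the
#'   forgiving evaluation
#' @return object of class `eval_report`: `iou`, `confusion`,
#'   `blobs_detected`, `ground_truth_count`, `count_ratio`,
#'   `count_report`, `instances`
#' @export
evaluate_prediction <- function(pred_prob, truth, config = NULL,
                                threshold = 0.5, full_truth = NULL,
                                disc_truth = NULL) {
  stopifnot(inherits(truth, "annotation_set"))
  if (is.null(config)) config <- counting_config(truth$variant)
  H <- nrow(pred_prob); W <- ncol(pred_prob)
  truth_mask <- rasterize_annotations(truth, H, W)
  pred_mask <- if (is_binary(pred_prob)) as_mask(pred_prob)
    else binarize(pred_prob, threshold)
  conf <- confusion_counts(pred_mask, truth_mask)
  iou_val <- if (conf$tp + conf$fp + conf$fn > 0) iou(conf) else NA_real_
  cr <- count_pipeline(pred_mask, config)
  gt <- length(truth$polygons)
  ratio <- if (gt > 0) count_ratio(cr$blobs_detected, gt) else NA_real_
  inst <- match_instances(cr$labels, truth)
  if (!is.null(full_truth) && !is.null(disc_truth))
    inst <- forgiving_adjust(inst, full_truth, disc_truth)
  structure(list(
    iou = iou_val,
    confusion = conf,
    blobs_detected = cr$blobs_detected,
    ground_truth_count = gt,
    count_ratio = ratio,
    count_report = cr,
    instances = inst
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> IOU:", format(x$iou, digits = 4),
      " blobs:", x$blobs_detected, "/", x$ground_truth_count,
      " ratio:", format(x$count_ratio, nsmall = 3), "\n")
  print(x$instances)
  invisible(x)
}
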