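# Polygon annotations: closed polygons per organism in one of two marker
# variants ("full" star shape with arms, or "disc" central body only),
# with JSON serialization and rasterization to binary ground-truth masks.
#
# Coordinate convention: 0-based pixel-centre coordinates, x rightward
# (column), y downward (row). A pixel is foreground if its centre lies
# inside the polygon (nonzero winding) or exactly on its boundary.

ANNOTATION_VARIANTS <- c("full", "disc")

#' Create a single polygon annotation
#'
#' @param vertices numeric matrix with columns (x, y): ordered, 0-based
#'   pixel-centre coordinates; the polygon is implicitly closed. At least
#'   3 vertices, all finite.
#' @param label organism label string
#' @param variant `"full"` (star shape with arms) or `"disc"` (central
#'   body disc only)
#' @param annotator annotator identifier
#' @return object of class `polygon_annotation`
#' @export
polygon_annotation <- function(vertices, label = "brittle_star",
                               variant = c("full", "disc"),
                               annotator = "synthetic") {
  variant <- match.arg(variant)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stop("vertices must be an n x 2 matrix of (x, y)")
  if (nrow(vertices) < 3) stop("polygon must have at least 3 vertices")
  if (!all(is.finite(vertices))) stop("polygon vertices must be finite")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, label = label, variant = variant,
                 annotator = annotator),
            class = "polygon_annotation")
}

#' Create an annotation set for one mosaic
#'
#' All polygons in a set share the set's marker variant and annotator,
#' mirroring an annotation campaign over a single mosaic.
#'
#' @param mosaic_id identifier of the annotated mosaic
#' @param variant marker variant, `"full"` or `"disc"`
#' @param annotator annotator identifier
#' @param polygons list of [polygon_annotation()] objects (may be empty)
#' @return object of class `annotation_set`
#' @export
annotation_set <- function(mosaic_id, variant = c("full", "disc"),
                           annotator = "synthetic", polygons = list()) {
  variant <- match.arg(variant)
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (!inherits(p, "polygon_annotation"))
      stop("polygon ", i, " is not a polygon_annotation")
    if (p$variant != variant)
      stop("polygon ", i, " has variant '", p$variant,
           "' but the set is '", variant, "'")
  }
  structure(list(mosaic_id = mosaic_id, variant = variant,
                 annotator = annotator, polygons = polygons),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> mosaic:", x$mosaic_id,
      " variant:", x$variant,
      " annotator:", x$annotator,
      " instances:", length(x$polygons), "\n")
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$polygons)

#' Write an annotation set to JSON
#'
#' Schema: an object with `mosaic_id`, `variant`, `annotator`, and
#' `polygons`, each polygon an object with `label` and `vertices`
#' (list of `[x, y]` pairs).
#'
#' @param set an [annotation_set()]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  obj <- list(
    mosaic_id = set$mosaic_id,
    variant = set$variant,
    annotator = set$annotator,
    polygons = lapply(set$polygons, function(p) {
      list(label = p$label,
           vertices = lapply(seq_len(nrow(p$vertices)),
                             function(i) unname(p$vertices[i, ])))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotation set from JSON
#'
#' Validates the schema; malformed polygons (fewer than 3 vertices,
#' non-finite coordinates) or an unknown variant raise an error naming
#' the offending polygon index.
#'
#' @param path JSON file written by [write_annotations()] (or following
#'   the same schema)
#' @return an [annotation_set()]
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("mosaic_id", "variant", "annotator"))
    if (is.null(obj[[field]])) stop("annotation file missing field '", field, "'")
  if (!obj$variant %in% ANNOTATION_VARIANTS)
    stop("unknown annotation variant '", obj$variant, "'")
  polys <- lapply(seq_along(obj$polygons), function(i) {
    p <- obj$polygons[[i]]
    v <- p$vertices
    if (is.null(v) || length(v) < 3)
      stop("polygon ", i, ": fewer than 3 vertices")
    m <- do.call(rbind, lapply(v, function(xy) {
      if (length(xy) != 2) stop("polygon ", i, ": vertex is not an (x, y) pair")
      as.numeric(xy)
    }))
    if (!all(is.finite(m))) stop("polygon ", i, ": non-finite vertex")
    polygon_annotation(m, label = p$label %||% "brittle_star",
                       variant = obj$variant, annotator = obj$annotator)
  })
  annotation_set(obj$mosaic_id, obj$variant, obj$annotator, polys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize an annotation set into a binary ground-truth mask
#'
#' Fills the union of all polygons (nonzero winding rule, boundary pixels
#' included); overlapping polygons merge. Vertices are clipped into the
#' image frame first, so border-touching (clipped) organisms are valid.
#'
#' @param set an [annotation_set()], or a plain list of
#'   [polygon_annotation()] objects
#' @param height,width mask dimensions in pixels
#' @return integer matrix `height` x `width`, values 0/1
#' @export
rasterize_annotations <- function(set, height, width) {
  polys <- if (inherits(set, "annotation_set")) set$polygons else set
  mats <- lapply(polys, function(p) {
    v <- p$vertices
    v[, 1] <- pmin(pmax(v[, 1], -0.5), width - 0.5)
    v[, 2] <- pmin(pmax(v[, 2], -0.5), height - 0.5)
    v
  })
  if (length(mats) == 0) return(matrix(0L, height, width))
  cpp_rasterize_polygons(mats, as.integer(height), as.integer(width))
}

# area centroid of a closed polygon (shoelace); falls back to the vertex
# mean for degenerate (zero-area) polygons
polygon_centroid <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}
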