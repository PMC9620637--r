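#' @useDynLib dks, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm setNames
#' @importFrom utils read.csv write.csv combn
NULL

# Coordinate convention used throughout the package: x rightward, y downward,
# origin at the centre of the top-left pixel, 0-based, sub-pixel positions
# allowed. A point (x, y) therefore lives at matrix cell [y + 1, x + 1].

#' The three standard echocardiographic views
#'
#' Atrial septal defects are assessed from three transthoracic views:
#' parasternal short-axis of the aorta (`PSSAX`), subxiphoid long-axis of the
#' two atria (`SXLAX`), and apical four-chamber (`A4C`).
#'
#' @return Character vector of the three view identifiers.
#' @export
view_ids <- function() c("PSSAX", "SXLAX", "A4C")

.assert_view <- function(view) {
  if (!(is.character(view) && length(view) == 1L && view %in% view_ids())) {
    stop("unknown view '", paste(view, collapse = ","),
         "'; must be one of ", paste(view_ids(), collapse = ", "),
         call. = FALSE)
  }
  view
}

#' Keypoint schema for a view
#'
#' Returns the fixed, ordered set of keypoint roles annotated in each view:
#' 3 points in PSSAX (the two defect endpoints and the atrial-wall landmark),
#' 4 in SXLAX (defect endpoints plus the superior/inferior vena cava
#' landmarks), and 4 in A4C (defect endpoints plus the atrial-roof and
#' mitral-annulus landmarks) - 11 points per case in total. The ordering is a
#' package convention; it is what lets the stadiometry module pair each rim
#' landmark with its defect endpoint deterministically.
#'
#' @param view One of `view_ids()`.
#' @return A `keypoint_schema`: list with `view`, `names` (ordered roles) and
#'   `count`.
#' @examples
#' schema_for("PSSAX")$count # 3
#' @export
schema_for <- function(view) {
  .assert_view(view)
  names <- switch(view,
    PSSAX = c("defect_end_A", "defect_end_B", "wall_point"),
    SXLAX = c("defect_end_sup", "defect_end_inf", "svc_point", "ivc_point"),
    A4C   = c("defect_end_roof", "defect_end_mitral", "roof_point",
              "mitral_point"))
  structure(list(view = view, names = names, count = length(names)),
            class = "keypoint_schema")
}

#' Construct an image frame
#'
#' @param pixels Integer matrix with values in \[0, 255\] (rows = y, cols = x).
#' @param view One of `view_ids()`.
#' @return An `image_frame` object.
#' @export
image_frame <- function(pixels, view) {
  .assert_view(view)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("pixels must be a non-empty matrix", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixels must be finite", call. = FALSE)
  if (any(pixels < 0 | pixels > 255))
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  structure(list(pixels = round(pixels), height = nrow(pixels),
                 width = ncol(pixels), view = view),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %s %dx%d px, intensity [%d, %d]>\n",
              x$view, x$width, x$height, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct scale information for an image
#'
#' Echocardiograms carry an on-image measuring scale; its physical length and
#' pixel length fix the millimetre-per-pixel calibration. Any two of the three
#' quantities determine the third; all three must be mutually consistent.
#'
#' @param mm_per_pixel Millimetres per pixel (> 0).
#' @param scale_bar_length_mm Physical length of the measuring scale in mm
#'   (default 10, a 1 cm bar).
#' @param scale_bar_length_px Length of the measuring scale in pixels.
#' @return A `scale_info` object.
#' @export
scale_info <- function(mm_per_pixel = NULL, scale_bar_length_mm = 10,
                       scale_bar_length_px = NULL) {
  if (is.null(mm_per_pixel)) {
    if (is.null(scale_bar_length_px) || is.null(scale_bar_length_mm))
      stop("supply mm_per_pixel or both scale-bar lengths", call. = FALSE)
    mm_per_pixel <- scale_bar_length_mm / scale_bar_length_px
  }
  if (is.null(scale_bar_length_px))
    scale_bar_length_px <- scale_bar_length_mm / mm_per_pixel
  if (mm_per_pixel <= 0 || scale_bar_length_px <= 0 || scale_bar_length_mm <= 0)
    stop("scale quantities must be positive", call. = FALSE)
  rel <- abs(mm_per_pixel - scale_bar_length_mm / scale_bar_length_px) /
    mm_per_pixel
  if (rel > 1e-9)
    stop("inconsistent scale: mm_per_pixel != scale_bar_length_mm / ",
         "scale_bar_length_px", call. = FALSE)
  structure(list(mm_per_pixel = mm_per_pixel,
                 scale_bar_length_mm = scale_bar_length_mm,
                 scale_bar_length_px = scale_bar_length_px),
            class = "scale_info")
}

#' Construct a keypoint set for a view
#'
#' @param view One of `view_ids()`.
#' @param points Numeric matrix with `schema_for(view)$count` rows and two
#'   columns (x, y), in schema order, 0-based pixel coordinates.
#' @param frame Optional `image_frame` against which coordinate bounds are
#'   checked.
#' @return A `keypoint_set` object (matrix `points` with row names set to the
#'   schema roles).
#' @export
keypoint_set <- function(view, points, frame = NULL) {
  sch <- schema_for(view)
  points <- as.matrix(points)
  if (nrow(points) != sch$count || ncol(points) != 2L)
    stop("keypoint set for ", view, " must be ", sch$count, " x 2",
         call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("keypoint coordinates must be finite", call. = FALSE)
  dimnames(points) <- list(sch$names, c("x", "y"))
  if (!is.null(frame)) {
    if (any(points[, "x"] < 0 | points[, "x"] >= frame$width |
            points[, "y"] < 0 | points[, "y"] >= frame$height))
      stop("keypoints fall outside the image frame", call. = FALSE)
  }
  structure(list(view = view, points = points), class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set %s, %d points>\n", x$view, nrow(x$points)))
  print(round(x$points, 3))
  invisible(x)
}

#' Construct a case record
#'
#' Bundles the three view frames, their scales, optional ground-truth
#' keypoints, and optional closure labels for one patient case. An occluder
#' size label is only meaningful for transcatheter cases.
#'
#' @param case_id Case identifier string.
#' @param frames Named list of `image_frame`, one per view.
#' @param scales Named list of `scale_info`, one per view.
#' @param keypoints Optional named list of `keypoint_set`, one per view.
#' @param label_plan Optional `"transcatheter"` or `"surgical"`.
#' @param label_size_mm Optional integer occluder waist size (transcatheter
#'   cases only).
#' @param geometry Optional generator geometry (kept for provenance by the
#'   synthetic generator).
#' @return A `case_record` object.
#' @export
case_record <- function(case_id, frames, scales, keypoints = NULL,
                        label_plan = NULL, label_size_mm = NULL,
                        geometry = NULL) {
  for (v in view_ids()) {
    if (is.null(frames[[v]]) || !inherits(frames[[v]], "image_frame"))
      stop("missing image_frame for view ", v, call. = FALSE)
    if (is.null(scales[[v]]) || !inherits(scales[[v]], "scale_info"))
      stop("missing scale_info for view ", v, call. = FALSE)
  }
  if (!is.null(label_plan) &&
      !label_plan %in% c("transcatheter", "surgical"))
    stop("label_plan must be 'transcatheter' or 'surgical'", call. = FALSE)
  if (!is.null(label_size_mm) && !identical(label_plan, "transcatheter"))
    stop("label_size_mm requires label_plan = 'transcatheter'", call. = FALSE)
  structure(list(case_id = as.character(case_id), frames = frames,
                 scales = scales, keypoints = keypoints,
                 label_plan = label_plan, label_size_mm = label_size_mm,
                 geometry = geometry),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record %s: 3 views%s%s>\n", x$case_id,
              if (!is.null(x$keypoints)) ", keypoints" else "",
              if (!is.null(x$label_plan))
                paste0(", plan=", x$label_plan) else ""))
  invisible(x)
}

#' Write a keypoint annotation file
#'
#' Annotations are stored as JSON: `{case_id, view, points: [{name, x, y}],
#' scale: {mm_per_pixel}}`.
#'
#' @param kps A `keypoint_set`.
#' @param scale A `scale_info`.
#' @param case_id Case identifier.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(kps, scale, case_id, path) {
  pts <- lapply(seq_len(nrow(kps$points)), function(i) {
    list(name = rownames(kps$points)[i],
         x = kps$points[i, "x"], y = kps$points[i, "y"])
  })
  obj <- list(case_id = case_id, view = kps$view, points = pts,
              scale = list(mm_per_pixel = scale$mm_per_pixel))
  # I(17) significant digits makes double coordinates round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a keypoint annotation file
#'
#' @param path Path to a JSON annotation written by [write_annotation()].
#' @return List with `case_id`, `keypoints` (a `keypoint_set`) and `scale`
#'   (a `scale_info`).
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- do.call(rbind, lapply(obj$points, function(p) c(p$x, p$y)))
  nm <- vapply(obj$points, function(p) p$name, character(1))
  sch <- schema_for(obj$view)
  if (!identical(nm, sch$names))
    pts <- pts[match(sch$names, nm), , drop = FALSE]
  list(case_id = obj$case_id,
       keypoints = keypoint_set(obj$view, pts),
       scale = scale_info(mm_per_pixel = obj$scale$mm_per_pixel))
}
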