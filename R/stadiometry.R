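# Stadiometry: converting keypoint pixel geometry plus the image's measuring
# scale into named millimetre measurements.
#
# Rim landmarks pair with a fixed defect endpoint through the schema order:
# SXLAX pairs the SVC landmark with the superior endpoint and the IVC landmark
# with the inferior endpoint; A4C pairs roof with the roof-side endpoint and
# mitral annulus with the mitral-side endpoint. PSSAX carries a single wall
# landmark for both endpoints, so its rim uses the nearer endpoint.

#' Euclidean distance between two points, in pixels
#'
#' @param p,q Numeric length-2 vectors `(x, y)`.
#' @return Distance in pixels.
#' @export
pixel_distance <- function(p, q) {
  if (any(!is.finite(p)) || any(!is.finite(q)))
    stop("coordinates must be finite", call. = FALSE)
  sqrt(sum((p - q)^2))
}

#' Convert a pixel distance to millimetres
#'
#' @param d_px Distance in pixels (>= 0).
#' @param scale A `scale_info`.
#' @return Distance in millimetres.
#' @export
to_mm <- function(d_px, scale) {
  if (!inherits(scale, "scale_info") || scale$mm_per_pixel <= 0)
    stop("invalid scale", call. = FALSE)
  if (d_px < 0) stop("d_px must be non-negative", call. = FALSE)
  d_px * scale$mm_per_pixel
}

#' Measure one view's named quantities from its keypoints
#'
#' Per view: the defect diameter is the distance between the two defect
#' endpoints; each rim is the distance from a defect endpoint to its
#' associated landmark; the A4C septum length is the roof-landmark to
#' mitral-landmark distance.
#'
#' @param kps A `keypoint_set`.
#' @param scale A `scale_info` for the same frame.
#' @return Named numeric vector of millimetre measurements for the view.
#' @export
measure_view <- function(kps, scale) {
  if (!inherits(kps, "keypoint_set")) stop("kps must be a keypoint_set",
                                           call. = FALSE)
  sch <- schema_for(kps$view)
  if (nrow(kps$points) != sch$count)
    stop("keypoint count does not match schema", call. = FALSE)
  p <- function(name) kps$points[name, ]
  d <- function(a, b) to_mm(pixel_distance(p(a), p(b)), scale)
  switch(kps$view,
    PSSAX = {
      diam <- d("defect_end_A", "defect_end_B")
      rim <- min(d("wall_point", "defect_end_A"),
                 d("wall_point", "defect_end_B"))
      c(defect_diameter_pssax_mm = diam, rim_wall_mm = rim)
    },
    SXLAX = {
      c(defect_diameter_sxlax_mm = d("defect_end_sup", "defect_end_inf"),
        rim_svc_mm = d("defect_end_sup", "svc_point"),
        rim_ivc_mm = d("defect_end_inf", "ivc_point"))
    },
    A4C = {
      c(defect_diameter_a4c_mm = d("defect_end_roof", "defect_end_mitral"),
        rim_roof_mm = d("defect_end_roof", "roof_point"),
        rim_mitral_mm = d("defect_end_mitral", "mitral_point"),
        septum_length_mm = d("roof_point", "mitral_point"))
    })
}

#' Assemble per-view measurements into a full measurement set
#'
#' @param pssax,sxlax,a4c Named vectors from [measure_view()] for the three
#'   views (order-free; matched by names).
#' @return A `measurement_set`: named numeric vector including
#'   `max_defect_diameter_mm`, the maximum of the three per-view diameters -
#'   the quantity that drives occluder sizing.
#' @export
assemble_measurements <- function(pssax, sxlax, a4c) {
  m <- c(pssax, sxlax, a4c)
  needed <- c("defect_diameter_pssax_mm", "defect_diameter_sxlax_mm",
              "defect_diameter_a4c_mm")
  if (!all(needed %in% names(m)))
    stop("all three views must be present", call. = FALSE)
  m["max_defect_diameter_mm"] <- max(m[needed])
  structure(as.list(m), class = "measurement_set")
}

#' Measure a whole case
#'
#' Convenience wrapper: applies [measure_view()] to each view of a case (using
#' the supplied keypoints, or the case's own ground-truth keypoints) and
#' assembles the result.
#'
#' @param case A `case_record`.
#' @param keypoints Optional named list of `keypoint_set` per view; defaults
#'   to `case$keypoints`.
#' @return A `measurement_set`.
#' @export
measure_case <- function(case, keypoints = NULL) {
  kps <- keypoints %||% case$keypoints
  if (is.null(kps)) stop("no keypoints available to measure", call. = FALSE)
  assemble_measurements(
    measure_view(kps$PSSAX, case$scales$PSSAX),
    measure_view(kps$SXLAX, case$scales$SXLAX),
    measure_view(kps$A4C, case$scales$A4C))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set (mm)>\n")
  v <- unlist(x)
  for (n in names(v)) cat(sprintf("  %-26s %8.3f\n", n, v[[n]]))
  invisible(x)
}
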