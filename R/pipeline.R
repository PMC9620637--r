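# End-to-end orchestration: normalization, per-view localization, measuring,
# decision, and the file-based clinician-intervention hook.

#' Min-max normalize a raw image to the 0-255 gray range
#'
#' @param raw Numeric matrix (any finite range).
#' @param view View the frame belongs to (default `"PSSAX"`).
#' @return An `image_frame` with integer intensities in `[0, 255]`; constant
#'   images map to all zeros.
#' @export
normalize_image <- function(raw, view = "PSSAX") {
  if (!is.matrix(raw) || length(raw) == 0L)
    stop("raw must be a non-empty matrix", call. = FALSE)
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("io-error: non-finite pixels", call. = FALSE)
  rng <- range(raw)
  px <- if (rng[1] == rng[2]) matrix(0L, nrow(raw), ncol(raw))
        else round((raw - rng[1]) / (rng[2] - rng[1]) * 255)
  image_frame(px, view)
}

#' Write a keypoint-overlay review bundle
#'
#' Emits, per view, a PNG with white crosses at the predicted keypoints and a
#' JSON file of the coordinates that a clinician can edit and feed back via
#' `edit_files`.
#'
#' @param case A `case_record`.
#' @param keypoints Named list of `keypoint_set` per view.
#' @param out_dir Output directory.
#' @return Named list of the JSON paths per view, invisibly.
#' @export
write_overlays <- function(case, keypoints, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  for (v in view_ids()) {
    fr <- case$frames[[v]]
    img <- fr$pixels
    for (k in seq_len(nrow(keypoints[[v]]$points))) {
      cx <- round(keypoints[[v]]$points[k, "x"]) + 1
      cy <- round(keypoints[[v]]$points[k, "y"]) + 1
      rows <- pmax(1, pmin(fr$height, (cy - 3):(cy + 3)))
      cols <- pmax(1, pmin(fr$width, (cx - 3):(cx + 3)))
      img[rows, cx] <- 255
      img[cy, cols] <- 255
    }
    png::writePNG(img / 255,
                  file.path(out_dir, sprintf("%s_%s_overlay.png",
                                             case$case_id, v)))
    jp <- file.path(out_dir, sprintf("%s_%s_keypoints.json", case$case_id, v))
    write_annotation(keypoints[[v]], case$scales[[v]], case$case_id, jp)
    paths[[v]] <- jp
  }
  invisible(paths)
}

#' Run the full pipeline on one case
#'
#' Per view: normalize, localize keypoints (MSHNet + RegNet, or the case's
#' ground-truth keypoints when `models = "oracle"`), then measure, assemble
#' and decide. In review mode, keypoint overlays are written and any supplied
#' per-view edit JSON replaces the predictions before measuring - the
#' clinician-intervention hook.
#'
#' @param case A `case_record`.
#' @param models `"oracle"` to inject the case's ground-truth keypoints
#'   (isolates the deterministic measurement + decision back half), or a
#'   named list per view of `list(model =, regnet =)` localizers.
#' @param rules,cat Rule set and occluder catalogue.
#' @param mode `"auto"` or `"review"`.
#' @param review_dir Directory for overlays in review mode.
#' @param edit_files Optional named list (per view) of edited keypoint JSON
#'   paths applied before measuring.
#' @return List with `keypoints`, `measurements`, `decision`.
#' @export
run_case <- function(case, models = "oracle", rules = default_ruleset(),
                     cat = occluder_catalogue(), mode = c("auto", "review"),
                     review_dir = tempfile("review"), edit_files = NULL) {
  mode <- match.arg(mode)
  kps <- list()
  for (v in view_ids()) {
    if (is.null(case$frames[[v]])) stop("missing view ", v, call. = FALSE)
    kps[[v]] <- if (identical(models, "oracle")) {
      if (is.null(case$keypoints[[v]]))
        stop("oracle mode needs ground-truth keypoints", call. = FALSE)
      case$keypoints[[v]]
    } else {
      mv <- models[[v]]
      if (is.null(mv$model)) stop("config-error: no localizer for view ", v,
                                  call. = FALSE)
      predict_keypoints(mv$model, case$frames[[v]], mv$regnet)
    }
  }
  if (mode == "review") {
    write_overlays(case, kps, review_dir)
    for (v in names(edit_files %||% list())) {
      ed <- read_annotation(edit_files[[v]])
      kps[[v]] <- ed$keypoints
    }
  }
  m <- measure_case(case, keypoints = kps)
  dec <- decide(m, rules, cat)
  list(keypoints = kps, measurements = m, decision = dec)
}

#' Run the black-box baseline on one case
#'
#' @param case A `case_record`.
#' @param model A `blackbox` model.
#' @param threshold Probability threshold for the plan (default 0.5).
#' @return List with `probability` (P(transcatheter)) and `plan`.
#' @export
run_blackbox <- function(case, model, threshold = 0.5) {
  p <- blackbox_forward(model, case$frames, case$scales)
  list(probability = p,
       plan = if (p >= threshold) "transcatheter" else "surgical")
}
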