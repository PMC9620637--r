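# Synthetic echocardiogram-like case generator.
#
# Each view is modelled as a sector-shaped grayscale frame containing a bright
# septum band interrupted by the defect gap, Gaussian landmark blobs at the
# rim anchor structures, optional Doppler-style jet overlay across the gap,
# multiplicative Rayleigh speckle and Gaussian blur. Keypoints are placed
# analytically, so ground truth is exact by construction and the decision
# labels are derived by applying the rule engine to the true geometry.

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Noise parameters for the synthetic renderer
#'
#' With `speckle_strength = 0` and `blur_sigma_px = 0` the rendered image is a
#' deterministic, noise-free function of the geometry.
#'
#' @param speckle_strength Mixing weight of multiplicative Rayleigh speckle in
#'   `[0, 1]` (default 0.35).
#' @param blur_sigma_px Gaussian blur sigma in pixels (default 1).
#' @param background_level Background gray level in `[0, 255]` (default 20).
#' @param jet_overlay Add a Doppler-style high-intensity flow blob across the
#'   defect gap (default `TRUE`; set `FALSE` for 2D-style frames).
#' @return A `noise_params` object.
#' @export
noise_params <- function(speckle_strength = 0.35, blur_sigma_px = 1,
                         background_level = 20, jet_overlay = TRUE) {
  stopifnot(speckle_strength >= 0, blur_sigma_px >= 0,
            background_level >= 0, background_level <= 255)
  structure(list(speckle_strength = speckle_strength,
                 blur_sigma_px = blur_sigma_px,
                 background_level = as.integer(background_level),
                 jet_overlay = isTRUE(jet_overlay)),
            class = "noise_params")
}

#' Sample a random case geometry
#'
#' Draws defect diameters, rim lengths, septum length and sector parameters.
#' With probability `class_mix` the geometry satisfies the default rule set
#' (all rims comfortably above 5 mm, sizeable catalogue match); otherwise one
#' eligibility rule is violated, either through a deficient rim or a defect
#' too large for the catalogue. Samples stay clear of the decision thresholds
#' so that sub-micrometre measurement error can never flip a label.
#'
#' @param rng_seed Integer seed; the same seed reproduces the geometry
#'   bit-identically.
#' @param class_mix Target fraction of transcatheter-eligible cases in
#'   `[0, 1]` (default 0.6, roughly the prevalence in interventional series).
#' @return A `geometry_params` object.
#' @export
sample_geometry <- function(rng_seed, class_mix = 0.6) {
  .with_seed(rng_seed, {
    eligible <- runif(1) < class_mix
    if (eligible) {
      base_d <- runif(1, 5, 20)
      rims <- runif(5, 5.8, 14)
    } else if (runif(1) < 0.6) {
      base_d <- runif(1, 5, 20)
      rims <- runif(5, 5.8, 14)
      rims[sample.int(5, 1)] <- runif(1, 1.5, 4.2) # deficient rim
    } else {
      base_d <- runif(1, 32, 34.5) # exceeds largest catalogue size + margin
      rims <- runif(5, 5.8, 14)
    }
    # keep the sizing target away from integer catalogue boundaries
    repeat {
      jit <- runif(3, 0.92, 1.0)
      d <- base_d * jit
      if (min(abs((max(d) + 4) - round(max(d) + 4))) > 1e-3) break
    }
    names(rims) <- c("wall", "svc", "ivc", "roof", "mitral")
    d <- setNames(d, view_ids())
    structure(list(
      defect_diameter_mm = d,
      rim_lengths_mm = rims,
      septum_length_mm = unname(d["A4C"] + rims["roof"] + rims["mitral"]),
      septum_angle_deg = runif(1, -25, 25),
      sector_apex = c(0.5, -0.05),
      sector_span_deg = 90), class = "geometry_params")
  })
}

# 1-D landmark layout along the septum line, in mm from the first landmark.
# Returned in schema order for the view.
.layout_view <- function(geom, view) {
  d <- geom$defect_diameter_mm[[view]]
  r <- geom$rim_lengths_mm
  switch(view,
    PSSAX = c(defect_end_A = r[["wall"]], defect_end_B = r[["wall"]] + d,
              wall_point = 0),
    SXLAX = c(defect_end_sup = r[["svc"]], defect_end_inf = r[["svc"]] + d,
              svc_point = 0, ivc_point = r[["svc"]] + d + r[["ivc"]]),
    A4C = c(defect_end_roof = r[["roof"]],
            defect_end_mitral = r[["roof"]] + d,
            roof_point = 0,
            mitral_point = r[["roof"]] + d + r[["mitral"]]))
}

#' True measurements implied by a geometry
#'
#' The millimetre measurement set that an ideal measurement of the analytic
#' keypoints would produce; used to derive case labels and to check
#' stadiometry soundness.
#'
#' @param geom A `geometry_params`.
#' @return A `measurement_set`.
#' @export
geometry_measurements <- function(geom) {
  d <- geom$defect_diameter_mm
  r <- geom$rim_lengths_mm
  assemble_measurements(
    c(defect_diameter_pssax_mm = unname(d[["PSSAX"]]),
      rim_wall_mm = unname(r[["wall"]])),
    c(defect_diameter_sxlax_mm = unname(d[["SXLAX"]]),
      rim_svc_mm = unname(r[["svc"]]), rim_ivc_mm = unname(r[["ivc"]])),
    c(defect_diameter_a4c_mm = unname(d[["A4C"]]),
      rim_roof_mm = unname(r[["roof"]]),
      rim_mitral_mm = unname(r[["mitral"]]),
      septum_length_mm = geom$septum_length_mm))
}

# Sample a per-view scale so the landmark span occupies a moderate fraction
# of the frame. mm/px is drawn toward [0.08, 0.3] but raised when a large
# heart at a small frame requires it (the span must fit).
.sample_scale <- function(span_mm, size_px) {
  frac <- runif(1, 0.55, 0.7)
  mpp <- span_mm / (frac * size_px)
  mpp <- min(max(mpp, 0.08), 0.3)
  mpp <- max(mpp, span_mm / (0.86 * size_px))
  scale_info(mm_per_pixel = mpp)
}

.render_view <- function(geom, noise, scale, view, size_px) {
  S <- size_px
  lay <- .layout_view(geom, view)
  mpp <- scale$mm_per_pixel
  theta <- geom$septum_angle_deg * pi / 180
  u <- c(cos(theta), sin(theta))
  t_mid <- (min(lay) + max(lay)) / 2
  ctr <- c((S - 1) / 2, (S - 1) / 2)
  pts <- t(vapply(lay, function(t)
    ctr + (t - t_mid) / mpp * u, numeric(2)))
  if (any(pts < 3) || any(pts > S - 4))
    stop("render-error: geometry does not fit inside a ", S, "px frame at ",
         signif(mpp, 4), " mm/px", call. = FALSE)
  sch <- schema_for(view)
  kps <- keypoint_set(view, pts[sch$names, , drop = FALSE])

  # signed coordinates along (t) and across (s) the septum line, in px
  xg <- seq_len(S) - 1; yg <- seq_len(S) - 1
  Xr <- matrix(xg, S, S, byrow = TRUE) - ctr[1]
  Yr <- matrix(yg, S, S) - ctr[2]
  Tpx <- Xr * u[1] + Yr * u[2]
  Spx <- -Xr * u[2] + Yr * u[1]

  lay_px <- (lay - t_mid) / mpp
  ends <- sort(lay_px[1:2]) # defect endpoints in schema order 1:2
  band0 <- min(lay_px) - 4 / mpp
  band1 <- max(lay_px) + 4 / mpp
  img <- matrix(as.numeric(noise$background_level), S, S)
  in_band <- abs(Spx) <= 2 & Tpx >= band0 & Tpx <= band1
  in_gap <- Tpx > ends[1] & Tpx < ends[2]
  img[in_band & !in_gap] <- 200

  # landmark blobs at the non-endpoint anchors
  for (nm in sch$names[-(1:2)]) {
    img <- img + 70 * gaussian_map(pts[nm, ], c(S, S), 2.5)
  }
  if (noise$jet_overlay) {
    mid <- (pts[sch$names[1], ] + pts[sch$names[2], ]) / 2
    jet_sigma <- max(1.5, (ends[2] - ends[1]) / 5)
    img <- img + 230 * gaussian_map(mid, c(S, S), jet_sigma)
  }

  # sector mask: apex above the top edge, symmetric span, radial cutoff
  apex <- c(geom$sector_apex[1] * (S - 1), geom$sector_apex[2] * (S - 1))
  Xa <- matrix(xg, S, S, byrow = TRUE) - apex[1]
  Ya <- matrix(yg, S, S) - apex[2]
  phi <- atan2(Xa, Ya)
  rad <- sqrt(Xa^2 + Ya^2)
  outside <- abs(phi) > (geom$sector_span_deg / 2) * pi / 180 | rad > 1.25 * S
  img[outside] <- 0

  if (noise$speckle_strength > 0) {
    sigma_r <- sqrt(2 / pi) # Rayleigh scale with unit mean
    ray <- sigma_r * sqrt(-2 * log(runif(S * S)))
    mult <- (1 - noise$speckle_strength) + noise$speckle_strength *
      matrix(ray, S, S)
    img <- img * mult
  }
  if (noise$blur_sigma_px > 0) img <- .gaussian_blur(img, noise$blur_sigma_px)
  img <- pmin(pmax(img, 0), 255)
  list(frame = image_frame(round(img), view), keypoints = kps)
}

# Gaussian blur through the package's own convolution kernel.
.gaussian_blur <- function(img, sigma) {
  k <- 2L * as.integer(ceiling(2.5 * sigma)) + 1L
  g <- stats::dnorm(seq_len(k) - (k + 1) / 2, sd = sigma)
  w <- outer(g, g); w <- w / sum(w)
  x <- array(img, dim = c(nrow(img), ncol(img), 1L))
  out <- conv2d_fwd(x, matrix(as.numeric(t(w)), ncol = 1), 0, k, k)
  out[, , 1]
}

#' Render a full synthetic case
#'
#' Renders the three view frames for a geometry, places the analytic ground
#' truth keypoints, samples (or applies) a per-view scale, and derives the
#' closure-plan and occluder-size labels by applying the decision rules to
#' the true geometry.
#'
#' @param geom A `geometry_params` from [sample_geometry()].
#' @param noise A `noise_params` (default [noise_params()]).
#' @param scale Optional `scale_info` applied to every view; by default a
#'   per-view scale is sampled so the anatomy fits the frame.
#' @param rng_seed Integer seed for scale sampling and speckle.
#' @param image_size Square frame size in pixels (default 256).
#' @param case_id Case identifier (default derived from the seed).
#' @param rules,cat Rule set and catalogue used to derive labels.
#' @return A `case_record` with frames, scales, keypoints and labels.
#' @export
render_case <- function(geom, noise = noise_params(), scale = NULL,
                        rng_seed = 1, image_size = 256,
                        case_id = sprintf("case_%06d", rng_seed),
                        rules = default_ruleset(),
                        cat = occluder_catalogue()) {
  .with_seed(rng_seed, {
    frames <- list(); scales <- list(); keypoints <- list()
    for (v in view_ids()) {
      sc <- if (is.null(scale)) {
        lay <- .layout_view(geom, v)
        .sample_scale(max(lay) - min(lay), image_size)
      } else scale
      rv <- .render_view(geom, noise, sc, v, image_size)
      frames[[v]] <- rv$frame
      scales[[v]] <- sc
      keypoints[[v]] <- rv$keypoints
    }
    dec <- decide(geometry_measurements(geom), rules, cat)
    case_record(case_id, frames, scales, keypoints,
                label_plan = dec$plan,
                label_size_mm = if (dec$plan == "transcatheter")
                  dec$suggested_size_mm else NULL,
                geometry = geom)
  })
}

#' Generate a list of synthetic cases in memory
#'
#' @param n_cases Number of cases (>= 1).
#' @param rng_seed Base seed; case `i` uses a seed derived from it.
#' @param class_mix Target transcatheter fraction (default 0.6).
#' @param image_size Frame size in pixels (default 256).
#' @param noise A `noise_params`.
#' @return List of `case_record`.
#' @export
generate_cases <- function(n_cases, rng_seed = 1, class_mix = 0.6,
                           image_size = 256, noise = noise_params()) {
  stopifnot(n_cases >= 1)
  lapply(seq_len(n_cases), function(i) {
    si <- (rng_seed * 7919L + i) %% 2147480000L
    geom <- sample_geometry(si, class_mix)
    render_case(geom, noise, rng_seed = si + 1L, image_size = image_size,
                case_id = sprintf("case_%06d", i))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes one 8-bit grayscale PNG per view, one annotation JSON per
#' case/view, and a manifest CSV listing paths and labels. Fully reproducible
#' from the seed.
#'
#' @inheritParams generate_cases
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a data frame, invisibly; also written to
#'   `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(n_cases, rng_seed = 1, class_mix = 0.6,
                             out_dir, image_size = 256,
                             noise = noise_params()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  cases <- generate_cases(n_cases, rng_seed, class_mix, image_size, noise)
  rows <- lapply(cases, function(cs) {
    row <- list(case_id = cs$case_id)
    for (v in view_ids()) {
      png_path <- file.path(out_dir, sprintf("%s_%s.png", cs$case_id, v))
      png::writePNG(cs$frames[[v]]$pixels / 255, png_path)
      ann_path <- file.path(out_dir, sprintf("%s_%s.json", cs$case_id, v))
      write_annotation(cs$keypoints[[v]], cs$scales[[v]], cs$case_id,
                       ann_path)
      row[[paste0("image_", v)]] <- png_path
      row[[paste0("annotation_", v)]] <- ann_path
    }
    row$label_plan <- cs$label_plan
    row$label_size_mm <- if (is.null(cs$label_size_mm)) NA_integer_
                         else cs$label_size_mm
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
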