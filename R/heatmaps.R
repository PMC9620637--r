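# Ground-truth heatmap construction and decoding.
#
# Targets are unnormalized Gaussians with peak value 1 (the standard target
# for hourglass-style heatmap regression); pair/triplet "co-occurrence" maps
# for the anatomical-aware supervision are element-wise maxima of the single
# point maps, which keeps values in [0,1] and is permutation invariant.

#' Render a single-keypoint Gaussian response map
#'
#' `grid[r, c] = exp(-((c - x)^2 + (r - y)^2) / (2 sigma^2))` on a 0-based
#' pixel grid, so the peak value is exactly 1 when the point coincides with a
#' grid cell. Points outside the grid produce a truncated map, flagged via the
#' `"off_grid"` attribute rather than an error.
#'
#' @param point Numeric length-2 vector `(x, y)`, 0-based pixel coordinates.
#' @param shape Integer length-2 vector `(h, w)`.
#' @param sigma_px Gaussian standard deviation in pixels (> 0).
#' @return `h x w` numeric matrix in `[0, 1]` with attribute `off_grid`.
#' @export
gaussian_map <- function(point, shape, sigma_px) {
  if (sigma_px <= 0) stop("sigma_px must be positive", call. = FALSE)
  h <- shape[1]; w <- shape[2]
  x <- point[1]; y <- point[2]
  dx2 <- (seq_len(w) - 1 - x)^2
  dy2 <- (seq_len(h) - 1 - y)^2
  m <- exp(-outer(dy2, dx2, "+") / (2 * sigma_px^2))
  attr(m, "off_grid") <- (x < 0 || x > w - 1 || y < 0 || y > h - 1)
  m
}

#' Build a multiscale ground-truth heatmap pyramid
#'
#' Keypoint coordinates are scaled to each pyramid level and a Gaussian map is
#' drawn per keypoint, with sigma scaled proportionally (floored at 0.5 px so
#' coarse levels retain a usable peak). Channel order follows the view schema.
#'
#' @param kps A `keypoint_set`.
#' @param input_shape Integer `(h, w)` of the full-resolution image.
#' @param scales Ascending ratios in (0, 1]; default `c(1/8, 1/4, 1/2, 1)`.
#' @param sigma_px Full-resolution Gaussian sigma in pixels (default 2).
#' @return A `heatmap_pyramid`: list with `scales` and `maps` (per scale an
#'   `h_s x w_s x K` array).
#' @export
build_pyramid <- function(kps, input_shape, scales = c(1/8, 1/4, 1/2, 1),
                          sigma_px = 2) {
  if (!inherits(kps, "keypoint_set") || nrow(kps$points) == 0L)
    stop("kps must be a non-empty keypoint_set", call. = FALSE)
  if (is.unsorted(scales) || any(scales <= 0) || any(scales > 1))
    stop("scales must be ascending ratios in (0, 1]", call. = FALSE)
  maps <- lapply(scales, function(s) {
    hs <- max(1L, as.integer(round(s * input_shape[1])))
    ws <- max(1L, as.integer(round(s * input_shape[2])))
    sig <- max(s * sigma_px, 0.5)
    arr <- array(0, dim = c(hs, ws, nrow(kps$points)))
    for (k in seq_len(nrow(kps$points))) {
      arr[, , k] <- gaussian_map(kps$points[k, ] * s, c(hs, ws), sig)
    }
    dimnames(arr) <- list(NULL, NULL, rownames(kps$points))
    arr
  })
  names(maps) <- as.character(scales)
  structure(list(view = kps$view, scales = scales, maps = maps,
                 input_shape = input_shape, sigma_px = sigma_px),
            class = "heatmap_pyramid")
}

.pair_indices <- function(K) if (K >= 2) combn(K, 2) else matrix(0L, 2, 0)
.triplet_indices <- function(K) if (K >= 3) combn(K, 3) else matrix(0L, 3, 0)

#' Build anatomical-aware pair/triplet target maps
#'
#' For every unordered keypoint pair and triple in the view, the target is the
#' element-wise maximum of the constituent single-point Gaussian maps - a
#' co-occurrence response that captures the joint spatial configuration of
#' anatomically related landmarks. A K-point view yields `choose(K, 2)` pair
#' maps and `choose(K, 3)` triplet maps.
#'
#' @inheritParams build_pyramid
#' @param shape Integer `(h, w)` of the target grid.
#' @return An `aas_targets`: list with `pair_maps` (`h x w x C(K,2)` array),
#'   `triplet_maps` (`h x w x C(K,3)`), and the index matrices.
#' @export
build_aas_targets <- function(kps, shape, sigma_px = 2) {
  K <- nrow(kps$points)
  if (K < 2) stop("need at least 2 keypoints for pair maps", call. = FALSE)
  singles <- lapply(seq_len(K), function(k)
    gaussian_map(kps$points[k, ], shape, sigma_px))
  pi_ <- .pair_indices(K)
  ti <- .triplet_indices(K)
  pair_maps <- array(0, dim = c(shape[1], shape[2], ncol(pi_)))
  for (j in seq_len(ncol(pi_)))
    pair_maps[, , j] <- pmax(singles[[pi_[1, j]]], singles[[pi_[2, j]]])
  triplet_maps <- array(0, dim = c(shape[1], shape[2], ncol(ti)))
  for (j in seq_len(ncol(ti)))
    triplet_maps[, , j] <- pmax(singles[[ti[1, j]]],
                                pmax(singles[[ti[2, j]]], singles[[ti[3, j]]]))
  structure(list(view = kps$view, pair_maps = pair_maps,
                 triplet_maps = triplet_maps, pairs = pi_, triplets = ti),
            class = "aas_targets")
}

# Sub-pixel argmax of one response map. Ties in the argmax are broken toward
# the smaller (row, col); the quarter-pixel offset moves toward the larger of
# the two axis neighbours (missing neighbours count as 0).
.decode_channel <- function(m) {
  h <- nrow(m); w <- ncol(m)
  mx <- max(m)
  if (!is.finite(mx) || mx == min(m)) {
    return(list(xy = c((w - 1) / 2, (h - 1) / 2), low_confidence = TRUE))
  }
  hits <- which(m == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  r <- unname(hits[1, 1]); c <- unname(hits[1, 2])
  right <- if (c < w) m[r, c + 1] else 0
  left  <- if (c > 1) m[r, c - 1] else 0
  down  <- if (r < h) m[r + 1, c] else 0
  up    <- if (r > 1) m[r - 1, c] else 0
  x <- (c - 1) + 0.25 * sign(right - left)
  y <- (r - 1) + 0.25 * sign(down - up)
  list(xy = c(x, y), low_confidence = FALSE)
}

#' Decode a heatmap stack to keypoint coordinates
#'
#' Per channel, the location is the argmax plus a quarter-pixel offset toward
#' the higher of the two axis neighbours (standard sub-pixel refinement for
#' heatmap regression). Degenerate all-constant channels fall back to the grid
#' centre and are flagged low-confidence.
#'
#' @param grid_stack `h x w x K` array, one channel per schema keypoint.
#' @param view One of `view_ids()`; channel count must match its schema.
#' @return A `keypoint_set` with attribute `low_confidence` (logical per
#'   keypoint).
#' @export
decode_heatmaps <- function(grid_stack, view) {
  sch <- schema_for(view)
  if (length(dim(grid_stack)) != 3L || dim(grid_stack)[3] != sch$count)
    stop("grid_stack must have one channel per schema keypoint",
         call. = FALSE)
  pts <- matrix(0, sch$count, 2)
  lc <- logical(sch$count)
  for (k in seq_len(sch$count)) {
    d <- .decode_channel(grid_stack[, , k])
    pts[k, ] <- d$xy
    lc[k] <- d$low_confidence
  }
  out <- keypoint_set(view, pts)
  attr(out, "low_confidence") <- lc
  out
}
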