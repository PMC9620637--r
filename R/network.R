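# Network architectures.
#
# MSHNet: cascaded hourglass. Each stack encodes 1/2 -> 1/4 -> 1/8 of the
# input resolution and decodes back symmetrically with skip connections; each
# decoder feature map (spatial sizes 1/8, 1/4, 1/2 of the input) is projected
# to per-keypoint heatmaps with a 1x1 convolution. With multiscale
# supervision disabled only the finest (1/2) head exists - the vanilla
# stacked-hourglass ablation. Anatomical-aware pair/triplet heads sit on the
# finest decoder feature. RegNet upsamples the final stack's heatmaps to full
# resolution, concatenates them and fuses them through a small fully
# convolutional refiner. All builders take a seed for weight initialization.

#' MSHNet configuration
#'
#' @param view One of `view_ids()` (fixes the number of keypoint channels).
#' @param n_stacks Number of cascaded hourglass stacks (default 2).
#' @param base_channels Feature channels throughout the hourglass
#'   (default 64).
#' @param input_size Square input size in pixels, divisible by 8
#'   (default 256).
#' @param msh_enabled Supervise all decoder scales (1/8, 1/4, 1/2); when
#'   `FALSE` only the finest scale is supervised (vanilla stacked hourglass).
#' @param aas_enabled Attach anatomical-aware pair/triplet heads at the
#'   finest supervised scale.
#' @param sigma_px Ground-truth Gaussian sigma at full resolution.
#' @return An `mshnet_config` list.
#' @export
mshnet_config <- function(view, n_stacks = 2, base_channels = 64,
                          input_size = 256, msh_enabled = TRUE,
                          aas_enabled = TRUE, sigma_px = 2) {
  .assert_view(view)
  if (input_size %% 8 != 0)
    stop("input_size must be divisible by 8", call. = FALSE)
  if (n_stacks < 1) stop("n_stacks must be >= 1", call. = FALSE)
  K <- schema_for(view)$count
  list(view = view, n_stacks = as.integer(n_stacks),
       base_channels = as.integer(base_channels),
       input_size = as.integer(input_size),
       n_keypoints = K,
       supervised_scales = if (msh_enabled) c(1/8, 1/4, 1/2) else 1/2,
       msh_enabled = isTRUE(msh_enabled),
       aas_enabled = isTRUE(aas_enabled),
       sigma_px = sigma_px)
}

#' Build an MSHNet model
#'
#' @param cfg An [mshnet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `mshnet` model object (configuration plus parameter tree).
#' @export
build_mshnet <- function(cfg, seed = 1) {
  .with_seed(seed, {
    C <- cfg$base_channels; K <- cfg$n_keypoints
    stacks <- lapply(seq_len(cfg$n_stacks), function(s) {
      st <- list(
        c2a = .conv_layer(3, 3, C, C),
        c4a = .conv_layer(3, 3, C, C),
        c8a = .conv_layer(3, 3, C, C),
        c4b = .conv_layer(3, 3, C, C),
        c2b = .conv_layer(3, 3, C, C),
        head2 = .conv_layer(1, 1, C, K, init_scale = 0.1))
      if (cfg$msh_enabled) {
        st$head8 <- .conv_layer(1, 1, C, K, init_scale = 0.1)
        st$head4 <- .conv_layer(1, 1, C, K, init_scale = 0.1)
      }
      if (cfg$aas_enabled) {
        st$pair_head <- .conv_layer(1, 1, C, ncol(.pair_indices(K)),
                                    init_scale = 0.1)
        if (K >= 3)
          st$triplet_head <- .conv_layer(1, 1, C,
                                         ncol(.triplet_indices(K)),
                                         init_scale = 0.1)
      }
      if (s < cfg$n_stacks) st$remap <- .conv_layer(1, 1, K, C)
      st
    })
    structure(list(cfg = cfg,
                   params = list(stem = .conv_layer(3, 3, 1, C),
                                 stacks = stacks)),
              class = "mshnet")
  })
}

#' Forward pass of an MSHNet
#'
#' @param model An `mshnet`.
#' @param x Input image as an `H x W x 1` array with values in `[0, 1]`, or
#'   an `image_frame` (normalized automatically).
#' @param keep_cache Keep intermediate activations for backpropagation.
#' @return List with `stacks` (per stack: `heatmaps` named by scale, and
#'   `pair` / `triplet` maps when enabled) and, if requested, `cache`.
#' @export
mshnet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg
  if (inherits(x, "image_frame"))
    x <- array(x$pixels / 255, dim = c(x$height, x$width, 1L))
  if (length(dim(x)) != 3L || dim(x)[3] != 1L)
    stop("input must be an H x W x 1 array", call. = FALSE)
  if (dim(x)[1] != cfg$input_size || dim(x)[2] != cfg$input_size)
    stop("input size ", dim(x)[1], "x", dim(x)[2],
         " does not match configured ", cfg$input_size, call. = FALSE)
  P <- model$params
  stem_z <- .conv_f(P$stem, x)
  stem_a <- .relu(stem_z)
  p0 <- .pool_f(stem_a)
  x2 <- p0$y
  outs <- vector("list", cfg$n_stacks)
  caches <- vector("list", cfg$n_stacks)
  for (s in seq_len(cfg$n_stacks)) {
    st <- P$stacks[[s]]
    z2a <- .conv_f(st$c2a, x2);  e2 <- .relu(z2a); p2 <- .pool_f(e2)
    z4a <- .conv_f(st$c4a, p2$y); e4 <- .relu(z4a); p4 <- .pool_f(e4)
    z8  <- .conv_f(st$c8a, p4$y); f8 <- .relu(z8)
    u4 <- .up2_f(f8) + e4
    z4b <- .conv_f(st$c4b, u4); f4 <- .relu(z4b)
    u2 <- .up2_f(f4) + e2
    z2b <- .conv_f(st$c2b, u2); f2 <- .relu(z2b)
    h2 <- .conv_f(st$head2, f2)
    hm <- list()
    if (cfg$msh_enabled) {
      hm[["0.125"]] <- .conv_f(st$head8, f8)
      hm[["0.25"]]  <- .conv_f(st$head4, f4)
    }
    hm[["0.5"]] <- h2
    out <- list(heatmaps = hm)
    if (cfg$aas_enabled) {
      out$pair <- .conv_f(st$pair_head, f2)
      if (!is.null(st$triplet_head))
        out$triplet <- .conv_f(st$triplet_head, f2)
    }
    outs[[s]] <- out
    if (keep_cache)
      caches[[s]] <- list(x2 = x2, z2a = z2a, e2 = e2, p2 = p2, z4a = z4a,
                          e4 = e4, p4 = p4, z8 = z8, f8 = f8, u4 = u4,
                          z4b = z4b, f4 = f4, u2 = u2, z2b = z2b, f2 = f2,
                          h2 = h2)
    if (s < cfg$n_stacks)
      x2 <- x2 + f2 + .conv_f(st$remap, h2)
  }
  res <- list(stacks = outs)
  if (keep_cache)
    res$cache <- list(x = x, stem_z = stem_z, stem_a = stem_a, p0 = p0,
                      stacks = caches)
  res
}

# Backpropagate head gradients through the MSHNet. dheads: per stack a list
# with (optionally) elements named like the forward heatmap scales, plus
# `pair` / `triplet`. Returns a trainable-parameter gradient tree.
.mshnet_backward <- function(model, cache, dheads) {
  cfg <- model$cfg
  P <- model$params
  g <- .zeros_like(.trainable(P))
  dx2_next <- NULL
  for (s in rev(seq_len(cfg$n_stacks))) {
    st <- P$stacks[[s]]
    cc <- cache$stacks[[s]]
    dh <- dheads[[s]]
    zero2 <- cc$f2 * 0
    d_f2 <- zero2
    d_x2 <- zero2
    dh2 <- dh[["0.5"]] %||% (cc$h2 * 0)
    if (!is.null(dx2_next)) {
      # x2_{s+1} = x2 + f2 + remap(h2)
      d_x2 <- d_x2 + dx2_next
      d_f2 <- d_f2 + dx2_next
      bb <- .conv_b(st$remap, cc$h2, dx2_next)
      g$stacks[[s]]$remap$w <- g$stacks[[s]]$remap$w + bb$dw
      g$stacks[[s]]$remap$b <- g$stacks[[s]]$remap$b + bb$db
      dh2 <- dh2 + bb$dx
    }
    bb <- .conv_b(st$head2, cc$f2, dh2)
    g$stacks[[s]]$head2$w <- g$stacks[[s]]$head2$w + bb$dw
    g$stacks[[s]]$head2$b <- g$stacks[[s]]$head2$b + bb$db
    d_f2 <- d_f2 + bb$dx
    if (cfg$aas_enabled && !is.null(dh$pair)) {
      bb <- .conv_b(st$pair_head, cc$f2, dh$pair)
      g$stacks[[s]]$pair_head$w <- g$stacks[[s]]$pair_head$w + bb$dw
      g$stacks[[s]]$pair_head$b <- g$stacks[[s]]$pair_head$b + bb$db
      d_f2 <- d_f2 + bb$dx
    }
    if (cfg$aas_enabled && !is.null(dh$triplet) &&
        !is.null(st$triplet_head)) {
      bb <- .conv_b(st$triplet_head, cc$f2, dh$triplet)
      g$stacks[[s]]$triplet_head$w <- g$stacks[[s]]$triplet_head$w + bb$dw
      g$stacks[[s]]$triplet_head$b <- g$stacks[[s]]$triplet_head$b + bb$db
      d_f2 <- d_f2 + bb$dx
    }
    dz2b <- .relu_b(cc$z2b, d_f2)
    bb <- .conv_b(st$c2b, cc$u2, dz2b)
    g$stacks[[s]]$c2b$w <- bb$dw; g$stacks[[s]]$c2b$b <- bb$db
    d_e2 <- bb$dx
    d_f4 <- .up2_b(bb$dx)
    if (cfg$msh_enabled && !is.null(dh[["0.25"]])) {
      bb <- .conv_b(st$head4, cc$f4, dh[["0.25"]])
      g$stacks[[s]]$head4$w <- bb$dw; g$stacks[[s]]$head4$b <- bb$db
      d_f4 <- d_f4 + bb$dx
    }
    dz4b <- .relu_b(cc$z4b, d_f4)
    bb <- .conv_b(st$c4b, cc$u4, dz4b)
    g$stacks[[s]]$c4b$w <- bb$dw; g$stacks[[s]]$c4b$b <- bb$db
    d_e4 <- bb$dx
    d_f8 <- .up2_b(bb$dx)
    if (cfg$msh_enabled && !is.null(dh[["0.125"]])) {
      bb <- .conv_b(st$head8, cc$f8, dh[["0.125"]])
      g$stacks[[s]]$head8$w <- bb$dw; g$stacks[[s]]$head8$b <- bb$db
      d_f8 <- d_f8 + bb$dx
    }
    dz8 <- .relu_b(cc$z8, d_f8)
    bb <- .conv_b(st$c8a, cc$p4$y, dz8)
    g$stacks[[s]]$c8a$w <- bb$dw; g$stacks[[s]]$c8a$b <- bb$db
    d_e4 <- d_e4 + .pool_b(cc$p4$idx, bb$dx, dim(cc$e4)[1], dim(cc$e4)[2])
    dz4a <- .relu_b(cc$z4a, d_e4)
    bb <- .conv_b(st$c4a, cc$p2$y, dz4a)
    g$stacks[[s]]$c4a$w <- bb$dw; g$stacks[[s]]$c4a$b <- bb$db
    d_e2 <- d_e2 + .pool_b(cc$p2$idx, bb$dx, dim(cc$e2)[1], dim(cc$e2)[2])
    dz2a <- .relu_b(cc$z2a, d_e2)
    bb <- .conv_b(st$c2a, cc$x2, dz2a)
    g$stacks[[s]]$c2a$w <- bb$dw; g$stacks[[s]]$c2a$b <- bb$db
    d_x2 <- d_x2 + bb$dx
    dx2_next <- d_x2
  }
  d_stem_a <- .pool_b(cache$p0$idx, dx2_next,
                      dim(cache$stem_a)[1], dim(cache$stem_a)[2])
  dz <- .relu_b(cache$stem_z, d_stem_a)
  bb <- .conv_b(model$params$stem, cache$x, dz)
  g$stem$w <- bb$dw; g$stem$b <- bb$db
  g
}

#' Build a RegNet fusion refiner
#'
#' A small fully convolutional network that upsamples each supervised scale's
#' heatmaps to full resolution, concatenates them along channels, and maps
#' them to refined full-resolution keypoint heatmaps.
#'
#' @param cfg The [mshnet_config()] of the MSHNet it refines.
#' @param fusion_channels Hidden channels of the refiner (default 32).
#' @param seed Integer seed for weight initialization.
#' @return A `regnet` model object.
#' @export
build_regnet <- function(cfg, fusion_channels = 32, seed = 1) {
  .with_seed(seed, {
    K <- cfg$n_keypoints
    n_scales <- length(cfg$supervised_scales)
    structure(list(cfg = cfg, fusion_channels = fusion_channels,
                   params = list(
                     fuse = .conv_layer(3, 3, K * n_scales, fusion_channels),
                     out = .conv_layer(1, 1, fusion_channels, K,
                                       init_scale = 0.1))),
              class = "regnet")
  })
}

# Scales are encoded as names like "0.5"; number of doublings to full res.
.up_times <- function(scale_name) as.integer(round(-log2(as.numeric(scale_name))))

#' Forward pass of a RegNet
#'
#' @param regnet A `regnet`.
#' @param heatmaps Named list of heatmap arrays by scale (an MSHNet stack's
#'   `heatmaps` output).
#' @param keep_cache Keep activations for backpropagation.
#' @return Full-resolution `H x W x K` heatmap array (with `cache` attribute
#'   when requested).
#' @export
regnet_forward <- function(regnet, heatmaps, keep_cache = FALSE) {
  expected <- as.character(regnet$cfg$supervised_scales)
  if (!all(expected %in% names(heatmaps)))
    stop("heatmaps must contain scales ", paste(expected, collapse = ", "),
         call. = FALSE)
  ups <- lapply(expected, function(sn)
    .upn_f(heatmaps[[sn]], .up_times(sn)))
  cat_ <- array(unlist(ups), dim = c(dim(ups[[1]])[1], dim(ups[[1]])[2],
                                     sum(vapply(ups, function(u) dim(u)[3],
                                                integer(1)))))
  z1 <- .conv_f(regnet$params$fuse, cat_)
  a1 <- .relu(z1)
  out <- .conv_f(regnet$params$out, a1)
  if (keep_cache)
    attr(out, "cache") <- list(cat_ = cat_, z1 = z1, a1 = a1,
                               scales = expected)
  out
}

# Returns parameter grads plus gradients w.r.t. the input heatmaps (named by
# scale) so they can be chained into the MSHNet head gradients.
.regnet_backward <- function(regnet, cache, dout) {
  K <- regnet$cfg$n_keypoints
  bb2 <- .conv_b(regnet$params$out, cache$a1, dout)
  dz1 <- .relu_b(cache$z1, bb2$dx)
  bb1 <- .conv_b(regnet$params$fuse, cache$cat_, dz1)
  dcat <- bb1$dx
  dheat <- list()
  for (i in seq_along(cache$scales)) {
    ch <- ((i - 1) * K + 1):(i * K)
    dheat[[cache$scales[i]]] <- .upn_b(dcat[, , ch, drop = FALSE],
                                       .up_times(cache$scales[i]))
  }
  list(grads = list(fuse = list(w = bb1$dw, b = bb1$db),
                    out = list(w = bb2$dw, b = bb2$db)),
       dheatmaps = dheat)
}

#' Black-box baseline configuration and builder
#'
#' The baseline formulates closure planning as direct binary classification:
#' three weight-shared convolutional towers embed the three views, the
#' embeddings are concatenated together with each view's mm-per-pixel scale
#' scalar, and fully connected layers output P(transcatheter).
#'
#' @param base_channels Channels of the first tower stage (default 8).
#' @param hidden Units of the fully connected hidden layer (default 16).
#' @param input_size Square input size in pixels (default 256).
#' @param seed Integer seed for weight initialization.
#' @return A `blackbox` model object.
#' @export
build_blackbox <- function(base_channels = 8, hidden = 16, input_size = 256,
                           seed = 1) {
  .with_seed(seed, {
    C1 <- base_channels; C2 <- 2L * base_channels
    feat <- 3L * C2 + 3L # three view embeddings + three scale scalars
    structure(list(input_size = as.integer(input_size),
                   params = list(
                     convA = .conv_layer(3, 3, 1, C1),
                     convB = .conv_layer(3, 3, C1, C2),
                     fc1_w = matrix(rnorm(feat * hidden,
                                          sd = sqrt(2 / feat)), feat, hidden),
                     fc1_b = numeric(hidden),
                     fc2_w = matrix(rnorm(hidden, sd = sqrt(2 / hidden)),
                                    hidden, 1),
                     fc2_b = 0)),
              class = "blackbox")
  })
}

#' Forward pass of the black-box baseline
#'
#' @param model A `blackbox`.
#' @param frames Named list of `image_frame` for all three views.
#' @param scales Named list of `scale_info` for all three views.
#' @return Probability of transcatheter closure in `[0, 1]`.
#' @export
blackbox_forward <- function(model, frames, scales) {
  embed <- function(fr) {
    if (is.null(fr)) stop("missing view input", call. = FALSE)
    x <- array(fr$pixels / 255, dim = c(fr$height, fr$width, 1L))
    a <- .relu(.conv_f(model$params$convA, x))
    a <- .pool_f(a)$y
    b <- .relu(.conv_f(model$params$convB, a))
    b <- .pool_f(b)$y
    apply(b, 3, mean) # global average pool
  }
  fvec <- c(unlist(lapply(view_ids(), function(v) embed(frames[[v]]))),
            vapply(view_ids(), function(v) {
              if (is.null(scales[[v]])) stop("missing view scale",
                                             call. = FALSE)
              scales[[v]]$mm_per_pixel
            }, numeric(1)))
  h <- .relu(as.numeric(fvec %*% model$params$fc1_w) + model$params$fc1_b)
  z <- as.numeric(h %*% model$params$fc2_w) + model$params$fc2_b
  1 / (1 + exp(-z))
}

#' Predict a view's keypoints with a trained localizer
#'
#' Runs the MSHNet forward pass and decodes keypoint coordinates - from the
#' RegNet-fused full-resolution heatmaps when a refiner is supplied,
#' otherwise from the final stack's finest-scale heatmaps (coordinates are
#' rescaled to full resolution).
#'
#' @param model An `mshnet`.
#' @param frame An `image_frame` (or `H x W x 1` array in `[0, 1]`).
#' @param regnet Optional `regnet` refiner.
#' @return A `keypoint_set` in full-resolution pixel coordinates.
#' @export
predict_keypoints <- function(model, frame, regnet = NULL) {
  out <- mshnet_forward(model, frame)
  last <- out$stacks[[length(out$stacks)]]
  if (!is.null(regnet)) {
    full <- regnet_forward(regnet, last$heatmaps)
    decode_heatmaps(full, model$cfg$view)
  } else {
    fin <- names(last$heatmaps)[length(last$heatmaps)]
    kps <- decode_heatmaps(last$heatmaps[[fin]], model$cfg$view)
    kps$points <- kps$points / as.numeric(fin)
    kps
  }
}

#' Summarize a model's layers and parameter count
#'
#' @param model An `mshnet`, `regnet`, or `blackbox`.
#' @return Total parameter count, invisibly; prints a per-layer summary.
#' @export
model_summary <- function(model) {
  total <- 0L
  walk <- function(node, prefix) {
    if (is.list(node) && is.numeric(node$w)) {
      n <- length(node$w) + length(node$b)
      total <<- total + n
      cat(sprintf("  %-28s %8d params (conv %dx%d, %d -> %d)\n", prefix, n,
                  node$kh, node$kw, node$cin, node$cout))
    } else if (is.list(node)) {
      nms <- names(node) %||% as.character(seq_along(node))
      for (i in seq_along(node))
        walk(node[[i]], paste0(prefix, ".", nms[i]))
    } else if (is.numeric(node)) {
      total <<- total + length(node)
      cat(sprintf("  %-28s %8d params\n", prefix, length(node)))
    }
  }
  cat(sprintf("<%s>\n", class(model)[1]))
  walk(model$params, class(model)[1])
  cat(sprintf("  total: %d parameters\n", total))
  invisible(total)
}

#' Save / load model checkpoints
#'
#' Checkpoints are single-file archives containing the model (and optional
#' refiner) with their configurations embedded.
#'
#' @param model An `mshnet` (or any model object).
#' @param path File path.
#' @param regnet Optional `regnet` stored alongside.
#' @return `path` invisibly (`save_checkpoint`); the restored list
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path, regnet = NULL) {
  saveRDS(list(model = model, regnet = regnet), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("missing checkpoint: ", path, call. = FALSE)
  readRDS(path)
}
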