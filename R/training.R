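# Losses and the optimization loop.
#
# The localization objective sums, over every supervised scale of every
# stack, the per-grid mean squared error against the downsampled ground-truth
# heatmaps (the multiscale loss). The anatomical-aware loss adds the MSE of
# the pair and triplet co-occurrence maps, and the RegNet refiner is trained
# against the full-resolution targets. Model selection keeps the checkpoint
# with the highest validation PCK.

#' Loss weights
#'
#' Setting `w_pair = w_triplet = 0` reproduces the no-anatomical-supervision
#' ablation; `w_reg` weights the RegNet refinement term.
#'
#' @param w_ms Multiscale heatmap MSE weight (default 1).
#' @param w_pair Pairwise co-occurrence MSE weight (default 0.5).
#' @param w_triplet Triplet co-occurrence MSE weight (default 0.25).
#' @param w_reg RegNet full-resolution MSE weight (default 1).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(w_ms = 1, w_pair = 0.5, w_triplet = 0.25,
                         w_reg = 1) {
  w <- list(w_ms = w_ms, w_pair = w_pair, w_triplet = w_triplet,
            w_reg = w_reg)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative",
                               call. = FALSE)
  structure(w, class = "loss_weights")
}

.maps_of <- function(x) if (inherits(x, "heatmap_pyramid")) x$maps else x

#' Multiscale heatmap loss
#'
#' Sum over scales of the per-grid mean squared error between predicted and
#' ground-truth heatmap stacks.
#'
#' @param pred,gt `heatmap_pyramid`s or named lists of heatmap arrays keyed
#'   by scale.
#' @return Scalar loss.
#' @export
multiscale_loss <- function(pred, gt) {
  p <- .maps_of(pred); g <- .maps_of(gt)
  if (!identical(sort(names(p)), sort(names(g))))
    stop("scale sets differ between pred and gt", call. = FALSE)
  total <- 0
  for (nm in names(p)) {
    if (!identical(dim(p[[nm]]), dim(g[[nm]])))
      stop("shape mismatch at scale ", nm, call. = FALSE)
    total <- total + mean((p[[nm]] - g[[nm]])^2)
  }
  total
}

#' Anatomical-aware pair/triplet loss
#'
#' @param pred_pairs,pred_triplets Predicted pair and triplet map arrays.
#' @param gt An `aas_targets`.
#' @return Named numeric `c(pair =, triplet =)` of mean squared errors
#'   (averaged over all maps of each kind).
#' @export
aas_loss <- function(pred_pairs, pred_triplets, gt) {
  if (!identical(dim(pred_pairs), dim(gt$pair_maps)))
    stop("pair map count/shape mismatch", call. = FALSE)
  lp <- mean((pred_pairs - gt$pair_maps)^2)
  lt <- if (length(gt$triplet_maps) == 0) 0 else {
    if (!identical(dim(pred_triplets), dim(gt$triplet_maps)))
      stop("triplet map count/shape mismatch", call. = FALSE)
    mean((pred_triplets - gt$triplet_maps)^2)
  }
  c(pair = lp, triplet = lt)
}

#' Weighted total training loss
#'
#' `w_ms * L_ms + w_pair * L_pair + w_triplet * L_triplet + w_reg * L_reg`.
#'
#' @param components Named list/vector with elements `ms`, `pair`, `triplet`,
#'   `reg` (missing components count as 0).
#' @param weights A [loss_weights()].
#' @return Scalar loss.
#' @export
total_loss <- function(components, weights = loss_weights()) {
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights,
                                                             weights)
  cmp <- unlist(components)
  pick <- function(nm) if (nm %in% names(cmp)) cmp[[nm]] else 0
  weights$w_ms * pick("ms") + weights$w_pair * pick("pair") +
    weights$w_triplet * pick("triplet") + weights$w_reg * pick("reg")
}

#' Training configuration
#'
#' @param epochs Number of epochs (default 30).
#' @param batch_size Minibatch size for gradient accumulation (default 4).
#' @param learning_rate Adam learning rate (default 1e-3; the small models
#'   and small batches used here want a larger step than the 2.5e-4
#'   customary for full-size hourglass training).
#' @param seed Integer seed controlling shuffling (and, through the model
#'   builders, initialization).
#' @param weights A [loss_weights()].
#' @param use_regnet Train and use the RegNet refiner (default `TRUE`).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30, batch_size = 4, learning_rate = 1e-3,
                         seed = 1, weights = loss_weights(),
                         use_regnet = TRUE) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate, seed = as.integer(seed),
       weights = weights, use_regnet = isTRUE(use_regnet))
}

# One case of a single-view training set: image array, keypoint_set, scale.
.view_sample <- function(case, view) {
  fr <- case$frames[[view]]
  list(x = array(fr$pixels / 255, dim = c(fr$height, fr$width, 1L)),
       kps = case$keypoints[[view]],
       scale = case$scales[[view]])
}

.scaled_kps <- function(kps, s) keypoint_set(kps$view, kps$points * s)

# Precompute ground-truth targets for one sample.
.make_targets <- function(kps, cfg) {
  S <- cfg$input_size
  pyr <- build_pyramid(kps, c(S, S), scales = cfg$supervised_scales,
                       sigma_px = cfg$sigma_px)
  gt <- list(pyr = pyr$maps)
  gt$full <- build_pyramid(kps, c(S, S), scales = 1,
                           sigma_px = cfg$sigma_px)$maps[["1"]]
  if (cfg$aas_enabled) {
    half <- .scaled_kps(kps, 0.5)
    gt$aas <- build_aas_targets(half, c(S / 2, S / 2),
                                sigma_px = max(cfg$sigma_px * 0.5, 0.5))
  }
  gt
}

#' Train an MSHNet (and optional RegNet) on single-view cases
#'
#' Minibatch Adam on the weighted multiscale + anatomical-aware + refinement
#' objective. After every epoch the validation PCK is computed and the
#' best-scoring parameter snapshot is retained.
#'
#' @param model An `mshnet` from [build_mshnet()].
#' @param regnet A `regnet` from [build_regnet()], or `NULL`.
#' @param train_cases,val_cases Lists of `case_record` with keypoints.
#' @param cfg A [train_config()].
#' @param alpha PCK correctness fraction used for model selection
#'   (default 0.1).
#' @param verbose Print per-epoch progress.
#' @return List with `model`, `regnet` (best-validation snapshots) and
#'   `history` (data frame: epoch, train loss, validation PCK).
#' @export
train_mshnet <- function(model, regnet, train_cases, val_cases, cfg,
                         alpha = 0.1, verbose = FALSE) {
  if (length(train_cases) == 0L || length(val_cases) == 0L)
    stop("training and validation sets must be non-empty", call. = FALSE)
  mcfg <- model$cfg
  view <- mcfg$view
  tr <- lapply(train_cases, .view_sample, view = view)
  va <- lapply(val_cases, .view_sample, view = view)
  targets <- lapply(tr, function(s) .make_targets(s$kps, mcfg))

  mt <- .trainable(model$params)
  mstate <- .adam_init(mt)
  if (!is.null(regnet)) {
    rt <- .trainable(regnet$params)
    rstate <- .adam_init(rt)
  }
  best <- list(pck = -Inf, model = model, regnet = regnet)
  history <- data.frame()
  n <- length(tr)

  val_pck <- function(mod, reg) {
    preds <- lapply(va, function(s) {
      fr <- image_frame(s$x[, , 1] * 255, view)
      predict_keypoints(mod, fr, reg)
    })
    pck(preds, lapply(va, `[[`, "kps"), lapply(va, `[[`, "scale"),
        alpha = alpha)
  }

  .with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      bstart <- seq(1, n, by = cfg$batch_size)
      for (b0 in bstart) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        gacc <- .zeros_like(mt)
        if (!is.null(regnet)) racc <- .zeros_like(rt)
        for (i in idx) {
          fw <- mshnet_forward(model, tr[[i]]$x, keep_cache = TRUE)
          gt <- targets[[i]]
          dheads <- vector("list", mcfg$n_stacks)
          loss_ms <- 0; loss_pair <- 0; loss_trip <- 0
          for (s in seq_len(mcfg$n_stacks)) {
            hm <- fw$stacks[[s]]$heatmaps
            dh <- list()
            for (nm in names(hm)) {
              diff <- hm[[nm]] - gt$pyr[[nm]]
              loss_ms <- loss_ms + mean(diff^2)
              dh[[nm]] <- cfg$weights$w_ms * 2 * diff / length(diff)
            }
            if (mcfg$aas_enabled) {
              al <- aas_loss(fw$stacks[[s]]$pair, fw$stacks[[s]]$triplet,
                             gt$aas)
              loss_pair <- loss_pair + al[["pair"]]
              loss_trip <- loss_trip + al[["triplet"]]
              dp <- fw$stacks[[s]]$pair - gt$aas$pair_maps
              dh$pair <- cfg$weights$w_pair * 2 * dp / length(dp)
              if (!is.null(fw$stacks[[s]]$triplet)) {
                dt <- fw$stacks[[s]]$triplet - gt$aas$triplet_maps
                dh$triplet <- cfg$weights$w_triplet * 2 * dt / length(dt)
              }
            }
            dheads[[s]] <- dh
          }
          loss_reg <- 0
          if (!is.null(regnet)) {
            last <- mcfg$n_stacks
            rfw <- regnet_forward(regnet, fw$stacks[[last]]$heatmaps,
                                  keep_cache = TRUE)
            rc <- attr(rfw, "cache")
            diff <- unclass(rfw) - gt$full
            attributes(diff) <- list(dim = dim(gt$full))
            loss_reg <- mean(diff^2)
            dreg <- cfg$weights$w_reg * 2 * diff / length(diff)
            rb <- .regnet_backward(regnet, rc, dreg)
            racc <- .tree_add(racc, rb$grads)
            for (nm in names(rb$dheatmaps))
              dheads[[last]][[nm]] <- dheads[[last]][[nm]] +
                rb$dheatmaps[[nm]]
          }
          g <- .mshnet_backward(model, fw$cache, dheads)
          gacc <- .tree_add(gacc, g)
          loss_i <- total_loss(list(ms = loss_ms, pair = loss_pair,
                                    triplet = loss_trip, reg = loss_reg),
                               cfg$weights)
          if (!is.finite(loss_i))
            stop("training diverged: non-finite loss at epoch ", epoch,
                 call. = FALSE)
          ep_loss <- ep_loss + loss_i
        }
        inv <- 1 / length(idx)
        upd <- .adam_step(mt, .tree_scale(gacc, inv), mstate,
                          cfg$learning_rate)
        mt <- upd$params; mstate <- upd$state
        model$params <- .merge_trainable(model$params, mt)
        if (!is.null(regnet)) {
          updr <- .adam_step(rt, .tree_scale(racc, inv), rstate,
                             cfg$learning_rate)
          rt <- updr$params; rstate <- updr$state
          regnet$params <- .merge_trainable(regnet$params, rt)
        }
      }
      vp <- val_pck(model, regnet)
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ep_loss / n,
                                  val_pck = vp))
      if (vp >= best$pck) best <- list(pck = vp, model = model,
                                      regnet = regnet)
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  val PCK %.3f", epoch,
                        ep_loss / n, vp))
    }
  })
  list(model = best$model, regnet = best$regnet, history = history,
       best_val_pck = best$pck)
}
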