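test_that("multiscale loss sums per-scale mean squared errors", {
  gt <- list("0.25" = array(0, c(4, 4, 2)), "0.5" = array(0, c(8, 8, 2)),
             "1" = array(0, c(16, 16, 2)))
  pred <- lapply(gt, function(g) g + 1)
  expect_equal(multiscale_loss(pred, gt), 3) # MSE 1 per scale, summed
  expect_equal(multiscale_loss(gt, gt), 0)
  expect_equal(multiscale_loss(pred, gt), multiscale_loss(gt, pred))
  bad <- gt; bad[["0.5"]] <- array(0, c(4, 4, 2))
  expect_error(multiscale_loss(pred, bad), "shape mismatch")
  expect_error(multiscale_loss(pred[1:2], gt), "scale sets differ")
})

test_that("AAS loss averages pair and triplet maps separately", {
  kps <- keypoint_set("PSSAX", matrix(c(5, 15, 25, 8, 8, 20), 3, 2))
  gt <- build_aas_targets(kps, c(32, 32), sigma_px = 2)
  expect_equal(dim(gt$pair_maps)[3], 3)
  expect_equal(dim(gt$triplet_maps)[3], 1)
  perfect <- aas_loss(gt$pair_maps, gt$triplet_maps, gt)
  expect_equal(unname(perfect), c(0, 0))
  off <- aas_loss(gt$pair_maps + 0.1, gt$triplet_maps + 0.1, gt)
  expect_equal(unname(off), c(0.01, 0.01))
  # quadratic scaling of the error
  off2 <- aas_loss(gt$pair_maps + 0.2, gt$triplet_maps + 0.2, gt)
  expect_equal(unname(off2), 4 * unname(off))
  expect_error(aas_loss(gt$pair_maps[, , 1:2], gt$triplet_maps, gt),
               "mismatch")
})

test_that("the weighted total follows the configured combination", {
  comp <- list(ms = 1, pair = 1, triplet = 1, reg = 1)
  expect_equal(total_loss(comp, loss_weights()), 2.75) # 1 + .5 + .25 + 1
  expect_equal(total_loss(comp, loss_weights(0, 0, 0, 0)), 0)
  # zeroing the AAS weights reproduces the MSH-only objective
  expect_equal(total_loss(comp, loss_weights(w_pair = 0, w_triplet = 0)),
               total_loss(list(ms = 1, reg = 1), loss_weights()))
  expect_error(loss_weights(w_pair = -1), "non-negative")
})

test_that("the analytic multiscale-loss gradient matches finite differences", {
  set.seed(13)
  gt <- list("1" = array(runif(16), c(4, 4, 1)))
  pred <- list("1" = array(runif(16), c(4, 4, 1)))
  analytic <- 2 * (pred[["1"]] - gt[["1"]]) / 16
  eps <- 1e-6
  for (i in seq_len(16)) {
    up <- pred; up[["1"]][i] <- up[["1"]][i] + eps
    dn <- pred; dn[["1"]][i] <- dn[["1"]][i] - eps
    num <- (multiscale_loss(up, gt) - multiscale_loss(dn, gt)) / (2 * eps)
    expect_equal(num, analytic[i], tolerance = 1e-4)
  }
})

test_that("network backpropagation matches finite differences", {
  cfg <- mshnet_config("PSSAX", n_stacks = 2, base_channels = 3,
                       input_size = 16)
  model <- build_mshnet(cfg, seed = 3)
  set.seed(9)
  kps <- keypoint_set("PSSAX", matrix(runif(6, 2, 13), 3, 2))
  x <- array(runif(16 * 16), dim = c(16, 16, 1))
  gt <- dks:::.make_targets(kps, cfg)
  lossfun <- function(m) {
    fw <- mshnet_forward(m, x)
    l <- 0
    for (s in 1:cfg$n_stacks) {
      for (nm in names(fw$stacks[[s]]$heatmaps))
        l <- l + mean((fw$stacks[[s]]$heatmaps[[nm]] - gt$pyr[[nm]])^2)
      al <- aas_loss(fw$stacks[[s]]$pair, fw$stacks[[s]]$triplet, gt$aas)
      l <- l + 0.5 * al[["pair"]] + 0.25 * al[["triplet"]]
    }
    l
  }
  fw <- mshnet_forward(model, x, keep_cache = TRUE)
  dheads <- lapply(1:cfg$n_stacks, function(s) {
    dh <- list()
    for (nm in names(fw$stacks[[s]]$heatmaps)) {
      diff <- fw$stacks[[s]]$heatmaps[[nm]] - gt$pyr[[nm]]
      dh[[nm]] <- 2 * diff / length(diff)
    }
    dp <- fw$stacks[[s]]$pair - gt$aas$pair_maps
    dh$pair <- 0.5 * 2 * dp / length(dp)
    dt <- fw$stacks[[s]]$triplet - gt$aas$triplet_maps
    dh$triplet <- 0.25 * 2 * dt / length(dt)
    dh
  })
  g <- dks:::.mshnet_backward(model, fw$cache, dheads)
  eps <- 1e-5
  probe <- list(c("stem", "w"), c("stacks", "1", "c8a", "w"),
                c("stacks", "1", "remap", "w"),
                c("stacks", "2", "head4", "w"),
                c("stacks", "2", "pair_head", "w"))
  for (pr in probe) {
    getp <- function(tr) Reduce(function(t, k) {
      if (grepl("^[0-9]+$", k)) t[[as.integer(k)]] else t[[k]]
    }, pr, tr)
    pv <- getp(model$params)
    gv <- getp(g)
    set.seed(sum(utf8ToInt(paste(pr, collapse = ""))))
    for (i in sample(length(pv), 3)) {
      m1 <- model; m2 <- model
      p1 <- pv; p1[i] <- p1[i] + eps
      p2 <- pv; p2[i] <- p2[i] - eps
      assignp <- function(m, val) {
        expr <- paste0("m$params",
                       paste0(vapply(pr, function(k)
                         if (grepl("^[0-9]+$", k))
                           paste0("[[", k, "]]")
                         else paste0("$", k), character(1)), collapse = ""))
        eval(parse(text = paste0(expr, " <- val")))
        m
      }
      m1 <- assignp(m1, p1); m2 <- assignp(m2, p2)
      num <- (lossfun(m1) - lossfun(m2)) / (2 * eps)
      expect_equal(num, gv[i], tolerance = 1e-4)
    }
  }
})

test_that("short training improves PCK and selects the best checkpoint", {
  cases <- generate_cases(16, rng_seed = 55, image_size = 64)
  train <- cases[1:10]; val <- cases[11:16]
  cfg <- mshnet_config("PSSAX", n_stacks = 1, base_channels = 8,
                       input_size = 64)
  model <- build_mshnet(cfg, seed = 1)
  reg <- build_regnet(cfg, seed = 2)
  tc <- train_config(epochs = 4, seed = 1)
  fit1 <- train_mshnet(model, reg, train, val, tc)
  fit2 <- train_mshnet(model, reg, train, val, tc)
  expect_equal(fit1$history, fit2$history) # single-thread determinism
  expect_equal(nrow(fit1$history), 4)
  expect_lt(fit1$history$loss[4], fit1$history$loss[1])
  expect_gte(fit1$best_val_pck, fit1$history$val_pck[4])
  expect_error(train_mshnet(model, reg, list(), val, tc), "non-empty")
})
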