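# Thin R wrappers over the compiled convolution / pooling kernels, plus the
# cheap layers (ReLU, nearest-neighbour up/down sampling) and the Adam
# optimizer. Tensors are (H, W, C) numeric arrays for a single image; batches
# are handled by gradient accumulation in the training loop.

# init_scale < 1 is used for output heads so predicted heatmaps start near
# zero (the background value of the targets) instead of random noise.
.conv_layer <- function(kh, kw, cin, cout, init_scale = 1) {
  fan_in <- kh * kw * cin
  list(w = matrix(rnorm(fan_in * cout, sd = init_scale * sqrt(2 / fan_in)),
                  fan_in, cout),
       b = numeric(cout), kh = kh, kw = kw, cin = cin, cout = cout)
}

.conv_f <- function(layer, x) conv2d_fwd(x, layer$w, layer$b, layer$kh,
                                         layer$kw)
.conv_b <- function(layer, x, dy) conv2d_bwd(x, layer$w, dy, layer$kh,
                                             layer$kw)

.relu <- function(x) { x[x < 0] <- 0; x }
.relu_b <- function(z, dy) { dy[z <= 0] <- 0; dy }

.pool_f <- function(x) maxpool2_fwd(x)
.pool_b <- function(idx, dy, H, W) maxpool2_bwd(idx, dy, H, W)

.up2_f <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

.up2_b <- function(dy) {
  d <- dim(dy)
  ro <- seq(1, d[1], by = 2); co <- seq(1, d[2], by = 2)
  dy[ro, co, , drop = FALSE] + dy[ro + 1, co, , drop = FALSE] +
    dy[ro, co + 1, , drop = FALSE] + dy[ro + 1, co + 1, , drop = FALSE]
}

.upn_f <- function(x, times) { for (i in seq_len(times)) x <- .up2_f(x); x }
.upn_b <- function(dy, times) { for (i in seq_len(times)) dy <- .up2_b(dy); dy }

# ---- parameter-tree utilities -------------------------------------------

.is_param <- function(x) is.numeric(x)

.tree_map <- function(f, tree) {
  if (.is_param(tree)) f(tree)
  else lapply(tree, .tree_map, f = f)
}

.tree_map2 <- function(f, a, b) {
  if (.is_param(a)) f(a, b)
  else mapply(.tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
}

.tree_map3 <- function(f, a, b, c) {
  if (.is_param(a)) f(a, b, c)
  else mapply(.tree_map3, a, b, c, MoreArgs = list(f = f), SIMPLIFY = FALSE)
}

.zeros_like <- function(tree) .tree_map(function(p) p * 0, tree)

.tree_add <- function(a, b) .tree_map2(`+`, a, b)
.tree_scale <- function(tree, s) .tree_map(function(p) p * s, tree)

# Only the numeric leaves named w/b are trainable; conv layer metadata
# (kh, kw, ...) is filtered out before the tree is handed to the optimizer.
.trainable <- function(tree) {
  if (!is.list(tree)) return(NULL)
  if (!is.null(tree$w)) return(list(w = tree$w, b = tree$b))
  out <- lapply(tree, .trainable)
  out[!vapply(out, is.null, logical(1))]
}

.merge_trainable <- function(tree, upd) {
  if (!is.list(tree)) return(tree)
  if (!is.null(tree$w)) { tree$w <- upd$w; tree$b <- upd$b; return(tree) }
  for (nm in names(upd)) tree[[nm]] <- .merge_trainable(tree[[nm]], upd[[nm]])
  tree
}

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- .tree_map3(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}
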