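# U-Net builder and smoke-scale training harness for binary mask
# segmentation.

#' Build a U-Net segmentation model
#'
#' Constructs the encoder/decoder segmentation network: a contracting path
#' of repeated double 3x3 convolutions followed by 2x2 max pooling with
#' channel doubling at each level, a mirrored expansive path using 2x2
#' up-convolutions with skip concatenations, and a final 1x1 convolution
#' mapping the `base_channels`-component feature vector to the class map.
#' With the default depth of 4 the layer census is 23 convolutional layers
#' (8 contracting + 2 bottleneck + 12 expansive including the four 2x2
#' up-convolutions + the final 1x1).
#'
#' @param input_dim Input grid `c(H, W)`; must be divisible by
#'   `2^depth`. Default 128 x 128.
#' @param depth Number of pooling levels.
#' @param base_channels Feature channels at the first level (the
#'   final-layer feature vector length). Default 16.
#' @param in_channels Input image channels.
#' @param classes Output channels (1 = binary mask).
#' @param seed Seed for the weight initialization.
#' @return An object of class `unet_model` with `params`, `census` (a data
#'   frame of all convolutional layers), and the architecture fields.
#' @export
build_unet <- function(input_dim = c(128L, 128L), depth = 4L,
                       base_channels = 16L, in_channels = 1L,
                       classes = 1L, seed = 42L) {
  if (any(input_dim %% (2L^depth) != 0L)) {
    stop("input_dim must be divisible by 2^depth for mirrored pooling")
  }
  old_seed <- get0(".Random.seed", globalenv(), mode = "integer",
                   inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  ch <- base_channels * 2L^(seq_len(depth) - 1L)
  cb <- base_channels * 2L^depth
  census <- list()
  note <- function(stage, name, kind, k, cin, cout) {
    census[[length(census) + 1L]] <<- data.frame(
      stage = stage, name = name, kind = kind, kernel = k,
      in_ch = cin, out_ch = cout
    )
  }
  enc <- vector("list", depth)
  for (l in seq_len(depth)) {
    cin <- if (l == 1L) in_channels else ch[l - 1L]
    enc[[l]] <- list(
      conv1 = conv_params(3L, cin, ch[l]),
      conv2 = conv_params(3L, ch[l], ch[l])
    )
    note("encoder", sprintf("enc%d_conv1", l), "conv3x3", 3L, cin, ch[l])
    note("encoder", sprintf("enc%d_conv2", l), "conv3x3", 3L, ch[l], ch[l])
  }
  bott <- list(
    conv1 = conv_params(3L, ch[depth], cb),
    conv2 = conv_params(3L, cb, cb)
  )
  note("bottleneck", "bott_conv1", "conv3x3", 3L, ch[depth], cb)
  note("bottleneck", "bott_conv2", "conv3x3", 3L, cb, cb)
  dec <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    cin <- if (l == depth) cb else ch[l + 1L]
    dec[[l]] <- list(
      up = upconv_params(cin, ch[l]),
      conv1 = conv_params(3L, 2L * ch[l], ch[l]),
      conv2 = conv_params(3L, ch[l], ch[l])
    )
    note("decoder", sprintf("dec%d_up", l), "upconv2x2", 2L, cin, ch[l])
    note("decoder", sprintf("dec%d_conv1", l), "conv3x3", 3L, 2L * ch[l], ch[l])
    note("decoder", sprintf("dec%d_conv2", l), "conv3x3", 3L, ch[l], ch[l])
  }
  final <- conv_params(1L, ch[1L], classes)
  note("final", "final_conv", "conv1x1", 1L, ch[1L], classes)
  structure(
    list(
      params = list(enc = enc, bott = bott, dec = dec, final = final),
      census = do.call(rbind, census),
      input_dim = input_dim, depth = depth,
      base_channels = base_channels, in_channels = in_channels,
      classes = classes
    ),
    class = "unet_model"
  )
}

#' Number of convolutional layers in a model
#' @param model A `unet_model` or `cnn_model`.
#' @return Integer count (up-convolutions and 1x1 convolutions included).
#' @export
n_conv_layers <- function(model) {
  sum(grepl("conv", model$census$kind))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model> input %dx%dx%d, depth %d, base %d channels, %d conv layers\n",
    x$input_dim[1], x$input_dim[2], x$in_channels, x$depth,
    x$base_channels, n_conv_layers(x)
  ))
  invisible(x)
}

conv_relu <- function(x, par) {
  cf <- conv_forward(x, par, pad = "same")
  rf <- relu_forward(cf$out)
  list(out = rf$out, conv = cf$cache, relu = rf$cache)
}

conv_relu_back <- function(dout, par, cache) {
  conv_backward(relu_backward(dout, cache$relu), par, cache$conv)
}

#' Forward pass of a U-Net
#' @param model A `unet_model`.
#' @param x Input array `H x W x in_channels` (a plain matrix is accepted
#'   for single-channel input).
#' @return A list with `prob` (sigmoid output array, same H x W as input)
#'   and `caches` (for the backward pass).
#' @export
unet_forward <- function(model, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  p <- model$params
  depth <- model$depth
  caches <- list(enc = vector("list", depth), dec = vector("list", depth))
  skips <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    c1 <- conv_relu(h, p$enc[[l]]$conv1)
    c2 <- conv_relu(c1$out, p$enc[[l]]$conv2)
    skips[[l]] <- c2$out
    mp <- maxpool_forward(c2$out)
    caches$enc[[l]] <- list(c1 = c1, c2 = c2, mp = mp$cache)
    h <- mp$out
  }
  b1 <- conv_relu(h, p$bott$conv1)
  b2 <- conv_relu(b1$out, p$bott$conv2)
  caches$bott <- list(c1 = b1, c2 = b2)
  h <- b2$out
  for (l in rev(seq_len(depth))) {
    up <- upconv_forward(h, p$dec[[l]]$up)
    cat_in <- array(c(up$out, skips[[l]]),
                    c(dim(up$out)[1:2], dim(up$out)[3] + dim(skips[[l]])[3]))
    c1 <- conv_relu(cat_in, p$dec[[l]]$conv1)
    c2 <- conv_relu(c1$out, p$dec[[l]]$conv2)
    caches$dec[[l]] <- list(up = up$cache, n_up = dim(up$out)[3],
                            c1 = c1, c2 = c2)
    h <- c2$out
  }
  fin <- conv_forward(h, p$final, pad = "same")
  caches$final <- fin$cache
  list(prob = sigmoid(fin$out), caches = caches)
}

unet_backward <- function(model, caches, dlogits) {
  p <- model$params
  depth <- model$depth
  g <- list(enc = vector("list", depth), dec = vector("list", depth))
  fb <- conv_backward(dlogits, p$final, caches$final)
  g$final <- fb[c("dW", "db")]
  dh <- fb$dx
  dskip <- vector("list", depth)
  for (l in seq_len(depth)) { # decoder levels, deepest applied last in fwd
    cc <- caches$dec[[l]]
    b2 <- conv_relu_back(dh, p$dec[[l]]$conv2, cc$c2)
    b1 <- conv_relu_back(b2$dx, p$dec[[l]]$conv1, cc$c1)
    n_up <- cc$n_up
    dup_out <- b1$dx[, , seq_len(n_up), drop = FALSE]
    dskip[[l]] <- b1$dx[, , -seq_len(n_up), drop = FALSE]
    ub <- upconv_backward(dup_out, p$dec[[l]]$up, cc$up)
    g$dec[[l]] <- list(up = ub[c("dW", "db")], conv1 = b1[c("dW", "db")],
                       conv2 = b2[c("dW", "db")])
    dh <- ub$dx
  }
  b2 <- conv_relu_back(dh, p$bott$conv2, caches$bott$c2)
  b1 <- conv_relu_back(b2$dx, p$bott$conv1, caches$bott$c1)
  g$bott <- list(conv1 = b1[c("dW", "db")], conv2 = b2[c("dW", "db")])
  dh <- b1$dx
  for (l in rev(seq_len(depth))) {
    cc <- caches$enc[[l]]
    dpool <- maxpool_backward(dh, cc$mp)
    dpool <- dpool + dskip[[l]]
    b2 <- conv_relu_back(dpool, p$enc[[l]]$conv2, cc$c2)
    b1 <- conv_relu_back(b2$dx, p$enc[[l]]$conv1, cc$c1)
    g$enc[[l]] <- list(conv1 = b1[c("dW", "db")], conv2 = b2[c("dW", "db")])
    dh <- b1$dx
  }
  g
}

unet_apply_grads <- function(model, grads, lr) {
  p <- model$params
  for (l in seq_len(model$depth)) {
    p$enc[[l]]$conv1 <- sgd_update(p$enc[[l]]$conv1, grads$enc[[l]]$conv1, lr)
    p$enc[[l]]$conv2 <- sgd_update(p$enc[[l]]$conv2, grads$enc[[l]]$conv2, lr)
    p$dec[[l]]$up <- sgd_update(p$dec[[l]]$up, grads$dec[[l]]$up, lr)
    p$dec[[l]]$conv1 <- sgd_update(p$dec[[l]]$conv1, grads$dec[[l]]$conv1, lr)
    p$dec[[l]]$conv2 <- sgd_update(p$dec[[l]]$conv2, grads$dec[[l]]$conv2, lr)
  }
  p$bott$conv1 <- sgd_update(p$bott$conv1, grads$bott$conv1, lr)
  p$bott$conv2 <- sgd_update(p$bott$conv2, grads$bott$conv2, lr)
  p$final <- sgd_update(p$final, grads$final, lr)
  model$params <- p
  model
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  merge2 <- function(u, v) {
    if (is.list(u)) mapply(merge2, u, v, SIMPLIFY = FALSE) else u + v
  }
  merge2(a, b)
}

#' One SGD training step of a U-Net on a small batch
#'
#' Accumulates binary cross-entropy gradients over the batch and applies a
#' single SGD update. The mean pre-update loss is returned so a
#' smoke test can verify that the step reduces it.
#'
#' @param model A `unet_model`.
#' @param xs List of input arrays (or matrices).
#' @param ys List of 0/1 target masks of the model's output size.
#' @param lr Learning rate.
#' @return A list with the updated `model` and the pre-update `loss`.
#' @export
unet_train_step <- function(model, xs, ys, lr = 0.5) {
  total <- NULL
  loss <- 0
  for (i in seq_along(xs)) {
    fw <- unet_forward(model, xs[[i]])
    y <- array(as.numeric(ys[[i]]), dim(fw$prob))
    loss <- loss + bce_loss(fw$prob, y)
    dlogits <- array(bce_grad_logits(fw$prob, y), dim(fw$prob))
    total <- add_grads(total, unet_backward(model, fw$caches, dlogits))
  }
  list(
    model = unet_apply_grads(model, total, lr / length(xs)),
    loss = loss / length(xs)
  )
}

#' Train a U-Net segmenter (smoke scale)
#'
#' The training recipe of the segmentation models: binary cross-entropy
#' loss, SGD, and random width/height shift augmentation with factor 0.2.
#' Designed for small problem sizes; the defaults for `epochs` and
#' `batch_size` follow the recipe (100 epochs, batch 8) but tests use far
#' smaller values.
#'
#' @param model A `unet_model`.
#' @param xs,ys Lists of inputs and target masks.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param augment Apply random shift augmentation.
#' @param shift_frac Maximum shift fraction.
#' @return A list with the trained `model` and the per-epoch `loss` trace.
#' @export
train_unet <- function(model, xs, ys, epochs = 100L, lr = 0.5,
                       batch_size = 8L, augment = TRUE, shift_frac = 0.2) {
  losses <- numeric(epochs)
  n <- length(xs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, n)]
      bx <- xs[ix]
      by <- ys[ix]
      if (augment) {
        for (q in seq_along(bx)) {
          im <- bx[[q]]
          if (is.matrix(im)) im <- array(im, c(dim(im), 1L))
          tg <- array(as.numeric(by[[q]]), c(dim(by[[q]])[1:2], 1L))
          both <- array(c(im, tg), c(dim(im)[1:2], dim(im)[3] + 1L))
          both <- augment_shift(both, shift_frac)
          bx[[q]] <- both[, , seq_len(dim(im)[3]), drop = FALSE]
          by[[q]] <- both[, , dim(im)[3] + 1L]
        }
      }
      stp <- unet_train_step(model, bx, by, lr)
      model <- stp$model
      ep_loss <- ep_loss + stp$loss
      nb <- nb + 1L
    }
    losses[ep] <- ep_loss / nb
  }
  list(model = model, loss = losses)
}

#' Use a trained U-Net as a segmentation backend
#'
#' Wraps a model into the `segment_mask()` backend contract: the scored
#' trace is rasterized to the model's input grid, segmented, and the
#' probability map thresholded.
#'
#' @param model A `unet_model`.
#' @param threshold Probability cut for a lit mask pixel.
#' @return A `function(trace, role, dim)` backend. The same model is used
#'   for every role; train one model per role and dispatch externally for
#'   multi-role scoring.
#' @export
unet_segmenter <- function(model, threshold = 0.5) {
  function(trace, role, dim = c(128L, 128L)) {
    x <- rasterize_trace(trace, extract_strokes(trace),
                         dim = model$input_dim)
    fw <- unet_forward(model, x * 1.0)
    m <- (fw$prob[, , 1] >= threshold) * 1L
    if (identical(dim(m), as.integer(dim))) return(m)
    # nearest-neighbour upscale to the requested grid
    ri <- pmin(pmax(ceiling(seq_len(dim[1]) / dim[1] * nrow(m)), 1L), nrow(m))
    ci <- pmin(pmax(ceiling(seq_len(dim[2]) / dim[2] * ncol(m)), 1L), ncol(m))
    m[ri, ci, drop = FALSE]
  }
}
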