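# CNN builder, training harness, and classifier backend for 28x28 digit
# crops.

#' Build the digit-classification CNN
#'
#' The fixed architecture for 28 x 28 digit images: a first convolution of
#' 32 kernels of size 5 x 5, a 2 x 2 non-overlapping max pool, a second
#' convolution of 64 kernels of size 5 x 5 x 32, another 2 x 2 max pool,
#' and two fully connected layers of 1024 and 10 neurons. Convolutions use
#' unit stride with no padding and ReLU outputs, so the feature maps run
#' 28 -> 24 -> 12 -> 8 -> 4 and flatten to 1024.
#'
#' @param input_dim Input size; must be `c(28, 28)` — the architecture's
#'   shape contract.
#' @param seed Seed for weight initialization.
#' @return An object of class `cnn_model` with `params` and `census`.
#' @export
build_cnn <- function(input_dim = c(28L, 28L), seed = 42L) {
  if (!identical(as.integer(input_dim), c(28L, 28L))) {
    stop("input_dim must be 28 x 28")
  }
  old_seed <- get0(".Random.seed", globalenv(), mode = "integer",
                   inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  census <- data.frame(
    name = c("C1", "D2", "C3", "D4", "F5", "F6"),
    kind = c("conv5x5", "maxpool2x2", "conv5x5", "maxpool2x2",
             "dense", "dense"),
    kernel = c(5L, 2L, 5L, 2L, NA, NA),
    in_ch = c(1L, 32L, 32L, 64L, 1024L, 1024L),
    out_ch = c(32L, 32L, 64L, 64L, 1024L, 10L)
  )
  structure(
    list(
      params = list(
        conv1 = conv_params(5L, 1L, 32L),
        conv2 = conv_params(5L, 32L, 64L),
        fc1 = dense_params(1024L, 1024L),
        fc2 = dense_params(1024L, 10L)
      ),
      census = census, input_dim = c(28L, 28L)
    ),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> 28x28 -> 32@5x5 -> pool -> 64@5x5x32 -> pool -> 1024 -> 10\n")
  invisible(x)
}

cnn_forward <- function(model, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  p <- model$params
  c1 <- conv_forward(x, p$conv1, pad = "valid")
  r1 <- relu_forward(c1$out)
  m1 <- maxpool_forward(r1$out)
  c2 <- conv_forward(m1$out, p$conv2, pad = "valid")
  r2 <- relu_forward(c2$out)
  m2 <- maxpool_forward(r2$out)
  v <- as.vector(m2$out)
  f1 <- dense_forward(v, p$fc1)
  rf <- relu_forward(f1$out)
  f2 <- dense_forward(rf$out, p$fc2)
  list(
    logits = f2$out,
    caches = list(c1 = c1$cache, r1 = r1$cache, m1 = m1$cache,
                  c2 = c2$cache, r2 = r2$cache, m2 = m2$cache,
                  f1 = f1$cache, rf = rf$cache, f2 = f2$cache,
                  flat_dim = dim(m2$out))
  )
}

cnn_backward <- function(model, caches, dlogits) {
  p <- model$params
  b2 <- dense_backward(dlogits, p$fc2, caches$f2)
  dr <- relu_backward(b2$dx, caches$rf)
  b1 <- dense_backward(dr, p$fc1, caches$f1)
  dm2 <- array(b1$dx, caches$flat_dim)
  dc2 <- maxpool_backward(dm2, caches$m2)
  cb2 <- conv_backward(relu_backward(dc2, caches$r2), p$conv2, caches$c2)
  dc1 <- maxpool_backward(cb2$dx, caches$m1)
  cb1 <- conv_backward(relu_backward(dc1, caches$r1), p$conv1, caches$c1)
  list(
    conv1 = cb1[c("dW", "db")], conv2 = cb2[c("dW", "db")],
    fc1 = b1[c("dW", "db")], fc2 = b2[c("dW", "db")]
  )
}

#' One SGD training step of the CNN on a small batch
#'
#' Cross-entropy loss over the batch and one SGD update; the pre-update
#' mean loss is returned.
#'
#' @param model A `cnn_model`.
#' @param xs List of 28 x 28 matrices (ink 1, background 0).
#' @param labels Integer labels 0..9, one per input.
#' @param lr Learning rate.
#' @return A list with the updated `model` and the pre-update `loss`.
#' @export
cnn_train_step <- function(model, xs, labels, lr = 0.05) {
  total <- NULL
  loss <- 0
  for (i in seq_along(xs)) {
    fw <- cnn_forward(model, xs[[i]] * 1.0)
    prob <- softmax(fw$logits)
    k <- labels[i] + 1L
    loss <- loss - log(max(prob[k], 1e-12))
    dlogits <- prob
    dlogits[k] <- dlogits[k] - 1
    total <- add_grads(total, cnn_backward(model, fw$caches, dlogits))
  }
  lr <- lr / length(xs)
  p <- model$params
  p$conv1 <- sgd_update(p$conv1, total$conv1, lr)
  p$conv2 <- sgd_update(p$conv2, total$conv2, lr)
  p$fc1 <- sgd_update(p$fc1, total$fc1, lr)
  p$fc2 <- sgd_update(p$fc2, total$fc2, lr)
  model$params <- p
  list(model = model, loss = loss / length(xs))
}

#' Train the digit CNN (smoke scale)
#'
#' @param model A `cnn_model`.
#' @param xs List of 28 x 28 matrices.
#' @param labels Integer labels 0..9.
#' @param epochs,lr,batch_size Training configuration.
#' @return A list with the trained `model` and the per-epoch `loss` trace.
#' @export
train_cnn <- function(model, xs, labels, epochs = 10L, lr = 0.05,
                      batch_size = 8L) {
  losses <- numeric(epochs)
  n <- length(xs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, n)]
      stp <- cnn_train_step(model, xs[ix], labels[ix], lr)
      model <- stp$model
      ep_loss <- ep_loss + stp$loss
      nb <- nb + 1L
    }
    losses[ep] <- ep_loss / nb
  }
  list(model = model, loss = losses)
}

#' Use a trained CNN as a digit-classifier backend
#'
#' @param model A `cnn_model`.
#' @return A `function(crop, box)` returning the argmax label 0..9,
#'   suitable for [classify_digits()].
#' @export
cnn_classifier <- function(model) {
  function(crop, box) {
    fw <- cnn_forward(model, crop * 1.0)
    which.max(fw$logits) - 1L
  }
}
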