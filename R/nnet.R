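# A compact neural-network engine in base R: im2col convolutions, 2x2 max
# pooling, 2x2 transpose convolutions, dense layers, and SGD, on
# single-sample H x W x C arrays. Sized for architecture verification and
# smoke-scale training of the segmentation and digit-classification
# builders.

nn_init <- function(fan_in, n, sd_scale = 1) {
  stats::rnorm(n, 0, sd_scale * sqrt(2 / fan_in))
}

conv_params <- function(k, cin, cout) {
  list(
    W = matrix(nn_init(k * k * cin, k * k * cin * cout), k * k * cin, cout),
    b = numeric(cout), k = k
  )
}

upconv_params <- function(cin, cout) {
  list(
    W = array(nn_init(cin, 4 * cin * cout), c(2, 2, cin, cout)),
    b = numeric(cout)
  )
}

dense_params <- function(nin, nout) {
  list(W = matrix(nn_init(nin, nin * nout), nin, nout), b = numeric(nout))
}

pad_array <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  xp
}

# Column matrix (Ho*Wo) x (k*k*C); column order (di fastest, then dj,
# then channel) — conv weights use the same order.
im2col <- function(xp, k, Ho, Wo) {
  C <- dim(xp)[3]
  cols <- matrix(0, Ho * Wo, k * k * C)
  col <- 0L
  for (ch in seq_len(C)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        cols[, col] <- as.vector(xp[di:(di + Ho - 1L), dj:(dj + Wo - 1L), ch])
      }
    }
  }
  cols
}

col2im <- function(dcols, k, Hp, Wp, C, Ho, Wo) {
  dxp <- array(0, c(Hp, Wp, C))
  col <- 0L
  for (ch in seq_len(C)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        dxp[di:(di + Ho - 1L), dj:(dj + Wo - 1L), ch] <-
          dxp[di:(di + Ho - 1L), dj:(dj + Wo - 1L), ch] +
          matrix(dcols[, col], Ho, Wo)
      }
    }
  }
  dxp
}

conv_forward <- function(x, par, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  k <- par$k
  p <- if (pad == "same") (k - 1L) %/% 2L else 0L
  d <- dim(x)
  xp <- pad_array(x, p)
  Ho <- d[1] + 2 * p - k + 1L
  Wo <- d[2] + 2 * p - k + 1L
  cols <- im2col(xp, k, Ho, Wo)
  out <- cols %*% par$W
  out <- sweep(out, 2, par$b, `+`)
  list(
    out = array(out, c(Ho, Wo, ncol(par$W))),
    cache = list(cols = cols, dims = d, p = p, k = k, Ho = Ho, Wo = Wo)
  )
}

conv_backward <- function(dout, par, cache) {
  cout <- ncol(par$W)
  dm <- matrix(dout, cache$Ho * cache$Wo, cout)
  dW <- crossprod(cache$cols, dm)
  db <- colSums(dm)
  dcols <- dm %*% t(par$W)
  d <- cache$dims
  dxp <- col2im(dcols, cache$k, d[1] + 2 * cache$p, d[2] + 2 * cache$p,
                d[3], cache$Ho, cache$Wo)
  p <- cache$p
  dx <- if (p > 0) dxp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , drop = FALSE] else dxp
  list(dx = array(dx, d), dW = dW, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

maxpool_forward <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  s <- list(
    x[i1, j1, , drop = FALSE], x[i2, j1, , drop = FALSE],
    x[i1, j2, , drop = FALSE], x[i2, j2, , drop = FALSE]
  )
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(m))
  masks <- vector("list", 4L)
  for (q in 1:4) {
    masks[[q]] <- (s[[q]] == m) & !taken
    taken <- taken | masks[[q]]
  }
  list(out = m, cache = list(masks = masks, dims = d))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dx[i1, j1, ] <- dout * cache$masks[[1]]
  dx[i2, j1, ] <- dout * cache$masks[[2]]
  dx[i1, j2, ] <- dout * cache$masks[[3]]
  dx[i2, j2, ] <- dout * cache$masks[[4]]
  dx
}

upconv_forward <- function(x, par) {
  d <- dim(x)
  cout <- dim(par$W)[4]
  xm <- matrix(x, d[1] * d[2], d[3])
  out <- array(0, c(2 * d[1], 2 * d[2], cout))
  for (di in 1:2) {
    for (dj in 1:2) {
      o <- xm %*% matrix(par$W[di, dj, , ], d[3], cout)
      out[seq(di, 2 * d[1], 2L), seq(dj, 2 * d[2], 2L), ] <-
        array(o, c(d[1], d[2], cout))
    }
  }
  out <- sweep(out, 3, par$b, `+`)
  list(out = out, cache = list(xm = xm, dims = d))
}

upconv_backward <- function(dout, par, cache) {
  d <- cache$dims
  cout <- dim(par$W)[4]
  dW <- array(0, dim(par$W))
  dxm <- matrix(0, d[1] * d[2], d[3])
  for (di in 1:2) {
    for (dj in 1:2) {
      dsub <- matrix(dout[seq(di, 2 * d[1], 2L), seq(dj, 2 * d[2], 2L), ],
                     d[1] * d[2], cout)
      dW[di, dj, , ] <- crossprod(cache$xm, dsub)
      dxm <- dxm + dsub %*% t(matrix(par$W[di, dj, , ], d[3], cout))
    }
  }
  db <- apply(dout, 3, sum)
  list(dx = array(dxm, d), dW = dW, db = db)
}

dense_forward <- function(v, par) {
  list(out = as.vector(v %*% par$W) + par$b, cache = v)
}

dense_backward <- function(dout, par, cache) {
  list(
    dx = as.vector(par$W %*% dout),
    dW = outer(as.vector(cache), dout), db = dout
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Mean binary cross entropy and its gradient w.r.t. the pre-sigmoid logits.
bce_loss <- function(prob, y) {
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

bce_grad_logits <- function(prob, y) (prob - y) / length(y)

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

sgd_update <- function(par, grad, lr) {
  par$W <- par$W - lr * grad$dW
  par$b <- par$b - lr * grad$db
  par
}

# Random shift augmentation (zero fill), the width/height-shift scheme
# used by the segmentation training recipe.
augment_shift <- function(img, max_frac = 0.2) {
  d <- dim(img)
  sh <- round(stats::runif(2, -max_frac, max_frac) * d[1:2])
  out <- array(0, d)
  src_i <- seq_len(d[1]) - sh[1]
  src_j <- seq_len(d[2]) - sh[2]
  ok_i <- src_i >= 1 & src_i <= d[1]
  ok_j <- src_j >= 1 & src_j <= d[2]
  out[which(ok_i), which(ok_j), ] <- img[src_i[ok_i], src_j[ok_j], ,
                                         drop = FALSE]
  out
}
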