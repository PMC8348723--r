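# Independent oracles and small trace builders used across the suite.

# Build touch records for one stroke along the given xy matrix.
stroke_records <- function(xy, t0 = 0, period = 0.02) {
  n <- nrow(xy)
  e <- c(-1L, rep(0L, max(0L, n - 2L)), 1L)[seq_len(n)]
  if (n == 1L) e <- 1L # degenerate; callers avoid this
  data.frame(t = t0 + period * (seq_len(n) - 1), x = xy[, 1], y = xy[, 2],
             e = e)
}

# A trace from a list of per-stroke xy matrices.
make_trace <- function(strokes, canvas_w = 2400, canvas_h = 1200,
                       pause = 0.3) {
  t0 <- 0
  recs <- list()
  for (xy in strokes) {
    r <- stroke_records(xy, t0 = t0)
    recs[[length(recs) + 1L]] <- r
    t0 <- max(r$t) + pause
  }
  parse_trace(do.call(rbind, recs), canvas_w, canvas_h)
}

circle_points <- function(cx, cy, r, n = 360, from = 0, to = 2 * pi) {
  a <- seq(from, to, length.out = n)
  cbind(cx + r * cos(a), cy + r * sin(a))
}

# Closed-form circumcircle through three points (independent of the
# least-squares fit).
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# Brute-force flood fill (8-connected) over a 0/1 matrix; returns one row
# per component with its bounding extremes in the same pixel convention as
# find_components (0-based column/row indices).
flood_fill_boxes <- function(img) {
  H <- nrow(img); W <- ncol(img)
  seen <- matrix(FALSE, H, W)
  out <- list()
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      if (img[i, j] == 1L && !seen[i, j]) {
        queue <- list(c(i, j))
        seen[i, j] <- TRUE
        ys <- integer(0); xs <- integer(0)
        while (length(queue) > 0L) {
          p <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          ys <- c(ys, p[1]); xs <- c(xs, p[2])
          for (dy in -1:1) {
            for (dx in -1:1) {
              yy <- p[1] + dy; xx <- p[2] + dx
              if (yy >= 1L && yy <= H && xx >= 1L && xx <= W &&
                  img[yy, xx] == 1L && !seen[yy, xx]) {
                seen[yy, xx] <- TRUE
                queue[[length(queue) + 1L]] <- c(yy, xx)
              }
            }
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          xmin = min(xs) - 1, xmax = max(xs) - 1,
          ymin = min(ys) - 1, ymax = max(ys) - 1,
          npix = length(xs)
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(xmin = numeric(0), xmax = numeric(0),
                      ymin = numeric(0), ymax = numeric(0),
                      npix = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$xmin, df$ymin, df$xmax, df$ymax), , drop = FALSE]
}

# Independent Ratcliff-Obershelp recursion on character strings: find the
# longest common substring (earliest start in a, then in b) by explicit
# enumeration and recurse on the flanks.
ro_oracle <- function(a, b) {
  match_count <- function(a, b) {
    na <- length(a); nb <- length(b)
    if (na == 0L || nb == 0L) return(0L)
    best <- 0L; bi <- 0L; bj <- 0L
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        k <- 0L
        while (i + k <= na && j + k <= nb && a[i + k] == b[j + k]) k <- k + 1L
        if (k > best) { best <- k; bi <- i; bj <- j }
      }
    }
    if (best == 0L) return(0L)
    best +
      match_count(a[seq_len(bi - 1L)], b[seq_len(bj - 1L)]) +
      match_count(
        if (bi + best <= na) a[(bi + best):na] else character(0),
        if (bj + best <= nb) b[(bj + best):nb] else character(0)
      )
  }
  200 * match_count(as.character(a), as.character(b)) /
    (length(a) + length(b))
}

# Default oracle-backed scoring of a synthetic clock.
score_synth <- function(clock, ...) {
  score_clock(clock$trace, oracle_segmenter(clock$truth),
              oracle_classifier(clock$truth), ...)
}
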