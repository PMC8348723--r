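# Digit cropping, classification, and drawing-order similarity.

#' Build the contour-removed binary drawing
#'
#' Redraws the clock image from the sensor data after excluding the contour
#' (and, by default in the pipeline, the hand strokes), binarized with black
#' background (0) and white ink (1). Digit crops are cut from this image.
#'
#' @param trace A `sensor_trace`.
#' @param exclude_runs Runs to leave out (the contour run, optionally hand
#'   runs): anything accepted by [rasterize_trace()]'s `runs` argument.
#'   Runs must be disjoint.
#' @param dim Raster size `c(H, W)`; defaults to the canvas resolution.
#' @return A 0/1 integer matrix (rows index y bottom-up).
#' @export
modified_image <- function(trace, exclude_runs = NULL, dim = NULL) {
  if (is.null(dim)) dim <- c(trace$canvas_h, trace$canvas_w)
  excl <- as_run_list(exclude_runs)
  if (length(excl) > 1L) {
    iv <- do.call(rbind, excl)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) stop("excluded runs overlap")
  }
  strokes <- extract_strokes(trace)
  excluded_starts <- vapply(excl, function(r) r[[1]], numeric(1))
  keep <- !(strokes$start %in% excluded_starts)
  rasterize_trace(trace, strokes[keep, , drop = FALSE], dim = dim)
}

#' Find white connected components and their boxes
#'
#' Locates the external boundaries ("suburb contours") of 8-connected white
#' components on the black background and returns one box per component,
#' with start/end time stamps taken from the trace samples whose rasterized
#' pixel falls inside the box. Components are sorted by `ti` ascending
#' (ties: `xmin` ascending), the order the digits were drawn in.
#'
#' @param img 0/1 matrix from [modified_image()].
#' @param trace Optional `sensor_trace` used to assign time stamps.
#' @param include_runs Runs of `trace` whose samples may claim a component
#'   (defaults to all strokes); pass the non-excluded strokes so contour or
#'   hand samples brushing past a box do not distort its time span.
#' @param min_extent Components whose box width and height are both below
#'   this (in pixels of `img`) are discarded as specks (e.g. a drawn center
#'   dot); set to 0 to keep everything.
#' @return A data frame with one row per component: `xmin`, `xmax`, `ymin`,
#'   `ymax` (pixel coordinates in the raster's frame), `npix`, `ti`, `tf`.
#' @export
find_components <- function(img, trace = NULL, include_runs = NULL,
                            min_extent = 0) {
  lit <- which(img == 1L)
  empty <- data.frame(
    xmin = numeric(0), xmax = numeric(0), ymin = numeric(0),
    ymax = numeric(0), npix = integer(0), ti = numeric(0), tf = numeric(0)
  )
  if (length(lit) == 0L) return(empty)
  H <- nrow(img)
  iy <- (lit - 1L) %% H + 1L
  ix <- (lit - 1L) %/% H + 1L
  comp <- label_components(lit, iy, ix, H, ncol(img))
  xmin <- tapply(ix, comp, min) - 1; xmax <- tapply(ix, comp, max) - 1
  ymin <- tapply(iy, comp, min) - 1; ymax <- tapply(iy, comp, max) - 1
  npix <- as.integer(tapply(comp, comp, length))
  boxes <- data.frame(
    xmin = as.numeric(xmin), xmax = as.numeric(xmax),
    ymin = as.numeric(ymin), ymax = as.numeric(ymax),
    npix = npix, ti = NA_real_, tf = NA_real_
  )
  if (min_extent > 0) {
    boxes <- boxes[(boxes$xmax - boxes$xmin) >= min_extent |
                     (boxes$ymax - boxes$ymin) >= min_extent, , drop = FALSE]
  }
  if (nrow(boxes) == 0L) return(empty)
  if (!is.null(trace)) {
    runs <- if (is.null(include_runs)) extract_strokes(trace) else include_runs
    runs <- as_run_list(runs)
    idx <- unlist(lapply(runs, function(r) r[[1]]:r[[2]]))
    s <- trace$samples[idx, ]
    g <- to_grid(s$x, s$y, trace$canvas_w, trace$canvas_h, dim(img))
    px <- g[, "ix"] - 1L; py <- g[, "iy"] - 1L
    for (i in seq_len(nrow(boxes))) {
      inside <- px >= boxes$xmin[i] & px <= boxes$xmax[i] &
        py >= boxes$ymin[i] & py <= boxes$ymax[i]
      if (any(inside)) {
        boxes$ti[i] <- min(s$t[inside])
        boxes$tf[i] <- max(s$t[inside])
      }
    }
  }
  ord <- order(boxes$ti, boxes$xmin, na.last = TRUE)
  boxes <- boxes[ord, , drop = FALSE]
  rownames(boxes) <- NULL
  boxes
}

# 8-connected labelling of lit pixels via the adjacency graph of their
# coordinates; igraph does the union-find.
label_components <- function(lit, iy, ix, H, W) {
  key <- (ix - 1L) * (H + 2L) + iy # collision-free over the padded grid
  n <- length(lit)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    nk <- (ix + s[2] - 1L) * (H + 2L) + (iy + s[1])
    j <- match(nk, key)
    ok <- !is.na(j)
    from <- c(from, which(ok)); to <- c(to, j[ok])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Crop, resize, and classify digit components
#'
#' Each component box is cropped from the binary image, padded to a square,
#' resized to `size` x `size` (ink = 1 on background 0, the MNIST polarity),
#' and passed to the classifier. Detection centers are the box midpoints.
#'
#' @param img 0/1 matrix the boxes refer to.
#' @param boxes Data frame from [find_components()].
#' @param classifier A `function(crop, box)` returning an integer label in
#'   0..9, e.g. from [oracle_classifier()] or [cnn_classifier()].
#' @param size Side length of the classifier input; default 28.
#' @return A data frame: `j`, `label`, the box columns, `xm`, `ym` (Eq.
#'   midpoint centers), `ti`, `tf`.
#' @export
classify_digits <- function(img, boxes, classifier, size = 28L) {
  n <- nrow(boxes)
  labels <- integer(n)
  for (i in seq_len(n)) {
    crop <- crop_box(img, boxes[i, ])
    labels[i] <- as.integer(classifier(resize_square(crop, size), boxes[i, ]))
  }
  out <- cbind(
    data.frame(j = seq_len(n), label = labels),
    boxes[, c("xmin", "xmax", "ymin", "ymax")],
    data.frame(
      xm = (boxes$xmin + boxes$xmax) / 2,
      ym = (boxes$ymin + boxes$ymax) / 2,
      ti = boxes$ti, tf = boxes$tf
    )
  )
  rownames(out) <- NULL
  out
}

crop_box <- function(img, box) {
  if (box$xmax < box$xmin || box$ymax < box$ymin) stop("empty box")
  img[(box$ymin + 1L):(box$ymax + 1L), (box$xmin + 1L):(box$xmax + 1L),
      drop = FALSE]
}

# Pad to square (centered) then nearest-neighbour resize.
resize_square <- function(m, size) {
  h <- nrow(m); w <- ncol(m)
  side <- max(h, w)
  sq <- matrix(0L, side, side)
  oy <- (side - h) %/% 2L; ox <- (side - w) %/% 2L
  sq[(oy + 1L):(oy + h), (ox + 1L):(ox + w)] <- m
  ri <- pmin(pmax(ceiling(seq_len(size) / size * side), 1L), side)
  sq[ri, ri, drop = FALSE]
}

#' Oracle digit classifier
#'
#' Returns a classifier closure that looks a component's time span up in the
#' generator's ground truth and returns the character value of the stroke
#' that drew it — a perfect classifier for testing the pipeline around it.
#'
#' @param truth A `clock_truth` from [generate_clock()].
#' @return A `function(crop, box)` returning an integer 0..9 (or `NA` for a
#'   component no glyph stroke explains).
#' @export
oracle_classifier <- function(truth) {
  r <- truth$roles
  glyphs <- r[!is.na(r$char), ]
  function(crop, box) {
    if (is.null(box$ti) || is.na(box$ti)) return(NA_integer_)
    hit <- which(glyphs$t0 <= box$ti + 1e-9 & glyphs$t1 >= box$ti - 1e-9)
    if (length(hit) == 0L) {
      hit <- which.min(abs((glyphs$t0 + glyphs$t1) / 2 - box$ti))
    }
    as.integer(glyphs$char[hit[1]])
  }
}

#' Reference digit-character drawing orders
#'
#' The three habitual orders a complete dial is written in, as decimal
#' character sequences (so "10" contributes "1" then "0"): ascending 1..12;
#' 12 first then 1..11; the quadrant anchors 12, 3, 6, 9 first, then the
#' remaining numbers ascending.
#'
#' @return A named list of character vectors `S1`, `S2`, `S3`.
#' @export
reference_sequences <- function() {
  chars <- function(nums) unlist(strsplit(as.character(nums), ""))
  list(
    S1 = chars(1:12),
    S2 = chars(c(12, 1:11)),
    S3 = chars(c(12, 3, 6, 9, 1, 2, 4, 5, 7, 8, 10, 11))
  )
}

#' Ratcliff-Obershelp sequence similarity
#'
#' Similarity of two symbol sequences as a percentage: recursively find the
#' longest common contiguous block (earliest in `a`, then earliest in `b`,
#' on ties), match it, and recurse on both flanks; with `M` total matched
#' elements the ratio is `200 M / (|a| + |b|)`.
#'
#' @param a,b Nonempty character (or coercible) vectors.
#' @return Percentage in `[0, 100]`.
#' @export
sequence_ratio <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty sequence")
  m <- ro_match_count(a, b, 1L, length(a), 1L, length(b))
  200 * m / (length(a) + length(b))
}

# Longest common block within a[alo..ahi] x b[blo..bhi] by dynamic
# programming over suffix run lengths, then recursion on the flanks.
ro_match_count <- function(a, b, alo, ahi, blo, bhi) {
  if (alo > ahi || blo > bhi) return(0L)
  na <- ahi - alo + 1L; nb <- bhi - blo + 1L
  best_len <- 0L; best_i <- 0L; best_j <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    ai <- a[alo + i - 1L]
    hit <- which(b[blo:bhi] == ai)
    for (j in hit) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best_len) {
        best_len <- cur[j]
        best_i <- i - cur[j] + 1L
        best_j <- j - cur[j] + 1L
      }
    }
    prev <- cur
  }
  if (best_len == 0L) return(0L)
  i0 <- alo + best_i - 1L; j0 <- blo + best_j - 1L
  best_len +
    ro_match_count(a, b, alo, i0 - 1L, blo, j0 - 1L) +
    ro_match_count(a, b, i0 + best_len, ahi, j0 + best_len, bhi)
}

#' Maximum order similarity against the reference sequences
#'
#' `Rseq`: the best [sequence_ratio()] of the drawn digit-character sequence
#' against the reference orders.
#'
#' @param sn Drawn character sequence (detections sorted by start time).
#' @param refs Reference sequences; default [reference_sequences()].
#' @return Percentage in `[0, 100]`; `NA` if `sn` is empty.
#' @export
rseq_max <- function(sn, refs = reference_sequences()) {
  if (length(sn) == 0L) return(NA_real_)
  max(vapply(refs, function(s) sequence_ratio(sn, s), numeric(1)))
}

#' Merge character crops into clock numbers and measure anchor distances
#'
#' The paper-style position statistic needs one distance per clock number,
#' while two-character numbers (10, 11, 12) crop per character. Temporally
#' consecutive crop pairs whose labels concatenate to 10, 11 or 12 and whose
#' boxes are horizontally adjacent are merged into one number box; each
#' number box is then measured against the anchor of its value (numbers
#' outside 1..12 fall back to the nearest anchor).
#'
#' @param dets Data frame from [classify_digits()].
#' @param anchors Matrix from [digit_anchors()].
#' @param gap_factor Maximum horizontal gap between merged character boxes,
#'   as a multiple of the mean character-box width.
#' @return A data frame with one row per number: `value`, `xm`, `ym`,
#'   `dcn` (distance to its anchor in pixels).
#' @export
number_distances <- function(dets, anchors, gap_factor = 1.5) {
  n <- nrow(dets)
  if (n == 0L) {
    return(data.frame(value = integer(0), xm = numeric(0), ym = numeric(0),
                      dcn = numeric(0)))
  }
  mean_w <- mean(dets$xmax - dets$xmin)
  group <- seq_len(n)
  i <- 1L
  while (i < n) {
    v <- dets$label[i] * 10L + dets$label[i + 1L]
    hgap <- dets$xmin[i + 1L] - dets$xmax[i]
    vover <- min(dets$ymax[i], dets$ymax[i + 1L]) -
      max(dets$ymin[i], dets$ymin[i + 1L])
    if (!is.na(v) && v %in% 10:12 && is.finite(hgap) &&
        hgap <= gap_factor * mean_w && hgap > -mean_w && vover > 0 &&
        group[i] == i) {
      group[i + 1L] <- i
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  out <- do.call(rbind, lapply(unique(group), function(g) {
    rows <- dets[group == g, , drop = FALSE]
    value <- if (nrow(rows) == 2L) rows$label[1] * 10L + rows$label[2] else rows$label[1]
    data.frame(
      value = value,
      xm = (min(rows$xmin) + max(rows$xmax)) / 2,
      ym = (min(rows$ymin) + max(rows$ymax)) / 2
    )
  }))
  out$dcn <- vapply(seq_len(nrow(out)), function(i) {
    v <- out$value[i]
    if (!is.na(v) && v >= 1 && v <= 12) {
      point_distance(c(out$xm[i], out$ym[i]), anchors[as.character(v), ])
    } else {
      min(sqrt((anchors[, "x"] - out$xm[i])^2 + (anchors[, "y"] - out$ym[i])^2))
    }
  }, numeric(1))
  rownames(out) <- NULL
  out
}
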