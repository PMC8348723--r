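# Binary masks, trace rasterization, and overlap percentages.
#
# Grid convention: a mask is an integer 0/1 matrix m[iy, ix] with nrow = H,
# ncol = W; row iy indexes y bottom-up (y-up mathematical convention, like
# all trace geometry). Image I/O flips rows (see write_mask_png).

grid_index <- function(v, canvas_extent, n) {
  pmin(pmax(floor(v / canvas_extent * n) + 1L, 1L), n)
}

# Map canvas coordinates to grid (iy, ix) pairs.
to_grid <- function(x, y, canvas_w, canvas_h, dim) {
  cbind(
    iy = grid_index(y, canvas_h, dim[1]),
    ix = grid_index(x, canvas_w, dim[2])
  )
}

# Interpolated pixel coverage of the segment chain through `pts` (grid
# coords): consecutive points are joined by a dense 1-px line.
chain_pixels <- function(iy, ix) {
  n <- length(ix)
  if (n == 1L) return(cbind(iy = iy, ix = ix))
  out_iy <- vector("list", n - 1L)
  out_ix <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    steps <- max(abs(ix[k + 1L] - ix[k]), abs(iy[k + 1L] - iy[k])) + 1L
    out_iy[[k]] <- round(seq(iy[k], iy[k + 1L], length.out = steps))
    out_ix[[k]] <- round(seq(ix[k], ix[k + 1L], length.out = steps))
  }
  cbind(iy = unlist(out_iy), ix = unlist(out_ix))
}

#' Rasterize trace strokes onto a binary grid
#'
#' Each sample is scaled from canvas to grid coordinates and lit; consecutive
#' samples within a stroke are connected by a 1-px line, so the lit-pixel
#' count is at least the number of distinct sample pixels.
#'
#' @param trace A `sensor_trace`.
#' @param runs A single index range `c(start, end)`, a data frame of
#'   `start`/`end` rows (e.g. from [extract_strokes()]), or a list of
#'   ranges. An empty list yields an all-zero mask.
#' @param dim Grid size `c(H, W)`; default 128 x 128, the segmentation
#'   resolution.
#' @return A 0/1 integer matrix of size `dim` (rows index y bottom-up).
#' @export
rasterize_trace <- function(trace, runs, dim = c(128L, 128L)) {
  m <- matrix(0L, nrow = dim[1], ncol = dim[2])
  runs <- as_run_list(runs)
  s <- trace$samples
  for (r in runs) {
    idx <- r[[1]]:r[[2]]
    g <- to_grid(s$x[idx], s$y[idx], trace$canvas_w, trace$canvas_h, dim)
    px <- chain_pixels(g[, "iy"], g[, "ix"])
    m[px] <- 1L
  }
  m
}

as_run_list <- function(runs) {
  if (is.null(runs)) return(list())
  if (is.data.frame(runs)) {
    return(lapply(seq_len(nrow(runs)), function(i) c(runs$start[i], runs$end[i])))
  }
  if (is.list(runs)) return(runs)
  list(runs)
}

#' Overlap percentage of a segmented mask against a reference mask
#'
#' The percentage of the reference's lit pixels that are also lit in the
#' segmented mask — the statistic behind `pfc` (contour) and `pfh` (hands).
#'
#' @param segmented,reference 0/1 matrices of identical size.
#' @return A list with `percentage` (in `[0, 100]`), `n_intersection`, and
#'   `n_reference`.
#' @export
overlap_percentage <- function(segmented, reference) {
  if (!identical(dim(segmented), dim(reference))) {
    stop("masks must have the same grid shape")
  }
  n_ref <- sum(reference == 1L)
  if (n_ref == 0L) stop("reference mask is all zero: overlap is undefined")
  n_int <- sum(segmented == 1L & reference == 1L)
  list(
    percentage = 100 * n_int / n_ref,
    n_intersection = n_int, n_reference = n_ref
  )
}

#' Binary dilation of a mask
#'
#' Chebyshev (8-neighbourhood) dilation by `r` pixels, used as the tolerance
#' applied to a segmented mask before intersecting with a rasterized trace:
#' sub-pixel effects of the canvas-to-grid scaling otherwise make exact
#' pixel coincidence brittle.
#'
#' @param mask 0/1 matrix.
#' @param r Radius in pixels; `r = 0` returns the mask unchanged.
#' @return Dilated 0/1 matrix.
#' @export
dilate_mask <- function(mask, r = 1L) {
  if (r <= 0L) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (k in seq_len(r)) {
    m <- out
    up <- rbind(m[-1, , drop = FALSE], 0L)
    dn <- rbind(0L, m[-H, , drop = FALSE])
    acc <- m + up + dn
    lf <- cbind(acc[, -1, drop = FALSE], 0L)
    rt <- cbind(0L, acc[, -W, drop = FALSE])
    out <- (acc + lf + rt > 0L) * 1L
  }
  out
}

#' Sensor-pixel overlap percentage against a segmentation mask
#'
#' Rasterizes the given runs and measures which fraction of their pixels the
#' (tolerance-dilated) segmentation mask covers: `pfc` when `runs` is the
#' contour run, `pfh` when it is the hand runs.
#'
#' @inheritParams rasterize_trace
#' @param mask Segmentation mask on the same grid.
#' @param dilate Tolerance dilation (pixels) applied to `mask` first.
#' @return Percentage in `[0, 100]`.
#' @export
sensor_overlap_pct <- function(trace, runs, mask, dilate = 1L) {
  ref <- rasterize_trace(trace, runs, dim = dim(mask))
  overlap_percentage(dilate_mask(mask, dilate), ref)$percentage
}

#' Oracle segmentation backend
#'
#' A segmenter driven by the synthetic generator's ground truth, standing in
#' for a trained network so the scoring logic can be tested independently of
#' model weights. Two modes:
#'
#' * `"strict"` rasterizes exactly the strokes labelled with the requested
#'   role, optionally degraded by pixel dropout (rate `dropout`) and/or
#'   dilation — imperfect-but-unbiased segmentation.
#' * `"emulate"` (default) additionally reproduces the two discriminative
#'   behaviours a circle-and-two-hands-trained segmenter exhibits and that
#'   the scoring thresholds rely on: the contour mask is the rasterized
#'   least-squares circle fitted to the contour stroke (so non-circular
#'   contours obtain a low `pfc`), and when exactly one hand stroke is
#'   present the hands mask only covers the leading
#'   `single_hand_coverage` fraction of it (so `pfh` falls between the
#'   one-hand and two-hand thresholds).
#'
#' @param truth A `clock_truth` object from [generate_clock()].
#' @param mode `"emulate"` or `"strict"`.
#' @param dropout Pixel dropout rate in `[0, 1)` (strict mode degradation;
#'   uses the session RNG).
#' @param dilate Structural dilation of the produced mask, in pixels.
#' @param single_hand_coverage Fraction of a lone hand stroke covered by the
#'   emulated hands mask.
#' @return An object of class `oracle_segmenter` usable with
#'   [segment_mask()] and [score_clock()].
#' @export
oracle_segmenter <- function(truth, mode = c("emulate", "strict"),
                             dropout = 0, dilate = 0L,
                             single_hand_coverage = 0.55) {
  mode <- match.arg(mode)
  structure(
    list(
      truth = truth, mode = mode, dropout = dropout, dilate = dilate,
      single_hand_coverage = single_hand_coverage
    ),
    class = "oracle_segmenter"
  )
}

role_runs <- function(truth, role) {
  r <- truth$roles
  keep <- if (role == "hands") grepl("^hand_", r$role) else r$role == role
  r[keep, c("start", "end")]
}

#' Produce a segmentation mask from a backend
#'
#' Generic over segmentation backends: any object with a `segment_mask`
#' method (or a plain `function(trace, role, dim)`) can drive the scoring
#' pipeline.
#'
#' @param segmenter A backend, e.g. from [oracle_segmenter()].
#' @param trace The `sensor_trace` being scored.
#' @param role `"contour"` or `"hands"`.
#' @param dim Grid size `c(H, W)`.
#' @return A 0/1 matrix of size `dim`.
#' @export
segment_mask <- function(segmenter, trace, role, dim = c(128L, 128L)) {
  UseMethod("segment_mask")
}

#' @export
segment_mask.function <- function(segmenter, trace, role, dim = c(128L, 128L)) {
  segmenter(trace, role, dim)
}

#' @export
segment_mask.oracle_segmenter <- function(segmenter, trace, role,
                                          dim = c(128L, 128L)) {
  truth <- segmenter$truth
  if (!role %in% c("contour", "hands")) stop("role absent from truth: ", role)
  runs <- role_runs(truth, role)
  m <- if (segmenter$mode == "emulate" && role == "contour" && nrow(runs) > 0) {
    circle_curve_mask(trace, c(runs$start[1], runs$end[1]), dim)
  } else if (segmenter$mode == "emulate" && role == "hands" &&
             nrow(runs) == 1L &&
             isTRUE(segmenter$truth$spec$n_hands == 1)) {
    partial_run_mask(trace, c(runs$start[1], runs$end[1]), dim,
                     segmenter$single_hand_coverage)
  } else {
    rasterize_trace(trace, runs, dim = dim)
  }
  if (segmenter$dropout > 0) {
    lit <- which(m == 1L)
    drop <- lit[stats::runif(length(lit)) < segmenter$dropout]
    m[drop] <- 0L
  }
  dilate_mask(m, segmenter$dilate)
}

# Rasterized least-squares circle fitted to the run: emulates a segmenter
# that recognises contours as circular curves, so a non-circular contour
# only overlaps it near the crossing points and obtains a low pfc.
circle_curve_mask <- function(trace, run, dim) {
  fit <- tryCatch(fit_circle(run_xy(trace, run)), error = function(e) NULL)
  if (is.null(fit)) return(rasterize_trace(trace, run, dim = dim))
  ang <- seq(0, 2 * pi, length.out = 2048L)
  x <- fit$center[["x"]] + fit$radius * cos(ang)
  y <- fit$center[["y"]] + fit$radius * sin(ang)
  ok <- x >= 0 & x <= trace$canvas_w & y >= 0 & y <= trace$canvas_h
  m <- matrix(0L, dim[1], dim[2])
  if (!any(ok)) return(m)
  g <- to_grid(x[ok], y[ok], trace$canvas_w, trace$canvas_h, dim)
  m[chain_pixels(g[, "iy"], g[, "ix"])] <- 1L
  m
}

partial_run_mask <- function(trace, run, dim, coverage) {
  n <- run[[2]] - run[[1]] + 1L
  keep <- max(2L, floor(n * coverage))
  rasterize_trace(trace, c(run[[1]], run[[1]] + keep - 1L), dim = dim)
}
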