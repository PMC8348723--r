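#' clockscore: automatic qualitative scoring of digitized clock drawings
#'
#' Tools for scoring the Clock Drawing Test from time-stamped touch-sensor
#' traces: stroke and contour extraction, digit cropping and classification,
#' hand-line analysis, and the 13-criterion qualitative score, together with
#' a synthetic clock generator and oracle backends for testing.
#'
#' @keywords internal
"_PACKAGE"

# Event codes of the touch stream: -1 pen down, 0 move, +1 pen up.
EVENT_DOWN <- -1L
EVENT_MOVE <- 0L
EVENT_UP <- 1L

#' Build a validated sensor trace from raw touch records
#'
#' A sensor trace is the ordered stream of touch samples recorded while a
#' subject draws a clock: time stamp in seconds, x/y position in canvas
#' pixels (y increases upwards), and a touch-event code (-1 pen down, 0 move,
#' +1 pen up). Every maximal stroke must start with a down event and end with
#' an up event.
#'
#' @param records A data frame or matrix with columns `t`, `x`, `y`, `e`
#'   (or four unnamed columns in that order).
#' @param canvas_w,canvas_h Canvas size in pixels. The default canvas is
#'   2400 x 1200, the resolution all pixel thresholds are expressed in.
#' @param sample_period Nominal sampling period in seconds (50 Hz -> 0.02).
#'   Deviations of the observed median period beyond 50% produce a warning,
#'   not an error: real logs jitter.
#' @return An object of class `sensor_trace`: a list with `samples`
#'   (data frame `t`, `x`, `y`, `e`), `canvas_w`, `canvas_h`,
#'   `sample_period`.
#' @examples
#' tr <- parse_trace(data.frame(
#'   t = c(0, 0.02, 0.04), x = c(10, 12, 13), y = c(10, 11, 12),
#'   e = c(-1, 0, 1)
#' ))
#' n_strokes(tr)
#' @export
parse_trace <- function(records, canvas_w = 2400, canvas_h = 1200,
                        sample_period = 0.02) {
  if (is.matrix(records)) records <- as.data.frame(records)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("empty input: at least one touch sample is required")
  }
  if (!all(c("t", "x", "y", "e") %in% names(records))) {
    if (ncol(records) < 4L) stop("records must have columns t, x, y, e")
    names(records)[1:4] <- c("t", "x", "y", "e")
  }
  s <- data.frame(
    t = as.numeric(records$t), x = as.numeric(records$x),
    y = as.numeric(records$y), e = as.integer(records$e)
  )
  if (anyNA(s)) stop("touch samples contain missing values")
  if (!all(s$e %in% c(EVENT_DOWN, EVENT_MOVE, EVENT_UP))) {
    stop("invalid event code: touch events must be -1 (down), 0 (move) or 1 (up)")
  }
  if (any(diff(s$t) < 0)) stop("decreasing time stamps")
  if (any(!is.finite(s$x)) || any(!is.finite(s$y)) ||
      any(s$x < 0) || any(s$y < 0)) {
    stop("x and y must be finite and non-negative")
  }
  # Stroke structure: down ... move* ... up, never nested.
  inside <- FALSE
  for (i in seq_len(nrow(s))) {
    e <- s$e[i]
    if (e == EVENT_DOWN) {
      if (inside) stop("unterminated stroke: two down events with no intervening up")
      inside <- TRUE
    } else if (e == EVENT_UP) {
      if (!inside) stop("up event outside a stroke")
      inside <- FALSE
    } else if (!inside) {
      stop("move event outside a stroke")
    }
  }
  if (inside) stop("unterminated stroke: trace ends without an up event")
  if (nrow(s) > 1L) {
    med <- stats::median(diff(s$t)[diff(s$t) > 0])
    if (is.finite(med) && abs(med - sample_period) > 0.5 * sample_period) {
      warning(sprintf(
        "median sample period %.4f s deviates from nominal %.4f s",
        med, sample_period
      ))
    }
  }
  structure(
    list(
      samples = s, canvas_w = as.numeric(canvas_w),
      canvas_h = as.numeric(canvas_h), sample_period = sample_period
    ),
    class = "sensor_trace"
  )
}

#' An empty sensor trace
#'
#' Convenience constructor for the degenerate no-ink case; the scoring
#' pipeline maps it to an all-zero report rather than an error.
#' @inheritParams parse_trace
#' @return A `sensor_trace` with zero samples.
#' @export
empty_trace <- function(canvas_w = 2400, canvas_h = 1200,
                        sample_period = 0.02) {
  structure(
    list(
      samples = data.frame(
        t = numeric(0), x = numeric(0),
        y = numeric(0), e = integer(0)
      ),
      canvas_w = as.numeric(canvas_w), canvas_h = as.numeric(canvas_h),
      sample_period = sample_period
    ),
    class = "sensor_trace"
  )
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf(
    "<sensor_trace> %d samples, %d strokes, canvas %g x %g px\n",
    nrow(x$samples), n_strokes(x), x$canvas_w, x$canvas_h
  ))
  invisible(x)
}

#' Number of strokes in a trace
#' @param trace A `sensor_trace`.
#' @return Integer stroke count.
#' @export
n_strokes <- function(trace) {
  sum(trace$samples$e == EVENT_DOWN)
}

#' Extract stroke index ranges from a trace
#'
#' Each maximal down...up run is one stroke. The returned ranges partition
#' the sample indices: concatenated in order they cover every sample exactly
#' once.
#'
#' @param trace A `sensor_trace`.
#' @return A data frame with columns `start` and `end` (inclusive sample
#'   indices), one row per stroke, in temporal order.
#' @export
extract_strokes <- function(trace) {
  stopifnot(inherits(trace, "sensor_trace"))
  e <- trace$samples$e
  data.frame(
    start = which(e == EVENT_DOWN),
    end = which(e == EVENT_UP)
  )
}

#' Identify the contour stroke
#'
#' The clock-face contour is taken to be the stroke with the longest
#' continuous run of move events (the longest sequence of 0s delimited by a
#' -1 and a +1 in the event stream). Ties are broken in favour of the
#' earliest stroke.
#'
#' @param trace A `sensor_trace` with at least one stroke.
#' @return A named integer vector `c(start =, end =)` delimiting the contour
#'   run (the indices `ci` and `cf`).
#' @export
find_contour_run <- function(trace) {
  strokes <- extract_strokes(trace)
  if (nrow(strokes) == 0L) stop("no stroke present")
  moves <- vapply(seq_len(nrow(strokes)), function(i) {
    sum(trace$samples$e[strokes$start[i]:strokes$end[i]] == EVENT_MOVE)
  }, integer(1))
  k <- which.max(moves) # which.max keeps the earliest on ties
  c(start = strokes$start[k], end = strokes$end[k])
}

run_xy <- function(trace, run) {
  idx <- run[[1]]:run[[2]]
  cbind(x = trace$samples$x[idx], y = trace$samples$y[idx])
}

#' Bounding box of a contour run
#'
#' Component-wise minima and maxima of the x and y coordinates over the run:
#' the estimated boundary of the contour (`xminc`, `xmaxc`, `yminc`,
#' `ymaxc`).
#'
#' @param trace A `sensor_trace`.
#' @param run An index range `c(start, end)`, e.g. from
#'   [find_contour_run()].
#' @return Named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
contour_bbox <- function(trace, run) {
  if (run[[2]] < run[[1]]) stop("empty range")
  p <- run_xy(trace, run)
  c(
    xmin = min(p[, "x"]), xmax = max(p[, "x"]),
    ymin = min(p[, "y"]), ymax = max(p[, "y"])
  )
}

#' Center of the contour bounding box
#'
#' The bisecting point of the extreme coordinates,
#' `((xmin + xmax) / 2, (ymin + ymax) / 2)` — the pre-estimated clock
#' center (`xmidc`, `ymidc`).
#'
#' @param bbox Named vector from [contour_bbox()].
#' @return Named numeric vector `c(x, y)`.
#' @export
contour_center <- function(bbox) {
  c(
    x = unname((bbox[["xmin"]] + bbox[["xmax"]]) / 2),
    y = unname((bbox[["ymin"]] + bbox[["ymax"]]) / 2)
  )
}

#' Canonical anchor positions of the twelve clock digits
#'
#' Pre-estimated positions of the numbers 1-12 on the dial, computed from
#' the contour bounding box and its center in a y-up coordinate convention
#' (12 sits at `ymax`, 6 at `ymin`, 3 at `xmax`, 9 at `xmin`; the corner
#' digits interpolate at thirds between the center and the boundary).
#' Anchors of diametrically opposite digits are point-symmetric about the
#' center.
#'
#' @param bbox Named vector from [contour_bbox()].
#' @param center Optional center point; defaults to [contour_center()].
#' @return A 12 x 2 matrix with rownames `"1"`..`"12"` and columns
#'   `x`, `y`.
#' @export
digit_anchors <- function(bbox, center = contour_center(bbox)) {
  xmin <- bbox[["xmin"]]; xmax <- bbox[["xmax"]]
  ymin <- bbox[["ymin"]]; ymax <- bbox[["ymax"]]
  xmid <- center[["x"]]; ymid <- center[["y"]]
  a <- rbind(
    `1` = c((2 * xmid + xmax) / 3, (2 * ymax + ymid) / 3),
    `2` = c((xmid + 2 * xmax) / 3, (ymax + 2 * ymid) / 3),
    `3` = c(xmax, ymid),
    `4` = c((xmid + 2 * xmax) / 3, (ymin + 2 * ymid) / 3),
    `5` = c((2 * xmid + xmax) / 3, (2 * ymin + ymid) / 3),
    `6` = c(xmid, ymin),
    `7` = c((2 * xmid + xmin) / 3, (2 * ymin + ymid) / 3),
    `8` = c((xmid + 2 * xmin) / 3, (ymin + 2 * ymid) / 3),
    `9` = c(xmin, ymid),
    `10` = c((xmid + 2 * xmin) / 3, (ymax + 2 * ymid) / 3),
    `11` = c((2 * xmid + xmin) / 3, (2 * ymax + ymid) / 3),
    `12` = c(xmid, ymax)
  )
  colnames(a) <- c("x", "y")
  a
}

#' Maximum contour closure distance
#'
#' The largest gap in the drawn contour: the maximum of (i) the distance
#' between the first and the last sample of the run and (ii) the distances
#' between consecutive internal up/down shift points (pen lifts and
#' re-touches inside the contour drawing episode), ordered by time. A run
#' drawn as one unbroken stroke reduces to the endpoint distance.
#'
#' @inheritParams contour_bbox
#' @return Distance in pixels (`dmaxc`).
#' @export
closure_distance <- function(trace, run) {
  if (run[[2]] < run[[1]]) stop("empty range")
  idx <- run[[1]]:run[[2]]
  s <- trace$samples[idx, ]
  n <- nrow(s)
  d_end <- sqrt((s$x[1] - s$x[n])^2 + (s$y[1] - s$y[n])^2)
  gaps <- numeric(0)
  if (n > 2L) {
    sh <- which(s$e[-c(1L, n)] != EVENT_MOVE) + 1L # internal shift points
    if (length(sh) >= 2L) {
      dx <- diff(s$x[sh]); dy <- diff(s$y[sh])
      gaps <- sqrt(dx^2 + dy^2)
    }
  }
  max(c(d_end, gaps))
}

#' Contour-to-window area ratio
#'
#' `Ac / Wc` where `Ac = (xmax - xmin)(ymax - ymin)` is the bounding-box
#' area of the contour and `Wc` the canvas area; the size-appropriateness
#' statistic.
#'
#' @param bbox Named vector from [contour_bbox()].
#' @param canvas_w,canvas_h Canvas size in pixels.
#' @return Unitless ratio; 0 for a degenerate bounding box.
#' @export
contour_area_ratio <- function(bbox, canvas_w, canvas_h) {
  wc <- canvas_w * canvas_h
  if (!is.finite(wc) || wc <= 0) stop("zero canvas")
  (bbox[["xmax"]] - bbox[["xmin"]]) * (bbox[["ymax"]] - bbox[["ymin"]]) / wc
}

as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  points
}

#' Algebraic least-squares circle fit
#'
#' Kasa-style fit: minimizes the algebraic residual of
#' `x^2 + y^2 = 2 a x + 2 b y + c` by linear least squares. Exact on
#' noiseless circular data.
#'
#' @param points A two-column matrix or data frame of x/y coordinates
#'   (at least 3 non-collinear points).
#' @return A list of class `circle_fit` with `center` (named vector) and
#'   `radius`.
#' @export
fit_circle <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 3L) stop("at least 3 points are required")
  A <- cbind(2 * p[, 1], 2 * p[, 2], 1)
  b <- p[, 1]^2 + p[, 2]^2
  qra <- qr(A)
  if (qra$rank < 3L) stop("collinear points: circle fit is singular")
  sol <- qr.coef(qra, b)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) stop("degenerate circle fit")
  structure(
    list(
      center = c(x = unname(sol[1]), y = unname(sol[2])),
      radius = unname(sqrt(r2))
    ),
    class = "circle_fit"
  )
}

#' Total-least-squares line fit
#'
#' Fits the first principal direction through the centroid, so the result is
#' stable for near-vertical strokes (unlike y-on-x regression). The
#' direction is a unit vector with a deterministic sign (largest-magnitude
#' component positive).
#'
#' @param points A two-column matrix or data frame (at least 2 distinct
#'   points).
#' @return A list of class `line_fit` with `point` (centroid) and
#'   `direction` (unit vector).
#' @export
fit_line <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 2L) stop("at least 2 points are required")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  if (all(abs(q) < 1e-12)) stop("all points identical: line fit is degenerate")
  sv <- svd(q, nu = 0, nv = 2)
  v <- sv$v[, 1]
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  structure(
    list(
      point = c(x = unname(ctr[1]), y = unname(ctr[2])),
      direction = c(x = v[1], y = v[2])
    ),
    class = "line_fit"
  )
}

#' Perpendicular distances from points to a fitted line
#' @param line A `line_fit`.
#' @param points Two-column matrix or data frame.
#' @return Numeric vector of distances in pixels.
#' @export
line_distance <- function(line, points) {
  p <- as_points(points)
  dx <- p[, 1] - line$point[["x"]]
  dy <- p[, 2] - line$point[["y"]]
  abs(dx * line$direction[["y"]] - dy * line$direction[["x"]])
}

point_distance <- function(a, b) {
  sqrt((a[[1]] - b[[1]])^2 + (a[[2]] - b[[2]])^2)
}
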