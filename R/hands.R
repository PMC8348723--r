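# Hand-stroke identification, two-hand splitting, lengths, and
# target-number indication by line extrapolation to the contour.

#' Identify the hand strokes
#'
#' Hand candidates are the strokes that are neither the contour nor part of
#' a digit crop. When a hands segmentation mask is supplied (the pipeline
#' case), a stroke is a hand if at least `overlap_min` of its rasterized
#' pixels lie in the mask; otherwise strokes mostly inside a digit box, and
#' strokes with a spatial extent below `min_extent` (dots, specks), are
#' excluded, and when more than two candidates remain the two with the
#' largest extent are kept.
#'
#' @param trace A `sensor_trace`.
#' @param contour_run The contour index range.
#' @param digit_boxes Data frame of digit component boxes (canvas-resolution
#'   coordinates), or `NULL`.
#' @param hands_mask Optional segmentation mask (e.g. from
#'   [segment_mask()]).
#' @param overlap_min Minimum mask-overlap fraction for the mask route.
#' @param min_extent Minimum bbox diagonal extent in pixels for a candidate.
#' @return A data frame of `start`/`end` rows (0, 1 or 2), in time order.
#' @export
extract_hand_runs <- function(trace, contour_run, digit_boxes = NULL,
                              hands_mask = NULL, overlap_min = 0.5,
                              min_extent = 60) {
  strokes <- extract_strokes(trace)
  strokes <- strokes[strokes$start != contour_run[[1]], , drop = FALSE]
  if (nrow(strokes) == 0L) return(strokes)
  keep <- logical(nrow(strokes))
  extent <- numeric(nrow(strokes))
  ov <- numeric(nrow(strokes))
  if (!is.null(hands_mask)) hands_mask <- dilate_mask(hands_mask, 1L)
  for (i in seq_len(nrow(strokes))) {
    run <- c(strokes$start[i], strokes$end[i])
    p <- run_xy(trace, run)
    extent[i] <- sqrt(diff(range(p[, "x"]))^2 + diff(range(p[, "y"]))^2)
    if (!is.null(hands_mask)) {
      ref <- rasterize_trace(trace, run, dim = dim(hands_mask))
      ov[i] <- overlap_percentage(hands_mask, ref)$percentage
      keep[i] <- ov[i] >= 100 * overlap_min
    } else {
      in_box <- if (!is.null(digit_boxes) && nrow(digit_boxes) > 0) {
        frac_in_any_box(p, digit_boxes)
      } else 0
      keep[i] <- in_box < 0.5 && extent[i] >= min_extent
    }
  }
  cand <- strokes[keep, , drop = FALSE]
  if (nrow(cand) > 2L) {
    # at most two hands: keep the two best-supported candidates
    rank_by <- if (!is.null(hands_mask)) ov[keep] else extent[keep]
    top <- sort(order(rank_by, decreasing = TRUE)[1:2])
    cand <- cand[top, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

frac_in_any_box <- function(p, boxes) {
  inside <- rep(FALSE, nrow(p))
  for (i in seq_len(nrow(boxes))) {
    inside <- inside |
      (p[, "x"] >= boxes$xmin[i] & p[, "x"] <= boxes$xmax[i] &
         p[, "y"] >= boxes$ymin[i] & p[, "y"] <= boxes$ymax[i])
  }
  mean(inside)
}

#' Split hand samples into the two hand sets
#'
#' With two strokes the split is the pen lift between them (the
#' intermission). A single stroke covering both hands is split by a
#' deterministic two-line clustering: the initial split is at the sample
#' with the maximum turning angle, then 20 Lloyd-style iterations
#' alternately fit a total-least-squares line to each set and reassign every
#' point to the nearer line.
#'
#' @param points Data frame with columns `t`, `x`, `y` and optionally
#'   `stroke` (stroke id per sample); at least 4 points.
#' @param iterations Number of refit/reassign iterations.
#' @return A list with `H1`, `H2` (data frames, both nonempty) and
#'   `split_time`.
#' @export
split_hand_sets <- function(points, iterations = 20L) {
  n <- nrow(points)
  if (n < 4L) stop("too few points to split into two hand sets")
  if (!is.null(points$stroke) && length(unique(points$stroke)) >= 2L) {
    first <- points$stroke == points$stroke[1]
    return(list(
      H1 = points[first, , drop = FALSE],
      H2 = points[!first, , drop = FALSE],
      split_time = max(points$t[first])
    ))
  }
  xy <- cbind(x = points$x, y = points$y)
  m <- max_turning_index(xy)
  assign <- c(rep(1L, m), rep(2L, n - m))
  for (it in seq_len(iterations)) {
    l1 <- tryCatch(fit_line(xy[assign == 1L, , drop = FALSE]),
                   error = function(e) NULL)
    l2 <- tryCatch(fit_line(xy[assign == 2L, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(l1) || is.null(l2)) break
    d1 <- line_distance(l1, xy); d2 <- line_distance(l2, xy)
    new_assign <- ifelse(d1 <= d2, 1L, 2L)
    if (sum(new_assign == 1L) < 2L || sum(new_assign == 2L) < 2L) break
    if (all(new_assign == assign)) break
    assign <- new_assign
  }
  list(
    H1 = points[assign == 1L, , drop = FALSE],
    H2 = points[assign == 2L, , drop = FALSE],
    split_time = points$t[m]
  )
}

# Interior sample with the sharpest direction change; collinear input
# degenerates to the midpoint, not an error.
max_turning_index <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(max(1L, n %/% 2L))
  d <- diff(xy)
  len <- sqrt(rowSums(d^2))
  ok <- len > 1e-12
  ang <- rep(0, n - 2L)
  for (i in seq_len(n - 2L)) {
    if (ok[i] && ok[i + 1L]) {
      cosang <- sum(d[i, ] * d[i + 1L, ]) / (len[i] * len[i + 1L])
      ang[i] <- acos(pmin(pmax(cosang, -1), 1))
    }
  }
  if (max(ang) < 1e-9) return(n %/% 2L)
  which.max(ang) + 1L
}

#' Length of one hand
#'
#' The distance between the point attaining the minimum y and the point
#' attaining the maximum y coordinate in the set (first by time on ties).
#'
#' @param set Data frame with `x`, `y` (time-ordered).
#' @return Length in pixels; 0 for a single point.
#' @export
hand_length <- function(set) {
  if (nrow(set) == 0L) stop("empty set")
  i <- which.min(set$y); j <- which.max(set$y)
  sqrt((set$x[i] - set$x[j])^2 + (set$y[i] - set$y[j])^2)
}

#' Test whether a hand indicates its target number
#'
#' Fits a total-least-squares line to the hand samples, extrapolates it to
#' the contour, and checks whether the closest contour point to the line —
#' restricted to the y-window and to the hand's pointing side — falls
#' within `eps` of the target digit's anchor.
#'
#' The pointing side keeps only contour points whose projection onto the
#' hand line lies beyond the hand endpoint farthest from the clock center,
#' preventing a hit on the antipodal intersection; if that filter empties
#' the candidate set it is relaxed. An explicit y-window that excludes every
#' contour point is an error.
#'
#' @param hand_set Data frame with `x`, `y` of the hand's samples.
#' @param contour_points Two-column matrix or data frame of contour samples.
#' @param anchors Matrix from [digit_anchors()].
#' @param target_digit Target number 1..12.
#' @param yrange Optional `c(ymin, ymax)` restriction on contour candidate
#'   y coordinates.
#' @param eps Hit radius in pixels around the anchor.
#' @param clock_center Clock center, used to orient the pointing side;
#'   `NULL` disables the side filter.
#' @return A list: `point` (the closest contour point), `distance` (to the
#'   target anchor, pixels), `hit` (logical), `line` (the fit).
#' @export
target_hit <- function(hand_set, contour_points, anchors, target_digit,
                       yrange = NULL, eps = 200, clock_center = NULL) {
  cp <- as_points(contour_points)
  if (nrow(cp) == 0L) stop("no contour candidates")
  line <- fit_line(cbind(x = hand_set$x, y = hand_set$y))
  cand <- rep(TRUE, nrow(cp))
  if (!is.null(yrange)) {
    cand <- cp[, "y"] >= yrange[1] & cp[, "y"] <= yrange[2]
    if (!any(cand)) stop("no contour candidates in the y-window")
  }
  u <- c(line$direction[["x"]], line$direction[["y"]])
  if (!is.null(clock_center)) {
    dctr <- sqrt((hand_set$x - clock_center[[1]])^2 +
                   (hand_set$y - clock_center[[2]])^2)
    far <- c(hand_set$x[which.max(dctr)], hand_set$y[which.max(dctr)])
    if (sum(u * (far - c(clock_center[[1]], clock_center[[2]]))) < 0) u <- -u
    t_far <- sum(u * (far - c(line$point[["x"]], line$point[["y"]])))
    t_cand <- (cp[, "x"] - line$point[["x"]]) * u[1] +
      (cp[, "y"] - line$point[["y"]]) * u[2]
    side <- cand & (t_cand >= t_far - 1e-9)
    if (any(side)) cand <- side
  }
  d_line <- line_distance(line, cp)
  d_line[!cand] <- Inf
  k <- which.min(d_line)
  pt <- c(x = cp[k, "x"], y = cp[k, "y"])
  d <- point_distance(pt, anchors[as.character(target_digit), ])
  list(point = pt, distance = d, hit = d < eps, line = line)
}

#' Assemble the hand statistics for scoring
#'
#' Computes the full hands record from the identified hand runs: `pfh`, the
#' two hand sets and their lengths, the length difference, and the hour and
#' minute target-indication results. With two sets the hour hand is the one
#' with more samples; with a single run the whole data is fitted as one line
#' for both target tests. The extrapolation y-window is
#' `[min y of the hand samples, max y of the contour samples]`, falling
#' back to the whole contour when it is degenerate.
#'
#' @param trace A `sensor_trace`.
#' @param hand_runs Data frame of hand runs from [extract_hand_runs()].
#' @param contour_run The contour index range.
#' @param anchors Matrix from [digit_anchors()].
#' @param hour_target,minute_target Target numbers 1..12.
#' @param pfh Percentage from [sensor_overlap_pct()] against the hands
#'   mask, or `NA` when unavailable.
#' @param eps Hit radius in pixels.
#' @param clock_center Clock center for the pointing-side filter.
#' @param th_two Two-hand presence threshold on `pfh`: a single run with
#'   `pfh` above it (two hands drawn in one stroke) is split by clustering
#'   for the target tests instead of being fitted as one line.
#' @return A list of class `hands_stats`: `pfh`, `n_runs`, `len_h1`,
#'   `len_h2`, `delta_len`, `hour_distance`, `minute_distance`,
#'   `hour_hit`, `minute_hit`, `split_time`.
#' @export
hands_stats <- function(trace, hand_runs, contour_run, anchors,
                        hour_target, minute_target, pfh = NA_real_,
                        eps = 200, clock_center = NULL, th_two = 65) {
  out <- list(
    pfh = pfh, n_runs = nrow(hand_runs), len_h1 = NA_real_,
    len_h2 = NA_real_, delta_len = NA_real_, hour_distance = NA_real_,
    minute_distance = NA_real_, hour_hit = FALSE, minute_hit = FALSE,
    split_time = NA_real_
  )
  class(out) <- "hands_stats"
  if (nrow(hand_runs) == 0L) return(out)
  idx <- unlist(lapply(seq_len(nrow(hand_runs)), function(i) {
    hand_runs$start[i]:hand_runs$end[i]
  }))
  pts <- trace$samples[idx, c("t", "x", "y")]
  pts$stroke <- rep(seq_len(nrow(hand_runs)),
                    hand_runs$end - hand_runs$start + 1L)
  cp <- run_xy(trace, contour_run)
  yr <- c(min(pts$y), max(cp[, "y"]))
  if (yr[1] > max(cp[, "y"]) || yr[2] < min(cp[, "y"])) yr <- NULL
  # a single run is fitted as one line for both targets (the one-hand
  # case) unless pfh indicates two hands drawn in one stroke, in which
  # case the clustered sets take the roles
  single_line <- nrow(hand_runs) == 1L && !isTRUE(pfh > th_two)
  if (nrow(pts) >= 4L) {
    sp <- split_hand_sets(pts)
    out$split_time <- sp$split_time
    out$len_h1 <- hand_length(sp$H1)
    out$len_h2 <- hand_length(sp$H2)
    out$delta_len <- abs(out$len_h2 - out$len_h1)
    if (!single_line) {
      hour_set <- if (nrow(sp$H1) >= nrow(sp$H2)) sp$H1 else sp$H2
      minute_set <- if (nrow(sp$H1) >= nrow(sp$H2)) sp$H2 else sp$H1
    }
  }
  if (single_line || nrow(pts) < 4L) {
    hour_set <- pts
    minute_set <- pts
  }
  hh <- tryCatch(
    target_hit(hour_set, cp, anchors, hour_target, yrange = yr, eps = eps,
               clock_center = clock_center),
    error = function(e) target_hit(hour_set, cp, anchors, hour_target,
                                   yrange = NULL, eps = eps,
                                   clock_center = clock_center)
  )
  mh <- tryCatch(
    target_hit(minute_set, cp, anchors, minute_target, yrange = yr,
               eps = eps, clock_center = clock_center),
    error = function(e) target_hit(minute_set, cp, anchors, minute_target,
                                   yrange = NULL, eps = eps,
                                   clock_center = clock_center)
  )
  out$hour_distance <- hh$distance; out$hour_hit <- hh$hit
  out$minute_distance <- mh$distance; out$minute_hit <- mh$hit
  out
}
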