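# The 13 binary scoring criteria, parameter sums, end-to-end pipeline, and
# confusion-matrix evaluation metrics.

#' Scoring thresholds
#'
#' The heuristic threshold set of the scoring method. Defaults:
#' `theta_c1 = 75` (% — circular contour), `theta_c2 = 50` (px — closure),
#' `theta_c3 = 0.1` (area ratio), `theta_n = 65` (% — order),
#' `l_dc = 100` (px — per-number position limit), `theta_dc = 0.65`
#' (fraction of numbers within `l_dc`), `theta_h1 = 65` / `theta_h2 = 50`
#' (% — two/one hand presence), `theta_pr = 30` (px — hand length
#' difference), `eps = 200` (px — target-number hit radius), `eps_c = 75`
#' (px — center evidence radius). Any subset may be overridden.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `cdt_thresholds`.
#' @export
default_thresholds <- function(...) {
  th <- list(
    theta_c1 = 75, theta_c2 = 50, theta_c3 = 0.1,
    theta_n = 65, l_dc = 100, theta_dc = 0.65,
    theta_h1 = 65, theta_h2 = 50, theta_pr = 30,
    eps = 200, eps_c = 75
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(ov)] <- ov
  if (th$theta_h2 >= th$theta_h1) stop("theta_h2 must be below theta_h1")
  structure(th, class = "cdt_thresholds")
}

#' Load a threshold configuration file
#'
#' Reads a JSON object whose fields override any subset of the defaults.
#' @param path Path to a JSON file, e.g. `{"theta_c2": 40}`.
#' @return A `cdt_thresholds` list.
#' @export
load_thresholds <- function(path) {
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_thresholds, as.list(ov))
}

flag <- function(x) isTRUE(x) # NA / NULL / missing statistics score 0

#' Score the contour parameter
#'
#' Three binary criteria from the contour statistics: circular
#' (`pfc >= theta_c1`), closed (`dmaxc < theta_c2`), appropriately sized
#' (`area_ratio >= theta_c3`).
#'
#' @param stats A list with `pfc` (%), `dmaxc` (px), `area_ratio`.
#' @param th Thresholds from [default_thresholds()].
#' @return List with `circular`, `closed`, `sized` (0/1) and `sum` (0-3).
#' @export
score_contour <- function(stats, th = default_thresholds()) {
  circular <- flag(stats$pfc >= th$theta_c1)
  closed <- flag(stats$dmaxc < th$theta_c2)
  sized <- flag(stats$area_ratio >= th$theta_c3)
  list(
    circular = as.integer(circular), closed = as.integer(closed),
    sized = as.integer(sized),
    sum = as.integer(circular + closed + sized)
  )
}

#' Score the numbers parameter
#'
#' Four binary criteria: presence (`N = 15` character crops, every label in
#' 0..9, five 1s and two 2s), order (`Rseq >= theta_n`), position (the
#' fraction of anchor distances `dcn` within `l_dc` exceeds `theta_dc`),
#' and within-contour (`RcN < RcL`, the numbers' fitted circle inside the
#' contour's).
#'
#' @param stats A list with `n`, `labels`, `rseq`, `dcn`, `rc_numbers`,
#'   `rc_contour`.
#' @param th Thresholds.
#' @return List with `presence`, `order`, `position`, `within` (0/1) and
#'   `sum` (0-4).
#' @export
score_numbers <- function(stats, th = default_thresholds()) {
  labels <- stats$labels
  presence <- flag(
    stats$n == 15L && length(labels) > 0 && !anyNA(labels) &&
      all(labels >= 0L & labels <= 9L) &&
      sum(labels == 1L) == 5L && sum(labels == 2L) == 2L
  )
  order <- flag(stats$rseq >= th$theta_n)
  position <- flag(
    length(stats$dcn) > 0 &&
      mean(stats$dcn <= th$l_dc, na.rm = FALSE) > th$theta_dc
  )
  within <- flag(stats$rc_numbers < stats$rc_contour)
  list(
    presence = as.integer(presence), order = as.integer(order),
    position = as.integer(position), within = as.integer(within),
    sum = as.integer(presence + order + position + within)
  )
}

#' Score the hands parameter
#'
#' Presence scores 2 when `pfh > theta_h1` (two hands), 1 when
#' `pfh > theta_h2` (one hand), else 0; the two presence criteria are
#' mutually exclusive. Proportion requires two-hand presence and
#' `delta_len > theta_pr`; the hour and minute criteria require the
#' respective target-hit distance below `eps`.
#'
#' @param stats A `hands_stats` list (or any list with `pfh`, `delta_len`,
#'   `hour_distance`, `minute_distance`).
#' @param th Thresholds.
#' @return List with `presence` (0/1/2), `two_hands`, `one_hand`,
#'   `proportion`, `hour`, `minute` (0/1) and `sum` (0-5).
#' @export
score_hands <- function(stats, th = default_thresholds()) {
  pfh <- stats$pfh
  presence <- if (flag(pfh > th$theta_h1)) 2L else if (flag(pfh > th$theta_h2)) 1L else 0L
  proportion <- flag(pfh > th$theta_h1) && flag(stats$delta_len > th$theta_pr)
  hour <- flag(stats$hour_distance < th$eps)
  minute <- flag(stats$minute_distance < th$eps)
  list(
    presence = presence,
    two_hands = as.integer(presence == 2L),
    one_hand = as.integer(presence == 1L),
    proportion = as.integer(proportion),
    hour = as.integer(hour), minute = as.integer(minute),
    sum = as.integer(presence + proportion + hour + minute)
  )
}

#' Score the center parameter
#'
#' The center is present or inferred (1) when at least one hand is present,
#' or when any non-contour sample lies within `eps_c` of the contour
#' center.
#'
#' @param hands_presence 0, 1 or 2 from [score_hands()].
#' @param trace A `sensor_trace`, or `NULL` (no sample evidence).
#' @param contour_run The contour index range (its samples are not
#'   evidence), or `NULL`.
#' @param center The contour center `c(x, y)`.
#' @param th Thresholds.
#' @return List with `center` (0/1) and `n_near` (count of near-center
#'   samples).
#' @export
score_center <- function(hands_presence, trace = NULL, contour_run = NULL,
                         center = NULL, th = default_thresholds()) {
  n_near <- 0L
  if (!is.null(trace) && !is.null(center) && nrow(trace$samples) > 0) {
    s <- trace$samples
    keep <- rep(TRUE, nrow(s))
    if (!is.null(contour_run)) keep[contour_run[[1]]:contour_run[[2]]] <- FALSE
    d <- sqrt((s$x[keep] - center[[1]])^2 + (s$y[keep] - center[[2]])^2)
    n_near <- sum(d < th$eps_c)
  }
  list(
    center = as.integer(hands_presence >= 1L || n_near > 0L),
    n_near = n_near
  )
}

criteria_names <- function() {
  c(
    "circular", "closed", "sized",
    "num_presence", "num_order", "num_position", "num_within",
    "two_hands", "one_hand", "proportion", "hour", "minute",
    "center"
  )
}

#' Assemble the full score report
#'
#' @param contour,numbers,hands,center Outputs of the four scoring
#'   operations.
#' @param stats Optional list of intermediate statistics to carry in the
#'   report.
#' @param thresholds The thresholds used.
#' @return An object of class `cdt_score_report`: `criteria` (13 named
#'   0/1 values), `scores` (the four parameter sums), `total` (0-13),
#'   `stats`, `thresholds`.
#' @export
score_total <- function(contour, numbers, hands, center, stats = list(),
                        thresholds = default_thresholds()) {
  criteria <- c(
    circular = contour$circular, closed = contour$closed,
    sized = contour$sized,
    num_presence = numbers$presence, num_order = numbers$order,
    num_position = numbers$position, num_within = numbers$within,
    two_hands = hands$two_hands, one_hand = hands$one_hand,
    proportion = hands$proportion, hour = hands$hour,
    minute = hands$minute,
    center = center$center
  )
  scores <- c(
    contour = contour$sum, numbers = numbers$sum,
    hands = hands$sum, center = center$center
  )
  structure(
    list(
      criteria = criteria, scores = scores,
      total = sum(scores), stats = stats,
      thresholds = unclass(thresholds)
    ),
    class = "cdt_score_report"
  )
}

#' @export
print.cdt_score_report <- function(x, ...) {
  cat(sprintf(
    "<cdt_score_report> total %d/13 (contour %d/3, numbers %d/4, hands %d/5, center %d/1)\n",
    x$total, x$scores[["contour"]], x$scores[["numbers"]],
    x$scores[["hands"]], x$scores[["center"]]
  ))
  invisible(x)
}

zero_report <- function(thresholds) {
  z3 <- list(circular = 0L, closed = 0L, sized = 0L, sum = 0L)
  z4 <- list(presence = 0L, order = 0L, position = 0L, within = 0L, sum = 0L)
  z5 <- list(presence = 0L, two_hands = 0L, one_hand = 0L, proportion = 0L,
             hour = 0L, minute = 0L, sum = 0L)
  zc <- list(center = 0L, n_near = 0L)
  score_total(z3, z4, z5, zc, stats = list(), thresholds = thresholds)
}

#' Score a clock drawing end to end
#'
#' Runs the full qualitative scoring pipeline on a sensor trace: contour
#' identification and statistics, segmentation overlaps, digit cropping and
#' classification, drawing-order similarity, hand analysis, and the center
#' criterion, assembled into the 13-criterion report.
#'
#' @param trace A `sensor_trace`; a trace without strokes yields an
#'   all-zero report.
#' @param segmenter Segmentation backend for [segment_mask()].
#' @param classifier Digit classifier `function(crop, box)`.
#' @param thresholds Thresholds from [default_thresholds()].
#' @param hour_target,minute_target The instructed time's target numbers
#'   (default 10 past 11).
#' @param grid_dim Segmentation grid, default `c(128, 128)`.
#' @param id_grid_dim Finer grid used only to match strokes against the
#'   hands mask when identifying hand runs.
#' @param exclude_hands Exclude identified hand strokes from the digit
#'   image before cropping (default `TRUE`).
#' @param dilate Tolerance dilation for mask overlaps (px).
#' @param min_component_extent Minimum component box extent (canvas px)
#'   for a digit crop.
#' @return A `cdt_score_report` whose `stats` element carries all
#'   intermediate statistics (`pfc`, `dmaxc`, `area_ratio`, `n`, `rseq`,
#'   `dcn`, `rc_contour`, `rc_numbers`, `pfh`, `delta_len`, hit distances,
#'   `n_near`).
#' @export
score_clock <- function(trace, segmenter, classifier,
                        thresholds = default_thresholds(),
                        hour_target = 11, minute_target = 2,
                        grid_dim = c(128L, 128L),
                        id_grid_dim = c(512L, 512L), exclude_hands = TRUE,
                        dilate = 1L, min_component_extent = 25) {
  if (nrow(trace$samples) == 0L || n_strokes(trace) == 0L) {
    return(zero_report(thresholds))
  }
  contour_run <- find_contour_run(trace)
  bbox <- contour_bbox(trace, contour_run)
  center <- contour_center(bbox)
  anchors <- digit_anchors(bbox, center)
  cmask <- segment_mask(segmenter, trace, "contour", dim = grid_dim)
  contour_stats <- list(
    pfc = sensor_overlap_pct(trace, contour_run, cmask, dilate = dilate),
    dmaxc = closure_distance(trace, contour_run),
    area_ratio = contour_area_ratio(bbox, trace$canvas_w, trace$canvas_h)
  )
  hmask <- segment_mask(segmenter, trace, "hands", dim = grid_dim)
  # hand strokes are identified on a finer grid: at 128 x 128 a one-pixel
  # tolerance spans ~19 canvas px and digit strokes brushed by a hand line
  # would be swallowed
  hmask_id <- segment_mask(segmenter, trace, "hands", dim = id_grid_dim)
  hand_runs <- if (sum(hmask_id) > 0) {
    extract_hand_runs(trace, contour_run, hands_mask = hmask_id)
  } else {
    extract_strokes(trace)[0, ]
  }
  pfh <- if (nrow(hand_runs) > 0) {
    sensor_overlap_pct(trace, hand_runs, hmask, dilate = dilate)
  } else {
    NA_real_
  }
  exclude <- as_run_list(contour_run)
  if (exclude_hands && nrow(hand_runs) > 0) {
    exclude <- c(exclude, as_run_list(hand_runs))
  }
  img <- modified_image(trace, exclude_runs = exclude)
  strokes <- extract_strokes(trace)
  excl_starts <- vapply(exclude, function(r) r[[1]], numeric(1))
  include_runs <- strokes[!(strokes$start %in% excl_starts), , drop = FALSE]
  boxes <- find_components(img, trace, include_runs = include_runs,
                           min_extent = min_component_extent)
  dets <- classify_digits(img, boxes, classifier)
  nd <- number_distances(dets, anchors)
  rc_contour <- tryCatch(fit_circle(run_xy(trace, contour_run))$radius,
                         error = function(e) NA_real_)
  rc_numbers <- if (nrow(nd) >= 3L) {
    tryCatch(fit_circle(cbind(x = nd$xm, y = nd$ym))$radius,
             error = function(e) NA_real_)
  } else {
    NA_real_
  }
  numbers_stats <- list(
    n = nrow(dets), labels = dets$label,
    rseq = if (nrow(dets) > 0) rseq_max(as.character(dets$label)) else NA_real_,
    dcn = nd$dcn, rc_numbers = rc_numbers, rc_contour = rc_contour
  )
  hstats <- hands_stats(
    trace, hand_runs, contour_run, anchors,
    hour_target = hour_target, minute_target = minute_target, pfh = pfh,
    eps = thresholds$eps, clock_center = center,
    th_two = thresholds$theta_h1
  )
  sc_contour <- score_contour(contour_stats, thresholds)
  sc_numbers <- score_numbers(numbers_stats, thresholds)
  sc_hands <- score_hands(hstats, thresholds)
  sc_center <- score_center(sc_hands$presence, trace, contour_run, center,
                            thresholds)
  score_total(
    sc_contour, sc_numbers, sc_hands, sc_center,
    stats = list(
      pfc = contour_stats$pfc, dmaxc = contour_stats$dmaxc,
      area_ratio = contour_stats$area_ratio,
      bbox = as.list(bbox), center = as.list(center),
      n = numbers_stats$n, labels = numbers_stats$labels,
      rseq = numbers_stats$rseq, dcn = numbers_stats$dcn,
      rc_contour = rc_contour, rc_numbers = rc_numbers,
      pfh = hstats$pfh, n_hand_runs = hstats$n_runs,
      len_h1 = hstats$len_h1, len_h2 = hstats$len_h2,
      delta_len = hstats$delta_len,
      hour_distance = hstats$hour_distance,
      minute_distance = hstats$minute_distance,
      n_near_center = sc_center$n_near
    ),
    thresholds = thresholds
  )
}

#' Score repeated executions and keep the best copy
#'
#' When a subject executes the task more than once the best copy is scored:
#' the report with the maximum total (earliest on ties).
#'
#' @param traces A list of `sensor_trace` objects.
#' @param ... Passed to [score_clock()].
#' @return The best `cdt_score_report`.
#' @export
score_best <- function(traces, ...) {
  reports <- lapply(traces, score_clock, ...)
  totals <- vapply(reports, function(r) r$total, numeric(1))
  reports[[which.max(totals)]]
}

#' Confusion-matrix evaluation metrics
#'
#' Sensitivity, specificity, accuracy and precision (as percentages) of
#' binary predictions against ground truth; metrics with an undefined
#' denominator are reported as `NA` (printed "-" in the source tables).
#'
#' @param pred,truth Equal-length binary (0/1 or logical) vectors; or pass
#'   `counts` directly.
#' @param counts Optional named list/vector with `tp`, `fp`, `fn`, `tn`,
#'   bypassing `pred`/`truth`.
#' @return A list with `counts` (tp, fp, fn, tn), `sensitivity`,
#'   `specificity`, `accuracy`, `precision`.
#' @export
confusion_metrics <- function(pred = NULL, truth = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (length(pred) != length(truth) || length(pred) == 0L) {
      stop("pred and truth must be nonempty and of equal length")
    }
    p <- as.integer(as.logical(pred)); t <- as.integer(as.logical(truth))
    counts <- list(
      tp = sum(p == 1L & t == 1L), fp = sum(p == 1L & t == 0L),
      fn = sum(p == 0L & t == 1L), tn = sum(p == 0L & t == 0L)
    )
  } else {
    counts <- as.list(counts)
  }
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(counts, list(
    counts = list(tp = tp, fp = fp, fn = fn, tn = tn),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    accuracy = rate(tp + tn, tp + fp + fn + tn),
    precision = rate(tp, tp + fp)
  ))
}
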