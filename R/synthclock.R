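# Synthetic clock drawings: parametric sensor traces with correct
# down/move/up event semantics, rendered raster images, per-stroke ground
# truth, and expected criterion outcomes, plus a catalogue of single
# defects mirroring the failure modes the scoring method targets.

# Digit glyph skeletons: fixed polylines in the unit box (x right, y up),
# one stroke per character.
GLYPHS <- list(
  `0` = cbind(c(0.5, 0.15, 0.15, 0.5, 0.85, 0.85, 0.5),
              c(1, 0.75, 0.25, 0, 0.25, 0.75, 1)),
  `1` = cbind(c(0.25, 0.5, 0.5, 0.25, 0.75),
              c(0.75, 1, 0, 0, 0)),
  `2` = cbind(c(0.1, 0.3, 0.7, 0.9, 0.1, 0.9),
              c(0.75, 1, 1, 0.75, 0, 0)),
  `3` = cbind(c(0.1, 0.8, 0.45, 0.85, 0.6, 0.1),
              c(1, 1, 0.6, 0.35, 0, 0.15)),
  `4` = cbind(c(0.7, 0.7, 0.1, 0.9),
              c(0, 1, 0.35, 0.35)),
  `5` = cbind(c(0.9, 0.1, 0.1, 0.6, 0.9, 0.6, 0.1),
              c(1, 1, 0.6, 0.6, 0.35, 0, 0.1)),
  `6` = cbind(c(0.8, 0.3, 0.15, 0.4, 0.75, 0.8, 0.5, 0.2),
              c(1, 0.5, 0.2, 0, 0.1, 0.35, 0.5, 0.4)),
  `7` = cbind(c(0.1, 0.9, 0.4),
              c(1, 1, 0)),
  `8` = cbind(c(0.5, 0.2, 0.5, 0.8, 0.2, 0.5, 0.8, 0.5),
              c(0.5, 0.75, 1, 0.75, 0.25, 0, 0.25, 0.5)),
  `9` = cbind(c(0.85, 0.5, 0.15, 0.15, 0.5, 0.85, 0.7),
              c(0.75, 1, 0.8, 0.55, 0.45, 0.6, 0))
)

#' Specification of a synthetic clock drawing
#'
#' Describes the drawing conditions: canvas and clock geometry, the contour
#' shape, which numbers are drawn where and in what order, the hands and
#' the time they indicate, optional center dot and stray glyphs, and the
#' sampling model (50 Hz pen with per-stroke speeds and positional jitter).
#' The defaults describe a well-executed clock set to 10 past 11 on the
#' 2400 x 1200 canvas: radius 500 px, numbers at 0.85 of the anchor radius
#' drawn in ascending order, a slow short hour hand (more samples) and a
#' fast long minute hand.
#'
#' @param canvas_w,canvas_h Canvas size in pixels.
#' @param cx,cy Clock center.
#' @param radius Contour radius (half side for polygonal contours).
#' @param contour_shape `"circle"`, `"diamond"`, or `"square"`.
#' @param contour_gap_px Endpoint gap left in the contour (0 = closed).
#' @param digits Clock numbers drawn, a subset of 1..12.
#' @param digit_scale Radial shrink of the anchor positions for glyph
#'   placement (numbers sit inside the rim).
#' @param digit_rotation_deg Rigid rotation of all number placements about
#'   the center (a position defect; anchors do not move).
#' @param digit_order `"ascending"`, `"twelve_first"`, `"quadrant_first"`,
#'   or an integer permutation of `digits`.
#' @param glyph_height Glyph height in px; default `0.18 * radius`.
#' @param extra_glyphs Optional data frame `char`, `x`, `y` of stray
#'   characters drawn after the numbers.
#' @param n_hands 0, 1 (hour only) or 2.
#' @param hour_target,minute_target Numbers the hands should indicate.
#' @param hour_err_deg,minute_err_deg Angular aiming errors.
#' @param hour_frac,minute_frac Hand lengths as fractions of the radius.
#' @param hour_speed,minute_speed Pen speeds (px/s); the hour hand is drawn
#'   slowly so its stroke carries more samples.
#' @param hands_single_stroke Draw both hands as one continuous stroke
#'   (hour tip to center to minute tip).
#' @param center_dot Draw a small dot at the center.
#' @param contour_speed,digit_speed Pen speeds for contour and glyphs.
#' @param rate Sampling rate in Hz.
#' @param jitter_px Gaussian positional jitter (px) applied to every
#'   sample.
#' @param pause_s Pen-up pause between strokes (s).
#' @param seed RNG seed; generation is reproducible given the seed.
#' @return A list of class `clock_spec`.
#' @export
clock_spec <- function(canvas_w = 2400, canvas_h = 1200,
                       cx = 1200, cy = 600, radius = 500,
                       contour_shape = c("circle", "diamond", "square"),
                       contour_gap_px = 0,
                       digits = 1:12, digit_scale = 0.85,
                       digit_rotation_deg = 0,
                       digit_order = "ascending",
                       glyph_height = NULL,
                       extra_glyphs = NULL,
                       n_hands = 2, hour_target = 11, minute_target = 2,
                       hour_err_deg = 0, minute_err_deg = 0,
                       hour_frac = 0.55, minute_frac = 0.75,
                       hour_speed = 400, minute_speed = 1200,
                       hands_single_stroke = FALSE,
                       center_dot = FALSE,
                       contour_speed = 1200, digit_speed = 600,
                       rate = 50, jitter_px = 1.5, pause_s = 0.3,
                       seed = 1L) {
  contour_shape <- match.arg(contour_shape)
  stopifnot(radius > 0, all(digits %in% 1:12), n_hands %in% 0:2)
  if (n_hands == 2 && hour_frac <= 0 && minute_frac <= 0) {
    stop("impossible spec: two hands with zero length")
  }
  # glyph_height = NULL resolves to 0.18 * radius at generation time, so
  # transforms that rescale the clock keep proportionate glyphs
  structure(as.list(environment()), class = "clock_spec")
}

resample_path <- function(pts, spacing) {
  seg <- sqrt(rowSums(diff(pts)^2))
  L <- sum(seg)
  if (L < 1e-9) return(pts[c(1, nrow(pts)), , drop = FALSE])
  s <- unique(c(seq(0, L, by = spacing), L))
  cum <- c(0, cumsum(seg))
  x <- stats::approx(cum, pts[, 1], xout = s)$y
  y <- stats::approx(cum, pts[, 2], xout = s)$y
  cbind(x, y)
}

circle_path <- function(cx, cy, r, gap_px = 0, start_deg = 45) {
  # gap (if any) centered at start_deg so the bbox extremes are untouched
  half <- if (gap_px > 0) asin(min(1, gap_px / (2 * r))) else 0
  a0 <- start_deg * pi / 180 + half
  a1 <- start_deg * pi / 180 + 2 * pi - half
  ang <- seq(a0, a1, length.out = 720)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

square_path <- function(cx, cy, r) {
  # start and close mid right edge so the loop endpoints coincide
  cbind(cx + c(r, r, -r, -r, r, r), cy + c(0, r, r, -r, -r, 0))
}

diamond_path <- function(cx, cy, r) {
  cbind(cx + c(r, 0, -r, 0, r), cy + c(0, r, 0, -r, 0))
}

resolved_glyph_height <- function(spec) {
  if (is.null(spec$glyph_height)) 0.18 * spec$radius else spec$glyph_height
}

digit_angle <- function(d) (90 - 30 * d) * pi / 180

rotate_about <- function(p, center, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sweep(sweep(p, 2, center) %*% t(R), 2, center, `+`)
}

glyph_path <- function(char, xc, yc, h) {
  g <- GLYPHS[[as.character(char)]]
  w <- 0.6 * h
  cbind(xc - w / 2 + g[, 1] * w, yc - h / 2 + g[, 2] * h)
}

resolve_order <- function(spec) {
  d <- spec$digits
  ord <- spec$digit_order
  if (is.character(ord)) {
    ord <- switch(ord,
      ascending = sort(d),
      twelve_first = c(intersect(12, d), sort(setdiff(d, 12))),
      quadrant_first = c(
        intersect(c(12, 3, 6, 9), d),
        sort(setdiff(d, c(12, 3, 6, 9)))
      ),
      as.integer(strsplit(ord, ",")[[1]])
    )
  }
  stopifnot(setequal(ord, d))
  ord
}

# Planned placement of each drawn number's glyph-group center.
planned_positions <- function(spec, anchors) {
  ctr <- c(spec$cx, spec$cy)
  pos <- sweep((anchors - matrix(ctr, 12, 2, byrow = TRUE)) * spec$digit_scale,
               2, ctr, `+`)
  if (spec$digit_rotation_deg != 0) {
    pos <- rotate_about(pos, ctr, spec$digit_rotation_deg)
  }
  dimnames(pos) <- dimnames(anchors)
  pos
}

hand_direction <- function(anchors, target, center, err_deg) {
  v <- anchors[as.character(target), ] - center
  v <- v / sqrt(sum(v^2))
  th <- err_deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

#' Generate a synthetic clock drawing
#'
#' Produces a sensor trace (down/move/up runs at the specified sampling
#' rate), the rendered canvas-resolution raster, and the ground truth:
#' per-stroke roles and character labels, role masks at 128 x 128, and the
#' expected outcome of each of the 13 scoring criteria, derived
#' analytically from the drawing plan.
#'
#' @param spec A [clock_spec()].
#' @return A list of class `synth_clock` with elements `trace`
#'   (`sensor_trace`), `image` (canvas-resolution 0/1 matrix), and `truth`
#'   (class `clock_truth`: `roles` data frame, `masks`, `expected` named
#'   0/1 vector, `expected_scores`, `spec`).
#' @export
generate_clock <- function(spec) {
  stopifnot(inherits(spec, "clock_spec"))
  old_seed <- get0(".Random.seed", globalenv(), mode = "integer",
                   inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  ctr <- c(spec$cx, spec$cy)
  bbox_plan <- c(
    xmin = spec$cx - spec$radius, xmax = spec$cx + spec$radius,
    ymin = spec$cy - spec$radius, ymax = spec$cy + spec$radius
  )
  anchors <- digit_anchors(bbox_plan)
  positions <- planned_positions(spec, anchors)

  strokes <- list() # each: list(path, speed, role, number, char_index, char)
  add <- function(path, speed, role, number = NA, char_index = NA,
                  char = NA) {
    strokes[[length(strokes) + 1L]] <<- list(
      path = path, speed = speed, role = role, number = number,
      char_index = char_index, char = char
    )
  }

  contour_path <- switch(spec$contour_shape,
    circle = circle_path(spec$cx, spec$cy, spec$radius, spec$contour_gap_px),
    diamond = diamond_path(spec$cx, spec$cy, spec$radius),
    square = square_path(spec$cx, spec$cy, spec$radius)
  )
  add(contour_path, spec$contour_speed, "contour")

  h <- resolved_glyph_height(spec)
  w <- 0.6 * h
  gap <- 0.35 * w
  for (d in resolve_order(spec)) {
    chars <- strsplit(as.character(d), "")[[1]]
    tw <- length(chars) * w + (length(chars) - 1) * gap
    for (i in seq_along(chars)) {
      xc <- positions[as.character(d), "x"] - tw / 2 + (i - 0.5) * w +
        (i - 1) * gap
      add(glyph_path(chars[i], xc, positions[as.character(d), "y"], h),
          spec$digit_speed, "digit", number = d, char_index = i,
          char = chars[i])
    }
  }
  if (!is.null(spec$extra_glyphs)) {
    for (i in seq_len(nrow(spec$extra_glyphs))) {
      g <- spec$extra_glyphs[i, ]
      add(glyph_path(g$char, g$x, g$y, h), spec$digit_speed, "extra",
          char = as.character(g$char))
    }
  }

  dir_h <- hand_direction(anchors, spec$hour_target, ctr, spec$hour_err_deg)
  dir_m <- hand_direction(anchors, spec$minute_target, ctr,
                          spec$minute_err_deg)
  period0 <- 1 / spec$rate
  if (spec$n_hands == 2 && isTRUE(spec$hands_single_stroke)) {
    # both hands in one continuous stroke: hour tip -> center -> minute
    # tip, each segment at its own pen speed
    tip_h <- ctr + spec$hour_frac * spec$radius * dir_h
    tip_m <- ctr + spec$minute_frac * spec$radius * dir_m
    seg1 <- resample_path(rbind(tip_h, ctr), spec$hour_speed * period0)
    seg2 <- resample_path(rbind(ctr, tip_m), spec$minute_speed * period0)
    add(rbind(seg1, seg2[-1, , drop = FALSE]), NA, "hand_pair")
  } else {
    if (spec$n_hands >= 1) {
      tip <- ctr + spec$hour_frac * spec$radius * dir_h
      add(rbind(ctr, tip), spec$hour_speed, "hand_hour")
    }
    if (spec$n_hands == 2) {
      tip <- ctr + spec$minute_frac * spec$radius * dir_m
      add(rbind(ctr, tip), spec$minute_speed, "hand_minute")
    }
  }
  if (spec$center_dot) {
    ang <- seq(0, 2 * pi, length.out = 9)
    add(cbind(spec$cx + 6 * cos(ang), spec$cy + 6 * sin(ang)),
        spec$digit_speed, "center_dot")
  }

  # Sample every stroke at the pen rate, with positional jitter, advancing
  # a global clock with a pen-up pause between strokes.
  period <- 1 / spec$rate
  t_now <- 0
  recs <- vector("list", length(strokes))
  roles <- vector("list", length(strokes))
  idx0 <- 0L
  for (k in seq_along(strokes)) {
    st <- strokes[[k]]
    p <- if (is.na(st$speed)) st$path else resample_path(st$path, st$speed * period)
    if (nrow(p) < 3L) p <- p[c(1, rep(1, 3 - nrow(p)), seq_len(nrow(p))[-1]), ]
    n <- nrow(p)
    x <- pmin(pmax(p[, 1] + stats::rnorm(n, 0, spec$jitter_px), 0),
              spec$canvas_w)
    y <- pmin(pmax(p[, 2] + stats::rnorm(n, 0, spec$jitter_px), 0),
              spec$canvas_h)
    t <- t_now + period * (seq_len(n) - 1)
    e <- c(EVENT_DOWN, rep(EVENT_MOVE, n - 2L), EVENT_UP)
    recs[[k]] <- data.frame(t = t, x = x, y = y, e = e)
    roles[[k]] <- data.frame(
      stroke = k, start = idx0 + 1L, end = idx0 + n,
      role = st$role, number = st$number, char_index = st$char_index,
      char = st$char, t0 = t[1], t1 = t[n], stringsAsFactors = FALSE
    )
    idx0 <- idx0 + n
    t_now <- t[n] + spec$pause_s
  }
  trace <- parse_trace(do.call(rbind, recs), spec$canvas_w, spec$canvas_h,
                       sample_period = period)
  roles <- do.call(rbind, roles)

  truth <- structure(
    list(
      roles = roles,
      masks = list(
        contour = rasterize_trace(trace, roles[roles$role == "contour",
                                               c("start", "end")]),
        hands = rasterize_trace(trace, roles[grepl("^hand", roles$role),
                                             c("start", "end")])
      ),
      expected = expected_criteria(spec, anchors, positions,
                                   resample_path(contour_path, 5),
                                   dir_h, dir_m),
      spec = spec
    ),
    class = "clock_truth"
  )
  truth$expected_scores <- expected_scores(truth$expected)
  structure(
    list(
      trace = trace,
      image = rasterize_trace(trace, extract_strokes(trace),
                              dim = c(spec$canvas_h, spec$canvas_w)),
      truth = truth
    ),
    class = "synth_clock"
  )
}

# Planned character sequence of the drawing (digits in drawing order, then
# stray glyphs).
planned_chars <- function(spec) {
  chars <- unlist(strsplit(as.character(resolve_order(spec)), ""))
  if (!is.null(spec$extra_glyphs)) {
    chars <- c(chars, as.character(spec$extra_glyphs$char))
  }
  chars
}

# Nearest ideal-contour point to the ray from the center along `dir`
# beyond the hand tip, and its distance to the target anchor.
expected_hit_distance <- function(contour_path, center, dir, tip_len,
                                  anchors, target) {
  rel <- sweep(contour_path, 2, center)
  t_proj <- rel[, 1] * dir[1] + rel[, 2] * dir[2]
  perp <- abs(rel[, 1] * dir[2] - rel[, 2] * dir[1])
  cand <- t_proj >= tip_len
  if (!any(cand)) cand <- t_proj > 0
  perp[!cand] <- Inf
  p <- contour_path[which.min(perp), ]
  point_distance(p, anchors[as.character(target), ])
}

expected_criteria <- function(spec, anchors, positions, contour_path,
                              dir_h, dir_m) {
  th <- default_thresholds()
  ctr <- c(spec$cx, spec$cy)
  spacing <- spec$contour_speed / spec$rate
  end_gap <- max(spec$contour_gap_px, spacing)

  chars <- planned_chars(spec)
  presence <- length(chars) == 15L && sum(chars == "1") == 5L &&
    sum(chars == "2") == 2L
  order_ok <- length(chars) > 0 && rseq_max(chars) >= th$theta_n

  drawn <- as.character(spec$digits)
  dcn <- sqrt(rowSums((positions[drawn, , drop = FALSE] -
                         anchors[drawn, , drop = FALSE])^2))
  if (!is.null(spec$extra_glyphs)) {
    for (i in seq_len(nrow(spec$extra_glyphs))) {
      g <- spec$extra_glyphs[i, ]
      v <- suppressWarnings(as.integer(as.character(g$char)))
      a <- if (!is.na(v) && v >= 1 && v <= 12) {
        anchors[as.character(v), , drop = FALSE]
      } else {
        anchors
      }
      dcn <- c(dcn, min(sqrt((a[, "x"] - g$x)^2 + (a[, "y"] - g$y)^2)))
    }
  }
  position_ok <- length(dcn) > 0 && mean(dcn <= th$l_dc) > th$theta_dc

  within_ok <- FALSE
  if (length(spec$digits) >= 3L) {
    rc_n <- tryCatch(fit_circle(positions[drawn, , drop = FALSE])$radius,
                     error = function(e) NA_real_)
    rc_c <- fit_circle(contour_path)$radius
    within_ok <- isTRUE(rc_n < rc_c)
  }

  two_hands <- spec$n_hands == 2
  one_hand <- spec$n_hands == 1
  len_h <- spec$hour_frac * spec$radius
  len_m <- spec$minute_frac * spec$radius
  proportion <- two_hands && abs(len_m - len_h) > th$theta_pr

  hour_ok <- FALSE
  minute_ok <- FALSE
  if (spec$n_hands >= 1) {
    dh <- expected_hit_distance(contour_path, ctr, dir_h, len_h, anchors,
                                spec$hour_target)
    hour_ok <- dh < th$eps
    dir_for_minute <- if (two_hands) dir_m else dir_h
    len_for_minute <- if (two_hands) len_m else len_h
    dm <- expected_hit_distance(contour_path, ctr, dir_for_minute,
                                len_for_minute, anchors,
                                spec$minute_target)
    minute_ok <- dm < th$eps
  }
  center_ok <- spec$n_hands >= 1 || isTRUE(spec$center_dot)

  out <- c(
    circular = spec$contour_shape == "circle",
    closed = end_gap < th$theta_c2,
    sized = (2 * spec$radius)^2 / (spec$canvas_w * spec$canvas_h) >=
      th$theta_c3,
    num_presence = presence, num_order = order_ok,
    num_position = position_ok, num_within = within_ok,
    two_hands = two_hands, one_hand = one_hand, proportion = proportion,
    hour = hour_ok, minute = minute_ok,
    center = center_ok
  )
  storage.mode(out) <- "integer"
  out
}

expected_scores <- function(ex) {
  c(
    contour = sum(ex[c("circular", "closed", "sized")]),
    numbers = sum(ex[c("num_presence", "num_order", "num_position",
                       "num_within")]),
    hands = 2L * ex[["two_hands"]] + ex[["one_hand"]] +
      sum(ex[c("proportion", "hour", "minute")]),
    center = ex[["center"]]
  )
}

#' Catalogue of single-defect drawing transforms
#'
#' Named transforms of a [clock_spec()], each introducing one drawing
#' defect, together with the set of scoring criteria the defect is expected
#' to change relative to the well-executed clock. Used for the
#' defect-isolation property: scoring a transformed drawing with oracle
#' backends must flip exactly the declared criteria.
#'
#' @return A named list; each element has `transform`
#'   (`function(spec) -> spec`) and `affected` (character vector of
#'   criterion names).
#' @export
defect_catalogue <- function() {
  mod <- function(...) {
    changes <- list(...)
    function(spec) {
      spec[names(changes)] <- changes
      spec
    }
  }
  list(
    open_contour = list(
      transform = mod(contour_gap_px = 120),
      affected = "closed"
    ),
    polygonal_contour = list(
      # a diamond: its edges pass through all twelve anchors, so only the
      # circularity criterion is disturbed
      transform = mod(contour_shape = "diamond"),
      affected = "circular"
    ),
    undersized_contour = list(
      transform = mod(radius = 225),
      affected = "sized"
    ),
    missing_digits = list(
      transform = mod(digits = setdiff(1:12, 7)),
      affected = "num_presence"
    ),
    extra_digits = list(
      transform = function(spec) {
        ang <- digit_angle(5) # stray mark in the lower-right interior
        spec$extra_glyphs <- data.frame(
          char = "7",
          x = spec$cx + 0.45 * spec$radius * cos(ang),
          y = spec$cy + 0.45 * spec$radius * sin(ang)
        )
        spec
      },
      affected = "num_presence"
    ),
    shuffled_order = list(
      transform = mod(digit_order = paste(12:1, collapse = ",")),
      affected = "num_order"
    ),
    off_anchor_digits = list(
      transform = mod(digit_rotation_deg = 20),
      affected = "num_position"
    ),
    digits_outside_contour = list(
      transform = mod(digit_scale = 1.35),
      affected = c("num_position", "num_within")
    ),
    one_hand = list(
      transform = mod(n_hands = 1),
      affected = c("two_hands", "one_hand", "proportion", "minute")
    ),
    no_hands = list(
      transform = mod(n_hands = 0, center_dot = TRUE),
      affected = c("two_hands", "proportion", "hour", "minute")
    ),
    equal_length_hands = list(
      transform = mod(hour_frac = 0.65, minute_frac = 0.65),
      affected = "proportion"
    ),
    wrong_time = list(
      transform = mod(hour_err_deg = 90, minute_err_deg = 90),
      affected = c("hour", "minute")
    ),
    no_center_evidence = list(
      transform = mod(n_hands = 0, center_dot = FALSE),
      affected = c("two_hands", "proportion", "hour", "minute", "center")
    )
  )
}

#' Apply a catalogue defect to a spec
#' @param spec A [clock_spec()].
#' @param name A name from [defect_catalogue()].
#' @return The transformed `clock_spec`.
#' @export
apply_defect <- function(spec, name) {
  cat <- defect_catalogue()
  if (!name %in% names(cat)) stop("unknown defect: ", name)
  cat[[name]]$transform(spec)
}
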