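test_that("parse_trace validates the event stream", {
  tr <- parse_trace(data.frame(t = c(0, 0.02, 0.04), x = c(10, 12, 13),
                               y = c(10, 11, 12), e = c(-1, 0, 1)))
  expect_s3_class(tr, "sensor_trace")
  expect_equal(n_strokes(tr), 1L)

  expect_error(parse_trace(data.frame(t = 0, x = 1, y = 1, e = 5)),
               "invalid event code")
  expect_error(
    parse_trace(data.frame(t = c(0, 0.02, 0.04), x = 1:3, y = 1:3,
                           e = c(-1, -1, 1))),
    "unterminated stroke"
  )
  expect_error(
    parse_trace(data.frame(t = c(0, 0.02), x = 1:2, y = 1:2, e = c(-1, 0))),
    "unterminated stroke"
  )
  expect_error(
    parse_trace(data.frame(t = c(0.04, 0.02, 0), x = 1:3, y = 1:3,
                           e = c(-1, 0, 1))),
    "decreasing time stamps"
  )
  expect_error(parse_trace(data.frame()), "empty")
  expect_warning(
    parse_trace(data.frame(t = c(0, 1, 2), x = 1:3, y = 1:3,
                           e = c(-1, 0, 1))),
    "sample period"
  )
})

test_that("extract_strokes partitions the samples in temporal order", {
  set.seed(101)
  for (trial in 1:20) {
    k <- sample(1:6, 1)
    strokes <- lapply(seq_len(k), function(i) {
      n <- sample(3:40, 1)
      cbind(runif(n, 0, 2400), runif(n, 0, 1200))
    })
    tr <- make_trace(strokes)
    rs <- extract_strokes(tr)
    expect_equal(nrow(rs), k)
    covered <- unlist(lapply(seq_len(k), function(i) rs$start[i]:rs$end[i]))
    expect_identical(covered, seq_len(nrow(tr$samples)))
    expect_true(all(tr$samples$e[rs$start] == -1L))
    expect_true(all(tr$samples$e[rs$end] == 1L))
  }
})

test_that("find_contour_run picks the longest move run, earliest on ties", {
  sizes <- c(30, 12, 9)
  tr <- make_trace(lapply(sizes, function(n) cbind(seq_len(n), seq_len(n))))
  run <- find_contour_run(tr)
  expect_equal(unname(run), c(1L, 30L))

  tied <- make_trace(list(cbind(1:10, 1:10), cbind(101:110, 1:10)))
  expect_equal(find_contour_run(tied)[["start"]], 1L)
  expect_error(find_contour_run(empty_trace()), "no stroke")

  ck <- generate_clock(clock_spec(seed = 5))
  run <- find_contour_run(ck$trace)
  ctruth <- ck$truth$roles[ck$truth$roles$role == "contour", ]
  expect_equal(unname(run), c(ctruth$start, ctruth$end))
  strokes <- extract_strokes(ck$trace)
  expect_true(any(strokes$start == run[["start"]] &
                    strokes$end == run[["end"]]))
})

test_that("contour_bbox and contour_center follow the extremes", {
  sq <- make_trace(list(rbind(c(100, 100), c(100, 900), c(900, 900),
                              c(900, 100))))
  bb <- contour_bbox(sq, c(1, 4))
  expect_equal(unname(bb), c(100, 900, 100, 900))
  expect_equal(unname(contour_center(bb)), c(500, 500))

  pt <- make_trace(list(rbind(c(5, 7), c(5, 7), c(5, 7))))
  bbp <- contour_bbox(pt, c(1, 3))
  expect_equal(bbp[["xmin"]], bbp[["xmax"]])
  expect_equal(unname(contour_center(bbp)), c(5, 7))

  circ <- make_trace(list(circle_points(1200, 600, 500, n = 360)))
  bbc <- contour_bbox(circ, c(1, 360))
  spacing <- 2 * pi * 500 / 360
  expect_equal(unname(bbc), c(700, 1700, 100, 1100), tolerance = 0.01,
               ignore_attr = TRUE)
  expect_lt(max(abs(bbc - c(700, 1700, 100, 1100))), spacing)

  expect_equal(unname(contour_center(c(xmin = 0, xmax = 1200, ymin = 0,
                                       ymax = 1200))), c(600, 600))
})

test_that("digit_anchors reproduces the canonical dial positions", {
  bb <- c(xmin = 0, xmax = 1200, ymin = 0, ymax = 1200)
  a <- digit_anchors(bb)
  expect_equal(unname(a["3", ]), c(1200, 600))
  expect_equal(unname(a["6", ]), c(600, 0))
  expect_equal(unname(a["9", ]), c(0, 600))
  expect_equal(unname(a["12", ]), c(600, 1200))
  expect_equal(unname(a["1", ]), c(800, 1000))
  expect_equal(unname(a["2", ]), c(1000, 800))

  ctr <- contour_center(bb)
  for (k in 1:6) {
    expect_equal(unname(a[as.character(k), ] + a[as.character(k + 6), ]),
                 unname(2 * ctr))
  }
})

test_that("contour geometry is translation-equivariant", {
  set.seed(7)
  xy <- circle_points(800, 500, 300, n = 120)
  tr <- make_trace(list(xy))
  d <- c(137, -62)
  tr2 <- make_trace(list(sweep(xy, 2, -d)))
  bb1 <- contour_bbox(tr, c(1, 120)); bb2 <- contour_bbox(tr2, c(1, 120))
  expect_equal(unname(bb2 - bb1), c(d[1], d[1], d[2], d[2]))
  expect_equal(unname(contour_center(bb2) - contour_center(bb1)), d)
  expect_equal(unname(digit_anchors(bb2) - digit_anchors(bb1)),
               matrix(rep(d, each = 12), 12))
})

test_that("closure_distance measures endpoint and lift gaps", {
  closed <- make_trace(list(rbind(circle_points(600, 600, 200, 100),
                                  c(800, 600))))
  expect_equal(closure_distance(closed, c(1, 101)), 0, tolerance = 1e-9)

  # arc leaving a known chord gap
  r <- 500; gap <- 55.6
  half <- asin(gap / (2 * r))
  arc <- circle_points(1200, 600, r, n = 200, from = half,
                       to = 2 * pi - half)
  tr <- make_trace(list(arc))
  expect_equal(closure_distance(tr, c(1, 200)), gap, tolerance = 1e-6)

  # two arcs: the 120-px lift gap dominates a 5-px endpoint gap
  a1 <- rbind(c(0, 0), c(100, 0), c(200, 0))
  a2 <- rbind(c(200, 120), c(100, 200), c(5, 0))
  two <- make_trace(list(a1, a2))
  expect_equal(closure_distance(two, c(1, 6)), 120)
  expect_error(closure_distance(two, c(4, 2)), "empty range")
})

test_that("contour_area_ratio scales with the bounding box", {
  expect_equal(contour_area_ratio(c(xmin = 0, xmax = 2400, ymin = 0,
                                    ymax = 1200), 2400, 1200), 1)
  expect_equal(contour_area_ratio(c(xmin = 0, xmax = 1200, ymin = 0,
                                    ymax = 600), 2400, 1200), 0.25)
  expect_equal(contour_area_ratio(c(xmin = 0, xmax = 900, ymin = 0,
                                    ymax = 900), 2400, 1200), 0.28125)
  expect_error(contour_area_ratio(c(xmin = 0, xmax = 1, ymin = 0,
                                    ymax = 1), 0, 0), "zero canvas")
})

test_that("fit_circle is exact on circles and matches the circumcircle", {
  p <- circle_points(5, 5, 2, n = 36)
  f <- fit_circle(p)
  expect_equal(unname(f$center), c(5, 5), tolerance = 1e-6)
  expect_equal(f$radius, 2, tolerance = 1e-6)

  expect_error(fit_circle(cbind(1:5, 2 * (1:5) + 1)), "collinear")
  expect_error(fit_circle(cbind(1:2, 1:2)), "at least 3")

  set.seed(31)
  for (trial in 1:15) {
    ctr <- runif(2, -50, 50)
    r <- runif(1, 1, 40)
    ang <- sort(runif(3, 0, 2 * pi))
    if (min(diff(ang)) < 0.2) next # avoid near-degenerate triples
    pts <- cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
    f <- fit_circle(pts)
    o <- circumcircle(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(unname(f$center), o$center, tolerance = 1e-6)
    expect_equal(f$radius, o$radius, tolerance = 1e-6)
  }
})

test_that("fit_circle recovers the radius under pixel noise", {
  set.seed(42)
  p <- circle_points(1200, 600, 450, n = 360)
  noisy <- p + matrix(rnorm(720, 0, 1), ncol = 2)
  f <- fit_circle(noisy)
  expect_lt(abs(f$radius - 450), 0.5)
})

test_that("fit_line is a total-least-squares fit stable for vertical data", {
  p <- cbind(seq(-5, 5, by = 0.5), 2 * seq(-5, 5, by = 0.5) + 1)
  l <- fit_line(p)
  expect_lt(line_distance(l, rbind(c(0, 1)))[1], 1e-9)
  expect_equal(abs(l$direction[["y"]] / l$direction[["x"]]), 2,
               tolerance = 1e-9)

  v <- fit_line(cbind(rep(600, 20), seq_len(20)))
  expect_equal(abs(unname(v$direction)), c(0, 1), tolerance = 1e-9)

  expect_error(fit_line(cbind(rep(1, 5), rep(2, 5))), "identical")

  set.seed(9)
  base <- cbind(seq(0, 99), 0.7 * seq(0, 99) + 3)
  noisy <- base + matrix(rnorm(200, 0, 0.5), ncol = 2)
  l2 <- fit_line(noisy)
  ang <- atan2(l2$direction[["y"]], l2$direction[["x"]]) - atan2(0.7, 1)
  expect_lt(abs(ang) * 180 / pi, 1)
})
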