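th <- default_thresholds()

test_that("contour scoring reproduces the worked cases and boundaries", {
  expect_equal(score_contour(list(pfc = 95.74, dmaxc = 9.67,
                                  area_ratio = 0.339), th)$sum, 3)
  expect_equal(score_contour(list(pfc = 89.66, dmaxc = 55.56,
                                  area_ratio = 0.337), th)$sum, 2)
  expect_equal(score_contour(list(pfc = 52.31, dmaxc = 51.56,
                                  area_ratio = 0.237), th)$sum, 1)
  expect_equal(score_contour(list(pfc = 97.44, dmaxc = 32.01,
                                  area_ratio = 0.061), th)$sum, 2)
  expect_equal(score_contour(list(pfc = 0, dmaxc = 1e6,
                                  area_ratio = 0), th)$sum, 0)

  # comparison directions pinned at exact threshold equality
  at <- score_contour(list(pfc = 75, dmaxc = 50, area_ratio = 0.1), th)
  expect_equal(at$circular, 1L) # pfc >= theta_c1
  expect_equal(at$closed, 0L)   # closed iff dmaxc < theta_c2
  expect_equal(at$sized, 1L)    # ratio >= theta_c3
  expect_equal(score_contour(list(pfc = NA, dmaxc = NA, area_ratio = NA),
                             th)$sum, 0)
})

test_that("numbers scoring reproduces the worked cases and boundaries", {
  full_labels <- c(1:9, 1, 0, 1, 1, 1, 2)
  fig8a <- list(
    n = 15L, labels = full_labels, rseq = 100,
    dcn = c(46.0, 66.9, 27.5, 32.0, 33.0, 16.6, 119.0, 123.0, 38.0,
            51.1, 40.7, 22.6),
    rc_numbers = 351.6, rc_contour = 454.7
  )
  expect_equal(score_numbers(fig8a, th)$sum, 4)

  fig8e <- list(
    n = 13L, labels = c(1:9, 1, 0, 1, 2), rseq = 85.71,
    dcn = c(497.8, 462.5, 350.7, 399.3, 415.1, 254.5, 208.5, 1037.8,
            836.2, 792.1, 743.6, 952.1),
    rc_numbers = 193.2, rc_contour = 319.8
  )
  expect_equal(score_numbers(fig8e, th)$sum, 2)

  fig8h <- list(
    n = 5L, labels = c(1, 2, 2, 5, 8), rseq = 42.10,
    dcn = c(545.5, 920.4, 1167.1, 1739.7, 1644.2, 1464.5, 1338.6,
            1095.1, 715.6, 630.7, 734.1, 153.0),
    rc_numbers = 446.3, rc_contour = 601.1
  )
  expect_equal(score_numbers(fig8h, th)$sum, 1)

  empty <- list(n = 0L, labels = integer(0), rseq = NA_real_,
                dcn = numeric(0), rc_numbers = NA_real_,
                rc_contour = 450)
  expect_equal(score_numbers(empty, th)$sum, 0)

  # boundary pins: order >=, position strictly >, within strictly <
  base <- fig8a
  base$rseq <- 65
  expect_equal(score_numbers(base, th)$order, 1L)
  base$dcn <- c(rep(100, 13), rep(101, 7)) # fraction exactly 0.65
  expect_equal(score_numbers(base, th)$position, 0L)
  base$rc_numbers <- base$rc_contour
  expect_equal(score_numbers(base, th)$within, 0L)
})

test_that("hands scoring reproduces the worked cases and boundaries", {
  fig9a <- list(pfh = 100, delta_len = 89.4, hour_distance = 123.9,
                minute_distance = 86.6)
  expect_equal(score_hands(fig9a, th)$sum, 5)

  fig9e <- list(pfh = 91.1, delta_len = 37.8, hour_distance = 610.1,
                minute_distance = 540.1)
  expect_equal(score_hands(fig9e, th)$sum, 3)

  fig9f <- list(pfh = 64.4, delta_len = NA, hour_distance = 133.6,
                minute_distance = 1888.6)
  s9f <- score_hands(fig9f, th)
  expect_equal(s9f$presence, 1L)
  expect_equal(s9f$sum, 2)

  none <- list(pfh = NA_real_, delta_len = NA, hour_distance = NA,
               minute_distance = NA)
  expect_equal(score_hands(none, th)$sum, 0)

  # strict > on presence and proportion, strict < on hit distances
  eq <- score_hands(list(pfh = 65, delta_len = 30, hour_distance = 200,
                         minute_distance = 200), th)
  expect_equal(eq$presence, 1L) # pfh == theta_h1 falls to the one-hand rule
  expect_equal(eq$proportion, 0L)
  expect_equal(eq$hour, 0L)
  expect_equal(score_hands(list(pfh = 50, delta_len = 99,
                                hour_distance = 1, minute_distance = 1),
                           th)$presence, 0L)
  # two-hands and one-hand criteria are mutually exclusive
  two <- score_hands(fig9a, th)
  expect_equal(two$two_hands + two$one_hand, 1L)
})

test_that("center scoring accepts hands or near-center evidence", {
  expect_equal(score_center(2L, th = th)$center, 1L)
  expect_equal(score_center(1L, th = th)$center, 1L)

  dot <- make_trace(list(circle_points(1200, 600, 500, 100),
                         rbind(c(1205, 603), c(1195, 598))))
  crun <- find_contour_run(dot)
  ctr <- contour_center(contour_bbox(dot, crun))
  got <- score_center(0L, dot, crun, ctr, th)
  expect_equal(got$center, 1L)
  expect_gt(got$n_near, 0)

  far <- make_trace(list(circle_points(1200, 600, 500, 100),
                         rbind(c(1600, 600), c(1650, 600))))
  crun2 <- find_contour_run(far)
  expect_equal(score_center(0L, far, crun2,
                            contour_center(contour_bbox(far, crun2)),
                            th)$center, 0L)
})

test_that("score_total assembles criteria, sums and total", {
  rep0 <- score_total(
    score_contour(list(pfc = 95.74, dmaxc = 9.67, area_ratio = 0.339), th),
    score_numbers(list(n = 0L, labels = integer(0), rseq = NA,
                       dcn = numeric(0), rc_numbers = NA,
                       rc_contour = NA), th),
    score_hands(list(pfh = NA, delta_len = NA, hour_distance = NA,
                     minute_distance = NA), th),
    score_center(0L, th = th)
  )
  expect_equal(rep0$total, 3)
  expect_equal(unname(rep0$scores), c(3, 0, 0, 0))
  expect_equal(rep0$total, sum(rep0$scores))
  expect_length(rep0$criteria, 13)
})

test_that("scores are monotone in the driving statistics", {
  set.seed(23)
  for (trial in 1:30) {
    pfc <- runif(2, 0, 100)
    s <- sapply(sort(pfc, decreasing = TRUE), function(p) {
      score_contour(list(pfc = p, dmaxc = 20, area_ratio = 0.3), th)$sum
    })
    expect_gte(s[1], s[2])

    d1 <- runif(12, 0, 300)
    d2 <- d1 + runif(12, 0, 200) # every distance increased
    base <- list(n = 15L, labels = c(1:9, 1, 0, 1, 1, 1, 2), rseq = 90,
                 rc_numbers = 300, rc_contour = 450)
    n1 <- score_numbers(c(base, list(dcn = d1)), th)$sum
    n2 <- score_numbers(c(base, list(dcn = d2)), th)$sum
    expect_gte(n1, n2)

    h <- runif(2, 0, 600)
    hlo <- score_hands(list(pfh = 90, delta_len = 50,
                            hour_distance = min(h),
                            minute_distance = min(h)), th)$sum
    hhi <- score_hands(list(pfh = 90, delta_len = 50,
                            hour_distance = max(h),
                            minute_distance = max(h)), th)$sum
    expect_gte(hlo, hhi)
  }
})

test_that("thresholds validate, override, and load from config", {
  expect_error(default_thresholds(bogus = 1), "unknown threshold")
  expect_error(default_thresholds(theta_h2 = 70), "theta_h2")
  custom <- default_thresholds(theta_c2 = 40)
  expect_equal(custom$theta_c2, 40)
  expect_equal(custom$theta_c1, 75)

  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(eps = 150, theta_n = 70), cfg,
                       auto_unbox = TRUE)
  loaded <- load_thresholds(cfg)
  expect_equal(loaded$eps, 150)
  expect_equal(loaded$theta_n, 70)
  expect_equal(loaded$l_dc, 100)
  # the report records the thresholds used
  ck <- generate_clock(clock_spec(seed = 12))
  r <- score_synth(ck, thresholds = loaded)
  expect_equal(r$thresholds$eps, 150)
})

test_that("confusion_metrics matches the published metric arithmetic", {
  m <- confusion_metrics(counts = list(tp = 159, fp = 3, fn = 19, tn = 38))
  expect_equal(m$sensitivity, 89.33, tolerance = 5e-5)
  expect_equal(m$specificity, 92.68, tolerance = 5e-5)
  expect_equal(m$accuracy, 89.95, tolerance = 5e-5)
  expect_equal(m$precision, 98.15, tolerance = 5e-5)

  allpos <- confusion_metrics(pred = rep(1, 5), truth = rep(1, 5))
  expect_equal(allpos$sensitivity, 100)
  expect_true(is.na(allpos$specificity))
  expect_error(confusion_metrics(pred = c(1, 0), truth = c(1, 0, 1)),
               "equal length")

  # vector route agrees with the count route
  set.seed(5)
  p <- rbinom(40, 1, 0.6); t <- rbinom(40, 1, 0.6)
  mv <- confusion_metrics(p, t)
  mc <- confusion_metrics(counts = mv$counts)
  expect_equal(mv, mc)
})

test_that("score_best keeps the best of repeated executions", {
  good <- generate_clock(clock_spec(seed = 13))
  r_good <- score_synth(good)
  picked <- score_best(list(empty_trace(), good$trace),
                       segmenter = oracle_segmenter(good$truth),
                       classifier = oracle_classifier(good$truth))
  expect_equal(picked$total, r_good$total)
  expect_gt(picked$total, 0)
})
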