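test_that("modified_image excludes exactly the requested strokes", {
  contour_only <- make_trace(list(circle_points(1200, 600, 500, n = 120)))
  img <- modified_image(contour_only, exclude_runs = c(1, 120))
  expect_equal(sum(img), 0)

  ck <- generate_clock(clock_spec(n_hands = 0, center_dot = FALSE,
                                  seed = 6))
  crun <- find_contour_run(ck$trace)
  img2 <- modified_image(ck$trace, exclude_runs = crun)
  digit_runs <- ck$truth$roles[ck$truth$roles$role == "digit",
                               c("start", "end")]
  direct <- rasterize_trace(ck$trace, digit_runs,
                            dim = c(ck$trace$canvas_h, ck$trace$canvas_w))
  expect_identical(img2, direct)

  full <- modified_image(ck$trace, exclude_runs = NULL)
  everything <- rasterize_trace(ck$trace, extract_strokes(ck$trace),
                                dim = c(1200, 2400))
  expect_identical(full, everything)

  expect_error(modified_image(ck$trace,
                              exclude_runs = list(c(1, 50), c(30, 80))),
               "overlap")
})

test_that("find_components matches exact corners on constructed blobs", {
  img <- matrix(0L, 80, 80)
  img[11:20, 11:20] <- 1L
  img[41:50, 61:70] <- 1L
  b <- find_components(img)
  b <- b[order(b$xmin), ]
  expect_equal(nrow(b), 2)
  expect_equal(unname(unlist(b[1, c("xmin", "xmax", "ymin", "ymax")])),
               c(10, 19, 10, 19))
  expect_equal(unname(unlist(b[2, c("xmin", "xmax", "ymin", "ymax")])),
               c(60, 69, 40, 49))
  expect_equal(b$npix, c(100, 100))
  expect_equal(nrow(find_components(matrix(0L, 10, 10))), 0)
})

test_that("find_components agrees with the flood-fill oracle", {
  set.seed(202)
  for (trial in 1:200) {
    H <- sample(5:64, 1); W <- sample(5:64, 1)
    img <- matrix(rbinom(H * W, 1, runif(1, 0.05, 0.35)), H, W)
    got <- find_components(img)
    got <- got[order(got$xmin, got$ymin, got$xmax, got$ymax), , drop = FALSE]
    want <- flood_fill_boxes(img)
    expect_equal(nrow(got), nrow(want))
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("xmin", "xmax", "ymin", "ymax", "npix")], want)
  }
})

test_that("merged and separate strokes crop as expected", {
  # two strokes whose ink touches form one component; distant strokes two
  touching <- make_trace(list(rbind(c(100, 100), c(140, 100)),
                              rbind(c(140, 100), c(140, 140))))
  img <- modified_image(touching)
  expect_equal(nrow(find_components(img)), 1)

  apart <- make_trace(list(rbind(c(100, 100), c(140, 100)),
                           rbind(c(400, 400), c(440, 400))))
  expect_equal(nrow(find_components(modified_image(apart))), 2)
})

test_that("a complete clock crops 15 characters in drawing order", {
  ck <- generate_clock(clock_spec(seed = 8))
  crun <- find_contour_run(ck$trace)
  hand_runs <- ck$truth$roles[grepl("^hand", ck$truth$roles$role),
                              c("start", "end")]
  img <- modified_image(ck$trace,
                        exclude_runs = c(as_run_list(crun),
                                         as_run_list(hand_runs)))
  digit_runs <- ck$truth$roles[ck$truth$roles$role == "digit",
                               c("start", "end")]
  boxes <- find_components(img, ck$trace, include_runs = digit_runs,
                           min_extent = 25)
  expect_equal(nrow(boxes), 15)
  expect_false(is.unsorted(boxes$ti))

  dets <- classify_digits(img, boxes, oracle_classifier(ck$truth))
  want <- as.integer(ck$truth$roles$char[ck$truth$roles$role == "digit"])
  expect_equal(dets$label, want)
  expect_equal(sum(dets$label == 1L), 5)
  expect_equal(sum(dets$label == 2L), 2)

  nd <- number_distances(dets, digit_anchors(contour_bbox(ck$trace, crun)))
  expect_equal(nrow(nd), 12)
  expect_setequal(nd$value, 1:12)
  expect_true(all(nd$dcn < 100))
})

test_that("detection centers are the box midpoints", {
  img <- matrix(0L, 300, 300)
  img[(230 + 1):(260 + 1), (100 + 1):(160 + 1)] <- 1L
  boxes <- find_components(img)
  dets <- classify_digits(img, boxes, function(crop, box) {
    expect_equal(dim(crop), c(28, 28)) # crop resize contract
    7L
  })
  expect_equal(dets$xm, 130)
  expect_equal(dets$ym, 245)
  expect_equal(dets$label, 7L)
})

test_that("sequence_ratio reproduces the reference similarity values", {
  refs <- reference_sequences()
  expect_equal(sequence_ratio(refs$S1, refs$S1), 100)
  expect_equal(rseq_max(refs$S1), 100)
  expect_equal(sequence_ratio(c("a", "b"), c("c", "d")), 0)
  expect_equal(sequence_ratio(as.character(1:4), as.character(2:5)), 75)
  expect_error(sequence_ratio(character(0), "1"), "empty")

  # frozen from the reference implementation of the similarity measure
  frozen <- list(
    list(a = "012002", b = "12", want = 50),
    list(a = "2", b = "0011", want = 0),
    list(a = "00", b = "0200222", want = 400 / 9),
    list(a = "2", b = "0020011", want = 25),
    list(a = "202", b = "22002", want = 75),
    list(a = "1022", b = "20", want = 100 / 3)
  )
  for (fz in frozen) {
    expect_equal(
      sequence_ratio(strsplit(fz$a, "")[[1]], strsplit(fz$b, "")[[1]]),
      fz$want, tolerance = 1e-9
    )
  }
  # the measure is directional in general (greedy longest-block recursion):
  # this pair is a frozen regression of both orientations
  a <- strsplit("00120210", "")[[1]]; b <- strsplit("1212001", "")[[1]]
  expect_equal(sequence_ratio(a, b), 40)
  expect_equal(sequence_ratio(b, a), 160 / 3, tolerance = 1e-9)
})

test_that("sequence_ratio agrees with the independent recursion oracle", {
  syms <- c("0", "1", "2")
  seqs <- unlist(lapply(1:3, function(L) {
    g <- do.call(expand.grid, c(rep(list(syms), L),
                                stringsAsFactors = FALSE))
    apply(g, 1, paste0, collapse = "")
  }))
  for (a in seqs) {
    aa <- strsplit(a, "")[[1]]
    expect_equal(sequence_ratio(aa, aa), 100)
    for (b in seqs) {
      bb <- strsplit(b, "")[[1]]
      got <- sequence_ratio(aa, bb)
      expect_gte(got, 0); expect_lte(got, 100)
      expect_equal(got, ro_oracle(aa, bb), tolerance = 1e-9)
    }
  }
  set.seed(404)
  for (trial in 1:400) {
    aa <- sample(syms, sample(4:8, 1), replace = TRUE)
    bb <- sample(syms, sample(4:8, 1), replace = TRUE)
    expect_equal(sequence_ratio(aa, bb), ro_oracle(aa, bb),
                 tolerance = 1e-9)
  }
})

test_that("reference sequences encode the three habitual orders", {
  refs <- reference_sequences()
  expect_equal(refs$S1, c("1", "2", "3", "4", "5", "6", "7", "8", "9",
                          "1", "0", "1", "1", "1", "2"))
  expect_equal(refs$S2, c("1", "2", "1", "2", "3", "4", "5", "6", "7",
                          "8", "9", "1", "0", "1", "1"))
  expect_equal(refs$S3, c("1", "2", "3", "6", "9", "1", "2", "4", "5",
                          "7", "8", "1", "0", "1", "1"))
  # a clock drawn twelve-first matches S2 perfectly
  ck <- generate_clock(clock_spec(digit_order = "twelve_first", seed = 3))
  chars <- ck$truth$roles$char[ck$truth$roles$role == "digit"]
  expect_equal(rseq_max(chars), 100)
})
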