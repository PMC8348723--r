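# Sensor-log and report I/O.
#
# The CSV dialect is fixed: header "t,x,y,e", LF line endings, '.' decimal
# separator, full double precision (%.17g) so write -> read round-trips are
# value-exact.

#' Read a sensor log from CSV
#'
#' @param path Path to a CSV file with header `t,x,y,e`.
#' @inheritParams parse_trace
#' @return A validated `sensor_trace`.
#' @export
read_trace_csv <- function(path, canvas_w = 2400, canvas_h = 1200,
                           sample_period = 0.02) {
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric", "numeric", "integer"))
  parse_trace(df, canvas_w = canvas_w, canvas_h = canvas_h,
              sample_period = sample_period)
}

#' Write a sensor log to CSV
#'
#' @param trace A `sensor_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  s <- trace$samples
  lines <- c(
    "t,x,y,e",
    sprintf("%.17g,%.17g,%.17g,%d", s$t, s$x, s$y, s$e)
  )
  con <- file(path, open = "wb") # binary mode keeps LF on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a sensor log from the JSON variant
#'
#' The JSON variant bundles the canvas size and optional metadata with the
#' samples.
#' @param path Path to a JSON file written by [write_trace_json()].
#' @return A validated `sensor_trace`.
#' @export
read_trace_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse_trace(as.data.frame(obj$samples),
    canvas_w = obj$canvas_w, canvas_h = obj$canvas_h,
    sample_period = if (!is.null(obj$sample_period)) obj$sample_period else 0.02
  )
}

#' Write a sensor log to the JSON variant
#' @param trace A `sensor_trace`.
#' @param path Output path.
#' @param metadata Optional named list stored alongside the samples.
#' @return `path`, invisibly.
#' @export
write_trace_json <- function(trace, path, metadata = NULL) {
  obj <- list(
    canvas_w = trace$canvas_w, canvas_h = trace$canvas_h,
    sample_period = trace$sample_period, samples = trace$samples
  )
  if (!is.null(metadata)) obj$metadata <- metadata
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a score report to JSON
#'
#' Serializes the per-criterion booleans, the four parameter sums, the
#' total, the thresholds used, and all intermediate statistics.
#' @param report A `cdt_score_report` from [score_clock()] or
#'   [score_total()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- unclass(report)
  obj$criteria <- as.list(obj$criteria)
  obj$scores <- as.list(obj$scores)
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Write a binary mask as a 1-bit style PNG
#'
#' Masks are stored row 1 = top of the image, so the y-up grid used
#' internally is flipped on write and on read.
#' @param mask A 0/1 matrix (rows indexed bottom-up).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG masks")
  }
  png::writePNG(apply(mask, 2, rev) * 1.0, path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path PNG path; any nonzero luminance becomes 1.
#' @return A 0/1 integer matrix (rows indexed bottom-up).
#' @export
read_mask_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to read PNG masks")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- (img > 0.5) * 1L
  apply(m, 2, rev)
}
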