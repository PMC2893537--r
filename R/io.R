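#' Read an eye-image sequence
#'
#' Reads a directory of PNG/TIFF frames (ordered by the numeric index in
#' their file names, which must be contiguous) or a single multi-frame
#' TIFF. Frames are returned as 8-bit grayscale matrices; color input is
#' converted by luminance with a warning. Inconsistent dimensions or a
#' gap in the frame numbering raise an error naming the offender.
#'
#' @param path directory of frames, or one .tif/.tiff file.
#' @return list of integer matrices in frame order.
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0) stop("no PNG/TIFF frames found in ", path)
    idx <- suppressWarnings(as.integer(sub("^.*?(\\d+)\\D*$", "\\1",
                                           basename(files))))
    if (!anyNA(idx)) {
      files <- files[order(idx)]
      idx <- sort(idx)
      gaps <- which(diff(idx) != 1)
      if (length(gaps) > 0)
        stop(sprintf("missing frame between index %d and %d", idx[gaps[1]],
                     idx[gaps[1] + 1]))
    }
    frames <- lapply(files, read_one_frame)
  } else if (file.exists(path)) {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
      stop("single-file input must be a multi-frame TIFF")
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    frames <- lapply(imgs, to_gray8)
  } else stop("no such file or directory: ", path)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop(sprintf("inconsistent frame dimensions at frame %d",
                 which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1] - 1))
  frames
}

read_one_frame <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE))
    png::readPNG(file) else tiff::readTIFF(file)
  tryCatch(to_gray8(img), error = function(e)
    stop(sprintf("unreadable frame '%s': %s", basename(file), conditionMessage(e))))
}

to_gray8 <- function(img) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      warning("color frame converted to grayscale by luminance")
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else img <- img[, , 1]
  }
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write a frame sequence as PNG files
#'
#' @param frames list of gray matrices (0-255).
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%04d.png", seq_along(frames) - 1))
  for (i in seq_along(frames))
    png::writePNG(frames[[i]] / 255, paths[i])
  invisible(paths)
}

trace_columns <- c("frame", "time_s", "pupil_radius_px", "pupil_row",
                   "pupil_col", "score", "valid", "iris_radius_px")

#' Write / read a per-frame measurement trace as CSV
#'
#' Comma-separated, UTF-8, '.' decimal, mandatory header with the
#' columns \code{frame, time_s, pupil_radius_px, pupil_row, pupil_col,
#' score, valid, iris_radius_px}. Numeric fields are written with 17
#' significant digits so a write/read round trip is lossless.
#'
#' @param measurements a \code{\link{measure_sequence}} data.frame.
#' @param path CSV path.
#' @return \code{write_trace}: invisibly, the path. \code{read_trace}:
#'   a \code{frame_measurements} data.frame.
#' @export
write_trace <- function(measurements, path) {
  df <- as.data.frame(measurements)[, trace_columns]
  fmt <- function(v) {
    if (is.logical(v)) as.character(v)
    else if (is.numeric(v)) sprintf("%.17g", v)
    else as.character(v)
  }
  lines <- c(paste(trace_columns, collapse = ","),
             do.call(paste, c(lapply(df, fmt), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed trace CSV: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("empty trace CSV")
  missing <- setdiff(trace_columns, names(df))
  if (length(missing) > 0)
    stop("trace CSV missing column(s): ", paste(missing, collapse = ", "),
         " (expected: ", paste(trace_columns, collapse = ", "), ")")
  df <- df[, trace_columns]
  df$valid <- as.logical(df$valid)
  df$frame <- as.integer(df$frame)
  for (col in setdiff(trace_columns, c("frame", "valid")))
    df[[col]] <- as.numeric(df[[col]])
  class(df) <- c("frame_measurements", "data.frame")
  df
}

#' Write ground truth / parameters / cohort tables
#'
#' \code{write_truth} stores a ground-truth trace as CSV (frame, time_s,
#' radius_px, blink); \code{write_params} stores an extracted parameter
#' set as JSON; \code{read_cohort}/\code{write_cohort} round-trip the
#' per-subject parameter table.
#'
#' @param truth,params,cohort the objects to write.
#' @param path destination.
#' @return invisibly, the path (readers return the object).
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth)[, c("frame", "time_s", "radius_px",
                                            "blink")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(as.list(as.data.frame(params)), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(df)) stop("cohort CSV needs a 'group' column")
  df
}
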