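#' Read a single-channel grayscale image
#'
#' Reads a TIFF into a numeric matrix with intensities in \[0, 1\]
#' (integer sample formats are scaled by their bit depth; float TIFFs are
#' read as stored). Multi-channel images are rejected: extract the bead
#' channel first.
#'
#' @param path Path to a TIFF file.
#' @return Numeric matrix (rows x cols).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) {
      img <- img[, , 1]
    } else {
      stop("multi-channel TIFF (", dim(img)[3], " channels): ",
           "extract the single bead channel before loading")
    }
  }
  img
}

#' Write a grayscale image as TIFF
#'
#' @param image Numeric matrix; values outside \[0, 1\] are clipped for
#'   integer outputs.
#' @param path Output path.
#' @param bits 8 or 16 for integer TIFF, 32 for IEEE float (lossless for
#'   arbitrary values in \[0, 1\]).
#' @export
write_image <- function(image, path, bits = 16L) {
  stopifnot(is.matrix(image))
  if (bits == 32) {
    tiff::writeTIFF(image, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(pmin(pmax(image, 0), 1), path,
                    bits.per.sample = as.integer(bits))
  }
  invisible(path)
}

#' Read bead centroids from CSV
#'
#' Expects a header `bead_id,row,col` with optional `diameter` and
#' `fully_visible` columns. Coordinates are 0-based; the coordinate frame
#' (original vs upsampled resolution) may be recorded in a leading
#' `# frame: ...` comment line, which is returned as the `frame` attribute.
#'
#' @param path CSV path.
#' @return data.frame with at least `bead_id`, `row`, `col`.
#' @export
read_centroids <- function(path) {
  if (!file.exists(path)) stop("centroid file not found: ", path)
  first <- readLines(path, n = 1L)
  frame <- "original"
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("frame:\\s*(\\S+)", first))[[1]]
    if (length(m) == 2) frame <- m[2]
  }
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  required <- c("bead_id", "row", "col")
  if (!all(required %in% names(df)))
    stop("centroid CSV must have columns bead_id,row,col; got: ",
         paste(names(df), collapse = ","))
  for (cn in c("row", "col", "diameter")) {
    if (cn %in% names(df)) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(is.na(v) & !is.na(df[[cn]]))
      if (length(bad))
        stop("malformed value in column '", cn, "' at data line ", bad[1],
             " of ", path)
      df[[cn]] <- v
    }
  }
  if ("fully_visible" %in% names(df))
    df$fully_visible <- as.logical(df$fully_visible)
  attr(df, "frame") <- frame
  df
}

#' Write bead centroids to CSV
#'
#' Coordinates are written 0-based to 6 decimal places; the coordinate
#' frame is recorded in a leading comment line.
#'
#' @param centroids data.frame with `bead_id`, `row`, `col` and optional
#'   extra columns.
#' @param path Output path.
#' @param frame `"original"` or `"upsampled"`.
#' @export
write_centroids <- function(centroids, path, frame = "original") {
  df <- as.data.frame(centroids)
  for (cn in intersect(c("row", "col", "diameter"), names(df)))
    df[[cn]] <- sprintf("%.6f", df[[cn]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame: %s", frame), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a detection set to CSV
#'
#' @param detections data.frame from [extract_centroids()].
#' @param path Output path.
#' @param frame Coordinate frame label.
#' @export
write_detections <- function(detections, path, frame = "upsampled") {
  df <- data.frame(detection_id = seq_len(nrow(detections)) - 1L,
                   row = sprintf("%.6f", detections$row),
                   col = sprintf("%.6f", detections$col),
                   area = detections$area)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame: %s", frame), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
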