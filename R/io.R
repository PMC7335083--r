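# Frame and mask I/O. Frames are PNG (primary) or JPEG (if the jpeg package
# is installed); masks are single-channel 0/255 PNG. Feature tables are CSV.

#' Read an image frame from disk
#'
#' Supports PNG and (when the `jpeg` package is available) JPEG. The result
#' is a numeric array dim (rows, cols, 3) scaled to \[0, 255\]; gray and
#' RGBA files are expanded/trimmed to 3 channels.
#'
#' @param path file path (.png, .jpg, .jpeg).
#' @return RGB array.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) lq_stop(paste("file not found:", path), "lq_io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      lq_stop("JPEG support requires the 'jpeg' package", "lq_io_error")
    jpeg::readJPEG(path)
  } else {
    lq_stop(paste("unsupported image format:", ext), "lq_io_error")
  }
  if (is.matrix(raw)) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' Write an RGB frame as PNG
#'
#' @param image RGB array in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(image, path) {
  check_rgb(image)
  png::writePNG(clamp(image, 0, 255) / 255, target = path)
  invisible(path)
}

#' Write a binary mask as a 0/255 single-channel PNG
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is_mask(mask)) lq_stop("expected a logical mask matrix")
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

#' Read a 0/255 mask PNG back into a logical matrix
#' @param path file path.
#' @return logical matrix (pixel > 0.5).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) lq_stop(paste("file not found:", path), "lq_io_error")
  m <- png::readPNG(path)
  if (!is.matrix(m)) m <- m[, , 1]
  m > 0.5
}

#' List frame files of a directory in lexicographic order
#' @noRd
list_frames <- function(dir) {
  if (!dir.exists(dir)) lq_stop(paste("directory not found:", dir), "lq_io_error")
  sort(list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                  full.names = TRUE))
}
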