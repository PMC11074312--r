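#' Multi-channel image container
#'
#' A light container for named fluorescence channels sharing one pixel grid.
#' Channels are plain numeric matrices (2-D) or arrays (3-D with a z
#' dimension), indexed `[row = y, col = x(, z)]` with pixel centers at
#' integer coordinates and the origin at the top-left; `x` is the column.
#'
#' @param channels Named list of numeric matrices/arrays of identical shape
#'   with non-negative intensities.
#' @param pixel_size Optional physical pixel size (e.g. micrometers per
#'   pixel); carried as metadata only.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  shapes <- lapply(channels, dim)
  if (length(unique(shapes)) != 1) {
    stop("all channels must share one shape", call. = FALSE)
  }
  for (ch in names(channels)) {
    if (!is.numeric(channels[[ch]]) || any(channels[[ch]] < 0)) {
      stop("channel '", ch, "' must be numeric and non-negative", call. = FALSE)
    }
  }
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<image_stack> ", paste(d, collapse = " x "), " px, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read and write 16-bit TIFF images
#'
#' Integer intensity arrays round-trip bit-identically: values are stored as
#' 16-bit samples (values above 65535 are clipped at write time).
#'
#' @param path File path.
#' @return `read_image()` returns an integer-valued numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  img <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(img) <- "double"
  img
}

#' @param image Numeric matrix of non-negative intensities; rounded to
#'   integers on write.
#' @rdname read_image
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image), all(is.finite(image)), all(image >= 0))
  x <- pmin(round(image), 65535)
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and write label-mask TIFFs
#'
#' Label images (0 = background, k > 0 = object k) use the same 16-bit TIFF
#' representation as intensity images.
#'
#' @param path File path.
#' @return `read_labels()` returns an integer matrix.
#' @export
read_labels <- function(path) {
  img <- read_image(path)
  storage.mode(img) <- "integer"
  img
}

#' @param labels Integer label matrix.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  write_image(labels, path)
}
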