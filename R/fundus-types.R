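# Shared raster and label-table types. Every pipeline stage consumes and
# produces these; constructors validate so malformed rasters fail early.
#
# Conventions: pixel coordinates are (row, col), 0-based in documentation,
# 1-based in R indexing; crops use half-open ranges; channel order is RGB.

#' Fundus image raster
#'
#' An H x W x 3 integer raster with values in 0..255 and RGB channel order.
#'
#' @param pixels numeric or integer H x W x 3 array with values in 0..255.
#' @param meta optional list of provenance metadata (source path or
#'   synthetic seed).
#' @return an object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, meta = list()) {
  abort_if(!is.array(pixels) || length(dim(pixels)) != 3L,
           "fundus_image: pixels must be an H x W x 3 array")
  abort_if(dim(pixels)[3] != 3L,
           "fundus_image: expected 3 channels, got ", dim(pixels)[3])
  abort_if(dim(pixels)[1] < 1L || dim(pixels)[2] < 1L,
           "fundus_image: empty raster")
  abort_if(anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255,
           "fundus_image: pixel values must lie in 0..255")
  abort_if(any(pixels != round(pixels)),
           "fundus_image: pixel values must be integers")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, meta = meta), class = "fundus_image")
}

#' Single-channel grey raster
#'
#' @param pixels numeric H x W matrix with integer values in 0..255.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  abort_if(!is.matrix(pixels), "gray_image: pixels must be a matrix")
  abort_if(anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255,
           "gray_image: pixel values must lie in 0..255")
  abort_if(any(pixels != round(pixels)),
           "gray_image: pixel values must be integers")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels), class = "gray_image")
}

#' Binary mask raster
#'
#' Values are strictly 0/1 in memory; [write_image()] serialises them as
#' 0/255 so mask files are viewable.
#'
#' @param pixels H x W matrix with values in \{0, 1\}.
#' @param semantics one of `"background-mask"`, `"vessel-mask"`,
#'   `"brightness-mask"`.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(pixels,
                        semantics = c("background-mask", "vessel-mask",
                                      "brightness-mask")) {
  semantics <- match.arg(semantics)
  if (is.logical(pixels)) {
    storage.mode(pixels) <- "integer"
  }
  abort_if(!is.matrix(pixels), "binary_mask: pixels must be a matrix")
  abort_if(anyNA(pixels) || !all(pixels %in% c(0L, 1L)),
           "binary_mask: values must be 0 or 1")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, semantics = semantics),
            class = "binary_mask")
}

#' Extract the pixel array from a raster object
#'
#' @param x a `fundus_image`, `gray_image`, `binary_mask`, or a bare
#'   array/matrix (returned as-is).
#' @return the underlying pixel array.
#' @export
pixels <- function(x) {
  if (inherits(x, c("fundus_image", "gray_image", "binary_mask"))) x$pixels
  else x
}

raster_dim <- function(x) dim(pixels(x))[1:2]

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image %d x %d x 3, values %d..%d>\n",
              d[1], d[2], min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_image %d x %d, values %d..%d>\n",
              d[1], d[2], min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<binary_mask (%s) %d x %d, %d foreground px>\n",
              x$semantics, d[1], d[2], sum(x$pixels)))
  invisible(x)
}

#' Two-class label table
#'
#' @param image_id character vector of unique image identifiers.
#' @param label character vector of labels; only `"glaucoma"` and
#'   `"normal"` are allowed (case-insensitive, stored lowercase).
#' @return a data.frame of class `label_table` with columns
#'   `image_id`, `label`.
#' @export
label_table <- function(image_id, label) {
  abort_if(length(image_id) != length(label),
           "label_table: image_id and label lengths differ")
  image_id <- as.character(image_id)
  label <- tolower(as.character(label))
  dup <- unique(image_id[duplicated(image_id)])
  abort_if(length(dup) > 0L,
           "label_table: duplicated image_id: ", paste(dup, collapse = ", "))
  bad <- !label %in% c("glaucoma", "normal")
  abort_if(any(bad),
           "label_table: labels outside {glaucoma, normal} in rows ",
           paste(which(bad), collapse = ", "), ": ",
           paste(unique(label[bad]), collapse = ", "))
  structure(data.frame(image_id = image_id, label = label,
                       stringsAsFactors = FALSE),
            class = c("label_table", "data.frame"))
}
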