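# Readers/writers for images and label tables. PNG is the lossless interchange
# format (bit-exact roundtrips); JPEG is accepted on input via EBImage.

#' Read a fundus photograph
#'
#' Decodes an 8-bit colour PNG or JPEG into a [fundus_image] with RGB channel
#' order, regardless of the decoder's native convention.
#'
#' @param path path to a PNG/JPEG file.
#' @param min_size minimum accepted edge length in pixels (default 64, the
#'   classifier input size); set to 1 to accept arbitrary rasters.
#' @return a [fundus_image]; `meta$source` records the path.
#' @export
read_image <- function(path, min_size = 64L) {
  abort_if(!file.exists(path), "read_image: file not found: ", path,
           class = "fundustruct_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- EBImage::readImage(path)
    px <- EBImage::imageData(img)
    # EBImage stores (x, y[, c]); transpose to (row, col[, c])
    px <- if (length(dim(px)) == 3L) aperm(px, c(2L, 1L, 3L)) else t(px)
  } else {
    abort("read_image: unsupported extension '", ext, "' (PNG/JPEG only)",
          class = "fundustruct_format_error")
  }
  abort_if(length(dim(px)) != 3L,
           "read_image: expected 3 channels, got a single-channel file: ", path,
           class = "fundustruct_format_error")
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  abort_if(dim(px)[3] != 3L,
           "read_image: expected 3 channels, got ", dim(px)[3], ": ", path,
           class = "fundustruct_format_error")
  v <- px * 255
  abort_if(max(abs(v - round(v))) > 1e-6,
           "read_image: expected an 8-bit file: ", path,
           class = "fundustruct_format_error")
  abort_if(any(dim(px)[1:2] < min_size),
           "read_image: raster smaller than ", min_size, " px: ", path,
           class = "fundustruct_format_error")
  fundus_image(round(v), meta = list(source = path))
}

#' Write a raster as PNG
#'
#' Lossless 8-bit PNG encoding, so `read_image(write_image(x)) == x`.
#' [binary_mask] objects are serialised as 0/255; numeric matrices in
#' \[0, 1\] (e.g. vessel probability maps) are scaled to 0..255.
#'
#' @param img a [fundus_image], [gray_image], [binary_mask], or a numeric
#'   matrix/array in \[0, 1\].
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  abort_if(!dir.exists(dirname(path)),
           "write_image: directory does not exist: ", dirname(path),
           class = "fundustruct_io_error")
  px <- pixels(img)
  scaled <-
    if (inherits(img, "binary_mask")) px  # {0,1} -> writePNG 0/255
    else if (inherits(img, c("fundus_image", "gray_image"))) px / 255
    else if (max(px) <= 1) px             # probability map
    else px / 255
  png::writePNG(clamp(scaled, 0, 1), target = path)
  invisible(path)
}

#' Read a two-class label table
#'
#' Expects a CSV with header columns `image_id,label`; labels are lowercased
#' and must be `glaucoma` or `normal`, ids unique.
#'
#' @param path path to the CSV file.
#' @return a [label_table].
#' @export
read_label_table <- function(path) {
  abort_if(!file.exists(path), "read_label_table: file not found: ", path,
           class = "fundustruct_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!all(c("image_id", "label") %in% names(df)),
           "read_label_table: header must contain image_id,label: ", path,
           class = "fundustruct_format_error")
  label_table(df$image_id, df$label)
}

#' Write a label table as CSV
#'
#' @param tbl a [label_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl)[, c("image_id", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
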