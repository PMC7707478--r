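#' En face OCTA image container
#'
#' Wraps a grayscale en face angiogram slab together with its plexus label,
#' acquisition mode and physical scale. Intensities are stored as a numeric
#' matrix in \[0, 255\] (rows = y, columns = x).
#'
#' @param pixels numeric matrix of intensities in \[0, 255\]; square, side
#'   at least 64 pixels.
#' @param plexus one of `"SCP"`, `"DCP"`, `"CC"`.
#' @param acquisition_mode acquisition label, e.g. `"V1"` (single volume) or
#'   `"V4"` (merged average of four volumes).
#' @param scale physical scale in mm per pixel. The default corresponds to a
#'   3x3 mm field sampled at 304x304.
#' @param eye_id identifier of the imaged eye.
#' @return An object of class `octa_image`.
#' @examples
#' img <- en_face_image(matrix(128, 64, 64), "SCP", "V1")
#' img
#' @export
en_face_image <- function(pixels, plexus = c("SCP", "DCP", "CC"),
                          acquisition_mode = "V1", scale = 3 / 304,
                          eye_id = "eye01") {
  plexus <- match.arg(plexus)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_octa("`pixels` must be a numeric matrix")
  if (nrow(pixels) != ncol(pixels) || nrow(pixels) < 64)
    stop_octa("en face images must be square with side >= 64 pixels, got ",
              nrow(pixels), "x", ncol(pixels))
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop_octa("`pixels` contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_octa("intensities must lie in [0, 255]")
  structure(
    list(pixels = pixels, plexus = plexus,
         acquisition_mode = acquisition_mode,
         scale = scale, eye_id = eye_id),
    class = "octa_image")
}

#' @export
print.octa_image <- function(x, ...) {
  cat(sprintf("<octa_image> %s %s %s: %dx%d px, %.4f mm/px, range [%d, %d]\n",
              x$eye_id, x$plexus, x$acquisition_mode,
              nrow(x$pixels), ncol(x$pixels), x$scale,
              round(min(x$pixels)), round(max(x$pixels))))
  invisible(x)
}

#' @export
as.matrix.octa_image <- function(x, ...) x$pixels

#' Read and write 8-bit grayscale OCTA images
#'
#' `write_octa_image()` writes the intensity grid as an 8-bit grayscale TIFF
#' or PNG (chosen from the file extension); `read_octa_image()` reads one
#' back, recovering plexus/mode/eye metadata from a
#' `<eyeID>_<plexus>_<mode>.<ext>` file name when present.
#'
#' @param img an [en_face_image()].
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param scale mm-per-pixel to attach on read.
#' @return `read_octa_image()` returns an `octa_image`;
#'   `write_octa_image()` returns `path` invisibly.
#' @export
write_octa_image <- function(img, path) {
  m <- round(img$pixels) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else stop_octa("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname write_octa_image
#' @export
read_octa_image <- function(path, scale = 3 / 304) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else stop_octa("unsupported image extension: ", ext)
  if (length(dim(m)) == 3) m <- m[, , 1]
  meta <- parse_image_name(basename(path))
  en_face_image(round(m * 255), plexus = meta$plexus,
                acquisition_mode = meta$mode, scale = scale,
                eye_id = meta$eye_id)
}

# `<eyeID>_<plexus>_<mode>.<ext>`; falls back to SCP/V1/file stem.
parse_image_name <- function(fname) {
  stem <- tools::file_path_sans_ext(fname)
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  n <- length(parts)
  if (n >= 3 && parts[n - 1] %in% c("SCP", "DCP", "CC")) {
    list(eye_id = paste(parts[seq_len(n - 2)], collapse = "_"),
         plexus = parts[n - 1], mode = parts[n])
  } else {
    list(eye_id = stem, plexus = "SCP", mode = "V1")
  }
}

#' Write a binary mask as an 8-bit {0, 255} image
#'
#' @param mask logical matrix (or an object with a `$mask` element).
#' @param path output path (`.tif`, `.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (is.list(mask)) mask <- mask$mask
  ext <- tolower(tools::file_ext(path))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "none")
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else stop_octa("unsupported image extension: ", ext)
  invisible(path)
}
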