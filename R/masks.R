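#' Tissue and compartment masks
#'
#' Light containers for per-pixel masks with physical scale.
#' A `tissue_mask` is a logical matrix flagging tissue pixels; a
#' `compartment_mask` is an integer label matrix with 0 = background,
#' 1 = tumour, 2 = stroma, together with per-class areas in mm^2.
#'
#' @param mask logical matrix (rows = y, cols = x).
#' @param pixel_size micrometres per pixel.
#' @export
tissue_mask <- function(mask, pixel_size) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, pixel_size = pixel_size,
                 area_mm2 = px_area_mm2(sum(mask), pixel_size)),
            class = "tissue_mask")
}

#' @rdname tissue_mask
#' @param labels integer matrix of labels in `{0, 1, 2}`.
#' @export
compartment_mask <- function(labels, pixel_size) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2))
    stop("labels must be 0 (background), 1 (tumour) or 2 (stroma)",
         call. = FALSE)
  structure(list(
    labels = labels, pixel_size = pixel_size,
    areas = c(tumour = px_area_mm2(sum(labels == 1L), pixel_size),
              stroma = px_area_mm2(sum(labels == 2L), pixel_size))),
    class = "compartment_mask")
}

# label value at physical coordinates; 0L for out-of-frame points
mask_label_at <- function(mask, x_um, y_um) {
  px <- mask$pixel_size
  col <- floor(x_um / px) + 1L
  row <- floor(y_um / px) + 1L
  lab <- integer(length(x_um))
  ok <- col >= 1L & col <= ncol(mask$labels) & row >= 1L & row <= nrow(mask$labels)
  lab[ok] <- mask$labels[cbind(row[ok], col[ok])]
  lab[!ok] <- NA_integer_
  lab
}

#' Write / read a compartment mask as an 8-bit label PNG
#'
#' Labels are stored verbatim (0 background, 1 tumour, 2 stroma) in the
#' first channel.
#' @param mask a `compartment_mask`.
#' @param path output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$labels / 255, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @param pixel_size micrometres per pixel of the stored mask.
#' @export
read_mask_png <- function(path, pixel_size) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  compartment_mask(round(img * 255), pixel_size)
}
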