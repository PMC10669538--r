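#' Clip and normalize a raw image to the unit interval
#'
#' Applies an intensity window to raw scanner values (e.g. Hounsfield units
#' for CT) and rescales to `[0, 1]`: values below `lo` map to 0, values above
#' `hi` map to 1, and the window interior maps linearly.  The default CT
#' window is `(-135, 215)`; a typical abdominal MRI window is `(100, 1000)`.
#'
#' @param raw Numeric matrix of raw intensities (H x W).
#' @param lo,hi Window bounds, `lo < hi`.
#' @return Numeric matrix of the same shape with values in `[0, 1]`.
#' @examples
#' clip_normalize(matrix(c(-500, 40, 215), 1), -135, 215)
#' @export
clip_normalize <- function(raw, lo = -135, hi = 215) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("clip_normalize: 'lo' must be strictly less than 'hi'", call. = FALSE)
  raw <- as.matrix(raw)
  (pmin(pmax(raw, lo), hi) - lo) / (hi - lo)
}

#' Resize an intensity image by bilinear interpolation
#'
#' Samples the source image on a regular grid using the pixel-center
#' alignment convention: output pixel center `(i + 0.5)/H_out` maps to source
#' coordinate `(i + 0.5)/H_out * H_in - 0.5`, clamped at the borders.
#' Constant images stay constant and output values remain inside the source
#' value range, so unit-interval images stay in `[0, 1]`.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param size Target `c(H, W)`, both at least 16.
#' @return Numeric matrix of dimension `size`.
#' @export
resize_image <- function(image, size) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 16L))
    stop("resize_image: target size must be c(H, W) with both >= 16", call. = FALSE)
  image <- as.matrix(image)
  h_in <- nrow(image); w_in <- ncol(image)
  h_out <- size[1L]; w_out <- size[2L]
  if (h_in == h_out && w_in == w_out) return(image)
  # source coordinates of output pixel centers (0-based continuous)
  src <- function(n_out, n_in) pmin(pmax((seq_len(n_out) - 0.5) / n_out * n_in - 0.5, 0), n_in - 1)
  ys <- src(h_out, h_in); xs <- src(w_out, w_in)
  y0 <- pmin(floor(ys), h_in - 1); y1 <- pmin(y0 + 1, h_in - 1); wy <- ys - y0
  x0 <- pmin(floor(xs), w_in - 1); x1 <- pmin(x0 + 1, w_in - 1); wx <- xs - x0
  a <- image[y0 + 1, x0 + 1, drop = FALSE]; b <- image[y1 + 1, x0 + 1, drop = FALSE]
  c_ <- image[y0 + 1, x1 + 1, drop = FALSE]; d <- image[y1 + 1, x1 + 1, drop = FALSE]
  wy_m <- matrix(wy, h_out, w_out); wx_m <- matrix(wx, h_out, w_out, byrow = TRUE)
  (1 - wy_m) * (1 - wx_m) * a + wy_m * (1 - wx_m) * b +
    (1 - wy_m) * wx_m * c_ + wy_m * wx_m * d
}

#' Resize a binary mask with nearest-neighbour sampling
#'
#' Masks must stay binary under resizing, so the nearest source pixel (by the
#' same pixel-center alignment as [resize_image()]) is taken instead of
#' interpolating.
#'
#' @param mask Logical matrix.
#' @param size Target `c(H, W)`.
#' @return Logical matrix of dimension `size`.
#' @export
resize_mask <- function(mask, size) {
  size <- as.integer(size)
  mask <- as.matrix(mask)
  h_in <- nrow(mask); w_in <- ncol(mask)
  ys <- pmin(pmax(round((seq_len(size[1L]) - 0.5) / size[1L] * h_in + 0.5), 1), h_in)
  xs <- pmin(pmax(round((seq_len(size[2L]) - 0.5) / size[2L] * w_in + 0.5), 1), w_in)
  mask[ys, xs, drop = FALSE]
}

#' Construct a click
#'
#' A click is a pixel position plus a polarity: positive clicks request mask
#' growth, negative clicks request removal.  Coordinates are 1-based
#' `(row, col)` image indices.
#'
#' @param row,col 1-based pixel indices.
#' @param positive Logical; `TRUE` for a positive click.
#' @return An object of class `"clickseg_click"`.
#' @export
click <- function(row, col, positive = TRUE) {
  structure(list(row = as.integer(row), col = as.integer(col),
                 positive = isTRUE(positive)),
            class = "clickseg_click")
}

#' @export
print.clickseg_click <- function(x, ...) {
  cat(sprintf("<click %s at (%d, %d)>\n",
              if (x$positive) "positive" else "negative", x$row, x$col))
  invisible(x)
}

check_click_bounds <- function(click, shape) {
  if (click$row < 1L || click$col < 1L || click$row > shape[1L] || click$col > shape[2L])
    stop(sprintf("click (%d, %d) outside image bounds %dx%d",
                 click$row, click$col, shape[1L], shape[2L]), call. = FALSE)
  invisible(click)
}

#' Rasterize a click as a unit-disk seed mask
#'
#' The seed mask `g0` is the closed Euclidean disk of radius 1 pixel around
#' the click: the clicked pixel and its four edge neighbours, clipped at the
#' image border.
#'
#' @param click A [click()].
#' @param shape Image dimensions `c(H, W)`.
#' @return Logical H x W matrix with at most 5 `TRUE` pixels.
#' @export
click_to_dot <- function(click, shape) {
  shape <- as.integer(shape)
  check_click_bounds(click, shape)
  m <- matrix(FALSE, shape[1L], shape[2L])
  pts <- rbind(c(click$row, click$col),
               c(click$row - 1L, click$col), c(click$row + 1L, click$col),
               c(click$row, click$col - 1L), c(click$row, click$col + 1L))
  keep <- pts[, 1L] >= 1L & pts[, 1L] <= shape[1L] &
          pts[, 2L] >= 1L & pts[, 2L] <= shape[2L]
  m[pts[keep, , drop = FALSE]] <- TRUE
  m
}

#' Read a grayscale image
#'
#' PNG files (8- or 16-bit grayscale; RGB is averaged to gray) are read with
#' values already in `[0, 1]`.  NIfTI volumes (`.nii` / `.nii.gz`) are read
#' with raw scanner values preserved and an axial slice extracted; pass the
#' result through [clip_normalize()] before segmenting.
#'
#' @param path File path.
#' @param slice Axial slice index for NIfTI volumes (1-based, third axis).
#' @return Numeric matrix (H x W).
#' @export
read_image <- function(path, slice = NULL) {
  if (!file.exists(path)) stop("read_image: no such file: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    return(as.matrix(img))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 2L) return(arr)
    if (is.null(slice)) stop("read_image: NIfTI volume needs a slice index", call. = FALSE)
    if (slice < 1L || slice > dim(arr)[3L])
      stop("read_image: slice index out of range", call. = FALSE)
    return(arr[, , slice])
  }
  stop("read_image: unsupported format (expect .png or .nii/.nii.gz): ", path,
       call. = FALSE)
}

#' Write an image or mask as PNG
#'
#' @param image Numeric matrix in `[0, 1]` or logical mask.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  m <- if (is.logical(image)) image * 1 else pmin(pmax(image, 0), 1)
  png::writePNG(m, path)
  invisible(path)
}

check_intensity_image <- function(image, what = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 16L || ncol(image) < 16L)
    stop(what, " must be at least 16x16", call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop(what, " values must lie in [0, 1]", call. = FALSE)
  invisible(image)
}
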