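#' Morphological dilation of a binary mask
#'
#' Iterated dilation with a full 3x3 structuring element: after `n`
#' iterations a pixel is on iff some originally-on pixel lies within
#' Chebyshev distance `n`.  The output always contains the input.
#'
#' @param mask Logical matrix, at least one `TRUE` pixel.
#' @param iterations Number of dilation iterations (0 = identity).
#' @return Logical matrix of the same shape.
#' @export
dilate_mask <- function(mask, iterations = 7L) {
  mask <- as.matrix(mask)
  if (!any(mask)) stop("dilate_mask: mask is empty", call. = FALSE)
  iterations <- as.integer(iterations)
  if (iterations == 0L) return(mask & TRUE)
  # n iterations of a 3x3 box = one dilation with a (2n+1) box
  brush <- EBImage::makeBrush(2L * iterations + 1L, shape = "box")
  EBImage::dilate(mask * 1, brush) > 0
}

#' Crop an image to the dilated bounding box of a mask
#'
#' The crop box is the bounding box of the mask after 7 iterations of 3x3
#' dilation (so roughly 7 pixels of context on each side), clipped to the
#' image; the KDE intensity remap is estimated from this window.
#'
#' @param image Numeric H x W matrix.
#' @param mask Logical H x W matrix, non-empty.
#' @param iterations Dilation iterations used to pad the box (default 7).
#' @return A list with `values` (the cropped sub-image) and `box`
#'   (`c(row0, row1, col0, col1)`, 1-based inclusive bounds).
#' @export
crop_to_mask <- function(image, mask, iterations = 7L) {
  if (!any(mask)) stop("crop_to_mask: mask is empty", call. = FALSE)
  big <- dilate_mask(mask, iterations)
  rows <- range(which(rowSums(big) > 0))
  cols <- range(which(colSums(big) > 0))
  list(values = image[rows[1L]:rows[2L], cols[1L]:cols[2L], drop = FALSE],
       box = c(row0 = rows[1L], row1 = rows[2L], col0 = cols[1L], col1 = cols[2L]))
}

#' Gaussian kernel density estimate of pixel intensities
#'
#' Fits a Gaussian KDE to a sample of pixel values and tabulates it on a
#' 256-point lookup grid over `[0, 1]`; evaluation interpolates linearly
#' between grid nodes (values beyond the grid ends are held constant).  At
#' the grid nodes the tabulated density equals the direct Gaussian sum
#' `(1/(n h)) * sum(phi((v - s_i)/h))` exactly.  The automatic bandwidth is
#' Scott's rule `n^(-1/5) * sd(samples)`, floored at 0.01 so tiny or
#' near-constant crops cannot produce spike densities.
#'
#' @param pixels Numeric vector of pixel values; zeros are *not* filtered
#'   here (the caller excludes them), at least 2 values required.
#' @param bandwidth Positive bandwidth, or `"auto"` for Scott's rule.
#' @param grid_n Number of lookup nodes (default 256).
#' @return An object of class `"density_fn"`: fields `grid`, `dens`,
#'   `bandwidth`, `sample_count`.  Evaluate with [density_eval()].
#' @export
estimate_density <- function(pixels, bandwidth = "auto", grid_n = 256L) {
  pixels <- as.numeric(pixels)
  if (length(pixels) < 2L)
    stop("estimate_density: need at least 2 sample pixels", call. = FALSE)
  if (identical(bandwidth, "auto")) {
    bandwidth <- max(length(pixels)^(-1 / 5) * sd(pixels), 0.01)
  } else {
    bandwidth <- as.numeric(bandwidth)
    if (!is.finite(bandwidth) || bandwidth <= 0)
      stop("estimate_density: bandwidth must be positive", call. = FALSE)
  }
  grid <- seq(0, 1, length.out = grid_n)
  dens <- kde_direct(grid, pixels, bandwidth)
  structure(list(grid = grid, dens = dens, bandwidth = bandwidth,
                 sample_count = length(pixels)),
            class = "density_fn")
}

# direct Gaussian-sum KDE, chunked over samples to bound memory
kde_direct <- function(at, samples, h) {
  out <- numeric(length(at))
  chunk <- 4096L
  for (s in seq(1L, length(samples), by = chunk)) {
    sl <- samples[s:min(s + chunk - 1L, length(samples))]
    out <- out + rowSums(dnorm(outer(at, sl, "-") / h))
  }
  out / (length(samples) * h)
}

#' Evaluate a fitted pixel-value density
#'
#' @param f A `"density_fn"` from [estimate_density()].
#' @param v Numeric vector (or matrix) of query values.
#' @return Density values, same shape as `v`.
#' @export
density_eval <- function(f, v) {
  out <- approx(f$grid, f$dens, xout = as.numeric(v), rule = 2)$y
  if (is.matrix(v)) out <- matrix(out, nrow(v), ncol(v))
  out
}

#' Density-based intensity adjustment
#'
#' Replaces every pixel value of `image` by the kernel-density estimate of
#' that value, where the density is fitted to the non-zero pixels of the
#' mask's dilated crop window.  Pixels whose intensity is common around the
#' current mask (the clicked organ) are mapped near 1; intensities rare in
#' that window are suppressed toward 0.  The output is rescaled so its
#' maximum density value is 1.
#'
#' If fewer than 2 non-zero pixels remain in the crop, the density falls
#' back to a Gaussian bump (bandwidth 0.01) at the mean crop value.
#'
#' @param image Numeric H x W matrix in `[0, 1]` (the raw normalized image).
#' @param mask Logical H x W matrix (the current segmentation), non-empty.
#' @param bandwidth Passed to [estimate_density()].
#' @param iterations Crop-padding dilation iterations (default 7).
#' @return Numeric H x W matrix in `[0, 1]` with maximum exactly 1.
#' @export
adjust_intensity <- function(image, mask, bandwidth = "auto", iterations = 7L) {
  cr <- crop_to_mask(image, mask, iterations)
  samples <- cr$values[cr$values > 0]
  f <- if (length(samples) >= 2L) estimate_density(samples, bandwidth)
       else estimate_density(rep(mean(cr$values), 2L) + c(-1e-9, 1e-9), 0.01)
  x <- density_eval(f, image)
  top <- max(x)
  if (top <= 0) stop("adjust_intensity: degenerate density", call. = FALSE)
  x / top
}
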