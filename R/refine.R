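#' Standard deviation of pixel distances to a click
#'
#' Population standard deviation of the Euclidean distances from every
#' `TRUE` pixel of a region to the click position.  Floored at
#' `sigma_floor` (1 pixel by default) so singleton regions still define a
#' finite Gaussian model.
#'
#' @param region Logical matrix, non-empty.
#' @param center A [click()].
#' @param sigma_floor Lower bound on the returned value.
#' @return A positive scalar.
#' @export
region_distance_std <- function(region, center, sigma_floor = 1) {
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("region_distance_std: region is empty", call. = FALSE)
  d <- sqrt((idx[, 1L] - center$row)^2 + (idx[, 2L] - center$col)^2)
  max(sqrt(mean((d - mean(d))^2)), sigma_floor)
}

#' Isotropic 2-D Gaussian density map around a click
#'
#' `(1 / (2 * pi * sigma^2)) * exp(-d^2 / (2 * sigma^2))` at every pixel,
#' where `d` is the Euclidean distance to the click.
#'
#' @param center A [click()].
#' @param sigma Positive standard deviation in pixels.
#' @param shape Image dimensions `c(H, W)`.
#' @return Numeric H x W matrix.
#' @export
gaussian_density_map <- function(center, sigma, shape) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("gaussian_density_map: sigma must be positive", call. = FALSE)
  dr <- (seq_len(shape[1L]) - center$row)^2
  dc <- (seq_len(shape[2L]) - center$col)^2
  d2 <- outer(dr, dc, "+")
  exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
}

#' Grow a mask with an additional positive click
#'
#' Runs the full initial-segmentation process from the new click and unions
#' the resulting mask with the existing one; the mask can only grow.
#'
#' @param image Numeric H x W matrix in `[0, 1]`.
#' @param mask Logical H x W matrix (current segmentation).
#' @param click A positive [click()].
#' @param weights An [ae_weights()] object.
#' @param config A [run_config()].
#' @return Logical H x W matrix containing `mask`.
#' @export
apply_positive_click <- function(image, mask, click, weights,
                                 config = run_config()) {
  if (!click$positive)
    stop("apply_positive_click: click must be positive", call. = FALSE)
  st <- run_initial_segmentation(image, click, weights, config)
  mask | st$current_mask
}

#' Carve a mask with a negative click
#'
#' Mask pixels are partitioned by their nearest click (the negative click
#' versus each recorded positive click); each partition's Gaussian model
#' takes its click as center and the distance standard deviation of its
#' pixels as sigma.  The positive density at a pixel is the maximum over
#' the per-positive-click models.  Every mask pixel where the negative
#' density *strictly* exceeds the positive density is removed (ties keep
#' the pixel), so the mask can only shrink.  An empty result is allowed and
#' flagged with attribute `emptied = TRUE`.
#'
#' A negative click placed exactly on a positive click is contradictory;
#' the tie rule keeps every pixel, so the mask is returned unchanged.
#'
#' @param mask Logical H x W matrix, non-empty.
#' @param positive_clicks Non-empty list of positive [click()]s.
#' @param negative_click A negative [click()].
#' @param sigma_neg,sigma_pos Optional fixed sigmas overriding the
#'   partition-based estimates (`sigma_pos` applies to every positive model).
#' @return Logical H x W matrix contained in `mask`.
#' @export
apply_negative_click <- function(mask, positive_clicks, negative_click,
                                 sigma_neg = NULL, sigma_pos = NULL) {
  if (!any(mask)) stop("apply_negative_click: mask is empty", call. = FALSE)
  if (length(positive_clicks) == 0L)
    stop("apply_negative_click: at least one positive click is required",
         call. = FALSE)
  if (any(vapply(positive_clicks, function(p)
        p$row == negative_click$row && p$col == negative_click$col, logical(1))))
    return(mask)
  shape <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  dist2_to <- function(ck) (idx[, 1L] - ck$row)^2 + (idx[, 2L] - ck$col)^2
  d2_neg <- dist2_to(negative_click)
  d2_pos <- vapply(positive_clicks, dist2_to, numeric(nrow(idx)))
  d2_pos_min <- if (is.matrix(d2_pos)) apply(d2_pos, 1L, min) else d2_pos
  # partition of mask pixels: nearest positive click vs the negative click;
  # ties go to the positive side (removal requires strict dominance anyway)
  neg_side <- d2_neg < d2_pos_min

  region_from <- function(sel) {
    r <- matrix(FALSE, shape[1L], shape[2L])
    r[idx[sel, , drop = FALSE]] <- TRUE
    r
  }
  if (is.null(sigma_neg))
    sigma_neg <- if (any(neg_side))
      region_distance_std(region_from(neg_side), negative_click) else 1
  dens_neg <- gaussian_density_map(negative_click, sigma_neg, shape)

  nearest_pos <- if (is.matrix(d2_pos)) max.col(-d2_pos, ties.method = "first")
                 else rep(1L, nrow(idx))
  dens_pos <- matrix(-Inf, shape[1L], shape[2L])
  for (p in seq_along(positive_clicks)) {
    sel <- !neg_side & nearest_pos == p
    sigma_p <- if (!is.null(sigma_pos)) sigma_pos
               else if (any(sel))
                 region_distance_std(region_from(sel), positive_clicks[[p]])
               else 1
    dens_pos <- pmax(dens_pos,
                     gaussian_density_map(positive_clicks[[p]], sigma_p, shape))
  }
  out <- mask & !(dens_neg > dens_pos)
  if (!any(out)) attr(out, "emptied") <- TRUE
  out
}
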