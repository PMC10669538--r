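#' Default phantom generation parameters
#'
#' 256 x 256 pixels, three organ blobs with mean intensities 0.7, 0.45 and
#' 0.3 (per-pixel s.d. 0.03) on a textured background of mean 0.1, plus
#' Gaussian pixel noise of s.d. 0.02.  The organ means are separated by at
#' least three times the noise level, which mimics the soft-tissue contrast
#' of a windowed abdominal CT slice and keeps the density remap well-posed.
#'
#' @param size Image dimensions `c(H, W)`.
#' @param organ_means Mean intensity per organ (length = organ count).
#' @param organ_sds Per-pixel intensity s.d. per organ (recycled).
#' @param background_mean Background mean intensity.
#' @param noise_sd Global additive Gaussian noise s.d.
#' @param radius_frac Range of organ base radii, as a fraction of the
#'   smaller image dimension.
#' @param boundary_amp Relative amplitude budget of the radial Fourier
#'   perturbation of each organ boundary (up to 5 harmonics).
#' @return A named list of generation parameters.
#' @export
phantom_config <- function(size = c(256L, 256L),
                           organ_means = c(0.7, 0.45, 0.3),
                           organ_sds = 0.03,
                           background_mean = 0.1,
                           noise_sd = 0.02,
                           radius_frac = c(0.10, 0.18),
                           boundary_amp = 0.08) {
  if (length(organ_means) < 1L)
    stop("phantom_config: at least one organ is required", call. = FALSE)
  list(size = as.integer(size), organ_means = organ_means,
       organ_sds = rep_len(organ_sds, length(organ_means)),
       background_mean = background_mean, noise_sd = noise_sd,
       radius_frac = radius_frac, boundary_amp = boundary_amp)
}

# smooth low-frequency field in [-1, 1] (sum of a few random 2-D cosines)
smooth_field <- function(h, w, n_waves = 4L) {
  ys <- seq_len(h) / h; xs <- seq_len(w) / w
  f <- matrix(0, h, w)
  for (k in seq_len(n_waves)) {
    fy <- runif(1, 0.5, 3); fx <- runif(1, 0.5, 3); ph <- runif(2, 0, 2 * pi)
    f <- f + outer(cos(2 * pi * fy * ys + ph[1L]),
                   cos(2 * pi * fx * xs + ph[2L]))
  }
  f / n_waves
}

# rasterize a Fourier-perturbed blob: radius(theta) = r0 * (1 + sum a_m cos(m theta + phi_m))
blob_mask <- function(h, w, center, r0, amp) {
  n_h <- 5L
  a <- runif(n_h, 0, amp) / seq_len(n_h)
  ph <- runif(n_h, 0, 2 * pi)
  dy <- matrix(seq_len(h) - center[1L], h, w)
  dx <- matrix(seq_len(w) - center[2L], h, w, byrow = TRUE)
  theta <- atan2(dx, dy)
  r_at <- r0 * (1 + Reduce(`+`, lapply(seq_len(n_h), function(m)
    a[m] * cos(m * theta + ph[m]))))
  sqrt(dy^2 + dx^2) <= r_at
}

#' Generate a CT-like phantom with ground-truth organ masks
#'
#' Renders smooth random organ blobs (Fourier-perturbed ellipse-like
#' boundaries) with distinct intensity distributions on a textured
#' background, adds Gaussian pixel noise, and clips to `[0, 1]`.  Organ
#' masks are pairwise disjoint and each at least 50 pixels.  Generation is
#' a pure function of `(config, seed)`.
#'
#' @param config A [phantom_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `"phantom_sample"`: `image` (H x W in
#'   `[0, 1]`), `organ_masks` (named list of logical matrices), `centers`
#'   (organ seed centers, rows of `(row, col)`), `config`, `seed`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 0L) {
  set.seed(seed)
  h <- config$size[1L]; w <- config$size[2L]
  n_org <- length(config$organ_means)
  r_px <- config$radius_frac * min(h, w)

  # place organ centers by rejection so blobs (with boundary wobble) stay disjoint
  centers <- matrix(NA_real_, 0L, 2L)
  radii <- numeric(0)
  tries <- 0L
  while (nrow(centers) < n_org) {
    tries <- tries + 1L
    if (tries > 2000L)
      stop("generate_phantom: organs cannot fit; reduce count or radii",
           call. = FALSE)
    r0 <- runif(1, r_px[1L], r_px[2L])
    margin <- r0 * (1 + config$boundary_amp) + 2
    cand <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
    ok <- TRUE
    if (nrow(centers) > 0L) {
      dmin <- sqrt((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2)
      ok <- all(dmin > (radii + r0) * (1 + config$boundary_amp) + 4)
    }
    if (ok) { centers <- rbind(centers, cand); radii <- c(radii, r0) }
  }

  masks <- vector("list", n_org)
  for (k in seq_len(n_org)) {
    m <- blob_mask(h, w, centers[k, ], radii[k], config$boundary_amp)
    if (sum(m) < 50L)
      stop("generate_phantom: organ ", k, " smaller than 50 pixels", call. = FALSE)
    masks[[k]] <- m
  }
  names(masks) <- paste0("organ", seq_len(n_org))

  img <- config$background_mean * (1 + 0.4 * smooth_field(h, w))
  for (k in seq_len(n_org)) {
    m <- masks[[k]]
    img[m] <- config$organ_means[k] + rnorm(sum(m), 0, config$organ_sds[k])
  }
  img <- img + rnorm(h * w, 0, config$noise_sd)
  img <- matrix(pmin(pmax(img, 0), 1), h, w)

  structure(list(image = img, organ_masks = masks, centers = centers,
                 config = config, seed = seed),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample: %dx%d, %d organ(s), seed %d>\n",
              nrow(x$image), ncol(x$image), length(x$organ_masks), x$seed))
  invisible(x)
}

#' Generate a texture corpus for fixture-autoencoder training
#'
#' A mixture of image families so the fixture learns to reconstruct both
#' anatomy-like and generic structure: multi-organ phantoms, linear and
#' radial gradients, smooth blob fields, and band-limited noise fields.
#' All images are in `[0, 1]`; generation is deterministic per seed.
#'
#' @param n Number of images (>= 1).
#' @param size Image dimensions `c(H, W)` (default 128 x 128).
#' @param seed Integer RNG seed.
#' @return A list of `n` numeric matrices.
#' @export
generate_texture_corpus <- function(n, size = c(128L, 128L), seed = 0L) {
  if (n < 1L) stop("generate_texture_corpus: n must be >= 1", call. = FALSE)
  set.seed(seed)
  h <- size[1L]; w <- size[2L]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- (i - 1L) %% 4L
    out[[i]] <- switch(as.character(kind),
      "0" = { # phantom-like; organ radii floored (>=50 px organ invariant)
              # and organ count capped so blobs can fit on small images
        nk_max <- if (min(h, w) >= 96L) 3L else if (min(h, w) >= 48L) 2L else 1L
        nk <- sample(seq_len(nk_max), 1L)
        r_lo <- max(0.10, 5.5 / min(h, w))
        cfg <- phantom_config(size = c(h, w),
                              organ_means = runif(nk, 0.25, 0.85),
                              organ_sds = runif(1, 0.01, 0.05),
                              background_mean = runif(1, 0.05, 0.2),
                              noise_sd = runif(1, 0.005, 0.03),
                              radius_frac = c(r_lo, r_lo + 0.08))
        generate_phantom(cfg, seed = sample.int(2^30, 1L))$image
      },
      "1" = { # linear / radial gradient
        if (runif(1) < 0.5) {
          ang <- runif(1, 0, 2 * pi)
          g <- outer(seq_len(h) / h * sin(ang), seq_len(w) / w * cos(ang), "+")
        } else {
          cy <- runif(1, 1, h); cx <- runif(1, 1, w)
          g <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
        }
        g <- (g - min(g)) / max(max(g) - min(g), 1e-12)
        if (runif(1) < 0.5) g <- 1 - g
        g
      },
      "2" = { # smooth blob field
        f <- smooth_field(h, w, n_waves = sample(2:6, 1L))
        (f - min(f)) / max(max(f) - min(f), 1e-12)
      },
      "3" = { # band-limited noise (noise blurred by a box filter)
        z <- matrix(runif(h * w), h, w)
        k <- sample(c(3L, 5L, 7L), 1L)
        z <- EBImage::filter2(z, matrix(1 / k^2, k, k))
        matrix(pmin(pmax(z, 0), 1), h, w)
      })
  }
  out
}
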