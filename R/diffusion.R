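#' Decode the latent-space blend of an image with a companion image
#'
#' Encodes both images, averages the latents element-wise, and decodes.
#' In the segmentation step the companion is either the current mask
#' rendered as a `{0,1}` intensity image or the all-black reference; with
#' two arbitrary images this operation demonstrates the reconstruction
#' noise that drives the whole method (the decoded blend differs from the
#' pixel-level average because of the bottleneck).
#'
#' @param image,companion Numeric H x W matrices in `[0, 1]`, same shape.
#' @param weights An [ae_weights()] object.
#' @return Numeric H x W matrix in `[0, 1]`.
#' @export
mixed_decode <- function(image, companion, weights) {
  if (!identical(dim(image), dim(companion)))
    stop("mixed_decode: image and companion shapes differ", call. = FALSE)
  ae_decode(mix_features(ae_encode(image, weights),
                         ae_encode(companion, weights)), weights)
}

#' Otsu threshold of a grid of values
#'
#' Builds a 256-bin histogram over the value range and returns the
#' threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`.  Classes are "bins 0..k" vs "bins k+1..255";
#' the returned threshold is the lower edge of bin `k+1`, so `values >=
#' threshold` reproduces the high class.  Ties are broken toward the lowest
#' maximizing bin.
#'
#' @param values Numeric vector or matrix with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value (scalar).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || !is.finite(hi) || lo == hi)
    stop("otsu_threshold: input is constant", call. = FALSE)
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((v - lo) / width), n_bins - 1L)   # 0-based bin index
  counts <- tabulate(bin + 1L, nbins = n_bins)
  n <- length(v)
  mids <- lo + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(counts)[-n_bins]
  s0 <- cumsum(counts * mids)[-n_bins]
  total <- sum(counts * mids)
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (total - s0[valid]) / w1[valid]
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  k <- which.max(bcv)                                  # lowest maximizing split
  lo + k * width
}

render_mask <- function(mask) {
  m <- matrix(0, nrow(mask), ncol(mask))
  m[mask] <- 1
  m
}

keep_touching_components <- function(mask, anchor) {
  lab <- label8(mask)
  keep_ids <- unique(lab[anchor & mask])
  keep_ids <- keep_ids[keep_ids != 0L]
  if (length(keep_ids) == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  matrix(lab %in% keep_ids, nrow(mask), ncol(mask))
}

#' One segmentation-growth step
#'
#' Given the image and the current mask `g`, computes the next mask:
#' 1. density-based intensity adjustment of the image around `g`
#'    ([adjust_intensity()]);
#' 2. latent blends of the adjusted image with the rendered mask and with
#'    the all-black reference ([mixed_decode()]);
#' 3. the absolute difference of the two blends (every region the mask's
#'    presence alters; `difference_mode = "signed"` instead keeps only
#'    brightened regions), thresholded by [otsu_threshold()];
#' 4. restriction to the 8-connected components that intersect `g`, so the
#'    mask cannot jump to disconnected look-alike regions.
#'
#' If the difference image is constant (degenerate Otsu) or no surviving
#' component touches `g`, the input mask is returned unchanged with
#' attribute `degenerate = TRUE`.
#'
#' @param image Numeric H x W matrix in `[0, 1]`.
#' @param mask Logical H x W matrix, non-empty.
#' @param weights An [ae_weights()] object.
#' @param config A [run_config()]; controls dilation iterations, bandwidth,
#'   component restriction and difference mode.
#' @return Logical H x W matrix; attribute `threshold` holds the Otsu
#'   threshold used (NA if degenerate).
#' @export
segmentation_step <- function(image, mask, weights, config = run_config()) {
  if (!any(mask)) stop("segmentation_step: mask is empty", call. = FALSE)
  x <- adjust_intensity(image, mask, bandwidth = config$kde_bandwidth,
                        iterations = config$dilation_iterations)
  fx <- ae_encode(x, weights)   # shared by both blends
  a_mask <- ae_decode(mix_features(fx, ae_encode(render_mask(mask), weights)),
                      weights)
  a_black <- ae_decode(mix_features(fx, ae_encode(matrix(0, nrow(x), ncol(x)),
                                                  weights)), weights)
  d <- if (identical(config$difference_mode, "abs")) abs(a_mask - a_black)
       else pmax(a_mask - a_black, 0)
  if (max(d) == min(d))
    return(structure(mask, threshold = NA_real_, degenerate = TRUE))
  thr <- otsu_threshold(d)
  nxt <- d >= thr
  if (isTRUE(config$restrict_components))
    nxt <- keep_touching_components(nxt, mask)
  if (!any(nxt))
    return(structure(mask, threshold = thr, degenerate = TRUE))
  structure(nxt, threshold = thr)
}

#' Grow a single click into an initial segmentation mask
#'
#' Starts from the unit-disk seed at the click and iterates
#' [segmentation_step()] until two successive masks are identical (a fixed
#' point), a previously seen mask recurs (a cycle, possible because the
#' Otsu threshold can oscillate early on), or `max_iterations` is reached.
#'
#' @param image Numeric H x W matrix in `[0, 1]`.
#' @param click A positive [click()] inside the image.
#' @param weights An [ae_weights()] object.
#' @param config A [run_config()]; `max_iterations` defaults to 50.
#' @return An object of class `"segmentation_state"`: `current_mask`,
#'   `iteration`, `converged`, `cycle`, `area_history`, `threshold_trace`,
#'   and the seeding `click`.
#' @export
run_initial_segmentation <- function(image, click, weights,
                                     config = run_config()) {
  check_intensity_image(image)
  if (!click$positive)
    stop("run_initial_segmentation: the seeding click must be positive",
         call. = FALSE)
  g <- click_to_dot(click, dim(image))
  seen <- new.env(parent = emptyenv())
  assign(rlang::hash(g), TRUE, envir = seen)
  areas <- sum(g)
  thresholds <- numeric(0)
  converged <- FALSE; cycle <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    nxt <- segmentation_step(image, g, weights, config)
    thresholds <- c(thresholds, attr(nxt, "threshold"))
    nxt_plain <- matrix(as.logical(nxt), nrow(nxt), ncol(nxt))
    areas <- c(areas, sum(nxt_plain))
    if (identical(nxt_plain, g)) { converged <- TRUE; break }
    key <- rlang::hash(nxt_plain)
    if (exists(key, envir = seen, inherits = FALSE)) {
      g <- nxt_plain; cycle <- TRUE; break
    }
    assign(key, TRUE, envir = seen)
    g <- nxt_plain
  }
  structure(list(current_mask = g, iteration = it, converged = converged,
                 cycle = cycle, area_history = areas,
                 threshold_trace = thresholds, click = click),
            class = "segmentation_state")
}

#' @export
print.segmentation_state <- function(x, ...) {
  cat(sprintf("<segmentation_state: %d px after %d iteration(s); %s>\n",
              sum(x$current_mask), x$iteration,
              if (x$converged) "converged"
              else if (x$cycle) "stopped on cycle" else "hit iteration cap"))
  invisible(x)
}
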