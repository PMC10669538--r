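# Independent brute-force oracles. These deliberately avoid the package's
# computational paths (no shared helpers): plain loops and closed forms.

# Otsu: exhaustive search over all 256-bin splits, explicit per-split means.
oracle_otsu <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((v - lo) / width), n_bins - 1L)  # 0-based
  best_bcv <- -Inf; best_k <- NA_integer_
  n <- length(v)
  for (k in 1:(n_bins - 1L)) {       # split: bins 0..k-1 vs k..n_bins-1
    left <- bin < k
    n0 <- sum(left); n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    mids <- lo + (bin + 0.5) * width
    mu0 <- mean(mids[left]); mu1 <- mean(mids[!left])
    bcv <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (bcv > best_bcv + 1e-18) { best_bcv <- bcv; best_k <- k }
  }
  lo + best_k * width
}

# KDE: direct Gaussian sum, scalar loop.
oracle_kde <- function(at, samples, h) {
  vapply(at, function(a)
    sum(exp(-((a - samples) / h)^2 / 2)) / (length(samples) * h * sqrt(2 * pi)),
    numeric(1))
}

# Dilation: pixel on iff any input-on pixel within Chebyshev distance n.
oracle_dilate <- function(mask, n) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  on <- which(mask, arr.ind = TRUE)
  for (j in 1:W) for (i in 1:H) {
    out[i, j] <- any(pmax(abs(on[, 1L] - i), abs(on[, 2L] - j)) <= n)
  }
  out
}

# Bilinear resize with explicit per-pixel arithmetic (pixel-center align).
oracle_bilinear <- function(img, size) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, size[1L], size[2L])
  for (i in seq_len(size[1L])) for (j in seq_len(size[2L])) {
    y <- min(max((i - 0.5) / size[1L] * H - 0.5, 0), H - 1)
    x <- min(max((j - 0.5) / size[2L] * W - 0.5, 0), W - 1)
    y0 <- min(floor(y), H - 1); y1 <- min(y0 + 1, H - 1); fy <- y - y0
    x0 <- min(floor(x), W - 1); x1 <- min(x0 + 1, W - 1); fx <- x - x0
    out[i, j] <- (1 - fy) * (1 - fx) * img[y0 + 1, x0 + 1] +
      fy * (1 - fx) * img[y1 + 1, x0 + 1] +
      (1 - fy) * fx * img[y0 + 1, x1 + 1] + fy * fx * img[y1 + 1, x1 + 1]
  }
  out
}

# Interior-most point: per-pixel minimum distance to any FALSE pixel
# (image border is not background); ties -> lowest row, then column.
oracle_interior_point <- function(region) {
  H <- nrow(region); W <- ncol(region)
  off <- which(!region, arr.ind = TRUE)
  best <- -Inf; best_pt <- NULL
  for (j in 1:W) for (i in 1:H) {
    if (!region[i, j]) next
    d <- if (nrow(off) == 0L) Inf
         else sqrt(min((off[, 1L] - i)^2 + (off[, 2L] - j)^2))
    if (d > best + 1e-12) { best <- d; best_pt <- c(i, j) }
  }
  best_pt
}

# Plain-R forward pass of an encoder layer stack (reflect padding, explicit
# quadruple loops at tiny sizes) — independent of the C++ path.
oracle_encoder_forward <- function(spec, enc_weights, image) {
  reflect <- function(i, n) { if (i < 1) i <- 2 - i; if (i > n) i <- 2 * n - i; i }
  x <- array(rep(image, 3L), dim = c(nrow(image), ncol(image), 3L))
  for (l in seq_along(spec$encoder_layers)) {
    ly <- spec$encoder_layers[[l]]
    if (ly$kind == "pool") {
      H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
      Ho <- ceiling(H / 2); Wo <- ceiling(W / 2)
      y <- array(NA_real_, c(Ho, Wo, C))
      for (c_ in 1:C) for (jo in 1:Wo) for (io in 1:Ho) {
        is <- (2 * io - 1):min(2 * io, H); js <- (2 * jo - 1):min(2 * jo, W)
        y[io, jo, c_] <- max(x[is, js, c_])
      }
      x <- y
      next
    }
    k <- ly$k; pad <- (k - 1) %/% 2
    H <- dim(x)[1L]; W <- dim(x)[2L]
    y <- array(0, c(H, W, ly$out_ch))
    Wm <- enc_weights[[l]]$W; b <- enc_weights[[l]]$b
    for (co in 1:ly$out_ch) for (j in 1:W) for (i in 1:H) {
      acc <- b[co]
      for (ci in 1:ly$in_ch) for (dj in 1:k) for (di in 1:k) {
        ri <- reflect(i + di - 1 - pad, H); rj <- reflect(j + dj - 1 - pad, W)
        wcol <- ((ci - 1) * k + (dj - 1)) * k + di
        acc <- acc + Wm[co, wcol] * x[ri, rj, ci]
      }
      y[i, j, co] <- if (ly$relu) max(acc, 0) else acc
    }
    x <- y
  }
  x
}
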