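#' Describe the VGG19-style autoencoder architecture
#'
#' The encoder is the convolutional part of VGG19 truncated after the first
#' convolution of the deepest configured block, preceded by a 1x1
#' input-preprocessing convolution ("conv0").  Each block is a run of 3x3
#' convolutions followed by a 2x2/stride-2 max pool; the latent feature is
#' the activation after the deepest block's first convolution (no pool).
#' The decoder mirrors the encoder with nearest-neighbour upsampling in
#' place of pooling, and ends with a 3x3 projection to 3 channels plus a
#' final linear 1x1 convolution.  All 3x3 convolutions use reflection
#' padding 1 so spatial size is preserved; every convolution is followed by
#' ReLU except the final projection.
#'
#' With the defaults (`depth_blocks = 3`, `width = 1`) the layer list is the
#' standard three-block VGG19 autoencoder: channels 64, 128, 256 and a
#' 256-channel latent at 1/4 spatial resolution.  `width` scales all channel
#' counts (the fixture autoencoder shipped for testing uses `width = 0.25`).
#'
#' @param depth_blocks Number of convolutional blocks used, 1 to 5.
#' @param width Channel-width multiplier (default 1 = full VGG19 widths).
#' @return An object of class `"ae_spec"`: lists of encoder and decoder
#'   layer descriptors (`name`, `kind`, `k`, `in_ch`, `out_ch`, `relu`).
#' @export
ae_spec <- function(depth_blocks = 3L, width = 1) {
  depth_blocks <- as.integer(depth_blocks)
  if (!depth_blocks %in% 1:5)
    stop("ae_spec: depth_blocks must be in 1..5", call. = FALSE)
  base_ch <- c(64L, 128L, 256L, 512L, 512L)
  n_convs <- c(2L, 2L, 4L, 4L, 4L)
  ch <- pmax(1L, as.integer(round(base_ch * width)))

  conv <- function(name, k, in_ch, out_ch, relu = TRUE)
    list(name = name, kind = "conv", k = as.integer(k),
         in_ch = as.integer(in_ch), out_ch = as.integer(out_ch), relu = relu)
  pool <- function() list(name = "pool", kind = "pool")
  upsm <- function() list(name = "upsample", kind = "upsample")

  enc <- list(conv("conv0", 1L, 3L, 3L))
  prev <- 3L
  for (b in seq_len(depth_blocks)) {
    last_block <- b == depth_blocks
    n <- if (last_block) 1L else n_convs[b]
    for (j in seq_len(n)) {
      enc[[length(enc) + 1L]] <- conv(sprintf("conv%d_%d", b, j), 3L, prev, ch[b])
      prev <- ch[b]
    }
    if (!last_block) enc[[length(enc) + 1L]] <- pool()
  }

  dec <- list()
  for (b in rev(seq_len(depth_blocks))) {
    last_block <- b == depth_blocks
    n <- if (last_block) 1L else n_convs[b]
    for (j in rev(seq_len(n))) {
      out_ch <- if (b == 1L && j == 1L) 3L else if (j == 1L) ch[b - 1L] else ch[b]
      dec[[length(dec) + 1L]] <- conv(sprintf("dconv%d_%d", b, j), 3L, prev, out_ch)
      prev <- out_ch
    }
    if (b > 1L) dec[[length(dec) + 1L]] <- upsm()
  }
  dec[[length(dec) + 1L]] <- conv("dconv0", 1L, 3L, 3L, relu = FALSE)

  structure(list(depth_blocks = depth_blocks, width = width,
                 encoder_layers = enc, decoder_layers = dec),
            class = "ae_spec")
}

#' @export
print.ae_spec <- function(x, ...) {
  cat(sprintf("<ae_spec: %d block(s), width %.3g, %d encoder / %d decoder layers>\n",
              x$depth_blocks, x$width,
              length(x$encoder_layers), length(x$decoder_layers)))
  invisible(x)
}

#' Number of trainable parameters of an architecture
#' @param spec An [ae_spec()].
#' @return Integer parameter count (weights + biases).
#' @export
ae_n_params <- function(spec) {
  n <- 0
  for (ly in c(spec$encoder_layers, spec$decoder_layers))
    if (ly$kind == "conv") n <- n + ly$k^2 * ly$in_ch * ly$out_ch + ly$out_ch
  as.integer(n)
}

# He-normal initialisation; the 1x1 pre/post-processing convolutions start
# at the identity so signal flows through untouched at step 0 (guards the
# all-ReLU stack against early dead-unit collapse)
init_conv <- function(ly) {
  fan_in <- ly$k^2 * ly$in_ch
  if (ly$k == 1L && ly$in_ch == ly$out_ch)
    return(list(W = diag(ly$out_ch), b = numeric(ly$out_ch)))
  list(W = matrix(rnorm(ly$out_ch * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = ly$out_ch, ncol = fan_in),
       b = numeric(ly$out_ch))
}

#' Initialise random autoencoder weights
#'
#' He-normal weights, zero biases; deterministic for a fixed seed.
#'
#' @param spec An [ae_spec()].
#' @param seed Integer RNG seed.
#' @return An object of class `"ae_weights"`.
#' @export
ae_init_weights <- function(spec, seed = 0L) {
  set.seed(seed)
  mk <- function(layers) lapply(layers, function(ly)
    if (ly$kind == "conv") init_conv(ly) else list())
  structure(list(spec = spec, encoder = mk(spec$encoder_layers),
                 decoder = mk(spec$decoder_layers), history = NULL),
            class = "ae_weights")
}

#' @export
print.ae_weights <- function(x, ...) {
  cat(sprintf("<ae_weights: %d block(s), width %.3g, %s parameters%s>\n",
              x$spec$depth_blocks, x$spec$width,
              format(ae_n_params(x$spec), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

# run one descriptor list forward; returns list(out, acts) when keep = TRUE,
# where acts[[l]] holds the layer *input* (and pool indices) for backprop
net_forward <- function(layers, weights, x, keep = FALSE) {
  acts <- if (keep) vector("list", length(layers)) else NULL
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$kind == "conv") {
      y <- conv_fwd(x, weights[[l]]$W, weights[[l]]$b, ly$k, ly$relu)
      if (keep) acts[[l]] <- list(x = x, out = y)
      x <- y
    } else if (ly$kind == "pool") {
      p <- maxpool_fwd(x)
      if (keep) acts[[l]] <- list(H = dim(x)[1L], W = dim(x)[2L], idx = p$idx)
      x <- p$out
    } else { # upsample
      if (keep) acts[[l]] <- list()
      x <- upsample_fwd(x)
    }
  }
  if (keep) list(out = x, acts = acts) else x
}

net_backward <- function(layers, weights, acts, gout) {
  grads <- vector("list", length(layers))
  g <- gout
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]
    if (ly$kind == "conv") {
      bw <- conv_bwd(acts[[l]]$x, weights[[l]]$W, acts[[l]]$out, g, ly$k, ly$relu)
      grads[[l]] <- list(W = bw$gW, b = as.numeric(bw$gb))
      g <- bw$gx
    } else if (ly$kind == "pool") {
      g <- maxpool_bwd(g, acts[[l]]$idx, acts[[l]]$H, acts[[l]]$W)
      grads[[l]] <- list()
    } else {
      g <- upsample_bwd(g)
      grads[[l]] <- list()
    }
  }
  list(grads = grads, gx = g)
}

gray_to_cube <- function(image) {
  array(rep(as.numeric(image), 3L), dim = c(nrow(image), ncol(image), 3L))
}

#' Encode an image into the autoencoder's latent feature
#'
#' Grayscale input is replicated to 3 channels, passed through the encoder,
#' and the activation after the deepest configured block is returned.  For
#' the default 3-block architecture the latent has `C = 256 * width`
#' channels at spatial size `(ceiling(H/4), ceiling(W/4))`.  Deterministic
#' for fixed weights.
#'
#' @param image Numeric H x W matrix with values in `[0, 1]`.
#' @param weights An [ae_weights()] object.
#' @return A 3-D array `(h, w, C)` of class `"latent_feature"` with
#'   attribute `source_shape = c(H, W)`.
#' @export
ae_encode <- function(image, weights) {
  check_intensity_image(image)
  z <- net_forward(weights$spec$encoder_layers, weights$encoder,
                   gray_to_cube(image))
  structure(z, source_shape = dim(image), class = "latent_feature")
}

#' Decode a latent feature back to an image
#'
#' Runs the mirrored decoder, averages the 3 output channels to gray, clamps
#' to `[0, 1]`, and crops to the source image size recorded on the latent.
#'
#' @param latent A `"latent_feature"` from [ae_encode()] (or an arithmetic
#'   combination of such; `source_shape` must be present).
#' @param weights An [ae_weights()] object.
#' @return Numeric H x W matrix in `[0, 1]`.
#' @export
ae_decode <- function(latent, weights) {
  dec1 <- weights$spec$decoder_layers[[1L]]
  if (dim(latent)[3L] != dec1$in_ch)
    stop(sprintf("ae_decode: latent has %d channels but decoder layer '%s' expects %d",
                 dim(latent)[3L], dec1$name, dec1$in_ch), call. = FALSE)
  y <- net_forward(weights$spec$decoder_layers, weights$decoder,
                   unclass_latent(latent))
  img <- (y[, , 1L] + y[, , 2L] + y[, , 3L]) / 3
  ss <- attr(latent, "source_shape")
  if (!is.null(ss)) img <- img[seq_len(ss[1L]), seq_len(ss[2L]), drop = FALSE]
  pmin(pmax(img, 0), 1)
}

unclass_latent <- function(latent) {
  a <- unclass(latent)
  attr(a, "source_shape") <- NULL
  a
}

#' Average two latent features element-wise
#'
#' The feature-mixing primitive: the blend of two images in latent space is
#' the element-wise mean of their encoder features.
#'
#' @param f1,f2 Latent features of identical shape.
#' @return A latent feature of the same shape (keeps `f1`'s source shape).
#' @export
mix_features <- function(f1, f2) {
  if (!identical(dim(f1), dim(f2)))
    stop("mix_features: latent shapes differ", call. = FALSE)
  structure((unclass_latent(f1) + unclass_latent(f2)) / 2,
            source_shape = attr(f1, "source_shape"), class = "latent_feature")
}

#' Save autoencoder weights to a self-describing JSON file
#'
#' The file records the architecture (depth, width, per-layer shapes) next
#' to the flattened weight arrays, so loading validates layer-by-layer.
#'
#' @param weights An [ae_weights()] object.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
ae_save_weights <- function(weights, path) {
  pack <- function(layers, wts) lapply(seq_along(layers), function(l) {
    ly <- layers[[l]]
    if (ly$kind != "conv") return(list(name = ly$name, kind = ly$kind))
    list(name = ly$name, kind = "conv", k = ly$k, in_ch = ly$in_ch,
         out_ch = ly$out_ch, relu = ly$relu,
         W = as.numeric(wts[[l]]$W), b = as.numeric(wts[[l]]$b))
  })
  obj <- list(format = "clickseg-ae-weights-v1",
              depth_blocks = weights$spec$depth_blocks,
              width = weights$spec$width,
              encoder = pack(weights$spec$encoder_layers, weights$encoder),
              decoder = pack(weights$spec$decoder_layers, weights$decoder))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load autoencoder weights saved by [ae_save_weights()]
#'
#' @param path Path to the JSON weights file.
#' @return An [ae_weights()] object identical to the one saved.
#' @export
ae_load_weights <- function(path) {
  if (!file.exists(path))
    stop("ae_load_weights: no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "clickseg-ae-weights-v1"))
    stop("ae_load_weights: unrecognised weight file format", call. = FALSE)
  spec <- ae_spec(obj$depth_blocks, obj$width)
  unpack <- function(layers, saved, side) lapply(seq_along(layers), function(l) {
    ly <- layers[[l]]
    if (l > length(saved))
      stop(sprintf("ae_load_weights: %s is missing layer %d ('%s')",
                   side, l, ly$name), call. = FALSE)
    sv <- saved[[l]]
    if (!identical(as.character(sv$name), ly$name))
      stop(sprintf("ae_load_weights: %s layer %d is '%s' but spec expects '%s'",
                   side, l, sv$name, ly$name), call. = FALSE)
    if (ly$kind != "conv") return(list())
    fan_in <- ly$k^2 * ly$in_ch
    W <- unlist(sv$W)
    if (length(W) != ly$out_ch * fan_in)
      stop(sprintf("ae_load_weights: %s layer '%s' has %d weights, expected %d",
                   side, ly$name, length(W), ly$out_ch * fan_in), call. = FALSE)
    list(W = matrix(W, nrow = ly$out_ch, ncol = fan_in), b = unlist(sv$b))
  })
  structure(list(spec = spec,
                 encoder = unpack(spec$encoder_layers, obj$encoder, "encoder"),
                 decoder = unpack(spec$decoder_layers, obj$decoder, "decoder"),
                 history = NULL),
            class = "ae_weights")
}
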