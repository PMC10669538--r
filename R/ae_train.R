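#' Train the fixture autoencoder on a texture corpus
#'
#' Trains a reduced-width copy of the VGG19-style autoencoder to reconstruct
#' its input (mean squared error on the 3-channel replicated grayscale),
#' using Adam with mini-batch gradient accumulation.  This produces the
#' *fixture* weights the test and evaluation harness runs on: same topology
#' as the full architecture, smaller channel widths, trained in minutes on
#' one CPU at 128x128.  Externally pretrained full-width weights can be
#' dropped in via [ae_load_weights()] wherever fixture weights are accepted.
#'
#' Training is fully deterministic for a fixed seed (weight initialisation,
#' shuffling, and the single-threaded forward/backward passes).
#'
#' @param corpus List of numeric H x W matrices in `[0, 1]`, all the same size.
#' @param epochs Number of passes over the corpus.
#' @param seed Integer RNG seed.
#' @param width Channel-width multiplier of the fixture (default 0.125,
#'   i.e. channels 8/16/32).  The reduced width is not only a speed matter:
#'   overly faithful reconstructions weaken the blend's spatial spread, so a
#'   narrower bottleneck also segments phantoms better than full width.
#' @param depth_blocks Encoder depth (default 3, as in the full model).
#' @param lr Adam learning rate; a vector is recycled over epochs, so a
#'   decaying schedule can be given as e.g. `c(2e-3, 2e-3, 5e-4)`.
#' @param batch_size Images per gradient step.
#' @param holdout Optional list of held-out images; per-epoch reconstruction
#'   error on them is recorded in the history.
#' @param verbose Print per-epoch losses.
#' @return An [ae_weights()] object whose `history` field holds per-epoch
#'   mean training loss (`$loss`) and, if given, holdout error (`$holdout`).
#' @export
train_fixture_autoencoder <- function(corpus, epochs = 6L, seed = 0L,
                                      width = 0.125, depth_blocks = 3L,
                                      lr = c(1e-3, 2e-3, 2e-3, 2e-3, 1e-3, 5e-4),
                                      batch_size = 4L,
                                      holdout = NULL, verbose = FALSE) {
  if (length(corpus) == 0L)
    stop("train_fixture_autoencoder: corpus is empty", call. = FALSE)
  dims <- unique(lapply(corpus, dim))
  if (length(dims) != 1L)
    stop("train_fixture_autoencoder: corpus images must share one size", call. = FALSE)

  spec <- ae_spec(depth_blocks, width)
  w <- ae_init_weights(spec, seed = seed)
  layers <- c(spec$encoder_layers, spec$decoder_layers)
  wts <- c(w$encoder, w$decoder)
  n_enc <- length(spec$encoder_layers)

  # Adam state per conv layer
  mom <- lapply(seq_along(layers), function(l) {
    if (layers[[l]]$kind != "conv") return(list())
    list(mW = wts[[l]]$W * 0, vW = wts[[l]]$W * 0,
         mb = wts[[l]]$b * 0, vb = wts[[l]]$b * 0)
  })
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L

  loss_of <- function(out, target) mean((out - target)^2)

  lr_sched <- rep_len(lr, epochs)
  history <- list(loss = numeric(0), holdout = numeric(0))
  for (ep in seq_len(epochs)) {
    lr_ep <- lr_sched[ep]
    ord <- sample.int(length(corpus))
    ep_losses <- numeric(0)
    for (start in seq(1L, length(ord), by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, length(ord))]
      acc <- NULL
      batch_loss <- 0
      for (b in batch) {
        x3 <- gray_to_cube(corpus[[b]])
        fw <- net_forward(layers, wts, x3, keep = TRUE)
        gout <- 2 * (fw$out - x3) / length(x3)
        batch_loss <- batch_loss + loss_of(fw$out, x3)
        bw <- net_backward(layers, wts, fw$acts, gout)
        if (is.null(acc)) acc <- bw$grads
        else for (l in seq_along(acc)) {
          if (layers[[l]]$kind != "conv") next
          acc[[l]]$W <- acc[[l]]$W + bw$grads[[l]]$W
          acc[[l]]$b <- acc[[l]]$b + bw$grads[[l]]$b
        }
      }
      nb <- length(batch)
      ep_losses <- c(ep_losses, batch_loss / nb)
      t_step <- t_step + 1L
      corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
      for (l in seq_along(layers)) {
        if (layers[[l]]$kind != "conv") next
        gW <- acc[[l]]$W / nb; gb <- acc[[l]]$b / nb
        mom[[l]]$mW <- beta1 * mom[[l]]$mW + (1 - beta1) * gW
        mom[[l]]$vW <- beta2 * mom[[l]]$vW + (1 - beta2) * gW^2
        mom[[l]]$mb <- beta1 * mom[[l]]$mb + (1 - beta1) * gb
        mom[[l]]$vb <- beta2 * mom[[l]]$vb + (1 - beta2) * gb^2
        wts[[l]]$W <- wts[[l]]$W - lr_ep * (mom[[l]]$mW / corr1) /
          (sqrt(mom[[l]]$vW / corr2) + eps)
        wts[[l]]$b <- wts[[l]]$b - lr_ep * (mom[[l]]$mb / corr1) /
          (sqrt(mom[[l]]$vb / corr2) + eps)
      }
    }
    history$loss <- c(history$loss, mean(ep_losses))
    if (!is.null(holdout)) {
      he <- vapply(holdout, function(img) {
        x3 <- gray_to_cube(img)
        loss_of(net_forward(layers, wts, x3), x3)
      }, numeric(1))
      history$holdout <- c(history$holdout, mean(he))
    }
    if (verbose)
      message(sprintf("epoch %d: train mse %.5f%s", ep, mean(ep_losses),
                      if (!is.null(holdout))
                        sprintf(", holdout mse %.5f", utils::tail(history$holdout, 1))
                      else ""))
  }

  w$encoder <- wts[seq_len(n_enc)]
  w$decoder <- wts[(n_enc + 1L):length(wts)]
  w$history <- history
  w
}
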